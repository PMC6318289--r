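## small shared helpers

.revcomp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## longest common prefix length of two strings
.lcp <- function(a, b) {
    ca <- .chars(a); cb <- .chars(b)
    n <- min(length(ca), length(cb))
    if (n == 0) return(0L)
    d <- which(ca[seq_len(n)] != cb[seq_len(n)])
    if (length(d)) d[1] - 1L else n
}

## Hamming distance between equal-length strings
.hamming <- function(a, b) {
    stopifnot(nchar(a) == nchar(b))
    sum(.chars(a) != .chars(b))
}
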