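## Readers/writers for FASTA/FASTQ and the read-collapse / frequency-filter
## steps. Parsing goes through Biostrings; a light pre-validation pass
## supplies precise format diagnostics (line / record numbers).

.validAlphabet <- list(nucleotide = "^[ACGTN]+$",
                       protein = "^[ACDEFGHIKLMNPQRSTVWYX*]+$")

.checkAlphabet <- function(seqs, kind, what) {
    bad <- which(!grepl(.validAlphabet[[kind]], seqs))
    if (length(bad))
        stop(sprintf("%s: record %d contains characters outside the %s alphabet",
                     what, bad[1], kind), call. = FALSE)
    invisible(TRUE)
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @param kind `"nucleotide"` (alphabet ACGTN) or `"protein"`.
#' @return A [Biostrings::DNAStringSet] (or `AAStringSet` for protein),
#'   upper-cased, one entry per record in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "acgt"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path, kind = c("nucleotide", "protein")) {
    kind <- match.arg(kind)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    nonblank <- which(nzchar(trimws(lines)))
    if (length(nonblank) && !startsWith(trimws(lines[nonblank[1]]), ">"))
        stop(sprintf("%s: line %d: expected a '>' FASTA header", path,
                     nonblank[1]), call. = FALSE)
    hdr <- which(startsWith(trimws(lines), ">"))
    for (k in seq_along(hdr)) {
        to <- if (k < length(hdr)) hdr[k + 1] - 1L else length(lines)
        body <- lines[seq.int(hdr[k] + 1L, length.out = max(0L, to - hdr[k]))]
        if (!any(nzchar(trimws(body))))
            stop(sprintf("%s: line %d: record has an empty sequence", path,
                         hdr[k]), call. = FALSE)
        if (!nzchar(trimws(sub("^>", "", lines[hdr[k]]))))
            stop(sprintf("%s: line %d: empty record id", path, hdr[k]),
                 call. = FALSE)
    }
    reader <- if (kind == "nucleotide") Biostrings::readDNAStringSet
              else Biostrings::readAAStringSet
    x <- reader(path)
    x <- setNames(toupper(as.character(x)), names(x))
    .checkAlphabet(unname(x), kind, path)
    if (kind == "nucleotide") Biostrings::DNAStringSet(x)
    else Biostrings::AAStringSet(x)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector, `DNAStringSet` or `AAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
    if (is.character(seqs))
        seqs <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Read a FASTQ file (sequence only)
#'
#' Quality strings are validated (4-line records; quality length equal to
#' sequence length) and then discarded: downstream analysis is
#' sequence-only.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return A [Biostrings::DNAStringSet], upper-cased; empty for an empty
#'   file.
#' @export
readFastq <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    if (!length(lines)) return(Biostrings::DNAStringSet())
    if (length(lines) %% 4 != 0)
        stop(sprintf("%s: truncated FASTQ (line count %d is not a multiple of 4)",
                     path, length(lines)), call. = FALSE)
    n <- length(lines) %/% 4
    ids <- lines[seq(1, by = 4, length.out = n)]
    seqs <- lines[seq(2, by = 4, length.out = n)]
    quals <- lines[seq(4, by = 4, length.out = n)]
    badid <- which(!startsWith(ids, "@"))
    if (length(badid))
        stop(sprintf("%s: record %d: header does not start with '@'", path,
                     badid[1]), call. = FALSE)
    badq <- which(nchar(quals) != nchar(seqs))
    if (length(badq))
        stop(sprintf("%s: record %d: quality length %d != sequence length %d",
                     path, badq[1], nchar(quals[badq[1]]),
                     nchar(seqs[badq[1]])), call. = FALSE)
    seqs <- toupper(seqs)
    .checkAlphabet(seqs, "nucleotide", path)
    Biostrings::DNAStringSet(setNames(seqs, sub("^@", "", ids)))
}

#' Collapse reads to counted unique sequences
#'
#' Exact-duplicate counting: one group per distinct sequence, sorted by
#' count descending with ties broken lexicographically by sequence. Reads
#' containing N are dropped before counting by default (exact-duplicate
#' counting is the unit of the downstream frequency filter); the number
#' dropped is attached as attribute `dropped` and messaged.
#'
#' @param reads `DNAStringSet` or character vector of reads.
#' @param dropAmbiguous drop reads containing N before counting
#'   (default TRUE).
#' @return data.frame with columns `sequence` and `count`; counts sum to
#'   the number of retained reads.
#' @examples
#' collapseReads(c("ACGT", "ACGT", "ACGG"))
#' @export
collapseReads <- function(reads, dropAmbiguous = TRUE) {
    reads <- toupper(as.character(reads))
    dropped <- 0L
    if (dropAmbiguous) {
        amb <- grepl("N", reads, fixed = TRUE)
        dropped <- sum(amb)
        if (dropped)
            message(dropped, " read(s) containing N dropped before collapsing")
        reads <- reads[!amb]
    }
    if (!length(reads)) {
        out <- data.frame(sequence = character(), count = integer())
    } else {
        tab <- table(reads)
        out <- data.frame(sequence = names(tab), count = as.integer(tab))
        out <- out[order(-out$count, out$sequence), , drop = FALSE]
        rownames(out) <- NULL
    }
    attr(out, "dropped") <- dropped
    out
}

#' Filter low-frequency read groups
#'
#' Strict "less than" semantics: groups with `count < minCount` are removed,
#' so a group whose count equals the threshold is retained. Input order is
#' preserved.
#'
#' @param groups data.frame from [collapseReads()].
#' @param minCount positive integer threshold.
#' @return The retained subset of `groups`.
#' @export
filterLowFrequency <- function(groups, minCount) {
    minCount <- as.integer(minCount)
    stopifnot(minCount >= 1)
    out <- groups[groups$count >= minCount, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write a read-group table as TSV
#'
#' @param groups data.frame with columns `sequence`, `count`.
#' @param path output path; header is `sequence<TAB>count`.
#' @return `path`, invisibly.
#' @export
writeReadGroups <- function(groups, path) {
    write.table(groups[, c("sequence", "count")], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
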