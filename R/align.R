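## Global alignment of each unique read to the wildtype amplicon, and
## extraction of a canonical (left-normalized) variant signature.

#' Global pairwise alignment (Needleman-Wunsch/Gotoh, affine gaps)
#'
#' Returns a maximum-score global alignment of `qry` against `ref` under
#' affine gap penalties. The traceback is deterministic: ties are resolved
#' diagonal first, then vertical (gap in query, a deletion relative to the
#' reference), then horizontal (gap in reference, an insertion), so the
#' same input always yields the same alignment and hence the same variant
#' signature.
#'
#' @param ref,qry non-empty nucleotide strings (character or DNAString).
#' @param scoring an [AlignmentScoring-class]; see [alignmentScoring()].
#' @return A [GlobalAlignment-class].
#' @examples
#' globalAlign("ACGT", "AGT")
#' @export
globalAlign <- function(ref, qry, scoring = alignmentScoring()) {
    ref <- toupper(as.character(ref)); qry <- toupper(as.character(qry))
    if (!nchar(ref) || !nchar(qry))
        stop("both sequences must be non-empty", call. = FALSE)
    res <- .gotoh_align(ref, qry, scoring@match, scoring@mismatch,
                        scoring@gapOpen, scoring@gapExtend)
    new("GlobalAlignment", refAln = res$ref_aln, qryAln = res$qry_aln,
        score = res$score)
}

#' Format an alignment as a three-line text block
#'
#' @param aln a [GlobalAlignment-class].
#' @return character vector of three lines: reference row, match bars,
#'   query row.
#' @export
formatAlignment <- function(aln) {
    r <- .chars(aln@refAln); q <- .chars(aln@qryAln)
    bars <- ifelse(r == q & r != "-", "|", " ")
    c(aln@refAln, paste(bars, collapse = ""), aln@qryAln)
}

## Left-normalize indel ops against the ungapped reference: shift each indel
## to the smallest refPos yielding the same edited sequence, without crossing
## a neighbouring op (uncovered positions are exact-match columns, so
## shifting across them preserves the alignment score and result).
.normalizeOps <- function(ops, ref) {
    if (!nrow(ops)) return(ops)
    rv <- .chars(ref)
    pri <- ifelse(ops$kind == "insertion", 0L, 1L)
    ops <- ops[order(ops$refPos, pri), , drop = FALSE]
    prevEnd <- 0L
    for (i in seq_len(nrow(ops))) {
        p <- ops$refPos[i]; L <- ops$length[i]
        if (ops$kind[i] == "deletion") {
            ## deleting [p, p+L) == deleting [p-1, p+L-1) iff ref[p-1]==ref[p+L-1]
            while (p > prevEnd && rv[p] == rv[p + L]) p <- p - 1L
            ops$refPos[i] <- p
            prevEnd <- p + L
        } else if (ops$kind[i] == "insertion") {
            alt <- ops$alt[i]
            while (p > prevEnd && rv[p] == substr(alt, L, L)) {
                alt <- paste0(rv[p], substr(alt, 1L, L - 1L))
                p <- p - 1L
            }
            ops$refPos[i] <- p
            ops$alt[i] <- alt
            prevEnd <- p
        } else {
            prevEnd <- p + L
        }
    }
    pri <- ifelse(ops$kind == "insertion", 0L, 1L)
    ops <- ops[order(ops$refPos, pri), , drop = FALSE]
    rownames(ops) <- NULL
    ops
}

#' Extract the canonical variant signature of an alignment
#'
#' Maximal runs of gap columns become single insertion/deletion operations
#' and maximal runs of mismatch columns become substitution operations.
#' Indels are left-normalized: shifted to the smallest reference position
#' producing the same edited sequence (e.g. within homopolymer runs), which
#' fixes one canonical coordinate per allele.
#'
#' @param aln a [GlobalAlignment-class].
#' @return A [VariantSignature-class]; empty ops iff the query equals the
#'   reference.
#' @examples
#' extractSignature(globalAlign("AAAA", "AAA"))
#' @export
extractSignature <- function(aln) {
    r <- .chars(aln@refAln); q <- .chars(aln@qryAln)
    n <- length(r)
    kind <- character(); refPos <- integer(); len <- integer(); alt <- character()
    i <- 1L
    refConsumed <- 0L
    while (i <= n) {
        if (r[i] == "-") {           # insertion run
            j <- i
            while (j <= n && r[j] == "-") j <- j + 1L
            kind <- c(kind, "insertion"); refPos <- c(refPos, refConsumed)
            len <- c(len, j - i)
            alt <- c(alt, paste(q[i:(j - 1L)], collapse = ""))
            i <- j
        } else if (q[i] == "-") {    # deletion run
            j <- i
            while (j <= n && q[j] == "-" && r[j] != "-") j <- j + 1L
            kind <- c(kind, "deletion"); refPos <- c(refPos, refConsumed)
            len <- c(len, j - i); alt <- c(alt, "")
            refConsumed <- refConsumed + (j - i)
            i <- j
        } else if (r[i] != q[i]) {   # mismatch run
            j <- i
            while (j <= n && r[j] != "-" && q[j] != "-" && r[j] != q[j])
                j <- j + 1L
            kind <- c(kind, "substitution"); refPos <- c(refPos, refConsumed)
            len <- c(len, j - i)
            alt <- c(alt, paste(q[i:(j - 1L)], collapse = ""))
            refConsumed <- refConsumed + (j - i)
            i <- j
        } else {
            refConsumed <- refConsumed + 1L
            i <- i + 1L
        }
    }
    ops <- data.frame(kind = kind, refPos = refPos, length = len, alt = alt,
                      stringsAsFactors = FALSE)
    ref <- gsub("-", "", aln@refAln, fixed = TRUE)
    variantSignature(.normalizeOps(ops, ref))
}

#' String form of a variant signature
#'
#' Compact, parseable encoding used in allele tables: semicolon-joined
#' operations `D:<pos>:<len>` (deletion), `I:<pos>:<bases>` (insertion),
#' `S:<pos>:<bases>` (substitution) with 1-based reference positions, or
#' `WT` for the empty signature.
#'
#' @param sig a [VariantSignature-class].
#' @return A single character string.
#' @export
signatureToString <- function(sig) {
    o <- ops(sig)
    if (!nrow(o)) return("WT")
    enc <- vapply(seq_len(nrow(o)), function(i) {
        p1 <- o$refPos[i] + 1L
        switch(o$kind[i],
               deletion = sprintf("D:%d:%d", p1, o$length[i]),
               insertion = sprintf("I:%d:%s", p1, o$alt[i]),
               substitution = sprintf("S:%d:%s", p1, o$alt[i]))
    }, character(1))
    paste(enc, collapse = ";")
}

#' Parse a signature string
#'
#' Inverse of [signatureToString()].
#'
#' @param x character string, e.g. `"D:118:3;I:121:GG"` or `"WT"`.
#' @return A [VariantSignature-class].
#' @export
parseSignature <- function(x) {
    x <- trimws(x)
    if (!nzchar(x) || identical(x, "WT")) return(variantSignature())
    parts <- strsplit(x, ";", fixed = TRUE)[[1]]
    rows <- lapply(parts, function(p) {
        f <- strsplit(p, ":", fixed = TRUE)[[1]]
        if (length(f) != 3) stop("malformed signature element: ", p, call. = FALSE)
        pos <- as.integer(f[2]) - 1L
        switch(f[1],
               D = data.frame(kind = "deletion", refPos = pos,
                              length = as.integer(f[3]), alt = ""),
               I = data.frame(kind = "insertion", refPos = pos,
                              length = nchar(f[3]), alt = f[3]),
               S = data.frame(kind = "substitution", refPos = pos,
                              length = nchar(f[3]), alt = f[3]),
               stop("unknown signature op code: ", f[1], call. = FALSE))
    })
    variantSignature(do.call(rbind, rows))
}
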