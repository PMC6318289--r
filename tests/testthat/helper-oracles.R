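## Shared fixtures and independent oracles used across the suite.

randSeq <- function(len, alphabet = c("A", "C", "G", "T"))
    paste(sample(alphabet, len, replace = TRUE), collapse = "")

## Exhaustive enumeration of all global alignments under the affine model
## (first gap base gapOpen, further bases gapExtend). Independent of the DP:
## plain recursion over the three moves, tracking the previous move so gap
## runs are charged correctly. Exponential - use only for short sequences.
bfAlignScore <- function(ref, qry, sc = alignmentScoring()) {
    rv <- strsplit(ref, "")[[1]]; qv <- strsplit(qry, "")[[1]]
    n <- length(rv); m <- length(qv)
    rec <- function(i, j, state) {
        if (i == n && j == m) return(0)
        best <- -Inf
        if (i < n && j < m) {
            s <- if (rv[i + 1] == qv[j + 1]) sc@match else sc@mismatch
            best <- max(best, s + rec(i + 1, j + 1, 0L))
        }
        if (i < n) {
            g <- if (state == 1L) sc@gapExtend else sc@gapOpen
            best <- max(best, g + rec(i + 1, j, 1L))
        }
        if (j < m) {
            g <- if (state == 2L) sc@gapExtend else sc@gapOpen
            best <- max(best, g + rec(i, j + 1, 2L))
        }
        best
    }
    rec(0L, 0L, 0L)
}

## Independent optimal-score oracle via Biostrings. Its gap model charges
## gapOpening once plus gapExtension per gap base, so a length-L gap costs
## gapOpening + L * gapExtension; matching the open + (L-1) * extend model
## requires gapOpening = -(gapOpen - gapExtend), gapExtension = -gapExtend.
bsAlignScore <- function(ref, qry, sc = alignmentScoring()) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
        match = sc@match, mismatch = sc@mismatch, baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(
        ref, qry, substitutionMatrix = mat,
        gapOpening = -(sc@gapOpen - sc@gapExtend),
        gapExtension = -sc@gapExtend, type = "global")
    Biostrings::score(pa)
}

## Recompute an alignment's score from its columns (affine gap runs).
scoreFromAlignment <- function(aln, sc = alignmentScoring()) {
    r <- strsplit(refAln(aln), "")[[1]]
    q <- strsplit(qryAln(aln), "")[[1]]
    total <- 0
    prev <- "none"
    for (k in seq_along(r)) {
        state <- if (r[k] == "-") "insR" else if (q[k] == "-") "insQ" else "sub"
        if (state == "sub") {
            total <- total + if (r[k] == q[k]) sc@match else sc@mismatch
        } else {
            total <- total + if (state == prev) sc@gapExtend else sc@gapOpen
        }
        prev <- state
    }
    total
}

## Small amplicon assay fixture: 12-nt primers flanking a 36-nt core,
## cut site at the centre of the reference.
toyAssay <- function(nhejWindow = 5L, minCount = 1L) {
    set.seed(424242)
    fwd <- randSeq(12)
    core <- randSeq(36)
    revSite <- randSeq(12)
    ref <- paste0(fwd, core, revSite)
    ampliconAssay(ref, fwd,
                  as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(revSite))),
                  cutSite = 30L, nhejWindow = nhejWindow,
                  minCount = minCount)
}

revcompChr <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

writeTempFasta <- function(seqs, ids = paste0("s", seq_along(seqs))) {
    tf <- tempfile(fileext = ".fa")
    writeLines(paste0(">", ids, "\n", seqs), tf)
    tf
}
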