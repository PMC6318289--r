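## sgRNA guide-site selection: NGG PAM scanning, cut-site-to-codon mapping,
## and conserved-site pairing between two orthologous coding sequences.

## + strand scan of one sequence; returns 0-based pamStart and cutNt in the
## coordinates of `seq`. Requires 23 bases of context 5' of the PAM
## (20-nt protospacer + the 3 bases between cut and PAM are part of it).
.scanPlus <- function(seq) {
    L <- nchar(seq)
    if (L < 23L) return(NULL)
    v <- .chars(seq)
    s <- which(v[-L] == "G" & v[-1] == "G") - 2L   # 0-based PAM start (NGG)
    s <- s[s >= 20L & s + 3L <= L]
    if (!length(s)) return(NULL)
    data.frame(pamStart = s,
               pam = substring(seq, s + 1L, s + 3L),
               protospacer = substring(seq, s - 19L, s),
               cutNt = s - 3L)
}

#' Scan a sequence for NGG PAM guide sites
#'
#' Every NGG occurrence with at least 20 bases of protospacer context 5' of
#' the PAM (on its strand) yields one site. The blunt cut is placed 3 bp 5'
#' of the PAM (canonical SpCas9). Coordinates are reported on the given
#' (plus) sequence: `pamStart` is the 0-based position of the PAM triplet
#' and `cutNt` the 0-based count of plus-strand bases 5' of the cut.
#'
#' @param seq nucleotide string (character or DNAString).
#' @param region optional length-2 integer vector, 1-based inclusive bounds
#'   on `pamStart + 1`; default the whole sequence.
#' @param strands subset of `c("+", "-")`.
#' @param map optional [CodingMap-class]; when given, a `cutCodon` column is
#'   added via [mapCutToCodon()] (NA for cuts outside the coding span).
#' @return data.frame with columns `strand`, `pamStart`, `pam`,
#'   `protospacer`, `cutNt` (and `cutCodon`), sorted by `pamStart`.
#' @examples
#' scanPams(paste0(strrep("A", 20), "TGG"))
#' @export
scanPams <- function(seq, region = NULL, strands = c("+", "-"), map = NULL) {
    seq <- toupper(as.character(seq))
    L <- nchar(seq)
    out <- list()
    if ("+" %in% strands) {
        p <- .scanPlus(seq)
        if (!is.null(p)) out <- c(out, list(cbind(strand = "+", p)))
    }
    if ("-" %in% strands) {
        m <- .scanPlus(.revcomp(seq))
        if (!is.null(m)) {
            ## reflect revcomp coordinates back onto the plus strand
            m$cutNt <- L - (m$pamStart - 3L)
            m$pamStart <- L - m$pamStart - 3L
            out <- c(out, list(cbind(strand = "-", m)))
        }
    }
    if (!length(out)) {
        res <- data.frame(strand = character(), pamStart = integer(),
                          pam = character(), protospacer = character(),
                          cutNt = integer())
    } else {
        res <- do.call(rbind, out)
        res <- res[order(res$pamStart, res$strand), , drop = FALSE]
        rownames(res) <- NULL
    }
    if (!is.null(region)) {
        keep <- res$pamStart + 1L >= region[1] & res$pamStart + 1L <= region[2]
        res <- res[keep, , drop = FALSE]
        rownames(res) <- NULL
    }
    if (!is.null(map) && nrow(res)) {
        res$cutCodon <- vapply(res$cutNt, function(ct) {
            tryCatch(mapCutToCodon(ct, map), error = function(e) NA_integer_)
        }, integer(1))
    }
    res
}

#' Map a cut position to a codon / residue index
#'
#' Returns the 1-based full-protein index of the last residue whose codon
#' lies entirely 5' of the blunt cut:
#' `upstreamAa + floor((cutNt - cdsStart) / 3)`.
#'
#' @param cutNt 0-based count of coding-strand bases 5' of the cut.
#' @param map a [CodingMap-class].
#' @return Integer residue index.
#' @export
mapCutToCodon <- function(cutNt, map) {
    cutNt <- as.integer(cutNt)
    span <- 3L * (map@wtProteinLength - map@upstreamAa)
    if (cutNt < map@cdsStart || cutNt > map@cdsStart + span)
        stop("cut position lies outside the coding span", call. = FALSE)
    map@upstreamAa + (cutNt - map@cdsStart) %/% 3L
}

#' Pair guide sites conserved between two orthologous sequences
#'
#' Anchors `seqB` to `seqA` by global alignment and pairs sites whose PAM
#' positions correspond under the anchoring, on the same strand, with an
#' NGG PAM in both sequences. "Conserved" requires only the PAM at the
#' homologous position - the protospacers may differ, and their Hamming
#' distance is reported per pair with no threshold imposed.
#'
#' @param seqA,seqB nucleotide strings.
#' @param scoring an [AlignmentScoring-class] for the anchoring alignment.
#' @param strands strands to scan.
#' @return data.frame with one row per conserved pair: `strand`,
#'   `pamStartA`, `pamStartB`, `cutNtA`, `cutNtB`, `pamA`, `pamB`,
#'   `pamIdentical`, `protospacerA`, `protospacerB`,
#'   `protospacerMismatches`.
#' @export
conservedSites <- function(seqA, seqB, scoring = alignmentScoring(),
                           strands = c("+", "-")) {
    seqA <- toupper(as.character(seqA)); seqB <- toupper(as.character(seqB))
    aln <- globalAlign(seqA, seqB, scoring)
    r <- .chars(refAln(aln)); q <- .chars(qryAln(aln))
    ## map: 0-based position on A -> 0-based position on B (NA through gaps)
    posmap <- rep(NA_integer_, nchar(seqA))
    ia <- cumsum(r != "-"); ib <- cumsum(q != "-")
    both <- r != "-" & q != "-"
    posmap[ia[both]] <- ib[both] - 1L
    sa <- scanPams(seqA, strands = strands)
    sb <- scanPams(seqB, strands = strands)
    rows <- list()
    for (i in seq_len(nrow(sa))) {
        bpos <- posmap[sa$pamStart[i] + 1L]
        if (is.na(bpos)) next
        j <- which(sb$pamStart == bpos & sb$strand == sa$strand[i])
        if (!length(j)) next
        j <- j[1]
        rows[[length(rows) + 1L]] <- data.frame(
            strand = sa$strand[i],
            pamStartA = sa$pamStart[i], pamStartB = sb$pamStart[j],
            cutNtA = sa$cutNt[i], cutNtB = sb$cutNt[j],
            pamA = sa$pam[i], pamB = sb$pam[j],
            pamIdentical = sa$pam[i] == sb$pam[j],
            protospacerA = sa$protospacer[i],
            protospacerB = sb$protospacer[j],
            protospacerMismatches = .hamming(sa$protospacer[i],
                                             sb$protospacer[j]),
            stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(strand = character(), pamStartA = integer(),
                          pamStartB = integer(), cutNtA = integer(),
                          cutNtB = integer(), pamA = character(),
                          pamB = character(), pamIdentical = logical(),
                          protospacerA = character(),
                          protospacerB = character(),
                          protospacerMismatches = integer()))
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
}
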