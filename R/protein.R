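## Post-editing translational-product prediction: reconstruct the edited
## allele, translate, find the divergence point from the wildtype protein,
## and report truncation / appended residues / epitope retention.

#' Apply a variant signature to a reference sequence
#'
#' Reconstructs the edited allele: deletions removed, insertions inserted,
#' substitutions replaced. The result has length
#' `nchar(ref) + netShift(sig)`.
#'
#' @param ref reference nucleotide string.
#' @param sig a [VariantSignature-class] whose ops lie within `ref`.
#' @return The edited sequence (character).
#' @examples
#' applySignature("ACGT", variantSignature(
#'     data.frame(kind = "insertion", refPos = 2L, length = 2L, alt = "GG")))
#' @export
applySignature <- function(ref, sig) {
    ref <- toupper(as.character(ref))
    o <- ops(sig)
    if (!nrow(o)) return(ref)
    n <- nchar(ref)
    w <- ifelse(o$kind == "insertion", 0L, o$length)
    if (any(o$refPos < 0L) || any(o$refPos + w > n))
        stop("signature operation out of reference bounds", call. = FALSE)
    out <- character()
    cursor <- 0L                          # 0-based ref bases emitted so far
    for (i in seq_len(nrow(o))) {
        p <- o$refPos[i]
        if (p > cursor) out <- c(out, substr(ref, cursor + 1L, p))
        out <- c(out, switch(o$kind[i],
                             insertion = o$alt[i],
                             substitution = o$alt[i],
                             deletion = ""))
        cursor <- p + w[i]
    }
    if (cursor < n) out <- c(out, substr(ref, cursor + 1L, n))
    paste(out, collapse = "")
}

#' Translate a coding sequence (standard genetic code)
#'
#' Translates codon by codon from position 1, stopping at (and excluding)
#' the first stop codon. Codons containing N translate to `X`; a trailing
#' partial codon is ignored.
#'
#' @param cds nucleotide string.
#' @return list with `protein` (character) and `stopFound` (logical).
#' @examples
#' translateCds("ATGTAA")
#' @export
translateCds <- function(cds) {
    cds <- toupper(as.character(cds))
    nc <- nchar(cds) %/% 3L
    if (nc == 0L) return(list(protein = "", stopFound = FALSE))
    starts <- seq.int(1L, by = 3L, length.out = nc)
    codons <- substring(cds, starts, starts + 2L)
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    aa[is.na(aa)] <- "X"
    stopAt <- which(aa == "*")
    if (length(stopAt)) {
        list(protein = paste(aa[seq_len(stopAt[1] - 1L)], collapse = ""),
             stopFound = TRUE)
    } else {
        list(protein = paste(aa, collapse = ""), stopFound = FALSE)
    }
}

#' Predict the post-editing translational product of an allele
#'
#' Applies the signature to the wildtype coding context, translates the
#' edited frame from `cdsStart`, and sets the last retained wildtype
#' residue by the longest common prefix with the wildtype protein (robust
#' to in-frame indels). Novel residues after the divergence point are
#' reported up to (not including) the new stop; the product is named
#' `<label>-<lastWtResidue>[-<appended>]`, e.g. `APP-659-GG`.
#'
#' @param context wildtype nucleotide context containing the edited region
#'   and (ideally) the downstream stop.
#' @param sig a [VariantSignature-class] on `context` coordinates.
#' @param map a [CodingMap-class] anchoring `context` in full-protein
#'   coordinates.
#' @param label protein label for the product name (default "protein").
#' @param wtProtein optional full-length wildtype protein sequence; when
#'   supplied, the wildtype translation of the context is checked against
#'   it and a configuration error identifies the first disagreeing
#'   residue.
#' @return A [ProteinProduct-class].
#' @export
predictProduct <- function(context, sig, map, label = "protein",
                           wtProtein = NULL) {
    context <- toupper(as.character(context))
    cds <- substr(context, map@cdsStart + 1L, nchar(context))
    wt <- translateCds(cds)
    if (!is.null(wtProtein)) {
        wtProtein <- toupper(as.character(wtProtein))
        expected <- substr(wtProtein, map@upstreamAa + 1L,
                           map@upstreamAa + nchar(wt$protein))
        if (!identical(wt$protein, expected)) {
            at <- .lcp(wt$protein, expected) + 1L
            stop(sprintf(paste("wildtype translation of the context disagrees",
                               "with the supplied protein at residue %d",
                               "(full-protein numbering)"),
                         map@upstreamAa + at), call. = FALSE)
        }
    }
    edited <- applySignature(context, sig)
    ed <- translateCds(substr(edited, map@cdsStart + 1L, nchar(edited)))
    lcp <- .lcp(ed$protein, wt$protein)
    lastWt <- map@upstreamAa + lcp
    appended <- substr(ed$protein, lcp + 1L, nchar(ed$protein))
    name <- paste0(label, "-", lastWt)
    if (nzchar(appended)) name <- paste0(name, "-", appended)
    new("ProteinProduct", label = label, lastWtResidue = as.integer(lastWt),
        appended = appended, stopFound = ed$stopFound, productName = name,
        truncatedCount = as.integer(map@wtProteinLength - lastWt),
        wtProteinLength = map@wtProteinLength)
}

#' Epitope retention of a predicted product
#'
#' Fraction of each epitope span retained in the product: residues of the
#' span with index `<= lastWtResidue`, divided by the span length.
#' Appended novel residues never count toward retention.
#'
#' @param product a [ProteinProduct-class].
#' @param epitopes data.frame with columns `name`, `start`, `end`
#'   (1-based inclusive residue interval on the wildtype protein).
#' @return Named numeric vector of retained fractions in [0, 1].
#' @examples
#' ## an antibody epitope covering the last 20 residues of a 695-aa protein
#' ep <- data.frame(name = "Y188", start = 676, end = 695)
#' @export
epitopeRetention <- function(product, epitopes) {
    stopifnot(all(c("name", "start", "end") %in% names(epitopes)))
    if (any(epitopes$start < 1) || any(epitopes$end > product@wtProteinLength) ||
        any(epitopes$start > epitopes$end))
        stop("epitope span outside 1..wtProteinLength", call. = FALSE)
    retained <- pmax(0, pmin(epitopes$end, product@lastWtResidue) -
                        epitopes$start + 1)
    setNames(retained / (epitopes$end - epitopes$start + 1), epitopes$name)
}
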