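#' @rdname GlobalAlignment-class
#' @param x a GlobalAlignment
#' @export
setGeneric("refAln", function(x) standardGeneric("refAln"))
#' @rdname GlobalAlignment-class
#' @export
setGeneric("qryAln", function(x) standardGeneric("qryAln"))
#' @rdname GlobalAlignment-class
#' @export
setGeneric("alnScore", function(x) standardGeneric("alnScore"))
#' @rdname VariantSignature-class
#' @param x a VariantSignature
#' @export
setGeneric("ops", function(x) standardGeneric("ops"))
#' @rdname VariantSignature-class
#' @export
setGeneric("netShift", function(x) standardGeneric("netShift"))
#' @rdname EditingSummary-class
#' @param x an EditingSummary
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))
#' @rdname EditingSummary-class
#' @export
setGeneric("matchProfile", function(x) standardGeneric("matchProfile"))
#' @rdname EditingSummary-class
#' @export
setGeneric("editingEfficiency", function(x) standardGeneric("editingEfficiency"))

#' @rdname GlobalAlignment-class
setMethod("refAln", "GlobalAlignment", function(x) x@refAln)
#' @rdname GlobalAlignment-class
setMethod("qryAln", "GlobalAlignment", function(x) x@qryAln)
#' @rdname GlobalAlignment-class
setMethod("alnScore", "GlobalAlignment", function(x) x@score)
#' @rdname VariantSignature-class
setMethod("ops", "VariantSignature", function(x) x@ops)

#' @rdname VariantSignature-class
setMethod("netShift", "VariantSignature", function(x) {
    o <- x@ops
    if (!nrow(o)) return(0L)
    sum(o$length[o$kind == "insertion"]) - sum(o$length[o$kind == "deletion"])
})

#' @rdname EditingSummary-class
setMethod("alleles", "EditingSummary", function(x) x@alleles)
#' @rdname EditingSummary-class
setMethod("matchProfile", "EditingSummary", function(x) x@profile)
#' @rdname EditingSummary-class
setMethod("editingEfficiency", "EditingSummary", function(x) x@editingEfficiency)

setMethod("show", "AlignmentScoring", function(object) {
    cat(sprintf(
        "AlignmentScoring: match %+g, mismatch %+g, gapOpen %+g, gapExtend %+g\n",
        object@match, object@mismatch, object@gapOpen, object@gapExtend))
})

setMethod("show", "GlobalAlignment", function(object) {
    cat(sprintf("GlobalAlignment (score %g)\n", object@score))
    cat(formatAlignment(object), sep = "\n")
})

setMethod("show", "VariantSignature", function(object) {
    cat(sprintf("VariantSignature: %s (net shift %+d)\n",
                signatureToString(object), netShift(object)))
})

setMethod("show", "AmpliconAssay", function(object) {
    cat(sprintf(
        "AmpliconAssay: %d bp reference, cut site %d, NHEJ window +/-%d, minCount %d\n",
        nchar(object@reference), object@cutSite, object@nhejWindow,
        object@minCount))
})

setMethod("show", "CodingMap", function(object) {
    cat(sprintf("CodingMap: cdsStart %d, upstreamAa %d, wtProteinLength %d\n",
                object@cdsStart, object@upstreamAa, object@wtProteinLength))
})

setMethod("show", "ProteinProduct", function(object) {
    cat(sprintf("ProteinProduct %s: last wildtype residue %d/%d (%d truncated)",
                object@productName, object@lastWtResidue,
                object@wtProteinLength, object@truncatedCount))
    if (nzchar(object@appended))
        cat(sprintf(", appended %s", object@appended))
    cat(sprintf(", stop %s\n", if (object@stopFound) "found" else "not found"))
})

setMethod("show", "EditingSummary", function(object) {
    cat("EditingSummary\n")
    cat(sprintf("  reads: %d total, %d after filter, %d target, %d NHEJ\n",
                object@totalReads, object@retainedAfterFilter,
                object@targetReads, object@nhejReads))
    cat(sprintf("  editing efficiency: %s\n",
                if (is.na(object@editingEfficiency)) "NA (no target reads)"
                else sprintf("%.4f", object@editingEfficiency)))
    cat(sprintf("  alleles: %d\n", nrow(object@alleles)))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: depth %d, editing rate %.3g, %d alleles, error %.3g, seed %d\n",
        object@depth, object@editingRate, object@nAlleles, object@errorRate,
        object@seed))
})
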