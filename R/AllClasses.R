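## S4 containers for the pipeline. Coordinates are 0-based, half-open
## internally; report writers add 1-based columns.

#' Alignment scoring parameters
#'
#' Affine-gap scoring for global alignment. A gap of length L scores
#' `gapOpen + (L - 1) * gapExtend`, so a single contiguous indel is preferred
#' over scattered gaps.
#'
#' @slot match numeric, score of an identical column (> mismatch).
#' @slot mismatch numeric, score of a substitution column (<= 0).
#' @slot gapOpen numeric, score of the first base of a gap (<= gapExtend).
#' @slot gapExtend numeric, score of each further gap base (<= 0).
#' @export
setClass("AlignmentScoring",
    representation(match = "numeric", mismatch = "numeric",
                   gapOpen = "numeric", gapExtend = "numeric"),
    validity = function(object) {
        msg <- character()
        if (!(object@match > object@mismatch))
            msg <- c(msg, "match must exceed mismatch")
        if (object@mismatch > 0) msg <- c(msg, "mismatch must be <= 0")
        if (object@gapExtend > 0) msg <- c(msg, "gapExtend must be <= 0")
        if (object@gapOpen > object@gapExtend)
            msg <- c(msg, "gapOpen must be <= gapExtend")
        if (length(msg)) msg else TRUE
    })

#' Construct alignment scoring
#'
#' Defaults (match +2, mismatch -3, gap open -6, gap extend -1) favour one
#' contiguous indel over scattered gaps, matching how NHEJ alleles are
#' tabulated.
#'
#' @param match,mismatch,gapOpen,gapExtend numeric scores; see
#'   [AlignmentScoring-class].
#' @return An [AlignmentScoring-class] object.
#' @examples
#' alignmentScoring()
#' @export
alignmentScoring <- function(match = 2, mismatch = -3,
                             gapOpen = -6, gapExtend = -1) {
    new("AlignmentScoring", match = as.numeric(match),
        mismatch = as.numeric(mismatch), gapOpen = as.numeric(gapOpen),
        gapExtend = as.numeric(gapExtend))
}

#' Global pairwise alignment
#'
#' Result of [globalAlign()]: two equal-length gapped rows plus the optimal
#' score. No column has a gap in both rows; removing gaps from each row
#' recovers the input sequences.
#'
#' @slot refAln character, reference row with `-` gaps.
#' @slot qryAln character, query row with `-` gaps.
#' @slot score numeric, optimal global score.
#' @export
setClass("GlobalAlignment",
    representation(refAln = "character", qryAln = "character",
                   score = "numeric"),
    validity = function(object) {
        r <- object@refAln; q <- object@qryAln
        msg <- character()
        if (nchar(r) != nchar(q))
            msg <- c(msg, "aligned rows must have equal length")
        rc <- strsplit(r, "")[[1]]; qc <- strsplit(q, "")[[1]]
        if (any(rc == "-" & qc == "-"))
            msg <- c(msg, "no column may be gapped in both rows")
        if (length(msg)) msg else TRUE
    })

#' Canonical variant signature of one allele
#'
#' The ordered, left-normalized indel/substitution operations of an allele
#' relative to the reference. `ops` is a data.frame with columns `kind`
#' (insertion/deletion/substitution), `refPos` (0-based; for an insertion,
#' the index of the reference base the inserted run precedes), `length`
#' and `alt` (inserted or substituted bases; empty for a deletion). An empty
#' `ops` table means the allele is identical to the reference.
#'
#' @slot ops data.frame of operations, sorted by `refPos`.
#' @export
setClass("VariantSignature",
    representation(ops = "data.frame"),
    validity = function(object) {
        o <- object@ops
        need <- c("kind", "refPos", "length", "alt")
        if (!all(need %in% names(o)))
            return(paste("ops needs columns:", paste(need, collapse = ", ")))
        if (nrow(o) == 0) return(TRUE)
        msg <- character()
        if (!all(o$kind %in% c("insertion", "deletion", "substitution")))
            msg <- c(msg, "unknown op kind")
        if (any(o$length < 1)) msg <- c(msg, "op length must be >= 1")
        sub <- o$kind == "substitution"
        if (any(o$length[sub] != nchar(o$alt[sub])))
            msg <- c(msg, "substitution length must equal nchar(alt)")
        if (any(nzchar(o$alt[o$kind == "deletion"])))
            msg <- c(msg, "deletion alt must be empty")
        if (is.unsorted(o$refPos)) msg <- c(msg, "ops must be sorted by refPos")
        w <- ifelse(o$kind == "insertion", 0L, o$length)
        if (nrow(o) > 1) {
            ends <- o$refPos + w
            if (any(ends[-nrow(o)] > o$refPos[-1]))
                msg <- c(msg, "ops must not overlap on the reference")
        }
        if (length(msg)) msg else TRUE
    })

#' Construct a variant signature
#'
#' @param ops data.frame with columns `kind`, `refPos`, `length`, `alt`;
#'   defaults to the empty (wildtype) signature.
#' @return A [VariantSignature-class].
#' @examples
#' variantSignature(data.frame(kind = "deletion", refPos = 10L,
#'                             length = 3L, alt = ""))
#' @export
variantSignature <- function(ops = data.frame(kind = character(),
                                              refPos = integer(),
                                              length = integer(),
                                              alt = character())) {
    ops <- data.frame(kind = as.character(ops$kind),
                      refPos = as.integer(ops$refPos),
                      length = as.integer(ops$length),
                      alt = as.character(ops$alt),
                      stringsAsFactors = FALSE)
    if (nrow(ops)) {
        pri <- ifelse(ops$kind == "insertion", 0L, 1L)
        ops <- ops[order(ops$refPos, pri), , drop = FALSE]
        rownames(ops) <- NULL
    }
    new("VariantSignature", ops = ops)
}

#' Amplicon assay definition
#'
#' The wildtype amplicon, its primer pair, the predicted blunt cut site and
#' the NHEJ-calling window.
#'
#' @slot reference character, wildtype amplicon sequence.
#' @slot fwdPrimer character, forward primer (substring of the reference).
#' @slot revPrimer character, reverse primer as ordered on the opposite
#'   strand (its reverse complement is a substring of the reference,
#'   downstream of the forward primer).
#' @slot cutSite integer, 0-based count of reference bases 5' of the
#'   predicted blunt cut.
#' @slot nhejWindow integer, bases on each side of the cut site in which an
#'   indel counts as NHEJ.
#' @slot minCount integer, read-frequency filter threshold (groups with
#'   fewer reads are discarded).
#' @export
setClass("AmpliconAssay",
    representation(reference = "character", fwdPrimer = "character",
                   revPrimer = "character", cutSite = "integer",
                   nhejWindow = "integer", minCount = "integer"),
    validity = function(object) {
        msg <- character()
        L <- nchar(object@reference)
        if (!(object@cutSite > 0 && object@cutSite < L))
            msg <- c(msg, "cutSite must satisfy 0 < cutSite < nchar(reference)")
        if (object@nhejWindow < 0) msg <- c(msg, "nhejWindow must be >= 0")
        if (object@minCount < 1) msg <- c(msg, "minCount must be >= 1")
        fpos <- regexpr(object@fwdPrimer, object@reference, fixed = TRUE)
        if (fpos == -1L)
            msg <- c(msg, "fwdPrimer is not a substring of the reference")
        rrc <- .revcomp(object@revPrimer)
        rpos <- regexpr(rrc, object@reference, fixed = TRUE)
        if (rpos == -1L) {
            msg <- c(msg, paste("reverse complement of revPrimer is not a",
                                "substring of the reference"))
        } else if (fpos != -1L && rpos <= fpos) {
            msg <- c(msg, "revPrimer site must lie downstream of fwdPrimer")
        }
        if (length(msg)) msg else TRUE
    })

#' Construct an amplicon assay
#'
#' @param reference wildtype amplicon sequence (character or DNAString).
#' @param fwdPrimer,revPrimer primer pair; `revPrimer` as ordered on the
#'   opposite strand.
#' @param cutSite 0-based count of reference bases 5' of the predicted cut.
#' @param nhejWindow half-width (bases) of the NHEJ-calling window around
#'   the cut site; default 5.
#' @param minCount read-frequency filter threshold; default 100, the
#'   HiSeq-scale cutoff (sequences seen fewer times are treated as noise).
#' @return An [AmpliconAssay-class].
#' @export
ampliconAssay <- function(reference, fwdPrimer, revPrimer, cutSite,
                          nhejWindow = 5L, minCount = 100L) {
    new("AmpliconAssay", reference = toupper(as.character(reference)),
        fwdPrimer = toupper(as.character(fwdPrimer)),
        revPrimer = toupper(as.character(revPrimer)),
        cutSite = as.integer(cutSite), nhejWindow = as.integer(nhejWindow),
        minCount = as.integer(minCount))
}

#' Coding-frame annotation of an amplicon or CDS context
#'
#' Anchors translation of a nucleotide context in full-protein coordinates.
#'
#' @slot cdsStart integer, 0-based offset of the first codon base within the
#'   context sequence.
#' @slot upstreamAa integer, protein residues encoded before the context
#'   begins (so residue numbering matches full-protein coordinates).
#' @slot wtProteinLength integer, total residues of the wildtype protein.
#' @export
setClass("CodingMap",
    representation(cdsStart = "integer", upstreamAa = "integer",
                   wtProteinLength = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@cdsStart < 0) msg <- c(msg, "cdsStart must be >= 0")
        if (object@upstreamAa < 0) msg <- c(msg, "upstreamAa must be >= 0")
        if (object@wtProteinLength <= object@upstreamAa)
            msg <- c(msg, "wtProteinLength must exceed upstreamAa")
        if (length(msg)) msg else TRUE
    })

#' Construct a coding map
#'
#' @param cdsStart 0-based offset of the first codon base in the context.
#' @param upstreamAa residues encoded before the context begins.
#' @param wtProteinLength total residues of the wildtype protein.
#' @return A [CodingMap-class].
#' @export
codingMap <- function(cdsStart, upstreamAa, wtProteinLength) {
    new("CodingMap", cdsStart = as.integer(cdsStart),
        upstreamAa = as.integer(upstreamAa),
        wtProteinLength = as.integer(wtProteinLength))
}

#' Predicted post-editing translational product
#'
#' @slot label character, protein label used in the product name.
#' @slot lastWtResidue integer, full-protein 1-based index of the last
#'   wildtype residue retained.
#' @slot appended character, novel residues translated after the divergence
#'   point, up to (not including) the new stop.
#' @slot stopFound logical, whether a stop codon was reached within the
#'   provided context.
#' @slot productName character, `<label>-<lastWtResidue>[-<appended>]`.
#' @slot truncatedCount integer, wildtype residues lost
#'   (`wtProteinLength - lastWtResidue`).
#' @slot wtProteinLength integer.
#' @export
setClass("ProteinProduct",
    representation(label = "character", lastWtResidue = "integer",
                   appended = "character", stopFound = "logical",
                   productName = "character", truncatedCount = "integer",
                   wtProteinLength = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@lastWtResidue < 0 ||
            object@lastWtResidue > object@wtProteinLength)
            msg <- c(msg, "lastWtResidue out of [0, wtProteinLength]")
        if (object@truncatedCount + object@lastWtResidue !=
            object@wtProteinLength)
            msg <- c(msg, "truncatedCount + lastWtResidue != wtProteinLength")
        if (grepl("\\*", object@appended))
            msg <- c(msg, "appended must not contain a stop symbol")
        if (length(msg)) msg else TRUE
    })

#' Editing summary for one amplicon assay
#'
#' Read accounting, editing efficiency, allele table and per-position match
#' profile produced by [quantifyEdits()].
#'
#' @slot totalReads,retainedAfterFilter,targetReads,nhejReads integers;
#'   each is a subset of the previous.
#' @slot editingEfficiency numeric, `nhejReads / targetReads` (NA when
#'   there are no target reads).
#' @slot alleles data.frame: `sequence`, `count`, `frequency` (fraction of
#'   target reads), `signature` (string form, see [signatureToString()]),
#'   `isNhej`.
#' @slot profile data.frame over reference positions: `pos` (1-based),
#'   `refBase`, `matches`, `mismatches`, `deletions`, `matchFraction`.
#' @slot parameters list of the assay/scoring parameters used.
#' @export
setClass("EditingSummary",
    representation(totalReads = "integer", retainedAfterFilter = "integer",
                   targetReads = "integer", nhejReads = "integer",
                   editingEfficiency = "numeric", alleles = "data.frame",
                   profile = "data.frame", parameters = "list"),
    validity = function(object) {
        msg <- character()
        if (!(object@nhejReads <= object@targetReads &&
              object@targetReads <= object@retainedAfterFilter &&
              object@retainedAfterFilter <= object@totalReads))
            msg <- c(msg,
                "need nhejReads <= targetReads <= retainedAfterFilter <= totalReads")
        e <- object@editingEfficiency
        if (!is.na(e) && (e < 0 || e > 1))
            msg <- c(msg, "editingEfficiency must lie in [0, 1]")
        if (nrow(object@alleles) &&
            abs(sum(object@alleles$frequency) - 1) > 1e-9)
            msg <- c(msg, "allele frequencies must sum to 1")
        if (length(msg)) msg else TRUE
    })

#' Simulation configuration
#'
#' Parameters of the synthetic amplicon read generator: a mixture of
#' unedited reads and NHEJ alleles (single indels clustered at the cut
#' site), with uniform per-base substitution sequencing error.
#'
#' @slot reference character, wildtype amplicon.
#' @slot cutSite integer, 0-based predicted cut position.
#' @slot editingRate numeric in [0,1], fraction of reads drawn from edited
#'   alleles.
#' @slot nAlleles integer, number of distinct edited alleles.
#' @slot delProb numeric, probability an edited allele is a deletion
#'   (vs insertion).
#' @slot sizeGeomP numeric, parameter of the truncated geometric indel-length
#'   distribution (support 1..20).
#' @slot maxOffset integer, max |start - cutSite| for indel placement.
#' @slot errorRate numeric, per-base substitution probability.
#' @slot depth integer, total reads.
#' @slot seed integer, RNG seed; all output is reproducible from it.
#' @export
setClass("SimulationConfig",
    representation(reference = "character", cutSite = "integer",
                   editingRate = "numeric", nAlleles = "integer",
                   delProb = "numeric", sizeGeomP = "numeric",
                   maxOffset = "integer", errorRate = "numeric",
                   depth = "integer", seed = "integer"),
    validity = function(object) {
        msg <- character()
        pr <- c(object@editingRate, object@delProb, object@sizeGeomP,
                object@errorRate)
        if (any(pr < 0 | pr > 1))
            msg <- c(msg, "probabilities must lie in [0, 1]")
        if (object@depth < 1) msg <- c(msg, "depth must be >= 1")
        if (object@nAlleles < 1) msg <- c(msg, "nAlleles must be >= 1")
        L <- nchar(object@reference)
        if (!(object@cutSite > 0 && object@cutSite < L))
            msg <- c(msg, "cutSite must lie strictly inside the reference")
        if (length(msg)) msg else TRUE
    })
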