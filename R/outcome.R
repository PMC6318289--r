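## Target classification, NHEJ calling around the predicted cut site, and
## the editing summary (allele table, per-position match profile,
## editing efficiency).

## first start (1-based) in `starts` where `pattern` matches `subject` with
## at most maxMM Hamming mismatches; NA if none
.hammingFind <- function(pattern, subject, starts, maxMM) {
    np <- nchar(pattern); ns <- nchar(subject)
    starts <- starts[starts >= 1 & starts + np - 1L <= ns]
    if (!length(starts)) return(NA_integer_)
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pattern),
                                      Biostrings::DNAString(subject),
                                      starting.at = starts,
                                      with.indels = FALSE)
    hit <- which(mm <= maxMM)
    if (length(hit)) starts[hit[1]] else NA_integer_
}

#' Classify a read as target or non-target
#'
#' A read is a target when the forward primer occurs (up to
#' `maxMismatches` Hamming mismatches) within the first
#' `nchar(fwdPrimer) + slack` bases, and the reverse complement of the
#' reverse primer occurs downstream of that match. Reads failing either
#' test (off-target amplification, chimeras) are counted but excluded from
#' the allele table and profile.
#'
#' @param seq read sequence (character).
#' @param assay an [AmpliconAssay-class].
#' @param maxMismatches allowed Hamming mismatches per primer (default 0).
#' @param slack allowed offset of the forward primer from the read start
#'   (default 3).
#' @return TRUE/FALSE.
#' @export
classifyTarget <- function(seq, assay, maxMismatches = 0L, slack = 3L) {
    seq <- toupper(as.character(seq))
    fp <- assay@fwdPrimer
    fstart <- .hammingFind(fp, seq, seq.int(1L, slack + 1L), maxMismatches)
    if (is.na(fstart)) return(FALSE)
    rrc <- .revcomp(assay@revPrimer)
    fend <- fstart + nchar(fp)            # first position after the fwd match
    rstart <- .hammingFind(rrc, seq,
                           seq.int(fend, max(fend, nchar(seq) - nchar(rrc) + 1L)),
                           maxMismatches)
    !is.na(rstart)
}

#' Classify a variant signature as an NHEJ event
#'
#' TRUE iff some insertion or deletion overlaps the closed window
#' `[cutSite - nhejWindow, cutSite + nhejWindow]` on reference coordinates:
#' a deletion overlaps when its span `[refPos, refPos + length)` intersects
#' the window, an insertion when its `refPos` lies in the window.
#' Substitutions never qualify - lone mismatches are treated as sequencing
#' error, not repair products.
#'
#' @param sig a canonical (left-normalized) [VariantSignature-class].
#' @param assay an [AmpliconAssay-class].
#' @return TRUE/FALSE.
#' @export
classifyNhej <- function(sig, assay) {
    o <- ops(sig)
    if (!nrow(o)) return(FALSE)
    lo <- assay@cutSite - assay@nhejWindow
    hi <- assay@cutSite + assay@nhejWindow
    for (i in seq_len(nrow(o))) {
        if (o$kind[i] == "substitution") next
        p <- o$refPos[i]
        hit <- if (o$kind[i] == "insertion") (p >= lo && p <= hi)
               else (p <= hi && p + o$length[i] - 1L >= lo)
        if (hit) return(TRUE)
    }
    FALSE
}

## per-reference-position tallies for one aligned group, weighted by count
.accumulateProfile <- function(prof, aln, count) {
    r <- .chars(aln@refAln); q <- .chars(aln@qryAln)
    onRef <- r != "-"
    pos <- cumsum(onRef)[onRef]          # 1-based ref position per ref column
    rr <- r[onRef]; qq <- q[onRef]
    del <- qq == "-"
    match <- !del & rr == qq
    mis <- !del & !match
    prof$matches[pos[match]] <- prof$matches[pos[match]] + count
    prof$mismatches[pos[mis]] <- prof$mismatches[pos[mis]] + count
    prof$deletions[pos[del]] <- prof$deletions[pos[del]] + count
    prof
}

#' Quantify editing outcomes
#'
#' Aligns each target read group to the wildtype amplicon, extracts
#' canonical variant signatures, classifies NHEJ events around the cut
#' site, and assembles the editing summary: allele table (sorted by count
#' descending), per-position match profile (weighted by counts;
#' insertions contribute no profile column, the profile is
#' reference-indexed) and editing efficiency
#' `nhejReads / targetReads` over the frequency-filtered target
#' population.
#'
#' @param groups data.frame of collapsed, frequency-filtered read groups
#'   (see [collapseReads()], [filterLowFrequency()]).
#' @param assay an [AmpliconAssay-class].
#' @param scoring an [AlignmentScoring-class].
#' @param maxPrimerMismatches,primerSlack passed to [classifyTarget()].
#' @param totalReads total reads before filtering (defaults to the sum of
#'   the group counts, i.e. no filtering upstream).
#' @return An [EditingSummary-class]. When there are no target reads the
#'   efficiency is NA and a warning is raised.
#' @export
quantifyEdits <- function(groups, assay, scoring = alignmentScoring(),
                          maxPrimerMismatches = 0L, primerSlack = 3L,
                          totalReads = sum(groups$count)) {
    retained <- sum(groups$count)
    isTarget <- vapply(groups$sequence, classifyTarget, logical(1),
                       assay = assay, maxMismatches = maxPrimerMismatches,
                       slack = primerSlack, USE.NAMES = FALSE)
    tg <- groups[isTarget, , drop = FALSE]
    targetReads <- sum(tg$count)

    n <- nchar(assay@reference)
    prof <- data.frame(pos = seq_len(n),
                       refBase = .chars(assay@reference),
                       matches = 0, mismatches = 0, deletions = 0)

    if (targetReads == 0L) {
        warning("no target reads; editing efficiency is undefined",
                call. = FALSE)
        prof$matchFraction <- NA_real_
        return(new("EditingSummary",
                   totalReads = as.integer(totalReads),
                   retainedAfterFilter = as.integer(retained),
                   targetReads = 0L, nhejReads = 0L,
                   editingEfficiency = NA_real_,
                   alleles = data.frame(sequence = character(),
                                        count = integer(),
                                        frequency = numeric(),
                                        signature = character(),
                                        isNhej = logical()),
                   profile = prof, parameters = .summaryParams(assay, scoring,
                       maxPrimerMismatches, primerSlack)))
    }

    sigs <- vector("list", nrow(tg))
    isNhej <- logical(nrow(tg))
    for (i in seq_len(nrow(tg))) {
        aln <- globalAlign(assay@reference, tg$sequence[i], scoring)
        sigs[[i]] <- extractSignature(aln)
        isNhej[i] <- classifyNhej(sigs[[i]], assay)
        prof <- .accumulateProfile(prof, aln, tg$count[i])
    }
    denom <- prof$matches + prof$mismatches + prof$deletions
    prof$matchFraction <- ifelse(denom > 0, prof$matches / denom, NA_real_)

    all <- data.frame(sequence = tg$sequence, count = tg$count,
                      frequency = tg$count / targetReads,
                      signature = vapply(sigs, signatureToString, character(1)),
                      isNhej = isNhej, stringsAsFactors = FALSE)
    all <- all[order(-all$count, all$sequence), , drop = FALSE]
    rownames(all) <- NULL

    new("EditingSummary",
        totalReads = as.integer(totalReads),
        retainedAfterFilter = as.integer(retained),
        targetReads = as.integer(targetReads),
        nhejReads = as.integer(sum(tg$count[isNhej])),
        editingEfficiency = sum(tg$count[isNhej]) / targetReads,
        alleles = all, profile = prof,
        parameters = .summaryParams(assay, scoring, maxPrimerMismatches,
                                    primerSlack))
}

.summaryParams <- function(assay, scoring, maxPrimerMismatches, primerSlack) {
    list(cutSite = assay@cutSite, nhejWindow = assay@nhejWindow,
         minCount = assay@minCount, fwdPrimer = assay@fwdPrimer,
         revPrimer = assay@revPrimer,
         scoring = list(match = scoring@match, mismatch = scoring@mismatch,
                        gapOpen = scoring@gapOpen,
                        gapExtend = scoring@gapExtend),
         maxPrimerMismatches = as.integer(maxPrimerMismatches),
         primerSlack = as.integer(primerSlack))
}

#' Write editing reports
#'
#' Emits `alleles.tsv` (sequence, count, frequency, signature, isNhej),
#' `profile.tsv` (1-based position, reference base, matches, mismatches,
#' deletions, matchFraction) and `summary.json` (scalar fields, parameters
#' and the package version). Output is deterministic: re-running on the
#' same input yields byte-identical files.
#'
#' @param summary an [EditingSummary-class].
#' @param outdir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
writeReports <- function(summary, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (file.access(outdir, 2) != 0)
        stop("output directory is not writable: ", outdir, call. = FALSE)
    af <- file.path(outdir, "alleles.tsv")
    pf <- file.path(outdir, "profile.tsv")
    sf <- file.path(outdir, "summary.json")
    write.table(summary@alleles, af, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(summary@profile, pf, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(
        totalReads = summary@totalReads,
        retainedAfterFilter = summary@retainedAfterFilter,
        targetReads = summary@targetReads,
        nhejReads = summary@nhejReads,
        editingEfficiency = summary@editingEfficiency,
        nAlleles = nrow(summary@alleles),
        parameters = summary@parameters,
        version = as.character(packageVersion("crisprEdits"))),
        sf, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    invisible(c(af, pf, sf))
}
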