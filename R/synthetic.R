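## Seeded amplicon read simulator with known editing structure: a mixture
## of unedited reads and single-indel NHEJ alleles clustered at the cut
## site, plus uniform per-base substitution sequencing error.

#' Construct a simulation configuration
#'
#' Defaults describe one HiSeq-scale amplicon sample: 20,000 reads, five
#' distinct NHEJ alleles (70% deletions), truncated-geometric indel sizes
#' (p = 0.5, support 1..20), indel starts within 5 bp of the cut, and a
#' 0.002 per-base substitution error rate.
#'
#' @param reference wildtype amplicon (character or DNAString).
#' @param cutSite 0-based predicted cut position.
#' @param editingRate fraction of reads drawn from edited alleles.
#' @param nAlleles number of distinct edited alleles.
#' @param delProb probability an edited allele is a deletion.
#' @param sizeGeomP truncated-geometric length parameter.
#' @param maxOffset max |start - cutSite| for indel placement.
#' @param errorRate per-base substitution probability.
#' @param depth total reads.
#' @param seed integer RNG seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(reference, cutSite, editingRate = 0.5,
                             nAlleles = 5L, delProb = 0.7, sizeGeomP = 0.5,
                             maxOffset = 5L, errorRate = 0.002,
                             depth = 20000L, seed = 1L) {
    new("SimulationConfig", reference = toupper(as.character(reference)),
        cutSite = as.integer(cutSite), editingRate = as.numeric(editingRate),
        nAlleles = as.integer(nAlleles), delProb = as.numeric(delProb),
        sizeGeomP = as.numeric(sizeGeomP), maxOffset = as.integer(maxOffset),
        errorRate = as.numeric(errorRate), depth = as.integer(depth),
        seed = as.integer(seed))
}

## truncated geometric pmf on 1..maxLen
.truncGeomPmf <- function(p, maxLen = 20L) {
    k <- seq_len(maxLen)
    w <- p * (1 - p)^(k - 1)
    w / sum(w)
}

#' Draw the edited-allele signatures of a simulation
#'
#' Each allele is a single left-normalized indel: length drawn from a
#' truncated geometric distribution (support 1..20), start uniform within
#' `maxOffset` of the cut site, deletion with probability `delProb` (else
#' an insertion with uniform random bases). Alleles are distinct both as
#' signatures and as edited sequences. Fully reproducible from the seed.
#'
#' @param cfg a [SimulationConfig-class].
#' @return list of [VariantSignature-class], length `nAlleles`.
#' @export
drawAlleles <- function(cfg) {
    set.seed(cfg@seed)
    .drawAllelesNoSeed(cfg)
}

.drawAllelesNoSeed <- function(cfg) {
    ref <- cfg@reference
    L <- nchar(ref)
    pmf <- .truncGeomPmf(cfg@sizeGeomP)
    sigs <- list(); seqs <- character()
    attempts <- 0L
    while (length(sigs) < cfg@nAlleles) {
        attempts <- attempts + 1L
        if (attempts > 100L * cfg@nAlleles)
            stop("could not place ", cfg@nAlleles,
                 " distinct alleles after ", attempts, " attempts",
                 call. = FALSE)
        len <- sample.int(20L, 1L, prob = pmf)
        ## sample.int avoids sample()'s scalar expansion when maxOffset = 0
        start <- cfg@cutSite - cfg@maxOffset +
            sample.int(2L * cfg@maxOffset + 1L, 1L) - 1L
        isDel <- runif(1) < cfg@delProb
        if (isDel) {
            if (start < 0L || start + len > L) next
            ops <- data.frame(kind = "deletion", refPos = start,
                              length = len, alt = "")
        } else {
            if (start < 0L || start > L) next
            ops <- data.frame(kind = "insertion", refPos = start,
                              length = len,
                              alt = paste(sample(c("A", "C", "G", "T"), len,
                                                 replace = TRUE),
                                          collapse = ""))
        }
        sig <- variantSignature(.normalizeOps(ops, ref))
        ## placement is defined on the canonical signature: reject draws
        ## whose left-normalized start escapes the configured interval
        p <- ops(sig)$refPos[1]
        if (p < cfg@cutSite - cfg@maxOffset ||
            p > cfg@cutSite + cfg@maxOffset) next
        key <- signatureToString(sig)
        aseq <- applySignature(ref, sig)
        if (key %in% vapply(sigs, signatureToString, character(1))) next
        if (aseq %in% seqs || aseq == ref) next
        sigs[[length(sigs) + 1L]] <- sig
        seqs <- c(seqs, aseq)
    }
    sigs
}

## substitute sequencing errors into a character vector of reads of equal
## length; returns the mutated vector (sparse: only affected reads touched)
.addErrors <- function(reads, len, errorRate) {
    n <- length(reads)
    if (!n || errorRate <= 0) return(reads)
    nerr <- rbinom(1L, n * len, errorRate)
    if (!nerr) return(reads)
    cells <- sample.int(n * len, nerr)
    rd <- (cells - 1L) %/% len + 1L
    ps <- (cells - 1L) %% len + 1L
    bases <- c("A", "C", "G", "T")
    for (k in seq_len(nerr)) {
        cur <- substr(reads[rd[k]], ps[k], ps[k])
        substr(reads[rd[k]], ps[k], ps[k]) <-
            sample(setdiff(bases, cur), 1L)
    }
    reads
}

#' Simulate an amplicon FASTQ with known truth
#'
#' Writes `depth` reads: each read is the reference (probability
#' `1 - editingRate`) or one of the drawn alleles (equal weights), then
#' per-base substitution noise at `errorRate`. Qualities are constant Q30
#' (`I`). Fully reproducible from the seed.
#'
#' @param cfg a [SimulationConfig-class].
#' @param outpath FASTQ output path.
#' @return The truth set, a list with `alleles` (data.frame: `signature`
#'   string, `trueFrequency` = realized fraction of all reads, `sequence`;
#'   the first row is the unedited `WT` allele, so frequencies sum to 1),
#'   `signatures` (list of [VariantSignature-class], edited alleles only),
#'   `readAllele` (per-read allele index; 0 = unedited) and
#'   `realizedEditFraction`.
#' @export
simulateFastq <- function(cfg, outpath) {
    set.seed(cfg@seed)
    sigs <- .drawAllelesNoSeed(cfg)
    alleleSeqs <- vapply(sigs, function(s) applySignature(cfg@reference, s),
                         character(1))
    templates <- c(cfg@reference, alleleSeqs)

    edited <- runif(cfg@depth) < cfg@editingRate
    idx <- integer(cfg@depth)
    idx[edited] <- sample.int(cfg@nAlleles, sum(edited), replace = TRUE)

    reads <- character(cfg@depth)
    for (a in 0:cfg@nAlleles) {
        sel <- which(idx == a)
        if (!length(sel)) next
        tpl <- templates[a + 1L]
        reads[sel] <- .addErrors(rep(tpl, length(sel)), nchar(tpl),
                                 cfg@errorRate)
    }

    con <- file(outpath, "w")
    on.exit(close(con))
    quals <- vapply(nchar(reads), function(L) strrep("I", L), character(1))
    writeLines(paste0("@read", seq_len(cfg@depth), "\n", reads, "\n+\n",
                      quals), con)

    counts <- tabulate(idx + 1L, nbins = cfg@nAlleles + 1L)
    list(alleles = data.frame(
             signature = c("WT", vapply(sigs, signatureToString,
                                        character(1))),
             trueFrequency = counts / cfg@depth,
             sequence = templates, stringsAsFactors = FALSE),
         signatures = sigs,
         readAllele = idx,
         realizedEditFraction = mean(edited))
}
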