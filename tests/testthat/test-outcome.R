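test_that("target classification requires both primers in order", {
    assay <- toyAssay()
    ref <- assay@reference
    expect_true(classifyTarget(ref, assay))
    set.seed(55)
    expect_false(classifyTarget(revcompChr(randSeq(60)), assay))

    ## a 10-base deletion between the primers leaves both primer sites intact
    del <- paste0(substr(ref, 1, 25), substr(ref, 36, nchar(ref)))
    expect_true(classifyTarget(del, assay))

    ## forward primer beyond the slack window fails
    shifted <- paste0("ACGTACGT", ref)
    expect_false(classifyTarget(shifted, assay))
    ## one primer mismatch tolerated only when allowed
    mut <- ref
    substr(mut, 2, 2) <- if (substr(ref, 2, 2) == "A") "C" else "A"
    expect_false(classifyTarget(mut, assay, maxMismatches = 0))
    expect_true(classifyTarget(mut, assay, maxMismatches = 1))
})

test_that("NHEJ calls need an indel overlapping the cut-site window", {
    assay <- toyAssay(nhejWindow = 5L)
    cut <- assay@cutSite
    sigDel <- function(pos, len) variantSignature(
        data.frame(kind = "deletion", refPos = pos, length = len, alt = ""))
    sigIns <- function(pos, alt) variantSignature(
        data.frame(kind = "insertion", refPos = pos, length = nchar(alt),
                   alt = alt))
    sigSub <- function(pos, alt) variantSignature(
        data.frame(kind = "substitution", refPos = pos,
                   length = nchar(alt), alt = alt))

    expect_false(classifyNhej(variantSignature(), assay))
    expect_true(classifyNhej(sigDel(cut, 2L), assay))
    ## substitutions never qualify, even at the cut itself
    expect_false(classifyNhej(sigSub(cut, "A"), assay))
    ## window edges: closed interval [cut - w, cut + w]
    expect_true(classifyNhej(sigIns(cut - 5L, "G"), assay))
    expect_true(classifyNhej(sigIns(cut + 5L, "G"), assay))
    expect_false(classifyNhej(sigIns(cut - 6L, "G"), assay))
    expect_false(classifyNhej(sigIns(cut + 6L, "G"), assay))
    ## a distal deletion whose span reaches the window counts
    expect_true(classifyNhej(sigDel(cut - 9L, 5L), assay))
    expect_false(classifyNhej(sigDel(cut - 9L, 4L), assay))
})

test_that("enlarging the NHEJ window never decreases NHEJ calls", {
    assay <- toyAssay()
    cut <- assay@cutSite
    set.seed(56)
    sigs <- lapply(1:40, function(k) {
        pos <- cut + sample(-12:12, 1)
        if (runif(1) < 0.5)
            variantSignature(data.frame(kind = "deletion", refPos = pos,
                                        length = sample(1:5, 1), alt = ""))
        else
            variantSignature(data.frame(kind = "insertion", refPos = pos,
                                        length = 1L, alt = "G"))
    })
    counts <- vapply(0:12, function(w) {
        a <- assay; a@nhejWindow <- as.integer(w)
        sum(vapply(sigs, classifyNhej, logical(1), assay = a))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
})

test_that("quantify on unedited reads gives efficiency 0 and a perfect profile", {
    assay <- toyAssay()
    g <- data.frame(sequence = assay@reference, count = 50L)
    sm <- quantifyEdits(g, assay)
    expect_equal(editingEfficiency(sm), 0)
    expect_equal(nrow(alleles(sm)), 1)
    expect_equal(alleles(sm)$frequency, 1)
    expect_false(alleles(sm)$isNhej)
    expect_true(all(matchProfile(sm)$matchFraction == 1))
})

test_that("a 60/40 reference/deletion mixture is quantified exactly", {
    assay <- toyAssay()
    ref <- assay@reference
    cut <- assay@cutSite
    delRead <- paste0(substr(ref, 1, cut), substr(ref, cut + 4, nchar(ref)))
    g <- data.frame(sequence = c(ref, delRead), count = c(60L, 40L))
    sm <- quantifyEdits(g, assay)
    expect_equal(editingEfficiency(sm), 0.40)
    al <- alleles(sm)
    expect_equal(al$frequency[al$sequence == delRead], 0.40)
    expect_true(al$isNhej[al$sequence == delRead])
    expect_equal(sum(al$frequency), 1)
    expect_equal(sum(al$count), sm@targetReads)
    prof <- matchProfile(sm)
    ## the three deleted positions drop to 60/100; note left-normalization
    ## may place the gap at the leftmost equivalent coordinate
    expect_equal(sort(table(round(prof$matchFraction, 2)), decreasing = TRUE),
                 sort(table(c(rep(1, nchar(ref) - 3), rep(0.6, 3))),
                      decreasing = TRUE), ignore_attr = TRUE)
    expect_equal(sum(prof$matchFraction < 1), 3)
    expect_true(all(prof$matches + prof$mismatches + prof$deletions == 100))
})

test_that("non-target groups are counted but excluded from alleles and profile", {
    assay <- toyAssay()
    set.seed(57)
    g <- data.frame(sequence = c(assay@reference, randSeq(60)),
                    count = c(30L, 20L))
    sm <- quantifyEdits(g, assay)
    expect_equal(sm@retainedAfterFilter, 50L)
    expect_equal(sm@targetReads, 30L)
    expect_equal(nrow(alleles(sm)), 1)
    expect_true(all(matchProfile(sm)$matches == 30))
})

test_that("zero target reads yields a warning and an NA efficiency", {
    assay <- toyAssay()
    set.seed(58)
    g <- data.frame(sequence = randSeq(60), count = 500L)
    expect_warning(sm <- quantifyEdits(g, assay), "no target reads")
    expect_true(is.na(editingEfficiency(sm)))
    expect_equal(sm@targetReads, 0L)
    expect_equal(nrow(alleles(sm)), 0)
})

test_that("editing efficiency is monotone in the simulated editing rate", {
    mod <- syntheticAppModel()
    rates <- c(0, 0.25, 0.5, 0.75, 1.0)
    eff <- vapply(seq_along(rates), function(i) {
        cfg <- simulationConfig(mod$context, mod$cutSite,
                                editingRate = rates[i], depth = 4000L,
                                errorRate = 0.001, seed = 100L + i)
        fq <- tempfile(fileext = ".fastq")
        on.exit(unlink(fq), add = TRUE)
        simulateFastq(cfg, fq)
        kept <- filterLowFrequency(collapseReads(readFastq(fq)), 4L)
        quantifyEdits(kept, mod$assay)@editingEfficiency
    }, numeric(1))
    expect_true(all(diff(eff) >= 0))
    expect_equal(eff[1], 0)
    expect_equal(eff[5], 1)
})

test_that("reports are complete and byte-identical across re-runs", {
    assay <- toyAssay()
    ref <- assay@reference
    delRead <- paste0(substr(ref, 1, 28), substr(ref, 32, nchar(ref)))
    g <- data.frame(sequence = c(ref, delRead), count = c(70L, 30L))
    sm <- quantifyEdits(g, assay)
    d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
    writeReports(sm, d1)
    writeReports(quantifyEdits(g, assay), d2)
    for (f in c("alleles.tsv", "profile.tsv", "summary.json")) {
        expect_true(file.exists(file.path(d1, f)))
        expect_equal(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
    }
    expect_equal(nrow(read.delim(file.path(d1, "alleles.tsv"))), 2)
    expect_equal(nrow(read.delim(file.path(d1, "profile.tsv"))), nchar(ref))
    js <- jsonlite::read_json(file.path(d1, "summary.json"))
    expect_equal(js$targetReads, 100L)
    unlink(c(d1, d2), recursive = TRUE)
})
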