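test_that("applySignature edits the reference as specified", {
    expect_equal(applySignature("ACGT", variantSignature()), "ACGT")
    ins <- variantSignature(data.frame(kind = "insertion", refPos = 2L,
                                       length = 2L, alt = "GG"))
    expect_equal(applySignature("ACGT", ins), "ACGGGT")
    expect_equal(nchar(applySignature("ACGT", ins)), 4 + netShift(ins))
    del <- variantSignature(data.frame(kind = "deletion", refPos = 1L,
                                       length = 2L, alt = ""))
    expect_equal(applySignature("ACGT", del), "AT")
    sub <- variantSignature(data.frame(kind = "substitution", refPos = 0L,
                                       length = 2L, alt = "TT"))
    expect_equal(applySignature("ACGT", sub), "TTGT")
    oob <- variantSignature(data.frame(kind = "deletion", refPos = 3L,
                                       length = 4L, alt = ""))
    expect_error(applySignature("ACGT", oob), "bounds")
})

test_that("translation follows the standard code with stop-at-first-stop", {
    tr <- translateCds("ATGTAA")
    expect_equal(tr$protein, "M")
    expect_true(tr$stopFound)

    tr <- translateCds("ATGGGTGG")   # trailing 2-base remainder ignored
    expect_equal(tr$protein, "MG")
    expect_false(tr$stopFound)

    expect_equal(translateCds("ATGNNTGGA")$protein, "MXG")
    expect_equal(translateCds("")$protein, "")

    ## random 300-mers against the Biostrings code table
    set.seed(71)
    for (k in 1:10) {
        cds <- randSeq(300)
        full <- as.character(Biostrings::translate(
            Biostrings::DNAString(cds), no.init.codon = TRUE))
        stopAt <- regexpr("*", full, fixed = TRUE)
        expected <- if (stopAt > 0) substr(full, 1, stopAt - 1) else full
        tr <- translateCds(cds)
        expect_equal(tr$protein, expected)
        expect_equal(tr$stopFound, stopAt > 0)
    }
})

test_that("product prediction recovers truncation point, appended residues and name", {
    mod <- syntheticAppModel("human")

    ## unedited allele: full-length product, nothing truncated
    pr <- predictProduct(mod$context, variantSignature(), mod$map,
                         label = mod$label)
    expect_equal(pr@truncatedCount, 0L)
    expect_equal(pr@lastWtResidue, 695L)
    expect_equal(pr@appended, "")
    expect_true(pr@stopFound)

    ## frameshifting 1-bp deletion at the cut: translated up to residue 659,
    ## Gly-Gly appended before the new stop, last 36 residues truncated
    fs <- variantSignature(data.frame(kind = "deletion",
                                      refPos = mod$cutSite, length = 1L,
                                      alt = ""))
    pr <- predictProduct(mod$context, fs, mod$map, label = "APP")
    expect_equal(pr@lastWtResidue, 659L)
    expect_equal(pr@truncatedCount, 36L)
    expect_equal(pr@appended, "GG")
    expect_equal(pr@productName, "APP-659-GG")
    expect_true(pr@stopFound)
})

test_that("wildtype protein cross-check identifies the first disagreeing residue", {
    mod <- syntheticAppModel("human")
    wtSeg <- translateCds(mod$context)$protein
    wtFull <- paste0(strrep("A", 600), wtSeg)
    pr <- predictProduct(mod$context, variantSignature(), mod$map,
                         label = "APP", wtProtein = wtFull)
    expect_equal(pr@lastWtResidue, 695L)
    bad <- wtFull
    substr(bad, 610, 610) <- "W"
    expect_error(predictProduct(mod$context, variantSignature(), mod$map,
                                wtProtein = bad), "residue 610")
})

test_that("in-frame deletions between codons match direct translation (oracle)", {
    mod <- syntheticAppModel("human")
    set.seed(72)
    for (k in 1:10) {
        codon0 <- sample(10:80, 1)          # delete whole codons
        len <- 3L * sample(1:3, 1)
        sig <- variantSignature(data.frame(kind = "deletion",
                                           refPos = 3L * codon0,
                                           length = len, alt = ""))
        sig <- variantSignature(crisprEdits:::.normalizeOps(ops(sig),
                                                            mod$context))
        pr <- predictProduct(mod$context, sig, mod$map)
        direct <- translateCds(applySignature(mod$context, sig))
        expect_equal(pr@stopFound, direct$stopFound)
        ## the predicted product re-assembles to the directly translated one
        wtSeg <- translateCds(mod$context)$protein
        rebuilt <- paste0(substr(wtSeg, 1, pr@lastWtResidue - 600L),
                          pr@appended)
        expect_equal(rebuilt, direct$protein)
    }
})

test_that("truncation shrinks as a frameshift moves 3' along the CDS", {
    mod <- syntheticAppModel("human")
    positions <- seq(30L, 270L, by = 30L)
    trunc <- vapply(positions, function(p) {
        sig <- variantSignature(data.frame(kind = "deletion", refPos = p,
                                           length = 1L, alt = ""))
        predictProduct(mod$context, sig, mod$map)@truncatedCount
    }, integer(1))
    expect_true(all(diff(trunc) <= 0))
})

test_that("epitope retention counts only retained wildtype residues", {
    mod <- syntheticAppModel("human")
    unedited <- predictProduct(mod$context, variantSignature(), mod$map,
                               label = "APP")
    expect_equal(unname(epitopeRetention(unedited, mod$epitopes)), 1.0)

    fs <- variantSignature(data.frame(kind = "deletion",
                                      refPos = mod$cutSite, length = 1L,
                                      alt = ""))
    pr <- predictProduct(mod$context, fs, mod$map, label = "APP")
    ## last-20-residue epitope (676-695) entirely lost at truncation 659
    expect_equal(unname(epitopeRetention(pr, mod$epitopes)), 0.0)
    ## a span straddling the truncation point is partially retained
    ep <- data.frame(name = "mid", start = 650, end = 669)
    expect_equal(unname(epitopeRetention(pr, ep)), 0.5)
    expect_error(epitopeRetention(pr, data.frame(name = "x", start = 0,
                                                 end = 10)), "span")
})
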