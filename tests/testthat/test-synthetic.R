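test_that("ancestral model validates its parameters", {
    expect_error(ancestralModel(fst = c(A = 1, B = 0.1), pops = c("A", "B")),
                 "degenerate")
    expect_error(ancestralModel(nHaplotypes = 1), "at least 2")
    expect_error(ancestralModel(afRange = c(0, 0.9)), "within")
})

test_that("zero divergence collapses population frequencies to the ancestral draw", {
    m <- ancestralModel(pops = c("P1", "P2"), fst = c(P1 = 0, P2 = 0),
                        nHaplotypes = 4000)
    pan <- generateAncestralPanels(m, 200, seed = 3)
    f1 <- rowMeans(alleles(pan$P1))
    f2 <- rowMeans(alleles(pan$P2))
    # same underlying frequency: differences are pure binomial noise
    expect_lt(max(abs(f1 - f2)), 4 * sqrt(0.5 * 0.5 * 2 / 4000) * 4)
    expect_gt(cor(f1, f2), 0.97)
})

test_that("panel generation is deterministic under a fixed seed", {
    m <- ancestralModel(nHaplotypes = 20)
    a <- generateAncestralPanels(m, 100, seed = 42)
    b <- generateAncestralPanels(m, 100, seed = 42)
    expect_identical(lapply(a, alleles), lapply(b, alleles))
    c2 <- generateAncestralPanels(m, 100, seed = 43)
    expect_false(identical(alleles(a$EUR), alleles(c2$EUR)))
})

test_that("simulated divergence is recovered by the Hudson estimator", {
    m <- ancestralModel(pops = c("P1", "P2"), fst = c(P1 = 0.1, P2 = 0.1),
                        nHaplotypes = 200)
    pan <- generateAncestralPanels(m, 5000, seed = 9)
    fst <- hudsonFstPanels(pan$P1, pan$P2)$ratioOfAverages
    # two populations each at F = 0.1 from the ancestor: pairwise Fst ~ 0.1
    # under the ratio-of-averages combination
    expect_equal(fst, 0.1, tolerance = 0.02 / 0.1)
})

test_that("degenerate mixture gives single-ancestry truth", {
    m <- ancestralModel(nHaplotypes = 10)
    pan <- generateAncestralPanels(m, 300, seed = 2)
    co <- simulateAdmixedCohort(pan,
        admixtureModel(c(EUR = 1, AFR = 0, NAT = 0), 16, 10), seed = 4)
    expect_true(all(ancestryLabels(truthCalls(co)) == "EUR"))
})

test_that("genome-wide ancestry proportions match the admixture model", {
    fix <- smallCohort(nVariants = 3000, nInd = 60, seed = 21)
    lab <- ancestryLabels(truthCalls(fix$cohort))
    got <- prop.table(table(factor(lab, c("EUR", "AFR", "NAT"))))
    expect_equal(as.numeric(got), c(0.746, 0.160, 0.094), tolerance = 0.15)
})

test_that("mean tract length approximates 1/g morgans", {
    m <- ancestralModel(nHaplotypes = 10)
    # dense uniform grid so tract boundaries are finely resolved
    gr <- makeVariantsGr(seq(1e4, 2e8, length.out = 4000))
    pan <- generateAncestralPanels(m, 4000, seed = 8, variants = gr)
    co <- simulateAdmixedCohort(pan,
        admixtureModel(c(EUR = 1/3, AFR = 1/3, NAT = 1/3), 16, 260), seed = 6)
    lab <- ancestryLabels(truthCalls(co))
    cM <- S4Vectors::mcols(variantRanges(haplotypePanel(co)))$cM
    lens <- unlist(lapply(seq_len(ncol(lab)), function(h) {
        r <- rle(lab[, h])
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
        (cM[ends] - cM[starts]) / 100
    }))
    expect_gt(length(lens), 10000)
    # labels drawn iid per tract merge adjacent same-ancestry tracts, so the
    # observed run length is 1/g divided by the prob a boundary switches label
    expected <- (1 / 16) / (2 / 3)
    expect_equal(mean(lens), expected, tolerance = 0.1)
})

test_that("breakpoint counts follow the Poisson tract law", {
    m <- ancestralModel(pops = c("A", "B"), fst = c(A = .1, B = .1),
                        nHaplotypes = 10)
    gr <- makeVariantsGr(seq(1e4, 2e8, length.out = 3000))
    pan <- generateAncestralPanels(m, 3000, seed = 1, variants = gr)
    co <- simulateAdmixedCohort(pan,
        admixtureModel(c(A = 0.5, B = 0.5), 12, 200), seed = 2)
    lab <- ancestryLabels(truthCalls(co))
    # switches per haplotype: Poisson(g*M) breaks thinned by label resampling
    switches <- vapply(seq_len(ncol(lab)), function(h)
        sum(lab[-1, h] != lab[-nrow(lab), h]), numeric(1))
    M <- diff(range(S4Vectors::mcols(variantRanges(pan$A))$cM)) / 100
    expected <- 12 * M * 0.5
    expect_equal(mean(switches), expected, tolerance = 0.1)
    expect_equal(var(switches) / mean(switches), 1, tolerance = 0.25)
})

test_that("sweep injection reaches the target proportion and is local", {
    fix <- smallCohort(nVariants = 4000, nInd = 50, seed = 31)
    region <- "1:50000000-90000000"
    before <- perVariantProportions(truthCalls(fix$cohort))
    sw <- injectAncestrySweep(fix$cohort, fix$panels, region, "NAT", 0.24,
                              seed = 7)
    after <- perVariantProportions(truthCalls(sw))
    idx <- admixscan:::.inRegion(variantRanges(haplotypePanel(sw)),
                                 parseRegion(region))
    expect_equal(mean(after$proportions[idx, "NAT"]), 0.24, tolerance = 0.02 / 0.24)
    # locality: outside the region nothing moved
    expect_identical(after$proportions[-idx, ], before$proportions[-idx, ])
    expect_identical(alleles(haplotypePanel(sw))[-idx, ],
                     alleles(haplotypePanel(fix$cohort))[-idx, ])
})

test_that("sweep at the current proportion is a fixed point in expectation", {
    fix <- smallCohort(nVariants = 1000, nInd = 20, seed = 41)
    region <- "1:1-200000000"
    cur <- mean(ancestryLabels(truthCalls(fix$cohort)) == "NAT")
    sw <- injectAncestrySweep(fix$cohort, fix$panels, region, "NAT", cur,
                              seed = 3)
    expect_identical(ancestryLabels(truthCalls(sw)),
                     ancestryLabels(truthCalls(fix$cohort)))
    expect_error(
        injectAncestrySweep(fix$cohort, fix$panels, region, "NAT", 1e-6,
                            seed = 3),
        "unsupported direction")
})

test_that("requesting no defects returns the cohort unchanged", {
    fix <- smallCohort(nVariants = 200, nInd = 10, seed = 51)
    out <- corruptForQc(fix$cohort, seed = 1)
    expect_identical(alleles(haplotypePanel(out)),
                     alleles(haplotypePanel(fix$cohort)))
    expect_identical(nrow(out@defects), 0L)
})

test_that("injected defects are detectable by the matching QC filters", {
    fix <- smallCohort(nVariants = 800, nInd = 60, seed = 61)
    bad <- corruptForQc(fix$cohort, nDuplicatePairs = 1L, nHetExcess = 1L,
                        nHweViolations = 2L, nAmbiguous = 3L, seed = 9)
    expect_identical(nrow(bad@defects), 7L)
    gm <- asGenotypeMatrix(bad)

    # duplicate pair: GRM entry near 1 and above the relatedness threshold
    pair <- strsplit(bad@defects$id[bad@defects$defect == "duplicate_pair"],
                     "|", fixed = TRUE)[[1]]
    K <- grm(gm)
    expect_gt(K[pair[1], pair[2]], 0.8)
    expect_gt(K[pair[1], pair[2]], 0.125)

    # het-excess individual flagged by the heterozygosity filter
    hetId <- bad@defects$id[bad@defects$defect == "het_excess"]
    expect_true(hetId %in% heterozygosityOutliers(gm))

    # all-het variants have tiny exact-test p at n >= 50
    hweRows <- as.integer(bad@defects$id[bad@defects$defect == "hwe_violation"])
    for (j in hweRows) {
        x <- dosage(gm)[j, ]
        p <- hweExactTest(sum(x == 0), sum(x == 1), sum(x == 2))
        expect_lt(p, 1e-6)
    }

    # ambiguous rewrites are caught by the allele filter
    ambRows <- as.integer(bad@defects$id[bad@defects$defect ==
                                             "ambiguous_alleles"])
    res <- removeAmbiguousVariants(gm)
    expect_identical(qcSteps(res$report)$n_removed[1], length(ambRows))
})

test_that("cohort simulation is reproducible end to end", {
    a <- smallCohort(nVariants = 400, nInd = 15, seed = 71)
    b <- smallCohort(nVariants = 400, nInd = 15, seed = 71)
    expect_identical(alleles(haplotypePanel(a$cohort)),
                     alleles(haplotypePanel(b$cohort)))
    expect_identical(ancestryLabels(truthCalls(a$cohort)),
                     ancestryLabels(truthCalls(b$cohort)))
})
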