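test_that("EHH equals pair-enumeration on hand-checkable panels", {
    # 4 carriers of allele 1, splitting 2/2 at the first flanking site:
    # EHH = (C(2,2)*2)/C(4,2) = 1/3 beyond it
    A <- cbind(c(0, 1, 0), c(0, 1, 0), c(1, 1, 1), c(1, 1, 1),
               c(0, 0, 1), c(1, 0, 0))
    pan <- makePanel(A)
    cv <- ehh(pan, core = 2, allele = 1)
    expect_identical(cv$ehh[cv$offset_cm == 0], 1)
    expect_equal(cv$ehh[cv$offset_cm > 0], 1 / 3)
    expect_equal(cv$ehh[cv$offset_cm < 0], 1 / 3)
    # oracle agreement at every offset of a random small panel
    set.seed(21)
    B <- matrix(rbinom(12 * 8, 1, 0.5), 12, 8)
    B[6, ] <- c(rep(1, 5), rep(0, 3))
    panB <- makePanel(B)
    cvB <- ehh(panB, core = 6, allele = 1)
    carriers <- which(B[6, ] == 1)
    for (i in seq_len(nrow(cvB))) {
        off <- cvB$offset_cm[i]
        idx <- 6 + sign(off) * sum(abs(cvB$offset_cm[sign(cvB$offset_cm) ==
                                                     sign(off)]) <= abs(off))
        if (off == 0) next
        expect_equal(cvB$ehh[i], ehhPairOracle(B, 6, idx, carriers),
                     tolerance = 1e-12)
    }
    # all carriers identical over the span: EHH = 1 everywhere
    C2 <- matrix(0L, 5, 6); C2[3, 1:4] <- 1L
    cvC <- ehh(makePanel(C2), core = 3, allele = 1)
    expect_true(all(cvC$ehh == 1))
    expect_error(ehh(makePanel(C2), core = 1, allele = 1), "undefined")
})

test_that("EHH curves are non-increasing outward from the core", {
    set.seed(22)
    for (r in 1:10) {
        A <- matrix(rbinom(15 * 10, 1, 0.5), 15, 10)
        core <- sample(3:13, 1)
        al <- sample(0:1, 1)
        if (sum(A[core, ] == al) < 2) next
        cv <- ehh(makePanel(A), core, al)
        right <- cv$ehh[cv$offset_cm >= 0]
        left <- rev(cv$ehh[cv$offset_cm <= 0])
        expect_true(all(diff(right) <= 1e-12))
        expect_true(all(diff(left) <= 1e-12))
    }
})

test_that("iHH matches dense-grid quadrature and respects bounds", {
    set.seed(23)
    A <- matrix(rbinom(12 * 8, 1, 0.4), 12, 8)
    A[6, ] <- c(rep(1, 6), 0, 0)
    cM <- sort(runif(12, 0, 0.5))
    pan <- makePanel(A, cM = cM)
    cv <- ehh(pan, core = 6, allele = 1)
    v <- ihh(cv, cutoff = 0.05)
    oracle <- ihhGridOracle(A, cM, core = 6, haps = which(A[6, ] == 1),
                            cutoff = 0.05)
    expect_equal(as.numeric(v), oracle, tolerance = 1e-8)
    # bound: iHH <= total genetic span (EHH <= 1)
    expect_lte(as.numeric(v), diff(range(cM)))
    # zero genetic span -> 0
    pan0 <- makePanel(A, cM = rep(0.1, 12))
    expect_equal(as.numeric(ihh(ehh(pan0, 6, 1))), 0)
    # compiled bulk scanner agrees with the R curve route
    bulk <- admixscan:::.ihhScan(pan, cores = 6, partition = 1L,
                                 cutoff = 0.05, maxExtendCm = 50)
    expect_equal(unname(bulk[1, "ihh"]), as.numeric(v), tolerance = 1e-10)
})

test_that("compiled iHH agrees with the R implementation across random panels", {
    set.seed(24)
    for (r in 1:20) {
        nv <- sample(8:14, 1); nh <- sample(4:10, 1)
        A <- matrix(rbinom(nv * nh, 1, runif(1, 0.3, 0.7)), nv, nh)
        cM <- sort(runif(nv, 0, 1))
        pan <- makePanel(A, cM = cM)
        core <- sample(seq_len(nv), 1)
        for (part in c(0L, 1L, -1L)) {
            n <- if (part < 0) nh else sum(A[core, ] == part)
            bulk <- admixscan:::.ihhScan(pan, cores = core, partition = part,
                                         cutoff = 0.05, maxExtendCm = 50)
            if (n < 2) {
                expect_true(is.na(bulk[1, "ihh"]))
                next
            }
            al <- if (part < 0) NULL else part
            v <- ihh(ehh(pan, core, al), cutoff = 0.05)
            expect_equal(unname(bulk[1, "ihh"]), as.numeric(v),
                         tolerance = 1e-10)
        }
    }
})

test_that("iHS is antisymmetric in polarity and standardises to N(0,1) per bin", {
    fix <- smallCohort(nVariants = 3000, nInd = 60, seed = 131)
    pan <- haplotypePanel(fix$cohort)
    res <- ihs(pan, nBins = 10)
    resSwap <- ihs(pan, nBins = 10, ancestralIsRef = FALSE)
    ok <- !is.na(res$unstd) & !is.na(resSwap$unstd)
    expect_gt(sum(ok), 100)
    expect_equal(res$unstd[ok], -resSwap$unstd[ok], tolerance = 1e-12)
    # equal iHH in both classes -> unstandardised score 0
    i <- which(abs(res$ihhA - res$ihhD) < 1e-12 & !is.na(res$unstd))
    if (length(i)) expect_true(all(abs(res$unstd[i]) < 1e-12))
    # standardisation self-consistency within populated bins
    bins <- cut(res$daf, seq(0, 1, length.out = 11), include.lowest = TRUE)
    for (b in levels(bins)) {
        i <- which(bins == b & !is.na(res$std))
        if (length(i) >= 50) {
            expect_lt(abs(mean(res$std[i])), 0.1)
            expect_lt(abs(sd(res$std[i]) - 1), 0.1)
        }
    }
})

test_that("delta-iHH scales linearly with the genetic map", {
    fix <- smallCohort(nVariants = 800, nInd = 30, seed = 141)
    pan <- haplotypePanel(fix$cohort)
    d1 <- deltaIhhIntra(pan, nBins = 5)
    pan2 <- pan
    S4Vectors::mcols(pan2@variants)$cM <- 3 * S4Vectors::mcols(pan@variants)$cM
    d3 <- deltaIhhIntra(pan2, nBins = 5, maxExtendCm = 150)
    ok <- !is.na(d1$unstd) & !is.na(d3$unstd) & !d1$truncated & !d3$truncated
    expect_gt(sum(ok), 50)
    expect_equal(d3$unstd[ok], 3 * d1$unstd[ok], tolerance = 1e-8)
})

test_that("XP-EHH is zero for identical panels and antisymmetric", {
    fix <- smallCohort(nVariants = 600, nInd = 25, seed = 151)
    pan <- haplotypePanel(fix$cohort)
    same <- xpehh(pan, pan)
    expect_true(all(abs(same$unstd[!is.na(same$unstd)]) < 1e-12))
    ref <- fix$panels$EUR
    ab <- xpehh(pan, ref); ba <- xpehh(ref, pan)
    ok <- !is.na(ab$unstd) & !is.na(ba$unstd)
    expect_equal(ab$unstd[ok], -ba$unstd[ok], tolerance = 1e-12)
})

test_that("XP-EHH sign tracks slower haplotype decay, matching hand integration", {
    # population A: all haplotypes identical (EHH stays 1);
    # population B: maximal diversity (EHH collapses immediately)
    nv <- 9
    cM <- seq(0, 0.8, length.out = nv)
    A <- matrix(0L, nv, 6)
    set.seed(25)
    B <- matrix(rbinom(nv * 6, 1, 0.5), nv, 6)
    B[5, ] <- 0L                       # shared core allele
    panA <- makePanel(A, cM = cM); panB <- makePanel(B, cM = cM)
    res <- xpehh(panA, panB)
    expect_gt(res$unstd[5], 0)
    # hand value for A at the core: EHH = 1 across the whole span
    ihhA <- admixscan:::.ihhScan(panA, cores = 5)[1, "ihh"]
    expect_equal(unname(ihhA), cM[nv] - cM[1], tolerance = 1e-12)
    oracleB <- ihhGridOracle(B, cM, core = 5, haps = 1:6, cutoff = 0.05)
    expect_equal(res$unstd[5], unname(log(ihhA / oracleB)),
                 tolerance = 1e-8)
})

test_that("Hudson Fst has the stated closed-form behaviour", {
    # fixed difference
    expect_equal(hudsonFst(0, 50, 1, 50)$ratio, 1)
    # equal frequencies: estimator near 0 within 1/(n-1)
    f <- hudsonFst(rep(0.3, 2000), 200, rep(0.3, 2000), 200)
    expect_lte(abs(f$ratioOfAverages), 1 / 199 + 1e-12)
    # Balding-Nichols recovery across divergence levels
    for (F in c(0.05, 0.1, 0.2)) {
        m <- ancestralModel(pops = c("P1", "P2"),
                            fst = stats::setNames(c(F, F), c("P1", "P2")),
                            nHaplotypes = 200)
        pan <- generateAncestralPanels(m, 5000, seed = round(1000 * F))
        est <- hudsonFstPanels(pan$P1, pan$P2)$ratioOfAverages
        expect_equal(est, F, tolerance = 0.02 / F)
    }
    expect_error(hudsonFst(0.5, 1, 0.5, 10))
})

test_that("PBS follows its closed form and is monotone in the focal branch", {
    expect_equal(as.numeric(pbs(0, 0, 0)), 0)
    expect_equal(as.numeric(pbs(0.1, 0.1, 0.1)), -log(0.9) / 2,
                 tolerance = 1e-12)
    x <- as.numeric(pbs(c(0.1, 0.2, 0.3), 0.1, 0.1))
    expect_true(all(diff(x) > 0))
    cl <- pbs(1, 0.1, 0.1)
    expect_identical(attr(cl, "clamped"), 1L)
    expect_true(is.finite(cl))
    expect_identical(as.numeric(pbs(-0.5, 0, 0, floorNegative = TRUE)), 0)
})

test_that("empirical p-values follow the rank formula with average ties", {
    x <- seq_len(999)
    p <- suppressWarnings(empiricalPvalues(x))
    expect_equal(p[999], 1 / 1000)
    expect_equal(p[1], 999 / 1000)
    # two tied maxima share the average rank
    y <- c(1:8, 9, 9)
    py <- suppressWarnings(empiricalPvalues(y))
    expect_equal(py[9], py[10])
    expect_equal(py[9], mean(c(1, 2)) / 11)
    # approximately uniform on uniform input
    set.seed(26)
    u <- runif(2000)
    pu <- empiricalPvalues(u)
    expect_gt(stats::ks.test(pu, "punif")$p.value, 0.01)
    expect_true(all(pu > 0 & pu < 1))
    expect_warning(empiricalPvalues(rep(1, 200)), "identical")
})

test_that("Fisher combined score is chi-squared with 2k df under the null", {
    expect_equal(fisherCombinedScore(matrix(1, 3, 5))$fcs, rep(0, 3))
    set.seed(27)
    pm <- matrix(runif(10000 * 5), ncol = 5)
    fc <- fisherCombinedScore(pm)
    expect_gt(stats::ks.test(fc$fcs, stats::pchisq, df = 10)$p.value, 0.01)
    # monotone: increasing any p decreases FCS
    p1 <- fisherCombinedScore(matrix(c(0.1, 0.2), 1))$fcs
    p2 <- fisherCombinedScore(matrix(c(0.1, 0.3), 1))$fcs
    expect_gt(p1, p2)
    # per-variant k adjustment for missing statistics
    pmNA <- rbind(c(0.5, NA), c(0.5, 0.5))
    fcNA <- fisherCombinedScore(pmNA)
    expect_identical(fcNA$k, c(1, 2))
    expect_equal(fcNA$fcs, c(-2 * log(0.5), -4 * log(0.5)))
    expect_error(fisherCombinedScore(matrix(c(0, 0.5), 1)), "positive")
})

test_that("outlier and block calling follow strict quantile rules", {
    set.seed(28)
    fcs <- sample(seq_len(10000))     # distinct values
    gr <- makeVariantsGr(seq_len(10000) * 100)
    ob <- outlierBlocks(fcs, gr)
    expect_identical(sum(ob$isOutlier), 100L)
    expect_identical(nrow(ob$blocks), 100L)   # ceil(10000/100) blocks
    expect_false(any(ob$blocks$partial))
    # engineered enriched block against a low background
    fcs2 <- rep(0, 10000)
    fcs2[2001:2050] <- 1000 + seq_len(50)          # 50 outliers in block 21
    spread <- setdiff(seq(1, 10000, by = 150), 2001:2100)[1:50]
    fcs2[spread] <- 500 + seq_len(50)              # <= 1 outlier elsewhere
    ob2 <- outlierBlocks(fcs2, gr)
    expect_identical(which(ob2$blocks$selected), 21L)
    # partial final block
    gr3 <- makeVariantsGr(seq_len(250) * 100)
    ob3 <- outlierBlocks(seq_len(250), gr3)
    expect_identical(nrow(ob3$blocks), 3L)
    expect_identical(ob3$blocks$n, c(100L, 100L, 50L))
    expect_true(ob3$blocks$partial[3])
})

test_that("full scan is calibrated on neutral data and variant order only affects blocks", {
    fix <- smallCohort(nVariants = 6000, nInd = 60, seed = 161, nHap = 80)
    sr <- runScan(haplotypePanel(fix$cohort),
                  fix$panels[c("EUR", "AFR")], nBins = 20)
    expect_identical(nrow(sr$table), 6000L)
    # outliers: 1% by construction of the strict quantile rule
    expect_equal(mean(sr$table$is_outlier), 0.01, tolerance = 0.2)
    # selected blocks: about the top 0.5%
    expect_lte(sum(sr$blocks$selected), 2L)
    expect_true(all(sr$table$fcs >= 0, na.rm = TRUE))
    expect_true(all(sr$table$k <= 5))
    # manifest records the decisions
    expect_identical(sr$manifest$polarity, "reference_as_ancestral")
    expect_identical(sr$manifest$cross_delta_ihh_mode, "all")
})

test_that("an injected long-haplotype sweep is enriched in scan outliers", {
    fix <- smallCohort(nVariants = 6000, nInd = 60, seed = 171, nHap = 80)
    region <- "1:90000000-110000000"
    sw <- injectAncestrySweep(fix$cohort, fix$panels, region, "NAT", 0.5,
                              seed = 3)
    sr <- runScan(haplotypePanel(sw), fix$panels[c("EUR", "AFR")], nBins = 20)
    idx <- admixscan:::.inRegion(variantRanges(haplotypePanel(sw)),
                                 parseRegion(region))
    inRate <- mean(sr$table$is_outlier[idx])
    outRate <- mean(sr$table$is_outlier[-idx])
    expect_gt(inRate, 3 * outRate)
})
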