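test_that("ambiguous-allele removal drops exactly the A/T and G/C pairs", {
    ref <- c("A", "A", "C", "G", "T", "C", "G", "T", "A", "C")
    alt <- c("T", "G", "G", "C", "A", "T", "A", "C", "C", "A")
    # ambiguous: A/T, C/G, G/C, T/A -> rows 1, 3, 4, 5 are ambiguous? recount:
    # 1 A/T amb; 2 A/G ok; 3 C/G amb; 4 G/C amb; 5 T/A amb; 6 C/T ok; 7 G/A ok;
    # 8 T/C ok; 9 A/C ok; 10 C/A ok
    d <- matrix(1, 10, 4)
    gm <- makeGm(d, ref = ref, alt = alt)
    res <- removeAmbiguousVariants(gm)
    expect_identical(qcSteps(res$report)$n_removed, 4L)
    expect_identical(nVariants(res$genotypes), 6L)
    expect_true(all(!paste0(S4Vectors::mcols(variantRanges(res$genotypes))$ref,
                            S4Vectors::mcols(variantRanges(res$genotypes))$alt)
                    %in% c("AT", "TA", "CG", "GC")))
    expect_error(removeAmbiguousVariants(makeGm(d, ref = rep("N", 10),
                                                alt = alt)), "non-ACGT")
})

test_that("biallelic autosomal filter drops sex chromosomes and multiallelics", {
    d <- matrix(1, 4, 3)
    gm <- new("GenotypeMatrix", dosage = d,
              variants = makeVariantsGr(c(100, 200, 100, 100),
                                        chrom = c("8", "8", "X", "chr21"),
                                        alt = c("G", "G,C", "G", "G")),
              phased = FALSE)
    res <- keepBiallelicAutosomal(gm)
    kept <- variantRanges(res$genotypes)
    expect_identical(length(kept), 2L)
    expect_setequal(as.character(GenomicRanges::seqnames(kept)),
                    c("8", "chr21"))
    gm2 <- new("GenotypeMatrix", dosage = matrix(1, 1, 3),
               variants = makeVariantsGr(5, chrom = "weird"), phased = FALSE)
    expect_error(keepBiallelicAutosomal(gm2, onUnknownChrom = "fail"),
                 "unknown chromosome")
    expect_identical(nVariants(keepBiallelicAutosomal(gm2)$genotypes), 0L)
})

test_that("HWE exact test matches full enumeration of allele pairings", {
    expect_identical(hweExactTest(7, 0, 0), 1)
    expect_identical(hweExactTest(0, 0, 9), 1)
    for (counts in list(c(3, 0, 3), c(3, 4, 3), c(2, 5, 1),
                        c(4, 1, 2), c(1, 6, 1))) {
        expect_equal(hweExactTest(counts[1], counts[2], counts[3]),
                     hweEnumerationOracle(counts[1], counts[2], counts[3]),
                     tolerance = 1e-10,
                     label = paste(counts, collapse = "/"))
    }
    # perfect HWE configuration is not rejected
    expect_gt(hweExactTest(25, 50, 25), 0.5)
    expect_error(hweExactTest(-1, 0, 2), "non-negative")
})

test_that("missingness filter uses a strict threshold", {
    d <- matrix(0, 3, 100)
    d[sample(100, 40)] <- 1          # keep variant 1 polymorphic
    d[1, 1:11] <- NA                 # 11% missing -> removed
    d[2, 1:10] <- NA                 # exactly 10% -> kept
    gm <- makeGm(d)
    res <- filterMissingness(gm, 0.10)
    expect_identical(qcSteps(res$report)$n_removed, 1L)
    expect_identical(nVariants(res$genotypes), 2L)
})

test_that("MAF filter uses a strict threshold", {
    d <- rbind(c(rep(0, 99), 1),     # maf 0.005 -> removed
               c(rep(0, 98), 1, 1),  # maf 0.01 exactly -> kept
               rep(1, 100))          # maf 0.5 -> kept
    gm <- makeGm(d)
    res <- filterMaf(gm, 0.01)
    expect_identical(qcSteps(res$report)$n_removed, 1L)
    expect_identical(nVariants(res$genotypes), 2L)
})

test_that("heterozygosity outliers are flagged against a one-pass mean/SD", {
    set.seed(1)
    d <- matrix(rbinom(200 * 40, 2, 0.3), 200, 40)
    gm <- makeGm(d)
    base <- heterozygosityOutliers(gm, 3)
    # inject an extreme individual: heterozygous everywhere
    d2 <- d; d2[, 7] <- 1
    out <- heterozygosityOutliers(makeGm(d2), 3)
    expect_true("I7" %in% out)
    expect_false("I7" %in% base)
    # identical rates: nobody removed
    expect_identical(heterozygosityOutliers(makeGm(matrix(1, 50, 5))),
                     character())
    # nSd = 0 removes everyone off the mean
    expect_gt(length(heterozygosityOutliers(gm, 0)), 30)
})

test_that("GRM has unit diagonal, near-zero unrelated entries, and detects duplicates", {
    set.seed(2)
    nv <- 4000
    p <- runif(nv, 0.1, 0.9)
    d <- matrix(rbinom(nv * 30, 2, p), nv, 30)   # independent individuals, HWE
    gm <- makeGm(d)
    K <- grm(gm)
    expect_equal(unname(diag(K)), rep(1, 30), tolerance = 0.1)
    off <- K[upper.tri(K)]
    expect_lt(max(abs(off)), 3 / sqrt(nv) * 2.5)
    expect_equal(K, t(K))
    d2 <- cbind(d, d[, 1])           # duplicate of individual 1
    K2 <- grm(makeGm(d2))
    expect_gt(K2[1, 31], 0.9)
})

test_that("greedy unrelated subset matches brute-force MIS size on small graphs", {
    mkK <- function(n, edges) {
        K <- matrix(0, n, n, dimnames = list(paste0("I", 1:n),
                                             paste0("I", 1:n)))
        for (e in edges) { K[e[1], e[2]] <- 0.5; K[e[2], e[1]] <- 0.5 }
        diag(K) <- 1
        K
    }
    # no edges: everyone kept
    expect_identical(greedyUnrelatedSubset(mkK(4, list())), paste0("I", 1:4))
    # single pair: exactly one survivor of the pair
    kept <- greedyUnrelatedSubset(mkK(3, list(c(1, 2))))
    expect_identical(length(kept), 2L)
    expect_true("I3" %in% kept)
    # star: hub removed, leaves kept
    star <- mkK(6, lapply(2:6, function(j) c(1, j)))
    expect_identical(greedyUnrelatedSubset(star), paste0("I", 2:6))
    # assorted graphs vs exhaustive maximum-independent-set size
    graphs <- list(
        list(n = 4, e = list(c(1, 2), c(2, 3), c(3, 4))),          # path
        list(n = 5, e = list(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                             c(5, 1))),                            # cycle
        list(n = 6, e = list(c(1, 2), c(3, 4), c(5, 6))),          # 3 pairs
        list(n = 7, e = list(c(1, 2), c(1, 3), c(2, 3), c(4, 5),
                             c(5, 6), c(6, 7))),
        list(n = 12, e = list(c(1, 2), c(2, 3), c(1, 3), c(4, 5),
                              c(6, 7), c(8, 9), c(9, 10), c(11, 12),
                              c(3, 6))))
    for (g in graphs) {
        K <- mkK(g$n, g$e)
        kept <- greedyUnrelatedSubset(K)
        adj <- K > 0.125; diag(adj) <- FALSE
        # kept set is independent ...
        i <- match(kept, rownames(K))
        expect_false(any(adj[i, i]))
        # ... and as large as the true maximum independent set
        expect_identical(length(kept), misSizeOracle(adj))
    }
})

test_that("LD pruning matches a brute-force oracle and is deterministic", {
    set.seed(3)
    base <- matrix(rbinom(10 * 120, 2, 0.4), 10, 120)
    base[2, ] <- base[1, ]                      # r2 = 1 pair
    base[7, ] <- ifelse(runif(120) < 0.9, base[6, ], rbinom(120, 2, 0.4))
    gm <- makeGm(base)
    kept <- ldPrune(gm, window = 10, step = 5, r2Max = 0.5)
    # forced removal: exactly one of the perfect pair
    expect_identical(sum(c(1, 2) %in% kept), 1L)
    # brute-force oracle: same rule, independent implementation
    oracle <- function(d, r2Max) {
        maf <- pmin(rowMeans(d) / 2, 1 - rowMeans(d) / 2)
        act <- seq_len(nrow(d))
        repeat {
            r2 <- cor(t(d[act, , drop = FALSE]))^2; diag(r2) <- 0
            if (max(r2) <= r2Max) return(act)
            w <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
            pair <- act[w]
            victim <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
                else if (maf[pair[2]] < maf[pair[1]]) pair[2] else max(pair)
            act <- setdiff(act, victim)
        }
    }
    expect_identical(kept, oracle(base, 0.5))
    # independent variants all kept
    set.seed(4)
    ind <- matrix(rbinom(8 * 500, 2, 0.5), 8, 500)
    expect_identical(ldPrune(makeGm(ind)), 1:8)
    # determinism
    expect_identical(kept, ldPrune(gm, window = 10, step = 5, r2Max = 0.5))
})

test_that("filters are idempotent and the ledger is conserved", {
    fix <- smallCohort(nVariants = 500, nInd = 40, seed = 81)
    bad <- corruptForQc(fix$cohort, nAmbiguous = 5, nHweViolations = 3,
                        nMissingVariants = 10, missingFraction = 0.3,
                        seed = 2)
    gm <- asGenotypeMatrix(bad)
    for (f in list(removeAmbiguousVariants,
                   function(g) filterHwe(g, 1e-6),
                   function(g) filterMissingness(g, 0.1),
                   function(g) filterMaf(g, 0.01))) {
        once <- f(gm)
        twice <- f(once$genotypes)
        expect_identical(dosage(twice$genotypes), dosage(once$genotypes))
        expect_identical(qcSteps(twice$report)$n_removed[1], 0L)
    }
    res <- qcPipeline(gm, ldPruneStep = TRUE)
    s <- qcSteps(res$report)
    expect_true(all(s$n_before - s$n_removed == s$n_after))
    # chained: each step starts from the previous step's survivors
    vsteps <- s[s$unit == "variant", ]
    expect_identical(vsteps$n_before[-1][1:3], vsteps$n_after[1:3])
    expect_identical(nVariants(res$genotypes),
                     vsteps$n_after[vsteps$step == "maf"])
    # removal order is recorded as applied
    expect_identical(s$step,
                     c("ambiguous_alleles", "biallelic_autosomal", "hwe",
                       "missingness", "heterozygosity", "relatedness", "maf",
                       "ld_prune"))
})
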