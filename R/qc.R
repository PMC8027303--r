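#' @importFrom stats sd cor
NULL

.emptyReport <- function() new("QCReport",
    steps = data.frame(step = character(), unit = character(),
                       n_before = integer(), n_removed = integer(),
                       n_after = integer(), params = character()),
    removed = list())

.addStep <- function(report, step, unit, before, removed, params = "") {
    report@steps <- rbind(report@steps, data.frame(
        step = step, unit = unit, n_before = before,
        n_removed = length(removed), n_after = before - length(removed),
        params = params))
    report@removed <- c(report@removed, stats::setNames(list(removed), step))
    validObject(report)
    report
}

.variantIds <- function(gm) {
    v <- variantRanges(gm)
    paste0(as.character(seqnames(v)), ":", start(v), "_",
           mcols(v)$ref, "/", mcols(v)$alt)
}

.dropVariants <- function(gm, drop) {
    if (!length(drop)) return(gm)
    new("GenotypeMatrix", dosage = gm@dosage[-drop, , drop = FALSE],
        variants = gm@variants[-drop], phased = gm@phased)
}

#' Remove strand-ambiguous variants
#'
#' Drops variants whose ref/alt pair is A/T or G/C (indistinguishable under a
#' strand flip), the first filter applied to each input exome set.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param report optional [QCReport-class] to append to.
#' @return list with elements `genotypes` (filtered matrix) and `report`.
#' @export
removeAmbiguousVariants <- function(gm, report = .emptyReport()) {
    v <- variantRanges(gm)
    ref <- mcols(v)$ref; alt <- mcols(v)$alt
    bad <- !(ref %in% c("A", "C", "G", "T")) | !grepl("^[ACGT](,[ACGT])*$", alt)
    if (any(bad))
        stop("non-ACGT alleles at variants: ",
             paste(utils::head(which(bad), 3), collapse = ", "))
    amb <- which(paste0(pmin(ref, alt), pmax(ref, alt)) %in% c("AT", "CG"))
    report <- .addStep(report, "ambiguous_alleles", "variant", nVariants(gm),
                       .variantIds(gm)[amb])
    list(genotypes = .dropVariants(gm, amb), report = report)
}

#' Keep biallelic autosomal variants
#'
#' Retains variants on chromosomes 1-22 (with or without a "chr" prefix) that
#' carry exactly one alternate allele.
#'
#' @inheritParams removeAmbiguousVariants
#' @param onUnknownChrom `"drop"` (default) or `"fail"` for unparseable
#'   chromosome labels.
#' @return list(genotypes, report).
#' @export
keepBiallelicAutosomal <- function(gm, report = .emptyReport(),
                                   onUnknownChrom = c("drop", "fail")) {
    onUnknownChrom <- match.arg(onUnknownChrom)
    v <- variantRanges(gm)
    chr <- sub("^chr", "", as.character(seqnames(v)))
    auto <- chr %in% as.character(1:22)
    known <- auto | chr %in% c("X", "Y", "MT", "M")
    if (onUnknownChrom == "fail" && any(!known))
        stop("unknown chromosome labels: ",
             paste(unique(chr[!known]), collapse = ", "))
    multi <- grepl(",", mcols(v)$alt)
    drop <- which(!auto | multi)
    report <- .addStep(report, "biallelic_autosomal", "variant", nVariants(gm),
                       .variantIds(gm)[drop])
    list(genotypes = .dropVariants(gm, drop), report = report)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of heterozygote counts whose conditional probability
#' does not exceed that of the observed count.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts (non-negative, sum >= 1).
#' @return p-value in (0, 1]; monomorphic input returns 1.
#' @examples
#' hweExactTest(25, 50, 25)
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
    if (any(c(nHomRef, nHet, nHomAlt) < 0)) stop("counts must be non-negative")
    n <- nHomRef + nHet + nHomAlt
    if (n < 1) stop("at least one genotype required")
    nAlt <- 2 * nHomAlt + nHet
    nMinor <- min(nAlt, 2 * n - nAlt)
    if (nMinor == 0) return(1)
    hs <- seq.int(nMinor %% 2L, nMinor, by = 2L)
    logp <- lgamma(n + 1) - lgamma((nMinor - hs) / 2 + 1) - lgamma(hs + 1) -
        lgamma(n - (nMinor + hs) / 2 + 1) + hs * log(2) +
        lgamma(nMinor + 1) + lgamma(2 * n - nMinor + 1) - lgamma(2 * n + 1)
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    pObs <- pr[match(nHet, hs)]
    min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

#' Filter variants out of Hardy-Weinberg equilibrium
#'
#' @inheritParams removeAmbiguousVariants
#' @param pThreshold exact-test p-value below which a variant is removed
#'   (default 1e-6, conventional exome practice).
#' @return list(genotypes, report).
#' @export
filterHwe <- function(gm, pThreshold = 1e-6, report = .emptyReport()) {
    d <- dosage(gm)
    p <- apply(d, 1L, function(x) {
        x <- x[!is.na(x)]
        if (!length(x)) return(1)
        hweExactTest(sum(x == 0), sum(x == 1), sum(x == 2))
    })
    drop <- which(p < pThreshold)
    report <- .addStep(report, "hwe", "variant", nVariants(gm),
                       .variantIds(gm)[drop], sprintf("p<%g", pThreshold))
    list(genotypes = .dropVariants(gm, drop), report = report)
}

#' Filter variants by missingness
#'
#' Removes variants whose fraction of missing genotypes is strictly greater
#' than `maxMissing`.
#'
#' @inheritParams removeAmbiguousVariants
#' @param maxMissing maximum tolerated missing fraction (default 0.10).
#' @return list(genotypes, report).
#' @export
filterMissingness <- function(gm, maxMissing = 0.10, report = .emptyReport()) {
    frac <- rowMeans(is.na(dosage(gm)))
    drop <- which(frac > maxMissing)
    report <- .addStep(report, "missingness", "variant", nVariants(gm),
                       .variantIds(gm)[drop], sprintf(">%g", maxMissing))
    list(genotypes = .dropVariants(gm, drop), report = report)
}

#' Filter variants by minor allele frequency
#'
#' Removes variants with MAF strictly below `minMaf`, computed on non-missing
#' genotypes.
#'
#' @inheritParams removeAmbiguousVariants
#' @param minMaf minimum MAF retained (default 0.01).
#' @return list(genotypes, report).
#' @export
filterMaf <- function(gm, minMaf = 0.01, report = .emptyReport()) {
    maf <- .mafOf(dosage(gm))
    drop <- which(maf < minMaf)
    report <- .addStep(report, "maf", "variant", nVariants(gm),
                       .variantIds(gm)[drop], sprintf("<%g", minMaf))
    list(genotypes = .dropVariants(gm, drop), report = report)
}

#' Heterozygosity-rate outliers
#'
#' Flags individuals whose heterozygosity rate (heterozygous genotypes over
#' non-missing genotypes) lies strictly outside mean +/- nSd standard
#' deviations; mean and SD are computed once on all individuals. Low rates
#' suggest inbreeding, high rates contamination.
#'
#' @param gm a [GenotypeMatrix-class] with >= 3 individuals.
#' @param nSd number of SDs (default 3).
#' @return character vector of removed individual ids (possibly empty).
#' @export
heterozygosityOutliers <- function(gm, nSd = 3) {
    d <- dosage(gm)
    if (ncol(d) < 3L) stop("need at least 3 individuals")
    rate <- colSums(d == 1, na.rm = TRUE) / colSums(!is.na(d))
    m <- mean(rate); s <- sd(rate)
    ids <- colnames(d) %||% as.character(seq_len(ncol(d)))
    if (is.na(s) || s == 0) {
        if (nSd == 0) return(ids[rate != m])
        return(character())
    }
    ids[rate > m + nSd * s | rate < m - nSd * s]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genomic relatedness matrix
#'
#' GRM of standardised-dosage cross-products: entry (i, j) is the mean over
#' variants of (x_i - 2p)(x_j - 2p) / (2p(1 - p)), with p the sample
#' alternate-allele frequency. Monomorphic variants are excluded; missing
#' genotypes are excluded pairwise. A value of 0.125 approximates third-degree
#' relatedness; duplicates/MZ twins sit near 1.
#'
#' @param gm a MAF-filtered [GenotypeMatrix-class].
#' @return symmetric individuals x individuals numeric matrix.
#' @export
grm <- function(gm) {
    d <- dosage(gm)
    p <- .altFreq(d)
    keep <- which(p > 0 & p < 1)
    d <- d[keep, , drop = FALSE]; p <- p[keep]
    Z <- (d - 2 * p) / sqrt(2 * p * (1 - p))
    M <- !is.na(Z)
    Z[!M] <- 0
    K <- crossprod(Z) / crossprod(M * 1)
    ids <- colnames(dosage(gm)) %||% as.character(seq_len(ncol(dosage(gm))))
    dimnames(K) <- list(ids, ids)
    K
}

#' Greedy unrelated-subset selection
#'
#' Builds the graph of pairs with relatedness strictly above `threshold` and
#' iteratively removes the individual with the highest degree (ties broken by
#' lowest id, i.e. earliest column) until no edge remains, maximising the
#' retained sample size on typical sparse relatedness graphs.
#'
#' @param K symmetric relatedness matrix, as from [grm()].
#' @param threshold relatedness above which a pair is considered related
#'   (default 0.125, approximately third degree).
#' @return character vector of kept individual ids.
#' @export
greedyUnrelatedSubset <- function(K, threshold = 0.125) {
    stopifnot(is.matrix(K), nrow(K) == ncol(K))
    ids <- rownames(K) %||% as.character(seq_len(nrow(K)))
    adj <- K > threshold
    diag(adj) <- FALSE
    alive <- rep(TRUE, nrow(K))
    repeat {
        deg <- rowSums(adj[, alive, drop = FALSE]) * alive
        if (max(deg) == 0) break
        drop <- which.max(deg)      # which.max returns the first (lowest id)
        alive[drop] <- FALSE
        adj[drop, ] <- FALSE; adj[, drop] <- FALSE
    }
    ids[alive]
}

#' Sliding-window LD pruning
#'
#' Within windows of `window` variants advanced by `step`, while any retained
#' pair has squared genotype correlation above `r2Max`, the member of the
#' currently worst pair with the lower MAF is removed (ties: the later
#' position). Missing genotypes are excluded pairwise from the correlation.
#'
#' @param gm a position-sorted [GenotypeMatrix-class].
#' @param window window size in variants (default 50).
#' @param step window shift in variants (default 5).
#' @param r2Max r-squared threshold (default 0.5).
#' @return integer vector of kept variant row indices.
#' @export
ldPrune <- function(gm, window = 50L, step = 5L, r2Max = 0.5) {
    d <- dosage(gm)
    nv <- nrow(d)
    if (nv <= 1L) return(seq_len(nv))
    maf <- .mafOf(d)
    v <- variantRanges(gm)
    sq <- as.character(seqnames(v))
    keep <- rep(TRUE, nv)
    for (chr in unique(sq)) {
        idx <- which(sq == chr)
        startsAt <- seq(1L, max(1L, length(idx) - 1L), by = step)
        for (s in startsAt) {
            win <- idx[s:min(s + window - 1L, length(idx))]
            repeat {
                act <- win[keep[win]]
                if (length(act) < 2L) break
                r2 <- suppressWarnings(
                    cor(t(d[act, , drop = FALSE]),
                        use = "pairwise.complete.obs"))^2
                diag(r2) <- 0
                r2[is.na(r2)] <- 0
                if (max(r2) <= r2Max) break
                w <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
                pair <- act[w]
                victim <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
                    else if (maf[pair[2]] < maf[pair[1]]) pair[2]
                    else max(pair)              # tie: later position
                keep[victim] <- FALSE
            }
            if (s + window - 1L >= length(idx)) break
        }
    }
    which(keep)
}

#' Exome QC pipeline with removal ledger
#'
#' Applies the full filter sequence — ambiguous alleles, biallelic/autosomal,
#' Hardy-Weinberg, missingness, heterozygosity outliers, relatedness (GRM +
#' greedy unrelated subset), MAF, LD pruning — in that order, recording every
#' removal in an ordered [QCReport-class].
#'
#' @param gm a [GenotypeMatrix-class].
#' @param hweP,maxMissing,hetSd,relThreshold,minMaf,ldWindow,ldStep,ldR2
#'   thresholds of the individual filters (see their documentation).
#' @param ldPruneStep logical: run the final LD-pruning step (needed for
#'   population structure, not for local ancestry).
#' @return list with `genotypes` (filtered matrix), `report` (QCReport) and
#'   `keptLdPruned` (indices into the filtered matrix, if pruning was run).
#' @export
qcPipeline <- function(gm, hweP = 1e-6, maxMissing = 0.10, hetSd = 3,
                       relThreshold = 0.125, minMaf = 0.01,
                       ldWindow = 50L, ldStep = 5L, ldR2 = 0.5,
                       ldPruneStep = TRUE) {
    st <- removeAmbiguousVariants(gm)
    st <- keepBiallelicAutosomal(st$genotypes, st$report)
    st <- filterHwe(st$genotypes, hweP, st$report)
    st <- filterMissingness(st$genotypes, maxMissing, st$report)
    gm2 <- st$genotypes; rep2 <- st$report

    hetOut <- heterozygosityOutliers(gm2, hetSd)
    ids <- colnames(dosage(gm2)) %||% as.character(seq_len(ncol(dosage(gm2))))
    rep2 <- .addStep(rep2, "heterozygosity", "individual", length(ids), hetOut,
                     sprintf("+/-%gSD", hetSd))
    keepInd <- setdiff(ids, hetOut)
    gm2@dosage <- gm2@dosage[, match(keepInd, ids), drop = FALSE]

    K <- grm(gm2)
    kept <- greedyUnrelatedSubset(K, relThreshold)
    rel <- setdiff(keepInd, kept)
    rep2 <- .addStep(rep2, "relatedness", "individual", length(keepInd), rel,
                     sprintf(">%g", relThreshold))
    gm2@dosage <- gm2@dosage[, match(kept, keepInd), drop = FALSE]

    st <- filterMaf(gm2, minMaf, rep2)
    gm2 <- st$genotypes; rep2 <- st$report
    keptLd <- NULL
    if (ldPruneStep) {
        keptLd <- ldPrune(gm2, ldWindow, ldStep, ldR2)
        prunedOut <- setdiff(seq_len(nVariants(gm2)), keptLd)
        rep2 <- .addStep(rep2, "ld_prune", "variant", nVariants(gm2),
                         .variantIds(gm2)[prunedOut],
                         sprintf("win=%d,step=%d,r2>%g", ldWindow, ldStep, ldR2))
    }
    list(genotypes = gm2, report = rep2, keptLdPruned = keptLd)
}
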