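#' @importFrom Rcpp sourceCpp
#' @useDynLib admixscan, .registration = TRUE
NULL

.chromCodes <- function(gr) as.integer(factor(as.character(seqnames(gr))))

#' Extended haplotype homozygosity curve
#'
#' EHH at offset x is the probability that two random haplotypes carrying the
#' core allele are identical at every variant from the core out to x:
#' sum over extended-haplotype classes k of C(n_k, 2) / C(n_c, 2). Computed
#' separately in both directions from the core; EHH at the core is 1 by
#' definition.
#'
#' @param panel a [HaplotypePanel-class].
#' @param core variant row index of the core.
#' @param allele core allele (0/1) whose carriers are followed, or `NULL` to
#'   use all haplotypes (as in XP-EHH).
#' @param maxExtendCm one-sided extension cap in cM.
#' @param floorEhh stop extending once EHH falls to or below this level.
#' @return an object of class `"ehhCurve"`: data.frame with signed `offset_cm`
#'   and `ehh`, plus attributes `core`, `allele`, `nCarriers`,
#'   `truncatedLeft`/`truncatedRight`.
#' @export
ehh <- function(panel, core, allele = 1L, maxExtendCm = Inf, floorEhh = 0) {
    A <- alleles(panel)
    v <- variantRanges(panel)
    cM <- mcols(v)$cM
    chr <- .chromCodes(v)
    stopifnot(core >= 1, core <= nrow(A))
    haps <- if (is.null(allele)) seq_len(ncol(A)) else
        which(!is.na(A[core, ]) & A[core, ] == allele)
    n <- length(haps)
    if (n < 2)
        stop(sprintf("EHH undefined: %d carrier(s) of allele %s at core %d",
                     n, as.character(allele), core))
    denom <- n * (n - 1) / 2
    oneSide <- function(dir) {
        grp <- rep(1L, n)
        off <- numeric(); eh <- numeric()
        idx <- core; cur <- 1
        truncated <- TRUE
        repeat {
            idx <- idx + dir
            if (idx < 1 || idx > nrow(A) || chr[idx] != chr[core] ||
                abs(cM[idx] - cM[core]) > maxExtendCm) break
            a <- A[idx, haps]
            a[is.na(a)] <- 2L
            grp <- match(paste(grp, a), unique(paste(grp, a)))
            tab <- tabulate(grp)
            cur <- sum(tab * (tab - 1) / 2) / denom
            off <- c(off, dir * abs(cM[idx] - cM[core]))
            eh <- c(eh, cur)
            if (cur <= floorEhh) { truncated <- FALSE; break }
        }
        list(off = off, ehh = eh, truncated = truncated)
    }
    L <- oneSide(-1L); R <- oneSide(1L)
    curve <- data.frame(offset_cm = c(rev(L$off), 0, R$off),
                        ehh = c(rev(L$ehh), 1, R$ehh))
    structure(curve, class = c("ehhCurve", "data.frame"),
              core = core, allele = allele, nCarriers = n,
              truncatedLeft = L$truncated, truncatedRight = R$truncated)
}

#' Integrated haplotype homozygosity
#'
#' Trapezoidal integral of an EHH curve over genetic distance, outward from
#' the core on each side until the (piecewise-linear) curve crosses `cutoff`;
#' the two sides are summed. Curves still above the cutoff at the data edge
#' are integrated to the edge and flagged truncated.
#'
#' @param curve an `"ehhCurve"` from [ehh()].
#' @param cutoff EHH level terminating the integral (default 0.05).
#' @return numeric iHH in cM, with attribute `truncated`.
#' @export
ihh <- function(curve, cutoff = 0.05) {
    stopifnot(inherits(curve, "ehhCurve"))
    sideIntegral <- function(off, eh) {
        # off increasing distances from core, eh the EHH values; prepend core
        x <- c(0, off); y <- c(1, eh)
        total <- 0
        for (i in seq_along(off)) {
            dx <- x[i + 1] - x[i]
            if (y[i + 1] >= cutoff) {
                total <- total + dx * (y[i] + y[i + 1]) / 2
            } else {
                if (y[i] > cutoff && dx > 0) {
                    f <- (y[i] - cutoff) / (y[i] - y[i + 1])
                    total <- total + dx * f * (y[i] + cutoff) / 2
                }
                return(list(v = total, hit = TRUE))
            }
        }
        list(v = total, hit = FALSE)
    }
    right <- curve$offset_cm > 0
    left <- curve$offset_cm < 0
    R <- sideIntegral(curve$offset_cm[right], curve$ehh[right])
    L <- sideIntegral(-rev(curve$offset_cm[left]), rev(curve$ehh[left]))
    truncated <- (!R$hit && attr(curve, "truncatedRight")) ||
        (!L$hit && attr(curve, "truncatedLeft"))
    structure(R$v + L$v, truncated = truncated)
}

# Bulk iHH via the compiled scanner. partition: -1 all haps, 0/1 carriers.
.ihhScan <- function(panel, cores, haps = seq_len(nHaplotypes(panel)),
                     partition = -1L, cutoff = 0.05, maxExtendCm = 50) {
    v <- variantRanges(panel)
    res <- cpp_ihh(alleles(panel), mcols(v)$cM, .chromCodes(v),
                   as.integer(cores - 1L), as.integer(haps - 1L),
                   as.integer(partition), cutoff, maxExtendCm)
    colnames(res) <- c("ihh", "truncated", "n")
    res
}

# Standardize x within equal-width frequency bins; bins with < minBin values
# get NA. Returns list(std, bin).
.standardizeInBins <- function(x, freq, nBins = 50L, minBin = 2L) {
    bin <- cut(freq, breaks = seq(0, 1, length.out = nBins + 1),
               include.lowest = TRUE)
    std <- rep(NA_real_, length(x))
    for (b in levels(bin)) {
        i <- which(bin == b & is.finite(x))
        if (length(i) >= minBin) {
            s <- sd(x[i])
            if (is.finite(s) && s > 0) std[i] <- (x[i] - mean(x[i])) / s
        }
    }
    list(std = std, bin = bin)
}

#' Integrated haplotype score (iHS)
#'
#' For every variant with both alleles carried by >= 2 haplotypes and minor
#' allele frequency above `mafMin`, computes ln(iHH_ancestral / iHH_derived)
#' and standardises it to mean 0, SD 1 within derived-allele-frequency bins.
#' Without an ancestral-allele table the reference (0) allele is used as the
#' ancestral proxy; this is recorded in the result's `polarity` attribute.
#'
#' @param panel a [HaplotypePanel-class] with a genetic map.
#' @param mafMin minimum MAF scored (default 0.05).
#' @param nBins number of equal-width derived-frequency bins (default 50).
#' @param cutoff,maxExtendCm EHH integration controls, see [ihh()].
#' @param ancestralIsRef logical; TRUE (default) treats the reference allele
#'   as ancestral.
#' @return data.frame with ihhA, ihhD, daf, unstd, std, truncated, skipReason;
#'   attribute `polarity` records the proxy decision.
#' @export
ihs <- function(panel, mafMin = 0.05, nBins = 50L, cutoff = 0.05,
                maxExtendCm = 50, ancestralIsRef = TRUE) {
    A <- alleles(panel)
    nv <- nrow(A)
    p1 <- rowMeans(A == 1L, na.rm = TRUE)   # alt (derived-proxy) frequency
    daf <- if (ancestralIsRef) p1 else 1 - p1
    maf <- pmin(p1, 1 - p1)
    cores <- seq_len(nv)
    anc <- .ihhScan(panel, cores, partition = if (ancestralIsRef) 0L else 1L,
                    cutoff = cutoff, maxExtendCm = maxExtendCm)
    der <- .ihhScan(panel, cores, partition = if (ancestralIsRef) 1L else 0L,
                    cutoff = cutoff, maxExtendCm = maxExtendCm)
    skip <- rep(NA_character_, nv)
    skip[maf < mafMin] <- "maf_below_min"
    skip[is.na(anc[, "ihh"]) | is.na(der[, "ihh"])] <- "fewer_than_2_carriers"
    ok <- is.na(skip) & anc[, "ihh"] > 0 & der[, "ihh"] > 0
    skip[is.na(skip) & !ok] <- "zero_ihh"
    unstd <- rep(NA_real_, nv)
    unstd[ok] <- log(anc[ok, "ihh"] / der[ok, "ihh"])
    std <- .standardizeInBins(unstd, daf, nBins)$std
    structure(data.frame(ihhA = anc[, "ihh"], ihhD = der[, "ihh"], daf = daf,
                         unstd = unstd, std = std,
                         truncated = anc[, "truncated"] | der[, "truncated"],
                         skipReason = skip),
              polarity = if (ancestralIsRef) "reference_as_ancestral" else
                  "alt_as_ancestral")
}

#' Intra-population iHH difference
#'
#' Same machinery as [ihs()] on the difference scale: iHH_derived minus
#' iHH_ancestral, standardised within derived-frequency bins. Its absolute
#' value enters the combined score.
#'
#' @inheritParams ihs
#' @return data.frame as [ihs()] with `unstd` the iHH difference (cM).
#' @export
deltaIhhIntra <- function(panel, mafMin = 0.05, nBins = 50L, cutoff = 0.05,
                          maxExtendCm = 50, ancestralIsRef = TRUE) {
    res <- ihs(panel, mafMin, nBins, cutoff, maxExtendCm, ancestralIsRef)
    res$unstd <- ifelse(is.na(res$skipReason), res$ihhD - res$ihhA, NA_real_)
    res$std <- .standardizeInBins(res$unstd, res$daf, nBins)$std
    res
}

#' Cross-population EHH test (XP-EHH)
#'
#' ln(iHH_A / iHH_B) per variant, with iHH computed over all haplotypes of
#' each population (no allele partition), standardised genome-wide. Positive
#' values indicate longer haplotype homozygosity in population A.
#' Antisymmetric under population swap before standardisation.
#'
#' @param panelA,panelB two [HaplotypePanel-class] objects on the same
#'   variant grid.
#' @inheritParams ihs
#' @return data.frame with ihhA, ihhB, unstd, std, truncated, skipReason.
#' @export
xpehh <- function(panelA, panelB, cutoff = 0.05, maxExtendCm = 50) {
    stopifnot(nVariants(panelA) == nVariants(panelB))
    nv <- nVariants(panelA)
    a <- .ihhScan(panelA, seq_len(nv), cutoff = cutoff,
                  maxExtendCm = maxExtendCm)
    b <- .ihhScan(panelB, seq_len(nv), cutoff = cutoff,
                  maxExtendCm = maxExtendCm)
    skip <- rep(NA_character_, nv)
    ok <- a[, "ihh"] > 0 & b[, "ihh"] > 0 & !is.na(a[, "ihh"]) &
        !is.na(b[, "ihh"])
    skip[!ok] <- "zero_ihh"
    unstd <- rep(NA_real_, nv)
    unstd[ok] <- log(a[ok, "ihh"] / b[ok, "ihh"])
    fin <- is.finite(unstd)
    std <- rep(NA_real_, nv)
    if (sum(fin) >= 2 && sd(unstd[fin]) > 0)
        std[fin] <- (unstd[fin] - mean(unstd[fin])) / sd(unstd[fin])
    data.frame(ihhA = a[, "ihh"], ihhB = b[, "ihh"], unstd = unstd, std = std,
               truncated = a[, "truncated"] | b[, "truncated"],
               skipReason = skip)
}

#' Cross-population iHH difference
#'
#' iHH_A minus iHH_B per variant over all haplotypes of each population
#' (`mode = "all"`, the default reading), or restricted to derived-allele
#' carriers in each population (`mode = "derived"`), standardised genome-wide.
#'
#' @inheritParams xpehh
#' @param mode `"all"` (whole-sample iHH) or `"derived"` (derived carriers
#'   only, reference allele as ancestral proxy).
#' @return data.frame with ihhA, ihhB, unstd, std, truncated, skipReason.
#' @export
deltaIhhCross <- function(panelA, panelB, cutoff = 0.05, maxExtendCm = 50,
                          mode = c("all", "derived")) {
    mode <- match.arg(mode)
    stopifnot(nVariants(panelA) == nVariants(panelB))
    nv <- nVariants(panelA)
    part <- if (mode == "all") -1L else 1L
    a <- .ihhScan(panelA, seq_len(nv), partition = part, cutoff = cutoff,
                  maxExtendCm = maxExtendCm)
    b <- .ihhScan(panelB, seq_len(nv), partition = part, cutoff = cutoff,
                  maxExtendCm = maxExtendCm)
    skip <- rep(NA_character_, nv)
    ok <- !is.na(a[, "ihh"]) & !is.na(b[, "ihh"])
    skip[!ok] <- "fewer_than_2_carriers"
    unstd <- rep(NA_real_, nv)
    unstd[ok] <- a[ok, "ihh"] - b[ok, "ihh"]
    std <- rep(NA_real_, nv)
    fin <- is.finite(unstd)
    if (sum(fin) >= 2 && sd(unstd[fin]) > 0)
        std[fin] <- (unstd[fin] - mean(unstd[fin])) / sd(unstd[fin])
    data.frame(ihhA = a[, "ihh"], ihhB = b[, "ihh"], unstd = unstd, std = std,
               truncated = a[, "truncated"] | b[, "truncated"],
               skipReason = skip)
}

#' Hudson's Fst estimator
#'
#' Per-variant numerator and denominator of Hudson's two-population Fst with
#' sample-size correction, plus the ratio-of-averages combination (sum of
#' numerators over sum of denominators), which is nearly unbiased and the
#' recommended way to average Fst across variants.
#'
#' @param p1,p2 allele frequencies per variant in each population.
#' @param n1,n2 haplotype counts (>= 2) per population (scalar or per-variant).
#' @return list with `num`, `den`, per-variant `ratio` (NA where the
#'   denominator is 0) and `ratioOfAverages`.
#' @examples
#' hudsonFst(0, 2, 1, 2)$ratio  # fixed difference: Fst = 1
#' @export
hudsonFst <- function(p1, n1, p2, n2) {
    stopifnot(all(p1 >= 0 & p1 <= 1, na.rm = TRUE),
              all(p2 >= 0 & p2 <= 1, na.rm = TRUE),
              all(n1 >= 2, na.rm = TRUE), all(n2 >= 2, na.rm = TRUE))
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    ratio <- ifelse(den > 0, num / den, NA_real_)
    ok <- den > 0 & !is.na(den) & !is.na(num)
    list(num = num, den = den, ratio = ratio,
         ratioOfAverages = sum(num[ok]) / sum(den[ok]))
}

#' Genome-wide Hudson Fst between two haplotype panels
#'
#' @param panelA,panelB two [HaplotypePanel-class] objects on one variant grid.
#' @return as [hudsonFst()].
#' @export
hudsonFstPanels <- function(panelA, panelB) {
    stopifnot(nVariants(panelA) == nVariants(panelB))
    a <- alleles(panelA); b <- alleles(panelB)
    hudsonFst(rowMeans(a == 1L, na.rm = TRUE), rowSums(!is.na(a)),
              rowMeans(b == 1L, na.rm = TRUE), rowSums(!is.na(b)))
}

#' Population branch statistic
#'
#' PBS isolates the focal population's branch on a three-population tree:
#' with T = -ln(1 - Fst), PBS = (T_focal,ref1 + T_focal,ref2 - T_ref1,ref2)/2.
#' Fst values at or above 1 are clamped to 1 - 1e-9 and flagged.
#'
#' @param fstFocalRef1,fstFocalRef2,fstRef1Ref2 per-variant Fst values.
#' @param floorNegative floor negative PBS at 0 (default FALSE: report raw).
#' @return numeric vector of PBS values with attribute `clamped` (indices).
#' @examples
#' pbs(0.1, 0.1, 0.1)  # -log(0.9)/2
#' @export
pbs <- function(fstFocalRef1, fstFocalRef2, fstRef1Ref2,
                floorNegative = FALSE) {
    cl <- function(f) pmin(f, 1 - 1e-9)
    clamped <- which(fstFocalRef1 >= 1 | fstFocalRef2 >= 1 | fstRef1Ref2 >= 1)
    tt <- function(f) -log(1 - cl(f))
    out <- (tt(fstFocalRef1) + tt(fstFocalRef2) - tt(fstRef1Ref2)) / 2
    if (floorNegative) out <- pmax(out, 0)
    structure(out, clamped = clamped)
}

#' Rank-based empirical p-values
#'
#' p_i = (rank of value_i counted from the extreme tail) / (n + 1), with
#' average ranks for ties, so p lies strictly in (0, 1). The most extreme of
#' 999 values gets p = 1/1000.
#'
#' @param x statistic values (NA allowed, returned as NA).
#' @param tail `"upper"` (large = extreme, default) or `"lower"`.
#' @return numeric vector of p-values.
#' @export
empiricalPvalues <- function(x, tail = c("upper", "lower")) {
    tail <- match.arg(tail)
    fin <- is.finite(x)
    n <- sum(fin)
    if (n < 100)
        warning("fewer than 100 finite values; empirical p-values are coarse")
    out <- rep(NA_real_, length(x))
    if (n == 0) return(out)
    xf <- x[fin]
    if (length(unique(xf)) == 1L)
        warning("all values identical; empirical p-values are all 0.5")
    r <- rank(if (tail == "upper") -xf else xf, ties.method = "average")
    out[fin] <- r / (n + 1)
    out
}

#' Fisher combined score
#'
#' FCS = -2 * sum(ln p) over the per-statistic empirical p-values available at
#' a variant. Missing statistics are allowed; the per-variant count k is
#' returned so it can be logged.
#'
#' @param pmat numeric matrix, variants x statistics, p in (0, 1]; NA allowed.
#' @return data.frame with `fcs` and `k` (statistics used per variant); fcs is
#'   NA where no statistic is available.
#' @export
fisherCombinedScore <- function(pmat) {
    pmat <- as.matrix(pmat)
    if (any(pmat <= 0, na.rm = TRUE))
        stop("p-values must be strictly positive")
    if (any(pmat > 1, na.rm = TRUE))
        stop("p-values must not exceed 1")
    k <- rowSums(!is.na(pmat))
    fcs <- -2 * rowSums(log(pmat), na.rm = TRUE)
    fcs[k == 0] <- NA_real_
    data.frame(fcs = fcs, k = k)
}

#' Block-based outlier calling
#'
#' Flags as outliers the variants whose FCS is strictly greater than the
#' `outlierQ` quantile of all FCS values, splits each chromosome into
#' consecutive blocks of `blockSize` variants (final partial block kept and
#' flagged), and selects the blocks whose outlier fraction is strictly greater
#' than the `blockQ` quantile of all block fractions. Selected regions are the
#' min-max bp span of a block's member variants.
#'
#' @param fcs per-variant FCS values (NA allowed, never outliers).
#' @param gr GRanges of the variants (position-sorted within chromosome).
#' @param outlierQ FCS quantile defining outliers (default 0.99).
#' @param blockSize variants per block (default 100).
#' @param blockQ block-fraction quantile defining selection (default 0.995).
#' @return list with `isOutlier` (per variant), `blocks` (data.frame: chrom,
#'   block, start, end, n, nOutliers, fraction, partial, selected),
#'   `fcsThreshold` and `fractionThreshold`.
#' @export
outlierBlocks <- function(fcs, gr, outlierQ = 0.99, blockSize = 100L,
                          blockQ = 0.995) {
    stopifnot(length(fcs) == length(gr))
    thr <- stats::quantile(fcs, outlierQ, na.rm = TRUE, names = FALSE)
    isOut <- !is.na(fcs) & fcs > thr
    sq <- as.character(seqnames(gr))
    pos <- start(gr)
    rows <- list()
    for (chr in unique(sq)) {
        idx <- which(sq == chr)
        nb <- ceiling(length(idx) / blockSize)
        bid <- rep(seq_len(nb), each = blockSize)[seq_along(idx)]
        for (b in seq_len(nb)) {
            vi <- idx[bid == b]
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = chr, block = b,
                start = min(pos[vi]), end = max(pos[vi]),
                n = length(vi), nOutliers = sum(isOut[vi]),
                fraction = mean(isOut[vi]),
                partial = length(vi) < blockSize)
        }
    }
    blocks <- do.call(rbind, rows)
    fthr <- stats::quantile(blocks$fraction, blockQ, names = FALSE)
    blocks$selected <- blocks$fraction > fthr
    list(isOutlier = isOut, blocks = blocks, fcsThreshold = thr,
         fractionThreshold = fthr)
}

#' Run the full five-statistic selection scan
#'
#' Computes |iHS|, intra-population |delta-iHH|, XP-EHH, cross-population
#' |delta-iHH| and PBS for the focal panel against two reference panels,
#' converts each to one-sided empirical p-values (extreme = putatively
#' selected direction), combines them into the Fisher combined score with
#' per-variant adjustment for missing statistics, and calls outlier blocks.
#'
#' @param focal focal-population [HaplotypePanel-class].
#' @param refPanels named list of two reference [HaplotypePanel-class] objects
#'   on the same variant grid.
#' @param mafMin,nBins,cutoff,maxExtendCm statistic controls, see [ihs()].
#' @param outlierQ,blockSize,blockQ outlier-block controls, see
#'   [outlierBlocks()].
#' @param crossMode `"all"` or `"derived"`, see [deltaIhhCross()].
#' @param ancestralIsRef reference-allele-as-ancestral proxy flag.
#' @return object of class `"scanResult"`: list with `table` (per-variant
#'   ScanTable data.frame), `blocks`, `thresholds` and `manifest` (the
#'   decisions and parameters used).
#' @export
runScan <- function(focal, refPanels, mafMin = 0.05, nBins = 50L,
                    cutoff = 0.05, maxExtendCm = 50, outlierQ = 0.99,
                    blockSize = 100L, blockQ = 0.995,
                    crossMode = c("all", "derived"), ancestralIsRef = TRUE) {
    crossMode <- match.arg(crossMode)
    stopifnot(length(refPanels) >= 2L)
    ref1 <- refPanels[[1]]; ref2 <- refPanels[[2]]
    si <- ihs(focal, mafMin, nBins, cutoff, maxExtendCm, ancestralIsRef)
    # delta-iHH reuses the allele-partitioned scans already done for iHS
    sd_ <- si
    sd_$unstd <- ifelse(is.na(si$skipReason), si$ihhD - si$ihhA, NA_real_)
    sd_$std <- .standardizeInBins(sd_$unstd, sd_$daf, nBins)$std
    sx <- xpehh(focal, ref1, cutoff, maxExtendCm)
    sc <- if (crossMode == "all") {
        # whole-sample iHH difference shares the XP-EHH scans
        ok <- !is.na(sx$ihhA) & !is.na(sx$ihhB)
        un <- ifelse(ok, sx$ihhA - sx$ihhB, NA_real_)
        stn <- rep(NA_real_, length(un))
        fin <- is.finite(un)
        if (sum(fin) >= 2 && sd(un[fin]) > 0)
            stn[fin] <- (un[fin] - mean(un[fin])) / sd(un[fin])
        data.frame(ihhA = sx$ihhA, ihhB = sx$ihhB, unstd = un, std = stn,
                   truncated = sx$truncated,
                   skipReason = ifelse(ok, NA_character_,
                                       "fewer_than_2_carriers"))
    } else deltaIhhCross(focal, ref1, cutoff, maxExtendCm, mode = crossMode)
    f1 <- hudsonFstPanels(focal, ref1)
    f2 <- hudsonFstPanels(focal, ref2)
    f12 <- hudsonFstPanels(ref1, ref2)
    spbs <- pbs(f1$ratio, f2$ratio, f12$ratio)
    pm <- cbind(
        ihs = empiricalPvalues(abs(si$std)),
        delta_ihh = empiricalPvalues(abs(sd_$std)),
        xpehh = empiricalPvalues(sx$std),
        delta_ihh_cross = empiricalPvalues(abs(sc$std)),
        pbs = empiricalPvalues(as.numeric(spbs)))
    fc <- fisherCombinedScore(pm)
    gr <- variantRanges(focal)
    ob <- outlierBlocks(fc$fcs, gr, outlierQ, blockSize, blockQ)
    tab <- data.frame(
        chrom = as.character(seqnames(gr)), pos = start(gr),
        ihs = si$std, delta_ihh = sd_$std, xpehh = sx$std,
        delta_ihh_cross = sc$std, pbs = as.numeric(spbs),
        p_ihs = pm[, "ihs"], p_delta_ihh = pm[, "delta_ihh"],
        p_xpehh = pm[, "xpehh"], p_delta_ihh_cross = pm[, "delta_ihh_cross"],
        p_pbs = pm[, "pbs"], fcs = fc$fcs, k = fc$k,
        is_outlier = ob$isOutlier)
    structure(list(table = tab, blocks = ob$blocks,
                   thresholds = list(fcs = ob$fcsThreshold,
                                     fraction = ob$fractionThreshold),
                   manifest = list(
                       statistics = colnames(pm),
                       polarity = attr(si, "polarity"),
                       cross_delta_ihh_mode = crossMode,
                       mafMin = mafMin, nBins = nBins, cutoff = cutoff,
                       maxExtendCm = maxExtendCm, outlierQ = outlierQ,
                       blockSize = blockSize, blockQ = blockQ,
                       per_variant_k_adjustment = TRUE)),
              class = "scanResult")
}

#' @export
print.scanResult <- function(x, ...) {
    cat(sprintf("scanResult: %d variants, %d blocks (%d selected)\n",
                nrow(x$table), nrow(x$blocks), sum(x$blocks$selected)))
    invisible(x)
}
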