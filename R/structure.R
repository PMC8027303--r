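#' Principal component analysis of genotypes
#'
#' Genotypes are mean-centred and scaled by sqrt(2p(1-p)) (the expected
#' binomial SD under Hardy-Weinberg), missing entries imputed to the mean,
#' and the top-k eigenvectors of the individual-by-individual covariance
#' extracted. Monomorphic variants are dropped.
#'
#' @param gm an LD-pruned, MAF-filtered [GenotypeMatrix-class].
#' @param k number of components (warns and truncates if above the rank).
#' @return object of class `"pcaResult"`: list with `coordinates`
#'   (individuals x k, eigenvector * sqrt(eigenvalue)), `explained`
#'   (fraction of variance per component, non-increasing) and `eigenvalues`.
#' @export
pcaGenotypes <- function(gm, k = 10L) {
    d <- dosage(gm)
    stopifnot(k >= 1)
    p <- .altFreq(d)
    keep <- which(p > 0 & p < 1 & !is.na(p))
    d <- d[keep, , drop = FALSE]; p <- p[keep]
    Z <- (d - 2 * p) / sqrt(2 * p * (1 - p))
    Z[is.na(Z)] <- 0
    C <- crossprod(Z) / nrow(Z)
    e <- eigen(C, symmetric = TRUE)
    tol <- max(e$values) * 1e-9
    avail <- sum(e$values > tol)
    if (k > avail) {
        warning(sprintf("only %d informative components available; k reduced",
                        avail))
        k <- max(1L, avail)
    }
    vals <- pmax(e$values, 0)
    coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
        diag(sqrt(vals[seq_len(k)]), k)
    ids <- colnames(dosage(gm)) %||% as.character(seq_len(ncol(dosage(gm))))
    dimnames(coords) <- list(ids, paste0("PC", seq_len(k)))
    structure(list(coordinates = coords,
                   explained = vals[seq_len(k)] / sum(vals),
                   eigenvalues = vals[seq_len(k)]),
              class = "pcaResult")
}

#' @export
print.pcaResult <- function(x, ...) {
    cat(sprintf("pcaResult: %d individuals, %d components (%.1f%% in PC1)\n",
                nrow(x$coordinates), ncol(x$coordinates),
                100 * x$explained[1]))
    invisible(x)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Two-level AMOVA on squared Euclidean dosage distances: the total sum of
#' squares is decomposed into among-group and within-group components via the
#' moment estimators (sigma2_within = MS_within; sigma2_among =
#' (MS_among - MS_within) / n0), phi = among / (among + within), with a
#' permutation p-value from random relabelling of group membership using the
#' add-one estimator. A random subset of `nSnps` variants is used, as is
#' standard for genome-wide AMOVA. Missing genotypes are excluded pairwise
#' (distances rescaled proportionally). A negative among-group component is
#' floored at zero, so phi = 0 exactly for indistinguishable groups.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param groups group label per individual (>= 2 groups of >= 2).
#' @param nSnps number of random variants used (default 10000; all if fewer
#'   available, with a warning).
#' @param nPermutations label permutations (default 999).
#' @param seed RNG seed for the SNP subsample and permutations.
#' @return object of class `"amovaResult"`: list with sigma2_among,
#'   sigma2_within, phi, pct_among, pct_within, p_perm, n_permutations, nSnps.
#' @export
amova <- function(gm, groups, nSnps = 10000L, nPermutations = 999L, seed = 1L) {
    d <- dosage(gm)
    stopifnot(length(groups) == ncol(d))
    groups <- as.character(groups)
    tab <- table(groups)
    if (length(tab) < 2L) stop("need at least 2 groups")
    if (any(tab < 2L)) stop("every group needs at least 2 individuals")
    if (nSnps > nrow(d)) {
        warning(sprintf("nSnps (%d) exceeds available variants (%d); using all",
                        nSnps, nrow(d)))
        nSnps <- nrow(d)
    }
    .withSeed(seed, {
        sub <- sort(sample.int(nrow(d), nSnps))
        D2 <- as.matrix(stats::dist(t(d[sub, , drop = FALSE])))^2
        N <- ncol(d)
        phiOf <- function(g) {
            ssTot <- sum(D2[upper.tri(D2)]) / N
            ssW <- 0
            for (lev in unique(g)) {
                i <- which(g == lev)
                ssW <- ssW + sum(D2[i, i][upper.tri(D2[i, i])]) / length(i)
            }
            ssA <- ssTot - ssW
            G <- length(unique(g))
            ng <- as.numeric(table(g))
            msA <- ssA / (G - 1)
            msW <- ssW / (N - G)
            n0 <- (N - sum(ng^2) / N) / (G - 1)
            s2w <- msW
            s2a <- max(0, (msA - msW) / n0)
            c(s2a = s2a, s2w = s2w,
              phi = if (s2a + s2w > 0) s2a / (s2a + s2w) else 0)
        }
        obs <- phiOf(groups)
        exceed <- 0L
        for (b in seq_len(nPermutations)) {
            if (phiOf(sample(groups))["phi"] >= obs["phi"]) exceed <- exceed + 1L
        }
        structure(list(sigma2_among = unname(obs["s2a"]),
                       sigma2_within = unname(obs["s2w"]),
                       phi = unname(obs["phi"]),
                       pct_among = unname(100 * obs["s2a"] /
                                          (obs["s2a"] + obs["s2w"])),
                       pct_within = unname(100 * obs["s2w"] /
                                           (obs["s2a"] + obs["s2w"])),
                       p_perm = (1 + exceed) / (1 + nPermutations),
                       n_permutations = nPermutations, nSnps = nSnps),
                  class = "amovaResult")
    })
}

#' @export
print.amovaResult <- function(x, ...) {
    cat(sprintf(paste0("AMOVA: %.2f%% among / %.2f%% within groups ",
                       "(phi = %.4f, p = %.4g, %d SNPs, %d permutations)\n"),
                x$pct_among, x$pct_within, x$phi, x$p_perm, x$nSnps,
                x$n_permutations))
    invisible(x)
}

#' @importFrom mclust Mclust mclustBIC
NULL

#' Inversion-karyotype clustering
#'
#' Emulates invClust-style inversion inference: the first MDS axis of the
#' region's genotypes is fit with a one-dimensional k-component Gaussian
#' mixture (EM, model-based hierarchical initialisation); components ordered
#' by mean give the karyotype dosage 0/1/2 by maximum posterior. Which
#' extreme cluster is "inverted" is arbitrary without an external anchor;
#' calls are comparable across call sets only via [callsetAgreement()].
#'
#' @param gmRegion a [GenotypeMatrix-class] restricted to the inversion
#'   region (>= 10 variants).
#' @param k number of karyotype clusters (default 3).
#'
#' Degeneracy is judged by BIC: if a single-component fit beats the
#' k-component fit, the axis carries no karyotype structure, the result is
#' flagged degenerate and all calls collapse to the majority component.
#' @return object of class `"inversionCalls"`: list with `karyotype` (named
#'   0/1/2 per individual), `clusterMeans` (ordered), `posterior`,
#'   `degenerate` flag and `axis` (the MDS coordinates).
#' @export
inversionCluster <- function(gmRegion, k = 3L) {
    d <- dosage(gmRegion)
    if (nrow(d) < 10L) stop("inversion region needs at least 10 variants")
    dd <- stats::dist(t(apply(d, 2, function(x) {
        x[is.na(x)] <- mean(x, na.rm = TRUE); x
    })))
    axis <- stats::cmdscale(dd, k = 1)[, 1]
    if (length(unique(round(axis, 12))) < k)
        stop("fewer distinct coordinates than clusters")
    fit <- Mclust(axis, G = k, modelNames = c("E", "V"), verbose = FALSE)
    if (is.null(fit)) stop("mixture fit failed")
    fit1 <- Mclust(axis, G = 1, verbose = FALSE)
    ord <- order(fit$parameters$mean)
    means <- fit$parameters$mean[ord]
    degenerate <- !is.null(fit1) && fit1$bic >= fit$bic
    post <- fit$z[, ord, drop = FALSE]
    colnames(post) <- as.character(seq_len(k) - 1L)
    ids <- colnames(d) %||% as.character(seq_len(ncol(d)))
    rownames(post) <- ids
    kar <- max.col(post) - 1L
    if (degenerate) kar <- rep(as.integer(names(which.max(table(kar)))),
                               length(kar))
    names(kar) <- ids
    structure(list(karyotype = kar, clusterMeans = unname(means),
                   posterior = post, degenerate = degenerate, axis = axis),
              class = "inversionCalls")
}

#' @export
print.inversionCalls <- function(x, ...) {
    cat("inversionCalls:", length(x$karyotype), "individuals; counts:\n")
    print(table(karyotype = x$karyotype))
    if (x$degenerate) cat("  (degenerate fit: calls collapsed)\n")
    invisible(x)
}

#' Agreement between two karyotype call sets
#'
#' Fraction of individuals with identical calls; both sets must cover the
#' same individual ids.
#'
#' @param callsA,callsB `"inversionCalls"` objects or named vectors of calls.
#' @return matched fraction in [0, 1].
#' @export
callsetAgreement <- function(callsA, callsB) {
    a <- if (inherits(callsA, "inversionCalls")) callsA$karyotype else callsA
    b <- if (inherits(callsB, "inversionCalls")) callsB$karyotype else callsB
    if (is.null(names(a)) || is.null(names(b)))
        stop("calls must be named by individual id")
    miss <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    if (length(miss))
        stop("individual ids missing from one call set: ",
             paste(unique(miss), collapse = ", "))
    mean(a == b[names(a)])
}
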