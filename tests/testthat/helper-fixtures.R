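# In-code fixtures and independent oracles shared across the suite.

# --- tiny container builders -------------------------------------------------

makeVariantsGr <- function(pos, chrom = "1", ref = NULL, alt = NULL,
                           cM = pos / 1e6) {
    n <- length(pos)
    if (is.null(ref)) ref <- rep("A", n)
    if (is.null(alt)) alt <- rep("G", n)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    S4Vectors::mcols(gr)$ref <- ref
    S4Vectors::mcols(gr)$alt <- alt
    S4Vectors::mcols(gr)$cM <- cM
    gr
}

makePanel <- function(alleles, pos = seq_len(nrow(alleles)) * 1000,
                      chrom = "1", cM = pos / 1e6) {
    new("HaplotypePanel", alleles = alleles,
        variants = makeVariantsGr(pos, chrom, cM = cM),
        haplotypeIds = paste0("h", seq_len(ncol(alleles))))
}

makeGm <- function(dosage, pos = seq_len(nrow(dosage)) * 1000, chrom = "1",
                   ref = NULL, alt = NULL) {
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("I", seq_len(ncol(dosage)))
    new("GenotypeMatrix", dosage = dosage,
        variants = makeVariantsGr(pos, chrom, ref = ref, alt = alt),
        phased = FALSE)
}

makeCalls <- function(labels, pos = seq_len(nrow(labels)) * 1000,
                      chrom = "1", alphabet = c("EUR", "AFR", "NAT")) {
    ids <- paste0("S", rep(seq_len(ncol(labels) / 2), each = 2), "_",
                  rep(1:2, ncol(labels) / 2))
    new("AncestryCalls", labels = labels,
        variants = makeVariantsGr(pos, chrom),
        haplotypeIds = ids, alphabet = alphabet)
}

smallCohort <- function(nVariants = 600, nInd = 25, seed = 5,
                        proportions = c(EUR = 0.746, AFR = 0.160, NAT = 0.094),
                        nHap = 60, generations = 16) {
    m <- ancestralModel(pops = names(proportions), nHaplotypes = nHap)
    panels <- generateAncestralPanels(m, nVariants, seed = seed)
    co <- simulateAdmixedCohort(panels,
        admixtureModel(proportions, generations, nInd), seed = seed + 1)
    list(panels = panels, cohort = co)
}

# --- independent oracles -----------------------------------------------------

# HWE exact distribution by explicit enumeration of minor-allele placements:
# choose which of the 2n allele slots carry the minor allele, pair slots
# (1,2), (3,4), ... into diploids, and tabulate heterozygote counts.
hweEnumerationOracle <- function(nHomRef, nHet, nHomAlt) {
    n <- nHomRef + nHet + nHomAlt
    nAlt <- 2 * nHomAlt + nHet
    nMinor <- min(nAlt, 2 * n - nAlt)
    if (nMinor == 0) return(1)
    slots <- combn(2 * n, nMinor)
    hetOf <- apply(slots, 2, function(s) {
        carrier <- rep(FALSE, 2 * n)
        carrier[s] <- TRUE
        sum(xor(carrier[seq(1, 2 * n, 2)], carrier[seq(2, 2 * n, 2)]))
    })
    tab <- table(hetOf) / ncol(slots)
    pObs <- tab[as.character(nHet)]
    sum(tab[tab <= pObs * (1 + 1e-12)])
}

# EHH by explicit pair enumeration: fraction of carrier pairs identical at
# every variant between the core and idx (inclusive).
ehhPairOracle <- function(A, core, idx, haps) {
    pairs <- combn(haps, 2)
    span <- min(core, idx):max(core, idx)
    span <- setdiff(span, core)
    if (!length(span)) return(1)
    mean(apply(pairs, 2, function(p) {
        a <- A[span, p[1]]; b <- A[span, p[2]]
        all((is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b))
    }))
}

# iHH oracle: build the EHH curve by pair enumeration at every site, then
# integrate the piecewise-linear curve on a dense grid, stopping at the
# interpolated cutoff crossing on each side.
ihhGridOracle <- function(A, cM, core, haps, cutoff = 0.05,
                          gridN = 20001) {
    oneSide <- function(dir) {
        idx <- core
        xs <- 0; ys <- 1
        repeat {
            idx <- idx + dir
            if (idx < 1 || idx > nrow(A)) break
            xs <- c(xs, abs(cM[idx] - cM[core]))
            ys <- c(ys, ehhPairOracle(A, core, idx, haps))
        }
        if (length(xs) == 1) return(0)
        # dense grid including the curve's knots, so the trapezoid rule is
        # exact on the piecewise-linear curve
        g <- sort(unique(c(seq(0, max(xs), length.out = gridN), xs)))
        e <- approx(xs, ys, xout = g)$y
        below <- which(e < cutoff)
        if (length(below)) {
            stopAt <- below[1]
            # exact crossing point on the linear segment
            x0 <- g[stopAt - 1]; y0 <- e[stopAt - 1]
            x1 <- g[stopAt]; y1 <- e[stopAt]
            xc <- x0 + (y0 - cutoff) / (y0 - y1) * (x1 - x0)
            g <- c(g[1:(stopAt - 1)], xc)
            e <- c(e[1:(stopAt - 1)], cutoff)
        }
        sum(diff(g) * (head(e, -1) + tail(e, -1)) / 2)
    }
    oneSide(1) + oneSide(-1)
}

# Fisher exact two-sided p by full enumeration over tables with fixed margins.
fisherEnumerationOracle <- function(m) {
    r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
    c1 <- sum(m[, 1])
    lo <- max(0, c1 - r2); hi <- min(r1, c1)
    probs <- vapply(lo:hi, function(a)
        exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)),
        numeric(1))
    pObs <- probs[m[1, 1] - lo + 1]
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Maximum independent set size by exhaustive subset enumeration (n <= 12).
misSizeOracle <- function(adj) {
    n <- nrow(adj)
    best <- 0
    for (code in 0:(2^n - 1)) {
        s <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
        if (length(s) <= best) next
        if (all(!adj[s, s][upper.tri(adj[s, s, drop = FALSE])]))
            best <- length(s)
    }
    best
}

# Build an AF table engineered to a known cross-classification composition.
# nCells: c(commonRef_commonStudy, commonRef_rareStudy, rareRef_commonStudy,
# rareRef_rareStudy); nExclusive split into common/rare.
makeAfFixture <- function(nCells = c(69, 3, 44, 239),
                          nExclusiveCommon = 9, nExclusiveRare = 80) {
    mk <- function(n, study, ref) {
        if (n == 0) return(NULL)
        data.frame(study = rep(study, n), gnomad = rep(ref, n),
                   kgp = rep(NA_real_, n))
    }
    df <- rbind(mk(nCells[1], 0.05, 0.05),   # common/common
                mk(nCells[2], 0.005, 0.05),  # ref common, study rare
                mk(nCells[3], 0.05, 0.002),  # ref rare, study common
                mk(nCells[4], 0.004, 0.003), # rare/rare
                mk(nExclusiveCommon, 0.02, NA_real_),
                mk(nExclusiveRare, 0.004, NA_real_))
    df$variant_id <- sprintf("v%03d", seq_len(nrow(df)))
    df[, c("variant_id", "study", "gnomad", "kgp")]
}

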