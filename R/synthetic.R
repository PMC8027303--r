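#' Ancestral-population model
#'
#' Parameters of the Balding-Nichols model used to generate diverged ancestral
#' reference panels: each population's allele frequency at a variant is drawn
#' from a Beta distribution with mean equal to the ancestral frequency p and
#' variance p(1-p)F, where F is that population's divergence from the
#' ancestral pool.
#'
#' @param pops character vector of population names (default EUR/AFR/NAT-like).
#' @param fst per-population divergence F, each in [0, 1).
#' @param afRange interval within (0, 1) from which ancestral frequencies are
#'   drawn uniformly.
#' @param nHaplotypes haplotypes simulated per population (>= 2).
#' @return a validated list of class `"ancestralModel"`.
#' @examples
#' ancestralModel(fst = c(EUR = 0.15, AFR = 0.15, NAT = 0.25))
#' @export
ancestralModel <- function(pops = c("EUR", "AFR", "NAT"),
                           fst = stats::setNames(rep(0.15, length(pops)), pops),
                           afRange = c(0.05, 0.95),
                           nHaplotypes = 100L) {
    stopifnot(length(pops) >= 1L, length(fst) == length(pops))
    if (any(fst < 0 | fst >= 1))
        stop("fst values must lie in [0, 1); F = 1 is a degenerate Beta")
    if (afRange[1] <= 0 || afRange[2] >= 1 || afRange[1] > afRange[2])
        stop("afRange must be an interval within (0, 1)")
    if (nHaplotypes < 2L)
        stop("nHaplotypes must be at least 2 per population")
    structure(list(pops = pops, fst = stats::setNames(as.numeric(fst), pops),
                   afRange = as.numeric(afRange),
                   nHaplotypes = as.integer(nHaplotypes)),
              class = "ancestralModel")
}

#' Admixture model
#'
#' Describes a single-pulse admixture event: ancestry proportions, the age of
#' the event in generations (which sets the exponential tract-length scale),
#' and the cohort size.
#'
#' @param proportions named numeric vector of ancestry fractions summing to 1;
#'   names must match the ancestral panels. Default is the genome-wide
#'   EUR/AFR/NAT composition typical of southeastern Brazilian cohorts.
#' @param generations admixture age g in generations (>= 1); breakpoints occur
#'   as a Poisson process with rate g per morgan.
#' @param nIndividuals diploid individuals to simulate.
#' @return a validated list of class `"admixtureModel"`.
#' @examples
#' admixtureModel()
#' @export
admixtureModel <- function(proportions = c(EUR = 0.746, AFR = 0.160, NAT = 0.094),
                           generations = 16, nIndividuals = 100L) {
    if (abs(sum(proportions) - 1) > 1e-9)
        stop("proportions must sum to 1")
    if (is.null(names(proportions)))
        stop("proportions must be named by ancestry")
    if (generations < 1) stop("generations must be >= 1")
    structure(list(proportions = proportions,
                   generations = as.numeric(generations),
                   nIndividuals = as.integer(nIndividuals)),
              class = "admixtureModel")
}

#' Simulate exome-like variant positions
#'
#' Draws variant positions clustered into "gene" windows to emulate the sparse,
#' clumped site density of exome data, with a uniform genetic map.
#'
#' @param nVariants number of variants.
#' @param chrom chromosome name.
#' @param chromLengthBp chromosome length in bp.
#' @param geneSpanBp width of each gene window in bp.
#' @param variantsPerGene average variants per gene window.
#' @param cmPerMb uniform recombination rate (centimorgans per megabase).
#' @param seed RNG seed.
#' @return GRanges with `ref`, `alt` and `cM` metadata.
#' @export
simulateExomePositions <- function(nVariants, chrom = "1",
                                   chromLengthBp = 2e8, geneSpanBp = 2e4,
                                   variantsPerGene = 25, cmPerMb = 1,
                                   seed = 1L) {
    stopifnot(nVariants >= 1)
    .withSeed(seed, {
        nGenes <- max(1L, ceiling(nVariants / variantsPerGene))
        starts <- sort(sample.int(max(1, chromLengthBp - geneSpanBp), nGenes,
                                  replace = nGenes > chromLengthBp - geneSpanBp))
        gene <- sample.int(nGenes, nVariants, replace = TRUE)
        pos <- starts[gene] + sample.int(geneSpanBp, nVariants, replace = TRUE)
        pos <- sort(unique(pos))
        while (length(pos) < nVariants) {   # top up collisions
            extra <- starts[sample.int(nGenes, nVariants - length(pos),
                                       replace = TRUE)] +
                sample.int(geneSpanBp, nVariants - length(pos), replace = TRUE)
            pos <- sort(unique(c(pos, extra)))
        }
        pos <- pos[seq_len(nVariants)]
        bases <- c("A", "C", "G", "T")
        ref <- sample(bases, nVariants, replace = TRUE)
        # avoid strand-ambiguous pairs by default; corruptForQc can inject them
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        alt <- vapply(ref, function(r)
            sample(setdiff(bases, c(r, comp[[r]])), 1L), character(1))
        .makeVariants(chrom, pos, ref, unname(alt), cM = pos / 1e6 * cmPerMb)
    })
}

#' Generate diverged ancestral haplotype panels
#'
#' Balding-Nichols surrogate for continental reference panels: for every
#' variant an ancestral frequency p is drawn uniformly from the model's
#' frequency range; each population's frequency is a Beta draw with mean p and
#' variance p(1-p)F; haplotype alleles are Bernoulli draws from the population
#' frequency. All panels share one variant grid.
#'
#' @param model an [ancestralModel()].
#' @param nVariants number of shared variants.
#' @param seed RNG seed; identical seeds give bit-identical panels.
#' @param variants optional GRanges of variant positions (default: simulated
#'   exome-like positions via [simulateExomePositions()]).
#' @param ... passed to [simulateExomePositions()] when `variants` is NULL.
#' @return named list of [HaplotypePanel-class], one per population.
#' @examples
#' panels <- generateAncestralPanels(ancestralModel(nHaplotypes = 10), 50, seed = 1)
#' @export
generateAncestralPanels <- function(model, nVariants, seed, variants = NULL, ...) {
    stopifnot(inherits(model, "ancestralModel"), nVariants >= 1)
    if (is.null(variants))
        variants <- simulateExomePositions(nVariants, seed = seed, ...)
    stopifnot(length(variants) == nVariants)
    .withSeed(seed, {
        p0 <- stats::runif(nVariants, model$afRange[1], model$afRange[2])
        panels <- lapply(model$pops, function(pop) {
            f <- model$fst[[pop]]
            pf <- if (f < 1e-12) p0 else
                stats::rbeta(nVariants, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
            a <- matrix(stats::rbinom(nVariants * model$nHaplotypes, 1L,
                                      rep(pf, model$nHaplotypes)),
                        nrow = nVariants, ncol = model$nHaplotypes)
            new("HaplotypePanel", alleles = a, variants = variants,
                haplotypeIds = paste0(pop, "_hap", seq_len(model$nHaplotypes)))
        })
        names(panels) <- model$pops
        panels
    })
}

# Sample tract breakpoints and ancestries for one haplotype on one chromosome.
# cmSpan: c(min cM, max cM). Returns data.frame(start_cm, end_cm, ancestry).
.sampleTracts <- function(cmSpan, generations, proportions) {
    M <- (cmSpan[2] - cmSpan[1]) / 100
    nb <- stats::rpois(1L, generations * M)
    bp <- sort(stats::runif(nb, cmSpan[1], cmSpan[2]))
    bounds <- c(cmSpan[1], bp, cmSpan[2])
    anc <- sample(names(proportions), length(bounds) - 1L, replace = TRUE,
                  prob = proportions)
    data.frame(start_cm = bounds[-length(bounds)], end_cm = bounds[-1],
               ancestry = anc)
}

#' Simulate an admixed cohort as a Markov tract mosaic
#'
#' Each admixed haplotype is built as a mosaic of ancestry tracts: breakpoints
#' follow a Poisson process with rate g per morgan along the genetic map, each
#' tract's ancestry is drawn independently from the admixture proportions, and
#' alleles within a tract are copied from one random haplotype of that
#' ancestry's reference panel. The generating ancestry label at every variant
#' is recorded as ground truth.
#'
#' @param panels named list of [HaplotypePanel-class] sharing one variant grid
#'   (as from [generateAncestralPanels()]); names must cover the admixture
#'   proportions' names.
#' @param model an [admixtureModel()].
#' @param seed RNG seed.
#' @param group group label stored in the sample metadata.
#' @param samplePrefix prefix for generated sample ids.
#' @return a [SimulatedCohort-class].
#' @export
simulateAdmixedCohort <- function(panels, model, seed, group = "cohort",
                                  samplePrefix = "S") {
    stopifnot(inherits(model, "admixtureModel"))
    anc <- names(model$proportions)
    if (!all(anc %in% names(panels)))
        stop("panels missing for ancestries: ",
             paste(setdiff(anc, names(panels)), collapse = ", "))
    v <- variantRanges(panels[[1]])
    for (p in panels)
        if (!identical(start(variantRanges(p)), start(v)))
            stop("panels must share a common variant list")
    cM <- mcols(v)$cM
    sq <- as.character(seqnames(v))
    if (any(vapply(split(cM, sq), is.unsorted, logical(1))))
        stop("genetic map must be strictly increasing within chromosome")
    nHap <- 2L * model$nIndividuals
    nv <- length(v)
    .withSeed(seed, {
        allele <- matrix(NA_integer_, nv, nHap)
        label <- matrix(NA_character_, nv, nHap)
        for (chr in unique(sq)) {
            idx <- which(sq == chr)
            span <- range(cM[idx])
            # tiny pad so findInterval assigns edge variants to a tract
            span <- span + c(-1e-9, 1e-9)
            for (h in seq_len(nHap)) {
                tr <- .sampleTracts(span, model$generations, model$proportions)
                ti <- findInterval(cM[idx], tr$start_cm, rightmost.closed = TRUE)
                for (t in unique(ti)) {
                    vi <- idx[ti == t]
                    pop <- tr$ancestry[t]
                    src <- sample.int(ncol(alleles(panels[[pop]])), 1L)
                    allele[vi, h] <- alleles(panels[[pop]])[vi, src]
                    label[vi, h] <- pop
                }
            }
        }
        ids <- sprintf("%s%03d", samplePrefix, seq_len(model$nIndividuals))
        hapIds <- paste0(rep(ids, each = 2L), "_", rep(1:2, model$nIndividuals))
        panel <- new("HaplotypePanel", alleles = allele, variants = v,
                     haplotypeIds = hapIds)
        truth <- new("AncestryCalls", labels = label, variants = v,
                     haplotypeIds = hapIds, alphabet = names(panels))
        new("SimulatedCohort", panel = panel, truth = truth,
            metadata = data.frame(sample_id = ids, group = group),
            seed = as.integer(seed),
            defects = data.frame(defect = character(), unit = character(),
                                 id = character()))
    })
}

#' Inject a local ancestry sweep
#'
#' Raises the proportion of one ancestry inside a genomic region by
#' resampling haplotype tracts: maximal non-target runs of variants within
#' the region are visited in random order and replaced by copies from random
#' target-ancestry panel haplotypes (relabelled in the truth) until the
#' regional proportion of the target ancestry reaches `targetProportion`
#' (the last run may be split at a variant boundary, so the realised
#' proportion matches the target up to rounding). Variants outside the
#' region are untouched.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param panels the ancestral panels the cohort was simulated from.
#' @param region GRanges or "chrom:start-end" string.
#' @param targetAncestry ancestry whose regional proportion is raised.
#' @param targetProportion desired expected proportion in (0, 1); must not be
#'   below the current regional proportion (downsampling is not supported).
#' @param seed RNG seed.
#' @return a modified [SimulatedCohort-class].
#' @export
injectAncestrySweep <- function(cohort, panels, region, targetAncestry,
                                targetProportion, seed) {
    stopifnot(targetProportion > 0, targetProportion < 1)
    region <- .regionAsGRanges(region)
    idx <- .inRegion(variantRanges(cohort@panel), region)
    if (!length(idx)) stop("region overlaps no variant")
    lab <- cohort@truth@labels
    cur <- mean(lab[idx, ] == targetAncestry)
    if (targetProportion < cur - 1e-12)
        stop(sprintf(paste0("unsupported direction: regional %s proportion is ",
                            "already %.3f > target %.3f (downsampling not ",
                            "implemented)"), targetAncestry, cur,
                     targetProportion))
    pan <- panels[[targetAncestry]]
    if (is.null(pan)) stop("no panel for target ancestry ", targetAncestry)
    A <- cohort@panel@alleles
    N <- length(idx) * ncol(lab)
    needed <- round(targetProportion * N) - sum(lab[idx, ] == targetAncestry)
    if (needed <= 0) return(cohort)
    .withSeed(seed, {
        # enumerate maximal non-target runs (haplotype tracts) in the region
        runs <- list()
        for (h in seq_len(ncol(lab))) {
            r <- rle(lab[idx, h] == targetAncestry)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            for (k in which(!r$values))
                runs[[length(runs) + 1L]] <- c(h, starts[k], ends[k])
        }
        # replace randomly ordered runs until the conversion quota is met;
        # the last run may be replaced partially (split at a variant boundary)
        for (ri in sample.int(length(runs))) {
            if (needed <= 0) break
            r <- runs[[ri]]
            h <- r[1]; len <- r[3] - r[2] + 1L
            take <- min(len, needed)
            vi <- idx[r[2]:(r[2] + take - 1L)]
            src <- sample.int(ncol(alleles(pan)), 1L)
            A[vi, h] <- alleles(pan)[vi, src]
            lab[vi, h] <- targetAncestry
            needed <- needed - take
        }
        out <- cohort
        out@panel@alleles <- A
        out@truth@labels <- lab
        out
    })
}

#' Inject known QC defects into a cohort
#'
#' Embeds exactly the requested defects — duplicated individuals, an
#' excess-heterozygosity individual, missingness masks, strand-ambiguous
#' allele pairs, and out-of-Hardy-Weinberg variants — and records each in the
#' cohort's defect ledger, so QC filters can be validated against known truth.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param nDuplicatePairs individuals overwritten with a copy of another.
#' @param nHetExcess individuals made heterozygous at every variant.
#' @param nMissingVariants variants given missing entries.
#' @param missingFraction fraction (in [0, 1]) of individuals set missing at
#'   each masked variant.
#' @param nAmbiguous variants whose ref/alt is rewritten to an A/T or G/C pair.
#' @param nHweViolations variants forced to all-heterozygous genotypes.
#' @param seed RNG seed.
#' @return the corrupted [SimulatedCohort-class] with a populated `defects`
#'   ledger (columns defect, unit, id).
#' @export
corruptForQc <- function(cohort, nDuplicatePairs = 0L, nHetExcess = 0L,
                         nMissingVariants = 0L, missingFraction = 0.2,
                         nAmbiguous = 0L, nHweViolations = 0L, seed = 1L) {
    if (missingFraction > 1 || missingFraction < 0)
        stop("missingFraction must lie in [0, 1]")
    n <- nrow(cohort@metadata)
    nv <- nVariants(cohort@panel)
    A <- cohort@panel@alleles
    v <- variantRanges(cohort@panel)
    led <- list()
    .withSeed(seed, {
        usedInd <- integer()
        if (nDuplicatePairs > 0) {
            pick <- matrix(sample.int(n, 2L * nDuplicatePairs), ncol = 2L)
            for (k in seq_len(nDuplicatePairs)) {
                src <- pick[k, 1]; dst <- pick[k, 2]
                A[, 2L * dst - 1L] <- A[, 2L * src - 1L]
                A[, 2L * dst] <- A[, 2L * src]
                cohort@truth@labels[, 2L * dst - 1L] <-
                    cohort@truth@labels[, 2L * src - 1L]
                cohort@truth@labels[, 2L * dst] <- cohort@truth@labels[, 2L * src]
                led[[length(led) + 1L]] <- data.frame(
                    defect = "duplicate_pair", unit = "individual",
                    id = paste(cohort@metadata$sample_id[c(src, dst)],
                               collapse = "|"))
            }
            usedInd <- c(usedInd, as.vector(pick))
        }
        if (nHetExcess > 0) {
            free <- setdiff(seq_len(n), usedInd)
            pick <- sample(free, nHetExcess)
            for (i in pick) {
                A[, 2L * i - 1L] <- 0L
                A[, 2L * i] <- 1L
                led[[length(led) + 1L]] <- data.frame(
                    defect = "het_excess", unit = "individual",
                    id = cohort@metadata$sample_id[i])
            }
        }
        usedVar <- integer()
        if (nMissingVariants > 0) {
            pick <- sample.int(nv, nMissingVariants)
            for (j in pick) {
                masked <- sample.int(n, max(1L, round(missingFraction * n)))
                A[j, c(2L * masked - 1L, 2L * masked)] <- NA_integer_
                led[[length(led) + 1L]] <- data.frame(
                    defect = "missingness", unit = "variant", id = as.character(j))
            }
            usedVar <- c(usedVar, pick)
        }
        if (nAmbiguous > 0) {
            pick <- sample(setdiff(seq_len(nv), usedVar), nAmbiguous)
            pair <- matrix(c("A", "T", "G", "C"), ncol = 2, byrow = TRUE)
            for (j in pick) {
                p <- pair[sample.int(2, 1L), ]
                mcols(v)$ref[j] <- p[1]; mcols(v)$alt[j] <- p[2]
                led[[length(led) + 1L]] <- data.frame(
                    defect = "ambiguous_alleles", unit = "variant",
                    id = as.character(j))
            }
            usedVar <- c(usedVar, pick)
        }
        if (nHweViolations > 0) {
            pick <- sample(setdiff(seq_len(nv), usedVar), nHweViolations)
            for (j in pick) {
                A[j, seq(1L, 2L * n, by = 2L)] <- 0L
                A[j, seq(2L, 2L * n, by = 2L)] <- 1L
                led[[length(led) + 1L]] <- data.frame(
                    defect = "hwe_violation", unit = "variant",
                    id = as.character(j))
            }
        }
        out <- cohort
        out@panel@alleles <- A
        out@panel@variants <- v
        out@truth@variants <- v
        out@defects <- if (length(led)) do.call(rbind, led) else cohort@defects
        out
    })
}
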