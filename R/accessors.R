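#' Accessors for admixscan containers
#'
#' Small read-only accessors; slots are never touched directly by user code.
#'
#' @param x an admixscan container object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("alleles", "HaplotypePanel", function(x) x@alleles)
#' @rdname accessors
setMethod("variantRanges", "HaplotypePanel", function(x) x@variants)
#' @rdname accessors
setMethod("haplotypeIds", "HaplotypePanel", function(x) x@haplotypeIds)
#' @rdname accessors
setMethod("nVariants", "HaplotypePanel", function(x) nrow(x@alleles))
#' @rdname accessors
setMethod("nHaplotypes", "HaplotypePanel", function(x) ncol(x@alleles))

#' @rdname accessors
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)
#' @rdname accessors
setMethod("variantRanges", "GenotypeMatrix", function(x) x@variants)
#' @rdname accessors
setMethod("nVariants", "GenotypeMatrix", function(x) nrow(x@dosage))
#' @rdname accessors
setMethod("nIndividuals", "GenotypeMatrix", function(x) ncol(x@dosage))

#' @rdname accessors
setMethod("ancestryLabels", "AncestryCalls", function(x) x@labels)
#' @rdname accessors
setMethod("variantRanges", "AncestryCalls", function(x) x@variants)
#' @rdname accessors
setMethod("haplotypeIds", "AncestryCalls", function(x) x@haplotypeIds)
#' @rdname accessors
setMethod("nVariants", "AncestryCalls", function(x) nrow(x@labels))
#' @rdname accessors
setMethod("nHaplotypes", "AncestryCalls", function(x) ncol(x@labels))

#' @rdname accessors
setMethod("haplotypePanel", "SimulatedCohort", function(x) x@panel)
#' @rdname accessors
setMethod("truthCalls", "SimulatedCohort", function(x) x@truth)
#' @rdname accessors
setMethod("sampleMetadata", "SimulatedCohort", function(x) x@metadata)
#' @rdname accessors
setMethod("nVariants", "SimulatedCohort", function(x) nVariants(x@panel))
#' @rdname accessors
setMethod("nIndividuals", "SimulatedCohort", function(x) nrow(x@metadata))

#' @rdname accessors
setMethod("qcSteps", "QCReport", function(x) x@steps)
#' @rdname accessors
setMethod("removedIds", "QCReport", function(x) x@removed)

setMethod("asGenotypeMatrix", "HaplotypePanel", function(x) {
    a <- x@alleles
    if (ncol(a) %% 2L != 0L)
        stop("haplotype panel must have an even number of haplotypes")
    h1 <- a[, seq(1L, ncol(a), by = 2L), drop = FALSE]
    h2 <- a[, seq(2L, ncol(a), by = 2L), drop = FALSE]
    d <- h1 + h2
    colnames(d) <- sub("_1$", "", x@haplotypeIds[seq(1L, ncol(a), by = 2L)])
    new("GenotypeMatrix", dosage = d, variants = x@variants, phased = TRUE)
})

setMethod("asGenotypeMatrix", "SimulatedCohort", function(x) {
    gm <- asGenotypeMatrix(x@panel)
    colnames(gm@dosage) <- x@metadata$sample_id
    gm
})

.regionAsGRanges <- function(region) {
    if (is(region, "GRanges")) return(region)
    parseRegion(region)
}

.inRegion <- function(gr, region) {
    region <- .regionAsGRanges(region)
    S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, region)) |>
        unique() |> sort()
}

setMethod("subsetRegion", "HaplotypePanel", function(x, region) {
    i <- .inRegion(x@variants, region)
    new("HaplotypePanel", alleles = x@alleles[i, , drop = FALSE],
        variants = x@variants[i], haplotypeIds = x@haplotypeIds)
})

setMethod("subsetRegion", "GenotypeMatrix", function(x, region) {
    i <- .inRegion(x@variants, region)
    new("GenotypeMatrix", dosage = x@dosage[i, , drop = FALSE],
        variants = x@variants[i], phased = x@phased)
})

setMethod("subsetRegion", "AncestryCalls", function(x, region) {
    i <- .inRegion(x@variants, region)
    new("AncestryCalls", labels = x@labels[i, , drop = FALSE],
        variants = x@variants[i], haplotypeIds = x@haplotypeIds,
        alphabet = x@alphabet)
})

setMethod("show", "HaplotypePanel", function(object) {
    cat(sprintf("HaplotypePanel: %d variants x %d haplotypes on %s\n",
        nrow(object@alleles), ncol(object@alleles),
        paste(unique(as.character(seqnames(object@variants))), collapse = ",")))
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat(sprintf("GenotypeMatrix: %d variants x %d individuals (%s)\n",
        nrow(object@dosage), ncol(object@dosage),
        if (object@phased) "phased origin" else "unphased"))
})

setMethod("show", "AncestryCalls", function(object) {
    cat(sprintf("AncestryCalls: %d variants x %d haplotypes, labels {%s}\n",
        nrow(object@labels), ncol(object@labels),
        paste(object@alphabet, collapse = ", ")))
})

setMethod("show", "SimulatedCohort", function(object) {
    cat(sprintf("SimulatedCohort: %d individuals, %d variants (seed %d)\n",
        nrow(object@metadata), nVariants(object@panel), object@seed))
    if (nrow(object@defects))
        cat(sprintf("  with %d injected QC defects\n", nrow(object@defects)))
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport:\n")
    print(object@steps[, c("step", "unit", "n_before", "n_removed", "n_after")])
})
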