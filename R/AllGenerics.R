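#' @rdname accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname accessors
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' @rdname accessors
#' @export
setGeneric("haplotypeIds", function(x) standardGeneric("haplotypeIds"))

#' @rdname accessors
#' @export
setGeneric("ancestryLabels", function(x) standardGeneric("ancestryLabels"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname accessors
#' @export
setGeneric("sampleMetadata", function(x) standardGeneric("sampleMetadata"))

#' @rdname accessors
#' @export
setGeneric("truthCalls", function(x) standardGeneric("truthCalls"))

#' @rdname accessors
#' @export
setGeneric("haplotypePanel", function(x) standardGeneric("haplotypePanel"))

#' @rdname accessors
#' @export
setGeneric("qcSteps", function(x) standardGeneric("qcSteps"))

#' @rdname accessors
#' @export
setGeneric("removedIds", function(x) standardGeneric("removedIds"))

#' Collapse to diploid dosages
#'
#' Collapses phased haplotypes (two per individual, in column order) to a
#' [GenotypeMatrix-class] of alternate-allele dosages.
#'
#' @param x a HaplotypePanel or SimulatedCohort.
#' @return a [GenotypeMatrix-class].
#' @export
setGeneric("asGenotypeMatrix", function(x) standardGeneric("asGenotypeMatrix"))

#' Subset by genomic region
#'
#' Restricts an object to variants falling in `region` (1-based inclusive,
#' either a GRanges or a "chrom:start-end" string).
#'
#' @param x object carrying variant coordinates.
#' @param region GRanges or region string such as `"8:8092025-11859740"`.
#' @return object of the same class restricted to the region.
#' @export
setGeneric("subsetRegion", function(x, region) standardGeneric("subsetRegion"))
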