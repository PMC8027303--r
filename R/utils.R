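#' Parse a region string
#'
#' Converts `"chrom:start-end"` (1-based, inclusive at both ends) into a
#' GRanges of length one. Commas in coordinates are tolerated.
#'
#' @param region character scalar, e.g. `"8:8092025-11859740"`.
#' @return GRanges of length 1.
#' @examples
#' parseRegion("8:8092025-11859740")
#' @export
parseRegion <- function(region) {
    stopifnot(is.character(region), length(region) == 1L)
    m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
    if (length(m) != 4L)
        stop("region must be of the form chrom:start-end, got: ", region)
    s <- as.numeric(gsub(",", "", m[3]))
    e <- as.numeric(gsub(",", "", m[4]))
    if (e < s) stop("region end precedes start: ", region)
    GRanges(m[2], IRanges(s, e))
}

#' Coordinate convention converters
#'
#' I/O boundaries use 1-based inclusive coordinates (VCF, region strings);
#' BED output is 0-based half-open. These two functions are inverse bijections.
#'
#' @param start,end 1-based inclusive interval.
#' @param bed_start,bed_end 0-based half-open interval.
#' @return a two-column data.frame in the other convention.
#' @export
toBedCoords <- function(start, end) {
    data.frame(bed_start = start - 1, bed_end = end)
}

#' @rdname toBedCoords
#' @export
fromBedCoords <- function(bed_start, bed_end) {
    data.frame(start = bed_start + 1, end = bed_end)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (has) old <- get(".Random.seed", envir = globalenv())
        on.exit({
            if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Build a variants GRanges with ref/alt/cM metadata.
.makeVariants <- function(chrom, pos, ref, alt, cM) {
    gr <- GRanges(chrom, IRanges(pos, pos))
    mcols(gr)$ref <- ref
    mcols(gr)$alt <- alt
    mcols(gr)$cM <- cM
    gr
}

# Alternate-allele frequency per variant on non-missing dosages.
.altFreq <- function(d) {
    rowMeans(d, na.rm = TRUE) / 2
}

# Minor-allele frequency per variant.
.mafOf <- function(d) {
    p <- .altFreq(d)
    pmin(p, 1 - p)
}
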