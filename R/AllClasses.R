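#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

.validVariantRanges <- function(gr, n) {
    msg <- character()
    if (length(gr) != n)
        msg <- c(msg, sprintf("variant ranges (%d) do not match matrix rows (%d)",
                              length(gr), n))
    # positions sorted within chromosome
    sq <- as.character(seqnames(gr))
    for (chr in unique(sq)) {
        p <- start(gr)[sq == chr]
        if (is.unsorted(p))
            msg <- c(msg, sprintf("positions not sorted on chromosome %s", chr))
    }
    msg
}

#' Phased haplotype panel
#'
#' Holds phased biallelic alleles as a variants x haplotypes 0/1 matrix
#' together with variant coordinates. The `variants` GRanges carries
#' metadata columns `ref`, `alt` and `cM` (cumulative genetic-map position).
#' This is the unit of all haplotype-based statistics (EHH, iHS, XP-EHH).
#'
#' @slot alleles integer matrix, variants x haplotypes, values 0/1 (NA = missing).
#' @slot variants GRanges of variant positions (1-based), with `ref`, `alt`, `cM`.
#' @slot haplotypeIds character vector naming haplotypes; two per individual,
#'   conventionally `<sample>_1` / `<sample>_2`.
#'
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
    slots = c(alleles = "matrix", variants = "GRanges", haplotypeIds = "character"))

setValidity("HaplotypePanel", function(object) {
    msg <- character()
    a <- object@alleles
    if (!all(is.na(a) | a == 0L | a == 1L))
        msg <- c(msg, "alleles must be 0, 1 or NA")
    if (ncol(a) != length(object@haplotypeIds))
        msg <- c(msg, "haplotypeIds length must equal number of columns")
    msg <- c(msg, .validVariantRanges(object@variants, nrow(a)))
    need <- c("ref", "alt", "cM")
    if (!all(need %in% names(mcols(object@variants))))
        msg <- c(msg, "variants must carry mcols ref, alt, cM")
    if (length(msg)) msg else TRUE
})

#' Diploid genotype matrix
#'
#' Unphased (or phase-collapsed) dosages of the alternate allele, one row per
#' variant and one column per individual, values 0/1/2 with NA for missing.
#' This is the substrate of the exome QC filters and population-structure
#' analyses.
#'
#' @slot dosage numeric matrix, variants x individuals, values 0/1/2/NA.
#' @slot variants GRanges with `ref`, `alt` metadata columns.
#' @slot phased logical flag: TRUE when derived from phased data.
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
    slots = c(dosage = "matrix", variants = "GRanges", phased = "logical"))

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    d <- object@dosage
    if (!all(is.na(d) | d %in% c(0, 1, 2)))
        msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
    msg <- c(msg, .validVariantRanges(object@variants, nrow(d)))
    if (!all(c("ref", "alt") %in% names(mcols(object@variants))))
        msg <- c(msg, "variants must carry mcols ref and alt")
    if (length(msg)) msg else TRUE
})

#' Per-haplotype local-ancestry calls
#'
#' One ancestry label per haplotype per variant, in a declared alphabet
#' (default EUR/AFR/NAT, with "UNK" for unknown). Mirrors the per-variant
#' Viterbi output of local-ancestry callers such as RFMix.
#'
#' @slot labels character matrix, variants x haplotypes.
#' @slot variants GRanges of variant positions.
#' @slot haplotypeIds character, two per individual (`<sample>_1`, `<sample>_2`).
#' @slot alphabet character vector of admissible labels.
#'
#' @exportClass AncestryCalls
setClass("AncestryCalls",
    slots = c(labels = "matrix", variants = "GRanges",
              haplotypeIds = "character", alphabet = "character"))

setValidity("AncestryCalls", function(object) {
    msg <- character()
    l <- object@labels
    ok <- l %in% c(object@alphabet, "UNK")
    if (!all(ok))
        msg <- c(msg, sprintf("unknown ancestry labels: %s",
                              paste(unique(l[!ok])[seq_len(min(3, sum(!ok)))],
                                    collapse = ", ")))
    if (ncol(l) != length(object@haplotypeIds))
        msg <- c(msg, "haplotypeIds length must equal number of columns")
    if (length(object@haplotypeIds) %% 2 != 0)
        msg <- c(msg, "expected two haplotypes per individual")
    msg <- c(msg, .validVariantRanges(object@variants, nrow(l)))
    if (length(msg)) msg else TRUE
})

#' Simulated admixed cohort
#'
#' Bundles a phased haplotype panel with its generating truth: per-haplotype
#' ancestry labels, sample metadata and the seed used.
#'
#' @slot panel HaplotypePanel of the admixed haplotypes.
#' @slot truth AncestryCalls holding the generating ancestry of every allele.
#' @slot metadata data.frame with columns `sample_id` and `group`.
#' @slot seed integer seed the cohort was generated from.
#' @slot defects data.frame ledger of QC defects injected by [corruptForQc()]
#'   (zero rows for a clean cohort).
#'
#' @exportClass SimulatedCohort
setClass("SimulatedCohort",
    slots = c(panel = "HaplotypePanel", truth = "AncestryCalls",
              metadata = "data.frame", seed = "integer", defects = "data.frame"))

setValidity("SimulatedCohort", function(object) {
    msg <- character()
    if (!identical(dim(object@panel@alleles), dim(object@truth@labels)))
        msg <- c(msg, "truth dimensions must equal panel dimensions")
    if (!all(c("sample_id", "group") %in% names(object@metadata)))
        msg <- c(msg, "metadata needs sample_id and group columns")
    if (2L * nrow(object@metadata) != ncol(object@panel@alleles))
        msg <- c(msg, "metadata must list one row per individual (2 haplotypes)")
    if (length(msg)) msg else TRUE
})

#' Ordered QC removal ledger
#'
#' Records, for every filter step applied, what was removed and why, with
#' before/after counts that must be mutually consistent.
#'
#' @slot steps data.frame with columns `step`, `unit` ("variant"/"individual"),
#'   `n_before`, `n_removed`, `n_after`, `params`.
#' @slot removed named list (one element per step) of removed ids.
#'
#' @exportClass QCReport
setClass("QCReport", slots = c(steps = "data.frame", removed = "list"))

setValidity("QCReport", function(object) {
    s <- object@steps
    msg <- character()
    if (nrow(s)) {
        if (!all(s$n_before - s$n_removed == s$n_after))
            msg <- c(msg, "ledger inconsistent: n_before - n_removed != n_after")
        if (length(object@removed) != nrow(s))
            msg <- c(msg, "removed list must have one element per step")
    }
    if (length(msg)) msg else TRUE
})
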