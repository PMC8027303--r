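#' Cross-classify allele frequencies against reference databases
#'
#' Variants present in at least one reference source are cross-classified as
#' common (AAF > threshold) or rare (AAF < threshold) in the study sample
#' versus the reference union: a variant is reference-common when common in
#' ANY source ("and/or" rule; an intersection mode is available for
#' sensitivity analysis). Variants absent from every reference form the
#' exclusive list with their own common/rare split. An AAF exactly equal to
#' the threshold is unclassifiable under the strict inequalities; it is
#' assigned to "rare" and recorded in a boundary ledger so the partition
#' stays exact.
#'
#' @param afTable data.frame with a `variant_id` column, a `study` AAF column
#'   and one AAF column per reference source; NA marks absence from a source
#'   (absent is distinct from frequency zero).
#' @param refCols names of the reference AAF columns (default: all columns
#'   except `variant_id` and `study`).
#' @param threshold common/rare threshold (default 0.01).
#' @param refRule `"union"` (common in any source, default) or
#'   `"intersection"` (common in all sources where present).
#' @return object of class `"crossClassification"`: list with `counts` (2x2
#'   matrix, rows = reference status, cols = study status), `cellPct`,
#'   `rowPct`, `colPct` (percentages of the shared-variant total), `shared`
#'   data.frame, `exclusive` data.frame (with `common` flag), `excluded`
#'   (variants with no study AAF), `boundary` ledger, `test` (from
#'   [contingencyTest()]) and `threshold`.
#' @export
classifyAf <- function(afTable, refCols = NULL, threshold = 0.01,
                       refRule = c("union", "intersection")) {
    refRule <- match.arg(refRule)
    stopifnot(threshold > 0, threshold < 0.5,
              all(c("variant_id", "study") %in% names(afTable)))
    if (is.null(refCols))
        refCols <- setdiff(names(afTable), c("variant_id", "study"))
    stopifnot(length(refCols) >= 1L)
    excluded <- afTable[is.na(afTable$study), , drop = FALSE]
    af <- afTable[!is.na(afTable$study), , drop = FALSE]
    refM <- as.matrix(af[, refCols, drop = FALSE])
    present <- rowSums(!is.na(refM)) > 0
    exclusive <- af[!present, , drop = FALSE]
    exclusive$common <- exclusive$study > threshold
    shared <- af[present, , drop = FALSE]
    refMs <- refM[present, , drop = FALSE]
    boundary <- shared$variant_id[abs(shared$study - threshold) < 1e-12]
    studyCommon <- shared$study > threshold
    refCommon <- if (refRule == "union")
        rowSums(refMs > threshold, na.rm = TRUE) > 0
    else {
        np <- rowSums(!is.na(refMs))
        rowSums(refMs > threshold, na.rm = TRUE) == np
    }
    counts <- matrix(c(sum(refCommon & studyCommon),
                       sum(refCommon & !studyCommon),
                       sum(!refCommon & studyCommon),
                       sum(!refCommon & !studyCommon)),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(reference = c("common", "rare"),
                                     study = c("common", "rare")))
    tot <- sum(counts)
    shared$study_common <- studyCommon
    shared$ref_common <- refCommon
    structure(list(counts = counts,
                   cellPct = 100 * counts / tot,
                   rowPct = 100 * rowSums(counts) / tot,
                   colPct = 100 * colSums(counts) / tot,
                   shared = shared, exclusive = exclusive,
                   excluded = excluded, boundary = boundary,
                   test = contingencyTest(counts),
                   threshold = threshold, refRule = refRule),
              class = "crossClassification")
}

#' @export
print.crossClassification <- function(x, ...) {
    cat(sprintf("crossClassification (threshold %g, %s rule):\n", x$threshold,
                x$refRule))
    print(x$counts)
    cat(sprintf("%d exclusive variants (%d common); Fisher p = %.3g\n",
                nrow(x$exclusive), sum(x$exclusive$common), x$test$fisher_p))
    invisible(x)
}

#' 2x2 contingency test
#'
#' Pearson chi-square (optionally continuity-corrected) and Fisher's exact
#' test, both reported. With a zero margin the chi-square statistic is
#' undefined (NA); the Fisher p-value is still computed.
#'
#' @param counts 2x2 matrix of non-negative integers.
#' @param correct apply Yates continuity correction to the chi-square
#'   (default FALSE).
#' @return list with chisq_stat, chisq_p, fisher_p, odds_ratio.
#' @export
contingencyTest <- function(counts, correct = FALSE) {
    stopifnot(identical(dim(counts), c(2L, 2L)), all(counts >= 0),
              all(counts == round(counts)))
    zeroMargin <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
    if (zeroMargin) {
        chis <- list(statistic = NA_real_, p.value = NA_real_)
    } else {
        chis <- suppressWarnings(stats::chisq.test(counts, correct = correct))
    }
    fish <- stats::fisher.test(counts)
    list(chisq_stat = unname(chis$statistic), chisq_p = unname(chis$p.value),
         fisher_p = fish$p.value, odds_ratio = unname(fish$estimate))
}

# canonical consequence vocabulary and common annotation-engine synonyms
.consequenceMap <- c(
    "nonsynonymous" = "nonsynonymous", "nonsynonymous snv" = "nonsynonymous",
    "missense" = "nonsynonymous", "missense_variant" = "nonsynonymous",
    "frameshift" = "frameshift", "frameshift insertion" = "frameshift",
    "frameshift deletion" = "frameshift", "frameshift_variant" = "frameshift",
    "inframe_deletion" = "inframe_deletion",
    "nonframeshift deletion" = "inframe_deletion",
    "inframe deletion" = "inframe_deletion",
    "start_loss" = "start_loss", "startloss" = "start_loss",
    "start lost" = "start_loss", "start_lost" = "start_loss",
    "stop_gain" = "stop_gain", "stopgain" = "stop_gain",
    "stop gained" = "stop_gain", "stop_gained" = "stop_gain",
    "stop_loss" = "stop_loss", "stoploss" = "stop_loss",
    "stop lost" = "stop_loss", "stop_lost" = "stop_loss",
    "splicing" = "splicing", "splice site" = "splicing",
    "splice_acceptor_variant" = "splicing", "splice_donor_variant" = "splicing")

#' Tally variant consequences
#'
#' Normalises free-text consequence strings (ANNOVAR/VEP style) to a fixed
#' vocabulary (nonsynonymous, frameshift, inframe_deletion, start_loss,
#' stop_gain, stop_loss, splicing, other) and counts them, overall and per
#' gene. Unknown strings map to "other" with a message.
#'
#' @param annotation data.frame with columns `consequence` and optionally
#'   `gene`.
#' @return list with `counts` (named vector over the vocabulary), `perGene`
#'   (gene x class table, if genes present) and `unknown` (unmapped strings).
#' @export
consequenceTally <- function(annotation) {
    stopifnot("consequence" %in% names(annotation))
    key <- tolower(trimws(annotation$consequence))
    cls <- unname(.consequenceMap[key])
    unknown <- unique(annotation$consequence[is.na(cls)])
    if (length(unknown))
        message("unknown consequence strings mapped to 'other': ",
                paste(unknown, collapse = ", "))
    cls[is.na(cls)] <- "other"
    vocab <- c("nonsynonymous", "frameshift", "inframe_deletion", "start_loss",
               "stop_gain", "stop_loss", "splicing", "other")
    counts <- table(factor(cls, levels = vocab))
    perGene <- NULL
    if ("gene" %in% names(annotation))
        perGene <- table(gene = annotation$gene,
                         class = factor(cls, levels = vocab))
    list(counts = c(counts), perGene = perGene, unknown = unknown)
}

#' Pathogenicity-predictor concordance
#'
#' Per variant, concordance is the fraction of non-absent algorithm calls in
#' the majority class; the consensus class is that majority (an exact 50/50
#' split gives concordance 0.5 and consensus "tied"). A variant is consensus
#' pathogenic when the deleterious fraction reaches `pathogenicThreshold`;
#' any benign call raises the benign-by-at-least-one flag. Concordance is
#' binned into a histogram (default 8 equal bins over (0.5, 1]).
#'
#' @param pm character matrix or data.frame, variants x algorithms, values
#'   "benign"/"deleterious"/NA.
#' @param pathogenicThreshold deleterious fraction for consensus-pathogenic
#'   (default 0.80).
#' @param nBins histogram bins over (0.5, 1] (default 8).
#' @return list with `perVariant` (data.frame: nCalls, nDeleterious, nBenign,
#'   concordance, consensus, consensusPathogenic, anyBenign), `histogram`
#'   (data.frame: bin, lower, upper, deleterious, benign, tied) and
#'   `threshold`.
#' @export
predictorConcordance <- function(pm, pathogenicThreshold = 0.80, nBins = 8L) {
    pm <- as.matrix(pm)
    ok <- pm %in% c("benign", "deleterious") | is.na(pm)
    if (!all(ok)) stop("calls must be 'benign', 'deleterious' or NA")
    nDel <- rowSums(pm == "deleterious", na.rm = TRUE)
    nBen <- rowSums(pm == "benign", na.rm = TRUE)
    nCalls <- nDel + nBen
    if (any(nCalls == 0))
        stop("every scored variant needs at least one non-absent call")
    conc <- pmax(nDel, nBen) / nCalls
    consensus <- ifelse(nDel > nBen, "deleterious",
                        ifelse(nBen > nDel, "benign", "tied"))
    perVariant <- data.frame(
        nCalls = nCalls, nDeleterious = nDel, nBenign = nBen,
        concordance = conc, consensus = consensus,
        consensusPathogenic = nDel / nCalls >= pathogenicThreshold,
        anyBenign = nBen > 0,
        row.names = rownames(pm))
    edges <- seq(0.5, 1, length.out = nBins + 1)
    bin <- cut(conc, breaks = edges, include.lowest = FALSE)
    hist <- data.frame(bin = levels(bin),
                       lower = edges[-length(edges)], upper = edges[-1])
    for (cl in c("deleterious", "benign", "tied"))
        hist[[cl]] <- as.integer(table(bin[consensus == cl]))
    list(perVariant = perVariant, histogram = hist,
         threshold = pathogenicThreshold)
}

#' Count common variants among the population-exclusive set
#'
#' @param classification a `"crossClassification"` from [classifyAf()], whose
#'   exclusive list is used.
#' @param threshold AAF above which an exclusive variant counts as common
#'   (default 0.01).
#' @return list with `count` and `ids`.
#' @export
exclusiveCommonCount <- function(classification, threshold = 0.01) {
    stopifnot(inherits(classification, "crossClassification"))
    ex <- classification$exclusive
    common <- ex$study > threshold
    list(count = sum(common), ids = ex$variant_id[common])
}
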