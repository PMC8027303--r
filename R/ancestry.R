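#' Per-variant ancestry proportions
#'
#' At every variant, the fraction of haplotypes labelled with each ancestry.
#' Unknown ("UNK") labels are excluded from the denominator with a warning.
#' Genome-wide mean and SD per ancestry are computed across variants.
#'
#' @param calls an [AncestryCalls-class].
#' @return object of class `"ancestryTrack"`: list with `proportions`
#'   (variants x ancestries matrix, rows summing to 1), `variants` (GRanges),
#'   `genomeMean` and `genomeSd` (named per ancestry).
#' @export
perVariantProportions <- function(calls) {
    lab <- ancestryLabels(calls)
    if (ncol(lab) < 1L) stop("need at least one haplotype")
    alpha <- calls@alphabet
    if (any(lab == "UNK"))
        warning("unknown labels excluded from the denominator at ",
                sum(rowSums(lab == "UNK") > 0), " variants")
    counts <- vapply(alpha, function(a) rowSums(lab == a),
                     numeric(nrow(lab)))
    counts <- matrix(counts, nrow = nrow(lab),
                     dimnames = list(NULL, alpha))
    denom <- rowSums(counts)
    prop <- counts / denom
    prop[denom == 0, ] <- NA_real_
    structure(list(proportions = prop, variants = variantRanges(calls),
                   genomeMean = colMeans(prop, na.rm = TRUE),
                   genomeSd = apply(prop, 2, sd, na.rm = TRUE)),
              class = "ancestryTrack")
}

#' @export
print.ancestryTrack <- function(x, ...) {
    cat("ancestryTrack:", nrow(x$proportions), "variants\n")
    print(round(rbind(mean = x$genomeMean, sd = x$genomeSd), 4))
    invisible(x)
}

#' Group-stratified global ancestry
#'
#' Each individual's global ancestry fraction is the fraction of its two
#' haplotypes' variant-level labels assigned to each ancestry; groups are then
#' summarised by mean and SD over individuals. Groups of one individual get
#' SD 0 and a flag.
#'
#' @param calls an [AncestryCalls-class].
#' @param metadata data.frame with `sample_id` and `group`; haplotype ids must
#'   be `<sample_id>_1` / `<sample_id>_2`.
#' @return list with `individual` (per-individual fractions) and `groups`
#'   (data.frame: group, ancestry, mean, sd, n, degenerate).
#' @export
groupMeans <- function(calls, metadata) {
    stopifnot(all(c("sample_id", "group") %in% names(metadata)))
    lab <- ancestryLabels(calls)
    alpha <- calls@alphabet
    hapSample <- sub("_[12]$", "", haplotypeIds(calls))
    miss <- setdiff(metadata$sample_id, hapSample)
    if (length(miss))
        stop("no haplotypes for samples: ", paste(miss, collapse = ", "))
    if (any(!table(metadata$group)))
        stop("empty group in metadata")
    frac <- t(vapply(metadata$sample_id, function(s) {
        cols <- which(hapSample == s)
        l <- lab[, cols]
        l <- l[l != "UNK"]
        vapply(alpha, function(a) mean(l == a), numeric(1))
    }, numeric(length(alpha))))
    rownames(frac) <- metadata$sample_id
    rows <- list()
    for (g in unique(metadata$group)) {
        i <- which(metadata$group == g)
        for (a in alpha) {
            rows[[length(rows) + 1L]] <- data.frame(
                group = g, ancestry = a, mean = mean(frac[i, a]),
                sd = if (length(i) > 1L) sd(frac[i, a]) else 0,
                n = length(i), degenerate = length(i) == 1L)
        }
    }
    list(individual = frac, groups = do.call(rbind, rows))
}

#' Regional ancestry deviation
#'
#' z-score of a region's mean ancestry proportion against the genome-wide
#' per-variant distribution: z = (regional mean - genome-wide mean) /
#' genome-wide SD, per ancestry; flagged when |z| exceeds the threshold.
#'
#' @param track an `"ancestryTrack"` from [perVariantProportions()].
#' @param region GRanges or "chrom:start-end" string.
#' @param zThreshold |z| above which the deviation is flagged (default 3).
#' @return data.frame with ancestry, regionalMean, genomeMean, genomeSd, z,
#'   flagged, undefined (TRUE where the genome-wide SD is zero).
#' @export
regionDeviation <- function(track, region, zThreshold = 3) {
    stopifnot(inherits(track, "ancestryTrack"))
    idx <- .inRegion(track$variants, region)
    if (!length(idx)) stop("region contains no variant")
    regMean <- colMeans(track$proportions[idx, , drop = FALSE], na.rm = TRUE)
    sdv <- track$genomeSd
    z <- ifelse(sdv > 0, (regMean - track$genomeMean) / sdv, NA_real_)
    data.frame(ancestry = names(regMean), regionalMean = regMean,
               genomeMean = track$genomeMean, genomeSd = sdv, z = z,
               flagged = !is.na(z) & abs(z) > zThreshold,
               undefined = sdv == 0, row.names = NULL)
}

# Majority label of a label vector; ties -> "mixed", empty -> NA.
.majorityLabel <- function(l) {
    l <- l[l != "UNK"]
    if (!length(l)) return(NA_character_)
    tab <- table(l)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) "mixed" else top
}

#' Flank-core-flank haplotype pattern counts
#'
#' For every haplotype, the core region and its upstream and downstream flanks
#' are each summarised by the majority ancestry over their variants (ties are
#' labelled "mixed" and excluded from named patterns). Haplotypes whose core
#' majority equals `coreAncestry` are counted by their (upstream, downstream)
#' ancestry pair, e.g. EUR-NAT-EUR. Haplotypes with an empty flank are counted
#' as unscorable.
#'
#' @param calls an [AncestryCalls-class].
#' @param coreRegion GRanges or "chrom:start-end" string.
#' @param flankBp flank width in bp on each side (default 3.7 Mb).
#' @param coreAncestry ancestry required in the core (default "NAT").
#' @return object of class `"patternCounts"`: list with `counts` (data.frame:
#'   upstream, downstream, pattern, n), `nCoreMatching`, `unscorable`,
#'   `flankBp`, `coreAncestry`.
#' @export
flankingPatterns <- function(calls, coreRegion, flankBp = 3.7e6,
                             coreAncestry = "NAT") {
    core <- .regionAsGRanges(coreRegion)
    stopifnot(length(core) == 1L)
    chr <- as.character(seqnames(core))
    gr <- variantRanges(calls)
    span <- range(start(gr)[as.character(seqnames(gr)) == chr])
    upStart <- start(core) - flankBp
    dnEnd <- end(core) + flankBp
    if (upStart < span[1] || dnEnd > span[2])
        warning("flanks truncated to the chromosome's variant span")
    up <- GRanges(chr, IRanges(max(upStart, span[1]),
                               max(start(core) - 1, span[1])))
    dn <- GRanges(chr, IRanges(min(end(core) + 1, span[2]),
                               min(dnEnd, span[2])))
    lab <- ancestryLabels(calls)
    iCore <- .inRegion(gr, core)
    iUp <- setdiff(.inRegion(gr, up), iCore)
    iDn <- setdiff(.inRegion(gr, dn), iCore)
    if (!length(iCore)) stop("core region contains no variant")
    res <- vapply(seq_len(ncol(lab)), function(h) c(
        up = .majorityLabel(lab[iUp, h]),
        core = .majorityLabel(lab[iCore, h]),
        dn = .majorityLabel(lab[iDn, h])), character(3))
    coreMatch <- !is.na(res["core", ]) & res["core", ] == coreAncestry
    unscorable <- coreMatch & (is.na(res["up", ]) | is.na(res["dn", ]))
    scor <- coreMatch & !unscorable
    if (any(scor)) {
        counts <- as.data.frame(table(upstream = res["up", scor],
                                      downstream = res["dn", scor]),
                                stringsAsFactors = FALSE)
        names(counts)[3] <- "n"
        counts <- counts[counts$n > 0, , drop = FALSE]
    } else {
        counts <- data.frame(upstream = character(), downstream = character(),
                             n = integer())
    }
    counts$pattern <- if (nrow(counts))
        paste(counts$upstream, coreAncestry, counts$downstream, sep = "-")
    else character()
    rownames(counts) <- NULL
    structure(list(counts = counts[, c("upstream", "downstream", "pattern", "n")],
                   nCoreMatching = sum(coreMatch), unscorable = sum(unscorable),
                   flankBp = flankBp, coreAncestry = coreAncestry),
              class = "patternCounts")
}

#' @export
print.patternCounts <- function(x, ...) {
    cat(sprintf("patternCounts: %d haplotypes with %s core (%d unscorable)\n",
                x$nCoreMatching, x$coreAncestry, x$unscorable))
    print(x$counts)
    invisible(x)
}
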