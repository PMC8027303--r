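#' @importClassesFrom vcfR vcfR
NULL

#' Interpolate genetic-map positions
#'
#' Linear interpolation of cM at arbitrary bp positions from a genetic-map
#' table; positions outside the map are extrapolated at the flanking map
#' interval's local rate held constant (rule-2 interpolation).
#'
#' @param map data.frame with columns `chrom`, `pos`, `cM`, strictly
#'   increasing in both `pos` and `cM` within chromosome.
#' @param chrom,pos query coordinates.
#' @return numeric cM per query position.
#' @export
geneticMapInterpolate <- function(map, chrom, pos) {
    stopifnot(all(c("chrom", "pos", "cM") %in% names(map)))
    out <- rep(NA_real_, length(pos))
    for (ch in unique(chrom)) {
        m <- map[map$chrom == ch, ]
        if (!nrow(m)) stop("genetic map has no entries for chromosome ", ch)
        if (is.unsorted(m$pos, strictly = TRUE) ||
            is.unsorted(m$cM, strictly = TRUE))
            stop("genetic map not strictly increasing on chromosome ", ch)
        i <- chrom == ch
        out[i] <- stats::approx(m$pos, m$cM, xout = pos[i], rule = 2)$y
    }
    out
}

#' Read a phased VCF into a haplotype panel or genotype matrix
#'
#' Parses GT fields; in haplotype mode every genotype must be phased
#' ("a|b") and diploid, and two haplotype columns per sample are produced.
#' In dosage mode unphased genotypes are accepted and collapsed to 0/1/2.
#' Missing GT becomes NA. cM positions come from `map` (a genetic-map table)
#' or a uniform `cmPerMb` rate.
#'
#' @param path VCF file (plain or gzipped).
#' @param region optional "chrom:start-end" restriction (1-based inclusive).
#' @param mode `"haplotype"` or `"dosage"`.
#' @param map optional genetic-map data.frame for [geneticMapInterpolate()].
#' @param cmPerMb uniform map rate used when `map` is NULL (default 1).
#' @return a [HaplotypePanel-class] or [GenotypeMatrix-class].
#' @export
readPhasedVcf <- function(path, region = NULL, mode = c("haplotype", "dosage"),
                          map = NULL, cmPerMb = 1) {
    mode <- match.arg(mode)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    chrom <- fix[, "CHROM"]; pos <- as.numeric(fix[, "POS"])
    if (!is.null(region)) {
        rg <- parseRegion(region)
        keep <- chrom == as.character(seqnames(rg)) & pos >= start(rg) &
            pos <= end(rg)
        v@fix <- v@fix[keep, , drop = FALSE]
        v@gt <- v@gt[keep, , drop = FALSE]
        fix <- fix[keep, , drop = FALSE]
        chrom <- chrom[keep]; pos <- pos[keep]
    }
    if (!nrow(fix)) stop("no variants in the requested region")
    gt <- vcfR::extract.gt(v, element = "GT")
    cM <- if (is.null(map)) pos / 1e6 * cmPerMb else
        geneticMapInterpolate(map, chrom, pos)
    vr <- .makeVariants(chrom, pos, fix[, "REF"], fix[, "ALT"], cM)
    samples <- colnames(gt)
    gtMiss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
    if (mode == "haplotype") {
        if (any(!gtMiss & !grepl("^[0-9]+\\|[0-9]+$", gt)))
            stop("unphased or non-diploid genotypes present; ",
                 "use mode = \"dosage\" or phase the data")
        a1 <- suppressWarnings(as.integer(sub("\\|.*", "", gt)))
        a2 <- suppressWarnings(as.integer(sub(".*\\|", "", gt)))
        a1[gtMiss] <- NA_integer_; a2[gtMiss] <- NA_integer_
        A <- matrix(NA_integer_, nrow(gt), 2L * ncol(gt))
        A[, seq(1L, ncol(A), 2L)] <- a1
        A[, seq(2L, ncol(A), 2L)] <- a2
        if (any(A > 1L, na.rm = TRUE))
            stop("multiallelic genotype codes present; split records first")
        new("HaplotypePanel", alleles = A, variants = vr,
            haplotypeIds = paste0(rep(samples, each = 2L), "_", c(1L, 2L)))
    } else {
        g <- gsub("\\|", "/", gt)
        nAllele <- lengths(regmatches(g, gregexpr("[0-9]+", g)))
        if (any(!gtMiss & nAllele != 2L))
            stop("mixed ploidy in GT fields")
        dose <- (as.integer(sub("/.*", "", g)) > 0) +
            (as.integer(sub(".*/", "", g)) > 0)
        dose[gtMiss] <- NA_integer_
        d <- matrix(dose, nrow(gt), ncol(gt), dimnames = list(NULL, samples))
        new("GenotypeMatrix", dosage = d, variants = vr,
            phased = all(grepl("\\|", gt[!gtMiss])))
    }
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal phased VCF (GT-only, "a|b" genotypes, missing as ".|.").
#' The file is gzip-compressed; use a ".vcf.gz" path.
#'
#' @param panel a [HaplotypePanel-class] with an even number of haplotypes.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePhasedVcf <- function(panel, path) {
    A <- alleles(panel)
    if (ncol(A) %% 2L) stop("need two haplotypes per sample")
    vr <- variantRanges(panel)
    samples <- unique(sub("_[12]$", "", haplotypeIds(panel)))
    if (length(samples) != ncol(A) / 2L)   # ids without the _1/_2 convention
        samples <- sprintf("S%03d", seq_len(ncol(A) / 2L))
    h1 <- A[, seq(1L, ncol(A), 2L), drop = FALSE]
    h2 <- A[, seq(2L, ncol(A), 2L), drop = FALSE]
    gtBody <- matrix(paste0(h1, "|", h2), nrow(A),
                     dimnames = list(NULL, samples))
    gtBody[is.na(h1) | is.na(h2)] <- ".|."
    fix <- cbind(CHROM = as.character(seqnames(vr)),
                 POS = as.character(start(vr)), ID = ".",
                 REF = mcols(vr)$ref, ALT = mcols(vr)$alt,
                 QUAL = ".", FILTER = "PASS", INFO = ".")
    out <- new("vcfR",
               meta = c("##fileformat=VCFv4.2",
                        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
               fix = fix, gt = cbind(FORMAT = "GT", gtBody))
    vcfR::write.vcf(out, path)
    invisible(path)
}

#' Read per-haplotype ancestry calls from TSV
#'
#' Expects a tab-separated file with header columns `chrom`, `pos`, then one
#' column per haplotype id, one row per variant, labels in `alphabet`.
#' Ragged rows and unknown labels are reported with their line numbers.
#'
#' @param path TSV path (the format written by [writeAncestryCalls()], and
#'   the shape of per-variant Viterbi output from local-ancestry callers).
#' @param alphabet admissible labels (default EUR/AFR/NAT; "UNK" is always
#'   allowed).
#' @param expectedSamples optional sample ids to reconcile against; calls for
#'   missing/extra samples raise an error listing the ids.
#' @return an [AncestryCalls-class].
#' @export
readAncestryCalls <- function(path, alphabet = c("EUR", "AFR", "NAT"),
                              expectedSamples = NULL) {
    lines <- readLines(path)
    if (length(lines) < 2L) stop("ancestry file has no data rows")
    cells <- strsplit(lines, "\t", fixed = TRUE)
    header <- cells[[1]]
    if (!identical(header[1:2], c("chrom", "pos")))
        stop("header must start with 'chrom' and 'pos'")
    ragged <- which(lengths(cells) != length(header))
    if (length(ragged))
        stop("ragged rows at line(s): ",
             paste(utils::head(ragged, 5), collapse = ", "))
    body <- do.call(rbind, cells[-1])
    lab <- body[, -(1:2), drop = FALSE]
    bad <- !(lab %in% c(alphabet, "UNK"))
    if (any(bad)) {
        badLine <- unique(row(lab)[bad]) + 1L
        stop("unknown ancestry labels (e.g. '",
             lab[bad][1], "') at line(s): ",
             paste(utils::head(badLine, 5), collapse = ", "))
    }
    hapIds <- header[-(1:2)]
    if (!is.null(expectedSamples)) {
        got <- unique(sub("_[12]$", "", hapIds))
        miss <- setdiff(expectedSamples, got)
        extra <- setdiff(got, expectedSamples)
        if (length(miss) || length(extra))
            stop("sample reconciliation failed; missing: [",
                 paste(miss, collapse = ", "), "], unexpected: [",
                 paste(extra, collapse = ", "), "]")
    }
    vr <- GRanges(body[, 1], IRanges(as.numeric(body[, 2]),
                                     as.numeric(body[, 2])))
    new("AncestryCalls", labels = matrix(lab, nrow = nrow(body),
                                         dimnames = list(NULL, hapIds)),
        variants = vr, haplotypeIds = hapIds, alphabet = alphabet)
}

#' Write ancestry calls as TSV
#'
#' @param calls an [AncestryCalls-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAncestryCalls <- function(calls, path) {
    vr <- variantRanges(calls)
    df <- data.frame(chrom = as.character(seqnames(vr)), pos = start(vr))
    lab <- ancestryLabels(calls)
    colnames(lab) <- haplotypeIds(calls)
    utils::write.table(cbind(df, lab), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write true ancestry tracts as BED
#'
#' One 0-based half-open BED record per maximal single-ancestry run of
#' variants per haplotype (tract bounds are the first/last member variant's
#' position).
#'
#' @param calls an [AncestryCalls-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTractsBed <- function(calls, path) {
    vr <- variantRanges(calls)
    sq <- as.character(seqnames(vr)); pos <- start(vr)
    lab <- ancestryLabels(calls)
    con <- file(path, "w")
    on.exit(close(con))
    for (h in seq_len(ncol(lab))) {
        for (ch in unique(sq)) {
            i <- which(sq == ch)
            r <- rle(lab[i, h])
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            bed <- toBedCoords(pos[i[starts]], pos[i[ends]])
            writeLines(sprintf("%s\t%d\t%d\t%s\t%s", ch, bed$bed_start,
                               bed$bed_end, haplotypeIds(calls)[h],
                               r$values), con)
        }
    }
    invisible(path)
}

#' Write the per-variant ancestry proportion track
#'
#' BEDGRAPH-like TSV: chrom, 0-based start, end, one proportion column per
#' ancestry.
#'
#' @param track an `"ancestryTrack"` from [perVariantProportions()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProportionsTrack <- function(track, path) {
    vr <- track$variants
    bed <- toBedCoords(start(vr), start(vr))
    df <- cbind(data.frame(chrom = as.character(seqnames(vr)),
                           start = bed$bed_start, end = bed$bed_end),
                as.data.frame(track$proportions))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a QC report as TSV plus JSON ledger
#'
#' @param report a [QCReport-class].
#' @param pathTsv,pathJson output paths (either may be NULL to skip).
#' @return invisibly, a list of the written paths.
#' @export
writeQcReport <- function(report, pathTsv = NULL, pathJson = NULL) {
    if (!is.null(pathTsv))
        utils::write.table(qcSteps(report), pathTsv, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    if (!is.null(pathJson))
        jsonlite::write_json(list(steps = qcSteps(report),
                                  removed = removedIds(report)),
                             pathJson, auto_unbox = TRUE, digits = NA)
    invisible(list(tsv = pathTsv, json = pathJson))
}
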