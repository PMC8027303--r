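.stageError <- function(stage, e, manifest) {
    stop(sprintf("pipeline stage '%s' failed: %s [stages completed: %s]",
                 stage, conditionMessage(e),
                 paste(names(manifest$timings), collapse = ", ")),
         call. = FALSE)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages — simulate, qc, ancestry, structure, scan,
#' summarize — in order, writing every stage's outputs under `outDir` and
#' collecting a run manifest (config snapshot, seeds, package version,
#' per-stage timings, decisions such as the ancestral-allele proxy, and md5
#' digests of the written files). Identical config and seed reproduce
#' identical outputs. A stage is run when its config entry is present; a
#' stage whose preconditions are unmet aborts naming the stage and the
#' missing input.
#'
#' @param config nested list; see Details.
#' @param outDir output directory (created if absent).
#'
#' @details Recognised entries, all optional except `seed`:
#' \describe{
#'   \item{simulate}{list(nVariants, nIndividuals, proportions, generations,
#'     fst, nHaplotypesPerPop, afRange, sweep = list(region, ancestry,
#'     proportion))}
#'   \item{qc}{list(hweP, maxMissing, hetSd, relThreshold, minMaf, ldPrune)}
#'   \item{ancestry}{list(region, zThreshold, flankBp, coreAncestry)}
#'   \item{structure}{list(k, nSnps, nPermutations, inversionRegion)}
#'   \item{scan}{list(mafMin, nBins, cutoff, maxExtendCm, outlierQ,
#'     blockSize, blockQ)}
#'   \item{summarize}{list(afTable, predictions, threshold) — paths to TSV
#'     inputs or data.frames}
#' }
#' Stages after `simulate` consume its outputs; `qc`/`ancestry`/`scan` abort
#' if no cohort is available (external-input runs must supply `vcf`, and for
#' scan additionally `map` and reference panels, in their config entries).
#'
#' @return list with per-stage results and `manifest`, which is also written
#'   to `outDir/manifest.json`.
#' @export
runPipeline <- function(config, outDir = tempfile("admixscan_run_")) {
    stopifnot(is.list(config), !is.null(config$seed))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(config = config, seed = config$seed,
                     version = as.character(utils::packageVersion("admixscan")),
                     timings = list(), decisions = list(), files = list())
    results <- list()
    cohort <- NULL; panels <- NULL
    tic <- function() Sys.time()
    took <- function(stage, t0) {
        manifest$timings[[stage]] <<- round(
            as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    }

    if (!is.null(config$simulate)) {
        t0 <- tic()
        tryCatch({
            sc <- config$simulate
            am <- ancestralModel(
                pops = names(sc$proportions %||% c(EUR = .746, AFR = .16,
                                                   NAT = .094)),
                fst = sc$fst %||% stats::setNames(
                    rep(0.15, length(sc$proportions %||% 1:3)),
                    names(sc$proportions %||% c(EUR = 1, AFR = 2, NAT = 3))),
                afRange = sc$afRange %||% c(0.05, 0.95),
                nHaplotypes = sc$nHaplotypesPerPop %||% 100L)
            panels <- generateAncestralPanels(am, sc$nVariants %||% 5000L,
                                               seed = config$seed)
            mm <- admixtureModel(
                proportions = sc$proportions %||% c(EUR = .746, AFR = .16,
                                                    NAT = .094),
                generations = sc$generations %||% 16,
                nIndividuals = sc$nIndividuals %||% 100L)
            cohort <- simulateAdmixedCohort(panels, mm,
                                             seed = config$seed + 1L)
            if (!is.null(sc$sweep))
                cohort <- injectAncestrySweep(cohort, panels,
                                               sc$sweep$region,
                                               sc$sweep$ancestry,
                                               sc$sweep$proportion,
                                               seed = config$seed + 2L)
            vcfPath <- file.path(outDir, "cohort.vcf.gz")
            writePhasedVcf(haplotypePanel(cohort), vcfPath)
            writeAncestryCalls(truthCalls(cohort),
                               file.path(outDir, "truth.tsv"))
            writeTractsBed(truthCalls(cohort),
                           file.path(outDir, "tracts.bed"))
            utils::write.table(sampleMetadata(cohort),
                               file.path(outDir, "samples.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            results$simulate <- cohort
        }, error = function(e) .stageError("simulate", e, manifest))
        took("simulate", t0)
    }

    gmQc <- NULL
    if (!is.null(config$qc)) {
        t0 <- tic()
        tryCatch({
            qcCfg <- config$qc
            gm <- if (!is.null(cohort)) asGenotypeMatrix(cohort)
                else if (!is.null(qcCfg$vcf))
                    readPhasedVcf(qcCfg$vcf, mode = "dosage")
                else stop("no cohort and no 'vcf' input configured")
            res <- qcPipeline(gm,
                hweP = qcCfg$hweP %||% 1e-6,
                maxMissing = qcCfg$maxMissing %||% 0.10,
                hetSd = qcCfg$hetSd %||% 3,
                relThreshold = qcCfg$relThreshold %||% 0.125,
                minMaf = qcCfg$minMaf %||% 0.01,
                ldPruneStep = qcCfg$ldPrune %||% TRUE)
            writeQcReport(res$report, file.path(outDir, "qc_report.tsv"),
                          file.path(outDir, "qc_ledger.json"))
            gmQc <- res$genotypes
            results$qc <- res
        }, error = function(e) .stageError("qc", e, manifest))
        took("qc", t0)
    }

    if (!is.null(config$ancestry)) {
        t0 <- tic()
        tryCatch({
            aCfg <- config$ancestry
            calls <- if (!is.null(cohort)) truthCalls(cohort)
                else if (!is.null(aCfg$calls)) readAncestryCalls(aCfg$calls)
                else stop("no cohort and no 'calls' input configured")
            track <- perVariantProportions(calls)
            writeProportionsTrack(track,
                                  file.path(outDir, "ancestry_track.tsv"))
            out <- list(track = track)
            if (!is.null(cohort))
                out$groups <- groupMeans(calls, sampleMetadata(cohort))
            if (!is.null(aCfg$region)) {
                out$deviation <- regionDeviation(track, aCfg$region,
                                                 aCfg$zThreshold %||% 3)
                out$patterns <- flankingPatterns(calls, aCfg$region,
                                                 aCfg$flankBp %||% 3.7e6,
                                                 aCfg$coreAncestry %||% "NAT")
                jsonlite::write_json(
                    list(deviation = out$deviation,
                         patterns = out$patterns$counts),
                    file.path(outDir, "ancestry_region.json"),
                    auto_unbox = TRUE, digits = NA)
            }
            results$ancestry <- out
        }, error = function(e) .stageError("ancestry", e, manifest))
        took("ancestry", t0)
    }

    if (!is.null(config$structure)) {
        t0 <- tic()
        tryCatch({
            sCfg <- config$structure
            gm <- gmQc %||% (if (!is.null(cohort)) asGenotypeMatrix(cohort)
                             else stop("no genotype matrix available"))
            out <- list(pca = pcaGenotypes(gm, sCfg$k %||% 10L))
            utils::write.table(out$pca$coordinates,
                               file.path(outDir, "pca.tsv"), sep = "\t",
                               quote = FALSE, col.names = NA)
            if (!is.null(cohort) &&
                length(unique(sampleMetadata(cohort)$group)) >= 2) {
                keep <- colnames(dosage(gm))
                md <- sampleMetadata(cohort)
                out$amova <- amova(gm, md$group[match(keep, md$sample_id)],
                                   nSnps = sCfg$nSnps %||% 10000L,
                                   nPermutations = sCfg$nPermutations %||% 999L,
                                   seed = config$seed + 3L)
                jsonlite::write_json(unclass(out$amova),
                                     file.path(outDir, "amova.json"),
                                     auto_unbox = TRUE, digits = NA)
            }
            if (!is.null(sCfg$inversionRegion))
                out$inversion <- inversionCluster(
                    subsetRegion(gm, sCfg$inversionRegion), k = 3L)
            results$structure <- out
        }, error = function(e) .stageError("structure", e, manifest))
        took("structure", t0)
    }

    if (!is.null(config$scan)) {
        t0 <- tic()
        tryCatch({
            kCfg <- config$scan
            if (is.null(cohort) || is.null(panels))
                stop("scan needs a simulated cohort with its reference ",
                     "panels (or configure focal VCF, reference VCFs and a ",
                     "genetic map)")
            res <- runScan(haplotypePanel(cohort), panels,
                mafMin = kCfg$mafMin %||% 0.05,
                nBins = kCfg$nBins %||% 50L,
                cutoff = kCfg$cutoff %||% 0.05,
                maxExtendCm = kCfg$maxExtendCm %||% 50,
                outlierQ = kCfg$outlierQ %||% 0.99,
                blockSize = kCfg$blockSize %||% 100L,
                blockQ = kCfg$blockQ %||% 0.995)
            utils::write.table(res$table, file.path(outDir, "scan.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            sel <- res$blocks[res$blocks$selected, , drop = FALSE]
            bed <- toBedCoords(sel$start, sel$end)
            writeLines(sprintf("%s\t%d\t%d\tselected_block_%d", sel$chrom,
                               bed$bed_start, bed$bed_end, sel$block),
                       file.path(outDir, "selected_regions.bed"))
            manifest$decisions$scan <- res$manifest
            results$scan <- res
        }, error = function(e) .stageError("scan", e, manifest))
        took("scan", t0)
    }

    if (!is.null(config$summarize)) {
        t0 <- tic()
        tryCatch({
            zCfg <- config$summarize
            if (is.null(zCfg$afTable))
                stop("summarize needs an 'afTable' input")
            af <- if (is.character(zCfg$afTable))
                utils::read.delim(zCfg$afTable) else zCfg$afTable
            out <- list(classification = classifyAf(
                af, threshold = zCfg$threshold %||% 0.01))
            if (!is.null(zCfg$predictions)) {
                pm <- if (is.character(zCfg$predictions))
                    utils::read.delim(zCfg$predictions, row.names = 1)
                    else zCfg$predictions
                out$concordance <- predictorConcordance(pm)
            }
            if (!is.null(zCfg$annotation)) {
                ann <- if (is.character(zCfg$annotation))
                    utils::read.delim(zCfg$annotation) else zCfg$annotation
                out$consequences <- consequenceTally(ann)
            }
            jsonlite::write_json(
                list(counts = out$classification$counts,
                     cellPct = out$classification$cellPct,
                     fisher_p = out$classification$test$fisher_p),
                file.path(outDir, "af_classification.json"),
                auto_unbox = TRUE, digits = NA)
            results$summarize <- out
        }, error = function(e) .stageError("summarize", e, manifest))
        took("summarize", t0)
    }

    written <- list.files(outDir, full.names = TRUE)
    written <- written[!grepl("manifest\\.json$", written)]
    manifest$files <- as.list(tools::md5sum(written))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    results$manifest <- manifest
    results$outDir <- outDir
    invisible(results)
}
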