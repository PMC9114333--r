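## End-to-end orchestration: simulate or ingest, chromosome filter, TAD
## assignment, normalization, correlation map, survival screen, modelling
## chain, differential accessibility, open-peak statistics, JSON report.

#' Default pipeline thresholds
#'
#' The analysis gates used throughout the pipeline: correlation strength
#' `r2_min` (0.6), TAD containment `tad_fraction` (0.9), consensus merge
#' `merge_fraction` (0.5), variance filter `variance` (0.45), features
#' kept after importance ranking `top_k` (20), differential gates
#' `lfc_min` (0.3) and `fdr_max` (0.05), and the open-peak abundance
#' cut-off `tpm_threshold` (10).
#'
#' @return Named list of threshold defaults.
#' @export
pipelineThresholds <- function() {
  list(r2_min = 0.6, tad_fraction = 0.9, merge_fraction = 0.5,
       variance = 0.45, top_k = 20, lfc_min = 0.3, fdr_max = 0.05,
       tpm_threshold = 10)
}

#' Read a pipeline configuration from YAML
#'
#' The file must contain exactly one of `simulate:` (arguments for
#' [simulationConfig()]) or `inputs:` (paths `cohort`, `peaks_bed`,
#' `tads_bed`, `genes_bed`, `peak_counts`, `gene_counts`), plus optional
#' `thresholds:` overriding [pipelineThresholds()] and a `seed`.
#'
#' @param path path to a YAML file.
#' @return A validated config list for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
}

validatePipelineConfig <- function(cfg) {
  if (is.null(cfg$simulate) == is.null(cfg$inputs))
    stop("config must contain exactly one of 'simulate' or 'inputs'")
  th <- pipelineThresholds()
  extra <- setdiff(names(cfg$thresholds), names(th))
  if (length(extra) > 0)
    stop("unknown threshold(s): ", paste(extra, collapse = ", "))
  th[names(cfg$thresholds)] <- cfg$thresholds
  stopifnot(th$r2_min >= 0, th$r2_min <= 1,
            th$tad_fraction > 0, th$tad_fraction <= 1,
            th$merge_fraction > 0, th$merge_fraction <= 1,
            th$variance >= 0, th$top_k >= 1,
            th$fdr_max >= 0, th$fdr_max <= 1)
  cfg$thresholds <- th
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

.stage <- function(name, expr) {
  message("[atacmap] stage: ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full accessibility analysis pipeline
#'
#' Executes, in order: input simulation or ingestion, chromosome
#' filtering, TAD assignment, library-size normalization, the
#' TAD-constrained peak-gene correlation map (on the expression-profiled
#' sample subset), the peak-survival screen, the prognostic modelling
#' chain (variance filter, forest importance ranking, top-k, elastic net,
#' compact linear model, three-way model comparison), group-vs-rest
#' differential accessibility, and per-sample open-peak statistics. Stage
#' outputs and a machine-readable JSON report are written to `outputDir`.
#'
#' @param config list from [readPipelineConfig()] or built in code; see
#'   that function for the schema.
#' @param outputDir directory for stage outputs and `report.json`
#'   (created if needed).
#' @return The report, invisibly (also written as JSON).
#' @export
runPipeline <- function(config, outputDir = tempfile("atacmap_run_")) {
  config <- validatePipelineConfig(config)
  th <- config$thresholds
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  report <- list(seed = config$seed, thresholds = th)

  if (!is.null(config$simulate)) {
    sim <- .stage("simulate", {
      simArgs <- config$simulate
      if (isTRUE(simArgs) || length(simArgs) == 0) simArgs <- list()
      simArgs$seed <- config$seed
      scfg <- do.call(simulationConfig, simArgs)
      genome <- simulateGenome(scfg)
      cohort <- simulateCohort(scfg)
      counts <- simulateCounts(genome, cohort, scfg)
      rad <- simulateRadiationPairs(genome, scfg)
      list(cfg = scfg, genome = genome, cohort = cohort,
           peakCounts = counts$peakCounts, geneCounts = counts$geneCounts,
           truth = counts$groundTruth, radiation = rad)
    })
    cohort <- sim$cohort
    peaks <- sim$genome$peaks; genes <- sim$genome$genes
    tads <- sim$genome$tads
    peakCounts <- sim$peakCounts; geneCounts <- sim$geneCounts
  } else {
    ing <- .stage("ingest", {
      inp <- config$inputs
      need <- c("cohort", "peaks_bed", "tads_bed", "genes_bed",
                "peak_counts", "gene_counts")
      miss <- setdiff(need, names(inp))
      if (length(miss) > 0)
        stop("missing input path(s): ", paste(miss, collapse = ", "))
      list(cohort = readCohortTable(inp$cohort),
           peaks = readBed(inp$peaks_bed), tads = readBed(inp$tads_bed),
           genes = readBed(inp$genes_bed),
           peakCounts = readCountMatrix(inp$peak_counts),
           geneCounts = readCountMatrix(inp$gene_counts))
    })
    cohort <- ing$cohort
    peaks <- ing$peaks; genes <- ing$genes; tads <- ing$tads
    if (is.null(names(peaks))) names(peaks) <- peakIDsFromCoords(peaks)
    peakCounts <- ing$peakCounts; geneCounts <- ing$geneCounts
  }
  report$cohort <- {
    s <- summarizeCohort(cohort)
    list(n_total = s@nTotal, by_grade_stage = as.list(s@nByGradeStage),
         by_idh1 = as.list(s@nByIDH1), n_rnaseq = s@nRNAseq,
         n_paired_patients = s@nPairedPatients)
  }

  peaks <- .stage("chromosome_filter", filterChromosomes(peaks))
  peakCounts <- peakCounts[intersect(rownames(peakCounts), names(peaks)), ,
                           drop = FALSE]
  peaks <- peaks[rownames(peakCounts)]
  report$n_peaks_after_chromosome_filter <- length(peaks)

  tadMap <- .stage("tad_assignment",
                   assignToTAD(peaks, tads, th$tad_fraction))
  geneTadMap <- assignToTAD(genes, tads, th$tad_fraction)
  report$n_peaks_in_tad <- length(tadMap)

  norm <- .stage("normalize", {
    list(peaks = logNormalize(peakCounts),
         genes = logNormalize(geneCounts))
  })
  writeBed(peaks, file.path(outputDir, "consensus_peaks.bed"))
  exportPeaksGTF(peaks, file.path(outputDir, "consensus_peaks.gtf"))

  rnaSamples <- sampleIDs(cohort)[records(cohort)$has_rnaseq]
  pairs <- .stage("correlation_map", {
    pg <- peakGeneCorrelations(norm$peaks[, rnaSamples],
                               norm$genes[, rnaSamples],
                               tadMap, geneTadMap, peaks, genes)
    writePairTable(pg, file.path(outputDir, "peak_gene_pairs.tsv"))
    pg
  })
  linked <- thresholdByR2(pairs, th$r2_min)
  report$n_pairs_total <- nrow(pairs)
  report$n_pairs_linked <- nrow(linked)
  if (nrow(linked) > 0) {
    report$sign_fraction_links <- signFraction(linked)
    report$nearest_gene_concordance <- nearestGeneConcordance(linked)
  }

  surv <- survivalVector(cohort, colnames(normValues(norm$peaks)))
  survCor <- .stage("survival_screen",
                    peakSurvivalCorrelations(norm$peaks, surv))
  survLinked <- thresholdByR2(survCor, th$r2_min)
  report$n_survival_associations <- nrow(survLinked)
  if (nrow(survLinked) > 0)
    report$sign_fraction_survival <- signFraction(survLinked)

  model <- .stage("modelling_chain", {
    kept <- varianceFilter(norm$peaks, th$variance)
    X <- t(normValues(norm$peaks)[kept, , drop = FALSE])
    ranking <- rfImportanceRanking(X, as.numeric(surv), seed = config$seed)
    utils::write.table(
      data.frame(feature_id = ranking@featureIDs,
                 importance = ranking@importance),
      file.path(outputDir, "importance_ranking.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    topK <- selectTopK(ranking, min(th$top_k, length(kept)))
    enet <- elasticNetFit(X[, topK, drop = FALSE], as.numeric(surv))
    nz <- names(sort(abs(nonzeroCoefficients(enet)), decreasing = TRUE))
    if (length(nz) >= 1) {
      six <- head(nz, 6)
      rule <- "nonzero_elastic_net_coefficients"
    } else {
      six <- head(topK, 6)
      rule <- "top_importance_fallback"
    }
    lmfit <- linearModelFit(X[, six, drop = FALSE], as.numeric(surv))
    ## leave-one-out R2 for the compact model via the hat matrix (PRESS)
    D <- cbind(1, X[, six, drop = FALSE])
    h <- diag(D %*% solve(crossprod(D)) %*% t(D))
    resid <- as.numeric(surv) - (lmfit@intercept +
                                   X[, six, drop = FALSE] %*% lmfit@coefficients)
    pressR2 <- 1 - sum((resid / (1 - h))^2) /
      sum((surv - mean(surv))^2)
    cmp <- compareModels(X[, topK, drop = FALSE], cohort)
    list(ranking = ranking, topK = topK, enet = enet, six = six,
         rule = rule, lmfit = lmfit, pressR2 = pressR2, cmp = cmp,
         nKept = length(kept))
  })
  report$n_variance_filtered_peaks <- model$nKept
  report$rf_oob_r2 <- oobR2(model$ranking)
  report$top_peaks <- model$topK
  report$six_peak_model <- list(
    peaks = model$six, selection_rule = model$rule,
    r2_in_sample = model$lmfit@r2InSample,
    r2_loocv = model$pressR2)
  report$model_comparison <- list(
    cv_r2_peaks = as.numeric(model$cmp$cvR2["peaks"]),
    cv_r2_clinical = as.numeric(model$cmp$cvR2["clinical"]),
    cv_r2_combined = as.numeric(model$cmp$cvR2["combined"]),
    n_samples = length(model$cmp$samples),
    alpha = vapply(model$cmp[c("peaks", "clinical", "combined")],
                   function(f) f@alpha, 0),
    lambda = vapply(model$cmp[c("peaks", "clinical", "combined")],
                    function(f) f@lambda, 0))
  jsonlite::write_json(
    c(report$model_comparison,
      list(nonzero_coefficients = lapply(
        model$cmp[c("peaks", "clinical", "combined")],
        function(f) as.list(nonzeroCoefficients(f))))),
    file.path(outputDir, "model_report.json"),
    auto_unbox = TRUE, digits = NA)

  rec <- records(cohort)
  groups <- paste(rec$grade, rec$stage, sep = ".")
  diffRes <- .stage("differential_accessibility", {
    res <- lapply(unique(groups), function(g)
      groupVsRestTest(norm$peaks, groups, g))
    names(res) <- unique(groups)
    allRes <- do.call(rbind, res)
    utils::write.table(allRes,
                       file.path(outputDir, "differential_accessibility.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  sigByGroup <- lapply(diffRes, significantPeaks,
                       lfcMin = th$lfc_min, fdrMax = th$fdr_max)
  tallies <- gradePeakGeneCounts(sigByGroup, pairs, th$r2_min)
  report$grade_counts <- tallies

  stats <- .stage("peak_count_statistics", {
    tpm <- tpmNormalize(peakCounts, peaks[rownames(peakCounts)])
    open <- totalOpenPeaks(tpm, th$tpm_threshold)
    byGroup <- split(as.numeric(open), groups)
    an <- if (length(byGroup) >= 2 &&
              all(vapply(byGroup, length, 1L) >= 2))
      anovaPeakCounts(byGroup) else list(F = NA_real_, p = NA_real_)
    pairedIds <- names(which(table(rec$patient_id[!is.na(rec$patient_id)]) >= 2))
    deltas <- if (length(pairedIds) > 0) {
      pre <- post <- setNames(numeric(length(pairedIds)), pairedIds)
      for (pid in pairedIds) {
        ids <- rec$sample_id[!is.na(rec$patient_id) & rec$patient_id == pid]
        st <- rec$stage[match(ids, rec$sample_id)]
        pre[pid] <- open[ids[st == "primary"][1]]
        post[pid] <- open[ids[st == "recurrent"][1]]
      }
      pairedDelta(pre, post)
    } else numeric(0)
    list(open = open, anova = an, deltas = deltas)
  })
  report$total_open_peaks_mean_by_group <-
    lapply(split(as.numeric(stats$open), groups), mean)
  report$anova_open_peaks <- stats$anova
  report$paired_open_peak_deltas <- as.list(stats$deltas)

  if (!is.null(config$simulate)) {
    rad <- sim$radiation
    radTpm <- tpmNormalize(rad$counts,
                           GenomicRanges::width(sim$genome$peaks))
    radOpen <- totalOpenPeaks(radTpm, th$tpm_threshold)
    report$radiation_deltas <- as.list(
      pairedDelta(setNames(radOpen[rad$pairs$pre], rad$pairs$line),
                  setNames(radOpen[rad$pairs$post], rad$pairs$line)))
    truth <- sim$truth
    plantedKey <- paste(truth$plantedLinks$peak_id,
                        truth$plantedLinks$gene_id)
    linkedKey <- paste(linked$peak_id, linked$gene_id)
    report$link_recovery <- list(
      recall = mean(plantedKey %in% linkedKey),
      precision = if (nrow(linked) > 0)
        mean(linkedKey %in% plantedKey) else NA_real_)
  }

  jsonlite::write_json(report, file.path(outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("[atacmap] report written to ",
          file.path(outputDir, "report.json"))
  invisible(report)
}
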