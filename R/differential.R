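## Group-vs-rest differential accessibility (Welch test on log-normalized
## values, BH FDR), threshold-gated peak sets, grade tallies, total-peak
## comparisons and paired deltas.

#' Group-versus-rest differential accessibility test
#'
#' For every peak, a two-sided Welch two-sample t-test of the group's
#' samples against all remaining samples, on log-normalized values; the
#' effect size is `log2fc = mean(group) - mean(rest)` (already a log2 fold
#' change on this scale). Peaks with zero variance in both groups are
#' flagged and given `p = 1` when the means agree (no evidence) or `p = 0`
#' when a deterministic difference is observed.
#'
#' @param nm [NormalizedMatrix-class] (or plain matrix) of log2 values.
#' @param labels character vector of group labels, one per sample.
#' @param group the label to test against the rest; must occur in
#'   `labels`, with at least 2 samples on each side.
#' @return data.frame with columns `peak_id`, `group`, `log2fc`,
#'   `p_value`, `fdr`, `flagged`.
#' @export
groupVsRestTest <- function(nm, labels, group) {
  values <- if (methods::is(nm, "NormalizedMatrix")) normValues(nm) else nm
  if (length(labels) != ncol(values))
    stop("one label per sample required")
  if (!group %in% labels)
    stop("group not present in labels: ", group)
  inG <- labels == group
  n1 <- sum(inG); n2 <- sum(!inG)
  if (n1 < 2 || n2 < 2)
    stop("need at least 2 samples in the group and in the rest")
  g <- values[, inG, drop = FALSE]
  r <- values[, !inG, drop = FALSE]
  m1 <- rowMeans(g); m2 <- rowMeans(r)
  v1 <- rowSums((g - m1)^2) / (n1 - 1)
  v2 <- rowSums((r - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  res <- data.frame(peak_id = rownames(values), group = group,
                    log2fc = m1 - m2, p_value = p, fdr = bhFdr(p),
                    flagged = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with the usual monotonicity enforcement.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values of the same length.
#' @export
bhFdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Select significantly enriched peaks
#'
#' Applies the joint fold-change and FDR gate, both bounds inclusive.
#' Enrichment is directional by default -- only peaks *more* accessible in
#' the group (`log2fc >= lfcMin`) are selected; `direction = "absolute"`
#' gates on `|log2fc|` instead.
#'
#' @param results data.frame from [groupVsRestTest()].
#' @param lfcMin minimum log2 fold change; default 0.3.
#' @param fdrMax maximum FDR; default 0.05.
#' @param direction `"greater"` (default) or `"absolute"`.
#' @return Character vector of selected peak ids.
#' @export
significantPeaks <- function(results, lfcMin = 0.3, fdrMax = 0.05,
                             direction = c("greater", "absolute")) {
  direction <- match.arg(direction)
  lfc <- if (direction == "absolute") abs(results$log2fc) else results$log2fc
  results$peak_id[lfc >= lfcMin & results$fdr <= fdrMax]
}

#' Grade-wise significant peak and linked-gene tallies
#'
#' For each group's significant peak set, counts the peaks and the
#' distinct genes linked to them in the correlation map at the given
#' `r2Min`.
#'
#' @param sigPeaksByGroup named list of peak-id vectors per group.
#' @param pairs data.frame from [peakGeneCorrelations()].
#' @param r2Min correlation-strength gate on links; default 0.6.
#' @return data.frame with columns `group`, `n_peaks`, `n_genes`.
#' @export
gradePeakGeneCounts <- function(sigPeaksByGroup, pairs, r2Min = 0.6) {
  linked <- thresholdByR2(pairs, r2Min)
  out <- lapply(names(sigPeaksByGroup), function(g) {
    pk <- sigPeaksByGroup[[g]]
    genes <- unique(linked$gene_id[linked$peak_id %in% pk])
    data.frame(group = g, n_peaks = length(pk), n_genes = length(genes),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' One-way ANOVA of per-sample open-peak totals across groups
#'
#' Fixed-effects one-way analysis of variance of total open-peak counts
#' (from [totalOpenPeaks()]) across sample groups.
#'
#' @param countsByGroup named list of numeric vectors, one per group,
#'   each with at least 2 samples; at least 2 groups.
#' @return list with elements `F` and `p`.
#' @export
anovaPeakCounts <- function(countsByGroup) {
  if (length(countsByGroup) < 2)
    stop("at least 2 groups required")
  if (any(vapply(countsByGroup, length, 1L) < 2))
    stop("each group needs at least 2 samples")
  df <- data.frame(
    count = unlist(countsByGroup, use.names = FALSE),
    group = factor(rep(names(countsByGroup),
                       vapply(countsByGroup, length, 1L))))
  tab <- anova(lm(count ~ group, data = df))
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1])
}

#' Post-minus-pre deltas for paired samples
#'
#' @param pre,post numeric vectors of per-sample totals with matching
#'   names (pair identifiers) and equal length.
#' @return Named numeric vector of `post - pre` deltas.
#' @export
pairedDelta <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length")
  if (!is.null(names(pre)) && !is.null(names(post))) {
    if (!setequal(names(pre), names(post)))
      stop("mismatched pair ids: ",
           paste(union(setdiff(names(pre), names(post)),
                       setdiff(names(post), names(pre))), collapse = ", "))
    post <- post[names(pre)]
  }
  post - pre
}

#' Export foreground/background peak sets for external motif analysis
#'
#' Writes two BED files (`foreground.bed`, `background.bed`) for use with
#' external motif-enrichment tools. The sets must be disjoint and the
#' foreground non-empty.
#'
#' @param foreground,background named [GenomicRanges::GRanges] peak sets.
#' @param dir output directory (created if needed).
#' @return Character vector of the two paths, invisibly.
#' @export
exportMotifSets <- function(foreground, background, dir) {
  if (length(foreground) == 0)
    stop("empty foreground set; nothing to enrich")
  fg <- if (is.null(names(foreground))) peakIDsFromCoords(foreground)
        else names(foreground)
  bg <- if (is.null(names(background))) peakIDsFromCoords(background)
        else names(background)
  shared <- intersect(fg, bg)
  if (length(shared) > 0)
    stop("foreground and background overlap: ",
         paste(head(shared, 5), collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("foreground.bed", "background.bed"))
  writeBed(foreground, paths[1])
  writeBed(background, paths[2])
  invisible(paths)
}
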