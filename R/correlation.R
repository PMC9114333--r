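## TAD-constrained peak-gene correlation map, peak-survival screen,
## r^2 thresholding and the summary fractions reported on the map.

#' Pearson correlation with explicit degenerate-input handling
#'
#' Standard product-moment coefficient; returns `NA` (rather than a silent
#' zero) when either vector has zero variance, so degenerate features can
#' be excluded downstream.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return The coefficient in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 observations required")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

## Row-wise Pearson of every row of m against every row of g (or vector y).
## Zero-variance rows give NA columns/rows.
.rowCor <- function(m, y) {
  mc <- m - rowMeans(m)
  ms <- sqrt(rowSums(mc^2))
  yc <- y - mean(y)
  ys <- sqrt(sum(yc^2))
  r <- as.numeric(mc %*% yc) / (ms * ys)
  r[ms == 0 | ys == 0] <- NA_real_
  r
}

#' TAD-constrained peak-gene correlation map
#'
#' Emits one candidate regulatory pair for every (peak, gene) combination
#' assigned to the same TAD, with the Pearson correlation of their
#' normalized profiles across the shared sample set. Pairs with undefined
#' correlation (constant peak or gene) are excluded. Each pair is annotated
#' with whether the gene is the peak's nearest gene (by TSS distance
#' against the full gene set, not just same-TAD genes) and the TSS
#' distance.
#'
#' @param peaksNM [NormalizedMatrix-class] of peak accessibility.
#' @param genesNM [NormalizedMatrix-class] of gene expression; must cover
#'   exactly the same samples (the expression-profiled subset).
#' @param peakTads named character vector peak id -> TAD id, from
#'   [assignToTAD()]; peaks absent from it contribute no pairs.
#' @param geneTads named character vector gene id -> TAD id.
#' @param peaks named [GenomicRanges::GRanges] of the peaks (for midpoints).
#' @param genes named [GenomicRanges::GRanges] of the full gene set.
#' @return data.frame with columns `peak_id`, `gene_id`, `tad_id`, `r`,
#'   `r2`, `is_nearest_gene`, `tss_distance`.
#' @export
peakGeneCorrelations <- function(peaksNM, genesNM, peakTads, geneTads,
                                 peaks, genes) {
  pv <- normValues(peaksNM)
  gv <- normValues(genesNM)
  if (!identical(colnames(pv), colnames(gv))) {
    onlyP <- setdiff(colnames(pv), colnames(gv))
    onlyG <- setdiff(colnames(gv), colnames(pv))
    if (length(onlyP) + length(onlyG) > 0)
      stop("sample sets differ; only in peaks: [",
           paste(onlyP, collapse = ", "), "]; only in genes: [",
           paste(onlyG, collapse = ", "), "]")
    gv <- gv[, colnames(pv), drop = FALSE]  # same set, different order
  }
  peakTads <- peakTads[names(peakTads) %in% rownames(pv)]
  geneTads <- geneTads[names(geneTads) %in% rownames(gv)]
  nearest <- nearestGeneTSS(peaks, genes)
  tss0 <- setNames(geneTSS(genes) - 1, names(genes))
  mid0 <- setNames(
    floor((GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) / 2),
    names(peaks))

  genesByTad <- split(names(geneTads), geneTads)
  out <- vector("list", length(peakTads))
  for (k in seq_along(peakTads)) {
    pid <- names(peakTads)[k]
    tad <- peakTads[[k]]
    gids <- genesByTad[[tad]]
    if (is.null(gids) || length(gids) == 0) next
    r <- .rowCor(gv[gids, , drop = FALSE], pv[pid, ])
    ok <- !is.na(r)
    if (!any(ok)) next
    gids <- gids[ok]; r <- r[ok]
    nn <- nearest$gene_id[match(pid, nearest$peak_id)]
    out[[k]] <- data.frame(
      peak_id = pid, gene_id = gids, tad_id = tad, r = r, r2 = r * r,
      is_nearest_gene = !is.na(nn) & gids == nn,
      tss_distance = abs(mid0[[pid]] - tss0[gids]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0)
    return(data.frame(peak_id = character(), gene_id = character(),
                      tad_id = character(), r = numeric(), r2 = numeric(),
                      is_nearest_gene = logical(), tss_distance = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Univariate peak-survival correlation screen
#'
#' Pearson correlation of each peak's normalized accessibility with
#' survival months, across all samples with accessibility data. Peaks with
#' constant accessibility are excluded.
#'
#' @param peaksNM [NormalizedMatrix-class] of peak accessibility.
#' @param survival named numeric vector of survival months; names must
#'   match the matrix samples exactly (order may differ).
#' @return data.frame with columns `peak_id`, `r`, `r2`.
#' @export
peakSurvivalCorrelations <- function(peaksNM, survival) {
  pv <- normValues(peaksNM)
  if (is.null(names(survival))) {
    if (length(survival) != ncol(pv))
      stop("survival length does not match sample count")
    names(survival) <- colnames(pv)
  }
  if (!setequal(names(survival), colnames(pv)))
    stop("survival samples do not match matrix samples; difference: ",
         paste(union(setdiff(names(survival), colnames(pv)),
                     setdiff(colnames(pv), names(survival))), collapse = ", "))
  survival <- survival[colnames(pv)]
  r <- .rowCor(pv, as.numeric(survival))
  keep <- !is.na(r)
  data.frame(peak_id = rownames(pv)[keep], r = r[keep], r2 = r[keep]^2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter correlation records by squared correlation
#'
#' Keeps records with `r2 >= r2Min`; the sign of `r` is untouched, so the
#' positive/negative tallies can still be formed afterwards.
#'
#' @param items data.frame carrying an `r2` column (and usually `r`).
#' @param r2Min threshold in `[0, 1]`; default 0.6.
#' @return The filtered data.frame.
#' @export
thresholdByR2 <- function(items, r2Min = 0.6) {
  if (!is.numeric(r2Min) || length(r2Min) != 1 || r2Min < 0 || r2Min > 1)
    stop("r2Min must be a single value in [0, 1]")
  items[items$r2 >= r2Min, , drop = FALSE]
}

#' Fraction of positively correlated records
#'
#' @param items non-empty data.frame carrying an `r` column.
#' @return Fraction of records with positive `r`, in `[0, 1]`.
#' @export
signFraction <- function(items) {
  if (nrow(items) == 0) stop("no correlation records")
  mean(items$r > 0)
}

#' Fraction of peak-gene pairs that point at the nearest gene
#'
#' @param pairs non-empty data.frame from [peakGeneCorrelations()].
#' @return Fraction of pairs whose gene is the peak's nearest gene.
#' @export
nearestGeneConcordance <- function(pairs) {
  if (nrow(pairs) == 0) stop("no peak-gene pairs")
  mean(pairs$is_nearest_gene)
}

#' Write a peak-gene pair table as TSV
#'
#' @param pairs data.frame from [peakGeneCorrelations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePairTable <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
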