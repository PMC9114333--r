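## Count-matrix ingestion, library-size normalization (median-of-ratios +
## log2 with pseudocount), TPM/CPM peak normalization, variance filtering,
## per-sample open-peak counts.

#' Read a feature-by-sample count matrix from TSV
#'
#' First column (or row names) are feature ids; remaining columns are
#' samples. Counts must be non-negative integers.
#'
#' @param path path to a tab-delimited count table.
#' @return Integer matrix with feature row names and sample column names.
#' @export
readCountMatrix <- function(path) {
  if (!file.exists(path)) stop("count matrix not found: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("count matrix has non-numeric entries: ", path)
  checkCountMatrix(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix in the layout [readCountMatrix()] reads
#'
#' @param counts matrix with feature row names and sample column names.
#' @param path output path.
#' @param idColumn header for the feature-id column.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(counts, path, idColumn = "feature_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

checkCountMatrix <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry feature and sample names")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integral")
  invisible(TRUE)
}

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over features (using
#' only features with nonzero counts in every sample) of the ratio of the
#' sample's count to the feature's geometric mean across samples. Factors
#' are rescaled to geometric mean 1 so the normalized scale is anchored to
#' the cohort average. If no feature is nonzero in all samples the
#' estimator falls back to total-count ratios, with a warning.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return Positive numeric vector of size factors, one per sample.
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
  checkCountMatrix(counts)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  allNonzero <- rowSums(counts == 0) == 0
  if (!any(allNonzero)) {
    warning("no feature has nonzero counts in all samples; ",
            "falling back to total-count size factors")
    sf <- colSums(counts)
    if (any(sf == 0)) stop("sample with all-zero counts")
  } else {
    logc <- log(counts[allNonzero, , drop = FALSE])
    logGeomean <- rowMeans(logc)
    sf <- apply(logc, 2, function(col) exp(median(col - logGeomean)))
  }
  sf <- sf / exp(mean(log(sf)))  # anchor to geometric mean 1
  setNames(sf, colnames(counts))
}

#' Library-size normalization with log2 transform
#'
#' Divides each sample column by its size factor and applies
#' `log2(x + pseudocount)`. This is the package's fully specified stand-in
#' for regularized-log transforms: monotone in the counts, exactly
#' invertible, and anchored to median-of-ratios library-size correction.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param sizeFactors positive numeric vector per sample; computed with
#'   [sizeFactorsMedianOfRatios()] when `NULL`.
#' @param pseudocount added before the log; default 1.
#' @return A [NormalizedMatrix-class].
#' @export
logNormalize <- function(counts, sizeFactors = NULL, pseudocount = 1) {
  checkCountMatrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianOfRatios(counts)
  if (length(sizeFactors) != ncol(counts))
    stop("one size factor per sample required")
  if (any(!is.finite(sizeFactors)) || any(sizeFactors <= 0))
    stop("size factors must be finite and positive")
  values <- log2(sweep(counts, 2, sizeFactors, "/") + pseudocount)
  dimnames(values) <- dimnames(counts)
  new("NormalizedMatrix", values = values,
      sizeFactors = setNames(as.numeric(sizeFactors), colnames(counts)),
      pseudocount = pseudocount)
}

#' @describeIn NormalizedMatrix-class the log2-scale value matrix.
#' @param nm,object a `NormalizedMatrix`.
#' @export
normValues <- function(nm) nm@values

#' Per-sample size factors of a NormalizedMatrix
#'
#' @param object a [NormalizedMatrix-class].
#' @return Named numeric vector of size factors.
#' @importFrom BiocGenerics sizeFactors
#' @exportMethod sizeFactors
#' @rdname NormalizedMatrix-class
setMethod("sizeFactors", "NormalizedMatrix",
          function(object) object@sizeFactors)

setMethod("dim", "NormalizedMatrix", function(x) dim(x@values))

setMethod("show", "NormalizedMatrix", function(object) {
  cat("NormalizedMatrix:", nrow(object@values), "features x",
      ncol(object@values), "samples (log2 scale, pseudocount",
      object@pseudocount, ")\n")
  cat("  size factor range:",
      paste(signif(range(object@sizeFactors), 4), collapse = " - "), "\n")
})

#' Subset a NormalizedMatrix by features and/or samples
#'
#' @param x a [NormalizedMatrix-class].
#' @param i feature index or names.
#' @param j sample index or names.
#' @param ... ignored.
#' @param drop ignored; result is always a `NormalizedMatrix`.
#' @export
setMethod("[", "NormalizedMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  new("NormalizedMatrix", values = x@values[i, j, drop = FALSE],
      sizeFactors = x@sizeFactors[j], pseudocount = x@pseudocount)
})

#' Transcripts-per-million normalization over peak (or transcript) lengths
#'
#' `rate[i, j] = counts[i, j] / length[i]`, columns rescaled to sum to
#' one million. A sample with all-zero counts yields an all-zero column
#' with a warning.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param featureLengths positive lengths in bp, one per feature; the
#'   widths are used if a `GRanges` is supplied.
#' @return Numeric matrix of TPM values.
#' @export
tpmNormalize <- function(counts, featureLengths) {
  checkCountMatrix(counts)
  if (methods::is(featureLengths, "GRanges"))
    featureLengths <- GenomicRanges::width(featureLengths)
  if (length(featureLengths) != nrow(counts))
    stop("one length per feature required")
  if (any(featureLengths <= 0)) stop("feature lengths must be positive")
  rate <- counts / featureLengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("sample(s) with all-zero counts yield all-zero TPM: ",
            paste(colnames(counts)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Counts-per-million normalization (no length correction)
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return Numeric matrix of CPM values.
#' @export
cpmNormalize <- function(counts) {
  checkCountMatrix(counts)
  tot <- colSums(counts)
  if (any(tot == 0)) {
    warning("sample(s) with all-zero counts yield all-zero CPM: ",
            paste(colnames(counts)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
  }
  sweep(counts, 2, tot, "/") * 1e6
}

#' Per-sample count of open peaks above a TPM threshold
#'
#' A peak counts as open in a sample when its normalized abundance is
#' strictly greater than `threshold`.
#'
#' @param tpm numeric matrix from [tpmNormalize()] or [cpmNormalize()].
#' @param threshold abundance cut-off; default 10.
#' @return Named integer vector of open-peak counts per sample.
#' @export
totalOpenPeaks <- function(tpm, threshold = 10) {
  setNames(as.integer(colSums(tpm > threshold)), colnames(tpm))
}

#' Retain features whose variance exceeds a threshold
#'
#' Population variance (divisor n, the convention of variance-threshold
#' feature filters) computed per feature on the normalized values.
#'
#' @param nm a [NormalizedMatrix-class] or a plain numeric matrix
#'   (features x samples).
#' @param threshold variance cut-off; features with variance strictly
#'   greater are retained. Default 0.45.
#' @return Character vector of retained feature ids, input order.
#' @export
varianceFilter <- function(nm, threshold = 0.45) {
  values <- if (methods::is(nm, "NormalizedMatrix")) normValues(nm) else nm
  if (ncol(values) < 2)
    stop("variance filter requires at least two samples")
  mu <- rowMeans(values)
  popVar <- rowMeans((values - mu)^2)
  rownames(values)[popVar > threshold]
}
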