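## Staged prognostic modelling: bagged-forest permutation importance with
## out-of-bag scoring, top-k selection, elastic net with LOOCV over an
## alpha grid, compact OLS models, and the three-way model comparison.

#' Rank peaks by random-forest permutation importance
#'
#' Fits a bagged regression forest of survival on the (variance-filtered)
#' peak matrix -- `nTrees` trees, each grown on a with-replacement sample
#' of `subsampleFraction * n` observations, all features eligible at every
#' split -- and ranks features by mean decrease in out-of-bag prediction
#' accuracy when the feature is permuted. The ensemble's out-of-bag
#' R-squared is reported alongside.
#'
#' Two estimators of the permutation importance are available:
#' `"tree"` (default) permutes each feature once per tree on that tree's
#' out-of-bag samples and averages the accuracy decrease over trees (the
#' classical forest permutation importance, computed natively by ranger);
#' `"ensemble"` permutes the feature's column `nPermutations` times over
#' the whole matrix and measures the drop in ensemble-level out-of-bag
#' R-squared. The two agree in ranking; the tree-level estimator averages
#' over `nTrees` permutations and is orders of magnitude cheaper, so it is
#' the default at genome scale.
#'
#' @param X numeric matrix, samples x features (normalized accessibility).
#' @param y numeric survival vector, length `nrow(X)`, at least 5.
#' @param nTrees number of trees; default 1000.
#' @param subsampleFraction per-tree sampling fraction in `(0, 1]`;
#'   default 0.9 (sampled with replacement).
#' @param seed integer seed fixing the ensemble and the permutations.
#' @param importanceMethod `"tree"` or `"ensemble"` (see Details).
#' @param nPermutations permutation repetitions per feature for the
#'   ensemble estimator; default 5.
#' @return An [ImportanceRanking-class]; features sorted by decreasing
#'   importance, ties broken by feature id.
#' @export
rfImportanceRanking <- function(X, y, nTrees = 1000, subsampleFraction = 0.9,
                                seed = 1L,
                                importanceMethod = c("tree", "ensemble"),
                                nPermutations = 5) {
  importanceMethod <- match.arg(importanceMethod)
  if (nTrees < 1) stop("nTrees must be at least 1")
  if (subsampleFraction <= 0 || subsampleFraction > 1)
    stop("subsampleFraction must be in (0, 1]")
  if (nrow(X) < 5) stop("at least 5 samples required")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- ranger::ranger(
    x = X, y = y, num.trees = nTrees, mtry = ncol(X),
    replace = TRUE, sample.fraction = subsampleFraction,
    importance = if (importanceMethod == "tree") "permutation" else "none",
    scale.permutation.importance = FALSE,
    keep.inbag = importanceMethod == "ensemble",
    num.threads = 1, seed = seed, oob.error = TRUE)
  oobPred <- fit$predictions
  ok <- !is.na(oobPred)
  oobR2 <- 1 - sum((y[ok] - oobPred[ok])^2) / sum((y[ok] - mean(y[ok]))^2)

  if (importanceMethod == "tree") {
    imp <- fit$variable.importance[colnames(X)]
  } else {
    inbag <- matrix(unlist(fit$inbag.counts), nrow = nrow(X))
    oobMask <- inbag == 0
    ensembleOobR2 <- function(M) {
      per <- predict(fit, data = M, predict.all = TRUE,
                     num.threads = 1)$predictions
      pred <- rowSums(per * oobMask) / rowSums(oobMask)
      use <- rowSums(oobMask) > 0
      1 - sum((y[use] - pred[use])^2) / sum((y[use] - mean(y[use]))^2)
    }
    base <- ensembleOobR2(X)
    set.seed(seed)
    imp <- vapply(seq_len(ncol(X)), function(f) {
      drops <- vapply(seq_len(nPermutations), function(rep) {
        Xp <- X
        Xp[, f] <- sample(Xp[, f])
        base - ensembleOobR2(Xp)
      }, 0)
      mean(drops)
    }, 0)
    names(imp) <- colnames(X)
  }
  ord <- order(-imp, names(imp))
  new("ImportanceRanking", featureIDs = names(imp)[ord],
      importance = as.numeric(imp[ord]), oobR2 = oobR2,
      seed = as.integer(seed), nTrees = as.integer(nTrees),
      subsampleFraction = subsampleFraction)
}

setMethod("show", "ImportanceRanking", function(object) {
  cat("ImportanceRanking over", length(object@featureIDs), "features\n")
  cat("  out-of-bag R2:", signif(object@oobR2, 4),
      " trees:", object@nTrees,
      " sample fraction:", object@subsampleFraction, "\n")
  top <- head(object@featureIDs, 5)
  cat("  top features:", paste(top, collapse = ", "), "\n")
})

#' @describeIn ImportanceRanking-class out-of-bag R-squared of the forest.
#' @param object an `ImportanceRanking`.
#' @export
oobR2 <- function(object) object@oobR2

#' Take the top-k features of an importance ranking
#'
#' @param ranking an [ImportanceRanking-class] (already sorted, ties by
#'   feature id) or a named importance vector.
#' @param k number of features; default 20.
#' @return Character vector of the k top feature ids.
#' @export
selectTopK <- function(ranking, k = 20) {
  ids <- if (methods::is(ranking, "ImportanceRanking"))
    ranking@featureIDs
  else
    names(ranking)[order(-ranking, names(ranking))]
  if (k > length(ids)) stop("k exceeds the number of ranked features")
  if (k == 0) return(character(0))
  ids[seq_len(k)]
}

#' Elastic net with leave-one-out cross-validated model selection
#'
#' Fits the elastic net
#' `(1/2n) * RSS + lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)`
#' over a grid of mixing values `alpha` and a per-alpha lambda path (100
#' log-spaced values from the smallest lambda zeroing every slope down to
#' `1e-4` of it), choosing the pair that maximizes the leave-one-out
#' predicted R-squared
#' `1 - sum((y_i - yhat_(-i))^2) / sum((y_i - mean(y))^2)`.
#' Features are standardized internally; coefficients are reported on the
#' original scale.
#'
#' @param X numeric matrix, samples x features (at least 2 features).
#' @param y numeric response, length `nrow(X)`, at least 3, non-constant.
#' @param alphaGrid mixing values; default `seq(0, 1, by = 0.1)` (11
#'   values).
#' @param lambda optional explicit decreasing lambda sequence overriding
#'   the automatic path (used e.g. to inspect the unpenalized limit).
#' @param nLambda,lambdaMinRatio automatic-path controls.
#' @return An [ElasticNetFit-class] at the selected `(alpha, lambda)`.
#' @export
elasticNetFit <- function(X, y, alphaGrid = seq(0, 1, by = 0.1),
                          lambda = NULL, nLambda = 100,
                          lambdaMinRatio = 1e-4) {
  n <- nrow(X)
  if (length(y) != n) stop("y length must match rows of X")
  if (n < 3) stop("at least 3 samples required")
  if (sd(y) == 0) stop("response is constant; model undefined")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  best <- NULL
  for (alpha in alphaGrid) {
    full <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda,
                           nlambda = nLambda,
                           lambda.min.ratio = lambdaMinRatio,
                           standardize = TRUE, thresh = 1e-12)
    lams <- full$lambda
    pred <- matrix(NA_real_, n, length(lams))
    for (i in seq_len(n)) {
      fi <- glmnet::glmnet(X[-i, , drop = FALSE], y[-i], alpha = alpha,
                           lambda = lams, standardize = TRUE, thresh = 1e-12)
      pred[i, ] <- predict(fi, newx = X[i, , drop = FALSE], s = lams)
    }
    cvR2 <- 1 - colSums((y - pred)^2) / sum((y - mean(y))^2)
    j <- which.max(cvR2)  # ties: first index = largest lambda (sparser)
    if (is.null(best) || cvR2[j] > best$cvR2) {
      cf <- as.numeric(coef(full, s = lams[j]))
      best <- list(alpha = alpha, lambda = lams[j], cvR2 = cvR2[j],
                   intercept = cf[1],
                   coefficients = setNames(cf[-1], colnames(X)))
    }
  }
  new("ElasticNetFit", alpha = best$alpha, lambda = best$lambda,
      coefficients = best$coefficients, intercept = best$intercept,
      cvR2 = best$cvR2)
}

setMethod("show", "ElasticNetFit", function(object) {
  nz <- sum(object@coefficients != 0)
  cat("ElasticNetFit: alpha =", object@alpha,
      " lambda =", signif(object@lambda, 4), "\n")
  cat("  LOOCV R2:", signif(object@cvR2, 4), " nonzero coefficients:", nz, "\n")
})

#' @describeIn ElasticNetFit-class leave-one-out predicted R-squared.
#' @param object an `ElasticNetFit`.
#' @export
cvR2 <- function(object) object@cvR2

#' @describeIn ElasticNetFit-class named vector of nonzero coefficients.
#' @export
nonzeroCoefficients <- function(object) {
  cf <- object@coefficients
  cf[cf != 0]
}

#' Ordinary least-squares fit of survival on a compact feature set
#'
#' @param X numeric matrix, samples x features, with `ncol(X) < nrow(X)`.
#' @param y numeric response.
#' @return A [LinearModelFit-class] with in-sample R-squared.
#' @export
linearModelFit <- function(X, y) {
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (ncol(X) >= nrow(X))
    stop("need fewer features than samples for an OLS fit")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  cf <- coef(fit)
  new("LinearModelFit",
      coefficients = setNames(as.numeric(cf[-1]), colnames(X)),
      intercept = as.numeric(cf[1]),
      r2InSample = summary(fit)$r.squared)
}

setMethod("show", "LinearModelFit", function(object) {
  cat("LinearModelFit with", length(object@coefficients), "features;",
      "in-sample R2:", signif(object@r2InSample, 4), "\n")
})

#' In-sample / held-out coefficient of determination
#'
#' @param y observed values (non-constant, length at least 2).
#' @param yhat predictions of the same length.
#' @return `1 - SS_res / SS_tot`.
#' @export
rSquared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2) stop("at least 2 observations required")
  if (sd(y) == 0) stop("constant response; R2 undefined")
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Encode clinical covariates as a numeric design matrix
#'
#' Age is numeric; gender (`male = 1`), IDH1 (`mutant = 1`) and stage
#' (`recurrent = 1`) are binary; grade is ordinal (II = 2, III = 3,
#' IV = 4); pathology is one-hot on the observed vocabulary, dropping the
#' alphabetically first level as reference. Samples with unknown IDH1
#' status receive `NA` in the IDH1 column; callers decide whether to drop
#' them.
#'
#' @param cohort a [GliomaCohort-class].
#' @return Numeric matrix, samples x covariates, rownames = sample ids.
#' @export
encodeClinical <- function(cohort) {
  rec <- records(cohort)
  m <- cbind(age = rec$age,
             gender_male = as.numeric(rec$gender == "male"),
             grade_ordinal = c(II = 2, III = 3, IV = 4)[rec$grade],
             stage_recurrent = as.numeric(rec$stage == "recurrent"),
             idh1_mutant = ifelse(rec$idh1 == "unknown", NA_real_,
                                  as.numeric(rec$idh1 == "mutant")))
  lev <- sort(unique(rec$pathology))
  if (length(lev) > 1) {
    for (p in lev[-1]) {
      col <- as.numeric(rec$pathology == p)
      m <- cbind(m, col)
      colnames(m)[ncol(m)] <- paste0("pathology_", gsub("\\s+", "_", p))
    }
  }
  rownames(m) <- rec$sample_id
  m
}

#' Compare peak-only, clinical-only and combined survival models
#'
#' Runs the same elastic-net / LOOCV protocol on three feature sets: the
#' selected peaks, the encoded clinical covariates, and their union.
#' Samples with unknown IDH1 status are excluded from all three models so
#' the comparison is made on a shared sample set.
#'
#' @param peakX numeric matrix, samples x selected peaks (rownames =
#'   sample ids).
#' @param cohort a [GliomaCohort-class] supplying clinical covariates and
#'   survival.
#' @param alphaGrid passed to [elasticNetFit()].
#' @return A list with elements `peaks`, `clinical`, `combined` (each an
#'   [ElasticNetFit-class]), `samples` (ids used) and `cvR2` (named
#'   numeric of the three LOOCV R-squared values).
#' @export
compareModels <- function(peakX, cohort, alphaGrid = seq(0, 1, by = 0.1)) {
  clin <- encodeClinical(cohort)
  surv <- survivalVector(cohort, rownames(clin))
  keep <- rownames(clin)[!is.na(clin[, "idh1_mutant"])]
  keep <- intersect(keep, rownames(peakX))
  if (length(keep) < 3) stop("fewer than 3 usable samples")
  clin <- clin[keep, , drop = FALSE]
  ## drop constant covariates (e.g. a pathology absent after exclusion)
  clin <- clin[, apply(clin, 2, sd) > 0, drop = FALSE]
  px <- peakX[keep, , drop = FALSE]
  y <- as.numeric(surv[keep])
  fits <- list(
    peaks = elasticNetFit(px, y, alphaGrid = alphaGrid),
    clinical = elasticNetFit(clin, y, alphaGrid = alphaGrid),
    combined = elasticNetFit(cbind(px, clin), y, alphaGrid = alphaGrid))
  fits$samples <- keep
  fits$cvR2 <- vapply(fits[c("peaks", "clinical", "combined")], cvR2, 0)
  fits
}
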