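test_that("forest importance ranks a planted linear signal first", {
  set.seed(9)
  n <- 40; p <- 50
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- X[, 1] + rnorm(n, 0, 0.2)
  rk <- rfImportanceRanking(X, y, nTrees = 500, seed = 42)
  expect_equal(rk@featureIDs[1], "f01")
  expect_gt(oobR2(rk), 0.3)

  ## deterministic given the seed
  rk2 <- rfImportanceRanking(X, y, nTrees = 500, seed = 42)
  expect_identical(rk@featureIDs, rk2@featureIDs)
  expect_identical(rk@importance, rk2@importance)

  expect_error(rfImportanceRanking(X, y, nTrees = 0), "nTrees")
  expect_error(rfImportanceRanking(X, y, subsampleFraction = 1.5),
               "subsampleFraction")
})

test_that("all-noise features have importance centred on zero", {
  set.seed(10)
  n <- 30; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  rk <- rfImportanceRanking(X, y, nTrees = 500, seed = 1)
  expect_lt(abs(mean(rk@importance)), 0.05)
})

test_that("ensemble-level permutation importance agrees with the tree-level default", {
  set.seed(11)
  n <- 40; p <- 8
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  y <- 2 * X[, 3] + rnorm(n, 0, 0.3)
  tree <- rfImportanceRanking(X, y, nTrees = 300, seed = 5)
  ens <- rfImportanceRanking(X, y, nTrees = 300, seed = 5,
                             importanceMethod = "ensemble")
  expect_equal(tree@featureIDs[1], "f3")
  expect_equal(ens@featureIDs[1], "f3")
})

test_that("top-k selection respects the ranking and its bounds", {
  rk <- new("ImportanceRanking",
            featureIDs = c("a", "b", "c"), importance = c(3, 2, 1),
            oobR2 = 0.5, seed = 1L, nTrees = 10L, subsampleFraction = 0.9)
  expect_equal(selectTopK(rk, 2), c("a", "b"))
  expect_equal(selectTopK(rk, 3), c("a", "b", "c"))
  expect_equal(selectTopK(rk, 0), character(0))
  expect_error(selectTopK(rk, 4), "exceeds")
  ## ties in a raw importance vector break lexicographically
  expect_equal(selectTopK(c(z = 1, b = 2, a = 2), 2), c("a", "b"))
})

test_that("the elastic-net alpha grid spans 0 to 1 in 11 steps", {
  grid <- eval(formals(elasticNetFit)$alphaGrid)
  expect_length(grid, 11L)
  expect_equal(grid, seq(0, 1, by = 0.1))
})

test_that("penalty limits of the elastic net behave as expected", {
  set.seed(12)
  n <- 30
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 5 + X[, 1] + rnorm(n, 0, 0.5)
  ## overwhelming penalty: all slopes zero, intercept at the mean
  big <- elasticNetFit(X, y, alphaGrid = 0.5, lambda = c(1e9, 1e8))
  expect_equal(unname(big@coefficients), c(0, 0, 0))
  expect_equal(big@intercept, mean(y), tolerance = 1e-6)

  ## exact linear response: LOOCV prefers the unpenalized end and the
  ## coefficients match the normal-equations solution
  yEx <- 3 + 2 * X[, 1] - 1 * X[, 2]
  fit <- elasticNetFit(X, yEx, alphaGrid = c(0, 0.5, 1),
                       lambda = c(10, 1, 0.1, 0.01, 0))
  ols <- coef(lm(yEx ~ X))
  expect_equal(fit@lambda, 0)
  expect_equal(unname(fit@coefficients), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit@intercept, unname(ols[1]), tolerance = 1e-6)
  expect_gt(fit@cvR2, 0.999)

  expect_error(elasticNetFit(X, rep(1, n)), "constant")
})

test_that("lasso on an orthonormal design soft-thresholds the OLS solution", {
  set.seed(13)
  n <- 32
  ## columns exactly centred and orthonormal (orthogonal to the
  ## intercept), scaled to unit population sd so the elastic net's
  ## internal standardization is a no-op
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4] * sqrt(n)
  colnames(Q) <- c("u", "v", "w")
  b <- c(2, -0.5, 0.05)
  y <- as.numeric(Q %*% b)
  lam <- 0.2
  fit <- elasticNetFit(Q, y, alphaGrid = 1, lambda = c(lam))
  olsB <- as.numeric(crossprod(Q, y) / n)
  soft <- sign(olsB) * pmax(abs(olsB) - lam, 0)
  expect_equal(unname(fit@coefficients), soft, tolerance = 1e-4)
})

test_that("ordinary least squares wrapper reports exact fits and failures", {
  set.seed(14)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + 2 * X[, 1] - X[, 3]
  fit <- suppressWarnings(linearModelFit(X, y))  # exact fit: lm warns
  expect_equal(fit@r2InSample, 1)
  expect_equal(unname(fit@coefficients), c(2, 0, -1), tolerance = 1e-10)

  ## single feature: slope is cov/var
  x1 <- X[, 1, drop = FALSE]
  y2 <- 3 * X[, 1] + rnorm(20)
  f1 <- linearModelFit(x1, y2)
  expect_equal(unname(f1@coefficients),
               cov(X[, 1], y2) / var(X[, 1]), tolerance = 1e-10)

  ## a pure-noise feature at large n explains nothing
  set.seed(15)
  Xn <- matrix(rnorm(2000), 2000, 1, dimnames = list(NULL, "noise"))
  expect_lt(linearModelFit(Xn, rnorm(2000))@r2InSample, 0.01)

  Xc <- cbind(X, d = X[, 1])
  expect_error(linearModelFit(Xc, y), "collinear")
})

test_that("rSquared is one minus the residual to total ratio", {
  y <- c(1, 2, 3)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 3)), 0)
  expect_equal(rSquared(y, c(1, 2, 4)), 0.5)
  expect_error(rSquared(c(2, 2), c(1, 2)), "constant")
})

## cohort whose survival depends on one peak and on age, for the
## three-way model comparison
.modelCohort <- function(seed = 16, n = 32, peakEffect = 8, ageEffect = 10) {
  set.seed(seed)
  age <- round(runif(n, 30, 70))
  peak <- rnorm(n, 7, 1.5)
  surv <- pmax(1, 40 + peakEffect * scale(peak)[, 1] +
                 ageEffect * scale(age)[, 1] + rnorm(n, 0, 3))
  rec <- data.frame(
    sample_id = sprintf("s%02d", 1:n), age = age,
    gender = sample(c("male", "female"), n, TRUE),
    pathology = sample(c("Glioblastoma", "Astrocytoma"), n, TRUE),
    grade = sample(c("II", "III", "IV"), n, TRUE),
    stage = "primary",
    idh1 = sample(c("mutant", "wildtype"), n, TRUE),
    survival = surv, has_rnaseq = FALSE, patient_id = NA_character_,
    stringsAsFactors = FALSE)
  rec$stage[rec$grade == "IV"][1] <- "recurrent"
  X <- cbind(pk1 = peak, pk2 = rnorm(n, 7, 1.5), pk3 = rnorm(n, 7, 1.5))
  rownames(X) <- rec$sample_id
  list(cohort = GliomaCohort(rec), X = X)
}

test_that("combining peaks and clinical covariates does not lose accuracy", {
  fx <- .modelCohort()
  cmp <- compareModels(fx$X, fx$cohort)
  expect_named(cmp$cvR2, c("peaks", "clinical", "combined"))
  expect_gte(cmp$cvR2["combined"], max(cmp$cvR2[c("peaks", "clinical")]) - 0.05)
  ## both sources carry predictive signal here
  expect_gt(cmp$cvR2["peaks"], 0.05)
  expect_gt(cmp$cvR2["clinical"], 0.1)
})

test_that("clinical-only models find nothing when no clinical effect exists", {
  fx <- .modelCohort(seed = 17, ageEffect = 0)
  cmp <- compareModels(fx$X, fx$cohort)
  expect_lt(cmp$cvR2["clinical"], 0.15)
})

test_that("samples with undetermined IDH1 are excluded from the comparison", {
  fx <- .modelCohort(seed = 18)
  rec <- records(fx$cohort)
  rec$idh1[1:4] <- "unknown"
  cmp <- compareModels(fx$X, GliomaCohort(rec))
  expect_equal(length(cmp$samples), nrow(rec) - 4)
  expect_false(any(rec$sample_id[1:4] %in% cmp$samples))
})

test_that("clinical encoding is numeric with the documented conventions", {
  fx <- .modelCohort(seed = 19)
  enc <- encodeClinical(fx$cohort)
  expect_true(all(c("age", "gender_male", "grade_ordinal",
                    "stage_recurrent", "idh1_mutant") %in% colnames(enc)))
  rec <- records(fx$cohort)
  expect_equal(unname(enc[, "grade_ordinal"]),
               unname(c(II = 2, III = 3, IV = 4)[rec$grade]))
  expect_equal(unname(enc[, "gender_male"]),
               as.numeric(rec$gender == "male"))
})
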