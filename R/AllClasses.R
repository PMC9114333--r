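#' @import methods
#' @importFrom stats cor median pt p.adjust rnorm rbinom runif rlnorm rnbinom
#'   sd var quantile setNames coef lm predict aov anova as.formula model.matrix
#' @importFrom utils read.table write.table head
NULL

#' Clinical cohort of tumour specimens
#'
#' Container for the per-sample clinical and demographic attributes of an
#' accessibility cohort: age, gender, histopathology, WHO grade (II/III/IV),
#' primary/recurrent status, IDH1 mutation status, overall survival in
#' months, RNA-seq availability and an optional patient identifier linking
#' paired resections from the same patient.
#'
#' Survival is carried as a fully observed continuous response (months from
#' resection to death); no censoring model is attached.
#'
#' @slot records data.frame with one row per sample and columns
#'   `sample_id`, `age`, `gender`, `pathology`, `grade`, `stage`, `idh1`,
#'   `survival`, `has_rnaseq`, `patient_id`.
#' @seealso [readCohortTable()], [summarizeCohort()], [survivalVector()]
#' @export
setClass("GliomaCohort", slots = c(records = "data.frame"))

setValidity("GliomaCohort", function(object) {
  rec <- object@records
  need <- c("sample_id", "age", "gender", "pathology", "grade", "stage",
            "idh1", "survival", "has_rnaseq", "patient_id")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0)
    return(paste("missing record columns:", paste(miss, collapse = ", ")))
  if (nrow(rec) == 0) return(TRUE)
  if (anyDuplicated(rec$sample_id))
    return(paste("duplicate sample_id:",
                 paste(unique(rec$sample_id[duplicated(rec$sample_id)]),
                       collapse = ", ")))
  if (!all(rec$grade %in% c("II", "III", "IV")))
    return("grade must be one of II, III, IV")
  if (!all(rec$stage %in% c("primary", "recurrent")))
    return("stage must be primary or recurrent")
  if (!all(rec$gender %in% c("male", "female")))
    return("gender must be male or female")
  if (!all(rec$idh1 %in% c("mutant", "wildtype", "unknown")))
    return("idh1 must be mutant, wildtype or unknown")
  if (any(!is.finite(rec$survival)) || any(rec$survival < 0))
    return("survival must be finite and non-negative (months)")
  if (any(!is.finite(rec$age)) || any(rec$age <= 0))
    return("age must be a positive number of years")
  if (!is.logical(rec$has_rnaseq))
    return("has_rnaseq must be logical")
  TRUE
})

#' Cohort composition summary
#'
#' Deterministic counts over the cohort partitions: total size, samples per
#' (grade, stage) group, per IDH1 status, RNA-seq availability, and the
#' number of patients contributing two or more specimens.
#'
#' @slot nTotal integer total sample count.
#' @slot nByGradeStage named integer vector, names `"<grade>.<stage>"`.
#' @slot nByIDH1 named integer vector over mutant/wildtype/unknown.
#' @slot nRNAseq integer count of samples with expression data.
#' @slot nPairedPatients integer count of patient_ids seen at least twice.
#' @export
setClass("CohortSummary",
         slots = c(nTotal = "integer", nByGradeStage = "integer",
                   nByIDH1 = "integer", nRNAseq = "integer",
                   nPairedPatients = "integer"))

#' Library-size normalized, log2-scale accessibility or expression matrix
#'
#' Holds log2-scale values derived from a raw count matrix together with
#' the per-sample size factors used: `values[i, j] = log2(counts[i, j] /
#' sizeFactors[j] + pseudocount)`.
#'
#' @slot values numeric matrix, features x samples, log2 scale.
#' @slot sizeFactors positive numeric vector, one per sample.
#' @slot pseudocount numeric scalar added before the log.
#' @seealso [logNormalize()], [sizeFactorsMedianOfRatios()]
#' @export
setClass("NormalizedMatrix",
         slots = c(values = "matrix", sizeFactors = "numeric",
                   pseudocount = "numeric"))

setValidity("NormalizedMatrix", function(object) {
  if (length(object@sizeFactors) != ncol(object@values))
    return("one size factor per sample column required")
  if (any(!is.finite(object@sizeFactors)) || any(object@sizeFactors <= 0))
    return("size factors must be finite and positive")
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    return("values must carry feature and sample names")
  TRUE
})

#' Permutation-importance ranking of features from a bagged forest
#'
#' Result of ranking features by mean decrease in out-of-bag prediction
#' accuracy under permutation, from a random-forest regression of survival
#' on accessibility.
#'
#' @slot featureIDs character, features sorted by decreasing importance.
#' @slot importance numeric, same order as `featureIDs`.
#' @slot oobR2 out-of-bag R-squared of the unpermuted ensemble.
#' @slot seed integer RNG seed used for the ensemble.
#' @slot nTrees number of trees.
#' @slot subsampleFraction per-tree sample fraction.
#' @seealso [rfImportanceRanking()], [selectTopK()]
#' @export
setClass("ImportanceRanking",
         slots = c(featureIDs = "character", importance = "numeric",
                   oobR2 = "numeric", seed = "integer", nTrees = "integer",
                   subsampleFraction = "numeric"))

setValidity("ImportanceRanking", function(object) {
  if (length(object@featureIDs) != length(object@importance))
    return("one importance value per feature required")
  if (is.unsorted(rev(object@importance)))
    return("importance must be sorted in decreasing order")
  TRUE
})

#' Elastic-net model selected by leave-one-out cross-validation
#'
#' @slot alpha mixing parameter in `[0, 1]` (0 = ridge, 1 = lasso).
#' @slot lambda penalty strength chosen on the LOOCV surface.
#' @slot coefficients named numeric vector on the original feature scale.
#' @slot intercept numeric scalar.
#' @slot cvR2 leave-one-out predicted R-squared at (alpha, lambda).
#' @seealso [elasticNetFit()], [compareModels()]
#' @export
setClass("ElasticNetFit",
         slots = c(alpha = "numeric", lambda = "numeric",
                   coefficients = "numeric", intercept = "numeric",
                   cvR2 = "numeric"))

setValidity("ElasticNetFit", function(object) {
  if (object@lambda < 0) return("lambda must be non-negative")
  if (object@cvR2 > 1) return("cross-validated R2 cannot exceed 1")
  if (object@alpha < 0 || object@alpha > 1) return("alpha must be in [0,1]")
  TRUE
})

#' Ordinary least-squares model of survival on a small feature set
#'
#' @slot coefficients named numeric vector of slopes.
#' @slot intercept numeric scalar.
#' @slot r2InSample in-sample R-squared.
#' @seealso [linearModelFit()]
#' @export
setClass("LinearModelFit",
         slots = c(coefficients = "numeric", intercept = "numeric",
                   r2InSample = "numeric"))
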