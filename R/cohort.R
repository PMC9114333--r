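## Cohort metadata: parsing, validation, summaries, survival response.

.COHORT_COLUMNS <- c(Sample = "sample_id", Age = "age", Gender = "gender",
                     Pathology = "pathology", Grade = "grade",
                     Stage = "stage", IDH1 = "idh1",
                     Survival_months = "survival", RNAseq = "has_rnaseq",
                     Patient = "patient_id")

.normalizeIDH1 <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  out[toupper(x) %in% c("MUT", "MUTANT")] <- "mutant"
  out[toupper(x) %in% c("WT", "WILDTYPE", "WILD-TYPE")] <- "wildtype"
  ## dashes (ASCII or typographic) and empty fields mean undetermined
  out[x %in% c("-", "–", "—", "", "NA", "unknown", "Unknown")] <- "unknown"
  if (anyNA(out))
    stop("unrecognized IDH1 value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Construct a GliomaCohort from a records data.frame
#'
#' Lower-level constructor used by [readCohortTable()] and the simulator.
#' Missing optional columns (`patient_id`) are filled with `NA`.
#'
#' @param records data.frame with the cohort record columns.
#' @return A [GliomaCohort-class] object.
#' @export
GliomaCohort <- function(records) {
  if (is.null(records$patient_id)) records$patient_id <- NA_character_
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  new("GliomaCohort", records = records)
}

#' Read a clinical cohort table
#'
#' Parses a TSV/CSV cohort table with columns Sample, Age, Gender,
#' Pathology, Grade, Stage, IDH1, Survival_months, RNAseq and optionally
#' Patient (case-insensitive, order-insensitive). A combined grade string
#' such as `"IV Recurrent"` in the Grade column is split into grade and
#' stage when no Stage column is present. IDH1 values `Mut`/`WT` map to
#' mutant/wildtype; a dash or empty field maps to unknown.
#'
#' @param path path to the table; delimiter inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param sep optional explicit field separator overriding the inference.
#' @return A [GliomaCohort-class] object (empty if the file has only a
#'   header row).
#' @examples
#' tab1 <- system.file("extdata", "table1_cohort.tsv", package = "atacmap")
#' cohort <- readCohortTable(tab1)
#' summarizeCohort(cohort)
#' @export
readCohortTable <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.table(path, sep = sep, header = TRUE, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", comment.char = "",
                    fill = TRUE, fileEncoding = "UTF-8")
  ## match columns case-insensitively, allowing 'Survival' for Survival_months
  cn <- names(raw)
  idx <- function(nm, alts = character()) {
    hit <- which(tolower(cn) %in% tolower(c(nm, alts)))
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  cols <- c(Sample = idx("Sample", "sample_id"), Age = idx("Age"),
            Gender = idx("Gender", "sex"), Pathology = idx("Pathology"),
            Grade = idx("Grade"), Stage = idx("Stage", "Primary/recurrent"),
            IDH1 = idx("IDH1"),
            Survival_months = idx("Survival_months", c("Survival", "Survival (months)")),
            RNAseq = idx("RNAseq", "RNA-seq"), Patient = idx("Patient", "patient_id"))
  required <- setdiff(names(cols), c("Stage", "Patient"))
  missing <- required[is.na(cols[required])]
  if (length(missing) > 0)
    stop("cohort table is missing required column(s): ",
         paste(missing, collapse = ", "))

  grade <- trimws(raw[[cols["Grade"]]])
  if (is.na(cols["Stage"])) {
    ## combined "IV Recurrent" style grade strings
    parts <- strsplit(grade, "\\s+")
    grade <- vapply(parts, `[`, "", 1L)
    stage <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
    if (anyNA(stage))
      stop("cohort table is missing required column(s): Stage ",
           "(and Grade column does not embed primary/recurrent status)")
  } else {
    stage <- trimws(raw[[cols["Stage"]]])
  }

  parseNum <- function(x, what) {
    v <- suppressWarnings(as.numeric(trimws(x)))
    bad <- which(is.na(v) & !(trimws(x) %in% c("", "NA")))
    bad <- union(bad, which(trimws(x) %in% c("", "NA")))
    if (length(bad) > 0)
      stop("unparseable ", what, " in row(s): ",
           paste(raw[[cols["Sample"]]][bad], collapse = ", "))
    v
  }

  n <- nrow(raw)
  if (n == 0) return(GliomaCohort(emptyCohortRecords()))
  rec <- data.frame(
    sample_id = trimws(raw[[cols["Sample"]]]),
    age = parseNum(raw[[cols["Age"]]], "age"),
    gender = tolower(trimws(raw[[cols["Gender"]]])),
    pathology = trimws(raw[[cols["Pathology"]]]),
    grade = grade,
    stage = tolower(stage),
    idh1 = .normalizeIDH1(raw[[cols["IDH1"]]]),
    survival = parseNum(raw[[cols["Survival_months"]]], "survival"),
    has_rnaseq = toupper(trimws(raw[[cols["RNAseq"]]])) %in% c("YES", "TRUE", "1"),
    patient_id = if (is.na(cols["Patient"])) NA_character_ else {
      p <- trimws(raw[[cols["Patient"]]]); p[p == ""] <- NA_character_; p
    },
    stringsAsFactors = FALSE)
  if (anyDuplicated(rec$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(rec$sample_id[duplicated(rec$sample_id)]), collapse = ", "))
  GliomaCohort(rec)
}

emptyCohortRecords <- function() {
  data.frame(sample_id = character(), age = numeric(), gender = character(),
             pathology = character(), grade = character(), stage = character(),
             idh1 = character(), survival = numeric(), has_rnaseq = logical(),
             patient_id = character(), stringsAsFactors = FALSE)
}

#' Write a cohort table back to disk
#'
#' Serializes in the same layout [readCohortTable()] reads, so that
#' parse -> write -> parse is the identity.
#'
#' @param cohort a [GliomaCohort-class].
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
writeCohortTable <- function(cohort, path) {
  rec <- records(cohort)
  capitalize <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))
  out <- data.frame(
    Sample = rec$sample_id, Age = rec$age,
    Gender = capitalize(rec$gender), Pathology = rec$pathology,
    Grade = rec$grade, Stage = capitalize(rec$stage),
    IDH1 = c(mutant = "Mut", wildtype = "WT", unknown = "-")[rec$idh1],
    Survival_months = rec$survival,
    RNAseq = ifelse(rec$has_rnaseq, "Yes", "No"),
    Patient = ifelse(is.na(rec$patient_id), "", rec$patient_id),
    stringsAsFactors = FALSE, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn GliomaCohort-class access the per-sample record table.
#' @param cohort,object a `GliomaCohort`.
#' @export
records <- function(cohort) cohort@records

#' @describeIn GliomaCohort-class sample identifiers in table order.
#' @export
sampleIDs <- function(cohort) records(cohort)$sample_id

setMethod("length", "GliomaCohort", function(x) nrow(x@records))

setMethod("show", "GliomaCohort", function(object) {
  rec <- object@records
  cat("GliomaCohort with", nrow(rec), "samples\n")
  if (nrow(rec) > 0) {
    tab <- table(paste(rec$grade, rec$stage))
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  RNA-seq available:", sum(rec$has_rnaseq), "\n")
  }
})

#' Summarize cohort composition
#'
#' Counts samples by (grade, stage) group and by IDH1 status, the number
#' with RNA-seq, and the number of patients represented by two or more
#' specimens. Partitions are exhaustive: each partition's counts sum to the
#' total.
#'
#' @param cohort a [GliomaCohort-class].
#' @return A [CohortSummary-class].
#' @export
summarizeCohort <- function(cohort) {
  rec <- records(cohort)
  groups <- c("II.primary", "III.primary", "III.recurrent", "IV.primary",
              "IV.recurrent", "II.recurrent")
  gs <- table(factor(paste(rec$grade, rec$stage, sep = "."), levels = groups))
  gs <- gs[gs > 0 | names(gs) %in% c("II.primary", "III.primary",
                                     "IV.primary", "IV.recurrent")]
  idh <- table(factor(rec$idh1, levels = c("mutant", "wildtype", "unknown")))
  paired <- sum(table(rec$patient_id[!is.na(rec$patient_id)]) >= 2)
  new("CohortSummary",
      nTotal = nrow(rec),
      nByGradeStage = setNames(as.integer(gs), names(gs)),
      nByIDH1 = setNames(as.integer(idh), names(idh)),
      nRNAseq = sum(rec$has_rnaseq),
      nPairedPatients = as.integer(paired))
}

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary:", object@nTotal, "samples\n")
  cat("  by grade/stage:",
      paste(names(object@nByGradeStage), object@nByGradeStage,
            sep = "=", collapse = ", "), "\n")
  cat("  by IDH1:",
      paste(names(object@nByIDH1), object@nByIDH1, sep = "=", collapse = ", "),
      "\n")
  cat("  RNA-seq:", object@nRNAseq,
      " paired patients:", object@nPairedPatients, "\n")
})

#' Survival response vector aligned to a sample order
#'
#' @param cohort a [GliomaCohort-class].
#' @param sampleOrder character vector of sample ids; every id must exist
#'   in the cohort.
#' @return Named numeric vector of survival in months, in `sampleOrder`.
#' @export
survivalVector <- function(cohort, sampleOrder) {
  rec <- records(cohort)
  unknown <- setdiff(sampleOrder, rec$sample_id)
  if (length(unknown) > 0)
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  setNames(rec$survival[match(sampleOrder, rec$sample_id)], sampleOrder)
}
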