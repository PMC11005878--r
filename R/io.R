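# Cohort CSV schema: patient_id, age_days, heart_rate, respiratory_rate,
# crt_seconds, avpu, lactate, glucose, outcome (optionally assigned_score
# and score columns appended by score_cohort).

cohort_schema <- c("patient_id", "age_days", "heart_rate", "respiratory_rate",
                   "crt_seconds", "avpu", "lactate", "glucose", "outcome")

#' Write a cohort to CSV
#'
#' @param cohort a cohort data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Schema violations are reported with the offending rows: missing
#' columns, non-numeric or non-finite vitals, unknown AVPU levels or
#' outcomes, and out-of-range ages.
#'
#' @param path path to a cohort CSV.
#' @return a validated data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cohort <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  validate_cohort(cohort)
}

validate_cohort <- function(cohort, require_biomarkers = FALSE) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop("cohort must be a non-empty data.frame", call. = FALSE)
  }
  required <- setdiff(cohort_schema, c("lactate", "glucose"))
  if (require_biomarkers) required <- cohort_schema
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_rows <- function(ok, what) {
    if (!all(ok)) {
      stop(what, " (rows ",
           paste(utils::head(which(!ok), 5), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  num_cols <- intersect(c("age_days", "heart_rate", "respiratory_rate",
                          "crt_seconds", "lactate", "glucose"),
                        names(cohort))
  for (col in num_cols) {
    if (!is.numeric(cohort[[col]])) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
    if (col %in% c("lactate", "glucose") && !require_biomarkers) next
    bad_rows(is.finite(cohort[[col]]), paste0("non-finite values in '", col, "'"))
  }
  bad_rows(cohort$age_days >= 0 & cohort$age_days < MAX_AGE_DAYS,
           "age_days outside [0 days, 18 years)")
  bad_rows(cohort$heart_rate > 0, "non-positive heart_rate")
  bad_rows(cohort$respiratory_rate > 0, "non-positive respiratory_rate")
  bad_rows(cohort$crt_seconds >= 0, "negative crt_seconds")
  bad_rows(cohort$avpu %in% c("A", "V", "P", "U"), "unknown AVPU level")
  bad_rows(cohort$outcome %in% c("survived", "died"), "unknown outcome")
  if (require_biomarkers) {
    bad_rows(cohort$lactate >= 0, "negative lactate")
    bad_rows(cohort$glucose >= 0, "negative glucose")
  }
  cohort
}
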