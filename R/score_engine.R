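# Age bands are half-open [lower_days, upper_days) intervals.
# Calendar conventions: 1 week = 7 d, 1 month = 30.4375 d, 1 year = 365.25 d.

DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25
MAX_AGE_DAYS <- 6575 # scoring is defined for children below 18 years

#' Convert an age in months to days
#'
#' Uses the mean Gregorian month of 30.4375 days.
#'
#' @param months numeric vector of ages in months.
#' @return numeric vector of ages in days.
#' @export
#' @examples
#' months_to_days(12) # 365.25
months_to_days <- function(months) {
  stopifnot(is.numeric(months))
  months * DAYS_PER_MONTH
}

#' Age-banded vital-sign thresholds (95th-centile cut-offs)
#'
#' Returns the table of age-specific tachycardia, bradycardia and
#' respiratory-rate thresholds used by the score: six bands from birth to 18
#' years, with the consensus 95th-centile cut-offs for heart rate and
#' respiratory rate.  Bradycardia is undefined (NA) from 2 years upward, so
#' a low heart rate never scores in those bands.  The infant band ("1 month
#' to 1 year") is extended through 23 months so that the bands jointly cover
#' all ages below 18 years; the next band starts at 2 years.
#'
#' The default table ships with the package as JSON; an alternative table
#' (same columns) can be supplied for sensitivity analyses.
#'
#' @param path optional path to a JSON file with columns `label`,
#'   `lower_days`, `upper_days`, `tachycardia_bpm`, `bradycardia_bpm`
#'   (`null` where bradycardia is undefined) and `rr_threshold`.
#' @return a data.frame, one row per age band, validated for contiguous
#'   coverage and monotone thresholds.
#' @export
#' @examples
#' vital_thresholds()
vital_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vital_thresholds.json",
                        package = "pqsofa", mustWork = TRUE)
  }
  tab <- as.data.frame(jsonlite::fromJSON(path))
  validate_threshold_table(tab)
  tab
}

validate_threshold_table <- function(tab) {
  need <- c("label", "lower_days", "upper_days", "tachycardia_bpm",
            "bradycardia_bpm", "rr_threshold")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("threshold table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(tab$lower_days >= tab$upper_days)) {
    stop("each age band needs lower_days < upper_days", call. = FALSE)
  }
  if (nrow(tab) > 1 &&
      any(abs(tab$lower_days[-1] - tab$upper_days[-nrow(tab)]) > 1e-9)) {
    stop("age bands must be contiguous (each band starts where the previous ends)",
         call. = FALSE)
  }
  present <- !is.na(tab$bradycardia_bpm)
  if (any(tab$tachycardia_bpm <= 0) || any(tab$rr_threshold <= 0) ||
      any(tab$bradycardia_bpm[present] <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  if (any(tab$tachycardia_bpm[present] <= tab$bradycardia_bpm[present])) {
    stop("tachycardia threshold must exceed bradycardia threshold", call. = FALSE)
  }
  if (any(diff(tab$tachycardia_bpm) > 0) || any(diff(tab$rr_threshold) > 0)) {
    stop("tachycardia and respiratory-rate thresholds must be non-increasing with age",
         call. = FALSE)
  }
  invisible(tab)
}

age_band_index <- function(age_days, thresholds) {
  if (!is.numeric(age_days) || any(!is.finite(age_days))) {
    stop("age_days must be finite numeric", call. = FALSE)
  }
  lo <- thresholds$lower_days[1]
  hi <- thresholds$upper_days[nrow(thresholds)]
  bad <- age_days < lo | age_days >= hi
  if (any(bad)) {
    stop(sprintf("age_days out of the supported range [%g, %g): %s",
                 lo, hi, paste(utils::head(age_days[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  findInterval(age_days, thresholds$lower_days)
}

#' Classify an age into its scoring band
#'
#' @param age_days numeric vector of ages in days; must lie in
#'   `[0, 6575)` (below 18 years).
#' @param thresholds a threshold table from [vital_thresholds()].
#' @return the matching rows of the threshold table (one per input age).
#' @export
#' @examples
#' classify_age_band(180)$label # "1 month to 1 year"
#' classify_age_band(3)$label   # "0 days to 1 week"
classify_age_band <- function(age_days, thresholds = vital_thresholds()) {
  thresholds[age_band_index(age_days, thresholds), , drop = FALSE]
}

check_vital <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be finite and positive", call. = FALSE)
  }
  invisible(x)
}

#' Score the heart-rate component
#'
#' One point when the heart rate is strictly above the band's tachycardia
#' threshold, or strictly below its bradycardia threshold where one is
#' defined (infants only); otherwise zero.
#'
#' @param heart_rate beats per minute, finite and positive.
#' @param band one or more rows of a threshold table (recycled against
#'   `heart_rate` if a single row).
#' @return integer vector of 0/1 points.
#' @export
score_heart_rate <- function(heart_rate, band) {
  check_vital(heart_rate, "heart_rate")
  tachy <- band$tachycardia_bpm
  brady <- band$bradycardia_bpm
  as.integer(heart_rate > tachy | (!is.na(brady) & heart_rate < brady))
}

#' Score the respiratory-rate component
#'
#' One point when the respiratory rate is strictly above the band's
#' 95th-centile threshold; a rate exactly at the threshold scores zero.
#'
#' @inheritParams score_heart_rate
#' @param respiratory_rate breaths per minute, finite and positive.
#' @return integer vector of 0/1 points.
#' @export
score_respiratory_rate <- function(respiratory_rate, band) {
  check_vital(respiratory_rate, "respiratory_rate")
  as.integer(respiratory_rate > band$rr_threshold)
}

#' Score the capillary refill time component
#'
#' One point for a refill time of 3 seconds or more (inclusive).
#'
#' @param crt_seconds capillary refill time in seconds, finite and >= 0.
#' @return integer vector of 0/1 points.
#' @export
score_crt <- function(crt_seconds) {
  if (!is.numeric(crt_seconds) || any(!is.finite(crt_seconds)) ||
      any(crt_seconds < 0)) {
    stop("crt_seconds must be finite and non-negative", call. = FALSE)
  }
  as.integer(crt_seconds >= 3)
}

#' Score the AVPU responsiveness component
#'
#' Alert scores zero; any reduced level of responsiveness (Voice, Pain,
#' Unresponsive) scores one point.
#'
#' @param level character vector with values in `{"A","V","P","U"}`.
#' @return integer vector of 0/1 points.
#' @export
score_avpu <- function(level) {
  level <- as.character(level)
  bad <- !level %in% c("A", "V", "P", "U")
  if (any(bad) || anyNA(level)) {
    stop("avpu level must be one of A, V, P, U; got: ",
         paste(unique(level[bad]), collapse = ", "), call. = FALSE)
  }
  as.integer(level != "A")
}

#' Compute the age-adjusted modified qSOFA score for one patient
#'
#' Sums the four 0/1 components (CRT, respiratory rate, heart rate, AVPU)
#' using the age band matching the patient's age in days.  Any missing
#' vital is an error: the score is defined only on complete admission
#' vitals and no imputation is attempted.
#'
#' @param obs a list or one-row data.frame with fields `age_days`,
#'   `heart_rate`, `respiratory_rate`, `crt_seconds` and `avpu`.
#' @param thresholds a threshold table from [vital_thresholds()].
#' @return an object of class `qsofa_result`: components `crt_point`,
#'   `rr_point`, `hr_point`, `avpu_point` (each 0/1) and `total` (0--4).
#' @export
#' @examples
#' compute_qsofa(list(age_days = 400, heart_rate = 120,
#'                    respiratory_rate = 30, crt_seconds = 1, avpu = "A"))
compute_qsofa <- function(obs, thresholds = vital_thresholds()) {
  need <- c("age_days", "heart_rate", "respiratory_rate", "crt_seconds", "avpu")
  for (f in need) {
    v <- obs[[f]]
    if (is.null(v) || length(v) != 1 || (f != "avpu" && is.na(v)) ||
        (f == "avpu" && is.na(v))) {
      stop("missing or invalid field: ", f, call. = FALSE)
    }
  }
  band <- classify_age_band(obs$age_days, thresholds)
  crt <- score_crt(obs$crt_seconds)
  rr <- score_respiratory_rate(obs$respiratory_rate, band)
  hr <- score_heart_rate(obs$heart_rate, band)
  avpu <- score_avpu(obs$avpu)
  structure(
    list(crt_point = crt, rr_point = rr, hr_point = hr, avpu_point = avpu,
         total = crt + rr + hr + avpu),
    class = "qsofa_result"
  )
}

#' @export
print.qsofa_result <- function(x, ...) {
  cat(sprintf("qSOFA %d/4  (CRT %d, RR %d, HR %d, AVPU %d)\n",
              x$total, x$crt_point, x$rr_point, x$hr_point, x$avpu_point))
  invisible(x)
}

#' Score every patient in a cohort
#'
#' Vectorised scoring over a cohort data.frame in the package's CSV schema.
#' Adds the four component columns and `qsofa_total`.
#'
#' @param cohort a data.frame with columns `age_days`, `heart_rate`,
#'   `respiratory_rate`, `crt_seconds`, `avpu` (other columns are kept).
#' @param thresholds a threshold table from [vital_thresholds()].
#' @return the cohort with columns `crt_point`, `rr_point`, `hr_point`,
#'   `avpu_point` and `qsofa_total` appended.
#' @export
score_cohort <- function(cohort, thresholds = vital_thresholds()) {
  need <- c("age_days", "heart_rate", "respiratory_rate", "crt_seconds", "avpu")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (f in need) {
    if (anyNA(cohort[[f]])) {
      stop("missing values in column '", f, "' (rows ",
           paste(utils::head(which(is.na(cohort[[f]])), 5), collapse = ", "),
           "); the score requires complete admission vitals", call. = FALSE)
    }
  }
  band <- classify_age_band(cohort$age_days, thresholds)
  cohort$crt_point <- score_crt(cohort$crt_seconds)
  cohort$rr_point <- score_respiratory_rate(cohort$respiratory_rate, band)
  cohort$hr_point <- score_heart_rate(cohort$heart_rate, band)
  cohort$avpu_point <- score_avpu(cohort$avpu)
  cohort$qsofa_total <- cohort$crt_point + cohort$rr_point +
    cohort$hr_point + cohort$avpu_point
  cohort
}
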