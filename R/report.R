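# End-to-end pipeline: score a cohort, evaluate discrimination for each
# predictor, fit the combined logistic model, and test calibration.

predictor_section <- function(values, y, level) {
  list(auc = delong_ci(values, y, level),
       cutoff = youden_cutoff(values, y))
}

#' Run the full prognostic analysis on a cohort
#'
#' Scores the cohort (unless a `qsofa_total` column is already present),
#' then for the score and — where available — serum lactate and blood
#' glucose computes the DeLong AUC with confidence interval, the
#' Youden-optimal cutoff and its confusion-matrix metrics.  When both
#' biomarkers are present it additionally fits the combined three-predictor
#' logistic model, evaluates the combined risk predictor's AUC, compares it
#' against each single predictor with paired DeLong tests, and reports
#' Hosmer-Lemeshow calibration for both the score-only and the combined
#' model (deciles of risk, or one group per distinct fitted probability
#' for the few-valued score).
#'
#' @param cohort a cohort data.frame or a path to a cohort CSV.
#' @param level confidence level for AUC intervals.
#' @param hl_groups target Hosmer-Lemeshow group count.
#' @param thresholds a threshold table from [vital_thresholds()].
#' @return an object of class `qsofa_report`.
#' @export
#' @examples
#' report <- run_full_analysis(sample_cohort(default_cohort_config(seed = 7)))
#' report$score$auc
run_full_analysis <- function(cohort, level = 0.95, hl_groups = 10L,
                              thresholds = vital_thresholds()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!"qsofa_total" %in% names(cohort)) {
    validate_cohort(cohort)
    cohort <- score_cohort(cohort, thresholds)
  } else if (!"outcome" %in% names(cohort)) {
    stop("cohort must contain an 'outcome' column", call. = FALSE)
  }
  y <- as_outcome01(cohort$outcome)
  if (length(unique(y)) < 2) {
    stop("all patients share one outcome; discrimination analysis needs ",
         "both survivors and deaths", call. = FALSE)
  }
  score <- cohort$qsofa_total

  has_bio <- function(col) {
    col %in% names(cohort) && is.numeric(cohort[[col]]) &&
      all(is.finite(cohort[[col]]))
  }

  report <- list(
    summary = list(
      n = nrow(cohort),
      deaths = sum(y),
      mortality = mean(y),
      score_table = as_grouped_counts(score, y)
    ),
    score = predictor_section(score, y, level),
    lactate = if (has_bio("lactate")) predictor_section(cohort$lactate, y, level),
    glucose = if (has_bio("glucose")) predictor_section(cohort$glucose, y, level)
  )

  # score-only calibration: the 5-level score has 5 distinct fitted
  # probabilities, so the HL grouping falls back to one group per level
  score_fit <- fit_logistic(cbind(qsofa = score), y)
  report$score$hosmer_lemeshow <-
    hosmer_lemeshow(score_fit$fitted, y, hl_groups)

  if (has_bio("lactate") && has_bio("glucose")) {
    X <- cbind(qsofa = score, lactate = cohort$lactate,
               glucose = cohort$glucose)
    fit <- fit_logistic(X, y)
    risk <- fit$fitted
    report$combined <- list(
      fit = fit,
      auc = delong_ci(risk, y, level),
      cutoff = youden_cutoff(risk, y),
      hosmer_lemeshow = hosmer_lemeshow(risk, y, hl_groups),
      vs_score = delong_test(risk, score, y),
      vs_lactate = delong_test(risk, cohort$lactate, y),
      vs_glucose = delong_test(risk, cohort$glucose, y)
    )
  }

  report$provenance <- list(
    package = "pqsofa",
    version = as.character(utils::packageVersion("pqsofa")),
    confidence_level = level,
    hl_groups = hl_groups
  )
  structure(report, class = "qsofa_report")
}

#' @export
print.qsofa_report <- function(x, ...) {
  cat(sprintf("Prognostic analysis of %d patients (%d deaths, %.0f%% mortality)\n",
              x$summary$n, x$summary$deaths, 100 * x$summary$mortality))
  cat("\nScore distribution by outcome:\n")
  print(x$summary$score_table)
  for (name in c("score", "lactate", "glucose")) {
    sec <- x[[name]]
    if (is.null(sec)) next
    cat("\n--", name, "--\n")
    print(sec$auc)
    print(sec$cutoff)
    if (!is.null(sec$hosmer_lemeshow)) {
      cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f, df = %d, p = %.3f\n",
                  sec$hosmer_lemeshow$chi2, sec$hosmer_lemeshow$df,
                  sec$hosmer_lemeshow$p))
    }
  }
  if (!is.null(x$combined)) {
    cat("\n-- combined (score + lactate + glucose) --\n")
    print(x$combined$auc)
    print(x$combined$cutoff)
    cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f, df = %d, p = %.3f\n",
                x$combined$hosmer_lemeshow$chi2, x$combined$hosmer_lemeshow$df,
                x$combined$hosmer_lemeshow$p))
    cat(sprintf("Paired DeLong vs score p = %.4g, vs lactate p = %.4g, vs glucose p = %.4g\n",
                x$combined$vs_score$p, x$combined$vs_lactate$p,
                x$combined$vs_glucose$p))
  }
  invisible(x)
}

auc_as_list <- function(a) {
  list(auc = a$auc, se = a$se, ci_low = a$ci_low, ci_high = a$ci_high,
       level = a$level)
}

cutoff_as_list <- function(m) {
  list(cutoff = m$cutoff, sensitivity = m$sensitivity,
       specificity = m$specificity, youden = m$youden,
       ppv = m$ppv, npv = m$npv,
       tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn)
}

#' Export an analysis report as JSON
#'
#' @param report a `qsofa_report` from [run_full_analysis()].
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to file.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "qsofa_report"))
  out <- list(summary = list(
    n = report$summary$n,
    deaths = report$summary$deaths,
    mortality = report$summary$mortality,
    score_levels = report$summary$score_table$levels,
    survived_counts = report$summary$score_table$neg_counts,
    died_counts = report$summary$score_table$pos_counts
  ))
  for (name in c("score", "lactate", "glucose")) {
    sec <- report[[name]]
    if (is.null(sec)) next
    out[[name]] <- list(auc = auc_as_list(sec$auc),
                        cutoff = cutoff_as_list(sec$cutoff))
    if (!is.null(sec$hosmer_lemeshow)) {
      hl <- sec$hosmer_lemeshow
      out[[name]]$hosmer_lemeshow <- list(chi2 = hl$chi2, df = hl$df, p = hl$p)
    }
  }
  if (!is.null(report$combined)) {
    cmb <- report$combined
    out$combined <- list(
      coefficients = as.list(cmb$fit$coefficients),
      se = as.list(cmb$fit$se),
      converged = cmb$fit$converged,
      auc = auc_as_list(cmb$auc),
      cutoff = cutoff_as_list(cmb$cutoff),
      hosmer_lemeshow = list(chi2 = cmb$hosmer_lemeshow$chi2,
                             df = cmb$hosmer_lemeshow$df,
                             p = cmb$hosmer_lemeshow$p),
      p_vs_score = cmb$vs_score$p,
      p_vs_lactate = cmb$vs_lactate$p,
      p_vs_glucose = cmb$vs_glucose$p
    )
  }
  out$provenance <- report$provenance
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
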