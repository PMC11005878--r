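# Published grouped score counts for the two study cohorts. These are the
# package's numeric anchors: grouped-count AUC, Youden cutoff and confusion
# metrics computed from them reproduce the published discrimination results.

#' Grouped score counts of the derivation cohort
#'
#' Per-score-level outcome counts for the 100-patient PICU derivation
#' cohort (48 survivors, 52 deaths over 28 days): survivors
#' (17, 15, 14, 1, 1) and deaths (7, 12, 16, 11, 6) at score levels 0--4.
#'
#' @return a [grouped_counts()] object.
#' @export
#' @examples
#' auc_grouped(derivation_counts())
derivation_counts <- function() {
  grouped_counts(0:4, c(17, 15, 14, 1, 1), c(7, 12, 16, 11, 6))
}

#' Grouped score counts of the temporal validation cohort
#'
#' Per-score-level outcome counts for the 20-patient validation cohort
#' (10 survivors, 10 deaths): survivors (5, 5, 0, 0, 0) and deaths
#' (0, 3, 3, 1, 3) at score levels 0--4.
#'
#' @return a [grouped_counts()] object.
#' @export
#' @examples
#' auc_grouped(validation_counts())
validation_counts <- function() {
  grouped_counts(0:4, c(5, 5, 0, 0, 0), c(0, 3, 3, 1, 3))
}

#' Published per-level patient totals of the derivation cohort
#'
#' The marginal number of patients at each score level 0--4 as published
#' for the derivation cohort: (23, 26, 32, 12, 7), hence 51 patients at
#' score 2 or above.  Note these printed totals disagree by two patients
#' with the sums of the published group-conditional cells at levels 0--2
#' (24, 27, 30); both are reproduced verbatim and the discrepancy is an
#' internal inconsistency of the source tables, documented in the methods
#' vignette.
#'
#' @return named integer vector of patient counts at score levels 0--4.
#' @export
derivation_level_totals <- function() {
  c("0" = 23L, "1" = 26L, "2" = 32L, "3" = 12L, "4" = 7L)
}
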