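# DeLong (1988) nonparametric inference for correlated AUCs via placement
# values. psi(x, y) = 1 if x > y, 1/2 if tied, 0 otherwise; the AUC is the
# mean of psi over all (death, survivor) pairs, V10 are per-death row means
# and V01 per-survivor column means.

delong_placements <- function(values, labels01) {
  x <- values[labels01 == 1]
  y <- values[labels01 == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi),
       v10 = rowMeans(psi), v01 = colMeans(psi),
       m = length(x), n = length(y))
}

delong_se <- function(pl) {
  sqrt(stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n)
}

#' DeLong confidence interval for an AUC
#'
#' Standard error from the placement-value decomposition of the
#' Mann-Whitney statistic; Wald interval truncated to `[0, 1]`.  Perfect
#' separation and an all-tied predictor both have zero placement variance
#' and are returned with `se = 0` rather than raised as errors.
#'
#' @param values per-patient predictor values.
#' @param labels per-patient outcomes; at least two patients per class.
#' @param level confidence level (default 0.95).
#' @return an `auc_estimate` with DeLong `se` and interval.
#' @export
delong_ci <- function(values, labels, level = 0.95) {
  y <- as_outcome01(labels)
  if (length(values) != length(y)) {
    stop("values and labels must have equal length", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("predictor values must be finite", call. = FALSE)
  }
  check_two_classes(y, min_each = 2L)
  pl <- delong_placements(values, y)
  new_auc_estimate(pl$auc, delong_se(pl), level, pl$m, pl$n, "DeLong")
}

#' DeLong test comparing two correlated AUCs
#'
#' Both predictors must be measured on the same patients (paired design).
#' The variance of the AUC difference uses the covariance of the paired
#' placement values; the z statistic is referred to the standard normal.
#' When both AUCs are equal and the difference has zero variance (e.g. a
#' predictor against itself) the test returns `z = 0`, `p = 1`.
#'
#' @param values_a,values_b the two per-patient predictors.
#' @param labels shared per-patient outcomes; at least two per class.
#' @return an object of class `delong_test`: `auc_a`, `auc_b`, `se_diff`,
#'   `z`, `p`.
#' @export
delong_test <- function(values_a, values_b, labels) {
  y <- as_outcome01(labels)
  if (length(values_a) != length(y) || length(values_b) != length(y)) {
    stop("both predictors must be measured on the same patients", call. = FALSE)
  }
  if (anyNA(c(values_a, values_b)) || any(!is.finite(c(values_a, values_b)))) {
    stop("predictor values must be finite", call. = FALSE)
  }
  check_two_classes(y, min_each = 2L)
  pa <- delong_placements(values_a, y)
  pb <- delong_placements(values_b, y)
  var_diff <- stats::var(pa$v10 - pb$v10) / pa$m +
    stats::var(pa$v01 - pb$v01) / pa$n
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) {
      z <- 0
      p <- 1
    } else {
      z <- sign(d) * Inf
      p <- 0
    }
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(auc_a = pa$auc, auc_b = pb$auc,
         se_diff = sqrt(max(var_diff, 0)), z = z, p = p),
    class = "delong_test"
  )
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong paired AUC test: %.4f vs %.4f  (z = %.3f, p = %.4g)\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}
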