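# Discrimination analysis. Death is the positive class throughout; higher
# predictor values mean higher predicted risk. A cutoff c means "predict
# death iff value > c".

as_outcome01 <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% c("survived", "died")
    if (any(bad) || anyNA(labels)) {
      stop("outcome must be 'survived' or 'died'; got: ",
           paste(unique(labels[bad]), collapse = ", "), call. = FALSE)
    }
    return(as.integer(labels == "died"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (anyNA(labels) || !all(labels %in% c(0, 1))) {
      stop("numeric outcome labels must be 0 (survived) or 1 (died)",
           call. = FALSE)
    }
    return(as.integer(labels))
  }
  stop("unsupported outcome label type", call. = FALSE)
}

check_two_classes <- function(y, min_each = 1L) {
  if (sum(y == 1) < min_each || sum(y == 0) < min_each) {
    stop("need at least ", min_each, " patient(s) in each outcome class",
         call. = FALSE)
  }
  invisible(y)
}

#' Grouped outcome counts over ordered predictor levels
#'
#' The printed form of a score's group-conditional distribution: for each
#' ordered predictor level, how many survivors and how many deaths fell at
#' that level.  This is sufficient for tie-corrected AUC, Youden cutoff
#' selection and confusion-matrix metrics.
#'
#' @param levels strictly increasing numeric predictor values.
#' @param neg_counts non-negative integer counts of survivors per level.
#' @param pos_counts non-negative integer counts of deaths per level.
#' @return an object of class `grouped_counts`.
#' @export
#' @examples
#' grouped_counts(0:4, c(17, 15, 14, 1, 1), c(7, 12, 16, 11, 6))
grouped_counts <- function(levels, neg_counts, pos_counts) {
  if (length(levels) != length(neg_counts) ||
      length(levels) != length(pos_counts)) {
    stop("levels, neg_counts and pos_counts must have equal length",
         call. = FALSE)
  }
  if (anyNA(levels) || is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be strictly increasing", call. = FALSE)
  }
  counts <- c(neg_counts, pos_counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(neg_counts) < 1 || sum(pos_counts) < 1) {
    stop("need at least one survivor and one death in total", call. = FALSE)
  }
  structure(
    list(levels = as.numeric(levels),
         neg_counts = as.integer(round(neg_counts)),
         pos_counts = as.integer(round(pos_counts))),
    class = "grouped_counts"
  )
}

#' @export
print.grouped_counts <- function(x, ...) {
  cat("Grouped outcome counts (", sum(x$neg_counts), " survived, ",
      sum(x$pos_counts), " died)\n", sep = "")
  print(data.frame(level = x$levels, survived = x$neg_counts,
                   died = x$pos_counts), row.names = FALSE)
  invisible(x)
}

#' Tabulate per-patient values into grouped counts
#'
#' @param values per-patient predictor values.
#' @param labels per-patient outcomes (`"survived"`/`"died"`, 0/1 or logical).
#' @return a [grouped_counts()] object over the distinct observed values.
#' @export
as_grouped_counts <- function(values, labels) {
  y <- as_outcome01(labels)
  if (length(values) != length(y)) {
    stop("values and labels must have equal length", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("predictor values must be finite", call. = FALSE)
  }
  check_two_classes(y)
  lev <- sort(unique(values))
  grouped_counts(
    lev,
    vapply(lev, function(l) sum(values == l & y == 0), numeric(1)),
    vapply(lev, function(l) sum(values == l & y == 1), numeric(1))
  )
}

expand_counts <- function(counts) {
  list(
    values = c(rep(counts$levels, counts$neg_counts),
               rep(counts$levels, counts$pos_counts)),
    labels = c(rep(0L, sum(counts$neg_counts)),
               rep(1L, sum(counts$pos_counts)))
  )
}

new_auc_estimate <- function(auc, se, level, n_pos, n_neg, method) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(auc = auc, se = se,
         ci_low = if (is.na(se)) NA_real_ else max(0, auc - z * se),
         ci_high = if (is.na(se)) NA_real_ else min(1, auc + z * se),
         level = level, n_pos = n_pos, n_neg = n_neg, method = method),
    class = "auc_estimate"
  )
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.4f", x$auc))
  if (!is.na(x$se)) {
    cat(sprintf("  (%.0f%% CI %.4f-%.4f, SE %.4f)",
                100 * x$level, x$ci_low, x$ci_high, x$se))
  }
  cat(sprintf("  [%d died / %d survived, %s]\n", x$n_pos, x$n_neg, x$method))
  invisible(x)
}

#' Tie-corrected AUC from grouped outcome counts
#'
#' Computes the Mann-Whitney AUC — the probability that a randomly chosen
#' death carries a higher predictor value than a randomly chosen survivor,
#' with ties counted half — directly from per-level counts:
#' `AUC = sum_l pos_l * (neg_below_l + neg_l / 2) / (n_pos * n_neg)`.
#' The standard error and Wald confidence interval use the DeLong
#' placement-value variance on the implied per-patient data.
#'
#' @param counts a [grouped_counts()] object.
#' @param level confidence level for the interval (default 0.95).
#' @return an `auc_estimate`: `auc`, `se`, `ci_low`, `ci_high`, `level`.
#' @export
#' @examples
#' auc_grouped(grouped_counts(0:4, c(17, 15, 14, 1, 1), c(7, 12, 16, 11, 6)))
auc_grouped <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "grouped_counts"))
  neg <- counts$neg_counts
  pos <- counts$pos_counts
  n_neg <- sum(neg)
  n_pos <- sum(pos)
  neg_below <- c(0, cumsum(neg))[seq_along(neg)]
  auc <- sum(pos * (neg_below + 0.5 * neg)) / (n_pos * n_neg)
  se <- if (n_pos >= 2 && n_neg >= 2) {
    ex <- expand_counts(counts)
    delong_se(delong_placements(ex$values, ex$labels))
  } else {
    NA_real_
  }
  new_auc_estimate(auc, se, level, n_pos, n_neg, "grouped Mann-Whitney")
}

#' Tie-corrected AUC from per-patient values
#'
#' Midrank (Wilcoxon) form of the Mann-Whitney AUC; identical to
#' [auc_grouped()] applied to the tabulated values.  The DeLong standard
#' error requires at least two patients per class; otherwise `se` is `NA`.
#'
#' @inheritParams as_grouped_counts
#' @param level confidence level.
#' @return an `auc_estimate`.
#' @export
auc_empirical <- function(values, labels, level = 0.95) {
  y <- as_outcome01(labels)
  if (length(values) != length(y)) {
    stop("values and labels must have equal length", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("predictor values must be finite", call. = FALSE)
  }
  check_two_classes(y)
  m <- sum(y == 1)
  n <- sum(y == 0)
  r <- rank(values)
  auc <- (mean(r[y == 1]) - (m + 1) / 2) / n
  se <- if (m >= 2 && n >= 2) delong_se(delong_placements(values, y)) else NA_real_
  new_auc_estimate(auc, se, level, m, n, "empirical Mann-Whitney")
}

#' Empirical ROC curve
#'
#' One operating point per distinct predictor value (rule: predict death
#' iff value >= threshold), plus the (0,0) endpoint at threshold `Inf`.
#' The curve always starts at (0,0) and ends at (1,1), and both
#' coordinates are non-decreasing along it.
#'
#' @inheritParams as_grouped_counts
#' @return an object of class `roc_curve` with `thresholds` (descending),
#'   `fpr` and `tpr`.
#' @export
roc_empirical <- function(values, labels) {
  y <- as_outcome01(labels)
  if (length(values) != length(y)) {
    stop("values and labels must have equal length", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("predictor values must be finite", call. = FALSE)
  }
  check_two_classes(y)
  thr <- c(Inf, sort(unique(values), decreasing = TRUE))
  m <- sum(y == 1)
  n <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(values >= t & y == 1) / m, numeric(1))
  fpr <- vapply(thr, function(t) sum(values >= t & y == 0) / n, numeric(1))
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("Empirical ROC curve with", length(x$thresholds), "operating points\n")
  print(data.frame(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr),
        row.names = FALSE)
  invisible(x)
}

#' Plot an empirical ROC curve
#'
#' @param x a `roc_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate (1 - specificity)",
                 ylab = "True positive rate (sensitivity)", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Trapezoidal area under an ROC curve
#'
#' Used mainly as a cross-check: for the empirical curve this equals the
#' tie-corrected Mann-Whitney AUC.
#'
#' @param roc a `roc_curve` from [roc_empirical()].
#' @return the area as a fraction in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  fpr <- roc$fpr
  tpr <- roc$tpr
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Confusion-matrix metrics at a fixed cutoff
#'
#' Applies the rule "predict death iff value > cutoff" to grouped counts
#' and reports sensitivity, specificity, Youden index, predictive values
#' and the raw confusion cells.  A predictive value whose denominator is
#' zero (no positive or no negative calls) is reported as `NA`, not 0.
#'
#' @param counts a [grouped_counts()] object.
#' @param cutoff the cutoff c; deaths are predicted for values strictly
#'   above c.
#' @return an object of class `cutoff_metrics`.
#' @export
#' @examples
#' confusion_metrics(
#'   grouped_counts(0:4, c(17, 15, 14, 1, 1), c(7, 12, 16, 11, 6)), 1)
confusion_metrics <- function(counts, cutoff) {
  stopifnot(inherits(counts, "grouped_counts"), is.numeric(cutoff),
            length(cutoff) == 1, is.finite(cutoff))
  above <- counts$levels > cutoff
  tp <- sum(counts$pos_counts[above])
  fp <- sum(counts$neg_counts[above])
  fn <- sum(counts$pos_counts[!above])
  tn <- sum(counts$neg_counts[!above])
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(
    list(cutoff = cutoff,
         sensitivity = sens,
         specificity = spec,
         youden = sens + spec - 1,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
         tp = tp, fp = fp, tn = tn, fn = fn),
    class = "cutoff_metrics"
  )
}

#' @export
print.cutoff_metrics <- function(x, ...) {
  cat(sprintf("Cutoff > %g: sens %.2f%%, spec %.2f%%, Youden %.4f",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity, x$youden))
  cat(sprintf("\n  PPV %s, NPV %s  (TP %d, FP %d, TN %d, FN %d)\n",
              if (is.na(x$ppv)) "NA" else sprintf("%.2f%%", 100 * x$ppv),
              if (is.na(x$npv)) "NA" else sprintf("%.2f%%", 100 * x$npv),
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' Scans every distinct predictor value as a candidate cutoff for the rule
#' "predict death iff value > c" and returns the metrics at the cutoff
#' maximising the Youden index (sensitivity + specificity - 1).  Ties are
#' broken toward the smallest cutoff, i.e. toward higher sensitivity, as
#' befits a triage score.
#'
#' @param x a [grouped_counts()] object, or per-patient predictor values
#'   (in which case `labels` is required).
#' @param labels per-patient outcomes when `x` is a value vector.
#' @return a `cutoff_metrics` object at the optimal cutoff.
#' @export
#' @examples
#' youden_cutoff(grouped_counts(0:4, c(17, 15, 14, 1, 1), c(7, 12, 16, 11, 6)))
youden_cutoff <- function(x, labels = NULL) {
  counts <- if (inherits(x, "grouped_counts")) x else as_grouped_counts(x, labels)
  cand <- counts$levels
  mets <- lapply(cand, function(c) confusion_metrics(counts, c))
  j <- vapply(mets, `[[`, numeric(1), "youden")
  best <- which(j >= max(j) - 1e-12)[1] # smallest cutoff among ties
  mets[[best]]
}
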