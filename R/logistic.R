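# Combined prognostic model: a main-effects logistic regression of 28-day
# mortality on the score, lactate and glucose. The IRLS fitter below is the
# package's own: each iteration solves the weighted least-squares normal
# equations at the current working response, tracking the Bernoulli
# log-likelihood until its change falls below tolerance.

logistic_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  # numerically stable: -log(1 + exp(-eta)) for y=1, -log(1 + exp(eta)) for y=0
  sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
             stats::plogis(-eta, log.p = TRUE)))
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression with an intercept and
#' main effects only.  Convergence is declared when the log-likelihood
#' improves by less than `tol` between iterations; quasi-complete
#' separation is flagged (not silently diverged) when any coefficient
#' exceeds 15 in absolute value on the log-odds scale.  A rank-deficient
#' design is an error naming the collinear columns.
#'
#' @param x numeric matrix or data.frame of predictors, one column per
#'   predictor (no intercept column; it is added internally), or `NULL`
#'   for an intercept-only model.
#' @param y outcomes: `"survived"`/`"died"`, 0/1 or logical, both classes
#'   present; `length(y)` must exceed the number of coefficients.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap.
#' @return an object of class `logistic_fit`: `coefficients` (named, with
#'   `(Intercept)` first), `se`, `vcov`, `converged`, `separation`,
#'   `n_iterations`, `log_likelihood`, `fitted` (per-patient probabilities)
#'   and the model dimensions.
#' @export
#' @examples
#' x <- cbind(score = c(0, 1, 2, 3, 4, 0, 1, 2))
#' y <- c(0, 0, 1, 1, 1, 0, 1, 0)
#' fit_logistic(x, y)
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 50L) {
  y <- as_outcome01(y)
  check_two_classes(y)
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  x <- as.matrix(x)
  if (ncol(x) > 0 && (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))) {
    stop("predictors must be finite numeric", call. = FALSE)
  }
  if (nrow(x) != length(y)) {
    stop("x and y must have the same number of patients", call. = FALSE)
  }
  if (ncol(x) > 0 && is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  X <- cbind("(Intercept)" = rep(1, length(y)), x)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    stop("need more patients than coefficients (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular design: column(s) ", paste(dropped, collapse = ", "),
         " are collinear with the others", call. = FALSE)
  }

  beta <- rep(0, p)
  ll <- logistic_loglik(X, y, beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta <- drop(solve(XtW %*% X, XtW %*% z))
    ll_new <- logistic_loglik(X, y, beta)
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }

  separation <- any(abs(beta) > 15)
  # keep fitted probabilities strictly inside (0, 1): under (quasi-)
  # separation the linear predictor can be extreme enough that plogis
  # rounds to exactly 0 or 1 in double precision
  mu <- pmin(pmax(stats::plogis(drop(X %*% beta)), 1e-12), 1 - 1e-12)
  info <- t(X * (mu * (1 - mu))) %*% X
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  names(beta) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = beta,
         se = sqrt(diag(vc)),
         vcov = vc,
         converged = converged,
         separation = separation,
         n_iterations = iter,
         log_likelihood = ll,
         fitted = mu,
         n = n,
         predictors = colnames(x)),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, logLik = %.3f, %d IRLS iterations%s%s)\n",
              x$n, x$log_likelihood, x$n_iterations,
              if (x$converged) "" else ", NOT converged",
              if (x$separation) ", separation suspected" else ""))
  print(data.frame(coef = x$coefficients, se = x$se))
  invisible(x)
}

#' Predicted mortality risk from a logistic fit
#'
#' Returns fitted probabilities for new patients.  Any strictly monotone
#' transform of the linear predictor (including the probability itself)
#' yields the same ROC curve and AUC, so these probabilities serve directly
#' as the combined risk predictor.
#'
#' @param fit a `logistic_fit`.
#' @param newx matrix or data.frame with the same predictor columns the
#'   model was fitted on.
#' @return numeric vector of probabilities in `(0, 1)`.
#' @export
predict_risk <- function(fit, newx) {
  stopifnot(inherits(fit, "logistic_fit"))
  newx <- as.matrix(newx)
  if (ncol(newx) != length(fit$predictors)) {
    stop("newx must have ", length(fit$predictors), " predictor column(s): ",
         paste(fit$predictors, collapse = ", "), call. = FALSE)
  }
  p <- stats::plogis(drop(cbind(1, newx) %*% fit$coefficients))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Partitions patients into risk-ordered groups and compares observed with
#' expected deaths by the chi-square statistic
#' `sum (O - E)^2 / (E (1 - E/n_g))` (equivalently, summing
#' `(O - E)^2 / E` over both outcome states in every group), referred to a
#' chi-square distribution with `groups - 2` degrees of freedom.
#'
#' Grouping rule: deciles of predicted risk when the predictor takes at
#' least `groups` distinct values; otherwise one group per distinct fitted
#' probability (so a 5-level score alone yields 5 groups and 3 degrees of
#' freedom).  Duplicate quantile breaks are merged, and `df` always uses
#' the realised number of groups.
#'
#' @param probabilities per-patient predicted probabilities, strictly in
#'   `(0, 1)`, with at least three distinct values.
#' @param labels per-patient outcomes.
#' @param groups target number of risk groups (default 10).
#' @return an object of class `hl_result`: `chi2`, `df`, `p` and
#'   `group_table` (per-group size, observed and expected deaths).
#' @export
hosmer_lemeshow <- function(probabilities, labels, groups = 10L) {
  y <- as_outcome01(labels)
  p <- probabilities
  if (length(p) != length(y)) {
    stop("probabilities and labels must have equal length", call. = FALSE)
  }
  if (anyNA(p) || any(p <= 0) || any(p >= 1)) {
    stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  if (groups < 3) stop("need at least 3 groups", call. = FALSE)
  distinct <- sort(unique(p))
  if (length(distinct) < 3) {
    stop("fewer than 3 distinct predicted probabilities; ",
         "the test needs at least 3 risk groups (one per distinct value)",
         call. = FALSE)
  }
  if (length(distinct) < groups) {
    bin <- match(p, distinct)
  } else {
    breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1),
                                     type = 2, names = FALSE))
    bin <- cut(p, breaks, include.lowest = TRUE, labels = FALSE)
  }
  g <- max(bin)
  n_g <- tabulate(bin, nbins = g)
  obs <- vapply(seq_len(g), function(b) sum(y[bin == b]), numeric(1))
  exp_d <- vapply(seq_len(g), function(b) sum(p[bin == b]), numeric(1))
  chi2 <- sum((obs - exp_d)^2 / exp_d +
              ((n_g - obs) - (n_g - exp_d))^2 / (n_g - exp_d))
  df <- g - 2L
  structure(
    list(chi2 = chi2, df = df,
         p = stats::pchisq(chi2, df, lower.tail = FALSE),
         group_table = data.frame(group = seq_len(g), n = n_g,
                                  observed_deaths = obs,
                                  expected_deaths = exp_d)),
    class = "hl_result"
  )
}

#' @export
print.hl_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f, df = %d, p = %.3f\n",
              x$chi2, x$df, x$p))
  print(x$group_table, row.names = FALSE)
  invisible(x)
}
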