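# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulations so they share no code path with the
# package implementations they check.

# AUC by explicit enumeration of all (death, survivor) pairs
brute_force_auc <- function(values, labels01) {
  x <- values[labels01 == 1]
  y <- values[labels01 == 0]
  total <- 0
  for (xi in x) {
    for (yj in y) {
      total <- total + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
    }
  }
  total / (length(x) * length(y))
}

# Youden scan over every candidate "value > c" rule, by direct counting
brute_force_youden <- function(values, labels01) {
  cand <- sort(unique(values))
  best <- NULL
  for (c in cand) {
    tp <- sum(values > c & labels01 == 1)
    fn <- sum(values <= c & labels01 == 1)
    tn <- sum(values <= c & labels01 == 0)
    fp <- sum(values > c & labels01 == 0)
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (is.null(best) || j > best$j + 1e-12) best <- list(cutoff = c, j = j)
  }
  best
}

# nonparametric bootstrap standard error of the Mann-Whitney AUC
bootstrap_auc_se <- function(values, labels01, reps) {
  n <- length(values)
  m <- sum(labels01 == 1)
  aucs <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- values[idx]
    y <- labels01[idx]
    m_r <- sum(y == 1)
    n_r <- sum(y == 0)
    if (m_r == 0 || n_r == 0) {
      aucs[r] <- NA
      next
    }
    rk <- rank(v)
    aucs[r] <- (mean(rk[y == 1]) - (m_r + 1) / 2) / n_r
  }
  stats::sd(aucs, na.rm = TRUE)
}

# small random tied-predictor test case for property loops
random_tied_case <- function(n = 40, n_levels = 5) {
  repeat {
    values <- sample.int(n_levels, n, replace = TRUE) - 1
    labels <- stats::rbinom(n, 1, 0.5)
    if (sum(labels) >= 2 && sum(labels == 0) >= 2) {
      return(list(values = values, labels = labels))
    }
  }
}
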