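test_that("log-normal quartile matching is exact in closed form", {
  spec <- lognormal_from_quartiles(1.55, 1.00, 3.00)
  expect_equal(spec$mu, log(1.55))
  expect_equal(spec$sigma, (log(3) - log(1)) / (2 * qnorm(0.75)))
  expect_equal(exp(spec$mu), spec$source_median)

  # degenerate zero-IQR spec is a point mass
  point <- lognormal_from_quartiles(2, 2, 2)
  expect_equal(point$sigma, 0)

  expect_error(lognormal_from_quartiles(1, 2, 3), "q1 <= median")
  expect_error(lognormal_from_quartiles(1, -1, 3), "q1 <= median")
})

test_that("sampling preserves the matched quartile structure", {
  set.seed(701)
  # a log-symmetric triple round-trips in full
  sym <- lognormal_from_quartiles(2, 1, 4)
  q_sym <- quantile(rlnorm(40000, sym$mu, sym$sigma), c(0.25, 0.5, 0.75),
                    names = FALSE)
  expect_equal(q_sym, c(1, 2, 4), tolerance = 0.03)

  # asymmetric published triples preserve the median and the q3/q1 spread
  # (a two-parameter log-normal cannot also match the asymmetry)
  spec <- lognormal_from_quartiles(4.5, 1.78, 13.98)
  q <- quantile(rlnorm(40000, spec$mu, spec$sigma), c(0.25, 0.5, 0.75),
                names = FALSE)
  expect_equal(q[2], 4.5, tolerance = 0.05)
  expect_equal(q[3] / q[1], 13.98 / 1.78, tolerance = 0.05)
})

test_that("identical configs generate byte-identical cohorts without touching the caller RNG", {
  cfg <- default_cohort_config(seed = 11)
  set.seed(999)
  before <- .Random.seed
  a <- sample_cohort(cfg)
  expect_identical(.Random.seed, before) # caller RNG restored
  b <- sample_cohort(cfg)
  expect_identical(a, b)

  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1)
  write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))

  # a different seed gives a different cohort
  c3 <- sample_cohort(default_cohort_config(seed = 12))
  expect_false(identical(a$heart_rate, c3$heart_rate))
})

test_that("generated vitals reproduce every assigned score when re-scored", {
  for (seed in c(21, 22, 23)) {
    co <- sample_cohort(default_cohort_config(seed = seed))
    rescored <- score_cohort(co)
    expect_identical(rescored$qsofa_total, co$assigned_score)
    expect_true(all(co$age_days >= 0 & co$age_days < 6575))
    expect_true(all(co$heart_rate > 0 & co$respiratory_rate > 0))
    expect_true(all(co$crt_seconds >= 0))
    expect_true(all(co$lactate >= 0 & co$glucose >= 0))
  }
  co_val <- sample_cohort(validation_cohort_config(seed = 24))
  expect_equal(nrow(co_val), 20)
  expect_identical(score_cohort(co_val)$qsofa_total, co_val$assigned_score)
})

test_that("large-sample frequencies converge to the configured distributions", {
  cfg <- default_cohort_config(seed = 31)
  cfg$n <- 20000L
  co <- sample_cohort(cfg)
  died <- co$outcome == "died"
  expect_equal(mean(died), 0.52, tolerance = 0.02)
  emp_died <- tabulate(co$assigned_score[died] + 1, 5) / sum(died)
  expect_true(all(abs(emp_died - cfg$score_dist_died) < 0.02))
  emp_surv <- tabulate(co$assigned_score[!died] + 1, 5) / sum(!died)
  expect_true(all(abs(emp_surv - cfg$score_dist_survived) < 0.02))
  expect_equal(median(co$lactate[died]), 4.5, tolerance = 0.1)
  expect_equal(median(co$glucose[!died]), 8.0, tolerance = 0.1)
})

test_that("the shipped fixture cohorts regenerate exactly from their configs", {
  fixtures <- list(
    list(file = "synthetic_derivation_cohort.csv", cfg = default_cohort_config()),
    list(file = "synthetic_validation_cohort.csv", cfg = validation_cohort_config())
  )
  for (fx in fixtures) {
    path <- system.file("extdata", fx$file, package = "pqsofa")
    shipped <- read_cohort(path)
    regen <- sample_cohort(fx$cfg)
    expect_equal(shipped$heart_rate, regen$heart_rate)
    expect_equal(shipped$lactate, regen$lactate)
    expect_equal(shipped$outcome, regen$outcome)
    expect_equal(shipped$assigned_score, regen$assigned_score)
  }
})

test_that("the shipped configurations carry the published group structure", {
  cfg <- default_cohort_config()
  expect_equal(cfg$n, 100L)
  expect_equal(cfg$mortality_p, 0.52)
  expect_equal(sum(cfg$score_dist_died), 1)
  expect_equal(cfg$score_dist_died[3], 16 / 52)
  expect_equal(cfg$lactate_survived$source_median, 1.55)

  val <- validation_cohort_config()
  expect_equal(val$n, 20L)
  expect_equal(val$score_dist_died[1], 0)
  expect_equal(val$lactate_survived$source_median, 2.05)

  expect_error(cohort_config(5, 0.5, rep(0.2, 5), rep(0.2, 5),
                             cfg$lactate_survived, cfg$lactate_died,
                             cfg$glucose_survived, cfg$glucose_died),
               "n must be")
  bad_dist <- c(0.5, 0.5, 0.1, 0, 0)
  expect_error(cohort_config(100, 0.5, bad_dist, rep(0.2, 5),
                             cfg$lactate_survived, cfg$lactate_died,
                             cfg$glucose_survived, cfg$glucose_died),
               "summing to 1")
})
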