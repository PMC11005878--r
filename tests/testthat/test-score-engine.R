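test_that("ages map to the documented bands and jointly cover [0, 18 years)", {
  tab <- vital_thresholds()
  expect_equal(nrow(tab), 6)

  expect_equal(classify_age_band(180)$label, "1 month to 1 year")
  expect_equal(classify_age_band(3)$label, "0 days to 1 week")
  # the 13-23-month gap belongs to the infant band (extended coverage)
  expect_equal(classify_age_band(540)$label, "1 month to 1 year")

  ages <- seq(0, 6574.9, by = 0.7)
  band <- classify_age_band(ages, tab)
  expect_true(all(ages >= band$lower_days & ages < band$upper_days))
  # boundaries belong to the upper band (half-open intervals)
  for (lo in tab$lower_days[-1]) {
    expect_equal(classify_age_band(lo, tab)$lower_days, lo)
  }

  expect_error(classify_age_band(-1), "range")
  expect_error(classify_age_band(6575), "range")
  expect_error(classify_age_band(NaN), "finite")
})

test_that("component scoring follows the strict/inclusive threshold conventions", {
  tab <- vital_thresholds()
  infant <- tab[tab$label == "1 month to 1 year", ]
  school <- tab[tab$label == "6-12 years", ]
  teen <- tab[tab$label == "13-18 years", ]

  expect_identical(score_heart_rate(185, infant), 1L)
  expect_identical(score_heart_rate(85, infant), 1L)
  expect_identical(score_heart_rate(120, school), 0L)
  # no bradycardia criterion from 2 years up: very low HR still scores 0
  expect_identical(score_heart_rate(45, school), 0L)

  expect_identical(score_respiratory_rate(36, infant), 1L)
  expect_identical(score_respiratory_rate(14, teen), 0L)
  expect_identical(score_respiratory_rate(15, teen), 1L)

  expect_identical(score_crt(c(3, 2.9, 0)), c(1L, 0L, 0L))
  expect_identical(score_avpu(c("A", "V", "P", "U")), c(0L, 1L, 1L, 1L))

  # the score flips exactly at threshold + eps (HR/RR strict >, CRT >= 3)
  eps <- 1e-3
  for (i in seq_len(nrow(tab))) {
    b <- tab[i, , drop = FALSE]
    expect_identical(score_heart_rate(b$tachycardia_bpm, b), 0L)
    expect_identical(score_heart_rate(b$tachycardia_bpm + eps, b), 1L)
    expect_identical(score_respiratory_rate(b$rr_threshold, b), 0L)
    expect_identical(score_respiratory_rate(b$rr_threshold + eps, b), 1L)
    if (!is.na(b$bradycardia_bpm)) {
      expect_identical(score_heart_rate(b$bradycardia_bpm, b), 0L)
      expect_identical(score_heart_rate(b$bradycardia_bpm - eps, b), 1L)
    }
  }
  expect_identical(score_crt(3 - eps), 0L)

  expect_error(score_heart_rate(0, infant), "positive")
  expect_error(score_respiratory_rate(-5, infant), "positive")
  expect_error(score_crt(-1), "non-negative")
  expect_error(score_avpu("alert"), "A, V, P, U")
})

test_that("the total is the component sum and stays in 0..4 over an input grid", {
  tab <- vital_thresholds()
  cases <- expand.grid(
    age_days = c(3, 100, 1500, 5000),
    heart_rate = c(60, 120, 150, 200),
    respiratory_rate = c(10, 20, 30, 60),
    crt_seconds = c(1, 3),
    avpu = c("A", "P"),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(cases))) {
    obs <- as.list(cases[i, ])
    res <- compute_qsofa(obs, tab)
    band <- classify_age_band(obs$age_days, tab)
    expect_identical(
      res$total,
      score_crt(obs$crt_seconds) +
        score_respiratory_rate(obs$respiratory_rate, band) +
        score_heart_rate(obs$heart_rate, band) +
        score_avpu(obs$avpu)
    )
    expect_true(res$total >= 0 && res$total <= 4)
    expect_true(all(c(res$crt_point, res$rr_point, res$hr_point,
                      res$avpu_point) %in% 0:1))
  }

  # worked examples: all-normal, all-abnormal, two-component
  normal <- list(age_days = 200, heart_rate = 120, respiratory_rate = 25,
                 crt_seconds = 1, avpu = "A")
  expect_identical(compute_qsofa(normal, tab)$total, 0L)
  worst <- list(age_days = 200, heart_rate = 190, respiratory_rate = 40,
                crt_seconds = 4, avpu = "P")
  expect_identical(compute_qsofa(worst, tab)$total, 4L)
  two <- list(age_days = 200, heart_rate = 120, respiratory_rate = 25,
              crt_seconds = 4, avpu = "V")
  expect_identical(compute_qsofa(two, tab)$total, 2L)
})

test_that("pushing heart rate above the tachycardia threshold never lowers the total", {
  tab <- vital_thresholds()
  base <- list(age_days = 200, heart_rate = 120, respiratory_rate = 25,
               crt_seconds = 1, avpu = "A")
  for (rr in c(20, 40)) {
    for (crt in c(1, 4)) {
      obs <- base
      obs$respiratory_rate <- rr
      obs$crt_seconds <- crt
      before <- compute_qsofa(obs, tab)$total
      obs$heart_rate <- classify_age_band(obs$age_days, tab)$tachycardia_bpm + 10
      expect_gte(compute_qsofa(obs, tab)$total, before)
    }
  }
})

test_that("missing vitals are an error, never imputed", {
  obs <- list(age_days = 200, heart_rate = 120, respiratory_rate = 25,
              crt_seconds = 1, avpu = "A")
  for (f in names(obs)) {
    broken <- obs
    broken[[f]] <- NA
    expect_error(compute_qsofa(broken), f)
    broken[[f]] <- NULL
    expect_error(compute_qsofa(broken), f)
  }
  cohort <- data.frame(age_days = c(100, 200), heart_rate = c(120, NA),
                       respiratory_rate = c(25, 25), crt_seconds = c(1, 1),
                       avpu = c("A", "A"))
  expect_error(score_cohort(cohort), "heart_rate")
})

test_that("a custom threshold table is validated before use", {
  tab <- vital_thresholds()
  bad <- tab
  bad$upper_days[2] <- bad$lower_days[2] - 1
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(vital_thresholds(tmp))

  bad2 <- tab
  bad2$tachycardia_bpm[4] <- 200 # violates monotone non-increasing thresholds
  jsonlite::write_json(bad2, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(vital_thresholds(tmp), "non-increasing")
})
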