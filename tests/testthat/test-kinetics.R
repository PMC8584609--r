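paper_model <- published_decay_model()

test_that("detect_peaks applies the preceded-and-followed-by-lower rule", {
  s <- tibble::tibble(
    day = c(1, 3, 5, 7, 9, 11, 13),
    crp_mg_L = c(10, 80, 120, 60, 40, 90, 50)
  )
  pk <- detect_peaks(s)
  expect_equal(pk$primary_peak, list(day = 5, value = 120))
  expect_true(pk$has_second_peak)
  expect_equal(pk$second_peak, list(day = 11, value = 90))

  mono <- tibble::tibble(day = c(1, 3, 5), crp_mg_L = c(50, 30, 10))
  pk <- detect_peaks(mono)
  expect_equal(pk$primary_peak, list(day = 1, value = 50))
  expect_false(pk$has_second_peak)
  expect_equal(nrow(pk$local_peaks), 0) # boundary max is never a local peak

  tie <- tibble::tibble(day = c(1, 3, 5), crp_mg_L = c(50, 50, 10))
  pk <- detect_peaks(tie)
  expect_equal(pk$primary_peak, list(day = 1, value = 50)) # first occurrence
  expect_false(pk$has_second_peak)

  expect_error(detect_peaks(tibble::tibble(day = numeric(), crp_mg_L = numeric())),
    "no postoperative measurements")
})

test_that("detect_peaks agrees with a brute-force interior-triple scan", {
  set.seed(7)
  for (i in 1:60) {
    s <- random_series(sample(3:12, 1))
    for (min_rise in c(0, 5)) {
      got <- detect_peaks(s, min_rise = min_rise)
      want <- oracle_local_peaks(s$day, s$crp_mg_L, min_rise)
      expect_equal(got$local_peaks$day, want$day)
      expect_equal(got$local_peaks$value, want$value)
      i_max <- which.max(s$crp_mg_L)
      expect_equal(got$primary_peak$day, s$day[i_max])
      others <- want[want$day != got$primary_peak$day, ]
      expect_equal(got$has_second_peak, nrow(others) > 0)
      if (nrow(others) > 0) {
        expect_equal(got$second_peak$value, max(others$value))
      }
    }
  }
})

test_that("align_to_peak normalizes to the peak and keeps post-peak days", {
  s <- tibble::tibble(day = c(5, 7, 9), crp_mg_L = c(120, 60, 40))
  al <- align_to_peak(s)
  expect_equal(al$x, c(0, 2, 4))
  expect_equal(al$y, c(1, 0.5, 1 / 3))

  s <- tibble::tibble(day = c(1, 3, 5), crp_mg_L = c(100, 50, 25))
  expect_equal(align_to_peak(s)$y, c(1, 0.5, 0.25))

  last_peak <- tibble::tibble(day = c(1, 4), crp_mg_L = c(10, 50))
  al <- align_to_peak(last_peak)
  expect_equal(nrow(al), 1)
  expect_equal(unlist(al), c(x = 0, y = 1))

  zero <- tibble::tibble(day = 1:2, crp_mg_L = c(0, 0))
  expect_error(align_to_peak(zero), "positive")
})

test_that("noiseless decay points are recovered to numerical precision", {
  x <- 0:20
  pts <- tibble::tibble(x = x, y = predict_relative_crp(paper_model, x))
  fit <- fit_one_phase_decay(pts)
  expect_equal(fit$span, 0.7235, tolerance = 1e-6)
  expect_equal(fit$rate_k, 0.2883, tolerance = 1e-6)
  expect_equal(fit$plateau, 0.2683, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("noisy pooled points recover the decay parameters within 5%", {
  set.seed(2024)
  x <- rep(0:20, times = 200) # 200 patients, one point per day after peak
  y <- pmax(predict_relative_crp(paper_model, x) + rnorm(length(x), sd = 0.05), 0)
  fit <- fit_one_phase_decay(tibble::tibble(x = x, y = y))
  expect_lt(abs(fit$span - 0.7235) / 0.7235, 0.05)
  expect_lt(abs(fit$rate_k - 0.2883) / 0.2883, 0.05)
  expect_lt(abs(fit$plateau - 0.2683) / 0.2683, 0.05)
  # R^2 should sit near its sampling-theory value var(f) / (var(f) + sigma^2)
  vf <- var(predict_relative_crp(paper_model, 0:20))
  expect_equal(fit$r_squared, vf / (vf + 0.05^2), tolerance = 0.02)
})

test_that("degenerate inputs to the decay fit raise informative errors", {
  expect_error(
    fit_one_phase_decay(tibble::tibble(x = c(0, 1), y = c(1, 0.5))),
    "3 distinct x"
  )
  expect_error(
    fit_one_phase_decay(tibble::tibble(x = 0:10, y = rep(0.5, 11))),
    "no decay"
  )
  expect_error(
    fit_one_phase_decay(tibble::tibble(x = 0:5, y = c(1, 0.9, -0.1, 0.5, 0.4, 0.3))),
    "non-negative"
  )
})

test_that("the published model predicts 49.67% and 43.95% of peak at 4 and 5 days", {
  expect_equal(round(100 * predict_relative_crp(paper_model, 4), 2), 49.67)
  expect_equal(round(100 * predict_relative_crp(paper_model, 5), 2), 43.95)
  m <- decay_model(0.6, 0.4, 0.3)
  expect_equal(predict_relative_crp(m, 0), 0.9)
  expect_error(predict_relative_crp(m, -1), ">= 0")
})

test_that("failure thresholds add 15 percentage points of peak at days 3 and 4", {
  rule <- ftd_rule()
  expect_equal(round(100 * failure_threshold(paper_model, rule, 3), 2), 72.30)
  expect_equal(round(100 * failure_threshold(paper_model, rule, 4), 2), 64.67)
  rule0 <- ftd_rule(margin = 0, threshold_days = c(3, 4))
  expect_equal(
    failure_threshold(paper_model, rule0, 4),
    predict_relative_crp(paper_model, 4)
  )
  # the additive margin is conserved at every assessment day
  rule_all <- ftd_rule(margin = 0.15, threshold_days = 1:10)
  for (x in 1:10) {
    expect_equal(
      failure_threshold(paper_model, rule_all, x) - predict_relative_crp(paper_model, x),
      0.15
    )
  }
  expect_error(failure_threshold(paper_model, rule, 7), "threshold_days")
})

test_that("predicted absolute CRP reproduces the worked per-patient values", {
  rule <- ftd_rule()
  expect_equal(predicted_absolute_crp(256.4, paper_model, rule, 4), 165.81, tolerance = 0.05 / 165.81)
  expect_equal(predicted_absolute_crp(74.6, paper_model, rule, 3), 53.93, tolerance = 0.05 / 53.93)
  # with zero margin the prediction is the bare decay curve scaled by the peak
  rule0 <- ftd_rule(margin = 0, threshold_days = 1:4)
  expect_equal(
    predicted_absolute_crp(100, paper_model, rule0, 1),
    100 * predict_relative_crp(paper_model, 1)
  )
  expect_error(predicted_absolute_crp(0, paper_model, rule, 4), "positive")
})

test_that("value_at_day_after_peak resolves exact, nearest, interpolated, absent", {
  s <- tibble::tibble(day = c(2, 5, 9), crp_mg_L = c(100, 60, 30))
  expect_equal(value_at_day_after_peak(s, peak_day = 2, x = 3, tolerance_days = 1), 60)
  # samples at x-1 and x+1 only: earlier wins the tie
  s <- tibble::tibble(day = c(2, 5, 7), crp_mg_L = c(100, 60, 40))
  expect_equal(value_at_day_after_peak(s, 2, 4, tolerance_days = 1), 60)
  # samples at x-2 and x+2 only: linear midpoint
  s <- tibble::tibble(day = c(2, 4, 8), crp_mg_L = c(100, 60, 40))
  expect_equal(value_at_day_after_peak(s, 2, 4, tolerance_days = 1), 50)
  # nothing beyond the target and nothing within tolerance: absent
  s <- tibble::tibble(day = c(2, 3), crp_mg_L = c(100, 80))
  expect_true(is.na(value_at_day_after_peak(s, 2, 4, tolerance_days = 1)))
  expect_error(value_at_day_after_peak(s, 2, 0), ">= 1")
})

test_that("failure_to_decline matches the worked examples and is strict", {
  rule <- ftd_rule()
  s3 <- tibble::tibble(day = c(1, 4, 6, 8, 10), crp_mg_L = c(30, 70, 105.1, 100, 96.60))
  ftd <- failure_to_decline(s3, paper_model, rule)
  expect_true(ftd$failure[ftd$x == 4])
  expect_equal(ftd$observed[ftd$x == 4], 96.60)
  expect_equal(ftd$predicted[ftd$x == 4], 67.96, tolerance = 0.05 / 67.96)

  s5 <- tibble::tibble(day = c(1, 3, 5), crp_mg_L = c(139.1, 70, 28.30))
  ftd <- failure_to_decline(s5, paper_model, rule)
  expect_false(ftd$failure[ftd$x == 4])
  expect_equal(ftd$predicted[ftd$x == 4], 89.95, tolerance = 0.05 / 89.95)

  # a value exactly on the threshold is not a failure
  pred <- predicted_absolute_crp(100, paper_model, rule, 3)
  s_eq <- tibble::tibble(day = c(1, 4), crp_mg_L = c(100, pred))
  ftd <- failure_to_decline(s_eq, paper_model, rule)
  expect_false(ftd$failure[ftd$x == 3])
  expect_true(ftd$assessable[ftd$x == 3])

  # unassessable day: no failure, flagged
  s_short <- tibble::tibble(day = 1, crp_mg_L = 100)
  ftd <- failure_to_decline(s_short, paper_model, rule)
  expect_false(any(ftd$failure))
  expect_false(any(ftd$assessable))
})

test_that("relative prediction decreases strictly and tends to the plateau", {
  set.seed(3)
  for (i in 1:10) {
    m <- decay_model(runif(1, 0.4, 0.8), runif(1, 0.1, 1), runif(1, 0, 0.3))
    x <- seq(0, 30, by = 0.5)
    y <- predict_relative_crp(m, x)
    expect_true(all(diff(y) < 0))
    expect_equal(predict_relative_crp(m, 1000), m$plateau, tolerance = 1e-8)
  }
})

test_that("decay models round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_decay_model(published_decay_model(), path)
  back <- read_decay_model(path)
  expect_equal(back, published_decay_model())
})
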