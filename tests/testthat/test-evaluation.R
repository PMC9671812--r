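test_that("concordance handles the canonical cases", {
  # perfect ranking of 4 uncensored distinct times
  expect_equal(harrell_c(c(1, 2, 3, 4), rep(1, 4), c(4, 3, 2, 1)), 1)
  # all scores equal
  expect_equal(harrell_c(c(1, 2, 3, 4), rep(1, 4), rep(0.5, 4)), 0.5)
  # no comparable pairs
  expect_error(harrell_c(c(1, 2), c(0, 0), c(1, 2)), "no comparable pairs")
})

test_that("concordance equals brute-force pair enumeration", {
  set.seed(31)
  for (k in 1:20) {
    d <- random_surv_instance(50)
    expect_identical(harrell_c(d$times, d$events, d$scores),
                     brute_concordance(d$times, d$events, d$scores))
  }
})

test_that("concordance agrees with the survival package on tie-free data", {
  set.seed(32)
  d <- random_surv_instance(300)
  ours <- harrell_c(d$times, d$events, d$scores)
  ref <- survival::concordance(
    survival::Surv(d$times, d$events) ~ d$scores, reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("bootstrap CIs are deterministic and degenerate correctly", {
  x <- rnorm(100)
  ci <- bootstrap_ci(function(d, idx) 42, x, 100, B = 50, seed = 1)
  expect_equal(c(ci$median, ci$lo, ci$hi), c(42, 42, 42))
  ci1 <- bootstrap_ci(function(d, idx) mean(d[idx]), x, 100, B = 200,
                      seed = 9)
  ci2 <- bootstrap_ci(function(d, idx) mean(d[idx]), x, 100, B = 200,
                      seed = 9)
  expect_identical(ci1, ci2)
  expect_lt(ci1$lo, ci1$median)
  expect_lt(ci1$median, ci1$hi)
})

test_that("bootstrap CI of a mean covers the truth at the nominal rate", {
  set.seed(5)
  covered <- replicate(200, {
    x <- rnorm(200)
    ci <- bootstrap_ci(function(d, idx) mean(d[idx]), x, 200, B = 200,
                       seed = sample.int(1e6, 1))
    ci$lo <= 0 && 0 <= ci$hi
  })
  expect_gte(mean(covered), 0.91)
  expect_lte(mean(covered), 0.99)
})

test_that("paired concordance deltas behave at the null and under separation", {
  set.seed(12)
  n <- 800
  eta <- rnorm(n)
  t0 <- rexp(n, 0.05 * exp(eta))
  cens <- 10 + runif(n)
  times <- pmin(t0, cens); events <- as.numeric(t0 <= cens)
  # identical models: delta exactly zero
  d0 <- c_delta(eta, eta, times, events, B = 100, seed = 2)
  expect_equal(d0$median, 0)
  expect_false(d0$significant)
  # oracle vs pure noise: significant positive delta
  d1 <- c_delta(eta, rnorm(n), times, events, B = 300, seed = 3)
  expect_gt(d1$median, 0)
  expect_true(d1$significant)
  expect_gt(d1$lo, 0)
  # tiny perturbation: CI straddles zero
  d2 <- c_delta(eta, eta + rnorm(n, sd = 0.005), times, events,
                B = 300, seed = 4)
  expect_true(d2$lo <= 0 && d2$hi >= 0)
  expect_error(c_delta(eta[-1], eta, times, events), "paired")
})

test_that("percentile curves conserve the event total", {
  set.seed(41)
  scores <- rnorm(5000)
  events <- rbinom(5000, 1, plogis(scores - 2))
  curve <- event_rate_by_percentile(scores, events, n_bins = 100)
  expect_equal(nrow(curve), 100)
  expect_equal(sum(curve$n * curve$rate), sum(events))
  expect_equal(sum(curve$n), 5000)
})

test_that("decile rate ratio reproduces a constructed 10x contrast", {
  # 1000 participants; top decile 20/100 events, bottom decile 2/100
  scores <- seq_len(1000)
  events <- rep(0, 1000)
  events[sample(901:1000, 20)] <- 1
  events[sample(1:100, 2)] <- 1
  set.seed(1)
  rr <- decile_rate_ratio(scores, events, B = 100, seed = 1)
  expect_equal(rr$rate_top, 0.20)
  expect_equal(rr$rate_bottom, 0.02)
  expect_equal(rr$risk_ratio, 10)
  expect_false(rr$lower_bound)
  # odds ratio labeled separately
  expect_equal(rr$odds_ratio, (0.2 / 0.8) / (0.02 / 0.98))
})

test_that("decile ratio of uninformative scores covers 1", {
  set.seed(77)
  scores <- rnorm(20000)
  events <- rbinom(20000, 1, 0.05)
  rr <- decile_rate_ratio(scores, events, B = 400, seed = 5)
  expect_true(rr$lo <= 1 && rr$hi >= 1)
})

test_that("an empty bottom decile is flagged as a lower bound", {
  scores <- seq_len(200)
  events <- c(rep(0, 180), rep(1, 20))
  rr <- decile_rate_ratio(scores, events, B = 50, seed = 2)
  expect_true(rr$lower_bound)
})

test_that("calibration is exact for a constant risk without censoring", {
  set.seed(51)
  n <- 2000
  events <- rbinom(n, 1, 0.3)
  times <- ifelse(events == 1, runif(n, 0, 10), 10.5)
  cal <- calibration_curve(rep(0.3, n), times, events, bins = 1,
                           horizon = 10)
  expect_equal(nrow(cal), 1)
  expect_equal(cal$observed, mean(events), tolerance = 1e-12)
  expect_equal(cal$mean_predicted, 0.3)
})

test_that("calibration bins are sorted by predicted risk", {
  set.seed(52)
  n <- 3000
  p <- runif(n, 0.01, 0.6)
  events <- rbinom(n, 1, p)
  times <- ifelse(events == 1, runif(n, 0, 10), 10.2)
  cal <- calibration_curve(p, times, events, bins = 10, horizon = 10)
  expect_equal(nrow(cal), 10)
  expect_true(all(diff(cal$mean_predicted) >= 0))
  expect_true(all(cal$lo <= cal$observed & cal$observed <= cal$hi))
  expect_error(calibration_curve(c(-0.1, 0.5), c(1, 2), c(1, 0)),
               "\\[0, 1\\]")
})

test_that("net benefit evaluates the constructed confusion table exactly", {
  nb <- net_benefit_from_counts(tp = 10, fp = 20, n = 100, threshold = 0.2,
                                prevalence = 0.15)
  expect_equal(nb$net_benefit, 0.05)
  expect_equal(nb$snb, 1 / 3)
})

test_that("decision curves satisfy the treat-all / treat-none limits", {
  set.seed(61)
  n <- 4000
  risk <- runif(n, 0, 0.5)
  events <- rbinom(n, 1, risk)
  times <- ifelse(events == 1, runif(n, 0, 10), 10.1)
  dc <- decision_curve(risk, times, events,
                       thresholds = c(1e-4, 0.05, 0.1, 0.2), horizon = 10)
  expect_true(all(dc$treat_none == 0))
  # sNB of treat-all tends to 1 as the threshold tends to 0
  expect_equal(dc$snb_treat_all[1], 1, tolerance = 0.01)
  # with zero pre-horizon censoring this equals the naive binary computation
  prev <- mean(events)
  w <- 0.2 / 0.8
  pos <- risk >= 0.2
  nb_naive <- sum(pos & events == 1) / n - sum(pos & events == 0) / n * w
  expect_equal(dc$net_benefit[dc$threshold == 0.2], nb_naive,
               tolerance = 1e-12)
  expect_equal(attr(dc, "n_excluded"), 0)
})

test_that("pre-horizon censored participants are excluded and reported", {
  risk <- c(0.9, 0.9, 0.1, 0.1, 0.5)
  times <- c(2, 11, 11, 3, 12)
  events <- c(1, 0, 0, 0, 0) # row 4 censored before horizon, no event
  dc <- decision_curve(risk, times, events, thresholds = 0.2, horizon = 10)
  expect_equal(attr(dc, "n_excluded"), 1)
  # included: rows 1,2,3,5 -> n = 4, one event
  expect_equal(attr(dc, "prevalence"), 0.25)
})

test_that("classification metrics at target FPRs match their definitions", {
  # perfectly separating scores
  y <- c(rep(0, 50), rep(1, 50))
  s <- c(rnorm(50, 0), rnorm(50, 10))
  m <- metrics_at_fpr(s, times = NULL, events = y,
                      fpr_grid = c(0.05, 0.1, 0.2))
  expect_true(all(m$sensitivity == 1))
  expect_true(all(m$lr_plus >= 1 / 0.2))
  # LR+ identity on imperfect data
  set.seed(71)
  y2 <- rbinom(4000, 1, 0.3)
  s2 <- rnorm(4000) + y2
  m2 <- metrics_at_fpr(s2, NULL, y2, fpr_grid = 0.1)
  expect_equal(m2$lr_plus, m2$sensitivity / m2$realized_fpr)
})

test_that("random scores give sensitivity near the FPR and LR+ near 1", {
  set.seed(72)
  y <- rbinom(20000, 1, 0.1)
  s <- rnorm(20000)
  m <- metrics_at_fpr(s, NULL, y, fpr_grid = c(0.05, 0.1, 0.2))
  expect_true(all(abs(m$sensitivity - m$target_fpr) < 0.1))
  expect_true(all(abs(m$lr_plus - 1) < 0.5))
})
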