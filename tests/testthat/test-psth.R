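test_that("PSTH rates follow the count / (n_events * bin_width) formula", {
  p0 <- build_psth(numeric(), event_times = 50, window = c(-1, 1),
                   bin_width = 0.1)
  expect_true(all(p0$rate == 0))

  p1 <- build_psth(c(10.005), event_times = 10, window = c(-0.05, 0.05),
                   bin_width = 0.01)
  hit <- p1$rate[p1$time_lo > -1e-9 & p1$time_lo < 0.01 - 1e-9]
  expect_equal(hit, 100)
  expect_equal(sum(p1$rate > 0), 1)

  # time-translation invariance
  set.seed(3)
  spikes <- sort(runif(200, 0, 100))
  events <- c(30, 60, 90)
  a <- build_psth(spikes, events, c(-2, 2), 0.05)
  b <- build_psth(spikes + 100, events + 100, c(-2, 2), 0.05)
  expect_equal(a$rate, b$rate)

  # events too close to the recording edges are dropped and counted
  d <- build_psth(spikes, c(1, 50, 99.5), c(-2, 2), 0.05,
                  session_length = 100)
  expect_equal(attr(d, "n_events"), 1)
  expect_equal(attr(d, "dropped_events"), 2)
  expect_error(build_psth(spikes, 0.5, c(-2, 2), 0.05), "zero usable")
})

test_that("z-scoring is exact against the baseline and flags zero SD", {
  set.seed(8)
  spikes <- sort(runif(3000, 0, 300))
  events <- seq(30, 270, by = 30)
  p <- zscore_psth(build_psth(spikes, events, c(-10.5, 2), 0.01),
                   baseline_window = c(-10.5, -0.5))
  base <- p[p$time_lo >= -10.5 & p$time_lo < -0.5, ]
  expect_equal(mean(base$z), 0, tolerance = 1e-9)
  expect_equal(sd(base$z), 1, tolerance = 1e-9)

  # recompute z for one bin from raw counts, independently
  bin <- p[abs(p$time_lo - 0.25) < 1e-9, ]
  counts <- sum(vapply(events, function(e) {
    sum(spikes >= e + 0.25 & spikes < e + 0.26)
  }, numeric(1)))
  rate <- counts / (length(events) * 0.01)
  expect_equal(bin$z, (rate - mean(base$rate)) / sd(base$rate),
               tolerance = 1e-9)

  # a constant-rate unit has zero baseline SD: flagged, not zeroed
  regular <- seq(0.005, 300, by = 1)  # one spike per bin-aligned second
  pc <- build_psth(regular, events, c(-10.5, 2), 1)
  pcz <- zscore_psth(pc, c(-10.5, -0.5))
  expect_false(any(pcz$baseline_defined))
  expect_true(all(is.na(pcz$z)))

  expect_error(zscore_psth(build_psth(1, 10, c(-1, 1), 0.1), c(-5, -1)),
               "outside")
})

test_that("half-normal smoothing is causal, linear, with unit DC gain", {
  x <- rep(3.7, 50)
  expect_equal(smooth_causal_halfnormal(x), x, tolerance = 1e-12)

  imp <- c(rep(0, 20), 1, rep(0, 20))
  sm <- smooth_causal_halfnormal(imp)
  expect_true(all(sm[1:20] == 0))
  expect_gt(sm[21], 0)

  # kernel weight ratio w0/w1 = exp(1 / (2 * 6.6^2))
  J <- ceiling(4 * 6.6)
  w <- exp(-(0:J)^2 / (2 * 6.6^2)); w <- w / sum(w)
  expect_equal(w[1] / w[2], exp(1 / (2 * 6.6^2)), tolerance = 1e-12)
  expect_equal(sm[22] / sm[21], w[2] / w[1], tolerance = 1e-12)

  # linearity: smoothing the sum equals the sum of smoothings
  set.seed(12)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(smooth_causal_halfnormal(a + b),
               smooth_causal_halfnormal(a) + smooth_causal_halfnormal(b),
               tolerance = 1e-12)

  # perturbing bin m leaves all earlier output bins unchanged
  y <- rnorm(40)
  y2 <- y; y2[25] <- y2[25] + 5
  s1 <- smooth_causal_halfnormal(y)
  s2 <- smooth_causal_halfnormal(y2)
  expect_equal(s1[1:24], s2[1:24])
  expect_false(isTRUE(all.equal(s1[25], s2[25])))
})

test_that("smooth_psth smooths each unit's series independently", {
  set.seed(2)
  spikes <- tibble::tibble(unit_id = rep(c("u1", "u2"), each = 300),
                           time_s = c(sort(runif(300, 0, 100)),
                                      sort(runif(300, 0, 100))))
  p <- smooth_psth(build_psth(spikes, c(30, 60), c(-2, 2), 0.1))
  u1 <- p[p$unit_id == "u1", ]
  expect_equal(u1$rate_smooth, smooth_causal_halfnormal(u1$rate))
})

test_that("modulation classification labels by sign at p < alpha", {
  # response identical to baseline rate for every event -> none
  events <- seq(20, 180, by = 20)
  regular <- seq(0.05, 200, by = 0.5)  # perfectly regular 2 Hz
  lab <- classify_modulation(regular, events)
  expect_equal(as.character(lab$label), "none")
  expect_equal(lab$p_value, 1)

  expect_error(
    classify_modulation(regular, events, response_window = c(-0.5, 0.5),
                        baseline_window = c(-1, 0)),
    "overlap")
})

test_that("classification has power for strong gain in both directions", {
  up <- validate_classification(n_sim = 60, gain = 5, seed = 14)
  expect_gte(up$frac_correct_direction, 0.95)
  dn <- validate_classification(n_sim = 60, gain = 0.2, seed = 15)
  expect_gte(dn$frac_correct_direction, 0.95)
})

test_that("modulation proportions sum to one per event type", {
  labs <- tibble::tibble(
    unit_id = sprintf("u%d", 1:10),
    event_type = "port_entry",
    label = factor(rep(c("excited", "inhibited", "none"), c(2, 2, 6)),
                   levels = c("excited", "inhibited", "none")))
  pr <- modulation_proportions(labs)
  expect_equal(pr$prop_excited, 0.2)
  expect_equal(pr$prop_inhibited, 0.2)
  expect_equal(pr$prop_none, 0.6)
  expect_equal(pr$prop_excited + pr$prop_inhibited + pr$prop_none, 1)
})
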