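test_that("bout segmentation follows the strict 210 ms rule", {
  expect_equal(nrow(segment_bouts(numeric())), 0)

  b <- segment_bouts(c(0, 0.14, 0.28, 1.0, 1.14))
  expect_equal(b$bout, c(1L, 1L, 1L, 2L, 2L))

  # a gap of exactly 0.210 splits (strict <)
  b2 <- segment_bouts(c(0, 0.210, 0.419))
  expect_equal(b2$bout, c(1L, 2L, 2L))

  expect_error(segment_bouts(c(1, 0.5)), "ascending")
})

test_that("cycles come from consecutive within-bout licks only", {
  b <- segment_bouts(c(0, 0.14, 0.28, 1.0))
  cy <- cycles_from_bouts(b)
  expect_equal(cy$start_s, c(0, 0.14))
  expect_equal(cy$end_s, c(0.14, 0.28))  # singleton bout adds no cycle
  expect_equal(nrow(cycles_from_bouts(segment_bouts(5))), 0)

  # cycle count invariant against the generator's ground truth
  lt <- gen_lick_train(sim_config(seed = 8, session_length = 1200))
  cy2 <- cycles_from_bouts(segment_bouts(lt$licks))
  expect_equal(nrow(cy2), sum(lt$bouts$n_licks - 1))
  expect_true(all(cy2$end_s - cy2$start_s < 0.210))
})

test_that("spike phases map linearly within each cycle", {
  cy <- cycles_from_bouts(segment_bouts(c(1.0, 1.2, 1.4)))
  ph <- assign_spike_phases(c(1.0, 1.1, 1.05, 1.2, 1.4, 2.0), cy)
  # spike at start -> 0; midpoint -> pi; 25% -> pi/2
  expect_equal(ph$phase[ph$time_s == 1.0], 0)
  expect_equal(ph$phase[ph$time_s == 1.1], pi)
  expect_equal(ph$phase[ph$time_s == 1.05], pi / 2)
  # boundary spike at 1.2 joins the next cycle at phase 0
  expect_equal(ph$phase[ph$time_s == 1.2], 0)
  expect_equal(ph$cycle[ph$time_s == 1.2], 2L)
  # final bout end and out-of-cycle spikes are excluded
  expect_false(any(ph$time_s %in% c(1.4, 2.0)))
})

test_that("phase assignment is invariant to rigid time shifts", {
  set.seed(4)
  licks <- sort(runif(30, 0, 10))
  spikes <- sort(runif(100, 0, 10))
  cy <- cycles_from_bouts(segment_bouts(licks))
  ph0 <- assign_spike_phases(spikes, cy)
  cy_s <- cycles_from_bouts(segment_bouts(licks + 100))
  ph1 <- assign_spike_phases(spikes + 100, cy_s)
  expect_equal(ph1$phase, ph0$phase, tolerance = 1e-9)
})

test_that("units below 50 spikes in cycles are excluded without a p-value", {
  res49 <- test_lick_modulation(rep(pi / 2, 49))
  expect_true(res49$excluded)
  expect_false(res49$modulated)
  expect_true(is.na(res49$rayleigh_p))

  res <- test_lick_modulation(rep(pi / 2, 200))
  expect_false(res$excluded)
  expect_true(res$modulated)
  expect_equal(res$R, 1)
  expect_equal(res$preferred_phase, pi / 2, tolerance = 1e-9)

  # property: excluded rows never carry a p-value
  set.seed(30)
  ph <- tibble::tibble(
    unit_id = rep(c("a", "b", "c"), c(10, 49, 80)),
    phase = runif(139, 0, 2 * pi))
  out <- test_lick_modulation(ph)
  expect_true(all(is.na(out$rayleigh_p[out$excluded])))
  expect_true(all(!is.na(out$rayleigh_p[!out$excluded])))
})

test_that("uniform phases are called modulated at roughly the nominal rate", {
  set.seed(55)
  hits <- vapply(1:400, function(i) {
    test_lick_modulation(runif(200, 0, 2 * pi))$modulated
  }, logical(1))
  expect_lt(mean(hits), 0.03)  # alpha = 0.01
})

test_that("spike-probability histogram is a probability over phase bins", {
  set.seed(66)
  h <- spike_probability_by_phase(runif(30000, 0, 2 * pi), n_bins = 30)
  expect_equal(sum(h$probability), 1)
  expect_true(all(abs(h$probability - 1 / 30) < 0.01))

  one <- spike_probability_by_phase(rep(0.1, 10), n_bins = 30)
  expect_equal(max(one$probability), 1)
  expect_error(spike_probability_by_phase(numeric()), "empty")

  # sharply concentrated sample so the peak bin dominates its neighbours
  vm <- spike_probability_by_phase(rvonmises(50000, pi / 2, 4), n_bins = 30)
  top <- vm[which.max(vm$probability), ]
  expect_true(top$phase_lo <= pi / 2 && pi / 2 <= top$phase_hi)
})

test_that("population summary reports proportions, V test and phase fraction", {
  units <- tibble::tibble(
    unit_id = sprintf("u%d", 1:6),
    n_spikes_in_cycles = c(60, 60, 60, 60, 60, 10),
    mean_direction = c(rep(pi / 2, 4), 3, NA),
    R = c(rep(1, 4), 0.1, NA),
    preferred_phase = c(rep(pi / 2, 4), 3.5, NA),
    rayleigh_p = c(rep(1e-6, 4), 0.5, NA),
    excluded = c(rep(FALSE, 5), TRUE),
    modulated = c(rep(TRUE, 4), FALSE, FALSE))
  ps <- population_summary(units)
  expect_equal(ps$n_tested, 5)
  expect_equal(ps$prop_modulated_tested, 4 / 5)
  expect_equal(ps$prop_modulated_all, 4 / 6)
  expect_equal(ps$frac_preferred_0_pi, 1)
  expect_equal(ps$v_statistic, 4)  # all preferred phases at mu0, R = 1

  none <- dplyr::mutate(units, modulated = FALSE)
  ps0 <- population_summary(none)
  expect_equal(ps0$n_modulated, 0)
  expect_equal(ps0$v_status, "skipped")
  expect_true(is.na(ps0$v_statistic))
})

test_that("a mixed population recovers the designed modulated fraction", {
  set.seed(91)
  n_units <- 60
  truth <- rep(c(TRUE, FALSE), c(15, 45))  # 25% locked at kappa = 2
  res <- vapply(seq_len(n_units), function(i) {
    ph <- if (truth[i]) rvonmises(300, pi / 2, 2) else runif(300, 0, 2 * pi)
    test_lick_modulation(ph)$modulated
  }, logical(1))
  # kappa = 2 with n = 300 is detected essentially always; false alarms ~1%
  expect_true(all(res[truth]))
  binom_hi <- qbinom(0.995, 45, 0.01)
  expect_lte(sum(res[!truth]), binom_hi)
})
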