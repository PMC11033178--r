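test_that("lick trains respect the configured ILI distribution and bouts", {
  expect_equal(length(gen_lick_train(sim_config(session_length = 0))$licks), 0)

  cfg <- sim_config(seed = 5, session_length = 20000)
  lt <- gen_lick_train(cfg)
  lt2 <- gen_lick_train(cfg)
  expect_identical(lt, lt2)  # determinism under a fixed seed
  expect_true(all(diff(lt$licks) > 0))

  # within-bout lick rate ~ 7 Hz (truncated-mean calibration + MC error)
  ilis <- unlist(lapply(split(lt$licks,
                              rep(seq_len(nrow(lt$bouts)), lt$bouts$n_licks)),
                        diff))
  expect_gt(length(ilis), 1000)
  expect_equal(mean(ilis), 1 / 7, tolerance = 0.02)
  expect_true(all(ilis >= 0.05 & ilis <= 0.205))

  # inter-bout gaps strictly exceed the 210 ms rule
  gaps <- lt$bouts$start_s[-1] - lt$bouts$end_s[-nrow(lt$bouts)]
  expect_true(all(gaps > 0.210))

  expect_error(sim_config(ili_bounds = c(0.05, 0.25)), "0.210")
  expect_error(sim_config(ili_bounds = c(0, 0.2)), "0.210|low|0 <")
})

test_that("bout segmentation reproduces the generator's boundaries exactly", {
  lt <- gen_lick_train(sim_config(seed = 17, session_length = 3000))
  seg <- segment_bouts(lt$licks)
  found <- seg |>
    dplyr::group_by(bout) |>
    dplyr::summarise(start_s = min(time_s), end_s = max(time_s),
                     n_licks = dplyr::n(), .groups = "drop")
  expect_equal(found$start_s, lt$bouts$start_s)
  expect_equal(found$end_s, lt$bouts$end_s)
  expect_equal(found$n_licks, lt$bouts$n_licks)
})

test_that("spike generator reduces to homogeneous Poisson when unmodulated", {
  cy <- tibble::tibble(bout = integer(), cycle = integer(),
                       start_s = numeric(), end_s = numeric())
  st <- gen_spike_train(cy, numeric(),
                        list(baseline_rate = 5, kappa = 0, mu = 0,
                             entry_gain = 1),
                        session_length = 600, seed = 99)
  expect_lt(abs(length(st) - 5 * 600), 4 * sqrt(5 * 600))
  expect_true(all(diff(st) > 0))

  expect_equal(gen_spike_train(cy, numeric(),
                               list(baseline_rate = 0, kappa = 1, mu = 0,
                                    entry_gain = 1), 600, seed = 1),
               numeric())
  expect_error(gen_spike_train(cy, numeric(),
                               list(baseline_rate = -1, kappa = 0, mu = 0,
                                    entry_gain = 1), 600), ">= 0")
})

test_that("realized spike counts match the intensity integral", {
  # over full lick cycles the von Mises factor integrates to 1, so with unit
  # gain the intensity integral is lambda0 * T regardless of kappa
  lt <- gen_lick_train(sim_config(seed = 23, session_length = 60,
                                  bout_rate = 0.1))
  cy <- cycles_from_bouts(segment_bouts(lt$licks))
  lambda0 <- 6
  expected <- lambda0 * 60
  set.seed(77)
  ok <- vapply(1:300, function(i) {
    st <- gen_spike_train(cy, numeric(),
                          list(baseline_rate = lambda0, kappa = 2,
                               mu = pi / 2, entry_gain = 1), 60)
    abs(length(st) - expected) <= 4 * sqrt(expected)
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("phase-locked units concentrate spikes at the preferred phase", {
  lt <- gen_lick_train(sim_config(seed = 31, session_length = 600,
                                  bout_rate = 0.1))
  cy <- cycles_from_bouts(segment_bouts(lt$licks))
  st <- gen_spike_train(cy, numeric(),
                        list(baseline_rate = 8, kappa = 2, mu = pi / 2,
                             entry_gain = 1), 600, seed = 41)
  ph <- assign_spike_phases(st, cy)
  res <- test_lick_modulation(ph$phase)
  expect_true(res$modulated)
  expect_lt(abs(res$mean_direction - pi / 2), 0.25)
})

test_that("pump accrual emits a delivery per 2 s of cumulative presence", {
  a <- simulate_port_task(cbind(0, 10))
  expect_equal(a$activations, c(2, 4, 6, 8, 10))
  expect_equal(a$total_volume_ml, 0.5)

  expect_equal(simulate_port_task(cbind(0, 1.9))$n_activations, 0)

  b <- simulate_port_task(rbind(c(0, 1.5), c(3.0, 3.7)))
  expect_equal(b$activations, 3.5)

  # accrual pausing during the 2 s delivery shifts later activations
  p <- simulate_port_task(cbind(0, 10), pause_during_delivery = TRUE)
  expect_equal(p$activations, c(2, 6, 10))

  expect_error(simulate_port_task(rbind(c(0, 2), c(1, 3))), "overlap")
})

test_that("closed-loop rules match hand-traced lick trains", {
  none <- simulate_closed_loop(numeric(), "excite")
  expect_equal(nrow(none), 0)

  tr <- simulate_closed_loop((0:20) / 7, "excite")
  expect_equal(tr$on_s, c(0, 1, 2))  # first lick at/after each train end

  # a lick exactly at train end retriggers
  re <- simulate_closed_loop(c(0, 1.0), "excite")
  expect_equal(re$on_s, c(0, 1))

  inh <- simulate_closed_loop(c(0, 0.3, 0.6), "inhibit")
  expect_equal(inh$on_s, 0)
  expect_equal(inh$off_s, 1.6)

  # a gap of exactly 1 s splits runs
  inh2 <- simulate_closed_loop(c(0, 1.0), "inhibit")
  expect_equal(inh2$on_s, c(0, 1))
  expect_equal(inh2$off_s, c(1, 2))

  expect_error(simulate_closed_loop(0.5, "both"), "arg")
})

test_that("whole sessions are deterministic and internally consistent", {
  cfg <- sim_config(seed = 12, session_length = 400, n_units = 3)
  s1 <- gen_session(cfg)
  s2 <- gen_session(cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$events, s2$events)

  d1 <- tempfile(); d2 <- tempfile()
  write_session(s1, d1)
  write_session(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }

  s0 <- gen_session(sim_config(seed = 2, session_length = 400, n_units = 0))
  expect_equal(nrow(s0$spikes), 0)
  expect_gt(nrow(s0$events), 0)
  expect_silent(validate_session(s0))

  # the generator's pump events obey the occupancy accrual rule
  ev <- s1$events
  occ <- cbind(ev$time_s[ev$event_type == "port_entry"],
               ev$time_s[ev$event_type == "port_exit"])
  recomputed <- simulate_port_task(occ)$activations
  expect_equal(ev$time_s[ev$event_type == "pump_on"], recomputed)
})

test_that("two-bottle sessions carry closed-loop laser events", {
  cfg <- sim_config(seed = 3, session_length = 600, n_units = 0,
                    task = "two_bottle", laser_mode = "excite",
                    laser_spout = "a")
  s <- gen_session(cfg)
  ev <- s$events
  licks_a <- ev$time_s[ev$event_type == "lick" & ev$spout == "a"]
  expect_gt(length(licks_a), 0)
  recomputed <- simulate_closed_loop(licks_a, "excite")
  expect_equal(ev$time_s[ev$event_type == "laser_on"], recomputed$on_s)
  expect_equal(ev$time_s[ev$event_type == "laser_off"], recomputed$off_s)
})
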