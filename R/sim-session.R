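# Whole-session generation: composes the lick, spike and task generators
# into one session object with ground truth attached.

merge_intervals <- function(m) {
  if (nrow(m) == 0) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    j <- nrow(out)
    if (m[i, 1] <= out[j, 2]) {
      out[j, 2] <- max(out[j, 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

new_session <- function(session_id, session_length, spikes, events, metadata,
                        ground_truth = NULL) {
  structure(list(
    session_id = session_id,
    session_length = session_length,
    spikes = spikes,
    events = events,
    metadata = metadata,
    ground_truth = ground_truth
  ), class = "lick_session")
}

#' @export
print.lick_session <- function(x, ...) {
  cat("<lick_session> ", x$session_id, "\n", sep = "")
  cat("  length: ", x$session_length, " s; units: ",
      length(unique(x$spikes$unit_id)), "; spikes: ", nrow(x$spikes),
      "\n", sep = "")
  ev <- table(x$events$event_type)
  cat("  events:", paste(names(ev), ev, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$ground_truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Generate a full synthetic session
#'
#' Composes [gen_lick_train()], the port/laser simulators and
#' [gen_spike_train()] into a single session with known ground truth. For the
#' self-administration task, port occupancy intervals are placed around lick
#' bouts (entry 0.2-1 s before the first lick, exit 0.2-1 s after the last,
#' overlapping visits merged) and pump activations follow the
#' cumulative-presence rule. For the two-bottle task, two spouts get
#' independent lick trains and the configured closed-loop laser rule runs on
#' the laser-paired spout. All randomness flows from `config$seed`;
#' unit-level substreams are derived from it, so sessions are bit-identical
#' across runs.
#'
#' @param config A [sim_config()].
#' @return A `lick_session` with `spikes`, `events`, `metadata` and a
#'   `ground_truth` list (`units`: per-unit true rate/kappa/mu/gain;
#'   `bouts`: generated bout boundaries per spout; `pump`/`laser` trigger
#'   times).
#' @export
gen_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, gen_session_impl(config))
}

gen_session_impl <- function(config) {
  T <- config$session_length
  spouts <- if (config$task == "two_bottle") c("a", "b") else "a"

  lick_tbl <- list()
  bout_tbl <- list()
  for (sp in spouts) {
    lt <- gen_lick_train_impl(config)
    lick_tbl[[sp]] <- tibble::tibble(event_type = "lick", time_s = lt$licks,
                                     spout = sp)
    bout_tbl[[sp]] <- dplyr::mutate(lt$bouts, spout = sp, .before = 1)
  }
  licks_a <- lick_tbl[["a"]]$time_s
  bouts_truth <- dplyr::bind_rows(bout_tbl)

  events <- dplyr::bind_rows(lick_tbl)
  pump_times <- numeric()
  laser <- tibble::tibble(on_s = numeric(), off_s = numeric())
  modulation_events <- numeric()

  if (config$task == "self_admin") {
    ba <- bout_tbl[["a"]]
    if (nrow(ba) > 0) {
      occ <- cbind(pmax(0, ba$start_s - stats::runif(nrow(ba), 0.2, 1)),
                   pmin(T, ba$end_s + stats::runif(nrow(ba), 0.2, 1)))
      occ <- merge_intervals(occ)
    } else {
      occ <- matrix(numeric(), ncol = 2)
    }
    pump <- simulate_port_task(
      occ, pause_during_delivery = config$pump_pause_during_delivery)
    pump_times <- pump$activations
    modulation_events <- as.numeric(t(occ))
    events <- dplyr::bind_rows(
      events,
      tibble::tibble(event_type = "port_entry", time_s = occ[, 1], spout = "a"),
      tibble::tibble(event_type = "port_exit", time_s = occ[, 2], spout = "a"),
      tibble::tibble(event_type = "pump_on", time_s = pump_times, spout = "a"))
    consumed <- tibble::tibble(spout = "a",
                               consumed_g = pump$total_volume_ml * 1.0)
  } else {
    if (config$laser_mode != "none") {
      trig <- lick_tbl[[config$laser_spout]]$time_s
      laser <- simulate_closed_loop(trig, config$laser_mode)
      laser$off_s <- pmin(laser$off_s, T)  # light cannot outlast the session
      events <- dplyr::bind_rows(
        events,
        tibble::tibble(event_type = "laser_on", time_s = laser$on_s,
                       spout = config$laser_spout),
        tibble::tibble(event_type = "laser_off", time_s = laser$off_s,
                       spout = config$laser_spout))
    }
    consumed <- events |>
      dplyr::filter(.data$event_type == "lick") |>
      dplyr::count(.data$spout) |>
      dplyr::mutate(consumed_g = .data$n * config$lick_volume_ml * 1.0) |>
      dplyr::select("spout", "consumed_g")
  }
  events <- dplyr::arrange(events, .data$time_s, .data$event_type)

  # spikes: phase-locked to the spout-a lick cycles, gain around port events
  cycles <- cycles_from_bouts(segment_bouts(licks_a))
  n_units <- config$n_units
  unit_seeds <- if (n_units > 0) sample.int(2147483646L, n_units) else integer()
  spikes <- tibble::tibble(unit_id = character(), time_s = numeric())
  if (n_units > 0) {
    unit_ids <- sprintf("u%03d", seq_len(n_units))
    spikes <- purrr::map2_dfr(seq_len(n_units), unit_ids, function(i, uid) {
      st <- gen_spike_train(
        cycles, modulation_events,
        list(baseline_rate = config$baseline_rate[i],
             kappa = config$phase_locking_strength[i],
             mu = config$preferred_phase_true[i],
             entry_gain = config$entry_gain[i],
             gain_width = config$gain_width,
             gain_shape = config$gain_shape),
        T, seed = unit_seeds[i])
      tibble::tibble(unit_id = uid, time_s = st)
    })
  }

  units_truth <- tibble::tibble(
    unit_id = if (n_units > 0) sprintf("u%03d", seq_len(n_units)) else character(),
    baseline_rate = config$baseline_rate,
    kappa = config$phase_locking_strength,
    mu = config$preferred_phase_true,
    entry_gain = config$entry_gain)

  pre_g <- stats::setNames(rep(120, length(spouts)), spouts)
  bw <- tibble::tibble(spout = spouts, pre_g = unname(pre_g[spouts]))
  bw <- dplyr::left_join(bw, consumed, by = "spout") |>
    dplyr::mutate(consumed_g = tidyr::replace_na(.data$consumed_g, 0),
                  post_g = .data$pre_g - .data$consumed_g) |>
    dplyr::select("spout", "pre_g", "post_g")

  metadata <- list(
    session_length = T,
    body_weight_kg = config$body_weight_kg,
    task = config$task,
    laser_mode = config$laser_mode,
    laser_spout = config$laser_spout,
    solutions = tibble::tibble(
      spout = spouts,
      solution = rep("ethanol", length(spouts)),
      concentration = rep(0.10, length(spouts)),
      basis = rep("v/v", length(spouts))),
    bottle_weights = bw)

  new_session(
    session_id = sprintf("sim-%08d", config$seed),
    session_length = T,
    spikes = spikes,
    events = events,
    metadata = metadata,
    ground_truth = list(units = units_truth, bouts = bouts_truth,
                        pump = pump_times, laser = laser))
}
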