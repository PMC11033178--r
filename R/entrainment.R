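# Lick-cycle entrainment: bout segmentation, cycle construction, spike-phase
# assignment, per-unit Rayleigh testing with the spike-count exclusion rule,
# and population-level phase summaries.

#' Segment licks into bouts
#'
#' A bout is a maximal run of licks whose successive inter-lick intervals are
#' strictly below `max_ili` (210 ms by default, the standard criterion for
#' rhythmic licking). A gap of exactly `max_ili` splits. Singleton bouts are
#' allowed; they contribute no lick cycles.
#'
#' @param lick_times Ascending numeric vector of lick timestamps (seconds).
#' @param max_ili Bout-splitting inter-lick interval, seconds.
#' @return A tibble with columns `time_s` and `bout` (1-based bout id).
#' @examples
#' segment_bouts(c(0, 0.14, 0.28, 1.0, 1.14))
#' @export
segment_bouts <- function(lick_times, max_ili = 0.210) {
  stopifnot(is.numeric(lick_times), max_ili > 0)
  if (is.unsorted(lick_times, strictly = FALSE)) {
    stop("`lick_times` must be ascending", call. = FALSE)
  }
  if (length(lick_times) == 0) {
    return(tibble::tibble(time_s = numeric(), bout = integer()))
  }
  gaps <- diff(lick_times)
  bout <- cumsum(c(1L, as.integer(gaps >= max_ili)))
  tibble::tibble(time_s = as.numeric(lick_times), bout = bout)
}

#' Lick cycles from bouts
#'
#' One cycle per consecutive pair of licks within a bout: the interval between
#' two contacts with the fluid delivery port. The number of cycles equals
#' `sum(bout_size - 1)` over bouts; no cycle is extrapolated past the last
#' lick of a bout.
#'
#' @param bouts A tibble as returned by [segment_bouts()].
#' @return A tibble with columns `bout`, `cycle` (id within session),
#'   `start_s`, `end_s`.
#' @export
cycles_from_bouts <- function(bouts) {
  stopifnot(is.data.frame(bouts), all(c("time_s", "bout") %in% names(bouts)))
  if (nrow(bouts) == 0) {
    return(tibble::tibble(bout = integer(), cycle = integer(),
                          start_s = numeric(), end_s = numeric()))
  }
  out <- bouts |>
    dplyr::group_by(.data$bout) |>
    dplyr::reframe(start_s = utils::head(.data$time_s, -1),
                   end_s = utils::tail(.data$time_s, -1))
  out |>
    dplyr::mutate(cycle = dplyr::row_number()) |>
    dplyr::select("bout", "cycle", "start_s", "end_s")
}

#' Assign spike phases on the lick cycle
#'
#' For a spike at time `t` inside the cycle `[s, e)`, the phase is
#' `2 * pi * (t - s) / (e - s)`, so phase 0 is tongue contact with the spout
#' and the phase grows linearly to `2 * pi` at the next contact. Spikes
#' outside all cycles are excluded. A spike exactly at a cycle end belongs to
#' the next cycle (phase 0) if one starts there, otherwise it is excluded.
#'
#' @param spikes Either a numeric vector of spike times or a data frame with
#'   columns `unit_id` and `time_s`.
#' @param cycles A tibble as returned by [cycles_from_bouts()].
#' @return A tibble with columns `unit_id` (absent for vector input),
#'   `time_s`, `cycle`, `phase` (radians in `[0, 2 * pi)`).
#' @export
assign_spike_phases <- function(spikes, cycles) {
  stopifnot(is.data.frame(cycles))
  if (is.data.frame(spikes)) {
    stopifnot(all(c("unit_id", "time_s") %in% names(spikes)))
    out <- spikes |>
      dplyr::group_by(.data$unit_id) |>
      dplyr::reframe(.phase_one_unit(.data$time_s, cycles))
    return(out)
  }
  .phase_one_unit(as.numeric(spikes), cycles)
}

.phase_one_unit <- function(times, cycles) {
  empty <- tibble::tibble(time_s = numeric(), cycle = integer(),
                          phase = numeric())
  if (length(times) == 0 || nrow(cycles) == 0) return(empty)
  starts <- cycles$start_s
  ends <- cycles$end_s
  if (any(starts[-1] < ends[-length(ends)] - 1e-12)) {
    stop("cycles must be non-overlapping and ordered", call. = FALSE)
  }
  idx <- findInterval(times, starts)  # last start <= t
  keep <- idx >= 1L
  inside <- keep & times < ends[pmax(idx, 1L)]
  # a spike at exactly end e with a following cycle starting at e lands in
  # that next cycle via findInterval already (t >= starts[idx+1]); spikes at
  # the final end of a bout fall outside and are dropped by `inside`.
  i <- idx[inside]
  t <- times[inside]
  phase <- 2 * pi * (t - starts[i]) / (ends[i] - starts[i])
  tibble::tibble(time_s = t, cycle = cycles$cycle[i], phase = phase %% (2 * pi))
}

# Preferred phase: centre of the maximal-count histogram bin (12-degree bins
# by default); ties broken by the circular mean of the spikes in tied bins.
preferred_phase <- function(phases, n_bins = 30) {
  edges <- seq(0, 2 * pi, length.out = n_bins + 1)
  bin <- pmin(findInterval(phases, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  top <- which(counts == max(counts))
  if (length(top) == 1L) {
    return((edges[top] + edges[top + 1L]) / 2)
  }
  tied <- phases[bin %in% top]
  cm <- circ_mean_resultant(tied)
  if (cm$mean_defined) cm$mean_direction else (edges[top[1]] + edges[top[1] + 1L]) / 2
}

#' Per-unit lick-modulation test
#'
#' For each unit, tests whether its spike-phase distribution over lick cycles
#' is non-uniform (Rayleigh test). Units with fewer than `min_spikes` spikes
#' in lick cycles are excluded, carry no p-value, and are never called
#' modulated. Modulated means `rayleigh_p < alpha` (default 0.01). The
#' preferred phase is the mode of the spike-phase histogram (30 bins of 12
#' degrees; ties broken by the circular mean of the tied bins).
#'
#' @param phases A tibble from [assign_spike_phases()] (with or without a
#'   `unit_id` column; a plain numeric vector of phases is also accepted).
#' @param alpha Significance level for the Rayleigh test.
#' @param min_spikes Minimum spikes in cycles for a unit to be tested.
#' @param n_bins Histogram bins for the preferred-phase mode.
#' @return A tibble with one row per unit: `unit_id`, `n_spikes_in_cycles`,
#'   `mean_direction`, `R`, `preferred_phase`, `rayleigh_p`, `excluded`,
#'   `modulated`. Excluded units have `NA` for the test fields.
#' @export
test_lick_modulation <- function(phases, alpha = 0.01, min_spikes = 50,
                                 n_bins = 30) {
  if (is.numeric(phases) && !is.data.frame(phases)) {
    phases <- tibble::tibble(unit_id = "unit", phase = phases)
  }
  stopifnot(is.data.frame(phases), "phase" %in% names(phases))
  if (!"unit_id" %in% names(phases)) phases$unit_id <- "unit"
  one <- function(ph) {
    n <- length(ph)
    if (n < min_spikes) {
      return(tibble::tibble(
        n_spikes_in_cycles = n, mean_direction = NA_real_, R = NA_real_,
        preferred_phase = NA_real_, rayleigh_p = NA_real_,
        excluded = TRUE, modulated = FALSE))
    }
    cm <- circ_mean_resultant(ph)
    rt <- rayleigh_test(ph)
    tibble::tibble(
      n_spikes_in_cycles = n,
      mean_direction = cm$mean_direction,
      R = cm$R,
      preferred_phase = preferred_phase(ph, n_bins),
      rayleigh_p = rt$p_value,
      excluded = FALSE,
      modulated = rt$p_value < alpha)
  }
  phases |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::reframe(one(.data$phase))
}

#' Spike probability by lick-cycle phase
#'
#' Normalised histogram of spike phases: bin probabilities sum to 1 and bin 1
#' starts at phase 0 (spout contact).
#'
#' @param phases Numeric vector of phases, or a phase tibble for one unit.
#' @param n_bins Number of phase bins (>= 2), default 30.
#' @return A tibble with `bin`, `phase_lo`, `phase_mid`, `phase_hi`,
#'   `probability`.
#' @export
spike_probability_by_phase <- function(phases, n_bins = 30) {
  if (is.data.frame(phases)) phases <- phases$phase
  stopifnot(n_bins >= 2)
  if (length(phases) == 0) stop("empty phase set", call. = FALSE)
  phases <- check_phases(phases)
  edges <- seq(0, 2 * pi, length.out = n_bins + 1)
  bin <- pmin(findInterval(phases, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  tibble::tibble(
    bin = seq_len(n_bins),
    phase_lo = edges[-(n_bins + 1)],
    phase_mid = (edges[-(n_bins + 1)] + edges[-1]) / 2,
    phase_hi = edges[-1],
    probability = counts / sum(counts))
}

#' Population summary of lick modulation
#'
#' Aggregates per-unit results from [test_lick_modulation()]: the proportion
#' of modulated units among tested (post-exclusion) units and among all
#' units, the fraction of modulated units whose preferred phase lies in
#' `(0, pi)` (the first half of the lick cycle, tongue retraction), and a V
#' test of the modulated units' preferred phases against `mu0` (90 degrees by
#' default). With zero modulated units the V test is skipped and its fields
#' are `NA` with `v_status = "skipped"`.
#'
#' @param unit_summary Tibble from [test_lick_modulation()].
#' @param mu0 Direction for the V test, radians.
#' @return A one-row tibble: `n_units`, `n_tested`, `n_modulated`,
#'   `prop_modulated_tested`, `prop_modulated_all`, `frac_preferred_0_pi`,
#'   `v_statistic`, `v_u`, `v_p`, `v_status`.
#' @export
population_summary <- function(unit_summary, mu0 = pi / 2) {
  stopifnot(is.data.frame(unit_summary), nrow(unit_summary) >= 1)
  tested <- dplyr::filter(unit_summary, !.data$excluded)
  mod <- dplyr::filter(tested, .data$modulated)
  n_all <- nrow(unit_summary)
  n_tested <- nrow(tested)
  n_mod <- nrow(mod)
  if (n_mod >= 2) {
    vt <- v_test(mod$preferred_phase, mu0 = mu0)
    v_stat <- vt$statistic; v_u <- vt$u; v_p <- vt$p_value; v_status <- "ok"
  } else {
    v_stat <- NA_real_; v_u <- NA_real_; v_p <- NA_real_
    v_status <- "skipped"
  }
  tibble::tibble(
    n_units = n_all,
    n_tested = n_tested,
    n_modulated = n_mod,
    prop_modulated_tested = if (n_tested > 0) n_mod / n_tested else NA_real_,
    prop_modulated_all = n_mod / n_all,
    frac_preferred_0_pi = if (n_mod > 0) {
      mean(mod$preferred_phase > 0 & mod$preferred_phase < pi)
    } else NA_real_,
    v_statistic = v_stat, v_u = v_u, v_p = v_p, v_status = v_status)
}

#' Plot a spike-phase histogram
#'
#' @param phases Numeric vector of phases or a phase tibble for one unit.
#' @param n_bins Number of phase bins.
#' @return A ggplot object (polar histogram; phase 0 = spout contact).
#' @export
plot_phase_histogram <- function(phases, n_bins = 30) {
  h <- spike_probability_by_phase(phases, n_bins)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$phase_mid, y = .data$probability)) +
    ggplot2::geom_col(width = 2 * pi / n_bins, fill = "steelblue") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(
      limits = c(0, 2 * pi),
      breaks = c(0, pi / 2, pi, 3 * pi / 2),
      labels = c("0", "π/2", "π", "3π/2")) +
    ggplot2::labs(x = "lick-cycle phase", y = "spike probability") +
    ggplot2::theme_minimal()
}
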