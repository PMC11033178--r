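# Event-aligned PSTHs, baseline z-scoring, causal half-normal smoothing, and
# Wilcoxon-based per-unit modulation classification.

#' Build an event-aligned PSTH
#'
#' Bins spikes relative to each event and averages over events:
#' rate in bin b = (total spikes across events falling in b) /
#' (n_events * bin_width). Events whose window would extend past the start of
#' the recording (or past `session_length` when given) are dropped and
#' counted in the `dropped_events` attribute.
#'
#' @param spikes Numeric vector of spike times, or a data frame with columns
#'   `unit_id` and `time_s`.
#' @param event_times Numeric vector of event timestamps (seconds).
#' @param window Length-2 numeric, seconds relative to the event
#'   (e.g. `c(-10.5, 2)`); must span at least one bin.
#' @param bin_width Bin width in seconds (default 0.01 s).
#' @param session_length Optional recording length used for edge dropping.
#' @return A tibble of class `psth` with columns `unit_id`, `bin`,
#'   `time_lo`, `time_mid`, `rate`, and attributes `bin_edges`, `bin_width`,
#'   `window`, `n_events`, `dropped_events`.
#' @export
build_psth <- function(spikes, event_times, window, bin_width = 0.01,
                       session_length = NULL) {
  stopifnot(bin_width > 0, length(window) == 2, window[2] > window[1])
  if (diff(window) < bin_width) stop("window must span >= 1 bin", call. = FALSE)
  if (!is.data.frame(spikes)) {
    spikes <- tibble::tibble(unit_id = "unit", time_s = as.numeric(spikes))
  }
  stopifnot(all(c("unit_id", "time_s") %in% names(spikes)))
  usable <- event_times + window[1] >= 0
  if (!is.null(session_length)) {
    usable <- usable & (event_times + window[2] <= session_length)
  }
  dropped <- sum(!usable)
  ev <- event_times[usable]
  if (length(ev) == 0) stop("zero usable events", call. = FALSE)
  n_bins <- floor(diff(window) / bin_width + 1e-9)
  edges <- window[1] + bin_width * (0:n_bins)
  units <- unique(spikes$unit_id)
  per_unit <- function(times) {
    counts <- numeric(n_bins)
    for (e in ev) {
      rel <- times - e
      rel <- rel[rel >= edges[1] & rel < edges[n_bins + 1]]
      if (length(rel)) {
        b <- floor((rel - edges[1]) / bin_width) + 1
        counts <- counts + tabulate(b, nbins = n_bins)
      }
    }
    counts / (length(ev) * bin_width)
  }
  if (nrow(spikes) == 0) {
    out <- tibble::tibble(unit_id = "unit", bin = seq_len(n_bins),
                          rate = 0)
  } else {
    out <- spikes |>
      dplyr::group_by(.data$unit_id) |>
      dplyr::reframe(bin = seq_len(n_bins), rate = per_unit(.data$time_s))
  }
  out <- dplyr::mutate(out, time_lo = edges[.data$bin],
                       time_mid = edges[.data$bin] + bin_width / 2,
                       .after = "bin")
  structure(out,
            class = c("psth", class(out)),
            bin_edges = edges, bin_width = bin_width, window = window,
            n_events = length(ev), dropped_events = dropped)
}

#' Z-score a PSTH against a baseline window
#'
#' Per unit, `z_i = (F_i - F_mean) / F_SD` where `F_mean` and `F_SD` are the
#' mean and SD of the rate over the baseline bins (a 10 s pre-event window by
#' default). Units with `F_SD = 0` get `z = NA` and `baseline_defined =
#' FALSE` rather than a silent zero.
#'
#' @param psth A `psth` object from [build_psth()].
#' @param baseline_window Length-2 numeric, seconds relative to the event;
#'   must lie within the PSTH window. Default `c(-10.5, -0.5)`.
#' @return The `psth` tibble with added columns `baseline_mean`,
#'   `baseline_sd`, `baseline_defined`, `z`.
#' @export
zscore_psth <- function(psth, baseline_window = c(-10.5, -0.5)) {
  stopifnot(inherits(psth, "psth"), length(baseline_window) == 2)
  win <- attr(psth, "window")
  if (baseline_window[1] < win[1] - 1e-9 || baseline_window[2] > win[2] + 1e-9) {
    stop("baseline window outside the PSTH window", call. = FALSE)
  }
  at <- attributes(psth)
  out <- psth |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::mutate(
      .base = .data$time_lo >= baseline_window[1] &
        .data$time_lo < baseline_window[2],
      baseline_mean = mean(.data$rate[.data$.base]),
      baseline_sd = stats::sd(.data$rate[.data$.base]),
      baseline_defined = .data$baseline_sd > 0,
      z = ifelse(.data$baseline_defined,
                 (.data$rate - .data$baseline_mean) / .data$baseline_sd,
                 NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::select(-".base")
  attributes(out) <- c(attributes(out)[c("names", "row.names")],
                       at[setdiff(names(at), c("names", "row.names"))],
                       list(baseline_window = baseline_window))
  class(out) <- unique(c("psth", class(out)))
  out
}

#' Causal half-normal smoothing
#'
#' Smooths a binned series with a half-normal kernel that weights the current
#' and previous bins only: `out_i = sum_j w_j * in_(i-j)` with
#' `w_j proportional to exp(-j^2 / (2 sigma^2))`, `j = 0..ceil(4 sigma)`,
#' weights normalised to sum 1 (unit DC gain). Bins before the series start
#' use edge replication of the first value.
#'
#' @param values Numeric vector (one unit's binned rates or z-scores).
#' @param sigma_bins Kernel width in bins (default 6.6).
#' @return Numeric vector, same length.
#' @export
smooth_causal_halfnormal <- function(values, sigma_bins = 6.6) {
  stopifnot(sigma_bins > 0)
  n <- length(values)
  if (n == 0) return(values)
  J <- ceiling(4 * sigma_bins)
  w <- exp(-(0:J)^2 / (2 * sigma_bins^2))
  w <- w / sum(w)
  padded <- c(rep(values[1], J), values)
  out <- numeric(n)
  for (j in 0:J) out <- out + w[j + 1] * padded[(J - j + 1):(J - j + n)]
  out
}

#' Smooth every unit of a PSTH
#'
#' Applies [smooth_causal_halfnormal()] per unit to the `z` column when
#' present (adding `z_smooth`), otherwise to `rate` (adding `rate_smooth`).
#'
#' @param psth A `psth` object.
#' @param sigma_bins Kernel width in bins.
#' @return The `psth` with the smoothed column added.
#' @export
smooth_psth <- function(psth, sigma_bins = 6.6) {
  stopifnot(inherits(psth, "psth"))
  at <- attributes(psth)
  col <- if ("z" %in% names(psth)) "z" else "rate"
  out <- psth |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::mutate("{col}_smooth" := smooth_causal_halfnormal(.data[[col]],
                                                             sigma_bins)) |>
    dplyr::ungroup()
  attributes(out) <- c(attributes(out)[c("names", "row.names")],
                       at[setdiff(names(at), c("names", "row.names"))])
  class(out) <- unique(c("psth", class(out)))
  out
}

#' Classify event modulation of units
#'
#' For each unit, compares the firing rate in a response window around each
#' event against that event's own baseline-window rate with a two-tailed
#' paired Wilcoxon signed-rank test (all tests on unsmoothed counts). A unit
#' is `excited` or `inhibited` — by the sign of the median paired difference
#' — when `p < alpha`, otherwise `none`. Zero differences are dropped before
#' testing (standard signed-rank convention); if every pair is zero the test
#' is undefined and the unit is labelled `none` with `p = 1`. The exact null
#' distribution is used for 25 or fewer informative pairs (without ties), the
#' normal approximation with continuity correction otherwise.
#'
#' Default windows follow the consumption-task analysis: response
#' `c(-0.5, 0.5)` s around port entries/exits (use `c(0, 0.03)` s for licks)
#' and a 10 s baseline at `c(-10.5, -0.5)` s.
#'
#' @param spikes Numeric vector of spike times or data frame with `unit_id`,
#'   `time_s`.
#' @param event_times Event timestamps, seconds.
#' @param response_window,baseline_window Length-2 windows relative to the
#'   event, seconds.
#' @param alpha Two-sided significance level.
#' @param event_type Optional label copied to the output.
#' @param session_length Optional recording length for edge dropping.
#' @return A tibble with one row per unit: `unit_id`, `event_type`,
#'   `n_events`, `median_diff` (response - baseline rate, Hz), `p_value`,
#'   `label` (factor excited/inhibited/none).
#' @export
classify_modulation <- function(spikes, event_times,
                                response_window = c(-0.5, 0.5),
                                baseline_window = c(-10.5, -0.5),
                                alpha = 0.05, event_type = "event",
                                session_length = NULL) {
  stopifnot(length(response_window) == 2, length(baseline_window) == 2)
  if (response_window[1] < baseline_window[2] &&
      baseline_window[1] < response_window[2]) {
    stop("response and baseline windows must not overlap", call. = FALSE)
  }
  if (!is.data.frame(spikes)) {
    spikes <- tibble::tibble(unit_id = "unit", time_s = as.numeric(spikes))
  }
  lo <- min(response_window[1], baseline_window[1])
  hi <- max(response_window[2], baseline_window[2])
  usable <- event_times + lo >= 0
  if (!is.null(session_length)) {
    usable <- usable & (event_times + hi <= session_length)
  }
  ev <- event_times[usable]
  if (length(ev) == 0) stop("zero usable events", call. = FALSE)
  rate_in <- function(times, win) {
    vapply(ev, function(e) {
      sum(times >= e + win[1] & times < e + win[2]) / diff(win)
    }, numeric(1))
  }
  one <- function(times) {
    d <- rate_in(times, response_window) - rate_in(times, baseline_window)
    dd <- d[d != 0]
    if (length(dd) == 0) {
      return(tibble::tibble(n_events = length(ev), median_diff = 0,
                            p_value = 1, label = "none"))
    }
    exact <- length(dd) <= 25 && !any(duplicated(abs(dd)))
    p <- suppressWarnings(
      stats::wilcox.test(dd, exact = exact, correct = TRUE)$p.value)
    md <- stats::median(d)
    label <- if (p < alpha && md > 0) "excited"
    else if (p < alpha && md < 0) "inhibited"
    else "none"
    tibble::tibble(n_events = length(ev), median_diff = md,
                   p_value = p, label = label)
  }
  spikes |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::reframe(one(.data$time_s)) |>
    dplyr::mutate(event_type = event_type, .after = "unit_id") |>
    dplyr::mutate(label = factor(.data$label,
                                 levels = c("excited", "inhibited", "none")))
}

#' Proportions of excited / inhibited units per event type
#'
#' @param labels A tibble from [classify_modulation()] (possibly row-bound
#'   over event types).
#' @return A tibble with `event_type`, `n_units`, `prop_excited`,
#'   `prop_inhibited`, `prop_none` (summing to 1 per event type).
#' @export
modulation_proportions <- function(labels) {
  stopifnot(is.data.frame(labels), nrow(labels) >= 1,
            all(c("event_type", "label") %in% names(labels)))
  labels |>
    dplyr::group_by(.data$event_type) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      prop_excited = mean(.data$label == "excited"),
      prop_inhibited = mean(.data$label == "inhibited"),
      prop_none = mean(.data$label == "none"),
      .groups = "drop")
}

#' Heatmap of a z-scored PSTH
#'
#' @param object A `psth` object (z-scored and optionally smoothed).
#' @param ... Unused.
#' @return A ggplot heatmap, units ordered by mean post-event response.
#' @exportS3Method ggplot2::autoplot
autoplot.psth <- function(object, ...) {
  col <- intersect(c("z_smooth", "z", "rate_smooth", "rate"), names(object))[1]
  ord <- object |>
    dplyr::filter(.data$time_lo >= 0) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(m = mean(.data[[col]], na.rm = TRUE), .groups = "drop") |>
    dplyr::arrange(.data$m)
  df <- dplyr::mutate(tibble::as_tibble(object),
                      unit_id = factor(.data$unit_id, levels = ord$unit_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_mid, y = .data$unit_id,
                                   fill = .data[[col]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "time from event (s)", y = "unit", fill = col) +
    ggplot2::theme_minimal()
}
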