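# Spike-train generation: inhomogeneous Poisson process with multiplicative
# von Mises phase locking to the lick cycle and an event gain around port
# entries/exits, sampled by thinning.

# Event-gain profile g(t): multiplicative factor around each event time.
event_gain <- function(t, event_times, gain, width = 0.5,
                       shape = c("step", "bump")) {
  shape <- match.arg(shape)
  g <- rep(1, length(t))
  if (length(event_times) == 0 || gain == 1) return(g)
  if (shape == "step") {
    for (e in event_times) {
      inside <- t >= e - width & t <= e + width
      g[inside] <- gain
    }
  } else {
    for (e in event_times) {
      g <- g * (1 + (gain - 1) * exp(-(t - e)^2 / (2 * width^2)))
    }
  }
  g
}

# Phase of each time point within its enclosing lick cycle, NA outside.
cycle_phase_at <- function(t, cycles) {
  if (nrow(cycles) == 0) return(rep(NA_real_, length(t)))
  idx <- findInterval(t, cycles$start_s)
  ok <- idx >= 1L
  ok[ok] <- t[ok] < cycles$end_s[idx[ok]]
  phase <- rep(NA_real_, length(t))
  i <- idx[ok]
  phase[ok] <- 2 * pi * (t[ok] - cycles$start_s[i]) /
    (cycles$end_s[i] - cycles$start_s[i])
  phase
}

# Intensity lambda(t) for one unit.
unit_intensity <- function(t, cycles, event_times, params) {
  lam <- rep(params$baseline_rate, length(t))
  kap <- params$kappa
  if (kap > 0 && nrow(cycles) > 0) {
    phase <- cycle_phase_at(t, cycles)
    inside <- !is.na(phase)
    lam[inside] <- lam[inside] *
      exp(kap * cos(phase[inside] - params$mu)) / besselI(kap, 0)
  }
  lam * event_gain(t, event_times, params$entry_gain,
                   params$gain_width, params$gain_shape)
}

#' Generate one unit's spike train
#'
#' Samples an inhomogeneous Poisson process by thinning with intensity
#' `lambda(t) = lambda0 * g_event(t) * exp(kappa * cos(phi(t) - mu)) /
#' I0(kappa)` inside lick cycles and `lambda0 * g_event(t)` outside, where
#' `phi(t)` is the linear phase within the enclosing cycle and `g_event` the
#' configured gain profile around port entries/exits. With `kappa = 0` and
#' unit gain this reduces to a homogeneous Poisson process at `lambda0`.
#'
#' @param cycles Lick-cycle tibble ([cycles_from_bouts()]).
#' @param event_times Port entry/exit times the gain profile is centred on.
#' @param unit_params List with `baseline_rate` (> 0), `kappa` (>= 0), `mu`,
#'   `entry_gain` (>= 0), `gain_width`, `gain_shape`.
#' @param session_length Session duration, seconds.
#' @param seed Optional seed (omit when the caller already seeded the RNG).
#' @return Ascending numeric vector of spike times.
#' @export
gen_spike_train <- function(cycles, event_times, unit_params, session_length,
                            seed = NULL) {
  p <- unit_params
  p$gain_width <- p$gain_width %||% 0.5
  p$gain_shape <- p$gain_shape %||% "step"
  if (p$baseline_rate < 0) stop("baseline_rate must be >= 0", call. = FALSE)
  if (p$kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (p$entry_gain < 0) stop("entry_gain must be >= 0", call. = FALSE)
  if (session_length <= 0 || p$baseline_rate == 0) return(numeric())
  run <- function() {
    lam_max <- p$baseline_rate * max(p$entry_gain, 1) *
      (if (p$kappa > 0) exp(p$kappa) / besselI(p$kappa, 0) else 1)
    n <- stats::rpois(1, lam_max * session_length)
    if (n == 0) return(numeric())
    t <- sort(stats::runif(n, 0, session_length))
    lam <- unit_intensity(t, cycles, event_times, p)
    t[stats::runif(n) < lam / lam_max]
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
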