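# Closed-loop task logic: the cumulative-presence pump rule and the
# lick-triggered excitation / inhibition laser rules.

#' Simulate the cumulative-presence pump rule
#'
#' A counter accrues time spent in the reward port; each time it reaches
#' `threshold` (2 s) it resets and the pump delivers for `pump_duration`
#' (2 s), `volume_ml` (0.1 mL) per activation. By default accrual continues
#' during delivery (delivery is matched to the consumption rate); set
#' `pause_during_delivery = TRUE` to suspend accrual while the pump runs.
#' Reaching the threshold exactly (e.g. at the instant of port exit) counts
#' as an activation.
#'
#' @param occupancy Two-column matrix or data frame of non-overlapping,
#'   ascending `(enter, exit)` intervals in seconds.
#' @param threshold Cumulative presence required per delivery, seconds.
#' @param pump_duration Delivery duration, seconds.
#' @param volume_ml Volume per activation, mL.
#' @param pause_during_delivery Suspend accrual during delivery.
#' @return A list with `activations` (times, seconds), `n_activations`,
#'   `total_volume_ml`, and `pump_intervals` (tibble `on_s`, `off_s`).
#' @examples
#' simulate_port_task(cbind(0, 10))  # 5 activations at 2, 4, 6, 8, 10 s
#' @export
simulate_port_task <- function(occupancy, threshold = 2, pump_duration = 2,
                               volume_ml = 0.1,
                               pause_during_delivery = FALSE) {
  occ <- as.matrix(occupancy)
  stopifnot(threshold > 0, pump_duration >= 0, volume_ml >= 0)
  if (length(occ) == 0) {
    occ <- matrix(numeric(), ncol = 2)
  }
  if (ncol(occ) != 2) stop("occupancy must have two columns", call. = FALSE)
  if (nrow(occ) > 0) {
    if (any(occ[, 2] < occ[, 1])) {
      stop("each interval needs exit >= enter", call. = FALSE)
    }
    if (nrow(occ) > 1 && any(occ[-1, 1] < occ[-nrow(occ), 2])) {
      stop("occupancy intervals overlap or are out of order", call. = FALSE)
    }
  }
  activations <- numeric()
  carry <- 0
  pause_until <- -Inf
  for (i in seq_len(nrow(occ))) {
    pos <- occ[i, 1]
    e <- occ[i, 2]
    repeat {
      if (pause_during_delivery && pos < pause_until) {
        pos <- min(e, pause_until)
      }
      if (pos >= e) break
      if (carry + (e - pos) >= threshold) {
        t_act <- pos + (threshold - carry)
        activations <- c(activations, t_act)
        carry <- 0
        pause_until <- t_act + pump_duration
        pos <- t_act
        if (pos >= e) break
      } else {
        carry <- carry + (e - pos)
        break
      }
    }
  }
  tibble_pump <- tibble::tibble(on_s = activations,
                                off_s = activations + pump_duration)
  list(activations = activations,
       n_activations = length(activations),
       total_volume_ml = volume_ml * length(activations),
       pump_intervals = tibble_pump)
}

#' Simulate closed-loop laser rules
#'
#' Excite mode ("first lick each second"): a lick triggers a
#' `train_duration` (1 s) stimulation train; licks during an active train
#' trigger nothing; the first lick at or after train end retriggers. The
#' lockout is anchored at each trigger, not at wall-clock seconds.
#'
#' Inhibit mode: light turns on at the first lick of a run and off
#' `off_after` (1 s) after the last lick of that run, where runs are maximal
#' lick sequences with gaps strictly below `off_after`.
#'
#' @param licks Ascending lick times on the laser-paired spout, seconds.
#' @param mode `"excite"` or `"inhibit"`.
#' @param train_duration Excite-mode train length, seconds.
#' @param off_after Inhibit-mode silence required before light-off, seconds.
#' @return A tibble of laser intervals with columns `on_s`, `off_s`.
#' @examples
#' simulate_closed_loop(c(0, 0.3, 0.6), "inhibit")  # one interval [0, 1.6]
#' @export
simulate_closed_loop <- function(licks, mode = c("excite", "inhibit"),
                                 train_duration = 1, off_after = 1) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(licks), train_duration > 0, off_after > 0)
  if (is.unsorted(licks)) stop("`licks` must be ascending", call. = FALSE)
  if (length(licks) == 0) {
    return(tibble::tibble(on_s = numeric(), off_s = numeric()))
  }
  if (mode == "excite") {
    on <- numeric()
    train_end <- -Inf
    for (t in licks) {
      if (t >= train_end) {
        on <- c(on, t)
        train_end <- t + train_duration
      }
    }
    return(tibble::tibble(on_s = on, off_s = on + train_duration))
  }
  # inhibit: maximal runs with gaps < off_after
  run_id <- cumsum(c(1, as.integer(diff(licks) >= off_after)))
  first <- tapply(licks, run_id, min)
  last <- tapply(licks, run_id, max)
  tibble::tibble(on_s = as.numeric(first), off_s = as.numeric(last) + off_after)
}
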