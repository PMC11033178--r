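# Simulation configuration: the study conditions for synthetic sessions.
# Defaults reproduce a 40-min consumption session: ~7 Hz within-bout licking,
# ~3.3 Hz baseline firing, von Mises phase locking at pi/2, and a step gain
# around port entries/exits.

#' Simulation configuration
#'
#' Builds a validated configuration for [gen_session()] and the component
#' generators. Per-unit fields (`baseline_rate`, `phase_locking_strength`,
#' `preferred_phase_true`, `entry_gain`) are recycled to `n_units`.
#'
#' Defaults describe one 40-minute self-administration session: licks
#' arrive in bouts (inter-bout gaps exceeding the 210 ms criterion by an
#' exponential margin) with within-bout inter-lick intervals drawn from a
#' truncated lognormal whose mean is `ili_mean` (1/7 s, i.e. 7 Hz licking),
#' about 0.02 bouts/s of 7 licks on average (~340 licks/session), and units
#' firing at 3.3 Hz with concentration `kappa = 1` at preferred phase
#' `pi / 2`.
#'
#' @param session_length Session duration, seconds (default 2400 = 40 min).
#' @param n_units Number of simulated units.
#' @param baseline_rate Baseline firing rate lambda0, spikes/s, > 0.
#' @param phase_locking_strength Von Mises concentration kappa, >= 0.
#' @param preferred_phase_true Preferred phase mu, radians.
#' @param entry_gain Multiplicative rate factor applied around port entries
#'   and exits (>= 0; 1 = no event modulation).
#' @param gain_width Half-width of the event-gain profile, seconds.
#' @param gain_shape `"step"` (gain inside +/- `gain_width`) or `"bump"`
#'   (Gaussian bump of SD `gain_width`).
#' @param bout_rate Bout initiation rate, bouts/s.
#' @param bout_size_mean Mean licks per bout (>= 1; sizes are
#'   1 + Poisson(`bout_size_mean` - 1)).
#' @param ili_mean Mean within-bout inter-lick interval, seconds.
#' @param ili_bounds Truncation bounds for the ILI distribution, seconds;
#'   the upper bound must stay below 0.210 s so generated bouts are never
#'   split by the bout rule.
#' @param ili_sdlog Log-scale SD of the lognormal ILI distribution.
#' @param task `"self_admin"` (port + pump) or `"two_bottle"` (two spouts,
#'   closed-loop laser).
#' @param laser_mode For two-bottle sessions: `"none"`, `"excite"` (1 s
#'   trains retriggered by the first lick at/after train end) or `"inhibit"`
#'   (light on until 1 s of lick silence).
#' @param laser_spout Spout whose licks trigger the laser.
#' @param pump_pause_during_delivery Whether port-presence accrual pauses
#'   during the 2 s delivery (default `FALSE`: accrual continues).
#' @param body_weight_kg Animal body weight for intake dosing.
#' @param lick_volume_ml Fluid volume per lick used to derive bottle weights.
#' @param seed Integer seed; fixed seed gives bit-identical sessions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(session_length = 2400,
                       n_units = 40,
                       baseline_rate = 3.3,
                       phase_locking_strength = 1,
                       preferred_phase_true = pi / 2,
                       entry_gain = 1,
                       gain_width = 0.5,
                       gain_shape = c("step", "bump"),
                       bout_rate = 0.02,
                       bout_size_mean = 7,
                       ili_mean = 1 / 7,
                       ili_bounds = c(0.05, 0.205),
                       ili_sdlog = 0.2,
                       task = c("self_admin", "two_bottle"),
                       laser_mode = c("none", "excite", "inhibit"),
                       laser_spout = "a",
                       pump_pause_during_delivery = FALSE,
                       body_weight_kg = 0.4,
                       lick_volume_ml = 0.005,
                       seed = 1L) {
  gain_shape <- match.arg(gain_shape)
  task <- match.arg(task)
  laser_mode <- match.arg(laser_mode)
  stopifnot(session_length >= 0, n_units >= 0)
  if (any(baseline_rate <= 0)) stop("baseline_rate must be > 0", call. = FALSE)
  if (any(phase_locking_strength < 0)) stop("kappa must be >= 0", call. = FALSE)
  if (any(entry_gain < 0)) stop("entry_gain must be >= 0", call. = FALSE)
  if (length(ili_bounds) != 2 || ili_bounds[1] <= 0 ||
      ili_bounds[2] <= ili_bounds[1] || ili_bounds[2] >= 0.210) {
    stop("ili_bounds must satisfy 0 < low < high < 0.210", call. = FALSE)
  }
  if (ili_mean <= ili_bounds[1] || ili_mean >= ili_bounds[2]) {
    stop("ili_mean must lie strictly inside ili_bounds", call. = FALSE)
  }
  stopifnot(bout_rate > 0, bout_size_mean >= 1, ili_sdlog > 0,
            body_weight_kg > 0, lick_volume_ml >= 0)
  rec <- function(x) rep_len(x, n_units)
  structure(list(
    session_length = session_length,
    n_units = n_units,
    baseline_rate = rec(baseline_rate),
    phase_locking_strength = rec(phase_locking_strength),
    preferred_phase_true = rec(preferred_phase_true) %% (2 * pi),
    entry_gain = rec(entry_gain),
    gain_width = gain_width,
    gain_shape = gain_shape,
    bout_rate = bout_rate,
    bout_size_mean = bout_size_mean,
    ili_mean = ili_mean,
    ili_bounds = ili_bounds,
    ili_sdlog = ili_sdlog,
    task = task,
    laser_mode = laser_mode,
    laser_spout = laser_spout,
    pump_pause_during_delivery = pump_pause_during_delivery,
    body_weight_kg = body_weight_kg,
    lick_volume_ml = lick_volume_ml,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Run code with the global RNG state saved/restored and seeded locally.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
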