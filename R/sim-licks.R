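# Lick-train generation: bouts with truncated-lognormal within-bout
# inter-lick intervals whose truncated mean is calibrated to ili_mean, and
# inter-bout gaps strictly above the 210 ms bout criterion.

# Mean of a lognormal(meanlog, sdlog) truncated to [a, b]. In the far tails
# (vanishing truncation mass) the mean degenerates to the nearer bound.
truncated_lognormal_mean <- function(meanlog, sdlog, a, b) {
  za <- (log(a) - meanlog) / sdlog
  zb <- (log(b) - meanlog) / sdlog
  denom <- stats::pnorm(zb) - stats::pnorm(za)
  if (!is.finite(denom) || denom < 1e-300) {
    return(if (meanlog < log(a)) a else b)
  }
  exp(meanlog + sdlog^2 / 2) *
    (stats::pnorm(zb - sdlog) - stats::pnorm(za - sdlog)) / denom
}

# Calibrate meanlog so the truncated mean equals the target.
calibrate_ili_meanlog <- function(target, sdlog, bounds) {
  f <- function(m) truncated_lognormal_mean(m, sdlog, bounds[1], bounds[2]) - target
  stats::uniroot(f, lower = log(bounds[1]) - 3, upper = log(bounds[2]) + 3,
                 tol = 1e-12)$root
}

# Inverse-CDF sampling from the truncated lognormal.
sample_ili <- function(n, meanlog, sdlog, bounds) {
  lo <- stats::plnorm(bounds[1], meanlog, sdlog)
  hi <- stats::plnorm(bounds[2], meanlog, sdlog)
  stats::qlnorm(stats::runif(n, lo, hi), meanlog, sdlog)
}

#' Generate a synthetic lick train
#'
#' Bouts start at inter-bout gaps of `0.210 + Exp(bout_rate)` seconds (so no
#' generated bout is ever split by the 210 ms rule), contain
#' `1 + Poisson(bout_size_mean - 1)` licks, and within-bout inter-lick
#' intervals are truncated-lognormal on `ili_bounds` with the log-mean
#' calibrated so the truncated mean equals `ili_mean` (1/7 s by default:
#' 7 Hz within-bout licking). Licks past `session_length` are dropped.
#'
#' @param config A [sim_config()].
#' @return A list with `licks` (ascending numeric vector, seconds) and
#'   `bouts` (tibble `bout`, `start_s`, `end_s`, `n_licks`: the generator's
#'   ground-truth bout boundaries).
#' @export
gen_lick_train <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, gen_lick_train_impl(config))
}

# Internal: assumes the RNG is already seeded (used inside gen_session).
gen_lick_train_impl <- function(config) {
  T <- config$session_length
  empty <- list(licks = numeric(),
                bouts = tibble::tibble(bout = integer(), start_s = numeric(),
                                       end_s = numeric(), n_licks = integer()))
  if (T <= 0) return(empty)
  meanlog <- calibrate_ili_meanlog(config$ili_mean, config$ili_sdlog,
                                   config$ili_bounds)
  licks <- list()
  starts <- numeric()
  ends <- numeric()
  sizes <- integer()
  t <- stats::rexp(1, config$bout_rate)
  k <- 0L
  while (t <= T) {
    size <- 1L + stats::rpois(1, config$bout_size_mean - 1)
    ilis <- if (size > 1) sample_ili(size - 1L, meanlog, config$ili_sdlog,
                                     config$ili_bounds) else numeric()
    bout <- t + c(0, cumsum(ilis))
    bout <- bout[bout <= T]
    if (length(bout) == 0) break
    k <- k + 1L
    licks[[k]] <- bout
    starts[k] <- bout[1]
    ends[k] <- bout[length(bout)]
    sizes[k] <- length(bout)
    t <- ends[k] + 0.210 + stats::rexp(1, config$bout_rate)
  }
  if (k == 0L) return(empty)
  list(licks = unlist(licks),
       bouts = tibble::tibble(bout = seq_len(k), start_s = starts,
                              end_s = ends, n_licks = sizes))
}
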