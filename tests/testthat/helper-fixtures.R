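# Shared fixtures: tiny sessions and an independent von Mises sampler used
# as a sampling oracle (Best-Fisher rejection; independent of the package's
# thinning-based spike generator).

tiny_session <- function(seed = 42, session_length = 300, n_units = 4,
                         ...) {
  gen_session(sim_config(seed = seed, session_length = session_length,
                         n_units = n_units, ...))
}

rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- (sign(u[3] - 0.5) * acos(f) + mu) %% (2 * pi)
      i <- i + 1
    }
  }
  out
}

# Brute-force cluster segmentation used as an oracle against lick_clusters().
brute_clusters <- function(times, split) {
  if (length(times) == 0) return(integer())
  sizes <- integer()
  cur <- 1L
  for (i in seq_along(times)[-1]) {
    if (times[i] - times[i - 1] < split) {
      cur <- cur + 1L
    } else {
      sizes <- c(sizes, cur)
      cur <- 1L
    }
  }
  c(sizes, cur)
}
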