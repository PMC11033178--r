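# Circular statistics: mean direction / resultant length, Rayleigh test,
# V test against a prespecified direction, two-sample Kuiper test, and the
# pooled two-proportion z test. All p-values are clamped to [0, 1].

new_circ_test <- function(method, statistic, p_value, n, m = NA_integer_,
                          approximation = NA_character_, extra = list()) {
  structure(
    c(list(
      method = method,
      statistic = statistic,
      p_value = min(max(p_value, 0), 1),
      n = n,
      m = m,
      approximation = approximation
    ), extra),
    class = "circ_test"
  )
}

#' @export
print.circ_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat("statistic = ", format(x$statistic, digits = 6),
      ", p-value = ", format.pval(x$p_value, digits = 4), "\n", sep = "")
  cat("n = ", x$n, if (!is.na(x$m)) paste0(", m = ", x$m), "\n", sep = "")
  if (!is.na(x$approximation)) {
    cat("approximation: ", x$approximation, "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a circular test result
#'
#' @param x A `circ_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, p-value and sample sizes.
#' @exportS3Method generics::tidy
tidy.circ_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p.value = x$p_value,
    n = x$n,
    m = x$m,
    approximation = x$approximation
  )
}

#' @rdname tidy.circ_test
#' @exportS3Method generics::glance
glance.circ_test <- function(x, ...) tidy.circ_test(x, ...)

check_phases <- function(phases, arg = "phases") {
  if (!is.numeric(phases)) {
    stop("`", arg, "` must be numeric (radians)", call. = FALSE)
  }
  if (anyNA(phases)) stop("`", arg, "` contains NA", call. = FALSE)
  phases %% (2 * pi)
}

#' Circular mean direction and resultant length
#'
#' Computes the mean direction `arg(sum(exp(i * theta)))` and the mean
#' resultant length `R = |sum(exp(i * theta))| / n` of a sample of angles.
#' When the resultant is (numerically) zero the mean direction is undefined
#' and returned as `NA` with `mean_defined = FALSE`.
#'
#' @param phases Numeric vector of angles in radians.
#' @return A list with `mean_direction` (radians in `[0, 2 * pi)`),
#'   `R` in `[0, 1]`, `n`, and `mean_defined`.
#' @examples
#' circ_mean_resultant(c(0, pi / 2))
#' @export
circ_mean_resultant <- function(phases) {
  phases <- check_phases(phases)
  n <- length(phases)
  if (n < 1) stop("need at least one phase", call. = FALSE)
  C <- sum(cos(phases))
  S <- sum(sin(phases))
  R <- sqrt(C^2 + S^2) / n
  defined <- R > 1e-12
  mu <- if (defined) atan2(S, C) %% (2 * pi) else NA_real_
  list(mean_direction = mu, R = min(R, 1), n = n, mean_defined = defined)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that the sample of angles is drawn from the
#' uniform circular distribution, against unimodal concentration. The
#' statistic is `Z = n * R^2`; the p-value uses the standard series
#' approximation
#' `p = exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2))`,
#' clamped to `[0, 1]`.
#'
#' @param phases Numeric vector of angles in radians, length >= 2.
#' @return A `circ_test` object with fields `statistic` (Z), `p_value`, `n`,
#'   and `R`.
#' @examples
#' rayleigh_test(rep(1, 50))$p_value    # fully concentrated: p ~ 0
#' rayleigh_test(c(0, pi/2, pi, 3*pi/2))$p_value  # perfectly uniform: 1
#' @export
rayleigh_test <- function(phases) {
  phases <- check_phases(phases)
  n <- length(phases)
  if (n < 2) stop("Rayleigh test needs n >= 2", call. = FALSE)
  cm <- circ_mean_resultant(phases)
  Z <- n * cm$R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  new_circ_test(
    method = "Rayleigh test of uniformity",
    statistic = Z, p_value = p, n = n,
    approximation = "series (clamped)",
    extra = list(R = cm$R, mean_direction = cm$mean_direction)
  )
}

#' V test of circular uniformity against a specified direction
#'
#' One-sided modification of the Rayleigh test when the alternative mean
#' direction `mu0` is specified a priori (here typically 90 degrees, the
#' mid lick cycle). `V = n * R * cos(mean - mu0)`, `u = V * sqrt(2 / n)`,
#' and the p-value is the upper tail of the standard normal at `u`.
#'
#' A precomputed summary may be supplied instead of raw phases, so printed
#' statistics can be checked directly: pass `n` and either (`R` and
#' `mean_direction`) or the statistic `V`.
#'
#' @param phases Numeric vector of angles in radians (or `NULL` if a summary
#'   is supplied).
#' @param mu0 Hypothesised mean direction, radians.
#' @param n,R,mean_direction,V Optional precomputed summary (used when
#'   `phases` is `NULL`).
#' @return A `circ_test` object; `statistic` is V, with `u` in the extras.
#' @examples
#' v_test(NULL, mu0 = pi / 2, n = 38, V = 19.92)  # printed-statistic check
#' @export
v_test <- function(phases, mu0, n = NULL, R = NULL, mean_direction = NULL,
                   V = NULL) {
  if (missing(mu0) || is.null(mu0)) stop("`mu0` must be given", call. = FALSE)
  if (!is.null(phases)) {
    phases <- check_phases(phases)
    n <- length(phases)
    if (n < 2) stop("V test needs n >= 2", call. = FALSE)
    cm <- circ_mean_resultant(phases)
    V <- n * cm$R * cos(cm$mean_direction - mu0)
  } else {
    if (is.null(n)) stop("summary form needs `n`", call. = FALSE)
    if (is.null(V)) {
      if (is.null(R) || is.null(mean_direction)) {
        stop("summary form needs `V` or both `R` and `mean_direction`",
             call. = FALSE)
      }
      V <- n * R * cos(mean_direction - mu0)
    }
  }
  u <- V * sqrt(2 / n)
  p <- stats::pnorm(u, lower.tail = FALSE)
  new_circ_test(
    method = "V test (specified mean direction)",
    statistic = V, p_value = p, n = n,
    approximation = "normal (one-sided)",
    extra = list(u = u, mu0 = mu0)
  )
}

# Two-sample Kuiper statistic on the circle: K = D+ + D- over the pooled
# sample, which is invariant to joint rotation of both samples.
kuiper_statistic <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  lab <- c(rep(TRUE, m), rep(FALSE, n))
  o <- order(pooled)
  la <- lab[o]
  d <- cumsum(ifelse(la, 1 / m, 0)) - cumsum(ifelse(la, 0, 1 / n))
  max(d, 0) + max(-d, 0)
}

#' Two-sample Kuiper test
#'
#' Rotation-invariant circular analogue of the two-sample Kolmogorov-Smirnov
#' test. The statistic is `K = max(F_a - F_b) + max(F_b - F_a)` over the
#' pooled empirical CDFs; the p-value uses the asymptotic series
#' `p = 2 * sum_j (4 j^2 lambda^2 - 1) exp(-2 j^2 lambda^2)` with
#' `lambda = K * (sqrt(Ne) + 0.155 + 0.24 / sqrt(Ne))` and
#' `Ne = m n / (m + n)`, clamped to `[0, 1]`.
#'
#' @param phases_a,phases_b Numeric vectors of angles in radians, each of
#'   length >= 5.
#' @return A `circ_test` object with the statistic K.
#' @export
kuiper_two_sample <- function(phases_a, phases_b) {
  a <- check_phases(phases_a, "phases_a")
  b <- check_phases(phases_b, "phases_b")
  if (length(a) < 5 || length(b) < 5) {
    stop("Kuiper test needs n >= 5 in both samples", call. = FALSE)
  }
  K <- kuiper_statistic(a, b)
  m <- length(a); n <- length(b)
  ne <- m * n / (m + n)
  lambda <- K * (sqrt(ne) + 0.155 + 0.24 / sqrt(ne))
  j <- seq_len(100)
  p <- 2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))
  new_circ_test(
    method = "two-sample Kuiper test",
    statistic = K, p_value = p, n = m, m = n,
    approximation = "asymptotic series with finite-sample correction"
  )
}

#' Two-proportion z test
#'
#' Large-sample z test comparing two binomial proportions,
#' `z = (p1 - p2) / sqrt(p * (1 - p) * (1/n1 + 1/n2))` with `p` pooled by
#' default, two-sided. When the (pooled) variance is zero the test is
#' degenerate and returns `z = 0`, `p = 1`.
#'
#' @param k1,n1,k2,n2 Successes and totals in the two groups.
#' @param pooled Use the pooled variance estimate (default `TRUE`); set
#'   `FALSE` for the unpooled form.
#' @return A `circ_test` object with the z statistic.
#' @export
two_proportion_z <- function(k1, n1, k2, n2, pooled = TRUE) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  if (pooled) {
    pp <- (k1 + k2) / (n1 + n2)
    v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  } else {
    v <- p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2
  }
  if (v <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- (p1 - p2) / sqrt(v)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  new_circ_test(
    method = sprintf("two-proportion z test (%s variance)",
                     if (pooled) "pooled" else "unpooled"),
    statistic = z, p_value = p, n = n1, m = n2,
    approximation = "normal (two-sided)",
    extra = list(p1 = p1, p2 = p2)
  )
}
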