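test_that("mean direction and resultant length follow the vector sum", {
  antipodal <- circ_mean_resultant(c(0, pi))
  expect_equal(antipodal$R, 0, tolerance = 1e-12)
  expect_false(antipodal$mean_defined)
  expect_true(is.na(antipodal$mean_direction))

  conc <- circ_mean_resultant(rep(1.0, 7))
  expect_equal(conc$mean_direction, 1.0)
  expect_equal(conc$R, 1)

  two <- circ_mean_resultant(c(0, pi / 2))
  expect_equal(two$mean_direction, pi / 4)
  expect_equal(two$R, cos(pi / 4))
})

test_that("resultant length stays in [0,1] and grows when reinforced", {
  set.seed(101)
  for (i in 1:25) {
    ph <- runif(sample(2:40, 1), 0, 2 * pi)
    cm <- circ_mean_resultant(ph)
    expect_gte(cm$R, 0)
    expect_lte(cm$R, 1)
    if (cm$mean_defined) {
      cm2 <- circ_mean_resultant(c(ph, cm$mean_direction))
      expect_gte(cm2$R, cm$R - 1e-12)
    }
  }
})

test_that("Rayleigh test handles full concentration and perfect uniformity", {
  conc <- rayleigh_test(rep(2.2, 50))
  expect_equal(conc$statistic, 50)
  expect_lt(conc$p_value, 1e-15)

  unif <- rayleigh_test(c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(unif$statistic, 0, tolerance = 1e-20)
  expect_equal(unif$p_value, 1)
})

test_that("Rayleigh analytic p tracks a Monte-Carlo null at small n", {
  set.seed(77)
  n <- 30
  B <- 20000
  for (case in 1:6) {
    obs <- runif(n, 0, 2 * pi)
    z_obs <- rayleigh_test(obs)$statistic
    null_c <- matrix(runif(n * B, 0, 2 * pi), n, B)
    z_null <- (colSums(cos(null_c))^2 + colSums(sin(null_c))^2) / n
    p_mc <- mean(z_null >= z_obs)
    expect_lt(abs(rayleigh_test(obs)$p_value - p_mc), 0.02)
  }
})

test_that("V test reproduces the published population statistic", {
  vt <- v_test(NULL, mu0 = pi / 2, n = 38, V = 19.92)
  expect_equal(vt$u, 19.92 * sqrt(2 / 38), tolerance = 1e-12)
  expect_equal(vt$u, 4.570, tolerance = 1e-3)
  expect_lt(vt$p_value, 1e-5)
})

test_that("V test is maximal at mu0 and rotation-equivariant", {
  ph <- rep(1.2, 12)
  expect_equal(v_test(ph, mu0 = 1.2)$statistic, 12)

  set.seed(9)
  ph <- runif(20, 0, 2 * pi)
  delta <- 0.83
  v1 <- v_test(ph, mu0 = pi / 2)
  v2 <- v_test((ph + delta) %% (2 * pi), mu0 = pi / 2 + delta)
  expect_equal(v1$statistic, v2$statistic, tolerance = 1e-9)
  expect_equal(v1$p_value, v2$p_value, tolerance = 1e-9)
})

test_that("Kuiper statistic is rotation invariant and minimal on self", {
  set.seed(13)
  a <- runif(50, 0, 2 * pi)
  b <- runif(50, 0, 2 * pi)
  k0 <- kuiper_two_sample(a, b)
  for (delta in c(0.5, 2.0, 5.5)) {
    kr <- kuiper_two_sample((a + delta) %% (2 * pi), (b + delta) %% (2 * pi))
    expect_equal(kr$statistic, k0$statistic, tolerance = 1e-12)
  }
  self <- kuiper_two_sample(a, a)
  expect_lte(self$statistic, 2 / 50)  # ECDFs never drift apart on self
  expect_gte(k0$p_value, 0)
  expect_lte(k0$p_value, 1)
})

test_that("Kuiper analytic p tracks a permutation null", {
  set.seed(21)
  n <- 50
  B <- 5000
  for (case in 1:4) {
    a <- runif(n, 0, 2 * pi)
    b <- runif(n, 0, 2 * pi)
    k_obs <- kuiper_two_sample(a, b)$statistic
    pooled <- sort(c(a, b))
    lab <- c(rep(1 / n, n), rep(0, n))
    perm <- replicate(B, {
      la <- sample(lab)
      d <- cumsum(la) - cumsum(ifelse(la == 0, 1 / n, 0))
      max(d, 0) + max(-d, 0)
    })
    p_mc <- mean(perm >= k_obs - 1e-12)
    expect_lt(abs(kuiper_two_sample(a, b)$p_value - p_mc), 0.04)
  }
})

test_that("two-proportion z matches the textbook formula", {
  eq <- two_proportion_z(10, 100, 10, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  # independent evaluation of the pooled formula
  k1 <- 38; n1 <- 208; k2 <- 76; n2 <- 208
  p1 <- k1 / n1; p2 <- k2 / n2; pp <- (k1 + k2) / (n1 + n2)
  z_ref <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  p_ref <- 2 * pnorm(-abs(z_ref))
  zt <- two_proportion_z(k1, n1, k2, n2)
  expect_equal(zt$statistic, z_ref, tolerance = 1e-12)
  expect_equal(zt$p_value, p_ref, tolerance = 1e-12)

  degen <- two_proportion_z(0, 50, 0, 50)
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p_value, 1)
})

test_that("circ_test results tidy into one-row tibbles", {
  td <- tidy(rayleigh_test(runif(20, 0, 2 * pi)))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("statistic", "p.value", "n") %in% names(td)))
})
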