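# Exact 3-point identification of (V0, alpha, beta) and the two-point
# growth rates.

test_that("exact exponential data give beta = 1, alpha = log(2)", {
  s <- lesion_series("L", times = c(0, 1, 2), volumes = c(1, 2, 4))
  f <- fit_vb_exponent(s)
  expect_identical(f$status, "converged")
  expect_identical(f$params$beta, 1)
  expect_equal(f$params$alpha, log(2), tolerance = 1e-10)
  expect_identical(f$params$v0, 1)
})

test_that("noiseless forward simulation round-trips the parameters", {
  p <- vb_params(1, 0.3, 0.7)
  tt <- c(0, 3.04, 5.46)
  s <- lesion_series("L", tt, vb_trajectory(p, tt))
  f <- fit_vb_exponent(s)
  expect_equal(f$params$beta, 0.7, tolerance = 1e-6)
  expect_equal(f$params$alpha, 0.3, tolerance = 1e-6)
})

test_that("super-exponential triplet matches the exhaustive grid oracle", {
  s <- lesion_series("L", c(0, 1, 2), c(1, 2, 8))
  f <- fit_vb_exponent(s)
  oracle <- grid_beta_oracle(c(0, 1, 2), c(1, 2, 8))
  expect_identical(oracle$n_sign_changes, 1L)
  expect_equal(f$params$beta, oracle$roots[1], tolerance = 1e-4)
  # V2/V1 > V1/V0: acceleration beyond exponential
  expect_gt(f$params$beta, 1)
})

test_that("parameters are recovered exactly from noiseless 3-point data", {
  set.seed(11)
  cfg <- cohort_config(noise_bound = 0)
  for (i in 1:200) {
    beta <- runif(1, -2, 3.5)
    lesion <- generate_trajectory(beta, cfg)
    f <- fit_vb_exponent(lesion$series)
    expect_identical(f$status, "converged")
    expect_equal(f$params$beta, beta, tolerance = 1e-6)
    expect_equal(f$params$alpha, lesion$true_params$alpha,
                 tolerance = 1e-5 * lesion$true_params$alpha)
    # fitted trajectory passes through all three points
    expect_equal(vb_trajectory(f$params, lesion$series$times),
                 lesion$series$volumes, tolerance = 1e-8)
    # any blow-up lies beyond the last scan
    expect_gt(vb_blowup_time(f$params), max(lesion$series$times))
  }
})

test_that("the interpolation condition has a unique root on random draws", {
  set.seed(12)
  cfg <- cohort_config(noise_bound = 0)
  for (i in 1:25) {
    lesion <- generate_trajectory(runif(1, -2, 3.5), cfg)
    oracle <- grid_beta_oracle(lesion$series$times, lesion$series$volumes,
                               step = 1e-3)
    expect_identical(oracle$n_sign_changes, 1L)
  }
})

test_that("beta and lambda are invariant to volume scale; time is affine", {
  set.seed(13)
  cfg <- cohort_config(noise_bound = 0)
  for (i in 1:30) {
    lesion <- generate_trajectory(runif(1, -1.5, 3), cfg)
    tt <- lesion$series$times; vv <- lesion$series$volumes
    f <- fit_vb_exponent(lesion$series)
    cc <- runif(1, 0.2, 20)
    f_scaled <- fit_vb_exponent(lesion_series("s", tt, cc * vv))
    expect_equal(f_scaled$params$beta, f$params$beta, tolerance = 1e-7)
    expect_equal(f_scaled$params$alpha,
                 cc^(1 - f$params$beta) * f$params$alpha,
                 tolerance = 1e-6 * f_scaled$params$alpha)
    g <- growth_rates(lesion$series)
    g_scaled <- growth_rates(lesion_series("s", tt, cc * vv))
    expect_equal(g_scaled$lambda1, g$lambda1, tolerance = 1e-12)
    # shifting all times leaves (beta, alpha) unchanged
    sh <- runif(1, -30, 30)
    f_shift <- fit_vb_exponent(lesion_series("s", tt + sh, vv))
    expect_equal(f_shift$params$beta, f$params$beta, tolerance = 1e-8)
    expect_equal(f_shift$params$alpha, f$params$alpha,
                 tolerance = 1e-8 * f$params$alpha)
    # scaling all intervals by k divides alpha and both lambdas by k
    k <- runif(1, 0.3, 4)
    f_k <- fit_vb_exponent(lesion_series("s", tt * k, vv))
    g_k <- growth_rates(lesion_series("s", tt * k, vv))
    expect_equal(f_k$params$beta, f$params$beta, tolerance = 1e-7)
    expect_equal(f_k$params$alpha, f$params$alpha / k,
                 tolerance = 1e-6 * f$params$alpha / k)
    expect_equal(g_k$lambda1, g$lambda1 / k, tolerance = 1e-12)
    expect_equal(g_k$lambda2, g$lambda2 / k, tolerance = 1e-12)
  }
})

test_that("growth_rate implements the log-ratio definition", {
  expect_equal(growth_rate(1, 2, 0, 1), log(2))
  expect_equal(growth_rate(3.7, 3.7, 1, 4), 0)
  expect_equal(growth_rate(2, 1, 0, 2), -log(2) / 2)
  expect_error(growth_rate(1, 2, 1, 1), "later")
  expect_error(growth_rate(-1, 2, 0, 1), "positive")
})

test_that("lambda pair reflects acceleration: exponential, arithmetic, dichotomy", {
  g <- growth_rates(lesion_series("L", c(0, 1, 2), c(1, 2, 4)))
  expect_equal(g$lambda1, log(2))
  expect_equal(g$lambda2, log(2))
  g2 <- growth_rates(lesion_series("L", c(0, 1, 2), c(1, 2, 8)))
  expect_equal(g2$lambda2, 2 * g2$lambda1)
  # fitted beta > 1 iff lambda2 > lambda1 iff V2/V1 > (V1/V0)^r
  set.seed(14)
  cfg <- cohort_config(noise_bound = 0)
  for (i in 1:200) {
    beta <- runif(1, -2, 3.5)
    lesion <- generate_trajectory(beta, cfg)
    g <- growth_rates(lesion$series)
    f <- fit_vb_exponent(lesion$series)
    vv <- lesion$series$volumes; tt <- lesion$series$times
    r <- (tt[3] - tt[2]) / (tt[2] - tt[1])
    super <- vv[3] / vv[2] > (vv[2] / vv[1])^r
    expect_identical(f$params$beta > 1, g$lambda2 > g$lambda1)
    expect_identical(g$lambda2 > g$lambda1, super)
    if (beta > 1) expect_gt(g$lambda2, g$lambda1) else
      if (beta < 1) expect_lt(g$lambda2, g$lambda1)
  }
})

test_that("series violating the inclusion criterion are rejected with context", {
  dec <- lesion_series("L", c(0, 1, 2), c(1, 2, 1.5))
  expect_false(is_fittable(dec))
  expect_error(fit_vb_exponent(dec), "inclusion criterion")
  short <- lesion_series("L", c(0, 1), c(1, 2))
  expect_error(fit_vb_exponent(short), "3 measurements")
  expect_error(growth_rates(short), "3 measurements")
})
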