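# Rotational-variance Monte Carlo evaluation.

test_that("the rotation grid has steps^3 proper rotations and contains the identity", {
  g <- make_rotation_grid(7)
  expect_length(g$rotations, 343)
  for (R in g$rotations[c(1, 50, 343)]) {
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  expect_equal(make_rotation_grid(1)$rotations[[1]], diag(3))
  expect_equal(g$rotations[[1]], diag(3))
})

test_that("fourth-order tensor rotation satisfies the ADC transport contract", {
  set.seed(81)
  t0 <- random_psd_profile_tensor()
  g <- make_rotation_grid(3)
  R1 <- g$rotations[[5]]
  R2 <- g$rotations[[17]]
  expect_equal(rotate_tensor4(t0, diag(3)), t0, tolerance = 1e-12)
  t_iso <- embed_second_order(diag(3))
  expect_equal(rotate_tensor4(t_iso, R1), t_iso, tolerance = 1e-12)
  tr <- rotate_tensor4(t0, R1)
  for (v in asplit(random_unit_vectors(100), 1))
    expect_equal(adc_values(tr, matrix(v, 1)),
                 adc_values(t0, matrix(drop(crossprod(R1, v)), 1)),
                 tolerance = 1e-10)
  # composition
  expect_equal(rotate_tensor4(rotate_tensor4(t0, R1), R2),
               rotate_tensor4(t0, R2 %*% R1), tolerance = 1e-10)
  expect_error(rotate_tensor4(t0, diag(c(1, 1, 2))), "orthogonal")
})

test_that("simulated signals follow the Rician magnitude model", {
  set.seed(82)
  P <- random_unit_vectors(30)
  t0 <- kopt_fixture("t01")
  # noiseless limit
  clean <- simulate_signals(t0, P, acq_params(b = 1500, snr = Inf))
  expect_equal(clean, exp(-1500 * adc_values(t0, P)), tolerance = 1e-12)
  # along the fiber of the first evaluation tensor: S = exp(-1500 * 17e-4)
  expect_equal(simulate_signals(t0, matrix(c(1, 0, 0), 1),
                                acq_params(b = 1500, snr = Inf)),
               exp(-2.55), tolerance = 1e-12)
  # zero-signal Rayleigh limit: mean sigma*sqrt(pi/2)
  sigma <- 1 / 12.5
  e1 <- rnorm(1e5, 0, sigma); e2 <- rnorm(1e5, 0, sigma)
  expect_equal(mean(sqrt(e1^2 + e2^2)), sigma * sqrt(pi / 2), tolerance = 0.01)
})

test_that("signal deviation is nonnegative, S0-invariant, and zero for exact fits", {
  set.seed(83)
  P <- random_unit_vectors(30)
  t0 <- kopt_fixture("t04")
  acq <- acq_params(b = 1500, S0 = 1, snr = 12.5)
  clean <- simulate_signals(t0, P, acq_params(snr = Inf))
  fit <- fit_tensor(-log(clean) / 1500, P, 4)
  expect_equal(signal_deviation(clean, fit, P, acq), 0, tolerance = 1e-12)
  noisy <- simulate_signals(t0, P, acq)
  eta1 <- signal_deviation(noisy, coef(fit), P, acq)
  expect_gt(eta1, 0)
  # S0 scaling drops out
  acq5 <- acq_params(b = 1500, S0 = 5, snr = 12.5)
  expect_equal(signal_deviation(5 * noisy, coef(fit), P, acq5), eta1,
               tolerance = 1e-12)
  # loop oracle
  s_hat <- exp(-1500 * adc_values(coef(fit), P))
  eta_loop <- 0
  for (i in 1:30) eta_loop <- eta_loop + abs(noisy[i] - s_hat[i]) / 30
  expect_equal(eta1, eta_loop, tolerance = 1e-14)
})

test_that("the experiment is seed-deterministic and exact in the noiseless limit", {
  ges <- kopt_fixture("table1")
  grid <- make_rotation_grid(2)
  e1 <- rotational_variance_experiment(ges, kopt_fixture("t01"), grid,
                                       n_mc = 5, seed = 99)
  e2 <- rotational_variance_experiment(ges, kopt_fixture("t01"), grid,
                                       n_mc = 5, seed = 99)
  expect_identical(e1$eta_bar, e2$eta_bar)
  expect_equal(e1$mean_eta, mean(e1$eta_bar), tolerance = 1e-12)
  expect_equal(e1$sd_eta, sd(e1$eta_bar), tolerance = 1e-12)
  expect_true(all(e1$eta_bar >= 0))
  e0 <- rotational_variance_experiment(ges, kopt_fixture("t01"), grid,
                                       n_mc = 2, acq = acq_params(snr = Inf),
                                       seed = 1)
  expect_equal(e0$eta_bar, rep(0, length(grid$rotations)), tolerance = 1e-12)
})

test_that("mean signal deviation shrinks as SNR grows", {
  ges <- shared_extraction(30, seed = 1)
  grid <- make_rotation_grid(3)
  etas <- vapply(c(12.5, 25, 50), function(snr)
    rotational_variance_experiment(ges, kopt_fixture("t01"), grid, n_mc = 200,
                                   acq = acq_params(snr = snr),
                                   seed = 5)$mean_eta, 0)
  expect_true(all(diff(etas) < 0))
})
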