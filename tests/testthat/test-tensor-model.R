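# Even-order tensor ADC model, design matrices, least-squares estimation.

test_that("monomial vector puts axis directions in the right slots", {
  a_z <- monomial_vector(c(0, 0, 1), 4)
  expect_equal(a_z, c(1, rep(0, 14)))
  a_x <- monomial_vector(c(1, 0, 0), 4)
  expect_equal(a_x, c(rep(0, 14), 1))
  expect_equal(monomial_vector(c(0, 1, 0), 2), c(0, 1, 0, 0, 0, 0))
  expect_error(monomial_vector(c(1, 1, 0), 4), "unit norm")
  expect_error(monomial_vector(c(0, 0, 1), 3), "unsupported")
})

test_that("isotropic embedded tensor has unit ADC everywhere on the sphere", {
  t_iso <- embed_second_order(diag(3))
  set.seed(41)
  for (g in asplit(random_unit_vectors(25), 1))
    expect_equal(sum(monomial_vector(g, 4) * t_iso), 1, tolerance = 1e-12)
})

test_that("design matrix rows are monomial vectors and G'G matches the accumulation oracle", {
  set.seed(42)
  for (order in c(2, 4)) {
    P <- random_unit_vectors(12)
    G <- design_matrix(P, order)
    expect_equal(nrow(G), 12)
    for (i in c(1, 7, 12))
      expect_equal(G[i, ], monomial_vector(P[i, ], order))
    expect_equal(crossprod(G), info_matrix_oracle(P, order), tolerance = 1e-12)
  }
  expect_equal(design_matrix(matrix(c(1, 0, 0), 1), 4),
               matrix(monomial_vector(c(1, 0, 0), 4), 1))
  expect_error(as_direction_set(matrix(numeric(0), 0, 3)), "at least one")
})

test_that("noiseless tensor recovery round-trips through the forward model", {
  set.seed(43)
  for (order in c(2, 4)) {
    P <- random_unit_vectors(20)
    t0 <- rnorm((order + 1) * (order + 2) / 2, sd = 1e-3)
    s <- drop(design_matrix(P, order) %*% t0)
    fit <- fit_tensor(s, P, order)
    expect_equal(coef(fit), t0, tolerance = 1e-10)
    # scale equivariance of the linear estimator
    expect_equal(coef(fit_tensor(7.5 * s, P, order)), 7.5 * t0, tolerance = 1e-10)
  }
})

test_that("a square full-rank system interpolates exactly", {
  set.seed(44)
  P <- random_unit_vectors(15)
  s <- rnorm(15, sd = 1e-3)
  fit <- fit_tensor(s, P, 4)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  expect_equal(fitted(fit), s, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with a singular-design error", {
  P <- matrix(rep(c(1, 0, 0), each = 30), 30, 3)
  expect_error(fit_tensor(rnorm(30), P, 4), "singular design")
  k <- condition_numbers(P, 4)
  expect_true(k$singular)
  expect_identical(k$kappa_G, Inf)
})

test_that("second-order embedding reproduces g'Dg pointwise", {
  set.seed(45)
  D <- random_symmetric3()
  t4 <- embed_second_order(D)
  for (g in asplit(random_unit_vectors(100), 1))
    expect_equal(sum(monomial_vector(g, 4) * t4), drop(g %*% D %*% g),
                 tolerance = 1e-12)
  # diagonal D leaves every odd-power slot empty
  td <- embed_second_order(diag(c(2, 3, 5)))
  odd_slots <- c(2, 4, 6, 7, 8, 9, 11, 13, 14)
  expect_equal(td[odd_slots], rep(0, 9))
  expect_error(embed_second_order(matrix(1:9, 3)), "symmetric")
})

test_that("order-4 fit of signals from a second-order tensor matches the embedding on the sphere", {
  set.seed(46)
  A <- matrix(rnorm(9, sd = 0.02), 3, 3)
  D <- crossprod(A)
  P <- random_unit_vectors(24)
  s <- drop(design_matrix(P, 2) %*% c(diag(D), D[1, 2], D[1, 3], D[2, 3]))
  fit4 <- fit_tensor(s, P, 4)
  Peval <- random_unit_vectors(100)
  expect_equal(adc_values(coef(fit4), Peval),
               adc_values(embed_second_order(D), Peval), tolerance = 1e-10)
})

test_that("kappa_G squared equals kappa_M for full-rank designs", {
  set.seed(47)
  for (rep in 1:5) {
    P <- random_unit_vectors(18)
    k <- condition_numbers(P, 4)
    expect_false(k$singular)
    expect_equal(k$kappa_G^2, k$kappa_M, tolerance = 1e-8)
    # independent oracle: eigenvalues of G'G
    ev <- eigen(crossprod(design_matrix(P, 4)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_equal(k$kappa_M, max(ev) / min(ev), tolerance = 1e-8)
  }
})

test_that("hot_fit predict and simulate follow the Stejskal-Tanner model", {
  set.seed(48)
  P <- random_unit_vectors(20)
  t0 <- random_psd_profile_tensor() * 5e-4
  acq <- acq_params(b = 1500, S0 = 2, snr = Inf)
  s <- drop(design_matrix(P, 4) %*% t0)
  fit <- fit_tensor(s, P, 4)
  expect_equal(predict(fit, type = "adc"), s, tolerance = 1e-10)
  expect_equal(predict(fit, type = "signal", acq = acq),
               2 * exp(-1500 * s), tolerance = 1e-10)
  expect_equal(drop(simulate(fit, 1, acq = acq)), 2 * exp(-1500 * s),
               tolerance = 1e-10)
})
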