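# Affine moment parameterization M(q) of the information matrix.

test_that("the order-4 basis enumerates all 45 degree-8 moments with the documented anchors", {
  b <- moment_basis(4)
  expect_equal(nrow(b$monomials), 45)
  expect_true(all(rowSums(b$monomials) == 8))
  expect_equal(nrow(unique(b$monomials)), 45)
  # anchors and class partition
  expect_equal(b$monomials[1, ], c(8, 0, 0))    # q1 = sum x^8
  expect_equal(b$monomials[10, ], c(4, 4, 0))   # q10 = sum x^4 y^4
  expect_equal(b$class[1:3], rep("pure", 3))
  expect_equal(b$class[4:9], rep("mixed62", 6))
  expect_equal(b$class[10:12], rep("mixed44", 3))
  expect_equal(b$class[13:15], rep("mixed422", 3))
  expect_equal(b$class[16:45], rep("odd", 30))
})

test_that("the weight vector u has the 1/4/6/12 class pattern and expands (g'g)^order to 1", {
  b <- moment_basis(4)
  expect_equal(sum(b$u != 0), 15)
  expect_equal(as.vector(table(b$u[b$u != 0])[c("1", "4", "6", "12")]),
               c(3L, 6L, 3L, 3L))
  expect_equal(b$u[b$class == "odd"], rep(0, 30))
  set.seed(51)
  for (order in c(2, 4)) {
    bb <- moment_basis(order)
    for (g in asplit(random_unit_vectors(50), 1)) {
      mono <- apply(bb$monomials, 1, function(e) g[1]^e[1] * g[2]^e[2] * g[3]^e[3])
      expect_equal(sum(bb$u * mono), 1, tolerance = 1e-12)
    }
  }
})

test_that("basis matrices are nonnegative integers and the x^4y^4 matrix has the 1/16/36 pattern", {
  b <- moment_basis(4)
  expect_true(all(b$B >= 0))
  expect_true(all(b$B == round(b$B)))
  M10 <- moment_basis_matrix(10, 4)
  expect_equal(M10, t(M10))
  # entries: a pair of 1s (y^4 * x^4), a pair of 16s (4xy^3 * 4x^3y), one 36
  # (6x^2y^2 squared) on the diagonal, zeros elsewhere
  expect_equal(sort(M10[M10 != 0]), c(1, 1, 16, 16, 36))
  expect_equal(sum(diag(M10)), 36)
})

test_that("M(q(P)) equals G'G for random designs of several sizes", {
  set.seed(52)
  for (order in c(2, 4)) {
    for (N in c(1, 6, 15, 30)) {
      P <- random_unit_vectors(N)
      q <- moments_from_points(P, order)
      expect_equal(moment_matrix(q, order), info_matrix_oracle(P, order),
                   tolerance = 1e-9)
      expect_equal(sum(moment_basis(order)$u * q), N, tolerance = 1e-9 * N)
    }
  }
})

test_that("moments of elementary configurations behave as the monomial sums dictate", {
  # single axis point: all mass in q1
  q <- moments_from_points(matrix(c(1, 0, 0), 1), 4)
  expect_equal(as.numeric(q), c(1, rep(0, 44)))
  # antipodal doubling: degree-8 monomials are sign-invariant
  set.seed(53)
  P <- random_unit_vectors(9)
  expect_equal(moments_from_points(rbind(P, -P), 4),
               2 * moments_from_points(P, 4), tolerance = 1e-12)
  # linearity of the assembly under unions
  P2 <- random_unit_vectors(7)
  expect_equal(
    moment_matrix(moments_from_points(P, 4) + moments_from_points(P2, 4), 4),
    moment_matrix(moments_from_points(rbind(P, P2), 4), 4), tolerance = 1e-12)
  expect_equal(moment_matrix(rep(0, 45), 4), matrix(0, 15, 15))
})

test_that("the printed 30-direction scheme has near-zero odd moments", {
  q <- moments_from_points(kopt_fixture("table1"), 4)
  b <- moment_basis(4)
  expect_lt(max(abs(q[b$class == "odd"])), 5e-3)
  expect_lt(abs(sum(b$u * q) - 30), 1e-2)
})

test_that("the order-2 basis has 15 moments with the 1/2 weight pattern", {
  b <- moment_basis(2)
  expect_equal(nrow(b$monomials), 15)
  expect_equal(as.vector(table(b$u[b$u != 0])[c("1", "2")]), c(3L, 3L))
  expect_equal(sum(b$class == "odd"), 9)
})
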