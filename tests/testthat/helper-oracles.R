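# Shared oracles and memoized expensive fixtures for the test suite.

random_unit_vectors <- function(n) {
  P <- matrix(rnorm(3 * n), n, 3)
  P / sqrt(rowSums(P^2))
}

random_symmetric3 <- function() {
  A <- matrix(rnorm(9), 3, 3)
  (A + t(A)) / 2
}

# a random fourth-order coefficient vector with a nonnegative ADC profile
# (mixture of embedded PSD second-order tensors)
random_psd_profile_tensor <- function() {
  t_sum <- numeric(15)
  for (k in 1:3) {
    A <- matrix(rnorm(9), 3, 3)
    t_sum <- t_sum + embed_second_order(crossprod(A) / 3)
  }
  t_sum
}

# brute-force information matrix: term-by-term accumulation of a_i a_i'
info_matrix_oracle <- function(dirs, order) {
  dirs <- as_direction_set(dirs)
  p <- (order + 1) * (order + 2) / 2
  M <- matrix(0, p, p)
  for (i in seq_len(nrow(dirs))) {
    a <- monomial_vector(dirs[i, ], order)
    M <- M + tcrossprod(a)
  }
  M
}

# memoized expensive objects, computed once per test run
.shared <- new.env()

shared_design <- function(order = 4, N = 30, method = "direct") {
  key <- paste("design", order, N, method, sep = "_")
  if (is.null(.shared[[key]]))
    .shared[[key]] <- solve_koptimal(N, order, method = method)
  .shared[[key]]
}

shared_extraction <- function(N = 30, seed = 1) {
  key <- paste("extract", N, seed, sep = "_")
  if (is.null(.shared[[key]]))
    .shared[[key]] <- extract_points(shared_design(4, 30), N = N, seed = seed)
  .shared[[key]]
}
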