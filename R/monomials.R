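# Monomial bases of the even-order symmetric tensor ADC model.
#
# For order n, the diffusivity profile is d(g) = t' a(g) where a(g) stacks the
# degree-n monomials of g = (x, y, z) weighted by their multinomial
# coefficients, and t holds the distinct tensor entries. The order-4 listing is
# fixed package-wide as
#   [z^4, 4yz^3, 6y^2z^2, 4y^3z, y^4, 4xz^3, 12xyz^2, 12xy^2z, 4xy^3,
#    6x^2z^2, 12x^2yz, 6x^2y^2, 4x^3z, 4x^3y, x^4]
# (ascending lexicographic in the (x, y) exponents), and the order-2 listing as
#   [x^2, y^2, z^2, 2xy, 2xz, 2yz].
# All moment indexing, fixtures and file formats inherit these orderings.

multinom_coef <- function(e) factorial(sum(e)) / prod(factorial(e))

# exponent triples (x, y, z powers) of the a-vector, one row per slot
a_exponents <- function(order) {
  if (order == 2L) {
    matrix(c(2, 0, 0, 0, 2, 0, 0, 0, 2, 1, 1, 0, 1, 0, 1, 0, 1, 1),
           ncol = 3, byrow = TRUE)
  } else if (order == 4L) {
    e <- matrix(0, 15, 3)
    r <- 0L
    for (i in 0:4) for (j in 0:(4 - i)) {
      r <- r + 1L
      e[r, ] <- c(i, j, 4L - i - j)
    }
    e
  } else {
    stop("unsupported tensor order ", order, ": only even orders 2 and 4 are implemented")
  }
}

a_coefficients <- function(order) apply(a_exponents(order), 1, multinom_coef)

check_order <- function(order) {
  if (length(order) != 1L || !order %in% c(2, 4))
    stop("unsupported tensor order ", paste(order, collapse = ","),
         ": only even orders 2 and 4 are implemented")
  as.integer(order)
}

#' Monomial vector of the tensor ADC model
#'
#' Evaluates the model vector `a(g)` so that the apparent diffusion
#' coefficient along unit direction `g` is `d(g) = sum(t * a(g))` for a
#' coefficient vector `t`. For order 4 this is the 15-vector
#' `(z^4, 4yz^3, 6y^2z^2, 4y^3z, y^4, 4xz^3, 12xyz^2, 12xy^2z, 4xy^3,
#' 6x^2z^2, 12x^2yz, 6x^2y^2, 4x^3z, 4x^3y, x^4)`; for order 2 the 6-vector
#' `(x^2, y^2, z^2, 2xy, 2xz, 2yz)`.
#'
#' @param g numeric 3-vector of unit norm (tolerance `1e-6`).
#' @param order even tensor order, 2 or 4.
#' @return numeric vector of length 15 (order 4) or 6 (order 2).
#' @export
monomial_vector <- function(g, order = 4) {
  order <- check_order(order)
  g <- as.numeric(g)
  if (length(g) != 3L || any(!is.finite(g)))
    stop("g must be a finite 3-vector")
  if (abs(sqrt(sum(g^2)) - 1) > 1e-6)
    stop(sprintf("g must have unit norm (|g| = %.8f)", sqrt(sum(g^2))))
  e <- a_exponents(order)
  a_coefficients(order) * g[1]^e[, 1] * g[2]^e[, 2] * g[3]^e[, 3]
}

#' Design matrix of a gradient encoding scheme
#'
#' Stacks the monomial vectors of the N directions into the `N x 15`
#' (order 4) or `N x 6` (order 2) least-squares design matrix `G`, whose
#' information matrix is `M = G'G`.
#'
#' @param dirs a [as_direction_set()] matrix of N unit directions.
#' @inheritParams monomial_vector
#' @return numeric matrix with one monomial-vector row per direction.
#' @export
design_matrix <- function(dirs, order = 4) {
  order <- check_order(order)
  dirs <- as_direction_set(dirs)
  e <- a_exponents(order)
  cf <- a_coefficients(order)
  G <- matrix(1, nrow(dirs), nrow(e))
  for (j in seq_len(nrow(e)))
    G[, j] <- cf[j] * dirs[, 1]^e[j, 1] * dirs[, 2]^e[j, 2] * dirs[, 3]^e[j, 3]
  G
}

#' Evaluate an ADC profile
#'
#' @param t tensor coefficient vector (length 15 or 6).
#' @param dirs directions at which to evaluate.
#' @return numeric vector of apparent diffusion coefficients `d(g) = t'a(g)`.
#' @export
adc_values <- function(t, dirs) {
  t <- as.numeric(t)
  order <- if (length(t) == 15L) 4L else if (length(t) == 6L) 2L else
    stop("tensor coefficient vector must have length 15 (order 4) or 6 (order 2)")
  drop(design_matrix(dirs, order) %*% t)
}

#' Condition numbers of a design
#'
#' Returns both conventions: `kappa_G`, the singular-value ratio of the design
#' matrix `G`, and `kappa_M = kappa_G^2`, the eigenvalue ratio of the
#' information matrix `M = G'G`. A rank-deficient design is reported with an
#' explicit `singular` flag and infinite condition numbers rather than an
#' error.
#'
#' @inheritParams design_matrix
#' @return list with elements `kappa_G`, `kappa_M`, `singular`.
#' @export
condition_numbers <- function(dirs, order = 4) {
  G <- design_matrix(dirs, order)
  sv <- svd(G, nu = 0, nv = 0)$d
  singular <- min(sv) <= max(sv) * 1e-12
  kG <- if (singular) Inf else max(sv) / min(sv)
  list(kappa_G = kG, kappa_M = kG^2, singular = singular)
}

#' Least-squares estimation of an even-order diffusion tensor
#'
#' Fits the tensor coefficient vector `t` minimizing `||s - G t||^2`, where
#' `s` holds the normalized log-attenuations `s_i = -log(S(g_i)/S0) / b` and
#' `G` is the [design_matrix()]. The closed-form solution is
#' `t = (G'G)^{-1} G' s`.
#'
#' @param s numeric vector of N log-attenuation measurements.
#' @param dirs the N measurement directions.
#' @param order even tensor order, 2 or 4; fitting needs N >= 15 (order 4) or
#'   N >= 6 (order 2) directions in general position.
#' @return an object of class `hot_fit` with components `coefficients`,
#'   `fitted.values`, `residuals`, `order`, `dirs`, `kappa_G`.
#' @seealso [coef()], [predict.hot_fit()], [simulate.hot_fit()]
#' @export
fit_tensor <- function(s, dirs, order = 4) {
  order <- check_order(order)
  dirs <- as_direction_set(dirs)
  s <- as.numeric(s)
  if (length(s) != nrow(dirs))
    stop("length(s) must equal the number of directions")
  G <- design_matrix(dirs, order)
  sv <- svd(G, nu = 0, nv = 0)$d
  if (nrow(G) < ncol(G) || min(sv) <= max(sv) * 1e-10)
    stop(sprintf(paste0("singular design: rank %d < %d parameters; ",
                        "the %d directions do not determine an order-%d tensor"),
                 sum(sv > max(sv) * 1e-10), ncol(G), nrow(G), order))
  t_hat <- qr.coef(qr(G), s)
  fit <- drop(G %*% t_hat)
  structure(list(coefficients = unname(t_hat), fitted.values = fit,
                 residuals = s - fit, order = order, dirs = dirs,
                 kappa_G = max(sv) / min(sv)),
            class = "hot_fit")
}

#' @export
print.hot_fit <- function(x, digits = 6, ...) {
  cat(sprintf("Order-%d tensor least-squares fit (%d directions, kappa_G = %.4f)\n",
              x$order, nrow(x$dirs), x$kappa_G))
  cat("Coefficients:\n")
  print(signif(x$coefficients, digits), ...)
  invisible(x)
}

#' @export
coef.hot_fit <- function(object, ...) object$coefficients

#' @export
residuals.hot_fit <- function(object, ...) object$residuals

#' @export
fitted.hot_fit <- function(object, ...) object$fitted.values

#' Predict ADC values or diffusion-weighted signals from a fitted tensor
#'
#' @param object a `hot_fit`.
#' @param newdirs directions at which to predict (default: fit directions).
#' @param type `"adc"` for the diffusivity profile, `"signal"` for the clean
#'   Stejskal-Tanner signal `S0 * exp(-b * d(g))`.
#' @param acq [acq_params()] (needed for `type = "signal"`).
#' @param ... unused.
#' @export
predict.hot_fit <- function(object, newdirs = object$dirs,
                            type = c("adc", "signal"), acq = acq_params(), ...) {
  type <- match.arg(type)
  d <- drop(design_matrix(newdirs, object$order) %*% object$coefficients)
  if (type == "adc") d else acq$S0 * exp(-acq$b * d)
}

#' Simulate Rician-noise signal measurements from a fitted tensor
#'
#' @param object a `hot_fit`.
#' @param nsim number of replicate measurement vectors.
#' @param seed optional RNG seed.
#' @param acq [acq_params()] giving b-value, S0 and SNR.
#' @param ... unused.
#' @return `N x nsim` matrix of noisy magnitude signals.
#' @export
simulate.hot_fit <- function(object, nsim = 1, seed = NULL, acq = acq_params(), ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simulate_signals(object$coefficients, object$dirs, acq))
}

#' Embed a second-order diffusion tensor as a fourth-order profile
#'
#' Returns the 15 fourth-order coefficients `t` with
#' `sum(t * monomial_vector(g, 4)) == g' D g` for every unit `g`, using the
#' identity `g'Dg = (g'Dg)(g'g)`. This exhibits the classical Gaussian
#' diffusion tensor model as a subset of the fourth-order profile model.
#'
#' @param D symmetric 3 x 3 matrix (asymmetry beyond `1e-9` is an error).
#' @return length-15 fourth-order coefficient vector.
#' @export
embed_second_order <- function(D) {
  D <- as.matrix(D)
  if (!all(dim(D) == c(3L, 3L)) || max(abs(D - t(D))) > 1e-9)
    stop("D must be a symmetric 3 x 3 matrix")
  c(D[3, 3], 0.5 * D[2, 3], (D[3, 3] + D[2, 2]) / 6, 0.5 * D[2, 3], D[2, 2],
    0.5 * D[1, 3], D[1, 2] / 6, D[1, 3] / 6, 0.5 * D[1, 2],
    (D[3, 3] + D[1, 1]) / 6, D[2, 3] / 6, (D[1, 1] + D[2, 2]) / 6,
    0.5 * D[1, 3], 0.5 * D[1, 2], D[1, 1])
}
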