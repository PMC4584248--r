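# Moment-space parameterization of the information matrix.
#
# Entry (k, l) of a(g) a(g)' is c_k c_l times the monomial of exponent
# e_k + e_l, a homogeneous polynomial of degree 2n in g. Summing over design
# points, every entry of M = G'G is a linear combination of the distinct
# degree-2n spherical moments q_j of the design, giving the affine map
# M(q) = q_1 M_1 + ... + q_m M_m with m = 45 (order 4) or 15 (order 2).
# The basis matrices M_j are derived here by exact integer expansion, never
# hand-typed.

.koptges_cache <- new.env(parent = emptyenv())

# moment monomials of degree 2*order, grouped by symmetry class.
# Order 4 classes and ordering: q1..q3 pure (x^8 type, q1 = sum x^8),
# q4..q9 mixed62 (x^6y^2), q10..q12 mixed44 (q10 = sum x^4y^4),
# q13..q15 mixed422 (x^4y^2z^2), q16..q45 all moments with an odd exponent.
# Within each class the exponent triples are in descending lexicographic
# order. Order 2: q1..q3 pure (x^4), q4..q6 mixed22 (x^2y^2), q7..q15 odd.
moment_monomials <- function(order) {
  deg <- 2L * check_order(order)
  e <- NULL
  for (i in deg:0) for (j in (deg - i):0) e <- rbind(e, c(i, j, deg - i - j))
  cl <- apply(e, 1, function(x) {
    s <- sort(x, decreasing = TRUE)
    if (any(x %% 2 == 1)) "odd"
    else if (s[1] == deg) "pure"
    else if (deg == 8L && all(s == c(6, 2, 0))) "mixed62"
    else if (deg == 8L && all(s == c(4, 4, 0))) "mixed44"
    else if (deg == 8L) "mixed422"
    else "mixed22"
  })
  rank <- c(pure = 1, mixed62 = 2, mixed44 = 3, mixed422 = 4, mixed22 = 2, odd = 9)
  idx <- order(rank[cl], -(e[, 1] * (deg + 1)^2 + e[, 2] * (deg + 1) + e[, 3]))
  list(exponents = e[idx, , drop = FALSE], class = cl[idx])
}

#' Moment basis of the information-matrix parameterization
#'
#' Builds the affine parameterization `M(q) = sum_j q_j M_j` of the
#' information matrix in the distinct even-degree moments of the design, and
#' the weight vector `u` with `u'q = N` for any N-point unit-norm design
#' (`u_j` is the coefficient of monomial `j` in the expansion of
#' `(x^2+y^2+z^2)^order`, nonzero for the 15 (order 4) / 6 (order 2)
#' even-exponent moments only).
#'
#' @param order even tensor order, 2 or 4.
#' @return list with components `order`; `monomials` (`m x 3` exponent
#'   triples, m = 45 or 15); `class` (symmetry class of each moment: `pure`,
#'   `mixed62`, `mixed44`, `mixed422`, `mixed22`, `odd`); `u`; `B`
#'   (`d^2 x m` matrix whose column j is `vec(M_j)`); `d` (size of `M`).
#' @export
moment_basis <- function(order = 4) {
  order <- check_order(order)
  key <- paste0("basis", order)
  if (!is.null(.koptges_cache[[key]])) return(.koptges_cache[[key]])
  mm <- moment_monomials(order)
  ae <- a_exponents(order)
  ac <- a_coefficients(order)
  d <- nrow(ae)
  m <- nrow(mm$exponents)
  mono_key <- apply(mm$exponents, 1, paste, collapse = ",")
  B <- matrix(0, d * d, m)
  for (k in seq_len(d)) for (l in seq_len(d)) {
    j <- match(paste(ae[k, ] + ae[l, ], collapse = ","), mono_key)
    B[(l - 1L) * d + k, j] <- ac[k] * ac[l]
  }
  u <- apply(mm$exponents, 1, function(e)
    if (any(e %% 2 == 1)) 0 else multinom_coef(e / 2))
  basis <- list(order = order, monomials = mm$exponents, class = mm$class,
                u = u, B = B, d = d)
  .koptges_cache[[key]] <- basis
  basis
}

#' Basis matrix for one moment variable
#'
#' @param j moment index (1..45 for order 4).
#' @inheritParams moment_basis
#' @return the symmetric integer matrix `M_j`.
#' @export
moment_basis_matrix <- function(j, order = 4) {
  b <- moment_basis(order)
  matrix(b$B[, j], b$d, b$d)
}

#' Spherical moments of a direction set
#'
#' Computes `q_j = sum_i g_i^{e_j}` over the design points for every distinct
#' degree-`2*order` monomial, in the package's fixed moment ordering
#' (`q1 = sum x^8`, `q10 = sum x^4 y^4` for order 4). Satisfies `u'q = N`.
#'
#' @inheritParams design_matrix
#' @return numeric moment vector of length 45 (order 4) or 15 (order 2), with
#'   the symmetry class of each entry in `attr(, "class_label")`.
#' @export
moments_from_points <- function(dirs, order = 4) {
  b <- moment_basis(order)
  dirs <- as_direction_set(dirs)
  e <- b$monomials
  q <- vapply(seq_len(nrow(e)), function(j)
    sum(dirs[, 1]^e[j, 1] * dirs[, 2]^e[j, 2] * dirs[, 3]^e[j, 3]), 0)
  attr(q, "class_label") <- b$class
  q
}

#' Assemble the information matrix from a moment vector
#'
#' Evaluates the affine map `M(q) = sum_j q_j M_j`; for `q` the moments of a
#' point set `P` this equals `G'G` of `P` exactly.
#'
#' @param q moment vector (length 45 for order 4, 15 for order 2).
#' @inheritParams moment_basis
#' @return symmetric `15 x 15` (order 4) or `6 x 6` (order 2) matrix.
#' @export
moment_matrix <- function(q, order = 4) {
  b <- moment_basis(order)
  if (length(q) != ncol(b$B))
    stop("q must have length ", ncol(b$B), " for order ", order)
  matrix(b$B %*% as.numeric(q), b$d, b$d)
}

# mean of q over each even symmetry class, named
moment_class_means <- function(q, order = 4) {
  b <- moment_basis(order)
  cls <- setdiff(unique(b$class), "odd")
  vapply(cls, function(cl) mean(q[b$class == cl]), 0)
}
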