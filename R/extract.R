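# Recovering gradient directions from optimal moments.
#
# The optimal moment vector q* fixes 45 (order 4) moment equations in the 3N
# point coordinates, plus N unit-norm equations. The unknowns are
# parameterized as unconstrained 3-vectors normalized to the sphere inside
# the residual, which eliminates the norm equations and leaves a smooth
# nonlinear least-squares problem in R^{3N}, solved by Levenberg-Marquardt
# (minpack.lm) with an analytic Jacobian and random restarts.

#' Class-scaled moment residual of a candidate point set
#'
#' Residual `(q(P) - q_target) / N` of the moment-matching system; the `1/N`
#' scaling makes tolerances independent of the design size. Points are
#' normalized to the unit sphere before the moments are taken, so candidates
#' may be non-unit during iteration. The residual is zero iff the (unit)
#' points reproduce the target moments exactly.
#'
#' @param points `N x 3` matrix of (not necessarily unit) points.
#' @param q_target target moment vector, usually `q_star` of a
#'   [solve_koptimal()] result.
#' @param order even tensor order, 2 or 4.
#' @return numeric residual vector (length 45 for order 4, 15 for order 2).
#' @export
moment_residual <- function(points, q_target, order = 4) {
  points <- as.matrix(points)
  pts <- points / sqrt(rowSums(points^2))
  b <- moment_basis(order)
  e <- b$monomials
  q <- vapply(seq_len(nrow(e)), function(j)
    sum(pts[, 1]^e[j, 1] * pts[, 2]^e[j, 2] * pts[, 3]^e[j, 3]), 0)
  (q - as.numeric(q_target)) / nrow(points)
}

# analytic Jacobian of moment_residual w.r.t. the flattened raw coordinates
moment_residual_jac <- function(points, order) {
  points <- as.matrix(points)
  n <- nrow(points)
  nrm <- sqrt(rowSums(points^2))
  U <- points / nrm
  b <- moment_basis(order)
  e <- b$monomials
  m <- nrow(e)
  J <- matrix(0, m, 3L * n)
  for (i in seq_len(n)) {
    u <- U[i, ]
    # d mono_j / d u (guarding 0^0 and zero exponents)
    pw <- function(base, ex) ifelse(ex == 0, 1, base^ex)
    g1 <- e[, 1] * pw(u[1], e[, 1] - 1) * pw(u[2], e[, 2]) * pw(u[3], e[, 3])
    g2 <- e[, 2] * pw(u[1], e[, 1]) * pw(u[2], e[, 2] - 1) * pw(u[3], e[, 3])
    g3 <- e[, 3] * pw(u[1], e[, 1]) * pw(u[2], e[, 2]) * pw(u[3], e[, 3] - 1)
    Gu <- cbind(g1, g2, g3)
    J[, 3L * (i - 1L) + 1:3] <- Gu %*% ((diag(3) - tcrossprod(u)) / nrm[i])
  }
  J / n
}

# antipodally symmetrized, perturbed spherical start
symmetric_start <- function(N, spread = 0.08) {
  half <- ceiling(N / 2)
  P <- fibonacci_sphere(half)
  P <- rbind(P, -P)[seq_len(N), , drop = FALSE]
  P <- unclass(P) + matrix(stats::rnorm(3L * N, sd = spread), N, 3)
  P / sqrt(rowSums(P^2))
}

uniform_start <- function(N) {
  P <- matrix(stats::rnorm(3L * N), N, 3)
  P / sqrt(rowSums(P^2))
}

#' Extract gradient directions from an optimal moment vector
#'
#' Solves the moment-matching system by trust-region nonlinear least squares
#' with random restarts, returning `N` unit directions whose even-degree
#' moments reproduce `q_target`. A returned set is feasible for the original
#' (unrelaxed) design problem, which certifies the relaxation's optimum as
#' globally optimal; its design-matrix condition number therefore equals the
#' SDP optimum up to the residual tolerance. Restarts alternate between
#' uniform random points and antipodally symmetrized perturbed spherical
#' starts (the odd-moment targets are zero, which favors symmetric starts).
#' The solution is not unique: different seeds give different point sets with
#' the same information matrix.
#'
#' @param design a `koptimal_design` from [solve_koptimal()], or a raw target
#'   moment vector (then `order` and `N` must be given).
#' @param N number of directions to extract (default: the design's `N`); at
#'   least 15 for order 4.
#' @param order even tensor order (taken from `design` when available).
#' @param seed integer RNG seed controlling all restarts.
#' @param restarts maximum number of restarts (>= 1); stops at the first
#'   restart meeting `residual_tol`.
#' @param residual_tol accept when `max(abs(moment_residual))` of the
#'   class-scaled residual falls below this.
#' @param max_iterations Levenberg-Marquardt iteration cap per restart
#'   (values above 1024 are truncated to minpack's limit).
#' @return a `direction_set` with attributes `residual` (max abs scaled
#'   residual), `restart` (index of the successful restart), `seed`,
#'   `kappa_G`, and `restart_log` (per-restart residuals).
#' @examples
#' des <- solve_koptimal(N = 30, order = 4)
#' ges <- extract_points(des, seed = 1)
#' attr(ges, "kappa_G")      # ~ 1.914
#' @export
extract_points <- function(design, N = NULL, order = NULL, seed = 1L,
                           restarts = 20L, residual_tol = 1e-6,
                           max_iterations = 1000L) {
  if (inherits(design, "koptimal_design")) {
    q_target <- design$q_star
    order <- design$order
    if (is.null(N)) N <- design$N
    if (N != design$N) q_target <- q_target * N / design$N
  } else {
    q_target <- as.numeric(design)
    if (is.null(order) || is.null(N))
      stop("order and N are required when design is a raw moment vector")
    order <- check_order(order)
  }
  p_min <- (order + 1) * (order + 2) / 2
  if (N < p_min) stop("N must be at least ", p_min, " for order ", order)
  if (restarts < 1L) stop("restarts must be >= 1")
  set.seed(seed)
  maxit <- min(as.integer(max_iterations), 1024L)
  # minpack requires at least as many residuals as parameters; the moment
  # system is underdetermined for N > 15, so pad with structural zeros (the
  # minimizer is unchanged, LM damping handles the rank deficiency)
  n_mom <- nrow(moment_basis(order)$monomials)
  pad <- max(0L, 3L * N - n_mom)
  best <- NULL
  best_res <- Inf
  log_res <- numeric(0)
  for (r in seq_len(restarts)) {
    P0 <- if (r %% 2L == 1L) uniform_start(N) else symmetric_start(N)
    fit <- minpack.lm::nls.lm(
      par = as.vector(t(P0)),
      fn = function(x) c(moment_residual(matrix(x, ncol = 3, byrow = TRUE),
                                         q_target, order), numeric(pad)),
      jac = function(x) rbind(
        moment_residual_jac(matrix(x, ncol = 3, byrow = TRUE), order),
        matrix(0, pad, 3L * N)),
      control = minpack.lm::nls.lm.control(maxiter = maxit, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 0))
    P <- matrix(fit$par, ncol = 3, byrow = TRUE)
    res <- max(abs(moment_residual(P, q_target, order)))
    log_res[r] <- res
    if (res < best_res) {
      best_res <- res
      best <- P / sqrt(rowSums(P^2))
      best_r <- r
    }
    if (res < residual_tol) break
  }
  if (best_res >= residual_tol)
    stop(sprintf(paste0("point extraction did not reach residual tolerance %g ",
                        "in %d restarts (best residual %.3g)"),
                 residual_tol, restarts, best_res))
  out <- as_direction_set(best, tol = 1e-9)
  attr(out, "residual") <- best_res
  attr(out, "restart") <- best_r
  attr(out, "seed") <- seed
  attr(out, "kappa_G") <- condition_numbers(out, order)$kappa_G
  attr(out, "restart_log") <- log_res
  out
}
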