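# K-optimal design by semidefinite programming.
#
# The relaxed design problem is
#     min_q  kappa(M(q))   s.t.  M(q) >= 0,  u'q = N,
# a quasiconvex problem. Two equivalent routes are implemented:
#   * line_search: for a fixed scalar c the feasibility-style LMI
#         min alpha  s.t.  M(q) >= 0,  I <= c M(q) <= alpha I,  u'q = N
#     is a semidefinite program; the optimum over c is found by a geometric
#     sweep followed by golden-section refinement (the reference procedure).
#   * direct: kappa is scale-invariant, so a single SDP
#         min alpha  s.t.  I <= M(q) <= alpha I
#     solves the problem after rescaling q to satisfy u'q = N.
# Both run on the package's dense log-det barrier interior-point solver below
# (the problems are small: <= 46 variables, 15 x 15 blocks).

# ---- generic barrier solver -------------------------------------------------
# minimize c'x subject to F0_b + sum_i x_i F_bi >= 0 for each block b.
# blocks: list of list(d, F0v = vec(F0), FA = d^2 x n matrix of vec(F_i)).
# x0 must be strictly feasible. Path following: minimize t*c'x + phi(x) by
# damped Newton, t <- mu*t until (sum of block sizes)/t < gap_tol.
sdp_barrier <- function(blocks, cvec, x0, gap_tol = 1e-9, mu = 20,
                        t0 = 1, max_outer = 60L) {
  n <- length(x0)
  Fx <- function(x, b) matrix(b$F0v + b$FA %*% x, b$d, b$d)
  for (b in blocks) {
    ev <- eigen(Fx(x0, b), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      return(list(x = x0, status = "infeasible_start", gap = Inf, newton = 0L))
  }
  m_total <- sum(vapply(blocks, `[[`, 0, "d"))
  barrier_val <- function(x, t) {
    s <- t * sum(cvec * x)
    for (b in blocks) {
      ch <- tryCatch(chol(Fx(x, b)), error = function(e) NULL)
      if (is.null(ch)) return(Inf)
      s <- s - 2 * sum(log(diag(ch)))
    }
    s
  }
  x <- x0
  t <- t0
  newton_total <- 0L
  for (outer in seq_len(max_outer)) {
    for (it in 1:200) {
      g <- t * cvec
      H <- matrix(0, n, n)
      for (b in blocks) {
        d <- b$d
        ch <- chol(Fx(x, b))
        W <- chol2inv(ch)
        g <- g - as.vector(crossprod(b$FA, as.vector(W)))
        WF <- W %*% matrix(b$FA, d, d * n)                      # [W F_1 ... W F_n]
        P <- matrix(WF, d * d, n)                               # vec(W F_i)
        Q <- matrix(aperm(array(WF, c(d, d, n)), c(2, 1, 3)), d * d, n)  # vec(F_i W)
        H <- H + crossprod(P, Q)
      }
      H <- (H + t(H)) / 2
      dx <- tryCatch(-solve(H, g),
                     error = function(e) -solve(H + 1e-11 * sum(diag(H)) / n * diag(n), g))
      lam2 <- -sum(g * dx)
      newton_total <- newton_total + 1L
      if (!is.finite(lam2) || lam2 < 1e-11) break
      f0 <- barrier_val(x, t)
      st <- 1
      while (barrier_val(x + st * dx, t) > f0 - 0.25 * st * lam2 && st > 1e-13)
        st <- st / 2
      if (st <= 1e-13) break
      x <- x + st * dx
    }
    if (m_total / t < gap_tol) break
    t <- t * mu
  }
  list(x = x, status = "optimal", gap = m_total / t, newton = newton_total)
}

nullspace_of <- function(u) qr.Q(qr(matrix(u, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]

#' Deterministic quasi-uniform points on the sphere (Fibonacci lattice)
#'
#' Used for strictly feasible interior-point starts and as reference designs
#' in tests; not an optimal scheme itself.
#'
#' @param n number of points.
#' @return `direction_set` of n points.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  as_direction_set(cbind(r * cos(phi), r * sin(phi), z), tol = 1e-9)
}

# E-optimal-style interior start: maximize lambda_min(M(q)) s.t. u'q = 1.
# Cached per order; scaling by N gives a strictly feasible point for any
# feasible fixed-c LMI.
eopt_start <- function(order) {
  key <- paste0("eopt", order)
  if (!is.null(.koptges_cache[[key]])) return(.koptges_cache[[key]])
  b <- moment_basis(order)
  m <- ncol(b$B)
  q_p <- b$u / sum(b$u^2)
  Z <- nullspace_of(b$u)
  vecI <- as.vector(diag(b$d))
  P <- fibonacci_sphere(200L)
  q_ref <- moments_from_points(P, order) / 200
  lam_ref <- min(eigen(moment_matrix(q_ref, order), symmetric = TRUE,
                       only.values = TRUE)$values)
  blocks <- list(list(d = b$d, F0v = as.vector(b$B %*% q_p),
                      FA = cbind(b$B %*% Z, -vecI)))
  x0 <- c(crossprod(Z, q_ref - q_p), 0.5 * lam_ref)
  sol <- sdp_barrier(blocks, c(rep(0, m - 1L), -1), x0, gap_tol = 1e-7)
  q <- q_p + drop(Z %*% sol$x[seq_len(m - 1L)])
  lam <- min(eigen(moment_matrix(q, order), symmetric = TRUE,
                   only.values = TRUE)$values)
  out <- list(q1 = q, lambda_min1 = lam)
  .koptges_cache[[key]] <- out
  out
}

#' Fixed-c LMI subproblem of the K-optimal design
#'
#' For a fixed nonnegative scalar `c` solves the linear matrix inequality
#' problem `min alpha` subject to `M(q) >= 0`, `I <= c M(q) <= alpha I` and
#' `u'q = N`. The K-optimal condition number is the minimum of this optimum
#' over `c`. Infeasible values of `c` (including `c = 0`, for which
#' `I <= 0` is impossible) are reported with a flag, not an error.
#'
#' @param c nonnegative scalar (the `1/lambda_min` scale of the bilinear
#'   formulation).
#' @param N number of measurements.
#' @param order even tensor order, 2 or 4.
#' @param gap_tol interior-point duality-gap tolerance.
#' @return list with `alpha` (optimum, `Inf` if infeasible), `kappa_M`
#'   (realized eigenvalue ratio of `M(q)`), `q`, `status`, `c`.
#' @export
solve_fixed_c <- function(c, N, order = 4, gap_tol = 1e-9) {
  order <- check_order(order)
  if (N < 1) stop("N must be >= 1")
  infeasible <- list(alpha = Inf, kappa_M = Inf, q = NULL,
                     status = "infeasible", c = c)
  if (c <= 0) return(infeasible)
  b <- moment_basis(order)
  es <- eopt_start(order)
  if (c * N * es$lambda_min1 <= 1 + 1e-7) return(infeasible)
  m <- ncol(b$B)
  q_p <- N * b$u / sum(b$u^2)
  Z <- nullspace_of(b$u)
  vecI <- as.vector(diag(b$d))
  BZ <- b$B %*% Z
  F0 <- as.vector(b$B %*% q_p)
  zero_col <- rep(0, b$d^2)
  blocks <- list(
    list(d = b$d, F0v = F0, FA = cbind(BZ, zero_col)),
    list(d = b$d, F0v = c * F0 - vecI, FA = cbind(c * BZ, zero_col)),
    list(d = b$d, F0v = -c * F0, FA = cbind(-c * BZ, vecI)))
  q0 <- N * es$q1
  lam <- eigen(moment_matrix(q0, order), symmetric = TRUE, only.values = TRUE)$values
  x0 <- c(crossprod(Z, q0 - q_p), 1.5 * c * max(lam))
  sol <- sdp_barrier(blocks, c(rep(0, m - 1L), 1), x0, gap_tol = gap_tol)
  if (sol$status != "optimal") return(infeasible)
  q <- q_p + drop(Z %*% sol$x[seq_len(m - 1L)])
  ev <- eigen(moment_matrix(q, order), symmetric = TRUE, only.values = TRUE)$values
  list(alpha = sol$x[m], kappa_M = max(ev) / min(ev), q = q,
       status = "optimal", c = c)
}

#' Control parameters for the K-optimal solver
#'
#' @param gap_tol final interior-point duality-gap tolerance.
#' @param search_gap_tol looser gap tolerance used during the line search.
#' @param sweep_range multiplicative range of the initial geometric sweep in
#'   `c`, scaled by `15/N`.
#' @param sweep_points number of sweep grid points.
#' @param golden_tol stop the golden-section refinement once the spread of
#'   the bracketed `alpha` values falls below this (absolute).
#' @param max_golden iteration cap for the golden-section phase.
#' @param mu barrier parameter multiplier.
#' @export
kopt_control <- function(gap_tol = 1e-9, search_gap_tol = 1e-6,
                         sweep_range = c(1e-2, 1e3), sweep_points = 25L,
                         golden_tol = 1e-5, max_golden = 40L, mu = 20) {
  list(gap_tol = gap_tol, search_gap_tol = search_gap_tol,
       sweep_range = sweep_range, sweep_points = sweep_points,
       golden_tol = golden_tol, max_golden = max_golden, mu = mu)
}

#' Solve the K-optimal gradient-scheme design problem
#'
#' Minimizes the condition number of the information matrix `M(q)` over the
#' relaxed moment space (subject to `M(q)` positive semidefinite and
#' `u'q = N`), returning the optimal moment vector and condition number.
#' `method = "line_search"` is the reference procedure (geometric sweep plus
#' golden-section line search in `c` over the fixed-c LMI optima,
#' [solve_fixed_c()]); `method = "direct"` exploits scale invariance of the
#' condition number to solve a single SDP `min alpha, I <= M(q) <= alpha I`
#' and rescales. The two agree to well within `1e-3` on `alpha`.
#'
#' The optimum is independent of `N` and the optimal moments are proportional
#' to `N`: for order 4 the condition number of `M` is about 3.664 (so about
#' 1.914 for the design matrix), with equal moments within each even symmetry
#' class and zero odd moments; for order 2 the design-matrix optimum is
#' `sqrt(7)/2 ~ 1.323`.
#'
#' @param N number of measurements; at least 15 (order 4) or 6 (order 2).
#' @param order even tensor order, 2 or 4.
#' @param method `"direct"` or `"line_search"`.
#' @param control see [kopt_control()].
#' @return object of class `koptimal_design`: a list with `order`, `N`,
#'   `method`, `q_star`, `alpha_star` (realized condition number of
#'   `M(q_star)`), `kappa_G_star = sqrt(alpha_star)`, `c_star`
#'   (`1/lambda_min(M(q_star))`; for the line search, the minimizing `c`),
#'   `class_values` (mean optimal moment per even symmetry class),
#'   `class_ratios` (`N / class_values`), `odd_max`, and `diagnostics`.
#' @examples
#' des <- solve_koptimal(N = 30, order = 4)
#' des$kappa_G_star          # ~ 1.914
#' des$class_ratios          # ~ (4.525, 101.84, 248.1, 1244.7)
#' @export
solve_koptimal <- function(N, order = 4, method = c("direct", "line_search"),
                           control = kopt_control()) {
  order <- check_order(order)
  method <- match.arg(method)
  p <- (order + 1) * (order + 2) / 2
  if (N < p) stop("N must be at least ", p, " for order ", order)
  b <- moment_basis(order)
  t_start <- proc.time()[3]

  if (method == "direct") {
    m <- ncol(b$B)
    vecI <- as.vector(diag(b$d))
    blocks <- list(
      list(d = b$d, F0v = -vecI, FA = cbind(b$B, rep(0, b$d^2))),
      list(d = b$d, F0v = rep(0, b$d^2), FA = cbind(-b$B, vecI)))
    P0 <- fibonacci_sphere(10L * p)
    q0 <- moments_from_points(P0, order)
    ev <- eigen(moment_matrix(q0, order), symmetric = TRUE, only.values = TRUE)$values
    q0 <- q0 * 1.5 / min(ev)
    x0 <- c(q0, 1.2 * 1.5 * max(ev) / min(ev))
    sol <- sdp_barrier(blocks, c(rep(0, m), 1), x0,
                       gap_tol = control$gap_tol, mu = control$mu)
    if (sol$status != "optimal") stop("SDP solver failed: ", sol$status)
    q <- sol$x[seq_len(m)]
    q <- q * N / sum(b$u * q)
    diag_info <- list(status = sol$status, gap = sol$gap, newton = sol$newton,
                      solves = 1L)
    c_star <- NULL
  } else {
    sweep_c <- exp(seq(log(control$sweep_range[1]), log(control$sweep_range[2]),
                       length.out = control$sweep_points)) * (p / N)
    sweep_a <- vapply(sweep_c, function(cc)
      solve_fixed_c(cc, N, order, gap_tol = control$search_gap_tol)$alpha, 0)
    if (all(!is.finite(sweep_a)))
      stop("fixed-c LMI infeasible over the entire sweep range")
    i <- which.min(sweep_a)
    lo <- log(sweep_c[max(i - 1L, 1L)])
    hi <- log(sweep_c[min(i + 1L, length(sweep_c))])
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f <- function(lc) solve_fixed_c(exp(lc), N, order,
                                    gap_tol = control$search_gap_tol)$alpha
    f1 <- f(x1); f2 <- f(x2)
    n_solves <- length(sweep_c) + 2L
    for (it in seq_len(control$max_golden)) {
      if (is.finite(f1) && is.finite(f2) &&
          abs(f1 - f2) < control$golden_tol && (hi - lo) < 0.5) break
      if (!is.finite(f1) || (is.finite(f2) && f2 < f1)) {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- f(x2)
      } else {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- f(x1)
      }
      n_solves <- n_solves + 1L
    }
    c_star <- exp(if (f1 < f2) x1 else x2)
    final <- solve_fixed_c(c_star, N, order, gap_tol = control$gap_tol)
    if (final$status != "optimal") stop("fixed-c LMI failed at c = ", c_star)
    q <- final$q
    diag_info <- list(status = "optimal", gap = NA_real_, newton = NA_integer_,
                      solves = n_solves + 1L)
  }

  M <- moment_matrix(q, order)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  alpha <- max(ev) / min(ev)
  odd <- b$class == "odd"
  res <- list(order = order, N = N, method = method, q_star = q,
              alpha_star = alpha, kappa_G_star = sqrt(alpha),
              c_star = if (is.null(c_star)) 1 / min(ev) else c_star,
              class_values = moment_class_means(q, order),
              class_ratios = N / moment_class_means(q, order),
              odd_max = max(abs(q[odd])),
              u_residual = sum(b$u * q) - N,
              diagnostics = c(diag_info, time = proc.time()[3] - t_start))
  class(res) <- "koptimal_design"
  res
}

#' @export
print.koptimal_design <- function(x, ...) {
  cat(sprintf("K-optimal design, order %d, N = %d (method: %s)\n",
              x$order, x$N, x$method))
  cat(sprintf("  kappa(M) = %.6f   kappa(G) = %.6f\n", x$alpha_star, x$kappa_G_star))
  cat("  optimal moments by symmetry class (value, N/value):\n")
  for (cl in names(x$class_values))
    cat(sprintf("    %-8s %12.6f %12.4f\n", cl, x$class_values[cl], x$class_ratios[cl]))
  cat(sprintf("  max |odd moment| = %.3g\n", x$odd_max))
  invisible(x)
}

#' @export
summary.koptimal_design <- function(object, ...) {
  structure(list(design = object), class = "summary.koptimal_design")
}

#' @export
print.summary.koptimal_design <- function(x, ...) {
  print(x$design)
  d <- x$design$diagnostics
  cat(sprintf("  solver: %s, gap %.2g, %s Newton steps, %d SDP solve(s), %.2f s\n",
              d$status, d$gap, format(d$newton), d$solves, d$time))
  cat(sprintf("  u'q - N = %.3g\n", x$design$u_residual))
  invisible(x)
}

#' @export
coef.koptimal_design <- function(object, ...) object$q_star

#' Check the N-scaling law of K-optimal designs
#'
#' The optimal moment vector is proportional to `N` while the optimal
#' condition number is independent of `N`: `q*(wN) = w q*(N)`. Compares two
#' solved designs of the same order.
#'
#' @param result_1,result_2 `koptimal_design` objects of the same order.
#' @param tol relative tolerance per even class and on `alpha`.
#' @return list with `w` (the size ratio), `alpha_match`, `class_match`,
#'   per-class relative errors, and overall `ok`.
#' @export
verify_scaling <- function(result_1, result_2, tol = 1e-3) {
  stopifnot(inherits(result_1, "koptimal_design"),
            inherits(result_2, "koptimal_design"),
            result_1$order == result_2$order)
  w <- result_2$N / result_1$N
  class_err <- abs(result_2$class_values / (w * result_1$class_values) - 1)
  alpha_err <- abs(result_2$alpha_star / result_1$alpha_star - 1)
  list(w = w, alpha_err = alpha_err, class_err = class_err,
       alpha_match = alpha_err < tol, class_match = all(class_err < tol),
       ok = alpha_err < tol && all(class_err < tol))
}
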