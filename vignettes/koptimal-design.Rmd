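---
title: "Condition-number-optimal gradient encoding schemes for tensor profile imaging"
author: "koptges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-number-optimal gradient encoding schemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koptges)
```

## The design problem

Diffusion-weighted MRI probes tissue microstructure by measuring signal
attenuation along a set of gradient directions $g_1,\dots,g_N$ on the unit
sphere (the *gradient encoding scheme*, GES). Under the Stejskal–Tanner
model the signal is $S(g_i) = S_0 \exp(-b\, d(g_i))$, where $d(g)$ is the
apparent diffusion coefficient (ADC) profile. Gaussian diffusion gives the
classical quadratic profile $d(g) = g^\top D g$; in voxels with crossing
fibers an even-order symmetric tensor of order 4 is a better model:
$d(g) = t^\top a(g)$, with $t \in \mathbb{R}^{15}$ the distinct tensor
entries and $a(g)$ the degree-4 monomials of $g$ weighted by their
multinomial coefficients (`monomial_vector()`; the package fixes the
$z^4$-first, $x^4$-last ordering throughout).

Given $N$ log-attenuation measurements
$s_i = -\ln(S(g_i)/S_0)/b$, the tensor is the linear least-squares solution
$\hat t = (G^\top G)^{-1} G^\top s$, where $G$ stacks the $a(g_i)$
(`design_matrix()`, `fit_tensor()`). The estimator covariance is
proportional to $M^{-1}$ with $M = G^\top G$ the *information matrix*, so
the noise amplification of the fit is governed by the condition number
$\kappa(M) = \lambda_{\max}/\lambda_{\min}$. A *K-optimal* design minimizes
it. Because the printed literature mixes the two conventions, the package
always reports both $\kappa(G) = \sigma_{\max}/\sigma_{\min}$ and
$\kappa(M) = \kappa(G)^2$ (`condition_numbers()`).

## Moment parameterization and convex relaxation

Minimizing $\kappa(M)$ over the directions themselves is nonconvex. Every
entry of $M$, however, is a sum over design points of a degree-8 monomial
(order 4), so $M$ is affine in the 45 distinct spherical moments
$q_j = \sum_i g_i^{e_j}$ of the design: $M(q) = \sum_j q_j M_j$
(`moment_basis()`, `moment_matrix()`). The basis matrices are derived by
exact integer expansion of $a(g)a(g)^\top$, never transcribed by hand. The
moments split into symmetry classes — three *pure* ($\sum x^8$-type), six
$\sum x^6 y^2$-type, three $\sum x^4y^4$-type, three $\sum x^4y^2z^2$-type,
and thirty with at least one odd exponent — with the anchors
$q_1 = \sum x_i^8$ and $q_{10} = \sum x_i^4 y_i^4$. Within each class the
package orders exponent triples descending-lexicographically; the class
partition and anchors, not the within-class order, carry all reported
results. Expanding $(x^2+y^2+z^2)^4 = 1$ on the sphere turns the unit-norm
constraints into one linear equality $u^\top q = N$, where $u$ holds the
multinomial weights (1, 4, 6, 12 over the even classes).

The relaxed problem
$$\min_q \kappa(M(q)) \quad \text{s.t.}\quad M(q) \succeq 0,\; u^\top q = N$$
is quasiconvex. Two solution routes are implemented
(`solve_koptimal()`):

* **line_search** — for a fixed scalar $c$, minimizing $\alpha$ subject to
  $M(q) \succeq 0$, $I \preceq c\,M(q) \preceq \alpha I$, $u^\top q = N$ is
  a semidefinite program (`solve_fixed_c()`); the design optimum is the
  minimum of these optima over $c$. The package sweeps 25 geometrically
  spaced values of $c$ over $[10^{-2}, 10^3] \cdot (15/N)$ and refines with
  golden-section search on $\log c$ until the bracketed optima agree to
  $10^{-5}$. The profile $\alpha^*_c$ is flat at the optimum over a ray of
  $c$ values (scaling $q$ up preserves both constraints), which makes the
  reported minimizing $c^\star$ non-unique but the optimum itself robust.
* **direct** — $\kappa$ is scale-invariant, so a single SDP
  $\min \alpha$ s.t. $I \preceq M(q) \preceq \alpha I$ followed by
  rescaling to $u^\top q = N$ gives the same optimum in one solve. This is
  the default; the line search is retained as the reference formulation and
  the two are compared in the test suite.

The strict inequality $I \prec c M(q)$ is implemented as the closed
constraint (the optimum is attained on the boundary, standard SDP
practice).

### The interior-point solver

No semidefinite-programming backend is available to R here, and the
problems are tiny (at most 46 variables, $15\times 15$ blocks), so the
package carries its own dense log-det barrier path-following solver: damped
Newton steps on $t\,c^\top x - \sum_b \log\det F_b(x)$ with backtracking
line search, $t$ increased geometrically (factor 20) until the barrier gap
$m/t$ falls below `gap_tol` ($10^{-9}$ final, $10^{-6}$ during the line
search — first-order accuracy well beyond the four to five significant
digits of the published optima). Strictly feasible starts come from
deterministic Fibonacci-lattice designs (`fibonacci_sphere()`), and for the
fixed-$c$ subproblem from a cached max-$\lambda_{\min}$ (E-optimal-style)
solve that also decides feasibility of a given $c$. All settings are
deterministic, so repeated runs agree to solver tolerance.

At the optimum the solver recovers, for any $N$, equal moments within each
even class, zero odd moments (to $10^{-10}$ and far below), moments
proportional to $N$, and an optimal $\kappa(M)$ independent of $N$ — about
3.663 for order 4 and exactly $7/4$ for order 2 ($\kappa(G) = \sqrt{7}/2
\approx 1.323$, the classical DTI result; the order-2 path uses the same
code on the 6-parameter quadratic model).

## Extracting design points

The optimal $q^\star$ must then be realized by $N$ unit vectors: 45 moment
equations plus $N$ unit-norm equations in $3N$ unknowns. The package
eliminates the norm equations by normalizing inside the residual
(`moment_residual()`, scaled by $1/N$ per entry so tolerances are
size-independent) and minimizes the squared residual with
Levenberg–Marquardt (`minpack.lm`) using an analytic Jacobian
(`extract_points()`). Because minpack requires at least as many residuals
as parameters, the system is padded with structural zero rows for
$N > 15$ — the minimizer is unchanged and the trust region handles the rank
deficiency. Restarts alternate uniform random sphere points with
antipodally symmetrized, perturbed Fibonacci configurations; a fixed seed
drives all restarts, and the first restart reaching
`residual_tol = 1e-6` is returned (defaults: 20 restarts, 1024 iterations
each).

A returned point set is feasible for the *original* nonconvex problem, so
its condition number certifies the relaxation bound as globally attained.
At $N = 30$ roughly a third of restarts converge to machine-zero residual
and the achieved $\kappa(G)$ matches the SDP optimum to six digits.
Solutions are non-unique: different seeds give genuinely different point
sets with identical information matrices, and negating any subset of
directions changes nothing (all moments have even total degree — note this
also means antipodal symmetrization does *not* annihilate the odd-class
moments of an arbitrary set; what does is closure under per-axis sign
flips).

**A realizability caveat at small $N$.** Counting parameters suggests
$N = 15$ (45 unknowns, 45 equations) should admit solutions, and unions of
optimal sets are again optimal, so one would like minimal building blocks.
In our experiments, however, trust-region searches from both start
families stall at a nonzero residual floor for every size we tried between
15 and 28 — the floor shrinking steadily with $N$ (about $1.5\times
10^{-3}$ at 15 down to $1\times 10^{-4}$ at 28) — while $N = 30$ converges
to machine-zero residual in a handful of restarts and every size from 32
upward succeeds on the first restart (29 and 31 land within about
$10^{-5}$, suggesting thin basins right at the onset). Direct minimization of
$\kappa(G)$ over 15-point sets independently bottoms out near 2.8, far
above the relaxation bound 1.914, so at the minimal size the gap is not a
solver artifact: no 15-point design appears to come close to the bound,
let alone realize $q^\star$. For order 2 the analogous minimal extraction
($N = 6$) succeeds immediately. We therefore treat exact equal-weight
realizability of the order-4 optimum below $N \approx 30$ as an open
question rather than a guarantee: the extraction interface accepts any
$N \ge 15$ and reports its best residual honestly in the convergence error
when the tolerance is not met.

## The rotational-variance evaluation

Estimation quality should not depend on how the tissue happens to be
oriented. The package quantifies this (`rotational_variance_experiment()`)
by rotating a ground-truth tensor over a grid of orientations and measuring
the *signal deviation*
$$\eta = \frac{1}{N}\sum_{i=1}^{N} \frac{|S(g_i) - \hat S(g_i)|}{S_0},$$
between the measured (noisy) signals and those reconstructed from the
fitted tensor. The absolute value is essential: the signed mean is near
zero by construction. Per rotation, `n_mc` Monte Carlo trials of
simulate–fit–evaluate are averaged to $\bar\eta(R)$; the mean and standard
deviation of $\bar\eta$ over the grid summarize accuracy and rotational
variance.

Choices a user should know:

* **Rotation grid** (`make_rotation_grid()`): $R = R_x(\theta) R_y(\phi)
  R_z(\psi)$ with `steps = 7` equispaced values of each angle over
  $[0, \pi)$ including 0, hence 343 rotations containing the identity. The
  grid convention is configurable; the reported two-digit summaries are
  insensitive to it.
* **Noise** (`simulate_signals()`): Rician magnitude
  $\sqrt{(S+\varepsilon_1)^2 + \varepsilon_2^2}$ with independent Gaussian
  $\varepsilon_k$, $\sigma = S_0/\mathrm{SNR}$ — the standard
  magnitude-MR model. Defaults: $b = 1500$ s/mm², $\mathrm{SNR} = 12.5$,
  $S_0 = 1$ ($\eta$ is $S_0$-invariant).
* **Fitting**: the plain unconstrained least-squares estimator on
  log-attenuations, with measured signals clipped below at
  $10^{-12} S_0$ before the logarithm (Rician samples can be arbitrarily
  small; the fit reuses a pseudoinverse precomputed once per scheme).
* **Ground truths**: ten published fourth-order tensors
  (`kopt_fixture("t01")` … `"t10"`, stored as multiples of $10^{-4}$
  mm²/s): single fibers, two crossing fibers at various angles and lobe
  weights, and three perpendicular fibers.
* **Problem sizes**: the full experiment (343 rotations × 200 trials × 30
  directions, i.e. about $2\times 10^6$ simulated signals and
  $6.9\times 10^4$ tensor fits) runs in a few seconds because each
  rotation's trials are vectorized into matrix operations; smaller grids
  (`steps = 2` or 3) are used in fast unit tests.

Everything is driven by one integer seed; identical seeds give
bit-identical results.

What the simulation does and does not emulate: signals are generated from
the same tensor model class that is fitted, so $\eta$ isolates noise
propagation through the design — exactly the quantity K-optimality
controls — and contains no model mismatch, no spatial correlation, no
eddy-current or motion artifacts, and no Rician floor correction in the
estimator. Conclusions about real acquisitions therefore concern the
relative merit of schemes, not absolute error levels.

## Known limitations

* Orders beyond 4 are architecturally possible (the basis generator is
  order-generic) but neither exercised nor validated; order 2 and 4 only.
* Only the condition-number criterion is implemented — no A-, D- or
  E-optimality, and no positivity-constrained tensor estimation.
* Extraction at the minimal sizes $N = 15,\dots,19$ may fail to meet the
  residual tolerance, as discussed above.
* The moment vector returned for a rank-deficient or near-singular input
  design is well-defined, but condition numbers are reported as infinite
  with a `singular` flag rather than estimated.

## A worked session

```{r, eval = FALSE}
des <- solve_koptimal(N = 30, order = 4)         # ~1 s
des$kappa_G_star                                 # 1.913971
ges <- extract_points(des, seed = 1)             # ~1 s
attr(ges, "kappa_G")                             # 1.913971
ev <- rotational_variance_experiment(ges, kopt_fixture("t01"), seed = 1)
c(ev$mean_eta, ev$sd_eta)                        # 0.0492, 0.00091
```
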