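Package: koptges
Title: K-Optimal Gradient Encoding Scheme Design for Diffusion Tensor Profile Imaging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs gradient encoding schemes for diffusion MRI by minimizing the
    condition number of the least-squares information matrix (K-optimal experiment
    design) for even-order symmetric tensor models of the apparent diffusion
    coefficient profile. The nonconvex design problem is relaxed to a semidefinite
    program through an affine parameterization of the information matrix in the
    even-degree spherical moments of the design, and solved with a log-det barrier
    interior-point method. Unit gradient directions are recovered from the optimal
    moments by nonlinear least-squares moment matching, and schemes are evaluated
    with Rician-noise Monte Carlo simulations of rotational variance in signal
    deviation. Supports the classical second-order diffusion tensor and the
    fourth-order tensor profile model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
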