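# Named fixtures: reference direction sets and evaluation tensors.
#
# "table1" is a published 30-direction K-optimal scheme for fourth-order
# estimation and "table2" a 6-direction K-optimal scheme for second-order
# DTI, both printed to four decimals. "t01".."t10" are ten fourth-order
# ground-truth tensors used in the rotational-variance evaluation (stored as
# multiples of 1e-4 mm^2/s and returned in mm^2/s): t01-t03 single fibers,
# t04-t09 two crossing fibers with varying angle and lobe weights, t10 three
# perpendicular fibers.

.table1_points <- matrix(c(
   0.1514, -0.9883, -0.0161,
   0.4840,  0.1736, -0.8576,
  -0.5357,  0.0645, -0.8419,
  -0.0633, -0.1941,  0.9789,
  -0.4457, -0.8893, -0.1024,
  -0.8564, -0.4798,  0.1908,
   0.9998,  0.0123,  0.0169,
   0.8391, -0.5377, -0.0829,
  -0.2315, -0.3334, -0.9139,
   0.3072, -0.9185, -0.2490,
   0.3527, -0.8791,  0.3207,
  -0.0048,  1.0000, -0.0068,
   0.9960, -0.0292,  0.0842,
   0.8959, -0.1044, -0.4317,
  -0.0111,  0.0185,  0.9998,
  -0.1289,  0.4227, -0.8970,
   0.9988, -0.0129,  0.0481,
   0.0341,  0.9994, -0.0089,
   0.0851,  0.8468,  0.5251,
   0.9867,  0.0077, -0.1623,
  -0.9125,  0.2478, -0.3253,
  -0.0163,  0.0245,  0.9996,
   0.0160,  0.0349,  0.9993,
   0.3204, -0.3626, -0.8751,
  -0.1819, -0.8503,  0.4938,
   0.0248,  0.9996, -0.0146,
   0.1318,  0.9903, -0.0441,
  -0.0149, -0.0427, -0.9990,
   0.8780,  0.3205,  0.3556,
   0.9973,  0.0662, -0.0304), ncol = 3, byrow = TRUE)

.table2_points <- matrix(c(
   0.9096,  0.0000,  0.4155,
   0.0000,  0.4155,  0.9096,
   0.4155,  0.9096,  0.0000,
   0.0000,  0.4155, -0.9096,
   0.4155, -0.9096,  0.0000,
  -0.9096,  0.0000,  0.4155), ncol = 3, byrow = TRUE)

# columns t01..t10; rows in the package's order-4 coefficient ordering
# (z^4 slot first, x^4 slot last); values are multiples of 1e-4 mm^2/s
.eval_tensors <- matrix(c(
   2,  0.60,  0.54,  0.73,  0.64,  0.45,  0.69,  0.56,  0.70, 8.50,
   0,  0,     0,     0,     0,     0,     0,     0,     0,    0,
   1,  0.38,  0,     0,     0.03,  0.79,  0.29,  0.84,  0.34, 0,
   0,  0,     0,     0,     0,     0,     0,     0,     0,    0,
   2, 13.31, 23.77, 12.51,  8.66,  5.47, 10.86,  7.48,  7.25, 8.50,
   0,  0,     0,     0,     0,     0,     0,     0,     0,    0,
   0, -1.23,  0,     0,     0,     0,     0.13,  0.38, -0.05, 0,
   0,  0,     0,     0,     0,     0,     0,     0,     0,    0,
   0, 30.02,  0,     0,     0,     0,    10.37,  6.80, 15.23, 0,
   3,  0.99,  2.16,  0,     0,     0,     0.02,  0.04,  0.01, 0,
   0,  0,     0,     0,     0,     0,     0,     0,     0,    0,
   3, 27.03,  0,     0,     0,     0,     3.93,  2.32, 12.49, 0,
   0,  0,     0,     0,     0,     0,     0,     0,     0,    0,
   0,  9.70,  0,     0,     0,     0,     0.69,  0.35,  4.35, 0,
  17,  1.83,  0.29, 12.27, 16.20, 19.33, 12.32, 16.18, 13.01, 8.50),
  nrow = 15, byrow = TRUE)

#' Named reference fixtures
#'
#' `kopt_fixture()` retrieves an embedded fixture by name:
#' direction sets `"table1"` (30 directions, fourth-order K-optimal) and
#' `"table2"` (6 directions, second-order K-optimal), or ground-truth
#' evaluation tensors `"t01"` ... `"t10"` (length-15 coefficient vectors in
#' mm^2/s). `kopt_fixtures()` lists the available names.
#'
#' @param name fixture name.
#' @return a `direction_set` or a numeric tensor coefficient vector.
#' @examples
#' condition_numbers(kopt_fixture("table1"), order = 4)$kappa_G   # ~ 1.914
#' kopt_fixture("t01")[15] * 1e4                                  # 17
#' @export
kopt_fixture <- function(name) {
  name <- match.arg(name, kopt_fixtures())
  if (name == "table1") return(as_direction_set(.table1_points))
  if (name == "table2") return(as_direction_set(.table2_points))
  i <- as.integer(sub("^t", "", name))
  .eval_tensors[, i] * 1e-4
}

#' @rdname kopt_fixture
#' @export
kopt_fixtures <- function() c("table1", "table2", sprintf("t%02d", 1:10))
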