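#' Construct a validated set of gradient encoding directions
#'
#' A direction set is an `N x 3` numeric matrix of unit vectors, the design
#' points of a gradient encoding scheme (GES). Input points must lie on the
#' unit sphere; points that are off by at most `tol` (as happens with
#' directions printed to four decimals in the literature) are renormalized
#' exactly, so that every stored direction has unit norm to machine precision.
#'
#' @param x numeric `N x 3` matrix (or coercible), one direction per row.
#' @param tol largest tolerated deviation of a row norm from 1 before the
#'   input is rejected. Default `5e-4` accommodates 4-decimal printed tables.
#' @return an `N x 3` matrix of class `direction_set` with rows of unit norm.
#' @export
as_direction_set <- function(x, tol = 5e-4) {
  if (inherits(x, "direction_set")) return(x)
  x <- as.matrix(x)
  if (is.null(dim(x)) || ncol(x) != 3L)
    stop("a direction set must be an N x 3 matrix of unit vectors")
  if (nrow(x) < 1L) stop("a direction set must contain at least one direction")
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("directions must be finite")
  nrm <- sqrt(rowSums(x^2))
  if (any(abs(nrm - 1) > tol))
    stop(sprintf("row %d has norm %.6f; directions must be unit vectors (tol %g)",
                 which.max(abs(nrm - 1)), nrm[which.max(abs(nrm - 1))], tol))
  x <- x / nrm
  dimnames(x) <- list(NULL, c("x", "y", "z"))
  class(x) <- c("direction_set", class(x))
  x
}

#' @export
print.direction_set <- function(x, ...) {
  cat(sprintf("Gradient encoding scheme: %d unit directions\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

n_directions <- function(dirs) nrow(as_direction_set(dirs))

#' Read gradient directions from a plain-text file
#'
#' Two dialects are auto-detected: the native format (N rows of three
#' whitespace-separated floats, `#` comments allowed) and the FSL `bvec`
#' dialect (three rows of N values). An ambiguous 3 x 3 file is resolved as
#' native with a warning.
#'
#' @param path file to read.
#' @param tol unit-norm tolerance passed to [as_direction_set()].
#' @return a `direction_set`.
#' @export
read_directions <- function(path, tol = 5e-4) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no directions found in ", path)
  rows <- suppressWarnings(lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric))
  ncols <- lengths(rows)
  if (any(is.na(unlist(rows)))) stop("non-numeric entry in ", path)
  if (all(ncols == 3L)) {
    if (length(rows) == 3L)
      warning("3 x 3 direction file is ambiguous; read as one direction per row")
    m <- do.call(rbind, rows)
  } else if (length(rows) == 3L && length(unique(ncols)) == 1L) {
    m <- t(do.call(rbind, rows))           # bvec: rows are x, y, z coordinates
  } else {
    stop("unrecognized direction file layout in ", path,
         ": expected N x 3 columns or 3 x N bvec rows")
  }
  as_direction_set(m, tol = tol)
}

#' Write gradient directions to a plain-text file
#'
#' One direction per line, three columns, 16 significant digits, with a `#`
#' provenance header.
#'
#' @param dirs a `direction_set` (or matrix coercible to one).
#' @param path output file.
#' @param header optional extra `#` comment lines (without the leading `#`).
#' @export
write_directions <- function(dirs, path, header = character()) {
  dirs <- as_direction_set(dirs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# koptges direction set, N = %d", nrow(dirs)),
               paste0("# ", header)[seq_along(header)]), con)
  writeLines(apply(dirs, 1, function(r) paste(sprintf("%.16g", r), collapse = " ")), con)
  invisible(path)
}

#' Read/write tensor coefficient vectors
#'
#' Plain text, one coefficient per line (15 values for order 4, 6 for
#' order 2), in the package's fixed monomial ordering; `#` comments allowed.
#'
#' @param path file to read or write.
#' @rdname tensor_io
#' @export
read_tensor <- function(path) {
  lines <- sub("#.*$", "", readLines(path))
  v <- suppressWarnings(
    as.numeric(unlist(strsplit(trimws(lines[nzchar(trimws(lines))]), "[[:space:]]+"))))
  if (anyNA(v)) stop("non-numeric entry in ", path)
  if (!length(v) %in% c(6L, 15L))
    stop("expected 6 (order 2) or 15 (order 4) coefficients, got ", length(v))
  v
}

#' @param t numeric tensor coefficient vector.
#' @param header optional extra `#` comment lines.
#' @rdname tensor_io
#' @export
write_tensor <- function(t, path, header = character()) {
  if (!length(t) %in% c(6L, 15L))
    stop("expected 6 (order 2) or 15 (order 4) coefficients")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# koptges tensor coefficients, order %d",
                       if (length(t) == 15L) 4L else 2L),
               paste0("# ", header)[seq_along(header)]), con)
  writeLines(sprintf("%.16g", t), con)
  invisible(path)
}
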