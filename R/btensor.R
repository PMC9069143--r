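#' Construct a linear tensor encoding (LTE) b-tensor
#'
#' An LTE b-tensor encodes diffusion along a single axis: it is the rank-1
#' outer product `b * n %*% t(n)` of the (normalized) encoding direction `n`,
#' so its trace equals the b-value and its only non-zero eigenvalue is `b`.
#'
#' @param b b-value in s/mm^2 (non-negative). Diffusivities throughout the
#'   package are in mm^2/s, so `b * D` is dimensionless.
#' @param direction numeric 3-vector; normalized internally. Must be non-zero.
#' @return A 3x3 symmetric matrix of class `"btensor"`.
#' @examples
#' make_lte_btensor(1000, c(0, 0, 1))
#' @seealso [make_ste_btensor()], [btensor_shape()]
#' @export
make_lte_btensor <- function(b, direction) {
  stopifnot(is.numeric(b), length(b) == 1, is.finite(b))
  if (b < 0) stop("b-value must be non-negative", call. = FALSE)
  direction <- as.numeric(direction)
  if (length(direction) != 3 || !all(is.finite(direction))) {
    stop("direction must be a finite 3-vector", call. = FALSE)
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must have non-zero length", call. = FALSE)
  n <- direction / nrm
  new_btensor(b * tcrossprod(n))
}

#' Construct a spherical tensor encoding (STE) b-tensor
#'
#' An STE b-tensor weights diffusion equally in all directions:
#' `(b/3) * I`. Its signal depends on the tissue only through the mean
#' diffusivity, which is what makes STE-DWI insensitive to anisotropy.
#'
#' @inheritParams make_lte_btensor
#' @return A 3x3 matrix of class `"btensor"` equal to `diag(b/3, 3)`.
#' @export
make_ste_btensor <- function(b) {
  stopifnot(is.numeric(b), length(b) == 1, is.finite(b))
  if (b < 0) stop("b-value must be non-negative", call. = FALSE)
  new_btensor(diag(b / 3, 3))
}

new_btensor <- function(mat) {
  structure(mat, class = c("btensor", "matrix", "array"))
}

#' Validate a b-tensor
#'
#' Checks symmetry (1e-12 absolute), positive semi-definiteness
#' (eigenvalues >= -1e-12) and a non-negative trace.
#'
#' @param B 3x3 matrix.
#' @return `B`, invisibly, as a `"btensor"`; errors otherwise.
#' @export
validate_btensor <- function(B) {
  B <- unclass(B)
  stopifnot(is.matrix(B), all(dim(B) == c(3, 3)), all(is.finite(B)))
  if (max(abs(B - t(B))) > 1e-12) {
    stop("b-tensor must be symmetric", call. = FALSE)
  }
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12) stop("b-tensor must be positive semi-definite", call. = FALSE)
  if (sum(diag(B)) < 0) stop("b-tensor trace must be non-negative", call. = FALSE)
  invisible(new_btensor(B))
}

#' b-value of a b-tensor
#' @param B a `"btensor"` (or plain 3x3 matrix).
#' @return trace of `B`, in s/mm^2.
#' @export
btensor_bvalue <- function(B) sum(diag(unclass(B)))

#' Normalized b-tensor shape (anisotropy) parameter
#'
#' Returns the standard normalized shape parameter: 1 for linear, 0 for
#' spherical, -0.5 for planar encoding. With eigenvalues written as
#' `b/3 * (1 + 2*delta)` (axial, the eigenvalue furthest from the mean) and
#' `b/3 * (1 - delta)` (radial), the returned value is
#' `delta = (lambda_axial - mean(lambda_radial)) / b`.
#'
#' @param B a b-tensor with strictly positive trace.
#' @return shape scalar in `[-0.5, 1]`.
#' @export
btensor_shape <- function(B) {
  B <- unclass(B)
  b <- sum(diag(B))
  if (b <= 0) stop("b-tensor shape is undefined for zero trace", call. = FALSE)
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  m <- b / 3
  ax <- which.max(abs(ev - m))
  lambda_axial <- ev[ax]
  lambda_radial <- mean(ev[-ax])
  (lambda_axial - lambda_radial) / b
}

#' Axially symmetric diffusion tensor from axial/radial diffusivities
#'
#' @param d_par,d_perp axial and radial diffusivities in mm^2/s,
#'   `d_par >= d_perp >= 0`.
#' @param orientation symmetry axis (3-vector, normalized internally).
#' @return 3x3 diffusion tensor `d_perp * I + (d_par - d_perp) * u u^T`.
#' @export
diffusion_tensor <- function(d_par, d_perp, orientation = c(0, 0, 1)) {
  stopifnot(is.finite(d_par), is.finite(d_perp))
  if (d_perp < 0 || d_par < d_perp) {
    stop("require 0 <= d_perp <= d_par", call. = FALSE)
  }
  u <- as.numeric(orientation)
  u <- u / sqrt(sum(u^2))
  diag(d_perp, 3) + (d_par - d_perp) * tcrossprod(u)
}

#' Axial/radial diffusivities from FA and MD
#'
#' Inverts the axially symmetric fractional-anisotropy formula
#' `FA = (d_par - d_perp) / sqrt(d_par^2 + 2 d_perp^2)` at fixed mean
#' diffusivity `MD = (d_par + 2 d_perp) / 3`. Only prolate (`d_par >= d_perp`)
#' solutions are returned.
#'
#' @param fa fractional anisotropy in `[0, 1)`.
#' @param md mean diffusivity in mm^2/s.
#' @return named numeric vector with elements `d_par` and `d_perp`.
#' @export
axisym_from_fa_md <- function(fa, md) {
  stopifnot(fa >= 0, fa < 1, md >= 0)
  # with d_par = md (1 + 2 f), d_perp = md (1 - f):  FA = 3 f / sqrt(3 + 6 f^2)
  f <- fa * sqrt(3 / (9 - 6 * fa^2))
  c(d_par = md * (1 + 2 * f), d_perp = md * (1 - f))
}

#' Fractional anisotropy of an axially symmetric tensor
#' @inheritParams diffusion_tensor
#' @return FA in `[0, 1]`.
#' @export
axisym_fa <- function(d_par, d_perp) {
  if (d_par == 0 && d_perp == 0) return(0)
  (d_par - d_perp) / sqrt(d_par^2 + 2 * d_perp^2)
}
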