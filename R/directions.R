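#' Direction schemes
#'
#' Encoding-direction sets are plain numeric matrices with one unit row vector
#' per direction and a `"scheme_name"` attribute. [scheme_axes3()] returns the
#' three coordinate axes; [scheme_icosa6()] the antipodally reduced vertex set
#' of the icosahedron, the standard rotationally efficient 6-direction scheme;
#' [scheme_fibonacci()] a spherical Fibonacci lattice for dense, nearly uniform
#' coverage.
#'
#' Both `scheme_axes3()` and `scheme_icosa6()` have an isotropic second moment
#' (`crossprod(S)/n = I/3`), which the powder-averaging theory relies on.
#'
#' @return numeric matrix with 3 columns of unit row vectors.
#' @name direction_schemes
NULL

new_scheme <- function(mat, name) {
  mat <- mat / sqrt(rowSums(mat^2))
  structure(mat, scheme_name = name)
}

#' @rdname direction_schemes
#' @export
scheme_axes3 <- function() new_scheme(diag(3), "axes3")

#' @rdname direction_schemes
#' @export
scheme_icosa6 <- function() {
  phi <- (1 + sqrt(5)) / 2
  m <- rbind(
    c(0, 1, phi), c(0, -1, phi),
    c(1, phi, 0), c(-1, phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1)
  )
  new_scheme(m, "icosa6")
}

#' @rdname direction_schemes
#' @param n number of directions.
#' @export
scheme_fibonacci <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  th <- ga * (seq_len(n) - 1)
  new_scheme(cbind(r * cos(th), r * sin(th), z), sprintf("fibonacci%d", n))
}

validate_scheme <- function(scheme) {
  stopifnot(is.matrix(scheme), ncol(scheme) == 3, nrow(scheme) >= 1)
  nrm <- sqrt(rowSums(scheme^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("all scheme directions must be unit vectors", call. = FALSE)
  }
  invisible(scheme)
}

#' Sample directions from a Watson distribution
#'
#' Draws axial directions with density proportional to
#' `exp(kappa * (mu' x)^2)` about a mean axis, modelling white-matter fiber
#' orientation dispersion. Sampling uses a truncated-exponential envelope for
#' the squared-cosine with O(1) acceptance at every concentration, so very
#' large `kappa` (near-parallel fibers) is handled exactly; `kappa = 0` gives
#' the uniform axial distribution.
#'
#' @param mean_axis mean orientation (3-vector, normalized internally).
#' @param kappa concentration parameter, `>= 0` (may be `Inf`).
#' @param n number of samples.
#' @param seed integer seed; the draw is deterministic given `seed`.
#' @return an `n` x 3 matrix of unit row vectors.
#' @export
sample_watson <- function(mean_axis, kappa, n, seed) {
  stopifnot(n >= 1)
  if (!is.finite(kappa) && !is.infinite(kappa)) stop("kappa must be numeric", call. = FALSE)
  if (kappa < 0) stop("kappa must be non-negative", call. = FALSE)
  mu <- as.numeric(mean_axis)
  mu <- mu / sqrt(sum(mu^2))
  if (is.infinite(kappa)) {
    return(new_scheme(matrix(mu, n, 3, byrow = TRUE), "watson"))
  }
  withr::with_seed(as.integer(seed), {
    t <- numeric(n)
    if (kappa == 0) {
      t <- stats::runif(n) # |cos(theta)| uniform on [0, 1] for the axial uniform
    } else {
      ek <- expm1(kappa) # e^kappa - 1, finite for practical kappa
      got <- 0L
      while (got < n) {
        m <- (n - got) * 3L + 8L
        u <- stats::runif(m)
        v <- stats::runif(m)
        # proposal density on [0,1] proportional to exp(kappa * t)
        tt <- if (is.finite(ek)) log1p(u * ek) / kappa else 1 + log(u) / kappa
        tt <- pmin(pmax(tt, 0), 1)
        keep <- v <= exp(kappa * (tt^2 - tt))
        tt <- tt[keep]
        take <- min(length(tt), n - got)
        if (take > 0) t[(got + 1):(got + take)] <- tt[seq_len(take)]
        got <- got + take
      }
    }
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    ct <- t * sgn
    st <- sqrt(pmax(0, 1 - ct^2))
    phi <- stats::runif(n, 0, 2 * pi)
    # orthonormal frame about mu
    a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * mu) * mu
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(
      mu[2] * e1[3] - mu[3] * e1[2],
      mu[3] * e1[1] - mu[1] * e1[3],
      mu[1] * e1[2] - mu[2] * e1[1]
    )
    out <- outer(ct, mu) + outer(st * cos(phi), e1) + outer(st * sin(phi), e2)
    new_scheme(out, "watson")
  })
}

#' Uniformly random 3-D rotation matrices
#'
#' Haar-uniform rotations via normalized random quaternions.
#'
#' @param n number of rotations.
#' @param seed integer seed.
#' @return list of `n` 3x3 rotation matrices.
#' @export
random_rotations <- function(n, seed) {
  stopifnot(n >= 1)
  withr::with_seed(as.integer(seed), {
    q <- matrix(stats::rnorm(4 * n), n, 4)
    q <- q / sqrt(rowSums(q^2))
    lapply(seq_len(n), function(i) quat_to_rotation(q[i, ]))
  })
}

quat_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
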