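#' Gaussian diffusion compartments
#'
#' A compartment is an axially symmetric Gaussian diffusion pool with axial
#' and radial diffusivities (mm^2/s), an orientation, a T2 relaxation time
#' (ms) and a signal fraction. Compartments are rows of a tibble so voxel
#' models compose with the usual data-frame verbs.
#'
#' @param d_par,d_perp axial/radial diffusivities in mm^2/s,
#'   `0 <= d_perp <= d_par <= d_max`.
#' @param orientation symmetry axis (any non-zero 3-vector).
#' @param t2 T2 relaxation time in ms (> 0).
#' @param fraction signal fraction in `[0, 1]`.
#' @param d_max physical diffusivity ceiling (free water at body temperature).
#' @return one-row tibble with columns `d_par`, `d_perp`, `ox`, `oy`, `oz`,
#'   `t2`, `fraction`.
#' @export
gaussian_compartment <- function(d_par, d_perp = d_par, orientation = c(0, 0, 1),
                                 t2, fraction = 1, d_max = 3.5e-3) {
  if (d_perp < 0 || d_par < d_perp) stop("require 0 <= d_perp <= d_par", call. = FALSE)
  if (d_par > d_max) stop("d_par exceeds the physical ceiling d_max", call. = FALSE)
  if (t2 <= 0) stop("t2 must be positive", call. = FALSE)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]", call. = FALSE)
  u <- as.numeric(orientation)
  u <- u / sqrt(sum(u^2))
  tibble::tibble(
    d_par = d_par, d_perp = d_perp,
    ox = u[1], oy = u[2], oz = u[3],
    t2 = t2, fraction = fraction
  )
}

#' Multi-compartment voxel model
#'
#' A voxel is a mixture of Gaussian compartments with a proton-density scale
#' `s0`. Orientation dispersion about each anisotropic compartment's axis is
#' realized at construction time by expanding the compartment into `n_disp`
#' Watson-sampled sub-compartments of equal fraction (fixed seed), which keeps
#' the forward model a pure Gaussian mixture. `dispersion_kappa = Inf` means
#' no dispersion; isotropic compartments are never expanded.
#'
#' @param compartments tibble of compartments (rows from
#'   [gaussian_compartment()]); fractions must sum to 1 within 1e-9.
#' @param s0 signal at `b = 0`, `TE = 0` (arbitrary units, >= 0).
#' @param dispersion_kappa Watson concentration (>= 0, may be `Inf`).
#' @param n_disp number of Watson sub-compartments per anisotropic compartment.
#' @param seed seed for the Watson expansion.
#' @return an object of class `"voxel_model"` with elements `compartments`
#'   (the expanded mixture), `base` (as supplied), `s0`, `dispersion_kappa`.
#' @export
voxel_model <- function(compartments, s0 = 1, dispersion_kappa = Inf,
                        n_disp = 64, seed = 1) {
  stopifnot(is.data.frame(compartments), nrow(compartments) >= 1)
  if (s0 < 0) stop("s0 must be non-negative", call. = FALSE)
  if (abs(sum(compartments$fraction) - 1) > 1e-9) {
    stop("compartment fractions must sum to 1", call. = FALSE)
  }
  comp <- tibble::as_tibble(compartments)
  expanded <- comp
  if (is.finite(dispersion_kappa)) {
    pieces <- purrr::map(seq_len(nrow(comp)), function(i) {
      row <- comp[i, ]
      if (row$d_par - row$d_perp <= 0) {
        return(row)
      }
      dirs <- sample_watson(c(row$ox, row$oy, row$oz), dispersion_kappa,
        n = n_disp, seed = seed + i
      )
      tibble::tibble(
        d_par = row$d_par, d_perp = row$d_perp,
        ox = dirs[, 1], oy = dirs[, 2], oz = dirs[, 3],
        t2 = row$t2, fraction = row$fraction / n_disp
      )
    })
    expanded <- dplyr::bind_rows(pieces)
  }
  structure(
    list(
      compartments = expanded, base = comp, s0 = s0,
      dispersion_kappa = dispersion_kappa
    ),
    class = "voxel_model"
  )
}

#' @export
print.voxel_model <- function(x, ...) {
  cat(sprintf(
    "<voxel_model> s0 = %g, kappa = %s, %d base / %d effective compartments\n",
    x$s0, format(x$dispersion_kappa), nrow(x$base), nrow(x$compartments)
  ))
  print(x$base)
  invisible(x)
}

#' Mean diffusivity of a voxel model
#'
#' Signal-fraction-weighted mean of the per-compartment mean diffusivities
#' `(d_par + 2 d_perp) / 3`.
#'
#' @param voxel a `"voxel_model"`.
#' @return MD in mm^2/s.
#' @export
voxel_md <- function(voxel) {
  with(voxel$base, sum(fraction * (d_par + 2 * d_perp) / 3))
}

#' Default tissue models for the digital glioma phantom
#'
#' Literature-typical parameters for the four phantom tissues (only the white
#' matter T2 of 80 ms is anchored by the imaging protocol this package
#' models; the rest are stand-ins chosen once and exposed for override):
#' dispersed anisotropic white matter (d_par 1.7e-3, d_perp 0.35e-3 mm^2/s,
#' so MD 0.8e-3; T2 80 ms; Watson kappa 9), isotropic tumor hyperintensity
#' (MD 0.5e-3, T2 110 ms), cortical gray matter (MD 0.9e-3, T2 90 ms) and CSF
#' (MD 3.0e-3, T2 500 ms). The lesion MD is below the white-matter MD, which
#' is the regime in which high b-value STE outperforms LTE.
#'
#' @param overrides optional named list of per-tissue parameter overrides,
#'   e.g. `list(lesion = list(md = 0.6e-3), wm = list(kappa = 12))`. Recognized
#'   fields: `d_par`, `d_perp`, `md` (isotropic tissues), `t2`, `kappa`, `s0`,
#'   `orientation`.
#' @param n_disp,seed Watson-expansion controls passed to [voxel_model()].
#' @return named list of `"voxel_model"` objects
#'   (`wm`, `lesion`, `gm`, `csf`).
#' @export
tissue_models <- function(overrides = list(), n_disp = 64, seed = 1) {
  defaults <- list(
    wm = list(
      d_par = 1.7e-3, d_perp = 0.35e-3, t2 = 80, kappa = 9, s0 = 100,
      orientation = c(1, 0, 0)
    ),
    lesion = list(md = 0.5e-3, t2 = 110, s0 = 100),
    gm = list(md = 0.9e-3, t2 = 90, s0 = 100),
    csf = list(md = 3.0e-3, t2 = 500, s0 = 100)
  )
  for (nm in names(overrides)) {
    if (!nm %in% names(defaults)) stop("unknown tissue label: ", nm, call. = FALSE)
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], overrides[[nm]])
  }
  build <- function(p, i) {
    if (!is.null(p$md)) {
      comp <- gaussian_compartment(p$md, p$md, t2 = p$t2)
      voxel_model(comp, s0 = p$s0)
    } else {
      comp <- gaussian_compartment(p$d_par, p$d_perp,
        orientation = p$orientation, t2 = p$t2
      )
      voxel_model(comp,
        s0 = p$s0, dispersion_kappa = p$kappa,
        n_disp = n_disp, seed = seed + 100 * i
      )
    }
  }
  purrr::imap(defaults, function(p, nm) build(p, match(nm, names(defaults))))
}
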