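#' Direction/repetition-averaged modality image
#'
#' Voxel-wise arithmetic mean over all volumes matching a b-value and
#' modality: the LTE-DWI (averaged across encoding directions) or STE-DWI
#' (averaged across repeats) map at that b-value. Arithmetic averaging of
#' magnitude signals is the default and what scanners produce; a geometric
#' mean is available behind a flag.
#'
#' @param dataset a [dwi_dataset()].
#' @param b b-value in s/mm^2.
#' @param modality `"LTE"` or `"STE"`.
#' @param averaging `"arithmetic"` (default) or `"geometric"`.
#' @return a `"modality_image"`: list with `values` (3-D array), `modality`,
#'   `b_value`, `n_averages`.
#' @export
directional_average <- function(dataset, b, modality, averaging = c("arithmetic", "geometric")) {
  averaging <- match.arg(averaging)
  stopifnot(inherits(dataset, "dwi_dataset"))
  idx <- which(dataset$protocol$b_value == b & dataset$protocol$shape == modality)
  if (length(idx) == 0) {
    stop("no volumes at b = ", b, " with modality ", modality, call. = FALSE)
  }
  vols <- dataset$signal[, , , idx, drop = FALSE]
  values <- if (averaging == "arithmetic") {
    apply(vols, 1:3, mean)
  } else {
    exp(apply(log(pmax(vols, .Machine$double.eps)), 1:3, mean))
  }
  structure(
    list(
      values = values, modality = modality, b_value = b,
      n_averages = length(idx)
    ),
    class = "modality_image"
  )
}

#' Per-acquisition noise SD from STE repetitions
#'
#' STE volumes at a given b-value are exact repeats, so their voxel-wise
#' variation is noise alone. The estimator is the voxel-wise sample SD
#' (n - 1 denominator) across the STE repetitions, averaged over the NAWM
#' ROI. LTE repeats are never used: their signal varies with direction as
#' well as noise. At low SNR the magnitude (Rician) SD underestimates the
#' Gaussian channel SD; a warning is emitted when the NAWM SNR falls below 5.
#'
#' @param dataset a [dwi_dataset()].
#' @param b b-value whose STE repeats to use (>= 2 repeats required).
#' @param nawm logical 3-D NAWM mask on the dataset grid.
#' @return scalar noise SD.
#' @export
estimate_sigma_n <- function(dataset, b, nawm) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  nawm <- check_mask(nawm, dim(dataset$signal)[1:3], "nawm")
  idx <- which(dataset$protocol$b_value == b & dataset$protocol$shape == "STE")
  if (length(idx) < 2) {
    stop("need >= 2 STE repetitions at b = ", b, " to estimate sigma_N", call. = FALSE)
  }
  vols <- dataset$signal[, , , idx, drop = FALSE]
  m <- matrix(vols, ncol = length(idx))[as.vector(nawm), , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  sigma <- mean(sds)
  mean_sig <- mean(m)
  if (sigma > 0 && mean_sig / sigma < 5) {
    warning("NAWM SNR below 5 at b = ", b,
      ": Rician bias makes sigma_N an underestimate of the channel SD",
      call. = FALSE
    )
  }
  sigma
}

check_mask <- function(mask, grid, what) {
  stopifnot(is.array(mask) || is.logical(mask))
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(as.integer(dim(mask)), as.integer(grid))) {
    stop(what, " mask shape (", paste(dim(mask), collapse = "x"),
      ") does not match the image grid (", paste(grid, collapse = "x"), ")",
      call. = FALSE
    )
  }
  if (!any(mask)) stop(what, " mask is empty", call. = FALSE)
  mask
}

roi_mean <- function(image, mask) mean(image$values[mask])

#' Signal intensity ratio (SIR) of a modality image
#'
#' `SIR = <S_hyperintensity> / <S_NAWM>`: the ratio of ROI-mean signals of
#' the hyperintensity and contralateral normal-appearing white matter.
#'
#' @param image a `"modality_image"` from [directional_average()].
#' @param hyper,nawm logical 3-D ROI masks.
#' @return one-row tibble with `modality`, `b_value`, `n_averages`,
#'   `mean_hyper`, `mean_nawm`, `sir`.
#' @export
compute_sir <- function(image, hyper, nawm) {
  grid <- dim(image$values)
  hyper <- check_mask(hyper, grid, "hyperintensity")
  nawm <- check_mask(nawm, grid, "nawm")
  mh <- roi_mean(image, hyper)
  mn <- roi_mean(image, nawm)
  if (mn <= 0) stop("NAWM mean signal is non-positive; SIR undefined", call. = FALSE)
  tibble::tibble(
    modality = image$modality, b_value = image$b_value,
    n_averages = image$n_averages, mean_hyper = mh, mean_nawm = mn,
    sir = mh / mn
  )
}

#' Contrast-to-noise ratio efficiency (CNR_eff) of a modality image
#'
#' `CNR_eff = (<S_hyperintensity> - <S_NAWM>) / sigma_N` with `sigma_N` the
#' per-acquisition noise SD ([estimate_sigma_n()]), which makes modalities
#' acquired with different numbers of directions or repeats comparable. The
#' conventional `CNR = CNR_eff * sqrt(n)` for `n` averages is also returned.
#'
#' @inheritParams compute_sir
#' @param sigma_n per-acquisition noise SD (> 0).
#' @return one-row tibble adding `sigma_n`, `cnr_eff`, `cnr` to the
#'   [compute_sir()] columns.
#' @export
compute_cnr_eff <- function(image, hyper, nawm, sigma_n) {
  if (!is.numeric(sigma_n) || sigma_n <= 0) {
    stop("sigma_n must be a positive scalar", call. = FALSE)
  }
  res <- compute_sir(image, hyper, nawm)
  res$sigma_n <- sigma_n
  res$cnr_eff <- (res$mean_hyper - res$mean_nawm) / sigma_n
  res$cnr <- res$cnr_eff * sqrt(res$n_averages)
  res
}

#' Per-case conspicuity analysis at one b-value
#'
#' Builds the LTE-DWI and STE-DWI maps at `b`, estimates `sigma_N` from the
#' STE repeats at `sigma_b` (by default the highest STE b-value) and returns
#' SIR, CNR_eff and CNR for both modalities. `sigma_N` is shared between the
#' modalities: it is estimated from STE only.
#'
#' @param dataset a [dwi_dataset()].
#' @param hyper,nawm logical 3-D ROI masks.
#' @param b analysis b-value (default: the dataset's highest).
#' @param sigma_b b-value whose STE repeats provide `sigma_N`.
#' @param averaging passed to [directional_average()].
#' @return tibble with one row per modality, columns as in
#'   [compute_cnr_eff()]; class `"conspicuity_result"`.
#' @export
conspicuity <- function(dataset, hyper, nawm, b = NULL, sigma_b = NULL,
                        averaging = "arithmetic") {
  stopifnot(inherits(dataset, "dwi_dataset"))
  b <- b %||% max(dataset$protocol$b_value)
  sigma_b <- sigma_b %||% max(dataset$protocol$b_value[dataset$protocol$shape == "STE"])
  sigma_n <- estimate_sigma_n(dataset, sigma_b, nawm)
  res <- dplyr::bind_rows(lapply(c("LTE", "STE"), function(mod) {
    img <- directional_average(dataset, b, mod, averaging = averaging)
    sir_cnr_row(img, hyper, nawm, sigma_n)
  }))
  class(res) <- c("conspicuity_result", class(res))
  res
}

# CNR columns are NA on noise-free data (sigma_n = 0), where CNR_eff is
# undefined; compute_cnr_eff() itself treats non-positive sigma_n as an error.
sir_cnr_row <- function(img, hyper, nawm, sigma_n) {
  if (sigma_n > 0) {
    compute_cnr_eff(img, hyper, nawm, sigma_n)
  } else {
    out <- compute_sir(img, hyper, nawm)
    out$sigma_n <- 0
    out$cnr_eff <- NA_real_
    out$cnr <- NA_real_
    out
  }
}

#' Conspicuity as a function of b-value
#'
#' One row per `(b, modality)` combination present in the dataset, with ROI
#' means, SIR, CNR_eff and CNR. `sigma_N` is taken once, from the STE repeats
#' at the highest STE b-value.
#'
#' @inheritParams conspicuity
#' @return tibble of class `"conspicuity_curves"`.
#' @export
conspicuity_vs_b <- function(dataset, hyper, nawm, averaging = "arithmetic") {
  stopifnot(inherits(dataset, "dwi_dataset"))
  bvals <- sort(unique(dataset$protocol$b_value))
  if (length(bvals) < 2) stop("need >= 2 b-values for a b-sweep", call. = FALSE)
  sigma_b <- max(dataset$protocol$b_value[dataset$protocol$shape == "STE"])
  sigma_n <- estimate_sigma_n(dataset, sigma_b, nawm)
  rows <- list()
  for (b in bvals) {
    for (mod in c("LTE", "STE")) {
      if (!any(dataset$protocol$b_value == b & dataset$protocol$shape == mod)) next
      img <- directional_average(dataset, b, mod, averaging = averaging)
      rows[[length(rows) + 1]] <- sir_cnr_row(img, hyper, nawm, sigma_n)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("conspicuity_curves", class(out))
  out
}

#' Voxel-wise LTE minus STE difference map
#'
#' In noise-free tissue the difference is non-negative everywhere and
#' strictly positive exactly where diffusion is anisotropic, so the map
#' highlights white-matter tracts and vanishes in isotropic lesions.
#'
#' @param lte,ste `"modality_image"` objects on the same grid and b-value.
#' @return 3-D numeric array `lte - ste`.
#' @export
difference_map <- function(lte, ste) {
  if (!identical(dim(lte$values), dim(ste$values))) {
    stop("difference map requires images on the same grid", call. = FALSE)
  }
  if (!isTRUE(all.equal(lte$b_value, ste$b_value))) {
    stop("difference map requires images at the same b-value", call. = FALSE)
  }
  lte$values - ste$values
}
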