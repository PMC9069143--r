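#' Phantom specification
#'
#' Describes a digital glioma phantom: grid, voxel size, geometric tissue
#' regions (spheres and boxes in 1-based voxel coordinates) and per-tissue
#' voxel models. Overlapping regions are resolved by the fixed precedence
#' lesion > csf > gm > wm; unassigned voxels are background (signal 0).
#'
#' @param grid integer 3-vector of grid dimensions.
#' @param voxel_size isotropic voxel size in mm.
#' @param regions named list of region descriptions, each
#'   `list(type = "sphere", center =, radius =)`,
#'   `list(type = "box", min =, max =)` or
#'   `list(type = "shell", min =, max =, inner_min =, inner_max =)` (a box
#'   with a box cut out), in voxel coordinates. Names must be a subset of
#'   `names(models)`.
#' @param models named list of [voxel_model()] objects per tissue label.
#' @param noise_sigma Rician channel noise SD per acquisition (same units as
#'   signal), or `NULL` to calibrate from `snr_b0` at simulation time.
#' @param snr_b0 target white-matter SNR at `b = 0` used when
#'   `noise_sigma` is `NULL`.
#' @param seed master seed for noise substreams.
#' @return a `"phantom_spec"` list.
#' @export
phantom_spec <- function(grid = c(32, 32, 16), voxel_size = 2.3,
                         regions = default_regions(grid),
                         models = tissue_models(),
                         noise_sigma = NULL, snr_b0 = 30, seed = 1) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, all(grid >= 1), voxel_size > 0)
  if (!is.null(noise_sigma) && noise_sigma < 0) {
    stop("noise_sigma must be non-negative", call. = FALSE)
  }
  extra <- setdiff(names(regions), names(models))
  if (length(extra) > 0) {
    stop("regions without a tissue model: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  for (nm in names(regions)) validate_region(regions[[nm]], grid, nm)
  structure(
    list(
      grid = grid, voxel_size = voxel_size, regions = regions,
      models = models, noise_sigma = noise_sigma, snr_b0 = snr_b0,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

validate_region <- function(region, grid, label) {
  if (region$type == "sphere") {
    ctr <- region$center
    r <- region$radius
    if (any(ctr - r < 0.5) || any(ctr + r > grid + 0.5)) {
      stop("region '", label, "' extends outside the grid", call. = FALSE)
    }
  } else if (region$type %in% c("box", "shell")) {
    if (any(region$min < 1) || any(region$max > grid) || any(region$min > region$max)) {
      stop("region '", label, "' extends outside the grid", call. = FALSE)
    }
  } else {
    stop("unknown region type for '", label, "'", call. = FALSE)
  }
  invisible(region)
}

#' Default phantom layout
#'
#' A white-matter slab spanning the mid-grid, a cortical gray-matter shell
#' around it, a spherical lesion embedded in one hemisphere of the slab and a
#' CSF pocket near the midline. Scaled to the supplied grid.
#'
#' @param grid integer 3-vector.
#' @return named list of region descriptions.
#' @export
default_regions <- function(grid = c(32, 32, 16)) {
  g <- as.numeric(grid)
  wm_min <- pmax(1, round(g * 0.2))
  wm_max <- pmin(g, round(g * 0.8))
  c1 <- round(g * c(0.32, 0.5, 0.5)) # lesion centre, one hemisphere of the slab
  list(
    gm = list(
      type = "shell", min = pmax(1, round(g * 0.08)),
      max = pmin(g, round(g * 0.92)),
      inner_min = wm_min, inner_max = wm_max
    ),
    wm = list(type = "box", min = wm_min, max = wm_max),
    csf = list(
      type = "sphere", center = round(g * c(0.5, 0.5, 0.5)),
      radius = max(1.5, min(g) * 0.12)
    ),
    lesion = list(type = "sphere", center = c1, radius = max(2, min(g) * 0.18))
  )
}

# tissue precedence when regions overlap (first wins)
.tissue_precedence <- c("lesion", "csf", "gm", "wm")

#' Build a digital phantom from a specification
#'
#' Voxel assignment is winner-take-all by voxel center (no partial volume):
#' a voxel belongs to the highest-precedence region containing its center.
#' Deterministic given the spec. Besides the per-tissue masks, two analysis
#' ROIs are derived: `hyperintensity` (the lesion) and `nawm` (white matter
#' in the hemisphere contralateral to the lesion).
#'
#' @param spec a [phantom_spec()].
#' @return a `"digital_phantom"` list with `labels` (3-D integer array, 0 =
#'   background), `label_names`, `masks` (named list of logical arrays),
#'   `models`, `voxel_size`, `affine`, `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  labels <- array(0L, dim = g)
  label_names <- intersect(.tissue_precedence, names(spec$regions))
  coords <- as.matrix(expand.grid(
    x = seq_len(g[1]), y = seq_len(g[2]), z = seq_len(g[3])
  ))
  assigned <- rep(FALSE, nrow(coords))
  lab_vec <- integer(nrow(coords))
  for (k in seq_along(label_names)) {
    nm <- label_names[k]
    rg <- spec$regions[[nm]]
    in_box <- function(lo, hi) {
      coords[, 1] >= lo[1] & coords[, 1] <= hi[1] &
        coords[, 2] >= lo[2] & coords[, 2] <= hi[2] &
        coords[, 3] >= lo[3] & coords[, 3] <= hi[3]
    }
    inside <- if (rg$type == "sphere") {
      d2 <- (coords[, 1] - rg$center[1])^2 + (coords[, 2] - rg$center[2])^2 +
        (coords[, 3] - rg$center[3])^2
      d2 <= rg$radius^2
    } else if (rg$type == "shell") {
      in_box(rg$min, rg$max) & !in_box(rg$inner_min, rg$inner_max)
    } else {
      in_box(rg$min, rg$max)
    }
    take <- inside & !assigned
    lab_vec[take] <- k
    assigned <- assigned | inside
  }
  labels[] <- lab_vec
  masks <- purrr::map(seq_along(label_names), function(k) array(lab_vec == k, dim = g))
  names(masks) <- label_names
  if ("lesion" %in% label_names && "wm" %in% label_names) {
    if (!any(masks$lesion)) {
      stop("lesion region contains no voxels; not a study-grade phantom", call. = FALSE)
    }
    lesion_x <- mean(coords[lab_vec == match("lesion", label_names), 1])
    contra <- if (lesion_x <= g[1] / 2) {
      coords[, 1] > g[1] / 2 + g[1] / 8
    } else {
      coords[, 1] < g[1] / 2 - g[1] / 8
    }
    masks$hyperintensity <- masks$lesion
    masks$nawm <- array(lab_vec == match("wm", label_names) & contra, dim = g)
    if (!any(masks$nawm)) stop("contralateral NAWM mask is empty", call. = FALSE)
  }
  vs <- spec$voxel_size
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- -vs * (g - 1) / 2
  structure(
    list(
      labels = labels, label_names = label_names, masks = masks,
      models = spec$models[label_names], voxel_size = vs,
      affine = affine, spec = spec
    ),
    class = "digital_phantom"
  )
}

#' @export
print.digital_phantom <- function(x, ...) {
  counts <- vapply(x$masks, sum, integer(1))
  cat(sprintf(
    "<digital_phantom> %s grid, %.2f mm voxels\n",
    paste(dim(x$labels), collapse = "x"), x$voxel_size
  ))
  print(counts)
  invisible(x)
}

#' A 4-D diffusion-weighted dataset
#'
#' @param signal 4-D array, last dimension indexes protocol entries.
#' @param protocol a [dwi_protocol()] with one row per volume.
#' @param affine 4x4 voxel-to-mm transform (NIfTI semantics: maps 0-based
#'   voxel indices of voxel centers to mm).
#' @return a `"dwi_dataset"` list.
#' @export
dwi_dataset <- function(signal, protocol, affine = diag(4)) {
  stopifnot(length(dim(signal)) == 4)
  if (dim(signal)[4] != nrow(protocol)) {
    stop("number of volumes (", dim(signal)[4], ") does not match protocol entries (",
      nrow(protocol), ")",
      call. = FALSE
    )
  }
  if (any(signal < 0)) stop("magnitude signal must be non-negative", call. = FALSE)
  structure(list(signal = signal, protocol = protocol, affine = affine),
    class = "dwi_dataset"
  )
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf(
    "<dwi_dataset> %dx%dx%d voxels, %d volumes (b: %s)\n",
    d[1], d[2], d[3], d[4],
    paste(sort(unique(x$protocol$b_value)), collapse = ", ")
  ))
  invisible(x)
}

# noise-free per-tissue signal for each protocol entry; rows = tissue labels
noise_free_signal_table <- function(phantom, protocol) {
  te <- protocol_te(protocol)
  vapply(seq_len(nrow(protocol)), function(j) {
    e <- protocol[j, ]
    dir <- c(e$dir_x, e$dir_y, e$dir_z)
    vapply(
      phantom$label_names,
      function(nm) voxel_signal_entry(phantom$models[[nm]], e$b_value, e$shape, dir, te),
      numeric(1)
    )
  }, numeric(length(phantom$label_names)))
}

#' Calibrate the Rician channel noise from a target SNR
#'
#' Returns the channel SD giving the requested white-matter SNR on the
#' unweighted (`b = 0`) image at the protocol's TE.
#'
#' @param phantom a `"digital_phantom"` containing a `wm` model.
#' @param te_ms echo time in ms.
#' @param snr target SNR (> 0).
#' @return noise SD in signal units.
#' @export
calibrate_noise_sigma <- function(phantom, te_ms, snr = 30) {
  stopifnot(snr > 0)
  s0 <- voxel_signal_entry(phantom$models[["wm"]], 0, "STE", NULL, te_ms)
  s0 / snr
}

#' Simulate the acquisition of a phantom under a protocol
#'
#' For every protocol entry the noise-free signal is evaluated per tissue
#' (LTE entries use their direction; STE entries are exact repeats, so they
#' differ only through noise) and broadcast over the tissue masks. Rician
#' magnitude noise is then applied per volume: `sqrt((s + g1*sigma)^2 +
#' (g2*sigma)^2)` with independent standard normal `g1`, `g2`. One master
#' seed spawns an independent substream per volume, so the result is
#' deterministic given `seed`.
#'
#' @param phantom a `"digital_phantom"`.
#' @param protocol a [dwi_protocol()].
#' @param seed master noise seed.
#' @param noise_sigma channel noise SD; `NULL` uses the spec (calibrating
#'   from `snr_b0` if the spec has no explicit sigma).
#' @return a [dwi_dataset()].
#' @export
simulate_acquisition <- function(phantom, protocol, seed = 1, noise_sigma = NULL) {
  stopifnot(inherits(phantom, "digital_phantom"))
  if (is.null(noise_sigma)) {
    noise_sigma <- phantom$spec$noise_sigma %||%
      calibrate_noise_sigma(phantom, protocol_te(protocol), phantom$spec$snr_b0)
  }
  g <- dim(phantom$labels)
  n_vol <- nrow(protocol)
  tab <- noise_free_signal_table(phantom, protocol) # labels x volumes
  lab_vec <- as.integer(phantom$labels)
  signal <- array(0, dim = c(g, n_vol))
  nv <- prod(g)
  lookup <- rbind(0, tab) # background row
  vol_seeds <- withr::with_seed(
    as.integer(seed),
    sample.int(.Machine$integer.max - 1L, n_vol)
  )
  for (j in seq_len(n_vol)) {
    s <- lookup[lab_vec + 1L, j]
    if (noise_sigma > 0) {
      s <- withr::with_seed(vol_seeds[j], {
        g1 <- stats::rnorm(nv)
        g2 <- stats::rnorm(nv)
        sqrt((s + noise_sigma * g1)^2 + (noise_sigma * g2)^2)
      })
    }
    signal[, , , j] <- s
  }
  dwi_dataset(signal, protocol, phantom$affine)
}

#' One-call study-grade phantom and noisy acquisition
#'
#' Builds the default digital glioma phantom and simulates the default
#' clinical protocol ([study_protocol()]) with Rician noise calibrated to a
#' white-matter SNR of 30 at `b = 0`.
#'
#' @param seed master noise seed.
#' @param spec optional [phantom_spec()] override.
#' @return list with elements `phantom` and `dataset`.
#' @export
study_phantom <- function(seed = 1, spec = phantom_spec(seed = seed)) {
  phantom <- build_phantom(spec)
  dataset <- simulate_acquisition(phantom, study_protocol(), seed = seed)
  list(phantom = phantom, dataset = dataset)
}
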