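# Random single- and multi-compartment voxel models for property tests.
# Draws stay inside the physical diffusivity ceiling; t2 spans tissue-like
# values. Call inside withr::with_seed for reproducibility.
random_voxel_model <- function(max_compartments = 3, dispersed = FALSE) {
  k <- sample.int(max_compartments, 1)
  f <- stats::runif(k)
  f <- f / sum(f)
  comps <- do.call(rbind, lapply(seq_len(k), function(i) {
    d_par <- stats::runif(1, 0.2e-3, 3.0e-3)
    d_perp <- stats::runif(1, 0, d_par)
    u <- stats::rnorm(3)
    gaussian_compartment(d_par, d_perp,
      orientation = u,
      t2 = stats::runif(1, 60, 400), fraction = f[i]
    )
  }))
  voxel_model(comps,
    s0 = stats::runif(1, 50, 150),
    dispersion_kappa = if (dispersed) stats::runif(1, 4, 20) else Inf,
    n_disp = 16, seed = sample.int(1e6, 1)
  )
}

# minimal phantom: full-grid WM box with an embedded lesion sphere
sphere_in_box_spec <- function(grid, center, radius, models = tissue_models(),
                               noise_sigma = 0, seed = 1) {
  phantom_spec(
    grid = grid,
    regions = list(
      wm = list(type = "box", min = c(1, 1, 1), max = grid),
      lesion = list(type = "sphere", center = center, radius = radius)
    ),
    models = models, noise_sigma = noise_sigma, seed = seed
  )
}

# small study-grade phantom for fast end-to-end tests
small_spec <- function(noise_sigma = NULL, seed = 1, models = tissue_models()) {
  phantom_spec(
    grid = c(16, 16, 8), regions = default_regions(c(16, 16, 8)),
    models = models, noise_sigma = noise_sigma, seed = seed
  )
}
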