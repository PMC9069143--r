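# small synthetic dataset with hand-set volumes for exact checks
toy_dataset <- function(values_list, b_values, shapes) {
  g <- dim(values_list[[1]])
  arr <- array(0, dim = c(g, length(values_list)))
  for (j in seq_along(values_list)) arr[, , , j] <- values_list[[j]]
  dirs <- scheme_icosa6()
  entries <- tibble::tibble(
    b_value = b_values, shape = shapes,
    dir_x = ifelse(shapes == "LTE", dirs[1, 1], NA_real_),
    dir_y = ifelse(shapes == "LTE", dirs[1, 2], NA_real_),
    dir_z = ifelse(shapes == "LTE", dirs[1, 3], NA_real_)
  )
  dwi_dataset(arr, dwi_protocol(entries, tr_ms = 5000, te_ms = 84))
}

g3 <- c(4L, 4L, 2L)
const_vol <- function(x) array(x, dim = g3)

test_that("directional averaging counts and averages matching volumes", {
  sp <- study_phantom(seed = 2)
  img <- directional_average(sp$dataset, 2000, "STE")
  expect_equal(img$n_averages, 16L)
  expect_equal(dim(img$values), dim(sp$dataset$signal)[1:3])
  # arithmetic mean across exactly the matching volumes
  idx <- which(sp$dataset$protocol$b_value == 2000 & sp$dataset$protocol$shape == "STE")
  expect_equal(img$values, apply(sp$dataset$signal[, , , idx], 1:3, mean))
  expect_error(directional_average(sp$dataset, 300, "STE"), "no volumes at b = 300")
})

test_that("single and constant volumes average to themselves", {
  ds <- toy_dataset(
    list(const_vol(7), const_vol(7), const_vol(3)),
    b_values = c(1000, 1000, 1000), shapes = c("STE", "STE", "LTE")
  )
  ste <- directional_average(ds, 1000, "STE")
  expect_equal(ste$values, const_vol(7))
  lte <- directional_average(ds, 1000, "LTE")
  expect_equal(lte$n_averages, 1L)
  expect_equal(lte$values, const_vol(3))
})

test_that("sigma_N is the NAWM mean of the repeat-wise sample SD", {
  nawm <- array(TRUE, dim = g3)
  same <- toy_dataset(rep(list(const_vol(5)), 3), rep(1000, 3), rep("STE", 3))
  expect_equal(estimate_sigma_n(same, 1000, nawm), 0)
  # two repetitions differing by d everywhere: SD = d / sqrt(2)
  two <- toy_dataset(list(const_vol(10), const_vol(13)), rep(1000, 2), rep("STE", 2))
  expect_equal(estimate_sigma_n(two, 1000, nawm), 3 / sqrt(2), tolerance = 1e-12)
  one <- toy_dataset(list(const_vol(10)), 1000, "STE")
  expect_error(estimate_sigma_n(one, 1000, nawm), "2 STE repetitions")
})

test_that("sigma_N recovers injected Gaussian noise on a large ROI", {
  sigma <- 0.8
  n_rep <- 16
  vols <- withr::with_seed(12, {
    lapply(seq_len(n_rep), function(i) array(50 + rnorm(prod(g3) * 64, 0, sigma), dim = c(8L, 8L, 8L)))
  })
  ds <- toy_dataset(vols, rep(2000, n_rep), rep("STE", n_rep))
  est <- estimate_sigma_n(ds, 2000, array(TRUE, dim = c(8L, 8L, 8L)))
  expect_equal(est, sigma, tolerance = 0.05)
})

test_that("SIR is the ratio of ROI means", {
  hyper <- array(FALSE, g3)
  hyper[1:2, , ] <- TRUE
  nawm <- !hyper
  img <- structure(
    list(
      values = const_vol(20) + 20 * hyper, modality = "LTE",
      b_value = 2000, n_averages = 6L
    ),
    class = "modality_image"
  )
  r <- compute_sir(img, hyper, nawm)
  expect_equal(r$sir, 2)
  expect_equal(r$mean_hyper, 40)
  r_same <- compute_sir(img, hyper, hyper)
  expect_equal(r_same$sir, 1)
  zero <- img
  zero$values <- const_vol(0)
  expect_error(compute_sir(zero, hyper, nawm), "non-positive")
  expect_error(compute_sir(img, array(FALSE, g3), nawm), "empty")
})

test_that("phantom STE SIR matches the analytic ratio of exponentials", {
  # isotropic lesion MD 0.7e-3 vs isotropic "WM" MD 0.8e-3, equal T2:
  # noise-free STE SIR at b = 2000 is exp(b * dMD) = exp(0.2)
  models <- tissue_models(overrides = list(
    lesion = list(md = 0.7e-3, t2 = 80),
    wm = list(d_par = 0.8e-3, d_perp = 0.8e-3)
  ))
  ph <- build_phantom(small_spec(noise_sigma = 0, models = models))
  ds <- simulate_acquisition(ph, study_protocol(), seed = 1)
  img <- directional_average(ds, 2000, "STE")
  r <- compute_sir(img, ph$masks$hyperintensity, ph$masks$nawm)
  expect_equal(r$sir, exp(0.2), tolerance = 1e-9)
})

test_that("CNR_eff scales ROI contrast by sigma_N and CNR by sqrt(n)", {
  hyper <- array(FALSE, g3)
  hyper[1:2, , ] <- TRUE
  nawm <- !hyper
  img <- structure(
    list(
      values = const_vol(20) + 10 * hyper, modality = "STE",
      b_value = 2000, n_averages = 16L
    ),
    class = "modality_image"
  )
  r <- compute_cnr_eff(img, hyper, nawm, sigma_n = 5)
  expect_equal(r$cnr_eff, 2)
  expect_equal(r$cnr, 8) # 2 * sqrt(16)
  eq <- compute_cnr_eff(img, hyper, hyper, sigma_n = 5)
  expect_equal(eq$cnr_eff, 0)
  expect_error(compute_cnr_eff(img, hyper, nawm, sigma_n = 0), "positive")
})

test_that("conspicuity results satisfy their internal consistency identities", {
  sp <- study_phantom(seed = 6)
  res <- conspicuity(sp$dataset, sp$phantom$masks$hyperintensity, sp$phantom$masks$nawm)
  expect_equal(res$sir, res$mean_hyper / res$mean_nawm, tolerance = 1e-9)
  expect_equal(res$cnr_eff, (res$mean_hyper - res$mean_nawm) / res$sigma_n, tolerance = 1e-9)
  expect_equal(res$cnr, res$cnr_eff * sqrt(res$n_averages), tolerance = 1e-9)
  expect_equal(res$sigma_n[1], res$sigma_n[2]) # STE-derived sigma shared with LTE
})

test_that("ROI means commute with volume averaging (arithmetic averaging)", {
  sp <- study_phantom(seed = 8)
  ds <- sp$dataset
  nawm <- sp$phantom$masks$nawm
  idx <- which(ds$protocol$b_value == 2000 & ds$protocol$shape == "STE")
  per_volume <- vapply(idx, function(j) mean(ds$signal[, , , j][nawm]), numeric(1))
  img <- directional_average(ds, 2000, "STE")
  expect_equal(mean(per_volume), mean(img$values[nawm]), tolerance = 1e-12)
})

test_that("b-sweeps are monotone noise-free and carry T2 contrast at low b", {
  ph <- build_phantom(small_spec(noise_sigma = 0))
  ds <- simulate_acquisition(ph, study_protocol(), seed = 1)
  curves <- conspicuity_vs_b(ds, ph$masks$hyperintensity, ph$masks$nawm)
  expect_s3_class(curves, "conspicuity_curves")
  for (m in c("LTE", "STE")) {
    s <- curves$sir[curves$modality == m]
    expect_true(all(diff(s) > 0))
  }
  # long lesion T2 keeps contrast positive already at the lowest b-value
  low <- curves[curves$b_value == 100, ]
  expect_true(all(low$mean_hyper > low$mean_nawm))
  # identical tissue everywhere gives SIR 1 at every b
  same <- tissue_models(overrides = list(
    lesion = list(md = 0.8e-3, t2 = 80),
    wm = list(d_par = 0.8e-3, d_perp = 0.8e-3)
  ))
  ph2 <- build_phantom(small_spec(noise_sigma = 0, models = same))
  ds2 <- simulate_acquisition(ph2, study_protocol(), seed = 1)
  curves2 <- conspicuity_vs_b(ds2, ph2$masks$hyperintensity, ph2$masks$nawm)
  expect_equal(curves2$sir, rep(1, nrow(curves2)), tolerance = 1e-9)
})

test_that("difference maps are antisymmetric and localize anisotropy", {
  ph <- build_phantom(small_spec(noise_sigma = 0))
  ds <- simulate_acquisition(ph, study_protocol(), seed = 1)
  lte <- directional_average(ds, 2000, "LTE")
  ste <- directional_average(ds, 2000, "STE")
  expect_equal(difference_map(lte, lte), array(0, dim = dim(lte$values)))
  d <- difference_map(lte, ste)
  expect_equal(difference_map(ste, lte), -d)
  expect_true(all(d[ph$masks$wm] > 0)) # anisotropic white matter
  expect_true(all(abs(d[ph$masks$lesion]) < 1e-9)) # isotropic lesion
  small <- ste
  small$values <- small$values[1:4, 1:4, 1:2]
  expect_error(difference_map(lte, small), "same grid")
  wrong_b <- directional_average(ds, 1400, "STE")
  expect_error(difference_map(lte, wrong_b), "same b-value")
})

test_that("plot methods return ggplot objects", {
  sp <- study_phantom(seed = 1, spec = small_spec(seed = 1))
  curves <- conspicuity_vs_b(sp$dataset, sp$phantom$masks$hyperintensity, sp$phantom$masks$nawm)
  expect_s3_class(ggplot2::autoplot(curves), "ggplot")
  expect_s3_class(ggplot2::autoplot(sp$phantom), "ggplot")
  expect_s3_class(
    ggplot2::autoplot(directional_average(sp$dataset, 2000, "STE")),
    "ggplot"
  )
})
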