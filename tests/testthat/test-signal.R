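test_that("attenuation follows the Gaussian closed forms", {
  expect_equal(attenuation(diag(0.5e-3, 3), make_ste_btensor(2000)), exp(-1), tolerance = 1e-12)
  expect_equal(attenuation(diag(c(1.7, 0.2, 0.2) * 1e-3), make_ste_btensor(0)), 1)
  D <- diag(c(1.7, 0.2, 0.2) * 1e-3)
  expect_equal(attenuation(D, make_lte_btensor(2000, c(1, 0, 0))), exp(-3.4), tolerance = 1e-12)
  # off-axis LTE picks up the quadratic form n' D n
  n <- c(1, 1, 0) / sqrt(2)
  expect_equal(
    attenuation(D, make_lte_btensor(2000, n)),
    exp(-2000 * as.numeric(t(n) %*% D %*% n)),
    tolerance = 1e-12
  )
  expect_error(attenuation(diag(c(-1e-3, 1e-3, 1e-3)), make_ste_btensor(100)), "semi-definite")
})

test_that("attenuation is non-increasing in b for fixed shape and tissue", {
  D <- diffusion_tensor(1.4e-3, 0.3e-3, c(1, 2, 2))
  bs <- seq(0, 3000, by = 250)
  ste <- vapply(bs, function(b) attenuation(D, make_ste_btensor(b)), numeric(1))
  lte <- vapply(bs, function(b) attenuation(D, make_lte_btensor(b, c(0, 1, 0))), numeric(1))
  expect_true(all(diff(ste) < 0))
  expect_true(all(diff(lte) < 0))
})

test_that("voxel signal combines fractions, T2 decay and diffusion attenuation", {
  iso <- voxel_model(gaussian_compartment(0.8e-3, t2 = 80), s0 = 3)
  expect_equal(voxel_signal(iso, make_ste_btensor(0), te_ms = 0), 3)
  expect_equal(voxel_signal(iso, NULL, te_ms = 84), 3 * exp(-84 / 80), tolerance = 1e-12)
  two <- voxel_model(
    rbind(
      gaussian_compartment(0.7e-3, t2 = 100, fraction = 0.5),
      gaussian_compartment(3.0e-3, t2 = 100, fraction = 0.5)
    ),
    s0 = 1
  )
  expect_equal(
    voxel_signal(two, make_ste_btensor(2000), te_ms = 0),
    0.5 * exp(-1.4) + 0.5 * exp(-6),
    tolerance = 1e-12
  )
  expect_error(voxel_signal(iso, make_ste_btensor(100), te_ms = -1), "TE")
  expect_error(
    voxel_model(gaussian_compartment(1e-3, t2 = 80, fraction = 0.5)),
    "sum to 1"
  )
})

test_that("powder averaging of an isotropic voxel equals the STE signal", {
  iso <- voxel_model(gaussian_compartment(0.9e-3, t2 = 90), s0 = 2)
  for (scheme in list(scheme_axes3(), scheme_icosa6(), scheme_fibonacci(20))) {
    expect_equal(
      powder_average_lte(iso, 2000, scheme, te_ms = 84),
      voxel_signal(iso, make_ste_btensor(2000), te_ms = 84),
      tolerance = 1e-12
    )
  }
  aniso <- voxel_model(gaussian_compartment(1.7e-3, 0.2e-3, t2 = 80), s0 = 1)
  expect_equal(powder_average_lte(aniso, 0, scheme_icosa6(), te_ms = 84),
    exp(-84 / 80),
    tolerance = 1e-12
  )
})

test_that("dense-scheme powder averages converge to the closed form", {
  d_par <- 1.7e-3
  d_perp <- 0.2e-3
  cmp <- voxel_model(gaussian_compartment(d_par, d_perp, orientation = c(1, 2, -1), t2 = 80))
  ref <- powder_closed_form(d_par, d_perp, 2000)
  dense <- powder_average_lte(cmp, 2000, scheme_fibonacci(1000), te_ms = 0)
  expect_lt(abs(dense - ref) / ref, 0.002)
  # error shrinks on average as the scheme grows
  errs <- vapply(c(10, 40, 160, 640), function(n) {
    abs(powder_average_lte(cmp, 2000, scheme_fibonacci(n), te_ms = 0) - ref) / ref
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("closed-form powder average matches a Monte-Carlo oracle", {
  expect_equal(powder_closed_form(1e-3, 1e-3, 2000), exp(-2), tolerance = 1e-12)
  expect_equal(powder_closed_form(1.7e-3, 0.2e-3, 0), 1)
  # continuity at vanishing anisotropy
  expect_equal(powder_closed_form(1e-3 + 1e-12, 1e-3, 2000), exp(-2), tolerance = 1e-6)
  n_mc <- 1e5
  mc <- withr::with_seed(99, {
    u <- matrix(rnorm(3 * n_mc), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    exp(-2000 * (0.2e-3 + 1.5e-3 * u[, 3]^2))
  })
  se <- stats::sd(mc) / sqrt(n_mc)
  expect_lt(abs(mean(mc) - powder_closed_form(1.7e-3, 0.2e-3, 2000)), 3 * se)
  expect_error(powder_closed_form(0.2e-3, 0.5e-3, 1000), "d_perp")
})

test_that("Watson sampling is concentrated, uniform at kappa 0, and unit norm", {
  tight <- sample_watson(c(0, 0, 1), kappa = 1e6, n = 500, seed = 4)
  expect_true(all(abs(tight[, 3]) > cos(0.5 * pi / 180)))
  unif <- sample_watson(c(1, 0, 0), kappa = 0, n = 20000, seed = 4)
  m2 <- mean((unif %*% c(0, 1, 0))^2)
  expect_lt(abs(m2 - 1 / 3), 0.01)
  mid <- sample_watson(c(1, 1, 1), kappa = 9, n = 1000, seed = 8)
  expect_equal(sqrt(rowSums(mid^2)), rep(1, 1000), tolerance = 1e-9)
  # deterministic given seed
  expect_equal(mid, sample_watson(c(1, 1, 1), kappa = 9, n = 1000, seed = 8))
  expect_error(sample_watson(c(0, 0, 1), kappa = -1, n = 10, seed = 1), "non-negative")
})

test_that("rotational variance vanishes for isotropic tissue and dense schemes", {
  expect_equal(rotational_variance(1e-3, 1e-3, scheme_icosa6(), 2000, 10, seed = 1), 0)
  d <- axisym_from_fa_md(0.9, 0.8e-3)
  rv_dense <- rotational_variance(d["d_par"], d["d_perp"], scheme_fibonacci(1000),
    2000,
    n_rotations = 200, seed = 2, statistic = "max"
  )
  expect_lt(rv_dense, 0.3)
})

test_that("MD/S0 fitting recovers noiseless monoexponentials exactly", {
  b <- c(100, 700, 1400, 2000)
  fit <- fit_md_s0(data.frame(b_value = b, signal = 100 * exp(-b * 0.8e-3)))
  expect_equal(fit$md, 0.8e-3, tolerance = 1e-12)
  expect_equal(fit$s0, 100, tolerance = 1e-9)
  expect_true(fit$valid)
  flat <- fit_md_s0(data.frame(b_value = b, signal = rep(42, 4)))
  expect_equal(flat$md, 0)
  expect_equal(flat$s0, 42, tolerance = 1e-9)
  bad <- fit_md_s0(data.frame(b_value = b, signal = c(10, 5, 0, 2)))
  expect_false(bad$valid)
  expect_true(is.na(bad$md))
  expect_error(fit_md_s0(data.frame(b_value = c(1000, 1000), signal = c(1, 2))), "distinct")
})

test_that("noise-free directional LTE averages dominate STE signals (Jensen)", {
  withr::with_seed(31, {
    for (i in 1:30) {
      vm <- random_voxel_model(dispersed = i %% 3 == 0)
      b <- runif(1, 500, 3000)
      lte <- powder_average_lte(vm, b, scheme_icosa6(), te_ms = 84)
      ste <- voxel_signal(vm, make_ste_btensor(b), te_ms = 84)
      expect_gte(lte, ste * (1 - 1e-12))
      aniso <- any(vm$compartments$d_par > vm$compartments$d_perp)
      if (aniso) expect_gt(lte, ste)
    }
  })
})

test_that("STE voxel signals are invariant under rotation of the tissue", {
  withr::with_seed(17, {
    vm <- random_voxel_model(dispersed = FALSE)
    B <- make_ste_btensor(2000)
    s0 <- voxel_signal(vm, B, te_ms = 84)
    for (R in random_rotations(8, seed = 23)) {
      rotated <- vm
      o <- as.matrix(vm$compartments[, c("ox", "oy", "oz")]) %*% t(R)
      rotated$compartments$ox <- o[, 1]
      rotated$compartments$oy <- o[, 2]
      rotated$compartments$oz <- o[, 3]
      expect_equal(voxel_signal(rotated, B, te_ms = 84), s0, tolerance = 1e-9)
    }
  })
})
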