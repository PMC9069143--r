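#' Median and interquartile range summary
#'
#' Median and (Q1, Q3) using the linear-interpolation quantile convention
#' (`stats::quantile` type 7), the convention used for all cohort summaries
#' in this package.
#'
#' @param values non-empty numeric vector.
#' @return one-row tibble with `median`, `q25`, `q75`, `n`.
#' @export
summarize_metric <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values))) {
    stop("values must be a non-empty finite numeric vector", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(median = q[2], q25 = q[1], q75 = q[3], n = length(values))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Zero differences are
#' dropped (signed-rank convention) and tied absolute differences receive
#' midranks. For `n <= 12` retained pairs the null distribution is obtained
#' by exact enumeration of all `2^n` sign assignments of the ranks (valid
#' with ties, as a permutation test); the two-sided p-value is
#' `min(1, 2 * min(P(V <= v), P(V >= v)))`. For larger `n` a normal
#' approximation with tie-corrected variance
#' `n(n+1)(2n+1)/24 - sum(t^3 - t)/48` is used, without continuity
#' correction.
#'
#' @param a,b paired numeric vectors of equal length; at least 5 non-zero
#'   differences are required.
#' @return one-row tibble with `statistic` (V, the positive-rank sum),
#'   `p_value`, `n` (retained pairs), `method` (`"exact"` or
#'   `"normal_approx"`).
#' @export
paired_wilcoxon <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  d <- a - b
  if (any(!is.finite(d))) stop("differences must be finite", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero; the signed-rank test is degenerate", call. = FALSE)
  if (n < 5) stop("need at least 5 non-zero differences", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 12) {
    # exact enumeration of all 2^n sign assignments of the ranks
    dist <- signed_rank_null(r)
    p_le <- mean(dist <= v + 1e-9)
    p_ge <- mean(dist >= v - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  tibble::tibble(statistic = v, p_value = p, n = n, method = method)
}

# all 2^n values of the positive-rank sum under random signs
signed_rank_null <- function(ranks) {
  n <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  as.numeric(signs %*% ranks)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests the sample against a normal distribution with mean and SD estimated
#' from the sample itself. With estimated parameters the standard KS critical
#' values are approximate (conservative); set `corrected = TRUE` for the
#' Lilliefors-corrected variant. Drives the parametric-vs-nonparametric
#' decision in cohort reports.
#'
#' @param values numeric vector, `n >= 5`.
#' @param alpha significance level for the `reject` flag.
#' @param corrected use the Lilliefors bias-corrected test
#'   (`nortest::lillie.test`) instead of the uncorrected KS.
#' @return one-row tibble with `statistic`, `p_value`, `reject`, `method`,
#'   `note`.
#' @export
ks_normality <- function(values, alpha = 0.05, corrected = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 5) stop("need n >= 5 for the KS normality check", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(tibble::tibble(
      statistic = 1, p_value = 0, reject = TRUE,
      method = "degenerate",
      note = "zero-variance sample; normality rejected by convention"
    ))
  }
  if (corrected) {
    t <- nortest::lillie.test(values)
    note <- "Lilliefors-corrected critical values"
  } else {
    t <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean = mean(values), sd = stats::sd(values))
    )
    note <- "reference normal uses sample mean/SD; uncorrected critical values are approximate"
  }
  tibble::tibble(
    statistic = unname(t$statistic), p_value = t$p.value,
    reject = t$p.value < alpha, method = if (corrected) "lilliefors" else "ks",
    note = note
  )
}

#' Improvement fractions across cases
#'
#' Fractions of cases in which STE-DWI beats LTE-DWI (strict inequality;
#' ties count as not improved) and in which the SIR exceeds 2 per modality.
#'
#' @param records data frame of per-case results with columns `sir_lte`,
#'   `sir_ste`, `cnr_eff_lte`, `cnr_eff_ste`.
#' @return one-row tibble with `frac_sir_improved`, `frac_cnr_improved`,
#'   `frac_sir_ste_above_2`, `frac_sir_lte_above_2`, `n_cases`.
#' @export
improvement_fractions <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  tibble::tibble(
    frac_sir_improved = mean(records$sir_ste > records$sir_lte),
    frac_cnr_improved = mean(records$cnr_eff_ste > records$cnr_eff_lte),
    frac_sir_ste_above_2 = mean(records$sir_ste > 2),
    frac_sir_lte_above_2 = mean(records$sir_lte > 2),
    n_cases = nrow(records)
  )
}

#' Simulate a multi-case synthetic cohort
#'
#' Generates `n_cases` digital glioma phantoms with per-case randomized
#' lesion mean diffusivity, white-matter dispersion and lesion size, acquires
#' each with the default clinical protocol and Rician noise, and runs the
#' per-case conspicuity analysis at the highest b-value. Lesion MD is drawn
#' below the white-matter MD, the regime the phantom is designed to emulate.
#'
#' @param n_cases number of cases (>= 1).
#' @param seed master seed; every per-case stochastic choice derives from it.
#' @param lesion_md_range range (mm^2/s) for the per-case lesion MD draw.
#' @param kappa_range range for the per-case white-matter Watson
#'   concentration.
#' @param lesion_radius_range range (voxels) for the lesion radius draw.
#' @param grid phantom grid dimensions.
#' @param noise_sigma per-acquisition channel noise SD; `NULL` calibrates to
#'   a white-matter SNR of 30 at `b = 0` per case.
#' @return tibble with one row per case: `case_id`, `sir_lte`, `sir_ste`,
#'   `cnr_eff_lte`, `cnr_eff_ste`, `signal_diff_hyper`, `signal_diff_nawm`
#'   (LTE-DWI minus STE-DWI ROI means), `sigma_n`, `lesion_md`, `kappa`.
#' @export
simulate_cohort <- function(n_cases = 25, seed = 1,
                            lesion_md_range = c(0.40e-3, 0.55e-3),
                            kappa_range = c(6, 12),
                            lesion_radius_range = c(2.5, 4),
                            grid = c(32, 32, 16), noise_sigma = NULL) {
  stopifnot(n_cases >= 1)
  draws <- withr::with_seed(as.integer(seed), tibble::tibble(
    case = seq_len(n_cases),
    lesion_md = stats::runif(n_cases, lesion_md_range[1], lesion_md_range[2]),
    kappa = stats::runif(n_cases, kappa_range[1], kappa_range[2]),
    radius = stats::runif(n_cases, lesion_radius_range[1], lesion_radius_range[2]),
    noise_seed = sample.int(2^30, n_cases)
  ))
  purrr::pmap_dfr(draws, function(case, lesion_md, kappa, radius, noise_seed) {
    regions <- default_regions(grid)
    # keep the lesion inside small grids
    ctr <- regions$lesion$center
    feasible <- min(ctr - 0.5, grid + 0.5 - ctr)
    regions$lesion$radius <- max(1.5, min(radius, feasible))
    models <- tissue_models(
      overrides = list(
        lesion = list(md = lesion_md),
        wm = list(kappa = kappa)
      ),
      seed = noise_seed
    )
    spec <- phantom_spec(
      grid = grid, regions = regions, models = models,
      noise_sigma = noise_sigma, seed = noise_seed
    )
    phantom <- build_phantom(spec)
    dataset <- simulate_acquisition(phantom, study_protocol(), seed = noise_seed)
    res <- conspicuity(dataset, phantom$masks$hyperintensity, phantom$masks$nawm)
    lte <- res[res$modality == "LTE", ]
    ste <- res[res$modality == "STE", ]
    tibble::tibble(
      case_id = sprintf("case%02d", case),
      sir_lte = lte$sir, sir_ste = ste$sir,
      cnr_eff_lte = lte$cnr_eff, cnr_eff_ste = ste$cnr_eff,
      signal_diff_hyper = lte$mean_hyper - ste$mean_hyper,
      signal_diff_nawm = lte$mean_nawm - ste$mean_nawm,
      sigma_n = lte$sigma_n, lesion_md = lesion_md, kappa = kappa
    )
  })
}

#' Cohort-level summary of per-case conspicuity results
#'
#' Median and IQR of SIR and CNR_eff per modality, paired-difference medians
#' and IQRs, paired Wilcoxon signed-rank p-values, KS normality checks (the
#' rationale for using nonparametric tests) and improvement fractions.
#'
#' @param records per-case tibble as returned by [simulate_cohort()] (or read
#'   from a per-case results CSV with the same columns).
#' @param corrected_ks use the Lilliefors-corrected normality check.
#' @return an object of class `"cohort_summary"`: list with `metrics` (tidy
#'   per-metric tibble), `tests`, `normality`, `fractions`, `n_cases`.
#' @export
cohort_summary <- function(records, corrected_ks = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  metric_rows <- function(metric, lte, ste) {
    dplyr::bind_rows(
      dplyr::mutate(summarize_metric(lte), metric = metric, quantity = "LTE"),
      dplyr::mutate(summarize_metric(ste), metric = metric, quantity = "STE"),
      dplyr::mutate(summarize_metric(ste - lte), metric = metric, quantity = "STE-LTE")
    )
  }
  metrics <- dplyr::bind_rows(
    metric_rows("sir", records$sir_lte, records$sir_ste),
    metric_rows("cnr_eff", records$cnr_eff_lte, records$cnr_eff_ste)
  )[, c("metric", "quantity", "median", "q25", "q75", "n")]
  safe_wilcoxon <- function(a, b) {
    tryCatch(paired_wilcoxon(a, b), error = function(e) {
      tibble::tibble(
        statistic = NA_real_, p_value = NA_real_,
        n = sum(a != b), method = paste0("unavailable: ", conditionMessage(e))
      )
    })
  }
  tests <- dplyr::bind_rows(
    dplyr::mutate(safe_wilcoxon(records$sir_ste, records$sir_lte), metric = "sir"),
    dplyr::mutate(safe_wilcoxon(records$cnr_eff_ste, records$cnr_eff_lte), metric = "cnr_eff")
  )
  safe_ks <- function(x) {
    tryCatch(ks_normality(x, corrected = corrected_ks), error = function(e) {
      tibble::tibble(
        statistic = NA_real_, p_value = NA_real_, reject = NA,
        method = "unavailable", note = conditionMessage(e)
      )
    })
  }
  normality <- dplyr::bind_rows(
    dplyr::mutate(safe_ks(records$sir_lte), metric = "sir", quantity = "LTE"),
    dplyr::mutate(safe_ks(records$sir_ste), metric = "sir", quantity = "STE"),
    dplyr::mutate(safe_ks(records$cnr_eff_lte), metric = "cnr_eff", quantity = "LTE"),
    dplyr::mutate(safe_ks(records$cnr_eff_ste), metric = "cnr_eff", quantity = "STE")
  )
  structure(
    list(
      metrics = metrics, tests = tests, normality = normality,
      fractions = improvement_fractions(records), n_cases = nrow(records)
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d cases\n\nMedians (IQR):\n", x$n_cases))
  print(x$metrics)
  cat("\nPaired signed-rank tests (STE vs LTE):\n")
  print(x$tests)
  cat("\nImprovement fractions:\n")
  print(x$fractions)
  invisible(x)
}

#' @rdname cohort_summary
#' @param x a `"cohort_summary"`.
#' @param ... unused.
#' @export
tidy.cohort_summary <- function(x, ...) {
  dplyr::left_join(
    x$metrics,
    dplyr::select(x$tests, "metric", "p_value", "method"),
    by = "metric"
  )
}

#' @rdname cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_cases = x$n_cases,
      p_sir = x$tests$p_value[x$tests$metric == "sir"],
      p_cnr_eff = x$tests$p_value[x$tests$metric == "cnr_eff"]
    ),
    x$fractions[, setdiff(names(x$fractions), "n_cases")]
  )
}
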