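# The generic "response ~ treatment (+ covariates) with atoll varying
# intercept" engine and its instantiations: GSI, growth-GSI correlation,
# tissue nitrogen, density/biomass, and size structure.

#' Fit a treatment-effect model
#'
#' Front end to [fit_bayes()] for island-contrast responses: checks the
#' design (at least 2 islands per treatment), fits the requested family, and
#' returns the posterior of the treatment effect (difference on the link
#' scale, rat_free minus the rat_infested baseline), the atoll intercept SD,
#' and family parameters.
#'
#' @param data data frame with the response, `treatment`, `island_id`, and
#'   (if `group_atoll`) `atoll_id` columns.
#' @inheritParams fit_bayes
#' @return an `fd_effect_fit`.
#' @export
fit_treatment_effect <- function(data, response,
                                 family = c("gaussian", "lognormal",
                                            "hurdle_gamma", "exgaussian"),
                                 covariates = character(),
                                 group_atoll = TRUE,
                                 hurdle_treatment = FALSE,
                                 mcmc = mcmc_config()) {
  family <- match.arg(family)
  if ("island_id" %in% names(data)) {
    per_trt <- dplyr::summarise(
      dplyr::group_by(data, treatment = parse_treatment(.data$treatment)),
      n_island = dplyr::n_distinct(.data$island_id), .groups = "drop"
    )
    if (nrow(per_trt) < 2 || any(per_trt$n_island < 2)) {
      warning("fewer than 2 islands per treatment; the treatment effect is weakly identified",
              call. = FALSE)
    }
  }
  fit_bayes(data, response, family = family, covariates = covariates,
            treatment = TRUE, group_atoll = group_atoll,
            hurdle_treatment = hurdle_treatment, mcmc = mcmc)
}

#' Treatment contrast of a fitted effect model
#'
#' Posterior of the treatment effect on the link scale (identity for
#' gaussian/exgaussian location, log for lognormal and the hurdle-gamma
#' positive part), evaluated at the centered covariates.
#'
#' @param fit an `fd_effect_fit`.
#' @return one-row tibble (`quantity`, `median`, HPDIs) with draws attached
#'   as attribute `"draws"`.
#' @export
treatment_contrast <- function(fit) {
  stopifnot(inherits(fit, "fd_fit"))
  draws <- posterior_draws(fit)
  eff <- switch(fit$model_type, exgaussian = draws$mT, draws$bT)
  if (is.null(eff)) abort_domain("fit has no treatment effect term")
  derived_summary(eff, "treatment_effect")
}

#' Fit the GSI reproductive-investment model
#'
#' Gaussian regression of the gonadosomatic index of spawning-capable
#' females on treatment plus a centered covariate (fish length by default,
#' optionally age, optionally collection day), with an atoll varying
#' intercept. Reports the treatment difference at the sample-mean covariate
#' and the percent difference relative to the rat-infested estimate.
#'
#' @inheritParams fit_vbgf
#' @param covariate `"length"` or `"age"`.
#' @param include_day also adjust for collection day.
#' @return an `fd_gsi_fit` (an `fd_effect_fit` with a `gsi` element holding
#'   the adjusted per-treatment GSI and percent-difference summaries).
#' @export
fit_gsi_model <- function(fish, covariate = c("length", "age"),
                          include_day = FALSE, mcmc = mcmc_config()) {
  covariate <- match.arg(covariate)
  fish <- validate_fish(fish)
  females <- dplyr::filter(
    fish, .data$stage == "spawning_capable_female", !is.na(.data$gonad_weight)
  )
  if (nrow(females) == 0) {
    abort_domain("no spawning-capable females with gonad weights")
  }
  females$gsi <- compute_gsi(females$gonad_weight, females$wet_weight)
  cov_col <- switch(covariate, length = "total_length", age = "age")
  covs <- c(cov_col, if (include_day) "collection_day")
  fit <- fit_bayes(females, "gsi", family = "gaussian", covariates = covs,
                   treatment = TRUE, group_atoll = TRUE, mcmc = mcmc)
  draws <- posterior_draws(fit)
  mu_i <- draws$b0              # adjusted GSI, rat-infested, mean covariate
  mu_f <- draws$b0 + draws$bT
  pct_lower <- 100 * (mu_i - mu_f) / mu_i
  fit$gsi <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(quantity = "gsi_rat_infested"),
                     interval_summary(mu_i)),
    dplyr::bind_cols(tibble::tibble(quantity = "gsi_rat_free"),
                     interval_summary(mu_f)),
    dplyr::bind_cols(tibble::tibble(quantity = "difference"),
                     interval_summary(draws$bT)),
    dplyr::bind_cols(tibble::tibble(quantity = "percent_lower_rat_free"),
                     interval_summary(pct_lower))
  )
  class(fit) <- c("fd_gsi_fit", class(fit))
  fit
}

#' Individual-level growth-fecundity correlation
#'
#' Pairs each spawning-capable female's growth deviate (observed length
#' minus the posterior-median VBGF mean at its age and treatment) with its
#' GSI deviate (observed GSI minus the posterior-median fitted GSI at its
#' length and treatment), and reports the Pearson correlation with a
#' nonparametric bootstrap interval. A negative correlation is the
#' individual-level signature of a growth-reproduction trade-off.
#'
#' @param fish validated fish tibble.
#' @param vbgf_fit an `fd_vbgf_fit` on these fish.
#' @param gsi_fit an `fd_gsi_fit` on these fish (length covariate).
#' @param n_boot bootstrap resamples for the interval (default 2000).
#' @param conf interval mass (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return one-row tibble: `correlation`, `conf_low`, `conf_high`, `n`.
#' @export
growth_gsi_correlation <- function(fish, vbgf_fit, gsi_fit, n_boot = 2000,
                                   conf = 0.95, seed = 1) {
  fish <- validate_fish(fish)
  females <- dplyr::filter(
    fish, .data$stage == "spawning_capable_female", !is.na(.data$gonad_weight)
  )
  if (nrow(females) < 10) {
    abort_domain("growth_gsi_correlation() needs at least 10 paired fish")
  }
  # growth deviate: observed length minus the per-fish posterior median of
  # the VBGF mean at its age and treatment
  vd <- posterior_draws(vbgf_fit)
  rf <- rf_indicator(females$treatment)
  S <- nrow(vd)
  Li <- matrix(vd$L_inf, S, nrow(females)) +
    if (!is.null(vd[["L_inf_b"]])) outer(vd$L_inf_b, rf) else 0
  kk <- matrix(vd$k, S, nrow(females)) + outer(vd$k_b, rf)
  mu_len <- Li - (Li - matrix(vd$L_0, S, nrow(females))) *
    exp(-kk * matrix(females$age, S, nrow(females), byrow = TRUE))
  growth_dev <- females$total_length - apply(mu_len, 2, stats::median)

  # GSI deviate: observed GSI minus the per-fish posterior median of the
  # fitted GSI at its length and treatment
  gd <- posterior_draws(gsi_fit)
  sp <- gsi_fit$spec
  cov_col <- sp$covariates[1]
  gsi_obs <- compute_gsi(females$gonad_weight, females$wet_weight)
  Sg <- nrow(gd)
  eta <- matrix(gd$b0, Sg, nrow(females)) + outer(gd$bT, rf) +
    outer(gd[[paste0("b_", cov_col)]],
          females[[cov_col]] - sp$centers[[cov_col]])
  if (isTRUE(sp$group_atoll)) {
    amat <- as.matrix(gd[paste0("a_", sp$atoll_levels)])
    eta <- eta + amat[, match(as.character(females$atoll_id),
                              sp$atoll_levels), drop = FALSE]
  }
  gsi_dev <- gsi_obs - apply(eta, 2, stats::median)

  r <- stats::cor(growth_dev, gsi_dev)
  n <- length(growth_dev)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    suppressWarnings(stats::cor(growth_dev[i], gsi_dev[i]))
  }, numeric(1)))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  tibble::tibble(correlation = r, conf_low = qs[1], conf_high = qs[2], n = n)
}

#' Back-transform a log-link treatment effect to a ratio
#'
#' For models fitted on a log link (lognormal, or the positive part of a
#' hurdle-gamma), exponentiates the per-draw treatment effect into the
#' multiplicative ratio rat_free : rat_infested.
#'
#' @param fit an `fd_effect_fit` with a log-link family.
#' @return one-row tibble (`quantity = "ratio_rat_free_vs_infested"`,
#'   `median`, HPDIs) with draws attached as attribute `"draws"`.
#' @export
back_transform_ratio <- function(fit) {
  stopifnot(inherits(fit, "fd_fit"))
  if (!fit$model_type %in% c("lognormal", "hurdle_gamma")) {
    abort_domain(
      "back_transform_ratio() needs a log-link model (lognormal or hurdle_gamma)"
    )
  }
  draws <- posterior_draws(fit)
  if (is.null(draws$bT)) abort_domain("fit has no treatment effect term")
  derived_summary(exp(draws$bT), "ratio_rat_free_vs_infested")
}

#' Fit the ex-Gaussian size-structure model
#'
#' Surveyed lengths are modelled as exponentially modified Gaussian with
#' treatment effects on the location `mu` and (log-linked) on the
#' exponential component `tau` — the skew parameter. The derived mean size
#' is `mu + tau` per draw; the mean contrast and the (additive) skew
#' contrast are returned with HPDIs.
#'
#' @param data data frame of surveyed fish with `length` and `treatment`
#'   columns (long-format survey rows; empty-transect rows are ignored).
#' @param group_atoll include an atoll varying intercept on the location
#'   (default `FALSE`: per-fish pooled across transects).
#' @param min_per_treatment minimum observed lengths per treatment
#'   (default 30).
#' @param mcmc an [mcmc_config()].
#' @return an `fd_size_fit` (an `fd_effect_fit` with a `size` element
#'   holding the derived mean/skew contrasts).
#' @export
fit_size_structure <- function(data, group_atoll = FALSE,
                               min_per_treatment = 30,
                               mcmc = mcmc_config()) {
  data <- dplyr::filter(tibble::as_tibble(data), !is.na(.data$length))
  data$treatment <- parse_treatment(data$treatment)
  counts <- table(data$treatment)
  if (length(counts) < 2 || any(counts < min_per_treatment)) {
    abort_domain(sprintf(
      "fit_size_structure() needs >= %d lengths in each treatment",
      min_per_treatment
    ))
  }
  fit <- fit_bayes(data, "length", family = "exgaussian",
                   treatment = TRUE, group_atoll = group_atoll, mcmc = mcmc)
  draws <- posterior_draws(fit)
  tau_i <- exp(draws$t0)
  tau_f <- exp(draws$t0 + draws$tT)
  mean_i <- draws$m0 + tau_i
  mean_f <- draws$m0 + draws$mT + tau_f
  fit$size <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(quantity = "mean_rat_infested"),
                     interval_summary(mean_i)),
    dplyr::bind_cols(tibble::tibble(quantity = "mean_rat_free"),
                     interval_summary(mean_f)),
    dplyr::bind_cols(tibble::tibble(quantity = "mean_difference"),
                     interval_summary(mean_f - mean_i)),
    dplyr::bind_cols(tibble::tibble(quantity = "skew_difference"),
                     interval_summary(tau_f - tau_i)),
    dplyr::bind_cols(tibble::tibble(quantity = "skew_log_effect"),
                     interval_summary(draws$tT))
  )
  class(fit) <- c("fd_size_fit", class(fit))
  fit
}

#' Size-frequency table
#'
#' Counts per treatment in left-closed, right-open bins aligned at the
#' survey minimum size (8 cm) with the given width.
#'
#' @param data data frame with `length` and `treatment` (NA lengths — empty
#'   transects — are dropped).
#' @param binwidth bin width in cm (default 2.5).
#' @param origin left edge of the first bin (default 8 cm); lengths below it
#'   are a domain error.
#' @return tibble: `treatment`, `bin_left`, `bin_right`, `count`.
#' @export
size_frequency <- function(data, binwidth = 2.5, origin = 8) {
  data <- dplyr::filter(tibble::as_tibble(data), !is.na(.data$length))
  if (nrow(data) == 0) {
    return(tibble::tibble(treatment = factor(character(), fd_treatments),
                          bin_left = numeric(), bin_right = numeric(),
                          count = integer()))
  }
  if (any(data$length < origin)) {
    abort_domain(sprintf("lengths below the %g cm origin", origin))
  }
  data$treatment <- parse_treatment(data$treatment)
  idx <- floor((data$length - origin) / binwidth)
  data$bin_left <- origin + idx * binwidth
  out <- dplyr::summarise(
    dplyr::group_by(data, .data$treatment, .data$bin_left),
    count = dplyr::n(), .groups = "drop"
  )
  out$bin_right <- out$bin_left + binwidth
  dplyr::arrange(
    dplyr::select(out, "treatment", "bin_left", "bin_right", "count"),
    .data$treatment, .data$bin_left
  )
}
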