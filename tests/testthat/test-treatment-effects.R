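# Treatment-effect engine instantiations: GSI, correlation, hurdle-gamma,
# ex-Gaussian size structure, size frequency.

test_that("the gaussian engine recovers a simulated nitrogen contrast", {
  fish <- suppressMessages(simulate_fish(synthetic_config(seed = 51)))
  fit <- fit_treatment_effect(fish, "percent_N", family = "gaussian",
                              mcmc = quick_mcmc())
  h <- hpdi(posterior_draws(fit)$bT, 0.95)
  expect_lt(h[["lower"]], 0.23) # generating treatment effect on %N
  expect_gt(h[["upper"]], 0.23)
  ctr <- treatment_contrast(fit)
  expect_equal(ctr$median, median(posterior_draws(fit)$bT))
})

test_that("with pooling, the treatment effect tracks the difference of means", {
  set.seed(53)
  n <- 4000
  dat <- tibble::tibble(
    y = rnorm(n, 10) + 0.4 * rep(0:1, each = n / 2),
    treatment = rep(fd_treatments, each = n / 2)
  )
  fit <- fit_bayes(dat, "y", treatment = TRUE, group_atoll = FALSE,
                   mcmc = quick_mcmc())
  d <- posterior_draws(fit)$bT
  obs_diff <- mean(dat$y[dat$treatment == "rat_free"]) -
    mean(dat$y[dat$treatment == "rat_infested"])
  mcse <- sd(d) / sqrt(ess(matrix(d, ncol = 2)))
  expect_lt(abs(mean(d) - obs_diff), 3 * mcse + 0.01)
})

test_that("a constant response collapses the treatment effect to zero", {
  dat <- tibble::tibble(
    y = rep(2.5, 24), treatment = rep(fd_treatments, 12),
    island_id = rep(c("i1", "i2", "i3", "i4"), 6)
  )
  expect_warning(
    fit <- fit_treatment_effect(dat, "y", family = "gaussian",
                                group_atoll = FALSE, mcmc = tiny_mcmc()),
    "constant"
  )
  d <- posterior_draws(fit)
  expect_lt(abs(median(d$bT)), 0.01)
  expect_lt(median(d$sigma), 0.01)
})

test_that("GSI model reports adjusted contrast and percent difference", {
  fish <- suppressMessages(simulate_fish(synthetic_config(seed = 57)))
  fit <- fit_gsi_model(fish, covariate = "length", mcmc = quick_mcmc())
  h <- hpdi(posterior_draws(fit)$bT, 0.95)
  expect_lt(h[["lower"]], -0.25) # generating GSI treatment shift
  expect_gt(h[["upper"]], -0.25)
  gs <- fit$gsi
  expect_setequal(
    gs$quantity,
    c("gsi_rat_infested", "gsi_rat_free", "difference",
      "percent_lower_rat_free")
  )
  # percent lower is consistent with the two adjusted GSI levels
  d <- posterior_draws(fit)
  expect_equal(
    gs$median[gs$quantity == "percent_lower_rat_free"],
    median(100 * (-d$bT) / d$b0)
  )
  # only spawning-capable females enter
  expect_equal(length(fit$data$y),
               sum(fish$stage == "spawning_capable_female" &
                     !is.na(fish$gonad_weight)))
})

test_that("GSI contrast is robust to the covariate choice", {
  fish <- suppressMessages(simulate_fish(synthetic_config(seed = 59)))
  f_len <- fit_gsi_model(fish, covariate = "length", mcmc = quick_mcmc())
  f_age <- fit_gsi_model(fish, covariate = "age", mcmc = quick_mcmc())
  f_day <- fit_gsi_model(fish, covariate = "length", include_day = TRUE,
                         mcmc = quick_mcmc())
  meds <- vapply(list(f_len, f_age, f_day),
                 function(f) median(posterior_draws(f)$bT), numeric(1))
  expect_lt(max(meds) - min(meds), 0.05)
})

test_that("GSI model demands spawning-capable females", {
  fish <- suppressMessages(simulate_fish(synthetic_config(seed = 3)))
  fish$stage <- "immature"
  expect_error(fit_gsi_model(fish, mcmc = tiny_mcmc()),
               "spawning-capable", class = "fishdemog_domain_error")
})

test_that("growth-GSI deviate correlation covers a null and needs pairs", {
  cfg0 <- synthetic_config(seed = 61)
  cfg0$gsi$rho_growth_gsi <- 0
  fish <- suppressMessages(simulate_fish(cfg0))
  vfit <- fit_vbgf(fish, mcmc = quick_mcmc())
  gfit <- fit_gsi_model(fish, mcmc = quick_mcmc())
  ct <- growth_gsi_correlation(fish, vfit, gfit, seed = 1)
  expect_lt(ct$conf_low, 0)
  expect_gt(ct$conf_high, 0)
  expect_error(growth_gsi_correlation(fish[1:5, ], vfit, gfit),
               "at least 10", class = "fishdemog_domain_error")
})

test_that("log-link ratios back-transform exactly and reject identity links", {
  expect_equal(back_transform_ratio(fake_effect_fit(rep(0, 8)))$median, 1)
  expect_equal(back_transform_ratio(fake_effect_fit(rep(log(2), 8)))$median, 2)
  gfit <- fake_effect_fit(rnorm(8), model_type = "gaussian")
  expect_error(back_transform_ratio(gfit), "log-link",
               class = "fishdemog_domain_error")
})

test_that("label swap inverts the back-transformed ratio", {
  study <- suppressMessages(simulate_study(synthetic_config(seed = 63)))
  isl <- study$islands
  fit1 <- fit_treatment_effect(isl, "seabird_density", family = "lognormal",
                               mcmc = quick_mcmc())
  isl2 <- isl
  isl2$treatment <- factor(
    ifelse(isl2$treatment == "rat_free", "rat_infested", "rat_free"),
    levels = fd_treatments
  )
  fit2 <- fit_treatment_effect(isl2, "seabird_density", family = "lognormal",
                               mcmc = quick_mcmc())
  r1 <- back_transform_ratio(fit1)$median
  r2 <- back_transform_ratio(fit2)$median
  expect_equal(log(r1), -log(r2), tolerance = 0.2)
})

test_that("hurdle-gamma reproduces the zero fraction and positive mean", {
  cfg <- synthetic_config(seed = 65)
  cfg$transects$n_per_island <- 25 # 200 transects
  cfg$transects$occupancy <- c(rat_infested = 0.6, rat_free = 0.6)
  study <- suppressMessages(simulate_study(cfg))
  ts <- transect_summaries(study$transects, study$length_weight)
  fit <- fit_treatment_effect(ts, "density_per_transect",
                              family = "hurdle_gamma", mcmc = quick_mcmc())
  p0 <- median(posterior_draws(fit)$p_zero)
  n <- nrow(ts)
  expect_lt(abs(p0 - 0.4), 3 * sqrt(0.4 * 0.6 / n) + 0.02)
  # the hurdle likelihood decomposes: fitted zero prob matches the observed
  # zero fraction (intercept-only hurdle)
  expect_lt(abs(p0 - mean(ts$count == 0)), 2.5 * sqrt(0.4 * 0.6 / n))
  rat <- back_transform_ratio(fit)
  expect_true(is.finite(rat$median))
})

test_that("ex-Gaussian size model: mean identity and null contrasts", {
  cfg <- synthetic_config(seed = 67)
  cfg$transects$n_per_island <- 10
  cfg$transects$occupancy <- c(rat_infested = 1, rat_free = 1)
  cfg$transects$exg_mu <- c(rat_infested = 13, rat_free = 13)
  cfg$transects$exg_tau <- c(rat_infested = 2, rat_free = 2)
  tr <- simulate_transects(cfg)
  fit <- fit_size_structure(tr, mcmc = quick_mcmc())
  d <- posterior_draws(fit)
  # derived mean = mu + tau holds per draw by construction
  sz <- fit$size
  mean_i <- sz$median[sz$quantity == "mean_rat_infested"]
  expect_equal(mean_i, median(d$m0 + exp(d$t0)))
  # equal generating parameters: both contrasts cover 0
  h_mean <- hpdi(attr_draws <- (d$m0 + d$mT + exp(d$t0 + d$tT)) -
                   (d$m0 + exp(d$t0)), 0.95)
  expect_lt(h_mean[["lower"]], 0)
  expect_gt(h_mean[["upper"]], 0)
  h_skew <- hpdi(exp(d$t0 + d$tT) - exp(d$t0), 0.95)
  expect_lt(h_skew[["lower"]], 0)
  expect_gt(h_skew[["upper"]], 0)
  expect_error(fit_size_structure(tr[1:20, ], mcmc = tiny_mcmc()),
               class = "fishdemog_domain_error")
})

test_that("size-frequency bins are left-closed and aligned at 8 cm", {
  one <- tibble::tibble(length = 8, treatment = "rat_free")
  out <- size_frequency(one)
  expect_equal(out$bin_left, 8)
  expect_equal(out$bin_right, 10.5)
  expect_equal(out$count, 1L)
  two <- tibble::tibble(length = c(10.4, 10.5), treatment = "rat_free")
  out2 <- size_frequency(two)
  expect_equal(out2$bin_left, c(8, 10.5))
  expect_equal(out2$count, c(1L, 1L))
  empty <- size_frequency(tibble::tibble(length = numeric(),
                                         treatment = character()))
  expect_equal(nrow(empty), 0)
  expect_error(size_frequency(tibble::tibble(length = 6,
                                             treatment = "rat_free")),
               class = "fishdemog_domain_error")
})
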