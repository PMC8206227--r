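# VBGF mean function, offset fits, three-age reparameterization, and
# upper-quartile extremes.

test_that("VBGF mean length matches closed-form evaluations", {
  p <- list(L_inf = 25, L_0 = 8, k = 0.27, k_b = 0.11)
  # t = 0 cancels the exponential: exactly L_0 for either treatment
  expect_identical(vbgf_mean_length(0, p), 8)
  expect_identical(vbgf_mean_length(0, p, rat_free = TRUE), 8)
  expect_equal(vbgf_mean_length(4, p), 25 - 17 * exp(-0.27 * 4),
               tolerance = 1e-12)
  expect_equal(vbgf_mean_length(4, p, rat_free = TRUE),
               25 - 17 * exp(-0.38 * 4), tolerance = 1e-12)
  expect_error(vbgf_mean_length(-1, p), class = "fishdemog_domain_error")
  expect_error(vbgf_mean_length(2, list(L_inf = 8, L_0 = 9, k = 0.2, k_b = 0)),
               class = "fishdemog_domain_error")
})

test_that("the VBGF curve rises monotonically to within 1% of the asymptote", {
  set.seed(19)
  for (i in 1:25) {
    p <- list(L_inf = runif(1, 20, 60), L_0 = runif(1, 0, 10),
              k = runif(1, 0.05, 0.8), k_b = runif(1, -0.04, 0.4))
    for (flag in c(FALSE, TRUE)) {
      ages <- seq(0, 20, by = 0.25)
      lens <- vbgf_mean_length(ages, p, rat_free = flag)
      expect_true(all(diff(lens) > 0))
      kk <- p$k + p$k_b * flag
      t_star <- log(100) / kk
      far <- vbgf_mean_length(t_star * 1.0001, p, rat_free = flag)
      expect_lt(abs(far - p$L_inf), 0.01 * (p$L_inf - p$L_0))
    }
  }
})

test_that("three-age mapping inverts exactly and reproduces the curve", {
  set.seed(23)
  for (i in 1:50) {
    L_inf <- runif(1, 20, 40)
    L_0 <- runif(1, 0, 10)
    k <- runif(1, 0.1, 0.7)
    la <- vbgf_to_three_age(L_inf, L_0, k)
    back <- three_age_to_vbgf(la$l_phi, la$l_chi, la$l_psi)
    expect_equal(back$L_inf, L_inf, tolerance = 1e-9)
    expect_equal(back$L_0, L_0, tolerance = 1e-9)
    expect_equal(back$k, k, tolerance = 1e-9)
    # the Francis mean curve is the same function of age
    ages <- seq(0.5, 10, by = 0.5)
    expect_equal(
      francis_mean(ages, la$l_phi, la$l_chi, la$l_psi),
      vbgf_mean_length(ages, list(L_inf = L_inf, L_0 = L_0, k = k, k_b = 0)),
      tolerance = 1e-9
    )
  }
  expect_error(three_age_to_vbgf(15, 14, 20), class = "fishdemog_domain_error")
  expect_error(francis_mean(2, 10, 15, 20, reference_ages = c(2, 3, 6)),
               "mean of the outer two")
})

test_that("the offset fit recovers k_b and derived contrasts cohere", {
  fish <- suppressMessages(simulate_fish(synthetic_config(seed = 31)))
  fit <- fit_vbgf(fish, variant = "offset_k", mcmc = quick_mcmc())
  d <- posterior_draws(fit)
  h <- hpdi(d$k_b, 0.95)
  expect_lt(h[["lower"]], 0.10)
  expect_gt(h[["upper"]], 0.10)
  # derived percent growth difference is the per-draw ratio
  pct <- percent_growth_difference(fit)
  expect_equal(pct$median, median(100 * d$k_b / d$k))
  # contrast at age 4 equals the difference of the mean curves per draw
  ctr <- length_at_age_contrast(fit, ages = 4)
  manual <- median(
    (d$L_inf - (d$L_inf - d$L_0) * exp(-(d$k + d$k_b) * 4)) -
      (d$L_inf - (d$L_inf - d$L_0) * exp(-d$k * 4))
  )
  expect_equal(ctr$median, manual)
})

test_that("point-mass draws yield the arithmetic percent difference", {
  fish <- suppressMessages(simulate_fish(synthetic_config(seed = 31)))
  fit <- fit_vbgf(fish, variant = "offset_k", mcmc = tiny_mcmc())
  fit$draws$k <- 0.27
  fit$draws$k_b <- 0.11
  fit$draws$L_inf <- 25
  fit$draws$L_0 <- 8
  expect_equal(percent_growth_difference(fit)$median, 100 * 0.11 / 0.27,
               tolerance = 1e-12)
  ctr <- length_at_age_contrast(fit, ages = 4)
  expect_equal(ctr$median,
               (25 - 17 * exp(-0.38 * 4)) - (25 - 17 * exp(-0.27 * 4)),
               tolerance = 1e-12)
})

test_that("a null simulation keeps 0 inside the k_b interval", {
  cfg <- synthetic_config(
    growth = list(L_inf = 25, L_0 = 8, k = 0.27, k_b = 0, sigma_L = 1),
    seed = 37
  )
  fish <- suppressMessages(simulate_fish(cfg))
  fit <- fit_vbgf(fish, variant = "offset_k", mcmc = quick_mcmc())
  h <- hpdi(posterior_draws(fit)$k_b, 0.95)
  expect_lt(h[["lower"]], 0)
  expect_gt(h[["upper"]], 0)
})

test_that("swapping treatment labels negates the growth offset", {
  fish <- suppressMessages(simulate_fish(synthetic_config(seed = 41)))
  fit <- fit_vbgf(fish, variant = "offset_k", mcmc = quick_mcmc())
  swapped <- fish
  swapped$treatment <- factor(
    ifelse(swapped$treatment == "rat_free", "rat_infested", "rat_free"),
    levels = fd_treatments
  )
  # islands keep one treatment each, so validation still holds
  fit_sw <- fit_vbgf(swapped, variant = "offset_k", mcmc = quick_mcmc())
  k1 <- posterior_draws(fit)$k_b
  k2 <- posterior_draws(fit_sw)$k_b
  expect_lt(abs(median(k1) + median(k2)), 3 * (sd(k1) + sd(k2)) / 2)
})

test_that("single-age treatments are rejected as unidentifiable", {
  fish <- suppressMessages(simulate_fish(synthetic_config(seed = 3)))
  fish$age[fish$treatment == "rat_free"] <- 4
  expect_error(fit_vbgf(fish, mcmc = tiny_mcmc()), "distinct ages",
               class = "fishdemog_domain_error")
})

test_that("three-age fit recovers a near-noiseless curve at the middle age", {
  cfg <- synthetic_config(
    growth = list(L_inf = 25, L_0 = 8, k = 0.27, k_b = 0.10, sigma_L = 0.05),
    seed = 43
  )
  fish <- suppressMessages(simulate_fish(cfg))
  expect_warning(
    fit <- fit_three_age_vbgf(fish, mcmc = quick_mcmc()),
    regexp = NA
  )
  d <- posterior_draws(fit)
  truth_chi_inf <- 25 - 17 * exp(-0.27 * 4)
  truth_chi_free <- 25 - 17 * exp(-0.37 * 4) # generating k + k_b = 0.37
  expect_equal(median(d$l_chi_rat_infested), truth_chi_inf, tolerance = 0.01)
  expect_equal(median(d$l_chi_rat_free), truth_chi_free, tolerance = 0.01)
  # treatment contrast at age 4 consistent with the standard-VBGF contrast
  ctr <- length_at_age_contrast(fit, ages = 4)
  expect_equal(ctr$median, truth_chi_free - truth_chi_inf, tolerance = 0.05)
})

test_that("upper-quartile island values follow the stated quantile rule", {
  expect_equal(upper_quartile_mean(c(2, 2, 2, 2)), 2)
  # quantile(1:8, .75) = 6.25 -> observations >= 6.25 are {7, 8}
  expect_equal(upper_quartile_mean(1:8), 7.5)
})

test_that("upper-quartile extremes flag small islands and contrast treatments", {
  cfg <- synthetic_config(seed = 47)
  fish <- suppressMessages(simulate_fish(cfg))
  # shrink one island below the quartile threshold
  drop <- which(fish$island_id == fish$island_id[1])[-(1:3)]
  fish <- fish[-drop, ]
  expect_message(
    ex <- upper_quartile_extremes(fish, metric = "length",
                                  mcmc = quick_mcmc()),
    "full-sample mean"
  )
  expect_true(any(ex$island_values$flagged))
  expect_true(all(ex$island_values$value <=
                    tapply(fish$total_length, fish$island_id, max)[
                      ex$island_values$island_id
                    ] + 1e-9))
  expect_equal(nrow(ex$contrast), 3)
  # lengths are larger around rat-free islands under the default truth
  expect_gt(ex$contrast$median[ex$contrast$quantity == "difference"], 0)
})
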