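# The synthetic-study generator: generative structure, determinism, and
# convergence of sample moments to the configured truth.

test_that("generated tables pass the domain validation", {
  study <- suppressMessages(simulate_study(synthetic_config(seed = 7)))
  expect_silent(validate_fish(study$fish))
  expect_silent(validate_transects(study$transects))
  expect_silent(validate_islands(study$islands))
  # design shape: 3 atolls, 2+1+1 islands per treatment arm, 15 fish each
  expect_equal(dplyr::n_distinct(study$fish$island_id), 8)
  expect_equal(nrow(study$fish), 120)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(seed = 11)
  s1 <- suppressMessages(simulate_study(cfg))
  s2 <- suppressMessages(simulate_study(cfg))
  expect_identical(s1$fish, s2$fish)
  expect_identical(s1$transects, s2$transects)
  expect_identical(s1$islands, s2$islands)
})

test_that("noiseless growth puts every length exactly on the treatment curve", {
  cfg <- synthetic_config(
    growth = list(L_inf = 25, L_0 = 8, k = 0.27, k_b = 0.10, sigma_L = 0),
    atoll_sd = list(length = 0, gsi = 0.1, isotope = 0.1), seed = 3
  )
  fish <- suppressMessages(simulate_fish(cfg))
  g <- cfg$growth
  rf <- as.integer(fish$treatment == "rat_free")
  curve <- g$L_inf - (g$L_inf - g$L_0) * exp(-(g$k + g$k_b * rf) * fish$age)
  expect_equal(fish$total_length, round(curve, 1)) # lengths recorded to 0.1 cm
})

test_that("latent growth-GSI deviates carry the configured correlation", {
  cfg <- synthetic_config(fish_per_island = 625, seed = 5) # n = 5000
  fish <- suppressMessages(simulate_fish(cfg, keep_latent = TRUE))
  expect_equal(stats::cor(fish$.growth_dev, fish$.gsi_dev), -0.26,
               tolerance = 0.03 / 0.26)
})

test_that("changing the GSI block leaves the growth columns untouched", {
  base <- synthetic_config(seed = 9)
  alt <- synthetic_config(
    gsi = list(intercept = 2, beta_length = 0, beta_treatment = 0,
               sigma_G = 0.1, rho_growth_gsi = 0.5),
    seed = 9
  )
  f1 <- suppressMessages(simulate_fish(base))
  f2 <- suppressMessages(simulate_fish(alt))
  expect_identical(f1$total_length, f2$total_length)
  expect_identical(f1$age, f2$age)
  expect_false(identical(f1$gonad_weight, f2$gonad_weight))
  # transects draw from separate streams entirely
  expect_identical(simulate_transects(base), simulate_transects(alt))
})

test_that("degenerate hurdle: zero occupancy gives only empty transects", {
  cfg <- synthetic_config(seed = 2)
  cfg$transects$occupancy <- c(rat_infested = 0, rat_free = 0)
  tr <- simulate_transects(cfg)
  expect_true(all(is.na(tr$length)))
  expect_equal(nrow(tr), 8 * 4) # one placeholder row per transect
})

test_that("occupied transect counts converge to the gamma mean", {
  cfg <- synthetic_config(
    n_atolls = 1, islands_per_atoll_per_treatment = 1, seed = 21
  )
  cfg$transects$n_per_island <- 1000 # 2000 transects in total
  cfg$transects$occupancy <- c(rat_infested = 1, rat_free = 1)
  cfg$transects$gamma_mean <- c(rat_infested = 10, rat_free = 10)
  tr <- simulate_transects(cfg)
  counts <- dplyr::count(dplyr::filter(tr, !is.na(.data$length)),
                         .data$transect_id)$n
  expect_length(counts, 2000)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 10), 3 * se)
})

test_that("the exponential component governs the right skew of sizes", {
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  base <- synthetic_config(n_atolls = 1, islands_per_atoll_per_treatment = 1,
                           seed = 13)
  base$transects$n_per_island <- 40
  base$transects$occupancy <- c(rat_infested = 1, rat_free = 1)
  base$transects$gamma_mean <- c(rat_infested = 30, rat_free = 30)
  base$transects$exg_mu <- c(rat_infested = 20, rat_free = 20)

  heavy <- base
  heavy$transects$exg_tau <- c(rat_infested = 6, rat_free = 6)
  light <- base
  light$transects$exg_tau <- c(rat_infested = 0, rat_free = 0)

  s_heavy <- skew(simulate_transects(heavy)$length |> stats::na.omit())
  s_light <- skew(simulate_transects(light)$length |> stats::na.omit())
  expect_gt(s_heavy, 0.5)   # strongly right-skewed
  expect_lt(abs(s_light), 0.25) # tau = 0 limit is symmetric
})

test_that("island covariates show the configured seabird ratio and nothing else", {
  cfg <- synthetic_config(n_atolls = 40, islands_per_atoll_per_treatment = 1,
                          seed = 17)
  cfg$islands$seabird_ratio <- 100
  isl <- simulate_islands(cfg)
  gm <- tapply(log(isl$seabird_density), isl$treatment, mean)
  ratio <- exp(gm[["rat_free"]] - gm[["rat_infested"]])
  # 3 MC SEs of the log-ratio at sdlog 1, n = 40 per arm
  tol <- exp(3 * sqrt(2 / 40))
  expect_gt(ratio, 100 / tol)
  expect_lt(ratio, 100 * tol)
  # shared covariates have no treatment structure by construction
  cfg$islands$sst_sd <- 0
  isl0 <- simulate_islands(cfg)
  expect_equal(dplyr::n_distinct(isl0$sst), 1)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(growth = list(L_inf = 25, L_0 = 8, k = 0.1,
                                              k_b = -0.2, sigma_L = 1)),
               "k \\+ k_b", class = "fishdemog_config_error")
  expect_error(
    synthetic_config(gsi = list(intercept = 1, beta_length = 0,
                                beta_treatment = 0, sigma_G = 0.4,
                                rho_growth_gsi = -1.2)),
    "rho", class = "fishdemog_config_error"
  )
  cfg <- synthetic_config()
  cfg$transects$occupancy <- c(rat_infested = 1.4, rat_free = 0.5)
  expect_error(simulate_transects(cfg), "occupancy",
               class = "fishdemog_config_error")
})
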