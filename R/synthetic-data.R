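# Synthetic study generator: fish collections, belt-transect surveys, and
# island covariates drawn from the exact generative structure the analysis
# models assume, under known ("truth") parameters, for simulation-based
# parameter recovery.

#' Build a synthetic-study configuration
#'
#' The defaults emulate the study design the package targets: 3 atolls with
#' paired rat-free / rat-infested islands (2+2, 1+1, 1+1 = 8 islands), 15
#' collected fish per island, growth on a von Bertalanffy curve whose growth
#' coefficient is offset by `k_b` around rat-free islands, GSI linear in
#' length with a negative treatment shift and an individual-level negative
#' growth-fecundity correlation, zero-inflated per-transect counts with
#' gamma-distributed positive densities, and right-skewed (ex-Gaussian) size
#' distributions with treatment effects on location and skew.
#'
#' @param n_atolls number of atolls.
#' @param islands_per_atoll_per_treatment islands per atoll in each treatment
#'   arm; scalar or one value per atoll.
#' @param fish_per_island collected fish per island.
#' @param growth list: `L_inf`, `L_0` (cm), `k`, `k_b` (yr^-1, offset applied
#'   for rat-free), `sigma_L` (residual SD, cm).
#' @param age_distribution list with integer `ages` and matching `prob`
#'   (default uniform on 1..8 years).
#' @param gsi list: `intercept` (percent, rat-infested at the mean length),
#'   `beta_length` (percent per cm), `beta_treatment` (shift for rat-free),
#'   `sigma_G`, and `rho_growth_gsi` in [-1, 1], the latent correlation
#'   between the growth and GSI deviates of an individual.
#' @param atoll_sd list of atoll-intercept SDs per response: `length`, `gsi`,
#'   `isotope`.
#' @param isotopes list of per-treatment means and SDs for muscle `percent_N`
#'   and `d15N`.
#' @param stage_probs named probabilities over reproductive stages.
#' @param weight_cv lognormal CV of wet weight around the length-weight curve.
#' @param transects list: `n_per_island`, `area` (m^2), per-treatment
#'   `occupancy` (probability a transect holds any fish), `gamma_mean`
#'   (expected count per occupied transect), `gamma_shape`, and per-treatment
#'   ex-Gaussian size parameters `exg_mu`, `exg_sigma`, `exg_tau` (cm).
#' @param islands list of island-covariate generators: lognormal seabird
#'   density with a multiplicative treatment `seabird_ratio`, and shared
#'   normal/lognormal SST, wave exposure, NPP, and island area.
#' @param length_weight synthetic per-species length-weight coefficients
#'   (`species`, `a`, `b`).
#' @param seed integer RNG seed; every simulator output is byte-identical
#'   under a fixed seed.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_atolls = 3,
    islands_per_atoll_per_treatment = c(2, 1, 1),
    fish_per_island = 15,
    growth = list(L_inf = 25, L_0 = 8, k = 0.27, k_b = 0.10, sigma_L = 1),
    age_distribution = list(ages = 1:8, prob = rep(1 / 8, 8)),
    gsi = list(intercept = 1.20, beta_length = 0.02, beta_treatment = -0.25,
               sigma_G = 0.45, rho_growth_gsi = -0.26),
    atoll_sd = list(length = 0, gsi = 0.1, isotope = 0.1),
    isotopes = list(
      percent_N_mean = c(rat_infested = 12.20, rat_free = 12.43),
      percent_N_sd = 0.25,
      d15N_mean = c(rat_infested = 11.00, rat_free = 11.02),
      d15N_sd = 0.40
    ),
    stage_probs = c(spawning_capable_female = 0.85, regenerating_female = 0.10,
                    immature = 0.03, transitional = 0.015, ip_male = 0.005),
    weight_cv = 0.05,
    transects = list(
      n_per_island = 4, area = 150,
      occupancy = c(rat_infested = 14 / 24, rat_free = 8 / 20),
      gamma_mean = c(rat_infested = 8, rat_free = 5.6),
      gamma_shape = 1.5,
      exg_mu = c(rat_infested = 12.5, rat_free = 14.37),
      exg_sigma = c(rat_infested = 2, rat_free = 2),
      exg_tau = c(rat_infested = 1.8, rat_free = 2.26)
    ),
    islands = list(
      seabird_baseline = 0.05, seabird_ratio = 760, seabird_sdlog = 1,
      sst_mean = 28.5, sst_sd = 0.2, wave_mean = 1, wave_sd = 0.2,
      npp_mean = 500, npp_sd = 50, area_meanlog = log(50), area_sdlog = 0.8
    ),
    length_weight = list(species = "synthetic_parrotfish", a = 0.0125, b = 3),
    seed = 1L) {
  cfg <- list(
    n_atolls = n_atolls,
    islands_per_atoll_per_treatment = islands_per_atoll_per_treatment,
    fish_per_island = fish_per_island,
    growth = growth, age_distribution = age_distribution, gsi = gsi,
    atoll_sd = atoll_sd, isotopes = isotopes, stage_probs = stage_probs,
    weight_cv = weight_cv, transects = transects, islands = islands,
    length_weight = length_weight, seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  assert_scalar_number(cfg$n_atolls, "n_atolls", lower = 1)
  ipa <- cfg$islands_per_atoll_per_treatment
  if (length(ipa) == 1L) ipa <- rep(ipa, cfg$n_atolls)
  if (length(ipa) != cfg$n_atolls || any(ipa < 1)) {
    abort_config("islands_per_atoll_per_treatment must give >= 1 island per atoll")
  }
  cfg$islands_per_atoll_per_treatment <- ipa
  assert_scalar_number(cfg$fish_per_island, "fish_per_island", lower = 1)
  g <- cfg$growth
  assert_scalar_number(g$sigma_L, "growth$sigma_L", lower = 0)
  if (g$k + g$k_b <= 0) abort_config("growth must satisfy k + k_b > 0")
  if (g$L_inf <= g$L_0 || g$L_0 < 0) {
    abort_config("growth must satisfy L_inf > L_0 >= 0")
  }
  ad <- cfg$age_distribution
  if (length(ad$ages) != length(ad$prob) || any(ad$prob < 0) ||
      abs(sum(ad$prob) - 1) > 1e-8) {
    abort_config("age_distribution$prob must be a probability vector over ages")
  }
  assert_scalar_number(cfg$gsi$sigma_G, "gsi$sigma_G", lower = 0)
  if (abs(cfg$gsi$rho_growth_gsi) > 1) {
    abort_config("|gsi$rho_growth_gsi| must be <= 1")
  }
  for (nm in names(cfg$atoll_sd)) {
    assert_scalar_number(cfg$atoll_sd[[nm]], paste0("atoll_sd$", nm), lower = 0)
  }
  tr <- cfg$transects
  if (any(tr$occupancy < 0 | tr$occupancy > 1)) {
    abort_config("transects$occupancy must lie in [0, 1]")
  }
  if (any(tr$gamma_mean <= 0) || tr$gamma_shape <= 0) {
    abort_config("transects gamma mean and shape must be > 0")
  }
  if (any(tr$exg_sigma <= 0) || any(tr$exg_tau < 0)) {
    abort_config("transects ex-Gaussian sigma must be > 0 and tau >= 0")
  }
  if (any(cfg$stage_probs < 0) || abs(sum(cfg$stage_probs) - 1) > 1e-8) {
    abort_config("stage_probs must be a probability vector")
  }
  if (cfg$length_weight$a <= 0 || cfg$length_weight$b <= 0) {
    abort_config("length_weight coefficients must be > 0")
  }
  structure(cfg, class = "synthetic_config")
}

# Island layout implied by a config: one row per island.
island_layout <- function(cfg) {
  rows <- list()
  for (a in seq_len(cfg$n_atolls)) {
    atoll <- sprintf("atoll_%d", a)
    for (tr in fd_treatments) {
      for (i in seq_len(cfg$islands_per_atoll_per_treatment[a])) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          atoll_id = atoll, treatment = tr,
          island_id = sprintf("%s_%s_%d", atoll, tr, i)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$treatment <- parse_treatment(out$treatment)
  out[, c("island_id", "atoll_id", "treatment")]
}

#' Expected mean collected length under a configuration
#'
#' Deterministic expectation of total length over the configured age
#' distribution, averaged over the two treatments; used as the centering
#' constant of the generative GSI-on-length regression.
#'
#' @param cfg a [synthetic_config()].
#' @return scalar mean length in cm.
#' @export
expected_mean_length <- function(cfg) {
  g <- cfg$growth
  ad <- cfg$age_distribution
  m <- vapply(c(0, 1), function(rf) {
    sum(ad$prob * (g$L_inf - (g$L_inf - g$L_0) *
                     exp(-(g$k + g$k_b * rf) * ad$ages)))
  }, numeric(1))
  mean(m)
}

#' Simulate a fish collection table
#'
#' For each fish: an age is drawn from the configured distribution; a latent
#' bivariate-standard-normal pair (u, v) with correlation `rho_growth_gsi`
#' supplies the growth and GSI deviates; length is the treatment-specific
#' VBGF mean plus an atoll intercept plus `sigma_L * u`; wet weight follows
#' the length-weight curve with lognormal noise; the gonad weight is chosen
#' so that GSI equals the linear predictor
#' `intercept + beta_length * (length - mean length) + beta_treatment *
#' rat_free + atoll intercept + sigma_G * v`, floored at zero (GSI is
#' physically nonnegative; the number of floored rows is reported as a
#' message); muscle percent nitrogen and d15N are normal per treatment.
#' Regenerating females carry a down-scaled resting GSI; non-female stages
#' have no gonad weight.
#'
#' @param cfg a [synthetic_config()].
#' @param keep_latent if `TRUE`, append the latent deviates as columns
#'   `.growth_dev` (u) and `.gsi_dev` (v).
#' @return a validated fish tibble (see [validate_fish()]).
#' @export
simulate_fish <- function(cfg, keep_latent = FALSE) {
  cfg <- validate_synthetic_config(unclass(cfg))
  layout <- island_layout(cfg)
  n_island <- nrow(layout)
  n <- n_island * cfg$fish_per_island
  fish <- layout[rep(seq_len(n_island), each = cfg$fish_per_island), ]
  rf <- rf_indicator(fish$treatment)
  g <- cfg$growth

  ages <- with_seed(cfg$seed + 1L, sample(
    cfg$age_distribution$ages, n, replace = TRUE,
    prob = cfg$age_distribution$prob
  ))
  atolls <- sort(unique(layout$atoll_id))
  a_int <- with_seed(cfg$seed + 2L, list(
    length = stats::setNames(stats::rnorm(length(atolls), 0, cfg$atoll_sd$length), atolls),
    gsi = stats::setNames(stats::rnorm(length(atolls), 0, cfg$atoll_sd$gsi), atolls),
    iso = stats::setNames(stats::rnorm(length(atolls), 0, cfg$atoll_sd$isotope), atolls)
  ))
  u <- with_seed(cfg$seed + 3L, stats::rnorm(n))
  z <- with_seed(cfg$seed + 4L, stats::rnorm(n))
  rho <- cfg$gsi$rho_growth_gsi
  v <- rho * u + sqrt(1 - rho^2) * z

  mean_len <- g$L_inf - (g$L_inf - g$L_0) * exp(-(g$k + g$k_b * rf) * ages)
  length_cm <- round(
    mean_len + unname(a_int$length[fish$atoll_id]) + g$sigma_L * u, 1
  )

  w_noise <- with_seed(cfg$seed + 5L, stats::rnorm(n, 0, cfg$weight_cv))
  weight_kg <- length_to_weight(length_cm, cfg$length_weight$a,
                                cfg$length_weight$b) * exp(w_noise) / 1000

  lbar <- expected_mean_length(cfg)
  gsi_mean <- cfg$gsi$intercept + cfg$gsi$beta_length * (length_cm - lbar) +
    cfg$gsi$beta_treatment * rf + unname(a_int$gsi[fish$atoll_id])
  gsi_val <- gsi_mean + cfg$gsi$sigma_G * v
  n_floored <- sum(gsi_val < 0)
  if (n_floored > 0) {
    message(sprintf("simulate_fish: floored %d negative GSI value(s) at 0",
                    n_floored))
  }
  gsi_val <- pmax(gsi_val, 0)

  iso <- with_seed(cfg$seed + 6L, {
    trt <- as.character(fish$treatment)
    list(
      pN = stats::rnorm(n, cfg$isotopes$percent_N_mean[trt],
                        cfg$isotopes$percent_N_sd) +
        unname(a_int$iso[fish$atoll_id]),
      dN = stats::rnorm(n, cfg$isotopes$d15N_mean[trt], cfg$isotopes$d15N_sd)
    )
  })
  stage <- with_seed(cfg$seed + 7L, sample(
    names(cfg$stage_probs), n, replace = TRUE, prob = cfg$stage_probs
  ))

  gonad_g <- dplyr::case_when(
    stage == "spawning_capable_female" ~ gsi_val / 100 * weight_kg * 1000,
    stage == "regenerating_female" ~ 0.35 * gsi_val / 100 * weight_kg * 1000,
    TRUE ~ NA_real_
  )
  day <- match(fish$atoll_id, atolls) * 5L - 4L +
    as.integer(factor(fish$island_id)) %% 3L

  out <- tibble::tibble(
    fish_id = sprintf("F%04d", seq_len(n)),
    island_id = fish$island_id, atoll_id = fish$atoll_id,
    treatment = fish$treatment,
    total_length = length_cm, wet_weight = round(weight_kg, 4),
    age = ages, stage = stage,
    gonad_weight = round(gonad_g, 2),
    percent_N = round(iso$pN, 2), d15N = round(iso$dN, 2),
    collection_day = day
  )
  out <- validate_fish(out)
  if (keep_latent) {
    out$.growth_dev <- u
    out$.gsi_dev <- v
  }
  out
}

# Ex-Gaussian draws truncated below at `lower`, rounded to the nearest cm
# (mirrors visual-census precision).
rexgauss_trunc <- function(n, mu, sigma, tau, lower = 8) {
  out <- numeric(n)
  left <- seq_len(n)
  while (length(left)) {
    cand <- stats::rnorm(length(left), mu, sigma) +
      if (tau > 0) stats::rexp(length(left), 1 / tau) else 0
    ok <- cand >= lower
    out[left[ok]] <- cand[ok]
    left <- left[!ok]
  }
  round(out)
}

#' Simulate a belt-transect survey table
#'
#' Per transect: with probability `1 - occupancy` the transect is a true
#' zero; otherwise a positive expected count is drawn from the treatment's
#' gamma component, integerised (rounded, floor 1), and that many lengths
#' are drawn from the treatment's ex-Gaussian size distribution truncated at
#' the survey's minimum size cutoff of 8 cm and rounded to the nearest cm.
#'
#' @inheritParams simulate_fish
#' @return a validated long-format survey tibble (see
#'   [validate_transects()]); zero transects appear as a single row with
#'   empty `species`/`length`.
#' @export
simulate_transects <- function(cfg) {
  cfg <- validate_synthetic_config(unclass(cfg))
  layout <- island_layout(cfg)
  tr <- cfg$transects
  grid <- layout[rep(seq_len(nrow(layout)), each = tr$n_per_island), ]
  grid$transect_id <- sprintf(
    "%s_T%d", grid$island_id,
    rep(seq_len(tr$n_per_island), times = nrow(layout))
  )
  grid$area <- tr$area
  trt <- as.character(grid$treatment)
  nt <- nrow(grid)

  occupied <- with_seed(cfg$seed + 10L,
                        stats::runif(nt) < tr$occupancy[trt])
  raw <- with_seed(cfg$seed + 11L, stats::rgamma(
    nt, shape = tr$gamma_shape, rate = tr$gamma_shape / tr$gamma_mean[trt]
  ))
  counts <- ifelse(occupied, pmax(1L, round(raw)), 0L)

  lengths <- with_seed(cfg$seed + 12L, {
    lapply(seq_len(nt), function(i) {
      if (counts[i] == 0) return(numeric())
      rexgauss_trunc(counts[i], tr$exg_mu[trt[i]], tr$exg_sigma[trt[i]],
                     tr$exg_tau[trt[i]])
    })
  })

  rows <- lapply(seq_len(nt), function(i) {
    base <- grid[i, c("island_id", "atoll_id", "treatment", "transect_id",
                      "area")]
    if (counts[i] == 0) {
      base$species <- NA_character_
      base$length <- NA_real_
      return(base)
    }
    out <- base[rep(1L, counts[i]), ]
    out$species <- cfg$length_weight$species
    out$length <- lengths[[i]]
    out
  })
  validate_transects(dplyr::bind_rows(rows))
}

#' Simulate an island covariate table
#'
#' Seabird density is lognormal with a configurable multiplicative treatment
#' ratio (rat-free islands richer by `seabird_ratio`); SST, wave exposure
#' and NPP are normal and shared across treatments; island area is
#' lognormal. Deterministic under the configured seed.
#'
#' @inheritParams simulate_fish
#' @return validated island tibble (see [validate_islands()]).
#' @export
simulate_islands <- function(cfg) {
  cfg <- validate_synthetic_config(unclass(cfg))
  layout <- island_layout(cfg)
  n <- nrow(layout)
  rf <- rf_indicator(layout$treatment)
  isl <- cfg$islands
  seabird <- with_seed(cfg$seed + 20L, stats::rlnorm(
    n, meanlog = log(isl$seabird_baseline) + log(isl$seabird_ratio) * rf,
    sdlog = isl$seabird_sdlog
  ))
  covs <- with_seed(cfg$seed + 21L, list(
    sst = stats::rnorm(n, isl$sst_mean, isl$sst_sd),
    wave = stats::rnorm(n, isl$wave_mean, isl$wave_sd),
    npp = stats::rnorm(n, isl$npp_mean, isl$npp_sd),
    area = stats::rlnorm(n, isl$area_meanlog, isl$area_sdlog)
  ))
  validate_islands(tibble::tibble(
    island_id = layout$island_id, atoll_id = layout$atoll_id,
    treatment = layout$treatment,
    seabird_density = seabird, sst = covs$sst, wave_exposure = covs$wave,
    npp = covs$npp, island_area = covs$area
  ))
}

#' Simulate the full synthetic study
#'
#' @inheritParams simulate_fish
#' @return list with elements `fish`, `transects`, `islands`,
#'   `length_weight` (coefficient tibble), and `truth` (the configuration).
#' @export
simulate_study <- function(cfg, keep_latent = FALSE) {
  cfg <- validate_synthetic_config(unclass(cfg))
  list(
    fish = simulate_fish(cfg, keep_latent = keep_latent),
    transects = simulate_transects(cfg),
    islands = simulate_islands(cfg),
    length_weight = tibble::tibble(
      species = cfg$length_weight$species,
      a = cfg$length_weight$a, b = cfg$length_weight$b
    ),
    truth = cfg
  )
}
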