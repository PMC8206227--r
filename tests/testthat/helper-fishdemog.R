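# Shared fixtures: reduced-draw sampler settings and an independent
# brute-force HPDI oracle.

quick_mcmc <- function(seed = 42) {
  mcmc_config(chains = 2, iterations = 1500, warmup = 500, seed = seed)
}

tiny_mcmc <- function(seed = 42) {
  mcmc_config(chains = 2, iterations = 800, warmup = 300, seed = seed)
}

# Independent oracle: scan every contiguous window of ceiling(mass * n)
# sorted draws and keep the narrowest (first on ties).
brute_hpdi <- function(x, mass) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    lo <- xs[i]
    hi <- xs[i + m - 1]
    if ((hi - lo) < (best[2] - best[1])) best <- c(lo, hi)
  }
  best
}

# A tiny hand-built fish table that satisfies every invariant.
demo_fish <- function() {
  tibble::tibble(
    fish_id = c("f1", "f2", "f3", "f4"),
    island_id = c("i1", "i1", "i2", "i2"),
    atoll_id = c("a1", "a1", "a1", "a1"),
    treatment = c("rat_free", "rat_free", "rat_infested", "rat_infested"),
    total_length = c(18.5, 21.0, 17.2, 19.9),
    wet_weight = c(0.12, 0.18, 0.10, 0.16),
    age = c(2, 4, 2, 4),
    stage = c("spawning_capable_female", "spawning_capable_female",
              "spawning_capable_female", "regenerating_female"),
    gonad_weight = c(1.2, 2.2, 1.5, NA),
    percent_N = c(12.1, 12.4, 12.0, 12.2),
    d15N = c(11.0, 11.2, 10.9, 11.1),
    collection_day = c(1, 1, 2, 2)
  )
}

# Minimal hand-built fitted object for closed-form contrast checks.
fake_effect_fit <- function(bT_draws, model_type = "lognormal") {
  n <- length(bT_draws)
  structure(
    list(
      draws = tibble::tibble(.chain = 1L, .iteration = seq_len(n),
                             b0 = 0, bT = bT_draws, sigma = 1),
      data = list(y = rep(1, 4), rf = c(0, 0, 1, 1), atoll = NULL),
      spec = list(response = "y", family = model_type,
                  covariates = character(), treatment = TRUE,
                  group_atoll = FALSE, baseline = "rat_infested"),
      model_type = model_type,
      mcmc = mcmc_config(seed = 1),
      diagnostics = tibble::tibble(parameter = c("b0", "bT", "sigma"),
                                   rhat = 1, ess = n)
    ),
    class = c("fd_effect_fit", "fd_fit")
  )
}
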