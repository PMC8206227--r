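# HPDI, R-hat, the sampler contract, model comparison, and posterior
# predictive checks.

test_that("hpdi matches the brute-force narrowest-window scan", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(5:400, 1)
    x <- switch(sample(3, 1), rnorm(n), rexp(n), rlnorm(n))
    mass <- runif(1, 0.5, 0.99)
    expect_identical(unname(hpdi(x, mass)), brute_hpdi(x, mass))
  }
})

test_that("hpdi handles edge shapes and tie-breaks deterministically", {
  # constant vector: zero-width interval at the value
  expect_equal(unname(hpdi(rep(3.5, 10), 0.95)), c(3.5, 3.5))
  # sorted 1..100 at 95%: every 95-draw window has width 94, so the
  # smallest-lower-bound tie-break picks the window starting at 1
  expect_equal(unname(hpdi(1:100, 0.95)), c(1, 95))
  expect_error(hpdi(numeric(0), 0.95), class = "fishdemog_domain_error")
  expect_error(hpdi(c(1, 2), 1.2), class = "fishdemog_domain_error")
})

test_that("hpdi of heavy normal samples recovers the analytic quantiles", {
  set.seed(7)
  x <- rnorm(50000)
  h <- hpdi(x, 0.95)
  expect_equal(unname(h), c(-1.959964, 1.959964), tolerance = 0.05 / 1.96)
  # symmetric unimodal: HPDI agrees with the central interval
  ci <- quantile(x, c(0.025, 0.975), names = FALSE)
  expect_lt(max(abs(unname(h) - ci)), 0.06)
})

test_that("rank-normalized split R-hat separates mixed from unmixed chains", {
  set.seed(5)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(rhat(good), 1.01)
  bad <- cbind(rnorm(500), rnorm(500) + 10) # 10 SDs apart
  expect_gt(rhat(bad), 1.5)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)),
               class = "fishdemog_domain_error")
  expect_warning(r0 <- rhat(matrix(1, 100, 2)), "zero-variance")
  expect_true(is.na(r0))
})

test_that("the sampler reproduces a conjugate normal-normal posterior", {
  set.seed(3)
  y <- rnorm(40, 1.5, 1)
  dat <- tibble::tibble(y = y)
  fit <- fit_bayes(dat, "y", family = "gaussian", treatment = FALSE,
                   group_atoll = FALSE, sigma_fixed = 1,
                   priors = list(intercept = list(dist = "normal",
                                                  mean = 0, sd = 1)),
                   mcmc = quick_mcmc())
  # closed form: sigma = 1 known, mu ~ N(0, 1) => posterior
  # N(sum(y)/(n+1), 1/(n+1))
  n <- length(y)
  post_mean <- sum(y) / (n + 1)
  post_sd <- sqrt(1 / (n + 1))
  d <- posterior_draws(fit)$b0
  mcse <- post_sd / sqrt(ess(matrix(d, ncol = fit$mcmc$chains)))
  expect_lt(abs(mean(d) - post_mean), 3 * mcse + 1e-6)
  expect_equal(sd(d), post_sd, tolerance = 0.15)
})

test_that("fits are deterministic under a fixed seed and guard empty data", {
  dat <- tibble::tibble(y = rnorm(20, 5))
  f1 <- fit_bayes(dat, "y", treatment = FALSE, group_atoll = FALSE,
                  mcmc = tiny_mcmc(seed = 9))
  f2 <- fit_bayes(dat, "y", treatment = FALSE, group_atoll = FALSE,
                  mcmc = tiny_mcmc(seed = 9))
  expect_identical(f1$draws, f2$draws)
  expect_error(
    fit_bayes(dat[0, , drop = FALSE], "y", treatment = FALSE,
              group_atoll = FALSE, mcmc = tiny_mcmc()),
    "empty data", class = "fishdemog_domain_error"
  )
  # prior-only sampling is available behind the explicit flag
  fp <- fit_bayes(dat[0, , drop = FALSE], "y", treatment = FALSE,
                  group_atoll = FALSE, prior_only = TRUE,
                  priors = list(intercept = list(dist = "normal",
                                                 mean = 2, sd = 0.5)),
                  mcmc = tiny_mcmc())
  expect_equal(mean(posterior_draws(fp)$b0), 2, tolerance = 0.1)
})

test_that("mcmc_config enforces its invariants", {
  expect_error(mcmc_config(chains = 1), class = "fishdemog_config_error")
  expect_error(mcmc_config(iterations = 500, warmup = 600),
               class = "fishdemog_config_error")
})

test_that("model comparison is exact for self-comparison and checks data", {
  set.seed(11)
  dat <- tibble::tibble(
    y = rnorm(30, 4), treatment = rep(fd_treatments, 15),
    island_id = rep(c("i1", "i2", "i3"), 10)
  )
  f <- fit_bayes(dat, "y", treatment = TRUE, group_atoll = FALSE,
                 mcmc = tiny_mcmc())
  cmp <- compare_models(a = f, b = f)
  expect_equal(cmp$elpd_diff, c(0, 0))
  g <- fit_bayes(dat, "y", treatment = FALSE, group_atoll = FALSE,
                 mcmc = tiny_mcmc())
  cmp3 <- compare_models(with = f, without = g, again = f)
  expect_equal(nrow(cmp3), 3)
  expect_true(!is.unsorted(rev(cmp3$elpd_loo)))
  h <- fit_bayes(dat[1:20, ], "y", treatment = FALSE, group_atoll = FALSE,
                 mcmc = tiny_mcmc())
  expect_error(compare_models(f, h), "different observation",
               class = "fishdemog_domain_error")
})

test_that("posterior predictive checks accept the true model and flag zeros", {
  set.seed(13)
  dat <- tibble::tibble(y = rnorm(60, 10, 2))
  fit <- fit_bayes(dat, "y", treatment = FALSE, group_atoll = FALSE,
                   mcmc = quick_mcmc())
  ppc <- posterior_predictive_check(fit, n_rep = 200, seed = 2)
  expect_true(all(ppc$ppc_quantile > 0.01 & ppc$ppc_quantile < 0.99))
  # zero-inflated data under a model without structural zeros: the observed
  # zero fraction sits at an extreme quantile among the replicates
  yz <- c(rep(0, 25), rlnorm(40, 2, 0.3))
  fitz <- fit_bayes(tibble::tibble(y = yz), "y", treatment = FALSE,
                    group_atoll = FALSE, mcmc = quick_mcmc())
  ppcz <- posterior_predictive_check(fitz, statistics = "zero_frac",
                                     n_rep = 200, seed = 2)
  expect_gte(ppcz$ppc_quantile, 0.99)
  # empty statistic set: empty table
  empty <- posterior_predictive_check(fit, statistics = character())
  expect_equal(nrow(empty), 0)
})
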