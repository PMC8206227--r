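# MCMC backend. Model likelihoods are expressed as JAGS graphs and sampled
# with rjags; everything around the sampler (priors, diagnostics, pointwise
# log-likelihood, replicate simulation) lives in R.

new_fd_fit <- function(subclass, model_type, draws, data, spec, mcmc,
                       diagnostics, extra = list()) {
  structure(
    c(list(draws = draws, data = data, spec = spec, mcmc = mcmc,
           model_type = model_type, diagnostics = diagnostics,
           divergences = NA_integer_), extra),
    class = c(subclass, "fd_fit")
  )
}

#' Extract posterior draws
#'
#' @param fit a fitted model object.
#' @return tibble of merged-chain draws, one column per parameter (chain and
#'   iteration columns dropped).
#' @export
posterior_draws <- function(fit) {
  dplyr::select(fit$draws, -dplyr::all_of(c(".chain", ".iteration")))
}

# Run a JAGS model string: deterministic under mcmc$seed, returns draws
# tibble plus per-parameter diagnostics; warns on R-hat > 1.01.
run_jags <- function(model_string, data, params, mcmc,
                     inits = NULL, monitor_warn = TRUE) {
  stopifnot(inherits(mcmc, "mcmc_config"))
  chain_inits <- lapply(seq_len(mcmc$chains), function(ch) {
    ini <- if (is.function(inits)) inits(ch) else inits
    c(ini %||% list(), list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = (abs(mcmc$seed) %% 20000000L) * 100L + ch
    ))
  })
  n_adapt <- min(500L, mcmc$warmup)
  model <- tryCatch(
    rjags::jags.model(textConnection(model_string), data = data,
                      inits = chain_inits, n.chains = mcmc$chains,
                      n.adapt = n_adapt, quiet = TRUE),
    error = function(e) {
      abort_domain(paste0(
        "MCMC initialization failed (non-finite likelihood or invalid ",
        "starting values): ", conditionMessage(e)
      ))
    }
  )
  if (mcmc$warmup > n_adapt) {
    stats::update(model, n.iter = mcmc$warmup - n_adapt, progress.bar = "none")
  }
  samp <- rjags::coda.samples(model, variable.names = params,
                              n.iter = mcmc$iterations - mcmc$warmup,
                              progress.bar = "none")
  n_iter <- nrow(samp[[1]])
  draws <- dplyr::bind_rows(lapply(seq_along(samp), function(ch) {
    out <- tibble::as_tibble(as.data.frame(as.matrix(samp[[ch]])))
    out$.chain <- ch
    out$.iteration <- seq_len(n_iter)
    out
  }))
  pars <- setdiff(names(draws), c(".chain", ".iteration"))
  diagnostics <- dplyr::bind_rows(lapply(pars, function(p) {
    m <- matrix(draws[[p]], nrow = n_iter, ncol = mcmc$chains)
    r <- if (stats::var(as.vector(m)) == 0) NA_real_ else rhat(m)
    tibble::tibble(parameter = p, rhat = r,
                   ess = if (is.na(r)) NA_real_ else ess(m))
  }))
  bad <- diagnostics$parameter[!is.na(diagnostics$rhat) &
                                 diagnostics$rhat > 1.01]
  if (monitor_warn && length(bad)) {
    warning(sprintf("R-hat > 1.01 for: %s (consider more iterations)",
                    paste(bad, collapse = ", ")), call. = FALSE)
  }
  list(draws = draws, diagnostics = diagnostics)
}

# Scale-aware weakly informative prior hyperparameters (precision scale).
# Coefficients ~ Normal(0, 2.5 sd(y)/sd(x)); intercept ~ t(3, median, 2.5 mad);
# SD-like parameters ~ half-t(3, 0, 2.5 mad). Degenerate spreads guarded.
prior_scales <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) s <- 1e-3
  m <- stats::mad(y)
  if (!is.finite(m) || m == 0) m <- max(s, 1e-3)
  list(sdy = s, mady = m, medy = stats::median(y))
}

prec <- function(sd) 1 / sd^2

# Assemble the shared data/ingredients of a regression-style fit.
build_regression_data <- function(data, response, covariates, treatment,
                                  group_atoll) {
  needed <- c(response, if (treatment) "treatment",
              if (group_atoll) "atoll_id", covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort_schema(sprintf("data lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  keep <- stats::complete.cases(data[, needed, drop = FALSE])
  if (sum(!keep) > 0) {
    message(sprintf("dropping %d row(s) with missing model variables",
                    sum(!keep)))
  }
  data <- data[keep, , drop = FALSE]
  y <- data[[response]]
  rf <- if (treatment) rf_indicator(data$treatment) else NULL
  centers <- NULL
  X <- NULL
  if (length(covariates)) {
    X <- as.matrix(data[, covariates, drop = FALSE])
    centers <- colMeans(X)
    X <- sweep(X, 2, centers)
  }
  atoll_levels <- NULL
  atoll <- NULL
  if (group_atoll) {
    atoll_levels <- sort(unique(as.character(data$atoll_id)))
    if (length(atoll_levels) < 2) {
      warning("fewer than 2 atolls; pooling (atoll intercept dropped)",
              call. = FALSE)
      group_atoll <- FALSE
      atoll_levels <- NULL
    } else {
      atoll <- match(as.character(data$atoll_id), atoll_levels)
    }
  }
  list(data = data, y = y, rf = rf, X = X, centers = centers,
       atoll = atoll, atoll_levels = atoll_levels, group_atoll = group_atoll)
}

rename_param_names <- function(nm, covariates, atoll_levels,
                               extra = character()) {
  if (length(covariates)) {
    for (j in seq_along(covariates)) {
      nm[nm == sprintf("beta[%d]", j)] <- paste0("b_", covariates[j])
    }
    nm[nm == "beta"] <- paste0("b_", covariates[1])
  }
  if (length(atoll_levels)) {
    for (j in seq_along(atoll_levels)) {
      nm[nm == sprintf("a[%d]", j)] <- paste0("a_", atoll_levels[j])
    }
  }
  for (old in names(extra)) nm[nm == old] <- extra[[old]]
  nm
}

# Apply one renaming to both the draw columns and the diagnostics table.
rename_draw_cols <- function(res, covariates, atoll_levels,
                             extra = character()) {
  names(res$draws) <- rename_param_names(names(res$draws), covariates,
                                         atoll_levels, extra)
  res$diagnostics$parameter <- rename_param_names(
    res$diagnostics$parameter, covariates, atoll_levels, extra
  )
  res
}

# ---------------------------------------------------------------------------
# Generic Bayesian regression fit

#' Fit a Bayesian response model
#'
#' The shared engine behind the treatment-effect models: a response with an
#' optional treatment effect (rat_free vs the rat_infested baseline),
#' optional centered covariates, and an optional atoll varying intercept,
#' under one of four families:
#'
#' * `gaussian` — identity link;
#' * `lognormal` — gaussian on the log response (log link for ratios);
#' * `hurdle_gamma` — a zero hurdle (logit-scale probability of a structural
#'   zero, intercept-only by default) plus a log-link gamma mean for the
#'   positive part, for zero-inflated densities and biomasses;
#' * `exgaussian` — exponentially modified normal with a log-linked
#'   treatment effect on the exponential (skew) component, fitted by exact
#'   exponential data augmentation.
#'
#' Priors are weakly informative and scale-aware (see the methods vignette);
#' individual priors can be overridden through `priors`.
#'
#' @param data data frame containing the response and model columns.
#' @param response name of the response column.
#' @param family model family, one of `"gaussian"`, `"lognormal"`,
#'   `"hurdle_gamma"`, `"exgaussian"`.
#' @param covariates character vector of numeric covariate columns, centered
#'   at their sample means.
#' @param treatment include the rat_free treatment effect (default `TRUE`).
#' @param group_atoll include an atoll varying intercept (default `TRUE`;
#'   automatically pooled with a warning when fewer than 2 atolls remain).
#' @param priors optional named list of prior overrides, e.g.
#'   `list(intercept = list(dist = "normal", mean = 0, sd = 1))`.
#' @param prior_only sample from the prior without conditioning on data.
#' @param sigma_fixed optionally fix the gaussian residual SD (used for
#'   conjugate checks).
#' @param hurdle_treatment put the treatment effect on the hurdle (zero)
#'   probability as well (hurdle_gamma only).
#' @param mcmc an [mcmc_config()].
#' @return an `fd_effect_fit` object; see [tidy.fd_fit()],
#'   [treatment_contrast()], [back_transform_ratio()].
#' @export
fit_bayes <- function(data, response, family = c("gaussian", "lognormal",
                                                 "hurdle_gamma", "exgaussian"),
                      covariates = character(), treatment = TRUE,
                      group_atoll = TRUE, priors = list(),
                      prior_only = FALSE, sigma_fixed = NULL,
                      hurdle_treatment = FALSE, mcmc = mcmc_config()) {
  family <- match.arg(family)
  if (nrow(data) == 0 && !prior_only) {
    abort_domain("empty data; set prior_only = TRUE for a prior-only fit")
  }
  reg <- build_regression_data(data, response, covariates, treatment,
                               group_atoll)
  fitter <- switch(family,
    gaussian = , lognormal = fit_gaussian_family,
    hurdle_gamma = fit_hurdle_gamma,
    exgaussian = fit_exgaussian
  )
  fitter(reg, response, family, covariates, priors, prior_only,
         sigma_fixed, hurdle_treatment, mcmc)
}

fit_gaussian_family <- function(reg, response, family, covariates, priors,
                                prior_only, sigma_fixed, hurdle_treatment,
                                mcmc) {
  y <- reg$y
  if (family == "lognormal") {
    if (any(y <= 0)) abort_domain("lognormal family requires a positive response")
    y <- log(y)
  }
  if (!prior_only && stats::sd(y) == 0) {
    # Degenerate posterior (likelihood unbounded as sigma -> 0): return the
    # exact limit instead of sampling it.
    warning("response is constant; residual SD collapses to 0 and the treatment effect to 0",
            call. = FALSE)
    n_draw <- (mcmc$iterations - mcmc$warmup)
    draws <- tibble::tibble(
      .chain = rep(seq_len(mcmc$chains), each = n_draw),
      .iteration = rep(seq_len(n_draw), mcmc$chains),
      b0 = y[1]
    )
    if (!is.null(reg$rf)) draws$bT <- 0
    for (cv in covariates) draws[[paste0("b_", cv)]] <- 0
    if (reg$group_atoll) {
      for (al in reg$atoll_levels) draws[[paste0("a_", al)]] <- 0
      draws$sd_atoll <- 0
    }
    draws$sigma <- 0
    pars <- setdiff(names(draws), c(".chain", ".iteration"))
    return(new_fd_fit(
      "fd_effect_fit", family, draws,
      data = list(y = reg$y, y_model = y, rf = reg$rf, X = reg$X,
                  atoll = reg$atoll),
      spec = list(response = response, family = family,
                  covariates = covariates, centers = reg$centers,
                  treatment = !is.null(reg$rf), group_atoll = reg$group_atoll,
                  atoll_levels = reg$atoll_levels, prior_only = FALSE,
                  baseline = "rat_infested", degenerate = TRUE),
      mcmc = mcmc,
      diagnostics = tibble::tibble(parameter = pars, rhat = NA_real_,
                                   ess = NA_real_)
    ))
  }
  ps <- prior_scales(if (prior_only) 0 else y)
  p_int <- priors$intercept %||%
    list(dist = "t", mean = ps$medy, sd = 2.5 * ps$mady)
  has_trt <- !is.null(reg$rf)
  has_cov <- !is.null(reg$X)
  has_grp <- reg$group_atoll
  fixed_sigma <- !is.null(sigma_fixed)

  lik <- if (prior_only) "" else "    y[i] ~ dnorm(mu[i], tau_y)\n"
  mu_terms <- c("b0",
                if (has_trt) "bT * rf[i]",
                if (has_cov) "inprod(X[i, ], beta)",
                if (has_grp) "a[atoll[i]]")
  int_prior <- if (identical(p_int$dist, "normal")) {
    "  b0 ~ dnorm(b0_loc, b0_prec)\n"
  } else {
    "  b0 ~ dt(b0_loc, b0_prec, 3)\n"
  }
  model <- paste0(
    "model {\n",
    if (!prior_only) paste0(
      "  for (i in 1:N) {\n",
      "    mu[i] <- ", paste(mu_terms, collapse = " + "), "\n",
      lik, "  }\n"
    ),
    int_prior,
    if (has_trt) "  bT ~ dnorm(0, bT_prec)\n",
    if (has_cov) "  for (j in 1:P) { beta[j] ~ dnorm(0, beta_prec[j]) }\n",
    if (has_grp) paste0(
      "  for (j in 1:J) { a[j] ~ dnorm(0, tau_a) }\n",
      "  sd_atoll ~ dt(0, sd_prec, 3) T(0,)\n",
      "  tau_a <- pow(sd_atoll, -2)\n"
    ),
    if (fixed_sigma) "  sigma <- sigma_fixed\n" else
      "  sigma ~ dt(0, sd_prec, 3) T(0,)\n",
    "  tau_y <- pow(sigma, -2)\n",
    "}\n"
  )
  jd <- list(b0_loc = p_int$mean, b0_prec = prec(p_int$sd),
             sd_prec = prec(2.5 * ps$mady))
  if (!prior_only) {
    jd$N <- length(y); jd$y <- y
    if (has_trt) jd$rf <- reg$rf
    if (has_cov) { jd$X <- reg$X; jd$P <- ncol(reg$X) }
    if (has_grp) { jd$atoll <- reg$atoll; jd$J <- length(reg$atoll_levels) }
  }
  if (has_trt) {
    sd_rf <- stats::sd(reg$rf)
    if (!is.finite(sd_rf)) sd_rf <- 0.5
    sd_rf <- max(sd_rf, 0.25)
    jd$bT_prec <- prec(priors$treatment$sd %||% (2.5 * ps$sdy / sd_rf))
  }
  if (has_cov) {
    jd$beta_prec <- prec(2.5 * ps$sdy /
                           pmax(apply(reg$X, 2, stats::sd), 1e-6))
  }
  if (fixed_sigma) jd$sigma_fixed <- sigma_fixed

  params <- c("b0", if (has_trt) "bT",
              if (has_cov) "beta", if (has_grp) c("a", "sd_atoll"),
              if (!fixed_sigma) "sigma")
  inits <- if (prior_only) NULL else {
    function(ch) {
      ini <- list(b0 = ps$medy)
      if (!fixed_sigma) ini$sigma <- max(stats::sd(y), 1e-3)
      ini
    }
  }
  res <- rename_draw_cols(run_jags(model, jd, params, mcmc, inits = inits),
                          covariates, reg$atoll_levels)
  draws <- res$draws
  if (fixed_sigma) draws$sigma <- sigma_fixed
  new_fd_fit(
    "fd_effect_fit", family, draws,
    data = list(y = reg$y, y_model = y, rf = reg$rf, X = reg$X,
                atoll = reg$atoll),
    spec = list(response = response, family = family,
                covariates = covariates, centers = reg$centers,
                treatment = !is.null(reg$rf), group_atoll = reg$group_atoll,
                atoll_levels = reg$atoll_levels, prior_only = prior_only,
                baseline = "rat_infested"),
    mcmc = mcmc, diagnostics = res$diagnostics
  )
}

fit_hurdle_gamma <- function(reg, response, family, covariates, priors,
                             prior_only, sigma_fixed, hurdle_treatment,
                             mcmc) {
  if (prior_only) abort_domain("prior_only is not supported for hurdle_gamma")
  y <- reg$y
  if (any(y < 0)) abort_domain("hurdle_gamma requires a nonnegative response")
  pos <- y > 0
  if (sum(pos) < 3) abort_domain("hurdle_gamma needs at least 3 positive values")
  ps <- prior_scales(log(y[pos]))
  has_trt <- !is.null(reg$rf)
  has_grp <- reg$group_atoll
  mu_terms <- c("b0",
                if (has_trt) "bT * rfp[j]",
                if (has_grp) "a[atollp[j]]")
  model <- paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    if (hurdle_treatment && has_trt)
      "    logit(pz[i]) <- g0 + gT * rf[i]\n    zero[i] ~ dbern(pz[i])\n"
    else "    zero[i] ~ dbern(p0)\n",
    "  }\n",
    if (!(hurdle_treatment && has_trt)) "  logit(p0) <- g0\n",
    "  g0 ~ dnorm(0, 0.16)\n",
    if (hurdle_treatment && has_trt) "  gT ~ dnorm(0, 0.16)\n",
    "  for (j in 1:Np) {\n",
    "    log(mup[j]) <- ", paste(mu_terms, collapse = " + "), "\n",
    "    yp[j] ~ dgamma(shape, shape / mup[j])\n",
    "  }\n",
    "  b0 ~ dt(b0_loc, b0_prec, 3)\n",
    if (has_trt) "  bT ~ dnorm(0, bT_prec)\n",
    if (has_grp) paste0(
      "  for (j in 1:J) { a[j] ~ dnorm(0, tau_a) }\n",
      "  sd_atoll ~ dt(0, sd_prec, 3) T(0,)\n",
      "  tau_a <- pow(sd_atoll, -2)\n"
    ),
    "  shape ~ dt(0, 0.04, 3) T(0,)\n",
    "}\n"
  )
  jd <- list(
    N = length(y), zero = as.integer(y == 0),
    Np = sum(pos), yp = y[pos],
    b0_loc = ps$medy, b0_prec = prec(2.5 * ps$mady),
    sd_prec = prec(2.5 * ps$mady)
  )
  if (has_trt) {
    sd_rfp <- stats::sd(reg$rf[pos])
    if (!is.finite(sd_rfp)) sd_rfp <- 0.5
    jd$bT_prec <- prec(2.5 * ps$sdy / max(sd_rfp, 0.25))
    jd$rfp <- reg$rf[pos]
    if (hurdle_treatment) jd$rf <- reg$rf
  }
  if (has_grp) { jd$atollp <- reg$atoll[pos]; jd$J <- length(reg$atoll_levels) }
  params <- c("g0", if (hurdle_treatment && has_trt) "gT", "b0",
              if (has_trt) "bT", "shape", if (has_grp) c("a", "sd_atoll"))
  res <- rename_draw_cols(
    run_jags(model, jd, params, mcmc,
             inits = function(ch) list(b0 = ps$medy, shape = 1)),
    character(), reg$atoll_levels
  )
  draws <- res$draws
  draws$p_zero <- stats::plogis(draws$g0)
  new_fd_fit(
    "fd_effect_fit", "hurdle_gamma", draws,
    data = list(y = y, rf = reg$rf, atoll = reg$atoll),
    spec = list(response = response, family = family,
                covariates = character(), treatment = has_trt,
                hurdle_treatment = hurdle_treatment && has_trt,
                group_atoll = has_grp, atoll_levels = reg$atoll_levels,
                baseline = "rat_infested"),
    mcmc = mcmc, diagnostics = res$diagnostics
  )
}

fit_exgaussian <- function(reg, response, family, covariates, priors,
                           prior_only, sigma_fixed, hurdle_treatment, mcmc) {
  if (prior_only) abort_domain("prior_only is not supported for exgaussian")
  y <- reg$y
  ps <- prior_scales(y)
  has_trt <- !is.null(reg$rf)
  has_grp <- reg$group_atoll
  mu_terms <- c("m0",
                if (has_trt) "mT * rf[i]",
                if (has_grp) "a[atoll[i]]")
  model <- paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    e[i] ~ dexp(rate_e[i])\n",
    "    rate_e[i] <- exp(-(t0",
    if (has_trt) " + tT * rf[i]", "))\n",
    "    mu[i] <- ", paste(mu_terms, collapse = " + "), "\n",
    "    y[i] ~ dnorm(mu[i] + e[i], tau_s)\n",
    "  }\n",
    "  m0 ~ dt(m0_loc, m0_prec, 3)\n",
    if (has_trt) "  mT ~ dnorm(0, mT_prec)\n",
    "  t0 ~ dnorm(t0_loc, 1)\n",
    if (has_trt) "  tT ~ dnorm(0, 1)\n",
    if (has_grp) paste0(
      "  for (j in 1:J) { a[j] ~ dnorm(0, tau_a) }\n",
      "  sd_atoll ~ dt(0, sd_prec, 3) T(0,)\n",
      "  tau_a <- pow(sd_atoll, -2)\n"
    ),
    "  sigma ~ dt(0, sd_prec, 3) T(0,)\n",
    "  tau_s <- pow(sigma, -2)\n",
    "}\n"
  )
  jd <- list(
    N = length(y), y = y,
    m0_loc = ps$medy, m0_prec = prec(2.5 * ps$mady),
    t0_loc = log(max(ps$sdy / 2, 1e-3)),
    sd_prec = prec(2.5 * ps$mady)
  )
  if (has_trt) {
    jd$rf <- reg$rf
    sd_rf <- stats::sd(reg$rf)
    if (!is.finite(sd_rf)) sd_rf <- 0.5
    jd$mT_prec <- prec(2.5 * ps$sdy / max(sd_rf, 0.25))
  }
  if (has_grp) { jd$atoll <- reg$atoll; jd$J <- length(reg$atoll_levels) }
  params <- c("m0", if (has_trt) c("mT", "tT"), "t0", "sigma",
              if (has_grp) c("a", "sd_atoll"))
  res <- rename_draw_cols(
    run_jags(model, jd, params, mcmc, inits = function(ch) {
      list(m0 = ps$medy - ps$sdy / 2, sigma = max(ps$sdy / 2, 1e-3),
           t0 = log(max(ps$sdy / 2, 1e-3)))
    }),
    character(), reg$atoll_levels
  )
  draws <- res$draws
  new_fd_fit(
    "fd_effect_fit", "exgaussian", draws,
    data = list(y = y, rf = reg$rf, atoll = reg$atoll),
    spec = list(response = response, family = family,
                covariates = character(), treatment = has_trt,
                group_atoll = has_grp, atoll_levels = reg$atoll_levels,
                baseline = "rat_infested"),
    mcmc = mcmc, diagnostics = res$diagnostics
  )
}

# ---------------------------------------------------------------------------
# Pointwise log-likelihood and replicate simulation

# Stable ex-Gaussian log-density; tau = 0 degenerates to the normal.
dexgauss <- function(x, mu, sigma, tau, log = TRUE) {
  out <- ifelse(
    tau < 1e-8,
    stats::dnorm(x, mu, sigma, log = TRUE),
    -base::log(tau) + (mu - x) / tau + sigma^2 / (2 * tau^2) +
      stats::pnorm((x - mu) / sigma - sigma / tau, log.p = TRUE)
  )
  if (log) out else exp(out)
}

# Linear predictor matrix (draws x observations) for regression-style fits.
fd_linpred <- function(fit, draws = posterior_draws(fit)) {
  d <- fit$data
  sp <- fit$spec
  S <- nrow(draws)
  n <- length(d$y)
  int_name <- switch(fit$model_type, exgaussian = "m0", "b0")
  eta <- matrix(draws[[int_name]], S, n)
  trt_name <- switch(fit$model_type, exgaussian = "mT", "bT")
  if (isTRUE(sp$treatment) && trt_name %in% names(draws)) {
    eta <- eta + outer(draws[[trt_name]], d$rf)
  }
  if (length(sp$covariates)) {
    for (j in seq_along(sp$covariates)) {
      eta <- eta + outer(draws[[paste0("b_", sp$covariates[j])]], d$X[, j])
    }
  }
  if (isTRUE(sp$group_atoll)) {
    amat <- as.matrix(draws[paste0("a_", sp$atoll_levels)])
    eta <- eta + amat[, d$atoll, drop = FALSE]
  }
  eta
}

#' Pointwise log-likelihood matrix
#'
#' @param fit a fitted model object.
#' @param ... unused.
#' @return draws x observations matrix used by [compare_models()].
#' @export
log_lik <- function(fit, ...) UseMethod("log_lik")

#' @export
log_lik.fd_fit <- function(fit, ...) {
  draws <- posterior_draws(fit)
  d <- fit$data
  switch(fit$model_type,
    gaussian = {
      eta <- fd_linpred(fit, draws)
      stats::dnorm(matrix(d$y, nrow(eta), ncol(eta), byrow = TRUE), eta,
                   draws$sigma, log = TRUE)
    },
    lognormal = {
      eta <- fd_linpred(fit, draws)
      ly <- matrix(log(d$y), nrow(eta), ncol(eta), byrow = TRUE)
      stats::dnorm(ly, eta, draws$sigma, log = TRUE) - ly
    },
    vbgf = , three_age = {
      eta <- growth_mean_matrix(fit, draws)
      stats::dnorm(matrix(d$y, nrow(eta), ncol(eta), byrow = TRUE), eta,
                   draws$sigma, log = TRUE)
    },
    hurdle_gamma = {
      S <- nrow(draws)
      n <- length(d$y)
      pz <- if (isTRUE(fit$spec$hurdle_treatment)) {
        stats::plogis(outer(draws$gT, d$rf) + matrix(draws$g0, S, n))
      } else matrix(draws$p_zero, S, n)
      eta <- matrix(draws$b0, S, n)
      if (isTRUE(fit$spec$treatment)) eta <- eta + outer(draws$bT, d$rf)
      if (isTRUE(fit$spec$group_atoll)) {
        amat <- as.matrix(draws[paste0("a_", fit$spec$atoll_levels)])
        eta <- eta + amat[, d$atoll, drop = FALSE]
      }
      mu <- exp(eta)
      ll <- matrix(NA_real_, S, n)
      ymat <- matrix(d$y, S, n, byrow = TRUE)
      shape <- matrix(draws$shape, S, n)
      zero <- ymat == 0
      ll[zero] <- log(pz[zero])
      ll[!zero] <- log1p(-pz[!zero]) +
        stats::dgamma(ymat[!zero], shape = shape[!zero],
                      rate = shape[!zero] / mu[!zero], log = TRUE)
      ll
    },
    exgaussian = {
      eta <- fd_linpred(fit, draws)
      S <- nrow(eta); n <- ncol(eta)
      tau <- exp(matrix(draws$t0, S, n) +
                   if (isTRUE(fit$spec$treatment)) outer(draws$tT, d$rf)
                   else 0)
      dexgauss(matrix(d$y, S, n, byrow = TRUE), eta,
               matrix(draws$sigma, S, n), tau, log = TRUE)
    },
    abort_domain(sprintf("log_lik not implemented for %s", fit$model_type))
  )
}

# One replicated dataset from a single posterior draw (1-row tibble).
simulate_replicate <- function(fit, draw) {
  d <- fit$data
  n <- length(d$y)
  switch(fit$model_type,
    gaussian = {
      stats::rnorm(n, as.numeric(fd_linpred(fit, draw)), draw$sigma)
    },
    lognormal = {
      exp(stats::rnorm(n, as.numeric(fd_linpred(fit, draw)), draw$sigma))
    },
    vbgf = , three_age = {
      stats::rnorm(n, as.numeric(growth_mean_matrix(fit, draw)), draw$sigma)
    },
    hurdle_gamma = {
      pz <- if (isTRUE(fit$spec$hurdle_treatment)) {
        stats::plogis(draw$g0 + draw$gT * d$rf)
      } else rep(draw$p_zero, n)
      eta <- rep(draw$b0, n)
      if (isTRUE(fit$spec$treatment)) eta <- eta + draw$bT * d$rf
      if (isTRUE(fit$spec$group_atoll)) {
        a <- as.numeric(draw[paste0("a_", fit$spec$atoll_levels)])
        eta <- eta + a[d$atoll]
      }
      mu <- exp(eta)
      y <- stats::rgamma(n, shape = draw$shape, rate = draw$shape / mu)
      y[stats::runif(n) < pz] <- 0
      y
    },
    exgaussian = {
      eta <- as.numeric(fd_linpred(fit, draw))
      tau <- exp(draw$t0 + if (isTRUE(fit$spec$treatment)) draw$tT * d$rf
                 else 0)
      stats::rnorm(n, eta, draw$sigma) + stats::rexp(n, 1 / tau)
    },
    abort_domain(sprintf("simulate_replicate not implemented for %s",
                         fit$model_type))
  )
}
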