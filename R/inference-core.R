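# Shared Bayesian machinery: interval summaries, convergence diagnostics,
# PSIS-LOO model comparison, posterior predictive checks.

#' Highest posterior density interval
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws; ties between equally narrow windows are broken in favour of
#' the smallest lower bound.
#'
#' @param draws numeric vector of posterior draws (at least 2 finite values).
#' @param mass probability mass in (0, 1); default 0.95.
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' hpdi(rnorm(1000), 0.95)
#' @export
hpdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 2) {
    abort_domain("hpdi() needs at least 2 finite draws")
  }
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    abort_domain("`mass` must be a single probability in (0, 1)")
  }
  xs <- sort(draws)
  n <- length(xs)
  m <- ceiling(mass * n)
  starts <- seq_len(n - m + 1L)
  widths <- xs[starts + m - 1L] - xs[starts]
  i <- which.min(widths) # which.min returns the first (smallest lower bound)
  c(lower = xs[i], upper = xs[i + m - 1L])
}

#' Median and HPDI summary of a draw vector
#'
#' @inheritParams hpdi
#' @param masses probability masses to report (default 75% and 95%, the
#'   intervals shown throughout the analysis).
#' @return one-row tibble: `median`, then `hpdiXX_low`/`hpdiXX_high` per mass.
#' @export
interval_summary <- function(draws, masses = c(0.75, 0.95)) {
  out <- tibble::tibble(median = stats::median(draws))
  for (m in masses) {
    h <- hpdi(draws, m)
    out[[sprintf("hpdi%d_low", round(100 * m))]] <- h[["lower"]]
    out[[sprintf("hpdi%d_high", round(100 * m))]] <- h[["upper"]]
  }
  out
}

# Classic potential-scale-reduction on an iterations x chains matrix.
rhat_basic <- function(x) {
  n <- nrow(x)
  w <- mean(apply(x, 2, stats::var))
  b <- n * stats::var(colMeans(x))
  sqrt(((n - 1) / n * w + b / n) / w)
}

split_chains <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  cbind(x[seq_len(half), , drop = FALSE],
        x[(n - half + 1):n, , drop = FALSE])
}

rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  matrix(stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4)),
         nrow = nrow(x), ncol = ncol(x))
}

#' Rank-normalized split R-hat
#'
#' The maximum of the bulk and tail (folded) rank-normalized split potential
#' scale reduction factors. Values near 1 indicate the chains agree; fits in
#' this package warn when any parameter exceeds 1.01.
#'
#' @param x iterations x chains numeric matrix of draws for one parameter
#'   (at least 2 chains, at least 4 iterations).
#' @return scalar R-hat; `NA` (with a warning) for zero-variance chains.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort_domain("rhat() needs at least 2 chains")
  if (nrow(x) < 4) abort_domain("rhat() needs at least 4 iterations per chain")
  if (stats::var(as.vector(x)) == 0) {
    warning("rhat(): zero-variance draws; returning NA")
    return(NA_real_)
  }
  bulk <- rhat_basic(rank_normalize(split_chains(x)))
  folded <- rhat_basic(rank_normalize(split_chains(
    abs(x - stats::median(x))
  )))
  max(bulk, folded)
}

#' Effective sample size
#'
#' Autocorrelation-adjusted effective number of draws, summed over split
#' chains (via [coda::effectiveSize()]).
#'
#' @inheritParams rhat
#' @return scalar effective sample size.
#' @export
ess <- function(x) {
  x <- as.matrix(x)
  sum(apply(split_chains(x), 2, function(ch) {
    unname(coda::effectiveSize(coda::mcmc(ch)))
  }))
}

#' MCMC sampler configuration
#'
#' @param chains number of chains (>= 2; default 4).
#' @param iterations total iterations per chain including warmup
#'   (default 3000).
#' @param warmup warmup (burn-in + adaptation) iterations per chain
#'   (default 1000); posterior draws are the remaining
#'   `iterations - warmup` per chain.
#' @param seed integer seed; chain RNGs are derived from it, so a fixed seed
#'   reproduces draws exactly.
#' @param target_accept advisory target acceptance rate retained for
#'   interface compatibility; the Gibbs/Metropolis backend tunes itself
#'   during adaptation and does not use it.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4, iterations = 3000, warmup = 1000,
                        seed = 1, target_accept = 0.9) {
  if (chains < 2) abort_config("mcmc_config: chains must be >= 2")
  if (iterations <= warmup) {
    abort_config("mcmc_config: iterations must exceed warmup")
  }
  structure(
    list(chains = as.integer(chains), iterations = as.integer(iterations),
         warmup = as.integer(warmup), seed = as.integer(seed),
         target_accept = target_accept),
    class = "mcmc_config"
  )
}

# ---------------------------------------------------------------------------
# PSIS-LOO model comparison

# Zhang & Stephens (2009) profile-likelihood fit of the generalized Pareto
# distribution to exceedances x > 0, with the mild regularization toward
# k = 0.5 used in practice for importance-ratio tails.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30 + floor(sqrt(n))
  j <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (prior * xstar)
  k_of <- function(th) -mean(log1p(-th * x))
  lp <- vapply(theta, function(th) {
    k <- k_of(th)
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(i) sum(exp(lp - lp[i])), numeric(1))
  theta_hat <- sum(theta * w)
  k_hat <- k_of(theta_hat)
  sigma_hat <- k_hat / theta_hat
  k_hat <- (n * k_hat + 10 * 0.5) / (n + 10)
  list(k = k_hat, sigma = sigma_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smoothed importance weights for one observation's log-ratios.
psis_smooth <- function(log_ratios) {
  s <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  m <- min(ceiling(0.2 * s), ceiling(3 * sqrt(s)))
  ord <- order(lw)
  tail_ids <- ord[(s - m + 1):s]
  cutoff <- lw[ord[s - m]]
  exc <- exp(lw[tail_ids]) - exp(cutoff)
  if (all(exc <= 0) || stats::var(exc) == 0) {
    return(list(lw = lw - log(sum(exp(lw))), k = -Inf))
  }
  fit <- gpd_fit(exc[exc > 0])
  p <- (rank(lw[tail_ids], ties.method = "first") - 0.5) / m
  sm <- log(exp(cutoff) + qgpd(p, fit$k, fit$sigma))
  sm <- pmin(sm, 0) # truncate at the raw maximum (max lw == 0)
  lw[tail_ids] <- sm
  list(lw = lw - log(sum(exp(lw))), k = fit$k)
}

#' PSIS-LOO expected log predictive density
#'
#' Pareto-smoothed importance-sampling approximation to leave-one-out
#' cross-validation from a draws x observations pointwise log-likelihood
#' matrix.
#'
#' @param log_lik draws x observations matrix of pointwise log-likelihood.
#' @return list with `elpd_loo`, `se_elpd`, per-observation `pointwise`, and
#'   the Pareto `khat` diagnostics.
#' @export
psis_loo <- function(log_lik) {
  n <- ncol(log_lik)
  pointwise <- numeric(n)
  khat <- numeric(n)
  for (i in seq_len(n)) {
    ll <- log_lik[, i]
    sm <- psis_smooth(-ll)
    pointwise[i] <- log(sum(exp(sm$lw + ll)))
    khat[i] <- sm$k
  }
  list(
    elpd_loo = sum(pointwise),
    se_elpd = sqrt(n * stats::var(pointwise)),
    pointwise = pointwise, khat = khat
  )
}

#' Compare fitted models by approximate leave-one-out predictive density
#'
#' Ranks models fitted to the same observations by PSIS-LOO expected log
#' predictive density; differences are reported against the top-ranked model
#' with the standard error of the pointwise differences.
#'
#' @param ... two or more fitted model objects (any `fd_fit`), or a single
#'   named list of them.
#' @return tibble sorted by decreasing `elpd_loo` with columns `model`,
#'   `elpd_loo`, `se_elpd`, `elpd_diff`, `se_diff`, `max_khat`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "fd_fit")) {
    fits <- fits[[1]]
  }
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  lls <- lapply(fits, log_lik)
  ns <- vapply(lls, ncol, integer(1))
  if (length(unique(ns)) != 1) {
    abort_domain("compare_models(): models were fit to different observation sets")
  }
  ys <- lapply(fits, function(f) f$data$y)
  for (i in seq_along(ys)[-1]) {
    if (!isTRUE(all.equal(ys[[1]], ys[[i]]))) {
      abort_domain("compare_models(): models were fit to different observation sets")
    }
  }
  loos <- lapply(lls, psis_loo)
  out <- tibble::tibble(
    model = names(fits),
    elpd_loo = vapply(loos, `[[`, numeric(1), "elpd_loo"),
    se_elpd = vapply(loos, `[[`, numeric(1), "se_elpd"),
    max_khat = vapply(loos, function(l) max(l$khat), numeric(1))
  )
  out <- out[order(-out$elpd_loo), ]
  best <- loos[[out$model[1]]]$pointwise
  out$elpd_diff <- vapply(out$model, function(m) {
    sum(loos[[m]]$pointwise) - sum(best)
  }, numeric(1), USE.NAMES = FALSE)
  out$se_diff <- vapply(out$model, function(m) {
    d <- loos[[m]]$pointwise - best
    sqrt(length(d) * stats::var(d))
  }, numeric(1), USE.NAMES = FALSE)
  dplyr::select(out, "model", "elpd_loo", "se_elpd", "elpd_diff",
                "se_diff", "max_khat")
}

#' Posterior predictive check
#'
#' Simulates replicate datasets from the fitted model's posterior and
#' locates each observed summary statistic among the replicated statistics.
#' Quantiles near 0 or 1 flag aspects of the data the model cannot
#' reproduce (e.g. the zero fraction of zero-inflated counts under a plain
#' gamma model).
#'
#' @param fit a fitted model object (`fd_fit`).
#' @param statistics character vector of summary statistics among `"mean"`,
#'   `"sd"`, `"min"`, `"max"`, `"zero_frac"`; the default applies
#'   `zero_frac` only where the family admits zeros.
#' @param n_rep number of replicated datasets (>= 200 recommended).
#' @param seed RNG seed for the replicates.
#' @return tibble with columns `statistic`, `observed`, `ppc_quantile`.
#' @export
posterior_predictive_check <- function(fit, statistics = NULL, n_rep = 200,
                                       seed = 1) {
  if (is.null(statistics)) {
    statistics <- c("mean", "sd", "min", "max")
    if (fit$model_type == "hurdle_gamma") {
      statistics <- c(statistics, "zero_frac")
    }
  }
  if (length(statistics) == 0) {
    return(tibble::tibble(statistic = character(), observed = numeric(),
                          ppc_quantile = numeric()))
  }
  stat_fns <- list(
    mean = mean, sd = stats::sd, min = min, max = max,
    zero_frac = function(y) mean(y == 0)
  )
  bad <- setdiff(statistics, names(stat_fns))
  if (length(bad)) {
    abort_domain(sprintf("unknown statistic(s): %s", paste(bad, collapse = ", ")))
  }
  y <- fit$data$y
  draws <- posterior_draws(fit)
  idx <- with_seed(seed, sample.int(nrow(draws), n_rep, replace = n_rep > nrow(draws)))
  reps <- with_seed(seed + 1L, {
    vapply(idx, function(s) {
      yrep <- simulate_replicate(fit, draws[s, , drop = FALSE])
      vapply(statistics, function(st) stat_fns[[st]](yrep), numeric(1))
    }, numeric(length(statistics)))
  })
  reps <- matrix(reps, nrow = length(statistics))
  obs <- vapply(statistics, function(st) stat_fns[[st]](y), numeric(1))
  q <- vapply(seq_along(statistics), function(i) {
    mean(reps[i, ] < obs[i]) + 0.5 * mean(reps[i, ] == obs[i])
  }, numeric(1))
  tibble::tibble(statistic = statistics, observed = obs, ppc_quantile = q)
}
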