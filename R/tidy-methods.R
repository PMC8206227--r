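# broom-style tidiers and print methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted model
#'
#' One row per parameter: posterior median, 95% HPDI bounds
#' (`conf.low`/`conf.high`), 75% HPDI bounds, rank-normalized split R-hat
#' and effective sample size.
#'
#' @param x an `fd_fit`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy fd_fit
#' @export
tidy.fd_fit <- function(x, ...) {
  draws <- posterior_draws(x)
  out <- dplyr::bind_rows(lapply(names(draws), function(p) {
    d <- draws[[p]]
    if (stats::var(d) == 0) {
      return(tibble::tibble(
        term = p, estimate = d[1], conf.low = d[1], conf.high = d[1],
        hpdi75_low = d[1], hpdi75_high = d[1]
      ))
    }
    h95 <- hpdi(d, 0.95)
    h75 <- hpdi(d, 0.75)
    tibble::tibble(
      term = p, estimate = stats::median(d),
      conf.low = h95[["lower"]], conf.high = h95[["upper"]],
      hpdi75_low = h75[["lower"]], hpdi75_high = h75[["upper"]]
    )
  }))
  dplyr::left_join(out, x$diagnostics, by = c(term = "parameter"))
}

#' Glance at a fitted model
#'
#' @param x an `fd_fit`.
#' @param ... unused.
#' @return one-row tibble: observations, draws, chains, worst R-hat,
#'   smallest effective sample size.
#' @method glance fd_fit
#' @export
glance.fd_fit <- function(x, ...) {
  tibble::tibble(
    nobs = length(x$data$y),
    n_draws = nrow(x$draws),
    n_chains = x$mcmc$chains,
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_ess = suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE))
  )
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("<%s> %s model, %d observations, %d draws (%d chains)\n",
              class(x)[1], x$model_type, length(x$data$y), nrow(x$draws),
              x$mcmc$chains))
  print(tidy(x), n = 20)
  invisible(x)
}

#' @export
print.fd_extremes <- function(x, ...) {
  cat(sprintf("Upper-quartile island-level %s contrast\n", x$metric))
  print(x$contrast)
  invisible(x)
}
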