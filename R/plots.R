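# ggplot2 figures for fitted objects and survey tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

fd_fill <- c(rat_infested = "#c0392b", rat_free = "#2c7fb8")

#' Plot fitted growth curves over the length-at-age data
#'
#' @param object an `fd_vbgf_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fd_vbgf_fit
#' @export
autoplot.fd_vbgf_fit <- function(object, ...) {
  d <- tibble::tibble(
    age = object$data$age, length = object$data$y,
    treatment = fd_treatments[object$data$rf + 1]
  )
  draws <- posterior_draws(object)
  p <- list(
    L_inf = stats::median(draws$L_inf), L_0 = stats::median(draws$L_0),
    k = stats::median(draws$k), k_b = stats::median(draws$k_b)
  )
  ages <- seq(min(d$age), max(d$age), length.out = 100)
  curves <- dplyr::bind_rows(
    tibble::tibble(age = ages, treatment = "rat_infested",
                   length = vbgf_mean_length(ages, p)),
    tibble::tibble(age = ages, treatment = "rat_free",
                   length = vbgf_mean_length(ages, p, rat_free = TRUE))
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data$length,
                                  colour = .data$treatment)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curves, linewidth = 1) +
    ggplot2::scale_colour_manual(values = fd_fill) +
    ggplot2::labs(x = "Age (yr)", y = "Total length (cm)",
                  colour = NULL,
                  title = "Posterior-median von Bertalanffy growth curves") +
    ggplot2::theme_minimal()
}

#' Posterior density of the treatment effect
#'
#' @param object an `fd_effect_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fd_effect_fit
#' @export
autoplot.fd_effect_fit <- function(object, ...) {
  draws <- posterior_draws(object)
  eff <- switch(object$model_type, exgaussian = draws$mT, draws$bT)
  if (is.null(eff)) abort_domain("fit has no treatment effect term")
  ggplot2::ggplot(tibble::tibble(effect = eff), ggplot2::aes(.data$effect)) +
    ggplot2::geom_density(fill = "#2c7fb8", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = sprintf("Treatment effect on %s (rat_free - rat_infested)",
                  object$spec$response),
      y = "Posterior density"
    ) +
    ggplot2::theme_minimal()
}

#' Size-frequency histogram per treatment
#'
#' @param data survey data with `length` and `treatment` columns.
#' @param binwidth bin width in cm (default 2.5).
#' @param origin first bin edge (default 8 cm).
#' @return a ggplot of the [size_frequency()] table.
#' @export
plot_size_frequency <- function(data, binwidth = 2.5, origin = 8) {
  freq <- size_frequency(data, binwidth = binwidth, origin = origin)
  ggplot2::ggplot(freq, ggplot2::aes(.data$bin_left + binwidth / 2,
                                     .data$count,
                                     fill = .data$treatment)) +
    ggplot2::geom_col(position = "dodge", width = binwidth * 0.9) +
    ggplot2::scale_fill_manual(values = fd_fill) +
    ggplot2::labs(x = sprintf("Total length (%g cm bins)", binwidth),
                  y = "Count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Island-level upper-quartile values by treatment
#'
#' @param object an `fd_extremes`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fd_extremes
#' @export
autoplot.fd_extremes <- function(object, ...) {
  ggplot2::ggplot(object$island_values,
                  ggplot2::aes(.data$treatment, .data$value,
                               colour = .data$treatment)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::scale_colour_manual(values = fd_fill, guide = "none") +
    ggplot2::labs(x = NULL,
                  y = sprintf("Island upper-quartile mean %s", object$metric)) +
    ggplot2::theme_minimal()
}
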