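# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

fd_treatments <- c("rat_infested", "rat_free")

fd_stages <- c(
  "spawning_capable_female", "regenerating_female", "immature",
  "transitional", "ip_male"
)

abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "fishdemog_schema_error", ...)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "fishdemog_validation_error", ...)
}

abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = "fishdemog_domain_error", ...)
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "fishdemog_config_error", ...)
}

#' Parse treatment labels
#'
#' Accepts the canonical labels `"rat_free"` / `"rat_infested"`
#' case-insensitively (also tolerating `-` or space for `_`) and returns a
#' factor with levels `rat_infested`, `rat_free` (the baseline first).
#'
#' @param x character vector of treatment labels.
#' @return factor with levels `c("rat_infested", "rat_free")`.
#' @keywords internal
parse_treatment <- function(x) {
  z <- gsub("[- ]", "_", tolower(trimws(as.character(x))))
  bad <- !is.na(z) & !z %in% fd_treatments
  if (any(bad)) {
    abort_validation(sprintf(
      "Unrecognised treatment label(s): %s (expected rat_free / rat_infested)",
      paste(unique(z[bad]), collapse = ", ")
    ))
  }
  factor(z, levels = fd_treatments)
}

parse_stage <- function(x) {
  z <- gsub("[- ]", "_", tolower(trimws(as.character(x))))
  bad <- !is.na(z) & !z %in% fd_stages
  if (any(bad)) {
    abort_validation(sprintf(
      "Unrecognised stage label(s): %s",
      paste(unique(z[bad]), collapse = ", ")
    ))
  }
  factor(z, levels = fd_stages)
}

# 0/1 indicator for the non-baseline (rat_free) treatment
rf_indicator <- function(treatment) {
  as.integer(parse_treatment(treatment) == "rat_free")
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number", name))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    abort_config(sprintf(
      "`%s` = %s is outside its valid range %s%s, %s]",
      name, format(x), if (strict_lower) "(" else "[", format(lower),
      format(upper)
    ))
  }
  invisible(x)
}
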