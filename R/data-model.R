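# Domain tables, CSV readers/writers, validation, and deterministic derived
# quantities (GSI, length-weight biomass, per-transect summaries).
#
# All tables are plain tibbles; validation is by column contract rather than
# by a formal class, so dplyr pipelines stay idiomatic.

fish_required_cols <- c(
  "fish_id", "island_id", "atoll_id", "treatment",
  "total_length", "wet_weight", "age", "stage"
)
fish_optional_cols <- c("gonad_weight", "percent_N", "d15N", "collection_day")

transect_required_cols <- c(
  "island_id", "atoll_id", "treatment", "transect_id", "area",
  "species", "length"
)

island_required_cols <- c("island_id", "atoll_id", "treatment")
island_covariate_cols <- c(
  "seabird_density", "sst", "wave_exposure", "npp", "island_area"
)

apply_col_map <- function(data, col_map) {
  if (is.null(col_map)) return(data)
  stopifnot(is.character(col_map), !is.null(names(col_map)))
  for (canonical in names(col_map)) {
    src <- col_map[[canonical]]
    if (!src %in% names(data)) {
      abort_schema(sprintf(
        "Column mapping points `%s` at missing column `%s`", canonical, src
      ))
    }
    names(data)[names(data) == src] <- canonical
  }
  data
}

check_required <- function(data, required, what) {
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    abort_schema(sprintf(
      "%s table is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

row_errors <- function(bad, msg) {
  if (!any(bad)) return(character())
  sprintf("rows %s: %s", paste(which(bad), collapse = ", "), msg)
}

#' Validate a table of collected fish
#'
#' Checks the one-fish-per-row collection table against the domain contract:
#' positive lengths and weights, whole ages of at least 1 year (all collected
#' fish had completed their first annulus), lengths inside a plausibility
#' window, recognised treatment and reproductive-stage labels, non-negative
#' gonad weights, percent nitrogen within [0, 100], and a single treatment
#' per island. Optional columns (`gonad_weight`, `percent_N`, `d15N`,
#' `collection_day`) may be absent or NA; downstream models drop only the
#' rows missing their own variables.
#'
#' @param data data frame with columns `fish_id`, `island_id`, `atoll_id`,
#'   `treatment`, `total_length` (cm), `wet_weight` (kg), `age` (yr),
#'   `stage`, and optionally `gonad_weight` (g), `percent_N`, `d15N`,
#'   `collection_day`.
#' @param length_window numeric length-2 vector, plausible total-length range
#'   in cm (default 5-60).
#' @return the validated data as a tibble, with `treatment` and `stage`
#'   parsed to factors; errors of class `fishdemog_validation_error` name the
#'   offending rows.
#' @export
validate_fish <- function(data, length_window = c(5, 60)) {
  data <- tibble::as_tibble(data)
  check_required(data, fish_required_cols, "fish")
  for (col in c("total_length", "wet_weight", "age")) {
    if (!is.numeric(data[[col]])) {
      abort_validation(sprintf("column `%s` must be numeric", col))
    }
  }
  data$treatment <- parse_treatment(data$treatment)
  data$stage <- parse_stage(data$stage)
  for (col in fish_optional_cols) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
  }

  errs <- c(
    row_errors(is.na(data$total_length) | data$total_length <= 0,
               "total_length must be > 0"),
    row_errors(!is.na(data$total_length) &
                 (data$total_length < length_window[1] |
                    data$total_length > length_window[2]),
               sprintf("total_length outside plausibility window [%g, %g] cm",
                       length_window[1], length_window[2])),
    row_errors(is.na(data$wet_weight) | data$wet_weight <= 0,
               "wet_weight must be > 0"),
    row_errors(is.na(data$age) | data$age < 1 | data$age != round(data$age),
               "age must be a whole number of years >= 1"),
    row_errors(!is.na(data$gonad_weight) & data$gonad_weight < 0,
               "gonad_weight must be >= 0"),
    row_errors(!is.na(data$percent_N) &
                 (data$percent_N < 0 | data$percent_N > 100),
               "percent_N must lie in [0, 100]")
  )
  if (length(errs)) {
    abort_validation(paste(c("Invalid fish table:", errs), collapse = "\n  "))
  }

  mixed <- dplyr::summarise(
    dplyr::group_by(data, .data$island_id),
    n_treat = dplyr::n_distinct(.data$treatment), .groups = "drop"
  )
  if (any(mixed$n_treat > 1)) {
    abort_validation(sprintf(
      "treatment must be constant within island; violated by island(s): %s",
      paste(mixed$island_id[mixed$n_treat > 1], collapse = ", ")
    ))
  }
  data
}

#' Validate a long-format survey table
#'
#' One row per observed fish on a belt transect (`species`, `length`); a
#' transect on which nothing was seen is represented by a single row whose
#' `species` and `length` are both empty/NA — true zero transects are legal
#' and are required by the hurdle models downstream.
#'
#' @param data data frame with columns `island_id`, `atoll_id`, `treatment`,
#'   `transect_id`, `area` (m^2), `species`, `length` (cm).
#' @param min_length minimum size cutoff of the visual census in cm
#'   (default 8); every recorded observation must be at least this long.
#' @return validated tibble.
#' @export
validate_transects <- function(data, min_length = 8) {
  data <- tibble::as_tibble(data)
  check_required(data, transect_required_cols, "transect")
  data$treatment <- parse_treatment(data$treatment)
  if (!is.numeric(data$area) || !is.numeric(data$length)) {
    abort_validation("`area` and `length` must be numeric")
  }
  empty_sp <- is.na(data$species) | !nzchar(trimws(as.character(data$species)))
  data$species <- ifelse(empty_sp, NA_character_, as.character(data$species))
  errs <- c(
    row_errors(is.na(data$area) | data$area <= 0, "area must be > 0"),
    row_errors(xor(is.na(data$species), is.na(data$length)),
               "species and length must be both present or both empty"),
    row_errors(!is.na(data$length) & data$length < min_length,
               sprintf("observation length below the %g cm survey cutoff",
                       min_length))
  )
  if (length(errs)) {
    abort_validation(paste(c("Invalid transect table:", errs),
                           collapse = "\n  "))
  }
  data
}

#' Validate an island covariate table
#'
#' @param data data frame with `island_id`, `atoll_id`, `treatment` and any of
#'   the covariate columns `seabird_density` (breeding pairs/ha), `sst` (deg C),
#'   `wave_exposure`, `npp`, `island_area` (ha).
#' @return validated tibble.
#' @export
validate_islands <- function(data) {
  data <- tibble::as_tibble(data)
  check_required(data, island_required_cols, "island")
  data$treatment <- parse_treatment(data$treatment)
  present <- intersect(island_covariate_cols, names(data))
  errs <- character()
  for (col in present) {
    errs <- c(errs, row_errors(!is.finite(data[[col]]),
                               sprintf("%s must be finite", col)))
  }
  if ("seabird_density" %in% names(data)) {
    errs <- c(errs, row_errors(data$seabird_density < 0,
                               "seabird_density must be >= 0"))
  }
  if (length(errs)) {
    abort_validation(paste(c("Invalid island table:", errs),
                           collapse = "\n  "))
  }
  data
}

read_table_csv <- function(path, col_map) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          na = c("", "NA"))
  apply_col_map(tibble::as_tibble(data), col_map)
}

#' Read a fish collection table from CSV
#'
#' Comma-separated UTF-8 with a header row; empty strings are missing values.
#' `col_map` renames non-canonical headers, e.g.
#' `c(total_length = "TL_cm")`.
#'
#' @inheritParams validate_fish
#' @param path path to the CSV file.
#' @param col_map optional named character vector mapping canonical column
#'   names to the names used in the file.
#' @return validated fish tibble.
#' @export
read_fish_table <- function(path, col_map = NULL, length_window = c(5, 60)) {
  validate_fish(read_table_csv(path, col_map), length_window = length_window)
}

#' @rdname read_fish_table
#' @param min_length survey minimum size cutoff in cm.
#' @export
read_transect_table <- function(path, col_map = NULL, min_length = 8) {
  validate_transects(read_table_csv(path, col_map), min_length = min_length)
}

#' @rdname read_fish_table
#' @export
read_island_table <- function(path, col_map = NULL) {
  validate_islands(read_table_csv(path, col_map))
}

#' Read per-species length-weight coefficients
#'
#' Expects columns `species`, `a` (g cm^-b) and `b` (dimensionless); both
#' coefficients must be positive.
#'
#' @inheritParams read_fish_table
#' @return tibble with columns `species`, `a`, `b`.
#' @export
read_length_weight <- function(path, col_map = NULL) {
  data <- read_table_csv(path, col_map)
  check_required(data, c("species", "a", "b"), "length-weight")
  if (any(!is.finite(data$a) | data$a <= 0 | !is.finite(data$b) | data$b <= 0)) {
    abort_validation("length-weight coefficients a and b must be > 0")
  }
  data
}

#' Write a table as CSV
#'
#' Writes the package's CSV dialect (comma-separated, header row, empty
#' string for missing) so that a validated table round-trips exactly through
#' [read_fish_table()] and friends.
#'
#' @param data a tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Gonadosomatic index
#'
#' GSI = gonad weight / body weight x 100, with both masses expressed in
#' grams; the body weight argument is in kilograms as measured in the field
#' and is converted internally.
#'
#' @param gonad_weight gonad mass in g (>= 0).
#' @param wet_weight whole-body wet weight in kg (> 0).
#' @return GSI in percent, a dimensionless vector.
#' @examples
#' compute_gsi(1.2, 0.120) # exactly 1 percent
#' @export
compute_gsi <- function(gonad_weight, wet_weight) {
  if (any(!is.na(wet_weight) & wet_weight <= 0)) {
    abort_domain("wet_weight must be > 0")
  }
  if (any(!is.na(gonad_weight) & gonad_weight < 0)) {
    abort_domain("gonad_weight must be >= 0")
  }
  100 * gonad_weight / (wet_weight * 1000)
}

#' Length-weight conversion
#'
#' Power-law allometry `W = a * L^b` mapping total length (cm) to body mass
#' (g), with published, user-supplied species coefficients.
#'
#' @param length total length in cm (>= 0).
#' @param a multiplier in g cm^-b (> 0).
#' @param b exponent (> 0).
#' @return mass in g.
#' @export
length_to_weight <- function(length, a, b) {
  if (any(!is.finite(a) | a <= 0) || any(!is.finite(b) | b <= 0)) {
    abort_domain("length-weight coefficients a and b must be > 0")
  }
  if (any(!is.na(length) & length < 0)) {
    abort_domain("length must be >= 0")
  }
  a * length^b
}

#' Per-transect count, density, and biomass
#'
#' Collapses a long-format survey table to one row per transect: the number
#' of retained observations, density both per transect and per square metre,
#' and summed biomass from the length-weight coefficients. Zero transects are
#' retained with (0, 0, 0) — the hurdle models need them.
#'
#' @param transects validated survey tibble (see [validate_transects()]).
#' @param coeffs length-weight coefficient tibble (`species`, `a`, `b`).
#' @param species optional character vector; retain only these species
#'   (default: all observed species).
#' @return tibble with one row per transect: `island_id`, `atoll_id`,
#'   `treatment`, `transect_id`, `area`, `count`, `density` (per m^2),
#'   `density_per_transect`, `biomass_g`.
#' @export
transect_summaries <- function(transects, coeffs, species = NULL) {
  transects <- validate_transects(transects)
  obs <- dplyr::filter(transects, !is.na(.data$length))
  if (!is.null(species)) {
    obs <- dplyr::filter(obs, .data$species %in% !!species)
  }
  need <- setdiff(unique(obs$species), coeffs$species)
  if (length(need)) {
    abort_config(sprintf(
      "no length-weight coefficients for species: %s",
      paste(need, collapse = ", ")
    ))
  }
  obs <- dplyr::left_join(obs, coeffs, by = "species")
  obs$mass_g <- length_to_weight(obs$length, obs$a, obs$b)

  frame <- dplyr::distinct(
    transects, .data$island_id, .data$atoll_id, .data$treatment,
    .data$transect_id, .data$area
  )
  sums <- dplyr::summarise(
    dplyr::group_by(obs, .data$transect_id),
    count = dplyr::n(), biomass_g = sum(.data$mass_g), .groups = "drop"
  )
  out <- dplyr::left_join(frame, sums, by = "transect_id")
  out$count <- dplyr::coalesce(out$count, 0L)
  out$biomass_g <- dplyr::coalesce(out$biomass_g, 0)
  out$density <- out$count / out$area
  out$density_per_transect <- as.numeric(out$count)
  dplyr::select(
    out, "island_id", "atoll_id", "treatment", "transect_id", "area",
    "count", "density", "density_per_transect", "biomass_g"
  )
}
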