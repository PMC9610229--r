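# Delimited-text readers and writers for release series and implant
# configuration files. Release series travel as two- or three-column
# CSV/TSV (time_days, cumulative_mass_mg[, mass_per_interval_mg]);
# implant configurations as flat YAML or JSON mappings with wall thickness
# in micrometres (the bench convention).

.delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a cumulative-release series from delimited text
#'
#' Expects columns `time_days` and `cumulative_mass_mg`, optionally
#' `mass_per_interval_mg`; the delimiter is chosen from the file extension
#' (`.tsv` is tab, anything else comma).
#'
#' @param path Input file.
#' @return A [release_series()].
#' @export
read_release_series <- function(path) {
  df <- utils::read.delim(path, sep = .delim_for(path), header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("time_days", "cumulative_mass_mg")
  if (!all(need %in% names(df)))
    stop("input error: release-series file needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  release_series(df$time_days, df$cumulative_mass_mg,
                 mass_per_interval_mg = df[["mass_per_interval_mg"]])
}

#' Write a release series as delimited text
#'
#' Full-precision values (no rounding); a round trip through
#' [read_release_series()] reproduces the series exactly.
#'
#' @param series A [release_series()].
#' @param path Output file (`.tsv` for tab-delimited, else CSV).
#' @export
write_release_series <- function(series, path) {
  stopifnot(inherits(series, "release_series"))
  df <- as.data.frame(series)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an implant configuration from YAML or JSON
#'
#' Flat mapping with keys `length_mm`, `wall_thickness_um`,
#' `outer_diameter_mm` (optional, default 2.5), `drug_loading_mg`
#' (optional), `ratio` (optional), `polymer_grade` (optional). Wall
#' thickness is given in micrometres and converted to mm.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return An [implant_config()].
#' @export
read_implant_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("length_mm", "wall_thickness_um")
  if (!all(need %in% names(cfg)))
    stop("input error: implant config needs keys ",
         paste(need, collapse = ", "), call. = FALSE)
  implant_config(
    length_mm = cfg$length_mm,
    wall_thickness_mm = cfg$wall_thickness_um / 1000,
    outer_diameter_mm = if (is.null(cfg$outer_diameter_mm)) 2.5
                        else cfg$outer_diameter_mm,
    drug_loading_mg = if (is.null(cfg$drug_loading_mg)) NA_real_
                      else cfg$drug_loading_mg,
    drug_excipient_ratio = if (is.null(cfg$ratio)) NA_character_ else cfg$ratio,
    polymer_grade = if (is.null(cfg$polymer_grade)) NA_character_
                    else cfg$polymer_grade)
}

#' Write an implant configuration as YAML or JSON
#' @param config An [implant_config()].
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @export
write_implant_config <- function(config, path) {
  stopifnot(inherits(config, "implant_config"))
  payload <- list(length_mm = config$length_mm,
                  wall_thickness_um = config$wall_thickness_mm * 1000,
                  outer_diameter_mm = config$outer_diameter_mm)
  if (!is.na(config$drug_loading_mg))
    payload$drug_loading_mg <- config$drug_loading_mg
  if (!is.na(config$drug_excipient_ratio))
    payload$ratio <- config$drug_excipient_ratio
  if (!is.na(config$polymer_grade))
    payload$polymer_grade <- config$polymer_grade
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(payload, path)
  else jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Row of the packaged implant-config table as an implant_config
#'
#' @param fixtures A [load_fixtures()] result.
#' @param drug Drug label of the configuration (one row per drug).
#' @return An [implant_config()].
#' @export
fixture_config <- function(fixtures, drug) {
  stopifnot(inherits(fixtures, "fixture_set"))
  row <- fixtures$configs[fixtures$configs$drug == drug, ]
  if (nrow(row) != 1L)
    stop("input error: unknown drug in config table: ", drug, call. = FALSE)
  implant_config(
    length_mm = row$length_mm,
    wall_thickness_mm = row$wall_thickness_um / 1000,
    outer_diameter_mm = row$outer_diameter_mm,
    drug_loading_mg = row$drug_loading_mg,
    drug_excipient_ratio = row$drug_excipient_ratio,
    polymer_grade = row$polymer_grade)
}
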