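# Tabular I/O with schema validation. All tables are comma-separated,
# UTF-8, header row, "." decimal separator; missing = empty cell.

# internal: read a CSV and validate required columns / numeric ranges.
# schema: list(required = c(name = "character"|"numeric"|"integer"),
#              nonneg = c(names of columns that must be >= 0))
read_checked <- function(path, schema, what) {
  if (!file.exists(path)) {
    abort_compsel(paste0(what, " file not found: ", path), "compsel_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  pr <- readr::problems(df)
  if (nrow(pr)) {
    abort_compsel(paste0("parse problems in ", path, " (first at line ",
                         pr$row[1] + 1L, ": ", pr$expected[1], ")"),
                  "compsel_io_error")
  }
  miss <- setdiff(names(schema$required), names(df))
  if (length(miss)) {
    abort_compsel(paste0(what, " table ", path, " is missing column(s): ",
                         paste(miss, collapse = ", ")), "compsel_schema_error")
  }
  for (col in names(schema$required)) {
    type <- schema$required[[col]]
    if (type %in% c("numeric", "integer") && !is.numeric(df[[col]])) {
      bad <- which(!grepl("^\\s*-?[0-9.eE+]*\\s*$", as.character(df[[col]])))[1]
      abort_compsel(paste0("column `", col, "` in ", path,
                           " must be numeric (line ",
                           if (is.na(bad)) "?" else bad + 1L, ")"),
                    "compsel_schema_error")
    }
  }
  for (col in intersect(schema$nonneg, names(df))) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) {
      abort_compsel(paste0("column `", col, "` in ", path,
                           " has negative value(s) at line(s) ",
                           paste(utils::head(bad + 1L, 5), collapse = ", ")),
                    "compsel_schema_error")
    }
  }
  df
}

#' Read a strain parameter table
#'
#' Columns: `strain_id`, `species`, `mu` (day^-1), plus optional per-metal
#' inhibition columns `I_Ag`, `I_Cd`, `I_Cu` (dimensionless) and optional
#' `drift_<metal>` chronic-drift columns (day^-1 of inhibition).
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_strain_table <- function(path) {
  df <- read_checked(path, list(
    required = c(strain_id = "character", species = "character",
                 mu = "numeric"),
    nonneg = character(0)), "strain")
  validate_strains(df)
  df
}

#' Read a dose-response assay table
#'
#' Columns: `strain_id`, `metal`, `concentration_uM` (>= 0), `replicate`,
#' `response` (growth rate or relative growth rate; blank = missing).
#'
#' @param path CSV path.
#' @return Tibble with a `concentration` column (uM) ready for
#'   [fit_dose_response()].
#' @export
read_dose_table <- function(path) {
  df <- read_checked(path, list(
    required = c(strain_id = "character", metal = "character",
                 concentration_uM = "numeric", response = "numeric"),
    nonneg = "concentration_uM"), "dose-response")
  dplyr::rename(df, concentration = "concentration_uM")
}

#' Read a co-culture observation table
#'
#' Columns: `replicate`, `treatment`, `day`, `species`, `abundance`
#' (cells mL^-1, >= 0); optional `biomass` and `extinct`.
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_coculture_table <- function(path) {
  read_checked(path, list(
    required = c(replicate = "character", treatment = "character",
                 day = "numeric", species = "character",
                 abundance = "numeric"),
    nonneg = c("abundance", "biomass")), "co-culture")
}

#' Read a scenario / pipeline configuration file
#'
#' A YAML key-value file; see [run_pipeline()] for recognised keys.
#'
#' @param path YAML path.
#' @return Named list.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) {
    abort_compsel(paste0("config file not found: ", path), "compsel_io_error")
  }
  yaml::read_yaml(path)
}

#' Write a table as CSV
#'
#' @param df Data frame.
#' @param path Output path (directories created as needed).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(df, path)
  invisible(path)
}
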