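#' Published interval-inhibition summary of the co-culture experiment
#'
#' Loads the packaged CSV of per-interval relative (0-1) growth-rate
#' inhibition means and replicate SDs (N = 3) for the two diatom species
#' under control, Ag, Cd and Cu treatments, as reported for the 10-day
#' semicontinuous co-culture experiment (intervals days 0-4, 4-7, 7-10).
#' Useful as a reference input for summary reproduction and model
#' comparison.
#'
#' @return Tibble `species`, `treatment`, `interval`, `mean_inhibition`,
#'   `sd`, `n`.
#' @export
published_inhibition_intervals <- function() {
  path <- system.file("extdata", "coculture_interval_inhibition.csv",
                      package = "compsel", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Published species growth-rate summaries
#'
#' The reported mean and SD of baseline specific growth rate (day^-1)
#' across four strains per species in mono-culture, and the average EC50
#' exposure concentrations (uM) used for the metal treatments.
#'
#' @return List with `growth` (tibble `species`, `mean`, `sd`, `n`) and
#'   `exposure` (named numeric vector, uM).
#' @export
published_species_summaries <- function() {
  list(
    growth = tibble::tibble(
      species = c("SM", "TB"),
      mean = c(1.55, 0.55),
      sd = c(0.12, 0.31),
      n = c(4L, 4L)),
    exposure = c(Ag = 0.046, Cd = 5.5, Cu = 9.7))
}
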