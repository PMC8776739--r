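#' Interval growth rates from co-culture observations
#'
#' Computes the specific growth rate \eqn{\mu = \ln(D_1/D_0)/\Delta t} for
#' every consecutive pair of observation days, per replicate, treatment and
#' species, after re-inflating post-dilution densities by the cumulative
#' dilution factors so the rate reflects true growth. Endpoints at or below
#' the detection limit yield a missing rate with an extinction flag rather
#' than an error.
#'
#' @param obs Tibble with columns `replicate`, `treatment`, `day`,
#'   `species`, and a density column (`abundance` in cells mL^-1 and/or
#'   `biomass` in surface-area units mL^-1).
#' @param dilution Optional tibble `day`, `factor` where `factor` is the
#'   fold-dilution (>= 1) applied immediately after sampling on that day;
#'   an optional `treatment` column restricts each factor to one treatment.
#' @param measure Which density column to use: `"abundance"` (default) or
#'   `"biomass"`.
#' @param detection_limit Densities below this are treated as unobservable
#'   (default 1 cell mL^-1).
#' @return Tibble `replicate`, `treatment`, `species`, `day0`, `day1`,
#'   `interval` (label), `mu`, `extinct`.
#' @export
interval_growth_rates <- function(obs, dilution = NULL,
                                  measure = c("abundance", "biomass"),
                                  detection_limit = 1) {
  measure <- match.arg(measure)
  need <- c("replicate", "treatment", "day", "species", measure)
  miss <- setdiff(need, names(obs))
  if (length(miss)) {
    abort_compsel(paste0("observation table is missing column(s): ",
                         paste(miss, collapse = ", ")), "compsel_schema_error")
  }
  cum_factor <- function(day, tr) {
    if (is.null(dilution) || nrow(dilution) == 0) return(rep(1, length(day)))
    dil <- dilution
    if ("treatment" %in% names(dil)) dil <- dil[dil$treatment == tr, ]
    vapply(day, function(d) prod(dil$factor[dil$day < d]), numeric(1))
  }
  obs |>
    dplyr::arrange(.data$replicate, .data$treatment, .data$species, .data$day) |>
    dplyr::group_by(.data$replicate, .data$treatment, .data$species) |>
    dplyr::reframe({
      d <- .data$day
      dens <- .data[[measure]] * cum_factor(d, dplyr::cur_group()$treatment)
      below <- .data[[measure]] < detection_limit
      k <- length(d)
      if (k < 2L) {
        tibble::tibble(day0 = numeric(0), day1 = numeric(0),
                       interval = character(0), mu = numeric(0),
                       extinct = logical(0))
      } else {
        i0 <- seq_len(k - 1L); i1 <- i0 + 1L
        ok <- !below[i0] & !below[i1]
        mu <- rep(NA_real_, k - 1L)
        mu[ok] <- log(dens[i1][ok] / dens[i0][ok]) / (d[i1][ok] - d[i0][ok])
        tibble::tibble(day0 = d[i0], day1 = d[i1],
                       interval = paste0(d[i0], "-", d[i1]),
                       mu = mu, extinct = !ok)
      }
    })
}

#' Relative inhibition of growth rate
#'
#' \eqn{I = 1 - \mu_{treat}/\mu_{control}}: the fractional reduction of
#' growth rate relative to the control. Exceeds 1 when the treated culture
#' declines (negative growth); the control compared with itself gives 0.
#'
#' @param mu_treat Treated growth rate(s), day^-1.
#' @param mu_control Control growth rate(s), day^-1, must be > 0.
#' @return Inhibition value(s), dimensionless.
#' @export
relative_inhibition <- function(mu_treat, mu_control) {
  if (any(!is.finite(mu_control)) || any(mu_control <= 0)) {
    abort_compsel("control growth rate must be finite and > 0 (inhibition undefined)",
                  "compsel_invalid_params")
  }
  1 - mu_treat / mu_control
}

#' Per-replicate inhibition from interval growth rates
#'
#' Joins treatment interval rates with the control rates of the same
#' species and interval and applies [relative_inhibition()]. By default the
#' control reference is the mean control rate across replicates
#' (`pairing = "mean_control"`); with `pairing = "replicate"` each
#' treatment replicate is compared to the control bottle with the same
#' replicate id.
#'
#' @param rates Output of [interval_growth_rates()].
#' @param control Treatment label of the control group. Default "Control".
#' @param pairing `"mean_control"` (default) or `"replicate"`.
#' @return Tibble `replicate`, `treatment`, `species`, `interval`, `day0`,
#'   `day1`, `mu`, `mu_control`, `inhibition`.
#' @export
compute_inhibition <- function(rates, control = "Control",
                               pairing = c("mean_control", "replicate")) {
  pairing <- match.arg(pairing)
  ctrl <- rates[rates$treatment == control & !is.na(rates$mu), ]
  if (!nrow(ctrl)) {
    abort_compsel("no usable control growth rates found", "compsel_invalid_params")
  }
  if (pairing == "mean_control") {
    ref <- ctrl |>
      dplyr::group_by(.data$species, .data$interval) |>
      dplyr::summarise(mu_control = mean(.data$mu), .groups = "drop")
    joined <- dplyr::left_join(rates, ref, by = c("species", "interval"))
  } else {
    ref <- ctrl |>
      dplyr::select("replicate", "species", "interval", mu_control = "mu")
    joined <- dplyr::left_join(rates, ref,
                               by = c("replicate", "species", "interval"))
  }
  ok <- !is.na(joined$mu) & !is.na(joined$mu_control) & joined$mu_control > 0
  joined$inhibition <- NA_real_
  joined$inhibition[ok] <- relative_inhibition(joined$mu[ok], joined$mu_control[ok])
  joined
}

#' Species relative biomass per sample
#'
#' Share of each species in the total biomass (or abundance) of a sample.
#' Extinct species (below the detection limit) contribute the detection
#' limit as a floor, so the share of the surviving species saturates just
#' below 1 instead of exactly 1.
#'
#' @param obs Observation tibble as in [interval_growth_rates()].
#' @param measure `"biomass"` (default when present) or `"abundance"`.
#' @param detection_limit Floor density for extinct species.
#' @return Tibble `replicate`, `treatment`, `day`, `species`, `share`;
#'   shares sum to 1 within each sample.
#' @export
species_relative_biomass <- function(obs, measure = NULL, detection_limit = 1) {
  if (is.null(measure)) {
    measure <- if ("biomass" %in% names(obs)) "biomass" else "abundance"
  }
  need <- c("replicate", "treatment", "day", "species", measure)
  miss <- setdiff(need, names(obs))
  if (length(miss)) {
    abort_compsel(paste0("observation table is missing column(s): ",
                         paste(miss, collapse = ", ")), "compsel_schema_error")
  }
  obs |>
    dplyr::group_by(.data$replicate, .data$treatment, .data$day) |>
    dplyr::mutate(floored = pmax(.data[[measure]], detection_limit)) |>
    dplyr::mutate(share = {
      tot <- sum(.data$floored)
      if (tot <= 0) {
        abort_compsel("zero total biomass in a sample", "compsel_invalid_params")
      }
      .data$floored / tot
    }) |>
    dplyr::ungroup() |>
    dplyr::select("replicate", "treatment", "day", "species", "share")
}

#' Summarise inhibition into an interval table with averages
#'
#' Builds the per-(species, treatment, interval) mean and replicate SD of
#' inhibition, plus an `"Average"` row per (species, treatment): the
#' unweighted mean of the interval means across the experiment. Values are
#' kept at full precision; use `signif(x, 2)` for display to match the
#' conventional 2-significant-figure reporting.
#'
#' @param inh Tibble with columns `species`, `treatment`, `interval`,
#'   `inhibition` (per replicate; `NA` dropped).
#' @return Tibble `species`, `treatment`, `interval`, `mean_inhibition`,
#'   `sd`, `n`, with `interval == "Average"` rows appended (their `sd` and
#'   `n` refer to the interval means).
#' @export
summarize_inhibition <- function(inh) {
  need <- c("species", "treatment", "interval", "inhibition")
  miss <- setdiff(need, names(inh))
  if (length(miss)) {
    abort_compsel(paste0("inhibition table is missing column(s): ",
                         paste(miss, collapse = ", ")), "compsel_schema_error")
  }
  per_int <- inh |>
    dplyr::filter(!is.na(.data$inhibition)) |>
    dplyr::group_by(.data$species, .data$treatment, .data$interval) |>
    dplyr::summarise(mean_inhibition = mean(.data$inhibition),
                     sd = if (dplyr::n() >= 2) stats::sd(.data$inhibition) else NA_real_,
                     n = dplyr::n(), .groups = "drop")
  avg <- per_int |>
    dplyr::group_by(.data$species, .data$treatment) |>
    dplyr::summarise(interval = "Average",
                     sd = if (dplyr::n() >= 2) stats::sd(.data$mean_inhibition) else NA_real_,
                     n = dplyr::n(),
                     mean_inhibition = mean(.data$mean_inhibition),
                     .groups = "drop") |>
    dplyr::select("species", "treatment", "interval", "mean_inhibition",
                  "sd", "n")
  dplyr::bind_rows(per_int, avg)
}

#' Coefficient of variation
#'
#' Sample SD divided by the mean (n - 1 denominator). Either supply raw
#' `values`, or `mean` and `sd` directly (e.g. from a published summary).
#'
#' @param values Numeric vector (length >= 2) or `NULL`.
#' @param mean,sd Summary statistics, used when `values` is `NULL`.
#' @return CV, dimensionless.
#' @examples
#' coefficient_of_variation(mean = 0.55, sd = 0.31)
#' @export
coefficient_of_variation <- function(values = NULL, mean = NULL, sd = NULL) {
  if (!is.null(values)) {
    if (length(values) < 2L) {
      abort_compsel("need >= 2 values for a CV", "compsel_invalid_params")
    }
    mean <- base::mean(values)
    sd <- stats::sd(values)
  }
  if (is.null(mean) || is.null(sd)) {
    abort_compsel("supply `values` or both `mean` and `sd`",
                  "compsel_invalid_params")
  }
  if (!is.finite(mean) || mean == 0) {
    abort_compsel("CV undefined for zero mean", "compsel_invalid_params")
  }
  sd / mean
}

#' Two-group frequentist comparisons
#'
#' Thin wrapper over the standard tests used for trait comparisons between
#' species: Welch's t (no homogeneity assumption), the variance-ratio
#' F-test, and the paired t-test, optionally on square-root transformed
#' data. The square-root transform requires non-negative values; negative
#' inhibition (growth stimulation) must be handled upstream.
#'
#' @param a,b Numeric vectors (equal length for `paired_t`).
#' @param test `"welch_t"`, `"var_f"`, or `"paired_t"`.
#' @param transform `"none"` (default) or `"sqrt"`.
#' @return Tibble `method`, `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(a, b, test = c("welch_t", "var_f", "paired_t"),
                           transform = c("none", "sqrt")) {
  test <- match.arg(test)
  transform <- match.arg(transform)
  if (length(a) < 2L || length(b) < 2L) {
    abort_compsel("need >= 2 values per group", "compsel_invalid_params")
  }
  if (transform == "sqrt") {
    if (any(a < 0) || any(b < 0)) {
      abort_compsel("square-root transform requires non-negative values",
                    "compsel_transform_error")
    }
    a <- sqrt(a); b <- sqrt(b)
  }
  res <- switch(test,
    welch_t = stats::t.test(a, b, var.equal = FALSE),
    var_f = stats::var.test(a, b),
    paired_t = {
      if (length(a) != length(b)) {
        abort_compsel("paired test needs equal-length groups",
                      "compsel_invalid_params")
      }
      stats::t.test(a, b, paired = TRUE)
    })
  tibble::tibble(method = res$method,
                 statistic = unname(res$statistic),
                 df = if (!is.null(res$parameter)) unname(res$parameter[1]) else NA_real_,
                 p_value = res$p.value)
}

#' PAM maximum quantum yield of photosystem II
#'
#' \eqn{F_V/F_M = (F_M - F_0)/F_M}, the instantaneous photophysiological
#' stress indicator from pulse-amplitude-modulated fluorometry.
#'
#' @param f0 Minimal fluorescence of the dark-acclimated sample (>= 0).
#' @param fm Maximal fluorescence after a saturating pulse (> 0, >= f0).
#' @return Quantum yield in `[0, 1]`.
#' @export
fv_fm <- function(f0, fm) {
  if (any(!is.finite(f0)) || any(!is.finite(fm)) || any(fm <= 0) ||
      any(f0 < 0) || any(f0 > fm)) {
    abort_compsel("need fm > 0 and 0 <= f0 <= fm", "compsel_invalid_params")
  }
  (fm - f0) / fm
}
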