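#' Specific growth rate from two density measurements
#'
#' \eqn{\mu = \ln(D_{t1}/D_{t0}) / (t_1 - t_0)}, the exponential growth rate
#' in day^-1 implied by two positive densities.
#'
#' @param d0,d1 Initial and final densities (> 0, any common unit).
#' @param t0,t1 Times in days, `t1 > t0`.
#' @return Growth rate(s) in day^-1; negative when the culture declined.
#' @examples
#' growth_rate_from_densities(1, exp(2), 0, 2) # 1 per day
#' @export
growth_rate_from_densities <- function(d0, d1, t0, t1) {
  if (any(!is.finite(d0)) || any(!is.finite(d1)) || any(d0 <= 0) || any(d1 <= 0)) {
    abort_compsel("densities must be finite and > 0", "compsel_invalid_params")
  }
  if (any(!is.finite(t0)) || any(!is.finite(t1)) || any(t1 <= t0)) {
    abort_compsel("need t1 > t0", "compsel_invalid_params")
  }
  log(d1 / d0) / (t1 - t0)
}

#' Growth rate under toxic inhibition
#'
#' \eqn{\mu_{MC} = \mu (1 - I)}: the baseline exponential growth rate scaled
#' down by a standardized inhibition coefficient. Under the default
#' `"clamp01"` policy the coefficient is restricted to `[0, 1]` before use,
#' so the model never predicts negative growth; `"allow_negative"` keeps the
#' raw coefficient (inhibition above 1 then yields decline).
#'
#' @param mu Baseline growth rate (day^-1).
#' @param I Inhibition coefficient (dimensionless).
#' @param clamp_policy `"clamp01"` (default) or `"allow_negative"`.
#' @return Inhibited growth rate (day^-1).
#' @export
inhibited_mu <- function(mu, I, clamp_policy = c("clamp01", "allow_negative")) {
  clamp_policy <- match.arg(clamp_policy)
  if (any(!is.finite(mu)) || any(!is.finite(I))) {
    abort_compsel("`mu` and `I` must be finite", "compsel_invalid_params")
  }
  if (clamp_policy == "clamp01") I <- clamp01(I)
  mu * (1 - I)
}

#' Exponential density projection
#'
#' \eqn{D_t = D_{t0}\, e^{\mu_{MC} t}}.
#'
#' @param d0 Initial density (`>= 0`).
#' @param mu_mc Growth rate (day^-1), possibly inhibited.
#' @param t Time in days (`>= 0`), vectorized.
#' @return Projected density.
#' @export
project_density <- function(d0, mu_mc, t) {
  if (any(!is.finite(d0)) || any(d0 < 0)) {
    abort_compsel("`d0` must be finite and >= 0", "compsel_invalid_params")
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    abort_compsel("`t` must be finite and >= 0", "compsel_invalid_params")
  }
  d0 * exp(mu_mc * t)
}

# internal: resolve per-strain inhibited growth rates for a treatment.
# `strains` is a tibble with strain_id, species, mu, and either I_<metal>
# columns or a `fits` list-column / `fits` argument of dr_fit objects.
strain_mu_mc <- function(strains, metal = NULL, concentration = NULL,
                         clamp_policy = "clamp01", fits = NULL) {
  validate_strains(strains)
  if (is.null(metal)) return(strains$mu)
  icol <- paste0("I_", metal)
  if (!is.null(fits)) {
    if (is.null(concentration)) {
      abort_compsel("`concentration` is required when resolving inhibition from fits",
                    "compsel_invalid_params")
    }
    I <- vapply(strains$strain_id, function(sid) {
      f <- fits[[paste(sid, metal, sep = ".")]]
      if (is.null(f)) f <- fits[[sid]]
      if (is.null(f)) {
        abort_compsel(paste0("no dose-response fit for strain ", sid,
                             " and metal ", metal), "compsel_invalid_params")
      }
      inhibition_at(f, concentration, clamp = FALSE)
    }, numeric(1))
  } else if (icol %in% names(strains)) {
    I <- strains[[icol]]
  } else {
    abort_compsel(paste0("strain table has no `", icol,
                         "` column and no fits were supplied"),
                  "compsel_schema_error")
  }
  if (any(!is.finite(I))) {
    abort_compsel("inhibition coefficients must resolve to finite numbers",
                  "compsel_invalid_params")
  }
  inhibited_mu(strains$mu, I, clamp_policy)
}

validate_strains <- function(strains) {
  need <- c("strain_id", "species", "mu")
  miss <- setdiff(need, names(strains))
  if (length(miss)) {
    abort_compsel(paste0("strain table is missing column(s): ",
                         paste(miss, collapse = ", ")), "compsel_schema_error")
  }
  if (any(!is.finite(strains$mu))) {
    abort_compsel("strain `mu` must be finite", "compsel_invalid_params")
  }
  if (anyDuplicated(strains$strain_id)) {
    abort_compsel("strain_id values must be unique", "compsel_schema_error")
  }
  invisible(strains)
}

#' Relative density of each strain under selection
#'
#' Deterministic share of each strain in the total ensemble density at time
#' t under exponential growth:
#' \deqn{RD_{i,t} = D_{0,i} e^{\mu_{MC,i} t} / \sum_j D_{0,j} e^{\mu_{MC,j} t}}
#' which reduces to the equal-start form
#' \eqn{e^{\mu_{MC,i} t} / \sum_j e^{\mu_{MC,j} t}} when all starting
#' densities are equal. Exponents are max-shifted before normalization so
#' long horizons do not overflow.
#'
#' @param strains Strain table (`strain_id`, `species`, `mu`, and `I_<metal>`
#'   columns when a metal is given).
#' @param metal Metal label (e.g. `"Cd"`) or `NULL` for the control.
#' @param concentration Exposure concentration (uM); only needed when
#'   inhibition is resolved from dose-response `fits`.
#' @param times Numeric vector of times (days, `>= 0`).
#' @param initial_density Per-strain starting densities: scalar, or vector
#'   named by `strain_id`. Default equal starts.
#' @param clamp_policy Passed to [inhibited_mu()].
#' @param fits Optional named list of `dr_fit` objects
#'   (`"<strain_id>.<metal>"`).
#' @return Tibble with columns `time`, `strain_id`, `species`, `mu_mc`, `rd`;
#'   `rd` sums to 1 within each time.
#' @examples
#' strains <- tibble::tibble(strain_id = c("a", "b"), species = c("A", "B"),
#'                           mu = c(1.0, 0.5))
#' relative_density(strains, times = 0:3)
#' @export
relative_density <- function(strains, metal = NULL, concentration = NULL,
                             times = 0:10, initial_density = NULL,
                             clamp_policy = "clamp01", fits = NULL) {
  validate_strains(strains)
  if (nrow(strains) < 2L) {
    abort_compsel("need at least two strains for relative densities",
                  "compsel_invalid_params")
  }
  if (any(times < 0)) {
    abort_compsel("`times` must be >= 0", "compsel_invalid_params")
  }
  d0 <- resolve_initial_density(strains, initial_density)
  if (all(d0 == 0)) {
    abort_compsel("all initial densities are zero", "compsel_invalid_params")
  }
  mu_mc <- strain_mu_mc(strains, metal, concentration, clamp_policy, fits)
  out <- purrr::map_dfr(times, function(tt) {
    w <- log(d0) + mu_mc * tt
    w <- w - max(w[is.finite(w)])
    rd <- exp(w)
    rd[d0 == 0] <- 0
    rd <- rd / sum(rd)
    tibble::tibble(time = tt, strain_id = strains$strain_id,
                   species = strains$species, mu_mc = mu_mc, rd = rd)
  })
  out
}

resolve_initial_density <- function(strains, initial_density) {
  if (is.null(initial_density)) return(rep(1, nrow(strains)))
  if (length(initial_density) == 1L && is.null(names(initial_density))) {
    return(rep(initial_density, nrow(strains)))
  }
  if (is.null(names(initial_density)) ||
      !all(strains$strain_id %in% names(initial_density))) {
    abort_compsel("`initial_density` must be a scalar or named by strain_id",
                  "compsel_invalid_params")
  }
  d0 <- unname(initial_density[strains$strain_id])
  if (any(!is.finite(d0)) || any(d0 < 0)) {
    abort_compsel("initial densities must be finite and >= 0",
                  "compsel_invalid_params")
  }
  d0
}

#' Species share of total biomass over time
#'
#' Aggregates strain relative densities to the species level, optionally
#' weighting strains by a per-cell biomass (e.g. surface area) so the share
#' is expressed in surface-area biomass rather than cell numbers.
#'
#' @inheritParams relative_density
#' @param biomass_per_cell Optional numeric vector named by species (or by
#'   strain_id) giving per-cell biomass weights.
#' @return Tibble `time`, `species`, `share`; `share` sums to 1 within time.
#' @export
species_share <- function(strains, metal = NULL, concentration = NULL,
                          times = 0:10, initial_density = NULL,
                          clamp_policy = "clamp01", fits = NULL,
                          biomass_per_cell = NULL) {
  rd <- relative_density(strains, metal, concentration, times,
                         initial_density, clamp_policy, fits)
  w <- rep(1, nrow(rd))
  if (!is.null(biomass_per_cell)) {
    if (all(rd$species %in% names(biomass_per_cell))) {
      w <- unname(biomass_per_cell[rd$species])
    } else if (all(rd$strain_id %in% names(biomass_per_cell))) {
      w <- unname(biomass_per_cell[rd$strain_id])
    } else {
      abort_compsel("`biomass_per_cell` must be named by species or strain_id",
                    "compsel_invalid_params")
    }
  }
  rd$wrd <- rd$rd * w
  rd |>
    dplyr::group_by(.data$time) |>
    dplyr::mutate(wrd = .data$wrd / sum(.data$wrd)) |>
    dplyr::group_by(.data$time, .data$species) |>
    dplyr::summarise(share = sum(.data$wrd), .groups = "drop")
}

#' Population growth rate under selection
#'
#' Relative-density-weighted mean strain growth rate within each species,
#' \eqn{\mu_{Pop,t} = \sum_i RD_{i,t}\, \mu_i}, where the weights are the
#' within-species relative densities at time t. As selection enriches the
#' fitter strains the population rate rises towards the species maximum.
#'
#' @inheritParams relative_density
#' @param weight Which rate enters the weighted sum: the inhibited rate
#'   `"mu_mc"` (default, the treated-population growth rate) or the
#'   baseline `"mu"`. The two coincide in the control.
#' @return Tibble `time`, `species`, `mu_pop`.
#' @export
population_mu <- function(strains, metal = NULL, concentration = NULL,
                          times = 0:10, initial_density = NULL,
                          clamp_policy = "clamp01", fits = NULL,
                          weight = c("mu_mc", "mu")) {
  weight <- match.arg(weight)
  validate_strains(strains)
  if (any(times < 0)) {
    abort_compsel("`times` must be >= 0", "compsel_invalid_params")
  }
  d0 <- resolve_initial_density(strains, initial_density)
  mu_mc <- strain_mu_mc(strains, metal, concentration, clamp_policy, fits)
  val <- if (weight == "mu_mc") mu_mc else strains$mu
  # within-species softmax weights, max-shifted per species so long
  # horizons never underflow the whole species
  purrr::map_dfr(times, function(tt) {
    purrr::map_dfr(unique(strains$species), function(sp) {
      i <- strains$species == sp
      if (all(d0[i] == 0)) {
        abort_compsel("species has zero total density", "compsel_invalid_params")
      }
      w <- log(d0[i]) + mu_mc[i] * tt
      w <- exp(w - max(w[is.finite(w)]))
      w[d0[i] == 0] <- 0
      tibble::tibble(time = tt, species = sp,
                     mu_pop = sum(w * val[i]) / sum(w))
    })
  })
}

#' Pairwise strain-by-strain competition matrix
#'
#' Projects every pair of one strain from each species as a two-strain
#' competition, yielding a factorial set of share trajectories (4 x 4
#' strains gives 16 predictions). Illustrates how strain-level variability
#' in tolerance spreads the predicted competitive outcome.
#'
#' @param strains_a,strains_b Strain tables for the two species (same
#'   columns as in [relative_density()]).
#' @inheritParams relative_density
#' @return Tibble `strain_a`, `strain_b`, `time`, `share_a` (share of the
#'   strain from `strains_a` in the pair).
#' @export
strain_by_strain_matrix <- function(strains_a, strains_b, metal = NULL,
                                    concentration = NULL, times = 0:10,
                                    clamp_policy = "clamp01", fits = NULL) {
  validate_strains(strains_a)
  validate_strains(strains_b)
  grid <- tidyr::expand_grid(a = strains_a$strain_id, b = strains_b$strain_id)
  purrr::pmap_dfr(grid, function(a, b) {
    pair <- dplyr::bind_rows(strains_a[strains_a$strain_id == a, ],
                             strains_b[strains_b$strain_id == b, ])
    rd <- relative_density(pair, metal, concentration, times,
                           clamp_policy = clamp_policy, fits = fits)
    rd <- rd[rd$strain_id == a, ]
    tibble::tibble(strain_a = a, strain_b = b, time = rd$time,
                   share_a = rd$rd)
  })
}
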