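#' Define a semicontinuous competition scenario
#'
#' Bundles a strain ensemble with a treatment, horizon, grid, clamping
#' policy, dilution schedule and detection limit into a validated scenario
#' object for [simulate_semicontinuous()].
#'
#' @param strains Strain table (`strain_id`, `species`, `mu`, optional
#'   `I_<metal>` and `drift_<metal>` columns). A `drift_<metal>` column adds
#'   a chronic component: inhibition grows linearly as
#'   `I(t) = I + drift * t` (clamped per policy), emulating toxicity that
#'   intensifies over multi-day exposure.
#' @param metal Metal label or `NULL` for the control treatment.
#' @param concentration Exposure concentration (uM), informational unless
#'   inhibition is resolved from fits.
#' @param initial_density Per-strain starting density (cells mL^-1 or any
#'   common biomass unit); scalar or vector named by strain_id. Must be > 0.
#' @param horizon Experiment length in days (> 0). Default 10.
#' @param time_step Output grid spacing in days. Default 1.
#' @param clamp_policy `"clamp01"` (default) or `"allow_negative"`.
#' @param dilution `NULL` for none, or a list with `days` (dilution days)
#'   and either `factor` (multiplier in (0, 1]) or `reset = "initial"`
#'   (dilute back to the initial total density; never concentrates).
#' @param detection_limit Density below which a strain is scored extinct
#'   (default 1, i.e. 1 cell mL^-1).
#' @param fits Optional named list of `dr_fit` objects.
#' @return A `competition_scenario` object.
#' @export
competition_scenario <- function(strains, metal = NULL, concentration = 0,
                                 initial_density = 500, horizon = 10,
                                 time_step = 1,
                                 clamp_policy = c("clamp01", "allow_negative"),
                                 dilution = list(days = c(4, 7), reset = "initial"),
                                 detection_limit = 1, fits = NULL) {
  clamp_policy <- match.arg(clamp_policy)
  validate_strains(strains)
  if (!is.numeric(horizon) || horizon <= 0) {
    abort_compsel("`horizon` must be > 0", "compsel_config_error")
  }
  if (!is.numeric(time_step) || time_step <= 0) {
    abort_compsel("`time_step` must be > 0", "compsel_config_error")
  }
  d0 <- resolve_initial_density(strains, initial_density)
  if (any(d0 <= 0)) {
    abort_compsel("initial densities must be > 0", "compsel_config_error")
  }
  if (!is.null(dilution)) {
    if (!is.list(dilution) || is.null(dilution$days)) {
      abort_compsel("`dilution` must be NULL or list(days=, factor=|reset=)",
                    "compsel_config_error")
    }
    if (!is.null(dilution$factor) &&
        (dilution$factor <= 0 || dilution$factor > 1)) {
      abort_compsel("dilution `factor` must lie in (0, 1]", "compsel_config_error")
    }
    if (is.null(dilution$factor) && !identical(dilution$reset, "initial")) {
      abort_compsel("`dilution` needs either `factor` or reset = \"initial\"",
                    "compsel_config_error")
    }
  }
  structure(list(strains = strains, metal = metal,
                 concentration = concentration, initial_density = d0,
                 horizon = horizon, time_step = time_step,
                 clamp_policy = clamp_policy, dilution = dilution,
                 detection_limit = detection_limit, fits = fits),
            class = "competition_scenario")
}

#' Simulate semicontinuous batch co-cultivation
#'
#' Deterministic piecewise-exponential projection of every strain in a
#' scenario, with serial dilution applied at the scheduled days (all strains
#' diluted by the same factor, so relative densities are unaffected) and an
#' extinction rule: a strain whose density crosses the detection limit is
#' flagged with its exact crossing time and contributes zero afterwards.
#' Densities reported at a dilution day are the pre-dilution values, as a
#' microscopy sample taken "in connection with dilution" would be.
#'
#' @param scenario A [competition_scenario()] object.
#' @return A tibble of class `compsel_trajectory` with columns `time`,
#'   `strain_id`, `species`, `density`, `rd` (strain share of total),
#'   `species_share`, plus attributes `population_mu` (tibble time, species,
#'   mu_pop), `dilution_events` (time, factor) and `extinct`
#'   (strain_id, time).
#' @export
simulate_semicontinuous <- function(scenario) {
  if (!inherits(scenario, "competition_scenario")) {
    abort_compsel("`scenario` must come from competition_scenario()",
                  "compsel_config_error")
  }
  s <- scenario
  strains <- s$strains
  n <- nrow(strains)
  mu <- strains$mu
  dcol <- if (!is.null(s$metal)) paste0("drift_", s$metal) else NULL
  drift <- if (!is.null(dcol) && dcol %in% names(strains)) strains[[dcol]] else rep(0, n)
  I0 <- if (!is.null(s$metal)) {
    icol <- paste0("I_", s$metal)
    if (!is.null(s$fits)) {
      vapply(strains$strain_id, function(sid) {
        f <- s$fits[[paste(sid, s$metal, sep = ".")]]
        if (is.null(f)) f <- s$fits[[sid]]
        inhibition_at(f, s$concentration, clamp = FALSE)
      }, numeric(1))
    } else if (icol %in% names(strains)) {
      strains[[icol]]
    } else {
      abort_compsel(paste0("strain table has no `", icol, "` column"),
                    "compsel_schema_error")
    }
  } else {
    rep(0, n)
  }

  mu_at <- function(tt) {
    # inhibited rate at absolute time tt, with linear chronic drift
    inhibited_mu(mu, I0 + drift * tt, s$clamp_policy)
  }

  grid <- seq(0, s$horizon, by = s$time_step)
  if (grid[length(grid)] < s$horizon) grid <- c(grid, s$horizon)
  dil_days <- if (!is.null(s$dilution)) {
    sort(s$dilution$days[s$dilution$days > 0 & s$dilution$days < s$horizon])
  } else {
    numeric(0)
  }
  events <- sort(unique(c(grid, dil_days)))

  dens <- s$initial_density
  extinct_time <- rep(NA_real_, n)
  rows <- vector("list", length(events))
  dil_events <- list()

  record <- function(tt, dens) {
    tot <- sum(dens)
    rd <- if (tot > 0) dens / tot else rep(0, n)
    sp_tot <- tapply(dens, strains$species, sum)
    sh <- if (tot > 0) sp_tot / tot else sp_tot * 0
    tibble::tibble(time = tt, strain_id = strains$strain_id,
                   species = strains$species, density = dens, rd = rd,
                   species_share = as.vector(sh[strains$species]))
  }

  t_prev <- 0
  rows[[1]] <- record(0, dens)
  k <- 2L
  for (tt in events[-1]) {
    dt <- tt - t_prev
    alive <- is.na(extinct_time)
    if (any(alive)) {
      if (all(drift == 0)) {
        g <- mu_at(t_prev) * dt          # constant rate: exact
      } else {
        # trapezoid on the (possibly clamp-kinked) linear-in-time rate
        nsub <- max(2L, ceiling(dt / 0.01))
        ts <- seq(t_prev, tt, length.out = nsub + 1L)
        rates <- vapply(ts, mu_at, numeric(n))
        if (n == 1L) rates <- matrix(rates, nrow = 1L)
        g <- apply(rates, 1L, function(r) {
          sum((r[-1] + r[-length(r)]) / 2) * dt / nsub
        })
      }
      new <- dens
      new[alive] <- dens[alive] * exp(g[alive])
      # exact detection-limit crossing time within the segment
      crossed <- alive & new < s$detection_limit & dens >= s$detection_limit
      if (any(crossed)) {
        gr <- g / dt
        tc <- t_prev + log(s$detection_limit / dens[crossed]) / gr[crossed]
        extinct_time[crossed] <- pmin(pmax(tc, t_prev), tt)
        new[crossed] <- 0
      }
      still_dead <- alive & new < s$detection_limit & !crossed
      if (any(still_dead)) {
        extinct_time[still_dead] <- tt
        new[still_dead] <- 0
      }
      dens <- new
      dens[!alive] <- 0
    }
    rows[[k]] <- record(tt, dens)
    k <- k + 1L
    if (tt %in% dil_days && sum(dens) > 0) {
      f <- if (!is.null(s$dilution$factor)) {
        s$dilution$factor
      } else {
        min(1, sum(s$initial_density) / sum(dens))
      }
      dens <- dens * f
      dil_events[[length(dil_events) + 1L]] <- tibble::tibble(time = tt, factor = f)
      newly_dead <- is.na(extinct_time) & dens < s$detection_limit & dens > 0
      if (any(newly_dead)) {
        extinct_time[newly_dead] <- tt
        dens[newly_dead] <- 0
      }
    }
    t_prev <- tt
  }

  traj <- dplyr::bind_rows(rows)
  traj <- traj[traj$time %in% grid, , drop = FALSE]

  mu_pop <- traj |>
    dplyr::mutate(mu_t = {
      mm <- vapply(unique(traj$time), mu_at, numeric(n))
      if (n == 1L) mm <- matrix(mm, nrow = 1L)
      mm[cbind(match(traj$strain_id, strains$strain_id),
               match(traj$time, unique(traj$time)))]
    }) |>
    dplyr::group_by(.data$time, .data$species) |>
    dplyr::summarise(
      mu_pop = ifelse(sum(.data$density) > 0,
                      sum(.data$density * .data$mu_t) / sum(.data$density),
                      NA_real_),
      .groups = "drop")

  attr(traj, "population_mu") <- mu_pop
  attr(traj, "dilution_events") <- if (length(dil_events)) {
    dplyr::bind_rows(dil_events)
  } else {
    tibble::tibble(time = numeric(0), factor = numeric(0))
  }
  attr(traj, "extinct") <- tibble::tibble(strain_id = strains$strain_id,
                                          time = extinct_time)
  attr(traj, "scenario") <- scenario
  class(traj) <- c("compsel_trajectory", class(traj))
  traj
}

#' @export
print.compsel_trajectory <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("Semicontinuous competition trajectory: %d strains, %s, %g days\n",
              length(unique(x$strain_id)),
              if (is.null(sc$metal)) "control" else
                sprintf("%s %g uM", sc$metal, sc$concentration),
              sc$horizon))
  ext <- attr(x, "extinct")
  gone <- ext[!is.na(ext$time), ]
  if (nrow(gone)) {
    cat("  extinct:", paste(sprintf("%s (day %.2f)", gone$strain_id, gone$time),
                            collapse = ", "), "\n")
  }
  NextMethod()
}
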