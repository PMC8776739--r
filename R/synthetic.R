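#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: two diatom species
#' with four strains each, species-level growth rates (mean +/- SD) of
#' 1.55 +/- 0.12 and 0.55 +/- 0.31 day^-1, monotone Weibull dose-response
#' structure per metal (W1 for Cd, W2 for Ag and Cu), exposure at the
#' species-average EC50s (0.046, 5.5, 9.7 uM for Ag, Cd, Cu), microscopy
#' counting of about 200 cells per species per sample, a 1 cell mL^-1
#' detection limit, serial dilution on days 4 and 7, and an optional
#' chronic (time-increasing) inhibition drift.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_strains Strains per species (default 4).
#' @param species Character vector of species labels (default SM, TB).
#' @param mu_mean,mu_sd Named per-species mean and SD of baseline growth
#'   rate (day^-1).
#' @param mu_floor Lower truncation for drawn growth rates (default 0.01
#'   day^-1, avoiding degenerate non-growing control strains).
#' @param exposure Named per-metal exposure concentration (uM).
#' @param family Named per-metal Weibull family.
#' @param inhibition_range Per-species, per-metal range (list of lists of
#'   length-2 vectors) from which each strain's true inhibition at the
#'   exposure concentration is drawn uniformly.
#' @param b_meanlog,b_sdlog Log-normal parameters for the magnitude of the
#'   Weibull shape b.
#' @param noise_sd Gaussian SD of relative response noise on dose-response
#'   plates (default 0.05).
#' @param n_rep Replicates per dose on a plate and bottles per treatment
#'   (default 3).
#' @param counting_target Cells counted per species per sample (default 200).
#' @param chronic_drift Optional named list `species -> metal -> drift`
#'   (inhibition increase per day, default none).
#' @param dilution_days Days on which cultures are diluted back to the
#'   initial total density (default 4 and 7).
#' @param obs_days Microscopy observation days (default 0, 4, 7, 10).
#' @param horizon Experiment length (days, default 10).
#' @param initial_density Starting density per strain (cells mL^-1,
#'   default 500).
#' @param detection_limit Extinction threshold (default 1 cell mL^-1).
#' @param biomass_per_cell Named per-species surface area per cell (um^2);
#'   defaults contrast small chain-forming cells with large solitary ones.
#' @param bottle_sd SD of a log-normal bottle effect on latent densities
#'   (default 0: counting noise is the only observation noise).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_strains = 4L,
                             species = c("SM", "TB"),
                             mu_mean = c(SM = 1.55, TB = 0.55),
                             mu_sd = c(SM = 0.12, TB = 0.31),
                             mu_floor = 0.01,
                             exposure = c(Ag = 0.046, Cd = 5.5, Cu = 9.7),
                             family = c(Ag = "W2", Cd = "W1", Cu = "W2"),
                             inhibition_range = list(
                               SM = list(Ag = c(0.75, 0.95), Cd = c(0.20, 0.40),
                                         Cu = c(0.45, 0.70)),
                               TB = list(Ag = c(0.24, 0.40), Cd = c(0.80, 0.98),
                                         Cu = c(0.10, 0.90))),
                             b_meanlog = log(2), b_sdlog = 0.3,
                             noise_sd = 0.05, n_rep = 3L,
                             counting_target = 200L,
                             chronic_drift = NULL,
                             dilution_days = c(4, 7),
                             obs_days = c(0, 4, 7, 10),
                             horizon = 10,
                             initial_density = 500,
                             detection_limit = 1,
                             biomass_per_cell = c(SM = 200, TB = 1600),
                             bottle_sd = 0) {
  if (any(mu_sd < 0) || noise_sd < 0 || bottle_sd < 0) {
    abort_compsel("standard deviations must be >= 0", "compsel_config_error")
  }
  if (counting_target < 1) {
    abort_compsel("`counting_target` must be >= 1 (Inf = exact enumeration)",
                  "compsel_config_error")
  }
  if (!all(species %in% names(mu_mean)) || !all(species %in% names(mu_sd))) {
    abort_compsel("`mu_mean`/`mu_sd` must be named for every species",
                  "compsel_config_error")
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a strain ensemble with ground truth
#'
#' Draws per-strain baseline growth rates from the species-level normal
#' distributions (truncated below at `mu_floor`) and, for each metal, a
#' Weibull dose-response curve whose inhibition at the exposure
#' concentration is drawn uniformly from the configured range (the scale
#' parameter `e` is solved from the drawn inhibition and shape, so the
#' ensemble spans the intended tolerance range by construction).
#'
#' @param config A [generator_config()].
#' @return Strain tibble (`strain_id`, `species`, `mu`, `I_<metal>`
#'   columns) with a `truth` attribute: tibble of the underlying
#'   (`strain_id`, `metal`, `family`, `b`, `e`, `I_at_exposure`).
#' @export
generate_strains <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    rows <- list(); truth <- list()
    for (sp in config$species) {
      for (k in seq_len(config$n_strains)) {
        sid <- sprintf("%s_%02d", sp, k)
        mu <- max(stats::rnorm(1, config$mu_mean[[sp]], config$mu_sd[[sp]]),
                  config$mu_floor)
        irow <- list(strain_id = sid, species = sp, mu = mu)
        for (m in names(config$exposure)) {
          fam <- config$family[[m]]
          rng <- config$inhibition_range[[sp]][[m]]
          I <- stats::runif(1, rng[1], rng[2])
          bmag <- stats::rlnorm(1, config$b_meanlog, config$b_sdlog)
          b <- if (fam == "W1") bmag else -bmag
          conc <- config$exposure[[m]]
          # solve e so that weibull_response(conc) = 1 - I
          e <- if (fam == "W1") {
            conc / exp(log(-log(1 - I)) / b)
          } else {
            conc / exp(log(-log(I)) / b)
          }
          irow[[paste0("I_", m)]] <- I
          truth[[length(truth) + 1L]] <- tibble::tibble(
            strain_id = sid, species = sp, metal = m, family = fam,
            b = b, e = e, I_at_exposure = I)
        }
        rows[[length(rows) + 1L]] <- tibble::as_tibble(irow)
      }
    }
    strains <- dplyr::bind_rows(rows)
    attr(strains, "truth") <- dplyr::bind_rows(truth)
    strains
  })
}

#' Simulate a 72 h dose-response plate
#'
#' Relative growth responses at a dose series (including the control at 0)
#' equal to the true Weibull curve plus Gaussian noise, truncated below at
#' -0.5 so a negative-growth signal can appear, with `n_rep` replicate
#' wells per dose.
#'
#' @param truth One row of the `truth` attribute of [generate_strains()]
#'   (fields `strain_id`, `metal`, `family`, `b`, `e`).
#' @param config A [generator_config()].
#' @param doses Dose series (uM, must include 0). Default: 0 plus five
#'   doses geometrically spanning 0.25x-4x the true scale `e`.
#' @param seed Optional seed for this plate (default: draw from the
#'   current RNG stream).
#' @return Tibble `strain_id`, `metal`, `concentration`, `replicate`,
#'   `response`.
#' @export
simulate_plate <- function(truth, config, doses = NULL, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(doses)) doses <- c(0, truth$e * c(0.25, 0.5, 1, 2, 4))
  if (!any(doses == 0)) {
    abort_compsel("dose series must include the control at 0",
                  "compsel_config_error")
  }
  run <- function() {
    grid <- tidyr::expand_grid(concentration = doses,
                               replicate = seq_len(config$n_rep))
    mu_true <- weibull_response(grid$concentration, truth$family,
                                truth$b, truth$e)
    resp <- mu_true + stats::rnorm(nrow(grid), 0, config$noise_sd)
    tibble::tibble(strain_id = truth$strain_id, metal = truth$metal,
                   concentration = grid$concentration,
                   replicate = grid$replicate,
                   response = pmax(resp, -0.5))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a microscopy-counted co-culture experiment
#'
#' Latent strain densities follow the deterministic semicontinuous model
#' (optionally with chronic inhibition drift); at each observation day and
#' replicate bottle, the species composition is observed by allocating the
#' total counting effort (counting target x number of species) across
#' species with a multinomial draw proportional to latent abundance, then
#' rescaling counts to cells mL^-1. Species falling below the detection
#' limit are recorded as 0 with an extinction flag.
#'
#' @param strains Strain tibble from [generate_strains()] (or any table
#'   with `strain_id`, `species`, `mu`, `I_<metal>`).
#' @param config A [generator_config()].
#' @param treatments Treatments to simulate; default control plus every
#'   configured metal.
#' @param seed Optional seed (default: current RNG stream).
#' @return Tibble `replicate`, `treatment`, `day`, `species`, `abundance`
#'   (cells mL^-1), `biomass` (surface-area units mL^-1), `extinct`, with
#'   attributes `latent` (noise-free per-day species densities) and
#'   `dilution` (per-treatment fold-dilution factors for growth-rate
#'   correction).
#' @export
simulate_coculture <- function(strains, config,
                               treatments = NULL, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(treatments)) treatments <- c("Control", names(config$exposure))
  run <- function() {
    out <- list(); latent <- list(); dil_tabs <- list()
    for (tr in treatments) {
      metal <- if (tr == "Control") NULL else tr
      st <- strains
      if (!is.null(metal) && !is.null(config$chronic_drift)) {
        dcol <- paste0("drift_", metal)
        st[[dcol]] <- vapply(st$species, function(sp) {
          d <- config$chronic_drift[[sp]][[metal]]
          if (is.null(d)) 0 else d
        }, numeric(1))
      }
      sc <- competition_scenario(
        st, metal = metal,
        concentration = if (is.null(metal)) 0 else config$exposure[[metal]],
        initial_density = config$initial_density,
        horizon = config$horizon, time_step = 1,
        dilution = list(days = config$dilution_days, reset = "initial"),
        detection_limit = config$detection_limit)
      traj <- simulate_semicontinuous(sc)
      de <- attr(traj, "dilution_events")
      if (nrow(de)) {
        dil_tabs[[tr]] <- tibble::tibble(treatment = tr, day = de$time,
                                         factor = 1 / de$factor)
      }
      day_sp <- traj |>
        dplyr::filter(.data$time %in% config$obs_days) |>
        dplyr::group_by(day = .data$time, .data$species) |>
        dplyr::summarise(density = sum(.data$density), .groups = "drop")
      latent[[tr]] <- dplyr::mutate(day_sp, treatment = tr)
      n_sp <- length(unique(day_sp$species))
      n_count <- config$counting_target * n_sp
      for (rep_i in seq_len(config$n_rep)) {
        for (d in unique(day_sp$day)) {
          dens <- day_sp[day_sp$day == d, ]
          lat <- dens$density
          if (config$bottle_sd > 0) {
            lat <- lat * stats::rlnorm(length(lat), 0, config$bottle_sd)
          }
          tot <- sum(lat)
          if (tot <= 0) {
            ab <- rep(0, length(lat))
          } else if (!is.finite(n_count)) {
            ab <- lat  # exact enumeration limit: no counting noise
          } else {
            counts <- as.vector(stats::rmultinom(1, n_count, lat / tot))
            ab <- counts / n_count * tot
          }
          below <- ab < config$detection_limit
          ab[below] <- 0
          out[[length(out) + 1L]] <- tibble::tibble(
            replicate = rep_i, treatment = tr, day = d,
            species = dens$species, abundance = ab,
            biomass = ab * unname(config$biomass_per_cell[dens$species]),
            extinct = below)
        }
      }
    }
    res <- dplyr::bind_rows(out)
    attr(res, "latent") <- dplyr::bind_rows(latent)
    attr(res, "dilution") <- dplyr::bind_rows(dil_tabs)
    res
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
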