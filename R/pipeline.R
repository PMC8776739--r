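#' Fit dose-response curves for every strain and metal in a table
#'
#' Applies [fit_dose_response()] per (strain, metal) group and collects
#' parameters and standard errors; per-group failures are reported, not
#' fatal.
#'
#' @param dose_tab Tibble from [read_dose_table()] (columns `strain_id`,
#'   `metal`, `concentration`, `response`).
#' @param family `"W1"`, `"W2"`, or `"auto"` (W1 for Cd, W2 otherwise —
#'   the convention used for these metals in growth-inhibition work).
#' @param normalized Passed to [fit_dose_response()].
#' @return List with `table` (tibble `strain_id`, `metal`, `family`, `b`,
#'   `e`, `se_b`, `se_e`, `n_obs`) and `fits` (named list
#'   `"<strain_id>.<metal>"` of `dr_fit` objects).
#' @export
fit_all_dose_responses <- function(dose_tab, family = "auto",
                                   normalized = TRUE) {
  groups <- dose_tab |> dplyr::distinct(.data$strain_id, .data$metal)
  fits <- list(); rows <- list()
  for (i in seq_len(nrow(groups))) {
    sid <- groups$strain_id[i]; m <- groups$metal[i]
    fam <- if (family == "auto") {
      if (m == "Cd") "W1" else "W2"
    } else {
      family
    }
    sub <- dose_tab[dose_tab$strain_id == sid & dose_tab$metal == m, ]
    fit <- tryCatch(fit_dose_response(sub, fam, normalized),
                    error = function(err) err)
    if (inherits(fit, "error")) {
      warning(sprintf("fit failed for %s/%s: %s", sid, m,
                      conditionMessage(fit)), call. = FALSE)
      next
    }
    fits[[paste(sid, m, sep = ".")]] <- fit
    rows[[length(rows) + 1L]] <- tibble::tibble(
      strain_id = sid, metal = m, family = fam, b = fit$b, e = fit$e,
      se_b = fit$se[["b"]], se_e = fit$se[["e"]], n_obs = fit$n_obs)
  }
  list(table = dplyr::bind_rows(rows), fits = fits)
}

#' Run the full competition-selection pipeline
#'
#' Chains the analysis stages: simulate (or load) input tables, fit
#' dose-response curves, project competition-selection trajectories per
#' treatment, analyze the co-culture observations into an inhibition
#' table, and write all artifacts plus a run manifest with md5 checksums.
#'
#' Config keys (list or YAML file): `seed`; either `synthetic: true` (with
#' optional generator overrides under `generator:`) or `strain_table`,
#' `dose_table`, `coculture_table` paths; `clamp_policy`; `horizon`;
#' `treatments`.
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory.
#' @param quiet Suppress stage messages?
#' @return Invisibly, a list with the in-memory artifacts (`strains`,
#'   `fits`, `trajectories`, `inhibition_table`, `manifest`).
#' @export
run_pipeline <- function(config = list(synthetic = TRUE, seed = 1L),
                         out_dir = tempfile("compsel_run_"), quiet = FALSE) {
  if (is.character(config)) config <- read_scenario_config(config)
  seed <- as.integer(config$seed %||% 1L)
  clamp <- config$clamp_policy %||% "clamp01"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()

  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(err) {
      abort_compsel(sprintf("pipeline stage `%s` failed: %s", name,
                            conditionMessage(err)), "compsel_pipeline_error")
    })
    say("stage %-10s done in %.2fs", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  gen_cfg <- NULL
  if (isTRUE(config$synthetic)) {
    inputs <- stage("simulate", {
      gen_args <- config$generator %||% list()
      gen_args$seed <- seed
      gen_cfg <- do.call(generator_config, gen_args)
      strains <- generate_strains(gen_cfg)
      truth <- attr(strains, "truth")
      plates <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
        simulate_plate(truth[i, ], gen_cfg, seed = seed + i)
      })
      cocult <- simulate_coculture(strains, gen_cfg, seed = seed + 10000L,
                                   treatments = config$treatments)
      list(strains = strains, truth = truth, plates = plates,
           cocult = cocult, dilution = attr(cocult, "dilution"),
           gen_cfg = gen_cfg)
    })
    gen_cfg <- inputs$gen_cfg
  } else {
    inputs <- stage("load", {
      list(strains = read_strain_table(config$strain_table),
           plates = if (!is.null(config$dose_table)) {
             read_dose_table(config$dose_table)
           },
           cocult = read_coculture_table(config$coculture_table),
           dilution = if (!is.null(config$dilution_table)) {
             readr::read_csv(config$dilution_table, show_col_types = FALSE)
           })
    })
  }

  drc <- if (!is.null(inputs$plates)) {
    stage("fit-drc", fit_all_dose_responses(inputs$plates))
  }

  treatments <- config$treatments %||%
    unique(inputs$cocult$treatment)
  exposure <- if (!is.null(gen_cfg)) {
    gen_cfg$exposure
  } else {
    unlist(config$exposure %||% c(Ag = 0.046, Cd = 5.5, Cu = 9.7))
  }
  horizon <- config$horizon %||% 10

  trajectories <- stage("predict", {
    purrr::map(stats::setNames(treatments, treatments), function(tr) {
      metal <- if (tr == "Control") NULL else tr
      sc <- competition_scenario(
        inputs$strains, metal = metal,
        concentration = if (is.null(metal)) 0 else exposure[[metal]],
        initial_density = if (!is.null(gen_cfg)) gen_cfg$initial_density else 500,
        horizon = horizon, clamp_policy = clamp)
      simulate_semicontinuous(sc)
    })
  })

  analysis <- stage("analyze", {
    rates <- interval_growth_rates(inputs$cocult, dilution = inputs$dilution)
    inh <- compute_inhibition(rates)
    list(rates = rates,
         inhibition = inh,
         table = summarize_inhibition(inh),
         shares = species_relative_biomass(inputs$cocult))
  })

  manifest_files <- stage("write", {
    paths <- c(
      strains = write_table(inputs$strains, file.path(out_dir, "strains.csv")),
      trajectories = write_table(
        purrr::imap_dfr(trajectories, \(x, nm) dplyr::mutate(as.data.frame(x),
                                                             treatment = nm)),
        file.path(out_dir, "trajectories.csv")),
      growth_rates = write_table(analysis$rates,
                                 file.path(out_dir, "growth_rates.csv")),
      inhibition_table = write_table(analysis$table,
                                     file.path(out_dir, "inhibition_table.csv")),
      species_shares = write_table(analysis$shares,
                                   file.path(out_dir, "species_shares.csv")))
    if (!is.null(drc)) {
      paths <- c(paths, drc_fits = write_table(
        drc$table, file.path(out_dir, "drc_fits.csv")))
    }
    paths
  })

  manifest <- tibble::tibble(
    file = basename(manifest_files),
    md5 = unname(tools::md5sum(manifest_files)))
  jsonlite::write_json(
    list(seed = seed, created = format(t_start, "%Y-%m-%dT%H:%M:%S"),
         r_version = as.character(getRversion()),
         files = manifest),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  say("pipeline complete: %s", out_dir)

  invisible(list(strains = inputs$strains,
                 fits = drc,
                 trajectories = trajectories,
                 rates = analysis$rates,
                 inhibition_table = analysis$table,
                 species_shares = analysis$shares,
                 manifest = manifest,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
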