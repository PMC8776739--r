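# Fixtures built in code: small strain ensembles and noiseless plates.

two_species_strains <- function(mu_sm = rep(1.55, 4), mu_tb = rep(0.55, 4),
                                I = NULL) {
  st <- tibble::tibble(
    strain_id = c(paste0("SM_", seq_along(mu_sm)),
                  paste0("TB_", seq_along(mu_tb))),
    species = c(rep("SM", length(mu_sm)), rep("TB", length(mu_tb))),
    mu = c(mu_sm, mu_tb))
  if (!is.null(I)) for (m in names(I)) st[[paste0("I_", m)]] <- I[[m]]
  st
}

noiseless_plate <- function(family, b, e, doses = c(0, 1, 2, 5, 10, 20)) {
  data.frame(concentration = doses,
             response = weibull_response(doses, family, b, e))
}

# independent inversion oracle: bisection on the forward curve
ecx_bisect <- function(fit, x) {
  target <- 1 - x / 100
  f <- function(conc) predict(fit, conc) - target
  stats::uniroot(f, interval = c(1e-6, 1e6), tol = 1e-12)$root
}
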