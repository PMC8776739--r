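#' Weibull dose-response curves
#'
#' Evaluates the two Weibull sigmoids commonly used for growth-inhibition
#' assays, in the parameterisation on the natural-log concentration scale:
#' \deqn{W1: f(x) = c + (d - c)\,\exp(-\exp(b(\ln x - \ln e)))}
#' \deqn{W2: f(x) = c + (d - c)\,(1 - \exp(-\exp(b(\ln x - \ln e))))}
#' A monotone-decreasing (toxic) response requires `b > 0` for W1 and
#' `b < 0` for W2. Concentration 0 is evaluated as the analytic limit,
#' never via `log(0)`; for a valid decreasing curve that limit is `d`.
#'
#' @param conc Concentration (same unit as `e`, typically uM), `>= 0`.
#' @param family `"W1"` or `"W2"`.
#' @param b Shape (slope) parameter, non-zero.
#' @param e Concentration-scale parameter, `> 0`.
#' @param c,d Lower and upper response asymptotes (defaults 0 and 1,
#'   the normalized mode).
#' @return Relative response, same length as `conc`, within
#'   `[min(c, d), max(c, d)]`.
#' @examples
#' weibull_response(0, "W1", b = 2, e = 5)          # control -> d = 1
#' weibull_response(5, "W1", b = 2, e = 5)          # exp(-1) at conc = e
#' weibull_response(0.046, "W2", b = -2, e = 0.046) # 1 - exp(-1)
#' @export
weibull_response <- function(conc, family = c("W1", "W2"), b, e, c = 0, d = 1) {
  family <- match.arg(family)
  if (!is.finite(e) || e <= 0) {
    abort_compsel("`e` must be finite and > 0", "compsel_invalid_params")
  }
  if (!is.finite(b) || b == 0) {
    abort_compsel("`b` must be finite and non-zero", "compsel_invalid_params")
  }
  if (c == d) {
    abort_compsel("asymptotes `c` and `d` must differ", "compsel_invalid_params")
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    abort_compsel("`conc` must be finite and >= 0", "compsel_invalid_params")
  }
  out <- numeric(length(conc))
  zero <- conc == 0
  # analytic limit at conc -> 0 depends on the sign of b
  lim0 <- if (family == "W1") {
    if (b > 0) d else c
  } else {
    if (b > 0) c else d
  }
  out[zero] <- lim0
  if (any(!zero)) {
    z <- exp(b * (log(conc[!zero]) - log(e)))
    out[!zero] <- if (family == "W1") {
      c + (d - c) * exp(-z)
    } else {
      c + (d - c) * (1 - exp(-z))
    }
  }
  out
}

#' Fit a Weibull dose-response curve
#'
#' Least-squares fit of the W1/W2 inhibition curve to a 72 h acute
#' dose-response assay. In the default normalized mode the responses are
#' divided by the mean control (zero-concentration) response and the
#' asymptotes are fixed at `(c, d) = (0, 1)`, so the fitted curve yields
#' standardized 0-1 inhibition coefficients directly. Fitting uses
#' Levenberg-Marquardt nonlinear least squares with a multi-start grid on
#' the shape parameter (|b| in 0.5, 1, 2, 4) and the geometric mean of the
#' positive doses as the starting scale; the converged start with the lowest
#' residual sum of squares wins. Only monotone-decreasing fits are accepted.
#'
#' @param obs Data frame with columns `concentration` (uM, `>= 0`, must
#'   include 0) and `response` (growth rate or relative growth rate);
#'   optional `strain_id`, `metal` are carried through.
#' @param family `"W1"` or `"W2"`.
#' @param normalized If `TRUE` (default), normalize by the mean control
#'   response and fix `(c, d) = (0, 1)`; if `FALSE`, fit all four
#'   parameters.
#' @return An object of class `dr_fit`: list with `family`, `b`, `e`, `c`,
#'   `d`, `se` (named standard errors), `vcov`, `n_obs`, `normalized`,
#'   `rss`, `conc_range`, and any `strain_id`/`metal` labels.
#' @examples
#' doses <- c(0, 1, 2, 5, 10, 20)
#' obs <- data.frame(concentration = doses,
#'                   response = weibull_response(doses, "W1", b = 2, e = 5))
#' fit <- fit_dose_response(obs, family = "W1")
#' ecx(fit, 50)
#' @export
fit_dose_response <- function(obs, family = c("W1", "W2"), normalized = TRUE) {
  family <- match.arg(family)
  if (!all(c("concentration", "response") %in% names(obs))) {
    abort_compsel("`obs` needs columns `concentration` and `response`",
                  "compsel_schema_error")
  }
  obs <- obs[is.finite(obs$response) & !is.na(obs$concentration), , drop = FALSE]
  conc <- obs$concentration
  resp <- obs$response
  if (any(conc < 0)) {
    abort_compsel("negative concentrations are invalid", "compsel_schema_error")
  }
  if (length(unique(conc)) < 4L) {
    abort_compsel("need >= 4 distinct concentrations to fit", "compsel_fit_error")
  }
  if (!any(conc == 0)) {
    abort_compsel("need at least one zero-concentration (control) observation",
                  "compsel_fit_error")
  }
  if (all(resp == 0)) {
    abort_compsel("all responses are zero; nothing to fit", "compsel_fit_error")
  }

  if (normalized) {
    ctrl <- mean(resp[conc == 0])
    if (!is.finite(ctrl) || ctrl <= 0) {
      abort_compsel("mean control response must be positive to normalize",
                    "compsel_fit_error")
    }
    y <- resp / ctrl
  } else {
    y <- resp
  }
  if (stats::sd(y) < 1e-9) {
    abort_compsel(
      "responses are constant across doses: no inhibition signal (e -> Inf)",
      "compsel_fit_error")
  }

  e0 <- exp(mean(log(conc[conc > 0])))
  b_grid <- c(0.5, 1, 2, 4)
  if (family == "W2") b_grid <- -b_grid
  ctrl_nls <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 1024)
  b_lower <- if (family == "W1") 1e-6 else -Inf
  b_upper <- if (family == "W1") Inf else -1e-6

  best <- NULL
  for (b0 in b_grid) {
    fit <- tryCatch({
      if (normalized) {
        minpack.lm::nlsLM(
          y ~ weibull_response(conc, family, b, e),
          start = list(b = b0, e = e0),
          lower = c(b = b_lower, e = 1e-12),
          upper = c(b = b_upper, e = Inf),
          control = ctrl_nls)
      } else {
        minpack.lm::nlsLM(
          y ~ weibull_response(conc, family, b, e, cc, dd),
          start = list(b = b0, e = e0, cc = min(y), dd = max(y)),
          lower = c(b = b_lower, e = 1e-12, cc = -Inf, dd = -Inf),
          upper = c(b = b_upper, e = Inf, cc = Inf, dd = Inf),
          control = ctrl_nls)
      }
    }, error = function(err) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    abort_compsel(
      paste0("dose-response fit failed to converge from all starts (family ",
             family, ", ", length(y), " observations)"),
      "compsel_fit_error")
  }

  cf <- stats::coef(best$fit)
  vc <- tryCatch(stats::vcov(best$fit), error = function(err) {
    matrix(NA_real_, length(cf), length(cf), dimnames = list(names(cf), names(cf)))
  })
  cc <- if (normalized) 0 else unname(cf["cc"])
  dd <- if (normalized) 1 else unname(cf["dd"])
  # decreasing-orientation check over the observed range
  rng <- range(conc[conc > 0])
  probe <- weibull_response(c(rng[1], rng[2]), family, cf[["b"]], cf[["e"]], cc, dd)
  if (probe[2] > probe[1] + 1e-8) {
    abort_compsel("fitted curve is increasing over the observed range; only monotone-decreasing (toxic) responses are valid",
                  "compsel_fit_error")
  }

  structure(list(
    family = family,
    b = unname(cf[["b"]]),
    e = unname(cf[["e"]]),
    c = cc,
    d = dd,
    se = sqrt(diag(vc)),
    vcov = vc,
    n_obs = length(y),
    normalized = normalized,
    rss = best$rss,
    conc_range = range(conc),
    strain_id = if ("strain_id" %in% names(obs)) obs$strain_id[1] else NA_character_,
    metal = if ("metal" %in% names(obs)) obs$metal[1] else NA_character_
  ), class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("Weibull %s dose-response fit%s%s\n", x$family,
              if (!is.na(x$strain_id)) paste0(" | strain ", x$strain_id) else "",
              if (!is.na(x$metal)) paste0(" | ", x$metal) else ""))
  cat(sprintf("  b = %.4g (se %.3g), e = %.4g (se %.3g), c = %g, d = %g\n",
              x$b, x$se[["b"]], x$e, x$se[["e"]], x$c, x$d))
  cat(sprintf("  n = %d, RSS = %.4g, normalized = %s\n",
              x$n_obs, x$rss, x$normalized))
  invisible(x)
}

#' @export
predict.dr_fit <- function(object, conc, ...) {
  weibull_response(conc, object$family, object$b, object$e, object$c, object$d)
}

#' Inhibition coefficient at a concentration
#'
#' Standardized 0-1 inhibition implied by a fitted dose-response curve at a
#' given exposure concentration: `I = 1 - f(conc)` for a normalized fit
#' (`I = 1 - f(conc)/d` otherwise). With `clamp = TRUE` the value is
#' restricted to `[0, 1]`, matching a selection model that cannot represent
#' negative growth (inhibition above 1).
#'
#' @param fit A `dr_fit` object.
#' @param conc Concentration (uM, `>= 0`), vectorized.
#' @param clamp Restrict the result to `[0, 1]`? Default `TRUE`.
#' @return Inhibition coefficient(s), dimensionless.
#' @export
inhibition_at <- function(fit, conc, clamp = TRUE) {
  if (!inherits(fit, "dr_fit")) {
    abort_compsel("`fit` must be a `dr_fit` object", "compsel_invalid_params")
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    abort_compsel("`conc` must be finite and >= 0", "compsel_invalid_params")
  }
  if (fit$c != 0) {
    abort_compsel("inhibition requires a fit with lower asymptote c = 0",
                  "compsel_invalid_params")
  }
  i <- 1 - predict(fit, conc) / fit$d
  if (clamp) clamp01(i) else i
}

#' Effective concentration for x percent inhibition (ECx)
#'
#' Closed-form inversion of the fitted Weibull curve: the concentration at
#' which relative response equals `1 - x/100`.
#' \deqn{W1: EC_x = e\,\exp(\ln(-\ln(1 - x/100))/b)}
#' \deqn{W2: EC_x = e\,\exp(\ln(-\ln(x/100))/b)}
#'
#' @param fit A `dr_fit` object with lower asymptote 0.
#' @param x Inhibition percentage, strictly between 0 and 100 (vectorized).
#' @return Concentration(s) in the unit of `e` (uM).
#' @examples
#' doses <- c(0, 0.25, 0.5, 1, 2, 4)
#' obs <- data.frame(concentration = doses,
#'                   response = weibull_response(doses, "W1", b = 1, e = 1))
#' fit <- fit_dose_response(obs, "W1")
#' ecx(fit, 50)   # EC50
#' @export
ecx <- function(fit, x) {
  if (!inherits(fit, "dr_fit")) {
    abort_compsel("`fit` must be a `dr_fit` object", "compsel_invalid_params")
  }
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 100)) {
    abort_compsel("`x` must lie strictly between 0 and 100", "compsel_domain_error")
  }
  if (fit$c != 0) {
    abort_compsel("ECx requires a fit with lower asymptote c = 0",
                  "compsel_invalid_params")
  }
  p <- x / 100
  if (fit$family == "W1") {
    fit$e * exp(log(-log(1 - p)) / fit$b)
  } else {
    fit$e * exp(log(-log(p)) / fit$b)
  }
}
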