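#' Clamp values to the unit interval
#'
#' @param x Numeric vector.
#' @return `x` with every element restricted to `[0, 1]`.
#' @export
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Surface area of a cylindrical cell
#'
#' Simple lateral-plus-caps cylinder model used to convert cell counts to
#' surface-area biomass (the biomass unit that tracks in vivo chlorophyll
#' fluorescence most closely for chain-forming and solitary centric diatoms).
#'
#' @param diameter Cell diameter (micrometres, > 0).
#' @param height Cell height along the pervalvar axis (micrometres, > 0).
#' @return Surface area in square micrometres.
#' @examples
#' cylinder_surface_area(5, 10)
#' @export
cylinder_surface_area <- function(diameter, height) {
  if (any(!is.finite(diameter)) || any(!is.finite(height)) ||
      any(diameter <= 0) || any(height <= 0)) {
    stop("`diameter` and `height` must be finite and positive", call. = FALSE)
  }
  pi * diameter * height + pi * diameter^2 / 2
}

# internal: stop with a condition class so callers can test failure modes
abort_compsel <- function(msg, class) {
  rlang::abort(msg, class = c(class, "compsel_error"))
}
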