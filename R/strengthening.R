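#' Precipitation-strengthening increment from hardness contrast
#'
#' Dispersed obstacles that pin dislocations raise both hardness and flow
#' stress; the two are linked by `H = H0 + C * delta_sigma_Y`, where `H` and
#' `H0` are the hardness of the defect-containing and defect-free crystal
#' and `C` is a material-specific constraint coefficient. Inverting gives
#' the strengthening increment `delta_sigma_Y = (H - H0) / C`. The default
#' `C = 3` is the classical Tabor-style hardness-to-flow-stress constraint
#' factor; it is always explicit in the interface and should be overridden
#' when a material-specific value is available.
#'
#' @param H Hardness of the strengthened (biogenic) crystal (GPa).
#' @param H0 Hardness of the reference (geological) crystal (GPa, > 0).
#' @param C Constraint coefficient (> 0).
#' @return A list: `delta_sigma_Y` (GPa) and a `softening` flag (negative
#'   increments are permitted but flagged).
#' @examples
#' strengthening_increment(H0 = 2.9, H = 2.9 + 1.08, C = 3)$delta_sigma_Y  # 0.36
#' @export
strengthening_increment <- function(H, H0, C = 3) {
  check_scalar(H, "H")
  check_scalar(H0, "H0", lower = 0, strict_lower = TRUE)
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    stop_input("`C` must be a single positive number")
  }
  d <- (H - H0) / C
  list(delta_sigma_Y = d, softening = d < 0)
}

#' Predicted intrinsic strength from a strengthening increment
#'
#' Adds a strengthening increment to a base (defect-free) yield strength and
#' optionally compares the prediction with a measured strength. A predicted
#' strength above the measured one indicates that the crystal fractures
#' before it yields by dislocation motion, so the measured strength is
#' fracture-limited rather than slip-limited.
#'
#' @param base Base yield strength (GPa), e.g. the geological calcite 0.96.
#' @param delta_sigma_Y Strengthening increment (GPa), or the list returned
#'   by [strengthening_increment()].
#' @param measured Optional measured strength (GPa) for the comparison flag.
#' @return A list: `predicted` (GPa), `measured`, and
#'   `fracture_before_yield` (`NA` when no measurement is supplied).
#' @examples
#' predicted_strength(0.96, 0.36, measured = 1.16)
#' @export
predicted_strength <- function(base, delta_sigma_Y, measured = NULL) {
  check_scalar(base, "base")
  if (is.list(delta_sigma_Y)) delta_sigma_Y <- delta_sigma_Y$delta_sigma_Y
  check_scalar(delta_sigma_Y, "delta_sigma_Y")
  pred <- base + delta_sigma_Y
  flag <- if (is.null(measured)) {
    NA
  } else {
    check_scalar(measured, "measured")
    pred > measured
  }
  list(
    predicted = pred,
    measured = if (is.null(measured)) NA_real_ else measured,
    fracture_before_yield = flag
  )
}
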