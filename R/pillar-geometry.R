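#' Micro-pillar geometry
#'
#' Describes a slightly tapered compression micro-pillar: top diameter `D1`,
#' bottom diameter `D2`, height `h` (all in micrometres), taper half-angle
#' (degrees) and the Poisson ratio of the material. The defaults are the
#' nominal dimensions of FIB-milled calcite pillars (top diameter ~2 um,
#' aspect ratio ~3, taper ~2.5 degrees) with the average Poisson ratio of
#' calcite, 0.3.
#'
#' Only two of `D2` and `taper` are needed: the missing one is computed from
#' `tan(taper) = (D2 - D1) / (2 h)`. When all three are supplied they must be
#' mutually consistent within `taper_tol` degrees.
#'
#' @param D1 Top diameter (um).
#' @param D2 Bottom diameter (um), or `NULL` to derive it from `taper`.
#' @param h Pillar height (um).
#' @param taper Taper half-angle (degrees), or `NULL` to derive it from `D2`.
#' @param nu Poisson ratio (dimensionless, in `[0, 0.5)`).
#' @param taper_tol Consistency tolerance on the taper angle (degrees).
#'
#' @return An object of class `"pillar_geometry"`.
#' @examples
#' pillar_geometry()                      # nominal calcite pillar
#' pillar_geometry(D1 = 2, D2 = 2.5, h = 6)
#' @export
pillar_geometry <- function(D1 = 2, D2 = NULL, h = 6, taper = 2.5, nu = 0.3,
                            taper_tol = 0.5) {
  check_scalar(D1, "D1", lower = 0, strict_lower = TRUE)
  check_scalar(h, "h", lower = 0, strict_lower = TRUE)
  check_scalar(nu, "nu", lower = 0, upper = 0.5, strict_upper = TRUE)
  d2_given <- !is.null(D2)
  taper_given <- !is.null(taper) && d2_given
  if (!d2_given) {
    if (is.null(taper)) {
      stop_input("supply at least one of `D2` and `taper`")
    }
    check_scalar(taper, "taper", lower = 0, upper = 45)
    D2 <- D1 + 2 * h * tan(taper * pi / 180)
  }
  check_scalar(D2, "D2", lower = D1)
  implied <- atan2(D2 - D1, 2 * h) * 180 / pi
  if (taper_given) {
    check_scalar(taper, "taper", lower = 0, upper = 45)
    if (abs(taper - implied) > taper_tol) {
      stop_input(sprintf(
        "invalid geometry: taper %.2f deg inconsistent with (D2 - D1)/(2h) = %.2f deg",
        taper, implied
      ))
    }
  }
  structure(
    list(D1 = D1, D2 = D2, h = h, taper = implied, nu = nu),
    class = "pillar_geometry"
  )
}

#' @export
print.pillar_geometry <- function(x, ...) {
  cat(sprintf(
    "Micro-pillar geometry: D1 = %.3g um, D2 = %.3g um, h = %.3g um, taper = %.2f deg, nu = %.2f\n",
    x$D1, x$D2, x$h, x$taper, x$nu
  ))
  invisible(x)
}

is_pillar_geometry <- function(x) inherits(x, "pillar_geometry")

assert_geometry <- function(geom) {
  if (!is_pillar_geometry(geom)) {
    stop_input("`geom` must be a pillar_geometry object")
  }
  invisible(geom)
}

# Normalized-stress factor of the tapered-pillar compliance correction:
# sigma_n [GPa] = stress_factor(geom) * F [mN], with diameters/heights in um.
stress_factor <- function(geom) {
  4 / (pi * geom$D1 * geom$D2) + (1 - geom$nu^2) / (geom$D2 * geom$h)
}

# Top-cross-section stress factor used for yield and maximum strength:
# sigma [GPa] = eq_top_factor(geom) * F [mN].
eq_top_factor <- function(geom) {
  4 / (pi * geom$D1^2)
}

# Ratio between the normalized stress and the top-cross-section stress for
# the same force; converts between the two stress scales.
stress_scale_ratio <- function(geom) {
  stress_factor(geom) / eq_top_factor(geom)
}
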