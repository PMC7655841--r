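#' Orientation factor of the wing-crack model
#'
#' The driving force for frictional sliding on an inclined defect under
#' uniaxial compression resolves as \eqn{\sin\theta\cos\theta - \mu\cos^2\theta},
#' where `theta` is measured from the transverse plane (so `theta = 0` means
#' the defect long axis is perpendicular to the load) and `mu` is the
#' friction coefficient between defect and matrix. The factor is floored at
#' `floor` so the strength model stays finite for near-transverse defects
#' whose sliding term vanishes. The whole function can be replaced by a
#' caller-supplied form via the `beta_fun` argument of
#' [wing_crack_strength()].
#'
#' @param theta Inclination angle(s), degrees in `[0, 90]`.
#' @param mu Friction coefficient (>= 0).
#' @param floor Lower bound on the factor (> 0).
#' @return Numeric vector of orientation factors.
#' @examples
#' beta_orientation_factor(45, mu = 0)  # 0.5, the frictionless maximum
#' @export
beta_orientation_factor <- function(theta, mu = 0.3, floor = 0.1) {
  check_scalar(mu, "mu", lower = 0)
  check_scalar(floor, "floor", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 90)) {
    stop_input("theta must lie in [0, 90] degrees")
  }
  th <- theta * pi / 180
  pmax(sin(th) * cos(th) - mu * cos(th)^2, floor)
}

#' Wing-crack compressive strength of a defect-laden crystal
#'
#' Evaluates the micromechanical strength model for a quasi-brittle solid
#' whose failure is governed by wing cracks nucleating at sliding
#' intracrystalline defects:
#' \deqn{\sigma_y = \left(\frac{2\pi}{11}\right)^{1/4} L^{1/2}
#'   \frac{\sigma_{Y,c}\sqrt{\pi a}}{20\,\beta(\theta)\,a},}
#' with `L` the defect spacing, `a` the defect half-length, `theta` the
#' inclination from the transverse plane, and `sigma_yc` the compressive
#' strength of the defect-free (geological) matrix. Only the ratio `L/a`
#' enters, so the result is independent of the length unit. Because the
#' absolute scale of \eqn{\beta} is a model convention, `beta_scale` (or
#' [calibrate_wing_crack()]) lets the prediction be anchored so that a
#' reference configuration reproduces a measured strength; the spacing and
#' orientation dependence is unaffected by the anchor.
#'
#' @param L Defect spacing(s) (nm, or any unit shared with `a`).
#' @param theta Inclination angle(s), degrees from the transverse plane.
#' @param a Defect half-length (same unit as `L`); 5.5 nm for the measured
#'   defects.
#' @param sigma_yc Matrix compressive strength (GPa); 0.96 GPa for geological
#'   calcite.
#' @param mu,beta_floor Parameters of the default orientation factor.
#' @param beta_fun Optional replacement for [beta_orientation_factor()],
#'   called as `beta_fun(theta)`.
#' @param beta_scale Multiplier applied to the orientation factor.
#' @return Predicted compressive strength(s), GPa.
#' @examples
#' s <- calibrate_wing_crack(L_ref = 32, target = 0.96)
#' wing_crack_strength(32, beta_scale = s) - wing_crack_strength(10, beta_scale = s)
#' @export
wing_crack_strength <- function(L, theta = 0, a = 5.5, sigma_yc = 0.96,
                                mu = 0.3, beta_floor = 0.1, beta_fun = NULL,
                                beta_scale = 1) {
  if (any(!is.finite(L)) || any(L <= 0)) stop_input("L must be positive")
  check_scalar(a, "a", lower = 0, strict_lower = TRUE)
  check_scalar(sigma_yc, "sigma_yc", lower = 0, strict_lower = TRUE)
  check_scalar(beta_scale, "beta_scale", lower = 0, strict_lower = TRUE)
  beta <- if (is.null(beta_fun)) {
    beta_orientation_factor(theta, mu = mu, floor = beta_floor)
  } else {
    beta_fun(theta)
  }
  beta_eff <- beta_scale * beta
  if (any(!is.finite(beta_eff)) || any(beta_eff <= 0)) {
    stop_input("singular model: orientation factor must be positive")
  }
  (2 * pi / 11)^(1 / 4) * sqrt(L) * sigma_yc * sqrt(pi * a) / (20 * beta_eff * a)
}

#' Calibrate the orientation-factor scale against an anchor strength
#'
#' Returns the `beta_scale` for which [wing_crack_strength()] evaluated at
#' the reference configuration `(L_ref, theta_ref)` equals `target`. The
#' model is linear in \eqn{1/\beta}, so this rescaling shifts the whole
#' strength map without touching its spacing or orientation dependence.
#'
#' @param L_ref,theta_ref Reference configuration.
#' @param target Strength the reference configuration must reproduce (GPa).
#' @param ... Passed to [wing_crack_strength()].
#' @return The calibrated `beta_scale` (dimensionless).
#' @export
calibrate_wing_crack <- function(L_ref = 32, theta_ref = 0, target = 0.96, ...) {
  check_scalar(target, "target", lower = 0, strict_lower = TRUE)
  wing_crack_strength(L_ref, theta_ref, ...) / target
}

#' Strength map over defect spacing and inclination
#'
#' Evaluates [wing_crack_strength()] on the tensor grid `L x theta` and marks
#' the observed-configuration box (spacings of roughly 10--32 nm at
#' inclinations below 5 degrees, the geometry measured for the nanoscopic
#' intracrystalline defects).
#'
#' @param L Spacing grid (nm), increasing.
#' @param theta Inclination grid (degrees), increasing.
#' @param ... Passed to [wing_crack_strength()] (including any calibration).
#' @param box Observed-configuration box `list(L = c(lo, hi), theta = c(lo, hi))`.
#' @return A `"strength_map"` list: `L`, `theta`, `sigma` (matrix, rows = L,
#'   cols = theta), `box`, `params`.
#' @export
strength_map <- function(L, theta, ...,
                         box = list(L = c(10, 32), theta = c(0, 5))) {
  if (!length(L) || !length(theta)) stop_input("empty grid")
  if (any(L <= 0)) stop_input("L grid must be positive")
  sigma <- outer(L, theta, function(l, t) wing_crack_strength(l, t, ...))
  dimnames(sigma) <- list(L = signif(L, 6), theta = signif(theta, 6))
  structure(
    list(L = L, theta = theta, sigma = sigma, box = box,
         params = list(...)),
    class = "strength_map"
  )
}

#' @export
print.strength_map <- function(x, ...) {
  cat(sprintf(
    "Wing-crack strength map: %d spacings (%.3g-%.3g nm) x %d angles (%.3g-%.3g deg)\n",
    length(x$L), min(x$L), max(x$L), length(x$theta), min(x$theta), max(x$theta)
  ))
  cat(sprintf("  sigma_y range: %.3g-%.3g GPa\n", min(x$sigma), max(x$sigma)))
  cat(sprintf("  observed box: L in [%g, %g] nm, theta in [%g, %g] deg\n",
              x$box$L[1], x$box$L[2], x$box$theta[1], x$box$theta[2]))
  invisible(x)
}

#' @export
as.data.frame.strength_map <- function(x, ...) {
  data.frame(
    L = rep(x$L, times = length(x$theta)),
    theta = rep(x$theta, each = length(x$L)),
    sigma_y = as.vector(x$sigma)
  )
}

#' @param x A `"strength_map"`.
#' @param ... Passed to [graphics::image()].
#' @rdname strength_map
#' @export
plot.strength_map <- function(x, ...) {
  graphics::image(x$L, x$theta, x$sigma,
                  xlab = "defect spacing L (nm)",
                  ylab = "inclination theta (deg)", ...)
  graphics::contour(x$L, x$theta, x$sigma, add = TRUE)
  graphics::rect(x$box$L[1], x$box$theta[1], x$box$L[2], x$box$theta[2],
                 border = "white", lwd = 2, lty = 2)
  invisible(x)
}

#' Stress-concentration anisotropy of an elliptical defect
#'
#' Inglis concentration for an elliptical hole under remote tension normal
#' to an axis: \eqn{k_t = 1 + 2 a/b} at the tip of the axis of half-length
#' `a`. The ratio of the long-axis-tip to short-axis-tip concentration,
#' \eqn{(1 + 2r)/(1 + 2/r)} with `r = lateral_span / height`, measures how
#' much more a flattened defect amplifies stress along its long axis. A
#' circular defect gives 1; the measured 10 x 5 nm defect geometry gives 2.5,
#' i.e. a more-than-doubled concentration along the long axes. This is a
#' simplified hole-concentration measure, used as a stand-in for a full
#' stress-intensity analysis of the ellipsoidal defect tips.
#'
#' @param lateral_span Defect extent along the long (transverse) axis (nm).
#' @param height Defect extent along the short axis (nm).
#' @return Ratio of long-axis to short-axis stress concentration (>= 1 for
#'   `lateral_span >= height`).
#' @examples
#' elliptical_concentration_ratio(10, 5)  # 2.5
#' @export
elliptical_concentration_ratio <- function(lateral_span, height) {
  check_scalar(lateral_span, "lateral_span", lower = 0, strict_lower = TRUE)
  check_scalar(height, "height", lower = 0, strict_lower = TRUE)
  r <- lateral_span / height
  (1 + 2 * r) / (1 + 2 / r)
}
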