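#' Specification of a synthetic compression curve
#'
#' Parameterizes the piecewise constitutive template used to emulate the two
#' observed material classes. A *biogenic*-type pillar deforms linearly to
#' yield, hardens linearly, and fractures abruptly at `eps_f`; a
#' *geological*-type pillar deforms linearly to yield, undergoes a
#' single-step displacement burst `delta_eps` with a load drop, reloads, and
#' flows at a steady plateau `sigma_f`. Default parameters are the cohort
#' means measured for the two calcites: biogenic E = 34.4 GPa, yield 1.16
#' GPa, failure strain 0.074; geological E = 47.9 GPa, yield 0.96 GPa, flow
#' plateau 0.47 GPa. The default hardening modulus of 4 GPa takes the
#' biogenic template from its yield strength to a maximum strength of about
#' 1.32 GPa at the default failure strain.
#'
#' Strengths are on the top-cross-section stress scale (the scale on which
#' yield and maximum strength are reported), and the modulus is the slope of
#' the *normalized* stress-strain curve, so a generated record reduces back
#' to exactly these parameters in the noise-free limit.
#'
#' @param material `"biogenic"` or `"geological"`.
#' @param E Young's modulus (GPa).
#' @param sigma_Y Yield strength (GPa).
#' @param hardening Post-yield hardening modulus (GPa, biogenic).
#' @param eps_f Failure strain (biogenic).
#' @param delta_eps Displacement-burst strain jump (geological).
#' @param sigma_f Flow plateau stress (GPa, geological, normalized scale).
#' @param eps_flow Plateau extent in strain beyond the reload (geological).
#' @param noise_sd Additive Gaussian stress noise (GPa, applied to the
#'   normalized stress and carried into the force channel).
#' @param step Strain sampling step.
#' @param rate Displacement rate (nm/s) used to synthesize time stamps.
#' @return A `"curve_spec"` list.
#' @export
curve_spec <- function(material = c("biogenic", "geological"),
                       E = NULL, sigma_Y = NULL, hardening = 4,
                       eps_f = 0.074, delta_eps = 0.015, sigma_f = 0.47,
                       eps_flow = 0.04, noise_sd = 0.01, step = 1e-4,
                       rate = 10) {
  material <- match.arg(material)
  if (is.null(E)) E <- if (material == "biogenic") 34.4 else 47.9
  if (is.null(sigma_Y)) sigma_Y <- if (material == "biogenic") 1.16 else 0.96
  check_scalar(E, "E", lower = 0, strict_lower = TRUE)
  check_scalar(sigma_Y, "sigma_Y", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(step, "step", lower = 0, strict_lower = TRUE)
  if (material == "biogenic") {
    check_scalar(hardening, "hardening", lower = 0)
    check_scalar(eps_f, "eps_f", lower = 0, strict_lower = TRUE)
  } else {
    check_scalar(delta_eps, "delta_eps", lower = 0, strict_lower = TRUE)
    check_scalar(sigma_f, "sigma_f", lower = 0, strict_lower = TRUE)
    check_scalar(eps_flow, "eps_flow", lower = 0, strict_lower = TRUE)
  }
  structure(
    list(material = material, E = E, sigma_Y = sigma_Y, hardening = hardening,
         eps_f = eps_f, delta_eps = delta_eps, sigma_f = sigma_f,
         eps_flow = eps_flow, noise_sd = noise_sd, step = step, rate = rate),
    class = "curve_spec"
  )
}

#' Mechanical summary implied by a curve specification
#'
#' The exact property values a noise-free synthetic curve encodes, given the
#' pillar geometry: the elastic limit follows from the yield strength, the
#' modulus and the stress-scale ratio of the compliance correction; the
#' maximum strength of a biogenic template follows from the hardening branch.
#' Useful as ground truth in round-trip tests.
#'
#' @param spec A [curve_spec()].
#' @param geom A [pillar_geometry()].
#' @return One-row data frame with `E`, `sigma_Y`, `eps_e`, `sigma_max`,
#'   `eps_f`, `sigma_f`, `delta_eps` (NA where not applicable).
#' @export
curve_spec_summary <- function(spec, geom = pillar_geometry()) {
  assert_geometry(geom)
  r <- stress_scale_ratio(geom)
  eps_e <- r * spec$sigma_Y / spec$E
  if (spec$material == "biogenic") {
    eps_f <- round(spec$eps_f / spec$step) * spec$step  # snapped to the grid
    data.frame(
      E = spec$E, sigma_Y = spec$sigma_Y, eps_e = eps_e,
      sigma_max = spec$sigma_Y + spec$hardening * (eps_f - eps_e),
      eps_f = eps_f, sigma_f = NA_real_, delta_eps = NA_real_
    )
  } else {
    data.frame(
      E = spec$E, sigma_Y = spec$sigma_Y, eps_e = eps_e,
      sigma_max = spec$sigma_Y, eps_f = NA_real_,
      sigma_f = spec$sigma_f, delta_eps = spec$delta_eps
    )
  }
}

#' Generate a synthetic force-displacement record
#'
#' Builds the stress-strain template of the spec, inverts the
#' substrate-compliance normalization to obtain force and depth, adds seeded
#' Gaussian stress noise, and returns an instrument-style record. Identical
#' `(spec, geom, seed)` give identical output.
#'
#' @param spec A [curve_spec()].
#' @param geom A [pillar_geometry()].
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @return A [force_displacement()] record with the spec and geometry
#'   attached as attributes.
#' @examples
#' rec <- generate_curve(curve_spec("geological"), pillar_geometry(), seed = 7)
#' summary(rec$force_mN)
#' @export
generate_curve <- function(spec, geom = pillar_geometry(), seed = NULL) {
  if (!inherits(spec, "curve_spec")) stop_input("`spec` must be a curve_spec")
  assert_geometry(geom)
  r <- stress_scale_ratio(geom)       # sigma_n / sigma_top at equal force
  eps_e <- r * spec$sigma_Y / spec$E  # knee strain of the normalized curve
  step <- spec$step
  if (spec$material == "biogenic") {
    eps_f <- round(spec$eps_f / step) * step
    if (eps_f <= eps_e) stop_input("eps_f must exceed the elastic limit implied by sigma_Y/E")
    eps <- seq(0, eps_f, by = step)
    if (abs(eps[length(eps)] - eps_f) > step / 2) eps <- c(eps, eps_f)
    # top-scale stress template; hardening stated on the top scale
    sig_top <- ifelse(eps <= eps_e,
                      (spec$E / r) * eps,
                      spec$sigma_Y + spec$hardening * (eps - eps_e))
    eps <- c(eps, eps_f + step)
    sig_top <- c(sig_top, 0.02 * sig_top[length(sig_top)])
  } else {
    eps_knee <- floor(eps_e / step) * step
    if (eps_knee < 3 * step) stop_input("sampling step too coarse for the elastic segment")
    eps1 <- seq(0, eps_knee, by = step)
    sig1 <- (spec$E / r) * eps1
    sig_plateau <- spec$sigma_f / r       # plateau stated on the normalized scale
    sig_drop <- 0.7 * sig_plateau
    eps_burst <- eps_knee + spec$delta_eps
    # reload at the elastic slope up to the plateau, then steady flow
    d_reload <- (sig_plateau - sig_drop) * r / spec$E
    eps2 <- seq(eps_burst, eps_burst + d_reload, by = step)
    sig2 <- sig_drop + (spec$E / r) * (eps2 - eps_burst)
    eps3 <- seq(eps_burst + d_reload + step, eps_knee + spec$delta_eps + spec$eps_flow,
                by = step)
    sig3 <- rep(sig_plateau, length(eps3))
    eps <- c(eps1, eps2, eps3)
    sig_top <- c(sig1, sig2, sig3)
  }
  sig_n <- stress_scale_ratio(geom) * sig_top
  if (spec$noise_sd > 0) {
    noise <- local_seed(seed, stats::rnorm(length(sig_n), 0, spec$noise_sd))
    sig_n <- sig_n + noise
    sig_n[1] <- 0
    sig_n <- pmax(sig_n, 0)
  }
  force <- sig_n / stress_factor(geom)
  depth <- eps * geom$h * 1000
  rec <- force_displacement(
    time_s = depth / spec$rate,
    force_mN = force,
    depth_nm = depth,
    segment = rep("loading", length(eps))
  )
  attr(rec, "spec") <- spec
  attr(rec, "geometry") <- geom
  rec
}

#' Draw curve specifications from the measured cohort statistics
#'
#' Samples per-pillar parameters from normal distributions with the cohort
#' means and standard deviations measured for each material (biogenic:
#' E 34.4 +/- 5.3 GPa, yield 1.16 +/- 0.22 GPa, failure strain
#' 0.0740 +/- 0.0341; geological: E 47.9 +/- 5.5 GPa, yield 0.96 +/- 0.37
#' GPa, flow 0.47 +/- 0.12 GPa). Draws are truncated away from unphysical
#' regions (non-positive moduli or strengths, failure strains at or below
#' the implied elastic limit).
#'
#' @param n Number of specifications.
#' @param material `"biogenic"` or `"geological"`.
#' @param geom Geometry used to enforce the failure-strain truncation.
#' @param seed Integer seed.
#' @param noise_sd,step Passed to every [curve_spec()].
#' @return A list of `n` [curve_spec()] objects.
#' @export
sample_curve_specs <- function(n, material = c("biogenic", "geological"),
                               geom = pillar_geometry(), seed = NULL,
                               noise_sd = 0.01, step = 1e-4) {
  material <- match.arg(material)
  check_scalar(n, "n", lower = 1)
  local_seed(seed, {
    lapply(seq_len(n), function(i) {
      if (material == "biogenic") {
        E <- max(stats::rnorm(1, 34.4, 5.3), 10)
        sY <- max(stats::rnorm(1, 1.16, 0.22), 0.3)
        eps_e <- stress_scale_ratio(geom) * sY / E
        ef <- max(stats::rnorm(1, 0.0740, 0.0341), eps_e + 0.005)
        curve_spec("biogenic", E = E, sigma_Y = sY, eps_f = ef,
                   noise_sd = noise_sd, step = step)
      } else {
        E <- max(stats::rnorm(1, 47.9, 5.5), 10)
        sY <- max(stats::rnorm(1, 0.96, 0.37), 0.2)
        sf <- max(stats::rnorm(1, 0.47, 0.12), 0.1)
        curve_spec("geological", E = E, sigma_Y = sY, sigma_f = sf,
                   noise_sd = noise_sd, step = step)
      }
    })
  })
}

#' Generate a Weibull-distributed strength sample
#'
#' Inverse-CDF sampling of the two-parameter Weibull strength model:
#' \eqn{\sigma = \sigma_{Y0} (-\ln(1-u))^{1/m}} with `u` uniform. Seeded and
#' strictly positive.
#'
#' @param n Sample size (>= 1).
#' @param shape Weibull modulus m (> 0).
#' @param scale Characteristic strength (GPa, > 0).
#' @param seed Integer seed.
#' @return Numeric vector of strengths.
#' @export
generate_strengths <- function(n, shape, scale = 1, seed = NULL) {
  check_scalar(n, "n", lower = 1)
  check_scalar(shape, "shape", lower = 0, strict_lower = TRUE)
  check_scalar(scale, "scale", lower = 0, strict_lower = TRUE)
  local_seed(seed, {
    u <- stats::runif(n)
    scale * (-log1p(-u))^(1 / shape)
  })
}
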