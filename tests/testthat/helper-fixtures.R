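# Shared fixtures: a nominal pillar and constructors for hand-made curves.

std_geom <- function() pillar_geometry(D1 = 2, D2 = 2.5, h = 6, taper = NULL, nu = 0.3)

# Build a stress_strain curve from a prescribed normalized stress-strain
# series by inverting the compliance correction into a force record.
curve_from_stress <- function(eps, sigma_n, geom = std_geom()) {
  force <- sigma_n / (4 / (pi * geom$D1 * geom$D2) + (1 - geom$nu^2) / (geom$D2 * geom$h))
  depth <- eps * geom$h * 1000
  rec <- force_displacement(seq_along(eps), force, depth)
  normalize_curve(rec, geom)
}

# Bilinear normalized curve: slope E1 to the knee, then E2.
bilinear_curve <- function(E1 = 40, E2 = 10, knee = 0.02, eps_end = 0.05,
                           step = 1e-4, geom = std_geom()) {
  eps <- seq(0, eps_end, by = step)
  sig <- ifelse(eps <= knee, E1 * eps, E1 * knee + E2 * (eps - knee))
  curve_from_stress(eps, sig, geom)
}

# Ratio between normalized and top-cross-section stress for a geometry,
# written out independently of the package internals.
stress_scale_ratio_oracle <- function(geom) {
  (4 / (pi * geom$D1 * geom$D2) + (1 - geom$nu^2) / (geom$D2 * geom$h)) /
    (4 / (pi * geom$D1^2))
}

# Exact ellipse sampled at n points.
ellipse_points <- function(cx, cy, a, b, angle_deg, n = 32) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- angle_deg * pi / 180
  ex <- a * cos(phi)
  ey <- b * sin(phi)
  cbind(cx + ex * cos(th) - ey * sin(th),
        cy + ex * sin(th) + ey * cos(th))
}
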