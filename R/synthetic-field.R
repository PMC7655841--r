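#' Specification of a synthetic intracrystalline defect field
#'
#' Describes the spatial structure the generator emulates: a rectangular
#' section of a calcite prism containing elliptical nanoscopic defects whose
#' local number density alternates between high- and low-density zones, and
#' whose long-axis inclination tilts up towards the crystal boundary (the
#' intercrystalline organic interface, here the left edge of the domain).
#'
#' Longitudinal sections show the zones as alternating horizontal bands with
#' a characteristic period of a few hundred nanometres (`layout = "bands"`);
#' transverse sections show patch-like zones assigned at random on a coarse
#' grid (`layout = "patches"`). Within a zone, defect centers sit on a
#' jittered square lattice whose pitch is the zone's nominal spacing: 32 nm
#' in low-density and 10 nm in high-density regions by default. Defects are
#' ellipses with semi-axes 5 x 2.5 nm (a 10 nm lateral span by 5 nm height),
#' and their inclination follows the decaying law
#' `theta(d) = theta_boundary * exp(-d / theta_decay)` with distance `d` to
#' the boundary, plus Gaussian scatter.
#'
#' @param domain Domain size `c(width, height)` (nm).
#' @param layout `"bands"` or `"patches"`.
#' @param band_period Zone alternation period (nm).
#' @param spacing_low,spacing_high Lattice pitch in the low/high-density
#'   zones (nm).
#' @param semi_major,semi_minor Nominal defect semi-axes (nm).
#' @param size_rel_sd Relative scatter of the semi-axes.
#' @param jitter_frac Lattice jitter, as a fraction of the local pitch.
#' @param theta_boundary Inclination at the boundary (degrees).
#' @param theta_decay Decay length of the inclination law (nm).
#' @param theta_sd Gaussian scatter on the inclination (degrees).
#' @param contour_points Points sampled per defect contour.
#' @param contour_noise Radial noise on contour points (nm).
#' @return A `"field_spec"` list.
#' @export
field_spec <- function(domain = c(400, 400), layout = c("bands", "patches"),
                       band_period = 200, spacing_low = 32, spacing_high = 10,
                       semi_major = 5, semi_minor = 2.5, size_rel_sd = 0.05,
                       jitter_frac = 0.02, theta_boundary = 35,
                       theta_decay = 50, theta_sd = 2, contour_points = 40,
                       contour_noise = 0.1) {
  layout <- match.arg(layout)
  if (length(domain) != 2L || any(!is.finite(domain)) || any(domain <= 0)) {
    stop_input("domain must be two positive lengths")
  }
  check_scalar(band_period, "band_period", lower = 0, strict_lower = TRUE)
  check_scalar(spacing_low, "spacing_low", lower = 0, strict_lower = TRUE)
  check_scalar(spacing_high, "spacing_high", lower = 0, strict_lower = TRUE)
  check_scalar(semi_major, "semi_major", lower = 0, strict_lower = TRUE)
  check_scalar(semi_minor, "semi_minor", lower = 0, strict_lower = TRUE)
  structure(
    list(domain = domain, layout = layout, band_period = band_period,
         spacing_low = spacing_low, spacing_high = spacing_high,
         semi_major = semi_major, semi_minor = semi_minor,
         size_rel_sd = size_rel_sd, jitter_frac = jitter_frac,
         theta_boundary = theta_boundary, theta_decay = theta_decay,
         theta_sd = theta_sd, contour_points = contour_points,
         contour_noise = contour_noise),
    class = "field_spec"
  )
}

# Jittered square lattice filling [x0,x1] x [y0,y1] with the given pitch.
lattice_points <- function(x0, x1, y0, y1, pitch, jitter_sd) {
  xs <- seq(x0 + pitch / 2, x1 - pitch / 2 + 1e-9, by = pitch)
  ys <- seq(y0 + pitch / 2, y1 - pitch / 2 + 1e-9, by = pitch)
  if (!length(xs) || !length(ys)) {
    return(matrix(numeric(0), ncol = 2))
  }
  g <- expand.grid(x = xs, y = ys)
  n <- nrow(g)
  if (jitter_sd > 0) {
    g$x <- g$x + stats::rnorm(n, 0, jitter_sd)
    g$y <- g$y + stats::rnorm(n, 0, jitter_sd)
  }
  as.matrix(g)
}

#' Generate a synthetic field of elliptical intracrystalline defects
#'
#' Places defect centers per zone on jittered lattices, assigns sizes and
#' inclinations, and samples a noisy contour for each defect. Identical
#' `(spec, seed)` give identical fields. A spacing smaller than the defect
#' extent triggers a best-effort warning rather than an error.
#'
#' @param spec A [field_spec()].
#' @param seed Integer seed.
#' @param contours Logical; sample per-defect contour point sets.
#' @return A `"defect_field"` list: `centers` (data frame `x`, `y`, `zone`,
#'   `theta`, `a`, `b`, `dist_boundary`), `boundary` (polyline matrix, the
#'   left domain edge), `contours` (list of n x 2 matrices or `NULL`), and
#'   the `spec`.
#' @examples
#' fld <- generate_defect_field(field_spec(), seed = 1)
#' table(fld$centers$zone)
#' @export
generate_defect_field <- function(spec, seed = NULL, contours = TRUE) {
  if (!inherits(spec, "field_spec")) stop_input("`spec` must be a field_spec")
  if (min(spec$spacing_low, spec$spacing_high) < 2 * spec$semi_major) {
    warning("spacing smaller than the defect extent; placing best-effort")
  }
  W <- spec$domain[1]
  H <- spec$domain[2]
  local_seed(seed, {
    zones <- list()
    if (spec$layout == "bands") {
      half <- spec$band_period / 2
      edges <- seq(0, H, by = half)
      if (edges[length(edges)] < H) edges <- c(edges, H)
      for (b in seq_len(length(edges) - 1L)) {
        zone <- if (b %% 2L == 1L) "high" else "low"
        pitch <- if (zone == "high") spec$spacing_high else spec$spacing_low
        pts <- lattice_points(0, W, edges[b], edges[b + 1L], pitch,
                              spec$jitter_frac * pitch)
        if (nrow(pts)) {
          zones[[length(zones) + 1L]] <- data.frame(x = pts[, 1], y = pts[, 2],
                                                    zone = zone)
        }
      }
    } else {
      cell <- spec$band_period
      gx <- seq(0, W, by = cell)
      gy <- seq(0, H, by = cell)
      if (gx[length(gx)] < W) gx <- c(gx, W)
      if (gy[length(gy)] < H) gy <- c(gy, H)
      for (i in seq_len(length(gx) - 1L)) {
        for (j in seq_len(length(gy) - 1L)) {
          zone <- if (stats::runif(1) < 0.5) "high" else "low"
          pitch <- if (zone == "high") spec$spacing_high else spec$spacing_low
          pts <- lattice_points(gx[i], gx[i + 1L], gy[j], gy[j + 1L], pitch,
                                spec$jitter_frac * pitch)
          if (nrow(pts)) {
            zones[[length(zones) + 1L]] <- data.frame(x = pts[, 1], y = pts[, 2],
                                                      zone = zone)
          }
        }
      }
    }
    centers <- do.call(rbind, zones)
    n <- nrow(centers)
    boundary <- cbind(c(0, 0), c(0, H))
    d <- dist_to_polyline(as.matrix(centers[, c("x", "y")]), boundary)
    theta <- spec$theta_boundary * exp(-d / spec$theta_decay)
    if (spec$theta_sd > 0) theta <- theta + stats::rnorm(n, 0, spec$theta_sd)
    a <- spec$semi_major * pmax(1 + stats::rnorm(n, 0, spec$size_rel_sd), 0.2)
    b <- spec$semi_minor * pmax(1 + stats::rnorm(n, 0, spec$size_rel_sd), 0.2)
    centers$theta <- theta
    centers$a <- a
    centers$b <- b
    centers$dist_boundary <- d
    cts <- NULL
    if (contours) {
      phi <- seq(0, 2 * pi, length.out = spec$contour_points + 1L)[-(spec$contour_points + 1L)]
      cts <- lapply(seq_len(n), function(i) {
        th <- theta[i] * pi / 180
        ex <- a[i] * cos(phi)
        ey <- b[i] * sin(phi)
        if (spec$contour_noise > 0) {
          r <- sqrt(ex^2 + ey^2)
          rr <- r + stats::rnorm(length(phi), 0, spec$contour_noise)
          ex <- ex * rr / r
          ey <- ey * rr / r
        }
        cbind(
          centers$x[i] + ex * cos(th) - ey * sin(th),
          centers$y[i] + ex * sin(th) + ey * cos(th)
        )
      })
    }
    structure(
      list(centers = centers, boundary = boundary, contours = cts, spec = spec),
      class = "defect_field"
    )
  })
}

#' @export
print.defect_field <- function(x, ...) {
  tab <- table(x$centers$zone)
  cat(sprintf(
    "Synthetic defect field: %d defects on %g x %g nm (%s)\n",
    nrow(x$centers), x$spec$domain[1], x$spec$domain[2],
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}
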