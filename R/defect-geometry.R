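#' Direct least-squares ellipse fit to contour points
#'
#' Fits the conic \eqn{ax^2 + bxy + cy^2 + dx + ey + f = 0} to digitized
#' contour points with the ellipse constraint \eqn{4ac - b^2 = 1}, using the
#' numerically stable partitioned formulation of the direct least-squares
#' method (the scatter matrix is split into quadratic and linear blocks, and
#' the constrained eigenproblem is solved on the 3x3 reduced system). The
#' conic is then converted to geometric parameters.
#'
#' @param points An n x 2 matrix or data frame of contour coordinates (nm),
#'   n >= 5, not collinear.
#' @return An `"ellipse_fit"` list: `center` (length 2), `semi_major`,
#'   `semi_minor`, `angle` (degrees of the major axis from the +x /
#'   transverse axis, in (-90, 90]), and the conic coefficients.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 33)[-33]
#' pts <- cbind(3 + 5 * cos(th), -2 + 2.5 * sin(th))
#' fit_ellipse(pts)
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop_input("points must have two columns")
  if (nrow(pts) < 5L) stop_input("at least 5 points are required")
  if (any(!is.finite(pts))) stop_input("points must be finite")
  # center/scale for conditioning
  mx <- colMeans(pts)
  x <- pts[, 1] - mx[1]
  y <- pts[, 2] - mx[2]
  s <- mean(sqrt(x^2 + y^2))
  if (s < 1e-12) stop_input("degenerate contour: coincident points")
  x <- x / s
  y <- y / s
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T2 <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    stop_input("degenerate contour: collinear points")
  })
  M <- S1 + S2 %*% T2
  # premultiply by inv(C), C the ellipse-constraint matrix
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 1e-12)
  if (!length(ok)) stop_input("no ellipse solution: degenerate point set")
  a1 <- vecs[, ok[1]]
  coef_s <- c(a1, drop(T2 %*% a1))  # (a, b, c, d, e, f) in scaled frame
  # undo the scaling: substitute x -> (x - mx)/s
  A <- coef_s[1]; B <- coef_s[2]; C <- coef_s[3]
  D <- coef_s[4]; E <- coef_s[5]; FF <- coef_s[6]
  a0 <- A / s^2
  b0 <- B / s^2
  c0 <- C / s^2
  d0 <- D / s - (2 * A * mx[1] + B * mx[2]) / s^2
  e0 <- E / s - (B * mx[1] + 2 * C * mx[2]) / s^2
  f0 <- FF - (D * mx[1] + E * mx[2]) / s +
    (A * mx[1]^2 + B * mx[1] * mx[2] + C * mx[2]^2) / s^2
  conic_to_ellipse(c(a0, b0, c0, d0, e0, f0))
}

conic_to_ellipse <- function(cf) {
  A <- matrix(c(cf[1], cf[2] / 2, cf[2] / 2, cf[3]), 2, 2)
  center <- tryCatch(drop(solve(2 * A, -cf[4:5])), error = function(e) {
    stop_input("degenerate conic")
  })
  # with the center defined by 2 A x_c = -(d, e), the conic reduces to
  # u' A u = x_c' A x_c - f on displacements u from the center
  F0 <- drop(center %*% A %*% center) - cf[6]
  ev <- eigen(A, symmetric = TRUE)
  ax2 <- F0 / ev$values
  if (any(ax2 <= 0)) stop_input("conic is not an ellipse")
  axes <- sqrt(ax2)
  i_maj <- which.max(axes)
  v <- ev$vectors[, i_maj]
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  structure(
    list(
      center = unname(center),
      semi_major = max(axes),
      semi_minor = min(axes),
      angle = ang,
      conic = cf
    ),
    class = "ellipse_fit"
  )
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "Ellipse fit: center (%.3g, %.3g), semi-axes %.4g x %.4g, major axis at %.2f deg\n",
    x$center[1], x$center[2], x$semi_major, x$semi_minor, x$angle
  ))
  invisible(x)
}

#' Summary statistics of a fitted defect population
#'
#' Means and standard deviations of the semi-axes and (signed) orientation
#' of a set of ellipse fits. When the raw contours are supplied, the mean
#' radial profile is also computed: each contour is re-centered on its fit
#' center, resampled on a common angular grid, and averaged -- the analogue
#' of overlaying individual defect contours and drawing their average
#' outline.
#'
#' @param fits A list of [fit_ellipse()] results.
#' @param contours Optional list of n x 2 contour matrices (same order).
#' @param n_angles Angular resolution of the mean profile.
#' @return A list: `n`, per-parameter `mean`/`sd` (sd is `NA` for a single
#'   fit), and `mean_profile` (data frame `angle`, `radius`) when contours
#'   are given.
#' @export
population_summary <- function(fits, contours = NULL, n_angles = 72) {
  if (!length(fits)) stop_input("at least one fit is required")
  if (inherits(fits, "ellipse_fit")) fits <- list(fits)
  maj <- vapply(fits, function(f) f$semi_major, numeric(1))
  mnr <- vapply(fits, function(f) f$semi_minor, numeric(1))
  ang <- vapply(fits, function(f) f$angle, numeric(1))
  n <- length(fits)
  sdn <- function(v) if (n >= 2L) stats::sd(v) else NA_real_
  prof <- NULL
  if (!is.null(contours)) {
    grid <- seq(-pi, pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
    rmat <- vapply(seq_along(contours), function(i) {
      p <- as.matrix(contours[[i]])
      ctr <- fits[[i]]$center
      dx <- p[, 1] - ctr[1]
      dy <- p[, 2] - ctr[2]
      phi <- atan2(dy, dx)
      r <- sqrt(dx^2 + dy^2)
      o <- order(phi)
      # wrap the contour so interpolation covers the full circle
      phi_w <- c(phi[o] - 2 * pi, phi[o], phi[o] + 2 * pi)
      r_w <- rep(r[o], 3)
      stats::approx(phi_w, r_w, xout = grid, ties = mean)$y
    }, numeric(n_angles))
    prof <- data.frame(angle = grid * 180 / pi, radius = rowMeans(rmat))
  }
  list(
    n = n,
    semi_major_mean = mean(maj), semi_major_sd = sdn(maj),
    semi_minor_mean = mean(mnr), semi_minor_sd = sdn(mnr),
    angle_mean = mean(ang), angle_sd = sdn(ang),
    mean_profile = prof
  )
}

#' Nearest-neighbour spacing of a defect field
#'
#' Center-to-center nearest-neighbour distances, optionally split by a
#' grouping factor (e.g. density zone). An edge-to-edge variant subtracts
#' the mean radii of the two defects from each center distance (an
#' approximation for non-circular defects).
#'
#' @param x An n x 2 matrix/data frame of defect centers, or a
#'   [generate_defect_field()] result (whose zones are then used as the
#'   default grouping).
#' @param by Optional grouping vector; distances are computed within groups.
#' @param method `"center"` (primary) or `"edge"`.
#' @param radii Per-defect mean radii (required for `method = "edge"`).
#' @return A data frame with one row per group: `group`, `n`, `mean`,
#'   `median`, `sd` (nm), with the raw distances attached as attribute
#'   `"distances"` (a named list).
#' @export
nearest_neighbor_spacing <- function(x, by = NULL,
                                     method = c("center", "edge"),
                                     radii = NULL) {
  method <- match.arg(method)
  if (inherits(x, "defect_field")) {
    if (is.null(by)) by <- x$centers$zone
    if (is.null(radii) && method == "edge") {
      radii <- (x$centers$a + x$centers$b) / 2
    }
    x <- as.matrix(x$centers[, c("x", "y")])
  }
  pts <- as.matrix(x)
  if (ncol(pts) != 2L) stop_input("centers must have two columns")
  n <- nrow(pts)
  if (n < 2L) stop_input("at least two defects are required")
  if (is.null(by)) by <- rep("all", n)
  if (method == "edge" && is.null(radii)) {
    stop_input("`radii` are required for edge-to-edge spacing")
  }
  groups <- split(seq_len(n), by)
  res <- list()
  dists <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) < 2L) {
      stop_input(sprintf("group '%s' has a single defect; spacing undefined", g))
    }
    dm <- as.matrix(stats::dist(pts[idx, , drop = FALSE]))
    if (method == "edge") {
      rr <- radii[idx]
      dm <- dm - outer(rr, rr, "+")
    }
    diag(dm) <- Inf
    nn <- apply(dm, 1L, min)
    dists[[g]] <- nn
    res[[g]] <- data.frame(
      group = g, n = length(idx), mean = mean(nn),
      median = stats::median(nn), sd = stats::sd(nn)
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "distances") <- dists
  out
}

#' Classify defects into high/low local-density classes
#'
#' Counts neighbours within `radius` of each defect and thresholds the count
#' at the field median, a simple operational split into high- and low-density
#' regions.
#'
#' @param centers n x 2 matrix of defect centers (nm).
#' @param radius Neighbourhood radius (nm).
#' @return Factor with levels `"high"` and `"low"`.
#' @export
classify_density <- function(centers, radius = 50) {
  pts <- as.matrix(centers)
  if (nrow(pts) < 2L) stop_input("at least two defects are required")
  dm <- as.matrix(stats::dist(pts))
  counts <- rowSums(dm <= radius) - 1L
  factor(ifelse(counts > stats::median(counts), "high", "low"),
         levels = c("high", "low"))
}

# Shortest distance from each point to a polyline (matrix of vertices).
dist_to_polyline <- function(pts, poly) {
  pts <- as.matrix(pts)
  poly <- as.matrix(poly)
  if (nrow(poly) < 2L) {
    # single vertex: plain point distance
    return(sqrt((pts[, 1] - poly[1, 1])^2 + (pts[, 2] - poly[1, 2])^2))
  }
  d2 <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(poly) - 1L)) {
    p1 <- poly[s, ]
    p2 <- poly[s + 1L, ]
    v <- p2 - p1
    len2 <- sum(v^2)
    if (len2 == 0) {
      dd <- (pts[, 1] - p1[1])^2 + (pts[, 2] - p1[2])^2
    } else {
      t <- ((pts[, 1] - p1[1]) * v[1] + (pts[, 2] - p1[2]) * v[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      dd <- (pts[, 1] - (p1[1] + t * v[1]))^2 + (pts[, 2] - (p1[2] + t * v[2]))^2
    }
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

#' Defect inclination versus distance to the crystal boundary
#'
#' Bins the defects by their shortest distance to the boundary polyline (the
#' trace of the intercrystalline organic interface) and reports the mean
#' absolute inclination per bin, quantifying how defect long axes tilt from
#' the transverse plane as the boundary is approached. A Spearman rank
#' correlation between bin distance and mean inclination is returned as a
#' monotonicity diagnostic.
#'
#' @param x A [generate_defect_field()] result, or an n x 2 matrix of
#'   centers (then `theta` and `boundary` must be given).
#' @param theta Defect inclinations (degrees).
#' @param boundary Boundary polyline (matrix of vertices, nm).
#' @param bin_width Distance bin width (nm).
#' @return A list: `profile` (data frame `distance` (bin center),
#'   `mean_theta`, `n`) and `rho` (Spearman correlation of mean inclination
#'   with distance; negative when the tilt decays away from the boundary).
#' @export
orientation_profile <- function(x, theta = NULL, boundary = NULL,
                                bin_width = 10) {
  if (inherits(x, "defect_field")) {
    if (is.null(theta)) theta <- x$centers$theta
    if (is.null(boundary)) boundary <- x$boundary
    x <- as.matrix(x$centers[, c("x", "y")])
  }
  if (is.null(boundary)) stop_input("a boundary polyline is required")
  if (is.null(theta)) stop_input("defect inclinations are required")
  pts <- as.matrix(x)
  if (nrow(pts) != length(theta)) stop_input("theta must match the centers")
  d <- dist_to_polyline(pts, boundary)
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  bin <- cut(d, breaks, include.lowest = TRUE)
  agg <- stats::aggregate(abs(theta), list(bin = bin), mean)
  cnt <- as.vector(table(bin)[as.character(agg$bin)])
  mids <- breaks[-length(breaks)] + bin_width / 2
  prof <- data.frame(
    distance = mids[match(agg$bin, levels(bin))],
    mean_theta = agg$x,
    n = cnt
  )
  prof <- prof[order(prof$distance), ]
  rownames(prof) <- NULL
  rho <- if (nrow(prof) >= 3L && stats::sd(prof$mean_theta) > 0) {
    suppressWarnings(stats::cor(prof$distance, prof$mean_theta, method = "spearman"))
  } else {
    NA_real_
  }
  list(profile = prof, rho = rho)
}
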