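#' Hexagonal lattice cell
#'
#' Lattice parameters of the hexagonal structural cell used to interpret
#' Miller-Bravais indices. The defaults are the calcite structural cell,
#' a = 4.99 A, c = 17.06 A, the modern convention for calcite deformation
#' analysis. Both parameters are configurable since the derived Schmid
#' factors depend (weakly) on the c/a ratio.
#'
#' @param a Basal lattice parameter (Angstrom).
#' @param c Axial lattice parameter (Angstrom).
#' @return An object of class `"hexagonal_lattice"`.
#' @export
hexagonal_lattice <- function(a = 4.99, c = 17.06) {
  check_scalar(a, "a", lower = 0, strict_lower = TRUE)
  check_scalar(c, "c", lower = 0, strict_lower = TRUE)
  structure(list(a = a, c = c), class = "hexagonal_lattice")
}

#' @export
print.hexagonal_lattice <- function(x, ...) {
  cat(sprintf("Hexagonal cell: a = %.4g A, c = %.4g A (c/a = %.4f)\n",
              x$a, x$c, x$c / x$a))
  invisible(x)
}

assert_lattice <- function(lat) {
  if (!inherits(lat, "hexagonal_lattice")) {
    stop_input("`lattice` must be a hexagonal_lattice object")
  }
  invisible(lat)
}

# Direct basis vectors (columns a1, a2, c) in Cartesian coordinates with
# a1 along +x and c along +z.
hex_direct_basis <- function(lat) {
  a <- lat$a
  cbind(
    a1 = c(a, 0, 0),
    a2 = c(-a / 2, a * sqrt(3) / 2, 0),
    c = c(0, 0, lat$c)
  )
}

# Reciprocal basis (columns b1, b2, b3), without the 2*pi factor.
hex_reciprocal_basis <- function(lat) {
  t(solve(hex_direct_basis(lat)))
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-14) stop_input("zero vector")
  v / n
}

#' Cartesian unit normal of a Miller-Bravais plane
#'
#' Converts a four-index plane `(h k i l)` of the hexagonal cell to its unit
#' normal via the reciprocal basis. The redundant index must satisfy
#' `h + k + i = 0`. The basal plane `(0001)` maps to the +c axis.
#'
#' @param hkil Integer vector of length 4.
#' @param lattice A [hexagonal_lattice()].
#' @return Cartesian unit vector (length 3).
#' @examples
#' plane_normal_cartesian(c(0, 0, 0, 1))          # (0, 0, 1)
#' plane_normal_cartesian(c(1, 0, -1, 4))         # r-plane normal
#' @export
plane_normal_cartesian <- function(hkil, lattice = hexagonal_lattice()) {
  assert_lattice(lattice)
  if (length(hkil) != 4L || any(!is.finite(hkil))) {
    stop_input("plane indices must be a numeric vector (h, k, i, l)")
  }
  if (abs(sum(hkil[1:3])) > 1e-9) {
    stop_input("invalid Miller-Bravais plane: h + k + i must be 0")
  }
  B <- hex_reciprocal_basis(lattice)
  unit3(drop(B %*% c(hkil[1], hkil[2], hkil[4])))
}

#' Cartesian unit vector of a Miller-Bravais direction
#'
#' Converts a four-index direction `[u v t w]` (with `u + v + t = 0`) to a
#' Cartesian unit vector through the direct basis, using the standard
#' three-index reduction `U = u - t`, `V = v - t`, `W = w`. `[0001]` maps to
#' the +c axis and `[2 -1 -1 0]` lies along a1.
#'
#' @param uvtw Integer vector of length 4.
#' @param lattice A [hexagonal_lattice()].
#' @return Cartesian unit vector (length 3).
#' @export
direction_cartesian <- function(uvtw, lattice = hexagonal_lattice()) {
  assert_lattice(lattice)
  if (length(uvtw) != 4L || any(!is.finite(uvtw))) {
    stop_input("direction indices must be a numeric vector (u, v, t, w)")
  }
  if (abs(sum(uvtw[1:3])) > 1e-9) {
    stop_input("invalid Miller-Bravais direction: u + v + t must be 0")
  }
  A <- hex_direct_basis(lattice)
  U <- uvtw[1] - uvtw[3]
  V <- uvtw[2] - uvtw[3]
  unit3(drop(A %*% c(U, V, uvtw[4])))
}

cyc3 <- function(idx4, k) {
  # cyclically permute the first three (basal) indices k times
  b <- idx4[1:3]
  for (i in seq_len(k)) b <- b[c(3, 1, 2)]
  c(b, idx4[4])
}

mb_label <- function(idx) {
  paste0("(", paste(idx, collapse = " "), ")")
}

#' Catalog of calcite twin and slip systems
#'
#' Enumerates the low-temperature deformation systems of calcite in
#' Miller-Bravais indices: three e-twin systems `{-1 0 1 8}<4 0 -4 1>`
#' (unidirectional, positive sense only), three r-slip systems
#' `{1 0 -1 4}<-2 0 2 1>` (bidirectional), and six f-slip systems
#' `{-1 0 1 2}<2 -2 0 1>` (bidirectional, two in-plane shear directions per
#' plane). Symmetry-equivalent systems are generated by cyclic permutation of
#' the basal indices, i.e. by the threefold rotation about c. Every catalog
#' entry satisfies the direction-in-plane condition to 1e-8.
#'
#' @param lattice A [hexagonal_lattice()].
#' @return A data frame of class `"slip_catalog"` with columns `system`,
#'   `family` (`"e"`, `"r"`, `"f"`), `sense` (`"positive"` or
#'   `"bidirectional"`), the plane indices `h, k, i, l`, the direction
#'   indices `u, v, t, w`, and a `label`. The lattice is attached as an
#'   attribute.
#' @examples
#' nrow(calcite_system_catalog())  # 12
#' @export
calcite_system_catalog <- function(lattice = hexagonal_lattice()) {
  assert_lattice(lattice)
  base <- list(
    e = list(plane = c(-1, 0, 1, 8), dirs = list(c(4, 0, -4, 1)), sense = "positive"),
    r = list(plane = c(1, 0, -1, 4), dirs = list(c(-2, 0, 2, 1)), sense = "bidirectional"),
    f = list(plane = c(-1, 0, 1, 2), dirs = list(c(2, -2, 0, 1), c(0, 2, -2, 1)),
             sense = "bidirectional")
  )
  rows <- list()
  for (fam in names(base)) {
    spec <- base[[fam]]
    for (k in 0:2) {
      p <- cyc3(spec$plane, k)
      for (d0 in spec$dirs) {
        d <- cyc3(d0, k)
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, sense = spec$sense,
          h = p[1], k = p[2], i = p[3], l = p[4],
          u = d[1], v = d[2], t = d[3], w = d[4],
          label = paste(mb_label(p), gsub("[()]", "", sprintf("[%s]", paste(d, collapse = " "))))
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(system = seq_len(nrow(out)), out)
  # direction-in-plane invariant
  for (s in seq_len(nrow(out))) {
    n <- plane_normal_cartesian(unlist(out[s, c("h", "k", "i", "l")]), lattice)
    d <- direction_cartesian(unlist(out[s, c("u", "v", "t", "w")]), lattice)
    if (abs(sum(n * d)) > 1e-8) {
      stop("internal error: slip direction not contained in its plane")
    }
  }
  class(out) <- c("slip_catalog", "data.frame")
  attr(out, "lattice") <- lattice
  out
}

catalog_lattice <- function(catalog, lattice) {
  if (!is.null(lattice)) return(lattice)
  lat <- attr(catalog, "lattice")
  if (is.null(lat)) lat <- hexagonal_lattice()
  lat
}

#' Cartesian normals and shear directions of a slip catalog
#'
#' @param catalog A `"slip_catalog"` (or compatible data frame).
#' @param lattice Optional [hexagonal_lattice()]; defaults to the catalog's.
#' @return A list with matrices `normal` and `direction` (rows = systems,
#'   unit vectors).
#' @export
catalog_cartesian <- function(catalog, lattice = NULL) {
  lat <- catalog_lattice(catalog, lattice)
  n <- t(vapply(seq_len(nrow(catalog)), function(s) {
    plane_normal_cartesian(unlist(catalog[s, c("h", "k", "i", "l")]), lat)
  }, numeric(3)))
  d <- t(vapply(seq_len(nrow(catalog)), function(s) {
    direction_cartesian(unlist(catalog[s, c("u", "v", "t", "w")]), lat)
  }, numeric(3)))
  list(normal = n, direction = d)
}

#' Schmid factors for uniaxial loading
#'
#' For each system the Schmid factor is \eqn{m = \cos\varphi \cos\lambda},
#' the product of the load-axis cosines with the plane normal and the shear
#' direction; it is reported signed, so the sign of the resolved shear stress
#' along the positive shear direction under the stated load is
#' `sign(m)` for tension and `-sign(m)` for compression. A system is
#' `activated` when its allowed sense matches the resolved shear: e-twinning
#' is unidirectional (positive sense only) while r- and f-slip operate in
#' either sense.
#'
#' @param axis Load axis (length-3 Cartesian vector). Non-unit axes are
#'   normalized with a warning.
#' @param catalog A [calcite_system_catalog()] (or subset).
#' @param lattice Optional lattice override.
#' @param load `"compression"` or `"tension"`.
#'
#' @return The catalog with extra columns `schmid` (signed m), `abs_schmid`,
#'   `resolved_sense` (`"positive"`, `"negative"`, `"none"`), `activated`.
#' @examples
#' sf <- schmid_factor(c(0, 0, 1), calcite_system_catalog())
#' max(sf$abs_schmid[sf$family == "r"])  # 0.49996 for the structural cell
#' @export
schmid_factor <- function(axis, catalog = calcite_system_catalog(),
                          lattice = NULL, load = c("compression", "tension")) {
  load <- match.arg(load)
  if (length(axis) != 3L || any(!is.finite(axis))) {
    stop_input("`axis` must be a finite length-3 vector")
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-14) stop_input("`axis` must be non-zero")
  if (abs(nrm - 1) > 1e-8) {
    warning("load axis is not a unit vector; normalizing")
    axis <- axis / nrm
  } else {
    axis <- axis / nrm
  }
  cart <- catalog_cartesian(catalog, lattice)
  m <- drop(cart$normal %*% axis) * drop(cart$direction %*% axis)
  tau <- if (load == "tension") m else -m
  sense_resolved <- ifelse(abs(tau) < 1e-12, "none",
                           ifelse(tau > 0, "positive", "negative"))
  activated <- ifelse(catalog$sense == "bidirectional",
                      abs(tau) > 1e-12,
                      tau > 1e-12)
  out <- as.data.frame(catalog)
  out$schmid <- m
  out$abs_schmid <- abs(m)
  out$resolved_sense <- sense_resolved
  out$activated <- activated
  attr(out, "axis") <- axis
  attr(out, "load") <- load
  out
}

#' Rank the deformation systems active under a uniaxial load
#'
#' Evaluates [schmid_factor()] over the catalog, drops systems whose allowed
#' shear sense cannot be activated under the given load, and sorts the rest
#' by decreasing `|m|`. Symmetry-degenerate systems (equal `|m|` to 1e-9)
#' share a `tie_group`.
#'
#' @inheritParams schmid_factor
#' @return Sorted data frame of activated systems with a `tie_group` column.
#' @examples
#' head(rank_active_systems(c(0, 0, 1)), 3)  # the three degenerate r systems
#' @export
rank_active_systems <- function(axis, catalog = calcite_system_catalog(),
                                lattice = NULL,
                                load = c("compression", "tension")) {
  sf <- schmid_factor(axis, catalog, lattice, load)
  act <- sf[sf$activated, , drop = FALSE]
  act <- act[order(-act$abs_schmid), , drop = FALSE]
  act$tie_group <- cumsum(c(TRUE, diff(round(act$abs_schmid / 1e-9)) != 0))
  rownames(act) <- NULL
  act
}
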