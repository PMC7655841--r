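# Independent oracle for the load-axis cosines under c-axis loading:
# for a hexagonal plane (hkil), the normal's cosine with c equals d_hkl * l/c
# with the textbook interplanar spacing; for a direction [uvtw], the cosine
# with c is w*c over the direct-metric length with U = u - t, V = v - t.
cosc_plane <- function(hkil, a, c) {
  d <- 1 / sqrt(4 / 3 * (hkil[1]^2 + hkil[1] * hkil[2] + hkil[2]^2) / a^2 +
                  hkil[4]^2 / c^2)
  d * hkil[4] / c
}
cosc_dir <- function(uvtw, a, c) {
  U <- uvtw[1] - uvtw[3]
  V <- uvtw[2] - uvtw[3]
  uvtw[4] * c / sqrt(a^2 * (U^2 + V^2 - U * V) + uvtw[4]^2 * c^2)
}

test_that("Miller-Bravais conversions reproduce the hexagonal cell geometry", {
  lat <- hexagonal_lattice()
  expect_equal(plane_normal_cartesian(c(0, 0, 0, 1), lat), c(0, 0, 1))
  prism <- plane_normal_cartesian(c(1, 0, -1, 0), lat)
  expect_equal(sum(prism * c(0, 0, 1)), 0, tolerance = 1e-12)
  expect_equal(direction_cartesian(c(0, 0, 0, 1), lat), c(0, 0, 1))
  a1 <- direction_cartesian(c(2, -1, -1, 0), lat)
  expect_equal(a1, c(1, 0, 0), tolerance = 1e-12)

  # r plane and its shear direction against the metric-formula oracle
  n <- plane_normal_cartesian(c(1, 0, -1, 4), lat)
  expect_equal(n[3], cosc_plane(c(1, 0, -1, 4), 4.99, 17.06), tolerance = 1e-12)
  d <- direction_cartesian(c(-2, 0, 2, 1), lat)
  expect_equal(d[3], cosc_dir(c(-2, 0, 2, 1), 4.99, 17.06), tolerance = 1e-12)

  expect_error(plane_normal_cartesian(c(1, 1, 1, 0), lat), "h \\+ k \\+ i")
  expect_error(direction_cartesian(c(1, 0, 0, 0), lat), "u \\+ v \\+ t")
  expect_error(plane_normal_cartesian(c(0, 0, 0, 0), lat), "zero")
})

test_that("the calcite catalog has 3 e-twin, 3 r-slip and 6 f-slip systems", {
  cat12 <- calcite_system_catalog()
  expect_equal(nrow(cat12), 12L)
  expect_equal(as.integer(table(cat12$family)[c("e", "r", "f")]), c(3L, 3L, 6L))
  expect_true(all(cat12$sense[cat12$family == "e"] == "positive"))
  expect_true(all(cat12$sense[cat12$family != "e"] == "bidirectional"))

  # direction-in-plane invariant, directly
  cart <- catalog_cartesian(cat12)
  expect_true(all(abs(rowSums(cart$normal * cart$direction)) < 1e-8))

  # the three r systems map onto one another under 120-degree rotation about c
  th <- 2 * pi / 3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  r_idx <- which(cat12$family == "r")
  n_r <- cart$normal[r_idx, ]
  d_r <- cart$direction[r_idx, ]
  for (i in seq_along(r_idx)) {
    nrot <- drop(R %*% n_r[i, ])
    drot <- drop(R %*% d_r[i, ])
    hit <- which(apply(n_r, 1, function(v) sqrt(sum((v - nrot)^2))) < 1e-9)
    expect_length(hit, 1L)
    expect_lt(sqrt(sum((d_r[hit, ] - drot)^2)), 1e-9)
  }
})

test_that("Schmid factors under c-axis compression match the known activation", {
  sf <- schmid_factor(c(0, 0, 1), load = "compression")

  # the r systems carry the highest factor, 0.49996 for the structural cell
  expect_equal(max(sf$abs_schmid[sf$family == "r"]), 0.49996, tolerance = 1e-3)

  # threefold degeneracy of the r systems to 1e-12 relative
  m_r <- sf$abs_schmid[sf$family == "r"]
  expect_lt(diff(range(m_r)) / mean(m_r), 1e-12)

  # r slip is resolved in the negative sense under compression
  expect_true(all(sf$resolved_sense[sf$family == "r"] == "negative"))
  expect_true(all(sf$activated[sf$family == "r"]))

  # e-twinning is unidirectional and not activated by c-axis compression
  expect_true(all(!sf$activated[sf$family == "e"]))

  # f systems against the metric-formula oracle
  lat <- hexagonal_lattice()
  f_rows <- sf[sf$family == "f", ]
  m_oracle <- vapply(seq_len(nrow(f_rows)), function(i) {
    abs(cosc_plane(unlist(f_rows[i, c("h", "k", "i", "l")]), lat$a, lat$c) *
          cosc_dir(unlist(f_rows[i, c("u", "v", "t", "w")]), lat$a, lat$c))
  }, numeric(1))
  expect_equal(f_rows$abs_schmid, m_oracle, tolerance = 1e-12)
})

test_that("the Schmid bound holds for random axes and index permutations", {
  cat12 <- calcite_system_catalog()
  set.seed(314)
  for (rep_ in seq_len(1000)) {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2))
    sf <- schmid_factor(v, cat12)
    expect_true(all(sf$abs_schmid <= 0.5 + 1e-9))
  }

  # cyclic permutation of the basal indices is a symmetry: same |m| under
  # c-axis load
  sf0 <- schmid_factor(c(0, 0, 1), cat12)
  for (fam in c("e", "r", "f")) {
    expect_lt(diff(range(sf0$abs_schmid[sf0$family == fam])), 1e-12)
  }

  # non-unit axes are normalized with a warning
  expect_warning(schmid_factor(c(0, 0, 2), cat12), "normaliz")
})

test_that("active-system ranking under various loads", {
  # c-axis compression: r family on top, three degenerate systems, no e twins
  rk <- rank_active_systems(c(0, 0, 1), load = "compression")
  expect_equal(rk$family[1:3], rep("r", 3))
  expect_equal(rk$tie_group[1:3], rep(1L, 3))
  expect_false(any(rk$family == "e"))

  # load along a1: ranking agrees with exhaustive evaluation via the
  # Cartesian catalog
  cat12 <- calcite_system_catalog()
  cart <- catalog_cartesian(cat12)
  ax <- c(1, 0, 0)
  m_all <- abs(drop(cart$normal %*% ax) * drop(cart$direction %*% ax))
  rk2 <- rank_active_systems(ax, cat12, load = "compression")
  act_oracle <- which(cat12$sense == "bidirectional" & m_all > 1e-12 |
                        cat12$sense == "positive" &
                        -drop(cart$normal %*% ax) * drop(cart$direction %*% ax) > 1e-12)
  expect_setequal(rk2$system, cat12$system[act_oracle])
  expect_equal(rk2$abs_schmid, sort(m_all[act_oracle], decreasing = TRUE),
               tolerance = 1e-12)

  # arbitrary axis: top-ranked |m| bounded by 0.5
  rk3 <- rank_active_systems(c(1, 2, 3) / sqrt(14))
  expect_lte(rk3$abs_schmid[1], 0.5 + 1e-9)
})

test_that("the r-system Schmid factor varies continuously with c/a", {
  # documentation-style sensitivity: a small change in c/a moves m smoothly
  m_at <- function(cc) {
    sf <- schmid_factor(c(0, 0, 1), calcite_system_catalog(hexagonal_lattice(4.99, cc)))
    max(sf$abs_schmid[sf$family == "r"])
  }
  ms <- vapply(c(16.9, 17.06, 17.2), m_at, numeric(1))
  expect_true(all(is.finite(ms)))
  expect_lt(max(abs(diff(ms))), 0.01)
})
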