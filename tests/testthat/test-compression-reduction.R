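test_that("normalization applies the tapered-pillar compliance correction", {
  geom <- std_geom()
  rec <- force_displacement(0:2, c(0, 1, 2), c(0, 50, 100))
  cur <- normalize_curve(rec, geom)

  # zero force maps to zero stress, zero depth to zero strain, exactly
  expect_identical(cur$stress[1], 0)
  expect_identical(cur$strain[1], 0)

  # independent hand evaluation of the two-term compliance sum at F = 1 mN
  k_hand <- 4 / (pi * 2 * 2.5) + (1 - 0.3^2) / (2.5 * 6)
  expect_equal(cur$stress[2], k_hand, tolerance = 1e-12)
  expect_equal(cur$stress[2], 0.3153, tolerance = 1e-3)
  expect_equal(cur$strain[2], 50 / 6000, tolerance = 1e-12)

  # substrate term vanishes as h grows: sigma -> 4F/(pi D1 D2)
  tall <- pillar_geometry(D1 = 2, D2 = 2.5, h = 1e6, taper = NULL)
  cur_tall <- normalize_curve(rec, tall)
  expect_equal(cur_tall$stress[2], 4 / (pi * 2 * 2.5), tolerance = 1e-4)

  # untapered limit D1 = D2 = D by direct substitution
  straight <- pillar_geometry(D1 = 2, D2 = 2, h = 6, taper = NULL)
  cur_str <- normalize_curve(rec, straight)
  expect_equal(cur_str$stress[3], (4 / (pi * 4) + (1 - 0.09) / (2 * 6)) * 2,
               tolerance = 1e-12)
})

test_that("geometry and record validation reject malformed input", {
  expect_error(pillar_geometry(D1 = -1, D2 = 2, h = 6, taper = NULL), "range")
  expect_error(pillar_geometry(D1 = 2, D2 = 1, h = 6, taper = NULL), "range")
  expect_error(pillar_geometry(D1 = 2, D2 = 2.5, h = 6, taper = 10), "inconsistent")
  expect_error(pillar_geometry(nu = 0.6), "range")
  expect_error(force_displacement(1:3, c(0, 1), c(0, 10, 20)), "equal length")
  expect_error(force_displacement(1:2, c(0, -1), c(0, 10)), "non-negative")
  expect_error(force_displacement(c(2, 1), c(0, 1), c(0, 10)), "non-decreasing")
  # derived taper angle matches (D2 - D1)/(2h)
  g <- pillar_geometry(D1 = 2, h = 6, taper = 2.5)
  expect_equal((g$D2 - g$D1) / (2 * g$h), tan(2.5 * pi / 180), tolerance = 1e-10)
})

test_that("modulus fitting recovers slopes on stress windows", {
  # exactly linear curve sigma = 40 * eps
  cur <- curve_from_stress(seq(0, 0.03, 1e-4), 40 * seq(0, 0.03, 1e-4))
  fit <- fit_modulus(cur)
  expect_equal(fit$E, 40, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # bilinear curve: a window confined below the knee ignores the soft branch
  cur2 <- bilinear_curve(E1 = 40, E2 = 10, knee = 0.02)
  knee_stress <- 40 * 0.02
  fit2 <- fit_modulus(cur2, window = c(0.5, 0.95), sigma_ref = knee_stress)
  expect_equal(fit2$E, 40, tolerance = 1e-9)

  # fewer than 3 points in the window is an error
  tiny <- curve_from_stress(c(0, 0.01, 0.02), c(0, 0.4, 0.8))
  expect_error(fit_modulus(tiny, window = c(0.99, 1.0)), "insufficient")
})

test_that("yield detection finds the knee and converges with the tolerance", {
  geom <- std_geom()
  # purely elastic curve: flagged, not an error
  lin <- curve_from_stress(seq(0, 0.03, 1e-4), 40 * seq(0, 0.03, 1e-4))
  flin <- fit_modulus(lin)
  expect_false(detect_yield(lin, flin)$yielded)

  # bilinear knee: refined detection lands on the programmed knee
  knee <- 0.02
  cur <- bilinear_curve(E1 = 40, E2 = 10, knee = knee)
  fit <- fit_modulus(cur, sigma_ref = 40 * knee)
  y <- detect_yield(cur, fit)
  expect_true(y$yielded)
  expect_equal(y$eps_e, knee, tolerance = 1e-6)

  # sigma_Y uses the top cross section only: 4 F_Y / (pi D1^2)
  expect_equal(y$sigma_Y, y$F_Y * 4 / (pi * geom$D1^2), tolerance = 1e-12)

  # shrinking the offset tolerance converges to the brute-force first
  # deviation from the elastic line
  dev_oracle <- function(curve, E, tol) {
    i <- which((E * curve$strain - curve$stress) / pmax(E * curve$strain, 1e-300) > tol &
                 curve$strain > 0)[1]
    curve$strain[i]
  }
  for (tol in c(0.02, 0.005, 0.001)) {
    yy <- detect_yield(cur, fit, offset_tol = tol, refine = FALSE)
    expect_lt(abs(yy$eps_e - dev_oracle(cur, 40, tol)), 1.5e-4)
    yr <- detect_yield(cur, fit, offset_tol = tol, refine = TRUE)
    expect_equal(yr$eps_e, knee, tolerance = 1e-6)
  }

  # the arithmetic of the yield equation: F_Y = 3.644 mN, D1 = 2 um
  expect_equal(3.644 * 4 / (pi * 4), 1.16, tolerance = 1e-2)
})

test_that("maximum strength and failure strain detection", {
  geom <- std_geom()
  # monotone curve ending at F = 4.15 mN: sigma_max = 4 F / (pi D1^2)
  eps <- seq(0, 0.05, 1e-3)
  frc <- seq(0, 4.15, length.out = length(eps))
  cur <- normalize_curve(force_displacement(seq_along(eps), frc, eps * 6000), geom)
  mx <- compute_max_strength(cur)
  expect_equal(mx$sigma_max, 4.15 * 4 / (pi * 4), tolerance = 1e-12)
  expect_equal(mx$sigma_max, 1.32, tolerance = 1e-2)
  expect_false(mx$fractured)   # no terminal drop: eps_f undefined, flagged
  expect_true(is.na(mx$eps_f))

  # hardening curve: sigma_max at least sigma_Y
  cur2 <- bilinear_curve(E1 = 40, E2 = 10, knee = 0.02)
  fit2 <- fit_modulus(cur2, sigma_ref = 0.8)
  y2 <- detect_yield(cur2, fit2)
  mx2 <- compute_max_strength(cur2)
  expect_gte(mx2$sigma_max, y2$sigma_Y)

  # programmed fracture strain is recovered within one sample step
  spec <- curve_spec("biogenic", eps_f = 0.074, noise_sd = 0)
  s <- reduce_curve(generate_curve(spec, geom), geom)
  expect_true(s$fractured)
  expect_equal(s$eps_f, 0.074, tolerance = 1e-4 / 0.074)
})

test_that("strain bursts and flow plateaus are detected", {
  geom <- std_geom()
  # biogenic-type curve has no burst
  bio <- normalize_curve(generate_curve(curve_spec("biogenic", noise_sd = 0), geom), geom)
  expect_false(detect_strain_burst(bio)$burst)

  # programmed single-step jump of 0.01 is recovered within one step
  eps <- c(seq(0, 0.02, 1e-4), seq(0.03, 0.05, 1e-4))
  sig <- c(40 * seq(0, 0.02, 1e-4), rep(0.45, length(seq(0.03, 0.05, 1e-4))))
  cur <- curve_from_stress(eps, sig, geom)
  br <- detect_strain_burst(cur, E = 40)
  expect_true(br$burst)
  expect_equal(br$delta_eps, 0.01, tolerance = 1e-4 / 0.01)
  expect_equal(br$sigma_f, 0.45, tolerance = 1e-9)

  # generated geological curve: plateau recovered within 2%
  geo <- curve_spec("geological", sigma_f = 0.47, noise_sd = 0)
  s <- reduce_curve(generate_curve(geo, geom), geom)
  expect_true(s$burst)
  expect_equal(s$sigma_f, 0.47, tolerance = 0.02)
  expect_equal(s$delta_eps, 0.015, tolerance = 1e-4 / 0.015)
})

test_that("cohort summaries aggregate and compare groups", {
  df <- data.frame(
    sigma_Y = c(1.0, 1.0, 1.0, 2.0, 2.1, 1.9),
    E = c(30, 31, 32, 30, 31, 32),
    group = rep(c("a", "b"), each = 3)
  )
  cs <- summarize_cohort(df, properties = c("sigma_Y", "E"))
  st <- cs$stats
  expect_equal(st$sd[st$group == "a" & st$property == "sigma_Y"], 0)
  # identical group means give t = 0
  tE <- cs$tests[cs$tests$property == "E", ]
  expect_equal(tE$t, 0, tolerance = 1e-12)
  # matches the standard equal-variance t-test
  tS <- cs$tests[cs$tests$property == "sigma_Y", ]
  ref <- t.test(df$sigma_Y[1:3], df$sigma_Y[4:6], var.equal = TRUE)
  expect_equal(tS$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tS$p_value, ref$p.value, tolerance = 1e-12)

  # single observation: sd flagged NA
  one <- summarize_cohort(data.frame(E = 30, group = "a"), properties = "E")
  expect_true(is.na(one$stats$sd))
})

test_that("biogenic cohorts are stronger than geological ones at the printed means", {
  geom <- std_geom()
  red <- function(material, n, seed0) {
    specs <- sample_curve_specs(n, material, geom, seed = seed0)
    do.call(rbind, lapply(seq_along(specs), function(i) {
      as.data.frame(reduce_curve(generate_curve(specs[[i]], geom, seed = seed0 + i), geom))
    }))
  }
  bio <- red("biogenic", 12, 500)
  geo <- red("geological", 12, 900)
  bio$group <- "biogenic"
  geo$group <- "geological"
  cs <- summarize_cohort(rbind(bio, geo), properties = "sigma_Y")
  m <- cs$stats
  expect_gt(m$mean[m$group == "biogenic"], m$mean[m$group == "geological"])
})
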