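#' Force-displacement record
#'
#' Container for one uniaxial micro-pillar compression test as exported by the
#' instrument: time in seconds, force in millinewtons, compression depth in
#' nanometres, and an optional segment label (`"loading"`, `"holding"`,
#' `"unloading"`). Time must be non-decreasing and forces non-negative.
#'
#' @param time_s Time stamps (s), non-decreasing.
#' @param force_mN Force (mN), non-negative.
#' @param depth_nm Compression depth (nm).
#' @param segment Optional character vector of segment labels.
#'
#' @return A data frame of class `"fd_record"`.
#' @export
force_displacement <- function(time_s, force_mN, depth_nm, segment = NULL) {
  n <- length(force_mN)
  if (length(time_s) != n || length(depth_nm) != n) {
    stop_input("time_s, force_mN and depth_nm must have equal length")
  }
  if (!is.null(segment) && length(segment) != n) {
    stop_input("segment must match the series length")
  }
  if (any(!is.finite(time_s)) || any(!is.finite(force_mN)) || any(!is.finite(depth_nm))) {
    stop_input("non-finite values in the record")
  }
  if (is.unsorted(time_s)) {
    stop_input("time_s must be non-decreasing")
  }
  if (any(force_mN < 0)) {
    stop_input("forces must be non-negative")
  }
  out <- data.frame(time_s = time_s, force_mN = force_mN, depth_nm = depth_nm)
  if (!is.null(segment)) out$segment <- as.character(segment)
  class(out) <- c("fd_record", "data.frame")
  out
}

#' Convert a force-displacement record to normalized stress and strain
#'
#' Applies the substrate-compliance correction for a slightly tapered pillar
#' on an elastic half-space:
#' \deqn{\varepsilon_n = \delta / h, \qquad
#'   \sigma_n = \left(\frac{4}{\pi D_1 D_2} + \frac{1 - \nu^2}{D_2 h}\right) F.}
#' With force in mN and lengths in micrometres the stress comes out directly
#' in GPa; depth is ingested in nm and divided by the height in nm. The first
#' term is the mean-cross-section stress of the tapered pillar; the second is
#' the Sneddon sink-in of the base into the substrate.
#'
#' @param record A [force_displacement()] record, or any data frame with
#'   columns `force_mN` and `depth_nm` (optionally `time_s`, `segment`).
#' @param geom A [pillar_geometry()].
#'
#' @return A data frame of class `"stress_strain"` with the original columns
#'   plus `strain` (dimensionless) and `stress` (GPa, normalized engineering
#'   stress), carrying the geometry as an attribute.
#' @examples
#' geom <- pillar_geometry(D1 = 2, D2 = 2.5, h = 6)
#' rec <- force_displacement(0:1, c(0, 1), c(0, 50))
#' normalize_curve(rec, geom)$stress  # 0 and ~0.315 GPa
#' @export
normalize_curve <- function(record, geom) {
  assert_geometry(geom)
  if (!all(c("force_mN", "depth_nm") %in% names(record))) {
    stop_input("record must have columns force_mN and depth_nm")
  }
  if (any(record$force_mN < 0)) {
    stop_input("forces must be non-negative")
  }
  out <- as.data.frame(record)
  out$strain <- out$depth_nm / (geom$h * 1000)
  out$stress <- stress_factor(geom) * out$force_mN
  class(out) <- c("stress_strain", "data.frame")
  attr(out, "geometry") <- geom
  out
}

curve_geometry <- function(curve) {
  g <- attr(curve, "geometry")
  if (is.null(g)) stop_input("curve carries no pillar geometry")
  g
}

#' Indices of the loading portion of a curve
#'
#' If a `segment` column is present, points labelled `"loading"` are used.
#' Otherwise the loading portion is taken as the longest contiguous run of
#' non-decreasing depth (raw exports often lack labels).
#'
#' @param curve A `"stress_strain"` curve (or `"fd_record"`).
#' @return Integer indices into the curve rows.
#' @export
loading_segment <- function(curve) {
  if (!is.null(curve$segment)) {
    idx <- which(curve$segment == "loading")
    if (length(idx)) return(idx)
  }
  x <- if (!is.null(curve$depth_nm)) curve$depth_nm else curve$strain
  n <- length(x)
  if (n < 2L) return(seq_len(n))
  up <- c(TRUE, diff(x) >= 0)
  longest_true_run(up)
}

#' Fit the Young's modulus on a stress window of the loading curve
#'
#' Least-squares linear regression of normalized stress on strain over the
#' points whose stress lies inside `window` (fractions of `sigma_ref`). The
#' default window is 50--95% of the peak loading stress; to confine the fit
#' to the elastic regime of a hardening curve, pass the yield-point stress as
#' `sigma_ref` (this is what [reduce_curve()] does on its second pass).
#'
#' @param curve A `"stress_strain"` curve.
#' @param window Fraction pair `(lo, hi)` of `sigma_ref` selecting the points.
#' @param sigma_ref Reference stress (GPa); defaults to the maximum stress on
#'   the loading portion.
#'
#' @return A `"modulus_fit"` list: `E` (slope, GPa), `intercept` (GPa),
#'   `r_squared`, `n_points`, `window`, `sigma_ref`.
#' @export
fit_modulus <- function(curve, window = c(0.5, 0.95), sigma_ref = NULL) {
  if (length(window) != 2L || window[1] < 0 || window[2] <= window[1]) {
    stop_input("window must be an increasing fraction pair")
  }
  idx <- loading_segment(curve)
  # fit on the rising portion only: points past the stress peak (post-burst
  # reloads, flow plateaus, terminal drops) are not elastic
  i_pk <- idx[which.max(curve$stress[idx])]
  idx <- idx[idx <= i_pk]
  if (is.null(sigma_ref)) sigma_ref <- max(curve$stress[idx])
  sel <- idx[curve$stress[idx] >= window[1] * sigma_ref &
               curve$stress[idx] <= window[2] * sigma_ref]
  if (length(sel) < 3L) {
    stop_input("insufficient data: fewer than 3 points in the fitting window")
  }
  xx <- curve$strain[sel]
  yy <- curve$stress[sel]
  E <- stats::cov(xx, yy) / stats::var(xx)
  b <- mean(yy) - E * mean(xx)
  resid <- yy - (b + E * xx)
  tss <- sum((yy - mean(yy))^2)
  structure(
    list(
      E = E,
      intercept = b,
      r_squared = if (tss > 0) 1 - sum(resid^2) / tss else NA_real_,
      sigma_resid = stats::sd(resid),
      n_points = length(sel),
      window = window,
      sigma_ref = sigma_ref
    ),
    class = "modulus_fit"
  )
}

#' @export
print.modulus_fit <- function(x, ...) {
  cat(sprintf(
    "Elastic modulus fit: E = %.3f GPa (R^2 = %.5f, %d points, window %.0f-%.0f%% of %.3g GPa)\n",
    x$E, x$r_squared, x$n_points, 100 * x$window[1], 100 * x$window[2], x$sigma_ref
  ))
  invisible(x)
}

elastic_line <- function(fit) {
  if (inherits(fit, "modulus_fit")) {
    c(E = fit$E, intercept = fit$intercept)
  } else {
    check_scalar(fit, "E", lower = 0, strict_lower = TRUE)
    c(E = fit, intercept = 0)
  }
}

#' Detect the yield point of a compression curve
#'
#' The yield point is taken as the onset of the nonlinear portion: the first
#' loading point whose (running-median smoothed) stress falls below the fitted
#' elastic line by more than `offset_tol` relative, sustained for
#' `consecutive` points. On a smooth hardening curve the knee is then refined
#' by intersecting the elastic line with a local post-yield secant, which
#' reduces to the exact knee for clean bilinear data; if the first deviating
#' point follows a displacement burst, the last pre-burst point is used
#' instead. The yield strength is the force at the knee over the top cross
#' section: \eqn{\sigma_Y = 4 F_Y / (\pi D_1^2)}.
#'
#' On noisy data the relative threshold alone would fire on transducer
#' scatter, so the deviation must also exceed `noise_mult` times the residual
#' standard deviation of the modulus fit (zero for clean data, leaving the
#' pure `offset_tol` rule and its exact-knee limit intact).
#'
#' @param curve A `"stress_strain"` curve (with geometry attribute).
#' @param fit A `"modulus_fit"` (preferred) or a plain modulus in GPa.
#' @param offset_tol Relative deviation from the elastic line marking yield.
#' @param smooth Odd width of the running-median pre-filter (1 disables).
#' @param consecutive Number of consecutive deviating points required.
#' @param refine Logical; refine the knee by elastic/secant intersection.
#' @param noise_mult Noise floor on the absolute deviation, in residual
#'   standard deviations of the modulus fit.
#'
#' @return A list: `yielded` flag, and when yielded `F_Y` (mN), `sigma_Y`
#'   (GPa), `eps_e` (elastic limit strain), `index` of the first deviating
#'   point. A purely elastic curve returns `yielded = FALSE` (no error).
#' @export
detect_yield <- function(curve, fit, offset_tol = 0.02, smooth = 5,
                         consecutive = 3, refine = TRUE, noise_mult = 4) {
  check_scalar(offset_tol, "offset_tol", lower = 0, strict_lower = TRUE)
  geom <- curve_geometry(curve)
  line <- elastic_line(fit)
  idx <- loading_segment(curve)
  eps <- curve$strain[idx]
  sig <- curve$stress[idx]
  frc <- curve$force_mN[idx]
  sm <- if (smooth > 1) stats::runmed(sig, k = smooth, endrule = "median") else sig
  pred <- line["intercept"] + line["E"] * eps
  # Only search above the lower edge of the modulus window: the relative
  # deviation is noise-dominated at small stresses.
  lo <- if (inherits(fit, "modulus_fit")) fit$window[1] * fit$sigma_ref else 0.2 * max(sig)
  noise_floor <- if (inherits(fit, "modulus_fit") && is.finite(fit$sigma_resid)) {
    noise_mult * fit$sigma_resid
  } else {
    0
  }
  dev_abs <- pred - sm
  dev <- dev_abs / pmax(pred, .Machine$double.eps)
  cand <- dev > offset_tol & dev_abs > noise_floor & pred >= lo
  if (consecutive > 1L) {
    run <- stats::filter(as.numeric(cand), rep(1, consecutive), sides = 1)
    first <- which(run == consecutive)[1] - consecutive + 1L
  } else {
    first <- which(cand)[1]
  }
  if (is.na(first) || length(first) == 0L) {
    return(list(yielded = FALSE, F_Y = NA_real_, sigma_Y = NA_real_,
                eps_e = NA_real_, index = NA_integer_))
  }
  j <- first
  step_med <- stats::median(diff(eps)[diff(eps) > 0])
  burst <- j > 1L && is.finite(step_med) && (eps[j] - eps[j - 1L]) > 5 * step_med
  if (burst || !refine) {
    k <- max(j - 1L, 1L)
    eps_e <- eps[k]
    F_Y <- frc[k]
  } else {
    hi <- min(j + 5L, length(eps))
    seg <- j:hi
    if (length(seg) >= 2L && stats::sd(eps[seg]) > 0) {
      cf <- stats::coef(stats::lm(sm[seg] ~ eps[seg]))
      denom <- line["E"] - cf[2]
      eps_k <- if (abs(denom) > 1e-8 * line["E"]) {
        unname((cf[1] - line["intercept"]) / denom)
      } else {
        NA_real_
      }
      if (!is.finite(eps_k) || eps_k <= 0 || eps_k > eps[hi]) eps_k <- eps[max(j - 1L, 1L)]
    } else {
      eps_k <- eps[max(j - 1L, 1L)]
    }
    eps_e <- eps_k
    F_Y <- stats::approx(eps, frc, xout = eps_e, rule = 2)$y
  }
  list(
    yielded = TRUE,
    F_Y = F_Y,
    sigma_Y = eq_top_factor(geom) * F_Y,
    eps_e = eps_e,
    index = idx[j]
  )
}

#' Maximum strength and failure strain
#'
#' The maximum force on the loading portion gives
#' \eqn{\sigma_{max} = 4 F_{max} / (\pi D_1^2)}. The failure strain is read at
#' the abrupt terminal fracture: the last point before a relative force drop
#' exceeding `drop_frac` within one step (among drops from at least half the
#' peak force) after which the force never recovers above `residual_frac`
#' of the peak -- this distinguishes terminal fracture from the recoverable
#' load drop of a displacement burst. Curves without such a drop are flagged
#' `fractured = FALSE` and `eps_f` is undefined; the strain at peak force is
#' always reported as `eps_at_max`.
#'
#' @param curve A `"stress_strain"` curve.
#' @param drop_frac Relative single-step force drop marking fracture.
#' @param residual_frac Fraction of the peak force below which the post-drop
#'   force must remain for the drop to count as terminal.
#'
#' @return List with `F_max` (mN), `sigma_max` (GPa), `eps_f`, `eps_at_max`,
#'   `fractured`.
#' @export
compute_max_strength <- function(curve, drop_frac = 0.5, residual_frac = 0.25) {
  check_scalar(drop_frac, "drop_frac", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(residual_frac, "residual_frac", lower = 0, upper = 1)
  geom <- curve_geometry(curve)
  idx <- loading_segment(curve)
  frc <- curve$force_mN[idx]
  eps <- curve$strain[idx]
  i_max <- which.max(frc)
  F_max <- frc[i_max]
  rel_drop <- -diff(frc) / pmax(frc[-length(frc)], .Machine$double.eps)
  drops <- which(rel_drop > drop_frac & frc[-length(frc)] > 0.5 * F_max)
  # keep only drops the curve never recovers from
  drops <- drops[vapply(drops, function(i) {
    max(frc[seq.int(i + 1L, length(frc))]) < residual_frac * F_max
  }, logical(1))]
  fractured <- length(drops) > 0L
  list(
    F_max = F_max,
    sigma_max = eq_top_factor(geom) * F_max,
    eps_f = if (fractured) eps[drops[1]] else NA_real_,
    eps_at_max = eps[i_max],
    fractured = fractured
  )
}

#' Detect a displacement burst and the post-burst flow plateau
#'
#' Geological-type calcite yields with a sudden strain jump under
#' displacement control (a slip avalanche), then settles into steady plastic
#' flow. A burst is a single-step strain increment exceeding `burst_factor`
#' times the median loading increment; the flow strength `sigma_f` is the
#' mean stress over the longest contiguous post-burst region whose local
#' slope magnitude stays below `slope_frac * E`.
#'
#' @param curve A `"stress_strain"` curve.
#' @param E Reference modulus (GPa) for the plateau slope bound; estimated
#'   from the pre-burst upper half of the curve when `NULL`.
#' @param burst_factor Multiple of the median strain step defining a burst.
#' @param slope_frac Plateau slope bound as a fraction of `E`.
#' @param min_plateau Minimum number of points to accept a plateau.
#'
#' @return List with `burst` flag and, when found, `delta_eps` (strain jump),
#'   `sigma_f` (GPa, `NA` if no plateau), `burst_index`.
#' @export
detect_strain_burst <- function(curve, E = NULL, burst_factor = 5,
                                slope_frac = 0.1, min_plateau = 5) {
  idx <- loading_segment(curve)
  eps <- curve$strain[idx]
  sig <- curve$stress[idx]
  d_eps <- diff(eps)
  pos <- d_eps[d_eps > 0]
  if (!length(pos)) {
    return(list(burst = FALSE, delta_eps = NA_real_, sigma_f = NA_real_,
                burst_index = NA_integer_))
  }
  med <- stats::median(pos)
  b <- which(d_eps > burst_factor * med)[1]
  if (is.na(b)) {
    return(list(burst = FALSE, delta_eps = NA_real_, sigma_f = NA_real_,
                burst_index = NA_integer_))
  }
  if (is.null(E)) {
    pre <- seq_len(b)
    pre <- pre[sig[pre] >= 0.5 * max(sig[pre])]
    E <- if (length(pre) >= 3L) {
      unname(stats::coef(stats::lm(sig[pre] ~ eps[pre]))[2])
    } else {
      max(sig) / max(eps)
    }
  }
  post <- seq.int(b + 1L, length(eps))
  sigma_f <- NA_real_
  plateau <- integer(0)
  if (length(post) >= min_plateau + 1L) {
    sl <- diff(sig[post]) / pmax(diff(eps[post]), .Machine$double.eps)
    if (length(sl) >= 5L) sl <- stats::runmed(sl, k = 5, endrule = "median")
    flat <- abs(sl) < slope_frac * E
    run <- longest_true_run(flat)
    if (length(run) >= min_plateau) {
      plateau <- post[c(run, run[length(run)] + 1L)]
      plateau <- plateau[plateau <= length(eps)]
      sigma_f <- mean(sig[plateau])
    }
  }
  list(
    burst = TRUE,
    delta_eps = d_eps[b],
    sigma_f = sigma_f,
    burst_index = idx[b],
    plateau_index = idx[plateau]
  )
}

#' Reduce one micro-pillar compression record to a mechanical summary
#'
#' Runs the full data-reduction chain: normalization through the tapered
#' pillar compliance correction, a preliminary modulus fit on the 25--50%
#' stress window, yield detection against that line, a final modulus fit on
#' the 50--95% window of the pre-yield stress range, a second yield pass,
#' maximum strength/failure strain, and burst/flow-plateau detection.
#'
#' @param record A [force_displacement()] record (or compatible data frame).
#' @param geom A [pillar_geometry()].
#' @param offset_tol Relative deviation for yield detection.
#' @param drop_frac Terminal-fracture force-drop fraction.
#' @param prelim_window Stress window for the preliminary modulus fit.
#' @param window Stress window for the final (pre-yield-referenced) fit.
#' @param ... Passed on to [detect_yield()].
#'
#' @return A `"mechanical_summary"` list with fields `E`, `r_squared`,
#'   `F_Y`, `sigma_Y`, `eps_e`, `F_max`, `sigma_max`, `eps_f`, `eps_at_max`,
#'   `sigma_f`, `delta_eps`, and flags `yielded`, `fractured`, `burst`.
#' @examples
#' geom <- pillar_geometry()
#' rec <- generate_curve(curve_spec("biogenic", noise_sd = 0), geom, seed = 1)
#' reduce_curve(rec, geom)
#' @export
reduce_curve <- function(record, geom, offset_tol = 0.02, drop_frac = 0.5,
                         prelim_window = c(0.25, 0.5), window = c(0.5, 0.95),
                         ...) {
  assert_geometry(geom)
  curve <- normalize_curve(record, geom)
  fit0 <- fit_modulus(curve, window = prelim_window)
  y0 <- detect_yield(curve, fit0, offset_tol = offset_tol, ...)
  fit <- fit0
  y <- y0
  if (y0$yielded) {
    sigma_knee <- fit0$intercept + fit0$E * y0$eps_e
    fit <- tryCatch(
      fit_modulus(curve, window = window, sigma_ref = sigma_knee),
      error = function(e) fit0
    )
    y <- detect_yield(curve, fit, offset_tol = offset_tol, ...)
    if (!y$yielded) y <- y0
  }
  mx <- compute_max_strength(curve, drop_frac = drop_frac)
  br <- detect_strain_burst(curve, E = fit$E)
  structure(
    list(
      E = fit$E,
      r_squared = fit$r_squared,
      yielded = y$yielded,
      F_Y = y$F_Y,
      sigma_Y = y$sigma_Y,
      eps_e = y$eps_e,
      F_max = mx$F_max,
      sigma_max = mx$sigma_max,
      eps_f = mx$eps_f,
      eps_at_max = mx$eps_at_max,
      fractured = mx$fractured,
      burst = br$burst,
      delta_eps = br$delta_eps,
      sigma_f = br$sigma_f,
      geometry = geom,
      n_points = nrow(curve)
    ),
    class = "mechanical_summary"
  )
}

#' @export
print.mechanical_summary <- function(x, ...) {
  cat("Micro-pillar mechanical summary\n")
  cat(sprintf("  E        = %8.3f GPa (R^2 = %.5f)\n", x$E, x$r_squared))
  if (x$yielded) {
    cat(sprintf("  sigma_Y  = %8.3f GPa (F_Y = %.3f mN), eps_e = %.4f\n",
                x$sigma_Y, x$F_Y, x$eps_e))
  } else {
    cat("  no yield detected (elastic only)\n")
  }
  cat(sprintf("  sigma_max= %8.3f GPa (F_max = %.3f mN)\n", x$sigma_max, x$F_max))
  if (x$fractured) {
    cat(sprintf("  eps_f    = %8.4f (abrupt terminal fracture)\n", x$eps_f))
  }
  if (x$burst) {
    cat(sprintf("  burst: delta_eps = %.4f, sigma_f = %s GPa\n", x$delta_eps,
                ifelse(is.na(x$sigma_f), "NA", sprintf("%.3f", x$sigma_f))))
  }
  invisible(x)
}

#' @export
as.data.frame.mechanical_summary <- function(x, ...) {
  data.frame(
    E = x$E, r_squared = x$r_squared, yielded = x$yielded,
    F_Y = x$F_Y, sigma_Y = x$sigma_Y, eps_e = x$eps_e,
    F_max = x$F_max, sigma_max = x$sigma_max, eps_f = x$eps_f,
    eps_at_max = x$eps_at_max, fractured = x$fractured,
    burst = x$burst, delta_eps = x$delta_eps, sigma_f = x$sigma_f
  )
}

#' Cohort statistics and pairwise tests for mechanical summaries
#'
#' Computes per-group mean and standard deviation of each mechanical property
#' and two-sample t-tests between every pair of groups, property by property.
#'
#' @param summaries A data frame of mechanical properties (e.g. rbind-ed
#'   [as.data.frame.mechanical_summary()] rows) or a list of
#'   `"mechanical_summary"` objects.
#' @param group Group labels (recycled), or the name of a column holding them.
#' @param var_equal Assume equal variances in the t-tests (classical two-sample
#'   t-test); set `FALSE` for Welch.
#' @param properties Property columns to summarize.
#'
#' @return A `"cohort_summary"` list with elements `stats` (group, property,
#'   n, mean, sd) and `tests` (property, group pair, t, df, p_value). Groups
#'   with a single observation get `sd = NA`.
#' @export
summarize_cohort <- function(summaries, group = "group", var_equal = TRUE,
                             properties = c("E", "sigma_Y", "sigma_max",
                                            "eps_e", "eps_f", "sigma_f",
                                            "delta_eps")) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(summaries, as.data.frame))
  }
  df <- as.data.frame(summaries)
  if (length(group) == 1L && is.character(group) && group %in% names(df)) {
    g <- as.character(df[[group]])
  } else {
    g <- as.character(rep_len(group, nrow(df)))
  }
  props <- intersect(properties, names(df))
  if (!length(props)) stop_input("no recognized property columns")
  stats_rows <- list()
  for (p in props) {
    for (lev in unique(g)) {
      v <- df[[p]][g == lev]
      v <- v[is.finite(v)]
      if (!length(v)) next
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        group = lev, property = p, n = length(v), mean = mean(v),
        sd = if (length(v) >= 2L) stats::sd(v) else NA_real_
      )
    }
  }
  test_rows <- list()
  levs <- unique(g)
  if (length(levs) >= 2L) {
    for (p in props) {
      for (i in seq_len(length(levs) - 1L)) {
        for (j in seq.int(i + 1L, length(levs))) {
          a <- df[[p]][g == levs[i]]
          b <- df[[p]][g == levs[j]]
          a <- a[is.finite(a)]
          b <- b[is.finite(b)]
          if (length(a) < 2L || length(b) < 2L) next
          tt <- stats::t.test(a, b, var.equal = var_equal)
          test_rows[[length(test_rows) + 1L]] <- data.frame(
            property = p, group1 = levs[i], group2 = levs[j],
            t = unname(tt$statistic), df = unname(tt$parameter),
            p_value = tt$p.value
          )
        }
      }
    }
  }
  structure(
    list(
      stats = do.call(rbind, stats_rows),
      tests = if (length(test_rows)) do.call(rbind, test_rows) else NULL
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, digits = 4, ...) {
  cat("Cohort statistics (mean +/- sd):\n")
  print(x$stats, digits = digits, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nTwo-sample t-tests:\n")
    print(x$tests, digits = digits, row.names = FALSE)
  }
  invisible(x)
}
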