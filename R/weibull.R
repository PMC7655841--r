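#' Empirical failure fractions for a strength sample
#'
#' Sorts the strengths ascending (stable, so ties keep their input order) and
#' assigns each rank a plotting position: the median-rank style
#' `f_i = (i - 0.5) / n` by default, or the mean rank `i / (n + 1)`.
#'
#' @param strengths Positive strengths (GPa).
#' @param position `"median"` for `(i - 0.5)/n`, `"mean"` for `i/(n + 1)`.
#'
#' @return Data frame with columns `strength` (ascending) and `f`.
#' @examples
#' empirical_failure_fraction(c(1.2, 0.9, 1.5, 1.1))$f  # 0.125 0.375 0.625 0.875
#' @export
empirical_failure_fraction <- function(strengths, position = c("median", "mean")) {
  position <- match.arg(position)
  if (!length(strengths)) stop_input("empty strength sample")
  if (any(!is.finite(strengths)) || any(strengths <= 0)) {
    stop_input("strengths must be positive and finite")
  }
  ord <- order(strengths)  # stable: ties keep input order
  n <- length(strengths)
  i <- seq_len(n)
  f <- switch(position, median = (i - 0.5) / n, mean = i / (n + 1))
  data.frame(strength = strengths[ord], f = f)
}

# Rank-regression (linearized) fit: ln(-ln(1 - f)) on ln(sigma).
weibull_linearized <- function(x, position) {
  eff <- empirical_failure_fraction(x, position)
  X <- log(eff$strength)
  Y <- log(-log(1 - eff$f))
  sxx <- stats::var(X)
  if (sxx == 0) stop_input("degenerate sample: all strengths equal")
  m <- stats::cov(X, Y) / sxx
  b <- mean(Y) - m * mean(X)
  r2 <- if (stats::var(Y) > 0) stats::cor(X, Y)^2 else NA_real_
  list(shape = m, scale = exp(-b / m), r_squared = r2)
}

# Maximum likelihood via the profiled score equation in the shape m:
#   g(m) = sum(x^m log x)/sum(x^m) - 1/m - mean(log x) = 0,
# then scale = (mean(x^m))^(1/m).
weibull_mle <- function(x) {
  lx <- log(x)
  if (stats::sd(lx) == 0) stop_input("degenerate sample: all strengths equal")
  g <- function(m) {
    xm <- exp(m * lx - max(m * lx))  # rescaled for overflow safety
    sum(xm * lx) / sum(xm) - 1 / m - mean(lx)
  }
  lo <- 1e-3
  hi <- 1
  while (g(hi) < 0 && hi < 1e4) hi <- hi * 2
  if (g(hi) < 0) stop_input("maximum-likelihood fit failed to bracket the shape")
  m <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  scale <- mean(x^m)^(1 / m)
  list(shape = m, scale = scale, r_squared = NA_real_)
}

#' Fit a two-parameter Weibull strength distribution
#'
#' Fits the strength model \eqn{f = 1 - e^{-(\sigma_Y/\sigma_{Y0})^m}} to a
#' sample of yield strengths. The default (`"linearized"`) regresses
#' \eqn{\ln(-\ln(1-f))} on \eqn{\ln \sigma_Y} through the empirical failure
#' fractions, so the slope is the Weibull modulus `m` and the intercept is
#' \eqn{-m \ln \sigma_{Y0}}; this matches the straight-line presentation of
#' classical Weibull plots. `"mle"` solves the standard two-parameter
#' likelihood score equations instead. Standard errors come from a seeded
#' nonparametric bootstrap.
#'
#' @param strengths Positive strengths (GPa), at least 3.
#' @param method `"linearized"` or `"mle"`.
#' @param position Plotting position rule, see [empirical_failure_fraction()].
#' @param n_boot Bootstrap resamples for the standard errors (0 skips them).
#' @param seed Seed for the bootstrap.
#'
#' @return A `"weibull_fit"` list: `shape` (Weibull modulus m), `scale`
#'   (characteristic strength, GPa), `shape_se`, `scale_se`, `method`,
#'   `r_squared` (linearized only), `n`, `n_boot`.
#' @examples
#' x <- generate_strengths(50, shape = 5.74, scale = 1.2, seed = 1)
#' fit_weibull(x, n_boot = 200, seed = 2)
#' @export
fit_weibull <- function(strengths, method = c("linearized", "mle"),
                        position = c("median", "mean"), n_boot = 2000,
                        seed = NULL) {
  method <- match.arg(method)
  position <- match.arg(position)
  x <- strengths
  if (length(x) < 3L) stop_input("need at least 3 strengths to fit")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_input("strengths must be positive and finite")
  }
  fit1 <- function(xx) {
    if (method == "linearized") weibull_linearized(xx, position) else weibull_mle(xx)
  }
  est <- fit1(x)
  shape_se <- scale_se <- NA_real_
  if (n_boot > 0) {
    boots <- local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        xb <- x[sample.int(length(x), replace = TRUE)]
        r <- tryCatch(fit1(xb), error = function(e) list(shape = NA_real_, scale = NA_real_))
        c(r$shape, r$scale)
      }, numeric(2))
    })
    shape_se <- stats::sd(boots[1, ], na.rm = TRUE)
    scale_se <- stats::sd(boots[2, ], na.rm = TRUE)
  }
  structure(
    list(
      shape = est$shape, scale = est$scale,
      shape_se = shape_se, scale_se = scale_se,
      method = method, position = position,
      r_squared = est$r_squared, n = length(x), n_boot = n_boot
    ),
    class = "weibull_fit"
  )
}

#' @export
print.weibull_fit <- function(x, ...) {
  se <- function(v) if (is.na(v)) "" else sprintf(" +/- %.3g", v)
  cat(sprintf(
    "Weibull strength fit (%s, n = %d):\n  modulus m = %.4g%s\n  scale sigma_Y0 = %.4g GPa%s\n",
    x$method, x$n, x$shape, se(x$shape_se), x$scale, se(x$scale_se)
  ))
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.5f\n", x$r_squared))
  invisible(x)
}

#' Fitted Weibull failure probability
#'
#' @param object A `"weibull_fit"`.
#' @param strengths Strengths at which to evaluate the fitted CDF.
#' @param ... Unused.
#' @return Failure fractions in `[0, 1)`.
#' @export
predict.weibull_fit <- function(object, strengths, ...) {
  stats::pweibull(strengths, shape = object$shape, scale = object$scale)
}
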