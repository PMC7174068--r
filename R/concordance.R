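#' Deming (errors-in-variables) regression
#'
#' Fits `y = intercept + slope * x` assuming measurement error in both
#' variables with error-variance ratio `lambda = var(err_y) / var(err_x)`.
#' With the (n-1)-denominator moments `s_xx`, `s_yy`, `s_xy`, the closed-form
#' slope is
#' \deqn{\hat\beta = \frac{s_{yy} - \lambda s_{xx} +
#'   \sqrt{(s_{yy} - \lambda s_{xx})^2 + 4 \lambda s_{xy}^2}}{2 s_{xy}}}
#' and the intercept passes through the centroid. `lambda = 1` gives
#' orthogonal regression, the conventional default when the two TMB methods
#' are assumed equally noisy. The slope confidence interval is a
#' leave-one-out jackknife with a normal approximation.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param lambda Error-variance ratio var(y-error) / var(x-error); default 1.
#' @param conf_level Confidence level for the jackknife slope CI.
#' @return A `deming_fit` list: `slope`, `intercept`, `lambda`, `pearson_r`,
#'   `n`, `slope_se`, `slope_ci` (low, high), `ci_method`.
#' @export
deming_fit <- function(x, y, lambda = 1, conf_level = 0.95) {
  stopifnot(length(x) == length(y), lambda > 0)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Deming regression needs at least 3 complete observations")
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0) stop("x is constant: Deming fit undefined")
  if (sxy == 0) stop("degenerate fit: covariance of x and y is zero")
  slope <- deming_slope(sxx, syy, sxy, lambda)
  intercept <- mean(y) - slope * mean(x)
  # Leave-one-out slopes from downdated sums (vectorized).
  Sx <- sum(x); Sy <- sum(y)
  Sxx <- sum(x^2); Syy <- sum(y^2); Sxy <- sum(x * y)
  n1 <- n - 1
  mx <- (Sx - x) / n1; my <- (Sy - y) / n1
  sxx_i <- (Sxx - x^2 - n1 * mx^2) / (n1 - 1)
  syy_i <- (Syy - y^2 - n1 * my^2) / (n1 - 1)
  sxy_i <- (Sxy - x * y - n1 * mx * my) / (n1 - 1)
  loo <- deming_slope(sxx_i, syy_i, sxy_i, lambda)
  pseudo <- n * slope - n1 * loo
  se <- stats::sd(pseudo) / sqrt(n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(slope = slope, intercept = intercept, lambda = lambda,
                 pearson_r = stats::cor(x, y), n = n, slope_se = se,
                 slope_ci = c(low = slope - z * se, high = slope + z * se),
                 ci_method = "jackknife-normal"),
            class = "deming_fit")
}

deming_slope <- function(sxx, syy, sxy, lambda) {
  d <- syy - lambda * sxx
  (d + sqrt(d^2 + 4 * lambda * sxy^2)) / (2 * sxy)
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf(
    "Deming regression (lambda = %g, n = %d)\n  slope %.4f [%.4f, %.4f]  intercept %.4f  Pearson r %.4f\n",
    x$lambda, x$n, x$slope, x$slope_ci[["low"]], x$slope_ci[["high"]],
    x$intercept, x$pearson_r))
  invisible(x)
}

#' Pearson product-moment correlation with degeneracy checks
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both non-constant.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("correlation needs at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(x, y)
}

#' Bland-Altman agreement summary
#'
#' Differences are taken as `y - x`; the bias is their mean and the limits of
#' agreement are bias +/- 1.96 standard deviations (sample SD, n-1).
#'
#' @param x,y Numeric vectors of equal length, n >= 2.
#' @return A `bland_altman` list: `mean_bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, plus the per-sample `means` and `diffs` for plotting.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("Bland-Altman needs at least 2 complete observations")
  d <- y - x
  bias <- mean(d); s <- stats::sd(d)
  structure(list(mean_bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = n, means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4f, limits of agreement [%.4f, %.4f]\n",
              x$n, x$mean_bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' All-pairs method comparison
#'
#' Fits a Deming regression for every ordered pair of TMB methods in a
#' cohort matrix. The diagonal is the identity (slope 1, r 1). A pair whose
#' fit fails (for example a method with constant TMB) is flagged in the
#' `error` column rather than aborting the whole grid.
#'
#' @param m A [tmb_matrix()].
#' @param lambda Error-variance ratio passed to [deming_fit()].
#' @return Tibble with `x_method`, `y_method`, `n`, `slope`, `slope_ci_low`,
#'   `slope_ci_high`, `intercept`, `pearson_r`, `error`.
#' @export
comparison_matrix <- function(m, lambda = 1) {
  wide <- tmb_wide(m)
  methods <- setdiff(names(wide), "sample_id")
  if (length(methods) < 2) stop("need at least 2 methods to compare")
  grid <- expand.grid(x_method = methods, y_method = methods,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    xm <- grid$x_method[i]; ym <- grid$y_method[i]
    x <- wide[[xm]]; y <- wide[[ym]]
    if (xm == ym) {
      return(tibble::tibble(x_method = xm, y_method = ym, n = length(x),
                            slope = 1, slope_ci_low = 1, slope_ci_high = 1,
                            intercept = 0, pearson_r = 1, error = NA_character_))
    }
    fit <- tryCatch(deming_fit(x, y, lambda = lambda), error = identity)
    if (inherits(fit, "error")) {
      tibble::tibble(x_method = xm, y_method = ym, n = sum(is.finite(x) & is.finite(y)),
                     slope = NA_real_, slope_ci_low = NA_real_,
                     slope_ci_high = NA_real_, intercept = NA_real_,
                     pearson_r = NA_real_, error = conditionMessage(fit))
    } else {
      tibble::tibble(x_method = xm, y_method = ym, n = fit$n,
                     slope = fit$slope,
                     slope_ci_low = fit$slope_ci[["low"]],
                     slope_ci_high = fit$slope_ci[["high"]],
                     intercept = fit$intercept, pearson_r = fit$pearson_r,
                     error = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}
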