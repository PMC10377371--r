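# Parameter-vs-StO2 regression and inverse derivation of safe cutoffs.

#' Fit a perfusion-parameter regression on tissue oxygen saturation
#'
#' Ordinary least squares of a quantitative perfusion parameter (response)
#' on StO2 (%), optionally with a squared-StO2 term. The fitted line is
#' later inverted by [predict_cutoff()] to read off the parameter value
#' corresponding to a given oxygenation level.
#'
#' @param points Data frame of assessment points with the parameter column
#'   and an StO2 column.
#' @param parameter Name of the response column (e.g. `"t_half_s"`).
#' @param model `"linear"` or `"quadratic"`.
#' @param sto2_col Name of the StO2 column (default `"sto2_pct"`).
#' @param drop_outliers If `TRUE`, refit once after removing points with
#'   absolute studentized residual above `outlier_sd` (the published fits
#'   report a handful of unexplained exclusions; the exact rule is unknown,
#'   so the filter is optional and off by default).
#' @param outlier_sd Studentized-residual threshold (default 4).
#' @return An object of class `icg_regression_fit`: list with `parameter`,
#'   `model`, `coefficients` (intercept, StO2, and StO2^2 when quadratic),
#'   `r_squared`, `n`, `sigma` (residual SD) and the underlying `lm` fit.
#' @export
fit_parameter_regression <- function(points, parameter,
                                     model = c("linear", "quadratic"),
                                     sto2_col = "sto2_pct",
                                     drop_outliers = FALSE, outlier_sd = 4) {
  model <- match.arg(model)
  if (!parameter %in% names(points))
    stop(sprintf("column '%s' not found", parameter), call. = FALSE)
  if (!sto2_col %in% names(points))
    stop(sprintf("column '%s' not found", sto2_col), call. = FALSE)
  y <- points[[parameter]]; x <- points[[sto2_col]]
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 10L)
    stop("need at least 10 points with finite parameter and StO2 values",
         call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate design: StO2 is constant", call. = FALSE)
  dat <- data.frame(y = y, sto2 = x)
  form <- if (model == "quadratic") y ~ sto2 + I(sto2^2) else y ~ sto2
  fit <- stats::lm(form, data = dat)
  if (drop_outliers) {
    keep2 <- abs(stats::rstudent(fit)) <= outlier_sd
    if (any(!keep2) && sum(keep2) >= 10L)
      fit <- stats::lm(form, data = dat[keep2, , drop = FALSE])
  }
  sm <- suppressWarnings(summary(fit)) # noiseless fits warn about perfection
  sst <- sum((fit$model$y - mean(fit$model$y))^2)
  r2 <- if (sst == 0) 0 else sm$r.squared
  structure(list(parameter = parameter, model = model,
                 coefficients = stats::coef(fit),
                 r_squared = r2,
                 n = stats::nobs(fit),
                 sigma = sm$sigma,
                 fit = fit),
            class = "icg_regression_fit")
}

#' @export
print.icg_regression_fit <- function(x, ...) {
  co <- x$coefficients
  eq <- sprintf("%.3f %+.3f x StO2", co[1], co[2])
  if (x$model == "quadratic") eq <- sprintf("%s %+.4f x StO2^2", eq, co[3])
  cat(sprintf("<icg_regression_fit> %s (%s, n = %d): %s = %s, R^2 = %.3f\n",
              x$parameter, x$model, x$n, x$parameter, eq, x$r_squared))
  invisible(x)
}

#' Predict a parameter cutoff at given StO2 levels
#'
#' Inverse use of the fitted regression: the safe cutoff of a perfusion
#' parameter at tissue oxygenation `sto2_level` is the mean response of the
#' fit at that level, reported with the 95% confidence interval of the mean
#' (t distribution on the fit's residual degrees of freedom) - a CI of the
#' mean, not a prediction interval, matching how the published cutoff table
#' is labelled.
#'
#' @param fit An [fit_parameter_regression()] result.
#' @param sto2_level StO2 level(s) in percent, each within \[40, 100\].
#' @param conf_level Confidence level (default 0.95).
#' @return A data frame with columns `sto2_level`, `mean_value`, `ci_low`,
#'   `ci_high`.
#' @export
predict_cutoff <- function(fit, sto2_level, conf_level = 0.95) {
  stopifnot(inherits(fit, "icg_regression_fit"))
  if (any(!is.finite(sto2_level)) || any(sto2_level < 40 | sto2_level > 100))
    stop("sto2_level must lie within [40, 100]", call. = FALSE)
  pr <- stats::predict(fit$fit, newdata = data.frame(sto2 = sto2_level),
                       interval = "confidence", level = conf_level)
  data.frame(sto2_level = sto2_level,
             mean_value = pr[, "fit"],
             ci_low = pr[, "lwr"],
             ci_high = pr[, "upr"],
             row.names = NULL)
}

#' Cutoff schedule over the safe oxygenation range
#'
#' Convenience wrapper evaluating [predict_cutoff()] at the conventional
#' StO2 levels 60-80% in 5%-steps.
#'
#' @inheritParams predict_cutoff
#' @param levels StO2 levels (default `seq(60, 80, by = 5)`).
#' @return See [predict_cutoff()].
#' @export
cutoff_schedule <- function(fit, levels = seq(60, 80, by = 5),
                            conf_level = 0.95) {
  predict_cutoff(fit, levels, conf_level)
}

#' Evaluate a printed regression equation at an StO2 level
#'
#' Plain polynomial evaluation of published (rounded) coefficients, with no
#' confidence interval - useful for checking a printed cutoff table against
#' its printed equations.
#'
#' @param intercept,beta_sto2,beta_sto2_sq Equation coefficients
#'   (`beta_sto2_sq` defaults to 0 for linear equations).
#' @param sto2_level StO2 level(s) in percent.
#' @return Numeric vector of mean parameter values.
#' @examples
#' equation_cutoff(76.287, -0.785, sto2_level = 60) # ~29.19
#' @export
equation_cutoff <- function(intercept, beta_sto2, beta_sto2_sq = 0,
                            sto2_level) {
  intercept + beta_sto2 * sto2_level + beta_sto2_sq * sto2_level^2
}

#' Descriptive cutoff from a 95% coverage interval
#'
#' For parameters whose scatter against StO2 is too irregular for a
#' regression fit (the perfusion time ratio and F_MAX), the safe cutoff is
#' taken from the sample's central 95% coverage interval: the 97.5th
#' percentile bounds a "less than or equal" cutoff, the 2.5th percentile a
#' "greater than or equal" one. The bound is then rounded to a clinically
#' convenient grid.
#'
#' @param values Numeric sample of the parameter (at least 10 finite
#'   values).
#' @param direction `"le"` (upper bound) or `"ge"` (lower bound).
#' @param method `"percentile"` (default; the distributions are explicitly
#'   non-normal) or `"normal"` for mean +/- 1.96 SD.
#' @param grid Rounding grid for the reported cutoff (default 0.1; use 5
#'   for intensity-scale parameters). `NULL` disables rounding.
#' @return List with `cutoff` (rounded), `raw` (unrounded bound) and
#'   `direction`.
#' @export
descriptive_cutoff <- function(values, direction = c("le", "ge"),
                               method = c("percentile", "normal"),
                               grid = 0.1) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 10L)
    stop("insufficient data: need at least 10 finite values", call. = FALSE)
  raw <- if (method == "percentile") {
    stats::quantile(values, if (direction == "le") 0.975 else 0.025,
                    names = FALSE)
  } else {
    mean(values) + (if (direction == "le") 1.96 else -1.96) * stats::sd(values)
  }
  cut <- if (is.null(grid)) raw else round_to_grid(raw, grid)
  list(cutoff = cut, raw = raw, direction = direction)
}

#' Round a cutoff to a presentation grid
#'
#' The published safe values round regression cutoffs to clinically
#' convenient numbers (e.g. 29.18 -> 30). This is presentation only; all
#' computation uses unrounded values.
#'
#' @param x Numeric values.
#' @param grid Grid step (e.g. 5, 1, 0.1).
#' @return `x` rounded to the nearest multiple of `grid`.
#' @export
round_to_grid <- function(x, grid) {
  grid * round(x / grid)
}
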