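# Contingency tables, diagnostic metrics, association tests and ROC
# analysis of perfusion parameters against the StO2 >= 60% criterion.

#' Construct a 2x2 contingency table of counts
#'
#' Convention: "test positive" means the parameter lies within its safe
#' range; "condition positive" means StO2 >= 60% (good tissue
#' oxygenation). So `tp` counts safe-range points with good oxygenation,
#' `fp` safe-range points with poor oxygenation, `fn` out-of-range points
#' with good oxygenation and `tn` out-of-range points with poor
#' oxygenation.
#'
#' @param tp,fp,fn,tn Non-negative integer counts (total > 0).
#' @return An object of class `icg_contingency`.
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0) stop("empty table: total count is zero", call. = FALSE)
  structure(as.list(counts), class = "icg_contingency")
}

#' @export
print.icg_contingency <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("within safe range", "outside safe range"),
                              c("StO2 >= 60%", "StO2 < 60%")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.icg_contingency <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
         dimnames = list(test = c("positive", "negative"),
                         condition = c("positive", "negative")))
}

#' Dichotomize assessment points at a parameter cutoff
#'
#' Cross-classifies points by parameter-within-safe-range against
#' StO2 >= `sto2_threshold`. The safe-range comparison follows the
#' printed inequality for the parameter: `"le"` (<= cutoff), `"lt"`,
#' `"ge"` (>= cutoff) or `"gt"` (strictly >, used for F_MAX), so ties at
#' the cutoff fall on the side the inequality includes.
#'
#' @param points Data frame with the parameter column and an StO2 column.
#' @param parameter Parameter column name.
#' @param cutoff Finite cutoff value; defaults to the registry entry.
#' @param direction Safe-range comparison; defaults to the registry entry.
#' @param sto2_col StO2 column name (default `"sto2_pct"`).
#' @param sto2_threshold Good-oxygenation criterion (default 60%).
#' @return A [contingency_2x2()] object.
#' @export
dichotomize <- function(points, parameter, cutoff = NULL, direction = NULL,
                        sto2_col = "sto2_pct", sto2_threshold = 60) {
  if (is.null(cutoff) || is.null(direction)) {
    row <- .registry_row(parameter)
    if (is.null(cutoff)) cutoff <- row$cutoff
    if (is.null(direction)) direction <- row$direction
  }
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  y <- points[[parameter]]; s <- points[[sto2_col]]
  if (is.null(y) || is.null(s))
    stop("points must contain the parameter and StO2 columns", call. = FALSE)
  keep <- is.finite(y) & is.finite(s)
  y <- y[keep]; s <- s[keep]
  if (!length(y)) stop("empty table: no points with finite values", call. = FALSE)
  within <- switch(direction,
                   le = y <= cutoff, lt = y < cutoff,
                   ge = y >= cutoff, gt = y > cutoff,
                   stop("direction must be one of le, lt, ge, gt", call. = FALSE))
  cond <- s >= sto2_threshold
  contingency_2x2(tp = sum(within & cond), fp = sum(within & !cond),
                  fn = sum(!within & cond), tn = sum(!within & !cond))
}

# exact (Clopper-Pearson) or Wilson CI for x successes in n trials
.proportion_ci <- function(x, n, conf_level, method) {
  if (n == 0) return(c(NA_real_, NA_real_))
  if (method == "clopper-pearson") {
    as.numeric(stats::binom.test(x, n, conf.level = conf_level)$conf.int)
  } else { # wilson
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    p <- x / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, ctr - hw), min(1, ctr + hw))
  }
}

#' Diagnostic metrics of a 2x2 table
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy (in percent) for predicting good tissue oxygenation
#' (StO2 >= 60%) from the parameter's safe range, each with a confidence
#' interval (Clopper-Pearson exact by default). A metric whose denominator
#' is zero is reported as `NA` with `NA` interval bounds rather than
#' raising an error.
#'
#' @param table A [contingency_2x2()] object.
#' @param ci_method `"clopper-pearson"` (default) or `"wilson"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A data frame with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate_pct`, `ci_low_pct`, `ci_high_pct`.
#' @examples
#' diagnostic_metrics(contingency_2x2(tp = 322, fp = 1, fn = 7, tn = 10))
#' @export
diagnostic_metrics <- function(table, ci_method = c("clopper-pearson", "wilson"),
                               conf_level = 0.95) {
  stopifnot(inherits(table, "icg_contingency"))
  ci_method <- match.arg(ci_method)
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  defs <- list(sensitivity = c(tp, tp + fn),
               specificity = c(tn, tn + fp),
               ppv = c(tp, tp + fp),
               npv = c(tn, tn + fn),
               accuracy = c(tp + tn, tp + fp + fn + tn))
  rows <- lapply(names(defs), function(m) {
    x <- defs[[m]][1]; n <- defs[[m]][2]
    if (n == 0) {
      data.frame(metric = m, numerator = x, denominator = n,
                 estimate_pct = NA_real_, ci_low_pct = NA_real_,
                 ci_high_pct = NA_real_)
    } else {
      ci <- .proportion_ci(x, n, conf_level, ci_method)
      data.frame(metric = m, numerator = x, denominator = n,
                 estimate_pct = 100 * x / n,
                 ci_low_pct = 100 * ci[1], ci_high_pct = 100 * ci[2])
    }
  })
  do.call(rbind, rows)
}

#' Association test for a 2x2 table
#'
#' Pearson's chi-square test (without continuity correction) when all
#' expected cell counts are at least 5, otherwise Fisher's exact test
#' (two-sided) - the conventional small-sample rule.
#'
#' @param table A [contingency_2x2()] object.
#' @return List with `method` (`"fisher"` or `"chi-square"`), `p_value`,
#'   and `expected` (matrix of expected counts).
#' @export
association_test <- function(table) {
  stopifnot(inherits(table, "icg_contingency"))
  m <- as.matrix(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    p <- stats::fisher.test(m)$p.value
    method <- "fisher"
  } else {
    p <- stats::chisq.test(m, correct = FALSE)$p.value
    method <- "chi-square"
  }
  list(method = method, p_value = p, expected = expected)
}

#' ROC analysis of a perfusion parameter against good oxygenation
#'
#' The parameter is oriented so that larger scores indicate good perfusion
#' (time parameters and the time ratio are negated) and the AUC for
#' discriminating StO2 >= `sto2_threshold` is computed with a DeLong
#' confidence interval and a DeLong test against AUC = 0.5. The
#' orientation is fixed by the parameter registry, never auto-flipped, so
#' non-discriminating parameters can report AUC below 0.5.
#'
#' @param points Data frame with the parameter column and an StO2 column.
#' @param parameter Parameter column name (must be in
#'   [parameter_registry()]).
#' @param sto2_col StO2 column name (default `"sto2_pct"`).
#' @param sto2_threshold Good-oxygenation criterion (default 60%).
#' @param conf_level Confidence level for the AUC interval (default 0.95).
#' @return List with `auc`, `ci_low`, `ci_high`, `p_value`, `n_pos`,
#'   `n_neg` and the underlying `pROC::roc` object (`roc`).
#' @export
roc_analysis <- function(points, parameter, sto2_col = "sto2_pct",
                         sto2_threshold = 60, conf_level = 0.95) {
  row <- .registry_row(parameter)
  y <- points[[parameter]]; s <- points[[sto2_col]]
  keep <- is.finite(y) & is.finite(s)
  y <- y[keep]; s <- s[keep]
  cond <- as.integer(s >= sto2_threshold)
  if (length(unique(cond)) < 2L)
    stop("undefined ROC: both oxygenation classes must be present", call. = FALSE)
  score <- if (row$higher_is_better) y else -y
  r <- pROC::roc(response = cond, predictor = score,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- as.numeric(suppressWarnings(
    pROC::ci.auc(r, conf.level = conf_level, method = "delong")))
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  p <- if (v > 0) 2 * stats::pnorm(-abs((auc - 0.5) / sqrt(v))) else 0
  list(auc = auc, ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
       p_value = p, n_pos = sum(cond == 1), n_neg = sum(cond == 0), roc = r)
}

#' Diagnostic summary of all registry parameters on a points table
#'
#' Dichotomizes each parameter at its registry cutoff, then binds the
#' diagnostic metrics, association p-value and AUC into one table.
#'
#' @param points Assessment-point data frame.
#' @param parameters Registry parameter names present in `points`.
#' @inheritParams dichotomize
#' @return A data frame, one row per parameter x metric, plus columns
#'   `p_value` and `auc`.
#' @export
diagnostic_summary <- function(points,
                               parameters = intersect(parameter_registry()$parameter,
                                                      names(points)),
                               sto2_col = "sto2_pct", sto2_threshold = 60) {
  out <- lapply(parameters, function(p) {
    tab <- dichotomize(points, p, sto2_col = sto2_col,
                       sto2_threshold = sto2_threshold)
    met <- diagnostic_metrics(tab)
    met$parameter <- p
    met$p_value <- association_test(tab)$p_value
    met$auc <- roc_analysis(points, p, sto2_col, sto2_threshold)$auc
    met
  })
  do.call(rbind, out)
}
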