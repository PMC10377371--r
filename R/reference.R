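# Published reference tables shipped with the package.

#' Reference tables from the source prospective cohort
#'
#' Small plain-text tables summarizing the reference prospective study of
#' intraoperative colonic perfusion (68 patients, 340 assessment points)
#' that the package's cutoffs and diagnostic conventions are anchored to:
#'
#' * `"contingency"` - counts of points cross-classified by
#'   parameter-within-safe-range against StO2 >= 60%, one row per
#'   parameter, in the (tp, fp, fn, tn) orientation of
#'   [contingency_2x2()].
#' * `"equations"` - the published parameter-on-StO2 regression equations
#'   (rounded coefficients), their R^2 and the printed cutoff values at
#'   StO2 60-80%.
#' * `"parameter_summary"` - per-parameter mean, SD, range, 95% CI of the
#'   mean and the adopted safe cutoff.
#'
#' @param name One of `"contingency"`, `"equations"`,
#'   `"parameter_summary"`.
#' @return A data frame.
#' @examples
#' reference_table("contingency")
#' @export
reference_table <- function(name = c("contingency", "equations",
                                     "parameter_summary")) {
  name <- match.arg(name)
  file <- switch(name,
                 contingency = "reference_contingency.csv",
                 equations = "reference_equations.csv",
                 parameter_summary = "reference_parameter_summary.csv")
  path <- system.file("extdata", file, package = "icgperf", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
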