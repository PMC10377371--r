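# Registry of quantitative perfusion parameters: orientation and cutoffs.

#' Perfusion parameter registry
#'
#' Fixes, for each quantitative parameter, which direction means "good
#' perfusion" and the clinically used safe cutoff: the time parameters
#' (T_1/2MAX, T_MAX) and the perfusion time ratio are favourable when LOW
#' (`<=` cutoff), while F_MAX, slope and the NIR perfusion index are
#' favourable when HIGH. Tie handling mirrors the printed inequalities:
#' `<=` / `>=` are inclusive, F_MAX uses a strict `>`.
#'
#' @return A data frame with columns `parameter`, `label`, `direction`
#'   (one of `"le"`, `"ge"`, `"gt"`: the comparison placing a value inside
#'   the safe range), `cutoff` (the published safe value),
#'   `higher_is_better`, and `round_grid` (presentation rounding grid).
#' @examples
#' parameter_registry()
#' @export
parameter_registry <- function() {
  data.frame(
    parameter = c("t_half_s", "t_max_s", "perfusion_tr",
                  "f_max_au", "slope_au_per_s", "nir_index"),
    label = c("T_1/2MAX (s)", "T_MAX (s)", "Perfusion TR",
              "F_MAX (AU)", "Slope (AU/s)", "NIR perfusion index"),
    direction = c("le", "le", "le", "gt", "ge", "ge"),
    cutoff = c(10, 30, 0.8, 25, 5, 50),
    higher_is_better = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    round_grid = c(1, 5, 0.1, 5, 5, 5),
    stringsAsFactors = FALSE
  )
}

.registry_row <- function(parameter) {
  reg <- parameter_registry()
  i <- match(parameter, reg$parameter)
  if (is.na(i))
    stop(sprintf("unknown parameter '%s'; see parameter_registry()", parameter),
         call. = FALSE)
  reg[i, ]
}

#' Default safe cutoff set
#'
#' The published safe values used by the stepwise StO2 prediction
#' algorithm: T_1/2MAX <= 10 s, T_MAX <= 30 s, slope >= 5 AU/s.
#'
#' @return Named list with elements `t_half_s`, `t_max_s`,
#'   `slope_au_per_s`.
#' @export
safe_cutoffs <- function() {
  list(t_half_s = 10, t_max_s = 30, slope_au_per_s = 5)
}
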