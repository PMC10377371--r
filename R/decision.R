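# Intraoperative perfusion decision protocol and stepwise StO2 prediction.

#' Intraoperative perfusion decision protocol
#'
#' Encodes the two-stage intraoperative protocol combining hyperspectral
#' StO2 with the ICG T_1/2MAX. At the first assessment of the planned
#' transection line: StO2 above 60% with T_1/2MAX under 10 s indicates good
#' perfusion (proceed with anastomosis); StO2 below 50% with T_1/2MAX
#' delayed beyond 25 s indicates poor perfusion (move the transection line
#' proximally and re-assess); anything in between is an intermediate state
#' left to surgeon review. At the second assessment (after moving the
#' line), StO2 maintained at 60% or higher with T_1/2MAX within 25 s is
#' acceptable and anastomosis proceeds; otherwise the case remains poor
#' and returns to surgeon review. Boundary strictness follows the protocol
#' prose exactly (strict first-stage comparisons, inclusive second-stage
#' ones).
#'
#' @param sto2_pct Tissue oxygen saturation in percent (0-100). Vectorized.
#' @param t_half_s T_1/2MAX in seconds. Vectorized.
#' @param stage `"first"` or `"second"` assessment.
#' @return A data frame with columns `category` (`"good"`,
#'   `"acceptable_intermediate"`, `"poor"`) and `action`
#'   (`"proceed_anastomosis"`, `"move_transection_line"`,
#'   `"surgeon_review"`).
#' @examples
#' intraoperative_protocol(65, 8)                  # good, proceed
#' intraoperative_protocol(45, 30)                 # poor, move line
#' intraoperative_protocol(62, 20, stage = "second") # acceptable, proceed
#' @export
intraoperative_protocol <- function(sto2_pct, t_half_s,
                                    stage = c("first", "second")) {
  stage <- match.arg(stage)
  if (any(!is.finite(sto2_pct)) || any(sto2_pct < 0 | sto2_pct > 100))
    stop("sto2_pct must lie in [0, 100]", call. = FALSE)
  if (any(!is.finite(t_half_s)) || any(t_half_s <= 0))
    stop("t_half_s must be positive", call. = FALSE)
  n <- max(length(sto2_pct), length(t_half_s))
  s <- rep_len(sto2_pct, n); th <- rep_len(t_half_s, n)
  if (stage == "first") {
    category <- rep("acceptable_intermediate", n)
    action <- rep("surgeon_review", n)
    good <- s > 60 & th < 10
    poor <- s < 50 & th > 25
    category[good] <- "good"; action[good] <- "proceed_anastomosis"
    category[poor] <- "poor"; action[poor] <- "move_transection_line"
  } else {
    ok <- s >= 60 & th <= 25
    category <- ifelse(ok, "acceptable_intermediate", "poor")
    action <- ifelse(ok, "proceed_anastomosis", "surgeon_review")
  }
  data.frame(category = category, action = action)
}

#' Stepwise prediction of tissue oxygenation class from ICG parameters
#'
#' The step-by-step reading of the quantitative parameters: when both time
#' parameters lie within their safe ranges (T_1/2MAX <= 10 s and
#' T_MAX <= 30 s) tissue oxygenation is predicted adequate (StO2 >= 60%);
#' when both are outside, it is predicted poor; when exactly one is
#' within, the slope adjudicates (slope >= 5 AU/s predicts adequate).
#'
#' @param t_half_s,t_max_s,slope_au_per_s Parameter values (vectorized,
#'   finite).
#' @param cutoffs Named list with entries `t_half_s`, `t_max_s` and
#'   `slope_au_per_s` (default [safe_cutoffs()]).
#' @return Character vector, `">=60"` or `"<60"`.
#' @examples
#' stepwise_prediction(6, 18, 12)  # ">=60"
#' stepwise_prediction(20, 50, 12) # "<60"
#' stepwise_prediction(8, 40, 3)   # "<60" (discordant, slope decides)
#' @export
stepwise_prediction <- function(t_half_s, t_max_s, slope_au_per_s,
                                cutoffs = safe_cutoffs()) {
  need <- c("t_half_s", "t_max_s", "slope_au_per_s")
  if (!all(need %in% names(cutoffs)) ||
      !all(vapply(cutoffs[need], is.finite, logical(1))))
    stop("cutoffs must contain finite t_half_s, t_max_s and slope_au_per_s entries",
         call. = FALSE)
  n <- max(length(t_half_s), length(t_max_s), length(slope_au_per_s))
  th <- rep_len(t_half_s, n); tm <- rep_len(t_max_s, n)
  sl <- rep_len(slope_au_per_s, n)
  if (any(!is.finite(th)) || any(!is.finite(tm)) || any(!is.finite(sl)))
    stop("parameters must be finite", call. = FALSE)
  n_within <- (th <= cutoffs$t_half_s) + (tm <= cutoffs$t_max_s)
  ifelse(n_within == 2L, ">=60",
         ifelse(n_within == 0L, "<60",
                ifelse(sl >= cutoffs$slope_au_per_s, ">=60", "<60")))
}
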