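# Seeded synthetic cohorts, bolus curves and frame stacks.
#
# The cohort generator emulates the structure of a 68-patient x 5-point
# intraoperative perfusion study: a high-StO2 bulk with a small low-StO2
# contamination, perfusion parameters tied to StO2 through published-style
# linear regressions, and physical floors (times > 0, TR in (0,1]).
# Because flooring censors a Gaussian residual, the generator calibrates
# its LATENT line and noise SD so that the OBSERVED cohort's OLS fit
# reproduces the configured equations and R^2 (see the methods vignette).

#' Configuration of a synthetic perfusion cohort
#'
#' Defaults emulate the reference study design: 68 patients x 5 colonic
#' assessment points; StO2 mostly between 60 and 98% with a fixed
#' 11-in-340 share of low-oxygenation points (20-60%); T_1/2MAX, T_MAX,
#' slope and NIR perfusion index tied to StO2 through the published linear
#' equations at their published R^2; F_MAX drawn independently of StO2
#' (it showed no discrimination); binary covariates at roughly the
#' published prevalences.
#'
#' @param n_patients Number of patients (default 68).
#' @param points_per_patient Assessment points per patient (default 5).
#' @param sto2_mean,sto2_sd,sto2_range Truncated-normal parameters of the
#'   well-oxygenated bulk (defaults 82, 8, \[60, 98\]).
#' @param low_fraction Share of low-StO2 points; the realized count is
#'   `round(low_fraction * n)` (default 11/340).
#' @param low_mean,low_sd,low_range Truncated-normal parameters of the
#'   low-StO2 component (defaults 45, 9, \[20, 59.9\]).
#' @param patient_sd SD of the patient-level random intercept on StO2
#'   (default 4%), acknowledging the clustered 5-points-per-patient
#'   design.
#' @param truth Named list of regression truths; each entry has `coef`
#'   (intercept, StO2 slope) and `r2` (target coefficient of
#'   determination of the observed fit).
#' @param f_max Truncated-normal parameters (mean, sd, min, max) for the
#'   StO2-independent F_MAX draw.
#' @param noise_scale Multiplier on all residual SDs; 0 generates
#'   noise-free points exactly on the truth lines (no calibration, no
#'   censoring expected).
#' @param noise_cor Correlation between the T_1/2MAX and T_MAX latent
#'   residuals (default 0.6): when flow is poor both times delay
#'   together.
#' @param floors Physical lower bounds for `t_half_s`, `t_max_s`,
#'   `slope_au_per_s`.
#' @param nir_range Bounds for the NIR perfusion index.
#' @param tr_cap Maximum admissible time ratio; `t_half_s` is capped at
#'   `tr_cap * t_max_s` so every point is feasible for the gamma-variate
#'   curve family (default 0.98).
#' @param covariates Named vector of binary-covariate prevalences
#'   (patient level).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 68,
                          points_per_patient = 5,
                          sto2_mean = 82, sto2_sd = 8, sto2_range = c(60, 98),
                          low_fraction = 11 / 340,
                          low_mean = 45, low_sd = 9, low_range = c(20, 59.9),
                          patient_sd = 4,
                          truth = list(
                            t_half_s = list(coef = c(26.351, -0.267), r2 = 0.183),
                            t_max_s = list(coef = c(76.287, -0.785), r2 = 0.250),
                            slope_au_per_s = list(coef = c(-2.236, 0.144), r2 = 0.025),
                            nir_index = list(coef = c(10.515, 0.699), r2 = 0.152)),
                          f_max = c(mean = 97.21, sd = 37,
                                    min = 7.62, max = 199.01),
                          noise_scale = 1,
                          noise_cor = 0.6,
                          floors = c(t_half_s = 0.03, t_max_s = 1.5,
                                     slope_au_per_s = 0.33),
                          nir_range = c(1, 99),
                          tr_cap = 0.98,
                          covariates = c(age_ge70 = 30 / 68, male = 47 / 68,
                                         bmi_ge25 = 23 / 68, asa_ge3 = 9 / 68,
                                         hypertension = 30 / 68,
                                         diabetes = 14 / 68, pcrt = 9 / 68,
                                         high_ligation = 40 / 68,
                                         diverting_ileostomy = 24 / 68,
                                         anastomotic_complication = 5 / 68)) {
  cfg <- list(n_patients = n_patients, points_per_patient = points_per_patient,
              sto2_mean = sto2_mean, sto2_sd = sto2_sd, sto2_range = sto2_range,
              low_fraction = low_fraction, low_mean = low_mean,
              low_sd = low_sd, low_range = low_range, patient_sd = patient_sd,
              truth = truth, f_max = f_max, noise_scale = noise_scale,
              noise_cor = noise_cor, floors = floors, nir_range = nir_range,
              tr_cap = tr_cap, covariates = covariates)
  .validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

.validate_cohort_config <- function(cfg) {
  ok <- cfg$n_patients >= 1 && cfg$points_per_patient >= 1 &&
    cfg$sto2_sd > 0 && cfg$low_sd > 0 &&
    cfg$sto2_range[1] < cfg$sto2_range[2] &&
    cfg$low_range[1] < cfg$low_range[2] &&
    cfg$low_fraction >= 0 && cfg$low_fraction < 1 &&
    cfg$patient_sd >= 0 && cfg$noise_scale >= 0 &&
    abs(cfg$noise_cor) <= 1 && cfg$tr_cap > 0 && cfg$tr_cap <= 1 &&
    all(cfg$sto2_range >= 0) && all(cfg$sto2_range <= 100) &&
    all(cfg$low_range >= 0) && all(cfg$low_range <= 100) &&
    cfg$f_max[["sd"]] > 0 && cfg$f_max[["min"]] > 0 &&
    cfg$f_max[["min"]] < cfg$f_max[["max"]] &&
    all(cfg$covariates >= 0) && all(cfg$covariates <= 1)
  if (!ok) stop("invalid cohort configuration", call. = FALSE)
  invisible(cfg)
}

# truncated-normal sampler via inverse-CDF (vectorized in mean)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# StO2 + latent-normal draws shared by calibration and generation.
# Returns sto2 plus the four standard-normal residual drivers.
.draw_cohort_base <- function(cfg, n_patients) {
  ppp <- cfg$points_per_patient
  n <- n_patients * ppp
  u <- rep(stats::rnorm(n_patients, 0, cfg$patient_sd), each = ppp)
  n_low <- round(cfg$low_fraction * n)
  low <- rep(FALSE, n)
  if (n_low > 0) low[sample.int(n, n_low)] <- TRUE
  sto2 <- numeric(n)
  if (any(!low))
    sto2[!low] <- .rtruncnorm(sum(!low), cfg$sto2_mean + u[!low], cfg$sto2_sd,
                              cfg$sto2_range[1], cfg$sto2_range[2])
  if (any(low))
    sto2[low] <- .rtruncnorm(sum(low), cfg$low_mean + u[low], cfg$low_sd,
                             cfg$low_range[1], cfg$low_range[2])
  list(sto2 = sto2, low = low,
       z = matrix(stats::rnorm(4 * n), n, 4,
                  dimnames = list(NULL, c("t_half_s", "t_max_s",
                                          "slope_au_per_s", "nir_index"))))
}

# observed parameters from latent lines + floors/cap; latents is a named
# list of c(intercept, slope, sd)
.apply_latents <- function(latents, sto2, z, cfg) {
  line <- function(p, l) l[1] + l[2] * sto2
  zc <- cfg$noise_cor * z[, "t_half_s"] +
    sqrt(1 - cfg$noise_cor^2) * z[, "t_max_s"]
  th <- line("t_half_s", latents$t_half_s) +
    latents$t_half_s[3] * z[, "t_half_s"]
  tm <- line("t_max_s", latents$t_max_s) + latents$t_max_s[3] * zc
  sl <- line("slope_au_per_s", latents$slope_au_per_s) +
    latents$slope_au_per_s[3] * z[, "slope_au_per_s"]
  nir <- line("nir_index", latents$nir_index) +
    latents$nir_index[3] * z[, "nir_index"]
  th <- pmax(th, cfg$floors[["t_half_s"]])
  tm <- pmax(tm, cfg$floors[["t_max_s"]])
  th <- pmin(th, cfg$tr_cap * tm)
  sl <- pmax(sl, cfg$floors[["slope_au_per_s"]])
  nir <- pmin(pmax(nir, cfg$nir_range[1]), cfg$nir_range[2])
  data.frame(t_half_s = th, t_max_s = tm, slope_au_per_s = sl,
             nir_index = nir)
}

.ols_line <- function(y, x) {
  f <- stats::lm.fit(cbind(1, x), y)
  r2 <- 1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  c(f$coefficients[1], f$coefficients[2], r2)
}

# cache of calibrated latents keyed by the config fields that matter
.calib_cache <- new.env(parent = emptyenv())

# Fixed-point calibration: adjust latent (intercept, slope, sd) per
# parameter until the OLS fit of the OBSERVED (floored/capped) values on
# StO2, over a large internal reference draw, matches the configured truth
# coefficients and R^2. Deterministic: uses its own RNG stream.
.calibrate_latents <- function(cfg, n_cal = 60000L, iters = 40L,
                               damp = 0.8) {
  key <- paste(deparse(cfg[setdiff(names(cfg), "covariates")],
                       control = "all"), collapse = "")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(990001L)
  ref <- .draw_cohort_base(cfg, max(2L, ceiling(n_cal / cfg$points_per_patient)))
  params <- names(cfg$truth)
  sd0 <- function(tr) stats::sd(tr$coef[1] + tr$coef[2] * ref$sto2) *
    sqrt((1 - tr$r2) / tr$r2) * cfg$noise_scale
  latents <- lapply(cfg$truth, function(tr) c(tr$coef, sd0(tr)))
  for (it in seq_len(iters)) {
    obs <- .apply_latents(latents, ref$sto2, ref$z, cfg)
    for (p in params) {
      f <- .ols_line(obs[[p]], ref$sto2)
      tgt <- cfg$truth[[p]]
      latents[[p]][1] <- latents[[p]][1] + damp * (tgt$coef[1] - f[1])
      latents[[p]][2] <- latents[[p]][2] + damp * (tgt$coef[2] - f[2])
      if (f[3] > 0 && f[3] < 1)
        latents[[p]][3] <- latents[[p]][3] *
          (((1 - tgt$r2) / tgt$r2) / ((1 - f[3]) / f[3]))^(damp / 2)
    }
  }
  .calib_cache[[key]] <- latents
  latents
}

#' Generate a synthetic cohort of assessment points
#'
#' Draws a full assessment-point table: per-patient covariates and random
#' intercept, per-point StO2 from a two-component truncated-normal mixture
#' (well-oxygenated bulk plus a fixed number of low-StO2 points), and the
#' ICG parameters from their configured regression truths with Gaussian
#' latent noise, floored at physical bounds and with T_1/2MAX capped below
#' T_MAX. F_MAX is drawn independently of StO2. The latent lines are
#' internally calibrated so that the observed cohort's OLS regressions
#' reproduce the configured equations and R^2 despite the censoring (see
#' the methods vignette); with `noise_scale = 0` the parameters fall
#' exactly on the truth lines.
#'
#' Identical `config` and `seed` give a bit-identical table.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed for the cohort draw.
#' @return A data frame with one row per assessment point: `patient_id`,
#'   `point_id`, `sto2_pct`, `nir_index`, `t_half_s`, `t_max_s`,
#'   `perfusion_tr`, `f_max_au`, `slope_au_per_s`, plus the binary
#'   covariate columns.
#' @examples
#' pts <- generate_cohort(cohort_config(n_patients = 4), seed = 1)
#' head(pts)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  .validate_cohort_config(config)
  latents <- if (config$noise_scale > 0) .calibrate_latents(config) else
    lapply(config$truth, function(tr) c(tr$coef, 0))
  set.seed(seed)
  n_pat <- config$n_patients; ppp <- config$points_per_patient
  n <- n_pat * ppp
  base <- .draw_cohort_base(config, n_pat)
  obs <- .apply_latents(latents, base$sto2, base$z, config)
  fm <- .rtruncnorm(n, config$f_max[["mean"]], config$f_max[["sd"]],
                    config$f_max[["min"]], config$f_max[["max"]])
  cov <- as.data.frame(lapply(config$covariates, function(pr)
    rep(as.integer(stats::runif(n_pat) < pr), each = ppp)))
  out <- data.frame(patient_id = rep(seq_len(n_pat), each = ppp),
                    point_id = rep(seq_len(ppp), times = n_pat),
                    sto2_pct = base$sto2,
                    nir_index = obs$nir_index,
                    t_half_s = obs$t_half_s,
                    t_max_s = obs$t_max_s,
                    perfusion_tr = obs$t_half_s / obs$t_max_s,
                    f_max_au = fm,
                    slope_au_per_s = obs$slope_au_per_s)
  cbind(out, cov)
}

#' Gamma-variate shape parameter for a target time ratio
#'
#' The normalized gamma-variate rise `g(x) = x^alpha exp(alpha (1 - x))`
#' (peak 1 at `x = 1`) crosses one half at the fraction `x` of the rise
#' time satisfying `alpha (log x + 1 - x) = log(1/2)`, so the shape that
#' realizes a target time ratio TR = T_1/2MAX / T_MAX is available in
#' closed form: `alpha = log(2) / (TR - 1 - log(TR))`.
#'
#' @param tr Target time ratio, in (0, 1); values above 0.995 need an
#'   astronomically flat curve foot and are rejected as infeasible
#'   (error class `icg_infeasible_target`).
#' @return The shape parameter `alpha` (positive scalar).
#' @examples
#' solve_gamma_shape(0.5)
#' @export
solve_gamma_shape <- function(tr) {
  if (!is.finite(tr) || tr <= 0 || tr >= 1 || tr > 0.995)
    stop(structure(class = c("icg_infeasible_target", "error", "condition"),
                   list(message = sprintf(
                     "infeasible time ratio %.4g for the gamma-variate family (need 0 < TR <= 0.995)",
                     tr), call = sys.call(-1))))
  log(2) / (tr - 1 - log(tr))
}

#' Normalized gamma-variate rise
#'
#' @param x Fraction of the rise time (vectorized); the rise is 0 for
#'   `x <= 0`, peaks at 1 for `x = 1`, and is held at 1 beyond the peak
#'   (plateau/recirculation phase).
#' @param alpha Shape parameter (see [solve_gamma_shape()]).
#' @return `g(x)` in \[0, 1\].
#' @export
gamma_variate_rise <- function(x, alpha) {
  g <- numeric(length(x))
  rising <- is.finite(x) & x > 0 & x < 1
  g[rising] <- exp(alpha * (log(x[rising]) + 1 - x[rising]))
  g[x >= 1] <- 1
  g
}

#' Generate a synthetic bolus fluorescence curve
#'
#' Builds a gamma-variate bolus curve realizing target perfusion
#' parameters exactly (before sampling and noise): peak `f_max_au` above
#' baseline at `t0_s + t_max_s`, half-maximum upward crossing at
#' `t0_s + t_half_s` (shape solved in closed form from the time ratio),
#' flat plateau after the peak, sampled at `frame_rate_hz` with optional
#' Gaussian noise.
#'
#' @param t_max_s,t_half_s,f_max_au Target parameters (see
#'   [perfusion_parameters()]); also accepted bundled as a
#'   `perfusion_parameters` object in `target`.
#' @param target Optional [perfusion_parameters()] object overriding the
#'   three scalars.
#' @param t0_s Bolus arrival (onset) time, seconds (default 10).
#' @param duration_s Observation window length (default 120 s); must
#'   cover `t0_s + t_max_s`.
#' @param frame_rate_hz Sampling rate (default 4 Hz).
#' @param noise_sd_au SD of additive Gaussian noise (default 0).
#' @param baseline_au Constant baseline offset (default 0).
#' @param plateau_decay_au_per_s Linear post-peak washout rate (default 0:
#'   the recirculation plateau is held flat at the peak). A mild decay
#'   makes the peak time identifiable under noise; the decay is floored at
#'   half the peak so it never interferes with the upward half-maximum
#'   crossing.
#' @param seed Optional seed for the noise draw.
#' @param point_id Curve identifier.
#' @return A [fluorescence_curve()].
#' @export
generate_curve <- function(t_max_s, t_half_s, f_max_au, target = NULL,
                           t0_s = 10, duration_s = 120, frame_rate_hz = 4,
                           noise_sd_au = 0, baseline_au = 0,
                           plateau_decay_au_per_s = 0, seed = NULL,
                           point_id = "p1") {
  if (!is.null(target)) {
    stopifnot(inherits(target, "perfusion_parameters"))
    t_max_s <- target$t_max_s; t_half_s <- target$t_half_s
    f_max_au <- target$f_max_au
  }
  if (f_max_au <= 0 || t_half_s <= 0 || t_half_s > t_max_s)
    stop("targets must satisfy f_max_au > 0 and 0 < t_half_s <= t_max_s",
         call. = FALSE)
  if (duration_s <= t0_s + t_max_s)
    stop("duration_s must cover onset + t_max_s", call. = FALSE)
  alpha <- solve_gamma_shape(t_half_s / t_max_s)
  time_s <- seq(0, duration_s, by = 1 / frame_rate_hz)
  rise <- f_max_au * gamma_variate_rise((time_s - t0_s) / t_max_s, alpha)
  if (plateau_decay_au_per_s > 0) {
    past <- pmax(time_s - t0_s - t_max_s, 0)
    rise <- pmax(rise - plateau_decay_au_per_s * past,
                 ifelse(past > 0, f_max_au / 2, 0))
  }
  y <- baseline_au + rise
  if (noise_sd_au > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- pmax(y + stats::rnorm(length(y), 0, noise_sd_au), 0)
  }
  fluorescence_curve(time_s, y, point_id)
}

#' Generate a synthetic fluorescence frame stack
#'
#' Builds a multi-frame image sequence in which each disc ROI carries one
#' input curve (all curves must share the same time stamps) over a
#' constant background, with optional per-pixel Gaussian noise. The ROI
#' mean of the returned stack reproduces each curve up to noise (and, if
#' written to TIFF, quantization).
#'
#' @param curves List of [fluorescence_curve()] objects with identical
#'   `time_s`.
#' @param roi Optional data frame `point_id,x_px,y_px,radius_px`; by
#'   default discs of radius 3 are placed on a grid. ROIs must be
#'   disjoint and fully in-bounds.
#' @param frame_shape `c(height, width)` in pixels (default 48 x 48).
#' @param background_au Constant background level (default 5).
#' @param noise_sd_au SD of per-pixel Gaussian noise (default 0).
#' @param seed Optional seed for the noise draw.
#' @return List with `stack` (a [frame_stack()]) and `roi` (the ROI
#'   table).
#' @export
generate_frame_stack <- function(curves, roi = NULL, frame_shape = c(48, 48),
                                 background_au = 5, noise_sd_au = 0,
                                 seed = NULL) {
  if (inherits(curves, "fluorescence_curve")) curves <- list(curves)
  times <- lapply(curves, `[[`, "time_s")
  if (length(unique(lapply(times, as.numeric))) != 1L)
    stop("all curves must share the same time stamps", call. = FALSE)
  time_s <- times[[1]]
  h <- frame_shape[1]; w <- frame_shape[2]
  if (is.null(roi)) {
    r <- 3
    per_row <- max(1L, floor((w - 2) / (2 * r + 4)))
    idx <- seq_along(curves) - 1L
    roi <- data.frame(
      point_id = vapply(curves, function(cv) as.character(cv$point_id),
                        character(1)),
      x_px = 2 + r + (idx %% per_row) * (2 * r + 4),
      y_px = 2 + r + (idx %/% per_row) * (2 * r + 4),
      radius_px = r)
  }
  if (nrow(roi) != length(curves))
    stop("need one ROI per curve", call. = FALSE)
  if (any(roi$x_px - roi$radius_px < 1) || any(roi$x_px + roi$radius_px > w) ||
      any(roi$y_px - roi$radius_px < 1) || any(roi$y_px + roi$radius_px > h))
    stop("ROI out of bounds for the requested frame shape", call. = FALSE)
  if (nrow(roi) > 1) {
    for (i in seq_len(nrow(roi) - 1)) for (j in (i + 1):nrow(roi)) {
      d <- sqrt((roi$x_px[i] - roi$x_px[j])^2 + (roi$y_px[i] - roi$y_px[j])^2)
      if (d <= roi$radius_px[i] + roi$radius_px[j])
        stop("overlapping ROIs", call. = FALSE)
    }
  }
  n <- length(time_s)
  frames <- array(background_au, dim = c(h, w, n))
  masks <- lapply(seq_len(nrow(roi)), function(i)
    .disc_mask(h, w, roi$x_px[i], roi$y_px[i], roi$radius_px[i]))
  for (k in seq_len(n)) {
    fr <- frames[, , k]
    for (i in seq_along(curves)) fr[masks[[i]]] <- curves[[i]]$intensity_au[k]
    frames[, , k] <- fr
  }
  if (noise_sd_au > 0) {
    if (!is.null(seed)) set.seed(seed)
    frames <- pmax(frames + array(stats::rnorm(length(frames), 0, noise_sd_au),
                                  dim = dim(frames)), 0)
  }
  list(stack = frame_stack(frames, time_s), roi = roi)
}
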