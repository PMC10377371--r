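# Time-fluorescence curve container and bolus kinetics extraction.

#' Construct a fluorescence curve
#'
#' A `fluorescence_curve` is a sampled time-intensity trace for a single
#' colonic assessment point over the angiography observation window
#' (typically 2 minutes). Time stamps must be strictly increasing and
#' intensities finite and non-negative; sampling need not be uniform.
#'
#' @param time_s Numeric vector of time stamps in seconds, strictly
#'   increasing, length at least 3.
#' @param intensity_au Numeric vector of fluorescence intensities in
#'   arbitrary camera units (AU), same length as `time_s`.
#' @param point_id Identifier of the assessment point (scalar).
#' @return An object of class `fluorescence_curve`: a list with elements
#'   `time_s`, `intensity_au` and `point_id`.
#' @examples
#' cv <- fluorescence_curve(0:30, c(rep(0, 10), seq(0, 100, length.out = 21)))
#' print(cv)
#' @export
fluorescence_curve <- function(time_s, intensity_au, point_id = "p1") {
  time_s <- as.numeric(time_s)
  intensity_au <- as.numeric(intensity_au)
  if (length(time_s) != length(intensity_au))
    stop("time_s and intensity_au must have the same length", call. = FALSE)
  if (length(time_s) < 3L)
    stop("a fluorescence curve needs at least 3 samples", call. = FALSE)
  if (any(!is.finite(time_s)) || any(diff(time_s) <= 0))
    stop("time_s must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(intensity_au)) || any(intensity_au < 0))
    stop("intensity_au must be finite and non-negative", call. = FALSE)
  structure(list(time_s = time_s, intensity_au = intensity_au,
                 point_id = point_id),
            class = "fluorescence_curve")
}

#' @export
print.fluorescence_curve <- function(x, ...) {
  cat(sprintf("<fluorescence_curve> point %s: %d samples, %.1f-%.1f s, %.1f-%.1f AU\n",
              x$point_id, length(x$time_s), min(x$time_s), max(x$time_s),
              min(x$intensity_au), max(x$intensity_au)))
  invisible(x)
}

#' @export
as.data.frame.fluorescence_curve <- function(x, ...) {
  data.frame(point_id = x$point_id, time_s = x$time_s,
             intensity_au = x$intensity_au)
}

#' Smooth a fluorescence curve with a centred moving average
#'
#' Each sample is replaced by the mean of all samples whose time stamp lies
#' within `window_s / 2` of it. This is a time-window (not sample-count)
#' average, so irregular sampling is handled correctly. A zero-width window
#' returns the input unchanged.
#'
#' @param curve A [fluorescence_curve()].
#' @param window_s Full window width in seconds (non-negative, shorter than
#'   the observation span).
#' @return A `fluorescence_curve` with identical time stamps.
#' @export
smooth_curve <- function(curve, window_s) {
  stopifnot(inherits(curve, "fluorescence_curve"))
  if (!is.finite(window_s) || window_s < 0)
    stop("window_s must be a non-negative number", call. = FALSE)
  if (window_s == 0) return(curve)
  span <- max(curve$time_s) - min(curve$time_s)
  if (window_s >= span)
    stop("invalid window: window_s must be shorter than the observation span",
         call. = FALSE)
  t <- curve$time_s
  half <- window_s / 2
  # window bounds per sample via sorted-time two-pointer lookup
  lo <- findInterval(t - half, t, left.open = TRUE) + 1L
  hi <- findInterval(t + half, t)
  cs <- c(0, cumsum(curve$intensity_au))
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  fluorescence_curve(t, sm, curve$point_id)
}

#' Detect the bolus arrival (onset) time of a fluorescence curve
#'
#' The onset is the paper-charted "first fluorescence increase": the earliest
#' time at which intensity exceeds the baseline mean plus `k_sd` baseline
#' standard deviations and stays above that threshold for `min_run`
#' consecutive samples. Baseline statistics are computed over the first
#' `baseline_window_s` seconds of the trace, which must precede any rise.
#'
#' @param curve A [fluorescence_curve()].
#' @param baseline_window_s Length of the baseline window in seconds
#'   (default 5); it must contain at least 3 samples.
#' @param k_sd Threshold in baseline standard deviations above the baseline
#'   mean (default 3).
#' @param min_run Number of consecutive supra-threshold samples required
#'   (default 3); guards against single-frame noise spikes.
#' @return Onset time in seconds (on the curve's absolute time axis).
#'   If no run of samples ever satisfies the criterion an error of class
#'   `icg_no_onset` is signalled (a flat, non-perfused trace).
#' @export
detect_onset <- function(curve, baseline_window_s = 5, k_sd = 3, min_run = 3) {
  stopifnot(inherits(curve, "fluorescence_curve"))
  if (baseline_window_s <= 0)
    stop("baseline_window_s must be positive", call. = FALSE)
  base_idx <- which(curve$time_s <= curve$time_s[1] + baseline_window_s)
  if (length(base_idx) < 3L)
    stop("baseline window must contain at least 3 samples", call. = FALSE)
  y <- curve$intensity_au
  thr <- mean(y[base_idx]) + k_sd * stats::sd(y[base_idx])
  above <- y > thr
  n <- length(y)
  min_run <- max(1L, as.integer(min_run))
  if (min_run > n) stop("min_run exceeds the number of samples", call. = FALSE)
  # earliest index starting a run of >= min_run supra-threshold samples
  ok <- vapply(seq_len(n - min_run + 1L),
               function(i) all(above[i:(i + min_run - 1L)]), logical(1))
  if (!any(ok)) {
    stop(structure(class = c("icg_no_onset", "error", "condition"),
                   list(message = "no onset: intensity never sustainably exceeds baseline",
                        call = sys.call(-1))))
  }
  curve$time_s[which(ok)[1]]
}

#' Construct a set of perfusion parameters
#'
#' Bundles the five quantitative ICG angiography parameters for one
#' assessment point and validates their defining identities:
#' `perfusion_tr = t_half_s / t_max_s` and
#' `slope_au_per_s = f_max_au / t_max_s`. Both time parameters are measured
#' from the bolus onset, so `0 < t_half_s <= t_max_s` and the time ratio
#' lies in (0, 1].
#'
#' @param t_max_s Time from onset to maximal fluorescence (T_MAX), seconds.
#' @param t_half_s Time from onset to half-maximal fluorescence (T_1/2MAX),
#'   seconds.
#' @param f_max_au Maximal fluorescence intensity above baseline (F_MAX), AU.
#' @param t_onset_s Absolute onset time on the curve's time axis, seconds.
#' @param point_id Assessment point identifier.
#' @return An object of class `perfusion_parameters` with fields
#'   `t_onset_s`, `t_max_s`, `t_half_s`, `perfusion_tr`, `f_max_au` and
#'   `slope_au_per_s`.
#' @examples
#' p <- perfusion_parameters(t_max_s = 30, t_half_s = 10, f_max_au = 150)
#' p$perfusion_tr   # 10/30
#' p$slope_au_per_s # 150/30
#' @export
perfusion_parameters <- function(t_max_s, t_half_s, f_max_au,
                                 t_onset_s = 0, point_id = "p1") {
  if (!is.finite(t_max_s) || !is.finite(t_half_s) || !is.finite(f_max_au))
    stop("perfusion parameters must be finite", call. = FALSE)
  if (f_max_au <= 0) stop("f_max_au must be positive", call. = FALSE)
  if (t_half_s <= 0 || t_half_s > t_max_s)
    stop("t_half_s must satisfy 0 < t_half_s <= t_max_s", call. = FALSE)
  structure(list(t_onset_s = t_onset_s,
                 t_max_s = t_max_s,
                 t_half_s = t_half_s,
                 perfusion_tr = t_half_s / t_max_s,
                 f_max_au = f_max_au,
                 slope_au_per_s = f_max_au / t_max_s,
                 point_id = point_id),
            class = "perfusion_parameters")
}

#' @export
print.perfusion_parameters <- function(x, ...) {
  cat(sprintf(paste0("<perfusion_parameters> point %s: onset %.2f s, ",
                     "T_MAX %.2f s, T_1/2MAX %.2f s, TR %.3f, ",
                     "F_MAX %.1f AU, slope %.2f AU/s\n"),
              x$point_id, x$t_onset_s, x$t_max_s, x$t_half_s,
              x$perfusion_tr, x$f_max_au, x$slope_au_per_s))
  invisible(x)
}

#' @export
as.data.frame.perfusion_parameters <- function(x, ...) {
  data.frame(point_id = x$point_id, t_onset_s = x$t_onset_s,
             t_max_s = x$t_max_s, t_half_s = x$t_half_s,
             perfusion_tr = x$perfusion_tr, f_max_au = x$f_max_au,
             slope_au_per_s = x$slope_au_per_s)
}

#' Extract quantitative perfusion parameters from a fluorescence curve
#'
#' Implements the time-fluorescence intensity graph analysis: F_MAX is the
#' curve maximum minus the baseline mean (removing the ambient-light
#' offset); T_MAX is the elapsed time from onset to the *first* attainment
#' of the maximum (plateaus and saturated sensors are common); T_1/2MAX is
#' the elapsed time from onset to the first upward crossing of
#' baseline + F_MAX/2, linearly interpolated between the bracketing
#' samples; the perfusion time ratio and slope follow from their defining
#' identities.
#'
#' The onset and baseline are normally estimated with [detect_onset()];
#' both can be overridden for curves that start mid-rise or whose baseline
#' is known externally.
#'
#' @param curve A [fluorescence_curve()].
#' @param baseline_window_s,k_sd,min_run Onset-detection settings passed to
#'   [detect_onset()].
#' @param smooth_window_s Optional moving-average window applied before
#'   onset detection (default 0, no smoothing). Parameters are always
#'   extracted from the unsmoothed intensities.
#' @param t_onset_s Optional explicit onset time; skips detection.
#' @param baseline_au Optional explicit baseline intensity; defaults to the
#'   baseline-window mean (or the pre-onset mean when `t_onset_s` is given).
#' @return A [perfusion_parameters()] object.
#' @details A curve whose maximum is only attained at the final sample is
#'   treated as truncated before its plateau and signalled as an error of
#'   class `icg_degenerate_curve` (no extrapolation is attempted), as is a
#'   curve whose maximum does not rise above baseline or occurs at/before
#'   onset.
#' @export
extract_parameters <- function(curve, baseline_window_s = 5, k_sd = 3,
                               min_run = 3, smooth_window_s = 0,
                               t_onset_s = NULL, baseline_au = NULL) {
  stopifnot(inherits(curve, "fluorescence_curve"))
  t <- curve$time_s; y <- curve$intensity_au
  if (is.null(t_onset_s)) {
    det <- if (smooth_window_s > 0) smooth_curve(curve, smooth_window_s) else curve
    t_onset_s <- detect_onset(det, baseline_window_s, k_sd, min_run)
  }
  if (is.null(baseline_au)) {
    pre <- which(t <= min(t[1] + baseline_window_s, t_onset_s))
    if (!length(pre)) pre <- 1L
    baseline_au <- mean(y[pre])
  }
  degenerate <- function(msg)
    stop(structure(class = c("icg_degenerate_curve", "error", "condition"),
                   list(message = msg, call = sys.call(-2))))
  from <- which(t >= t_onset_s)
  ymax <- max(y[from])
  f_max <- ymax - baseline_au
  if (f_max <= 0) degenerate("degenerate curve: maximum does not exceed baseline")
  i_peak <- from[which(y[from] == ymax)[1]]
  if (i_peak == length(t))
    degenerate("degenerate curve: maximum at the final sample (truncated before plateau)")
  t_peak <- t[i_peak]
  if (t_peak <= t_onset_s)
    degenerate("degenerate curve: maximum at or before onset")
  half_level <- baseline_au + f_max / 2
  t_half_abs <- .first_upward_crossing(t, y, half_level, from[1], i_peak)
  if (t_half_abs <= t_onset_s) t_half_abs <- t_onset_s + .Machine$double.eps * 100
  perfusion_parameters(t_max_s = t_peak - t_onset_s,
                       t_half_s = t_half_abs - t_onset_s,
                       f_max_au = f_max,
                       t_onset_s = t_onset_s,
                       point_id = curve$point_id)
}

# first upward crossing of `level` between indices i0..i1, linear in time
.first_upward_crossing <- function(t, y, level, i0, i1) {
  for (j in i0:i1) {
    if (y[j] >= level) {
      if (j == i0 || y[j - 1] >= level) return(t[j])
      # interpolate between the bracketing samples
      return(t[j - 1] + (level - y[j - 1]) / (y[j] - y[j - 1]) * (t[j] - t[j - 1]))
    }
  }
  t[i1]
}

#' Read fluorescence curves from CSV
#'
#' Accepts either a two-column file `time_s,intensity_au` (one curve) or a
#' long-format file `point_id,time_s,intensity_au` (several curves).
#'
#' @param path CSV file path.
#' @return A list of [fluorescence_curve()] objects, named by point id.
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "intensity_au") %in% names(df)))
    stop("curve CSV needs columns time_s and intensity_au", call. = FALSE)
  if (!"point_id" %in% names(df)) df$point_id <- "p1"
  out <- lapply(split(df, df$point_id), function(d)
    fluorescence_curve(d$time_s, d$intensity_au, d$point_id[1]))
  out[order(names(out))]
}

#' Write fluorescence curves to a long-format CSV
#'
#' @param curves A single [fluorescence_curve()] or a list of them.
#' @param path Output CSV path (columns `point_id,time_s,intensity_au`).
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  if (inherits(curves, "fluorescence_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
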