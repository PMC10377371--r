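# Frame-stack container and region-of-interest time-series extraction.

#' Construct a fluorescence frame stack
#'
#' @param frames A numeric `height x width x n_frames` array of pixel
#'   intensities (AU), or a list of equally sized matrices.
#' @param time_s Frame time stamps in seconds (strictly increasing, one per
#'   frame).
#' @return An object of class `frame_stack` with elements `frames` (array)
#'   and `time_s`.
#' @export
frame_stack <- function(frames, time_s) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("all frames must have the same size", call. = FALSE)
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3L)
    stop("frames must be a height x width x n_frames array", call. = FALSE)
  if (dim(frames)[3] < 3L) stop("a frame stack needs at least 3 frames", call. = FALSE)
  if (length(time_s) != dim(frames)[3] || any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing with one entry per frame", call. = FALSE)
  structure(list(frames = frames, time_s = as.numeric(time_s)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d px, %.1f-%.1f s\n",
              d[3], d[1], d[2], min(x$time_s), max(x$time_s)))
  invisible(x)
}

# logical disc mask; x = column, y = row, 1-based pixel centres
.disc_mask <- function(height, width, x, y, radius) {
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  rows <- matrix(seq_len(height), height, width)
  (cols - x)^2 + (rows - y)^2 <= radius^2
}

#' Extract a ROI mean-intensity time series from a frame stack
#'
#' Realizes the manual point selection along the colon segment: the trace is
#' the per-frame mean intensity over the disc of pixels within
#' `radius_px` (Euclidean distance) of the ROI centre. `radius_px = 0`
#' returns the single-pixel trace.
#'
#' @param stack A [frame_stack()].
#' @param center_xy Length-2 vector `c(x, y)` in pixel coordinates
#'   (x = column, y = row, 1-based).
#' @param radius_px Disc radius in pixels (non-negative).
#' @param point_id Identifier for the resulting curve.
#' @return A [fluorescence_curve()] with the stack's time stamps.
#' @export
roi_time_series <- function(stack, center_xy, radius_px, point_id = "p1") {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  x <- center_xy[1]; y <- center_xy[2]
  if (x - radius_px < 1 || x + radius_px > d[2] ||
      y - radius_px < 1 || y + radius_px > d[1])
    stop("ROI out of bounds: disc must lie fully inside the frame", call. = FALSE)
  mask <- .disc_mask(d[1], d[2], x, y, radius_px)
  flat <- matrix(stack$frames, d[1] * d[2], d[3])
  fluorescence_curve(stack$time_s, colMeans(flat[as.vector(mask), , drop = FALSE]),
                     point_id)
}

#' Write a frame stack as a multi-page TIFF
#'
#' Intensities are scaled by `scale_max` into \[0, 1\] and stored at
#' `bits_per_sample` bits, so the round trip quantizes values to
#' `scale_max / (2^bits - 1)` AU.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @param scale_max Intensity mapped to full scale (default 255 AU).
#' @param bits_per_sample TIFF bit depth (default 16).
#' @param time_csv Optional path for a sidecar CSV `frame,time_s`; defaults
#'   to `path` with a `.times.csv` suffix. Use `NA` to skip.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, scale_max = 255,
                              bits_per_sample = 16,
                              time_csv = paste0(path, ".times.csv")) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$frames)[3]
  pages <- lapply(seq_len(n), function(i)
    pmin(pmax(stack$frames[, , i] / scale_max, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  if (!is.na(time_csv))
    utils::write.csv(data.frame(frame = seq_len(n), time_s = stack$time_s),
                     time_csv, row.names = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path TIFF path.
#' @param time_s Optional frame time stamps. If missing, they are read from
#'   the sidecar CSV written by [write_frame_stack()], or derived from
#'   `frame_rate_hz`.
#' @param frame_rate_hz Constant frame rate used when no time stamps are
#'   available (frames at 0, 1/rate, 2/rate, ...).
#' @param scale_max Intensity represented by full scale (default 255 AU).
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, time_s = NULL, frame_rate_hz = NULL,
                             scale_max = 255) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  if (is.null(time_s)) {
    sidecar <- paste0(path, ".times.csv")
    if (file.exists(sidecar)) {
      time_s <- utils::read.csv(sidecar)$time_s
    } else if (!is.null(frame_rate_hz)) {
      time_s <- (seq_len(n) - 1) / frame_rate_hz
    } else stop("no frame time stamps: give time_s or frame_rate_hz", call. = FALSE)
  }
  frame_stack(lapply(pages, function(p) p * scale_max), time_s)
}

#' Read ROI specifications from CSV
#'
#' @param path CSV with columns `point_id,x_px,y_px,radius_px`.
#' @return A data frame with those columns.
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("point_id", "x_px", "y_px", "radius_px")
  if (!all(need %in% names(df)))
    stop("ROI CSV needs columns point_id,x_px,y_px,radius_px", call. = FALSE)
  df[need]
}

#' Extract curves for every ROI in a specification table
#'
#' @param stack A [frame_stack()].
#' @param roi A data frame as returned by [read_roi_csv()].
#' @return A named list of [fluorescence_curve()] objects.
#' @export
extract_roi_curves <- function(stack, roi) {
  out <- lapply(seq_len(nrow(roi)), function(i)
    roi_time_series(stack, c(roi$x_px[i], roi$y_px[i]), roi$radius_px[i],
                    point_id = roi$point_id[i]))
  names(out) <- roi$point_id
  out
}
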