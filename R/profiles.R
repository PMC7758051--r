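# Averaged line profiles with confidence intervals, dynamic (concatenated)
# profiles, and kymographs.

#' Averaged line profile across the wound
#'
#' Averages `width_px` parallel pixel lines through a point (by default the
#' image center) and reports, per position along the profile axis, the mean
#' intensity with a 95% confidence interval computed across the `width_px`
#' samples (mean +/- t-quantile * sd / sqrt(width_px)).
#'
#' @param frame Intensity matrix.
#' @param pixel_size Micrometres per pixel.
#' @param center (row, col) the axis passes through; default image center.
#' @param orientation `"horizontal"` (positions run along columns) or
#'   `"vertical"` (positions run along rows, matching profiles read
#'   left-to-right that correspond to image top-to-bottom).
#' @param width_px Number of parallel lines averaged (default 10).
#' @param conf_level Confidence level (default 0.95).
#' @param smooth_window Optional odd moving-average window applied to the
#'   mean profile (disabled by default).
#' @return A `profile_result` data.frame: `position_um`, `mean`, `ci_low`,
#'   `ci_high`, with attributes `n_lines` and `pixel_size`.
#' @export
line_profile <- function(frame, pixel_size, center = NULL,
                         orientation = c("horizontal", "vertical"),
                         width_px = 10, conf_level = 0.95,
                         smooth_window = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(frame), pixel_size > 0, width_px >= 2)
  if (is.null(center)) center <- (dim(frame) + 1) / 2
  band_center <- if (orientation == "horizontal") center[1] else center[2]
  extent <- if (orientation == "horizontal") nrow(frame) else ncol(frame)
  first <- round(band_center - width_px / 2 + 0.5)
  lines_idx <- first + seq_len(width_px) - 1L
  if (first < 1 || max(lines_idx) > extent) {
    stop("profile band of width_px lines extends outside the frame")
  }
  band <- if (orientation == "horizontal") frame[lines_idx, , drop = FALSE]
          else t(frame[, lines_idx, drop = FALSE])
  mu <- colMeans(band)
  sd_ <- apply(band, 2, stats::sd)
  crit <- stats::qt(1 - (1 - conf_level) / 2, df = width_px - 1)
  se <- sd_ / sqrt(width_px)
  if (!is.null(smooth_window)) {
    k <- rep(1 / smooth_window, smooth_window)
    mu <- stats::filter(mu, k, sides = 2)
    mu[is.na(mu)] <- colMeans(band)[is.na(mu)]
    mu <- as.numeric(mu)
  }
  out <- data.frame(position_um = (seq_along(mu) - 1) * pixel_size,
                    mean = mu, ci_low = mu - crit * se, ci_high = mu + crit * se)
  attr(out, "n_lines") <- width_px
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("profile_result", "data.frame")
  out
}

#' Dynamic profile: per-frame line profiles concatenated in time
#'
#' @param stack A `wound_stack`.
#' @param ... Passed to [line_profile()].
#' @return A list of `profile_result`s (one per frame, in time order), with
#'   attribute `frame_times`.
#' @export
dynamic_profile <- function(stack, ...) {
  stopifnot(inherits(stack, "wound_stack"))
  out <- lapply(stack$frames, line_profile, pixel_size = stack$pixel_size, ...)
  attr(out, "frame_times") <- stack$frame_times
  class(out) <- "dynamic_profile"
  out
}

#' @export
print.dynamic_profile <- function(x, ...) {
  cat(sprintf("<dynamic_profile> %d frames x %d positions\n",
              length(x), nrow(x[[1]])))
  invisible(x)
}

#' Space-time kymograph from a band ROI
#'
#' For every frame, a band (default 94.9 um long and 5.3 um wide) through
#' `center` is averaged across its width into a single spatial column;
#' columns are concatenated in time order. One column per frame is produced
#' regardless of the acquisition cadence; with `uniform_time = TRUE` columns
#' are repeated to approximate a uniform time axis at the smallest frame
#' interval.
#'
#' @param stack A `wound_stack`.
#' @param center (row, col) the band passes through; default image center.
#' @param length_um Band length along the profile axis, micrometres.
#' @param width_um Band width (averaged over), micrometres.
#' @param orientation `"horizontal"` or `"vertical"` band axis.
#' @param uniform_time Interpolate (by repetition) to a uniform time grid.
#' @return A `kymograph`: matrix (space x time) with attributes
#'   `frame_times`, `position_um` and the roi specification.
#' @export
kymograph <- function(stack, center = NULL, length_um = 94.9, width_um = 5.3,
                      orientation = c("horizontal", "vertical"),
                      uniform_time = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(stack, "wound_stack"))
  ps <- stack$pixel_size
  d <- dim(stack$frames[[1]])
  if (is.null(center)) center <- (d + 1) / 2
  len_px <- max(2L, round(length_um / ps))
  wid_px <- max(1L, round(width_um / ps))
  axis_center <- if (orientation == "horizontal") center[2] else center[1]
  band_center <- if (orientation == "horizontal") center[1] else center[2]
  axis_extent <- if (orientation == "horizontal") d[2] else d[1]
  band_extent <- if (orientation == "horizontal") d[1] else d[2]
  a0 <- round(axis_center - len_px / 2 + 0.5)
  axis_idx <- a0 + seq_len(len_px) - 1L
  b0 <- round(band_center - wid_px / 2 + 0.5)
  band_idx <- b0 + seq_len(wid_px) - 1L
  if (a0 < 1 || max(axis_idx) > axis_extent || b0 < 1 || max(band_idx) > band_extent) {
    stop("kymograph roi extends outside the image")
  }
  cols <- vapply(stack$frames, function(fr) {
    band <- if (orientation == "horizontal") fr[band_idx, axis_idx, drop = FALSE]
            else t(fr[axis_idx, band_idx, drop = FALSE])
    colMeans(band)
  }, numeric(len_px))
  times <- stack$frame_times
  if (uniform_time && length(times) > 1) {
    dt <- min(diff(times))
    grid <- seq(times[1], times[length(times)], by = dt)
    nearest <- vapply(grid, function(g) which.min(abs(times - g)), integer(1))
    cols <- cols[, nearest, drop = FALSE]
    times <- grid
  }
  structure(cols, frame_times = times,
            position_um = (seq_len(len_px) - 1) * ps,
            roi = list(center = center, length_um = length_um,
                       width_um = width_um, orientation = orientation),
            class = c("kymograph", "matrix"))
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d positions x %d timepoints (%.1f x %.1f um roi)\n",
              nrow(x), ncol(x), attr(x, "roi")$length_um, attr(x, "roi")$width_um))
  invisible(x)
}
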