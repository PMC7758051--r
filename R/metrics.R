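# Repair statistics: Feret diameters, ring width and intensity, expansion
# fold, t_max / t_half, contraction rate, and the per-stack summary.

#' Feret (maximum caliper) diameter of a binary mask
#'
#' The maximum pairwise Euclidean distance between boundary-pixel centers,
#' computed on the convex hull of the boundary set (caliper search over hull
#' vertices). A single pixel has diameter 0 under the pixel-center
#' convention.
#'
#' @param mask Logical matrix; must contain at least one `TRUE` pixel.
#' @param pixel_size Micrometres per pixel.
#' @return Feret diameter in micrometres.
#' @export
feret_diameter <- function(mask, pixel_size = 1) {
  if (!is.matrix(mask) || !any(mask)) stop("mask must be a nonempty logical matrix")
  b <- which(mask_boundary(mask), arr.ind = TRUE)
  if (nrow(b) == 1) return(0)
  pts <- b
  if (nrow(pts) > 3) {
    hull <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[hull, , drop = FALSE]
  }
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2)) * pixel_size
}

#' Actin ring width from its edge Feret diameters
#'
#' Half the difference between the outer- and inner-edge Feret diameters.
#'
#' @param geometry A `ring_geometry` from [detect_ring_edges()], or any list
#'   with `outer_feret` and `inner_feret` in micrometres.
#' @return Ring width in micrometres.
#' @export
ring_width <- function(geometry) {
  if (geometry$outer_feret < geometry$inner_feret) {
    stop("invariant violation: outer Feret smaller than inner Feret")
  }
  (geometry$outer_feret - geometry$inner_feret) / 2
}

#' Mean intensity of the actin ring annulus
#'
#' The integrated intensity of the outer region minus that of the inner
#' region, divided by the annulus pixel count: the mean per-pixel intensity
#' over the ring.
#'
#' @param frame Intensity matrix the geometry was measured on.
#' @param geometry A `ring_geometry`.
#' @return Mean intensity (per pixel) over the annulus.
#' @export
ring_mean_intensity <- function(frame, geometry) {
  n_out <- sum(geometry$outer_mask)
  n_in <- sum(geometry$inner_mask)
  if (n_out <= n_in) stop("outer area must exceed inner area")
  (sum(frame[geometry$outer_mask]) - sum(frame[geometry$inner_mask])) /
    (n_out - n_in)
}

#' Unwounded-cortex baseline intensity
#'
#' Mean intensity over the centered 50 x 50 px window of a pre-wound frame.
#'
#' @param pre_wound_frame Intensity matrix, at least `window` pixels in each
#'   dimension.
#' @param window Window side length in pixels.
#' @return Mean intensity of the window.
#' @export
uw_baseline <- function(pre_wound_frame, window = 50) {
  h <- nrow(pre_wound_frame); w <- ncol(pre_wound_frame)
  if (h < window || w < window) stop(sprintf("frame smaller than %dx%d window", window, window))
  r0 <- floor((h - window) / 2)
  c0 <- floor((w - window) / 2)
  mean(pre_wound_frame[r0 + seq_len(window), c0 + seq_len(window)])
}

#' Ring intensity relative to the unwounded baseline
#'
#' @param ring_series Numeric vector of ring mean intensities over time.
#' @param baseline Unwounded baseline intensity (positive).
#' @return `ring_series / baseline`.
#' @export
relative_ring_intensity <- function(ring_series, baseline) {
  if (!is.numeric(baseline) || length(baseline) != 1 || is.na(baseline) ||
      baseline <= 0) {
    stop("baseline must be a single positive number")
  }
  ring_series / baseline
}

trace_areas <- function(trace) {
  if (inherits(trace, "wound_trace")) trace$areas
  else as.data.frame(trace)[c("frame_time", "area_um2")]
}

#' Wound expansion fold
#'
#' Maximum post-wound area divided by the area of the first post-wound
#' frame (the "initial wound size").
#'
#' @param trace A `wound_trace` or data.frame with `frame_time`, `area_um2`.
#' @return Expansion fold (unitless, >= 1).
#' @export
expansion_fold <- function(trace) {
  a <- trace_areas(trace)
  post <- a[a$frame_time >= 0, , drop = FALSE]
  if (nrow(post) == 0 || all(post$area_um2 <= 0)) {
    stop("trace has no post-wound frame with positive area")
  }
  if (post$area_um2[1] <= 0) stop("initial wound area is zero; fold undefined")
  max(post$area_um2) / post$area_um2[1]
}

#' Times of maximal area and of fractional closure
#'
#' `t_max` is the (earliest) time of maximal wound area; `t_half` is the
#' earliest subsequent time at which the area has fallen to `fraction` of
#' the maximum, the point after which the slope of the area curve changes.
#'
#' @param trace A `wound_trace` or data.frame with `frame_time`, `area_um2`.
#' @param fraction Closure fraction in \[0.35, 0.5\] (default 0.5).
#' @return Named list `t_max`, `t_half` (seconds).
#' @export
find_tmax_thalf <- function(trace, fraction = 0.5) {
  if (fraction < 0.35 || fraction > 0.5) stop("fraction must lie in [0.35, 0.5]")
  a <- trace_areas(trace)
  post <- a[a$frame_time >= 0, , drop = FALSE]
  if (nrow(post) == 0) stop("trace has no post-wound frames")
  i_max <- which.max(post$area_um2) # which.max takes the earliest tie
  a_max <- post$area_um2[i_max]
  after <- post[seq.int(i_max, nrow(post)), , drop = FALSE]
  hit <- which(after$area_um2 <= fraction * a_max)
  if (length(hit) == 0) {
    stop(sprintf("wound did not contract to %.0f%% of its maximum area", 100 * fraction))
  }
  list(t_max = post$frame_time[i_max], t_half = after$frame_time[min(hit)])
}

#' Wound contraction rate
#'
#' The secant slope of the area curve between `t_max` and `t_half`,
#' reported as a positive speed:
#' `(A(t_max) - A(t_half)) / (t_half - t_max)`.
#'
#' @inheritParams find_tmax_thalf
#' @return Contraction rate in square micrometres per second.
#' @export
contraction_rate <- function(trace, fraction = 0.5) {
  a <- trace_areas(trace)
  tt <- find_tmax_thalf(trace, fraction)
  a_max <- a$area_um2[match(tt$t_max, a$frame_time)]
  a_half <- a$area_um2[match(tt$t_half, a$frame_time)]
  (a_max - a_half) / (tt$t_half - tt$t_max)
}

#' Summarize repair dynamics of one stack
#'
#' Runs the full imaging pipeline on a stack: traces the wound area,
#' computes expansion fold, t_max / t_half and contraction rate, evaluates
#' the ring geometry at the frame nearest the reference time (default
#' 120 s post-wounding), and normalizes ring intensity by the unwounded
#' baseline taken from the pre-wound frame.
#'
#' @param stack A `wound_stack` containing one pre-wound frame.
#' @param config A [pipeline_config()]; its `thalf_fraction`,
#'   `ring_reference_time_s` and `closure_area_um2` fields are used.
#' @param ring_series If `TRUE` (default), also evaluate the relative ring
#'   intensity at every open post-wound frame.
#' @return A `repair_metrics` object: `expansion_fold`, `t_max_s`,
#'   `t_half_s`, `contraction_rate_um2_s`, `ring_width_um`,
#'   `ring_mean_intensity`, `relative_ring_intensity` (at the reference
#'   time), `uw_baseline`, the reference `ring_geometry`, the `wound_trace`,
#'   and (optionally) the relative-intensity time series.
#' @export
summarize_repair <- function(stack, config = pipeline_config(),
                             ring_series = TRUE) {
  stopifnot(inherits(stack, "wound_stack"))
  pre <- which(stack$frame_times < 0)
  if (length(pre) == 0) {
    stop("configuration error: stack lacks the pre-wound frame needed for uw_baseline")
  }
  baseline <- uw_baseline(stack$frames[[max(pre)]])

  trace <- trace_wound_areas(stack, closure_area_um2 = config$closure_area_um2)
  fold <- expansion_fold(trace)
  tt <- find_tmax_thalf(trace, config$thalf_fraction)
  rate <- contraction_rate(trace, config$thalf_fraction)

  ref_i <- which.min(abs(stack$frame_times - config$ring_reference_time_s))
  geom <- detect_ring_edges(stack$frames[[ref_i]], trace$masks[[ref_i]],
                            stack$pixel_size,
                            frame_time = stack$frame_times[ref_i])
  rmi <- ring_mean_intensity(stack$frames[[ref_i]], geom)

  rel_series <- NULL
  if (ring_series) {
    open_idx <- which(stack$frame_times >= 0 &
                        vapply(trace$masks, function(m) m$area_um2, numeric(1)) > 0)
    vals <- vapply(open_idx, function(i) {
      g <- tryCatch(detect_ring_edges(stack$frames[[i]], trace$masks[[i]],
                                      stack$pixel_size),
                    error = function(e) NULL)
      if (is.null(g)) NA_real_ else ring_mean_intensity(stack$frames[[i]], g)
    }, numeric(1))
    rel_series <- data.frame(frame_time = stack$frame_times[open_idx],
                             relative_ring_intensity = vals / baseline)
  }

  structure(list(
    expansion_fold = fold, t_max_s = tt$t_max, t_half_s = tt$t_half,
    contraction_rate_um2_s = rate,
    ring_width_um = ring_width(geom),
    ring_mean_intensity = rmi,
    relative_ring_intensity = rmi / baseline,
    uw_baseline = baseline,
    ring_geometry = geom, trace = trace,
    relative_ring_intensity_series = rel_series
  ), class = "repair_metrics")
}

#' @export
print.repair_metrics <- function(x, ...) {
  cat("<repair_metrics>\n")
  cat(sprintf("  expansion fold        %.3f\n", x$expansion_fold))
  cat(sprintf("  t_max / t_half        %g / %g s\n", x$t_max_s, x$t_half_s))
  cat(sprintf("  contraction rate      %.4f um^2/s\n", x$contraction_rate_um2_s))
  cat(sprintf("  ring width            %.3f um (at t = %g s)\n",
              x$ring_width_um, x$ring_geometry$frame_time))
  cat(sprintf("  relative ring intens. %.3f (baseline %.2f)\n",
              x$relative_ring_intensity, x$uw_baseline))
  invisible(x)
}

#' One-row cohort summary of a repair_metrics object
#'
#' @param metrics A `repair_metrics`.
#' @param stack_id Identifier for the stack.
#' @return One-row data.frame suitable for cohort aggregation.
#' @export
repair_metrics_row <- function(metrics, stack_id = "stack") {
  data.frame(stack_id = stack_id,
             expansion_fold = metrics$expansion_fold,
             t_max_s = metrics$t_max_s, t_half_s = metrics$t_half_s,
             contraction_rate_um2_per_s = metrics$contraction_rate_um2_s,
             ring_width_um = metrics$ring_width_um,
             ring_rel_intensity = metrics$relative_ring_intensity,
             stringsAsFactors = FALSE)
}

#' Cohort mean and SEM per genotype label
#'
#' Aggregates per-stack metric rows into mean and standard error of the mean
#' per group, the summary reported for wound-repair cohorts, with an optional
#' two-sample Student's t-test of each group against a control group.
#'
#' @param rows A data.frame of [repair_metrics_row()] rows plus a `group`
#'   column.
#' @param control Optional control group label for t-tests.
#' @return data.frame of group x metric mean, sem, n (and p vs control).
#' @export
cohort_summary <- function(rows, control = NULL) {
  metrics <- c("expansion_fold", "contraction_rate_um2_per_s",
               "ring_width_um", "ring_rel_intensity")
  metrics <- intersect(metrics, names(rows))
  out <- do.call(rbind, lapply(split(rows, rows$group), function(g) {
    do.call(rbind, lapply(metrics, function(m) {
      x <- g[[m]]
      p <- NA_real_
      if (!is.null(control) && g$group[1] != control) {
        y <- rows[[m]][rows$group == control]
        if (length(x) >= 2 && length(y) >= 2) p <- stats::t.test(x, y)$p.value
      }
      data.frame(group = g$group[1], metric = m, mean = mean(x),
                 sem = stats::sd(x) / sqrt(length(x)), n = length(x),
                 p_vs_control = p, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
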