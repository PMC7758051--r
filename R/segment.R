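# Wound segmentation and actin-ring edge detection.
#
# These operations automate what is otherwise done by hand in Fiji: outlining
# the dark, plug-filled wound interior enclosed by the bright actomyosin
# ring, and locating the ring's inner and outer edges.

# Logical mask of pixels whose 4-neighbourhood leaves the mask (or the image).
mask_boundary <- function(mask) {
  if (!any(mask)) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, mask[-h, , drop = FALSE])
  left <- cbind(mask[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, mask[, -w, drop = FALSE])
  mask & !(up & down & left & right)
}

touches_border <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) || any(mask[, 1]) || any(mask[, ncol(mask)])
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

empty_wound_mask <- function(dim_hw, pixel_size, frame_time = NA_real_) {
  structure(list(mask = matrix(FALSE, dim_hw[1], dim_hw[2]),
                 area_um2 = 0, pixel_size = pixel_size,
                 frame_time = frame_time),
            class = "wound_mask")
}

new_wound_mask <- function(mask, pixel_size, frame_time = NA_real_) {
  structure(list(mask = mask, area_um2 = sum(mask) * pixel_size^2,
                 pixel_size = pixel_size, frame_time = frame_time),
            class = "wound_mask")
}

#' @export
print.wound_mask <- function(x, ...) {
  cat(sprintf("<wound_mask> %.2f um^2 (%d px) at t = %s s\n",
              x$area_um2, sum(x$mask),
              ifelse(is.na(x$frame_time), "?", format(x$frame_time))))
  invisible(x)
}

#' Segment the wound interior of a single frame
#'
#' Finds the dark wound interior enclosed by the bright actin ring.
#' The recipe is deterministic: Gaussian blur (sigma = 1 px), intensity
#' inversion, Otsu threshold (optionally restricted to a search region),
#' rejection of components that touch the image border or are smaller than
#' `min_area_px`, then refinement of the accepted component's boundary to the
#' radial half-intensity level between wound interior and ring peak, followed
#' by hole filling and a 3 px morphological closing. The refined region is
#' accepted only if its interior is genuinely dark (mean below
#' `dark_fraction` times the frame median), which rejects noise blobs on
#' wounds that have closed.
#'
#' @param frame Numeric intensity matrix.
#' @param pixel_size Micrometres per pixel.
#' @param hint Optional (row, col) seed point used only to disambiguate
#'   between several candidate components.
#' @param search_mask Optional logical matrix restricting the thresholding
#'   neighbourhood (e.g. the previous frame's mask, dilated).
#' @param min_area_px Minimum accepted component size in pixels.
#' @param blur_sigma Gaussian blur SD in pixels.
#' @param closing_px Diameter of the closing brush in pixels.
#' @param dark_fraction Interior-darkness acceptance threshold.
#' @return A `wound_mask` (empty when no enclosed dark region qualifies).
#' @export
segment_wound <- function(frame, pixel_size, hint = NULL, search_mask = NULL,
                          min_area_px = 5, blur_sigma = 1, closing_px = 3,
                          dark_fraction = 0.6) {
  stopifnot(is.matrix(frame), pixel_size > 0)
  if (!is.null(hint)) {
    if (length(hint) != 2 || any(hint < 1) || hint[1] > nrow(frame) ||
        hint[2] > ncol(frame)) {
      stop("hint must be a (row, col) pixel inside the image")
    }
  }
  if (diff(range(frame)) == 0) return(empty_wound_mask(dim(frame), pixel_size))

  sm <- EBImage::gblur(frame, sigma = blur_sigma)
  inv <- max(sm) - sm
  region <- if (is.null(search_mask)) matrix(TRUE, nrow(frame), ncol(frame)) else search_mask
  vals <- inv[region]
  if (diff(range(vals)) == 0) return(empty_wound_mask(dim(frame), pixel_size))
  thr <- EBImage::otsu(matrix(vals, ncol = 1), range = range(vals))

  cand <- inv > thr & region
  lab <- EBImage::bwlabel(cand)
  n_lab <- max(lab)
  if (n_lab == 0) return(empty_wound_mask(dim(frame), pixel_size))

  frame_med <- stats::median(frame)
  ok <- logical(n_lab)
  sizes <- tabulate(lab[lab > 0], nbins = n_lab)
  for (l in seq_len(n_lab)) {
    if (sizes[l] < min_area_px) next
    if (touches_border(lab == l)) next
    ok[l] <- TRUE
  }
  if (!any(ok)) return(empty_wound_mask(dim(frame), pixel_size))

  pick <- NA_integer_
  if (!is.null(hint)) {
    l <- lab[hint[1], hint[2]]
    if (l > 0 && ok[l]) pick <- l
  }
  if (is.na(pick)) pick <- which(ok)[which.max(sizes[ok])]
  rough <- lab == pick

  # refine to the half-level between wound interior and ring peak so the
  # recovered boundary sits at the true wound edge rather than at whatever
  # level Otsu happened to pick
  margin_px <- max(3L, round(3 / pixel_size))
  halo_zone <- EBImage::dilate(rough, EBImage::makeBrush(2L * margin_px + 1L, "disc")) > 0
  peak <- max(sm[halo_zone])
  interior <- stats::quantile(sm[rough], 0.1, names = FALSE)
  half <- (interior + peak) / 2

  refined_bin <- sm < half & halo_zone
  lab2 <- EBImage::bwlabel(refined_bin)
  overlaps <- tabulate(lab2[rough & lab2 > 0], nbins = max(lab2))
  if (length(overlaps) == 0 || max(overlaps) == 0) {
    return(empty_wound_mask(dim(frame), pixel_size))
  }
  refined <- lab2 == which.max(overlaps)
  refined <- EBImage::fillHull(refined) > 0
  if (closing_px >= 2) {
    refined <- EBImage::closing(refined, EBImage::makeBrush(closing_px, "disc")) > 0
  }
  if (sum(refined) < min_area_px || touches_border(refined) ||
      mean(frame[refined]) >= dark_fraction * frame_med) {
    return(empty_wound_mask(dim(frame), pixel_size))
  }
  new_wound_mask(refined, pixel_size)
}

#' Trace wound area over a whole stack
#'
#' Segments every frame independently (pre-wound frames are zero-area by
#' definition) and flags closure once the area has fallen below
#' `closure_area_um2` for two consecutive frames and stays below it.
#'
#' @param stack A `wound_stack`.
#' @param closure_area_um2 Closure threshold in square micrometres.
#' @param track If `TRUE`, restrict each frame's threshold search to the
#'   previous frame's mask dilated by `track_margin_um`; the default is a
#'   pure per-frame segmentation.
#' @param track_margin_um Dilation margin for tracking, micrometres.
#' @param ... Passed on to [segment_wound()].
#' @return A `wound_trace`: list with data.frame `areas` (`frame_time`,
#'   `area_um2`, `closed`), the per-frame `masks`, and `pixel_size`.
#' @export
trace_wound_areas <- function(stack, closure_area_um2 = 1, track = FALSE,
                              track_margin_um = 5, ...) {
  stopifnot(inherits(stack, "wound_stack"))
  n <- length(stack$frames)
  masks <- vector("list", n)
  prev_mask <- NULL
  for (i in seq_len(n)) {
    ti <- stack$frame_times[i]
    if (ti < 0) {
      masks[[i]] <- empty_wound_mask(dim(stack$frames[[i]]), stack$pixel_size, ti)
      next
    }
    search <- NULL
    if (track && !is.null(prev_mask) && any(prev_mask)) {
      r <- max(3L, round(track_margin_um / stack$pixel_size))
      search <- EBImage::dilate(prev_mask, EBImage::makeBrush(2L * r + 1L, "disc")) > 0
    }
    wm <- segment_wound(stack$frames[[i]], stack$pixel_size,
                        search_mask = search, ...)
    wm$frame_time <- ti
    masks[[i]] <- wm
    if (any(wm$mask)) prev_mask <- wm$mask
  }
  areas <- vapply(masks, function(m) m$area_um2, numeric(1))

  below <- areas < closure_area_um2 & stack$frame_times >= 0
  closed <- rep(FALSE, n)
  # closed from the first index of a terminal run of sub-threshold areas that
  # is at least two frames long
  run <- rev(cumprod(rev(below))) == 1
  if (sum(run) >= 2) closed[run] <- TRUE

  structure(list(areas = data.frame(frame_time = stack$frame_times,
                                    area_um2 = areas, closed = closed),
                 masks = masks, pixel_size = stack$pixel_size),
            class = "wound_trace")
}

#' @export
print.wound_trace <- function(x, ...) {
  a <- x$areas
  cat(sprintf("<wound_trace> %d frames, peak area %.1f um^2 at t = %g s%s\n",
              nrow(a), max(a$area_um2), a$frame_time[which.max(a$area_um2)],
              if (any(a$closed)) sprintf(", closed by t = %g s",
                                         min(a$frame_time[a$closed])) else ""))
  invisible(x)
}

#' Detect the inner and outer edges of the actin ring
#'
#' Builds the radial mean-intensity profile around the wound centroid, finds
#' the ring peak, and places the inner (outer) edge at the first (last)
#' half-maximum crossing -- the level halfway between the far-field cortex
#' baseline and the peak. Each edge encloses a filled region whose Feret
#' diameter, area and integrated intensity are reported; the ring annulus is
#' the difference of the two regions.
#'
#' @param frame Numeric intensity matrix.
#' @param wound_mask A `wound_mask` (or logical matrix) locating the wound.
#' @param pixel_size Micrometres per pixel.
#' @param rel_margin Minimum peak prominence, as a fraction of the larger of
#'   peak and baseline; below it a "no ring detected" error is thrown.
#' @param frame_time Timestamp carried into the result, seconds.
#' @return A `ring_geometry`: inner/outer region masks, Feret diameters (um),
#'   areas (um^2), integrated intensities (intensity * px), pixel counts and
#'   the radial profile used.
#' @export
detect_ring_edges <- function(frame, wound_mask, pixel_size,
                              rel_margin = 0.05, frame_time = NA_real_) {
  m <- if (inherits(wound_mask, "wound_mask")) wound_mask$mask else wound_mask
  if (!any(m)) stop("wound_mask must be nonempty")
  cen <- mask_centroid(m)
  h <- nrow(frame); w <- ncol(frame)
  dist_px <- sqrt(outer((seq_len(h) - cen["row"])^2,
                        (seq_len(w) - cen["col"])^2, "+"))
  r_valid <- min(cen["row"] - 1, h - cen["row"], cen["col"] - 1, w - cen["col"])
  if (r_valid < 3) stop("wound centroid too close to the image border")

  bin <- pmin(floor(dist_px) + 1L, ceiling(r_valid))
  use <- dist_px <= r_valid
  prof <- as.vector(tapply(frame[use], bin[use], mean))
  r_centers <- seq_along(prof) - 0.5

  far <- r_centers >= 0.85 * r_valid
  baseline <- stats::median(prof[far])
  peak_idx <- which.max(prof)
  peak_val <- prof[peak_idx]
  if (peak_val - baseline <= rel_margin * max(abs(peak_val), abs(baseline), 1e-12)) {
    stop("no ring detected: radial profile has no peak above the cortex baseline")
  }
  half <- baseline + (peak_val - baseline) / 2

  cross_up <- function(k) { # interpolated radius where prof rises through half
    r_centers[k] + (half - prof[k]) / (prof[k + 1] - prof[k])
  }
  below_pre <- which(prof[seq_len(peak_idx - 1)] < half)
  r_inner <- if (length(below_pre) == 0) 0 else cross_up(max(below_pre))
  after <- seq.int(peak_idx, length(prof))
  below_post <- after[prof[after] < half]
  if (length(below_post) == 0) stop("ring outer edge extends beyond the frame")
  k <- min(below_post)
  r_outer <- r_centers[k - 1] + (prof[k - 1] - half) / (prof[k - 1] - prof[k])

  inner_mask <- dist_px <= r_inner
  outer_mask <- dist_px <= r_outer
  if (!any(inner_mask) || sum(outer_mask) <= sum(inner_mask)) {
    stop("degenerate ring geometry")
  }
  new_ring_geometry(frame, inner_mask, outer_mask, pixel_size, frame_time,
                    radial_profile = data.frame(r_px = r_centers,
                                                intensity = prof))
}

new_ring_geometry <- function(frame, inner_mask, outer_mask, pixel_size,
                              frame_time = NA_real_, radial_profile = NULL) {
  g <- list(
    inner_mask = inner_mask, outer_mask = outer_mask,
    inner_feret = feret_diameter(inner_mask, pixel_size),
    outer_feret = feret_diameter(outer_mask, pixel_size),
    inner_area = sum(inner_mask) * pixel_size^2,
    outer_area = sum(outer_mask) * pixel_size^2,
    inner_px = sum(inner_mask), outer_px = sum(outer_mask),
    inner_integrated_intensity = sum(frame[inner_mask]),
    outer_integrated_intensity = sum(frame[outer_mask]),
    pixel_size = pixel_size, frame_time = frame_time,
    radial_profile = radial_profile
  )
  if (g$outer_feret < g$inner_feret) stop("invariant violation: outer Feret < inner Feret")
  class(g) <- "ring_geometry"
  g
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf(paste0("<ring_geometry> inner/outer Feret %.2f/%.2f um, ",
                     "annulus %.1f um^2, t = %s s\n"),
              x$inner_feret, x$outer_feret, x$outer_area - x$inner_area,
              ifelse(is.na(x$frame_time), "?", format(x$frame_time))))
  invisible(x)
}
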