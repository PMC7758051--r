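# The wound_stack container and its TIFF + JSON sidecar interchange format.

#' Construct a wound stack
#'
#' A `wound_stack` is the unit every imaging operation consumes: an ordered
#' list of single-channel frame matrices with strictly increasing timestamps
#' (seconds relative to wounding; at most one pre-wound frame is expected by
#' the repair summary) and a physical pixel size.
#'
#' @param frames List of numeric H x W matrices, all the same shape, with
#'   nonnegative intensities.
#' @param frame_times Numeric vector, seconds relative to wounding.
#' @param pixel_size Micrometres per pixel.
#' @param channel_label Free-text channel description.
#' @return An object of class `wound_stack`.
#' @export
new_wound_stack <- function(frames, frame_times, pixel_size,
                            channel_label = "") {
  if (!is.list(frames) || length(frames) == 0) stop("frames must be a non-empty list")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share one shape")
  }
  if (length(frame_times) != length(frames)) stop("one timestamp per frame required")
  if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(frames = frames, frame_times = frame_times,
                 pixel_size = pixel_size, channel_label = channel_label),
            class = "wound_stack")
}

#' @export
print.wound_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<wound_stack> %d frames, %dx%d px, %.3g um/px, t = [%g, %g] s (%s)\n",
              length(x$frames), d[1], d[2], x$pixel_size,
              min(x$frame_times), max(x$frame_times), x$channel_label))
  invisible(x)
}

#' @export
length.wound_stack <- function(x) length(x$frames)

#' Write a wound stack to multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 16-bit unsigned TIFF pages (values clamped to
#' 0..65535 and rounded); timestamps, pixel size and any extra metadata go
#' into `<path>.json`.
#'
#' @param stack A `wound_stack`.
#' @param path Output TIFF path.
#' @param extra Optional named list merged into the sidecar (e.g. simulation
#'   parameters and seed).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, extra = NULL) {
  stopifnot(inherits(stack, "wound_stack"))
  pages <- lapply(stack$frames, function(fr) {
    pmin(pmax(round(fr), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  side <- c(list(frame_times = stack$frame_times,
                 pixel_size = stack$pixel_size,
                 channel_label = stack$channel_label),
            extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a wound stack written by [write_stack()]
#'
#' @param path TIFF path; `<path>.json` must exist alongside it.
#' @return A `wound_stack`.
#' @export
read_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(p) round(p * 65535))
  new_wound_stack(frames, side$frame_times, side$pixel_size,
                  channel_label = side$channel_label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
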