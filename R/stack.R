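#' Construct a frame stack
#'
#' A time-ordered stack of 2-D 8-bit grayscale frames with temporal and
#' spatial calibration; the universal video currency of the pipeline.
#' Pixel coordinates are 0-based with row 0 at the top.
#'
#' @param frames Numeric array `T x H x W` with values in `[0, 255]`.
#' @param frame_interval_s Seconds per frame (> 0); frame 1 is `t = 0`,
#'   the moment of UV exposure.
#' @param pixel_size_um Microns per pixel.
#' @return An object of class `"frame_stack"`.
#' @export
frame_stack <- function(frames, frame_interval_s, pixel_size_um = 1 / 14) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a T x H x W array")
  if (dim(frames)[1] < 3L)
    stop("a stack needs at least 3 frames")
  if (min(frames) < 0 || max(frames) > 255)
    stop("frame values must lie in [0, 255]")
  if (frame_interval_s <= 0) stop("frame_interval_s must be positive")
  structure(list(frames = frames,
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack: %d frames of %dx%d px, %.3g s/frame, %.4g um/px>\n",
              d[1], d[2], d[3], x$frame_interval_s, x$pixel_size_um))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

stack_times <- function(stack) {
  (seq_len(dim(stack$frames)[1]) - 1L) * stack$frame_interval_s
}

#' Define a square region of interest
#'
#' @param top_row,left_col 0-based pixel indices of the ROI's top-left
#'   corner (row 0 is the top of the frame).
#' @param side_px Positive integer side length; the ROI covers the half-open
#'   square `[top, top+side) x [left, left+side)`.
#' @param label Free-text label.
#' @return An object of class `"roi"`.
#' @export
roi <- function(top_row, left_col, side_px, label = "roi") {
  if (side_px < 1) stop("side_px must be a positive integer")
  structure(list(top_row = as.integer(top_row),
                 left_col = as.integer(left_col),
                 side_px = as.integer(side_px), label = label),
            class = "roi")
}

#' Crop a region of interest from a stack
#'
#' @param stack A [frame_stack()].
#' @param region An [roi()] fully inside the frame bounds.
#' @return A `frame_stack` of the cropped sub-frames; calibration metadata
#'   is preserved.
#' @export
crop_roi <- function(stack, region) {
  stopifnot(inherits(stack, "frame_stack"), inherits(region, "roi"))
  d <- dim(stack$frames)
  h <- d[2]; w <- d[3]
  if (region$top_row < 0)
    stop("ROI extends past the top edge of the frame")
  if (region$left_col < 0)
    stop("ROI extends past the left edge of the frame")
  if (region$top_row + region$side_px > h)
    stop("ROI extends past the bottom edge of the frame")
  if (region$left_col + region$side_px > w)
    stop("ROI extends past the right edge of the frame")
  rows <- (region$top_row + 1L):(region$top_row + region$side_px)
  cols <- (region$left_col + 1L):(region$left_col + region$side_px)
  sub <- stack$frames[, rows, cols, drop = FALSE]
  frame_stack(sub, stack$frame_interval_s, stack$pixel_size_um)
}

#' Mean intensity trace of a whole stack
#'
#' Average gray level per frame, typically of a cropped ROI.
#'
#' @param stack A [frame_stack()].
#' @param source Label for the resulting trace.
#' @return An [intensity_trace()].
#' @export
mean_trace <- function(stack, source = "roi") {
  stopifnot(inherits(stack, "frame_stack"))
  intensity_trace(stack_times(stack),
                  apply(stack$frames, 1, mean), source = source)
}

#' Superpixel intensity traces
#'
#' Bins each frame into square superpixels of side `bin_px` (1 or 2, the
#' neighborhood sizes used for spatial binning) and returns one intensity
#' trace per superpixel (value = arithmetic mean of the bin).  A trailing
#' remainder of rows/columns not filling a whole bin is dropped with a
#' message.
#'
#' @param stack A [frame_stack()].
#' @param bin_px Superpixel side length in pixels, 1 or 2.
#' @return List of [intensity_trace()]s; each carries attributes `row` and
#'   `col`, the 0-based superpixel coordinates.
#' @export
superpixel_traces <- function(stack, bin_px = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  bin_px <- as.integer(bin_px)
  if (!bin_px %in% c(1L, 2L)) stop("bin_px must be 1 or 2")
  d <- dim(stack$frames)
  nT <- d[1]; h <- d[2]; w <- d[3]
  hb <- h %/% bin_px; wb <- w %/% bin_px
  if (hb * bin_px < h || wb * bin_px < w)
    message(sprintf("dropping trailing remainder: using %d x %d of %d x %d pixels",
                    hb * bin_px, wb * bin_px, h, w))
  if (hb < 1L || wb < 1L) stop("stack smaller than one superpixel")
  times <- stack_times(stack)
  f <- stack$frames[, seq_len(hb * bin_px), seq_len(wb * bin_px), drop = FALSE]
  if (bin_px == 2L) {
    f <- (f[, seq(1, 2 * hb, 2), , drop = FALSE] +
            f[, seq(2, 2 * hb, 2), , drop = FALSE]) / 2
    f <- (f[, , seq(1, 2 * wb, 2), drop = FALSE] +
            f[, , seq(2, 2 * wb, 2), drop = FALSE]) / 2
  }
  out <- vector("list", hb * wb)
  k <- 1L
  for (j in seq_len(wb)) {
    for (i in seq_len(hb)) {
      tr <- intensity_trace(times, f[, i, j],
                            source = sprintf("sp_r%d_c%d", i - 1L, j - 1L))
      attr(tr, "row") <- i - 1L
      attr(tr, "col") <- j - 1L
      out[[k]] <- tr
      k <- k + 1L
    }
  }
  out
}

#' Read a multi-page TIFF as a frame stack
#'
#' 8-bit grayscale expected; color pages are converted to luma
#' (0.299 R + 0.587 G + 0.114 B) with a warning.
#'
#' @param path TIFF file path.
#' @param frame_interval_s,pixel_size_um Calibration to attach.
#' @return A [frame_stack()].
#' @export
read_stack_tiff <- function(path, frame_interval_s, pixel_size_um = 1 / 14) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  to_gray <- function(p) {
    if (length(dim(p)) == 3L) {
      warning("color TIFF converted to grayscale by luma")
      p <- 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
    }
    p
  }
  pages <- lapply(pages, to_gray)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0, dim = c(length(pages), h, w))
  for (k in seq_along(pages)) frames[k, , ] <- round(pages[[k]] * 255)
  frame_stack(frames, frame_interval_s, pixel_size_um)
}

#' Write a frame stack as an 8-bit multi-page TIFF
#'
#' @param stack A [frame_stack()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(k) stack$frames[k, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
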