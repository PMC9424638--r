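#' Specification of a synthetic crystal video
#'
#' Describes a birefringent crystal on a dark background whose transmitted
#' intensity switches from a baseline to a final level as a solid-to-solid
#' phase transition sweeps across it.  The temporal profile at each pixel is
#' a two-component normal-CDF mixture: a small "shoulder" preceding the
#' Gaussian-profile primary transition, reproducing the smaller initial peak
#' seen in first-derivative curves of real crystals.  Per-pixel transition
#' times vary as a linear spatial gradient plus a smooth correlated random
#' field.
#'
#' @param image_height_px,image_width_px Frame dimensions in pixels.
#' @param pixel_size_um Microns per pixel.  Default 1/14 um (14 px per um).
#' @param frame_interval_s Seconds per frame.  Default 0.5 s.
#' @param duration_s Recording length in seconds.
#' @param crystal_polygon Two-column matrix of (row, col) vertices (0-based
#'   pixel coordinates) outlining the crystal; at least 3 vertices, inside
#'   the image.
#' @param baseline_intensity,final_intensity Gray levels (0-255) inside the
#'   crystal before and after the transition.  `final` may be smaller than
#'   `baseline` (intensity may rise or fall through the transition).
#' @param background_intensity Gray level outside the crystal.
#' @param t1_mean_s Mean transition time in seconds.
#' @param t1_gradient_s_per_um Linear drift of T1 per micron along
#'   `t1_gradient_direction_deg`.
#' @param t1_gradient_direction_deg Direction of the gradient in degrees;
#'   0 points along increasing column, 90 along increasing row.
#' @param t1_noise_sd_s Standard deviation of the smooth random T1 component.
#' @param t1_corr_length_um Correlation length of that component in microns.
#' @param primary_width_s Sigma of the Gaussian primary derivative peak.
#' @param shoulder_fraction Amplitude share in `[0, 1)` of the pre-peak
#'   shoulder.
#' @param shoulder_lead_s,shoulder_width_s Shoulder offset before T1 and its
#'   sigma.
#' @param noise_sd Additive Gaussian sensor noise, gray levels.
#' @param drift_px_per_frame Length-2 numeric `(row, col)`: rigid translation
#'   of the crystal per frame.
#' @param seed Integer RNG seed; drives the T1 field and the sensor noise
#'   through independent substreams.
#' @return An object of class `"crystal_spec"`.
#' @export
crystal_spec <- function(image_height_px = 60, image_width_px = 60,
                         pixel_size_um = 1 / 14,
                         frame_interval_s = 0.5,
                         duration_s = 150,
                         crystal_polygon = rbind(c(8, 8), c(8, 51),
                                                 c(51, 51), c(51, 8)),
                         baseline_intensity = 40, final_intensity = 200,
                         background_intensity = 8,
                         t1_mean_s = 60,
                         t1_gradient_s_per_um = 0,
                         t1_gradient_direction_deg = 0,
                         t1_noise_sd_s = 0, t1_corr_length_um = 0.5,
                         primary_width_s = 6,
                         shoulder_fraction = 0.15,
                         shoulder_lead_s = 15, shoulder_width_s = 6,
                         noise_sd = 1,
                         drift_px_per_frame = c(0, 0),
                         seed = 1L) {
  spec <- list(image_height_px = as.integer(image_height_px),
               image_width_px = as.integer(image_width_px),
               pixel_size_um = pixel_size_um,
               frame_interval_s = frame_interval_s,
               duration_s = duration_s,
               crystal_polygon = as.matrix(crystal_polygon),
               baseline_intensity = baseline_intensity,
               final_intensity = final_intensity,
               background_intensity = background_intensity,
               t1_mean_s = t1_mean_s,
               t1_gradient_s_per_um = t1_gradient_s_per_um,
               t1_gradient_direction_deg = t1_gradient_direction_deg,
               t1_noise_sd_s = t1_noise_sd_s,
               t1_corr_length_um = t1_corr_length_um,
               primary_width_s = primary_width_s,
               shoulder_fraction = shoulder_fraction,
               shoulder_lead_s = shoulder_lead_s,
               shoulder_width_s = shoulder_width_s,
               noise_sd = noise_sd,
               drift_px_per_frame = as.numeric(drift_px_per_frame),
               seed = as.integer(seed))
  class(spec) <- "crystal_spec"
  validate_crystal_spec(spec)
  spec
}

validate_crystal_spec <- function(spec) {
  with(spec, {
    if (image_height_px < 1 || image_width_px < 1)
      stop("image dimensions must be positive")
    if (pixel_size_um <= 0 || frame_interval_s <= 0 || duration_s <= 0)
      stop("pixel size, frame interval and duration must be positive")
    if (duration_s / frame_interval_s < 3)
      stop("need at least 3 frame intervals: duration_s / frame_interval_s >= 3")
    for (v in c(baseline_intensity, final_intensity, background_intensity))
      if (v < 0 || v > 255) stop("intensities must lie in [0, 255]")
    if (nrow(crystal_polygon) < 3)
      stop("crystal polygon needs at least 3 vertices")
    if (ncol(crystal_polygon) != 2)
      stop("crystal polygon must be a two-column (row, col) matrix")
    if (any(crystal_polygon[, 1] < 0) || any(crystal_polygon[, 1] > image_height_px - 1) ||
        any(crystal_polygon[, 2] < 0) || any(crystal_polygon[, 2] > image_width_px - 1))
      stop("crystal polygon lies outside the image")
    if (shoulder_fraction < 0 || shoulder_fraction >= 1)
      stop("shoulder_fraction must be in [0, 1)")
    if (primary_width_s <= 0 || shoulder_width_s <= 0)
      stop("transition widths must be positive")
    if (t1_mean_s < 0 || t1_noise_sd_s < 0 || noise_sd < 0)
      stop("t1_mean_s, t1_noise_sd_s and noise_sd must be non-negative")
    if (t1_corr_length_um <= 0)
      stop("t1_corr_length_um must be positive")
  })
  invisible(spec)
}

# Even-odd rule point-in-polygon test; px/py are 0-based pixel centers.
points_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

crystal_mask <- function(spec) {
  h <- spec$image_height_px; w <- spec$image_width_px
  rows <- rep(0:(h - 1), times = w)
  cols <- rep(0:(w - 1), each = h)
  inside <- points_in_polygon(cols, rows,
                              spec$crystal_polygon[, 2],
                              spec$crystal_polygon[, 1])
  matrix(inside, nrow = h, ncol = w)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Ground-truth transition-time field
#'
#' Builds the per-pixel map of true transition times for a synthetic crystal:
#' mean + linear spatial gradient + a smooth zero-mean Gaussian random field
#' (white noise convolved with a Gaussian kernel of the requested correlation
#' length, rescaled to the requested standard deviation).  Pixels outside the
#' crystal mask are `NA`.
#'
#' @param spec A [crystal_spec()].
#' @return An object of class `"t1_field"`: list with `t1_s` (H x W matrix,
#'   `NA` off-mask), `mask` (logical matrix) and the generating `spec`.
#' @export
generate_t1_field <- function(spec) {
  validate_crystal_spec(spec)
  mask <- crystal_mask(spec)
  if (!any(mask)) stop("crystal polygon encloses no pixel centers")
  h <- spec$image_height_px; w <- spec$image_width_px

  rows <- matrix(rep(0:(h - 1), times = w), nrow = h)
  cols <- matrix(rep(0:(w - 1), each = h), nrow = h)
  theta <- spec$t1_gradient_direction_deg * pi / 180
  proj_um <- (cols * cos(theta) + rows * sin(theta)) * spec$pixel_size_um
  field <- spec$t1_mean_s + spec$t1_gradient_s_per_um * proj_um

  if (spec$t1_noise_sd_s > 0) {
    g <- with_seed(spec$seed, {
      wn <- matrix(stats::rnorm(h * w), nrow = h)
      smooth_field(wn, spec$t1_corr_length_um / spec$pixel_size_um)
    })
    s <- stats::sd(g[mask])
    if (s > 0) field <- field + g * (spec$t1_noise_sd_s / s)
  }
  field[field < 0] <- 0
  field[!mask] <- NA_real_
  structure(list(t1_s = field, mask = mask, spec = spec), class = "t1_field")
}

# Separable Gaussian convolution with sigma in pixels (reflected edges).
smooth_field <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    idx <- c(pmin(half:1 + 1L, n), 1:n, pmax(n - (1:half), 1L))
    as.numeric(stats::filter(v[idx], k, sides = 2))[(half + 1L):(half + n)]
  }
  m2 <- apply(m, 2, conv1)
  t(apply(m2, 1, conv1))
}

#' @export
print.t1_field <- function(x, ...) {
  v <- x$t1_s[x$mask]
  cat(sprintf("<t1_field %dx%d px, %d mask pixels, T1 mean %.2f s (sd %.2f)>\n",
              nrow(x$t1_s), ncol(x$t1_s), sum(x$mask), mean(v), stats::sd(v)))
  invisible(x)
}

#' Noise-free intensity profile of one pixel
#'
#' Continuous gray level at time `t` for a pixel transitioning at `t1`:
#' `baseline + dI * (f * Phi((t - (t1 - lead)) / sw) + (1 - f) * Phi((t - t1) / pw))`
#' with `Phi` the standard normal CDF, `f` the shoulder fraction, `sw`/`pw`
#' the shoulder and primary widths, and `dI = final - baseline`.  The start
#' of the transition is gradual (the shoulder) followed by a Gaussian-profile
#' primary step whose derivative peaks exactly at `t1`.
#'
#' @param t Time(s) in seconds (vectorized).
#' @param t1 Transition time in seconds (scalar or same length as `t`).
#' @param spec A [crystal_spec()].
#' @return Continuous gray level(s), not yet quantized.
#' @export
pixel_intensity_curve <- function(t, t1, spec) {
  dI <- spec$final_intensity - spec$baseline_intensity
  f <- spec$shoulder_fraction
  spec$baseline_intensity + dI *
    (f * stats::pnorm((t - (t1 - spec$shoulder_lead_s)) / spec$shoulder_width_s) +
       (1 - f) * stats::pnorm((t - t1) / spec$primary_width_s))
}

#' Render a synthetic PVM video
#'
#' Produces the full 8-bit frame stack together with its ground-truth
#' transition-time field.  Mask pixels follow [pixel_intensity_curve()],
#' background pixels sit at the background level, optional rigid drift
#' translates the crystal, Gaussian sensor noise is added, and frames are
#' clipped to `[0, 255]` and quantized.  Deterministic for a given spec
#' (the seed drives the T1 field and the noise via separate substreams).
#'
#' @param spec A [crystal_spec()].
#' @return List with `stack` (a [frame_stack()]) and `truth` (a `t1_field`).
#'   If drift pushes the whole crystal out of the frame the result carries
#'   attribute `truncated = TRUE` and a warning is raised.
#' @export
render_video <- function(spec) {
  truth <- generate_t1_field(spec)
  mask <- truth$mask
  h <- spec$image_height_px; w <- spec$image_width_px
  n_frames <- floor(spec$duration_s / spec$frame_interval_s) + 1L
  times <- (seq_len(n_frames) - 1L) * spec$frame_interval_s

  idx <- which(mask)
  t1 <- truth$t1_s[idx]
  rows0 <- ((idx - 1L) %% h)        # 0-based
  cols0 <- ((idx - 1L) %/% h)

  frames <- array(spec$background_intensity, dim = c(n_frames, h, w))
  truncated <- FALSE
  for (k in seq_len(n_frames)) {
    shift <- round((k - 1L) * spec$drift_px_per_frame)
    r <- rows0 + shift[1]
    cl <- cols0 + shift[2]
    keep <- r >= 0 & r < h & cl >= 0 & cl < w
    if (!any(keep)) {
      truncated <- TRUE
      next
    }
    vals <- pixel_intensity_curve(times[k], t1[keep], spec)
    frames[cbind(k, r[keep] + 1L, cl[keep] + 1L)] <- vals
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed + 1L,
                       stats::rnorm(length(frames), sd = spec$noise_sd))
    frames <- frames + noise
  }
  frames <- round(pmin(pmax(frames, 0), 255))
  stack <- frame_stack(frames, frame_interval_s = spec$frame_interval_s,
                       pixel_size_um = spec$pixel_size_um)
  if (truncated) {
    warning("drift moved the crystal entirely out of at least one frame; result flagged as truncated")
    attr(stack, "truncated") <- TRUE
  }
  list(stack = stack, truth = truth)
}

#' Write a ground-truth field as CSV
#'
#' Columns `row`, `col` (0-based) and `t1_s`, one line per mask pixel.
#'
#' @param truth A `t1_field`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_t1_csv <- function(truth, path) {
  stopifnot(inherits(truth, "t1_field"))
  idx <- which(truth$mask)
  h <- nrow(truth$t1_s)
  df <- data.frame(row = (idx - 1L) %% h,
                   col = (idx - 1L) %/% h,
                   t1_s = truth$t1_s[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
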