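#' Extract a transition event from a first-derivative trace
#'
#' The transition time T1 is the time of the primary peak of the first
#' derivative of a (smoothed) intensity trace; the transition width is the
#' half-width at half-maximum (HWHM) of that peak.  The transition direction
#' (intensity rising or falling) is auto-detected from the sign of the net
#' intensity change unless given.  Secondary "shoulder" peaks preceding T1
#' are reported when they exceed a configurable fraction of the primary peak
#' height.
#'
#' Half-height crossings on each flank are located by linear interpolation
#' between samples; the HWHM is half the full width between them.  If one
#' flank never crosses half height inside the trace, the one-sided width is
#' used and the event is flagged `"one_sided_flank"`.
#'
#' @param deriv An [intensity_trace()] holding a first derivative (see
#'   [first_derivative()]), normally computed from a boxcar-smoothed trace.
#' @param direction `"auto"` (default), `"rise"` or `"fall"`.
#' @param shoulder_fraction Minimum height of a pre-T1 local maximum,
#'   relative to the primary peak, to count as a shoulder.  Default 0.2.
#' @param shoulder_min_sep_s Minimum separation in seconds between reported
#'   shoulders (and between a shoulder and T1).  Default 2 s.
#' @param noise_floor_mult The primary peak must exceed this multiple of a
#'   robust (MAD-based) noise scale estimated from the first and last 10% of
#'   the derivative; otherwise a no-transition error is raised.  Default 3.
#' @return An object of class `"transition_event"`: list with `t1_s`,
#'   `hwhm_s`, `peak_height` (derivative magnitude at T1), `direction`
#'   (+1 rising / -1 falling), `shoulder_times_s`, `flags`.
#' @export
detect_transition <- function(deriv, direction = c("auto", "rise", "fall"),
                              shoulder_fraction = 0.2,
                              shoulder_min_sep_s = 2,
                              noise_floor_mult = 3) {
  stopifnot(inherits(deriv, "intensity_trace"))
  direction <- match.arg(direction)
  t <- deriv$times_s
  d <- deriv$values
  n <- length(d)
  if (n < 5L) stop("derivative trace too short for peak detection")

  if (direction == "auto") {
    # net intensity change = integral of the derivative
    net <- sum(diff(t) * (d[-1] + d[-n]) / 2)
    dir_sign <- if (net >= 0) 1 else -1
  } else {
    dir_sign <- if (direction == "rise") 1 else -1
  }
  s <- d * dir_sign  # signed derivative: primary peak is a maximum

  m <- max(2L, ceiling(0.1 * n))
  tails <- c(s[seq_len(m)], s[seq.int(n - m + 1L, n)])
  noise <- stats::mad(tails)
  if (noise == 0) noise <- 1e-12

  height <- max(s)
  if (height <= 0 || height < noise_floor_mult * noise)
    stop("no transition detected: primary derivative peak below the noise floor")
  # quantized traces can tie at the maximum: T1 is the mean of tied times
  tied <- which(s == height)
  t1 <- mean(t[tied])
  ipk <- tied[which.min(abs(t[tied] - t1))]

  half <- height / 2
  flags <- character()

  cross_left <- NA_real_
  for (i in seq.int(ipk, 2L)) {
    if (s[i - 1L] < half && s[i] >= half) {
      cross_left <- t[i - 1L] + (half - s[i - 1L]) / (s[i] - s[i - 1L]) *
        (t[i] - t[i - 1L])
      break
    }
  }
  cross_right <- NA_real_
  if (ipk < n) {
    for (i in seq.int(ipk, n - 1L)) {
      if (s[i] >= half && s[i + 1L] < half) {
        cross_right <- t[i] + (s[i] - half) / (s[i] - s[i + 1L]) *
          (t[i + 1L] - t[i])
        break
      }
    }
  }
  if (is.na(cross_left) && is.na(cross_right)) {
    hwhm <- NA_real_
    flags <- c(flags, "no_half_crossing")
  } else if (is.na(cross_left)) {
    hwhm <- cross_right - t1
    flags <- c(flags, "one_sided_flank")
  } else if (is.na(cross_right)) {
    hwhm <- t1 - cross_left
    flags <- c(flags, "one_sided_flank")
  } else {
    hwhm <- (cross_right - cross_left) / 2
  }

  # shoulders: local maxima before T1 above the threshold, separated
  shoulder_times <- numeric()
  thr <- shoulder_fraction * height
  if (ipk > 2L) {
    pre <- seq_len(ipk - 1L)
    is_max <- which(diff(sign(diff(s[pre]))) < 0) + 1L
    cand <- is_max[s[is_max] >= thr]
    # outside the primary peak's own half-height region
    if (!is.na(cross_left)) cand <- cand[t[cand] < cross_left]
    if (length(cand)) {
      cand <- cand[order(t[cand])]
      kept <- numeric()
      last <- -Inf
      for (i in cand) {
        if (t[i] - last >= shoulder_min_sep_s && (t1 - t[i]) >= shoulder_min_sep_s) {
          kept <- c(kept, t[i])
          last <- t[i]
        }
      }
      shoulder_times <- kept
    }
  }

  structure(list(t1_s = t1, hwhm_s = hwhm, peak_height = height,
                 direction = dir_sign, shoulder_times_s = shoulder_times,
                 flags = flags),
            class = "transition_event")
}

#' @export
print.transition_event <- function(x, ...) {
  cat(sprintf("<transition_event: T1 = %.3g s, HWHM = %.3g s, height %.3g, %s%s>\n",
              x$t1_s, x$hwhm_s, x$peak_height,
              if (x$direction > 0) "rising" else "falling",
              if (length(x$shoulder_times_s))
                sprintf(", %d shoulder(s)", length(x$shoulder_times_s)) else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
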