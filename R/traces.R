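#' Construct an intensity trace
#'
#' An intensity trace is a time-ordered record of mean gray level for one
#' superpixel or region of interest, the basic currency of the PVM pipeline.
#'
#' @param times_s Numeric vector of times in seconds, strictly increasing.
#' @param values Numeric vector of intensities (gray levels, or 0-1 if
#'   normalized), same length as `times_s`.
#' @param normalized Logical; `TRUE` if `values` have been min-max scaled.
#' @param source Free-text identifier of where the trace came from.
#' @return An object of class `"intensity_trace"`: a list with elements
#'   `times_s`, `values`, `normalized`, `source`.
#' @export
intensity_trace <- function(times_s, values, normalized = FALSE,
                            source = "trace") {
  times_s <- as.numeric(times_s)
  values <- as.numeric(values)
  if (length(times_s) != length(values))
    stop("`times_s` and `values` must have equal length")
  if (length(times_s) < 2L)
    stop("a trace needs at least two samples")
  if (any(!is.finite(times_s)) || any(!is.finite(values)))
    stop("trace contains non-finite entries")
  if (any(diff(times_s) <= 0))
    stop("`times_s` must be strictly increasing")
  if (isTRUE(normalized)) {
    rng <- range(values)
    if (abs(rng[1]) > 1e-9 || abs(rng[2] - 1) > 1e-9)
      stop("normalized trace must have min 0 and max 1")
  }
  structure(list(times_s = times_s, values = values,
                 normalized = isTRUE(normalized), source = source),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace '%s': %d samples, t = [%g, %g] s%s>\n",
              x$source, length(x$values), min(x$times_s), max(x$times_s),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
length.intensity_trace <- function(x) length(x$values)

#' Boxcar (centered moving-average) smoothing
#'
#' Smooths a trace with a centered boxcar of odd length, the same filter the
#' PVM analysis applies before differentiation (window 65 for the positional
#' analysis, 39 for the ROI-size analysis).  Edges are handled by reflection
#' padding so the output has the same length as the input.
#'
#' @param trace An [intensity_trace()].
#' @param window Odd positive integer, at most the trace length.
#' @return The smoothed trace.
#' @export
boxcar_smooth <- function(trace, window) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$values)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd positive integer")
  if (window > n)
    stop(sprintf("`window` (%d) exceeds trace length (%d); maximum usable window is %d",
                 window, n, if (n %% 2L == 1L) n else n - 1L))
  if (window == 1L) return(trace)
  h <- (window - 1L) %/% 2L
  v <- trace$values
  # reflect about the end samples (no duplication of the edge sample)
  padded <- c(v[(h + 1L):2L], v, v[(n - 1L):(n - h)])
  sm <- as.numeric(stats::filter(padded, rep(1 / window, window), sides = 2))
  out <- sm[(h + 1L):(h + n)]
  intensity_trace(trace$times_s, out, normalized = FALSE,
                  source = paste0(trace$source, "|boxcar", window))
}

#' Min-max normalization of a trace
#'
#' Rescales values to `(v - min) / (max - min)`, the normalization applied to
#' intensity plots before graphing.
#'
#' @param trace An [intensity_trace()].
#' @return A normalized trace (min 0, max 1).
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  rng <- range(trace$values)
  if (diff(rng) == 0)
    stop("cannot normalize a constant (degenerate) trace")
  intensity_trace(trace$times_s, (trace$values - rng[1]) / diff(rng),
                  normalized = TRUE, source = trace$source)
}

#' First derivative of a trace
#'
#' Central differences at interior points with local time spacing, one-sided
#' differences at the ends; units are value per second.  Length is preserved.
#'
#' @param trace An [intensity_trace()].
#' @return An `intensity_trace` holding `d(value)/dt`.
#' @export
first_derivative <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  t <- trace$times_s
  v <- trace$values
  n <- length(v)
  if (n < 3L) stop("derivative needs at least three samples")
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / (t[2] - t[1])
  d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  d[i] <- (v[i + 1] - v[i - 1]) / (t[i + 1] - t[i - 1])
  structure(list(times_s = t, values = d, normalized = FALSE,
                 source = paste0(trace$source, "|deriv")),
            class = "intensity_trace")
}
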