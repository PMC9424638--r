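#' Fit an HPLC standard curve
#'
#' Ordinary least squares of peak area on loaded amount for adenine
#' quantification standards.
#'
#' @param points Data frame with columns `nmol` (amount loaded) and `area`
#'   (HPLC peak area); at least 3 points.
#' @return An object of class `"standard_curve"`: `slope`, `intercept`,
#'   `r_squared`, the `points` and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points), all(c("nmol", "area") %in% names(points)))
  if (nrow(points) < 3) stop("a standard curve needs at least 3 points")
  if (stats::var(points$nmol) == 0) stop("standards have zero variance in amount")
  fit <- stats::lm(area ~ nmol, data = points)
  sst <- sum((points$area - mean(points$area))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 points = points, fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve: area = %.4g x nmol + %.4g, R^2 = %.4f (n = %d)>\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Percent ligand released from a photocaged precursor
#'
#' Compares an observed elution peak area against the area the standard
#' curve predicts for the full amount loaded:
#' `100 * area / (slope * amount + intercept)`.  Values are clipped to
#' `[0, 120]`; results above 100 carry an `out_of_range` flag.
#'
#' @param peak_area Observed adenine peak area.
#' @param amount_loaded_nmol Amount of caged compound loaded, nmol (> 0).
#' @param curve A [fit_standard_curve()] result.
#' @param through_origin If `TRUE`, ignore the intercept.
#' @return Percent released (numeric, possibly with attribute
#'   `out_of_range = TRUE`).
#' @export
percent_released <- function(peak_area, amount_loaded_nmol, curve,
                             through_origin = FALSE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (amount_loaded_nmol <= 0) stop("amount loaded must be positive")
  expected <- curve$slope * amount_loaded_nmol +
    if (through_origin) 0 else curve$intercept
  if (expected <= 0) stop("standard curve predicts non-positive expected area")
  pct <- 100 * peak_area / expected
  out <- min(max(pct, 0), 120)
  if (pct > 100 + 1e-9) attr(out, "out_of_range") <- TRUE
  out
}

#' Summarize replicate uncaging yields
#'
#' @param yields_percent Numeric vector of replicate percent-released
#'   values, each in `[0, 100]`.
#' @return List with `mean`, `sd` (sample sd, n-1; 0 with flag `"n=1"` for
#'   a single replicate) and `n`.
#' @export
summarize_replicates <- function(yields_percent) {
  y <- as.numeric(yields_percent)
  if (!length(y)) stop("need at least one replicate")
  if (any(y < 0 | y > 100)) stop("yields must lie in [0, 100]")
  n <- length(y)
  list(mean = mean(y),
       sd = if (n > 1) stats::sd(y) else 0,
       n = n,
       flag = if (n == 1) "n=1" else "")
}

#' UV beam power density
#'
#' Power density of a circular beam: `(power_mW / 1000) / (pi * (d/20)^2)`
#' with the diameter in mm converted to a radius in cm.
#'
#' @param power_mW Measured power in milliwatts (> 0).
#' @param diameter_mm Beam (or aperture) diameter in millimeters (> 0).
#' @return Power density in W/cm^2.
#' @export
power_density <- function(power_mW, diameter_mm) {
  if (power_mW <= 0 || diameter_mm <= 0) stop("power and diameter must be positive")
  (power_mW / 1000) / (pi * (diameter_mm / 20)^2)
}

#' Illuminated fraction of a drop
#'
#' Cross-sectional area ratio of beam to drop, `(beam/drop)^2`, ignoring
#' the height and shape of the liquid drop.  A beam wider than the drop is
#' capped at 1 with a warning.
#'
#' @param beam_diameter_mm,drop_diameter_mm Diameters in mm (> 0).
#' @return Fraction in `(0, 1]`.
#' @export
illuminated_fraction <- function(beam_diameter_mm, drop_diameter_mm) {
  if (beam_diameter_mm <= 0 || drop_diameter_mm <= 0)
    stop("diameters must be positive")
  if (beam_diameter_mm > drop_diameter_mm) {
    warning("beam wider than drop; fraction capped at 1")
    return(1)
  }
  (beam_diameter_mm / drop_diameter_mm)^2
}

#' Nominal uncaged-ligand concentration
#'
#' Concentration of free ligand produced from a caged stock at a given
#' percent yield: `c0 * yield / 100`.
#'
#' @param c0_mM Starting caged-compound concentration, mM.
#' @param yield_percent Percent released, `[0, 100]`.
#' @return Concentration in mM.
#' @export
nominal_uncaged_concentration <- function(c0_mM, yield_percent) {
  if (c0_mM < 0) stop("concentration must be non-negative")
  if (yield_percent < 0 || yield_percent > 100)
    stop("yield_percent must lie in [0, 100]")
  c0_mM * yield_percent / 100
}

#' Published uncaging-yield replicates
#'
#' Percent adenine released at 1, 5 and 10 s of 365-nm exposure, for the
#' bare LED (`direct`) and for the LED focused through the microscope
#' optics (`microscope`), three replicates each.
#'
#' @return Data frame with columns `mode`, `exposure_s`, `r1`, `r2`, `r3`.
#' @export
uncaging_replicates <- function() {
  data.frame(mode = rep(c("direct", "microscope"), each = 3),
             exposure_s = rep(c(1, 5, 10), 2),
             r1 = c(32.9, 61.0, 64.3, 8.9, 23.7, 28.5),
             r2 = c(34.5, 57.8, 60.4, 8.1, 28.1, 30.0),
             r3 = c(36.9, 66.9, 67.5, 10.4, 24.5, 26.1))
}
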