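#' Fit the four-state model to a normalized transition curve
#'
#' Reproducible replacement for by-eye parameter fitting: a coarse
#' logarithmic grid search over the free parameters followed by local
#' least-squares refinement (Levenberg-Marquardt on log-parameters) of the
#' sum of squared residuals between the model's normalized bound-state
#' curve ([transition_curve()]) and the data.  The binding constant `k_on`
#' is held fixed by default, as its value has little influence once the
#' other parameters are free.
#'
#' @param data An [intensity_trace()] of the observed normalized transition
#'   (0 to 1), covering the transition; times in seconds from UV exposure.
#' @param free Character vector of parameters to fit; any of `"B0_mM"`,
#'   `"k_op"`, `"k_f"` (default all three).
#' @param start Named list of starting/fixed values; defaults
#'   `B0_mM = 0.45`, `k_op = 2e-4`, `k_on = 3e-2`, `k_f = 0.7`.
#' @param lower,upper Named numeric bounds on the free parameters
#'   (multiplicative grid limits; defaults span two orders of magnitude).
#' @param grid_n Grid points per free parameter in the coarse stage
#'   (default 6).
#' @param R0_mM Each apo conformer's initial concentration, mM.
#' @param convention A [kinetic_convention()].
#' @param n_points Trajectory grid for each model evaluation.
#' @return An object of class `"kinetic_fit"` with components
#'   `coefficients`, `fixed`, `residual_norm`, `fitted` (model trace at the
#'   data times), `data`, `trajectory`, `convergence` and `call`.  If the
#'   local refinement fails, the best grid point is returned with
#'   `convergence$converged = FALSE`.
#' @seealso [coef.kinetic_fit()], [predict.kinetic_fit()],
#'   [plot.kinetic_fit()]
#' @export
fit_kinetics <- function(data, free = c("B0_mM", "k_op", "k_f"),
                         start = list(B0_mM = 0.45, k_op = 2e-4,
                                      k_on = 3e-2, k_f = 0.7),
                         lower = NULL, upper = NULL, grid_n = 6,
                         R0_mM = 16, convention = default_convention(),
                         n_points = 601) {
  stopifnot(inherits(data, "intensity_trace"))
  free <- match.arg(free, c("B0_mM", "k_op", "k_f"), several.ok = TRUE)
  v <- data$values
  if (diff(range(v)) < 1e-6) stop("flat data: no transition to fit")
  if (length(v) < 10) stop("too few samples to fit")
  t_end <- max(data$times_s)

  defaults <- list(B0_mM = 0.45, k_op = 2e-4, k_on = 3e-2, k_f = 0.7)
  start <- utils::modifyList(defaults, start)
  lo <- c(B0_mM = 0.05, k_op = 1e-5, k_f = 0.02)
  hi <- c(B0_mM = 3, k_op = 5e-3, k_f = 10)
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)

  model_resid <- function(theta) {
    p <- start
    p[free] <- as.list(theta)
    kp <- kinetic_params(B0_mM = p$B0_mM, k_op = p$k_op, k_on = p$k_on,
                         k_f = p$k_f, R0_mM = R0_mM, convention = convention)
    tc <- tryCatch(transition_curve(
      simulate_four_state(kp, t_end_s = t_end, n_points = n_points)),
      error = function(e) NULL)
    if (is.null(tc)) return(rep(1e3, length(v)))
    stats::approx(tc$times_s, tc$values, xout = data$times_s, rule = 2)$y - v
  }

  # coarse log-grid
  grids <- lapply(free, function(nm)
    exp(seq(log(lo[[nm]]), log(hi[[nm]]), length.out = grid_n)))
  names(grids) <- free
  grid <- as.matrix(expand.grid(grids))
  ss <- apply(grid, 1, function(th) sum(model_resid(th)^2))
  ord <- order(ss)
  best_grid <- grid[ord[1], ]

  # local Levenberg-Marquardt on log-parameters, multi-started from the
  # best grid points (the residual surface has sloppy valleys)
  starts <- lapply(ord[seq_len(min(4L, length(ord)))], function(i) grid[i, ])
  fit <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = log(st),
                         fn = function(lp) model_resid(exp(lp)),
                         lower = log(lo[free]), upper = log(hi[free]),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(fit) || f$deviance < fit$deviance)) fit <- f
  }
  converged <- !is.null(fit) && fit$info %in% 1:4 &&
    fit$deviance <= min(ss) + 1e-12
  theta <- if (!is.null(fit) && fit$deviance < min(ss)) exp(fit$par) else best_grid
  names(theta) <- free

  final <- start
  final[free] <- as.list(theta)
  kp <- kinetic_params(B0_mM = final$B0_mM, k_op = final$k_op,
                       k_on = final$k_on, k_f = final$k_f, R0_mM = R0_mM,
                       convention = convention)
  traj <- simulate_four_state(kp, t_end_s = t_end, n_points = n_points)
  tc <- transition_curve(traj)
  fitted_vals <- stats::approx(tc$times_s, tc$values,
                               xout = data$times_s, rule = 2)$y
  res <- fitted_vals - v
  structure(list(coefficients = theta,
                 fixed = unlist(start[setdiff(names(defaults), free)]),
                 residual_norm = sum(res^2),
                 fitted = intensity_trace(data$times_s, fitted_vals,
                                          source = "fit"),
                 data = data, params = kp, trajectory = traj,
                 convergence = list(converged = converged,
                                    grid_ss = min(ss),
                                    info = if (!is.null(fit)) fit$info else NA),
                 call = match.call()),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Four-state kinetic fit\n")
  cat("  coefficients:\n")
  for (nm in names(x$coefficients))
    cat(sprintf("    %-6s = %.4g\n", nm, x$coefficients[[nm]]))
  cat(sprintf("  residual sum of squares: %.4g%s\n", x$residual_norm,
              if (!x$convergence$converged) "  (NOT converged; best grid point)" else ""))
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  t1 <- tryCatch(inflection_time(object$trajectory), error = function(e) NA)
  cat("Four-state kinetic fit\n")
  print(object$params)
  cat(sprintf("  fitted T1 (inflection of B): %.2f s\n", t1))
  cat(sprintf("  residual sum of squares: %.4g over %d points\n",
              object$residual_norm, length(object$data$values)))
  cat(sprintf("  converged: %s\n", object$convergence$converged))
  invisible(object)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$coefficients

#' @export
fitted.kinetic_fit <- function(object, ...) object$fitted$values

#' @export
residuals.kinetic_fit <- function(object, ...)
  object$fitted$values - object$data$values

#' Predict the fitted transition curve
#'
#' @param object A [fit_kinetics()] result.
#' @param times Times (s) at which to evaluate; default the data times.
#' @param ... Unused.
#' @return Numeric vector of normalized model values.
#' @export
predict.kinetic_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted$values)
  kp <- object$params
  traj <- simulate_four_state(kp, t_end_s = max(times),
                              n_points = max(601, length(times)))
  tc <- transition_curve(traj)
  stats::approx(tc$times_s, tc$values, xout = times, rule = 2)$y
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  graphics::plot(x$data$times_s, x$data$values, pch = 1, col = "cyan4",
                 xlab = "time (s)", ylab = "normalized transition", ...)
  graphics::lines(x$fitted$times_s, x$fitted$values, col = "magenta", lwd = 2)
  graphics::legend("bottomright", legend = c("data", "fit"),
                   col = c("cyan4", "magenta"), pch = c(1, NA),
                   lty = c(NA, 1), bty = "n")
  invisible(x)
}
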