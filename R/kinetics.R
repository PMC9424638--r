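#' Rate-law convention for the four-state model
#'
#' The forward four-state model of ligand-driven conformational switching,
#'
#' \deqn{apo1 \rightarrow apo2 \; (+ ade) \rightarrow IB{\cdot}ade \rightarrow B{\cdot}ade,}
#'
#' is integrated with forward rate constants `k_op` (conformer opening),
#' `k_on` (ligand binding) and `k_f` (final conformational switch); the
#' reverse constants are fixed at zero because the in-crystal transition is
#' unidirectional.  Published parameter tables for this model print all
#' three constants in bimolecular units (per molar per second) even though
#' the first and third steps are unimolecular as written, so the exact rate
#' law and concentration-unit pairing the fitted numbers belong to is
#' ambiguous.  This object pins every ambiguous choice down explicitly:
#'
#' * `step1_order`, `step3_order` — whether the opening and switching steps
#'   are `"unimolecular"` or `"bimolecular"` (ligand-promoted, rate
#'   proportional to free ligand).
#' * `k_op_pairing`, `k_on_pairing`, `k_f_pairing` — the concentration unit
#'   a bimolecular constant multiplies when species are carried in mM:
#'   `"per_mM"` (use the printed number as mM^-1 s^-1), `"per_M"` (strict
#'   M^-1 s^-1 reading, factor 1e-3) or `"per_uM"` (uM^-1 s^-1 reading,
#'   factor 1e3).  Ignored for a unimolecular step.
#' * `ade_mode` — `"clamped"` (free ligand held at `B0`, exchange with the
#'   surrounding drop) or `"closed"` (free ligand depleted by binding).
#' * `apo2_init` — `"equal"` (both apo conformers start at `R0`) or
#'   `"empty"` (all RNA initially gated in apo1).
#'
#' The shipped default, [default_convention()], is the combination selected
#' by [calibrate_convention()] as best reproducing the three published
#' inflection times; see the methods vignette for the calibration.
#'
#' @param step1_order,step3_order `"unimolecular"` or `"bimolecular"`.
#' @param k_op_pairing,k_on_pairing,k_f_pairing `"per_M"`, `"per_mM"` or
#'   `"per_uM"`.
#' @param ade_mode `"clamped"` or `"closed"`.
#' @param apo2_init `"equal"` or `"empty"`.
#' @return An object of class `"kinetic_convention"`.
#' @export
kinetic_convention <- function(step1_order = c("unimolecular", "bimolecular"),
                               step3_order = c("unimolecular", "bimolecular"),
                               k_op_pairing = c("per_mM", "per_M", "per_uM"),
                               k_on_pairing = c("per_mM", "per_M", "per_uM"),
                               k_f_pairing = c("per_mM", "per_M", "per_uM"),
                               ade_mode = c("clamped", "closed"),
                               apo2_init = c("equal", "empty")) {
  structure(list(step1_order = match.arg(step1_order),
                 step3_order = match.arg(step3_order),
                 k_op_pairing = match.arg(k_op_pairing),
                 k_on_pairing = match.arg(k_on_pairing),
                 k_f_pairing = match.arg(k_f_pairing),
                 ade_mode = match.arg(ade_mode),
                 apo2_init = match.arg(apo2_init)),
            class = "kinetic_convention")
}

#' @rdname kinetic_convention
#' @export
default_convention <- function() {
  kinetic_convention(step1_order = "bimolecular",
                     step3_order = "unimolecular",
                     k_op_pairing = "per_uM",
                     k_on_pairing = "per_M",
                     k_f_pairing = "per_mM",
                     ade_mode = "closed",
                     apo2_init = "empty")
}

pairing_scale <- function(pairing) {
  switch(pairing, per_M = 1e-3, per_mM = 1, per_uM = 1e3)
}

#' @export
print.kinetic_convention <- function(x, ...) {
  cat(sprintf("<kinetic_convention: step1 %s (k_op %s), k_on %s, step3 %s (k_f %s), ade %s, apo2 %s>\n",
              x$step1_order, x$k_op_pairing, x$k_on_pairing, x$step3_order,
              x$k_f_pairing, x$ade_mode, x$apo2_init))
  invisible(x)
}

#' Parameters of the four-state forward model
#'
#' @param B0_mM Bulk adenine concentration in mM (> 0).
#' @param k_op,k_on,k_f Forward rate constants as printed (bimolecular units;
#'   their effective rate law is set by the `convention`).  All `>= 0`.
#' @param R0_mM Initial concentration of each apo conformer, mM; default 16,
#'   the in-crystal estimate from the unit-cell volume.
#' @param convention A [kinetic_convention()]; default the calibrated
#'   [default_convention()].
#' @return An object of class `"kinetic_params"`.  Reverse rate constants
#'   (`k_cl`, `k_off`, `k_r`) are identically zero and not parameters.
#' @export
kinetic_params <- function(B0_mM, k_op, k_on = 3.00e-2, k_f, R0_mM = 16,
                           convention = default_convention()) {
  stopifnot(inherits(convention, "kinetic_convention"))
  if (B0_mM <= 0) stop("B0_mM must be positive")
  if (R0_mM <= 0) stop("R0_mM must be positive")
  if (any(c(k_op, k_on, k_f) < 0)) stop("rate constants must be non-negative")
  structure(list(B0_mM = B0_mM, k_op = k_op, k_on = k_on, k_f = k_f,
                 R0_mM = R0_mM, convention = convention),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params: B0 = %g mM, k_op = %g, k_on = %g, k_f = %g, R0 = %g mM>\n",
              x$B0_mM, x$k_op, x$k_on, x$k_f, x$R0_mM))
  print(x$convention)
  invisible(x)
}

four_state_rates <- function(params) {
  cv <- params$convention
  list(kop = params$k_op *
         (if (cv$step1_order == "bimolecular") pairing_scale(cv$k_op_pairing) else 1),
       kon = params$k_on * pairing_scale(cv$k_on_pairing),
       kf = params$k_f *
         (if (cv$step3_order == "bimolecular") pairing_scale(cv$k_f_pairing) else 1),
       s1bi = cv$step1_order == "bimolecular",
       s3bi = cv$step3_order == "bimolecular",
       clamped = cv$ade_mode == "clamped")
}

four_state_deriv <- function(y, params, r = four_state_rates(params)) {
  ade <- if (r$clamped) params$B0_mM else y[5]
  rop <- r$kop * y[1] * (if (r$s1bi) ade else 1)
  ron <- r$kon * y[2] * ade
  rf <- r$kf * y[3] * (if (r$s3bi) ade else 1)
  c(-rop, rop - ron, ron - rf, rf, if (r$clamped) 0 else -ron)
}

#' Integrate the four-state forward model
#'
#' Mass-action ODE system for species apo1, apo2, free adenine (ade), the
#' ligand-bound intermediate (IB) and the switched bound state (B),
#' integrated with a stiff-capable adaptive solver.  Initial state:
#' `apo1 = R0`, `apo2 = R0` or 0 (per the convention's `apo2_init`),
#' `IB = B = 0`, `ade = B0`.
#'
#' @param params A [kinetic_params()].
#' @param t_end_s End of the integration window, seconds.
#' @param n_points Number of equally spaced output times (including 0).
#' @param rtol,atol Solver tolerances (relative; absolute in mM).
#' @return An object of class `"kinetic_trajectory"`: data.frame `species`
#'   with columns `time_s`, `apo1`, `apo2`, `IB`, `B`, `ade` (mM), plus the
#'   generating `params` and solver metadata.
#' @export
simulate_four_state <- function(params, t_end_s = 400, n_points = 2001,
                                rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "kinetic_params"))
  if (t_end_s <= 0 || n_points < 3) stop("need t_end_s > 0 and n_points >= 3")
  r <- four_state_rates(params)
  y0 <- c(apo1 = params$R0_mM,
          apo2 = if (params$convention$apo2_init == "equal") params$R0_mM else 0,
          IB = 0, B = 0, ade = params$B0_mM)
  times <- seq(0, t_end_s, length.out = n_points)
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, p) list(four_state_deriv(y, params, r)),
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  df <- as.data.frame(sol)
  names(df)[1] <- "time_s"
  if (min(df$apo1, df$apo2, df$IB, df$B, df$ade) < -1e4 * atol)
    stop("solver produced negative concentrations beyond tolerance; retry with tighter atol/rtol")
  df[df < 0] <- 0
  structure(list(species = df, params = params,
                 solver = list(method = "lsoda", rtol = rtol, atol = atol,
                               n_points = n_points, t_end_s = t_end_s)),
            class = "kinetic_trajectory")
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  df <- x$species
  cat(sprintf("<kinetic_trajectory: %d points over 0-%g s; final B = %.4g mM>\n",
              nrow(df), max(df$time_s), df$B[nrow(df)]))
  invisible(x)
}

#' @export
plot.kinetic_trajectory <- function(x, species = c("apo1", "apo2", "IB", "B"),
                                    ...) {
  df <- x$species
  cols <- c(apo1 = "black", apo2 = "gray40", IB = "red", B = "magenta",
            ade = "blue")
  graphics::matplot(df$time_s, as.matrix(df[, species, drop = FALSE]),
                    type = "l", lty = 1, col = cols[species],
                    xlab = "time (s)", ylab = "concentration (mM)", ...)
  graphics::legend("right", legend = species, col = cols[species], lty = 1,
                   bty = "n")
  invisible(x)
}

#' Inflection time of a species trajectory
#'
#' Time of the maximum first derivative of a species curve — for the bound
#' switched state this is the model's transition time T1.  The grid argmax
#' is refined by a parabolic fit through the three neighboring derivative
#' samples.
#'
#' @param traj A [simulate_four_state()] trajectory.
#' @param species Column to analyze; default `"B"`.
#' @return Inflection time in seconds.
#' @export
inflection_time <- function(traj, species = "B") {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  df <- traj$species
  t <- df$time_s
  v <- df[[species]]
  if (is.null(v)) stop("unknown species: ", species)
  d <- diff(v) / diff(t)
  tm <- (t[-1] + t[-length(t)]) / 2
  i <- which.max(d)
  if (i <= 1L || i >= length(d) || max(d) <= 0 ||
      diff(range(d)) <= 1e-9 * max(abs(d)))
    stop("no interior inflection point: derivative has no interior maximum")
  den <- d[i - 1] - 2 * d[i] + d[i + 1]
  if (den == 0) return(tm[i])
  tm[i] + 0.5 * (d[i - 1] - d[i + 1]) / den * (tm[i + 1] - tm[i])
}

#' Normalized transition curve
#'
#' The switched-state concentration scaled by its final value: the model's
#' counterpart of a normalized PVM intensity trace, aligned to `t = 0` at
#' UV exposure.
#'
#' @param traj A [simulate_four_state()] trajectory.
#' @return An [intensity_trace()] rising from 0 to 1 (last point exactly 1).
#' @export
transition_curve <- function(traj) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  df <- traj$species
  b <- df$B
  fin <- b[length(b)]
  if (fin <= 0) stop("no conversion: B stays at zero over the window")
  intensity_trace(df$time_s, b / fin, source = "four_state_B")
}

#' Sensitivity of T1 to one rate constant
#'
#' Rescales one rate constant over a factor grid and records the resulting
#' inflection time; quantifies statements like "changes to the binding rate
#' constant have little effect on the kinetic profiles".
#'
#' @param params A [kinetic_params()].
#' @param which One of `"k_op"`, `"k_on"`, `"k_f"`, `"B0_mM"`.
#' @param factors Multiplicative factors to apply.
#' @param t_end_s,n_points Passed to [simulate_four_state()].
#' @return Data frame with `factor`, `value`, `t1_s`; attribute
#'   `max_rel_change` holds `max |T1/T1(factor=1) - 1|`.
#' @export
sensitivity_scan <- function(params, which = "k_on",
                             factors = 10^seq(-1, 1, length.out = 9),
                             t_end_s = 400, n_points = 2001) {
  stopifnot(inherits(params, "kinetic_params"),
            which %in% c("k_op", "k_on", "k_f", "B0_mM"))
  rows <- lapply(factors, function(f) {
    p <- params
    p[[which]] <- params[[which]] * f
    t1 <- tryCatch(inflection_time(simulate_four_state(p, t_end_s, n_points)),
                   error = function(e) NA_real_)
    data.frame(factor = f, value = p[[which]], t1_s = t1)
  })
  out <- do.call(rbind, rows)
  base <- out$t1_s[which.min(abs(out$factor - 1))]
  attr(out, "max_rel_change") <- max(abs(out$t1_s / base - 1), na.rm = TRUE)
  out
}

#' Enumerate candidate rate-law conventions
#'
#' The default calibration grid: both orders for steps 1 and 3, three unit
#' pairings for `k_op`, strict-M and per-mM pairings for `k_on`, both ligand
#' modes and both initial apo2 occupancies (96 conventions; `k_f` is paired
#' per-mM when step 3 is bimolecular).
#'
#' @return List of [kinetic_convention()] objects.
#' @export
enumerate_conventions <- function() {
  out <- list()
  for (s1 in c("unimolecular", "bimolecular"))
    for (s3 in c("unimolecular", "bimolecular"))
      for (p_op in c("per_M", "per_mM", "per_uM"))
        for (p_on in c("per_M", "per_mM"))
          for (mode in c("clamped", "closed"))
            for (a2 in c("equal", "empty"))
              out[[length(out) + 1L]] <- kinetic_convention(
                step1_order = s1, step3_order = s3,
                k_op_pairing = p_op, k_on_pairing = p_on,
                k_f_pairing = "per_mM", ade_mode = mode, apo2_init = a2)
  out
}

#' Published parameter sets for the three reference crystals
#'
#' The fitted four-state parameters for the small (S2), medium (M3) and
#' large (L1) reference crystals, with the transition times measured from
#' their 1 x 1 um PVM traces.  `B0` in mM; rate constants as printed.
#'
#' @return Data frame with columns `crystal`, `B0_mM`, `k_op`, `k_on`,
#'   `k_f`, `t1_s`.
#' @export
reference_crystals <- function() {
  data.frame(crystal = c("S2", "M3", "L1"),
             B0_mM = c(0.46, 0.42, 0.43),
             k_op = c(2.35e-4, 2.00e-4, 1.60e-4),
             k_on = c(3.00e-2, 3.00e-2, 3.00e-2),
             k_f = c(0.5, 1.0, 0.9),
             t1_s = c(55.7, 60.4, 72.1))
}

#' Calibrate the rate-law convention against published transition times
#'
#' Integrates every candidate convention with each reference crystal's
#' printed parameter column and scores the root-mean-square relative error
#' between the simulated bound-state inflection times and the measured
#' transition times.  The convention minimizing that score is returned;
#' conventions whose trajectories have no interior inflection inside the
#' window are discarded.
#'
#' @param reference Data frame as from [reference_crystals()].
#' @param conventions List of candidates; default [enumerate_conventions()].
#' @param t_end_s Integration window per run (default 2000 s, generous
#'   enough to expose slow conventions as poor fits).
#' @param n_points Output grid size per run.
#' @return List with `best` (the winning convention), `score` (its RMS
#'   relative error) and `table` (data.frame of all scored candidates).
#' @export
calibrate_convention <- function(reference = reference_crystals(),
                                 conventions = enumerate_conventions(),
                                 t_end_s = 2000, n_points = 4001) {
  rows <- lapply(seq_along(conventions), function(ci) {
    cv <- conventions[[ci]]
    rel <- vapply(seq_len(nrow(reference)), function(i) {
      p <- kinetic_params(B0_mM = reference$B0_mM[i], k_op = reference$k_op[i],
                          k_on = reference$k_on[i], k_f = reference$k_f[i],
                          convention = cv)
      t1 <- tryCatch(
        inflection_time(simulate_four_state(p, t_end_s, n_points,
                                            rtol = 1e-8, atol = 1e-10)),
        error = function(e) NA_real_)
      (t1 - reference$t1_s[i]) / reference$t1_s[i]
    }, numeric(1))
    data.frame(convention = ci,
               step1 = cv$step1_order, step3 = cv$step3_order,
               k_op_pairing = cv$k_op_pairing, k_on_pairing = cv$k_on_pairing,
               ade_mode = cv$ade_mode, apo2_init = cv$apo2_init,
               rmse = if (any(is.na(rel))) NA_real_ else sqrt(mean(rel^2)))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$rmse))
  if (!length(ok)) stop("no candidate convention produced an inflection for every reference crystal")
  best_i <- ok[which.min(tab$rmse[ok])]
  list(best = conventions[[best_i]], score = tab$rmse[best_i],
       table = tab[order(tab$rmse), ])
}
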