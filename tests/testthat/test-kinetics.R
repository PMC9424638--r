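ref <- reference_crystals()

params_for <- function(i, convention = default_convention()) {
  kinetic_params(B0_mM = ref$B0_mM[i], k_op = ref$k_op[i], k_on = ref$k_on[i],
                 k_f = ref$k_f[i], convention = convention)
}

test_that("degenerate rate limits behave as conservation laws demand", {
  # all forward rates zero: every species constant
  p0 <- kinetic_params(B0_mM = 0.46, k_op = 0, k_on = 0, k_f = 0,
                       convention = kinetic_convention(apo2_init = "equal"))
  tr0 <- simulate_four_state(p0, 100, 101)
  for (sp in c("apo1", "apo2", "IB", "B", "ade"))
    expect_equal(diff(range(tr0$species[[sp]])), 0)

  # k_op = 0 in closed mode: apo1 frozen, ligand pool conserved
  pc <- kinetic_params(B0_mM = 0.46, k_op = 0, k_f = 0.5,
                       convention = kinetic_convention(ade_mode = "closed",
                                                       apo2_init = "equal"))
  trc <- simulate_four_state(pc, 200, 201)
  expect_equal(trc$species$apo1, rep(16, 201))
  lig <- trc$species$IB + trc$species$B + trc$species$ade
  expect_lt(max(abs(lig - 0.46)) / 0.46, 1e-6)
})

test_that("RNA is conserved and the forward flux is monotone", {
  for (i in 1:3) for (cv in list(default_convention(),
                                 kinetic_convention(ade_mode = "clamped",
                                                    apo2_init = "equal"))) {
    tr <- simulate_four_state(params_for(i, cv), 400, 1001)
    sp <- tr$species
    total <- sp$apo1 + sp$apo2 + sp$IB + sp$B
    total0 <- sp$apo1[1] + sp$apo2[1]
    expect_lt(max(abs(total - total0)) / total0, 1e-6)
    expect_true(all(diff(sp$B) >= -1e-9))
    expect_true(all(diff(sp$apo1) <= 1e-9))
    expect_true(all(sp[, -1] >= -1e-8))
  }
})

test_that("the adaptive solver agrees with a fixed-step RK4 reference", {
  for (i in c(1, 3)) {
    p <- params_for(i)
    oracle <- rk4_four_state(p, t_end = 60, dt = 1e-3)
    tr <- simulate_four_state(p, 60, 601)
    ours <- approx(tr$species$time_s, tr$species$B, xout = oracle$time)$y
    expect_lt(max(abs(ours - oracle$B)) / max(oracle$B), 1e-4)
  }
})

test_that("a clamped unimolecular cascade matches the Bateman closed form", {
  # step1/step3 unimolecular, ligand clamped: a linear chain
  cv <- kinetic_convention(step1_order = "unimolecular",
                           step3_order = "unimolecular",
                           k_on_pairing = "per_mM",
                           ade_mode = "clamped", apo2_init = "empty")
  p <- kinetic_params(B0_mM = 0.4, k_op = 0.03, k_on = 0.05, k_f = 0.3,
                      R0_mM = 16, convention = cv)
  tr <- simulate_four_state(p, 300, 601)
  lam <- c(0.03, 0.05 * 0.4, 0.3)  # k_op, k_on*B0, k_f
  expected <- bateman_terminal(tr$species$time_s, 16, lam)
  expect_equal(tr$species$B, expected, tolerance = 1e-6)
})

test_that("inflection extraction: analytic curves and error cases", {
  fake <- function(t, v) structure(list(species = data.frame(time_s = t, B = v)),
                                   class = "kinetic_trajectory")
  t <- seq(0, 120, 0.25)
  expect_equal(inflection_time(fake(t, pnorm((t - 60) / 10))), 60,
               tolerance = 0.05)
  expect_error(inflection_time(fake(t, 0.01 * t)), "no interior inflection")
  expect_error(inflection_time(fake(t, rep(0, length(t)))), "no interior")
})

test_that("reference parameter columns give the calibrated transition times", {
  # regression guard on the shipped convention: S2/M3/L1 inflection times
  got <- vapply(1:3, function(i)
    inflection_time(simulate_four_state(params_for(i), 400, 4001)),
    numeric(1))
  expect_equal(got, c(52.44, 62.72, 73.62), tolerance = 2e-3)
  # and they reproduce the measured transition times to better than 7%
  expect_true(all(abs(got - ref$t1_s) / ref$t1_s < 0.07))
})

test_that("convention calibration selects the shipped default", {
  cal <- calibrate_convention()
  expect_identical(unclass(cal$best), unclass(default_convention()))
  expect_lt(cal$score, 0.05)
})

test_that("normalized transition curve is a scale-free monotone sigmoid", {
  tr <- simulate_four_state(params_for(1), 400, 801)
  tc <- transition_curve(tr)
  expect_equal(tc$values[length(tc$values)], 1)
  expect_true(all(diff(tc$values) >= -1e-9))
  # inflection of the normalized curve equals that of the raw trajectory
  fake <- structure(list(species = data.frame(time_s = tc$times_s,
                                              B = tc$values)),
                    class = "kinetic_trajectory")
  expect_equal(inflection_time(fake), inflection_time(tr), tolerance = 0.5)
})

test_that("T1 sensitivity scans behave as expected", {
  p <- params_for(1)
  sc <- sensitivity_scan(p, "k_f", factors = c(0.5, 1, 2, 4))
  expect_equal(nrow(sc), 4)
  base <- inflection_time(simulate_four_state(p, 400, 2001))
  expect_equal(sc$t1_s[sc$factor == 1], base, tolerance = 0.2)
  # larger k_f never delays the transition
  expect_true(all(diff(sc$t1_s) <= 0.2))
})

test_that("parameter validation rejects unphysical input", {
  expect_error(kinetic_params(B0_mM = 0, k_op = 1e-4, k_f = 0.5), "positive")
  expect_error(kinetic_params(B0_mM = 0.4, k_op = -1, k_f = 0.5),
               "non-negative")
  expect_error(kinetic_params(B0_mM = 0.4, k_op = 1e-4, k_f = 0.5,
                              R0_mM = -1), "positive")
})
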