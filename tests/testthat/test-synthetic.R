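test_that("T1 field: degenerate, gradient and random components", {
  # degenerate: no gradient, no noise -> constant field on the mask
  sp <- square_spec(noise = 0, t1_noise = 0, gradient = 0)
  f <- generate_t1_field(sp)
  expect_true(all(is.finite(f$t1_s[f$mask])))
  expect_true(all(is.na(f$t1_s[!f$mask])))
  expect_equal(unique(as.numeric(f$t1_s[f$mask])), 60)

  # pure column gradient: T1 difference = g * dcol * pixel size
  g <- 2.5
  sp <- square_spec(h = 40, w = 40, margin = 2, gradient = g)
  f <- generate_t1_field(sp)
  cols <- which(f$mask, arr.ind = TRUE)[, 2]
  left <- f$t1_s[cbind(10, min(cols))]
  right <- f$t1_s[cbind(10, max(cols))]
  expect_equal(right - left,
               g * (max(cols) - min(cols)) * sp$pixel_size_um,
               tolerance = 1e-10)

  # random field rescaled to the requested sd (10% tolerance on a big mask)
  sp <- crystal_spec(image_height_px = 210, image_width_px = 210,
                     duration_s = 150,
                     crystal_polygon = rbind(c(2, 2), c(2, 205),
                                             c(205, 205), c(205, 2)),
                     t1_mean_s = 60, t1_noise_sd_s = 3,
                     t1_corr_length_um = 0.5, seed = 3)
  f <- generate_t1_field(sp)
  expect_gt(sd(f$t1_s[f$mask]), 2.7)
  expect_lt(sd(f$t1_s[f$mask]), 3.3)

  # determinism
  f2 <- generate_t1_field(sp)
  expect_identical(f$t1_s, f2$t1_s)

  expect_error(crystal_spec(image_height_px = 20, image_width_px = 20,
                            crystal_polygon = rbind(c(0, 0), c(0, 30), c(30, 30))),
               "outside the image")
})

test_that("pixel intensity curve matches its closed form", {
  sp <- square_spec(noise = 0, shoulder = 0)
  # far before the transition: baseline
  expect_equal(pixel_intensity_curve(0, 120, sp), sp$baseline_intensity,
               tolerance = 1e-6)
  # CDF midpoint at t = t1 when there is no shoulder
  dI <- sp$final_intensity - sp$baseline_intensity
  expect_equal(pixel_intensity_curve(60, 60, sp),
               sp$baseline_intensity + dI / 2)
  # numeric derivative: argmax at t1, HWHM = sigma * sqrt(2 ln 2)
  t <- seq(0, 150, by = 0.01)
  v <- pixel_intensity_curve(t, 60, sp)
  d <- diff(v) / diff(t)
  tm <- (t[-1] + t[-length(t)]) / 2
  expect_equal(tm[which.max(d)], 60, tolerance = 0.01)
  br <- brute_detect(tm, d)
  expect_equal(br$hwhm, sp$primary_width_s * sqrt(2 * log(2)),
               tolerance = 1e-3)
  # monotone when dI != 0
  expect_true(all(diff(v) >= 0))
})

test_that("rendering: frame count, determinism, mass of change", {
  sp <- square_spec(h = 24, w = 24, margin = 3, noise = 0, duration = 30)
  sim <- render_video(sp)
  expect_equal(dim(sim$stack$frames)[1], floor(30 / 0.5) + 1)

  # noise 0 and dI = 0 -> every frame identical
  sp0 <- square_spec(h = 24, w = 24, margin = 3, noise = 0, duration = 30)
  sp0$final_intensity <- sp0$baseline_intensity
  sim0 <- render_video(sp0)
  for (k in 2:dim(sim0$stack$frames)[1])
    expect_identical(sim0$stack$frames[k, , ], sim0$stack$frames[1, , ])

  # bit-identical reruns
  sp1 <- square_spec(h = 24, w = 24, margin = 3, noise = 1.5, duration = 30,
                     t1_noise = 2, seed = 42)
  expect_identical(render_video(sp1)$stack$frames,
                   render_video(sp1)$stack$frames)

  # mass of change: |I(last) - I(first)| = |dI| (+/- 1 level) on the mask,
  # 0 off the mask (noise-free, transition fully inside the window)
  spm <- square_spec(h = 24, w = 24, margin = 3, noise = 0, t1 = 60)
  simm <- render_video(spm)
  nT <- dim(simm$stack$frames)[1]
  delta <- abs(simm$stack$frames[nT, , ] - simm$stack$frames[1, , ])
  dI <- abs(spm$final_intensity - spm$baseline_intensity)
  expect_true(all(abs(delta[simm$truth$mask] - dI) <= 1))
  expect_true(all(delta[!simm$truth$mask] == 0))
})

test_that("falling transitions and drift are rendered faithfully", {
  sp <- square_spec(h = 24, w = 24, margin = 3, noise = 0)
  sp$baseline_intensity <- 200; sp$final_intensity <- 40
  sim <- render_video(sp)
  nT <- dim(sim$stack$frames)[1]
  expect_true(mean(sim$stack$frames[nT, , ] - sim$stack$frames[1, , ]) < 0)

  spd <- square_spec(h = 24, w = 24, margin = 8, noise = 0, duration = 30)
  spd$drift_px_per_frame <- c(1, 0)  # 1 row per frame: exits the 24-px frame
  expect_warning(simd <- render_video(spd), "truncated")
  expect_true(isTRUE(attr(simd$stack, "truncated")))
})

test_that("analyzer round trip recovers a constant T1 field without smoothing", {
  sp <- square_spec(h = 28, w = 28, margin = 4, noise = 0, shoulder = 0,
                    t1 = 60)
  sim <- render_video(sp)
  tr <- superpixel_traces(crop_roi(sim$stack, roi(8, 8, 12)), 1L)
  t1s <- vapply(tr, function(x)
    detect_transition(first_derivative(x))$t1_s, numeric(1))
  expect_true(all(abs(t1s - 60) <= sp$frame_interval_s))
})

test_that("ground truth CSV round-trips", {
  sp <- square_spec(h = 16, w = 16, margin = 3, duration = 20, t1 = 10)
  f <- generate_t1_field(sp)
  path <- tempfile(fileext = ".csv")
  write_t1_csv(f, path)
  df <- read.csv(path)
  expect_equal(nrow(df), sum(f$mask))
  expect_equal(df$t1_s, f$t1_s[cbind(df$row + 1, df$col + 1)])
})
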