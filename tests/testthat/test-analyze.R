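test_that("positional analysis recovers a uniform transition", {
  sp <- square_spec(h = 36, w = 36, margin = 4, t1 = 58, noise = 0)
  sim <- render_video(sp)
  rois <- list(roi(6, 6, 10, "A"), roi(6, 20, 10, "B"),
               roi(20, 6, 10, "C"), roi(20, 20, 10, "D"))
  res <- analyze_positions(sim$stack, rois, window = 15)
  expect_equal(nrow(res$events), 4)
  expect_true(all(res$events$status == "ok"))
  expect_equal(res$summary$mean_t1_s, 58, tolerance = 0.6)
  expect_lt(res$summary$sd_t1_s, 0.5)

  single <- analyze_positions(sim$stack, list(roi(6, 6, 10, "only")),
                              window = 15)
  expect_equal(single$summary$sd_t1_s, 0)
  expect_equal(single$summary$flag, "n=1")
})

test_that("per-ROI T1 ordering follows a spatial gradient", {
  sp <- square_spec(h = 56, w = 56, margin = 2, gradient = 5, noise = 1,
                    seed = 11)
  sim <- render_video(sp)
  res <- analyze_positions(sim$stack,
                           list(roi(24, 4, 10, "left"),
                                roi(24, 24, 10, "mid"),
                                roi(24, 44, 10, "right")),
                           window = 15)
  t1 <- res$events$t1_s
  expect_true(t1[1] < t1[2] && t1[2] < t1[3])
})

test_that("ROI-size sweep: uniform field gives zero spread, gradient grows it", {
  spc <- square_spec(h = 56, w = 56, margin = 2, noise = 0, shoulder = 0)
  simc <- render_video(spc)
  swc <- roi_size_sweep(simc$stack, center = c(28, 28),
                        sizes_px = c(2, 4, 8, 14), window = 15, bin_px = 1)
  expect_true(all(swc$stats$sd_t1_s < 1e-9))

  spg <- square_spec(h = 56, w = 56, margin = 2, gradient = 5, seed = 11)
  simg <- render_video(spg)
  swg <- roi_size_sweep(simg$stack, center = c(28, 28),
                        sizes_px = c(2, 4, 8, 14, 28, 42), window = 15,
                        bin_px = 2)
  expect_true(all(diff(swg$stats$sd_t1_s) >= -1e-9))

  # size 2 with bin 2: exactly one superpixel, flagged n=1
  one <- swg$stats[swg$stats$size_px == 2, ]
  expect_equal(one$n_superpixels, 1)
  expect_equal(one$flag, "n=1")

  # sizes larger than the frame are clipped with a warning
  expect_warning(
    roi_size_sweep(simc$stack, center = c(28, 28), sizes_px = c(64),
                   window = 15), "clipping")
})

test_that("time-shifting a video shifts every T1 by exactly the shift", {
  sp <- square_spec(h = 28, w = 28, margin = 4, noise = 0, t1 = 50,
                    duration = 120)
  sim <- render_video(sp)
  f <- sim$stack$frames
  k <- 20L  # shift by 20 frames = 10 s
  shifted <- f[c(rep(1L, k), seq_len(dim(f)[1] - k)), , ]
  st2 <- frame_stack(shifted, sp$frame_interval_s, sp$pixel_size_um)
  r <- roi(8, 8, 10, "r")
  e1 <- analyze_positions(sim$stack, list(r), window = 15)$events$t1_s
  e2 <- analyze_positions(st2, list(r), window = 15)$events$t1_s
  expect_equal(e2 - e1, k * sp$frame_interval_s)
})

test_that("affine intensity scaling leaves T1 and HWHM unchanged", {
  # built directly (real-valued frames) so re-quantization cannot blur it
  t <- seq(0, 120, 0.5)
  h <- 12; w <- 12
  arr <- array(rep(40 + 120 * pnorm((t - 60) / 6), h * w),
               dim = c(length(t), h, w))
  st1 <- frame_stack(arr, 0.5)
  st2 <- frame_stack(0.5 * arr + 30, 0.5)
  r <- list(roi(2, 2, 8, "r"))
  a1 <- analyze_positions(st1, r, window = 15)$events
  a2 <- analyze_positions(st2, r, window = 15)$events
  expect_equal(a1$t1_s, a2$t1_s)
  expect_equal(a1$hwhm_s, a2$hwhm_s, tolerance = 1e-9)
})

test_that("k-means classification of T1 values", {
  expect_equal(cluster_t1(c(50, 60, 70), 1)$centroids, 60)

  v <- c(50, 51, 52, 90, 91, 92)
  cl <- cluster_t1(v, 2, seed = 3)
  expect_equal(cl$centroids, c(51, 91))
  expect_equal(cl$labels, c(1, 1, 1, 2, 2, 2))

  # oracle: exhaustive scan over all contiguous 2-partitions of sorted data
  best_ss <- Inf
  sv <- sort(v)
  for (cut in 1:(length(sv) - 1)) {
    a <- sv[1:cut]; b <- sv[(cut + 1):length(sv)]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    best_ss <- min(best_ss, ss)
  }
  expect_equal(cl$tot_withinss, best_ss)

  # permutation invariance of the partition
  perm <- c(4, 1, 6, 2, 5, 3)
  cl2 <- cluster_t1(v[perm], 2, seed = 3)
  expect_equal(cl2$labels, cl$labels[perm])

  expect_error(cluster_t1(c(1, 2), 3), "at least k")
})

test_that("HWHM tabulation by crystal and ROI size", {
  empty <- hwhm_report(data.frame())
  expect_equal(nrow(empty), 0)

  one <- hwhm_report(data.frame(crystal = "S2", size_px = 14, hwhm_s = 17.2))
  expect_equal(one$mean_hwhm_s, 17.2)
  expect_equal(one$sd_hwhm_s, 0)
  expect_equal(one$flag, "n=1")

  ev <- data.frame(crystal = rep(c("A", "B"), each = 4),
                   size_px = rep(c(2, 2, 14, 14), 2),
                   hwhm_s = c(10, 12, 9, 11, 20, 22, 19, 21))
  rep_ <- hwhm_report(ev)
  expect_equal(nrow(rep_), 4)
  expect_equal(rep_$mean_hwhm_s[rep_$crystal == "A" & rep_$size_px == 2], 11)
  expect_equal(rep_$sd_hwhm_s[rep_$crystal == "B" & rep_$size_px == 14],
               sd(c(19, 21)))
})
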