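# Shared fixture builders: everything is generated in code at test time.

square_spec <- function(h = 48, w = 48, margin = 4, t1 = 60, duration = 150,
                        noise = 1, shoulder = 0.15, gradient = 0,
                        t1_noise = 0, seed = 7, ...) {
  crystal_spec(image_height_px = h, image_width_px = w,
               duration_s = duration, frame_interval_s = 0.5,
               crystal_polygon = rbind(c(margin, margin),
                                       c(margin, w - margin - 1),
                                       c(h - margin - 1, w - margin - 1),
                                       c(h - margin - 1, margin)),
               t1_mean_s = t1, t1_gradient_s_per_um = gradient,
               t1_noise_sd_s = t1_noise, primary_width_s = 6,
               shoulder_fraction = shoulder, shoulder_lead_s = 15,
               shoulder_width_s = 6, noise_sd = noise, seed = seed, ...)
}

# Gaussian derivative pulse as an intensity_trace (for detector tests)
gauss_pulse <- function(center, sigma, height = 1, t = seq(0, 150, 0.1)) {
  intensity_trace(t, height * exp(-(t - center)^2 / (2 * sigma^2)))
}

# Brute-force transition oracle: argmax over raw samples, half-height
# crossings located by linear scan + interpolation.
brute_detect <- function(t, v) {
  i <- which.max(v)
  h <- v[i] / 2
  left <- NA_real_
  if (i > 1) {
    for (j in seq.int(i - 1, 1)) {
      if (v[j] < h) {
        left <- t[j] + (h - v[j]) / (v[j + 1] - v[j]) * (t[j + 1] - t[j])
        break
      }
    }
  }
  right <- NA_real_
  if (i < length(v)) {
    for (j in seq.int(i + 1, length(v))) {
      if (v[j] < h) {
        right <- t[j - 1] + (v[j - 1] - h) / (v[j - 1] - v[j]) * (t[j] - t[j - 1])
        break
      }
    }
  }
  hwhm <- if (is.na(left) && is.na(right)) NA_real_
  else if (is.na(left)) right - t[i]
  else if (is.na(right)) t[i] - left
  else (right - left) / 2
  list(t1 = t[i], hwhm = hwhm)
}

# Bateman solution for an irreversible linear chain
# X1 -l1-> X2 -l2-> X3 -l3-> X4 (terminal), X1(0) = x0: returns X4(t).
bateman_terminal <- function(t, x0, l) {
  stopifnot(length(l) == 3, length(unique(l)) == 3)
  lam <- c(l, 0)
  x4 <- numeric(length(t))
  for (i in seq_along(lam)) {
    denom <- prod(lam[-i] - lam[i])
    x4 <- x4 + exp(-lam[i] * t) / denom
  }
  x0 * prod(l) * x4
}

# Fixed-step classical RK4 integrator for the four-state system.
rk4_four_state <- function(params, t_end, dt) {
  r <- sspt:::four_state_rates(params)
  y <- c(params$R0_mM,
         if (params$convention$apo2_init == "equal") params$R0_mM else 0,
         0, 0, params$B0_mM)
  n <- ceiling(t_end / dt)
  keep_every <- max(1L, floor(n / 400))
  out_t <- numeric(0); out_B <- numeric(0)
  f <- function(y) sspt:::four_state_deriv(y, params, r)
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %% keep_every == 0L) {
      out_t <- c(out_t, i * dt)
      out_B <- c(out_B, y[4])
    }
  }
  list(time = out_t, B = out_B)
}
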