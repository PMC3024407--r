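test_that("phase differences map linearly to velocity", {
  ref <- matrix(complex(modulus = 1, argument = 0.3), 4, 4)
  enc <- ref * exp(1i * pi / 2)
  expect_equal(phase_to_velocity(ref, enc, 30),
               matrix(15, 4, 4))
  expect_equal(phase_to_velocity(ref, ref, 30), matrix(0, 4, 4))
  # zero-magnitude pixels are flagged invalid
  ref[1, 1] <- 0
  v <- phase_to_velocity(ref, enc, 30)
  expect_true(is.na(v[1, 1]))
  expect_false(anyNA(v[-1, ]))
  expect_error(phase_to_velocity(ref, enc[1:2, ], 30), "dimensions")
})

test_that("encoding followed by phase mapping is the identity", {
  ph <- tiny_phantom(n_phases = 4)
  enc <- encode_velocity(ph, background_coeffs = c(0.2, 0.01, -0.02))
  for (e in 1:3) {
    v <- phase_to_velocity(enc$images[, , 2, 1], enc$images[, , 2, e + 1], 30)
    expect_lt(max(abs(v - ph$velocity[, , 2, e]), na.rm = TRUE), 1e-10)
  }
})

test_that("background plane fit recovers injected coefficients", {
  n <- 32
  sm <- matrix(FALSE, n, n); sm[3:8, 4:28] <- TRUE
  rows <- matrix(0:(n - 1), n, n); cols <- t(rows)
  coeffs <- c(0.5, 0.01, -0.02)
  img <- coeffs[1] + coeffs[2] * rows + coeffs[3] * cols
  fit <- correct_background(img, sm)
  expect_equal(fit$coeffs, coeffs, tolerance = 1e-6)
  expect_lt(max(abs(fit$corrected)), 1e-6)
  # zero background: nothing changes
  fit0 <- correct_background(matrix(0, n, n), sm)
  expect_equal(fit0$coeffs, c(0, 0, 0))
  # constant offset: corrected static pixels are all zero
  fitc <- correct_background(matrix(3, n, n), sm)
  expect_true(all(abs(fitc$corrected[sm]) < 1e-12))
  # collinear mask geometry is rejected
  sm1 <- matrix(FALSE, n, n); sm1[5, ] <- TRUE
  expect_error(correct_background(img, sm1), "collinear")
})

test_that("curve extraction projects onto the radial direction", {
  n <- 41
  ctr <- c(21, 21)
  dist <- sqrt(outer((1:n - 21)^2, (1:n - 21)^2, "+"))
  ring <- dist >= 6 & dist <= 12
  myo <- array(ring, c(n, n, 2))
  vf <- array(0, c(n, n, 2, 3))
  # uniform inward velocity of 2 cm/s: v = 2 * unit vector toward centre
  u_row <- -(matrix(1:n, n, n) - 21) / pmax(dist, 1e-12)
  u_col <- -(matrix(1:n, n, n, byrow = TRUE) - 21) / pmax(dist, 1e-12)
  vf[, , 1, 1] <- 2 * u_col
  vf[, , 1, 2] <- 2 * u_row
  # uniform translation in +x at phase 2: cancels by symmetry
  vf[, , 2, 1] <- 3
  curves <- extract_curves(vf, myo, ctr, window_ms = 800)
  expect_equal(curves$radial$samples$v_cm_s[1], 2, tolerance = 1e-12)
  expect_lt(abs(curves$radial$samples$v_cm_s[2]), 1e-12)
  # linearity in the velocity field
  vf2 <- vf; vf2[, , , ] <- 2 * vf[, , , ]
  c2 <- extract_curves(vf2, myo, ctr, window_ms = 800)
  expect_equal(c2$radial$samples$v_cm_s,
               2 * curves$radial$samples$v_cm_s)
  expect_error(extract_curves(vf, array(FALSE, dim(myo)), ctr, 800),
               "empty")
})

test_that("periodic spline resampling interpolates and converges", {
  t_ms <- (0:19) / 20 * 800
  v <- sin(2 * pi * t_ms / 800) + 0.5 * cos(4 * pi * t_ms / 800)
  cv <- velocity_curve("radial", t_ms, v, window_ms = 800)
  cv <- resample_spline(cv, dt_ms = 1)
  # reproduces the samples exactly
  at_knots <- cv$dense$v_cm_s[round(t_ms) + 1]
  expect_equal(at_knots, v, tolerance = 1e-9)
  # dense error against the analytic curve obeys the cubic-spline bound
  truth <- sin(2 * pi * cv$dense$t_ms / 800) +
    0.5 * cos(4 * pi * cv$dense$t_ms / 800)
  expect_lt(max(abs(cv$dense$v_cm_s - truth)), 2e-3)
  expect_error(resample_spline(velocity_curve("radial", c(0, 1, 2),
                                              c(0, 1, 0), 800)),
               "at least 4")
})

test_that("zero shift removes exactly the cycle mean and is idempotent", {
  t_ms <- (0:15) / 16 * 900
  v <- 1.5 + sin(2 * pi * t_ms / 900)
  cv <- zero_shift(resample_spline(velocity_curve("radial", t_ms, v, 900),
                                   dt_ms = 0.5))
  # independent trapezoidal quadrature over the closed cycle
  td <- c(cv$dense$t_ms, 900)
  vd <- c(cv$dense$v_cm_s, cv$dense$v_cm_s[1])
  expect_lt(abs(pracma::trapz(td, vd) / 900), 1e-9)
  expect_equal(cv$zero_shift_cm_s, 1.5, tolerance = 1e-9)
  cv2 <- zero_shift(cv)
  expect_equal(cv2$dense$v_cm_s, cv$dense$v_cm_s)
  # constant curve collapses to zero
  cvc <- zero_shift(resample_spline(velocity_curve("radial", t_ms,
                                                   rep(3, 16), 900),
                                    dt_ms = 1))
  expect_true(all(abs(cvc$dense$v_cm_s) < 1e-12))
})

test_that("peak detection finds the configured extrema", {
  m <- tiny_motion()
  t_ms <- (0:29) / 30 * 900
  v <- velocity_waveform(t_ms / 900, m, "radial")
  cv <- zero_shift(resample_spline(velocity_curve("radial", t_ms, v, 900),
                                   dt_ms = 0.1))
  f <- find_peaks(cv)
  expect_equal(f$v_p_sys, m$peak_radial_sys, tolerance = 0.01)
  expect_equal(f$v_p_dias, m$peak_radial_dias, tolerance = 0.01)
  expect_equal(f$delta_v, f$v_p_sys - f$v_p_dias)
  expect_equal(f$t_dias_ms, m$t_dias_peak * 900, tolerance = 5)
  # negating the curve swaps the peak signs
  cvn <- cv; cvn$dense$v_cm_s <- -cvn$dense$v_cm_s
  fn <- find_peaks(cvn)
  expect_equal(fn$v_p_sys, -f$v_p_sys, tolerance = 1e-12)
  expect_equal(fn$v_p_dias, -f$v_p_dias, tolerance = 1e-12)
  expect_equal(fn$delta_v, -f$delta_v, tolerance = 1e-12)
  # flat zero curve: zero features, t_dias at window start (tie rule)
  cv0 <- resample_spline(velocity_curve("radial", t_ms, rep(0, 30), 900),
                         dt_ms = 1)
  f0 <- find_peaks(cv0)
  expect_equal(f0$delta_v, 0)
  expect_equal(f0$t_dias_ms, 450)
})

test_that("the noise-free pipeline recovers ground-truth curves", {
  m <- tiny_motion()
  ph <- build_phantom(m, n_phases = 10, matrix_size = c(48, 48),
                      r_endo_mm = 10, r_epi_mm = 18)
  enc <- encode_velocity(ph, background_coeffs = c(0.3, 0.004, -0.006))
  rec <- reconstruct_full(to_kspace(enc, noise_sd = 0))
  q <- quantify_arm(rec, ph, 30, dt_ms = 1)
  t_frac <- (0:9) / 10
  for (dir in c("radial", "longitudinal")) {
    truth <- velocity_waveform(t_frac, m, dir)
    got <- q$curves[[dir]]$samples$v_cm_s + q$curves[[dir]]$zero_shift_cm_s
    expect_lt(max(abs(got - truth)), 1e-6)
  }
})
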