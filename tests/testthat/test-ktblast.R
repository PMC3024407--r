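test_that("full reconstruction is the exact inverse of encoding", {
  acq <- tiny_acquisition(noise_sd = 0)
  rec <- reconstruct_full(acq$k)
  expect_lt(max(Mod(rec - acq$enc$images)), 1e-12)
  expect_error(reconstruct_full(acq$und), "unsampled")
})

test_that("full reconstruction is linear", {
  set.seed(4)
  d <- c(8, 8, 3, 1)
  mk <- function() {
    k <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
    structure(list(data = k, sampled = matrix(TRUE, 8, 3),
                   matrix_size = c(8L, 8L), n_phases = 3L, noise_sd = 0),
              class = "kspace_series")
  }
  k1 <- mk(); k2 <- mk(); a <- 2.7 - 1.3i
  k3 <- k1; k3$data <- a * k1$data + k2$data
  expect_equal(reconstruct_full(k3),
               a * reconstruct_full(k1) + reconstruct_full(k2))
})

test_that("training variance of a static scene concentrates at DC", {
  ph <- tiny_phantom(n_phases = 4, m = motion_model(0, 0, 0, 0))
  enc <- encode_velocity(ph)
  k <- to_kspace(enc, noise_sd = 0)
  svm <- estimate_signal_variance(acquire_training(k, 24), psi = 1e-4)
  off_dc <- svm$theta2[, , 2:4]
  expect_lt(max(off_dc), 1e-20 * max(svm$theta2))
  # zero training data -> zero variance map
  k0 <- k; k0$data[] <- 0
  svm0 <- estimate_signal_variance(acquire_training(k0, 11), psi = 1e-4)
  expect_true(all(svm0$theta2 == 0))
})

test_that("training variance localizes a known temporal harmonic", {
  # scene oscillating at exactly one temporal frequency
  nt <- 8; n <- 16
  imgs <- array(0i, c(n, n, nt))
  blob <- outer(dnorm(1:n, 8, 2), dnorm(1:n, 8, 2))
  for (t in 1:nt) imgs[, , t] <- blob * exp(2i * pi * 2 * (t - 1) / nt)
  k <- structure(list(
    data = array(0i, c(n, n, nt, 1)), sampled = matrix(TRUE, n, nt),
    matrix_size = c(n, n), n_phases = nt, noise_sd = 0),
    class = "kspace_series")
  for (t in 1:nt) k$data[, , t, 1] <- kttpm:::ft2c(imgs[, , t])
  svm <- estimate_signal_variance(acquire_training(k, n), psi = 1e-4)
  per_f <- apply(svm$theta2, 3, sum)
  expect_equal(which.max(per_f), 3L)   # f-index 3 == 2 cycles/window
  expect_gt(per_f[3], 1e6 * max(per_f[-3]))
})

test_that("alias kernel matches the analytic sheared-lattice formula", {
  for (case in list(c(8, 4, 2), c(12, 6, 3), c(15, 6, 3), c(16, 8, 4))) {
    ny <- case[1]; nt <- case[2]; R <- case[3]
    psf <- kt_psf(make_kt_pattern(ny, nt, R))
    expect_equal(nrow(psf), R)
    expect_equal(sort(psf$dy), sort((0:(R - 1)) * ny / R))
    expect_equal(sort(psf$df), sort((0:(R - 1)) * nt / R))
    expect_equal(Mod(psf$w), rep(1 / R, R))
    expect_equal(psf$w[psf$dy == 0 & psf$df == 0], complex(real = 1 / R))
  }
  expect_error(kt_psf(make_kt_pattern(9, 4, 2)), "divisible")
})

test_that("R = 1 reconstruction equals the direct inverse transform", {
  acq <- tiny_acquisition(R = 1, noise_sd = 0.02)
  svm <- estimate_signal_variance(acq$tr, psi = 1e-4)
  rec_kt <- reconstruct_ktblast(acq$und, acq$pat, svm)
  rec <- reconstruct_full(acq$k)
  expect_lt(max(Mod(rec_kt - rec)) / max(Mod(rec)), 1e-10)
})

test_that("the unaliasing filter recovers a DC-only scene exactly as psi -> 0", {
  ph <- tiny_phantom(n_phases = 4, m = motion_model(0, 0, 0, 0))
  enc <- encode_velocity(ph)
  k <- to_kspace(enc, noise_sd = 0)
  pat <- make_kt_pattern(24, 4, 2)
  und <- undersample(k, pat)
  svm <- structure(list(
    theta2 = array(0, c(24, 24, 4)), psi = 1e-12),
    class = "signal_variance_map")
  svm$theta2[, , 1] <- 1    # exactly one nonzero member per alias set
  rec <- reconstruct_ktblast(und, pat, svm, baseline = FALSE)
  expect_lt(max(Mod(rec - enc$images)), 1e-6)
})

test_that("reconstruction matches the brute-force per-alias-set solve", {
  # random 8 x 8 x 4 instance at R = 2
  acq <- random_acquisition(n = 8, n_phases = 4, R = 2, seed = 12)
  svm <- estimate_signal_variance(acq$tr, psi = 0.01)
  rec <- reconstruct_ktblast(acq$und, acq$pat, svm, baseline = FALSE)
  rec_oracle <- oracle_ktblast(acq$und, acq$pat, svm)
  expect_lt(max(Mod(rec - rec_oracle)), 1e-8)
  # and a phantom-driven 16 x 16 x 8 instance at R = 4
  acq4 <- tiny_acquisition(R = 4, n_phases = 8, n = 24, noise_sd = 0.02,
                           training_lines = 7)
  svm4 <- estimate_signal_variance(acq4$tr, psi = 0.01)
  rec4 <- reconstruct_ktblast(acq4$und, acq4$pat, svm4, baseline = FALSE)
  expect_lt(max(Mod(rec4 - oracle_ktblast(acq4$und, acq4$pat, svm4))), 1e-8)
  # baseline handling agrees too on a DC-heavy scene
  rec_b <- reconstruct_ktblast(acq4$und, acq4$pat, svm4, baseline = TRUE)
  expect_false(identical(rec_b, rec4))
})

test_that("the filter never amplifies an alias set", {
  # re-aliased estimate must not exceed the measured value in magnitude
  set.seed(5)
  for (rep in 1:50) {
    R <- sample(2:6, 1)
    w <- exp(2i * pi * runif(R)) / R
    th <- runif(R, 0, 10) * rbinom(R, 1, 0.8)
    psi <- runif(1, 1e-4, 1)
    d <- complex(real = rnorm(1), imaginary = rnorm(1))
    s_hat <- th * Conj(w) * d / (sum(Mod(w)^2 * th) + psi)
    expect_lte(Mod(sum(w * s_hat)), Mod(d))
    # and the estimate's prior-weighted norm stays bounded
    expect_lte(sum(Mod(s_hat)^2 / pmax(th, 1e-12))[1],
               Mod(d)^2 / psi + 1e-9)
  }
})

test_that("static pixels reconstruct within the noise level at every R", {
  noise_sd <- 0.05
  m <- tiny_motion()
  for (R in c(2, 3, 4, 6)) {
    ph <- build_phantom(m, n_phases = 12, matrix_size = c(48, 48),
                        r_endo_mm = 10, r_epi_mm = 18)
    enc <- encode_velocity(ph)
    k <- to_kspace(enc, noise_sd = noise_sd, seed = 20 + R)
    pat <- make_kt_pattern(48, 12, R)
    und <- undersample(k, pat)
    svm <- estimate_signal_variance(acquire_training(k, 11),
                                    psi = max(estimate_noise_psi(und), 1e-8))
    rec <- reconstruct_ktblast(und, pat, svm)
    rec_full <- reconstruct_full(k)
    sm <- ph$static_mask
    rel_err <- function(r) sapply(1:12, function(i) {
      v <- Mod(r[, , i, 1] - enc$images[, , i, 1])
      mean(v[sm]) / mean(Mod(enc$images[, , i, 1])[sm])
    })
    # unaliasing does not degrade static tissue beyond the noise floor
    # of the direct reconstruction of the same noisy acquisition
    expect_lt(mean(rel_err(rec)), 1.5 * mean(rel_err(rec_full)))
    expect_lt(mean(rel_err(rec)), 2 * noise_sd)
  }
})

test_that("temporal smoothing attenuates a sharp peak monotonically in R", {
  m <- motion_model(pulse_width = 0.2)
  dv <- sapply(c(1, 2, 4, 6), function(R) {
    ph <- build_phantom(m, n_phases = 12, matrix_size = c(48, 48),
                        r_endo_mm = 10, r_epi_mm = 18)
    enc <- encode_velocity(ph)
    k <- to_kspace(enc, noise_sd = 0.02, seed = 31)
    if (R == 1) rec <- reconstruct_full(k) else {
      pat <- make_kt_pattern(48, 12, R)
      und <- undersample(k, pat)
      svm <- estimate_signal_variance(acquire_training(k, 11),
                                      psi = max(estimate_noise_psi(und),
                                                1e-8))
      rec <- reconstruct_ktblast(und, pat, svm)
    }
    q <- quantify_arm(rec, ph, 30, dt_ms = 1)
    q$features$delta_v[q$features$direction == "longitudinal"]
  })
  expect_true(all(diff(dv) <= 0))
})
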