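# Shared fixtures and independent oracles for the test suite.

# small motion model that fits tiny grids
tiny_motion <- function(...) {
  motion_model(peak_radial_sys = 2, peak_radial_dias = -1.5,
               peak_long_sys = 3, peak_long_dias = -2.5, ...)
}

tiny_phantom <- function(n_phases = 4, n = 24, m = tiny_motion()) {
  build_phantom(m, n_phases = n_phases, matrix_size = c(n, n),
                r_endo_mm = 8, r_epi_mm = 16)
}

# centered unitary DFT matrix (image -> k), built independently of the
# package's FFT helpers: explicit DFT matrix plus explicit half swaps
centered_dft <- function(n) {
  W <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n) / sqrt(n)
  M <- matrix(0i, n, n)
  for (j in 1:n) {
    e <- rep(0i, n); e[j] <- 1
    u <- e[c((n %/% 2 + 1):n, 1:(n %/% 2))[1:n]]          # ifftshift
    u <- W %*% u
    M[, j] <- u[c(((n + 1) %/% 2 + 1):n, 1:((n + 1) %/% 2))[1:n]]  # fftshift
  }
  M
}

# brute-force k-t BLAST oracle: explicit DFT matrices and an explicit
# regularized 1 x R solve per alias set (solve(), no shared code with
# reconstruct_ktblast beyond the alias kernel table)
oracle_ktblast <- function(und, pat, svm) {
  ny <- pat$n_pe; nx <- dim(und$data)[2]; nt <- pat$n_phases
  R <- pat$R; ne <- dim(und$data)[4]
  Fy <- centered_dft(ny); Fx <- centered_dft(nx)
  Ft <- exp(-2i * pi * outer(0:(nt - 1), 0:(nt - 1)) / nt) / sqrt(nt)
  psf <- kt_psf(pat)
  out <- array(0i, dim(und$data))
  for (e in seq_len(ne)) {
    imgs <- array(0i, c(ny, nx, nt))
    for (t in 1:nt)
      imgs[, , t] <- solve(Fy) %*% und$data[, , t, e] %*% t(solve(Fx))
    for (x in 1:nx) {
      D <- imgs[, x, ] %*% t(Ft)
      th <- svm$theta2[, x, ]
      Mh <- matrix(0i, ny, nt)
      for (f0 in 0:(nt / R - 1)) for (y0 in 0:(ny - 1)) {
        py <- (y0 - psf$dy) %% ny + 1
        pf <- (f0 - psf$df) %% nt + 1
        th_set <- th[cbind(py, pf)]
        A <- matrix(psf$w, nrow = 1)                      # 1 x R system
        Theta <- diag(th_set, nrow = R)
        gain <- Theta %*% Conj(t(A)) %*%
          solve(A %*% Theta %*% Conj(t(A)) + svm$psi)
        Mh[cbind(py, pf)] <- gain %*% D[y0 + 1, f0 + 1]
      }
      out[, x, , e] <- Mh %*% Conj(Ft)
    }
  }
  out
}

# tiny undersampled acquisition bundle used by several tests
tiny_acquisition <- function(R = 2, n_phases = 4, n = 24, noise_sd = 0.02,
                             seed = 9, training_lines = 7) {
  ph <- tiny_phantom(n_phases = n_phases, n = n)
  enc <- encode_velocity(ph, background_coeffs = c(0.2, 0.003, -0.004))
  k <- to_kspace(enc, noise_sd = noise_sd, seed = seed)
  pat <- make_kt_pattern(n, n_phases, R)
  und <- undersample(k, pat)
  tr <- acquire_training(k, training_lines)
  list(ph = ph, enc = enc, k = k, pat = pat, und = und, tr = tr)
}

# random complex k-space acquisition (no phantom), for small oracle cases
random_acquisition <- function(n = 8, n_phases = 4, R = 2, seed = 1) {
  set.seed(seed)
  d <- c(n, n, n_phases, 2)
  dat <- array(complex(real = stats::rnorm(prod(d)),
                       imaginary = stats::rnorm(prod(d))), d)
  k <- structure(list(data = dat, sampled = matrix(TRUE, n, n_phases),
                      matrix_size = c(n, n), n_phases = n_phases,
                      noise_sd = 0),
                 class = "kspace_series")
  pat <- make_kt_pattern(n, n_phases, R)
  list(k = k, pat = pat, und = undersample(k, pat),
       tr = acquire_training(k, min(5, n)))
}
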