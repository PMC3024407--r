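# Unitary centered Fourier transforms.
#
# Conventions (documented and relied on throughout):
#  * k-space arrays are stored centered: for a dimension of size n the DC
#    sample sits at 1-based index floor(n/2) + 1 (0-based n %/% 2).
#  * ft2c / ift2c are a unitary pair: ift2c(ft2c(x)) == x to machine
#    precision; energy is preserved.
#  * The temporal transform tft maps phase series to temporal-frequency
#    bins with DC at index 1 (uncentered), again unitarily.

shift_idx <- function(n, s) c((s + 1):n, 1:s)[seq_len(n)]

fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[shift_idx(n1, (n1 + 1) %/% 2), shift_idx(n2, (n2 + 1) %/% 2),
    drop = FALSE]
}

ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[shift_idx(n1, n1 %/% 2), shift_idx(n2, n2 %/% 2), drop = FALSE]
}

# image -> centered k-space (unitary)
ft2c <- function(img) {
  n <- length(img)
  fftshift2(stats::fft(ifftshift2(img))) / sqrt(n)
}

# centered k-space -> image (unitary)
ift2c <- function(ksp) {
  n <- length(ksp)
  fftshift2(stats::fft(ifftshift2(ksp), inverse = TRUE)) / sqrt(n)
}

# temporal DFT along the 3rd margin of a rows x cols x n_t array (unitary,
# DC at frequency index 1)
tft <- function(x) {
  nt <- dim(x)[3]
  aperm(apply(x, c(1, 2), stats::fft), c(2, 3, 1)) / sqrt(nt)
}

itft <- function(x) {
  nt <- dim(x)[3]
  aperm(apply(x, c(1, 2), function(v) stats::fft(v, inverse = TRUE)),
        c(2, 3, 1)) / sqrt(nt)
}

# 0-based index of the DC line/column after centering
dc_index <- function(n) n %/% 2
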