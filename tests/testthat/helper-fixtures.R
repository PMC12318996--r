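# Shared fixtures, built in code at test time.

# Small wavelength grid for fast tests.
tiny_grid <- function(n = 16) seq(425, 965, length.out = n)

# Profile set with all sample variability switched off (pure class means).
noiseless_profiles <- function(wavelengths = tiny_grid()) {
  make_class_profiles(profile_config(wavelengths = wavelengths,
                                     noise_sd = 0, gain_sd = 0,
                                     offset_sd = 0))
}

# Two-rectangle test cube: rectangles at reflectance `dark` on a bright
# background, constant across bands.
rect_cube <- function(h = 20, w = 30, bands = 5, dark = 0.2, bright = 0.9) {
  data <- array(bright, dim = c(h, w, bands))
  r1 <- list(y = 3:8, x = 4:9)
  r2 <- list(y = 12:17, x = 18:26)
  for (b in seq_len(bands)) {
    data[r1$y, r1$x, b] <- dark
    data[r2$y, r2$x, b] <- dark
  }
  list(cube = spectral_cube(data, seq(650, 658, length.out = bands)),
       r1 = r1, r2 = r2)
}

# Hand-coded scalar LSTM oracle following the gate equations directly;
# intentionally plain arithmetic, independent of the package's matrix path.
scalar_lstm_oracle <- function(wfx, wfh, bf, wix, wih, bi, wox, woh, bo,
                               wgx, wgh, bg, x, h, c) {
  sg <- function(z) 1 / (1 + exp(-z))
  f <- sg(wfx * x + wfh * h + bf)
  i <- sg(wix * x + wih * h + bi)
  o <- sg(wox * x + woh * h + bo)
  g <- tanh(wgx * x + wgh * h + bg)
  c_t <- f * c + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t)
}

# Exhaustive-projection SPA oracle: rebuilds the projector from scratch at
# every step (no recursive residual update).
spa_brute_chain <- function(X, start, k) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  chain <- start
  for (step in seq_len(k - 1)) {
    Q <- Xc[, chain, drop = FALSE]
    P <- diag(nrow(Xc)) - Q %*% solve(crossprod(Q), t(Q))
    resid <- P %*% Xc
    norms <- sqrt(colSums(resid^2))
    norms[chain] <- -Inf
    chain <- c(chain, which.max(norms))
  }
  chain
}

scalar_cell_params <- function(wfx, wfh, bf, wix, wih, bi, wox, woh, bo,
                               wgx, wgh, bg) {
  list(W_fx = matrix(wfx), W_fh = matrix(wfh), b_f = bf,
       W_ix = matrix(wix), W_ih = matrix(wih), b_i = bi,
       W_ox = matrix(wox), W_oh = matrix(woh), b_o = bo,
       W_gx = matrix(wgx), W_gh = matrix(wgh), b_g = bg)
}
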