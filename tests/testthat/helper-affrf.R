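# shared fixtures and small oracles; everything is generated in code

# independent branch reduction into (-pi, pi]
wrap_pi_oracle <- function(a) {
  a <- a %% (2 * pi)
  if (a > pi) a - 2 * pi else a
}

random_near_identity_map <- function() {
  c0 <- runif(1, 0.5, 2)
  E <- matrix(runif(4, -0.3, 0.3), 2L, 2L)
  c0 * (diag(2) + E)
}

rel_rms <- function(test, ref) {
  sqrt(mean((test - ref)^2)) / sqrt(mean(ref^2))
}

# band-limited periodic noise sampled at two resolutions of the same
# underlying function: `fine` has half the pixel spacing of `coarse`
noise_pair <- function(n_coarse = 128L, cutoff_coarse = 8, seed = 11L) {
  fine <- make_stimulus(stimulus_spec("band_limited_noise",
                                      size = 2L * n_coarse,
                                      cutoff = 2 * cutoff_coarse, seed = seed))
  sub <- seq(1L, 2L * n_coarse, by = 2L)
  list(coarse = sampled_field(fine$values[sub, sub], spacing = 1),
       fine = sampled_field(fine$values, spacing = 0.5))
}

# 4th-order central-difference oracle for aligned directional
# derivatives of the affine Gaussian, sampled at spacing h; returns the
# sup-norm error of the closed forms relative to the kernel sup norm
fd_closed_form_error <- function(sigma1, sigma2, phi, h = min(sigma1, sigma2) / 16) {
  S <- covariance_from_shape(sigma1, sigma2, phi)
  r <- 4 * max(sigma1, sigma2)
  n <- 2L * ceiling(r / h) + 1L
  ax <- (seq_len(n) - (n + 1) / 2) * h
  G <- matrix(gaussian_value(cbind(rep(ax, n), rep(ax, each = n)), S), n, n)
  d1 <- c(1, -8, 0, 8, -1) / 12
  d2 <- c(-1, 16, -30, 16, -1) / 12
  ii <- 3:(n - 2); ni <- length(ii)
  Dx <- Dy <- Dxx <- Dyy <- Dxy <- matrix(0, ni, ni)
  for (k in -2:2) {
    Dx <- Dx + d1[k + 3] * G[ii + k, ii] / h
    Dy <- Dy + d1[k + 3] * G[ii, ii + k] / h
    Dxx <- Dxx + d2[k + 3] * G[ii + k, ii] / h^2
    Dyy <- Dyy + d2[k + 3] * G[ii, ii + k] / h^2
    for (l in -2:2) {
      if (d1[k + 3] != 0 && d1[l + 3] != 0) {
        Dxy <- Dxy + d1[k + 3] * d1[l + 3] * G[ii + k, ii + l] / h^2
      }
    }
  }
  x <- cbind(rep(ax[ii], ni), rep(ax[ii], each = ni))
  c1 <- simple_cell_value(x, rf_spec(sigma1, sigma2, phi, m1 = 1))
  c2 <- simple_cell_value(x, rf_spec(sigma1, sigma2, phi, m1 = 2))
  fd1 <- sigma1 * (cos(phi) * Dx + sin(phi) * Dy)
  fd2 <- sigma1^2 * (cos(phi)^2 * Dxx + 2 * cos(phi) * sin(phi) * Dxy +
                       sin(phi)^2 * Dyy)
  c(order1 = max(abs(fd1 - matrix(c1, ni))) / max(abs(c1)),
    order2 = max(abs(fd2 - matrix(c2, ni))) / max(abs(c2)))
}
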