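test_that("covariance parameterization has the prescribed entries and spectrum", {
  expect_equal(unclass(covariance_from_shape(1.3, 1.3, 0.9)),
               1.3^2 * diag(2), tolerance = 1e-14)
  expect_equal(unclass(covariance_from_shape(2, 1, 0)), diag(c(4, 1)))
  expect_equal(unclass(covariance_from_shape(2, 1, pi / 2)), diag(c(1, 4)),
               tolerance = 1e-14)
  expect_equal(unclass(covariance_from_shape(2, 1, pi / 4)),
               matrix(c(2.5, 1.5, 1.5, 2.5), 2), tolerance = 1e-14)
  expect_error(covariance_from_shape(-1, 1, 0), "positive")

  set.seed(10)
  for (i in 1:100) {
    s1 <- runif(1, 0.3, 4); s2 <- runif(1, 0.3, 4); ph <- runif(1, -pi, pi)
    S <- covariance_from_shape(s1, s2, ph)
    ev <- eigen(unclass(S), symmetric = TRUE)$values
    expect_equal(sort(ev), sort(c(s1^2, s2^2)), tolerance = 1e-12)
    expect_equal(sum(diag(S)), s1^2 + s2^2, tolerance = 1e-12)
  }
})

test_that("shape_from_covariance inverts the parameterization up to relabelling", {
  expect_equal(shape_from_covariance(4 * diag(2)),
               list(sigma1 = 2, sigma2 = 2, phi = 0))
  expect_equal(shape_from_covariance(diag(c(4, 1))),
               list(sigma1 = 2, sigma2 = 1, phi = 0))
  sh <- shape_from_covariance(matrix(c(2.5, 1.5, 1.5, 2.5), 2))
  expect_equal(c(sh$sigma1, sh$sigma2, sh$phi), c(2, 1, pi / 4))
  expect_error(shape_from_covariance(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")

  set.seed(11)
  for (i in 1:50) {
    s1 <- runif(1, 1, 3); s2 <- runif(1, 0.3, 0.9); ph <- runif(1, -pi / 2, pi / 2)
    sh <- shape_from_covariance(covariance_from_shape(s1, s2, ph))
    expect_equal(sh$sigma1, s1, tolerance = 1e-10) # sigma1 > sigma2 here
    expect_equal(sh$sigma2, s2, tolerance = 1e-10)
    dphi <- (sh$phi - ph) %% pi
    expect_lt(min(dphi, pi - dphi), 1e-10)
  }
})

test_that("rotating the kernel preserves size and eccentricity, shifts phi", {
  set.seed(12)
  for (i in 1:25) {
    s1 <- runif(1, 1, 3); s2 <- runif(1, 0.3, 0.9)
    ph <- runif(1, -pi / 2, pi / 2); th <- runif(1, -pi, pi)
    S <- covariance_from_shape(s1, s2, ph)
    Sr <- rot2_matrix(th) %*% unclass(S) %*% t(rot2_matrix(th))
    sh <- shape_from_covariance(Sr)
    expect_equal(c(sh$sigma1, sh$sigma2), c(s1, s2), tolerance = 1e-10)
    dphi <- (sh$phi - ph - th) %% pi
    expect_lt(min(dphi, pi - dphi), 1e-10)
  }
})

test_that("affine Gaussian is normalized, even, and correct at the origin", {
  S <- covariance_from_shape(1.5, 0.8, 0.6)
  expect_equal(gaussian_value(c(0, 0), spatial_covariance(4, 4)),
               1 / (2 * pi * 4))
  set.seed(13)
  x <- matrix(runif(40, -3, 3), ncol = 2)
  expect_equal(gaussian_value(x, S), gaussian_value(-x, S))
  # Riemann sum over +-6 sigma
  g <- seq(-9, 9, by = 0.1)
  xs <- cbind(rep(g, length(g)), rep(g, each = length(g)))
  expect_equal(sum(gaussian_value(xs, S)) * 0.1^2, 1, tolerance = 1e-6)
})

test_that("closed-form simple-cell kernels match their defining expressions", {
  set.seed(14)
  xs <- matrix(runif(60, -4, 4), ncol = 2)
  for (i in 1:10) {
    s1 <- runif(1, 0.7, 2.5); s2 <- runif(1, 0.4, 2.5); ph <- runif(1, -pi / 2, pi / 2)
    sp1 <- rf_spec(s1, s2, ph, m1 = 1)
    sp2 <- rf_spec(s1, s2, ph, m1 = 2)
    expect_equal(simple_cell_value(xs, sp1), general_directional_value(xs, sp1),
                 tolerance = 1e-12)
    expect_equal(simple_cell_value(xs, sp2), general_directional_value(xs, sp2),
                 tolerance = 1e-12)
    # first order vanishes at the origin; second order is -1/(2 pi s1 s2)
    expect_equal(simple_cell_value(c(0, 0), sp1), 0)
    expect_equal(simple_cell_value(c(0, 0), sp2), -1 / (2 * pi * s1 * s2),
                 tolerance = 1e-14)
  }
  # isotropic first-order limit
  s <- 1.2
  spi <- rf_spec(s, s, 0, m1 = 1)
  x <- c(0.7, -0.3)
  expect_equal(simple_cell_value(x, spi),
               -x[1] / (2 * pi * s^3) * exp(-sum(x^2) / (2 * s^2)),
               tolerance = 1e-14)
  expect_error(simple_cell_value(x, rf_spec(1, 1, m1 = 3)), "order")
  expect_error(simple_cell_value(x, rf_spec(2, 1, 0, deriv_theta = 1, m1 = 1)),
               "general_directional_value")
})

test_that("general directional derivatives agree with finite differences", {
  # zeroth order reduces to the Gaussian
  S <- covariance_from_shape(1.5, 0.8, 0.3)
  x <- matrix(runif(20, -2, 2), ncol = 2)
  expect_equal(general_directional_value(x, rf_spec(1.5, 0.8, 0.3)),
               gaussian_value(x, S))
  # first order, arbitrary direction, vs 4th-order central differences
  set.seed(15)
  for (i in 1:5) {
    s1 <- runif(1, 0.8, 2); s2 <- runif(1, 0.5, 2); ph <- runif(1, -pi / 2, pi / 2)
    th <- runif(1, -pi, pi)
    sp <- rf_spec(s1, s2, ph, deriv_theta = th, m1 = 1)
    Sc <- covariance_from_shape(s1, s2, ph)
    h <- min(s1, s2) / 16
    u <- c(cos(th), sin(th))
    x0 <- matrix(runif(30, -2, 2), ncol = 2)
    fd <- (-gaussian_value(x0 + 2 * h * rep(1, nrow(x0)) %o% u, Sc) +
             8 * gaussian_value(x0 + h * rep(1, nrow(x0)) %o% u, Sc) -
             8 * gaussian_value(x0 - h * rep(1, nrow(x0)) %o% u, Sc) +
             gaussian_value(x0 - 2 * h * rep(1, nrow(x0)) %o% u, Sc)) / (12 * h)
    expect_equal(general_directional_value(x0, sp), s1 * fd, tolerance = 1e-4)
  }
  # mixed order (m1 = 1, m2 = 1) against nested differences
  sp <- rf_spec(1.4, 0.9, 0.5, deriv_theta = 1.1, m1 = 1, m2 = 1)
  Sc <- covariance_from_shape(1.4, 0.9, 0.5)
  h <- 1e-3
  u <- c(cos(1.1), sin(1.1)); v <- c(-sin(1.1), cos(1.1))
  x0 <- c(0.4, -0.8)
  fd2 <- (gaussian_value(x0 + h * u + h * v, Sc) -
            gaussian_value(x0 + h * u - h * v, Sc) -
            gaussian_value(x0 - h * u + h * v, Sc) +
            gaussian_value(x0 - h * u - h * v, Sc)) / (4 * h^2)
  expect_equal(general_directional_value(x0, sp), 1.4 * 0.9 * fd2,
               tolerance = 1e-4)
})

test_that("scale normalization: kernels transform with the density factor only", {
  set.seed(16)
  x <- matrix(runif(20, -2, 2), ncol = 2)
  for (orders in list(c(0L, 0L), c(1L, 0L), c(2L, 0L), c(1L, 1L))) {
    sp <- rf_spec(1.3, 0.7, 0.4, deriv_theta = 0.9,
                  m1 = orders[1], m2 = orders[2])
    for (s in c(0.5, 2, 3)) {
      sps <- rf_spec(s * 1.3, s * 0.7, 0.4, deriv_theta = 0.9,
                     m1 = orders[1], m2 = orders[2])
      expect_equal(general_directional_value(s * x, sps),
                   general_directional_value(x, sp) / s^2,
                   tolerance = 1e-12)
    }
  }
})

test_that("sampled kernels have the right discrete mass and symmetry", {
  k0 <- sample_kernel(rf_spec(2, 1, 0.6), spacing = 0.25)
  expect_equal(sum(k0$values) * k0$spacing^2, 1, tolerance = 1e-4)
  k1 <- sample_kernel(rf_spec(2, 1, 0.6, m1 = 1), spacing = 0.25)
  expect_lt(abs(sum(k1$values)) * k1$spacing^2, 1e-6)
  expect_warning(sample_kernel(rf_spec(2, 1), extent = 5), "truncated")
  expect_error(sample_kernel(rf_spec(2, 1), extent = 5, on_small = "error"),
               "truncated")
  kr <- sample_kernel(rf_spec(1, 1), spacing = 0.5, renormalize = TRUE)
  expect_equal(sum(kr$values) * kr$spacing^2, 1, tolerance = 1e-14)
})

test_that("spatio-temporal kernel is separable, normalized and velocity-shifted", {
  S <- spatial_covariance(1, 1)
  spec0 <- st_rf_spec(S, tau = 1, velocity = c(0, 0))
  x <- matrix(runif(20, -2, 2), ncol = 2)
  expect_equal(spatiotemporal_value(x, 0.7, spec0),
               gaussian_value(x, S) * dnorm(0.7))
  # bounded space-time integral
  spec <- st_rf_spec(S, tau = 0.8, velocity = c(0.3, 0.1))
  g <- seq(-6, 6, by = 0.2)
  tot <- 0
  for (t0 in g) {
    xs <- cbind(rep(g, length(g)), rep(g, each = length(g)))
    tot <- tot + sum(spatiotemporal_value(xs, t0, spec)) * 0.2^3
  }
  expect_equal(tot, 1, tolerance = 1e-4)
  # Galilean shift of the Gaussian factor along the velocity line
  v <- c(0.3, 0.1); dt <- 1.3
  x0 <- matrix(c(0.5, -0.2), 1)
  lhs <- spatiotemporal_value(x0, 1, spec) / dnorm(1, sd = sqrt(0.8))
  rhs <- spatiotemporal_value(x0 + dt * matrix(v, 1), 1 + dt, spec) /
    dnorm(1 + dt, sd = sqrt(0.8))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(st_rf_spec(S, tau = 0), "positive")
})
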