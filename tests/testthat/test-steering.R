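test_that("first-order steering on the axis basis gives (cos, sin)", {
  for (th in c(0, pi / 7, -1.2, 2.5)) {
    s <- steer_coefficients(1, th, c(0, pi / 2))
    expect_equal(s$coefficients, c(cos(th), sin(th)), tolerance = 1e-14)
    expect_lt(s$residual, 1e-12)
  }
  # target on a basis angle selects that kernel
  s <- steer_coefficients(2, pi / 3, c(0, pi / 3, 2 * pi / 3))
  expect_equal(s$coefficients, c(0, 1, 0), tolerance = 1e-12)
})

test_that("steering is exact for any order with m + 1 distinct angles", {
  set.seed(17)
  for (m in 1:4) {
    angles <- sort(runif(m + 1, 0, pi - 0.2))
    th <- runif(1, -pi, pi)
    shape <- list(sigma1 = runif(1, 1, 2), sigma2 = runif(1, 0.5, 1),
                  kernel_phi = runif(1, -pi / 2, pi / 2))
    s <- steer_coefficients(m, th, angles, shape = shape)
    expect_lt(s$residual, 1e-10)
    expect_lt(s$condition_estimate, 1e6)
  }
  # least squares with an over-complete basis still reconstructs
  s <- steer_coefficients(2, 0.4, c(0, pi / 4, pi / 2, 3 * pi / 4))
  expect_lt(s$residual, 1e-10)
})

test_that("degenerate bases are rejected", {
  expect_error(steer_coefficients(2, 1, c(0, 0, pi / 3)), "degenerate basis")
  # angles equal modulo pi are the same orientation up to sign: for even
  # order they are linearly dependent
  expect_error(steer_coefficients(2, 1, c(0, pi, pi / 3)), "degenerate basis")
  expect_error(steer_coefficients(2, 1, c(0, pi / 3)), "at least")
})

test_that("responses match across a rotation via steering + gradient transform", {
  img <- make_stimulus(stimulus_spec("band_limited_noise", size = 128,
                                     cutoff = 8, seed = 5))
  A <- rot2_matrix(pi / 5)
  S <- spatial_covariance(36, 36)
  sh <- shape_from_covariance(S)
  theta <- pi / 7
  src <- rf_response(img, rf_spec(sh$sigma1, sh$sigma2, sh$phi,
                                  deriv_theta = theta, m1 = 1),
                     truncation = 6, method = "fft")
  wimg <- warp_image(img, A)
  S2 <- transform_covariance(S, A)
  sh2 <- shape_from_covariance(S2)
  basis <- c(0, pi / 2)
  tgt <- lapply(basis, function(b) {
    rf_response(wimg, rf_spec(sh2$sigma1, sh2$sigma2, sh2$phi,
                              deriv_theta = b, m1 = 1),
                truncation = 6, method = "fft")
  })
  sol <- match_responses(src, tgt, A, margin = 44, basis_angles = basis)
  # for a rotation the gradient direction rotates with the map
  expect_equal(sol$coefficients, c(cos(theta + pi / 5), sin(theta + pi / 5)),
               tolerance = 1e-3)
  expect_lt(sol$residual, 0.01)

  # identity map with the source angle in the basis selects it
  tgt0 <- lapply(c(theta, theta + pi / 2), function(b) {
    rf_response(img, rf_spec(sh$sigma1, sh$sigma2, sh$phi,
                             deriv_theta = b, m1 = 1),
                truncation = 6, method = "fft")
  })
  sol0 <- match_responses(src, tgt0, diag(2), margin = 40)
  expect_equal(sol0$coefficients, c(1, 0), tolerance = 1e-8)
  expect_lt(sol0$residual, 1e-8)
})

test_that("second-order responses match across a stretch with a 3-angle basis", {
  img <- make_stimulus(stimulus_spec("band_limited_noise", size = 128,
                                     cutoff = 8, seed = 5))
  A <- affine_map(1.5, 0, 0, 1)
  S <- spatial_covariance(36, 36)
  sh <- shape_from_covariance(S)
  src <- rf_response(img, rf_spec(sh$sigma1, sh$sigma2, sh$phi,
                                  deriv_theta = pi / 4, m1 = 2),
                     truncation = 6, method = "fft")
  w <- warp_image(img, A)
  S2 <- transform_covariance(S, A)
  sh2 <- shape_from_covariance(S2)
  basis <- c(0, pi / 3, 2 * pi / 3)
  tgt <- lapply(basis, function(b) {
    rf_response(w, rf_spec(sh2$sigma1, sh2$sigma2, sh2$phi,
                           deriv_theta = b, m1 = 2),
                truncation = 6, method = "fft")
  })
  sol <- match_responses(src, tgt, A, margin = 56, basis_angles = basis)
  expect_lt(sol$residual, 0.02)
  # repeating a basis response makes the fit degenerate
  expect_error(match_responses(src, tgt[c(1, 1, 2)], A, margin = 56),
               "degenerate basis")
})

test_that("covariance transform and decomposition are mutually consistent", {
  set.seed(18)
  for (i in 1:20) {
    A <- random_near_identity_map()
    f <- affine_decompose(A)
    if (f$similarity || f$stretch < 1.02) next
    sg <- runif(1, 0.5, 2)
    Sp <- transform_covariance(spatial_covariance(sg^2, sg^2), A)
    sh <- shape_from_covariance(Sp)
    expect_equal(c(sh$sigma1, sh$sigma2), sg * c(f$rho1, f$rho2),
                 tolerance = 1e-10)
    a <- svd_form(f)$alpha
    dphi <- (sh$phi - a) %% pi
    expect_lt(min(dphi, pi - dphi), 1e-8)
  }
})
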