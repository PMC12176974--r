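test_that("identity map verifies with zero error", {
  img <- make_stimulus(stimulus_spec("band_limited_noise", size = 64,
                                     cutoff = 8, seed = 6))
  r <- verify_affine_covariance(img, diag(2), spatial_covariance(4, 4),
                                truncation = 4, method = "fft")
  expect_identical(r$max_relative_error, 0)
  expect_lte(r$interior_rms_relative_error, r$max_relative_error)
})

test_that("exact 90-degree rotation verifies to interpolation precision", {
  img <- make_stimulus(stimulus_spec("band_limited_noise", size = 128,
                                     cutoff = 8, seed = 11))
  r <- verify_affine_covariance(img, rot2_matrix(pi / 2),
                                spatial_covariance(36, 36), method = "fft")
  expect_lt(r$max_relative_error, 1e-3)
})

test_that("anisotropic stretch verifies within the discretization regime", {
  img <- make_stimulus(stimulus_spec("band_limited_noise", size = 128,
                                     cutoff = 8, seed = 11))
  r <- verify_affine_covariance(img, affine_map(1.5, 0, 0, 1),
                                spatial_covariance(36, 36), method = "fft")
  expect_lt(r$interior_rms_relative_error, 0.01)
  # gradient responses transform by the inverse transpose (same regime)
  rg <- verify_affine_covariance(img, affine_map(1.5, 0, 0, 1),
                                 spatial_covariance(36, 36),
                                 deriv_spec = rf_spec(6, 6), method = "fft")
  expect_lt(rg$interior_rms_relative_error, 0.01)
  expect_gte(rg$interior_rms_relative_error, r$interior_rms_relative_error)
})

test_that("verification error at least halves under grid refinement", {
  pair <- noise_pair(128L, 8, seed = 11L)
  S <- spatial_covariance(36, 36)
  A <- affine_map(1.5, 0, 0, 1)
  rc <- verify_affine_covariance(pair$coarse, A, S, method = "fft")
  rf <- verify_affine_covariance(pair$fine, A, S, method = "fft")
  expect_lt(rf$interior_rms_relative_error,
            rc$interior_rms_relative_error / 2)
})

test_that("verification rejects misconfigured requests", {
  img <- make_stimulus(stimulus_spec("band_limited_noise", size = 32,
                                     cutoff = 4, seed = 1))
  expect_error(
    verify_affine_covariance(img, affine_map(5, 0, 0, 1),
                             spatial_covariance(1, 1)),
    "stretch")
  expect_error(
    verify_affine_covariance(img, diag(2), spatial_covariance(64, 64)),
    "extent|interior")
})

test_that("spatio-temporal covariance holds on a drifting grating", {
  vid <- make_stimulus(stimulus_spec("grating", size = 64, wavelength = 8,
                                     orientation = pi / 6, frames = 16,
                                     drift_velocity = c(0.5, 0.25)))
  spec <- st_rf_spec(spatial_covariance(9, 9), tau = 1, velocity = c(0, 0))
  A <- affine_map(1.5, 0, 0, 1)
  r <- verify_st_covariance(vid, A, spec, method = "fft")
  expect_lt(r$interior_rms_relative_error, 0.02)
  # identity map: exact
  r0 <- verify_st_covariance(vid, diag(2), spec, method = "fft")
  expect_identical(r0$max_relative_error, 0)
})

test_that("static video reduces to the frame-wise spatial check", {
  vid <- make_stimulus(stimulus_spec("band_limited_noise", size = 64,
                                     cutoff = 8, seed = 9, frames = 8))
  spec <- st_rf_spec(spatial_covariance(4, 4), tau = 0.5, velocity = c(0, 0))
  A <- rot2_matrix(pi / 2)
  r <- verify_st_covariance(vid, A, spec, truncation = 4, method = "fft")
  rs <- verify_affine_covariance(vid[[1]], A, spatial_covariance(4, 4),
                                 truncation = 4, method = "fft",
                                 margin = r$interior_margin)
  expect_equal(r$interior_rms_relative_error, rs$interior_rms_relative_error,
               tolerance = 1e-10)
})

test_that("velocity-adapted kernels need the mapped velocity for exactness", {
  vid <- make_stimulus(stimulus_spec("grating", size = 64, wavelength = 8,
                                     orientation = pi / 6, frames = 16,
                                     drift_velocity = c(0.5, 0.25)))
  spec <- st_rf_spec(spatial_covariance(9, 9), tau = 1,
                     velocity = c(0.5, 0.25))
  A <- affine_map(1.5, 0, 0, 1)
  r_map <- verify_st_covariance(vid, A, spec, velocity_rule = "map",
                                method = "fft")
  r_eq <- verify_st_covariance(vid, A, spec, velocity_rule = "equal",
                               method = "fft")
  expect_lt(r_map$interior_rms_relative_error,
            r_eq$interior_rms_relative_error)
})
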