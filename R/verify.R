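covariance_report <- function(rms, mx, margin) {
  structure(list(interior_rms_relative_error = rms,
                 max_relative_error = mx,
                 interior_margin = margin),
            class = "covariance_report")
}

#' @export
print.covariance_report <- function(x, ...) {
  cat(sprintf(
    "<covariance_report> interior RMS rel. error %.3g, max rel. error %.3g (margin %.3g)\n",
    x$interior_rms_relative_error, x$max_relative_error, x$interior_margin))
  invisible(x)
}

# interior grid positions of a field, excluding a boundary band of
# physical width `margin`, optionally requiring the mapped positions
# A x to stay `margin2` inside the same extent
interior_positions <- function(field, margin, map = NULL, margin2 = margin) {
  ax <- field_axes(field)
  he <- field_half_extent(field)
  keep1 <- abs(ax$x1 - field$origin[1]) <= he[1] - margin
  keep2 <- abs(ax$x2 - field$origin[2]) <= he[2] - margin
  x <- cbind(rep(ax$x1[keep1], times = sum(keep2)),
             rep(ax$x2[keep2], each = sum(keep1)))
  if (!is.null(map)) {
    xp <- x %*% t(unclass(as_affine_map(map)))
    ok <- abs(xp[, 1] - field$origin[1]) <= he[1] - margin2 &
      abs(xp[, 2] - field$origin[2]) <= he[2] - margin2
    x <- x[ok, , drop = FALSE]
  }
  x
}

relative_errors <- function(ref, test) {
  d <- test - ref
  scale_rms <- sqrt(mean(ref^2))
  scale_max <- max(abs(ref))
  list(rms = sqrt(mean(d^2)) / max(scale_rms, 1e-300),
       mx = max(abs(d)) / max(scale_max, 1e-300))
}

#' Verify affine covariance of smoothed image responses
#'
#' Checks the covariance identity \eqn{L'(\mathcal{A}x;\,
#' \mathcal{A}\Sigma\mathcal{A}^T) = L(x;\Sigma)} on discrete data: the
#' source image is smoothed at \eqn{\Sigma}; the image warped by
#' \eqn{\mathcal{A}} is smoothed at the transformed covariance; the
#' warped-domain response is interpolated at the mapped positions
#' \eqn{\mathcal{A}x} and compared with the source response over an
#' interior region (a boundary band of kernel-truncation plus
#' interpolation width is excluded, since the identity is exact only in
#' the continuum and away from boundary effects).
#'
#' When `deriv_spec` is given, the first-order gradient responses are
#' additionally compared after the contravariant transformation
#' \eqn{\nabla_{x'} = \mathcal{A}^{-T}\nabla_x}, and the reported errors
#' are the worse of the scalar and gradient checks.
#'
#' @param image A `sampled_field`.
#' @param map An invertible `affine_map`; its decomposition must be
#'   valid and the stretch within `max_stretch`.
#' @param cov Source-domain `spatial_covariance`.
#' @param deriv_spec Optional `rf_spec` whose covariance shape is taken
#'   from `cov`; only its presence triggers the gradient check.
#' @param truncation Kernel truncation radius in standard deviations
#'   (the default 6 keeps the truncated-mass error below the
#'   discretization error, so that grid refinement shows first-order
#'   convergence).
#' @param method Convolution method, see [smooth_field()].
#' @param margin Physical interior margin; defaults to
#'   `truncation * max(sigma') + 4 * spacing` (kernel support in the
#'   warped domain plus interpolation stencil).
#' @param max_stretch Configuration limit on the map's stretch
#'   \eqn{\rho_1/\rho_2}.
#' @return A `covariance_report`.
#' @export
verify_affine_covariance <- function(image, map, cov, deriv_spec = NULL,
                                     truncation = 6,
                                     method = c("direct", "fft"),
                                     margin = NULL, max_stretch = 4) {
  stopifnot(inherits(image, "sampled_field"))
  method <- match.arg(method)
  m <- as_affine_map(map)
  f <- affine_decompose(m)
  if (f$stretch > max_stretch) {
    stop(sprintf("configuration error: map stretch %.3g exceeds limit %.3g",
                 f$stretch, max_stretch), call. = FALSE)
  }
  s <- as_spatial_covariance(cov)
  s2 <- transform_covariance(s, m)
  sh <- shape_from_covariance(s)
  sh2 <- shape_from_covariance(s2)
  margin <- margin %||% (truncation * sh2$sigma1 + 4 * image$spacing)
  he <- field_half_extent(image)
  if (margin >= min(he)) {
    stop("configuration error: kernel/extent mismatch leaves no interior",
         call. = FALSE)
  }

  L <- smooth_field(image, s, truncation = truncation, method = method)
  fw <- warp_image(image, m)
  L2 <- smooth_field(fw, s2, truncation = truncation, method = method)

  x <- interior_positions(image, margin, map = m)
  if (nrow(x) == 0L) {
    stop("configuration error: interior region is empty", call. = FALSE)
  }
  xp <- x %*% t(unclass(m))
  ref <- field_sample(L, x)
  tst <- field_sample(L2, xp)
  err <- relative_errors(ref, tst)

  if (!is.null(deriv_spec)) {
    ginv <- unclass(transform_gradient(m)) # A^{-T}
    gspec <- function(th, shp) rf_spec(shp$sigma1, shp$sigma2, shp$phi,
                                       deriv_theta = th, m1 = 1L)
    # Cartesian gradient components in both domains
    Lx <- rf_response(image, rf_spec(sh$sigma1, sh$sigma2, sh$phi, 0, 1L),
                      truncation = truncation, method = method)
    Ly <- rf_response(image, rf_spec(sh$sigma1, sh$sigma2, sh$phi, pi / 2, 1L),
                      truncation = truncation, method = method)
    L2x <- rf_response(fw, rf_spec(sh2$sigma1, sh2$sigma2, sh2$phi, 0, 1L),
                       truncation = truncation, method = method)
    L2y <- rf_response(fw, rf_spec(sh2$sigma1, sh2$sigma2, sh2$phi, pi / 2, 1L),
                       truncation = truncation, method = method)
    # normalized kernels include sigma1 factors; strip to raw partials
    gx <- field_sample(Lx, x) / sh$sigma1
    gy <- field_sample(Ly, x) / sh$sigma1
    gpx <- field_sample(L2x, xp) / sh2$sigma1
    gpy <- field_sample(L2y, xp) / sh2$sigma1
    pred_x <- ginv[1, 1] * gx + ginv[1, 2] * gy
    pred_y <- ginv[2, 1] * gx + ginv[2, 2] * gy
    eg <- relative_errors(c(pred_x, pred_y), c(gpx, gpy))
    err$rms <- max(err$rms, eg$rms)
    err$mx <- max(err$mx, eg$mx)
  }
  covariance_report(err$rms, err$mx, margin)
}

## Spatio-temporal -----------------------------------------------------------

# discrete unit-mass Gaussian temporal kernel of variance tau over
# offsets -rt..rt (frame spacing 1)
temporal_kernel <- function(tau, truncation = 4) {
  rt <- max(1L, ceiling(truncation * sqrt(tau)))
  s <- (-rt):rt
  h <- dnorm(s, sd = sqrt(tau))
  list(offsets = s, weights = h / sum(h), radius = rt)
}

#' Spatio-temporal receptive-field response of a video
#'
#' Convolves a video with the separable velocity-adapted kernel
#' \eqn{T(x,t;\Sigma,\tau,v) = g(x - vt;\Sigma)h(t;\tau)}: each frame is
#' smoothed spatially at \eqn{\Sigma}, then frames are combined
#' temporally with weights \eqn{h(s;\tau)}, sampling the smoothed frame
#' at \eqn{x - v s} (the shifted-kernel identity for the velocity
#' adaptation). Only frames with full temporal support are returned.
#'
#' @param video A `sampled_video` (list of `sampled_field` frames).
#' @param spec An `st_rf_spec`.
#' @param truncation Spatial and temporal truncation radius in standard
#'   deviations.
#' @param method Convolution method.
#' @return A list with `frames` (list of `sampled_field`) and
#'   `frame_index` (indices into the input video).
#' @export
st_response <- function(video, spec, truncation = 4,
                        method = c("direct", "fft")) {
  stopifnot(inherits(spec, "st_rf_spec"))
  method <- match.arg(method)
  nt <- length(video)
  tk <- temporal_kernel(spec$tau, truncation)
  if (2L * tk$radius + 1L > nt) {
    stop("configuration error: temporal kernel longer than the video",
         call. = FALSE)
  }
  smoothed <- lapply(video, smooth_field, cov = spec$cov,
                     truncation = truncation, method = method)
  valid <- (tk$radius + 1L):(nt - tk$radius)
  n1 <- nrow(video[[1]]$values); n2 <- ncol(video[[1]]$values)
  ax <- field_axes(video[[1]])
  base_x <- cbind(rep(ax$x1, times = n2), rep(ax$x2, each = n1))
  frames <- lapply(valid, function(t0) {
    acc <- matrix(0, n1, n2)
    for (k in seq_along(tk$offsets)) {
      s <- tk$offsets[k]
      Ls <- smoothed[[t0 - s]]
      if (all(spec$velocity == 0)) {
        acc <- acc + tk$weights[k] * Ls$values
      } else {
        xq <- base_x - matrix(spec$velocity * s, n1 * n2, 2L, byrow = TRUE)
        acc <- acc + tk$weights[k] * matrix(field_sample(Ls, xq), n1, n2)
      }
    }
    sampled_field(acc, spacing = video[[1]]$spacing, origin = video[[1]]$origin)
  })
  list(frames = frames, frame_index = valid)
}

#' Verify spatio-temporal affine covariance
#'
#' Checks \eqn{L'(\mathcal{A}x, t;\, \mathcal{A}\Sigma\mathcal{A}^T,
#' \tau', v') = L(x, t;\, \Sigma, \tau, v)} for a video pair related by
#' a pure spatial affine transformation (\eqn{x' = \mathcal{A}x},
#' \eqn{t' = t}): the source video is filtered with the
#' spatio-temporal kernel, each frame of the warped video is filtered
#' with the transformed spatial covariance and the same temporal scale,
#' and responses are compared at corresponding positions over the
#' spatial interior and temporally valid frames.
#'
#' The velocity parameter of the warped-domain kernel follows
#' `velocity_rule`: `"equal"` keeps \eqn{v' = v} (exact for \eqn{v = 0},
#' the separable case); `"map"` uses the mathematically exact
#' \eqn{v' = \mathcal{A}v} for velocity-adapted kernels.
#'
#' @param video A `sampled_video`.
#' @param map An invertible `affine_map`.
#' @param spec An `st_rf_spec` for the source domain.
#' @param velocity_rule `"equal"` or `"map"` (see Details).
#' @param truncation,method,margin,max_stretch As in
#'   [verify_affine_covariance()] (default truncation 4 here: video
#'   frames are small and the spatio-temporal tolerance regime is
#'   percent-level, far above the 4-sigma truncated-mass deficit).
#' @return A `covariance_report`.
#' @export
verify_st_covariance <- function(video, map, spec,
                                 velocity_rule = c("equal", "map"),
                                 truncation = 4,
                                 method = c("direct", "fft"),
                                 margin = NULL, max_stretch = 4) {
  velocity_rule <- match.arg(velocity_rule)
  method <- match.arg(method)
  m <- as_affine_map(map)
  f <- affine_decompose(m)
  if (f$stretch > max_stretch) {
    stop(sprintf("configuration error: map stretch %.3g exceeds limit %.3g",
                 f$stretch, max_stretch), call. = FALSE)
  }
  s2 <- transform_covariance(spec$cov, m)
  vprime <- if (velocity_rule == "map") {
    as.numeric(unclass(m) %*% spec$velocity)
  } else {
    spec$velocity
  }
  spec2 <- st_rf_spec(s2, spec$tau, vprime)
  sh2 <- shape_from_covariance(s2)
  first <- video[[1]]
  vmax <- max(abs(spec$velocity), abs(vprime)) * (temporal_kernel(spec$tau, truncation)$radius)
  margin <- margin %||% (truncation * sh2$sigma1 + 4 * first$spacing + vmax)
  he <- field_half_extent(first)
  if (margin >= min(he)) {
    stop("configuration error: kernel/extent mismatch leaves no interior",
         call. = FALSE)
  }

  warped <- structure(lapply(video, warp_image, map = m), class = "sampled_video")
  L <- st_response(video, spec, truncation = truncation, method = method)
  L2 <- st_response(warped, spec2, truncation = truncation, method = method)

  x <- interior_positions(first, margin, map = m)
  xp <- x %*% t(unclass(m))
  ref <- unlist(lapply(L$frames, field_sample, x = x))
  tst <- unlist(lapply(L2$frames, field_sample, x = xp))
  err <- relative_errors(ref, tst)
  covariance_report(err$rms, err$mx, margin)
}
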