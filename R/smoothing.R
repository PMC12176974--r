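## Discrete convolution ------------------------------------------------------

# symmetric (edge-repeating) reflective padding by r1 rows / r2 cols
pad_reflect <- function(V, r1, r2) {
  n1 <- nrow(V); n2 <- ncol(V)
  idx1 <- reflect_index(seq.int(1L - r1, n1 + r1), n1)
  idx2 <- reflect_index(seq.int(1L - r2, n2 + r2), n2)
  V[idx1, idx2, drop = FALSE]
}

# true convolution out(x) = sum_u K(u) V(x - u), kernel indices centred;
# reflective boundary handling
conv2_direct <- function(V, K) {
  r1 <- (nrow(K) - 1L) %/% 2L
  r2 <- (ncol(K) - 1L) %/% 2L
  pad <- pad_reflect(V, r1, r2)
  n1 <- nrow(V); n2 <- ncol(V)
  out <- matrix(0, n1, n2)
  for (i in seq_len(nrow(K))) {
    di <- i - r1 - 1L # kernel offset
    for (j in seq_len(ncol(K))) {
      w <- K[i, j]
      if (w == 0) next
      dj <- j - r2 - 1L
      # V(x - u): shift the padded image by -offset
      out <- out + w * pad[(r1 + 1L - di):(r1 + n1 - di),
                           (r2 + 1L - dj):(r2 + n2 - dj), drop = FALSE]
    }
  }
  out
}

conv2_fft <- function(V, K) {
  r1 <- (nrow(K) - 1L) %/% 2L
  r2 <- (ncol(K) - 1L) %/% 2L
  pad <- pad_reflect(V, r1, r2)
  N1 <- nrow(pad); N2 <- ncol(pad)
  kbig <- matrix(0, N1, N2)
  idx1 <- ((-r1):r1) %% N1 + 1L
  idx2 <- ((-r2):r2) %% N2 + 1L
  kbig[idx1, idx2] <- K
  full <- Re(fft(fft(pad) * fft(kbig), inverse = TRUE)) / (N1 * N2)
  full[(r1 + 1L):(r1 + nrow(V)), (r2 + 1L):(r2 + ncol(V)), drop = FALSE]
}

conv2 <- function(V, K, method = c("direct", "fft")) {
  method <- match.arg(method)
  if (method == "direct") conv2_direct(V, K) else conv2_fft(V, K)
}

# sampled convolution kernel for a given rf_spec at the image spacing;
# discrete mass scaled by spacing^2 so the convolution approximates the
# continuous integral
make_conv_kernel <- function(spec, spacing, truncation) {
  smax <- max(spec$sigma1, spec$sigma2)
  r <- ceiling(truncation * smax / spacing)
  ax <- (-r:r) * spacing
  n <- length(ax)
  x <- cbind(rep(ax, times = n), rep(ax, each = n))
  matrix(general_directional_value(x, spec), n, n) * spacing^2
}

#' Smooth an image with an affine Gaussian kernel
#'
#' Discrete convolution of the image with a sampled affine Gaussian
#' kernel (truncated at `truncation` standard deviations, reflective
#' boundaries). Linear and shift-covariant; the affine scale-space
#' smoothing underlying the covariance relations.
#'
#' @param image A `sampled_field`.
#' @param cov A `spatial_covariance`.
#' @param truncation Kernel truncation radius in units of the largest
#'   eigen-scale.
#' @param method `"direct"` (truncated spatial accumulation; the
#'   default, keeping truncation behaviour explicit) or `"fft"`
#'   (identical result up to round-off, faster for large kernels).
#' @param renormalize If `TRUE`, rescale the discrete kernel to unit
#'   sum.
#' @return A `sampled_field` with the same geometry.
#' @export
smooth_field <- function(image, cov, truncation = 4,
                         method = c("direct", "fft"), renormalize = FALSE) {
  stopifnot(inherits(image, "sampled_field"))
  method <- match.arg(method)
  s <- as_spatial_covariance(cov)
  sh <- shape_from_covariance(s)
  spec <- rf_spec(sh$sigma1, sh$sigma2, sh$phi)
  he <- field_half_extent(image)
  if (truncation * sh$sigma1 > max(he)) {
    stop(sprintf(
      "extent error: kernel truncation radius %.3g exceeds image half extent %.3g",
      truncation * sh$sigma1, max(he)), call. = FALSE)
  }
  K <- make_conv_kernel(spec, image$spacing, truncation)
  if (renormalize) K <- K / sum(K)
  sampled_field(conv2(image$values, K, method), spacing = image$spacing,
                origin = image$origin)
}

#' Derivative receptive-field response of an image
#'
#' Convolves an image with a sampled (scale-normalized) directional
#' derivative of the affine Gaussian given by `spec`.
#'
#' @param image A `sampled_field`.
#' @param spec An `rf_spec`.
#' @param truncation,method As in [smooth_field()].
#' @return A `sampled_field` with the same geometry.
#' @export
rf_response <- function(image, spec, truncation = 4,
                        method = c("direct", "fft")) {
  stopifnot(inherits(image, "sampled_field"), inherits(spec, "rf_spec"))
  method <- match.arg(method)
  K <- make_conv_kernel(spec, image$spacing, truncation)
  sampled_field(conv2(image$values, K, method), spacing = image$spacing,
                origin = image$origin)
}

#' Cascade smoothing via the semigroup property
#'
#' Affine Gaussian kernels form a semigroup under convolution:
#' \eqn{g(\cdot;\Sigma_1) * g(\cdot;\Sigma_2) = g(\cdot;\Sigma_1+\Sigma_2)}.
#' A response already computed at \eqn{\Sigma_1} (possibly a derivative
#' response) can therefore be carried to any coarser
#' \eqn{\Sigma_2 = \Sigma_1 + \Delta\Sigma} by one further convolution
#' with \eqn{g(\cdot;\Delta\Sigma)}, provided the increment
#' \eqn{\Delta\Sigma} is symmetric positive definite. A zero increment
#' is the identity.
#'
#' @param response A `sampled_field` (smoothed image or derivative
#'   response at the finer covariance).
#' @param delta_cov The covariance increment \eqn{\Delta\Sigma}: a 2x2
#'   symmetric matrix, possibly all-zero.
#' @param truncation,method As in [smooth_field()].
#' @return A `sampled_field` at the coarser covariance.
#' @export
cascade_smooth <- function(response, delta_cov, truncation = 4,
                           method = c("direct", "fft")) {
  stopifnot(inherits(response, "sampled_field"))
  method <- match.arg(method)
  d <- as.matrix(delta_cov)
  if (!all(dim(d) == c(2L, 2L)) || abs(d[1, 2] - d[2, 1]) > 1e-12 * max(abs(d), 1)) {
    stop("delta_cov must be a symmetric 2x2 matrix", call. = FALSE)
  }
  if (all(abs(d) < 1e-14)) return(response)
  ev <- eigen((d + t(d)) / 2, symmetric = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf(
      "cascade infeasible: covariance increment has non-positive eigenvalue %.6g",
      min(ev)), call. = FALSE)
  }
  smooth_field(response, spatial_covariance(d), truncation = truncation,
               method = method)
}
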