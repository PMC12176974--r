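#' Spatial covariance matrix of an affine Gaussian kernel
#'
#' A symmetric positive-definite 2x2 matrix \eqn{\Sigma} describing the
#' shape of an anisotropic Gaussian receptive field.
#'
#' @param c11,c22 Diagonal entries (squared length units), positive.
#' @param c12 Off-diagonal entry. Alternatively `c11` may be a 2x2
#'   symmetric matrix.
#' @return A `spatial_covariance` object (classed 2x2 matrix).
#' @export
spatial_covariance <- function(c11, c22 = NULL, c12 = 0) {
  if (is.matrix(c11)) {
    m <- c11
    if (!all(dim(m) == c(2L, 2L)) || abs(m[1, 2] - m[2, 1]) > 1e-12 * max(abs(m), 1)) {
      stop("invalid covariance: must be a symmetric 2x2 matrix", call. = FALSE)
    }
    m[1, 2] <- m[2, 1] <- (m[1, 2] + m[2, 1]) / 2
  } else {
    m <- matrix(c(c11, c12, c12, c22), 2L, 2L)
  }
  storage.mode(m) <- "double"
  stopifnot_finite(m, "covariance entries")
  if (m[1, 1] <= 0 || m[2, 2] <= 0 || m[1, 1] * m[2, 2] - m[1, 2]^2 <= 0) {
    stop("invalid covariance: matrix must be positive definite", call. = FALSE)
  }
  structure(m, class = c("spatial_covariance", "matrix"))
}

as_spatial_covariance <- function(x) {
  if (inherits(x, "spatial_covariance")) return(x)
  spatial_covariance(as.matrix(x))
}

#' @export
print.spatial_covariance <- function(x, ...) {
  cat("<spatial_covariance>\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Covariance matrix from eigen-scales and orientation
#'
#' Parameterizes \eqn{\Sigma} by standard deviations
#' \eqn{\sigma_1, \sigma_2} along its eigendirections and the
#' orientation \eqn{\varphi} of the first eigendirection:
#' \deqn{C_{11} = \sigma_1^2\cos^2\varphi + \sigma_2^2\sin^2\varphi,}
#' \deqn{C_{12} = (\sigma_1^2-\sigma_2^2)\cos\varphi\sin\varphi,}
#' \deqn{C_{22} = \sigma_1^2\sin^2\varphi + \sigma_2^2\cos^2\varphi,}
#' so that the eigenvalues of \eqn{\Sigma} are \eqn{\sigma_1^2} and
#' \eqn{\sigma_2^2}.
#'
#' @param sigma1,sigma2 Positive standard deviations (length units).
#' @param phi Orientation of the \eqn{\sigma_1} eigendirection,
#'   radians.
#' @return A `spatial_covariance`.
#' @examples
#' covariance_from_shape(2, 1, 0)      # diag(4, 1)
#' covariance_from_shape(2, 1, pi / 4) # [[2.5, 1.5], [1.5, 2.5]]
#' @export
covariance_from_shape <- function(sigma1, sigma2, phi = 0) {
  stopifnot_finite(c(sigma1, sigma2, phi), "shape parameters")
  if (sigma1 <= 0 || sigma2 <= 0) {
    stop("invalid shape: sigma1 and sigma2 must be positive", call. = FALSE)
  }
  cphi <- cos(phi); sphi <- sin(phi)
  spatial_covariance(
    c11 = sigma1^2 * cphi^2 + sigma2^2 * sphi^2,
    c22 = sigma1^2 * sphi^2 + sigma2^2 * cphi^2,
    c12 = (sigma1^2 - sigma2^2) * cphi * sphi)
}

#' Eigen-scales and orientation from a covariance matrix
#'
#' Inverse of [covariance_from_shape()], unique only up to the
#' relabelling `(sigma1, sigma2, phi) -> (sigma2, sigma1, phi + pi/2)`
#' and `phi` modulo `pi`. Convention: `sigma1` is the square root of the
#' larger eigenvalue and `phi` (in `(-pi/2, pi/2]`) the orientation of
#' its eigenvector; for an isotropic matrix `phi = 0` and the (equal)
#' scales are paired with the coordinate axes.
#'
#' @param cov A `spatial_covariance` or positive-definite 2x2 matrix.
#' @return A list with `sigma1`, `sigma2`, `phi`.
#' @export
shape_from_covariance <- function(cov) {
  m <- as_spatial_covariance(cov)
  e <- eigen(unclass(m), symmetric = TRUE)
  if (any(e$values <= 0)) {
    stop("invalid covariance: matrix must be positive definite", call. = FALSE)
  }
  if (diff(range(e$values)) <= 1e-14 * max(e$values)) {
    s <- sqrt(mean(e$values))
    return(list(sigma1 = s, sigma2 = s, phi = 0))
  }
  v1 <- e$vectors[, 1] # eigenvector of the larger eigenvalue
  list(sigma1 = sqrt(e$values[1]),
       sigma2 = sqrt(e$values[2]),
       phi = wrap_half_pi(atan2(v1[2], v1[1])))
}

#' Transform a covariance matrix under an affine map
#'
#' Affine covariance requires the receptive-field covariance matrices in
#' the two image domains to be related by
#' \eqn{\Sigma' = \mathcal{A}\,\Sigma\,\mathcal{A}^T}.
#'
#' @param cov A `spatial_covariance`.
#' @param map An invertible `affine_map`.
#' @return The transformed `spatial_covariance`.
#' @export
transform_covariance <- function(cov, map) {
  m <- as_affine_map(map)
  if (abs(det(m)) < .Machine$double.eps * 4) {
    stop("invalid map: matrix is singular", call. = FALSE)
  }
  s <- as_spatial_covariance(cov)
  spatial_covariance(unclass(m) %*% unclass(s) %*% t(unclass(m)))
}

#' Gradient transformation under an affine map
#'
#' Spatial derivative operators transform contravariantly:
#' \eqn{\nabla_{x'} = \mathcal{A}^{-T}\,\nabla_x}. Returns
#' \eqn{\mathcal{A}^{-T}} as an `affine_map`.
#'
#' @param map An invertible `affine_map`.
#' @return The inverse-transpose as an `affine_map`.
#' @export
transform_gradient <- function(map) {
  m <- as_affine_map(map)
  if (abs(det(m)) < .Machine$double.eps * 4) {
    stop("invalid map: matrix is singular", call. = FALSE)
  }
  affine_map(t(solve(unclass(m))))
}
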