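#' Receptive-field specification
#'
#' Describes an affine Gaussian derivative receptive field: the kernel
#' shape (eigen-scales `sigma1`, `sigma2` and orientation `kernel_phi`
#' of the spatial covariance matrix), the direction `deriv_theta` of
#' differentiation, and the derivative orders `m1` (along `deriv_theta`)
#' and `m2` (orthogonal to it). In the classical 3-parameter model the
#' differentiation direction coincides with the kernel orientation; the
#' 4-parameter extension lets `deriv_theta` vary freely, which is needed
#' to span the full four degrees of freedom of 2-D affine
#' transformations.
#'
#' Derived descriptors: overall size \eqn{\bar\sigma =
#' \sqrt{\sigma_1\sigma_2}} and eccentricity
#' \eqn{\epsilon = \sigma_2/\sigma_1}.
#'
#' @param sigma1,sigma2 Positive eigen-scales (length units);
#'   \eqn{\sigma_1^2, \sigma_2^2} are the eigenvalues of the covariance
#'   matrix.
#' @param kernel_phi Orientation of the `sigma1` eigendirection,
#'   wrapped into `(-pi/2, pi/2]` (orientation, period pi).
#' @param deriv_theta Direction of differentiation, wrapped into
#'   `(-pi, pi]`; defaults to `kernel_phi`.
#' @param m1,m2 Non-negative integer derivative orders along
#'   `deriv_theta` and its orthogonal direction.
#' @return An object of class `rf_spec`.
#' @export
rf_spec <- function(sigma1, sigma2, kernel_phi = 0, deriv_theta = kernel_phi,
                    m1 = 0L, m2 = 0L) {
  stopifnot_finite(c(sigma1, sigma2, kernel_phi, deriv_theta, m1, m2), "rf_spec")
  if (sigma1 <= 0 || sigma2 <= 0) {
    stop("invalid shape: sigma1 and sigma2 must be positive", call. = FALSE)
  }
  if (m1 < 0 || m2 < 0 || m1 != round(m1) || m2 != round(m2)) {
    stop("derivative orders must be non-negative integers", call. = FALSE)
  }
  structure(
    list(sigma1 = sigma1, sigma2 = sigma2,
         kernel_phi = wrap_half_pi(kernel_phi),
         deriv_theta = wrap_pi(deriv_theta),
         m1 = as.integer(m1), m2 = as.integer(m2),
         size_bar = sqrt(sigma1 * sigma2),
         eccentricity = sigma2 / sigma1),
    class = "rf_spec")
}

#' @export
print.rf_spec <- function(x, ...) {
  cat(sprintf(
    "<rf_spec> sigma = (%.4g, %.4g), kernel_phi = %.4g, theta = %.4g, orders (%d, %d)\n",
    x$sigma1, x$sigma2, x$kernel_phi, x$deriv_theta, x$m1, x$m2))
  invisible(x)
}

rf_covariance <- function(spec) {
  covariance_from_shape(spec$sigma1, spec$sigma2, spec$kernel_phi)
}

#' Affine Gaussian kernel values
#'
#' Evaluates the zero-mean anisotropic Gaussian density
#' \deqn{g(x;\Sigma) = \frac{1}{2\pi\sqrt{\det\Sigma}}
#'   e^{-x^T \Sigma^{-1} x / 2}.}
#'
#' @param x An n x 2 matrix (or length-2 vector) of positions.
#' @param cov A `spatial_covariance` (positive definite).
#' @return Numeric vector of kernel values.
#' @examples
#' gaussian_value(c(0, 0), spatial_covariance(1, 1)) # 1 / (2 * pi)
#' @export
gaussian_value <- function(x, cov) {
  s <- as_spatial_covariance(cov)
  x <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  b <- solve(unclass(s))
  q <- rowSums((x %*% b) * x)
  exp(-q / 2) / (2 * pi * sqrt(det(unclass(s))))
}

## Polynomial machinery for Gaussian partial derivatives ---------------------
#
# Any partial derivative of g(x; Sigma) equals P(x) * g(x; Sigma) with P
# a bivariate (Hermite-type) polynomial. Polynomials are stored as
# coefficient matrices coef[p+1, q+1] for the monomial x1^p x2^q, and
# built by the recursion d/dx1 (P g) = (dP/dx1 - P * (B x)_1) g with
# B = Sigma^{-1}.

poly_pad <- function(P, nr, nc) {
  out <- matrix(0, nr, nc)
  out[seq_len(nrow(P)), seq_len(ncol(P))] <- P
  out
}

poly_add <- function(P, Q) {
  nr <- max(nrow(P), nrow(Q)); nc <- max(ncol(P), ncol(Q))
  poly_pad(P, nr, nc) + poly_pad(Q, nr, nc)
}

poly_shift_x1 <- function(P) rbind(0, P)          # multiply by x1
poly_shift_x2 <- function(P) cbind(0, P)          # multiply by x2

poly_d_x1 <- function(P) {
  if (nrow(P) == 1L) return(matrix(0, 1L, ncol(P)))
  P[-1L, , drop = FALSE] * seq_len(nrow(P) - 1L)
}
poly_d_x2 <- function(P) {
  if (ncol(P) == 1L) return(matrix(0, nrow(P), 1L))
  P[, -1L, drop = FALSE] * rep(seq_len(ncol(P) - 1L), each = nrow(P))
}

# apply d/dx1 or d/dx2 to P(x) g(x; Sigma), B = Sigma^{-1}
poly_deriv_step <- function(P, B, axis) {
  if (axis == 1L) {
    dP <- poly_d_x1(P)
    lin <- poly_add(B[1, 1] * poly_shift_x1(P), B[1, 2] * poly_shift_x2(P))
  } else {
    dP <- poly_d_x2(P)
    lin <- poly_add(B[2, 1] * poly_shift_x1(P), B[2, 2] * poly_shift_x2(P))
  }
  poly_add(dP, -lin)
}

# polynomial factor of d^i/dx1^i d^j/dx2^j g(x; Sigma)
gauss_deriv_poly <- function(i, j, B) {
  P <- matrix(1, 1L, 1L)
  for (k in seq_len(i)) P <- poly_deriv_step(P, B, 1L)
  for (k in seq_len(j)) P <- poly_deriv_step(P, B, 2L)
  P
}

poly_eval <- function(P, x) {
  # x: n x 2 matrix
  pow1 <- outer(x[, 1], 0:(nrow(P) - 1L), `^`)
  pow2 <- outer(x[, 2], 0:(ncol(P) - 1L), `^`)
  rowSums((pow1 %*% P) * pow2)
}

# Cartesian-basis coefficients of the directional operator
# (cos t d1 + sin t d2)^{m1} (-sin t d1 + cos t d2)^{m2}:
# returns coef matrix c[i+1, j+1] for d1^i d2^j (i + j = m1 + m2).
directional_operator_coeffs <- function(m1, m2, theta) {
  ct <- cos(theta); st <- sin(theta)
  m <- m1 + m2
  coef <- matrix(0, m + 1L, m + 1L)
  for (a in 0:m1) {
    ca <- choose(m1, a) * ct^a * st^(m1 - a)
    for (b in 0:m2) {
      cb <- choose(m2, b) * (-st)^b * ct^(m2 - b)
      i <- a + b; j <- m - i
      coef[i + 1L, j + 1L] <- coef[i + 1L, j + 1L] + ca * cb
    }
  }
  coef
}

#' Generalized directional-derivative receptive field values
#'
#' Evaluates the scale-normalized directional derivative of the affine
#' Gaussian kernel,
#' \deqn{\sigma_1^{m_1}\,\sigma_2^{m_2}\,
#'   (\cos\theta\,\partial_{x_1} + \sin\theta\,\partial_{x_2})^{m_1}
#'   (-\sin\theta\,\partial_{x_1} + \cos\theta\,\partial_{x_2})^{m_2}\,
#'   g(x;\Sigma),}
#' for arbitrary orders and an arbitrary differentiation direction
#' \eqn{\theta} (not necessarily aligned with the kernel
#' eigendirections). The operator is expanded binomially into Cartesian
#' partial derivatives, each of which is a Hermite-type polynomial times
#' the Gaussian.
#'
#' Normalization note: one \eqn{\sigma_1} power per derivative order
#' along \eqn{\theta} and one \eqn{\sigma_2} power per order orthogonal
#' to it (the per-axis generalization of the \eqn{\sigma_1^m} factor of
#' the aligned closed forms).
#'
#' @param x An n x 2 matrix (or length-2 vector) of positions.
#' @param spec An `rf_spec`.
#' @return Numeric vector of kernel values.
#' @seealso [simple_cell_value()] for the aligned first/second-order
#'   closed forms.
#' @export
general_directional_value <- function(x, spec) {
  stopifnot(inherits(spec, "rf_spec"))
  x <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  s <- rf_covariance(spec)
  if (spec$m1 + spec$m2 == 0L) return(gaussian_value(x, s))
  B <- solve(unclass(s))
  coef <- directional_operator_coeffs(spec$m1, spec$m2, spec$deriv_theta)
  m <- spec$m1 + spec$m2
  P <- matrix(0, 1L, 1L)
  for (i in 0:m) {
    j <- m - i
    cij <- coef[i + 1L, j + 1L]
    if (cij != 0) P <- poly_add(P, cij * gauss_deriv_poly(i, j, B))
  }
  norm <- spec$sigma1^spec$m1 * spec$sigma2^spec$m2
  norm * poly_eval(P, x) * gaussian_value(x, s)
}

#' Closed-form simple-cell receptive field values
#'
#' Evaluates the idealized simple-cell model
#' \eqn{T(x;\sigma_1,\sigma_2,\varphi,m) = \sigma_1^m\,
#' \partial_\varphi^m\, g(x;\Sigma)} for orders `m = 1, 2` with the
#' differentiation direction aligned with the kernel orientation, using
#' the explicit closed forms (first-order: an odd linear factor times
#' the anisotropic Gaussian; second-order: a quadratic factor).
#'
#' @param x An n x 2 matrix (or length-2 vector) of positions.
#' @param spec An `rf_spec` with `deriv_theta == kernel_phi`,
#'   `m2 == 0`, and `m1` 1 or 2.
#' @return Numeric vector of kernel values.
#' @export
simple_cell_value <- function(x, spec) {
  stopifnot(inherits(spec, "rf_spec"))
  if (spec$m2 != 0L || !(spec$m1 %in% c(1L, 2L))) {
    stop("order error: closed forms cover m = m1 in {1, 2} with m2 = 0; ",
         "use general_directional_value() for other orders", call. = FALSE)
  }
  if (abs(wrap_pi(spec$deriv_theta - spec$kernel_phi)) > 1e-12 &&
      abs(wrap_pi(spec$deriv_theta - spec$kernel_phi - pi)) > 1e-12) {
    stop("order error: closed forms require differentiation along the kernel ",
         "orientation; use general_directional_value()", call. = FALSE)
  }
  x <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  s1 <- spec$sigma1; s2 <- spec$sigma2; phi <- spec$kernel_phi
  x1 <- x[, 1]; x2 <- x[, 2]
  expo <- -((s1^2 + s2^2) * (x1^2 + x2^2) -
              (s1^2 - s2^2) * (2 * x1 * x2 * sin(2 * phi) +
                                 cos(2 * phi) * (x1^2 - x2^2))) /
    (4 * s1^2 * s2^2)
  sign_theta <- if (abs(wrap_pi(spec$deriv_theta - spec$kernel_phi)) <= 1e-12) 1 else -1
  if (spec$m1 == 1L) {
    sign_theta * (-(x1 * cos(phi) + x2 * sin(phi)) / (2 * pi * s1^2 * s2)) * exp(expo)
  } else {
    ((cos(2 * phi) * (x1^2 - x2^2) + 2 * x1 * x2 * sin(2 * phi) -
        2 * s1^2 + x1^2 + x2^2) / (4 * pi * s1^3 * s2)) * exp(expo)
  }
}

#' Sample a receptive-field kernel on a grid
#'
#' Pointwise evaluation of the (derivative of the) affine Gaussian at
#' pixel centres on a centred square grid. The default geometry truncates
#' at `truncation` times the largest eigen-scale.
#'
#' @param spec An `rf_spec`.
#' @param spacing Grid spacing.
#' @param extent Half side length (physical units); defaults to
#'   `truncation * max(sigma1, sigma2)`.
#' @param truncation Truncation radius in units of the largest scale.
#' @param renormalize If `TRUE` and the kernel is zeroth order,
#'   renormalize the discrete sum to 1 (off by default, keeping the
#'   samples analytically comparable).
#' @param on_small What to do when `extent` is below
#'   `4 * max(sigma1, sigma2)`: `"warn"` (default), `"error"`, or
#'   `"none"`.
#' @return A `sampled_field` with attributes `spec` and
#'   `truncation_radius`.
#' @export
sample_kernel <- function(spec, spacing = 1, extent = NULL, truncation = 4,
                          renormalize = FALSE,
                          on_small = c("warn", "error", "none")) {
  stopifnot(inherits(spec, "rf_spec"))
  on_small <- match.arg(on_small)
  smax <- max(spec$sigma1, spec$sigma2)
  extent <- extent %||% (truncation * smax)
  if (extent < 4 * smax - 1e-12) {
    msg <- sprintf("kernel truncated at %.3g < 4 max(sigma) = %.3g", extent, 4 * smax)
    if (on_small == "error") stop(msg, call. = FALSE)
    if (on_small == "warn") warning(msg, call. = FALSE)
  }
  r <- ceiling(extent / spacing)
  ax <- (-r:r) * spacing
  n <- length(ax)
  x <- cbind(rep(ax, times = n), rep(ax, each = n))
  vals <- general_directional_value(x, spec)
  V <- matrix(vals, n, n)
  if (renormalize && spec$m1 + spec$m2 == 0L) {
    V <- V / (sum(V) * spacing^2)
  }
  out <- sampled_field(V, spacing = spacing, origin = c(0, 0))
  attr(out, "spec") <- spec
  attr(out, "truncation_radius") <- r * spacing
  out
}

## Spatio-temporal model ------------------------------------------------------

#' Spatio-temporal receptive-field specification
#'
#' Idealized space-time separable (velocity-adapted) model
#' \eqn{T(x,t;\Sigma,\tau,v) = g(x - v t;\Sigma)\,h(t;\tau)} with
#' \eqn{h} a unit-mass temporal kernel of variance \eqn{\tau}. This
#' package uses a (non-causal) Gaussian temporal kernel; the covariance
#' results used here depend only on the variance.
#'
#' @param cov Spatial covariance `spatial_covariance` (or 2x2 matrix).
#' @param tau Temporal variance \eqn{\tau = \sigma_t^2 > 0} (squared
#'   time units).
#' @param velocity Length-2 image velocity (length per time).
#' @return An object of class `st_rf_spec`.
#' @export
st_rf_spec <- function(cov, tau, velocity = c(0, 0)) {
  cov <- as_spatial_covariance(cov)
  stopifnot_finite(c(tau, velocity), "spatio-temporal parameters")
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  structure(list(cov = cov, tau = tau, velocity = as.numeric(velocity)),
            class = "st_rf_spec")
}

#' Spatio-temporal receptive-field values
#'
#' Evaluates \eqn{T(x,t;\Sigma,\tau,v) = g(x - vt;\Sigma)\,h(t;\tau)}
#' with a Gaussian temporal kernel \eqn{h(t;\tau)} of variance
#' \eqn{\tau}.
#'
#' @param x An n x 2 matrix (or length-2 vector) of spatial positions.
#' @param t Time value(s), scalar or length n.
#' @param spec An `st_rf_spec`.
#' @return Numeric vector of kernel values.
#' @export
spatiotemporal_value <- function(x, t, spec) {
  stopifnot(inherits(spec, "st_rf_spec"))
  x <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  t <- rep_len(t, nrow(x))
  xs <- x - cbind(t * spec$velocity[1], t * spec$velocity[2])
  gaussian_value(xs, spec$cov) * dnorm(t, sd = sqrt(spec$tau))
}
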