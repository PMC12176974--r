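steering_solution <- function(coefficients, basis_angles, residual, condition) {
  structure(list(coefficients = coefficients, basis_angles = basis_angles,
                 residual = residual, condition_estimate = condition),
            class = "steering_solution")
}

#' @export
print.steering_solution <- function(x, ...) {
  cat(sprintf("<steering_solution> %d coefficients, residual %.3g, condition %.3g\n",
              length(x$coefficients), x$residual, x$condition_estimate))
  cat("  p =", paste(sprintf("%.6g", x$coefficients), collapse = ", "), "\n")
  invisible(x)
}

# columns of the steering system: Cartesian-monomial coefficients of the
# pure order-m directional derivative operator at each angle,
# coef_i = choose(m, i) cos(theta)^i sin(theta)^(m-i) for d1^i d2^(m-i)
steering_basis_matrix <- function(m, angles) {
  vapply(angles, function(th) {
    i <- 0:m
    choose(m, i) * cos(th)^i * sin(th)^(m - i)
  }, numeric(m + 1L))
}

condition_2norm <- function(A) {
  sv <- svd(A, nu = 0, nv = 0)$d
  if (min(sv) <= 0) Inf else max(sv) / min(sv)
}

#' Steering coefficients for directional derivatives
#'
#' For a fixed spatial covariance matrix, the order-\eqn{m} directional
#' derivative of the affine Gaussian at any angle is a linear
#' combination of order-\eqn{m} directional derivatives at
#' \eqn{M \ge m+1} sufficiently different fixed angles:
#' \deqn{\partial_\theta^m g = \sum_k p_k\, \partial_{\varphi_k}^m g.}
#' The coefficients are found by expressing every kernel in the
#' Cartesian partial-derivative basis
#' \eqn{\{\partial_{x_1}^i \partial_{x_2}^{m-i} g\}} (dimension
#' \eqn{m+1}) and solving the resulting linear system, by least squares
#' when over-determined in the basis count. Since all kernels share the
#' covariance and the scale normalization, the coefficients are
#' independent of the kernel shape; the shape only enters the reported
#' pointwise reconstruction residual.
#'
#' @param order_m Derivative order \eqn{m \ge 1}.
#' @param target_theta Angle at which the derivative is wanted.
#' @param basis_angles Angles of the available responses; at least
#'   `order_m + 1`, pairwise distinct modulo pi.
#' @param shape Optional list/vector `(sigma1, sigma2, kernel_phi)` used
#'   for the pointwise residual check (defaults to an isotropic
#'   unit-scale kernel).
#' @param condition_limit Bases with a steering-system condition number
#'   above this are rejected as degenerate (the operational reading of
#'   "sufficiently different directions").
#' @return A `steering_solution` with `coefficients`, `basis_angles`,
#'   pointwise `residual` (max abs reconstruction error relative to the
#'   max abs target kernel value on a test grid) and
#'   `condition_estimate`.
#' @examples
#' steer_coefficients(1, pi / 6, c(0, pi / 2))$coefficients # (cos, sin)(pi/6)
#' @export
steer_coefficients <- function(order_m, target_theta, basis_angles,
                               shape = NULL, condition_limit = 1e6) {
  m <- as.integer(order_m)
  if (m < 1L) stop("order_m must be >= 1", call. = FALSE)
  M <- length(basis_angles)
  if (M < m + 1L) {
    stop(sprintf("need at least m + 1 = %d basis angles, got %d", m + 1L, M),
         call. = FALSE)
  }
  A <- steering_basis_matrix(m, basis_angles)
  cond <- condition_2norm(A)
  if (!is.finite(cond) || cond > condition_limit) {
    stop(sprintf(
      "degenerate basis: steering-system condition estimate %.3g exceeds %.3g; %s",
      cond, condition_limit,
      "basis directions must be sufficiently different (distinct modulo pi)"),
      call. = FALSE)
  }
  b <- steering_basis_matrix(m, target_theta)[, 1]
  p <- qr.solve(A, b)

  shape <- shape %||% list(sigma1 = 1, sigma2 = 1, kernel_phi = 0)
  shape <- as.list(shape)
  if (is.null(names(shape)) || !all(c("sigma1", "sigma2") %in% names(shape))) {
    names(shape) <- c("sigma1", "sigma2", "kernel_phi")[seq_along(shape)]
  }
  spec_at <- function(th) rf_spec(shape$sigma1, shape$sigma2,
                                  shape$kernel_phi %||% 0,
                                  deriv_theta = th, m1 = m)
  smax <- max(shape$sigma1, shape$sigma2)
  g <- seq(-3 * smax, 3 * smax, length.out = 15L)
  xg <- cbind(rep(g, times = length(g)), rep(g, each = length(g)))
  target_vals <- general_directional_value(xg, spec_at(target_theta))
  recon <- rep(0, nrow(xg))
  for (k in seq_len(M)) {
    recon <- recon + p[k] * general_directional_value(xg, spec_at(basis_angles[k]))
  }
  residual <- max(abs(recon - target_vals)) / max(abs(target_vals))
  steering_solution(as.numeric(p), basis_angles, residual, cond)
}

#' Match a receptive-field response across an affine transformation
#'
#' Solves for coefficients \eqn{q_k} such that the source-domain
#' response matches a linear combination of warped-domain responses:
#' \eqn{L_\theta(x) \approx \sum_k q_k\, L'_{\varphi'_k}(\mathcal{A}x)},
#' where the warped-domain responses were computed at the transformed
#' covariance \eqn{\Sigma' = \mathcal{A}\Sigma\mathcal{A}^T} over at
#' least \eqn{m+1} distinct angles. The fit is least squares over the
#' interior pixels; for first order the closed-form route (gradient
#' transformation plus steering) gives the same coefficients.
#'
#' @param source_response A `sampled_field`: the order-`m` response in
#'   the source domain.
#' @param target_responses List of `sampled_field`s: responses in the
#'   warped domain at the basis angles.
#' @param map The `affine_map` relating the domains.
#' @param margin Physical width of the excluded boundary band.
#' @param condition_limit Degenerate-basis threshold on the (normalized)
#'   design matrix.
#' @param basis_angles Optional angles, recorded in the solution.
#' @return A `steering_solution`; `residual` is the interior relative
#'   RMS mismatch.
#' @export
match_responses <- function(source_response, target_responses, map,
                            margin, basis_angles = NULL,
                            condition_limit = 1e6) {
  stopifnot(inherits(source_response, "sampled_field"))
  m <- as_affine_map(map)
  x <- interior_positions(source_response, margin, map = m)
  if (nrow(x) < length(target_responses) + 1L) {
    stop("configuration error: interior region too small", call. = FALSE)
  }
  xp <- x %*% t(unclass(m))
  y <- field_sample(source_response, x)
  X <- vapply(target_responses, field_sample, numeric(nrow(xp)), x = xp)
  norms <- sqrt(colSums(X^2))
  if (any(norms == 0)) stop("degenerate basis: zero target response", call. = FALSE)
  cond <- condition_2norm(X / rep(norms, each = nrow(X)))
  if (!is.finite(cond) || cond > condition_limit) {
    stop(sprintf(
      "degenerate basis: response design condition estimate %.3g exceeds %.3g",
      cond, condition_limit), call. = FALSE)
  }
  q <- qr.solve(X, y)
  resid <- sqrt(mean((X %*% q - y)^2)) / max(sqrt(mean(y^2)), 1e-300)
  steering_solution(as.numeric(q), basis_angles, resid, cond)
}
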