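#' Scalar descriptors of a 2-D affine map
#'
#' Computes the four elementary descriptors of a 2x2 matrix
#' \deqn{T = (a_{11}+a_{22})/2, \quad A = (a_{21}-a_{12})/2,}
#' \deqn{C = (a_{11}-a_{22})/2, \quad S = (a_{12}+a_{21})/2,}
#' together with the derived radii \eqn{P = \sqrt{T^2+A^2}} and
#' \eqn{Q = \sqrt{C^2+S^2}}. (T, A) describe the similarity part of the
#' map (uniform scaling + rotation) and (C, S) the deviation from it;
#' they drive the closed-form factorization in [affine_decompose()].
#'
#' @param map An `affine_map` or 2x2 matrix.
#' @return An object of class `affine_descriptors`: a list with fields
#'   `t`, `a`, `c`, `s`, `p`, `q`.
#' @examples
#' compute_descriptors(affine_map(2, 0, 0, 1)) # t = 1.5, c = 0.5
#' @export
compute_descriptors <- function(map) {
  m <- as_affine_map(map)
  t_ <- (m[1, 1] + m[2, 2]) / 2
  a_ <- (m[2, 1] - m[1, 2]) / 2
  c_ <- (m[1, 1] - m[2, 2]) / 2
  s_ <- (m[1, 2] + m[2, 1]) / 2
  structure(
    list(t = t_, a = a_, c = c_, s = s_,
         p = sqrt(t_^2 + a_^2), q = sqrt(c_^2 + s_^2)),
    class = "affine_descriptors")
}

#' @export
print.affine_descriptors <- function(x, ...) {
  cat("<affine_descriptors>\n")
  cat(sprintf("  T = %.6g  A = %.6g  C = %.6g  S = %.6g\n", x$t, x$a, x$c, x$s))
  cat(sprintf("  P = %.6g  Q = %.6g\n", x$p, x$q))
  invisible(x)
}

#' Canonical factors of a 2-D affine map
#'
#' Container for the rotation-stretch-rotation parameterization
#' \eqn{(\rho_1, \rho_2, \varphi, \psi)}: singular values
#' \eqn{\rho_1 \ge \rho_2 > 0}, total rotation angle \eqn{\varphi}, and
#' \eqn{\psi} equal to twice the orientation of the symmetry axis of the
#' non-isotropic stretch. Derived quantities: uniform `scale`
#' \eqn{\sqrt{\rho_1\rho_2}}, `stretch` \eqn{\rho_1/\rho_2}, and the
#' equivalent SVD angles \eqn{\alpha = (\psi+\varphi)/2},
#' \eqn{\beta = (\psi-\varphi)/2}.
#'
#' @param rho1,rho2 Singular values, `rho1 >= rho2 > 0` (unless
#'   `valid = FALSE` from a permissive decomposition).
#' @param phi Total rotation angle, wrapped into `(-pi, pi]`.
#' @param psi Twice the symmetry-axis orientation, wrapped into
#'   `(-pi, pi]`.
#' @param similarity Logical; `TRUE` when the map is (numerically) a
#'   similarity transform, in which case `psi` is undefined and fixed at
#'   0 by convention.
#' @param valid Logical; `FALSE` marks factors outside the applicability
#'   regime (`rho2 <= 0`), only produced by
#'   `affine_decompose(..., permissive = TRUE)`.
#' @return An object of class `affine_factors`.
#' @export
affine_factors <- function(rho1, rho2, phi = 0, psi = 0,
                           similarity = FALSE, valid = TRUE) {
  stopifnot_finite(c(rho1, rho2, phi, psi), "affine factors")
  if (valid && !(rho1 >= rho2 && rho2 > 0)) {
    stop("invalid factors: singular values must satisfy rho1 >= rho2 > 0",
         call. = FALSE)
  }
  phi <- wrap_pi(phi)
  psi <- wrap_pi(psi)
  structure(
    list(rho1 = rho1, rho2 = rho2, phi = phi, psi = psi,
         scale = sqrt(rho1 * max(rho2, 0)),
         stretch = rho1 / rho2,
         alpha = (psi + phi) / 2, beta = (psi - phi) / 2,
         similarity = isTRUE(similarity), valid = isTRUE(valid)),
    class = "affine_factors")
}

#' @export
print.affine_factors <- function(x, ...) {
  cat("<affine_factors>\n")
  cat(sprintf("  rho1 = %.6g  rho2 = %.6g  (scale %.6g, stretch %.6g)\n",
              x$rho1, x$rho2, x$scale, x$stretch))
  cat(sprintf("  phi = %.6g rad  psi = %.6g rad (symmetry axis %.6g rad)%s\n",
              x$phi, x$psi, x$psi / 2,
              if (x$similarity) "  [similarity: psi by convention]" else ""))
  if (!x$valid) cat("  [outside applicability: rho2 <= 0]\n")
  invisible(x)
}

#' Closed-form canonical decomposition of a 2-D affine map
#'
#' Factorizes a 2x2 affine transformation matrix, assumed reasonably
#' close to a scalar multiple of the identity, into
#' \deqn{\mathcal{A} = \mathcal{R}_{\psi/2}\,\mathcal{R}_{\varphi/2}\,
#'   \mathrm{diag}(\rho_1,\rho_2)\,\mathcal{R}_{\varphi/2}\,
#'   \mathcal{R}_{-\psi/2},}
#' a modified singular value decomposition whose outer factors are
#' guaranteed rotation matrices. In closed form:
#' \eqn{\rho_1 = P + Q}, \eqn{\rho_2 = P - Q},
#' \eqn{\varphi = \mathrm{atan2}(A, T)},
#' \eqn{\psi = \mathrm{atan2}(S, C)}, with the descriptors of
#' [compute_descriptors()]. The two-argument arctangent (rather than the
#' ratio forms \eqn{\tan\varphi = A/T}, \eqn{\tan\psi = S/C}) resolves
#' the quadrant when \eqn{T \le 0} or \eqn{C \le 0}.
#'
#' For similarity transforms (\eqn{Q = 0}) the symmetry-axis angle is
#' undefined; the convention \eqn{\psi = 0} is used and flagged, with a
#' relative threshold `q_tol` guarding against numerical noise
#' producing an arbitrary angle.
#'
#' @param map An `affine_map` or 2x2 matrix with finite entries.
#' @param permissive If `TRUE`, maps with \eqn{\rho_2 \le 0} (outside
#'   the applicability regime) return factors flagged `valid = FALSE`
#'   instead of an error.
#' @param verify If `TRUE`, check that [affine_compose()] reconstructs
#'   the input to within `tol` (relative to the max-norm of the input).
#' @param tol Reconstruction tolerance used when `verify = TRUE`.
#' @param q_tol Relative threshold: `q < q_tol * p` triggers the
#'   similarity convention `psi = 0`.
#' @return An `affine_factors` object.
#' @examples
#' affine_decompose(affine_map(1.5, 0.5, 0.5, 1.5)) # rho = (2, 1), psi = pi/2
#' affine_decompose(rot2_matrix(pi / 3))            # phi = pi/3
#' @seealso [affine_compose()], [svd_form()]
#' @export
affine_decompose <- function(map, permissive = FALSE, verify = FALSE,
                             tol = 1e-10, q_tol = 1e-14) {
  m <- as_affine_map(map)
  d <- compute_descriptors(m)
  if (d$p == 0) {
    stop("degenerate map: P = 0 (e.g. a pure skew-symmetric map); the ",
         "factorization requires P > 0", call. = FALSE)
  }
  rho1 <- d$p + d$q
  rho2 <- d$p - d$q
  if (rho2 <= 0 && !permissive) {
    stop(sprintf(
      "outside applicability: smaller singular value rho2 = P - Q = %.6g <= 0; %s",
      rho2, "the factorization applies to maps near a positive scalar multiple of the identity"),
      call. = FALSE)
  }
  phi <- atan2(d$a, d$t)
  similarity <- d$q < q_tol * d$p
  psi <- if (similarity) 0 else atan2(d$s, d$c)
  f <- affine_factors(rho1, rho2, phi, psi,
                      similarity = similarity, valid = rho2 > 0)
  if (verify && f$valid) {
    err <- max(abs(unclass(affine_compose(f)) - unclass(m)))
    if (err > tol * max(abs(m), 1)) {
      stop(sprintf("reconstruction check failed: max error %.3g exceeds tol %.3g",
                   err, tol), call. = FALSE)
    }
  }
  f
}

#' Compose a 2-D affine map from canonical factors
#'
#' Inverse of [affine_decompose()]: forms
#' \eqn{\mathcal{R}_{\psi/2}\,\mathcal{R}_{\varphi/2}\,
#' \mathrm{diag}(\rho_1,\rho_2)\,\mathcal{R}_{\varphi/2}\,
#' \mathcal{R}_{-\psi/2}}.
#'
#' @param factors An `affine_factors` object, or a list/vector with
#'   elements `rho1`, `rho2`, `phi`, `psi`.
#' @return An `affine_map`.
#' @examples
#' affine_compose(affine_factors(2, 1, phi = 0, psi = pi / 2))
#' @export
affine_compose <- function(factors) {
  f <- as_affine_factors(factors)
  if (!(f$rho1 >= f$rho2 && f$rho2 > 0)) {
    stop("invalid factors: singular values must satisfy rho1 >= rho2 > 0",
         call. = FALSE)
  }
  m <- rot2(f$psi / 2) %*% rot2(f$phi / 2) %*% diag(c(f$rho1, f$rho2)) %*%
    rot2(f$phi / 2) %*% rot2(-f$psi / 2)
  affine_map(m)
}

as_affine_factors <- function(x) {
  if (inherits(x, "affine_factors")) return(x)
  x <- as.list(x)
  affine_factors(x$rho1, x$rho2, x$phi %||% 0, x$psi %||% 0)
}

#' Standard SVD form of canonical affine factors
#'
#' Converts the \eqn{(\rho_1,\rho_2,\varphi,\psi)} parameterization into
#' the equivalent singular value decomposition
#' \eqn{\mathcal{A} = \mathcal{R}_\alpha\,\mathrm{diag}(\rho_1,\rho_2)\,
#' \mathcal{R}_\beta^T} with \eqn{\alpha = (\psi+\varphi)/2} and
#' \eqn{\beta = (\psi-\varphi)/2}.
#'
#' @param factors An `affine_factors` object.
#' @return A list with `alpha`, `singular_values = c(rho1, rho2)`,
#'   `beta`.
#' @export
svd_form <- function(factors) {
  f <- as_affine_factors(factors)
  list(alpha = f$alpha,
       singular_values = c(f$rho1, f$rho2),
       beta = f$beta)
}

## Factor IO ----------------------------------------------------------------

#' Write canonical affine factors to JSON or one-row CSV
#'
#' The CSV variant uses the header
#' `rho1,rho2,phi,psi,scale,stretch`.
#'
#' @param factors An `affine_factors` object.
#' @param path Output path.
#' @param format `"json"` or `"csv"`; guessed from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_affine_factors <- function(factors, path, format = NULL) {
  f <- as_affine_factors(factors)
  format <- format %||% (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  fields <- f[c("rho1", "rho2", "phi", "psi", "scale", "stretch")]
  if (format == "json") {
    jsonlite::write_json(
      c(fields, list(alpha = f$alpha, beta = f$beta,
                     similarity = f$similarity, valid = f$valid)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(as.data.frame(fields), path, sep = ",",
                row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
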