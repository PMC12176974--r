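#' Affine map of a monocular locally linearized perspective projection
#'
#' First-order (linearized) mapping from the tangent plane of a smooth
#' surface patch to the tangent plane of a spherical camera, for a patch
#' at distance \eqn{\Lambda} viewed at slant angle \eqn{\nu} (angle
#' between the surface normal and the viewing direction):
#' \deqn{\mathcal{A}_{\mathrm{mono}} =
#'   \frac{1}{\Lambda}\,\mathrm{diag}(1, \cos\nu).}
#' The second coordinate axis is aligned with the tilt direction (the
#' image projection of the surface normal), so foreshortening compresses
#' `x2` by \eqn{\cos\nu}.
#'
#' @param distance Viewing distance \eqn{\Lambda > 0} (length units).
#' @param slant Slant angle \eqn{\nu} in radians, in `[0, pi/2)`.
#' @return An `affine_map`.
#' @examples
#' monocular_map(1, pi / 3) # diag(1, 0.5)
#' @export
monocular_map <- function(distance, slant) {
  stopifnot_finite(c(distance, slant), "viewing geometry")
  if (distance <= 0) stop("invalid geometry: distance must be positive", call. = FALSE)
  if (slant < 0 || slant >= pi / 2) {
    stop("grazing view: slant must lie in [0, pi/2) so that cos(slant) > 0",
         call. = FALSE)
  }
  affine_map(diag(c(1, cos(slant))) / distance)
}

#' Affine map of a binocular disparity gradient
#'
#' Locally linearized left-to-right mapping between the two image
#' domains of a symmetric (cyclopean) binocular observer fixating a
#' smooth surface point:
#' \deqn{\mathcal{A}_{\mathrm{bino}} =
#'   \frac{\cos(\gamma-\mu)}{\cos(\gamma+\mu)}
#'   \begin{pmatrix}
#'     \frac{\cos\mu + Z_X\sin\mu}{\cos\mu - Z_X\sin\mu} &
#'     \frac{Z_Y\sin 2\mu}{\cos\mu - Z_X\sin\mu} \\ 0 & 1
#'   \end{pmatrix},}
#' where \eqn{2\mu} is the vergence angle between the two viewing
#' directions, \eqn{\gamma} the gaze angle from the frontal direction to
#' the fixation point, and \eqn{(Z_X, Z_Y)} the depth gradient in world
#' coordinates aligned with the image axes. The lower-left entry is a
#' structural zero. The inverse (right-to-left) map is obtained by
#' matrix inversion.
#'
#' @param half_vergence Half-vergence angle \eqn{\mu} in radians.
#' @param gaze Gaze angle \eqn{\gamma} in radians.
#' @param depth_gradient Numeric length-2 vector \eqn{(Z_X, Z_Y)}.
#' @return An `affine_map`.
#' @examples
#' binocular_map(pi / 4, 0, c(1 / 3, 0)) # diag(2, 1)
#' @export
binocular_map <- function(half_vergence, gaze, depth_gradient = c(0, 0)) {
  stopifnot_finite(c(half_vergence, gaze, depth_gradient), "viewing geometry")
  mu <- half_vergence; g <- gaze
  zx <- depth_gradient[1]; zy <- depth_gradient[2]
  den1 <- cos(g + mu)
  if (abs(den1) < .Machine$double.eps * 4) {
    stop("invalid geometry: cos(gaze + half_vergence) vanishes", call. = FALSE)
  }
  den2 <- cos(mu) - zx * sin(mu)
  if (abs(den2) < .Machine$double.eps * 4) {
    stop("invalid geometry: cos(mu) - Z_X sin(mu) vanishes", call. = FALSE)
  }
  pre <- cos(g - mu) / den1
  affine_map(pre * matrix(c(
    (cos(mu) + zx * sin(mu)) / den2, 0,
    zy * sin(2 * mu) / den2, 1), 2L, 2L))
}

#' Deformation field of an affine map
#'
#' Displacements \eqn{\Delta x = (\mathcal{A} - \mathcal{I})x} of grid
#' positions under an affine map, for visualization of the image
#' deformation induced by viewing geometry.
#'
#' @param map An `affine_map`.
#' @param grid An n x 2 matrix of positions (defaults to
#'   [square_grid()]).
#' @return An object of class `deformation_field`: list with `grid` and
#'   `vectors` (both n x 2 matrices).
#' @export
deformation_field <- function(map, grid = square_grid()) {
  m <- as_affine_map(map)
  grid <- as.matrix(grid)
  if (nrow(grid) == 0L) stop("grid must be non-empty", call. = FALSE)
  if (ncol(grid) != 2L) stop("grid must have two columns", call. = FALSE)
  vectors <- grid %*% t(unclass(m)) - grid
  structure(list(grid = grid, vectors = vectors), class = "deformation_field")
}

#' Square lattice of evaluation positions
#'
#' @param n Number of samples per side.
#' @param half Half side length; the lattice covers `[-half, half]^2`.
#' @return An `n^2` x 2 matrix of positions.
#' @export
square_grid <- function(n = 11L, half = 1) {
  v <- seq(-half, half, length.out = n)
  as.matrix(expand.grid(x1 = v, x2 = v))
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> %d positions, max |dx| = %.4g\n",
              nrow(x$grid), max(sqrt(rowSums(x$vectors^2)))))
  invisible(x)
}

#' Export a deformation field as CSV
#'
#' Columns `x1, x2, dx1, dx2`.
#'
#' @param field A `deformation_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deformation_csv <- function(field, path) {
  df <- data.frame(x1 = field$grid[, 1], x2 = field$grid[, 2],
                   dx1 = field$vectors[, 1], dx2 = field$vectors[, 2])
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quiver plot of a deformation field
#'
#' Renders unit-length direction arrows with displacement magnitude
#' colour-coded (blue = small, yellow = large), written to a PNG file.
#'
#' @param field A `deformation_field`.
#' @param path Output PNG path.
#' @param arrow_scale Length of the drawn unit arrows, in grid units.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
plot_deformation <- function(field, path, arrow_scale = NULL,
                             width = 480, height = 480) {
  g <- field$grid; v <- field$vectors
  mag <- sqrt(rowSums(v^2))
  spanx <- diff(range(g[, 1]))
  arrow_scale <- arrow_scale %||% (0.6 * spanx / max(1, sqrt(nrow(g)) - 1))
  dir <- v / pmax(mag, .Machine$double.eps)
  cols <- grDevices::hcl.colors(64, "viridis")
  ci <- 1L + as.integer(63 * (mag - min(mag)) / max(max(mag) - min(mag), 1e-300))
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(g, type = "n", asp = 1, xlab = "x1", ylab = "x2")
  keep <- mag > 1e-12
  if (any(keep)) {
    suppressWarnings(arrows(
      g[keep, 1], g[keep, 2],
      g[keep, 1] + arrow_scale * dir[keep, 1],
      g[keep, 2] + arrow_scale * dir[keep, 2],
      length = 0.05, col = cols[ci[keep]]))
  }
  invisible(path)
}
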