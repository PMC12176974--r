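#' Sampled scalar field on a regular grid
#'
#' Container for discretized kernels, images, and filter responses. The
#' value matrix is indexed `values[i1, i2]` with `i1` along the `x1`
#' axis and `i2` along `x2`. Pixel centres sit at continuous coordinates
#' \eqn{x_k = \mathrm{origin}_k + (i_k - (n_k+1)/2)\,\mathrm{spacing}},
#' i.e. the grid is centred on `origin` (for even `n` the centre falls
#' between pixels). The centred convention makes the grid invariant
#' under exact 90-degree rotations, which the warping and covariance
#' verification code exploits.
#'
#' @param values Numeric matrix of samples.
#' @param spacing Grid spacing (length per sample), positive.
#' @param origin Length-2 physical position of the grid centre.
#' @return An object of class `sampled_field`.
#' @export
sampled_field <- function(values, spacing = 1, origin = c(0, 0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("field values must be finite", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("spacing must be a positive scalar", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "sampled_field")
}

#' @export
print.sampled_field <- function(x, ...) {
  cat(sprintf("<sampled_field> %d x %d, spacing %.4g, origin (%.3g, %.3g), range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$spacing, x$origin[1], x$origin[2],
              min(x$values), max(x$values)))
  invisible(x)
}

# physical coordinates of the pixel centres along each axis
field_axes <- function(field) {
  n1 <- nrow(field$values); n2 <- ncol(field$values)
  list(x1 = field$origin[1] + (seq_len(n1) - (n1 + 1) / 2) * field$spacing,
       x2 = field$origin[2] + (seq_len(n2) - (n2 + 1) / 2) * field$spacing)
}

# half side lengths (physical) from centre to outermost pixel centre
field_half_extent <- function(field) {
  c((nrow(field$values) - 1) / 2, (ncol(field$values) - 1) / 2) * field$spacing
}

## Interpolation ------------------------------------------------------------

# Cubic convolution (Catmull-Rom, a = -1/2) kernel; interpolating, so
# evaluation at grid points is exact.
cubic_kernel <- function(s) {
  s <- abs(s)
  w <- numeric(length(s))
  i1 <- s <= 1
  w[i1] <- ((1.5 * s[i1] - 2.5) * s[i1]) * s[i1] + 1
  i2 <- s > 1 & s < 2
  w[i2] <- ((-0.5 * s[i2] + 2.5) * s[i2] - 4) * s[i2] + 2
  w
}

# reflect an integer index (possibly out of range) into 1..n
# (whole-sample symmetric reflection about the boundary pixels)
reflect_index <- function(k, n) {
  if (n == 1L) return(rep(1L, length(k)))
  p <- (k - 1L) %% (2L * (n - 1L))
  ifelse(p < n, p + 1L, 2L * n - 1L - p)
}

# bicubic interpolation of matrix V at continuous (1-based) matrix
# indices (u, v); reflective boundary handling
interp_bicubic <- function(V, u, v) {
  n1 <- nrow(V); n2 <- ncol(V)
  i0 <- floor(u); j0 <- floor(v)
  fu <- u - i0; fv <- v - j0
  out <- numeric(length(u))
  wu <- cbind(cubic_kernel(fu + 1), cubic_kernel(fu),
              cubic_kernel(1 - fu), cubic_kernel(2 - fu))
  wv <- cbind(cubic_kernel(fv + 1), cubic_kernel(fv),
              cubic_kernel(1 - fv), cubic_kernel(2 - fv))
  for (a in 0:3) {
    ii <- reflect_index(as.integer(i0) - 1L + a, n1)
    for (b in 0:3) {
      jj <- reflect_index(as.integer(j0) - 1L + b, n2)
      out <- out + wu[, a + 1] * wv[, b + 1] * V[cbind(ii, jj)]
    }
  }
  out
}

#' Sample a field at arbitrary physical positions
#'
#' Separable cubic (Catmull-Rom) interpolation with reflective
#' boundaries; exact at pixel centres.
#'
#' @param field A `sampled_field`.
#' @param x An n x 2 matrix (or length-2 vector) of physical positions.
#' @return Numeric vector of interpolated values.
#' @export
field_sample <- function(field, x) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  n1 <- nrow(field$values); n2 <- ncol(field$values)
  u <- (x[, 1] - field$origin[1]) / field$spacing + (n1 + 1) / 2
  v <- (x[, 2] - field$origin[2]) / field$spacing + (n2 + 1) / 2
  interp_bicubic(field$values, u, v)
}

#' Warp an image by an affine map
#'
#' Produces the transformed image \eqn{f'(x') = f(\mathcal{A}^{-1}x')}
#' on the same grid geometry as the input: each target pixel takes the
#' interpolated source value at the back-projected position. Exact (a
#' pure pixel permutation) for 90-degree rotations on the centred square
#' grid.
#'
#' @param image A `sampled_field`.
#' @param map An invertible `affine_map`.
#' @return A `sampled_field` with the same geometry.
#' @export
warp_image <- function(image, map) {
  m <- as_affine_map(map)
  if (abs(det(m)) < .Machine$double.eps * 4) {
    stop("invalid map: matrix is singular", call. = FALSE)
  }
  inv <- solve(unclass(m))
  n1 <- nrow(image$values); n2 <- ncol(image$values)
  ax <- field_axes(image)
  xp <- cbind(rep(ax$x1, times = n2), rep(ax$x2, each = n1)) # target positions
  xs <- xp %*% t(inv)
  vals <- field_sample(image, xs)
  sampled_field(matrix(vals, n1, n2), spacing = image$spacing,
                origin = image$origin)
}

## Plain-text IO ------------------------------------------------------------

#' Read and write sampled fields as plain text with a JSON sidecar
#'
#' The value matrix is written as whitespace-separated text (rows of the
#' matrix, i.e. the `x1` index); grid geometry (spacing, origin, dims)
#' and optional metadata go into `<path>.json`.
#'
#' @param field A `sampled_field`.
#' @param path Path of the text array file.
#' @param meta Optional named list of extra metadata for the sidecar.
#' @return `read_field()` returns a `sampled_field`; `write_field()`
#'   returns `path` invisibly.
#' @export
write_field <- function(field, path, meta = list()) {
  write.table(field$values, path, row.names = FALSE, col.names = FALSE)
  side <- c(list(spacing = field$spacing, origin = field$origin,
                 dim = dim(field$values)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  values <- as.matrix(read.table(path, header = FALSE))
  dimnames(values) <- NULL
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    sampled_field(values, spacing = side$spacing, origin = side$origin)
  } else {
    sampled_field(values)
  }
}
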