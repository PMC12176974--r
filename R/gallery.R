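#' Parameter sweeps of receptive-field specifications
#'
#' Convenience constructors for the four one-parameter families of
#' affine Gaussian derivative receptive fields: overall size
#' \eqn{\bar\sigma} (at fixed eccentricity), kernel orientation
#' \eqn{\varphi}, eccentricity \eqn{\epsilon = \sigma_2/\sigma_1} (at
#' fixed \eqn{\sigma_2}), and the direction \eqn{\theta} of the
#' directional derivative relative to the kernel eigendirections.
#' Logarithmic spacing is used for the scale-type sweeps.
#'
#' @param n Number of panels.
#' @param from,to Sweep endpoints.
#' @param eccentricity Fixed \eqn{\sigma_2/\sigma_1} for the size sweep.
#' @param sigma1,sigma2 Fixed eigen-scales where applicable.
#' @param phi Fixed kernel orientation where applicable.
#' @param order Derivative order along the differentiation direction.
#' @return A list of `rf_spec` objects.
#' @name rf_sweeps
NULL

#' @rdname rf_sweeps
#' @export
rf_size_sweep <- function(n = 6L, from = 1 / sqrt(2), to = 4,
                          eccentricity = 1, phi = 0, order = 1L) {
  sb <- exp(seq(log(from), log(to), length.out = n))
  lapply(sb, function(s) {
    # size_bar = sqrt(s1 s2), eccentricity = s2 / s1
    s1 <- s / sqrt(eccentricity)
    rf_spec(s1, s1 * eccentricity, phi, m1 = order)
  })
}

#' @rdname rf_sweeps
#' @export
rf_orientation_sweep <- function(n = 6L, sigma1 = 2, sigma2 = 4, order = 1L) {
  phis <- seq(0, pi, length.out = n + 1L)[seq_len(n)]
  lapply(phis, function(p) rf_spec(sigma1, sigma2, wrap_half_pi(p), m1 = order))
}

#' @rdname rf_sweeps
#' @export
rf_eccentricity_sweep <- function(n = 6L, from = 1, to = 1 / 4,
                                  sigma2 = 2, phi = pi / 2, order = 1L) {
  eps <- exp(seq(log(from), log(to), length.out = n))
  # sigma2 kept constant; eccentricity = sigma2 / sigma1
  lapply(eps, function(e) rf_spec(sigma2 / e, sigma2, wrap_half_pi(phi),
                                  m1 = order))
}

#' @rdname rf_sweeps
#' @export
rf_deriv_orientation_sweep <- function(n = 6L, sigma1 = 4, sigma2 = 1,
                                       phi = 0, order = 1L) {
  thetas <- seq(0, pi, length.out = n + 1L)[seq_len(n)]
  lapply(thetas, function(th) rf_spec(sigma1, sigma2, phi,
                                      deriv_theta = th, m1 = order))
}

#' Render a gallery of receptive-field kernels
#'
#' Writes one PNG with one panel per specification, sampled on a common
#' grid, in sweep order with a deterministic layout.
#'
#' @param specs Non-empty list of `rf_spec` objects.
#' @param path Output PNG path.
#' @param extent Common half side length of the panels (defaults to
#'   covering 4 standard deviations of the largest kernel).
#' @param spacing Sampling step.
#' @param panel_px Pixel size of each panel.
#' @return `path`, invisibly; attribute `"fields"` on the return value
#'   holds the sampled kernels.
#' @export
render_gallery <- function(specs, path, extent = NULL, spacing = 0.25,
                           panel_px = 160) {
  if (length(specs) == 0L) stop("sweep must be non-empty", call. = FALSE)
  smax <- max(vapply(specs, function(s) max(s$sigma1, s$sigma2), numeric(1)))
  extent <- extent %||% (4 * smax)
  fields <- lapply(specs, sample_kernel, spacing = spacing, extent = extent,
                   on_small = "none")
  ncolp <- length(specs)
  grDevices::png(path, width = panel_px * ncolp, height = panel_px)
  on.exit(grDevices::dev.off(), add = TRUE)
  # par() settings die with the device; no restore needed
  par(mfrow = c(1, ncolp), mar = c(0.5, 0.5, 0.5, 0.5))
  for (f in fields) {
    z <- f$values
    lim <- max(abs(z))
    image(z, zlim = c(-lim, lim), col = gray.colors(64), axes = FALSE,
          useRaster = TRUE, asp = 1)
    box()
  }
  invisible(structure(path, fields = fields))
}
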