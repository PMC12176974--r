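#' Synthetic stimulus specification
#'
#' Deterministic generators for the test imagery used throughout the
#' package: sine gratings, band-limited Gaussian noise, impulses and
#' constants, optionally as drifting multi-frame videos. All generators
#' are pure functions of the spec (seed included).
#'
#' @param kind One of `"grating"`, `"band_limited_noise"`, `"impulse"`,
#'   `"constant"`.
#' @param size Image side length in pixels (>= 16).
#' @param wavelength Grating wavelength in pixels (>= 4, anti-aliasing
#'   bound).
#' @param orientation Grating orientation, radians (0 = variation along
#'   `x1`).
#' @param phase Grating phase, radians.
#' @param cutoff Shortest retained wavelength of the noise, pixels
#'   (>= 4).
#' @param seed Integer RNG seed for the noise (restores the global RNG
#'   state afterwards).
#' @param frames Number of frames (>= 1); `1` yields a single field.
#' @param drift_velocity Length-2 drift in pixels per frame.
#' @param value Constant value for `kind = "constant"`.
#' @return A `stimulus_spec` object.
#' @export
stimulus_spec <- function(kind = c("grating", "band_limited_noise",
                                   "impulse", "constant"),
                          size = 64L, wavelength = 8, orientation = 0,
                          phase = 0, cutoff = 8, seed = 1L, frames = 1L,
                          drift_velocity = c(0, 0), value = 1) {
  kind <- match.arg(kind)
  if (size < 16L) stop("parameter error: size must be >= 16", call. = FALSE)
  if (kind == "grating" && wavelength < 4) {
    stop("parameter error: wavelength < 4 px is aliasing-prone", call. = FALSE)
  }
  if (kind == "band_limited_noise" && cutoff < 4) {
    stop("parameter error: cutoff < 4 px is aliasing-prone", call. = FALSE)
  }
  if (frames < 1L) stop("parameter error: frames must be >= 1", call. = FALSE)
  structure(list(kind = kind, size = as.integer(size), wavelength = wavelength,
                 orientation = orientation, phase = phase, cutoff = cutoff,
                 seed = as.integer(seed), frames = as.integer(frames),
                 drift_velocity = as.numeric(drift_velocity), value = value),
            class = "stimulus_spec")
}

with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# zero-mean, unit-sd periodic band-limited Gaussian noise; wavelengths
# shorter than `cutoff` pixels are removed in the Fourier domain
band_limited_noise_matrix <- function(n, cutoff, seed) {
  w <- with_local_seed(seed, matrix(rnorm(n * n), n, n))
  f <- c(0:(n %/% 2), -((n - ceiling(n / 2) - 1):1)) / n # cycles per px
  f <- f[seq_len(n)]
  fr <- sqrt(outer(f^2, f^2, `+`))
  mask <- fr <= 1 / cutoff
  mask[1, 1] <- FALSE # remove DC -> zero mean
  v <- Re(fft(fft(w) * mask, inverse = TRUE)) / (n * n)
  v / sd(as.vector(v))
}

# periodic (FFT phase-ramp) shift of a matrix by a continuous offset
fft_shift_matrix <- function(V, d1, d2) {
  n1 <- nrow(V); n2 <- ncol(V)
  f1 <- c(0:(n1 %/% 2), -((n1 - ceiling(n1 / 2) - 1):1))[seq_len(n1)] / n1
  f2 <- c(0:(n2 %/% 2), -((n2 - ceiling(n2 / 2) - 1):1))[seq_len(n2)] / n2
  ph <- exp(-2i * pi * (outer(f1 * d1, f2 * d2, `+`)))
  Re(fft(fft(V) * ph, inverse = TRUE)) / (n1 * n2)
}

grating_matrix <- function(size, wavelength, orientation, phase, shift = c(0, 0)) {
  ctr <- (size + 1) / 2
  ax <- (seq_len(size) - ctr)
  u <- c(cos(orientation), sin(orientation))
  arg <- outer((ax - shift[1]) * u[1], (ax - shift[2]) * u[2], `+`)
  sin(2 * pi * arg / wavelength + phase)
}

#' Generate a synthetic stimulus
#'
#' @param spec A `stimulus_spec`.
#' @return A `sampled_field` (single frame) or a `sampled_video` (a
#'   list of `sampled_field` frames) when `frames > 1`.
#' @examples
#' img <- make_stimulus(stimulus_spec("band_limited_noise", size = 32, seed = 7))
#' @export
make_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- spec$size
  one_frame <- function(k) {
    shift <- spec$drift_velocity * (k - 1)
    vals <- switch(spec$kind,
      grating = grating_matrix(n, spec$wavelength, spec$orientation,
                               spec$phase, shift),
      band_limited_noise = {
        base <- band_limited_noise_matrix(n, spec$cutoff, spec$seed)
        if (all(shift == 0)) base else fft_shift_matrix(base, shift[1], shift[2])
      },
      impulse = {
        v <- matrix(0, n, n)
        ctr <- as.integer((n + 1) %/% 2)
        v[ctr, ctr] <- 1
        v
      },
      constant = matrix(spec$value, n, n))
    sampled_field(vals, spacing = 1, origin = c(0, 0))
  }
  if (spec$frames == 1L) return(one_frame(1L))
  structure(lapply(seq_len(spec$frames), one_frame), class = "sampled_video")
}

#' @export
print.sampled_video <- function(x, ...) {
  cat(sprintf("<sampled_video> %d frames of %d x %d\n",
              length(x), nrow(x[[1]]$values), ncol(x[[1]]$values)))
  invisible(x)
}
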