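# Shared numerical helpers.
#
# Conventions used throughout the package:
#  * lengths in micrometres, spatial frequencies in cycles per micrometre;
#  * 2D arrays are indexed [row, col] = [y, x];
#  * FFTs use the standard unshifted ordering (zero frequency first) with
#    stats::fft; inverse transforms divide by the number of elements;
#  * a forward-travelling plane wave at frequency f acquires the phase
#    exp(+2i*pi*z*sqrt((n0/lambda)^2 - |f|^2)) over a distance z.

#' Sample frequencies for an FFT grid
#'
#' @param n number of samples (must be a positive integer).
#' @param spacing sample spacing (micrometres).
#' @return numeric vector of length `n` with frequencies in cycles per
#'   micrometre, in standard FFT order (0, positive, negative).
#' @export
fft_freq <- function(n, spacing = 1) {
  stopifnot(n >= 1, spacing > 0)
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * spacing)
}

#' Centre the zero-frequency component of an FFT array
#'
#' @param x matrix (or vector) in standard FFT ordering.
#' @param inverse undo the shift instead.
#' @return array of the same shape.
#' @export
fft_shift <- function(x, inverse = FALSE) {
  shift1 <- function(v, n) {
    s <- if (inverse) ceiling(n / 2) else floor(n / 2)
    if (n == 1) return(v)
    c(v[(n - s + 1):n], v[1:(n - s)])
  }
  if (is.null(dim(x))) return(x[shift1(seq_along(x), length(x))])
  d <- dim(x)
  idx <- lapply(d, function(n) shift1(seq_len(n), n))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# 2D FFT pair (unnormalized forward, normalized inverse).
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# 3D FFT pair.
fftn <- function(x) stats::fft(x)
ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Centred spatial coordinates of a sampled grid
#'
#' Coordinate vector whose origin falls on index `n %/% 2 + 1`, matching
#' the convention used by all fields and volumes in the package.
#'
#' @param n number of samples.
#' @param spacing sample spacing (micrometres).
#' @return numeric vector of length `n`.
#' @export
grid_coords <- function(n, spacing) (seq_len(n) - (n %/% 2 + 1)) * spacing

# Squared-radius grid |f|^2 on an FFT frequency grid [ny, nx].
freq_radius2 <- function(ny, nx, dy, dx) {
  fy <- fft_freq(ny, dy)
  fx <- fft_freq(nx, dx)
  outer(fy^2, fx^2, `+`)
}

# Axial frequency fz(f) = sqrt((n0/lambda)^2 - |f|^2) with the positive
# (forward / decaying-evanescent) branch; returns complex when evanescent.
axial_frequency <- function(f2, n0, wavelength) {
  fm2 <- (n0 / wavelength)^2
  sqrt(as.complex(fm2 - f2))
}

# Raised-cosine disc window on an FFT frequency grid: 1 inside
# radius*(1-width), tapering to 0 at radius.
raised_cosine_disc <- function(ny, nx, dy, dx, radius, width = 0.1,
                               center = c(0, 0)) {
  fy <- fft_freq(ny, dy) - center[1]
  fx <- fft_freq(nx, dx) - center[2]
  r <- sqrt(outer(fy^2, fx^2, `+`))
  w <- matrix(0, ny, nx)
  inner <- radius * (1 - width)
  w[r <= inner] <- 1
  sel <- r > inner & r < radius
  w[sel] <- 0.5 * (1 + cos(pi * (r[sel] - inner) / (radius - inner)))
  w
}

# Internal RNG helper: run expr with a local seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Relative RMS difference between two complex arrays.
rel_rms <- function(a, b) {
  sqrt(mean(Mod(a - b)^2)) / sqrt(mean(Mod(b)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a band-limited field by Fourier cropping or padding
#'
#' Changes the pixel pitch of a [complex_field()] by keeping (or
#' zero-padding) the central block of its Fourier transform; exact for
#' fields band-limited below the coarser Nyquist frequency.
#'
#' @param field a [complex_field()].
#' @param ny,nx target grid dimensions (even).
#' @return a [complex_field()] with pitch `old_pitch * old_n / new_n`.
#' @export
resample_field <- function(field, ny, nx) {
  v <- field$values
  ny0 <- nrow(v); nx0 <- ncol(v)
  if (ny0 == ny && nx0 == nx) return(field)
  F0 <- fft_shift(fft2(v))
  out <- matrix(0i, ny, nx)
  ry <- min(ny, ny0); rx <- min(nx, nx0)
  src_y <- (ny0 %/% 2 + 1) + seq_len(ry) - (ry %/% 2 + 1)
  src_x <- (nx0 %/% 2 + 1) + seq_len(rx) - (rx %/% 2 + 1)
  dst_y <- (ny %/% 2 + 1) + seq_len(ry) - (ry %/% 2 + 1)
  dst_x <- (nx %/% 2 + 1) + seq_len(rx) - (rx %/% 2 + 1)
  out[dst_y, dst_x] <- F0[src_y, src_x]
  out <- ifft2(fft_shift(out, inverse = TRUE)) * (ny * nx) / (ny0 * nx0)
  complex_field(out, field$pixel_pitch * ny0 / ny, field$wavelength,
                field$background_index, field$z_position)
}
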