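# Off-axis holography: sideband demodulation, reference estimation, and
# weighted least-squares phase unwrapping.

#' Off-axis hologram
#'
#' @param intensity non-negative real matrix of recorded intensity.
#' @param reference_frequency length-2 tilt frequency (fy, fx) of the
#'   reference beam (cycles per micrometre).
#' @param pixel_pitch sample-referred pixel pitch (micrometres).
#' @param wavelength vacuum wavelength (micrometres).
#' @param background_index background refractive index n0.
#' @return an object of class `hologram`.
#' @export
hologram <- function(intensity, reference_frequency, pixel_pitch, wavelength,
                     background_index) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0)) stop("hologram intensity must be non-negative")
  structure(list(intensity = intensity,
                 reference_frequency = as.numeric(reference_frequency),
                 pixel_pitch = pixel_pitch, wavelength = wavelength,
                 background_index = background_index),
            class = "hologram")
}

#' Synthesize an off-axis hologram from a complex field
#'
#' Forms `|E + A exp(2i pi f_ref . r)|^2`.
#'
#' @param field a [complex_field()] (the signal field at the detector).
#' @param reference_frequency length-2 reference tilt (cycles/um).
#' @param reference_amplitude amplitude of the reference beam.
#' @return a [hologram()].
#' @export
synthesize_hologram <- function(field, reference_frequency,
                                reference_amplitude = 1) {
  v <- field$values
  y <- grid_coords(nrow(v), field$pixel_pitch)
  x <- grid_coords(ncol(v), field$pixel_pitch)
  ref <- reference_amplitude *
    exp(2i * pi * outer(reference_frequency[1] * y, reference_frequency[2] * x, `+`))
  hologram(Mod(v + ref)^2, reference_frequency, field$pixel_pitch,
           field$wavelength, field$background_index)
}

#' Demodulate an off-axis hologram
#'
#' Shifts the sideband at the reference frequency to baseband (an exact
#' modulation in real space), applies a raised-cosine disc of radius
#' `band_radius`, and returns the complex signal field relative to a unit
#' reference.
#'
#' @param holo a [hologram()].
#' @param band_radius radius of the extracted signal band (cycles/um); must
#'   be smaller than the reference frequency magnitude so the sideband
#'   separates from the DC term.
#' @param edge_width relative raised-cosine edge width of the band window.
#' @return a [complex_field()].
#' @export
demodulate_hologram <- function(holo, band_radius, edge_width = 0.1) {
  fref <- sqrt(sum(holo$reference_frequency^2))
  if (band_radius >= fref) {
    # overlap fraction between the sideband disc and its DC-centred mirror
    d <- fref; b <- band_radius
    ov <- if (d >= 2 * b) 0 else {
      2 * b^2 * acos(d / (2 * b)) - d / 2 * sqrt(pmax(4 * b^2 - d^2, 0))
    }
    stop(sprintf(
      "sideband (radius %.3g/um) overlaps the DC band: |f_ref| = %.3g/um, overlap fraction %.2f",
      band_radius, fref, ov / (pi * b^2)))
  }
  v <- holo$intensity
  ny <- nrow(v); nx <- ncol(v)
  y <- grid_coords(ny, holo$pixel_pitch)
  x <- grid_coords(nx, holo$pixel_pitch)
  # the E * conj(R) sideband sits at -f_ref; modulating by +f_ref moves it
  # to baseband and recovers E (not its conjugate)
  demod <- v * exp(2i * pi * outer(holo$reference_frequency[1] * y,
                                   holo$reference_frequency[2] * x, `+`))
  win <- raised_cosine_disc(ny, nx, holo$pixel_pitch, holo$pixel_pitch,
                            band_radius, width = edge_width)
  out <- ifft2(fft2(demod) * win)
  complex_field(out, holo$pixel_pitch, holo$wavelength, holo$background_index, 0)
}

#' Estimate the incident (reference) field from a time series
#'
#' Returns the complex time average of the frames. For dilute dynamic
#' samples the refractive-index inhomogeneities average out over time, so
#' the mean approximates the sample-free illumination. The residual
#' temporal variance is attached as attribute `residual_variance`; a very
#' small value suggests a static object contaminating the background and
#' is flagged with a message.
#'
#' @param fields list of [complex_field()] (time-ordered; the estimate is
#'   permutation-invariant).
#' @return a [complex_field()] with attribute `residual_variance`.
#' @export
estimate_reference <- function(fields) {
  if (length(fields) == 0) stop("no frames supplied")
  if (length(fields) == 1) {
    warning("single frame supplied; returning it as the reference")
    return(fields[[1]])
  }
  acc <- fields[[1]]$values
  for (i in 2:length(fields)) acc <- acc + fields[[i]]$values
  avg <- acc / length(fields)
  v <- mean(vapply(fields, function(f) mean(Mod(f$values - avg)^2), numeric(1)))
  rel <- v / mean(Mod(avg)^2)
  if (rel < 1e-6)
    message("estimate_reference: residual temporal variance ~ 0; background may contain sample")
  out <- complex_field(avg, fields[[1]]$pixel_pitch, fields[[1]]$wavelength,
                       fields[[1]]$background_index, fields[[1]]$z_position)
  attr(out, "residual_variance") <- rel
  out
}

# --- DCT helpers -------------------------------------------------------------

# Orthogonal-free DCT-II along columns via FFT of the even extension.
.dct_cols <- function(m) {
  n <- nrow(m)
  ext <- rbind(m, m[n:1, , drop = FALSE])
  Y <- stats::mvfft(ext)
  w <- exp(-1i * pi * (0:(n - 1)) / (2 * n))
  Re(Y[1:n, , drop = FALSE] * w) / 2
}

# Inverse of .dct_cols (DCT-III along columns):
# m_j = (2/n) Re sum_k c'_k exp(i pi k (2j+1)/(2n)), c'_0 = c_0 / 2.
.idct_cols <- function(m) {
  n <- nrow(m)
  v <- m * exp(1i * pi * (0:(n - 1)) / (2 * n))
  v[1, ] <- v[1, ] / 2
  spec <- rbind(v, matrix(0i, n, ncol(m)))
  ext <- Re(stats::mvfft(spec, inverse = TRUE))
  ext[1:n, , drop = FALSE] * (2 / n)
}

dct2d <- function(m) t(.dct_cols(t(.dct_cols(m))))
idct2d <- function(m) t(.idct_cols(t(.idct_cols(m))))

# Solve the Neumann Poisson problem laplacian(phi) = rho via DCT.
.poisson_dct <- function(rho) {
  ny <- nrow(rho); nx <- ncol(rho)
  d <- dct2d(rho)
  denom <- outer(2 * cos(pi * (0:(ny - 1)) / ny),
                 2 * cos(pi * (0:(nx - 1)) / nx), `+`) - 4
  denom[1, 1] <- 1
  d <- d / denom
  d[1, 1] <- 0
  idct2d(d)
}

.wrap_to_pi <- function(x) (x + pi) %% (2 * pi) - pi

# forward differences with zero at the far edge (Neumann)
.dx <- function(m) cbind(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE], 0)
.dy <- function(m) rbind(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE], 0)
# divergence paired with the gradient above (out-of-range terms are zero;
# the inputs' last row/column are zero by construction)
.div <- function(gy, gx) {
  dy <- rbind(gy[1, , drop = FALSE],
              gy[-1, , drop = FALSE] - gy[-nrow(gy), , drop = FALSE])
  dx <- cbind(gx[, 1, drop = FALSE],
              gx[, -1, drop = FALSE] - gx[, -ncol(gx), drop = FALSE])
  dy + dx
}

#' Weighted least-squares phase unwrapping
#'
#' Transform-based (DCT) least-squares unwrapping with Picard iteration for
#' the weights: each iteration solves an unweighted Neumann Poisson problem
#' whose right-hand side combines the weighted wrapped gradients with the
#' unweighted gradients of the current solution. The result is made
#' congruent to the input, so the output equals the input modulo 2*pi at
#' every pixel.
#'
#' @param phase wrapped phase matrix (radians).
#' @param weights non-negative weight matrix (e.g. squared field
#'   amplitude); uniform weights reduce to the classic single-solve DCT
#'   unwrapper.
#' @param tol relative-change convergence tolerance of the Picard loop.
#' @param max_iter maximum Picard iterations.
#' @return unwrapped phase matrix.
#' @export
unwrap_phase_weighted <- function(phase, weights = NULL, tol = 1e-6,
                                  max_iter = 50) {
  phase <- as.matrix(phase)
  if (is.null(weights)) weights <- matrix(1, nrow(phase), ncol(phase))
  weights <- as.matrix(weights)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (max(weights) == 0) stop("all-zero weights")
  W <- weights / max(weights)
  gy <- .wrap_to_pi(.dy(phase))
  gx <- .wrap_to_pi(.dx(phase))
  # fast path: when no wrapped gradient comes near the branch cut and the
  # values stay inside one branch, the input is already unwrapped
  if (max(abs(gy)) < pi / 2 && max(abs(gx)) < pi / 2 &&
        diff(range(phase)) < 1.8 * pi) {
    return(phase)
  }
  # edge weights: minimum of the two pixels sharing each difference
  Wy <- pmin(rbind(W[-1, , drop = FALSE], 0), rbind(W[-nrow(W), , drop = FALSE], 0))
  Wy[nrow(Wy), ] <- 0
  Wx <- pmin(cbind(W[, -1, drop = FALSE], 0), cbind(W[, -ncol(W), drop = FALSE], 0))
  Wx[, ncol(Wx)] <- 0
  uniform <- max(abs(W - W[1, 1])) < 1e-12
  phi <- .poisson_dct(.div(Wy * gy, Wx * gx))
  if (!uniform) {
    for (it in seq_len(max_iter)) {
      rhs <- .div(Wy * gy + (1 - Wy) * .dy(phi),
                  Wx * gx + (1 - Wx) * .dx(phi))
      phi_new <- .poisson_dct(rhs)
      dl <- sqrt(mean((phi_new - phi)^2)) / max(sqrt(mean(phi^2)), 1e-12)
      phi <- phi_new
      if (dl < tol) break
    }
  }
  # fix the free constant by the circular mean of the residual, then snap
  # the least-squares solution to the input so the output is congruent
  r <- phi - phase
  phi <- phi - atan2(mean(sin(r)), mean(cos(r)))
  phase + 2 * pi * round((phi - phase) / (2 * pi))
}
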