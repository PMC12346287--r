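# Weak-scattering reconstruction: Rytov fields, Ewald-sphere gridding of the
# scattering potential, and the low-resolution Rytov demultiplexing
# initializer for multiplexed acquisitions.
#
# Conventions. The scattering potential is V(r) = k0^2 (n(r)^2 - n0^2) with
# k0 = 2*pi/lambda. With fields referenced to the mid-volume plane z = 0 and
# the 2D transform Ehat(f) = integral E(rho) exp(-2i pi f.rho) d rho, the
# first-order (Born/Rytov) relation reads
#   Vhat3(F) = -4i pi fz(f) * FT2[E0 * psi](f) / c0 ,
#   F = (f - f_inc, fz(f) - fz(f_inc)),   fz(f) = sqrt((n0/lambda)^2 - |f|^2),
# where c0 is the complex amplitude of the incident plane wave and psi the
# Rytov phase: each 2D frequency of one view samples Vhat3 on a spherical
# cap through the origin (the Ewald sphere shifted by the incident wave).

# 2D FT with the spatial origin at the grid centre.
cfft2 <- function(m, pitch) {
  fft2(fft_shift(m, inverse = TRUE)) * pitch^2
}

# Inverse 3D FT (frequency grid in FFT order) returning a centred-origin
# real-space array; dfs = c(dfy, dfx, dfz).
cifft3 <- function(M, dfs) {
  fft_shift(stats::fft(M, inverse = TRUE)) * prod(dfs)
}

#' Fourier-domain scattering potential accumulator
#'
#' Holds the 3D Fourier transform of the scattering potential on an FFT
#' frequency grid matched to a target volume, together with the gridding
#' multiplicity (`fill_count`) used to average overlapping Ewald caps.
#'
#' @param ny,nx,nz target volume dimensions (y, x, z).
#' @param voxel_xy,voxel_z target voxel sizes (micrometres).
#' @param background_index background index n0.
#' @param wavelength vacuum wavelength (micrometres).
#' @param band_radius detection band radius (cycles/um); 2D frequencies
#'   beyond it are not gridded. Defaults to n0/lambda.
#' @return an object of class `scattering_potential`.
#' @export
scattering_potential <- function(ny, nx, nz, voxel_xy, voxel_z,
                                 background_index, wavelength,
                                 band_radius = background_index / wavelength) {
  structure(list(
    values = array(0i, c(ny, nx, nz)),
    fill_count = array(0L, c(ny, nx, nz)),
    dfs = c(1 / (ny * voxel_xy), 1 / (nx * voxel_xy), 1 / (nz * voxel_z)),
    ny = ny, nx = nx, nz = nz, voxel_xy = voxel_xy, voxel_z = voxel_z,
    background_index = background_index, wavelength = wavelength,
    band_radius = band_radius, dropped = 0L
  ), class = "scattering_potential")
}

#' Rytov field of a measured view
#'
#' `psi = ln|E/E0| + i unwrap(arg(E/E0))`, unwrapped with
#' [unwrap_phase_weighted()] using squared-amplitude weights. Pixels where
#' `|E0|` falls below `1e-6 * max|E0|` receive weight zero.
#'
#' @param total measured [complex_field()] (relative to unit reference).
#' @param incident incident [complex_field()] for the same view.
#' @param beam the [plane_wave()] that produced `incident`.
#' @return an object of class `rytov_field`: list with `psi` (complex
#'   matrix), `beam`, and the grid metadata of `total`.
#' @export
rytov_field <- function(total, incident, beam) {
  E0 <- incident$values
  E <- total$values
  lim <- 1e-6 * max(Mod(E0))
  bad <- Mod(E0) < lim
  ratio <- E / ifelse(bad, lim, E0)
  w <- Mod(E)^2
  w[bad] <- 0
  amp <- log(pmax(Mod(ratio), 1e-12))
  ph <- unwrap_phase_weighted(Arg(ratio), w)
  structure(list(psi = amp + 1i * ph, beam = beam,
                 pixel_pitch = total$pixel_pitch,
                 wavelength = total$wavelength,
                 background_index = total$background_index),
            class = "rytov_field")
}

#' Deposit one view onto its Ewald cap
#'
#' Maps each 2D frequency `f` of `FT2[exp(2i pi f_inc . rho) * psi]` to the
#' 3D frequency `(f - f_inc, fz(f) - fz(f_inc))` by nearest-voxel gridding,
#' accumulating values and multiplicities. Components with `|f|` beyond the
#' potential's band radius (or evanescent) are dropped and counted.
#'
#' @param psi a [rytov_field()].
#' @param pot a [scattering_potential()].
#' @return the updated [scattering_potential()].
#' @export
grid_ewald_cap <- function(psi, pot) {
  p <- psi$pixel_pitch
  n0 <- pot$background_index
  lam <- pot$wavelength
  ny <- nrow(psi$psi); nx <- ncol(psi$psi)
  # snap the incident frequency to the detector FFT grid for the deposit:
  # the lateral scattering vector f - f_inc then lands exactly on grid
  # frequencies, avoiding a per-view half-bin shift of the whole cap (a
  # phase ramp that speckles the volume); the implied angle error is below
  # half a frequency bin
  f_inc <- c(round(psi$beam$object_frequency[1] * ny * p) / (ny * p),
             round(psi$beam$object_frequency[2] * nx * p) / (nx * p))
  fm <- n0 / lam
  fz_inc <- sqrt(fm^2 - sum(f_inc^2))
  # unit-amplitude incident carrier at z = 0
  y <- grid_coords(ny, p); x <- grid_coords(nx, p)
  carrier <- exp(2i * pi * outer(f_inc[1] * y, f_inc[2] * x, `+`))
  D <- cfft2(carrier * psi$psi, p)
  fy <- fft_freq(ny, p); fx <- fft_freq(nx, p)
  f2 <- outer(fy^2, fx^2, `+`)
  keep <- which(f2 <= min(pot$band_radius, fm)^2)
  pot$dropped <- pot$dropped + (length(f2) - length(keep))
  iy <- ((keep - 1) %% ny) + 1
  ix <- ((keep - 1) %/% ny) + 1
  fyv <- fy[iy]; fxv <- fx[ix]
  fzv <- sqrt(fm^2 - f2[keep])
  vals <- -4i * pi * fzv * D[keep]
  Fy <- fyv - f_inc[1]; Fx <- fxv - f_inc[2]; Fz <- fzv - fz_inc
  ky <- round(Fy / pot$dfs[1]) %% pot$ny
  kx <- round(Fx / pot$dfs[2]) %% pot$nx
  kz <- round(Fz / pot$dfs[3])
  ok <- abs(kz) <= (pot$nz %/% 2 - 1)
  # guard against lateral aliasing when the target grid is coarser
  ok <- ok & abs(round(Fy / pot$dfs[1])) < (pot$ny %/% 2) &
    abs(round(Fx / pot$dfs[2])) < (pot$nx %/% 2)
  idx <- cbind(ky[ok] + 1, kx[ok] + 1, (kz[ok] %% pot$nz) + 1)
  pot$dropped <- pot$dropped + sum(!ok)
  # accumulate with multiplicity (duplicated voxels summed correctly)
  lin <- idx[, 1] + pot$ny * (idx[, 2] - 1) + pot$ny * pot$nx * (idx[, 3] - 1)
  add <- vals[ok]
  sums <- rowsum(cbind(Re(add), Im(add), 1), group = lin)
  tgt <- as.integer(rownames(sums))
  pot$values[tgt] <- pot$values[tgt] + sums[, 1] + 1i * sums[, 2]
  pot$fill_count[tgt] <- pot$fill_count[tgt] + as.integer(sums[, 3])
  pot
}

#' Convert a gridded scattering potential to a refractive-index volume
#'
#' Averages overlapping cap contributions by `fill_count`, inverse
#' transforms, and takes `n = sqrt(n0^2 + V / k0^2)` with the principal
#' branch `Re(n) >= 0`. Unfilled voxels (the missing cone) remain zero,
#' i.e. background.
#'
#' @param pot a [scattering_potential()].
#' @return an [ri_volume()].
#' @export
potential_to_ri <- function(pot) {
  vals <- pot$values
  filled <- pot$fill_count > 0L
  vals[filled] <- vals[filled] / pot$fill_count[filled]
  V <- cifft3(vals, pot$dfs)
  k0 <- 2 * pi / pot$wavelength
  n <- sqrt(pot$background_index^2 + V / k0^2 + 0i)  # principal branch, Re >= 0
  flip <- Re(n) < 0
  n[flip] <- -n[flip]
  ri_volume(n, pot$voxel_xy, pot$voxel_z, pot$background_index,
            pot$wavelength)
}

#' Fourier-domain scattering potential of a refractive-index volume
#'
#' Inverse of [potential_to_ri()] (up to gridding multiplicity, which is
#' set to 1 everywhere): `V = k0^2 (n^2 - n0^2)` transformed to the FFT
#' frequency grid.
#'
#' @param volume an [ri_volume()].
#' @param wavelength vacuum wavelength; defaults to the volume's.
#' @return a [scattering_potential()].
#' @export
ri_to_potential <- function(volume, wavelength = volume$wavelength) {
  d <- dim(volume$index)
  pot <- scattering_potential(d[1], d[2], d[3], volume$voxel_xy,
                              volume$voxel_z, volume$background_index,
                              wavelength)
  k0 <- 2 * pi / wavelength
  V <- k0^2 * (volume$index^2 - volume$background_index^2)
  # centred-origin forward 3D FT (inverse of cifft3)
  pot$values <- stats::fft(fft_shift(V, inverse = TRUE)) / prod(d) / prod(pot$dfs)
  pot$fill_count <- array(1L, d)
  pot
}

# Voronoi + disc demultiplexing radius for one frame's beams (cycles/um).
demultiplex_radius <- function(beams, band_radius) {
  if (length(beams) <= 1) return(band_radius)
  fr <- t(vapply(beams, function(b) b$object_frequency, numeric(2)))
  dmin <- min(stats::dist(fr))
  min(dmin / 2, band_radius)
}

#' Low-resolution Rytov demultiplexing initializer
#'
#' Splits each multiplexed view's Fourier plane into the regions closest to
#' each constituent beam's carrier (additionally capped by a disc of radius
#' half the minimum inter-carrier distance so regions stay isotropic),
#' treats each region as a low-resolution single-beam acquisition, computes
#' its Rytov phase, grids all Ewald caps with multiplicity averaging, and
#' converts the potential to a refractive index with the physical
#' constraints `Re(n) >= n0`, `Im(n) >= 0`.
#'
#' @param fields list of measured [complex_field()], one per frame
#'   (relative to unit reference, referenced to z = 0).
#' @param beams_per_frame list of lists of [plane_wave()] matching `fields`.
#' @param shape list with `ny`, `nx`, `nz`, `voxel_xy`, `voxel_z` of the
#'   target volume.
#' @param band_radius detection band radius (cycles/um); defaults to the
#'   full medium band n0/lambda.
#' @param apply_constraints apply the physical projections (default TRUE).
#' @return an [ri_volume()].
#' @export
demultiplex_rytov_initialize <- function(fields, beams_per_frame, shape,
                                         band_radius = NULL,
                                         apply_constraints = TRUE) {
  stopifnot(length(fields) == length(beams_per_frame))
  f1 <- fields[[1]]
  n0 <- f1$background_index
  lam <- f1$wavelength
  band_radius <- band_radius %||% (n0 / lam)
  pot <- scattering_potential(shape$ny, shape$nx, shape$nz, shape$voxel_xy,
                              shape$voxel_z, n0, lam, band_radius)
  for (fr in seq_along(fields)) {
    fld <- fields[[fr]]
    beams <- beams_per_frame[[fr]]
    ny <- nrow(fld$values); nx <- ncol(fld$values)
    p <- fld$pixel_pitch
    fy <- fft_freq(ny, p); fx <- fft_freq(nx, p)
    carriers <- t(vapply(beams, function(b) b$object_frequency, numeric(2)))
    if (length(beams) > 1) {
      dmin <- min(stats::dist(carriers))
      if (dmin < 2 * max(1 / (ny * p), 1 / (nx * p)))
        stop(sprintf("frame %d: beam carriers closer than 2 frequency bins; partition is degenerate", fr))
    }
    r_cap <- demultiplex_radius(beams, band_radius)
    # subtract the known unscattered carriers before splitting the Fourier
    # plane: off-grid carriers leak across the whole DFT plane at a level
    # comparable to weak scattered signals, and each beam's carrier is
    # restored analytically after extraction
    inc_all <- incident_field(beams, ny, nx, p, lam, n0)$values
    Fhat <- fft2(fld$values - inc_all)
    band <- outer(fy^2, fx^2, `+`) <= band_radius^2
    # squared distance of every FFT bin to every carrier
    d2 <- array(0, c(ny, nx, length(beams)))
    for (b in seq_along(beams)) {
      d2[, , b] <- outer((fy - carriers[b, 1])^2, (fx - carriers[b, 2])^2, `+`)
    }
    nearest <- apply(d2, c(1, 2), which.min)
    for (b in seq_along(beams)) {
      # Voronoi cell around this beam's carrier, kept isotropic by the
      # disc cap when several beams share the frame; a single beam keeps
      # the whole detection band (classical Rytov)
      region <- if (length(beams) == 1) band else {
        band & (nearest == b) & (d2[, , b] <= r_cap^2)
      }
      inc <- plane_wave_field(beams[[b]], ny, nx, p, lam, n0)
      Eb <- ifft2(Fhat * region) + inc$values
      Eb_field <- complex_field(Eb, p, lam, n0, 0)
      psi <- rytov_field(Eb_field, inc, beams[[b]])
      pot <- grid_ewald_cap(psi, pot)
    }
  }
  vol <- potential_to_ri(pot)
  if (apply_constraints) {
    vol$index <- pmax(Re(vol$index), n0) + 1i * pmax(Im(vol$index), 0)
  }
  vol
}
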