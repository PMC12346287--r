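# Scalar wave propagation: angular spectrum, multislice beam propagation
# (BPM), and the split-step non-paraxial scheme (SSNP).
#
# The SSNP evolves the pair (E, dE/dz) through the volume. Free space is
# handled exactly per Fourier component by the 2x2 propagator
#   [ cos(kz dz)          sin(kz dz)/kz ]
#   [ -kz sin(kz dz)      cos(kz dz)    ]
# with kz = 2*pi*sqrt((n0/lambda)^2 - |f|^2), and each slice adds a
# scattering kick dE'/dz contribution  E' <- E' - k0^2 (n^2 - n0^2) dz E.
# Unlike the paraxial BPM with its 1/cos(theta) obliquity factor, the SSNP
# is valid for superpositions of plane waves at different angles, which is
# what multiplexed illumination produces.

#' Propagation configuration
#'
#' @param padding_factor lateral grid enlargement factor used during
#'   propagation to suppress wrap-around (>= 1).
#' @param pupil_na detection NA applied to model outputs (NA values above
#'   the background index are clipped); `NULL` to skip.
#' @param model forward model: `"bpm"`, `"bpm_obliquity"`, or `"ssnp"`.
#' @param boundary `"periodic"` or `"padded"` (zero-padded with edge
#'   apodization of the incident field).
#' @param evanescent_cutoff fraction of the medium frequency n0/lambda
#'   beyond which components are suppressed during multislice propagation
#'   (the homogeneous 2x2 propagator is hyperbolic there).
#' @return an object of class `propagation_config`.
#' @export
propagation_config <- function(padding_factor = 1, pupil_na = NULL,
                               model = c("ssnp", "bpm", "bpm_obliquity"),
                               boundary = c("periodic", "padded"),
                               evanescent_cutoff = 0.98) {
  model <- match.arg(model)
  boundary <- match.arg(boundary)
  if (padding_factor < 1) stop("padding_factor must be >= 1")
  structure(list(padding_factor = padding_factor, pupil_na = pupil_na,
                 model = model, boundary = boundary,
                 evanescent_cutoff = evanescent_cutoff),
            class = "propagation_config")
}

# Angular-spectrum transfer kernel for distance d on an FFT grid.
# Evanescent components decay for either sign of d.
as_kernel <- function(ny, nx, dy, dx, n0, wavelength, d) {
  f2 <- freq_radius2(ny, nx, dy, dx)
  fz <- axial_frequency(f2, n0, wavelength)
  exp(2i * pi * d * Re(fz)) * exp(-2 * pi * abs(d) * Im(fz))
}

#' Propagate a field through homogeneous medium
#'
#' Multiplies each plane-wave component at frequency `f` by
#' `exp(2i*pi*distance*sqrt((n0/lambda)^2 - |f|^2))`; evanescent components
#' (`|f| > n0/lambda`) decay for either propagation direction.
#'
#' @param field a [complex_field()].
#' @param distance propagation distance (micrometres; may be negative).
#' @return a [complex_field()] at `z_position + distance`.
#' @export
angular_spectrum_propagate <- function(field, distance) {
  stopifnot(is.finite(distance))
  v <- field$values
  ker <- as_kernel(nrow(v), ncol(v), field$pixel_pitch, field$pixel_pitch,
                   field$background_index, field$wavelength, distance)
  out <- ifft2(fft2(v) * ker)
  complex_field(out, field$pixel_pitch, field$wavelength,
                field$background_index, field$z_position + distance)
}

#' Apply a hard detection pupil
#'
#' Zeroes Fourier components with `|f| > na / lambda`. Idempotent.
#'
#' @param field a [complex_field()].
#' @param na detection numerical aperture (must not exceed n0).
#' @return a [complex_field()].
#' @export
apply_detection_pupil <- function(field, na) {
  if (na > field$background_index)
    stop("detection NA cannot exceed the background index")
  v <- field$values
  f2 <- freq_radius2(nrow(v), ncol(v), field$pixel_pitch, field$pixel_pitch)
  mask <- f2 <= (na / field$wavelength)^2
  out <- ifft2(fft2(v) * mask)
  complex_field(out, field$pixel_pitch, field$wavelength,
                field$background_index, field$z_position)
}

# --- internal padded-grid machinery -----------------------------------------

# Precompute grid quantities shared by the multislice models.
.propagation_grid <- function(ny, nx, dy, dx, n0, wavelength, dz, cfg) {
  pf <- cfg$padding_factor
  nyp <- if (cfg$boundary == "padded" || pf > 1) 2 * ceiling(ny * pf / 2) else ny
  nxp <- if (cfg$boundary == "padded" || pf > 1) 2 * ceiling(nx * pf / 2) else nx
  f2 <- freq_radius2(nyp, nxp, dy, dx)
  fzc <- axial_frequency(f2, n0, wavelength)
  mask <- f2 <= (cfg$evanescent_cutoff * n0 / wavelength)^2
  # SSNP stability: the kicked two-component recursion is parametrically
  # unstable where the per-slice axial phase 2*pi*fz*dz crosses a multiple
  # of pi, so the retained band must sit inside one stability window.
  fm <- n0 / wavelength
  m_win <- floor(2 * fm * dz)
  mask_ssnp <- mask
  if (m_win >= 1) {
    mask_ssnp <- mask_ssnp & (Re(fzc) > 1.02 * m_win / (2 * dz))
  }
  kz <- 2 * pi * Re(fzc)
  kz[!mask] <- 1  # avoid 0/0; these components are masked anyway
  list(ny = ny, nx = nx, nyp = nyp, nxp = nxp, dy = dy, dx = dx, dz = dz,
       n0 = n0, wavelength = wavelength, k0 = 2 * pi / wavelength,
       f2 = f2, fz = Re(fzc), kz = kz, mask = mask, mask_ssnp = mask_ssnp)
}

# Zero-centred embedding of an ny x nx matrix into the padded grid.
.pad_embed <- function(m, g, fill = 0) {
  if (g$nyp == g$ny && g$nxp == g$nx) return(m)
  out <- matrix(fill + 0i, g$nyp, g$nxp)
  r0 <- (g$nyp - g$ny) %/% 2
  c0 <- (g$nxp - g$nx) %/% 2
  out[r0 + seq_len(g$ny), c0 + seq_len(g$nx)] <- m
  out
}

.pad_crop <- function(m, g) {
  if (g$nyp == g$ny && g$nxp == g$nx) return(m)
  r0 <- (g$nyp - g$ny) %/% 2
  c0 <- (g$nxp - g$nx) %/% 2
  m[r0 + seq_len(g$ny), c0 + seq_len(g$nx), drop = FALSE]
}

# Replicate-edge embedding with a Tukey roll-off to suppress the discontinuity
# at the pad boundary (used for incident fields).
.pad_field <- function(m, g) {
  if (g$nyp == g$ny && g$nxp == g$nx) return(m)
  iy <- pmin(pmax(seq_len(g$nyp) - (g$nyp - g$ny) %/% 2, 1), g$ny)
  ix <- pmin(pmax(seq_len(g$nxp) - (g$nxp - g$nx) %/% 2, 1), g$nx)
  out <- m[iy, ix, drop = FALSE]
  tuk <- function(n) {
    a <- 0.2
    t <- seq(0, 1, length.out = n)
    w <- rep(1, n)
    sel <- t < a / 2
    w[sel] <- 0.5 * (1 + cos(2 * pi / a * (t[sel] - a / 2)))
    sel <- t > 1 - a / 2
    w[sel] <- 0.5 * (1 + cos(2 * pi / a * (t[sel] - 1 + a / 2)))
    w
  }
  out * (tuk(g$nyp) %o% tuk(g$nxp))
}

# Free-space 2x2 SSNP step arrays for a distance d (stability-masked band).
.ssnp_step_arrays <- function(g, d) {
  C <- cos(g$kz * d) * g$mask_ssnp
  S <- sin(g$kz * d) / g$kz * g$mask_ssnp
  K <- -g$kz * sin(g$kz * d) * g$mask_ssnp
  list(C = C, S = S, K = K)
}

# Apply the 2x2 step (or its conjugate transpose) to the Fourier state.
.ssnp_apply <- function(st, A, adjoint = FALSE) {
  if (!adjoint) {
    e <- A$C * st$e + A$S * st$p
    p <- A$K * st$e + A$C * st$p
  } else {
    e <- Conj(A$C) * st$e + Conj(A$K) * st$p
    p <- Conj(A$S) * st$e + Conj(A$C) * st$p
  }
  list(e = e, p = p)
}

# Run the SSNP forward model. `nvol` is the [ny, nx, nz] complex RI array,
# `inc` the incident field at the z = 0 reference plane (mid-volume).
# Returns the exit field refocused to z = 0 (padded grid) and, when
# `keep_fields`, the per-slice real-space fields needed by the adjoint pass.
.ssnp_forward <- function(nvol, inc, g, cfg, keep_fields = FALSE) {
  nz <- dim(nvol)[3]
  zc <- grid_coords(nz, g$dz)
  z_entry <- zc[1] - g$dz / 2
  z_exit <- zc[nz] + g$dz / 2
  half <- .ssnp_step_arrays(g, g$dz / 2)
  ehat <- fft2(.pad_field(inc, g)) *
    as_kernel(g$nyp, g$nxp, g$dy, g$dx, g$n0, g$wavelength, z_entry)
  st <- list(e = ehat * g$mask_ssnp, p = 1i * g$kz * ehat * g$mask_ssnp)
  c_kick <- -g$k0^2 * g$dz
  fields <- if (keep_fields) vector("list", nz) else NULL
  for (j in seq_len(nz)) {
    st <- .ssnp_apply(st, half)
    Ej <- ifft2(st$e)
    if (keep_fields) fields[[j]] <- Ej
    q <- .pad_embed(nvol[, , j]^2 - g$n0^2, g)
    st$p <- st$p + fft2(c_kick * q * Ej)
    st <- .ssnp_apply(st, half)
  }
  ghat <- 0.5 * (st$e - 1i * st$p / g$kz) * g$mask_ssnp
  ghat <- ghat * as_kernel(g$nyp, g$nxp, g$dy, g$dx, g$n0, g$wavelength, -z_exit)
  if (!is.null(cfg$pupil_na)) {
    ghat <- ghat * (g$f2 <= (min(cfg$pupil_na, g$n0) / g$wavelength)^2)
  }
  list(exit_hat = ghat, exit = ifft2(ghat), fields = fields,
       z_entry = z_entry, z_exit = z_exit)
}

# Adjoint/backpropagation pass for the SSNP. `gE` is dL/d(conj(E_out)) on the
# padded grid (real space); returns dL/d(conj n) as an [ny, nx, nz] array.
.ssnp_adjoint <- function(nvol, fwd, gE, g, cfg) {
  nz <- dim(nvol)[3]
  half <- .ssnp_step_arrays(g, g$dz / 2)
  npix <- g$nyp * g$nxp
  ghat <- fft2(gE) / npix
  ghat <- ghat * Conj(as_kernel(g$nyp, g$nxp, g$dy, g$dx, g$n0, g$wavelength,
                                -fwd$z_exit))
  if (!is.null(cfg$pupil_na)) {
    ghat <- ghat * (g$f2 <= (min(cfg$pupil_na, g$n0) / g$wavelength)^2)
  }
  st <- list(e = 0.5 * ghat * g$mask_ssnp,
             p = Conj(-1i / g$kz) * 0.5 * ghat * g$mask_ssnp)
  c_kick <- -g$k0^2 * g$dz
  grad <- array(0i, dim(nvol))
  for (j in rev(seq_len(nz))) {
    st <- .ssnp_apply(st, half, adjoint = TRUE)
    # adjoint of the scattering kick
    p_real <- ifft2(st$p)
    q <- .pad_embed(nvol[, , j]^2 - g$n0^2, g)
    gq <- Conj(c_kick * fwd$fields[[j]]) * p_real * npix
    npad <- .pad_embed(nvol[, , j], g, fill = g$n0)
    grad[, , j] <- .pad_crop(Conj(2 * npad) * gq, g)
    st$e <- st$e + fft2(Conj(c_kick * q) * p_real)
    st <- .ssnp_apply(st, half, adjoint = TRUE)
  }
  grad
}

# BPM forward: paraxial phase screens with symmetric free-space half steps.
# `cos_obl` is 1 for plain BPM or the axial direction cosine of the single
# dominant beam for the obliquity-corrected variant.
.bpm_forward <- function(nvol, inc, g, cfg, cos_obl = 1, keep_fields = FALSE) {
  nz <- dim(nvol)[3]
  zc <- grid_coords(nz, g$dz)
  z_entry <- zc[1] - g$dz / 2
  z_exit <- zc[nz] + g$dz / 2
  ker_half <- as_kernel(g$nyp, g$nxp, g$dy, g$dx, g$n0, g$wavelength, g$dz / 2) * g$mask
  ehat <- fft2(.pad_field(inc, g)) *
    as_kernel(g$nyp, g$nxp, g$dy, g$dx, g$n0, g$wavelength, z_entry) * g$mask
  fields <- if (keep_fields) vector("list", nz) else NULL
  screens <- if (keep_fields) vector("list", nz) else NULL
  for (j in seq_len(nz)) {
    ehat <- ehat * ker_half
    Ej <- ifft2(ehat)
    if (keep_fields) fields[[j]] <- Ej
    S <- exp(1i * g$k0 * (.pad_embed(nvol[, , j], g, fill = g$n0) - g$n0) *
               g$dz / cos_obl)
    if (keep_fields) screens[[j]] <- S
    ehat <- fft2(S * Ej) * ker_half
  }
  ghat <- ehat * as_kernel(g$nyp, g$nxp, g$dy, g$dx, g$n0, g$wavelength, -z_exit)
  if (!is.null(cfg$pupil_na)) {
    ghat <- ghat * (g$f2 <= (min(cfg$pupil_na, g$n0) / g$wavelength)^2)
  }
  list(exit_hat = ghat, exit = ifft2(ghat), fields = fields, screens = screens,
       z_entry = z_entry, z_exit = z_exit, cos_obl = cos_obl)
}

.bpm_adjoint <- function(nvol, fwd, gE, g, cfg) {
  nz <- dim(nvol)[3]
  ker_half <- as_kernel(g$nyp, g$nxp, g$dy, g$dx, g$n0, g$wavelength, g$dz / 2) * g$mask
  npix <- g$nyp * g$nxp
  ghat <- fft2(gE) / npix
  ghat <- ghat * Conj(as_kernel(g$nyp, g$nxp, g$dy, g$dx, g$n0, g$wavelength,
                                -fwd$z_exit))
  if (!is.null(cfg$pupil_na)) {
    ghat <- ghat * (g$f2 <= (min(cfg$pupil_na, g$n0) / g$wavelength)^2)
  }
  grad <- array(0i, dim(nvol))
  scale <- 1i * g$k0 * g$dz / fwd$cos_obl
  for (j in rev(seq_len(nz))) {
    ghat <- ghat * Conj(ker_half)
    gv <- ifft2(ghat) * npix  # adjoint state at the screen output, real space
    grad[, , j] <- .pad_crop(Conj(scale * fwd$screens[[j]] * fwd$fields[[j]]) * gv, g)
    ghat <- fft2(Conj(fwd$screens[[j]]) * gv) / npix
    ghat <- ghat * Conj(ker_half)
  }
  grad
}

# --- public multislice wrappers ---------------------------------------------

.check_volume_field <- function(volume, incident) {
  d <- dim(volume$index)
  if (!all(dim(incident$values) == d[1:2]))
    stop("incident field grid must match the volume's lateral grid")
  if (abs(volume$voxel_xy - incident$pixel_pitch) > 1e-9)
    stop("incident field pixel pitch must equal the volume's lateral voxel size")
}

#' Multislice beam propagation through a refractive-index volume
#'
#' Plain BPM applies phase screens `exp(i k0 (n - n0) dz)` between exact
#' homogeneous half steps. The obliquity-corrected variant divides the
#' screen phase by the axial direction cosine of the (single) incident
#' beam; it refuses multi-beam illumination because superposed beams at
#' different angles do not share a common obliquity factor.
#'
#' @param volume an [ri_volume()].
#' @param incident a [complex_field()] giving the illumination at the z = 0
#'   (mid-volume) reference plane.
#' @param cfg a [propagation_config()].
#' @param beam the illuminating [plane_wave()]; required by
#'   `model = "bpm_obliquity"` (a list of more than one is an error).
#' @return a [complex_field()]: the exit field refocused to z = 0.
#' @export
bpm_propagate <- function(volume, incident, cfg = propagation_config(model = "bpm"),
                          beam = NULL) {
  .check_volume_field(volume, incident)
  cos_obl <- 1
  if (cfg$model == "bpm_obliquity") {
    if (is.null(beam)) stop("bpm_obliquity requires the illuminating beam")
    if (is.list(beam) && !inherits(beam, "plane_wave")) {
      if (length(beam) > 1)
        stop(paste("obliquity-corrected BPM is undefined for multiplexed",
                   "illumination: beams do not share a common obliquity factor"))
      beam <- beam[[1]]
    }
    fm <- volume$background_index / incident$wavelength
    fz <- sqrt(fm^2 - sum(beam$object_frequency^2))
    cos_obl <- fz / fm
  }
  g <- .propagation_grid(dim(volume$index)[1], dim(volume$index)[2],
                         volume$voxel_xy, volume$voxel_xy,
                         volume$background_index, incident$wavelength,
                         volume$voxel_z, cfg)
  fwd <- .bpm_forward(volume$index, incident$values, g, cfg, cos_obl = cos_obl)
  complex_field(.pad_crop(fwd$exit, g), incident$pixel_pitch,
                incident$wavelength, volume$background_index, 0)
}

#' Split-step non-paraxial propagation through a refractive-index volume
#'
#' Evolves the field and its axial derivative slice by slice; the incident
#' field is complemented with its derivative under the forward-only
#' assumption, and the final state is projected onto the forward-travelling
#' component. Valid for multiplexed (multi-angle) illumination.
#'
#' @inheritParams bpm_propagate
#' @return a [complex_field()]: the exit field refocused to z = 0.
#' @export
ssnp_propagate <- function(volume, incident, cfg = propagation_config()) {
  .check_volume_field(volume, incident)
  dn_max <- max(abs(Re(volume$index) - volume$background_index))
  if (dn_max > 0 && volume$voxel_z > incident$wavelength / (4 * dn_max)) {
    message(sprintf(
      "ssnp_propagate: slice thickness %.3g um exceeds lambda/(4 dn_max) = %.3g um; accuracy may degrade",
      volume$voxel_z, incident$wavelength / (4 * dn_max)))
  }
  # the normal-incidence phase per slice must stay away from the
  # split-step resonance at multiples of pi (see .propagation_grid)
  frac <- (2 * volume$background_index / incident$wavelength * volume$voxel_z) %% 1
  if (min(frac, 1 - frac) < 0.05) {
    message(sprintf(
      "ssnp_propagate: slice thickness %.3g um puts the axial phase near a split-step resonance; accuracy degrades (choose dz away from multiples of lambda/(2 n0))",
      volume$voxel_z))
  }
  g <- .propagation_grid(dim(volume$index)[1], dim(volume$index)[2],
                         volume$voxel_xy, volume$voxel_xy,
                         volume$background_index, incident$wavelength,
                         volume$voxel_z, cfg)
  fwd <- .ssnp_forward(volume$index, incident$values, g, cfg)
  complex_field(.pad_crop(fwd$exit, g), incident$pixel_pitch,
                incident$wavelength, volume$background_index, 0)
}
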