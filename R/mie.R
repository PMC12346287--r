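# Scalar Mie partial-wave oracle for spheres.
#
# Solves scattering of a scalar plane wave by a homogeneous sphere with
# continuity of the field and its radial derivative at the surface -- the
# scalar counterpart of the electromagnetic Mie problem, and the consistent
# independent oracle for the scalar Helmholtz forward models in this
# package. With x = k a, y = m k a (m = n_sphere / n0) the partial-wave
# coefficients are
#   c_l = [j_l'(x) j_l(y) - m j_l'(y) j_l(x)] /
#         [m j_l'(y) h_l(x) - h_l'(x) j_l(y)]
# and the total exterior field for unit incident amplitude is
#   psi = exp(i k s.r) + sum_l i^l (2l+1) c_l h_l(k r) P_l(cos theta).

# spherical bessel j_l, y_l via half-integer Bessel functions; either `l`
# or `x` may be a vector (besselJ/besselY recycle their arguments)
.sph_jl <- function(l, x) sqrt(pi / (2 * x)) * besselJ(x, l + 0.5)
.sph_yl <- function(l, x) sqrt(pi / (2 * x)) * besselY(x, l + 0.5)

#' Partial-wave scattering coefficients for a sphere
#'
#' @param radius sphere radius (micrometres).
#' @param index sphere refractive index (real).
#' @param n0 background index.
#' @param wavelength vacuum wavelength (micrometres).
#' @return list with `c_l` (complex coefficients for l = 0..n_max), `k`
#'   (medium wavenumber, rad/um), `x` (size parameter), and `n_max`
#'   (truncation order `ceil(x + 4 x^(1/3) + 2)`).
#' @export
mie_coefficients <- function(radius, index, n0, wavelength) {
  if (abs(Im(index)) > 0)
    stop("the scalar Mie oracle supports real sphere indices only")
  index <- Re(index)
  k <- 2 * pi * n0 / wavelength
  m <- index / n0
  x <- k * radius
  n_max <- ceiling(x + 4 * x^(1 / 3) + 2)
  l <- 0:n_max
  y <- m * x
  jx <- .sph_jl(l, x); jy <- .sph_jl(l, y)
  yx <- .sph_yl(l, x)
  hx <- jx + 1i * yx
  # derivatives: f_l'(x) = f_{l-1}(x) - (l+1)/x f_l(x), with f_{-1} = cos(x)/x
  jm1x <- c(cos(x) / x, jx[-length(jx)])
  jm1y <- c(cos(y) / y, jy[-length(jy)])
  hm1x <- jm1x + 1i * c(sin(x) / x, yx[-length(yx)])
  djx <- jm1x - (l + 1) / x * jx
  djy <- jm1y - (l + 1) / y * jy
  dhx <- hm1x - (l + 1) / x * hx
  c_l <- (djx * jy - m * djy * jx) / (m * djy * hx - dhx * jy)
  if (index == n0) c_l[] <- 0
  list(c_l = c_l, k = k, x = x, n_max = n_max, m = m)
}

#' Far-field scattering amplitude f(theta)
#'
#' `psi_s -> f(theta) exp(i k r) / r`, so
#' `f(theta) = (1 / (i k)) sum_l (2l+1) c_l P_l(cos theta)`.
#'
#' @param coef output of [mie_coefficients()].
#' @param theta scattering angles (radians).
#' @return complex amplitudes (micrometres).
#' @export
mie_far_field <- function(coef, theta) {
  mu <- cos(theta)
  acc <- numeric(length(mu)) + 0i
  Pm2 <- rep(1, length(mu))   # P_0
  Pm1 <- mu                   # P_1
  for (l in 0:coef$n_max) {
    P <- if (l == 0) Pm2 else if (l == 1) Pm1 else {
      Pn <- ((2 * l - 1) * mu * Pm1 - (l - 1) * Pm2) / l
      Pm2 <- Pm1; Pm1 <- Pn
      Pn
    }
    acc <- acc + (2 * l + 1) * coef$c_l[l + 1] * P
  }
  acc / (1i * coef$k)
}

#' Extinction and scattering cross-sections
#'
#' The scattering cross-section comes from the partial-wave sum
#' `(4 pi / k^2) sum (2l+1) |c_l|^2`; the extinction cross-section from the
#' optical theorem `(4 pi / k) Im f(0)`. For lossless spheres the two
#' agree, which the test-suite uses as an internal consistency oracle.
#'
#' @param coef output of [mie_coefficients()].
#' @return list with `scattering` and `extinction` (square micrometres).
#' @export
mie_cross_sections <- function(coef) {
  scat <- 4 * pi / coef$k^2 * sum((2 * (0:coef$n_max) + 1) * Mod(coef$c_l)^2)
  ext <- 4 * pi / coef$k * Im(mie_far_field(coef, 0))
  list(scattering = scat, extinction = ext)
}

# Exterior scattered field of one sphere at 3D points (rows of `pts`,
# columns y, x, z in um relative to the sphere centre), for unit-amplitude
# incidence along unit vector s_hat (y, x, z).
.mie_scattered_points <- function(coef, pts, s_hat) {
  r <- sqrt(rowSums(pts^2))
  r <- pmax(r, 1e-9)
  mu <- as.vector(pts %*% s_hat) / r
  kr <- coef$k * r
  acc <- numeric(length(r)) + 0i
  Pm2 <- rep(1, length(mu))
  Pm1 <- mu
  for (l in 0:coef$n_max) {
    P <- if (l == 0) Pm2 else if (l == 1) Pm1 else {
      Pn <- ((2 * l - 1) * mu * Pm1 - (l - 1) * Pm2) / l
      Pm2 <- Pm1; Pm1 <- Pn
      Pn
    }
    hl <- .sph_jl(l, kr) + 1i * .sph_yl(l, kr)
    acc <- acc + (1i)^l * (2 * l + 1) * coef$c_l[l + 1] * hl * P
  }
  acc
}

# Unit propagation direction (y, x, z) of a plane wave.
beam_direction <- function(beam, n0, wavelength) {
  st <- wavelength / n0 * beam$object_frequency
  sz2 <- 1 - sum(st^2)
  if (sz2 < 0) stop("beam frequency exceeds the medium frequency n0/lambda")
  c(st, sqrt(sz2))
}

#' Total field of a sphere scene under plane-wave illumination (Mie oracle)
#'
#' Evaluates the incident-plus-scattered scalar field on a lateral grid at
#' axial position `plane_z`. Multi-sphere scenes are superposed in the
#' single-scattering approximation (each sphere is illuminated by the
#' incident wave only), which is the intended validation regime; dense
#' media should go through [ssnp_propagate()] instead. The evaluation plane
#' must lie outside every sphere.
#'
#' @param scene a [sphere_scene()].
#' @param beam a [plane_wave()].
#' @param plane_z axial position of the evaluation plane (micrometres).
#' @param grid list with `ny`, `nx`, `pixel_pitch` (micrometres), and
#'   `wavelength`.
#' @return a [complex_field()] at `plane_z`.
#' @export
mie_scattered_field <- function(scene, beam, plane_z, grid) {
  ny <- grid$ny; nx <- grid$nx; dp <- grid$pixel_pitch
  lam <- grid$wavelength
  n0 <- scene$background_index
  s_hat <- beam_direction(beam, n0, lam)
  y <- grid_coords(ny, dp); x <- grid_coords(nx, dp)
  # incident plane wave referenced to z = 0 (phase as in plane_wave_field)
  fz <- n0 / lam * s_hat[3]
  ph <- 2 * pi * (outer(beam$object_frequency[1] * y,
                        beam$object_frequency[2] * x, `+`) + fz * plane_z) +
    beam$phase - 2 * pi * sum(beam$object_frequency * beam$position_offset)
  vals <- beam$amplitude * exp(1i * ph)
  pts <- cbind(rep(y, times = nx), rep(x, each = ny), plane_z)
  for (i in seq_along(scene$radii)) {
    c0 <- scene$centers[i, ]
    if (abs(plane_z - c0[3]) <= scene$radii[i])
      warning("evaluation plane intersects a sphere; exterior series is invalid there")
    if (Re(scene$indices[i]) == n0 && Im(scene$indices[i]) == 0) next
    coef <- mie_coefficients(scene$radii[i], scene$indices[i], n0, lam)
    # incident amplitude and phase at the sphere centre
    amp0 <- beam$amplitude * exp(1i * (
      2 * pi * (sum(beam$object_frequency * c0[1:2]) + fz * c0[3]) +
        beam$phase - 2 * pi * sum(beam$object_frequency * beam$position_offset)))
    rel <- cbind(pts[, 1] - c0[1], pts[, 2] - c0[2], pts[, 3] - c0[3])
    sc <- .mie_scattered_points(coef, rel, s_hat)
    vals <- vals + amp0 * matrix(sc, ny, nx)
  }
  complex_field(vals, dp, lam, n0, plane_z)
}

#' Mie-oracle field refocused to the reference plane
#'
#' Evaluates the total field just past the scene (at `plane_z`, default one
#' wavelength beyond the last sphere), numerically refocuses it to z = 0
#' through the homogeneous background, and applies the detection pupil --
#' i.e. what an aberration-free microscope focused mid-scene records.
#'
#' @inheritParams mie_scattered_field
#' @param na detection numerical aperture.
#' @param plane_z evaluation plane; defaults to just past the last sphere.
#' @return a [complex_field()] at z = 0.
#' @export
mie_microscope_field <- function(scene, beam, grid, na, plane_z = NULL) {
  if (is.null(plane_z)) {
    plane_z <- max(scene$centers[, 3] + scene$radii) + grid$wavelength
  }
  fld <- mie_scattered_field(scene, beam, plane_z, grid)
  fld <- angular_spectrum_propagate(fld, -plane_z)
  apply_detection_pupil(fld, na)
}
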