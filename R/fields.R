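# Containers for sampled complex fields and refractive-index volumes.

#' Sampled 2D complex field
#'
#' @param values complex matrix (rows = y, cols = x); dimensions should be
#'   even for FFT friendliness.
#' @param pixel_pitch lateral sample spacing (micrometres).
#' @param wavelength vacuum wavelength (micrometres).
#' @param background_index background refractive index n0.
#' @param z_position axial position of the plane (micrometres).
#' @return an object of class `complex_field`.
#' @export
complex_field <- function(values, pixel_pitch, wavelength,
                          background_index, z_position = 0) {
  values <- as.matrix(values)
  if (!is.complex(values)) values <- values + 0i
  stopifnot(pixel_pitch > 0, wavelength > 0, background_index > 0)
  if (any(dim(values) %% 2 != 0))
    stop("field grid dimensions must be even")
  structure(list(values = values, pixel_pitch = pixel_pitch,
                 wavelength = wavelength, background_index = background_index,
                 z_position = z_position),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d, pitch %.3f um, lambda %.3f um, n0 %.4f, z %.2f um\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch, x$wavelength,
              x$background_index, x$z_position))
  invisible(x)
}

# Plane-wave field exp(2i pi f.(r - r0) + i phase) on the grid of `template`
# (a complex_field used for its geometry) or explicit grid parameters.
plane_wave_field <- function(beam, ny, nx, pixel_pitch, wavelength,
                             background_index, z_position = 0) {
  y <- grid_coords(ny, pixel_pitch)
  x <- grid_coords(nx, pixel_pitch)
  # a lateral position offset of an infinite plane wave is a pure phase shift
  ph <- 2 * pi * outer(beam$object_frequency[1] * y,
                       beam$object_frequency[2] * x, `+`) +
    beam$phase - 2 * pi * sum(beam$object_frequency * beam$position_offset)
  complex_field(beam$amplitude * exp(1i * ph), pixel_pitch, wavelength,
                background_index, z_position)
}

# Superposition of an illumination frame's beams on one grid.
incident_field <- function(beams, ny, nx, pixel_pitch, wavelength,
                           background_index, z_position = 0) {
  vals <- matrix(0 + 0i, ny, nx)
  for (b in beams) {
    vals <- vals + plane_wave_field(b, ny, nx, pixel_pitch, wavelength,
                                    background_index, z_position)$values
  }
  complex_field(vals, pixel_pitch, wavelength, background_index, z_position)
}

#' 3D complex refractive-index volume
#'
#' The reconstruction target: `index[y, x, z]` holds n(r), with the
#' absorptive convention Im(n) >= 0. The volume is centred axially: slice
#' `z` sits at `(z - nz %/% 2 - 1) * voxel_z` so z = 0 falls mid-volume.
#'
#' @param index 3D complex array (y, x, z).
#' @param voxel_xy lateral voxel size (micrometres).
#' @param voxel_z axial slice thickness dz (micrometres).
#' @param background_index background index n0.
#' @param wavelength vacuum wavelength carried for convenience (micrometres).
#' @return an object of class `ri_volume`.
#' @export
ri_volume <- function(index, voxel_xy, voxel_z, background_index,
                      wavelength = NA_real_) {
  if (!is.complex(index)) index <- index + 0i
  if (length(dim(index)) != 3) stop("index must be a 3D array")
  stopifnot(voxel_xy > 0, voxel_z > 0, background_index > 0)
  if (!all(is.finite(Re(index))) || !all(is.finite(Im(index))))
    stop("index must be finite")
  structure(list(index = index, voxel_xy = voxel_xy, voxel_z = voxel_z,
                 background_index = background_index, wavelength = wavelength),
            class = "ri_volume")
}

#' @export
print.ri_volume <- function(x, ...) {
  d <- dim(x$index)
  cat(sprintf("<ri_volume> %d x %d x %d, voxel %.3f x %.3f um, n0 %.4f\n",
              d[1], d[2], d[3], x$voxel_xy, x$voxel_z, x$background_index))
  cat(sprintf("  Re(n) in [%.4f, %.4f]\n", min(Re(x$index)), max(Re(x$index))))
  invisible(x)
}

# Axial coordinates of the slice centres (z = 0 mid-volume).
volume_z <- function(vol) grid_coords(dim(vol$index)[3], vol$voxel_z)

#' Uniform background volume
#'
#' @param ny,nx,nz grid dimensions (y, x, z).
#' @inheritParams ri_volume
#' @export
background_volume <- function(ny, nx, nz, voxel_xy, voxel_z, background_index,
                              wavelength = NA_real_) {
  ri_volume(array(background_index + 0i, c(ny, nx, nz)), voxel_xy, voxel_z,
            background_index, wavelength)
}

#' Scene of spheres embedded in a background medium
#'
#' @param centers numeric matrix with one row per sphere, columns (y, x, z)
#'   in micrometres.
#' @param radii numeric vector of radii (micrometres).
#' @param indices refractive indices of the spheres (complex allowed).
#' @param background_index background index n0.
#' @return an object of class `sphere_scene`.
#' @export
sphere_scene <- function(centers, radii, indices, background_index) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  n <- nrow(centers)
  radii <- rep_len(as.numeric(radii), n)
  indices <- rep_len(indices, n)
  if (any(radii <= 0)) stop("sphere radii must be positive")
  structure(list(centers = centers, radii = radii, indices = indices,
                 background_index = background_index),
            class = "sphere_scene")
}

#' Rasterize a sphere scene onto a refractive-index volume
#'
#' @param scene a [sphere_scene()].
#' @param ny,nx,nz output grid dimensions.
#' @param voxel_xy,voxel_z voxel sizes (micrometres).
#' @param wavelength carried into the volume metadata.
#' @return an [ri_volume()].
#' @export
rasterize_scene <- function(scene, ny, nx, nz, voxel_xy, voxel_z,
                            wavelength = NA_real_) {
  vol <- array(scene$background_index + 0i, c(ny, nx, nz))
  y <- grid_coords(ny, voxel_xy)
  x <- grid_coords(nx, voxel_xy)
  z <- grid_coords(nz, voxel_z)
  for (i in seq_along(scene$radii)) {
    c0 <- scene$centers[i, ]
    r <- scene$radii[i]
    zi <- which(abs(z - c0[3]) <= r)
    if (!length(zi)) next
    d2xy <- outer((y - c0[1])^2, (x - c0[2])^2, `+`)
    for (k in zi) {
      sel <- d2xy <= r^2 - (z[k] - c0[3])^2
      sl <- vol[, , k]
      sl[sel] <- scene$indices[i]
      vol[, , k] <- sl
    }
  }
  ri_volume(vol, voxel_xy, voxel_z, scene$background_index, wavelength)
}
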