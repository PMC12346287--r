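# Synthetic dynamic scenes and hologram time series: Brownian colloids with
# hindered diffusion near a wall and gravitational sedimentation, wobbling
# rod-like microswimmers, and the rendering loop that turns scenes into
# noisy off-axis holograms.

.kB <- 1.380649e-23  # J/K

#' Motion model for Brownian / sedimenting / swimming particles
#'
#' @param diffusion_coefficient bulk diffusion coefficient Do (um^2/s).
#' @param hindered apply the near-wall hindrance
#'   `D_par(h) = Do (1 - (9/16) R/h)` parallel to the wall (and, as a
#'   documented leading-order simplification, the same form axially).
#' @param radius bead radius R (um).
#' @param bead_density,solvent_density densities (g/ml); the effective
#'   gravitational mass is `m = (4/3) pi R^3 (rho_bead - rho_solvent)`.
#' @param temperature temperature (K).
#' @param gravity include the buoyancy/sedimentation drift (and the
#'   Boltzmann height statistics it implies).
#' @param swim_speed swimming speed (um/s) for rod scenes.
#' @param wobble_angle mean angle between body axis and velocity (degrees).
#' @param wobble_rate body-axis precession rate about the velocity (rad/s).
#' @param direction_noise angular diffusion of the velocity direction
#'   (rad^2/s).
#' @return an object of class `motion_model`.
#' @export
motion_model <- function(diffusion_coefficient = 0.4, hindered = FALSE,
                         radius = 0.5, bead_density = 1.05,
                         solvent_density = 1.0, temperature = 295.65,
                         gravity = FALSE, swim_speed = 20,
                         wobble_angle = 20, wobble_rate = 2 * pi * 10,
                         direction_noise = 0.1) {
  stopifnot(diffusion_coefficient >= 0, radius > 0, bead_density > 0,
            solvent_density > 0, temperature > 0)
  structure(list(diffusion_coefficient = diffusion_coefficient,
                 hindered = hindered, radius = radius,
                 bead_density = bead_density,
                 solvent_density = solvent_density,
                 temperature = temperature, gravity = gravity,
                 swim_speed = swim_speed, wobble_angle = wobble_angle,
                 wobble_rate = wobble_rate,
                 direction_noise = direction_noise),
            class = "motion_model")
}

# effective gravitational mass * g / kBT, as an inverse length (1/um);
# positive values pull the particle towards the coverslip (h = 0)
.inv_gravitational_length <- function(model) {
  vol_m3 <- 4 / 3 * pi * (model$radius * 1e-6)^3
  drho <- (model$bead_density - model$solvent_density) * 1000  # kg/m^3
  mg <- vol_m3 * drho * 9.80665                                # N
  (mg / (.kB * model$temperature)) * 1e-6                      # 1/um
}

#' Effective gravitational mass of a bead
#'
#' `m = (4/3) pi R^3 (rho_bead - rho_solvent)` in kilograms.
#'
#' @param radius bead radius (um).
#' @param bead_density,solvent_density densities (g/ml).
#' @return mass in kg (negative for buoyant beads).
#' @export
effective_mass <- function(radius, bead_density, solvent_density) {
  4 / 3 * pi * (radius * 1e-6)^3 * (bead_density - solvent_density) * 1000
}

#' Hindered parallel diffusion coefficient near a wall
#'
#' Leading-order wall correction `D(h) = Do (1 - (9/16) R / h)` for motion
#' parallel to a no-slip wall at h = 0; clipped below at zero (the formula
#' root at h = 9 R / 16 lies below sphere contact, outside the expansion's
#' domain of validity).
#'
#' @param h height of the sphere centre above the wall (um).
#' @param Do bulk diffusion coefficient (um^2/s).
#' @param R sphere radius (um).
#' @return diffusion coefficients (um^2/s).
#' @export
hindered_diffusion <- function(h, Do, R) pmax(Do * (1 - (9 / 16) * R / h), 0)

#' Simulate a Brownian sphere scene
#'
#' Euler-Maruyama integration with per-axis variance `2 D_axis(h) dt`.
#' With `hindered`, the parallel law above is used laterally and the same
#' leading-order form axially; the axial step then also carries the Ito
#' spurious-drift term `dD_z/dh dt` so the stationary height distribution
#' remains exactly Boltzmann. With `gravity`, a drift
#' `-(m g / kBT) D_z dt` (towards the wall for dense beads) is added.
#' Reflecting boundaries act at the coverslip (`h = R`) and, if
#' `chamber_height` is finite, at the chamber top.
#'
#' @param model a [motion_model()].
#' @param n_particles,n_frames scene size.
#' @param dt frame interval (s).
#' @param seed RNG seed (scenes are bit-reproducible per seed).
#' @param chamber_height chamber height (um); `Inf` for unbounded.
#' @param lateral_extent half-width of the initial lateral positions (um).
#' @param bead_index refractive index of the beads.
#' @param background_index medium index.
#' @param initial_positions optional [n_particles x 3] matrix (y, x, h).
#' @return an object of class `dynamic_scene`: positions
#'   `[n_particles, 3, n_frames]` (y, x, z with z the height above the
#'   coverslip), plus radius/index/timing metadata.
#' @export
simulate_brownian_scene <- function(model, n_particles, n_frames, dt,
                                    seed = 1, chamber_height = 10,
                                    lateral_extent = 10,
                                    bead_index = 1.57,
                                    background_index = 1.333,
                                    initial_positions = NULL) {
  stopifnot(dt > 0, n_particles >= 1, n_frames >= 1)
  R <- model$radius
  hmin <- R
  hmax <- if (is.finite(chamber_height)) chamber_height - R else Inf
  if (hmax <= hmin && is.finite(hmax))
    stop("chamber too short for the bead radius")
  Do <- model$diffusion_coefficient
  ig <- if (model$gravity) .inv_gravitational_length(model) else 0
  pos <- array(0, c(n_particles, 3, n_frames))
  with_seed(seed, {
    if (is.null(initial_positions)) {
      h0 <- stats::runif(n_particles, hmin, min(hmax, hmin + 20))
      initial_positions <- cbind(
        stats::runif(n_particles, -lateral_extent, lateral_extent),
        stats::runif(n_particles, -lateral_extent, lateral_extent),
        h0)
    }
    if (any(initial_positions[, 3] < hmin))
      stop("start positions must satisfy h >= R (sphere above the coverslip)")
    p <- initial_positions
    for (t in seq_len(n_frames)) {
      pos[, , t] <- p
      if (t == n_frames) break
      h <- p[, 3]
      if (model$hindered) {
        Dpar <- hindered_diffusion(h, Do, R)
        Dz <- Dpar
        dDz <- Do * (9 / 16) * R / h^2  # d D_z / d h
      } else {
        Dpar <- rep(Do, n_particles)
        Dz <- Dpar
        dDz <- 0
      }
      drift_z <- dDz * dt - ig * Dz * dt
      step <- cbind(stats::rnorm(n_particles, 0, sqrt(2 * Dpar * dt)),
                    stats::rnorm(n_particles, 0, sqrt(2 * Dpar * dt)),
                    stats::rnorm(n_particles, drift_z, sqrt(2 * Dz * dt)))
      p <- p + step
      # reflecting boundaries
      p[, 3] <- ifelse(p[, 3] < hmin, 2 * hmin - p[, 3], p[, 3])
      if (is.finite(hmax))
        p[, 3] <- ifelse(p[, 3] > hmax, 2 * hmax - p[, 3], p[, 3])
      p[, 3] <- pmin(pmax(p[, 3], hmin), ifelse(is.finite(hmax), hmax, Inf))
    }
  })
  structure(list(positions = pos, radius = R, bead_index = bead_index,
                 background_index = background_index, dt = dt,
                 chamber_height = chamber_height, model = model,
                 kind = "spheres", axes = NULL, seed = seed),
            class = "dynamic_scene")
}

#' Simulate a wobbling rod-like swimmer
#'
#' The swimmer translates along a smoothly varying velocity direction (a
#' random walk on the unit sphere with angular diffusion
#' `direction_noise`); its body axis precesses about the velocity at the
#' prescribed mean wobble angle. The ground-truth wobble angle is kept in
#' the metadata.
#'
#' @param model a [motion_model()] (uses `swim_speed`, `wobble_angle`,
#'   `wobble_rate`, `direction_noise`).
#' @param n_frames,dt,seed as in [simulate_brownian_scene()].
#' @param start start position (y, x, z in um).
#' @param rod_length,rod_radius body dimensions (um).
#' @param body_index,background_index refractive indices.
#' @return a `dynamic_scene` with `kind = "rods"`, positions
#'   `[1, 3, n_frames]` and unit body axes `[1, 3, n_frames]`.
#' @export
simulate_swimmer_scene <- function(model, n_frames, dt, seed = 1,
                                   start = c(0, 0, 5), rod_length = 2,
                                   rod_radius = 0.4, body_index = 1.39,
                                   background_index = 1.333) {
  stopifnot(model$swim_speed >= 0, n_frames >= 1, dt > 0)
  theta <- model$wobble_angle * pi / 180
  pos <- array(0, c(1, 3, n_frames))
  axes <- array(0, c(1, 3, n_frames))
  with_seed(seed, {
    v_dir <- c(0, 1, 0)
    phi <- stats::runif(1, 0, 2 * pi)  # precession phase
    p <- start
    for (t in seq_len(n_frames)) {
      pos[1, , t] <- p
      # orthonormal frame around the velocity direction
      ref <- if (abs(v_dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- ref - sum(ref * v_dir) * v_dir
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(v_dir[2] * e1[3] - v_dir[3] * e1[2],
              v_dir[3] * e1[1] - v_dir[1] * e1[3],
              v_dir[1] * e1[2] - v_dir[2] * e1[1])
      axes[1, , t] <- cos(theta) * v_dir +
        sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
      if (t == n_frames) break
      p <- p + model$swim_speed * v_dir * dt
      phi <- phi + model$wobble_rate * dt
      if (model$direction_noise > 0) {
        kick <- stats::rnorm(3, 0, sqrt(model$direction_noise * dt))
        v_dir <- v_dir + kick - sum(kick * v_dir) * v_dir
        v_dir <- v_dir / sqrt(sum(v_dir^2))
      }
    }
  })
  structure(list(positions = pos, axes = axes, radius = rod_radius,
                 rod_length = rod_length, bead_index = body_index,
                 background_index = background_index, dt = dt,
                 chamber_height = Inf,
                 model = model, kind = "rods",
                 wobble_angle_true = model$wobble_angle, seed = seed),
            class = "dynamic_scene")
}

#' @export
print.dynamic_scene <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<dynamic_scene> %d %s, %d frames, dt %.4g s\n",
              d[1], x$kind, d[3], x$dt))
  invisible(x)
}

#' Sphere scene of one frame of a dynamic scene
#'
#' @param scene a `dynamic_scene` with `kind = "spheres"`.
#' @param frame frame index.
#' @param z_offset shift applied to heights so the volume z = 0 plane can
#'   sit mid-chamber (scene heights are measured from the coverslip).
#' @return a [sphere_scene()].
#' @export
scene_frame_spheres <- function(scene, frame, z_offset = 0) {
  p <- scene$positions[, , frame, drop = FALSE]
  centers <- cbind(p[, 1, 1], p[, 2, 1], p[, 3, 1] + z_offset)
  sphere_scene(centers, scene$radius, scene$bead_index,
               scene$background_index)
}

#' Rasterize one frame of a rod scene
#'
#' Rods are drawn as cylinders with hemispherical caps at the volume's
#' voxel pitch.
#'
#' @param scene a `dynamic_scene` with `kind = "rods"`.
#' @param frame frame index.
#' @param ny,nx,nz,voxel_xy,voxel_z target grid.
#' @param z_offset shift applied to scene heights.
#' @param wavelength carried into the volume metadata.
#' @return an [ri_volume()].
#' @export
rasterize_rod_frame <- function(scene, frame, ny, nx, nz, voxel_xy, voxel_z,
                                z_offset = 0, wavelength = NA_real_) {
  vol <- array(scene$background_index + 0i, c(ny, nx, nz))
  y <- grid_coords(ny, voxel_xy); x <- grid_coords(nx, voxel_xy)
  z <- grid_coords(nz, voxel_z)
  n_rods <- dim(scene$positions)[1]
  half <- scene$rod_length / 2
  for (i in seq_len(n_rods)) {
    c0 <- scene$positions[i, , frame]
    c0[3] <- c0[3] + z_offset
    ax <- scene$axes[i, , frame]
    pts <- expand.grid(y = y, x = x, z = z)
    rel <- cbind(pts$y - c0[1], pts$x - c0[2], pts$z - c0[3])
    t_ax <- pmin(pmax(rel %*% ax, -half), half)
    d2 <- rowSums((rel - t_ax %*% t(ax))^2)
    inside <- d2 <= scene$radius^2
    vol[inside] <- scene$bead_index
  }
  ri_volume(vol, voxel_xy, voxel_z, scene$background_index, wavelength)
}

#' Render a hologram time series from a dynamic scene
#'
#' For each scene frame and each illumination frame, superposes the frame's
#' beams, forms the transmitted field (Mie single-scattering superposition
#' for sparse sphere scenes, or SSNP through the rasterized scene), applies
#' the detection pupil, adds a tilted plane-wave reference, and records the
#' intensity with Poisson shot noise at the stated photon budget plus
#' Gaussian read noise.
#'
#' @param scene a `dynamic_scene`.
#' @param illum an `illumination_set`.
#' @param grid list with `ny`, `nx`, `pixel_pitch`, `wavelength`.
#' @param reference_frequency length-2 reference tilt (cycles/um).
#' @param detection_na detection NA.
#' @param photons expected photon count per unit intensity; `Inf` disables
#'   shot noise.
#' @param read_noise Gaussian read noise (intensity units); 0 disables.
#' @param seed RNG seed.
#' @param method `"mie"` (sparse sphere scenes) or `"ssnp"`.
#' @param reference_amplitude amplitude of the tilted reference.
#' @param z_offset axial offset applied to scene heights so that z = 0 is
#'   mid-volume (default centres the chamber).
#' @param nz,voxel_z rasterization depth grid for `method = "ssnp"`.
#' @return list over scene frames; each element a list of [hologram()]
#'   (one per illumination frame).
#' @export
render_hologram_series <- function(scene, illum, grid, reference_frequency,
                                   detection_na = 1.0, photons = Inf,
                                   read_noise = 0, seed = 1,
                                   method = c("mie", "ssnp"),
                                   reference_amplitude = 5,
                                   z_offset = NULL, nz = 32, voxel_z = 0.5) {
  method <- match.arg(method)
  if (scene$kind == "rods" && method == "mie")
    stop("rod scenes require method = \"ssnp\"")
  n_frames <- dim(scene$positions)[3]
  if (is.null(z_offset)) {
    z_offset <- if (is.finite(scene$chamber_height))
      -scene$chamber_height / 2 else 0
  }
  lam <- grid$wavelength
  out <- vector("list", n_frames)
  with_seed(seed, {
    for (t in seq_len(n_frames)) {
      frames_t <- vector("list", length(illum$beams_per_frame))
      for (fr in seq_along(illum$beams_per_frame)) {
        beams <- illum$beams_per_frame[[fr]]
        if (method == "mie") {
          sph <- scene_frame_spheres(scene, t, z_offset = z_offset)
          vals <- 0
          for (b in beams) {
            fld <- mie_microscope_field(sph, b, grid, na = detection_na)
            vals <- vals + fld$values
          }
          fld <- complex_field(vals, grid$pixel_pitch, lam,
                               scene$background_index, 0)
        } else {
          vol <- rasterize_rod_frame(scene, t, grid$ny, grid$nx, nz,
                                     grid$pixel_pitch, voxel_z,
                                     z_offset = z_offset, wavelength = lam)
          inc <- incident_field(beams, grid$ny, grid$nx, grid$pixel_pitch,
                                lam, scene$background_index)
          fld <- ssnp_propagate(vol, inc,
                                propagation_config(pupil_na = detection_na))
        }
        holo <- synthesize_hologram(fld, reference_frequency,
                                    reference_amplitude)
        I <- holo$intensity
        if (is.finite(photons)) {
          I <- stats::rpois(length(I), lambda = pmax(I, 0) * photons) / photons
          I <- matrix(I, nrow(holo$intensity), ncol(holo$intensity))
        }
        if (read_noise > 0) {
          I <- I + matrix(stats::rnorm(length(I), 0, read_noise),
                          nrow(I), ncol(I))
          I <- pmax(I, 0)
        }
        holo$intensity <- I
        frames_t[[fr]] <- holo
      }
      out[[t]] <- frames_t
    }
  })
  out
}
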