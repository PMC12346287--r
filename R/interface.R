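# Dataset and configuration I/O plus the pipeline driver.
#
# On-disk layout of a dataset directory:
#   descriptor.json    acquisition metadata (wavelength, n0, pitch,
#                      reference frequency, frame timing)
#   illumination.csv   beam table (write_illumination format)
#   holograms.tif      multi-page float TIFF, frames in acquisition order
#                      (time-major: all illumination frames of volume 1,
#                      then volume 2, ...)

#' Acquisition descriptor
#'
#' @param wavelength vacuum wavelength (um).
#' @param background_index medium index n0.
#' @param pixel_pitch sample-referred camera pixel pitch (um).
#' @param reference_frequency length-2 off-axis reference tilt (cycles/um).
#' @param frames_per_volume DMD frames composing one volume.
#' @param volumetric_rate volumes per second (Hz).
#' @param detection_na detection numerical aperture.
#' @param reference_amplitude amplitude of the off-axis reference beam
#'   (demodulated fields are divided by it).
#' @return an object of class `acquisition_descriptor`.
#' @export
acquisition_descriptor <- function(wavelength, background_index, pixel_pitch,
                                   reference_frequency, frames_per_volume = 1,
                                   volumetric_rate = NA_real_,
                                   detection_na = 1.0,
                                   reference_amplitude = 1) {
  stopifnot(wavelength > 0, background_index > 0, pixel_pitch > 0,
            frames_per_volume >= 1, reference_amplitude > 0)
  structure(list(wavelength = wavelength,
                 background_index = background_index,
                 pixel_pitch = pixel_pitch,
                 reference_frequency = as.numeric(reference_frequency),
                 frames_per_volume = as.integer(frames_per_volume),
                 volumetric_rate = volumetric_rate,
                 detection_na = detection_na,
                 reference_amplitude = reference_amplitude),
            class = "acquisition_descriptor")
}

#' Lag time of a frame separation
#'
#' Converts a separation in volumes to seconds via the volumetric rate
#' (e.g. 200 volumes at 1.032 kHz is 0.194 s).
#'
#' @param n_volumes separation in volumes (frames of the volume series).
#' @param volumetric_rate volumes per second (Hz).
#' @return lag time in seconds.
#' @export
lag_time <- function(n_volumes, volumetric_rate) {
  stopifnot(volumetric_rate > 0)
  n_volumes / volumetric_rate
}

#' Save and load hologram datasets
#'
#' `save_dataset()` writes holograms (multi-page float TIFF), the
#' illumination beam table, and the acquisition descriptor into a
#' directory; `load_dataset()` restores them, validating shapes and
#' metadata, and returns `list(holograms, illum, descriptor)`.
#'
#' @param holograms flat list of [hologram()] in acquisition order
#'   (time-major), or a nested list (volumes of frames) which is
#'   flattened.
#' @param illum an `illumination_set`.
#' @param descriptor an [acquisition_descriptor()].
#' @param path dataset directory.
#' @return `save_dataset()` the path, invisibly; `load_dataset()` a list.
#' @export
save_dataset <- function(holograms, illum, descriptor, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (length(holograms) && is.list(holograms[[1]]) &&
        !inherits(holograms[[1]], "hologram")) {
    holograms <- do.call(c, holograms)
  }
  n_illum <- length(illum$beams_per_frame)
  if (length(holograms) %% n_illum != 0)
    stop(sprintf("hologram count %d is not a multiple of the %d illumination frames",
                 length(holograms), n_illum))
  pages <- lapply(holograms, function(h) h$intensity)
  mx <- max(1e-12, max(vapply(pages, max, numeric(1))))
  tiff::writeTIFF(lapply(pages, function(p) p / mx),
                  file.path(path, "holograms.tif"),
                  bits.per.sample = 32, reduce = FALSE)
  meta <- unclass(descriptor)
  meta$intensity_scale <- mx
  meta$n_holograms <- length(holograms)
  jsonlite::write_json(meta, file.path(path, "descriptor.json"),
                       auto_unbox = TRUE, digits = NA)
  write_illumination(illum, file.path(path, "illumination.csv"))
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  dpath <- file.path(path, "descriptor.json")
  if (!file.exists(dpath)) stop("descriptor.json not found in ", path)
  meta <- jsonlite::read_json(dpath, simplifyVector = TRUE)
  illum <- read_illumination(file.path(path, "illumination.csv"))
  pages <- tiff::readTIFF(file.path(path, "holograms.tif"), all = TRUE)
  if (length(pages) != meta$n_holograms)
    stop(sprintf("expected %d hologram pages, found %d",
                 meta$n_holograms, length(pages)))
  n_illum <- length(illum$beams_per_frame)
  if (length(pages) %% n_illum != 0)
    stop(sprintf("hologram page count %d does not match the %d-frame illumination set",
                 length(pages), n_illum))
  holos <- lapply(pages, function(p) {
    hologram(p * meta$intensity_scale, meta$reference_frequency,
             meta$pixel_pitch, meta$wavelength, meta$background_index)
  })
  desc <- acquisition_descriptor(meta$wavelength, meta$background_index,
                                 meta$pixel_pitch, meta$reference_frequency,
                                 meta$frames_per_volume,
                                 meta$volumetric_rate %||% NA_real_,
                                 meta$detection_na %||% 1.0,
                                 meta$reference_amplitude %||% 1)
  message(sprintf("loaded %d holograms (%d x %d px), %d illumination frames",
                  length(holos), nrow(holos[[1]]$intensity),
                  ncol(holos[[1]]$intensity), n_illum))
  list(holograms = holos, illum = illum, descriptor = desc)
}

#' Save and load refractive-index volumes
#'
#' Volumes are stored as multi-page float TIFF (the `nz` real-part pages
#' followed by the `nz` imaginary-part pages, affinely rescaled to [0, 1])
#' with a JSON sidecar holding voxel sizes, the background index, and the
#' rescaling.
#'
#' @param volume an [ri_volume()].
#' @param path output TIFF path (the sidecar gets extension `.json`).
#' @return `write_volume()` the path, invisibly; `read_volume()` an
#'   [ri_volume()].
#' @export
write_volume <- function(volume, path) {
  d <- dim(volume$index)
  re <- Re(volume$index); im <- Im(volume$index)
  lo <- min(re, im); hi <- max(re, im, lo + 1e-12)
  pages <- c(lapply(seq_len(d[3]), function(k) (re[, , k] - lo) / (hi - lo)),
             lapply(seq_len(d[3]), function(k) (im[, , k] - lo) / (hi - lo)))
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(ny = d[1], nx = d[2], nz = d[3], voxel_xy = volume$voxel_xy,
         voxel_z = volume$voxel_z,
         background_index = volume$background_index,
         wavelength = volume$wavelength, scale_lo = lo, scale_hi = hi),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$nz
  if (length(pages) != 2 * nz)
    stop(sprintf("expected %d pages, found %d", 2 * nz, length(pages)))
  arr <- array(0i, c(meta$ny, meta$nx, nz))
  for (k in seq_len(nz)) {
    re <- pages[[k]] * (meta$scale_hi - meta$scale_lo) + meta$scale_lo
    im <- pages[[nz + k]] * (meta$scale_hi - meta$scale_lo) + meta$scale_lo
    arr[, , k] <- re + 1i * im
  }
  ri_volume(arr, meta$voxel_xy, meta$voxel_z, meta$background_index,
            if (is.null(meta$wavelength)) NA_real_ else meta$wavelength)
}

# write a provenance sidecar next to an output file
.write_provenance <- function(path, stage, params) {
  jsonlite::write_json(
    list(stage = stage, parameters = params,
         package = "holotomo",
         version = tryCatch(as.character(utils::packageVersion("holotomo")),
                            error = function(e) "dev"),
         timestamp = format(Sys.time(), tz = "UTC")),
    paste0(path, ".provenance.json"), auto_unbox = TRUE, digits = NA)
}

#' Run a configured pipeline
#'
#' Executes the configured stages in order. The configuration is a JSON
#' file (or an equivalent list) with a `stages` array; each stage has a
#' `kind` (`design`, `simulate`, `reconstruct`, `track`, `analyze`) and
#' its parameters. Every output gets a `.provenance.json` sidecar with the
#' parameters and seed that produced it. Required keys are validated
#' before any computation starts.
#'
#' @param config path to a JSON config file, or a list.
#' @param output_dir output directory (created if needed).
#' @return named list of stage results, invisibly.
#' @export
run_pipeline <- function(config, output_dir = ".") {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$stages)) stop("config must contain a 'stages' array")
  stages <- config$stages
  if (is.data.frame(stages)) stages <- split(stages, seq_len(nrow(stages)))
  for (st in stages) {
    if (is.null(st$kind))
      stop("every stage needs a 'kind' (design/simulate/reconstruct/track/analyze)")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (si in seq_along(stages)) {
    st <- as.list(stages[[si]])
    kind <- st$kind
    res <- tryCatch(switch(
      kind,
      design = {
        geom <- do.call(system_geometry, st$geometry %||% list())
        angles <- design_angle_set(st$n_angles %||% 147, geom)
        illum <- partition_angles(angles, st$multiplex %||% 1L, geom,
                                  seed = st$seed %||% 1L)
        if (!is.null(st$carriers)) {
          illum <- compose_position_multiplex(
            illum, lapply(st$carriers, as.numeric), geom)
        }
        out <- file.path(output_dir, st$output %||% "illumination.csv")
        write_illumination(illum, out)
        .write_provenance(out, "design", st)
        illum
      },
      simulate = {
        model <- do.call(motion_model, st$motion %||% list())
        scene <- simulate_brownian_scene(
          model, st$n_particles %||% 5, st$n_frames %||% 16,
          st$dt %||% 1e-3, seed = st$seed %||% 1,
          chamber_height = st$chamber_height %||% 10)
        illum <- results[[st$illumination %||% "design"]] %||%
          illumination_set(list(list(plane_wave(c(0, 0)))))
        grid <- st$grid %||% list(ny = 64, nx = 64, pixel_pitch = 0.25,
                                  wavelength = 0.785)
        holos <- render_hologram_series(
          scene, illum, grid, st$reference_frequency %||% c(1.1, 1.1),
          detection_na = st$detection_na %||% 1.0,
          photons = st$photons %||% Inf,
          read_noise = st$read_noise %||% 0, seed = st$seed %||% 1)
        desc <- acquisition_descriptor(
          grid$wavelength, scene$background_index, grid$pixel_pitch,
          st$reference_frequency %||% c(1.1, 1.1),
          frames_per_volume = length(illum$beams_per_frame),
          volumetric_rate = 1 / ((st$dt %||% 1e-3) ),
          detection_na = st$detection_na %||% 1.0)
        out <- file.path(output_dir, st$output %||% "dataset")
        save_dataset(holos, illum, desc, out)
        .write_provenance(file.path(out, "dataset"), "simulate", st)
        list(scene = scene, path = out)
      },
      reconstruct = {
        src <- st$input %||% file.path(output_dir, "dataset")
        ds <- load_dataset(src)
        shape <- st$shape
        if (is.null(shape)) stop("reconstruct stage needs a 'shape'")
        ref <- NULL
        if ((ds$descriptor$reference_amplitude %||% 1) != 1) {
          h1 <- ds$holograms[[1]]
          ref <- complex_field(
            matrix(ds$descriptor$reference_amplitude + 0i,
                   nrow(h1$intensity), ncol(h1$intensity)),
            h1$pixel_pitch, h1$wavelength, h1$background_index)
        }
        vol <- reconstruct_volume(
          ds$holograms[seq_along(ds$illum$beams_per_frame)], ds$illum,
          shape = as.list(shape),
          detection_na = ds$descriptor$detection_na,
          n_iter = st$n_iter %||% 20, seed = st$seed %||% 1,
          reference = ref)
        out <- file.path(output_dir, st$output %||% "volume.tif")
        write_volume(vol, out)
        .write_provenance(out, "reconstruct", st)
        vol
      },
      track = {
        vols <- results[[st$input %||% "reconstruct"]]
        if (inherits(vols, "ri_volume")) vols <- list(vols)
        locs <- lapply(vols, localize_particles,
                       threshold = st$threshold %||% 0.01,
                       particle_radius = st$particle_radius %||% 0.5)
        tracks <- link_trajectories(locs, max_disp = st$max_disp %||% 2,
                                    memory = st$memory %||% 1)
        out <- file.path(output_dir, st$output %||% "tracks.csv")
        utils::write.csv(tracks, out, row.names = FALSE)
        .write_provenance(out, "track", st)
        tracks
      },
      analyze = {
        tracks <- results[[st$input %||% "track"]]
        md <- msd_diffusion(tracks, dt = st$dt %||% 1e-3,
                            stride = st$stride %||% 1)
        out <- file.path(output_dir, st$output %||% "msd.csv")
        utils::write.csv(md$msd, out, row.names = FALSE)
        .write_provenance(out, "analyze",
                          c(st, list(D_estimate = md$D)))
        md
      },
      stop(sprintf("unknown stage kind '%s'", kind))),
      error = function(e) stop(sprintf("stage %d (%s) failed: %s",
                                       si, kind, conditionMessage(e)),
                               call. = FALSE))
    results[[st$name %||% kind]] <- res
  }
  invisible(results)
}
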