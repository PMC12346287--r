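# Design and rendering of multiplexed DMD illumination patterns.
#
# A spot displayed at DMD position rp with binary carrier frequency fp
# produces a plane wave in the sample whose angle is set by rp and whose
# lateral position offset is set by fp:
#   delta_r = (fl * lambda / M) * (fp - fc)
#   f       = (M / (fl * lambda)) * (rp - rc)
# Angle multiplexing displays several spots at different positions with a
# common carrier; position multiplexing replicates the spots at additional
# carrier frequencies, displacing each replica in the sample plane.

#' Map a DMD spot to the plane wave it generates
#'
#' @param spot a [spot_spec()].
#' @param geom a [system_geometry()].
#' @return a [plane_wave()].
#' @export
spot_to_beam <- function(spot, geom) {
  validate_spot(spot, geom)
  fl <- .fl_um(geom)
  scale <- fl * geom$wavelength / geom$magnification_dmd_to_bfp  # um^2
  dr <- scale * (spot$spot_frequency - geom$carrier_frequency)
  f <- (spot$spot_position - geom$dmd_center) / scale
  fmax <- geom$illumination_na / geom$wavelength
  if (sqrt(sum(f^2)) > fmax + 1e-12) {
    stop(sprintf(
      "spot at DMD position (%.1f, %.1f) um maps outside the illumination pupil: |f| = %.4f > %.4f 1/um",
      spot$spot_position[1], spot$spot_position[2], sqrt(sum(f^2)), fmax))
  }
  plane_wave(object_frequency = f, position_offset = dr, phase = spot$phase)
}

#' Map a plane wave to the DMD spot that generates it
#'
#' Exact algebraic inverse of [spot_to_beam()]; the spot diameter is not
#' determined by the beam and is supplied separately.
#'
#' @param beam a [plane_wave()].
#' @param geom a [system_geometry()].
#' @param diameter spot diameter in mirrors.
#' @return a [spot_spec()].
#' @export
beam_to_spot <- function(beam, geom, diameter = 20) {
  fmax <- geom$illumination_na / geom$wavelength
  if (sqrt(sum(beam$object_frequency^2)) > fmax + 1e-12)
    stop("beam lies outside the illumination pupil")
  fl <- .fl_um(geom)
  scale <- fl * geom$wavelength / geom$magnification_dmd_to_bfp
  rp <- geom$dmd_center + scale * beam$object_frequency
  if (any(rp < 0) || any(rp > geom$dmd_shape * geom$mirror_pitch))
    stop(sprintf("requested spot position (%.1f, %.1f) um falls off the DMD face",
                 rp[1], rp[2]))
  fp <- geom$carrier_frequency + beam$position_offset / scale
  spot_spec(spot_frequency = fp, spot_position = rp, phase = beam$phase,
            diameter = diameter)
}

#' Render a binary DMD frame from spot descriptors
#'
#' A mirror is ON when it lies inside a spot disc and the thresholded carrier
#' `cos(2*pi*fp.r + phase) >= 0` for that spot. Overlapping discs are
#' rejected by default because they corrupt the purity of each spot's
#' carrier; `overlap = "union"` instead ORs the spots together.
#'
#' @param spots list of [spot_spec()].
#' @param geom a [system_geometry()].
#' @param overlap `"error"` (default) or `"union"`.
#' @return an object of class `dmd_frame` with elements `mirrors` (binary
#'   integer matrix of `geom$dmd_shape`) and `spots`.
#' @export
render_dmd_frame <- function(spots, geom, overlap = c("error", "union")) {
  overlap <- match.arg(overlap)
  if (length(spots) == 0) stop("spots must be non-empty")
  for (s in spots) validate_spot(s, geom)
  nr <- geom$dmd_shape[1]; nc <- geom$dmd_shape[2]
  p <- geom$mirror_pitch
  mirrors <- matrix(0L, nr, nc)
  covered <- matrix(FALSE, nr, nc)
  y <- (seq_len(nr) - 1) * p  # 0-based mirror indices scaled to um
  x <- (seq_len(nc) - 1) * p
  for (s in spots) {
    rad <- s$diameter * p / 2
    if (rad <= 0) next
    ri <- which(abs(y - s$spot_position[1]) <= rad)
    ci <- which(abs(x - s$spot_position[2]) <= rad)
    if (!length(ri) || !length(ci)) next
    dy <- y[ri] - s$spot_position[1]
    dx <- x[ci] - s$spot_position[2]
    disc <- outer(dy^2, dx^2, `+`) <= rad^2
    if (overlap == "error" && any(covered[ri, ci] & disc))
      stop("spot discs overlap; use overlap = \"union\" to OR them together")
    covered[ri, ci] <- covered[ri, ci] | disc
    carg <- 2 * pi * (outer(s$spot_frequency[1] * y[ri],
                            s$spot_frequency[2] * x[ci], `+`)) + s$phase
    on <- disc & (cos(carg) >= 0)
    mirrors[ri, ci][on] <- 1L
  }
  structure(list(mirrors = mirrors, spots = spots), class = "dmd_frame")
}

#' Quasi-uniform plane-wave direction set over the illumination pupil
#'
#' Lays `n_angles` object-space frequencies on a Fermat spiral scaled to the
#' illumination pupil, which is quasi-uniform over the disc and deterministic.
#'
#' @param n_angles number of directions (>= 1).
#' @param geom a [system_geometry()].
#' @param fill_fraction fraction of the pupil radius covered by the outermost
#'   direction (default 0.95, keeping every beam strictly inside the pupil).
#' @return list of [plane_wave()] with distinct `object_frequency`.
#' @export
design_angle_set <- function(n_angles, geom, fill_fraction = 0.95) {
  if (n_angles < 1) stop("n_angles must be >= 1")
  fmax <- fill_fraction * geom$illumination_na / geom$wavelength
  if (n_angles == 1) return(list(plane_wave(c(0, 0))))
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n_angles) - 1
  r <- fmax * sqrt(k / (n_angles - 1))
  th <- k * golden
  lapply(seq_len(n_angles), function(i) {
    plane_wave(object_frequency = c(r[i] * sin(th[i]), r[i] * cos(th[i])))
  })
}

# DMD-plane positions (um, relative to centre) of a list of beams.
beam_dmd_positions <- function(beams, geom) {
  scale <- .fl_um(geom) * geom$wavelength / geom$magnification_dmd_to_bfp
  t(vapply(beams, function(b) scale * b$object_frequency, numeric(2)))
}

# Capped average pairwise distance of within-frame DMD spot positions,
# summed over frames. `assign` is an integer vector of frame labels.
.partition_loss <- function(pos, assign, cap) {
  loss <- 0
  for (fr in unique(assign)) {
    idx <- which(assign == fr)
    if (length(idx) < 2) next
    d <- stats::dist(pos[idx, , drop = FALSE])
    loss <- loss + mean(pmin(d, cap))
  }
  loss
}

#' Partition an angle set into multiplexed frames
#'
#' Greedy farthest-point initialization followed by random pairwise swaps:
#' frames are seeded by iteratively picking, for each frame in turn, the
#' remaining angle farthest (on the DMD face) from those already in the
#' frame; then 5 iterations of 300 random swaps between frames are proposed
#' and a swap is kept iff it increases the loss, defined as the average
#' pairwise within-frame DMD distance capped at `distance_cap`. When the
#' number of angles is not divisible by the multiplexing factor, angles are
#' duplicated (never within one frame) to fill the last slots.
#'
#' @param angles list of distinct [plane_wave()].
#' @param multiplex beams per frame (>= 1).
#' @param geom a [system_geometry()].
#' @param seed integer seed for the swap RNG.
#' @param distance_cap cap on pairwise distances entering the loss
#'   (micrometres on the DMD face); defaults to the illumination pupil
#'   radius on the DMD.
#' @param n_sweeps,swaps_per_sweep swap-optimization schedule.
#' @return an `illumination_set`: list with `frames` (NULL until rendered),
#'   `beams_per_frame` (list of lists of [plane_wave()]), `angle_multiplex`,
#'   `position_multiplex`, and the optimization `loss_history`.
#' @export
partition_angles <- function(angles, multiplex, geom, seed = 1,
                             distance_cap = dmd_pupil_radius(geom),
                             n_sweeps = 5, swaps_per_sweep = 300) {
  n <- length(angles)
  if (multiplex < 1) stop("multiplex must be >= 1")
  if (multiplex > n) stop("multiplex must not exceed the number of angles")
  pos <- beam_dmd_positions(angles, geom)
  if (anyDuplicated(pos)) stop("angles must be distinct")
  n_frames <- ceiling(n / multiplex)
  n_slots <- n_frames * multiplex
  # Duplicate angles (fewest-used first, deterministic) to fill the last frame.
  idx_all <- c(seq_len(n), seq_len(n_slots - n))
  assign <- integer(n_slots)
  if (multiplex == 1) {
    assign <- seq_len(n_frames)
    beam_idx <- idx_all
  } else {
    # Farthest-point initialization: fill frames round-robin, placing in each
    # frame the unassigned angle that maximizes the min distance to the
    # angles already in that frame (ties broken by lowest index).
    remaining <- idx_all
    frame_members <- vector("list", n_frames)
    for (fr in seq_len(n_frames)) frame_members[[fr]] <- integer(0)
    for (slot in seq_len(n_slots)) {
      fr <- ((slot - 1) %% n_frames) + 1
      mem <- frame_members[[fr]]
      cand <- remaining
      # a duplicate may not share a frame with its twin
      cand <- cand[!(cand %in% mem)]
      if (!length(cand)) cand <- remaining
      if (!length(mem)) {
        pick_pos <- 1L  # lowest index wins
      } else {
        dmin <- vapply(cand, function(i) {
          min(sqrt(rowSums((pos[mem, , drop = FALSE] -
                              matrix(pos[i, ], length(mem), 2, byrow = TRUE))^2)))
        }, numeric(1))
        pick_pos <- which.max(dmin)
      }
      pick <- cand[pick_pos]
      frame_members[[fr]] <- c(mem, pick)
      remaining <- remaining[-match(pick, remaining)]
    }
    beam_idx <- unlist(frame_members)
    assign <- rep(seq_len(n_frames), times = vapply(frame_members, length, 1L))
  }
  loss <- .partition_loss(pos[beam_idx, , drop = FALSE], assign, distance_cap)
  loss_history <- loss
  if (multiplex > 1 && n_frames > 1) {
    with_seed(seed, {
      for (sweep in seq_len(n_sweeps)) {
        for (sw in seq_len(swaps_per_sweep)) {
          ij <- sample.int(n_slots, 2)
          if (assign[ij[1]] == assign[ij[2]]) next
          cand <- beam_idx
          cand[ij] <- cand[rev(ij)]
          # forbid a duplicated angle appearing twice in one frame
          ok <- TRUE
          for (s in ij) {
            fr <- assign[s]
            if (sum(cand[assign == fr] == cand[s]) > 1) ok <- FALSE
          }
          if (!ok) next
          new_loss <- .partition_loss(pos[cand, , drop = FALSE], assign,
                                      distance_cap)
          if (new_loss > loss) {
            beam_idx <- cand
            loss <- new_loss
            loss_history <- c(loss_history, loss)
          }
        }
      }
    })
  }
  beams_per_frame <- lapply(seq_len(n_frames), function(fr) {
    lapply(beam_idx[assign == fr], function(i) angles[[i]])
  })
  illumination_set(beams_per_frame, angle_multiplex = multiplex,
                   position_multiplex = 1L, loss_history = loss_history)
}

#' Construct an illumination set
#'
#' @param beams_per_frame list (one element per frame) of lists of
#'   [plane_wave()].
#' @param angle_multiplex,position_multiplex multiplexing factors.
#' @param frames optional list of rendered [render_dmd_frame()] results.
#' @param loss_history optional numeric vector from the partition optimizer.
#' @return an object of class `illumination_set`.
#' @export
illumination_set <- function(beams_per_frame, angle_multiplex = 1L,
                             position_multiplex = 1L, frames = NULL,
                             loss_history = NULL) {
  if (!is.null(frames) && length(frames) != length(beams_per_frame))
    stop("frames and beams_per_frame must have equal length")
  structure(list(
    frames = frames,
    beams_per_frame = beams_per_frame,
    angle_multiplex = as.integer(angle_multiplex),
    position_multiplex = as.integer(position_multiplex),
    loss_history = loss_history
  ), class = "illumination_set")
}

#' @export
print.illumination_set <- function(x, ...) {
  nb <- sum(lengths(x$beams_per_frame))
  cat(sprintf(
    "<illumination_set> %d frames, %d beams (%dx angle, %dx position multiplexing)\n",
    length(x$beams_per_frame), nb, x$angle_multiplex, x$position_multiplex))
  invisible(x)
}

#' Total number of beams in an illumination set
#' @param illum an `illumination_set`.
#' @export
n_beams <- function(illum) sum(lengths(illum$beams_per_frame))

#' Replicate an angle-multiplexed set at several carrier frequencies
#'
#' Position multiplexing: every frame's spots are repeated once per carrier
#' frequency. Each carrier displaces its beam replica in the sample plane by
#' `delta_r = (fl * lambda / M) * (fc_i - fc)`, extending the illuminated
#' field of view.
#'
#' @param angle_set an `illumination_set` (typically from
#'   [partition_angles()]).
#' @param carrier_frequencies list of length-2 DMD carrier frequencies
#'   (cycles per micrometre).
#' @param geom a [system_geometry()].
#' @return an `illumination_set` with `position_multiplex =
#'   length(carrier_frequencies)`.
#' @export
compose_position_multiplex <- function(angle_set, carrier_frequencies, geom) {
  nyq <- 1 / (2 * geom$mirror_pitch)
  cf <- lapply(carrier_frequencies, as.numeric)
  for (c1 in cf) {
    if (sqrt(sum(c1^2)) >= nyq) stop("carrier frequency above DMD Nyquist")
  }
  if (anyDuplicated(do.call(rbind, cf))) stop("carrier frequencies must be distinct")
  scale <- .fl_um(geom) * geom$wavelength / geom$magnification_dmd_to_bfp
  beams_per_frame <- lapply(angle_set$beams_per_frame, function(beams) {
    out <- list()
    for (c1 in cf) {
      dr <- scale * (c1 - geom$carrier_frequency)
      out <- c(out, lapply(beams, function(b) {
        plane_wave(object_frequency = b$object_frequency,
                   position_offset = b$position_offset + dr,
                   phase = b$phase, amplitude = b$amplitude)
      }))
    }
    out
  })
  illumination_set(beams_per_frame,
                   angle_multiplex = angle_set$angle_multiplex,
                   position_multiplex = length(cf))
}

#' Render every frame of an illumination set to binary DMD patterns
#'
#' @param illum an `illumination_set`.
#' @param geom a [system_geometry()].
#' @param diameter spot diameter in mirrors.
#' @inheritParams render_dmd_frame
#' @return the `illumination_set` with `frames` populated.
#' @export
render_illumination <- function(illum, geom, diameter = 20,
                                overlap = c("error", "union")) {
  overlap <- match.arg(overlap)
  illum$frames <- lapply(illum$beams_per_frame, function(beams) {
    spots <- lapply(beams, beam_to_spot, geom = geom, diameter = diameter)
    render_dmd_frame(spots, geom, overlap = overlap)
  })
  illum
}

#' Serialize an illumination set to a plain-text beam table
#'
#' One CSV record per beam: frame, fy, fx (1/um), dry, drx (um), phase
#' (rad), amplitude. [read_illumination()] restores the set.
#'
#' @param illum an `illumination_set`.
#' @param path output CSV path.
#' @export
write_illumination <- function(illum, path) {
  rows <- list()
  for (fr in seq_along(illum$beams_per_frame)) {
    for (b in illum$beams_per_frame[[fr]]) {
      rows[[length(rows) + 1]] <- data.frame(
        frame = fr,
        fy = b$object_frequency[1], fx = b$object_frequency[2],
        dry = b$position_offset[1], drx = b$position_offset[2],
        phase = b$phase, amplitude = b$amplitude)
    }
  }
  df <- do.call(rbind, rows)
  attr_line <- sprintf("# angle_multiplex=%d position_multiplex=%d",
                       illum$angle_multiplex, illum$position_multiplex)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_illumination
#' @param path CSV path written by [write_illumination()].
#' @export
read_illumination <- function(path) {
  header <- readLines(path, n = 1)
  am <- as.integer(sub(".*angle_multiplex=(\\d+).*", "\\1", header))
  pm <- as.integer(sub(".*position_multiplex=(\\d+).*", "\\1", header))
  df <- utils::read.csv(path, comment.char = "#")
  beams_per_frame <- lapply(split(df, df$frame), function(d) {
    lapply(seq_len(nrow(d)), function(i) {
      plane_wave(object_frequency = c(d$fy[i], d$fx[i]),
                 position_offset = c(d$dry[i], d$drx[i]),
                 phase = d$phase[i], amplitude = d$amplitude[i])
    })
  })
  illumination_set(unname(beams_per_frame), angle_multiplex = am,
                   position_multiplex = pm)
}

#' Write rendered DMD frames as a multi-page TIFF
#'
#' Binary frames are stored as 0/255 8-bit pages.
#'
#' @param illum an `illumination_set` with rendered `frames`.
#' @param path output TIFF path.
#' @export
write_dmd_frames <- function(illum, path) {
  if (is.null(illum$frames)) stop("illumination set has no rendered frames")
  pages <- lapply(illum$frames, function(fr) fr$mirrors * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}
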