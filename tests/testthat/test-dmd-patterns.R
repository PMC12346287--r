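# Spot/beam mapping, frame rendering, angle-set design, and multiplex
# partitioning.

test_that("spot/beam mapping follows the Fourier-plane relations and inverts", {
  geom <- test_geometry()
  # centred spot gives the axial, centred beam
  s0 <- spot_spec(geom$carrier_frequency, geom$dmd_center)
  b0 <- spot_to_beam(s0, geom)
  expect_equal(b0$object_frequency, c(0, 0))
  expect_equal(b0$position_offset, c(0, 0))
  b0s <- beam_to_spot(plane_wave(c(0, 0)), geom)
  expect_equal(b0s$spot_position, geom$dmd_center)
  expect_equal(b0s$spot_frequency, geom$carrier_frequency)

  # direct substitution: fl*lambda/M = 2000 um^2, fp - fc = (0.01, 0)
  g2 <- system_geometry(objective_focal_length = 2,
                        magnification_dmd_to_bfp = 0.785,
                        wavelength = 0.785, background_index = 1.515,
                        illumination_na = 1.2, detection_na = 1.0)
  s <- spot_spec(g2$carrier_frequency + c(0.01, 0), g2$dmd_center)
  b <- spot_to_beam(s, g2)
  expect_equal(b$position_offset, c(20, 0), tolerance = 1e-12)
  expect_equal(b$object_frequency, c(0, 0))

  # algebraic inverse on random valid beams
  fmax <- geom$illumination_na / geom$wavelength
  with_seed(5, {
    for (i in 1:100) {
      r <- sqrt(runif(1)) * 0.95 * fmax
      th <- runif(1, 0, 2 * pi)
      b <- plane_wave(r * c(sin(th), cos(th)), runif(2, -20, 20),
                      runif(1, -pi, pi))
      s <- beam_to_spot(b, geom, diameter = 20)
      b2 <- spot_to_beam(s, geom)
      expect_equal(b2$object_frequency, b$object_frequency, tolerance = 1e-9)
      expect_equal(b2$position_offset, b$position_offset, tolerance = 1e-9)
      s2 <- beam_to_spot(b2, geom, diameter = 20)
      expect_equal(s2$spot_frequency, s$spot_frequency, tolerance = 1e-9)
      expect_equal(s2$spot_position, s$spot_position, tolerance = 1e-9)
    }
  })
})

test_that("beams outside the pupil or off the DMD face are rejected", {
  geom <- test_geometry()
  fmax <- geom$illumination_na / geom$wavelength
  expect_error(beam_to_spot(plane_wave(c(1.1 * fmax, 0)), geom), "pupil")
  # a spot far from centre maps outside the pupil
  far <- spot_spec(geom$carrier_frequency,
                   geom$dmd_center + c(dmd_pupil_radius(geom) * 1.2, 0))
  expect_error(spot_to_beam(far, geom), "pupil")
  # pupil-edge beam maps to the pupil-radius circle on the DMD
  edge <- beam_to_spot(plane_wave(c(0, 0.999 * fmax)), geom)
  expect_equal(sqrt(sum((edge$spot_position - geom$dmd_center)^2)),
               0.999 * dmd_pupil_radius(geom), tolerance = 1e-9)
})

test_that("rendered frames are carrier-modulated discs", {
  geom <- system_geometry(dmd_shape = c(128L, 128L), mirror_pitch = 7.56,
                          illumination_na = 0.9, detection_na = 1.0,
                          background_index = 1.515,
                          carrier_frequency = c(0, 1 / (4 * 7.56)))
  ctr <- geom$dmd_center
  # zero diameter renders all-OFF
  f0 <- render_dmd_frame(list(spot_spec(geom$carrier_frequency, ctr,
                                        diameter = 0)), geom)
  expect_true(all(f0$mirrors == 0L))

  # stripes with period 4 mirrors along x, clipped to the disc
  fr <- render_dmd_frame(list(spot_spec(geom$carrier_frequency, ctr,
                                        diameter = 40)), geom)
  row <- fr$mirrors[round(ctr[1] / geom$mirror_pitch) + 1, ]
  on_cols <- which(row == 1L)
  expect_gt(length(on_cols), 20)
  # the ON pattern is 4-periodic inside the disc
  expect_true(all(diff(on_cols) %in% c(1L, 2L, 3L)))
  run <- rle(row[min(on_cols):max(on_cols)])
  expect_true(all(run$lengths[run$values == 0][-c(1, sum(run$values == 0))] <= 2))

  # largest nonzero-frequency FT peak sits at the carrier
  M <- fr$mirrors
  Fm <- Mod(stats::fft(M))
  fy <- fft_freq(nrow(M), geom$mirror_pitch)
  fx <- fft_freq(ncol(M), geom$mirror_pitch)
  # exclude a small DC neighbourhood
  f2 <- outer(fy^2, fx^2, `+`)
  Fm[f2 < (0.5 * sqrt(sum(geom$carrier_frequency^2)))^2] <- 0
  pk <- which(Fm == max(Fm), arr.ind = TRUE)[1, ]
  expect_equal(abs(fx[pk[2]]), geom$carrier_frequency[2], tolerance = 1e-3)
  expect_equal(abs(fy[pk[1]]), geom$carrier_frequency[1], tolerance = 1e-3)

  # ON count is monotone in spot diameter
  counts <- vapply(c(8, 16, 24, 32), function(d) {
    sum(render_dmd_frame(list(spot_spec(geom$carrier_frequency, ctr,
                                        diameter = d)), geom)$mirrors)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))

  # overlapping discs rejected by default, merged in union mode
  two <- list(spot_spec(geom$carrier_frequency, ctr, diameter = 30),
              spot_spec(geom$carrier_frequency, ctr + c(0, 10), diameter = 30))
  expect_error(render_dmd_frame(two, geom), "overlap")
  expect_s3_class(render_dmd_frame(two, geom, overlap = "union"), "dmd_frame")
})

test_that("angle sets are distinct, in-pupil, and quasi-uniform", {
  geom <- test_geometry()
  expect_error(design_angle_set(0, geom), "n_angles")
  one <- design_angle_set(1, geom)
  expect_equal(one[[1]]$object_frequency, c(0, 0))

  ang <- design_angle_set(147, geom)
  fr <- t(vapply(ang, function(b) b$object_frequency, numeric(2)))
  expect_equal(nrow(unique(fr)), 147)
  fmax <- geom$illumination_na / geom$wavelength
  expect_true(all(sqrt(rowSums(fr^2)) <= fmax + 1e-12))

  # quasi-uniform: mean nearest-neighbour spacing close to the uniform-disc
  # value R * sqrt(pi / N), with low spread
  for (n in c(50, 147)) {
    fr <- t(vapply(design_angle_set(n, geom),
                   function(b) b$object_frequency, numeric(2)))
    d <- as.matrix(stats::dist(fr)); diag(d) <- Inf
    nn <- apply(d, 1, min)
    ideal <- 0.95 * fmax * sqrt(pi / n)
    expect_lt(abs(mean(nn) - ideal) / ideal, 0.2)
    expect_lt(stats::sd(nn) / mean(nn), 0.2)
  }
})

test_that("partitioning fills frames, duplicates minimally, and improves the loss", {
  geom <- test_geometry()
  ang <- design_angle_set(147, geom)
  expect_error(partition_angles(ang, 200, geom), "multiplex")

  # multiplex 1: one beam per frame, untouched order
  p1 <- partition_angles(ang, 1, geom)
  expect_length(p1$beams_per_frame, 147)
  expect_true(all(lengths(p1$beams_per_frame) == 1))

  p19 <- partition_angles(ang, 19, geom, seed = 2)
  expect_length(p19$beams_per_frame, 8)         # ceil(147/19)
  expect_equal(n_beams(p19), 152)               # 8 * 19 slots
  freqs <- lapply(p19$beams_per_frame, function(beams)
    t(vapply(beams, function(b) b$object_frequency, numeric(2))))
  all_f <- do.call(rbind, freqs)
  # every input angle covered at least once; exactly 5 duplicates
  orig <- t(vapply(ang, function(b) b$object_frequency, numeric(2)))
  expect_equal(nrow(unique(all_f)), 147)
  expect_equal(nrow(all_f) - nrow(unique(all_f)), 5)
  # no duplicate within a frame
  for (fm in freqs) expect_equal(anyDuplicated(fm), 0)
  # accepted swaps only ever increase the loss
  expect_true(all(diff(p19$loss_history) >= 0))
  # deterministic given the seed
  p19b <- partition_angles(ang, 19, geom, seed = 2)
  expect_identical(p19$beams_per_frame, p19b$beams_per_frame)
})

test_that("pairing six ring angles matches the exhaustive optimum", {
  geom <- test_geometry()
  ring <- lapply(0:5, function(k)
    plane_wave(0.5 * c(sin(k * pi / 3), cos(k * pi / 3))))
  il <- partition_angles(ring, 2, geom, seed = 7)
  # brute force over all ways to split 6 angles into 3 pairs
  pos <- t(vapply(ring, function(b) b$object_frequency, numeric(2))) *
    1000 * geom$objective_focal_length * geom$wavelength /
    geom$magnification_dmd_to_bfp
  cap <- dmd_pupil_radius(geom)
  pairings <- list()
  perm3 <- function(items) {
    if (!length(items)) return(list(list()))
    out <- list()
    a <- items[1]
    for (j in 2:length(items)) {
      rest <- items[-c(1, j)]
      for (sub in perm3(rest)) out <- c(out, list(c(list(c(a, items[j])), sub)))
    }
    out
  }
  best <- -Inf
  for (pr in perm3(1:6)) {
    loss <- sum(vapply(pr, function(ij)
      min(sqrt(sum((pos[ij[1], ] - pos[ij[2], ])^2)), cap), numeric(1)))
    best <- max(best, loss)
  }
  got <- sum(vapply(il$beams_per_frame, function(beams) {
    p <- t(vapply(beams, function(b) b$object_frequency, numeric(2))) *
      1000 * geom$objective_focal_length * geom$wavelength /
      geom$magnification_dmd_to_bfp
    min(sqrt(sum((p[1, ] - p[2, ])^2)), cap)
  }, numeric(1)))
  expect_equal(got, best, tolerance = 1e-9)
  # the optimum pairs antipodal angles (distance = ring diameter)
  for (beams in il$beams_per_frame) {
    d <- sqrt(sum((beams[[1]]$object_frequency -
                     beams[[2]]$object_frequency)^2))
    expect_equal(d, 1, tolerance = 1e-9)
  }
})

test_that("position multiplexing replicates beams per carrier with offsets", {
  geom <- test_geometry()
  ang <- design_angle_set(147, geom)
  p19 <- partition_angles(ang, 19, geom, seed = 1)

  # single carrier equal to the alignment carrier: identity with zero offsets
  same <- compose_position_multiplex(p19, list(geom$carrier_frequency), geom)
  expect_equal(n_beams(same), n_beams(p19))
  offs <- unlist(lapply(same$beams_per_frame, function(b)
    lapply(b, function(x) x$position_offset)))
  expect_true(all(abs(offs) < 1e-12))

  # four carriers: the kilohertz-experiment bookkeeping
  pitch <- geom$mirror_pitch
  carriers <- list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  carriers <- lapply(carriers, function(s) s / (4 * pitch))
  p4 <- compose_position_multiplex(p19, carriers, geom)
  expect_equal(length(p4$beams_per_frame), 8)
  expect_equal(n_beams(p4), 608)
  # one frame holds 19 x 4 = 76 distinct beams in Fourier-plane terms
  fr1 <- p4$beams_per_frame[[1]]
  key <- vapply(fr1, function(b)
    paste(signif(c(b$object_frequency, b$position_offset), 10),
          collapse = ","), character(1))
  expect_equal(length(unique(key)), 76)
  expect_error(compose_position_multiplex(p19, list(c(0.01, 0), c(0.01, 0)),
                                          geom), "distinct")
})
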