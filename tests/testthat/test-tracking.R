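# Localization, linking, and the dynamics statistics.

test_that("a constant volume yields no localizations", {
  vol <- background_volume(24, 24, 16, 0.25, 0.25, 1.333)
  locs <- localize_particles(vol, threshold = 0.005)
  expect_equal(nrow(locs), 0)
})

test_that("synthetic Gaussian blobs localize to sub-voxel accuracy", {
  n0 <- 1.333
  vol <- background_volume(32, 32, 24, 0.25, 0.25, n0)
  y <- grid_coords(32, 0.25); x <- grid_coords(32, 0.25)
  z <- grid_coords(24, 0.25)
  put_blob <- function(vol, c0, amp = 0.05, s = 0.4) {
    g <- amp * outer(outer(exp(-(y - c0[1])^2 / (2 * s^2)),
                           exp(-(x - c0[2])^2 / (2 * s^2))),
                     exp(-(z - c0[3])^2 / (2 * s^2)))
    vol$index <- vol$index + g
    vol
  }
  c1 <- c(0.62, -1.13, 0.37)
  vol1 <- put_blob(vol, c1)
  locs <- localize_particles(vol1, threshold = 0.005, particle_radius = 0.5)
  expect_equal(nrow(locs), 1)
  expect_lt(abs(locs$y - c1[1]), 0.025)
  expect_lt(abs(locs$x - c1[2]), 0.025)
  expect_lt(abs(locs$z - c1[3]), 0.025)
  # two blobs 5 um apart give exactly two localizations
  vol2 <- put_blob(put_blob(vol, c(0.62, -2.6, 0.37)), c(0.62, 2.4, 0.37))
  locs2 <- localize_particles(vol2, threshold = 0.005, particle_radius = 0.5)
  expect_equal(nrow(locs2), 2)
})

test_that("linking follows particles, splits on long gaps, and matches brute force", {
  # single static particle: one track spanning all frames
  frames <- lapply(1:100, function(i) data.frame(y = 1, x = 2, z = 3))
  tr <- link_trajectories(frames, max_disp = 1)
  expect_equal(length(unique(tr$track)), 1)
  expect_equal(nrow(tr), 100)

  # a gap longer than the memory splits the track
  frames_gap <- frames
  for (i in 40:44) frames_gap[[i]] <- data.frame(y = numeric(0),
                                                 x = numeric(0),
                                                 z = numeric(0))
  tr2 <- link_trajectories(frames_gap, max_disp = 1, memory = 2)
  expect_equal(length(unique(tr2$track)), 2)
  tr3 <- link_trajectories(frames_gap, max_disp = 1, memory = 5)
  expect_equal(length(unique(tr3$track)), 1)

  # well-separated particles match the exhaustive optimal assignment
  with_seed(51, {
    p1 <- cbind(cumsum(rnorm(30, 0, 0.1)), cumsum(rnorm(30, 0, 0.1)),
                cumsum(rnorm(30, 0, 0.1)))
    p2 <- p1 + 10
    frames_2p <- lapply(1:30, function(t)
      data.frame(y = c(p1[t, 1], p2[t, 1]), x = c(p1[t, 2], p2[t, 2]),
                 z = c(p1[t, 3], p2[t, 3])))
  })
  tr4 <- link_trajectories(frames_2p, max_disp = 2)
  expect_equal(length(unique(tr4$track)), 2)
  t1 <- tr4[tr4$track == 1, ]
  expect_equal(t1$y, p1[, 1])

  # scenes of 5 well-separated particles with small displacements agree
  # with the exhaustive optimal assignment frame by frame
  with_seed(52, {
    base <- cbind(c(0, 8, 16, 0, 16), c(0, 8, 0, 16, 16), c(0, 4, 8, 2, 6))
    pts <- lapply(1:3, function(t) base + matrix(rnorm(15, 0, 0.4), 5, 3))
  })
  frames_5p <- lapply(pts, function(m) data.frame(y = m[, 1], x = m[, 2],
                                                  z = m[, 3]))
  tr5 <- link_trajectories(frames_5p, max_disp = 3)
  expect_equal(length(unique(tr5$track)), 5)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  for (t in 1:2) {
    cost <- function(perm) sum(sqrt(rowSums((pts[[t]] - pts[[t + 1]][perm, ])^2)))
    best <- perms(1:5)[[which.min(vapply(perms(1:5), cost, numeric(1)))]]
    # the linker continues frame-t point i at frame-(t+1) point got[i]
    ft <- tr5[tr5$frame == t, ]
    ft1 <- tr5[tr5$frame == t + 1, ]
    got <- vapply(seq_len(5), function(i) {
      id <- ft$track[which.min((ft$y - pts[[t]][i, 1])^2 +
                                 (ft$x - pts[[t]][i, 2])^2 +
                                 (ft$z - pts[[t]][i, 3])^2)]
      j <- which(ft1$track == id)
      which.min((pts[[t + 1]][, 1] - ft1$y[j])^2 +
                  (pts[[t + 1]][, 2] - ft1$x[j])^2 +
                  (pts[[t + 1]][, 3] - ft1$z[j])^2)
    }, integer(1))
    expect_equal(got, best)
  }
})

test_that("MSD of ballistic and Brownian tracks behaves as expected", {
  # ballistic track: MSD(tau) = v^2 tau^2 exactly
  v <- 2; dt <- 0.1
  tr <- data.frame(track = 1, frame = 1:50, y = 0, x = v * (1:50) * dt, z = 0)
  out <- msd_diffusion(tr, dt, stride = 1, dims = 3)
  expect_equal(out$msd$msd, (v * out$msd$lag)^2, tolerance = 1e-12)

  # Brownian tracks recover D within 5%
  D <- 0.3; dt <- 1e-3
  model <- motion_model(diffusion_coefficient = D, gravity = FALSE)
  sc <- simulate_brownian_scene(model, 50, 800, dt, seed = 53,
                                chamber_height = Inf,
                                initial_positions = cbind(rep(0, 50),
                                                          rep(0, 50),
                                                          rep(1000, 50)))
  rows <- list()
  for (i in 1:50) rows[[i]] <- data.frame(track = i, frame = 1:800,
                                          y = sc$positions[i, 1, ],
                                          x = sc$positions[i, 2, ],
                                          z = sc$positions[i, 3, ])
  tracks <- do.call(rbind, rows)
  est <- msd_diffusion(tracks, dt, stride = 1, fit_max_lag = 20 * dt)
  expect_lt(abs(est$D - D) / D, 0.05)

  # a strided computation reproduces the shared lags of the unstrided one
  m1 <- msd_diffusion(tracks, dt, stride = 1, overlapping = TRUE)
  m8 <- msd_diffusion(tracks, dt, stride = 8, overlapping = TRUE)
  shared <- match(m8$msd$lag, m1$msd$lag)
  expect_equal(m8$msd$msd, m1$msd$msd[shared], tolerance = 1e-12)
  expect_error(msd_diffusion(tr[1:3, ], dt, stride = 8), "stride")
})

test_that("step-size CDFs are monotone and recover Gaussian widths", {
  # deterministic equal steps: a unit-step CDF with sigma ~ 0
  tr <- data.frame(track = 1, frame = 1:60, y = 0, x = (1:60) * 0.5, z = 0)
  out <- stepsize_cdf(tr, lag = 1, axis = "x")
  expect_lt(out$sigma, 1e-12)
  expect_equal(out$cdf(0.5), 1)
  expect_equal(out$cdf(0.49), 0)

  # synthetic Gaussian steps: fitted sigma within 3% at n = 1e4
  with_seed(54, {
    steps <- rnorm(10000, 0, 0.5)
  })
  tr2 <- data.frame(track = 1, frame = 1:10001, y = 0,
                    x = cumsum(c(0, steps)), z = 0)
  out2 <- stepsize_cdf(tr2, lag = 1, axis = "x")
  expect_lt(abs(out2$sigma - 0.5) / 0.5, 0.03)
  expect_lt(out2$ks_distance, 0.02)
  # CDF is monotone from 0 to 1
  grid <- seq(-2, 2, length.out = 200)
  expect_true(all(diff(out2$cdf(grid)) >= 0))
  expect_equal(out2$cdf(-10), 0)
  expect_equal(out2$cdf(10), 1)
  expect_warning(stepsize_cdf(tr[1:10, ], lag = 1, axis = "x"), "steps")
})

test_that("the hindered-diffusion fit is exact on noiseless model data", {
  Do <- 0.06; R <- 0.5; dt <- 1e-3
  # tracks whose single-step lateral MSD follows the wall law exactly:
  # step size sqrt(2 D(h) dt) alternating in +-x and +-y, one fixed
  # height per bin so the binned estimate is exact
  hs <- seq(0.7, 5, length.out = 12)
  rows <- list()
  for (i in seq_along(hs)) {
    D <- Do * (1 - 9 / 16 * R / hs[i])
    s <- sqrt(2 * D * dt)
    n <- 41
    x <- s * c(0, cumsum(rep(c(1, -1), length.out = n - 1)))
    y <- s * c(0, cumsum(rep(c(1, -1), length.out = n - 1)))
    rows[[i]] <- data.frame(track = i, frame = 1:n, y = y, x = x, z = hs[i])
  }
  dh <- hs[2] - hs[1]
  fit <- hindered_diffusion_fit(do.call(rbind, rows), dt,
                                bin_edges = c(hs - dh / 2, max(hs) + dh / 2))
  expect_lt(abs(fit$Do - Do) / Do, 1e-10)
  expect_lt(abs(fit$R - R) / R, 1e-10)
  expect_lt(max(abs(stats::residuals(fit$fit))), 1e-12)
  # the formula root sits at h = 9 R / 16 and D tends to Do far away
  expect_equal(hindered_diffusion(9 * R / 16, Do, R), 0)
  expect_equal(hindered_diffusion(1e9, Do, R), Do, tolerance = 1e-8)
  expect_error(hindered_diffusion_fit(do.call(rbind, rows), dt,
                                      bin_edges = c(0, 10, 20, 30)),
               "one height bin")
})

test_that("simulated hindered trajectories reproduce the wall law", {
  Do <- 0.06; R <- 0.5; dt <- 2e-3
  model <- motion_model(diffusion_coefficient = Do, hindered = TRUE,
                        radius = R, gravity = FALSE)
  sc <- simulate_brownian_scene(model, 150, 1200, dt, seed = 55,
                                chamber_height = 8)
  rows <- list()
  for (i in 1:150) rows[[i]] <- data.frame(track = i, frame = 1:1200,
                                           y = sc$positions[i, 1, ],
                                           x = sc$positions[i, 2, ],
                                           z = sc$positions[i, 3, ])
  fit <- hindered_diffusion_fit(do.call(rbind, rows), dt,
                                bin_edges = seq(0.5, 5.5, by = 0.5))
  expect_lt(abs(fit$Do - Do) / Do, 0.02)
  expect_lt(abs(fit$R - R) / R, 0.15)
})

test_that("the Boltzmann height fit recovers the effective mass", {
  # closed-form arithmetic for a buoyant bead
  m <- effective_mass(0.5, 1.05, 1.13)
  expect_equal(m, 4 / 3 * pi * (0.5e-6)^3 * (-0.08 * 1000), tolerance = 1e-12)

  # equal densities: flat distribution, mass ~ 0
  with_seed(56, h_flat <- runif(5000, 1, 9))
  fit_flat <- boltzmann_height_fit(h_flat, 0.5, 1.0, 1.0)
  expect_equal(fit_flat$mass, 0)

  # simulator scene with known mass recovered within 10% (short chamber
  # so the chain equilibrates within the simulated span)
  model <- motion_model(diffusion_coefficient = 0.4, radius = 0.5,
                        bead_density = 1.66, solvent_density = 1.0,
                        gravity = TRUE, hindered = FALSE)
  sc <- simulate_brownian_scene(model, 100, 15000, 2e-3, seed = 57,
                                chamber_height = 4)
  h <- as.vector(sc$positions[, 3, 7500:15000])
  fit <- boltzmann_height_fit(h, 0.5, 1.66, 1.0)
  m_true <- effective_mass(0.5, 1.66, 1.0)
  expect_lt(abs(fit$mass - m_true) / m_true, 0.1)
})

test_that("wobble analysis recovers swimmer angles and applies track filters", {
  # axis parallel to velocity: zero wobble
  m0 <- motion_model(swim_speed = 15, wobble_angle = 0, direction_noise = 0)
  sc0 <- simulate_swimmer_scene(m0, 120, 1e-2, seed = 58)
  w0 <- wobble_analysis(sc0, dt = 1e-2)
  expect_equal(nrow(w0), 1)
  expect_lt(w0$wobble_angle, 0.5)

  # prescribed 20-degree wobble recovered within 2 degrees
  m20 <- motion_model(swim_speed = 15, wobble_angle = 20,
                      wobble_rate = 2 * pi * 8, direction_noise = 0.02)
  sc20 <- simulate_swimmer_scene(m20, 500, 1e-2, seed = 59)
  w20 <- wobble_analysis(sc20, dt = 1e-2)
  expect_equal(nrow(w20), 1)
  expect_lt(abs(w20$wobble_angle - 20), 2)

  # a 49-frame track is excluded by the length filter
  sc_short <- simulate_swimmer_scene(m20, 49, 1e-2, seed = 60)
  expect_message(w_short <- wobble_analysis(sc_short, dt = 1e-2), "filters")
  expect_equal(nrow(w_short), 0)
})

test_that("wobble analysis segments rod volumes by threshold and PCA", {
  # rasterized rods at a known angle: segmentation recovers axis/centroid
  m <- motion_model(swim_speed = 12, wobble_angle = 10,
                    wobble_rate = 2 * pi * 5, direction_noise = 0)
  sc <- simulate_swimmer_scene(m, 60, 1e-2, seed = 61,
                               start = c(0, -3, 0), rod_length = 2,
                               rod_radius = 0.3, body_index = 1.39,
                               background_index = 1.333)
  vols <- lapply(1:60, function(t)
    rasterize_rod_frame(sc, t, 48, 48, 24, 0.25, 0.25, z_offset = 0))
  w <- wobble_analysis(vols, dt = 1e-2, threshold = 0.02, min_frames = 50,
                       min_distance = 4, max_disp = 1)
  expect_equal(nrow(w), 1)
  expect_lt(abs(w$wobble_angle - 10), 4)
  expect_lt(abs(w$mean_speed - 12) / 12, 0.15)
})
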