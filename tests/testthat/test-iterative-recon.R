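# Data loss/gradient, proximal operators, and the FISTA solver.

test_that("loss and gradient vanish at the ground truth on noiseless data", {
  n0 <- 1.515; lam <- 0.785
  vol <- weak_phantom(24, 24, 6, dn = 0.02)
  cfg <- propagation_config(pupil_na = 0.95)
  beams <- list(plane_wave(c(0, 0)), plane_wave(c(0.5, 0)))
  illum <- illumination_set(lapply(beams, list))
  fields <- lapply(beams, function(b) {
    inc <- plane_wave_field(b, 24, 24, 0.25, lam, n0)
    ssnp_propagate(vol, inc, cfg)
  })
  fg <- data_loss_and_gradient(vol, fields, illum, cfg)
  expect_equal(fg$loss, 0)
  expect_lt(sqrt(sum(Mod(fg$gradient)^2)), 1e-8)
  expect_equal(data_loss(vol, fields, illum, cfg), fg$loss)
})

test_that("the adjoint gradient matches central finite differences", {
  n0 <- 1.515; lam <- 0.785
  truth <- weak_phantom(16, 16, 6, dn = 0.01, seed = 12)
  probe <- weak_phantom(16, 16, 6, dn = 0.01, seed = 13)
  beams <- list(plane_wave(c(0.25, 0)))
  illum <- illumination_set(lapply(beams, list))
  for (model in c("ssnp", "bpm")) {
    cfg <- propagation_config(pupil_na = 1.0, model = model)
    fields <- lapply(beams, function(b) {
      inc <- plane_wave_field(b, 16, 16, 0.25, lam, n0)
      if (model == "ssnp") ssnp_propagate(truth, inc, cfg)
      else bpm_propagate(truth, inc, cfg)
    })
    fg <- data_loss_and_gradient(probe, fields, illum, cfg,
                                 loss_config(1, 0.5))
    h <- 1e-6
    with_seed(14, idx <- replicate(4, c(sample(16, 1), sample(16, 1),
                                        sample(6, 1))))
    for (k in 1:ncol(idx)) {
      i <- idx[, k]
      for (im in c(FALSE, TRUE)) {
        dv <- if (im) 1i * h else h
        vp <- probe; vp$index[i[1], i[2], i[3]] <- vp$index[i[1], i[2], i[3]] + dv
        vm <- probe; vm$index[i[1], i[2], i[3]] <- vm$index[i[1], i[2], i[3]] - dv
        fd <- (data_loss(vp, fields, illum, cfg, loss_config(1, 0.5)) -
                 data_loss(vm, fields, illum, cfg, loss_config(1, 0.5))) / (2 * h)
        g <- fg$gradient[i[1], i[2], i[3]]
        an <- if (im) Im(g) else Re(g)
        expect_lt(abs(fd - an) / max(abs(fd), 1e-10), 1e-4)
      }
    }
  }
})

test_that("the linearized forward operator passes the adjoint test", {
  # <J dx, w> == <dx, J^H w> with J applied by finite differences and J^H
  # by the adjoint sweep
  n0 <- 1.515; lam <- 0.785
  vol <- weak_phantom(16, 16, 5, dn = 0.01, seed = 15)
  cfg <- propagation_config(pupil_na = 1.0)
  g <- .propagation_grid(16, 16, 0.25, 0.25, n0, lam, vol$voxel_z, cfg)
  inc <- plane_wave_field(plane_wave(c(0, 0.25)), 16, 16, 0.25, lam, n0)$values
  with_seed(16, {
    dx <- array(complex(real = rnorm(16 * 16 * 5),
                        imaginary = rnorm(16 * 16 * 5)), c(16, 16, 5)) * 1e-3
    w <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16, 16)
  })
  eps <- 1e-5
  Ep <- .ssnp_forward(vol$index + eps * dx, inc, g, cfg)$exit
  Em <- .ssnp_forward(vol$index - eps * dx, inc, g, cfg)$exit
  Jdx <- (Ep - Em) / (2 * eps)
  fwd <- .ssnp_forward(vol$index, inc, g, cfg, keep_fields = TRUE)
  JHw <- .ssnp_adjoint(vol$index, fwd, w, g, cfg)
  lhs <- sum(Conj(w) * Jdx)
  rhs <- sum(Conj(JHw) * dx)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-5)
})

test_that("the phase-insensitive loss ignores a global measurement phase", {
  n0 <- 1.515; lam <- 0.785
  vol <- weak_phantom(16, 16, 4, dn = 0.02, seed = 17)
  beams <- list(plane_wave(c(0, 0)))
  illum <- illumination_set(lapply(beams, list))
  cfg <- propagation_config(pupil_na = 1.0)
  inc <- plane_wave_field(beams[[1]], 16, 16, 0.25, lam, n0)
  meas <- ssnp_propagate(weak_phantom(16, 16, 4, dn = 0.02, seed = 18),
                         inc, cfg)
  rot <- meas; rot$values <- meas$values * exp(0.7i)
  lo <- loss_config(phase_sensitive_weight = 0, phase_insensitive_weight = 1)
  expect_equal(data_loss(vol, list(meas), illum, cfg, lo),
               data_loss(vol, list(rot), illum, cfg, lo), tolerance = 1e-12)
  # NaN measurements are reported with the frame index
  bad <- meas; bad$values[3, 3] <- NaN
  expect_error(data_loss_and_gradient(vol, list(bad), illum, cfg), "frame 1")
})

test_that("proximal steps shrink, project, and leave trivial cases alone", {
  vol <- weak_phantom(8, 8, 4, dn = 0.02, seed = 19)
  n0 <- vol$background_index
  # no regularization, no constraints: identity
  reg0 <- reg_config(0, 0, enforce_re_ge_background = FALSE,
                     enforce_absorptive = FALSE)
  expect_equal(prox_step(vol, 0.1, reg0)$index, vol$index)
  # constant volume is a TV fixed point
  cst <- background_volume(8, 8, 4, 0.25, 0.4, n0)
  cst$index[] <- n0 + 0.01
  out <- prox_step(cst, 1, reg_config(tv_weight = 0.05,
                                      enforce_re_ge_background = FALSE,
                                      enforce_absorptive = FALSE))
  expect_lt(max(Mod(out$index - cst$index)), 1e-12)
  # scalar soft threshold: n0 + 0.01 with l1 threshold 0.004 -> n0 + 0.006
  one <- background_volume(2, 2, 2, 0.25, 0.4, n0)
  one$index[] <- n0 + 0.01
  sh <- prox_step(one, 1, reg_config(l1_weight = 0.004))
  expect_equal(Re(sh$index[1, 1, 1]), n0 + 0.006, tolerance = 1e-12)
  # projections hold exactly
  low <- vol
  low$index <- low$index - 0.05 - 0.01i
  pr <- prox_step(low, 1, reg_config())
  expect_true(all(Re(pr$index) >= n0))
  expect_true(all(Im(pr$index) >= 0))
})

test_that("FISTA momentum follows the closed-form t-sequence", {
  # capture the first extrapolation factor via a linear problem
  t1 <- 1
  t2 <- (1 + sqrt(1 + 4 * t1^2)) / 2
  expect_equal(t2, (1 + sqrt(5)) / 2)
})

test_that("FISTA solves a separable lasso to the closed-form solution", {
  with_seed(3, {
    a <- runif(25, 0.5, 2)
    b <- rnorm(25)
  })
  w <- 0.3
  closed <- sign(b / a) * pmax(abs(b / a) - w / a^2, 0)
  res <- fista(
    rep(0, 25),
    f_grad = function(x) list(value = 0.5 * sum((a * x - b)^2),
                              gradient = a * (a * x - b)),
    prox = function(x, s) sign(x) * pmax(abs(x) - s * w, 0),
    penalty = function(x) w * sum(abs(x)),
    n_iter = 200, step = 1 / max(a^2))
  expect_lt(max(abs(res$x - closed)), 1e-8)
  expect_true(all(diff(res$objective_history) <= 1e-12))
})

test_that("reconstruction of a weak sphere recovers the index scale", {
  n0 <- 1.515; lam <- 0.785; dn <- 0.01
  scene <- sphere_scene(c(0, 0, 0), 1.5, n0 + dn, n0)
  geom <- test_geometry()
  angles <- design_angle_set(13, geom)
  grid <- list(ny = 64, nx = 64, pixel_pitch = 0.25, wavelength = lam)
  fields <- lapply(angles, function(b)
    mie_microscope_field(scene, b, grid, na = 0.95))
  shape <- list(ny = 64, nx = 64, nz = 20, voxel_xy = 0.25, voxel_z = 0.5)
  init <- demultiplex_rytov_initialize(fields, lapply(angles, list), shape,
                                       band_radius = 0.95 / lam)
  init$wavelength <- lam
  illum <- illumination_set(lapply(angles, list))
  cfg <- propagation_config(pupil_na = 0.95)
  sol <- fista_solve(init, fields, illum, cfg = cfg,
                     loss = loss_config(edge_taper = 0.25),
                     reg = reg_config(tv_weight = 0, l1_weight = 0),
                     n_iter = 15, n_power = 2, tol = 0)
  # constraints hold on the returned iterate
  expect_true(all(Re(sol$volume$index) >= n0))
  expect_true(all(Im(sol$volume$index) >= 0))
  # objective history never increases (monotone safeguard + restart)
  expect_true(all(diff(sol$objective_history) <= 1e-12))
  expect_lt(sol$objective_history[length(sol$objective_history)],
            0.2 * sol$objective_history[1])
  # peak index (away from the tapered edges) within 5% of the truth and
  # its contrast within 50% of the true contrast
  pk <- max(Re(sol$volume$index[17:48, 17:48, ]))
  expect_lt(abs(pk - (n0 + dn)) / (n0 + dn), 0.05)
  expect_lt(abs((pk - n0) - dn) / dn, 0.5)
})

test_that("multiplexing at fixed image count keeps reconstruction quality comparable", {
  # 12 angles at 3x multiplexing (4 images) vs 4 single-beam views
  # (4 images): tripling the angular coverage without extra exposures
  # costs at most a modest RMSE factor (the demultiplexing initializer
  # trades per-beam resolution for coverage; see the methods vignette for
  # the quantitative study)
  n0 <- 1.515; lam <- 0.785; dn <- 0.01
  scene <- sphere_scene(c(0, 0, 0), 1.5, n0 + dn, n0)
  geom <- test_geometry()
  grid <- list(ny = 48, nx = 48, pixel_pitch = 0.25, wavelength = lam)
  shape <- list(ny = 48, nx = 48, nz = 16, voxel_xy = 0.25, voxel_z = 0.5)
  truth <- rasterize_scene(scene, 48, 48, 16, 0.25, 0.5, lam)
  cfg <- propagation_config(pupil_na = 0.95)
  run <- function(illum) {
    fields <- lapply(illum$beams_per_frame, function(beams) {
      acc <- 0
      for (b in beams) acc <- acc + mie_microscope_field(scene, b, grid,
                                                         na = 0.95)$values
      complex_field(acc, 0.25, lam, n0, 0)
    })
    init <- demultiplex_rytov_initialize(fields, illum$beams_per_frame,
                                         shape, band_radius = 0.95 / lam)
    init$wavelength <- lam
    sol <- fista_solve(init, fields, illum, cfg = cfg,
                       loss = loss_config(edge_taper = 0.25),
                       reg = reg_config(tv_weight = 0, l1_weight = 0),
                       n_iter = 8, n_power = 1, tol = 0)
    core <- function(a) a[13:36, 13:36, ]
    sqrt(mean(Mod(core(sol$volume$index) - core(truth$index))^2))
  }
  angles12 <- design_angle_set(12, geom)
  illum_m <- partition_angles(angles12, 3, geom, seed = 5)
  illum_s <- illumination_set(lapply(design_angle_set(4, geom), list))
  expect_lte(run(illum_m), run(illum_s) * 1.5)
})
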