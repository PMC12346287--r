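# Iterative refractive-index reconstruction: FISTA proximal-gradient descent
# against the multislice forward models, with total-variation and l1
# regularization and physical constraints.

#' Data-fidelity configuration
#'
#' The data term per frame is
#' `w_ps * sum |E_model - E_meas|^2 + w_pi * sum (|E_model| - |E_meas|)^2`.
#' The phase-insensitive term is invariant to a global phase of the
#' measurement and is useful when phase unwrapping is unreliable.
#'
#' @param phase_sensitive_weight,phase_insensitive_weight non-negative
#'   weights (not both zero).
#' @param edge_taper fraction of the lateral field of view whose residuals
#'   are tapered to zero at the detector edges (0 disables). Measured
#'   fields carry wrap-around artifacts at the grid boundary that the
#'   model should not be forced to fit.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(phase_sensitive_weight = 1,
                        phase_insensitive_weight = 0,
                        edge_taper = 0) {
  if (phase_sensitive_weight < 0 || phase_insensitive_weight < 0)
    stop("loss weights must be non-negative")
  if (phase_sensitive_weight == 0 && phase_insensitive_weight == 0)
    stop("at least one loss weight must be positive")
  if (edge_taper < 0 || edge_taper >= 1) stop("edge_taper must be in [0, 1)")
  structure(list(phase_sensitive_weight = phase_sensitive_weight,
                 phase_insensitive_weight = phase_insensitive_weight,
                 edge_taper = edge_taper),
            class = "loss_config")
}

# Tukey residual weighting for the data loss (1 in the interior, rolling
# to 0 over the outer `frac` of each lateral axis).
.loss_mask <- function(ny, nx, frac) {
  if (is.null(frac) || frac <= 0) return(1)
  tuk <- function(n) {
    t <- seq(0, 1, length.out = n)
    w <- rep(1, n)
    sel <- t < frac / 2
    w[sel] <- 0.5 * (1 + cos(2 * pi / frac * (t[sel] - frac / 2)))
    sel <- t > 1 - frac / 2
    w[sel] <- 0.5 * (1 + cos(2 * pi / frac * (t[sel] - 1 + frac / 2)))
    w
  }
  tuk(ny) %o% tuk(nx)
}

#' Regularization and constraint configuration
#'
#' @param tv_weight isotropic total-variation weight (promotes piecewise
#'   smoothness).
#' @param l1_weight l1 weight on the index contrast `n - n0` (promotes
#'   sparsity).
#' @param enforce_re_ge_background project `Re(n) >= n0`.
#' @param enforce_absorptive project `Im(n) >= 0`.
#' @param tv_iter inner iterations of the TV proximal operator.
#' @return an object of class `reg_config`.
#' @export
reg_config <- function(tv_weight = 0, l1_weight = 0,
                       enforce_re_ge_background = TRUE,
                       enforce_absorptive = TRUE, tv_iter = 10) {
  if (tv_weight < 0 || l1_weight < 0) stop("regularization weights must be non-negative")
  structure(list(tv_weight = tv_weight, l1_weight = l1_weight,
                 enforce_re_ge_background = enforce_re_ge_background,
                 enforce_absorptive = enforce_absorptive, tv_iter = tv_iter),
            class = "reg_config")
}

# forward difference gradient of a 3D array along each axis (zero at far edge)
.grad3 <- function(a) {
  d <- dim(a)
  gy <- a; gy[] <- 0; gx <- gy; gz <- gy
  gy[-d[1], , ] <- a[-1, , ] - a[-d[1], , ]
  gx[, -d[2], ] <- a[, -1, ] - a[, -d[2], ]
  gz[, , -d[3]] <- a[, , -1] - a[, , -d[3]]
  list(gy = gy, gx = gx, gz = gz)
}

# negative adjoint of .grad3 (discrete divergence)
.div3 <- function(gy, gx, gz) {
  d <- dim(gy)
  dv <- array(0, d)
  dv[1, , ] <- gy[1, , ]
  dv[2:d[1], , ] <- gy[2:d[1], , ] - gy[1:(d[1] - 1), , ]
  dv[, 1, ] <- dv[, 1, ] + gx[, 1, ]
  dv[, 2:d[2], ] <- dv[, 2:d[2], ] + gx[, 2:d[2], ] - gx[, 1:(d[2] - 1), ]
  dv[, , 1] <- dv[, , 1] + gz[, , 1]
  dv[, , 2:d[3]] <- dv[, , 2:d[3]] + gz[, , 2:d[3]] - gz[, , 1:(d[3] - 1)]
  dv
}

# isotropic TV value of a real 3D array
.tv_value <- function(a) {
  g <- .grad3(a)
  sum(sqrt(g$gy^2 + g$gx^2 + g$gz^2))
}

# Chambolle dual-projection proximal operator for isotropic 3D TV:
# argmin_x ||x - y||^2 / 2 + w TV(x).
.tv_prox_real <- function(y, w, n_iter = 10) {
  if (w <= 0 || n_iter < 1) return(y)
  d <- dim(y)
  py <- array(0, d); px <- array(0, d); pz <- array(0, d)
  tau <- 1 / 12
  for (it in seq_len(n_iter)) {
    g <- .grad3(.div3(py, px, pz) - y / w)
    den <- 1 + tau * sqrt(g$gy^2 + g$gx^2 + g$gz^2)
    py <- (py + tau * g$gy) / den
    px <- (px + tau * g$gx) / den
    pz <- (pz + tau * g$gz) / den
  }
  y - w * .div3(py, px, pz)
}

#' Proximal/projection step on a refractive-index volume
#'
#' Applies, in order: the isotropic TV proximal operator (on real and
#' imaginary parts separately, weight `step * tv_weight`), complex
#' soft-thresholding of the contrast `n - n0` (weight `step * l1_weight`),
#' and the physical projections `Re(n) >= n0`, `Im(n) >= 0`. The
#' composition approximates the joint proximal operator.
#'
#' @param volume an [ri_volume()].
#' @param step step size multiplying the regularization weights.
#' @param reg a [reg_config()].
#' @return an [ri_volume()].
#' @export
prox_step <- function(volume, step, reg) {
  if (step <= 0) stop("step must be positive")
  n <- volume$index
  n0 <- volume$background_index
  if (reg$tv_weight > 0) {
    n <- .tv_prox_real(Re(n), step * reg$tv_weight, reg$tv_iter) +
      1i * .tv_prox_real(Im(n), step * reg$tv_weight, reg$tv_iter)
  }
  if (reg$l1_weight > 0) {
    u <- n - n0
    mag <- Mod(u)
    shrink <- pmax(1 - step * reg$l1_weight / pmax(mag, 1e-300), 0)
    n <- n0 + u * shrink
  }
  if (reg$enforce_re_ge_background) n <- pmax(Re(n), n0) + 1i * Im(n)
  if (reg$enforce_absorptive) n <- Re(n) + 1i * pmax(Im(n), 0)
  volume$index <- n
  volume
}

# regularization penalty value (for the recorded objective)
.reg_value <- function(volume, reg) {
  v <- 0
  if (reg$tv_weight > 0)
    v <- v + reg$tv_weight * (.tv_value(Re(volume$index)) +
                                .tv_value(Im(volume$index)))
  if (reg$l1_weight > 0)
    v <- v + reg$l1_weight * sum(Mod(volume$index - volume$background_index))
  v
}

#' Data loss and gradient for a candidate volume
#'
#' Runs the configured forward model (SSNP or BPM) for every frame,
#' evaluates the phase-sensitive / phase-insensitive data loss against the
#' measured fields, and returns the loss together with its gradient with
#' respect to the complex refractive index, packed as
#' `dL/dRe(n) + i dL/dIm(n)` (twice the Wirtinger derivative
#' `dL/d conj(n)`), computed by the adjoint (reverse slice sweep) of the
#' forward model. Frame losses and gradients are averaged.
#'
#' @param volume an [ri_volume()].
#' @param holo_fields list of measured [complex_field()] per frame,
#'   referenced to z = 0 relative to a unit reference.
#' @param illum an `illumination_set` whose `beams_per_frame` matches
#'   `holo_fields`.
#' @param cfg a [propagation_config()].
#' @param loss a [loss_config()].
#' @return list with `loss` (scalar) and `gradient` (complex 3D array).
#' @export
data_loss_and_gradient <- function(volume, holo_fields, illum,
                                   cfg = propagation_config(),
                                   loss = loss_config()) {
  stopifnot(length(holo_fields) == length(illum$beams_per_frame))
  d <- dim(volume$index)
  lam <- holo_fields[[1]]$wavelength
  g <- .propagation_grid(d[1], d[2], volume$voxel_xy, volume$voxel_xy,
                         volume$background_index, lam, volume$voxel_z, cfg)
  total_loss <- 0
  grad <- array(0i, d)
  nf <- length(holo_fields)
  w_ps <- loss$phase_sensitive_weight
  w_pi <- loss$phase_insensitive_weight
  wm <- .loss_mask(d[1], d[2], loss$edge_taper %||% 0)
  for (fr in seq_len(nf)) {
    meas <- holo_fields[[fr]]$values
    if (any(is.na(meas)))
      stop(sprintf("NaN in measured field of frame %d", fr))
    inc <- incident_field(illum$beams_per_frame[[fr]], d[1], d[2],
                          volume$voxel_xy, lam, volume$background_index)$values
    if (cfg$model == "ssnp") {
      fwd <- .ssnp_forward(volume$index, inc, g, cfg, keep_fields = TRUE)
    } else {
      cos_obl <- 1
      if (cfg$model == "bpm_obliquity") {
        beams <- illum$beams_per_frame[[fr]]
        if (length(beams) > 1)
          stop("obliquity-corrected BPM is undefined for multiplexed illumination")
        fm <- volume$background_index / lam
        cos_obl <- sqrt(fm^2 - sum(beams[[1]]$object_frequency^2)) / fm
      }
      fwd <- .bpm_forward(volume$index, inc, g, cfg, cos_obl = cos_obl,
                          keep_fields = TRUE)
    }
    E <- .pad_crop(fwd$exit, g)
    r <- E - meas
    l_ps <- sum(wm * Mod(r)^2)
    gE <- w_ps * wm * r
    l_pi <- 0
    if (w_pi > 0) {
      dm <- Mod(E) - Mod(meas)
      l_pi <- sum(wm * dm^2)
      gE <- gE + w_pi * wm * dm * E / pmax(Mod(E), 1e-300)
    }
    total_loss <- total_loss + (w_ps * l_ps + w_pi * l_pi) / nf
    gEp <- .pad_embed(gE, g) / nf
    if (cfg$model == "ssnp") {
      grad <- grad + .ssnp_adjoint(volume$index, fwd, gEp, g, cfg)
    } else {
      grad <- grad + .bpm_adjoint(volume$index, fwd, gEp, g, cfg)
    }
  }
  list(loss = total_loss, gradient = 2 * grad)
}

#' @rdname data_loss_and_gradient
#' @export
data_loss <- function(volume, holo_fields, illum, cfg = propagation_config(),
                      loss = loss_config()) {
  d <- dim(volume$index)
  lam <- holo_fields[[1]]$wavelength
  g <- .propagation_grid(d[1], d[2], volume$voxel_xy, volume$voxel_xy,
                         volume$background_index, lam, volume$voxel_z, cfg)
  total <- 0
  nf <- length(holo_fields)
  wm <- .loss_mask(d[1], d[2], loss$edge_taper %||% 0)
  for (fr in seq_len(nf)) {
    meas <- holo_fields[[fr]]$values
    inc <- incident_field(illum$beams_per_frame[[fr]], d[1], d[2],
                          volume$voxel_xy, lam, volume$background_index)$values
    fwd <- if (cfg$model == "ssnp") {
      .ssnp_forward(volume$index, inc, g, cfg)
    } else {
      .bpm_forward(volume$index, inc, g, cfg)
    }
    E <- .pad_crop(fwd$exit, g)
    r <- E - meas
    l <- loss$phase_sensitive_weight * sum(wm * Mod(r)^2)
    if (loss$phase_insensitive_weight > 0)
      l <- l + loss$phase_insensitive_weight * sum(wm * (Mod(E) - Mod(meas))^2)
    total <- total + l / nf
  }
  total
}

# Lipschitz estimate by power iteration on the (finite-difference) Hessian
# of the data term at `volume`.
.lipschitz_estimate <- function(volume, holo_fields, illum, cfg, loss,
                                n_power = 5, seed = 1, eps = 1e-6) {
  d <- dim(volume$index)
  g0 <- data_loss_and_gradient(volume, holo_fields, illum, cfg, loss)$gradient
  v <- with_seed(seed, array(complex(real = stats::rnorm(prod(d)),
                                     imaginary = stats::rnorm(prod(d))), d))
  v <- v / sqrt(sum(Mod(v)^2))
  L <- 1
  for (it in seq_len(n_power)) {
    vol2 <- volume
    vol2$index <- volume$index + eps * v
    g1 <- data_loss_and_gradient(vol2, holo_fields, illum, cfg, loss)$gradient
    w <- (g1 - g0) / eps
    L <- sqrt(sum(Mod(w)^2))
    if (L == 0) return(1)
    v <- w / L
  }
  L
}

#' FISTA reconstruction solver
#'
#' Standard FISTA (accelerated proximal gradient descent): gradient step at
#' the momentum point, [prox_step()], momentum update
#' `t_{k+1} = (1 + sqrt(1 + 4 t_k^2)) / 2`, extrapolation; with adaptive
#' restart and a monotone safeguard (the recorded objective history is
#' non-increasing: if a step would increase the objective, momentum is
#' restarted from the best iterate). The step size defaults to the inverse
#' of a power-iteration Lipschitz estimate, halved by backtracking whenever
#' the quadratic majorization is violated.
#'
#' @param initial an [ri_volume()] initial guess (e.g. from
#'   [demultiplex_rytov_initialize()]).
#' @param holo_fields,illum,cfg,loss as in [data_loss_and_gradient()].
#' @param reg a [reg_config()].
#' @param n_iter number of iterations (default 50).
#' @param step step size; `NULL` for the automatic estimate.
#' @param n_power power iterations for the Lipschitz estimate.
#' @param tol stop when the relative objective change falls below this.
#' @param restart enable adaptive restart (default TRUE).
#' @param seed seed for the power-iteration probe.
#' @param verbose print per-iteration objectives.
#' @return list with `volume` (the reconstructed [ri_volume()]) and
#'   `objective_history`.
#' @export
fista_solve <- function(initial, holo_fields, illum,
                        cfg = propagation_config(), loss = loss_config(),
                        reg = reg_config(), n_iter = 50, step = NULL,
                        n_power = 5, tol = 1e-5, restart = TRUE, seed = 1,
                        verbose = FALSE) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (is.null(step)) {
    L <- .lipschitz_estimate(initial, holo_fields, illum, cfg, loss,
                             n_power = n_power, seed = seed)
    step <- 1 / max(L, 1e-12)
  }
  template <- initial
  wrap <- function(arr) { template$index <- arr; template }
  sol <- fista(
    x0 = initial$index,
    f_grad = function(arr) {
      fg <- data_loss_and_gradient(wrap(arr), holo_fields, illum, cfg, loss)
      list(value = fg$loss, gradient = fg$gradient)
    },
    f_value = function(arr) data_loss(wrap(arr), holo_fields, illum, cfg, loss),
    prox = function(arr, s) prox_step(wrap(arr), s, reg)$index,
    penalty = function(arr) .reg_value(wrap(arr), reg),
    n_iter = n_iter, step = step, tol = tol, restart = restart,
    verbose = verbose)
  list(volume = wrap(sol$x), objective_history = sol$objective_history)
}

#' Generic FISTA solver for composite objectives
#'
#' Minimizes `f(x) + h(x)` where `f` is smooth (for complex `x` the
#' gradient is packed as `dL/dRe(x) + i dL/dIm(x)`) and `h` has a proximal
#' operator. Implements Nesterov momentum with the
#' `t_{k+1} = (1 + sqrt(1 + 4 t_k^2)) / 2` sequence, backtracking on the
#' quadratic majorization, adaptive restart on objective increase, and a
#' monotone safeguard so the recorded objective history never increases.
#'
#' @param x0 initial iterate (numeric or complex array).
#' @param f_grad function of `x` returning `list(value, gradient)`.
#' @param f_value optional cheaper function of `x` returning only the
#'   smooth-term value (used during backtracking); defaults to `f_grad`.
#' @param prox function of `(x, step)` returning the proximal point.
#' @param penalty function of `x` returning the value of `h` (for the
#'   recorded objective).
#' @param n_iter maximum iterations.
#' @param step initial step size.
#' @param tol relative objective-change stopping tolerance.
#' @param restart enable adaptive restart.
#' @param verbose print per-iteration objectives.
#' @return list with `x` (the best iterate) and `objective_history`.
#' @export
fista <- function(x0, f_grad, prox, penalty = function(x) 0, n_iter = 100,
                  step = 1, tol = 0, restart = TRUE, verbose = FALSE,
                  f_value = NULL) {
  if (is.null(f_value)) f_value <- function(x) f_grad(x)$value
  x <- x0
  y <- x0
  x_prev <- x0
  tk <- 1
  obj <- f_value(x0) + penalty(x0)
  history <- obj
  for (it in seq_len(n_iter)) {
    fy <- f_grad(y)
    repeat {
      cand <- prox(y - step * fy$gradient, step)
      f_cand <- f_value(cand)
      diffv <- cand - y
      lin <- sum(Re(Conj(fy$gradient) * diffv))
      qmaj <- fy$value + lin + sum(Mod(diffv)^2) / (2 * step)
      if (f_cand <= qmaj + 1e-10 * max(abs(qmaj), 1) || step < 1e-14) break
      step <- step / 2
    }
    obj_cand <- f_cand + penalty(cand)
    if (is.finite(history[1]) && history[1] > 0 && obj_cand > 10 * history[1])
      stop("fista: objective diverged beyond 10x the initial value")
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    if (obj_cand <= obj || !restart) {
      y <- cand + ((tk - 1) / t_next) * (cand - x_prev)
      x_prev <- cand
      if (obj_cand <= obj) {
        x <- cand
        obj <- obj_cand
      }
      tk <- t_next
    } else {
      y <- x
      x_prev <- x
      tk <- 1
    }
    history <- c(history, obj)
    if (verbose)
      message(sprintf("iter %3d  objective %.6e  step %.3e", it, obj, step))
    if (tol > 0 && length(history) > 2) {
      rel <- abs(history[length(history) - 1] - obj) /
        max(abs(history[length(history) - 1]), 1e-300)
      if (rel < tol && obj_cand <= obj) break
    }
  }
  list(x = x, objective_history = history)
}

#' End-to-end reconstruction from holograms
#'
#' Demodulates each hologram, normalizes by the reference, builds the
#' Rytov-demultiplexed initial guess, and refines it with [fista_solve()]
#' against the SSNP forward model (default). A provenance list (parameters,
#' seed, package version) is attached as attribute `provenance`.
#'
#' @param holograms list of [hologram()], one per frame.
#' @param illum an `illumination_set`.
#' @param shape target volume shape (see
#'   [demultiplex_rytov_initialize()]).
#' @param band_radius demodulation band radius (cycles/um); default the
#'   detection NA band.
#' @param detection_na detection numerical aperture.
#' @param cfg,loss,reg,n_iter,step,tol,seed solver settings.
#' @param reference optional [complex_field()] reference to divide out
#'   (e.g. from [estimate_reference()]).
#' @return an [ri_volume()] with attributes `objective_history` and
#'   `provenance`.
#' @export
reconstruct_volume <- function(holograms, illum, shape,
                               band_radius = NULL, detection_na = 1.0,
                               cfg = propagation_config(pupil_na = detection_na),
                               loss = loss_config(), reg = reg_config(),
                               n_iter = 50, step = NULL, tol = 1e-5,
                               seed = 1, reference = NULL) {
  lam <- holograms[[1]]$wavelength
  band_radius <- band_radius %||% (detection_na / lam)
  fields <- lapply(holograms, demodulate_hologram, band_radius = band_radius)
  if (!is.null(reference)) {
    fields <- lapply(fields, function(f) {
      f$values <- f$values / reference$values
      f
    })
  }
  init <- demultiplex_rytov_initialize(fields, illum$beams_per_frame, shape,
                                       band_radius = band_radius)
  init$wavelength <- lam
  sol <- fista_solve(init, fields, illum, cfg = cfg, loss = loss, reg = reg,
                     n_iter = n_iter, step = step, tol = tol, seed = seed)
  out <- sol$volume
  attr(out, "objective_history") <- sol$objective_history
  attr(out, "provenance") <- list(
    n_frames = length(holograms), model = cfg$model,
    band_radius = band_radius, detection_na = detection_na,
    tv_weight = reg$tv_weight, l1_weight = reg$l1_weight,
    phase_sensitive_weight = loss$phase_sensitive_weight,
    phase_insensitive_weight = loss$phase_insensitive_weight,
    n_iter = n_iter, seed = seed,
    package_version = tryCatch(as.character(utils::packageVersion("holotomo")),
                               error = function(e) "dev"),
    timestamp = format(Sys.time(), tz = "UTC"))
  out
}
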