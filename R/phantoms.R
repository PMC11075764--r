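#' Flow scenario for the advection-diffusion simulator
#'
#' Bundles a constant diffusion coefficient, a velocity field sampled at the
#' grid nodes, and an initial concentration field.
#'
#' @param name Scenario identifier.
#' @param grid An [lcfr_grid()].
#' @param D Scalar diffusion coefficient (mm^2/s, >= 0).
#' @param ux,uy Velocity components (mm/s) as `nx x ny` matrices.
#' @param init Nonnegative initial concentration, `nx x ny`.
#' @return An object of class `flow_scenario`.
#' @export
flow_scenario <- function(name, grid, D, ux, uy, init) {
  stopifnot(D >= 0)
  dm <- c(grid$nx, grid$ny)
  for (f in list(ux, uy, init))
    if (!identical(dim(f), as.integer(dm)))
      stop("velocity and initial-condition fields must be nx x ny matrices")
  if (any(init < 0)) stop("initial condition must be nonnegative")
  structure(list(name = name, grid = grid, D = D, ux = ux, uy = uy, init = init),
            class = "flow_scenario")
}

#' Centred super-Gaussian bolus initial condition
#'
#' A smooth, compactly concentrated blob exp(-(r/radius)^4): flat-topped like a
#' deposited contrast bolus, but with smooth shoulders that avoid ringing in
#' the explicit finite-difference stepping.
#'
#' @param grid An [lcfr_grid()].
#' @param radius Bolus radius in mm.
#' @param amplitude Peak concentration (a.u.).
#' @return An `nx x ny` matrix.
#' @export
bolus_init <- function(grid, radius = 8, amplitude = 1) {
  co <- grid_coords(grid)
  r2 <- outer(co$x^2, co$y^2, `+`)
  amplitude * exp(-(r2 / radius^2)^2)
}

#' Divergent (radially outward) flow phantom
#'
#' Unit-speed outward flow, u = (sqrt(2)/2) * (sign(x), sign(y)) mm/s, with
#' constant diffusion: the pattern expected of a high-pressure source region,
#' used to test whether advective and diffusive dispersion can be separated.
#'
#' @param grid An [lcfr_grid()]; coordinates are centred so x = y = 0 falls
#'   mid-domain.
#' @param D Diffusion coefficient (mm^2/s).
#' @param speed Component magnitude (mm/s); the default gives |u| = 1 mm/s.
#' @param bolus_radius,bolus_amplitude Passed to [bolus_init()].
#' @return A `flow_scenario`.
#' @export
make_divergent_field <- function(grid, D = 0.75, speed = sqrt(2) / 2,
                                 bolus_radius = 8, bolus_amplitude = 1) {
  co <- grid_coords(grid)
  sx <- sign(co$x); sy <- sign(co$y)
  ux <- speed * matrix(sx, grid$nx, grid$ny)
  uy <- speed * matrix(sy, grid$nx, grid$ny, byrow = TRUE)
  flow_scenario("divergent", grid, D, ux, uy,
                bolus_init(grid, bolus_radius, bolus_amplitude))
}

#' Poiseuille shear flow phantom
#'
#' Parabolic channel flow u_x = u_max * (1 - (y / half_width)^2), u_y = 0,
#' with no-slip walls at y = +/- half_width and constant diffusion. The
#' default initial condition is a channel-spanning stripe
#' (`exp(-(x / radius)^4)` at every y): a shear-flow validation should place
#' contrast in every lamina, since the slow near-wall flow is unidentifiable
#' wherever contrast never arrives. A centred bolus is available via
#' `init = "bolus"`.
#'
#' @param grid An [lcfr_grid()].
#' @param D Diffusion coefficient (mm^2/s).
#' @param u_max Mid-channel speed (mm/s).
#' @param half_width Channel half-width in mm (walls of the parabola).
#' @param bolus_radius,bolus_amplitude Stripe half-width / bolus radius (mm)
#'   and peak amplitude.
#' @param init `"stripe"` (default) or `"bolus"`.
#' @return A `flow_scenario`.
#' @export
make_poiseuille_field <- function(grid, D = 0.75, u_max = 2.5, half_width = 32,
                                  bolus_radius = 8, bolus_amplitude = 1,
                                  init = c("stripe", "bolus")) {
  init <- match.arg(init)
  co <- grid_coords(grid)
  prof <- pmax(u_max * (1 - (co$y / half_width)^2), 0)
  ux <- matrix(prof, grid$nx, grid$ny, byrow = TRUE)
  uy <- matrix(0, grid$nx, grid$ny)
  ic <- if (init == "stripe")
    matrix(bolus_amplitude * exp(-(co$x / bolus_radius)^4), grid$nx, grid$ny)
  else bolus_init(grid, bolus_radius, bolus_amplitude)
  flow_scenario("poiseuille", grid, D, ux, uy, ic)
}

#' True velocity-magnitude map of a flow scenario
#' @param scenario A `flow_scenario`.
#' @return An `nx x ny` matrix of |u| in mm/s.
#' @export
scenario_speed <- function(scenario) sqrt(scenario$ux^2 + scenario$uy^2)

# zero-filled matrix shift: entry (i, j) of result is m(i + di, j + dj)
shift_mat <- function(m, di, dj) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0, n, p)
  si <- max(1, 1 - di):min(n, n - di)
  sj <- max(1, 1 - dj):min(p, p - dj)
  out[si, sj] <- m[si + di, sj + dj]
  out
}

#' Explicit finite-difference advection-diffusion simulation
#'
#' Steps d(c)/dt = D * laplacian(c) - div(u c) with first-order upwind
#' advection in flux form, second-order central diffusion, and zero Dirichlet
#' boundaries. The saved 2D frames are replicated across `z_slices` identical
#' z-slices (with zero z-velocity) so that the full 3D estimation pipeline can
#' be exercised on the result; z-coefficients are then expected to vanish.
#'
#' @param scenario A `flow_scenario`.
#' @param grid Optionally override the scenario's grid.
#' @param z_slices Number of replicated z-slices in the output volume. The
#'   default (5) leaves one fully valid central slice for 3x3x3 windows after
#'   convolution with a z half-width-1 kernel.
#' @param z_spacing Voxel size along z in mm.
#' @return A [conc_image()] with frame interval `dt * save_stride`.
#' @export
simulate_advection_diffusion <- function(scenario, grid = scenario$grid,
                                         z_slices = 5L, z_spacing = grid$dx) {
  D <- scenario$D; ux <- scenario$ux; uy <- scenario$uy
  c0 <- scenario$init
  if (any(c0 < 0)) stop("initial condition must be nonnegative")
  umax <- max(abs(ux), abs(uy))
  cfl <- min(if (D > 0) min(grid$dx, grid$dy)^2 / (4 * D) else Inf,
             if (umax > 0) min(grid$dx, grid$dy) / umax else Inf)
  if (grid$dt > cfl)
    stop(sprintf("CFL stability violated: dt = %g s exceeds the stable limit %g s",
                 grid$dt, cfl), call. = FALSE)
  nx <- grid$nx; ny <- grid$ny
  dx <- grid$dx; dy <- grid$dy; dt <- grid$dt

  # face-centred velocities for flux-form upwind advection
  uxf <- (ux[-nx, , drop = FALSE] + ux[-1, , drop = FALSE]) / 2   # (nx-1) x ny
  uyf <- (uy[, -ny, drop = FALSE] + uy[, -1, drop = FALSE]) / 2   # nx x (ny-1)
  upx <- uxf > 0; upy <- uyf > 0

  zero_border <- function(m) { m[1, ] <- 0; m[nx, ] <- 0; m[, 1] <- 0; m[, ny] <- 0; m }
  cc <- zero_border(c0)
  n_saved <- length(seq(0L, grid$n_steps, by = grid$save_stride))
  frames <- array(0, dim = c(nx, ny, n_saved))
  frames[, , 1] <- cc
  k <- 1L
  for (step in seq_len(grid$n_steps)) {
    lap <- (shift_mat(cc, 1L, 0L) + shift_mat(cc, -1L, 0L) - 2 * cc) / dx^2 +
           (shift_mat(cc, 0L, 1L) + shift_mat(cc, 0L, -1L) - 2 * cc) / dy^2
    fx <- uxf * ifelse(upx, cc[-nx, , drop = FALSE], cc[-1, , drop = FALSE])
    fy <- uyf * ifelse(upy, cc[, -ny, drop = FALSE], cc[, -1, drop = FALSE])
    div <- matrix(0, nx, ny)
    div[2:(nx - 1), ] <- div[2:(nx - 1), ] +
      (fx[2:(nx - 1), , drop = FALSE] - fx[1:(nx - 2), , drop = FALSE]) / dx
    div[, 2:(ny - 1)] <- div[, 2:(ny - 1)] +
      (fy[, 2:(ny - 1), drop = FALSE] - fy[, 1:(ny - 2), drop = FALSE]) / dy
    cc <- zero_border(cc + dt * (D * lap - div))
    if (step %% grid$save_stride == 0L) {
      k <- k + 1L
      frames[, , k] <- cc
    }
  }
  vol <- array(frames, dim = c(nx, ny, 1L, n_saved))[, , rep(1L, z_slices), , drop = FALSE]
  conc_image(vol, spacing = c(dx, dy, z_spacing),
             frame_interval = dt * grid$save_stride)
}

#' Gamma-variate vascular input function
#'
#' A standard first-pass bolus shape, zero before arrival, normalised to unit
#' peak, with an optional slow recirculation/washout tail.
#'
#' @param times Sample times in seconds.
#' @param t0 Bolus-arrival time (s).
#' @param alpha Gamma-variate shape parameter.
#' @param beta Gamma-variate time scale (s); the first-pass peak occurs
#'   `alpha * beta` seconds after arrival.
#' @param amplitude Peak concentration (mM or a.u.).
#' @param recirc Amplitude fraction of the recirculation tail.
#' @param tau_rise,tau_wash Tail rise and washout time constants (s).
#' @return A [vif_series()] with `bat = t0`.
#' @export
gamma_variate_vif <- function(times, t0 = 20, alpha = 3, beta = 10,
                              amplitude = 1, recirc = 0.25,
                              tau_rise = 30, tau_wash = 300) {
  x <- pmax(times - t0, 0)
  gv <- (x / (alpha * beta))^alpha * exp(alpha - x / beta)
  tail <- recirc * (1 - exp(-x / tau_rise)) * exp(-x / tau_wash)
  v <- amplitude * (gv + tail)
  v[times <= t0] <- 0
  vif_series(times, v, bat = t0)
}

#' Quadrant extended Tofts-Kety scenario
#'
#' A piecewise-constant transfer-rate map split into four quadrants about the
#' domain centre, with scalar extravascular-extracellular and plasma volume
#' fractions and a shared vascular input function.
#'
#' @param grid An [lcfr_grid()] (only nx, ny, dx, dy are used).
#' @param ktrans Length-4 quadrant values of K^trans in 1/s, assigned
#'   counter-clockwise from the (+x, +y) quadrant.
#' @param ve Extravascular-extracellular volume fraction (0 < ve <= 1).
#' @param vp Plasma volume fraction (0 <= vp <= 1).
#' @param vif A [vif_series()] sampled at the simulation frame times.
#' @param dt Frame interval in seconds.
#' @return An object of class `tofts_scenario`.
#' @export
make_tofts_scenario <- function(grid, ktrans = c(0.1, 0.2, 0.4, 1),
                                ve = 0.5, vp = 0.05, vif = NULL, dt = 3.75) {
  stopifnot(ve > 0, ve <= 1, vp >= 0, vp <= 1, all(ktrans >= 0),
            length(ktrans) == 4)
  co <- grid_coords(grid)
  xpos <- matrix(co$x >= 0, grid$nx, grid$ny)
  ypos <- matrix(co$y >= 0, grid$nx, grid$ny, byrow = TRUE)
  km <- matrix(NA_real_, grid$nx, grid$ny)
  km[xpos & ypos]   <- ktrans[1]
  km[!xpos & ypos]  <- ktrans[2]
  km[!xpos & !ypos] <- ktrans[3]
  km[xpos & !ypos]  <- ktrans[4]
  if (is.null(vif)) vif <- gamma_variate_vif((seq_len(50L) - 1L) * dt)
  structure(list(name = "tofts", grid = grid, ktrans_map = km, ve = ve,
                 vp = vp, vif = vif, dt = dt),
            class = "tofts_scenario")
}

#' Forward simulation of extended Tofts-Kety dynamics
#'
#' Integrates, independently per voxel,
#' `dc/dt = Ktrans * VIF(t) - Kep * c + vp * dVIF/dt` with
#' `Kep = Ktrans / ve`, sampled at the scenario frame interval. The default
#' integrator applies the exact exponential update of the linear ODE with the
#' VIF interpolated linearly within each frame (the efflux rates reach
#' 2 1/s, for which a plain forward-Euler step at the 3.75 s frame interval is
#' unstable); `method = "euler"` performs forward Euler on `n_substeps`
#' internal substeps per frame.
#'
#' @param scenario A [make_tofts_scenario()] object.
#' @param grid Optionally override the scenario grid.
#' @param z_slices Replicated z-slices in the output (see
#'   [simulate_advection_diffusion()]).
#' @param z_spacing Voxel size along z in mm.
#' @param method `"exact"` (default) or `"euler"`.
#' @param n_substeps Internal substeps per frame for the Euler integrator.
#' @return A [conc_image()] whose frames align with `scenario$vif$times`.
#' @export
simulate_extended_tofts <- function(scenario, grid = scenario$grid,
                                    z_slices = 5L, z_spacing = grid$dx,
                                    method = c("exact", "euler"),
                                    n_substeps = 1L) {
  method <- match.arg(method)
  vif <- scenario$vif
  nt <- length(vif$values)
  if (any(abs(diff(vif$times) - scenario$dt) > 1e-9))
    stop("VIF must be sampled at the scenario frame interval dt")
  km <- scenario$ktrans_map
  kep <- km / scenario$ve
  h <- scenario$dt
  nx <- grid$nx; ny <- grid$ny
  ct <- matrix(0, nx, ny)                # interstitial compartment
  frames <- array(0, dim = c(nx, ny, nt))
  frames[, , 1] <- ct + scenario$vp * vif$values[1]
  if (method == "exact") {
    E <- exp(-kep * h)
    # int_0^h (a + b s) exp(-kep (h - s)) ds, for VIF(t_n + s) = a + b s
    pos <- kep > 0
    w_a <- ifelse(pos, (1 - E) / ifelse(pos, kep, 1), h)
    w_b <- ifelse(pos, (h - w_a) / ifelse(pos, kep, 1), h^2 / 2)
    for (n in seq_len(nt - 1L)) {
      a <- vif$values[n]
      b <- (vif$values[n + 1L] - vif$values[n]) / h
      ct <- ct * E + km * (a * w_a + b * w_b)
      frames[, , n + 1L] <- ct + scenario$vp * vif$values[n + 1L]
    }
  } else {
    stopifnot(n_substeps >= 1)
    hs <- h / n_substeps
    for (n in seq_len(nt - 1L)) {
      a <- vif$values[n]
      b <- (vif$values[n + 1L] - vif$values[n]) / h
      for (m in seq_len(n_substeps)) {
        v <- a + b * (m - 1L) * hs
        ct <- ct + hs * (km * v - kep * ct)
      }
      frames[, , n + 1L] <- ct + scenario$vp * vif$values[n + 1L]
    }
  }
  vol <- array(frames, dim = c(nx, ny, 1L, nt))[, , rep(1L, z_slices), , drop = FALSE]
  conc_image(vol, spacing = c(grid$dx, grid$dy, z_spacing), frame_interval = h)
}

#' Additive Gaussian noise specification
#'
#' @param strength Noise level as a fraction of the global spatiotemporal
#'   signal maximum (>= 0); the noise standard deviation is
#'   `strength * max(c)`.
#' @param seed Base RNG seed.
#' @param n_instantiations Number of independent noise draws in sweeps (>= 1).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(strength, seed = 1L, n_instantiations = 1L) {
  stopifnot(strength >= 0, n_instantiations >= 1)
  structure(list(strength = strength, seed = as.integer(seed),
                 n_instantiations = as.integer(n_instantiations)),
            class = "noise_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Add i.i.d. Gaussian noise scaled to the signal maximum
#'
#' The noise standard deviation is `strength * max(c)` over all voxels and
#' frames. Draws are reproducible: instantiation `i` of a sweep uses seed
#' `seed + i - 1`.
#'
#' @param image A [conc_image()] (or 4D array).
#' @param noise A [noise_spec()], or a numeric strength.
#' @param instantiation Which noise instantiation to draw (1-based).
#' @return An object of the same type as `image`.
#' @export
add_noise <- function(image, noise, instantiation = 1L) {
  if (is.numeric(noise)) noise <- noise_spec(noise)
  dat <- as_image_data(image)
  if (!all(is.finite(dat))) stop("image must be finite-valued")
  if (noise$strength == 0) return(image)
  sigma <- noise$strength * max(dat)
  eps <- with_seed(noise$seed + as.integer(instantiation) - 1L,
                   array(stats::rnorm(length(dat), sd = sigma), dim = dim(dat)))
  out <- dat + eps
  if (inherits(image, "conc_image")) { image$data <- out; image } else out
}
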