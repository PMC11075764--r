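# Shared fixtures: everything is generated in code at test time.

small_grid <- function(nx = 24, ny = 24, n_steps = 16, dt = 0.125,
                       save_stride = 1) {
  lcfr_grid(nx = nx, ny = ny, dx = 1, dy = 1, dt = dt, n_steps = n_steps,
            save_stride = save_stride)
}

# smooth random 4D field: white noise convolved with a separable box filter,
# deterministic under the given seed
smooth_field <- function(dims, seed = 1, passes = 2) {
  set.seed(seed)
  a <- array(rnorm(prod(dims)), dim = dims)
  for (p in seq_len(passes))
    for (ax in seq_along(dims))
      if (dims[ax] >= 5) a <- lcfr:::conv_axis(a, rep(0.2, 5), ax)
  a
}

# analytic free-space 2D Gaussian diffusion solution, replicated over z
gaussian_diffusion_image <- function(nx = 48, ny = 48, nz = 5, nt = 40,
                                     D = 0.75, t0 = 15, dt_frame = 1,
                                     dx = 1) {
  x <- (seq_len(nx) - (nx + 1) / 2) * dx
  y <- (seq_len(ny) - (ny + 1) / 2) * dx
  r2 <- outer(x^2, y^2, `+`)
  tt <- t0 + (seq_len(nt) - 1) * dt_frame
  a <- array(0, c(nx, ny, nz, nt))
  for (k in seq_len(nt)) {
    sl <- exp(-r2 / (4 * D * tt[k])) / (4 * pi * D * tt[k])
    a[, , , k] <- sl
  }
  conc_image(a, spacing = c(dx, dx, dx), frame_interval = dt_frame)
}

# hand-built library stack with random smooth columns and an exact target,
# for self-consistency oracles
synthetic_stack <- function(xi_true, dims = c(11, 11, 5, 9),
                            margins = c(2, 2, 1, 2), seed = 42) {
  k <- length(xi_true)
  cols <- lapply(seq_len(k), function(i) smooth_field(dims, seed = seed + i))
  target <- Reduce(`+`, Map(function(a, w) a * w, cols, xi_true))
  terms <- c("cxx", "cyy", "czz", "cx", "cy", "cz", "c0", "vif0", "vift")[seq_len(k)]
  names(cols) <- terms
  structure(list(columns = cols, target = target, terms = terms,
                 dims = dims, margins = as.integer(margins),
                 tf = NULL, frame_interval = 1, spacing = c(1, 1, 1)),
            class = "library_stack")
}

# tiny image with one synthetic "artery" voxel and slow background tissue
vif_phantom <- function(nt = 30, frame_interval = 2) {
  times <- (seq_len(nt) - 1) * frame_interval
  artery <- ifelse(times < 6, 0, pmin((times - 6) / 4, 1)) * 10 *
    exp(-pmax(times - 14, 0) / 60)
  tissue <- ifelse(times < 30, 0, (times - 30) / 40) # late, slow, low
  a <- array(rep(tissue, each = 5 * 5 * 3), dim = c(5, 5, 3, nt))
  a[3, 3, 2, ] <- artery
  list(conc = conc_image(a, frame_interval = frame_interval),
       artery = artery, times = times)
}
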