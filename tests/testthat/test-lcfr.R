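test_that("library stack has the contracted shape and content", {
  dims <- c(12, 12, 3, 20)
  tf <- build_test_function(c(2, 2, 1, 2), c(4, 4, 3, 3), rep(1, 4))
  zero <- array(0, dims)
  times <- 0:19
  vif <- vif_series(times, exp(-(times - 8)^2 / 10))
  stack <- assemble_library(conc_image(zero), vif = vif, tf = tf)
  expect_setequal(stack$terms,
                  c("cxx", "cyy", "czz", "cx", "cy", "cz", "c0", "vif0", "vift"))
  for (cl in stack$columns) expect_equal(dim(cl), dims)
  expect_equal(dim(stack$target), dims)
  # zero data: all c-columns vanish, VIF columns do not
  for (tm in c("cxx", "cx", "c0")) expect_true(all(stack$columns[[tm]] == 0))
  expect_gt(max(abs(stack$columns$vif0)), 0)

  # pure plasma compartment c = VIF(t): weak d/dt of c equals the VIF~t column
  vfield <- array(rep(vif$values, each = prod(dims[1:3])), dims)
  st2 <- assemble_library(conc_image(vfield), vif = vif, tf = tf)
  ok <- array(TRUE, dims)
  m <- st2$margins
  for (a in 1:4) {
    id <- slice.index(ok, a); ok <- ok & id > m[a] & id <= dims[a] - m[a]
  }
  expect_equal(st2$target[ok], st2$columns$vift[ok], tolerance = 1e-12)

  expect_error(assemble_library(conc_image(zero),
                                vif = vif_series(0:10, rep(1, 11)), tf = tf),
               "length")
  # six-column transport library by default without a VIF
  st3 <- assemble_library(conc_image(zero), tf = tf)
  expect_equal(st3$terms, c("cxx", "cyy", "czz", "cx", "cy", "cz"))
})

test_that("coefficients are recovered exactly on library-generated data", {
  xi <- c(0.8, -0.3, 0.1, 1.2, -0.7, 0.25, -0.05, 0.4, 0.05)
  stack <- synthetic_stack(xi)
  fv <- fit_voxel(stack, c(6, 6, 3))
  expect_false(fv$flag)
  expect_lt(max(abs(fv$coef - xi)) / max(abs(xi)), 1e-8)
  expect_lt(fv$residual, 1e-10)

  # the volume (Gram-matrix) path agrees with the explicit-design path
  cm <- fit_volume(stack, trim = c(3, 3, 1))
  v <- which(cm$valid, arr.ind = TRUE)
  expect_gt(nrow(v), 0)
  for (r in seq_len(min(5, nrow(v)))) {
    idx <- v[r, ]
    ref <- fit_voxel(stack, idx)
    got <- vapply(cm$maps, function(m) m[idx[1], idx[2], idx[3]], numeric(1))
    expect_equal(unname(got), unname(ref$coef), tolerance = 1e-6)
  }
})

test_that("degenerate windows are flagged, zero columns dropped as zeros", {
  xi <- c(0.5, -0.2, 0.3)
  stack <- synthetic_stack(xi)
  stack$columns <- lapply(stack$columns, function(a) { a[] <- 0; a })
  stack$target[] <- 0
  fv <- fit_voxel(stack, c(6, 6, 3))
  expect_true(fv$flag)
  expect_true(all(is.na(fv$coef)))

  # a single identically zero column yields coefficient 0, not a failure
  stack2 <- synthetic_stack(c(0.5, -0.2, 0.3, 0.7))
  stack2$columns[[2]][] <- 0
  stack2$target <- Reduce(`+`, Map(`*`, stack2$columns, c(0.5, 0, 0.3, 0.7)))
  fv2 <- fit_voxel(stack2, c(6, 6, 3))
  expect_false(fv2$flag)
  expect_equal(unname(fv2$coef), c(0.5, 0, 0.3, 0.7), tolerance = 1e-8)
})

test_that("window outside the valid region is rejected", {
  stack <- synthetic_stack(c(1, 2))
  expect_error(fit_voxel(stack, c(3, 6, 3)), "valid region")
  expect_error(fit_volume(stack, mask = array(FALSE, c(11, 11, 5))), "empty")
})

test_that("noiseless diffusion data yields near-zero velocity coefficients", {
  D <- 0.75
  img <- gaussian_diffusion_image(nx = 40, ny = 40, nz = 5, nt = 30, D = D,
                                  t0 = 25, dt_frame = 1)
  fit <- recover_transport(img, support = c(6, 6, 1, 6),
                           degrees = c(4, 4, 3, 3))
  sel <- fit$physical$valid
  # velocity contamination under 1% of the diffusion scale D / dx
  expect_lt(stats::median(fit$physical$maps$speed[sel]), 0.01 * D / 1)
  expect_equal(stats::median(fit$physical$maps$D_x[sel]), D, tolerance = 0.02)
  expect_equal(stats::median(fit$physical$maps$D_y[sel]), D, tolerance = 0.02)
})

test_that("fitting is deterministic and local", {
  cfg <- default_config()
  cfg$grid$nx <- 32L; cfg$grid$ny <- 32L; cfg$grid$n_steps <- 48L
  sim <- simulate_scenario("divergent", cfg)
  noisy <- add_noise(sim$conc, noise_spec(0.01, seed = 5))
  f1 <- recover_transport(noisy, support = c(3, 3, 1, 3))
  f2 <- recover_transport(noisy, support = c(3, 3, 1, 3))
  expect_identical(f1$coef$maps, f2$coef$maps)

  # perturbing data beyond (support + window) of a voxel leaves it unchanged
  tf <- f1$tf
  st <- assemble_library(noisy, tf = tf)
  ref <- fit_voxel(st, c(16, 16, 3))
  pert <- noisy
  pert$data[28, 28, 3, ] <- pert$data[28, 28, 3, ] + 10
  st2 <- assemble_library(pert, tf = tf)
  expect_identical(fit_voxel(st2, c(16, 16, 3))$coef, ref$coef)
})

test_that("divergent flow is recovered radially outward; transposition permutes axes", {
  cfg <- default_config()
  cfg$grid$n_steps <- 96L
  sim <- simulate_scenario("divergent", cfg)
  noisy <- add_noise(sim$conc, noise_spec(0.001, seed = 2))
  fit <- recover_transport(noisy)
  pm <- fit$physical
  sel <- pm$valid & mask_enhancing(sim$conc)
  co <- grid_coords(sim$scenario$grid)
  xs <- array(co$x, dim(pm$valid))
  ys <- array(rep(co$y, each = 64), dim(pm$valid))
  # radial outwardness: u . x_hat > 0 for the overwhelming majority, in all
  # four quadrants (stay away from the sign-change axes)
  away <- abs(xs) > 4 & abs(ys) > 4
  proj <- (pm$maps$u_x * sign(xs) + pm$maps$u_y * sign(ys))[sel & away]
  expect_gt(mean(proj > 0), 0.99)
  for (qx in c(-1, 1)) for (qy in c(-1, 1)) {
    qsel <- sel & away & (sign(xs) == qx) & (sign(ys) == qy)
    expect_gt(mean((pm$maps$u_x * qx + pm$maps$u_y * qy)[qsel] > 0), 0.98)
  }

  # x <-> y transposition of the data permutes the velocity components
  tdat <- aperm(noisy$data, c(2, 1, 3, 4))
  tfit <- recover_transport(conc_image(tdat, noisy$spacing,
                                       noisy$frame_interval))
  expect_equal(tfit$physical$maps$u_x, aperm(pm$maps$u_y, c(2, 1, 3)),
               tolerance = 1e-10)
  expect_equal(tfit$physical$maps$u_y, aperm(pm$maps$u_x, c(2, 1, 3)),
               tolerance = 1e-10)
})

test_that("physical mapping applies the advective sign convention", {
  xi <- c(0.75, 0.75, 0, -1, 0, 0)   # xi_u = (-1, 0, 0) => u = (1, 0, 0)
  stack <- synthetic_stack(xi, dims = c(9, 9, 5, 9), margins = c(2, 2, 1, 2))
  stack$target <- Reduce(`+`, Map(`*`, stack$columns, xi))
  cm <- fit_volume(stack, trim = c(3, 3, 1))
  pm <- coefficients_to_physical(cm)
  v <- which(pm$valid)[1]
  expect_equal(pm$maps$u_x[v], 1, tolerance = 1e-6)
  expect_equal(pm$maps$u_y[v], 0, tolerance = 1e-6)
  expect_equal(pm$maps$speed[v], 1, tolerance = 1e-6)
  expect_equal(pm$maps$D_x[v], 0.75, tolerance = 1e-6)
})

test_that("a diffusion gradient masquerades as advection (documented confound)", {
  # c_t = d/dx(D(x) dc/dx) = D c_xx + D'(x) c_x: with linear D and u = 0 the
  # recovered |xi_u| approaches |grad D|
  nx <- 48; ny <- 16; nz <- 5; nt <- 60
  dx <- 1; dt <- 0.05
  x <- (seq_len(nx) - (nx + 1) / 2) * dx
  Dx <- 0.5 + 0.02 * (x - min(x))          # grad D = 0.02 mm/s
  cc <- matrix(rep(exp(-x^2 / 36), ny), nx, ny)
  frames <- array(0, c(nx, ny, nt))
  frames[, , 1] <- cc
  for (k in 2:nt) {
    for (sub in 1:5) {
      dcdx <- (rbind(cc[-1, ], 0) - rbind(0, cc[-nx, ])) / (2 * dx)
      flux <- Dx * dcdx
      div <- (rbind(flux[-1, ], 0) - rbind(0, flux[-nx, ])) / (2 * dx)
      cc <- cc + (dt / 5) * div
    }
    frames[, , k] <- cc
  }
  vol <- array(frames, c(nx, ny, 1, nt))[, , rep(1, nz), ]
  img <- conc_image(vol, spacing = c(dx, dx, dx), frame_interval = dt)
  fit <- recover_transport(img, support = c(5, 3, 1, 5))
  sel <- fit$physical$valid
  med_u <- stats::median(abs(fit$physical$maps$u_x[sel]))
  expect_equal(med_u, 0.02, tolerance = 0.5)   # order of |grad D|, not zero
  expect_gt(med_u, 0.005)
})

test_that("recovery metrics have their closed forms", {
  pm <- structure(list(
    maps = list(speed = array(1, c(4, 4, 1))),
    valid = array(TRUE, c(4, 4, 1)),
    units = c(speed = "mm/s")), class = "physical_maps")
  m0 <- summarize_recovery(pm, truth = list(speed = array(1, c(4, 4, 1))))
  expect_equal(m0$rmse, 0)
  expect_equal(m0$median_rel_err, 0)
  # constant bias b: RMSE = b
  mb <- summarize_recovery(pm, truth = list(speed = array(1 - 0.2, c(4, 4, 1))))
  expect_equal(mb$rmse, 0.2)
  # scaling by 1.1: median relative error 10%
  pm$maps$speed <- array(1.1, c(4, 4, 1))
  ms <- summarize_recovery(pm, truth = list(speed = array(1, c(4, 4, 1))))
  expect_equal(ms$median_rel_err, 10, tolerance = 1e-9)
})

test_that("tidy and glance expose the fit as tibbles", {
  stack <- synthetic_stack(c(0.5, -0.2, 0.3))
  cm <- fit_volume(stack, trim = c(3, 3, 1))
  td <- tidy(cm)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$term), c("cxx", "cyy", "czz"))
  expect_equal(nrow(td), 3 * sum(cm$valid))
  gl <- glance(cm)
  expect_equal(gl$n_valid, sum(cm$valid))
  pm <- coefficients_to_physical(cm)
  tp <- tidy(pm)
  expect_true(all(c("parameter", "estimate", "units") %in% names(tp)))
})
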