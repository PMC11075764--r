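test_that("grid and scenario constructors validate their invariants", {
  expect_error(lcfr_grid(nx = 4), "8 x 8")
  expect_error(lcfr_grid(dt = -1))
  g <- small_grid()
  expect_equal(mean(grid_coords(g)$x), 0)   # centred domain
  bad <- make_divergent_field(g)
  bad_init <- bad$init; bad_init[1, 1] <- -1
  expect_error(flow_scenario("x", g, 0.75, bad$ux, bad$uy, bad_init),
               "nonnegative")
})

test_that("divergent field has unit speed and quadrant sign symmetry", {
  g <- lcfr_grid(nx = 64, ny = 64)
  sc <- make_divergent_field(g)
  co <- grid_coords(g)
  i <- which.min(abs(co$x - 5.5)); j <- which.min(abs(co$y - 5.5))
  i2 <- which.min(abs(co$x + 5.5))
  expect_equal(c(sc$ux[i, j], sc$uy[i, j]), c(0.7071, 0.7071), tolerance = 1e-4)
  expect_equal(scenario_speed(sc)[i, j], 1, tolerance = 1e-12)
  expect_equal(c(sc$ux[i2, j], sc$uy[i2, j]), c(-0.7071, 0.7071),
               tolerance = 1e-4)
  expect_true(all(abs(scenario_speed(sc) - 1) < 1e-12))  # |u| = 1 everywhere
  expect_equal(sc$D, 0.75)
})

test_that("poiseuille profile is parabolic with no-slip walls", {
  g <- lcfr_grid(nx = 65, ny = 65)   # odd grid: integer-mm cell centres
  sc <- make_poiseuille_field(g)
  co <- grid_coords(g)
  expect_equal(max(sc$ux), 2.5)                    # peak 2.5 mm/s at y = 0
  j16 <- which(co$y == 16)
  expect_equal(sc$ux[1, j16], 2.5 * (1 - 0.25))    # 1.875 mm/s at y = 16
  j32 <- which(co$y == 32)
  expect_equal(sc$ux[1, j32], 0)                   # no-slip wall at y = 32
  expect_true(all(sc$uy == 0))
})

test_that("advection-diffusion stepping honours conservation and transport", {
  g <- small_grid(n_steps = 20)
  sc0 <- make_divergent_field(g, D = 0, bolus_radius = 5)
  sc0$ux[] <- 0; sc0$uy[] <- 0
  out <- simulate_advection_diffusion(sc0, z_slices = 3)
  # no dynamics: every frame equals the (border-zeroed) initial condition
  for (k in c(2, 10, 21)) expect_equal(out$data[, , 1, k], out$data[, , 1, 1])

  # pure diffusion: nonnegative, mass non-increasing under zero Dirichlet
  scd <- make_divergent_field(g, D = 0.75, bolus_radius = 5)
  scd$ux[] <- 0; scd$uy[] <- 0
  outd <- simulate_advection_diffusion(scd, z_slices = 3)
  mass <- apply(outd$data[, , 1, ], 3, sum)
  expect_true(all(diff(mass) <= 1e-12))
  expect_true(all(outd$data >= -1e-15))

  # pure advection: centroid moves at u * t; mass conserved away from walls
  sca <- make_divergent_field(g, D = 0, bolus_radius = 4)
  sca$ux[] <- 1; sca$uy[] <- 0
  outa <- simulate_advection_diffusion(sca, z_slices = 3)
  co <- grid_coords(g)
  centroid_x <- function(f) sum(co$x * rowSums(f)) / sum(f)
  tt <- 10 * g$dt
  drift <- centroid_x(outa$data[, , 1, 11]) - centroid_x(outa$data[, , 1, 1])
  expect_equal(drift, 1 * tt, tolerance = g$dx)      # within one voxel
  massa <- apply(outa$data[, , 1, ], 3, sum)
  expect_lt(abs(massa[11] / massa[1] - 1), 0.01)     # < 1% over 10 steps
})

test_that("CFL violations and bad inputs are rejected", {
  g <- lcfr_grid(nx = 24, ny = 24, dt = 0.5, n_steps = 4)   # dt > dx^2/(4D)
  sc <- make_divergent_field(g, D = 0.75)
  expect_error(simulate_advection_diffusion(sc), "CFL")
  g2 <- lcfr_grid(nx = 24, ny = 24, dt = 0.5, n_steps = 4)
  sc2 <- make_poiseuille_field(g2, D = 0)                   # dt > dx/2.5
  expect_error(simulate_advection_diffusion(sc2), "CFL")
})

test_that("extended Tofts-Kety dynamics match their closed forms", {
  g <- lcfr_grid(nx = 8, ny = 8, dt = 3.75, n_steps = 39)
  times <- (0:39) * 3.75
  # plateau VIF switched on at t = 0
  vif <- vif_series(times, rep(2, 40))

  # no transfer, no plasma: identically zero
  sc0 <- make_tofts_scenario(g, ktrans = rep(0, 4), ve = 0.5, vp = 0,
                             vif = vif)
  expect_true(all(simulate_extended_tofts(sc0, z_slices = 1)$data == 0))

  # no transfer: pure plasma compartment c = vp * VIF exactly
  scp <- make_tofts_scenario(g, ktrans = rep(0, 4), ve = 0.5, vp = 0.05,
                             vif = vif)
  outp <- simulate_extended_tofts(scp, z_slices = 1)
  expect_equal(as.vector(outp$data[3, 3, 1, ]), 0.05 * vif$values)

  # constant input: exact integrator reproduces the analytic solution
  # c_t(t) = ve * V * (1 - exp(-Kep t)), approaching equilibrium ve * V
  sck <- make_tofts_scenario(g, ktrans = rep(1, 4), ve = 0.5, vp = 0,
                             vif = vif)
  outk <- simulate_extended_tofts(sck, z_slices = 1)
  kep <- 1 / 0.5
  analytic <- 0.5 * 2 * (1 - exp(-kep * times))
  expect_equal(as.vector(outk$data[3, 3, 1, ]), analytic, tolerance = 1e-12)
  expect_equal(outk$data[3, 3, 1, 40], 0.5 * 2, tolerance = 1e-9)

  # Euler with substeps converges to the exact integrator at first order
  sce <- make_tofts_scenario(g, ktrans = c(0.1, 0.2, 0.4, 1), ve = 0.5,
                             vp = 0.05,
                             vif = gamma_variate_vif(times, t0 = 18.75))
  ex <- simulate_extended_tofts(sce, z_slices = 1)$data
  e1 <- simulate_extended_tofts(sce, z_slices = 1, method = "euler",
                                n_substeps = 64)$data
  e2 <- simulate_extended_tofts(sce, z_slices = 1, method = "euler",
                                n_substeps = 128)$data
  err1 <- max(abs(e1 - ex)); err2 <- max(abs(e2 - ex))
  expect_equal(err1 / err2, 2, tolerance = 0.15)
  # Richardson check of the exact integrator: the only discretisation error
  # is the within-step linear VIF interpolation (second order), so halving
  # the step twice pins the solution to < 0.1% of the signal scale
  at_dt <- function(h) {
    tt <- seq(0, max(times), by = h)
    gg <- lcfr_grid(nx = 8, ny = 8, dt = h, n_steps = length(tt) - 1L)
    sch <- make_tofts_scenario(gg, ktrans = c(0.1, 0.2, 0.4, 1), ve = 0.5,
                               vp = 0.05,
                               vif = gamma_variate_vif(tt, t0 = 18.75), dt = h)
    simulate_extended_tofts(sch, z_slices = 1)$data
  }
  s2 <- at_dt(3.75 / 2); s4 <- at_dt(3.75 / 4)
  i2 <- seq(1, dim(s2)[4], by = 2); i4 <- seq(1, dim(s4)[4], by = 4)
  d1 <- max(abs(s2[, , 1, i2] - ex[, , 1, ]))
  d2 <- max(abs(s4[, , 1, i4] - s2[, , 1, seq(1, dim(s2)[4], by = 2)]))
  expect_equal(d1 / d2, 4, tolerance = 0.3)          # second-order convergence
  expect_lt(d2 / (3 * max(ex)), 1e-3)               # Richardson error estimate

  # VIF sampling mismatch is rejected
  bad <- sce; bad$vif <- vif_series(times * 2, vif$values)
  expect_error(simulate_extended_tofts(bad), "frame interval")
})

test_that("quadrant Ktrans layout covers the four stated rates", {
  g <- lcfr_grid(nx = 16, ny = 16)
  sc <- make_tofts_scenario(g)
  expect_setequal(unique(as.vector(sc$ktrans_map)), c(0.1, 0.2, 0.4, 1))
  expect_equal(sort(unique(as.vector(table(sc$ktrans_map)))), 64)  # equal areas
})

test_that("additive noise is scaled to the global maximum and reproducible", {
  img <- conc_image(array(runif(20 * 20 * 3 * 30), c(20, 20, 3, 30)) * 2)
  expect_identical(add_noise(img, 0)$data, img$data)
  n1 <- add_noise(img, noise_spec(0.01, seed = 9))
  n2 <- add_noise(img, noise_spec(0.01, seed = 9))
  expect_identical(n1$data, n2$data)
  n3 <- add_noise(img, noise_spec(0.01, seed = 9), instantiation = 2)
  expect_false(identical(n1$data, n3$data))

  # empirical residual sd ~ strength * max over >= 1e5 voxels, and the
  # residuals look Gaussian: mean within 3 sigma / sqrt(n), variance within 5%
  big <- conc_image(array(runif(50 * 50 * 5 * 10), c(50, 50, 5, 10)) * 2)
  resid <- add_noise(big, noise_spec(0.01, seed = 4))$data - big$data
  sigma <- 0.01 * max(big$data)
  n <- length(resid)
  expect_gte(n, 1e5)
  expect_equal(sd(resid), sigma, tolerance = 0.025)
  expect_lt(abs(mean(resid)), 3 * sigma / sqrt(n))
  expect_lt(abs(var(resid) / sigma^2 - 1), 0.05)
})
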