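test_that("pressure gradient vanishes for a uniform steady field", {
  tb <- small_tube(n_phases = 3, vz = 0.8)
  g <- pressure_gradient(tb$field, tb$mask)
  expect_lt(max(abs(g$values)), 1e-12)
  expect_true(all(vapply(g$face, function(fp) max(abs(unlist(fp))),
                         numeric(1)) < 1e-12))
})

test_that("solid-body rotation yields the centripetal pressure gradient", {
  ## v_theta = Omega r over (almost) the whole tube: radial G = rho Omega^2 r
  sp <- phantom_spec(shape = c(17, 17, 9), radius_mm = 14, v_mean = 0,
                     n_phases = 2,
                     swirl = list(r_core_mm = 13.9, omega = 50, sign = 1,
                                  phases = 1:2, band_mm = c(0, 18)))
  ph <- make_tube_phantom(sp)
  g <- pressure_gradient(ph$field, ph$mask)
  co <- helixflow:::grid_coords(ph$mask$dim, ph$mask$spacing)
  cx <- (17 - 1) / 2 * 2
  rx <- co[, 1] - cx; ry <- co[, 2] - cx
  r <- sqrt(rx^2 + ry^2)
  ## interior voxels, away from axis, wall, and tube ends
  sel <- which(ph$mask$voxels & r >= 4 & r <= 9 &
               co[, 3] >= 6 & co[, 3] <= 10)
  gx <- g$values[, , , 1, 1][sel]; gy <- g$values[, , , 2, 1][sel]
  g_rad <- (gx * rx[sel] + gy * ry[sel]) / r[sel]       # mmHg/mm
  expected <- 1060 * 50^2 * (r[sel] / 1000) / (133.322 * 1000)
  expect_equal(g_rad, expected, tolerance = 0.02)
})

test_that("a uniform temporal ramp gives G = -rho a", {
  tb <- small_tube(shape = c(7, 7, 7), n_phases = 6, dt = 40)
  a_mps2 <- 2                       # m/s^2
  f <- tb$field
  for (p in 1:6) f$values[, , , 3, p] <- a_mps2 * (p - 1) * 0.04
  g <- pressure_gradient(f, tb$mask)
  expected <- -1060 * a_mps2 / (133.322 * 1000)   # mmHg/mm
  ## interior phases (the cyclic wrap breaks the ramp at the ends)
  in_vox <- which(tb$mask$voxels)
  for (p in 2:5)
    expect_equal(g$values[, , , 3, p][in_vox],
                 rep(expected, length(in_vox)), tolerance = 0.01)
})

test_that("zero gradient solves to zero pressure; constant gradient to a ramp", {
  tb <- small_tube(shape = c(7, 7, 17), radius = 5)
  z0 <- array(0, c(tb$mask$dim, 3, 2))
  pm <- solve_relative_pressure(z0, tb$mask)
  expect_equal(max(abs(pm$values)), 0)
  expect_true(all(pm$converged))

  gz <- 0.05                        # mmHg/mm
  gr <- z0; gr[, , , 3, ] <- gz
  pm <- solve_relative_pressure(gr, tb$mask)
  idx <- which(tb$mask$voxels)
  z <- helixflow:::grid_coords(tb$mask$dim, tb$mask$spacing)[idx, 3]
  p1 <- pm$values[, , , 1][idx]
  fit <- stats::lm(p1 ~ z)
  expect_equal(unname(stats::coef(fit)[2]), gz, tolerance = 0.01)
  expect_gt(summary(fit)$r.squared, 0.999)
  ## Neumann gauge: zero mean per phase
  expect_lt(abs(mean(p1)), 1e-9)
})

test_that("halving the tolerance monotonically reduces the closed-form error", {
  tb <- small_tube(shape = c(7, 7, 17), radius = 5)
  gr <- array(0, c(tb$mask$dim, 3, 2)); gr[, , , 3, ] <- 0.05
  idx <- which(tb$mask$voxels)
  z <- helixflow:::grid_coords(tb$mask$dim, tb$mask$spacing)[idx, 3]
  truth <- 0.05 * z; truth <- truth - mean(truth)
  errs <- vapply(c(1e-2, 5e-3, 2.5e-3, 1e-5), function(tol) {
    pm <- suppressWarnings(
      solve_relative_pressure(gr, tb$mask, case_config(tolerance = tol)))
    sqrt(mean((pm$values[, , , 1][idx] - truth)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("degenerate mask (no face neighbours) is rejected", {
  vox <- array(FALSE, c(5, 5, 5))
  vox[cbind(c(1, 3, 5), c(1, 3, 5), c(1, 3, 5))] <- TRUE   # isolated voxels
  mask <- seg_mask(vox, c(2, 2, 2))
  tb_field <- velocity_field(array(0.1, c(5, 5, 5, 3, 2)), c(2, 2, 2),
                             40, 80)
  expect_error(pressure_gradient(tb_field, mask), "degenerate")
})

test_that("postprocessing: smoothing, clamping and centring behave as defined", {
  tb <- small_tube(shape = c(9, 9, 9), radius = 7)
  m <- tb$mask$voxels
  ## constant map: unchanged by smoothing, exactly centred afterwards
  v4 <- array(0, c(tb$mask$dim, 2))
  for (p in 1:2) { v <- array(0, tb$mask$dim); v[m] <- 3.7; v4[, , , p] <- v }
  pp <- postprocess_pressure(make_pm(v4, tb$mask))
  expect_lt(max(abs(pp$values[, , , 1][m])), 1e-12)
  expect_equal(pp$mean_shift, 3.7)

  ## unit impulse deep inside the mask: (1/2)^3 at the centre after smoothing
  v4 <- array(0, c(tb$mask$dim, 2))
  v4[5, 5, 5, 1] <- 1
  sm <- helixflow:::binomial_smooth3(v4[, , , 1], m)
  expect_equal(sm[5, 5, 5], 1 / 8)
  ## smoothing conserves the sum for constant fields (renormalized weights)
  cst <- array(0, tb$mask$dim); cst[m] <- 2
  expect_equal(sum(helixflow:::binomial_smooth3(cst, m)[m]), sum(cst[m]))
})

test_that("clamp bounds are the linear-interpolation quantiles and mean is 0", {
  ## 100 interior voxels valued 1..100, far enough apart not to smooth
  vox <- array(TRUE, c(5, 5, 4))
  mask <- seg_mask(vox, c(2, 2, 2))
  v4 <- array(0, c(5, 5, 4, 1))
  v4[, , , 1] <- array(1:100, c(5, 5, 4))
  pm <- make_pm(v4, mask)
  pp <- postprocess_pressure(pm)
  sm <- helixflow:::binomial_smooth3(v4[, , , 1], vox)
  qb <- unname(stats::quantile(sm[vox], c(0.01, 0.99), type = 7))
  expect_equal(unname(pp$clamp_bounds), qb)
  expect_lt(abs(mean(pp$values[, , , 1][vox])), 1e-12)
})

test_that("finalized map is gauge invariant to raw per-phase offsets", {
  tb <- small_tube(shape = c(7, 7, 7), radius = 5)
  set.seed(3)
  v4 <- array(0, c(tb$mask$dim, 3))
  for (p in 1:3) {
    v <- array(0, tb$mask$dim)
    vals <- rnorm(sum(tb$mask$voxels))
    v[tb$mask$voxels] <- vals - mean(vals)   # the solver's per-phase gauge
    v4[, , , p] <- v
  }
  pp1 <- postprocess_pressure(make_pm(v4, tb$mask))
  v4b <- v4
  for (p in 1:3) {
    v <- v4b[, , , p]; v[tb$mask$voxels] <- v[tb$mask$voxels] + c(5, -2, 11)[p]
    v4b[, , , p] <- v
  }
  ## re-fix the gauge (as the solver does) before postprocessing
  for (p in 1:3) {
    v <- v4b[, , , p]
    v[tb$mask$voxels] <- v[tb$mask$voxels] - mean(v[tb$mask$voxels])
    v4b[, , , p] <- v
  }
  pp2 <- postprocess_pressure(make_pm(v4b, tb$mask))
  expect_equal(pp2$values, pp1$values, tolerance = 1e-12)
})

test_that("helix mask is strict P<0 and a subset of the segmentation", {
  tb <- small_tube(shape = c(7, 7, 7), radius = 5)
  m <- tb$mask$voxels
  v4 <- array(0, c(tb$mask$dim, 2))
  v <- array(1, tb$mask$dim); v4[, , , 1] <- v        # all positive
  neg <- array(1, tb$mask$dim); neg[, , 1:3] <- -0.5  # half negative
  v4[, , , 2] <- neg
  pm <- make_pm(v4, tb$mask, postprocessed = TRUE)
  hm <- helix_mask(pm)
  expect_equal(sum(hm$voxels[, , , 1]), 0)
  expect_equal(which(hm$voxels[, , , 2]), which(neg < 0 & m))
  ## subset of segmentation at every phase
  expect_true(all(!(hm$voxels[, , , 1] & !m)))
  expect_true(all(!(hm$voxels[, , , 2] & !m)))
  ## significance floor
  hm2 <- helix_mask(pm, depth_mmHg = 0.6)
  expect_equal(sum(hm2$voxels), 0)
})

test_that("solver matches the Rankine closed form on a short tube", {
  sp <- phantom_spec(shape = c(15, 15, 21), radius_mm = 10, v_mean = 0,
                     n_phases = 2,
                     swirl = list(r_core_mm = 5, omega = 100, sign = -1,
                                  phases = 1:2, band_mm = c(0, 42)))
  ph <- make_tube_phantom(sp)
  g <- pressure_gradient(ph$field, ph$mask)
  pm <- solve_relative_pressure(g, ph$mask)
  idx <- which(ph$mask$voxels)
  co <- helixflow:::grid_coords(ph$mask$dim, ph$mask$spacing)[idx, ]
  r <- sqrt((co[, 1] - 14)^2 + (co[, 2] - 14)^2)
  pa <- analytic_rankine_pressure(r, sp)
  pa <- pa - mean(pa)
  ps <- pm$values[, , , 1][idx]
  expect_lt(sqrt(sum((ps - pa)^2) / sum(pa^2)), 0.12)
})
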