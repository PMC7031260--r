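test_that("velocity_field validates shape, timing and finiteness", {
  vals <- array(0, c(4, 4, 4, 3, 5))
  f <- velocity_field(vals, c(2, 2, 2), dt = 40, cycle_length = 200)
  expect_s3_class(f, "velocity_field")
  expect_equal(f$n_phases, 5)
  expect_error(velocity_field(array(0, c(4, 4, 4, 2, 5)), c(2, 2, 2), 40, 200),
               "nx, ny, nz")
  expect_error(velocity_field(vals, c(2, 2, 2), dt = 50, cycle_length = 200),
               "exceeds cycle_length")
  vals[1] <- NA
  expect_error(velocity_field(vals, c(2, 2, 2), 40, 200), "finite")
})

test_that("load_case converts cm/s to m/s and rejects incongruent grids", {
  dir <- withr::local_tempdir()
  dm <- c(6, 6, 6)
  set.seed(11)
  comps <- file.path(dir, paste0("v", 1:3, ".nii.gz"))
  for (f in comps)
    RNifti::writeNifti(array(round(runif(prod(dm) * 3, -150, 150)),
                             c(dm, 3)), f, datatype = "double")
  RNifti::writeNifti(array(1L, dm), file.path(dir, "mask.nii.gz"))
  meta <- list(spacing = c(2, 2, 2), dt = 40, cycle_length = 120,
               units = "cm/s", venc = 150)
  cs <- load_case(comps, file.path(dir, "mask.nii.gz"), meta)
  expect_lte(max(abs(cs$field$values)), 1.5)
  ## unit round trip: cm/s -> m/s -> cm/s to double-rounding precision
  orig <- array(as.numeric(RNifti::readNifti(comps[1])), c(dm, 3))
  expect_equal(cs$field$values[, , , 1, ] * 100, orig, tolerance = 1e-13)

  RNifti::writeNifti(array(1L, c(8, 8, 8)), file.path(dir, "mask8.nii.gz"))
  expect_error(load_case(comps, file.path(dir, "mask8.nii.gz"), meta),
               "shape mismatch")
  expect_error(load_case(comps, file.path(dir, "mask.nii.gz"),
                         meta[c("spacing", "units")]),
               "metadata error")
})

test_that("case bundles round-trip exactly", {
  ph <- make_tube_phantom(phantom_spec(shape = c(7, 7, 9), radius_mm = 5,
                                       n_phases = 3, noise_sigma = 0.05,
                                       seed = 4))
  dir <- withr::local_tempdir()
  write_case(dir, ph$field, ph$mask, ph$centerline, ph$ground_truth)
  back <- read_case(dir)
  expect_identical(back$field$values, ph$field$values)
  expect_identical(back$mask$voxels, ph$mask$voxels)
  expect_equal(unname(back$centerline$points), unname(ph$centerline$points))
  expect_equal(back$ground_truth$th_ex_rel_pct,
               ph$ground_truth$th_ex_rel_pct)
})

test_that("centerline of a straight tube recovers the axis and length", {
  tb <- small_tube(shape = c(9, 9, 61), radius = 7)
  ends <- rbind(c(tb$axis, 0), c(tb$axis, 120))
  cl <- compute_centerline(tb$mask, ends, sampling_step = 1)
  expect_equal(max(cl$arc_length), 120, tolerance = 2 / 120)
  ## within one voxel of the true axis everywhere
  off <- sqrt((cl$points[, 1] - tb$axis[1])^2 +
              (cl$points[, 2] - tb$axis[2])^2)
  expect_lt(max(off), 2)
  ## unit tangents
  expect_equal(sqrt(rowSums(cl$tangents^2)), rep(1, nrow(cl$points)),
               tolerance = 1e-9)
})

test_that("degenerate centerline endpoints are rejected", {
  tb <- small_tube()
  expect_error(compute_centerline(tb$mask, rbind(c(tb$axis, 10),
                                                 c(tb$axis, 10))),
               "degenerate")
  expect_error(compute_centerline(tb$mask, rbind(c(-10, -10, 0),
                                                 c(tb$axis, 10))),
               "inside the mask")
})

test_that("torus-segment centerline length matches the analytic arc", {
  ## quarter circle of radius 40 mm in the xz plane, tube radius 7 mm
  dm <- c(31, 9, 31); sp <- c(2, 2, 2)
  co <- expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                    k = seq_len(dm[3]))
  x <- (co$i - 1) * sp[1]; y <- (co$j - 1) * sp[2] - 8; z <- (co$k - 1) * sp[3]
  rad <- sqrt(x^2 + z^2)
  d <- sqrt((rad - 40)^2 + y^2)
  vox <- array(d <= 7, dm)
  mask <- seg_mask(vox, sp)
  p1 <- c(40, 8, 0); p2 <- c(0, 8, 40)
  cl <- compute_centerline(mask, rbind(p1, p2), sampling_step = 1)
  expect_equal(max(cl$arc_length), pi / 2 * 40, tolerance = 0.05)
})

test_that("ROI volume matches the analytic cylinder and its halves", {
  ph <- make_tube_phantom(phantom_preset("poiseuille"))
  roi <- define_roi(ph$mask, ph$centerline)
  ## exact voxel counting ...
  expect_equal(roi$volume_ml, sum(ph$mask$voxels) * 8 / 1000)
  ## ... and near the continuum cylinder; the voxel-centre criterion
  ## overfills a 10 mm disc on a 2 mm lattice by ~3% radially plus half a
  ## voxel of axial footprint, hence the 6% bound at this resolution
  expect_equal(roi$volume_ml, pi * 10^2 * 120 / 1000, tolerance = 0.06)
  half <- define_roi(ph$mask, ph$centerline, 0, 60)
  expect_equal(half$volume_ml, roi$volume_ml / 2, tolerance = 0.05)
  expect_equal(roi$length_mm, 120)
})

test_that("ROI volume is exact voxel counting and ROIs partition the mask", {
  ## 25 x 25 x 10 cuboid = 6250 voxels at 2 mm isotropic = 50.0 ml
  vox <- array(TRUE, c(25, 25, 10))
  mask <- seg_mask(vox, c(2, 2, 2))
  cl <- centerline(cbind(24, 24, seq(0, 18, by = 1)), sampling_step = 1)
  roi <- define_roi(mask, cl)
  expect_equal(roi$volume_ml, 50.0)
  ## disjoint arc partition sums to the whole
  parts <- list(c(0, 6), c(6, 12), c(12, 18))
  vols <- vapply(parts, function(p)
    define_roi(mask, cl, p[1], p[2])$volume_ml, numeric(1))
  expect_equal(sum(vols), roi$volume_ml)
})

test_that("every mask voxel maps to exactly one centerline index", {
  tb <- small_tube()
  idx <- which(tb$mask$voxels)
  co <- helixflow:::grid_coords(tb$mask$dim, tb$mask$spacing)[idx, ]
  ci <- helixflow:::nearest_cl_index(co, tb$centerline)
  expect_length(ci, length(idx))
  expect_true(all(ci >= 1 & ci <= nrow(tb$centerline$points)))
})

test_that("body surface area follows DuBois with its power-law scaling", {
  expect_equal(body_surface_area(170, 70), 1.810, tolerance = 0.005 / 1.81)
  expect_equal(body_surface_area(180, 80), 1.996, tolerance = 0.005 / 2)
  ## direct formula oracle
  expect_equal(body_surface_area(164, 58.2),
               0.007184 * 58.2^0.425 * 164^0.725)
  ## doubling weight multiplies BSA by 2^0.425
  expect_equal(body_surface_area(170, 140) / body_surface_area(170, 70),
               2^0.425)
  expect_error(body_surface_area(-170, 70), "positive")
  ## Mosteller alternative
  expect_equal(body_surface_area(180, 80, "mosteller"),
               sqrt(180 * 80 / 3600))
})

test_that("case_config rejects unknown or out-of-range parameters", {
  expect_error(case_config(not_a_param = 1), "unknown config")
  expect_error(case_config(tolerance = -1))
  cfg <- case_config(rho = 1050)
  expect_equal(cfg$rho, 1050)
  expect_equal(cfg$mu, 0.004)
})
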