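make_roi <- function(mask, cl) define_roi(mask, cl)

test_that("empty helix mask yields zero everything", {
  tb <- small_tube(shape = c(9, 9, 11))
  hm <- make_hm(array(FALSE, c(tb$mask$dim, 4)))
  roi <- make_roi(tb$mask, tb$centerline)
  rs <- extract_helix_regions(hm, roi)
  expect_true(all(lengths(rs$components) == 0))
  expect_equal(sum(rs$accumulated), 0)
  th <- temporal_helical_existence(rs, dt = 40, cycle_length = 160)
  expect_equal(th$th_ex_abs_ms, 0)
  expect_equal(th$th_ex_rel_pct, 0)
  hv <- helical_volumes(rs, roi)
  expect_equal(hv$hv_max_ml, 0)
  expect_equal(hv$hv_acc_ml, 0)
  expect_equal(accumulated_helix_length(rs, tb$centerline, roi)$hvl_acc_mm, 0)
})

test_that("two disjoint 100-voxel blobs are two 0.8 ml components", {
  vox <- array(TRUE, c(20, 20, 12))
  mask <- seg_mask(vox, c(2, 2, 2))
  cl <- centerline(cbind(19, 19, seq(0, 22, 1)), sampling_step = 1)
  roi <- make_roi(mask, cl)
  hm4 <- array(FALSE, c(20, 20, 12, 5))
  hm4[1:5, 1:5, 1:4, 3] <- TRUE        # 100 voxels
  hm4[14:18, 14:18, 8:11, 3] <- TRUE   # 100 voxels, disjoint
  rs <- extract_helix_regions(make_hm(hm4), roi)
  expect_length(rs$components[[3]], 2)
  vols <- sort(vapply(rs$components[[3]], length, integer(1))) *
    rs$voxel_volume_ml
  expect_equal(vols, c(0.8, 0.8))
  ## size filter drops both
  rs2 <- extract_helix_regions(make_hm(hm4), roi, min_component_ml = 1.0)
  expect_length(rs2$components[[3]], 0)
})

test_that("a drifting blob accumulates the brute-force temporal union", {
  vox <- array(TRUE, c(12, 12, 20))
  mask <- seg_mask(vox, c(2, 2, 2))
  cl <- centerline(cbind(11, 11, seq(0, 38, 1)), sampling_step = 1)
  roi <- make_roi(mask, cl)
  hm4 <- array(FALSE, c(12, 12, 20, 6))
  for (p in 2:4)                      # blob drifts one voxel per phase
    hm4[4:7, 4:7, (4:9) + p, p] <- TRUE
  rs <- extract_helix_regions(make_hm(hm4), roi)
  oracle <- apply(hm4, 1:3, any)      # per-voxel logical OR
  expect_identical(rs$accumulated, oracle)
  hv <- helical_volumes(rs, roi)
  expect_equal(hv$hv_acc_ml, sum(oracle) * 8 / 1000)
  expect_gt(hv$hv_acc_ml, hv$hv_max_ml)
  th <- temporal_helical_existence(rs, 40, 240)
  expect_equal(th$th_ex_abs_ms, 120)
})

test_that("static blob: HV_max = HV_acc, relative to ROI volume", {
  ## ROI 50 ml (25x25x10 at 2 mm); blob 1250 voxels = 10 ml, all phases
  vox <- array(TRUE, c(25, 25, 10))
  mask <- seg_mask(vox, c(2, 2, 2))
  cl <- centerline(cbind(24, 24, seq(0, 18, 1)), sampling_step = 1)
  roi <- make_roi(mask, cl)
  expect_equal(roi$volume_ml, 50)
  hm4 <- array(FALSE, c(25, 25, 10, 4))
  hm4[1:25, 1:10, 3:7, ] <- TRUE      # 1250 voxels every phase
  rs <- extract_helix_regions(make_hm(hm4), roi)
  hv <- helical_volumes(rs, roi)
  expect_equal(hv$hv_max_ml, 10)
  expect_equal(hv$hv_max_pct, 20)
  expect_equal(hv$hv_acc_ml, 10)
  th <- temporal_helical_existence(rs, 40, 160)
  expect_equal(th$th_ex_rel_pct, 100)
})

test_that("TH_Ex counts phases, not components", {
  vox <- array(TRUE, c(10, 10, 10))
  mask <- seg_mask(vox, c(2, 2, 2))
  cl <- centerline(cbind(9, 9, seq(0, 18, 1)), sampling_step = 1)
  roi <- make_roi(mask, cl)
  one <- array(FALSE, c(10, 10, 10, 2)); one[2:5, 2:5, 2:5, 1] <- TRUE
  two <- array(FALSE, c(10, 10, 10, 2))
  two[2:3, 2:5, 2:5, 1] <- TRUE; two[7:8, 2:5, 2:5, 1] <- TRUE
  th1 <- temporal_helical_existence(
    extract_helix_regions(make_hm(one), roi), 40, 80)
  th2 <- temporal_helical_existence(
    extract_helix_regions(make_hm(two), roi), 40, 80)
  expect_equal(th1$th_ex_abs_ms, th2$th_ex_abs_ms)
})

test_that("HVL_acc measures covered centerline length", {
  tb <- small_tube(shape = c(9, 9, 61), radius = 7)
  roi <- make_roi(tb$mask, tb$centerline)
  ## accumulated slab z in [40, 80): expect 40 mm, full-coverage case 100%
  hm4 <- array(FALSE, c(tb$mask$dim, 2))
  kz <- (seq_len(61) - 1) * 2
  hm4[, , kz >= 40 & kz < 80, 1] <- array(tb$mask$voxels[, , kz >= 40 & kz < 80],
                                          dim = c(9, 9, sum(kz >= 40 & kz < 80)))
  rs <- extract_helix_regions(make_hm(hm4), roi)
  hl <- accumulated_helix_length(rs, tb$centerline, roi)
  expect_equal(hl$hvl_acc_mm, 40, tolerance = 2 / 40)
  ## full coverage
  hm4[, , , 1] <- array(tb$mask$voxels, dim(hm4)[1:3])
  rs <- extract_helix_regions(make_hm(hm4), roi)
  hl <- accumulated_helix_length(rs, tb$centerline, roi)
  expect_equal(hl$hvl_acc_pct, 100)
})

test_that("helical volume index divides by BSA", {
  expect_equal(helical_volume_index(12, list(bsa = 2)), 6)
  expect_equal(helical_volume_index(0, list(bsa = 2)), 0)
  meta <- subject_meta(170, 70)
  expect_equal(helical_volume_index(19.9, meta), 19.9 / meta$bsa)
  expect_equal(helical_volume_index(19.9, meta), 10.99, tolerance = 0.002)
  expect_error(helical_volume_index(1, list(bsa = 0)), "positive")
})

test_that("relative metrics stay in [0, 100] on random masks", {
  set.seed(99)
  vox <- array(TRUE, c(10, 10, 12))
  mask <- seg_mask(vox, c(2, 2, 2))
  cl <- centerline(cbind(9, 9, seq(0, 22, 1)), sampling_step = 1)
  roi <- make_roi(mask, cl)
  for (rep in 1:5) {
    hm4 <- array(stats::runif(10 * 10 * 12 * 4) < 0.3, c(10, 10, 12, 4))
    rs <- extract_helix_regions(make_hm(hm4), roi)
    mx <- helix_metrics(rs, roi, cl, 40, 160)
    expect_gte(min(mx$th_ex_rel_pct, mx$hv_max_pct, mx$hv_acc_pct,
                   mx$hvl_acc_pct), 0)
    expect_lte(max(mx$th_ex_rel_pct, mx$hv_max_pct, mx$hv_acc_pct,
                   mx$hvl_acc_pct), 100)
    expect_gte(mx$hv_acc_ml, mx$hv_max_ml)
    expect_lte(mx$hv_acc_ml, roi$volume_ml + 1e-9)
    ## accumulated union equals the per-voxel OR oracle
    expect_identical(rs$accumulated, apply(hm4, 1:3, any))
  }
})

test_that("metrics CSV/JSON export uses the documented column names", {
  tb <- small_tube(shape = c(9, 9, 11))
  roi <- make_roi(tb$mask, tb$centerline)
  hm4 <- array(FALSE, c(tb$mask$dim, 2)); hm4[4:6, 4:6, 4:6, 1] <- TRUE
  rs <- extract_helix_regions(make_hm(hm4), roi)
  mx <- helix_metrics(rs, roi, tb$centerline, 40, 80, subject_meta(170, 70))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_helix_metrics(mx, csv)
  df <- read.csv(csv)
  expect_named(df, c("th_ex_abs_ms", "th_ex_rel_pct", "hv_max_ml",
                     "hv_max_pct", "hv_acc_ml", "hv_acc_pct", "hvl_acc_mm",
                     "hvl_acc_pct", "hvi_max_ml_m2", "hvi_acc_ml_m2"))
  js <- withr::local_tempfile(fileext = ".json")
  write_helix_metrics(mx, js)
  expect_equal(jsonlite::read_json(js)$th_ex_abs_ms, mx$th_ex_abs_ms)
})
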