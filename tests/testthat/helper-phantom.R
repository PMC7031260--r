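# Shared fixtures, all generated in code.

# small straight-tube mask + field factory for unit tests
small_tube <- function(shape = c(9, 9, 21), spacing = c(2, 2, 2),
                       radius = 7, n_phases = 2, dt = 40,
                       cycle = dt * n_phases, vz = 0) {
  cx <- (shape[1] - 1) / 2 * spacing[1]
  cy <- (shape[2] - 1) / 2 * spacing[2]
  xs <- (seq_len(shape[1]) - 1) * spacing[1] - cx
  ys <- (seq_len(shape[2]) - 1) * spacing[2] - cy
  r2 <- outer(xs^2, ys^2, "+")
  m3 <- array(rep(r2 <= radius^2, shape[3]), shape)
  vals <- array(0, c(shape, 3, n_phases))
  if (vz != 0) for (p in seq_len(n_phases)) vals[, , , 3, p] <- vz * m3
  list(field = velocity_field(vals, spacing, dt, cycle),
       mask = seg_mask(m3, spacing),
       axis = c(cx, cy),
       centerline = centerline(
         cbind(cx, cy, seq(0, (shape[3] - 1) * spacing[3], by = 1)),
         sampling_step = 1))
}

# helix_mask object built directly from a logical 4D array
make_hm <- function(vox4, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  structure(list(voxels = vox4, spacing = spacing, origin = origin,
                 n_phases = dim(vox4)[4]),
            class = "helix_mask")
}

# raw pressure_map object from a 4D value array and a seg_mask
make_pm <- function(values, mask, postprocessed = FALSE) {
  structure(list(values = values, mask = mask, clamp_bounds = NULL,
                 mean_shift = NULL,
                 converged = rep(TRUE, dim(values)[4]),
                 iterations = rep(0L, dim(values)[4]),
                 postprocessed = postprocessed,
                 spacing = mask$spacing, origin = mask$origin),
            class = "pressure_map")
}

# small gated-swirl case bundle on disk, shared by pipeline tests
small_case_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "helixflow-case")
      sp <- phantom_spec(shape = c(13, 13, 31), spacing = c(2, 2, 2),
                         n_phases = 10, cycle_length_ms = 1000,
                         radius_mm = 8, v_mean = 0,
                         swirl = list(r_core_mm = 4, omega = 100, sign = -1,
                                      phases = 3:6, band_mm = c(20, 40)),
                         seed = 5)
      ph <- make_tube_phantom(sp)
      write_case(dir, ph$field, ph$mask, ph$centerline, ph$ground_truth)
      cache <<- dir
    }
    cache
  }
})

# cached full gated phantom analysis shared by metrics / pathline / RD /
# acceptance tests (computed once per test run)
gated_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_tube_phantom(phantom_preset("gated-helix"))
      cfg <- case_config(helix_depth_mmHg = 0.01)
      pm <- compute_pressure_map(ph$field, ph$mask, cfg)
      hm <- helix_mask(pm, cfg$helix_depth_mmHg)
      roi <- define_roi(ph$mask, ph$centerline)
      rs <- extract_helix_regions(hm, roi)
      mx <- helix_metrics(rs, roi, ph$centerline, ph$field$dt,
                          ph$field$cycle_length)
      cache <<- list(ph = ph, cfg = cfg, pm = pm, hm = hm, roi = roi,
                     rs = rs, mx = mx)
    }
    cache
  }
})
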