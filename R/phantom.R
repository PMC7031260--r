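## Analytic synthetic 4D flow phantoms: pulsatile Poiseuille tube flow with an
## optional gated, axially bounded Rankine swirl of known handedness. The
## closed-form velocity and pressure fields are the test oracle for the
## pressure solver, the helix metrics, the pathline integrator and the
## rotation-direction classifier.

#' Specification of a tube-flow phantom
#'
#' The phantom is a straight rigid tube along the z axis carrying parabolic
#' (Poiseuille) axial flow scaled by a cardiac waveform, optionally with a
#' Rankine vortex superimposed during a contiguous block of phases and within
#' an axial band. Defaults mirror a typical aortic 4D flow acquisition:
#' 25 cardiac phases at 40 ms on a 2 mm isotropic grid, velocities below a
#' 150 cm/s encoding limit.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel spacing (mm).
#' @param n_phases number of cardiac phases.
#' @param cycle_length_ms cardiac cycle duration (ms).
#' @param radius_mm tube radius R.
#' @param v_mean mean axial speed (m/s); 0 disables axial flow.
#' @param waveform `"constant"` or `"raised-cosine"`; the raised-cosine pulse
#'   is `w(t) = 0.5*(1 - cos(2*pi*(t - t0)/width))` inside the systolic
#'   window and 0 outside, scaled so its cycle mean is 1.
#' @param systole_ms `c(t0, t0 + width)` window of the raised-cosine pulse.
#' @param swirl `NULL`, or a list with `r_core_mm` (Rankine core radius),
#'   `omega` (angular rate rad/s), `sign` (+1 counter-clockwise about +z /
#'   -1 clockwise), `phases` (integer phase indices with swirl on) and
#'   `band_mm` (`c(z1, z2)` axial band, half-open).
#' @param noise_sigma Gaussian velocity noise s.d. (m/s).
#' @param seed RNG seed for the noise.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(17, 17, 61), spacing = c(2, 2, 2),
                         n_phases = 25, cycle_length_ms = 1000,
                         radius_mm = 10, v_mean = 0.2,
                         waveform = c("constant", "raised-cosine"),
                         systole_ms = c(0, 400),
                         swirl = NULL, noise_sigma = 0, seed = 1L) {
  waveform <- match.arg(waveform)
  spec <- list(shape = shape, spacing = spacing, n_phases = n_phases,
               cycle_length_ms = cycle_length_ms,
               dt_ms = cycle_length_ms / n_phases,
               radius_mm = radius_mm,
               length_mm = (shape[3] - 1) * spacing[3],
               v_mean = v_mean, waveform = waveform, systole_ms = systole_ms,
               swirl = swirl, noise_sigma = noise_sigma,
               seed = as.integer(seed))
  if (!is.null(swirl)) {
    stopifnot(swirl$r_core_mm < radius_mm,
              all(swirl$phases >= 1), all(swirl$phases <= n_phases),
              swirl$band_mm[1] < swirl$band_mm[2],
              swirl$band_mm[2] <= spec$length_mm + spacing[3],
              abs(swirl$sign) == 1)
  }
  stopifnot(radius_mm < min(shape[1:2] - 1) / 2 * min(spacing[1:2]),
            n_phases >= 2, noise_sigma >= 0)
  class(spec) <- "phantom_spec"
  spec
}

#' Preset phantom specifications
#'
#' * `"gated-helix"`: pure Rankine swirl (no axial bulk flow), on for phases
#'   5--14 of 25 (10 of 25 phases, 400 ms of a 1000 ms cycle) and confined to
#'   the axial band 40--80 mm of a 120 mm tube; core radius 5 mm, 100 rad/s.
#'   Ground truth for temporal helical existence, helix volumes/length and
#'   rotation direction.
#' * `"rankine-steady"`: the same swirl, steady and covering the whole tube;
#'   oracle case for the pressure solver.
#' * `"poiseuille"`: steady parabolic axial flow, mean 0.2 m/s; oracle case
#'   for measuring-plane flow quantification.
#'
#' @param preset preset name.
#' @param seed RNG seed recorded in the spec.
#' @param ... overrides passed to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
phantom_preset <- function(preset = c("gated-helix", "rankine-steady",
                                      "poiseuille"),
                           seed = 1L, ...) {
  preset <- match.arg(preset)
  base_swirl <- list(r_core_mm = 5, omega = 100, sign = -1,
                     phases = 5:14, band_mm = c(40, 80))
  spec <- switch(preset,
    "gated-helix" = phantom_spec(v_mean = 0, swirl = base_swirl,
                                 seed = seed, ...),
    "rankine-steady" = phantom_spec(
      v_mean = 0, n_phases = 2,
      swirl = utils::modifyList(base_swirl,
                                list(phases = 1:2, band_mm = c(0, 121))),
      seed = seed, ...),
    "poiseuille" = phantom_spec(v_mean = 0.2, seed = seed, ...))
  spec$preset <- preset
  spec
}

phantom_waveform <- function(spec) {
  t <- (seq_len(spec$n_phases) - 1) * spec$dt_ms
  if (spec$waveform == "constant") return(rep(1, spec$n_phases))
  t0 <- spec$systole_ms[1]; width <- diff(spec$systole_ms)
  w <- ifelse(t >= t0 & t < t0 + width,
              0.5 * (1 - cos(2 * pi * (t - t0) / width)), 0)
  w / mean(w)
}

#' Generate the tube phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `field` ([velocity_field()]), `mask` ([seg_mask()]),
#'   `centerline` (the tube axis), and `ground_truth` (known helix phase
#'   count, swirl sign and expected rotation label, axial band length,
#'   analytic net flow in ml/cycle, and Rankine pressure parameters).
#' @export
make_tube_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$shape
  cx <- (dm[1] - 1) / 2 * spec$spacing[1]
  cy <- (dm[2] - 1) / 2 * spec$spacing[2]
  xs <- (seq_len(dm[1]) - 1) * spec$spacing[1] - cx
  ys <- (seq_len(dm[2]) - 1) * spec$spacing[2] - cy
  r2 <- outer(xs^2, ys^2, "+")          # nx x ny, squared radius (mm^2)
  inside <- r2 <= spec$radius_mm^2
  mask3 <- array(rep(inside, dm[3]), dm)

  w <- phantom_waveform(spec)
  vals <- array(0, c(dm, 3, spec$n_phases))
  if (spec$v_mean != 0) {
    prof <- 2 * spec$v_mean * (1 - r2 / spec$radius_mm^2)
    prof[!inside] <- 0
    vz3 <- array(rep(prof, dm[3]), dm)
    for (p in seq_len(spec$n_phases)) vals[, , , 3, p] <- vz3 * w[p]
  }
  field <- velocity_field(vals, spec$spacing, spec$dt_ms,
                          spec$cycle_length_ms)
  field <- add_swirl(field, spec)
  if (spec$noise_sigma > 0)
    field <- add_noise(field, spec$noise_sigma, spec$seed)

  mask <- seg_mask(mask3, spec$spacing)
  zmax <- (dm[3] - 1) * spec$spacing[3]
  npts <- floor(zmax) + 1
  axis_pts <- cbind(rep(cx, npts), rep(cy, npts), seq(0, zmax, length.out = npts))
  cl <- centerline(axis_pts, sampling_step = zmax / (npts - 1))

  gt <- list(
    preset = spec$preset, seed = spec$seed,
    n_helix_phases = if (is.null(spec$swirl)) 0L else length(spec$swirl$phases),
    th_ex_abs_ms = if (is.null(spec$swirl)) 0 else
      length(spec$swirl$phases) * spec$dt_ms,
    th_ex_rel_pct = if (is.null(spec$swirl)) 0 else
      100 * length(spec$swirl$phases) * spec$dt_ms / spec$cycle_length_ms,
    swirl_sign = if (is.null(spec$swirl)) NA else spec$swirl$sign,
    ## flow direction is +z: clockwise about +z (sign -1) is right-handed
    expected_rd = if (is.null(spec$swirl)) NA_character_ else
      if (spec$swirl$sign < 0) "RD+" else "RD-",
    band_length_mm = if (is.null(spec$swirl)) 0 else
      min(diff(spec$swirl$band_mm), zmax),
    net_flow_ml_per_cycle = pi * spec$radius_mm^2 * spec$v_mean *
      spec$cycle_length_ms / 1000,
    peak_velocity_m_s = 2 * spec$v_mean *
      if (spec$waveform == "constant") 1 else max(phantom_waveform(spec)),
    rankine = if (is.null(spec$swirl)) NULL else
      list(r_core_mm = spec$swirl$r_core_mm, omega = spec$swirl$omega,
           axis_deficit_mmHg = -1060 * spec$swirl$omega^2 *
             (spec$swirl$r_core_mm / 1000)^2 / MMHG_PA))
  list(field = field, mask = mask, centerline = cl, ground_truth = gt,
       spec = spec)
}

#' Superimpose a gated, axially bounded Rankine swirl
#'
#' Adds the azimuthal velocity `v_theta(r) = s*omega*r` for `r <= r_core`,
#' `s*omega*r_core^2/r` outside the core, about the tube axis, only at the
#' gated phases and inside the axial band.
#'
#' @param field a `velocity_field` on the phantom grid.
#' @param spec a `phantom_spec` with a non-NULL `swirl` entry.
#' @return the modified `velocity_field`.
#' @export
add_swirl <- function(field, spec) {
  sw <- spec$swirl
  if (is.null(sw) || length(sw$phases) == 0L) return(field)
  dm <- spec$shape
  cx <- (dm[1] - 1) / 2 * spec$spacing[1]
  cy <- (dm[2] - 1) / 2 * spec$spacing[2]
  xs <- (seq_len(dm[1]) - 1) * spec$spacing[1] - cx
  ys <- (seq_len(dm[2]) - 1) * spec$spacing[2] - cy
  X <- matrix(xs, dm[1], dm[2])
  Y <- matrix(ys, dm[1], dm[2], byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  rc <- sw$r_core_mm
  ## angular speed in rad/ms times radius in mm gives mm/ms = m/s;
  ## omega is rad/s -> vt [m/s] = omega * r[mm] / 1000 inside the core
  vt <- ifelse(r <= rc, sw$omega * r / 1000, sw$omega * rc^2 / (1000 * pmax(r, 1e-9)))
  vt <- vt * sw$sign
  inside <- r <= spec$radius_mm
  ## unit azimuthal direction for counter-clockwise rotation about +z
  ex <- ifelse(r > 1e-9, -Y / pmax(r, 1e-9), 0) * vt
  ey <- ifelse(r > 1e-9, X / pmax(r, 1e-9), 0) * vt
  ex[!inside] <- 0; ey[!inside] <- 0
  zc <- (seq_len(dm[3]) - 1) * spec$spacing[3]
  in_band <- zc >= sw$band_mm[1] & zc < sw$band_mm[2]
  for (p in sw$phases) for (k in which(in_band)) {
    field$values[, , k, 1, p] <- field$values[, , k, 1, p] + ex
    field$values[, , k, 2, p] <- field$values[, , k, 2, p] + ey
  }
  field
}

#' Closed-form Rankine vortex pressure (relative to the far field)
#'
#' `dp(r) = -rho*omega^2*r_c^2 + rho*omega^2*r^2/2` inside the core and
#' `-rho*omega^2*r_c^4 / (2 r^2)` outside, converted from Pa to mmHg. This is
#' the cyclostrophic balance of the steady Rankine swirl and serves as the
#' independent oracle for the iterative pressure solver.
#'
#' @param r_mm radius (mm), scalar or vector.
#' @param spec a `phantom_spec` with swirl, or a list with `omega` (rad/s)
#'   and `r_core_mm`.
#' @param rho fluid density (kg/m^3).
#' @return relative pressure in mmHg (0 at infinity).
#' @export
analytic_rankine_pressure <- function(r_mm, spec, rho = 1060) {
  sw <- if (!is.null(spec$swirl)) spec$swirl else spec
  rc <- sw$r_core_mm / 1000    # m
  r <- r_mm / 1000             # m
  om <- sw$omega
  p_pa <- ifelse(r <= rc,
                 -rho * om^2 * rc^2 + rho * om^2 * r^2 / 2,
                 -rho * om^2 * rc^4 / (2 * pmax(r, 1e-12)^2))
  p_pa / MMHG_PA
}

#' Add i.i.d. Gaussian velocity noise
#'
#' @param field a `velocity_field`.
#' @param sigma noise standard deviation (m/s).
#' @param seed RNG seed; the same seed reproduces the same noise.
#' @return the noisy `velocity_field`.
#' @export
add_noise <- function(field, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(field)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  field$values <- field$values +
    array(stats::rnorm(length(field$values), 0, sigma), dim(field$values))
  field
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
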