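## Optional standard phase-contrast corrections applied before analysis:
## velocity aliasing (phase-wrap) repair, static-tissue eddy-current offset
## removal, and temporal-noise masking. All are off by default; the
## phantoms are generated clean.

## median over the 3x3x3x3 spatiotemporal neighbourhood of every voxel of a
## 4D (x,y,z,phase) array, cyclic in the phase axis, edge-replicated in
## space
spatiotemporal_median <- function(arr) {
  dm <- dim(arr)
  np <- dm[4]
  med <- array(0, dm)
  clampi <- function(i, n) pmin(pmax(i, 1L), n)
  has_ms <- requireNamespace("matrixStats", quietly = TRUE)
  for (p in seq_len(np)) {
    phs <- unique(((p - 1L) + (-1:1)) %% np + 1L)
    nb <- matrix(0, prod(dm[1:3]), 27L * length(phs))
    col <- 0L
    for (q in phs) for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      col <- col + 1L
      nb[, col] <- arr[clampi(seq_len(dm[1]) + di, dm[1]),
                       clampi(seq_len(dm[2]) + dj, dm[2]),
                       clampi(seq_len(dm[3]) + dk, dm[3]), q]
    }
    med[, , , p] <- if (has_ms) matrixStats::rowMedians(nb) else
      apply(nb, 1, stats::median)
  }
  med
}

#' Correct velocity aliasing (phase wraps)
#'
#' A voxel whose value differs from the median of its 3x3x3x3
#' spatiotemporal neighbourhood by more than Venc is shifted by multiples
#' of 2 Venc until it lies within one Venc of that median -- the standard
#' repair for phase-contrast aliasing, where true velocities beyond the
#' encoding limit wrap around by 2 Venc. A no-op on clean data.
#'
#' @param field a [velocity_field()].
#' @param venc encoding velocity in cm/s (default: the field's own).
#' @return list with the corrected `field` and a `report`
#'   (`n_unwrapped_voxels`).
#' @export
unwrap_phase <- function(field, venc = field$venc) {
  if (is.null(venc) || venc <= 0)
    stop("venc (cm/s) must be positive", call. = FALSE)
  v_lim <- venc / 100          # m/s
  n_fixed <- 0L
  for (c3 in 1:3) {
    a <- field$values[, , , c3, , drop = TRUE]
    dim(a) <- c(field$dim, field$n_phases)
    med <- spatiotemporal_median(a)
    dev <- a - med
    wraps <- round(dev / (2 * v_lim))
    bad <- abs(dev) > v_lim & wraps != 0
    n_fixed <- n_fixed + sum(bad)
    a[bad] <- a[bad] - 2 * v_lim * wraps[bad]
    field$values[, , , c3, ] <- a
  }
  list(field = field,
       report = list(n_unwrapped_voxels = n_fixed, venc_cm_s = venc))
}

poly_design <- function(coords, order) {
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  if (order == 1) cbind(1, x, y, z)
  else cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z)
}

#' Remove eddy-current velocity offsets using static tissue
#'
#' Fits, per velocity component, a spatial polynomial (order 1 or 2) to the
#' temporal-mean velocity over the static-tissue mask by least squares and
#' subtracts it from every phase -- the standard correction for the slowly
#' varying phase offsets that eddy currents superimpose on phase-contrast
#' data.
#'
#' @param field a [velocity_field()].
#' @param static_mask a [seg_mask()] of static tissue.
#' @param order polynomial order, 1 (default) or 2.
#' @return list with the corrected `field` and a `report`
#'   (`eddy_poly_order`, `eddy_coefficients` per component).
#' @export
correct_eddy_currents <- function(field, static_mask, order = 1) {
  if (!order %in% 1:2) stop("order must be 1 or 2", call. = FALSE)
  stop_if_incongruent(field, static_mask)
  idx <- which(static_mask$voxels)
  nterms <- if (order == 1) 4L else 10L
  if (length(idx) < nterms)
    stop("underdetermined eddy-current fit: ", length(idx),
         " static voxels < ", nterms, " polynomial terms", call. = FALSE)
  coords <- grid_coords(field$dim, field$spacing, field$origin)
  Xs <- poly_design(coords[idx, , drop = FALSE], order)
  Xall <- poly_design(coords, order)
  coefs <- vector("list", 3)
  for (c3 in 1:3) {
    tm <- array(0, field$dim)
    for (p in seq_len(field$n_phases))
      tm <- tm + field$values[, , , c3, p]
    tm <- tm / field$n_phases
    beta <- stats::lm.fit(Xs, tm[idx])$coefficients
    beta[is.na(beta)] <- 0
    offset <- array(Xall %*% beta, field$dim)
    for (p in seq_len(field$n_phases))
      field$values[, , , c3, p] <- field$values[, , , c3, p] - offset
    coefs[[c3]] <- unname(beta)
  }
  list(field = field,
       report = list(eddy_poly_order = order, eddy_coefficients = coefs))
}

#' Flag noise voxels by temporal velocity-magnitude variation
#'
#' Voxels whose temporal standard deviation of the velocity magnitude
#' exceeds `threshold_std` are flagged as noise candidates (static
#' background should be temporally quiet; thermal noise is not).
#'
#' @param field a [velocity_field()].
#' @param threshold_std threshold in m/s (> 0).
#' @return logical array (`nx x ny x nz`) of flagged voxels, with the
#'   flagged fraction as attribute `fraction`.
#' @export
noise_mask <- function(field, threshold_std) {
  if (threshold_std <= 0) stop("threshold_std must be > 0", call. = FALSE)
  np <- field$n_phases
  s1 <- array(0, field$dim); s2 <- array(0, field$dim)
  for (p in seq_len(np)) {
    mag <- sqrt(field$values[, , , 1, p]^2 + field$values[, , , 2, p]^2 +
                field$values[, , , 3, p]^2)
    s1 <- s1 + mag; s2 <- s2 + mag^2
  }
  sd_t <- sqrt(pmax(0, (s2 - s1^2 / np) / (np - 1)))
  flag <- sd_t > threshold_std
  attr(flag, "fraction") <- mean(flag)
  flag
}
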