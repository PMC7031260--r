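## Time-resolved pathline integration through the 4D velocity field:
## 4th-order Runge-Kutta in time with trilinear spatial and linear temporal
## interpolation. Dense seeding inside helix regions, termination at the
## vessel wall, and helix-mask filtering. With mm/ms conventions a velocity
## in m/s is numerically a displacement rate in mm/ms, so no unit factors
## appear in the integrator.

#' Seed positions inside the helix mask at one phase
#'
#' Seeds at the centres of every `stride`-th flagged voxel (per axis) of the
#' helix mask at the given phase; `stride = 1` seeds every flagged voxel.
#'
#' @param hm a [helix_mask()].
#' @param phase phase index (1-based).
#' @param stride positive integer lattice stride in voxels.
#' @return matrix (n x 3) of world coordinates (mm); 0 rows if the mask is
#'   empty at that phase.
#' @export
seed_helix <- function(hm, phase, stride = 1) {
  stopifnot(phase >= 1, phase <= hm$n_phases, stride >= 1)
  v <- hm$voxels[, , , phase]
  idx <- which(v)
  if (length(idx) == 0L)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  pos <- arrayInd(idx, dim(v))
  if (stride > 1) {
    keep <- (pos[, 1] - 1) %% stride == 0 & (pos[, 2] - 1) %% stride == 0 &
      (pos[, 3] - 1) %% stride == 0
    pos <- pos[keep, , drop = FALSE]
  }
  out <- (pos - 1) * matrix(hm$spacing, nrow(pos), 3, byrow = TRUE) +
    matrix(hm$origin, nrow(pos), 3, byrow = TRUE)
  colnames(out) <- c("x", "y", "z")
  out
}

## Trilinear interpolation of one 3D volume at an n x 3 matrix of continuous
## (1-based) voxel indices. Out-of-grid points return NA.
trilinear <- function(vol, ij) {
  dm <- dim(vol)
  ok <- rowSums(is.na(ij)) == 0
  ok[ok] <- ij[ok, 1] >= 1 & ij[ok, 1] <= dm[1] & ij[ok, 2] >= 1 &
    ij[ok, 2] <= dm[2] & ij[ok, 3] >= 1 & ij[ok, 3] <= dm[3]
  out <- rep(NA_real_, nrow(ij))
  if (!any(ok)) return(out)
  p <- ij[ok, , drop = FALSE]
  i0 <- pmin(floor(p[, 1]), dm[1] - 1); fi <- p[, 1] - i0
  j0 <- pmin(floor(p[, 2]), dm[2] - 1); fj <- p[, 2] - j0
  k0 <- pmin(floor(p[, 3]), dm[3] - 1); fk <- p[, 3] - k0
  ## degenerate single-slab axes
  if (dm[1] == 1) { i0 <- rep(1, nrow(p)); fi <- rep(0, nrow(p)) }
  if (dm[2] == 1) { j0 <- rep(1, nrow(p)); fj <- rep(0, nrow(p)) }
  if (dm[3] == 1) { k0 <- rep(1, nrow(p)); fk <- rep(0, nrow(p)) }
  at <- function(di, dj, dk)
    vol[cbind(pmin(i0 + di, dm[1]), pmin(j0 + dj, dm[2]),
              pmin(k0 + dk, dm[3]))]
  val <-
    at(0, 0, 0) * (1 - fi) * (1 - fj) * (1 - fk) +
    at(1, 0, 0) * fi * (1 - fj) * (1 - fk) +
    at(0, 1, 0) * (1 - fi) * fj * (1 - fk) +
    at(0, 0, 1) * (1 - fi) * (1 - fj) * fk +
    at(1, 1, 0) * fi * fj * (1 - fk) +
    at(1, 0, 1) * fi * (1 - fj) * fk +
    at(0, 1, 1) * (1 - fi) * fj * fk +
    at(1, 1, 1) * fi * fj * fk
  out[ok] <- val
  out
}

## Velocity sampler: positions (n x 3, mm) and time (ms) -> n x 3 velocity
## (m/s = mm/ms). Linear in time between phase centres at (k-1)*dt, cyclic
## sampling over the cycle. NA where outside the grid.
sample_velocity <- function(field, pos, t_ms) {
  np <- field$n_phases
  tc <- (t_ms %% field$cycle_length) / field$dt   # 0-based phase coordinate
  k0 <- floor(tc); f <- tc - k0
  kA <- (as.integer(k0) %% np) + 1L
  kB <- (as.integer(k0 + 1) %% np) + 1L
  ij <- world_to_index(pos, field$spacing, field$origin)
  out <- matrix(NA_real_, nrow(pos), 3)
  for (c3 in 1:3) {
    vA <- trilinear(field$values[, , , c3, kA], ij)
    vB <- if (f > 1e-12) trilinear(field$values[, , , c3, kB], ij) else vA
    out[, c3] <- (1 - f) * vA + f * vB
  }
  out
}

## Nearest-voxel mask membership of world positions
in_mask <- function(mask, pos) {
  ij <- round(world_to_index(pos, mask$spacing, mask$origin))
  dm <- mask$dim
  ok <- rowSums(is.na(ij)) == 0
  ok[ok] <- ij[ok, 1] >= 1 & ij[ok, 1] <= dm[1] & ij[ok, 2] >= 1 &
    ij[ok, 2] <= dm[2] & ij[ok, 3] >= 1 & ij[ok, 3] <= dm[3]
  res <- rep(FALSE, nrow(pos))
  if (any(ok))
    res[ok] <- mask$voxels[ij[ok, , drop = FALSE]]
  res
}

#' Integrate time-resolved pathlines
#'
#' Fourth-order Runge-Kutta integration in time with step `dt/substeps`,
#' trilinear spatial and linear temporal interpolation of the velocity.
#' Integration runs forward from the seed phase to the end of the cardiac
#' cycle (optionally wrapping for phantoms); a line terminates when it
#' leaves the segmentation mask.
#'
#' @param field a [velocity_field()].
#' @param seeds n x 3 matrix of seed world positions (mm).
#' @param mask a [seg_mask()]; velocity outside it is treated as undefined
#'   (lines terminate rather than being dragged along walls).
#' @param seed_phase phase index at which the seeds are released.
#' @param substeps RK4 substeps per phase interval (default 4).
#' @param wrap integrate past the end of the cycle back into the next one
#'   for up to one extra full cycle (default FALSE).
#' @return list of `pathline` objects: each has `samples` (matrix with
#'   columns `t_ms, x, y, z`), `seed`, `seed_phase`, `in_helix_fraction`
#'   (NA until [filter_pathlines()]), and `rd_label` (`"pending"` until
#'   [classify_pathline()]).
#' @export
integrate_pathlines <- function(field, seeds, mask, seed_phase = 1,
                                substeps = 4, wrap = FALSE) {
  stopifnot(substeps >= 1)
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0L) return(list())
  alive <- in_mask(mask, seeds)
  if (any(!alive))
    warning(sum(!alive), " seed(s) outside the mask skipped", call. = FALSE)
  n <- nrow(seeds)
  h <- field$dt / substeps
  t0 <- (seed_phase - 1) * field$dt
  t_end <- field$cycle_length * (if (wrap) 2 else 1)
  nsteps <- max(1L, floor((t_end - t0) / h + 1e-9))
  traj <- vector("list", n)
  for (i in which(alive)) traj[[i]] <- list(cbind(t0, seeds[i, 1, drop = FALSE],
                                                  seeds[i, 2], seeds[i, 3]))
  pos <- seeds
  t <- t0
  for (s in seq_len(nsteps)) {
    if (!any(alive)) break
    act <- which(alive)
    P <- pos[act, , drop = FALSE]
    k1 <- sample_velocity(field, P, t)
    k2 <- sample_velocity(field, P + k1 * (h / 2), t + h / 2)
    k3 <- sample_velocity(field, P + k2 * (h / 2), t + h / 2)
    k4 <- sample_velocity(field, P + k3 * h, t + h)
    step <- (k1 + 2 * k2 + 2 * k3 + k4) * (h / 6)
    bad <- !is.finite(rowSums(step))
    Pn <- P + ifelse(is.na(step), 0, step)
    inm <- in_mask(mask, Pn) & !bad
    t <- t + h
    for (r in seq_along(act)) {
      i <- act[r]
      if (!inm[r]) { alive[i] <- FALSE; next }
      pos[i, ] <- Pn[r, ]
      traj[[i]] <- c(traj[[i]], list(cbind(t, Pn[r, 1], Pn[r, 2], Pn[r, 3])))
    }
  }
  lines <- list()
  for (i in seq_len(n)) {
    if (is.null(traj[[i]]) || length(traj[[i]]) < 2L) next
    sm <- do.call(rbind, traj[[i]])
    colnames(sm) <- c("t_ms", "x", "y", "z")
    lines[[length(lines) + 1L]] <- structure(
      list(samples = sm, seed = seeds[i, ], seed_phase = seed_phase,
           in_helix_fraction = NA_real_, rd_label = "pending"),
      class = "pathline")
  }
  lines
}

#' @export
print.pathline <- function(x, ...) {
  cat(sprintf("<pathline> %d samples, t %.0f..%.0f ms, label %s\n",
              nrow(x$samples), x$samples[1, 1],
              x$samples[nrow(x$samples), 1], x$rd_label))
  invisible(x)
}

## fraction of samples whose nearest voxel+phase is inside the helix mask
helix_fraction <- function(line, hm) {
  sm <- line$samples
  np <- hm$n_phases
  dt <- attr(hm, "dt")
  phase_of <- function(t_ms) {
    k <- round(t_ms / dt) %% np
    as.integer(k) + 1L
  }
  ij <- round(world_to_index(sm[, 2:4, drop = FALSE], hm$spacing, hm$origin))
  dm <- dim(hm$voxels)[1:3]
  ok <- ij[, 1] >= 1 & ij[, 1] <= dm[1] & ij[, 2] >= 1 & ij[, 2] <= dm[2] &
    ij[, 3] >= 1 & ij[, 3] <= dm[3]
  ph <- phase_of(sm[, 1])
  hit <- rep(FALSE, nrow(sm))
  if (any(ok))
    hit[ok] <- hm$voxels[cbind(ij[ok, , drop = FALSE], ph[ok])]
  mean(hit)
}

#' Filter pathlines by their helix-mask residence fraction
#'
#' Computes, for each line, the fraction of samples whose nearest voxel at
#' the nearest phase lies inside the helix mask, and retains lines with
#' fraction >= `min_fraction`. The retained lines carry the computed
#' `in_helix_fraction`.
#'
#' @param lines list of `pathline` objects.
#' @param hm a [helix_mask()].
#' @param dt temporal resolution (ms), needed to map sample times to phases.
#' @param min_fraction threshold in `[0, 1]` (default 0.25).
#' @return filtered list of `pathline` objects.
#' @export
filter_pathlines <- function(lines, hm, dt, min_fraction = 0.25) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  attr(hm, "dt") <- dt
  out <- list()
  for (ln in lines) {
    ln$in_helix_fraction <- helix_fraction(ln, hm)
    if (ln$in_helix_fraction >= min_fraction)
      out[[length(out) + 1L]] <- ln
  }
  out
}

#' Export pathlines as long-format CSV
#'
#' Columns `line_id, t_ms, x_mm, y_mm, z_mm, rd_label`.
#'
#' @param lines list of `pathline` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pathlines_csv <- function(lines, path) {
  rows <- lapply(seq_along(lines), function(i) {
    sm <- lines[[i]]$samples
    data.frame(line_id = i, t_ms = sm[, 1], x_mm = sm[, 2], y_mm = sm[, 3],
               z_mm = sm[, 4], rd_label = lines[[i]]$rd_label)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
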