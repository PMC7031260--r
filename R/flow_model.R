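#' helixflow: pressure-based helix extraction from 4D flow MRI
#'
#' Unit conventions used throughout the package: world coordinates and voxel
#' spacing in millimetres, velocities in metres per second (conveniently equal
#' to mm/ms), time in milliseconds, pressure in mmHg, volumes in millilitres.
#' All conversions happen at I/O boundaries; internal arithmetic never mixes
#' units.
#'
#' @keywords internal
"_PACKAGE"

MMHG_PA <- 133.322  # 1 mmHg in pascal

vnorm <- function(v) sqrt(sum(v * v))

#' Time-resolved three-component velocity field on a regular grid
#'
#' Container for a 4D flow MRI velocity dataset: three velocity components
#' sampled on a common regular 3D grid across the phases of one cardiac cycle.
#'
#' @param values numeric array of dimension `c(nx, ny, nz, 3, n_phases)`,
#'   velocity in m/s; the fourth dimension orders the x, y, z components.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param dt temporal resolution in ms.
#' @param cycle_length cardiac cycle duration in ms.
#' @param origin world position (mm) of the centre of voxel (1,1,1).
#' @param venc velocity-encoding limit in cm/s, or `NULL` if unknown.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(values, spacing, dt, cycle_length,
                           origin = c(0, 0, 0), venc = NULL) {
  dm <- dim(values)
  if (length(dm) != 5L || dm[4] != 3L)
    stop("`values` must be a (nx, ny, nz, 3, n_phases) array", call. = FALSE)
  if (dm[5] < 2L) stop("need at least 2 cardiac phases", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel edge lengths (mm)", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive (ms)", call. = FALSE)
  if (dt * dm[5] > cycle_length * (1 + 1e-6))
    stop("dt * n_phases exceeds cycle_length", call. = FALSE)
  if (!all(is.finite(values)))
    stop("velocity values must be finite", call. = FALSE)
  structure(
    list(values = values, spacing = as.numeric(spacing), dt = as.numeric(dt),
         cycle_length = as.numeric(cycle_length),
         origin = as.numeric(origin), venc = venc,
         n_phases = dm[5], dim = dm[1:3]),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %s voxels x %d phases, spacing %s mm, dt %g ms, cycle %g ms\n",
              paste(x$dim, collapse = "x"), x$n_phases,
              paste(signif(x$spacing, 3), collapse = "x"), x$dt, x$cycle_length))
  invisible(x)
}

#' Binary vessel segmentation on the velocity grid
#'
#' @param voxels logical (or 0/1) array, same spatial dimensions as the field.
#' @param spacing,origin grid metadata as in [velocity_field()].
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (!any(voxels)) stop("segmentation mask is empty", call. = FALSE)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), dim = dim(voxels)),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s grid, %d voxels set (%.1f ml)\n",
              paste(x$dim, collapse = "x"), sum(x$voxels),
              sum(x$voxels) * prod(x$spacing) / 1000))
  invisible(x)
}

#' Voxel volume of a grid (mm^3)
#' @param x a `seg_mask` or `velocity_field`.
#' @return voxel volume in mm^3.
#' @export
voxel_volume <- function(x) prod(x$spacing)

stop_if_incongruent <- function(field, mask) {
  if (!identical(as.integer(field$dim), as.integer(mask$dim)))
    stop("field and mask grids are not congruent: ",
         paste(field$dim, collapse = "x"), " vs ",
         paste(mask$dim, collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

## World coordinates (mm) of all voxel centres, as an n x 3 matrix in the
## array's storage order (i fastest). 1-based array indices map to world
## position origin + (index - 1) * spacing.
grid_coords <- function(dim, spacing, origin = c(0, 0, 0)) {
  ii <- (seq_len(dim[1]) - 1) * spacing[1] + origin[1]
  jj <- (seq_len(dim[2]) - 1) * spacing[2] + origin[2]
  kk <- (seq_len(dim[3]) - 1) * spacing[3] + origin[3]
  cbind(x = rep(ii, times = dim[2] * dim[3]),
        y = rep(rep(jj, each = dim[1]), times = dim[3]),
        z = rep(kk, each = dim[1] * dim[2]))
}

world_to_index <- function(p, spacing, origin) {
  ## continuous (1-based) voxel index of world point(s) p
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  sweep(sweep(p, 2, origin, "-"), 2, spacing, "/") + 1
}

#' Ordered vessel centerline with arc length and unit tangents
#'
#' @param points n x 3 matrix of ordered world coordinates (mm), n >= 2.
#' @param sampling_step target spacing between points (mm); metadata only.
#' @return An object of class `centerline` with fields `points`,
#'   `arc_length` (cumulative, starting at 0) and `tangents` (unit vectors,
#'   central differences).
#' @export
centerline <- function(points, sampling_step = 1) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("centerline needs an n x 3 matrix with n >= 2", call. = FALSE)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0))
    stop("centerline points must be strictly ordered (positive arc steps)",
         call. = FALSE)
  arc <- c(0, cumsum(seg))
  n <- nrow(points)
  tang <- matrix(0, n, 3)
  tang[1, ] <- points[2, ] - points[1, ]
  tang[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2)
    tang[2:(n - 1), ] <- points[3:n, ] - points[1:(n - 2), ]
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = points, arc_length = arc, tangents = tang,
                 sampling_step = sampling_step),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.1f mm (step %.2g mm)\n",
              nrow(x$points), max(x$arc_length), x$sampling_step))
  invisible(x)
}

#' Interpolate a centerline position and tangent at a given arc length
#' @param cl a `centerline`.
#' @param s arc length (mm), within `[0, max(arc_length)]`.
#' @return list with `point` and `tangent` (unit length).
#' @export
centerline_at <- function(cl, s) {
  arc <- cl$arc_length
  if (s < arc[1] - 1e-9 || s > arc[length(arc)] + 1e-9)
    stop("arc length ", s, " outside centerline range", call. = FALSE)
  s <- min(max(s, arc[1]), arc[length(arc)])
  i <- findInterval(s, arc, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(cl$points) - 1L)
  f <- (s - arc[i]) / (arc[i + 1] - arc[i])
  p <- (1 - f) * cl$points[i, ] + f * cl$points[i + 1, ]
  tg <- (1 - f) * cl$tangents[i, ] + f * cl$tangents[i + 1, ]
  list(point = p, tangent = tg / vnorm(tg))
}

## ---- centerline extraction -------------------------------------------------

## City-block distance (voxel units) to the nearest background voxel,
## computed by layered 6-neighbour dilation of the background.
distance_to_wall <- function(vox) {
  d <- array(0, dim(vox))
  current <- !vox           # background = distance 0
  level <- 0L
  while (!all(current)) {
    level <- level + 1L
    grown <- current
    grown[-1, , ] <- grown[-1, , ] | current[-dim(vox)[1], , ]
    grown[-dim(vox)[1], , ] <- grown[-dim(vox)[1], , ] | current[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | current[, -dim(vox)[2], ]
    grown[, -dim(vox)[2], ] <- grown[, -dim(vox)[2], ] | current[, -1, ]
    grown[, , -1] <- grown[, , -1] | current[, , -dim(vox)[3]]
    grown[, , -dim(vox)[3]] <- grown[, , -dim(vox)[3]] | current[, , -1]
    d[grown & !current] <- level
    current <- grown
  }
  d
}

## 26-neighbourhood offsets (excluding the centre)
neighbor_offsets_26 <- function() {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ])
}

## Edge list between mask voxels for a given offset set; returns two integer
## vectors of linear indices (from, to), each edge once per ordered offset.
mask_edges <- function(vox, offsets) {
  dm <- dim(vox)
  idx <- which(vox)
  pos <- arrayInd(idx, dm)
  lab <- array(0L, dm); lab[idx] <- seq_along(idx)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    q <- pos + matrix(offsets[r, ], nrow(pos), 3, byrow = TRUE)
    ok <- q[, 1] >= 1 & q[, 1] <= dm[1] & q[, 2] >= 1 & q[, 2] <= dm[2] &
          q[, 3] >= 1 & q[, 3] <= dm[3]
    qi <- lab[q[ok, , drop = FALSE]]
    keep <- qi > 0L
    from <- c(from, which(ok)[keep])
    to <- c(to, qi[keep])
  }
  list(from = from, to = to, n = length(idx), pos = pos, idx = idx)
}

#' Extract a vessel centerline between two endpoints
#'
#' Finds the path through the mask that stays maximally far from the wall
#' (Dijkstra shortest path on the 26-connected voxel graph with edge cost
#' equal to the Euclidean step length divided by the mean distance-to-wall of
#' the two voxels), smooths it with a spline, and resamples it at a uniform
#' arc-length step.
#'
#' @param mask a `seg_mask`.
#' @param endpoints 2 x 3 matrix of world coordinates (mm); both must lie
#'   inside the mask.
#' @param sampling_step resampling interval in mm (default 1).
#' @param smooth logical; spline-smooth the raw voxel path (default TRUE).
#' @return A [centerline()].
#' @export
compute_centerline <- function(mask, endpoints, sampling_step = 1,
                               smooth = TRUE) {
  endpoints <- as.matrix(endpoints)
  if (nrow(endpoints) != 2L) stop("need exactly two endpoints", call. = FALSE)
  dm <- mask$dim
  ivox <- round(world_to_index(endpoints, mask$spacing, mask$origin))
  ivox[, 1] <- pmin(pmax(ivox[, 1], 1), dm[1])
  ivox[, 2] <- pmin(pmax(ivox[, 2], 1), dm[2])
  ivox[, 3] <- pmin(pmax(ivox[, 3], 1), dm[3])
  lin <- ivox[, 1] + dm[1] * (ivox[, 2] - 1) + dm[1] * dm[2] * (ivox[, 3] - 1)
  if (!all(mask$voxels[lin]))
    stop("both endpoints must lie inside the mask", call. = FALSE)
  if (lin[1] == lin[2])
    stop("endpoints coincide: degenerate single-segment centerline",
         call. = FALSE)

  dwall <- distance_to_wall(mask$voxels)
  ed <- mask_edges(mask$voxels, neighbor_offsets_26())
  step_mm <- sqrt(rowSums((ed$pos[ed$from, , drop = FALSE] -
                           ed$pos[ed$to, , drop = FALSE])^2 *
                          matrix(mask$spacing^2, length(ed$from), 3,
                                 byrow = TRUE)))
  dw <- dwall[ed$idx]
  w <- step_mm / pmax((dw[ed$from] + dw[ed$to]) / 2, 0.5)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$from, to = ed$to, weight = w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(ed$n)))
  src <- match(lin[1], ed$idx); dst <- match(lin[2], ed$idx)
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = as.character(src),
                           to = as.character(dst), output = "vpath"))
  vp <- as.integer(names(sp$vpath[[1]]))
  if (length(vp) < 2L)
    stop("endpoints are disconnected in the mask", call. = FALSE)
  pts <- (ed$pos[vp, , drop = FALSE] - 1) *
    matrix(mask$spacing, length(vp), 3, byrow = TRUE) +
    matrix(mask$origin, length(vp), 3, byrow = TRUE)

  resample_polyline(pts, sampling_step, smooth = smooth)
}

## Smooth (optionally) and resample a polyline at uniform arc steps.
resample_polyline <- function(pts, sampling_step, smooth = TRUE) {
  seg <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, seg > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  n <- nrow(pts)
  if (smooth && n >= 8) {
    df <- max(4, min(n - 2, ceiling(max(s) / 10)))
    pts <- sapply(1:3, function(a)
      stats::predict(stats::smooth.spline(s, pts[, a], df = df), s)$y)
    s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  }
  s_out <- seq(0, max(s), by = sampling_step)
  if (max(s) - s_out[length(s_out)] > sampling_step / 2)
    s_out <- c(s_out, max(s))
  out <- sapply(1:3, function(a) stats::approx(s, pts[, a], xout = s_out)$y)
  centerline(out, sampling_step = sampling_step)
}

## ---- ROI -------------------------------------------------------------------

## Index of nearest centerline sample for each row of an m x 3 coordinate
## matrix (brute force; centerlines are short).
nearest_cl_index <- function(coords, cl) {
  cp <- cl$points
  ## squared distances via (a-b)^2 = a^2 - 2ab + b^2
  d2 <- outer(rowSums(coords^2), rep(1, nrow(cp))) -
    2 * coords %*% t(cp) + outer(rep(1, nrow(coords)), rowSums(cp^2))
  max.col(-d2, ties.method = "first")
}

#' Define a vessel region of interest by centerline arc-length bounds
#'
#' Every mask voxel is assigned to its nearest centerline sample; the ROI
#' keeps the voxels whose assigned sample has arc length in
#' `[s_start, s_end]`.
#'
#' @param mask a `seg_mask`.
#' @param cl a `centerline`.
#' @param s_start,s_end arc-length bounds in mm, `0 <= s_start < s_end`.
#' @return An object of class `vessel_roi` with `voxel_set` (logical array),
#'   `volume_ml`, `length_mm`, and the bounds.
#' @export
define_roi <- function(mask, cl, s_start = 0, s_end = max(cl$arc_length)) {
  if (!(s_start >= 0 && s_start < s_end))
    stop("need 0 <= s_start < s_end", call. = FALSE)
  if (s_end > max(cl$arc_length) + 1e-6)
    stop("s_end exceeds centerline length", call. = FALSE)
  idx <- which(mask$voxels)
  coords <- grid_coords(mask$dim, mask$spacing, mask$origin)[idx, , drop = FALSE]
  ci <- nearest_cl_index(coords, cl)
  s <- cl$arc_length[ci]
  ## half-open [s_start, s_end) so that adjacent ROIs partition the mask;
  ## closed at the far end of the centerline
  sel <- s >= s_start &
    (s < s_end | s_end >= max(cl$arc_length) - 1e-9 & s <= s_end)
  if (!any(sel)) stop("empty ROI: no mask voxel maps into the arc range",
                      call. = FALSE)
  vox <- array(FALSE, mask$dim)
  vox[idx[sel]] <- TRUE
  structure(list(voxel_set = vox, s_start = s_start, s_end = s_end,
                 volume_ml = sum(sel) * prod(mask$spacing) / 1000,
                 length_mm = s_end - s_start,
                 spacing = mask$spacing, origin = mask$origin),
            class = "vessel_roi")
}

#' @export
print.vessel_roi <- function(x, ...) {
  cat(sprintf("<vessel_roi> arc [%.1f, %.1f] mm, %.1f ml, length %.1f mm\n",
              x$s_start, x$s_end, x$volume_ml, x$length_mm))
  invisible(x)
}

## ---- subject metadata ------------------------------------------------------

#' Body surface area from height and weight
#'
#' DuBois formula `0.007184 * W^0.425 * H^0.725` (the cardiology default for
#' indexing cardiac volumes); Mosteller `sqrt(H*W/3600)` available as an
#' alternative.
#'
#' @param height_cm height in cm (> 0).
#' @param weight_kg weight in kg (> 0).
#' @param formula `"dubois"` (default) or `"mosteller"`.
#' @return body surface area in m^2.
#' @export
body_surface_area <- function(height_cm, weight_kg,
                              formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive", call. = FALSE)
  switch(formula,
         dubois = 0.007184 * weight_kg^0.425 * height_cm^0.725,
         mosteller = sqrt(height_cm * weight_kg / 3600))
}

#' Subject metadata record
#'
#' @param height_cm,weight_kg anthropometrics (> 0).
#' @param heart_rate resting heart rate in 1/min, optional.
#' @param bsa_formula passed to [body_surface_area()].
#' @return list with `height`, `weight`, `bsa` (m^2), `heart_rate`.
#' @export
subject_meta <- function(height_cm, weight_kg, heart_rate = NULL,
                         bsa_formula = "dubois") {
  list(height = height_cm, weight = weight_kg,
       bsa = body_surface_area(height_cm, weight_kg, bsa_formula),
       heart_rate = heart_rate)
}

## ---- run configuration -----------------------------------------------------

#' Default analysis configuration
#'
#' All tunable parameters of the pipeline with their defaults. Values can be
#' overridden by name.
#'
#' @param ... named overrides of the defaults.
#' @return list of parameters (class `case_config`).
#' @export
case_config <- function(...) {
  cfg <- list(
    rho = 1060,              # blood density, kg/m^3
    mu = 0.004,              # dynamic viscosity, Pa s
    tolerance = 1e-6,        # pressure solver stopping threshold, mmHg
    max_iterations = 5000,
    quantile_bounds = c(0.01, 0.99),
    postprocess_scope = "global",  # "global" or "per-phase" clamp/shift
    min_component_ml = 0,    # helix component size filter
    helix_depth_mmHg = 0,    # voxel significance floor for P<0 (phantoms: 0.01)
    connectivity = 26,       # component connectivity
    substeps = 4,            # pathline RK4 substeps per phase interval
    min_helix_fraction = 0.25,  # pathline filter threshold
    seed_stride = 1,
    plane_position = "mid",  # measuring plane arc position
    peak_velocity_mode = "magnitude",  # or "through-plane"
    bsa_formula = "dubois",
    orientation = "LPS",     # stored-axis convention; flips RD labels only
    unwrap = FALSE, eddy_order = 0, noise_std = 0,  # preprocessing (off)
    sampling_step = 1)       # centerline resampling, mm
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(ov)] <- ov
  stopifnot(cfg$rho > 0, cfg$mu >= 0, cfg$tolerance > 0,
            cfg$max_iterations >= 1, cfg$substeps >= 1,
            cfg$min_helix_fraction >= 0, cfg$min_helix_fraction <= 1,
            cfg$connectivity %in% c(6, 18, 26))
  class(cfg) <- "case_config"
  cfg
}
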