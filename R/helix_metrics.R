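## Helix-region extraction within an ROI and the quantitative helix
## parameters: temporal helical existence (TH_Ex), maximum and accumulated
## helical volumes (HV_max, HV_acc), accumulated helical volume length along
## the centerline (HVL_acc), and BSA-indexed volumes (HV(I)).

connectivity_offsets <- function(connectivity) {
  off <- neighbor_offsets_26()
  ord <- rowSums(abs(off))
  switch(as.character(connectivity),
         "6" = off[ord == 1, , drop = FALSE],
         "18" = off[ord <= 2, , drop = FALSE],
         "26" = off,
         stop("connectivity must be 6, 18 or 26", call. = FALSE))
}

## connected components of a logical 3D array; returns integer labels (0 =
## background) via the mask-voxel neighbour graph
label_components <- function(vox, connectivity = 26) {
  lab <- array(0L, dim(vox))
  if (!any(vox)) return(lab)
  ed <- mask_edges(vox, connectivity_offsets(connectivity))
  g <- igraph::graph_from_edgelist(cbind(ed$from, ed$to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, ed$n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[ed$idx] <- as.integer(comp)
  lab
}

#' Extract per-phase helix regions and their temporal union
#'
#' Intersects the helix mask with the ROI at every phase, labels the
#' connected components (26-connectivity by default; helices run obliquely
#' through the grid), discards components smaller than `min_component_ml`,
#' and accumulates the temporal union of all retained voxels (the "temporal
#' maximum intensity projection" of the helix).
#'
#' @param hm a [helix_mask()].
#' @param roi a `vessel_roi` (from [define_roi()]), or a `seg_mask` to use
#'   the whole vessel.
#' @param min_component_ml size filter in ml; the default 0 keeps every
#'   component regardless of size.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return object of class `helix_regions`: `components[[phase]]` is a list
#'   of integer voxel-index vectors, `accumulated` the logical union array,
#'   plus `voxel_volume_ml` and the applied filter.
#' @export
extract_helix_regions <- function(hm, roi, min_component_ml = 0,
                                  connectivity = 26) {
  roi_vox <- if (inherits(roi, "vessel_roi")) roi$voxel_set else roi$voxels
  if (!identical(dim(roi_vox), dim(hm$voxels)[1:3]))
    stop("helix mask and ROI grids are not congruent", call. = FALSE)
  np <- hm$n_phases
  vv_ml <- prod(hm$spacing) / 1000
  min_vox <- ceiling(min_component_ml / vv_ml - 1e-9)
  acc <- array(FALSE, dim(roi_vox))
  comps <- vector("list", np)
  for (p in seq_len(np)) {
    v <- hm$voxels[, , , p] & roi_vox
    if (!any(v)) { comps[[p]] <- list(); next }
    lab <- label_components(v, connectivity)
    idx <- which(lab > 0L)
    cl <- split(idx, lab[idx])
    cl <- cl[lengths(cl) >= max(min_vox, 1L)]
    comps[[p]] <- unname(cl)
    for (cc in cl) acc[cc] <- TRUE
  }
  structure(list(components = comps, accumulated = acc,
                 n_phases = np, voxel_volume_ml = vv_ml,
                 min_component_ml = min_component_ml,
                 spacing = hm$spacing, origin = hm$origin),
            class = "helix_regions")
}

#' @export
print.helix_regions <- function(x, ...) {
  cat(sprintf("<helix_regions> %d phases, %d with helix, accumulated %.2f ml\n",
              x$n_phases, sum(lengths(x$components) > 0),
              sum(x$accumulated) * x$voxel_volume_ml))
  invisible(x)
}

#' Temporal helical existence (TH_Ex)
#'
#' Duration of helical flow over the cardiac cycle: the number of phases
#' with at least one retained helix component (regardless of size or number
#' of helices) times the temporal resolution; also as percent of the cycle.
#'
#' @param rs a `helix_regions` set.
#' @param dt temporal resolution (ms).
#' @param cycle_length cardiac cycle duration (ms).
#' @return list with `th_ex_abs_ms` and `th_ex_rel_pct`.
#' @export
temporal_helical_existence <- function(rs, dt, cycle_length) {
  stopifnot(dt > 0, cycle_length >= dt)
  n <- sum(vapply(rs$components, length, integer(1)) > 0L)
  list(th_ex_abs_ms = dt * n,
       th_ex_rel_pct = 100 * dt * n / cycle_length)
}

#' Per-phase and accumulated helical volumes (HV_max, HV_acc)
#'
#' `hv_series` is the retained helix volume per phase (ml); `hv_max` its
#' maximum (with the phase index); `hv_acc` the volume of the temporal
#' union. Relative values are percent of the (static) ROI volume.
#'
#' @param rs a `helix_regions` set.
#' @param roi the `vessel_roi` the regions were extracted in.
#' @return list with `hv_series_ml`, `hv_max_ml`, `hv_max_pct`,
#'   `hv_max_phase`, `hv_acc_ml`, `hv_acc_pct`.
#' @export
helical_volumes <- function(rs, roi) {
  vv <- rs$voxel_volume_ml
  series <- vapply(rs$components,
                   function(cl) sum(lengths(cl)) * vv, numeric(1))
  hv_max <- max(series)
  acc_ml <- sum(rs$accumulated) * vv
  list(hv_series_ml = series,
       hv_max_ml = hv_max,
       hv_max_pct = 100 * hv_max / roi$volume_ml,
       hv_max_phase = which.max(series),
       hv_acc_ml = acc_ml,
       hv_acc_pct = 100 * acc_ml / roi$volume_ml)
}

#' Accumulated helical volume length (HVL_acc)
#'
#' Maps every voxel of the accumulated helix to its nearest centerline
#' sample and measures the centerline length covered by the voxels' axial
#' footprints: each covered arc position contributes an interval of half a
#' voxel to either side, and the union of these intervals (clipped to the
#' ROI arc range) is summed. Coverage, not the max-min arc span, so axially
#' split helices are not overcounted; the footprint half-width keeps the
#' measure independent of the centerline sampling step when voxels are
#' coarser than the samples. Relative value is percent of the ROI
#' centerline length, capped at 100.
#'
#' @param rs a `helix_regions` set.
#' @param cl a `centerline` covering the ROI arc range.
#' @param roi the `vessel_roi`.
#' @return list with `hvl_acc_mm` and `hvl_acc_pct`.
#' @export
accumulated_helix_length <- function(rs, cl, roi) {
  idx <- which(rs$accumulated)
  if (length(idx) == 0L) return(list(hvl_acc_mm = 0, hvl_acc_pct = 0))
  coords <- grid_coords(dim(rs$accumulated), rs$spacing, rs$origin)[idx, ,
                                                                    drop = FALSE]
  ci <- nearest_cl_index(coords, cl)
  arcs <- sort(unique(cl$arc_length[ci]))
  halfw <- max(rs$spacing) / 2
  lo <- pmax(arcs - halfw, roi$s_start)
  hi <- pmin(arcs + halfw, roi$s_end)
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]
  if (length(lo) == 0L) return(list(hvl_acc_mm = 0, hvl_acc_pct = 0))
  ## merge overlapping intervals (already sorted by lo)
  hvl <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
    else { hvl <- hvl + (cur_hi - cur_lo); cur_lo <- lo[i]; cur_hi <- hi[i] }
  }
  hvl <- hvl + (cur_hi - cur_lo)
  list(hvl_acc_mm = hvl,
       hvl_acc_pct = min(100, 100 * hvl / roi$length_mm))
}

#' Helical volume index: volume normalized to body surface area
#'
#' @param hv_ml helix volume (ml).
#' @param meta a [subject_meta()] (uses `bsa`).
#' @return index in ml/m^2.
#' @export
helical_volume_index <- function(hv_ml, meta) {
  if (is.null(meta$bsa) || meta$bsa <= 0)
    stop("subject BSA must be positive", call. = FALSE)
  hv_ml / meta$bsa
}

#' All helix parameters for one case
#'
#' Convenience wrapper combining [temporal_helical_existence()],
#' [helical_volumes()], [accumulated_helix_length()] and (when subject
#' metadata is given) [helical_volume_index()].
#'
#' @param rs a `helix_regions` set.
#' @param roi the `vessel_roi`.
#' @param cl the `centerline`.
#' @param dt,cycle_length timing (ms).
#' @param meta optional [subject_meta()] for the BSA indices.
#' @return object of class `helix_metrics` (a named list).
#' @export
helix_metrics <- function(rs, roi, cl, dt, cycle_length, meta = NULL) {
  out <- c(temporal_helical_existence(rs, dt, cycle_length),
           helical_volumes(rs, roi),
           accumulated_helix_length(rs, cl, roi))
  if (!is.null(meta)) {
    out$hvi_max_ml_m2 <- helical_volume_index(out$hv_max_ml, meta)
    out$hvi_acc_ml_m2 <- helical_volume_index(out$hv_acc_ml, meta)
  } else {
    out$hvi_max_ml_m2 <- NA_real_
    out$hvi_acc_ml_m2 <- NA_real_
  }
  class(out) <- "helix_metrics"
  out
}

#' @export
print.helix_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<helix_metrics>\n",
           "  TH_Ex   %.1f ms (%.1f%% of cycle)\n",
           "  HV_max  %.2f ml (%.1f%%) at phase %d\n",
           "  HV_acc  %.2f ml (%.1f%%)\n",
           "  HVL_acc %.1f mm (%.1f%%)\n",
           "  HV(I)   max %.2f / acc %.2f ml/m2\n"),
    x$th_ex_abs_ms, x$th_ex_rel_pct, x$hv_max_ml, x$hv_max_pct,
    x$hv_max_phase, x$hv_acc_ml, x$hv_acc_pct, x$hvl_acc_mm, x$hvl_acc_pct,
    x$hvi_max_ml_m2, x$hvi_acc_ml_m2))
  invisible(x)
}

#' Write helix metrics as a one-row CSV / JSON
#'
#' Column names: `th_ex_abs_ms, th_ex_rel_pct, hv_max_ml, hv_max_pct,
#' hv_acc_ml, hv_acc_pct, hvl_acc_mm, hvl_acc_pct, hvi_max_ml_m2,
#' hvi_acc_ml_m2`.
#'
#' @param hm a `helix_metrics` object.
#' @param path output path; extension selects the format (`.csv` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_helix_metrics <- function(hm, path) {
  cols <- c("th_ex_abs_ms", "th_ex_rel_pct", "hv_max_ml", "hv_max_pct",
            "hv_acc_ml", "hv_acc_pct", "hvl_acc_mm", "hvl_acc_pct",
            "hvi_max_ml_m2", "hvi_acc_ml_m2")
  row <- hm[cols]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(row, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    utils::write.csv(as.data.frame(row), path, row.names = FALSE)
  }
  invisible(path)
}
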