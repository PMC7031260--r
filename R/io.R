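## File I/O: NIfTI velocity/mask volumes, case bundles, centerline CSV.

#' Load a 4D flow case from NIfTI component files
#'
#' Reads one 4D NIfTI file per velocity component plus a binary mask and
#' assembles a [velocity_field()] / [seg_mask()] pair. Velocities are
#' converted to m/s internally.
#'
#' @param velocity_paths character length-3: NIfTI paths for the x, y, z
#'   component series (each `nx x ny x nz x n_phases`).
#' @param mask_path NIfTI path of the binary segmentation.
#' @param meta list with `spacing` (mm, length 3), `dt` (ms), `cycle_length`
#'   (ms), `units` ("m/s" or "cm/s"), and optionally `origin`, `venc`
#'   (cm/s), `height`, `weight`.
#' @return list with elements `field` and `mask`.
#' @export
load_case <- function(velocity_paths, mask_path, meta) {
  if (length(velocity_paths) != 3L)
    stop("need exactly three velocity component files", call. = FALSE)
  for (f in c(velocity_paths, mask_path))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  need <- c("spacing", "dt", "cycle_length", "units")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata error: missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  comp <- lapply(velocity_paths, function(f) {
    a <- as.array(RNifti::readNifti(f))
    if (length(dim(a)) == 3L) a <- array(a, c(dim(a), 1L))
    a
  })
  dims <- lapply(comp, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("shape mismatch between velocity components", call. = FALSE)
  mk <- as.array(RNifti::readNifti(mask_path))
  if (length(dim(mk)) == 4L) mk <- mk[, , , 1]
  if (!identical(as.integer(dim(mk)), as.integer(dims[[1]][1:3])))
    stop("shape mismatch between mask (", paste(dim(mk), collapse = "x"),
         ") and velocity grid (", paste(dims[[1]][1:3], collapse = "x"), ")",
         call. = FALSE)
  divisor <- switch(meta$units, "m/s" = 1, "cm/s" = 100,
                    stop("units must be 'm/s' or 'cm/s'", call. = FALSE))
  dm <- dims[[1]]
  vals <- array(0, c(dm[1:3], 3, dm[4]))
  for (c3 in 1:3) vals[, , , c3, ] <- comp[[c3]] / divisor
  origin <- if (!is.null(meta$origin)) meta$origin else c(0, 0, 0)
  field <- velocity_field(vals, meta$spacing, meta$dt, meta$cycle_length,
                          origin = origin, venc = meta$venc)
  mask <- seg_mask(mk > 0.5, meta$spacing, origin)
  list(field = field, mask = mask)
}

#' Write a case bundle to a directory
#'
#' Writes `vel_x/y/z.nii.gz`, `mask.nii.gz`, `meta.yaml`, optionally
#' `centerline.csv` and `ground_truth.json`. The inverse of [read_case()].
#'
#' @param dir output directory (created if needed).
#' @param field a `velocity_field`.
#' @param mask a `seg_mask`.
#' @param cl optional `centerline`.
#' @param ground_truth optional list (phantom ground truth).
#' @param meta optional extra metadata entries (height, weight, ...).
#' @return `dir`, invisibly.
#' @export
write_case <- function(dir, field, mask, cl = NULL, ground_truth = NULL,
                       meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comp_names <- c("vel_x.nii.gz", "vel_y.nii.gz", "vel_z.nii.gz")
  for (c3 in 1:3)
    RNifti::writeNifti(field$values[, , , c3, ],
                       file.path(dir, comp_names[c3]), datatype = "double")
  RNifti::writeNifti(array(as.integer(mask$voxels), mask$dim),
                     file.path(dir, "mask.nii.gz"))
  m <- utils::modifyList(list(
    spacing = field$spacing, dt = field$dt,
    cycle_length = field$cycle_length, origin = field$origin,
    units = "m/s", venc = field$venc), meta)
  yaml::write_yaml(m, file.path(dir, "meta.yaml"))
  if (!is.null(cl)) write_centerline_csv(cl, file.path(dir, "centerline.csv"))
  if (!is.null(ground_truth))
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a case bundle written by [write_case()]
#' @param dir case directory.
#' @return list with `field`, `mask`, and (if present) `centerline`,
#'   `ground_truth`, `meta`.
#' @export
read_case <- function(dir) {
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(meta_path))
    stop("not a case bundle (missing meta.yaml): ", dir, call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  meta$spacing <- as.numeric(meta$spacing)
  meta$origin <- as.numeric(meta$origin)
  lc <- load_case(file.path(dir, c("vel_x.nii.gz", "vel_y.nii.gz",
                                   "vel_z.nii.gz")),
                  file.path(dir, "mask.nii.gz"), meta)
  out <- list(field = lc$field, mask = lc$mask, meta = meta)
  clp <- file.path(dir, "centerline.csv")
  if (file.exists(clp)) out$centerline <- read_centerline_csv(clp)
  gtp <- file.path(dir, "ground_truth.json")
  if (file.exists(gtp)) out$ground_truth <- jsonlite::read_json(
    gtp, simplifyVector = TRUE)
  out
}

#' Write / read a centerline as CSV (`x_mm,y_mm,z_mm,arc_mm`)
#' @param cl a `centerline`.
#' @param path CSV path.
#' @return `path` (write) or a `centerline` (read).
#' @export
write_centerline_csv <- function(cl, path) {
  df <- data.frame(x_mm = cl$points[, 1], y_mm = cl$points[, 2],
                   z_mm = cl$points[, 3], arc_mm = cl$arc_length)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("centerline CSV needs columns x_mm,y_mm,z_mm", call. = FALSE)
  step <- if (nrow(df) > 1)
    stats::median(diff(if ("arc_mm" %in% names(df)) df$arc_mm
                       else seq_len(nrow(df)))) else 1
  centerline(as.matrix(df[, need]), sampling_step = step)
}

#' Export a per-voxel, per-phase scalar (e.g. pressure) as 4D NIfTI
#' @param values 4D array (`nx x ny x nz x n_phases`).
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_scalar_nifti <- function(values, path) {
  RNifti::writeNifti(values, path)
  invisible(path)
}
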