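#!/usr/bin/env Rscript

# Thin command-line wrapper over the helixflow package.
#
#   Rscript scripts/helixflow.R synth --preset gated-helix --seed 7 --out case/
#   Rscript scripts/helixflow.R run case/ [--depth 0.01] [--out case/out]
#   Rscript scripts/helixflow.R compare a.csv b.csv --out agreement.json
#
# `synth` writes a phantom case bundle (NIfTI velocity components + mask,
# meta.yaml, centerline.csv, ground_truth.json); `run` executes the full
# pressure -> helix -> pathline -> rotation -> flow pipeline on a bundle;
# `compare` computes paired agreement statistics between two one-row-per-case
# metric tables sharing a column layout.

suppressPackageStartupMessages(library(helixflow))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: helixflow.R <synth|run|compare> ...")
cmd <- args[1]
opts <- args[-1]
get_opt <- function(flag, default = NULL) {
  i <- which(opts == flag)
  if (length(i) == 1 && i < length(opts)) opts[i + 1] else default
}
positional <- function() opts[!grepl("^--", opts) &
                              !seq_along(opts) %in% (which(grepl("^--", opts)) + 1)]

if (cmd == "synth") {
  preset <- get_opt("--preset", "gated-helix")
  seed <- as.integer(get_opt("--seed", "1"))
  out <- get_opt("--out", paste0(preset, "-case"))
  ph <- make_tube_phantom(phantom_preset(preset, seed = seed))
  write_case(out, ph$field, ph$mask, ph$centerline, ph$ground_truth)
  message("wrote phantom bundle to ", out)
} else if (cmd == "run") {
  dirs <- positional()
  if (length(dirs) != 1) stop("run needs exactly one case directory")
  cfg <- case_config(
    helix_depth_mmHg = as.numeric(get_opt("--depth", "0")),
    min_component_ml = as.numeric(get_opt("--min-component", "0")),
    substeps = as.integer(get_opt("--substeps", "4")),
    unwrap = !is.null(get_opt("--venc")),
    eddy_order = as.integer(get_opt("--eddy-order", "0")))
  out <- get_opt("--out", file.path(dirs, "out"))
  res <- run_pipeline(dirs, cfg, out_dir = out)
  print(res$metrics)
  cat(sprintf("net flow %.1f ml/cycle, peak velocity %.2f m/s\n",
              res$flow$net_flow_ml_per_cycle, res$flow$peak_velocity_m_s))
  message("artifacts in ", out)
} else if (cmd == "compare") {
  files <- positional()
  if (length(files) != 2) stop("compare needs two metrics CSV files")
  a <- utils::read.csv(files[1]); b <- utils::read.csv(files[2])
  shared <- intersect(names(a), names(b))
  out <- lapply(shared, function(col) {
    if (!is.numeric(a[[col]])) return(NULL)
    unclass(agreement_report(a[[col]], b[[col]]))
  })
  names(out) <- shared
  out <- Filter(Negate(is.null), out)
  path <- get_opt("--out", "agreement.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  message("wrote ", path)
} else {
  stop("unknown command: ", cmd)
}
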