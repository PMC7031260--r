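## Paired agreement statistics for helix-metric tables (two scanners, two
## observers, two noise realizations): Bland-Altman bias and limits of
## agreement, Wilcoxon signed-rank (exact for small n), Pearson
## correlation, and ICC(2,1) absolute agreement. Plus the end-to-end
## pipeline runner.

#' Bland-Altman bias and limits of agreement
#'
#' Differences `d = a - b` per subject; bias is their mean and the limits
#' of agreement are `bias +/- 1.96 sd(d)` (sample sd, the conventional
#' multiplier rather than a small-sample t quantile).
#'
#' @param a,b paired measurements (equal length >= 2, finite).
#' @return list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("need paired vectors of equal length >= 2", call. = FALSE)
  d <- a - b
  if (!all(is.finite(d))) stop("differences must be finite", call. = FALSE)
  s <- stats::sd(d)
  bias <- mean(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}

## exact two-sided signed-rank p-value by dynamic programming over the
## generating function prod_i (1 + x^(2 r_i)) (doubled midranks keep ties
## integral)
signed_rank_exact_p <- function(ranks2, w2) {
  total <- sum(ranks2)
  f <- numeric(total + 1); f[1] <- 1          # f[k+1] = #subsets with sum k
  for (r in ranks2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f <- f / sum(f)
  lo <- sum(f[seq_len(floor(w2 + 1e-9) + 1)])          # P(W2 <= w2)
  hi <- sum(f[(ceiling(w2 - 1e-9) + 1):(total + 1)])   # P(W2 >= w2)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on the differences `a - b`. Zero differences are handled
#' by the Pratt method: they take part in the ranking of `|d|` and their
#' ranks are then discarded. The exact null distribution (enumerated by
#' dynamic programming over the subset-sum generating function, valid with
#' midrank ties) is used up to `exact_max` nonzero differences; above that
#' a normal approximation with tie correction.
#'
#' @param a,b paired measurements.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list with `p`, `statistic` (W+, midranks), `n_nonzero`,
#'   `method`, and `all_zero` flag (p = 1 by convention when every
#'   difference is zero).
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25) {
  if (length(a) != length(b)) stop("unequal lengths", call. = FALSE)
  d <- a - b
  if (all(d == 0))
    return(list(p = 1, statistic = 0, n_nonzero = 0L, method = "degenerate",
                all_zero = TRUE))
  r <- rank(abs(d))                   # Pratt: zeros participate in ranking
  nz <- d != 0
  rnz <- r[nz]
  w_plus <- sum(rnz[d[nz] > 0])
  n <- sum(nz)
  if (n <= exact_max) {
    p <- signed_rank_exact_p(round(2 * rnz), 2 * w_plus)
    method <- "exact"
  } else {
    ## normal approximation, Pratt-adjusted moments with tie correction
    mu <- sum(rnz) / 2
    sigma2 <- sum(rnz^2) / 4
    z <- (w_plus - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(p = p, statistic = w_plus, n_nonzero = n, method = method,
       all_zero = FALSE)
}

#' Intraclass correlation ICC(2,1): two-way random, absolute agreement
#'
#' Single-measurement ICC from the two-way mean-squares decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `MSR` the
#' between-subject, `MSC` the between-rater and `MSE` the residual mean
#' square. Undefined (flagged, NA) when the between-subject mean square
#' does not exceed the residual, i.e. no detectable subject variance.
#'
#' @param ratings n x k matrix: n subjects (>= 3) by k raters (>= 2).
#' @return list with `icc`, `msr`, `msc`, `mse`, `defined`.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 raters", call. = FALSE)
  gm <- mean(ratings)
  rm <- rowMeans(ratings); cm <- colMeans(ratings)
  msr <- k * sum((rm - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  sse <- sum((ratings - outer(rm, rep(1, k)) -
              outer(rep(1, n), cm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= mse + 1e-12 * max(1, abs(msr)))
    return(list(icc = NA_real_, msr = msr, msc = msc, mse = mse,
                defined = FALSE))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, msr = msr, msc = msc, mse = mse, defined = TRUE)
}

#' Full paired agreement report
#'
#' Wilcoxon signed-rank p, Pearson correlation, Bland-Altman bias/LOA and
#' ICC(2,1) for one metric measured under two conditions.
#'
#' @param a,b paired measurements (length >= 3).
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return list of class `agreement_report` with `wilcoxon_p`,
#'   `correlation_r`, `bias`, `loa_low`, `loa_high`, `icc`, `n`.
#' @export
agreement_report <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b) || length(a) < 3)
    stop("need paired vectors of equal length >= 3", call. = FALSE)
  ba <- bland_altman(a, b)
  ic <- icc_agreement(cbind(a, b))
  structure(list(
    wilcoxon_p = wilcoxon_signed_rank(a, b)$p,
    correlation_r = stats::cor(a, b, method = method),
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    icc = ic$icc, n = length(a)),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> n=%d  r=%.3f  p(Wilcoxon)=%.3g  bias=%.3g  LOA [%.3g, %.3g]  ICC=%.3f\n",
    x$n, x$correlation_r, x$wilcoxon_p, x$bias, x$loa_low, x$loa_high,
    x$icc))
  invisible(x)
}

## ---- pipeline runner -------------------------------------------------------

#' Run the full analysis pipeline on a case bundle
#'
#' Executes, in order: optional preprocessing (aliasing repair, eddy-current
#' fit, noise mask), pressure mapping, helix-region extraction and metrics,
#' pathline integration with helix filtering, rotation-direction
#' classification, and measuring-plane flow quantification. Writes
#' `metrics.json`, `metrics.csv`, `pathlines.csv`, `flow_quant.json` and
#' `run_log.json` into `out_dir`. Deterministic: identical input and
#' configuration produce byte-identical outputs.
#'
#' @param case_dir directory holding a case bundle (see [write_case()]).
#' @param cfg a [case_config()].
#' @param out_dir output directory (default `file.path(case_dir, "out")`).
#' @param roi_range optional `c(s_start, s_end)` arc-length bounds (mm);
#'   default: the whole centerline.
#' @param meta optional [subject_meta()] for BSA indices.
#' @return list with `metrics`, `rd_counts`, `flow`, `pressure` (the map),
#'   `lines`, invisibly writable artifacts in `out_dir`.
#' @export
run_pipeline <- function(case_dir, cfg = case_config(),
                         out_dir = file.path(case_dir, "out"),
                         roi_range = NULL, meta = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cs <- stage("io", read_case(case_dir))
  field <- cs$field; mask <- cs$mask
  reports <- list()
  if (isTRUE(cfg$unwrap)) {
    up <- stage("preprocess", unwrap_phase(field))
    field <- up$field; reports$unwrap <- up$report
  }
  if (cfg$eddy_order > 0) {
    static <- seg_mask(!mask$voxels, mask$spacing, mask$origin)
    ec <- stage("preprocess", correct_eddy_currents(field, static,
                                                    cfg$eddy_order))
    field <- ec$field; reports$eddy <- ec$report
  }
  cl <- if (!is.null(cs$centerline)) cs$centerline else
    stop("[centerline] case bundle has no centerline.csv; supply one",
         call. = FALSE)
  if (is.null(roi_range)) roi_range <- c(0, max(cl$arc_length))
  roi <- stage("roi", define_roi(mask, cl, roi_range[1], roi_range[2]))
  pm <- stage("pressure", compute_pressure_map(field, mask, cfg))
  hm <- stage("pressure", helix_mask(pm, cfg$helix_depth_mmHg))
  rs <- stage("helix_metrics",
              extract_helix_regions(hm, roi, cfg$min_component_ml,
                                    cfg$connectivity))
  hx <- stage("helix_metrics",
              helix_metrics(rs, roi, cl, field$dt, field$cycle_length, meta))
  ## pathlines seeded at the phase of maximum helix volume
  seed_phase <- hx$hv_max_phase
  seeds <- stage("pathlines", seed_helix(hm, seed_phase, cfg$seed_stride))
  lines <- stage("pathlines",
                 integrate_pathlines(field, seeds, mask, seed_phase,
                                     cfg$substeps))
  lines <- stage("pathlines",
                 filter_pathlines(lines, hm, field$dt,
                                  cfg$min_helix_fraction))
  rd <- stage("rotation_direction",
              classify_pathlines(lines, cl, cfg$orientation))
  plane <- stage("flow_quant",
                 measuring_plane(cl, roi, mask, cfg$plane_position))
  flow <- list(net_flow_ml_per_cycle = stage("flow_quant",
                                             net_forward_flow(field, plane)),
               peak_velocity_m_s = stage("flow_quant",
                                         peak_velocity(field, plane,
                                                       cfg$peak_velocity_mode)),
               plane_arc_mm = plane$s)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_helix_metrics(hx, file.path(out_dir, "metrics.json"))
  write_helix_metrics(hx, file.path(out_dir, "metrics.csv"))
  write_pathlines_csv(rd$lines, file.path(out_dir, "pathlines.csv"))
  jsonlite::write_json(flow, file.path(out_dir, "flow_quant.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- list(config = unclass(cfg),
              rd_counts = as.list(rd$counts),
              n_pathlines = length(rd$lines),
              preprocess = reports,
              solver = list(converged = pm$converged,
                            iterations = pm$iterations),
              seed = cs$ground_truth$seed)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(metrics = hx, rd_counts = rd$counts, flow = flow,
                 pressure = pm, lines = rd$lines, roi = roi,
                 reports = reports))
}
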