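## Rotation-direction (handedness) classification of pathlines about the
## vessel centerline. Each pathline segment is projected into the vessel
## cross-section at the nearest centerline point; the sign of the in-plane
## rotation angle between the projected endpoints labels the segment
## right-handed (RD+) or left-handed (RD-), and a majority vote over the
## segments labels the line. A single signed-angle rule reproduces the
## quadrant cases (first->second quadrant: RD+; fourth->third: RD-;
## diagonal quadrants: decided by where the connecting line crosses the
## y-axis) without case analysis.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Cross-section frame at the centerline point nearest to a position
#'
#' The plane is centred at the nearest centerline sample `c` with normal
#' equal to the tangent `n` there. The in-plane x-axis is
#' `nx = normalize(n x (1,0,0))` and the y-axis `ny = normalize(nx x n)`.
#' When the tangent is (near) parallel to the world x-axis the crossing
#' axis falls back to world (0,1,0).
#'
#' @param cl a `centerline`.
#' @param point world position (mm).
#' @return list of class `cross_section_frame` with `c`, `n`, `nx`, `ny`
#'   (all unit length, mutually orthogonal) and `index` of the centerline
#'   sample.
#' @export
cross_section_frame <- function(cl, point) {
  i <- nearest_cl_index(matrix(point, 1, 3), cl)
  n <- cl$tangents[i, ]
  ax <- c(1, 0, 0)
  v <- cross3(n, ax)
  if (vnorm(v) < 1e-6) {        # tangent parallel to world x: fall back
    ax <- c(0, 1, 0)
    v <- cross3(n, ax)
  }
  nx <- v / vnorm(v)
  ny <- cross3(nx, n)
  ny <- ny / vnorm(ny)
  structure(list(c = cl$points[i, ], n = n, nx = nx, ny = ny, index = i),
            class = "cross_section_frame")
}

#' Classify one pathline segment as right- or left-handed
#'
#' Projects both endpoints into the frame's `(nx, ny)` plane and takes the
#' sign of the shortest signed angle from the first to the second projected
#' point: +1 is a right-handed (RD+) segment, -1 left-handed (RD-), 0
#' degenerate (zero projected radius or no angular motion). The quadrant of
#' each projection and the applied rule (`adjacent`, `diagonal` or
#' `degenerate`) are reported for inspection.
#'
#' @param p_first,p_second segment endpoints, world coordinates (mm).
#' @param frame a [cross_section_frame()].
#' @return list with `rd` (+1/-1/0), `quadrant_first`, `quadrant_second`,
#'   `rule`, and `angle` (signed, radians).
#' @export
classify_segment <- function(p_first, p_second, frame) {
  u1 <- c(sum((p_first - frame$c) * frame$nx),
          sum((p_first - frame$c) * frame$ny))
  u2 <- c(sum((p_second - frame$c) * frame$nx),
          sum((p_second - frame$c) * frame$ny))
  quad <- function(u) {
    if (u[1] >= 0 && u[2] >= 0) 1L
    else if (u[1] < 0 && u[2] >= 0) 2L
    else if (u[1] < 0) 3L else 4L
  }
  r1 <- vnorm(u1); r2 <- vnorm(u2)
  if (r1 < 1e-12 || r2 < 1e-12)
    return(list(rd = 0L, quadrant_first = quad(u1),
                quadrant_second = quad(u2), rule = "degenerate", angle = 0))
  ang <- atan2(u1[1] * u2[2] - u1[2] * u2[1], sum(u1 * u2))
  q1 <- quad(u1); q2 <- quad(u2)
  rule <- if (abs(ang) < 1e-9) "degenerate"
    else if (abs(q1 - q2) == 2L) "diagonal" else "adjacent"
  rd <- if (abs(ang) < 1e-9) 0L else as.integer(sign(ang))
  list(rd = rd, quadrant_first = q1, quadrant_second = q2, rule = rule,
       angle = ang)
}

#' Classify a pathline as RD+ or RD-
#'
#' Every segment (consecutive sample pair) is classified in the
#' cross-section frame at the centerline point nearest its first sample;
#' the line label is the majority vote over the nonzero segment labels
#' (`"RD+"`, `"RD-"`, or `"indeterminate"` on a tie or when no segment
#' rotates). With `orientation = "RAS"` the reported label (not the
#' internal sign) is flipped, reflecting the mirrored axis convention.
#'
#' @param line a `pathline` (>= 2 samples).
#' @param cl a `centerline`.
#' @param orientation `"LPS"` (default) or `"RAS"`.
#' @return the `pathline` with `rd_label` set and attributes
#'   `n_pos`/`n_neg` (segment counts).
#' @export
classify_pathline <- function(line, cl, orientation = c("LPS", "RAS")) {
  orientation <- match.arg(orientation)
  sm <- line$samples
  if (nrow(sm) < 2L) stop("pathline needs at least 2 samples", call. = FALSE)
  npos <- 0L; nneg <- 0L
  for (i in seq_len(nrow(sm) - 1L)) {
    fr <- cross_section_frame(cl, sm[i, 2:4])
    s <- classify_segment(sm[i, 2:4], sm[i + 1, 2:4], fr)
    if (s$rd > 0) npos <- npos + 1L
    else if (s$rd < 0) nneg <- nneg + 1L
  }
  lab <- if (npos > nneg) "RD+" else if (nneg > npos) "RD-" else
    "indeterminate"
  if (orientation == "RAS" && lab != "indeterminate")
    lab <- if (lab == "RD+") "RD-" else "RD+"
  line$rd_label <- lab
  attr(line, "n_pos") <- npos
  attr(line, "n_neg") <- nneg
  line
}

#' Rotation-direction summary over a set of pathlines
#'
#' @param lines list of `pathline` objects.
#' @param cl a `centerline`.
#' @param orientation passed to [classify_pathline()].
#' @return list with the classified `lines` and `counts` (named: `RD+`,
#'   `RD-`, `indeterminate`).
#' @export
classify_pathlines <- function(lines, cl, orientation = "LPS") {
  lines <- lapply(lines, classify_pathline, cl = cl,
                  orientation = orientation)
  labs <- vapply(lines, function(l) l$rd_label, character(1))
  counts <- c("RD+" = sum(labs == "RD+"), "RD-" = sum(labs == "RD-"),
              indeterminate = sum(labs == "indeterminate"))
  list(lines = lines, counts = counts)
}
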