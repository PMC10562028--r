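#' CT volume container
#'
#' Hounsfield units on a rectilinear grid in the DICOM patient frame.
#'
#' @param hu 3-D array of Hounsfield units (finite).
#' @param origin,spacing grid geometry, mm (see [grid3d()]).
#' @param orientation 3x3 direction-cosine matrix (rows/cols/slices);
#'   only the identity is supported downstream.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(hu, origin, spacing, orientation = diag(3)) {
  stopifnot(length(dim(hu)) == 3L)
  if (any(!is.finite(hu))) stop("ct_volume: HU values must be finite")
  g <- grid3d(origin, spacing, dim(hu))
  structure(list(hu = hu, grid = g, orientation = orientation),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("CT volume:", format(x$grid), "\n")
  cat(sprintf("  HU range [%d, %d]\n", round(min(x$hu)), round(max(x$hu))))
  invisible(x)
}

#' TPS dose grid container
#'
#' @param dose 3-D array, Gy, all >= 0.
#' @param origin,spacing grid geometry, mm.
#' @return object of class `tps_dose`.
#' @export
tps_dose <- function(dose, origin, spacing) {
  stopifnot(length(dim(dose)) == 3L)
  if (any(dose < 0)) stop("tps_dose: dose must be non-negative")
  structure(list(dose = dose, grid = grid3d(origin, spacing, dim(dose))),
            class = "tps_dose")
}

#' VMAT control point
#'
#' Machine state sampled along an arc: gantry angle, jaw rectangle, MLC leaf
#' positions (two banks projected to the isocenter plane) and the cumulative
#' meterset weight.
#'
#' @param gantry_deg gantry angle, degrees (wrapped to `[0, 360)`).
#' @param jaws named numeric `c(x1=,x2=,y1=,y2=)`, mm at isocenter.
#' @param mlc_a,mlc_b per-leaf-pair leaf-tip positions, mm at isocenter;
#'   bank A (left) must not cross bank B (right): `mlc_a <= mlc_b`.
#' @param cum_weight cumulative meterset weight in `[0, 1]`.
#' @return object of class `control_point`.
#' @export
control_point <- function(gantry_deg, jaws, mlc_a, mlc_b, cum_weight) {
  jaws <- as.numeric(jaws); names(jaws) <- c("x1", "x2", "y1", "y2")
  if (jaws["x1"] > jaws["x2"] || jaws["y1"] > jaws["y2"])
    stop("control_point: jaws must satisfy x1<=x2, y1<=y2")
  if (length(mlc_a) != length(mlc_b))
    stop("control_point: MLC banks must have equal leaf counts")
  crossed <- which(mlc_a > mlc_b + 1e-9)
  if (length(crossed))
    stop(sprintf("control_point: crossed leaves at pair(s) %s",
                 paste(crossed, collapse = ", ")))
  if (cum_weight < -1e-12 || cum_weight > 1 + 1e-12)
    stop("control_point: cum_weight must lie in [0, 1]")
  structure(list(gantry_deg = gantry_deg %% 360, jaws = jaws,
                 mlc_a = as.numeric(mlc_a), mlc_b = as.numeric(mlc_b),
                 cum_weight = min(max(cum_weight, 0), 1)),
            class = "control_point")
}

#' VMAT arc beam
#'
#' @param energy one of `"6X"`, `"6FFF"`, `"10X"`, `"10FFF"`.
#' @param beam_mu monitor units for the arc, > 0 (0 allowed for QA plans).
#' @param control_points ordered list of [control_point()]s (>= 2); cumulative
#'   weights must be non-decreasing from 0 to 1.
#' @param leaf_edges leaf-pair boundary positions along y at isocenter,
#'   mm, length `n_pairs + 1`, ascending.
#' @param is_arc logical; static (non-arc) beams are flagged, not rejected.
#' @return object of class `arc_beam`.
#' @export
arc_beam <- function(energy, beam_mu, control_points, leaf_edges,
                     is_arc = TRUE) {
  energy <- match.arg(energy, supported_energies())
  if (length(control_points) < 2L)
    stop("arc_beam: need >= 2 control points")
  w <- vapply(control_points, function(cp) cp$cum_weight, numeric(1))
  if (any(diff(w) < -1e-9))
    stop("arc_beam: cumulative meterset weights must be non-decreasing")
  if (abs(w[1]) > 1e-9 || abs(w[length(w)] - 1) > 1e-9)
    stop("arc_beam: cumulative weights must run from 0 to 1")
  npairs <- length(control_points[[1]]$mlc_a)
  if (length(leaf_edges) != npairs + 1L || any(diff(leaf_edges) <= 0))
    stop("arc_beam: leaf_edges must be ascending with length n_pairs+1")
  structure(list(energy = energy, beam_mu = beam_mu,
                 control_points = control_points,
                 leaf_edges = as.numeric(leaf_edges), is_arc = is_arc),
            class = "arc_beam")
}

#' Supported nominal beam energy labels
#' @return character vector.
#' @export
supported_energies <- function() c("6X", "6FFF", "10X", "10FFF")

#' VMAT plan container
#'
#' @param beams list of [arc_beam()]s.
#' @param isocenter patient-space isocenter, mm (shared by all beams in v1).
#' @param plan_label free-text label.
#' @return object of class `vmat_plan`.
#' @export
vmat_plan <- function(beams, isocenter = c(0, 0, 0), plan_label = "plan") {
  stopifnot(length(beams) >= 1L)
  structure(list(beams = beams, isocenter = as.numeric(isocenter),
                 plan_label = plan_label),
            class = "vmat_plan")
}

#' @export
print.vmat_plan <- function(x, ...) {
  cat(sprintf("VMAT plan '%s': %d beam(s), isocenter (%.1f, %.1f, %.1f) mm\n",
              x$plan_label, length(x$beams),
              x$isocenter[1], x$isocenter[2], x$isocenter[3]))
  for (b in x$beams)
    cat(sprintf("  %s  %s  %.1f MU  %d control points\n",
                if (b$is_arc) "arc   " else "static", b$energy, b$beam_mu,
                length(b$control_points)))
  invisible(x)
}

#' Structure set container
#'
#' Named regions of interest, each carrying its source contours (per-slice
#' polygons, mm) and a boolean mask rasterized on a stated grid.
#'
#' @param rois named list; each element has `contours` (list of n x 3
#'   matrices) and `mask` (logical array) on `grid`.
#' @param grid the `grid3d` the masks live on (usually the CT grid).
#' @return object of class `structure_set`.
#' @export
structure_set <- function(rois, grid) {
  structure(list(rois = rois, grid = grid), class = "structure_set")
}
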