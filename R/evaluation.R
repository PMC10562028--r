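# Reference-point selection inside the PTV, TPS-vs-secondary dose
# comparison against the action limit, and study-level pooling.

#' Evaluation configuration
#'
#' @param action_limit_percent action limit on the absolute percent
#'   difference; the flag fires on strict excess (`|diff| > limit`), so a
#'   boundary value of exactly the limit does not flag.
#' @param offset_mm offset magnitude for the four non-centroid reference
#'   points, mm; must lie in the 5-10 mm band.
#' @return object of class `eval_config`.
#' @export
eval_config <- function(action_limit_percent = 5, offset_mm = 7.5) {
  if (action_limit_percent <= 0) stop("eval_config: action limit must be > 0")
  if (offset_mm < 5 || offset_mm > 10)
    stop("eval_config: offset magnitude must lie in [5, 10] mm")
  structure(list(action_limit_percent = action_limit_percent,
                 offset_mm = offset_mm),
            class = "eval_config")
}

#' Select the five reference points inside a PTV
#'
#' Centroid of the PTV mask (voxel-center mean) plus four points offset by
#' `config$offset_mm` along +/- superior-inferior (z) when the PTV's
#' sup-inf extent is at least `2 * (offset + 2 mm)`, else along +/- left-
#' right (x); the second offset pair uses the other of the two axes under
#' the same extent rule. Any offset point falling outside the PTV is pulled
#' inward along its axis to the deepest interior voxel center and flagged.
#'
#' @param mask logical 3-D array (PTV rasterized on `grid`).
#' @param grid the [grid3d()] the mask lives on.
#' @param config an [eval_config()].
#' @return object of class `reference_points`: matrix `points` (5 x 3, mm),
#'   logical `pulled_inward`, chosen `axes`.
#' @export
select_reference_points <- function(mask, grid, config = eval_config()) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("select_reference_points: empty PTV mask")
  centers <- cbind(grid_axis(grid, 1)[idx[, 1]],
                   grid_axis(grid, 2)[idx[, 2]],
                   grid_axis(grid, 3)[idx[, 3]])
  centroid <- colMeans(centers)
  off <- config$offset_mm
  extent <- apply(centers, 2, function(v) diff(range(v)))
  ax_pairs <- if (extent[3] >= 2 * (off + 2)) c(3L, 1L) else c(1L, 2L)
  inside <- function(p) {
    i <- vapply(1:3, function(ax)
      which.min(abs(grid_axis(grid, ax) - p[ax])), integer(1))
    isTRUE(mask[i[1], i[2], i[3]])
  }
  pts <- matrix(rep(centroid, 5), nrow = 5, byrow = TRUE)
  pulled <- logical(5)
  row <- 2L
  for (ax in ax_pairs) for (sgn in c(1, -1)) {
    p <- centroid; p[ax] <- p[ax] + sgn * off
    if (!inside(p)) {
      # pull inward along the axis to the deepest interior voxel center
      on_axis <- centers[abs(centers[, setdiff(1:3, ax)[1]] - centroid[setdiff(1:3, ax)[1]]) <= grid$spacing[setdiff(1:3, ax)[1]] / 2 &
                           abs(centers[, setdiff(1:3, ax)[2]] - centroid[setdiff(1:3, ax)[2]]) <= grid$spacing[setdiff(1:3, ax)[2]] / 2, ,
                         drop = FALSE]
      cand <- on_axis[sign(on_axis[, ax] - centroid[ax]) == sgn, ax]
      if (length(cand)) {
        p[ax] <- if (sgn > 0) max(cand) else min(cand)
        pulled[row] <- TRUE
      } else {
        p <- centroid # degenerate: fall back to centroid
        pulled[row] <- TRUE
      }
    }
    pts[row, ] <- p
    row <- row + 1L
  }
  if (nrow(unique(round(pts, 3))) < 5)
    stop("select_reference_points: PTV too small to host 5 distinct points")
  structure(list(points = pts, pulled_inward = pulled,
                 axes = ax_pairs, offset_mm = off),
            class = "reference_points")
}

#' Dose at physical points (trilinear)
#'
#' @param dose a `dose_result` or `tps_dose` (any object with `dose` array
#'   and `grid`).
#' @param points n x 3 matrix, mm.
#' @return numeric vector, Gy.
#' @export
point_dose <- function(dose, points) {
  interp_trilinear(dose$dose, dose$grid, points)
}

#' Compare TPS and secondary doses at reference points
#'
#' Percent difference is `100 * (D_secondary - D_tps) / D_tps` per point
#' (TPS denominator, secondary-minus-TPS sign). Points with zero TPS dose
#' are flagged invalid and excluded from summaries with a warning.
#' Quartiles use the inclusive linear-interpolation rule
#' (`quantile(type = 7)`).
#'
#' @param tps a `tps_dose` (or `dose_result`).
#' @param secondary a dose object, or a numeric vector of point doses (Gy)
#'   aligned with `points`.
#' @param points a `reference_points` object or n x 3 matrix, mm.
#' @param config an [eval_config()].
#' @return object of class `eval_report`: data.frame `points` with doses,
#'   percent differences and flags, plus a `summary` list.
#' @export
compare_doses <- function(tps, secondary, points, config = eval_config()) {
  pts <- if (inherits(points, "reference_points")) points$points else points
  d_tps <- point_dose(tps, pts)
  d_sec <- if (is.numeric(secondary)) secondary else point_dose(secondary, pts)
  valid <- d_tps > 0
  if (any(!valid))
    warning(sprintf("compare_doses: %d point(s) with zero TPS dose excluded",
                    sum(!valid)))
  diff_pct <- ifelse(valid, 100 * (d_sec - d_tps) / d_tps, NA_real_)
  # strict excess, with a relative epsilon so a difference that is exactly
  # the limit up to floating-point rounding does not flag
  exceeds <- !is.na(diff_pct) &
    abs(diff_pct) > config$action_limit_percent * (1 + 1e-9)
  tab <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    d_tps_gy = d_tps, d_secondary_gy = d_sec,
                    diff_percent = diff_pct, exceeds_limit = exceeds,
                    valid = valid)
  v <- diff_pct[valid]
  summary <- list(
    n = sum(valid),
    mean = mean(v),
    mean_abs = mean(abs(v)),
    sd = stats::sd(v),
    quartiles = stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7),
    n_exceeding = sum(exceeds),
    fraction_exceeding = sum(exceeds) / sum(valid),
    action_limit_percent = config$action_limit_percent)
  structure(list(points = tab, summary = summary, config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Evaluation report: %d point(s), action limit %.1f%%\n",
              s$n, s$action_limit_percent))
  print(x$points[, c("d_tps_gy", "d_secondary_gy", "diff_percent",
                     "exceeds_limit")], digits = 4)
  cat(sprintf("mean %+.2f%%  mean|.| %.2f%%  sd %.2f%%  Q1/Q2/Q3 %+.2f/%+.2f/%+.2f%%  exceeding %d/%d\n",
              s$mean, s$mean_abs, s$sd, s$quartiles[1], s$quartiles[2],
              s$quartiles[3], s$n_exceeding, s$n))
  invisible(x)
}

#' Pool per-arc evaluation reports into a study summary
#'
#' @param reports list of `eval_report`s (one per arc), optionally named;
#'   `site` and `method` vectors (recycled) allow per-site/per-method
#'   aggregation.
#' @param site,method optional grouping labels, one per report.
#' @return object of class `study_summary`: pooled counts and fraction
#'   exceeding, plus a per-group table.
#' @export
study_summary <- function(reports, site = NULL, method = NULL) {
  stopifnot(length(reports) >= 1L)
  n <- vapply(reports, function(r) r$summary$n, numeric(1))
  ex <- vapply(reports, function(r) r$summary$n_exceeding, numeric(1))
  diffs <- unlist(lapply(reports, function(r)
    r$points$diff_percent[r$points$valid]))
  groups <- data.frame(
    site = if (is.null(site)) "all" else rep(site, length.out = length(reports)),
    method = if (is.null(method)) "secondary" else rep(method, length.out = length(reports)),
    n = n, n_exceeding = ex)
  per_group <- stats::aggregate(cbind(n, n_exceeding) ~ site + method,
                                data = groups, FUN = sum)
  per_group$fraction_exceeding <- per_group$n_exceeding / per_group$n
  structure(list(
    n_arcs = length(reports),
    n_points = sum(n),
    n_exceeding = sum(ex),
    fraction_exceeding = sum(ex) / sum(n),
    mean_abs = mean(abs(diffs)),
    per_group = per_group),
    class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("Study: %d arc(s), %d point(s), %d exceeding (%.1f%%), mean|diff| %.2f%%\n",
              x$n_arcs, x$n_points, x$n_exceeding,
              100 * x$fraction_exceeding, x$mean_abs))
  print(x$per_group, digits = 3)
  invisible(x)
}

#' Write an evaluation report as a tabular text file
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  utils::write.table(report$points, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
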