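#' Rectilinear 3-D grid geometry
#'
#' Lightweight descriptor shared by CT volumes, phantoms and dose grids.
#' `origin` is the patient-space position (mm) of the *center* of voxel
#' `[1,1,1]`; `spacing` is the per-axis voxel size (mm); `dims` the voxel
#' counts. Axes follow the DICOM patient frame (x: patient left, y:
#' posterior, z: superior) with identity orientation.
#'
#' @param origin numeric length 3, mm.
#' @param spacing numeric length 3, mm; all > 0.
#' @param dims integer length 3; all >= 1.
#' @return an object of class `grid3d`.
#' @export
grid3d <- function(origin, spacing, dims) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dims) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid3d: spacing must be positive and finite")
  if (any(dims < 1L)) stop("grid3d: dims must be >= 1")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "grid3d")
}

#' @export
format.grid3d <- function(x, ...) {
  sprintf("grid3d %dx%dx%d, spacing %.4g/%.4g/%.4g mm, origin (%.4g, %.4g, %.4g) mm",
          x$dims[1], x$dims[2], x$dims[3],
          x$spacing[1], x$spacing[2], x$spacing[3],
          x$origin[1], x$origin[2], x$origin[3])
}

#' @export
print.grid3d <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Voxel-center coordinates along one axis
#' @param g a `grid3d`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of voxel-center positions, mm.
#' @export
grid_axis <- function(g, axis) {
  g$origin[axis] + (seq_len(g$dims[axis]) - 1) * g$spacing[axis]
}

#' Physical extent of a grid (outer voxel faces)
#' @param g a `grid3d`.
#' @return 2x3 matrix: rows lower/upper bounds, mm.
#' @export
grid_extent <- function(g) {
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (g$dims - 0.5) * g$spacing
  rbind(lower = lo, upper = hi)
}

grids_equal <- function(a, b, tol = 1e-9) {
  identical(a$dims, b$dims) &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$spacing - b$spacing)) < tol
}

#' Trilinear interpolation of a 3-D array at physical points
#'
#' Values refer to voxel centers; points must lie within the voxel-center
#' bounding box (no extrapolation).
#'
#' @param arr 3-D numeric array with `dim(arr) == g$dims`.
#' @param g the `grid3d` describing `arr`.
#' @param pts n x 3 matrix of points, mm.
#' @return numeric vector of length n.
#' @export
interp_trilinear <- function(arr, g, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  n <- nrow(pts)
  # fractional voxel index (0-based)
  fx <- (pts[, 1] - g$origin[1]) / g$spacing[1]
  fy <- (pts[, 2] - g$origin[2]) / g$spacing[2]
  fz <- (pts[, 3] - g$origin[3]) / g$spacing[3]
  eps <- 1e-9
  bad <- fx < -eps | fy < -eps | fz < -eps |
    fx > g$dims[1] - 1 + eps | fy > g$dims[2] - 1 + eps | fz > g$dims[3] - 1 + eps
  if (any(bad))
    stop(sprintf("interp_trilinear: %d point(s) outside the voxel-center bounding box", sum(bad)))
  clamp <- function(f, d) pmin(pmax(f, 0), d - 1)
  fx <- clamp(fx, g$dims[1]); fy <- clamp(fy, g$dims[2]); fz <- clamp(fz, g$dims[3])
  i0 <- pmin(floor(fx), g$dims[1] - 2); i0[g$dims[1] == 1] <- 0
  j0 <- pmin(floor(fy), g$dims[2] - 2); j0[g$dims[2] == 1] <- 0
  k0 <- pmin(floor(fz), g$dims[3] - 2); k0[g$dims[3] == 1] <- 0
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  i1 <- pmin(i0 + 1, g$dims[1] - 1)
  j1 <- pmin(j0 + 1, g$dims[2] - 1)
  k1 <- pmin(k0 + 1, g$dims[3] - 1)
  at <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  v <- at(i0, j0, k0) * (1 - tx) * (1 - ty) * (1 - tz) +
    at(i1, j0, k0) * tx * (1 - ty) * (1 - tz) +
    at(i0, j1, k0) * (1 - tx) * ty * (1 - tz) +
    at(i1, j1, k0) * tx * ty * (1 - tz) +
    at(i0, j0, k1) * (1 - tx) * (1 - ty) * tz +
    at(i1, j0, k1) * tx * (1 - ty) * tz +
    at(i0, j1, k1) * (1 - tx) * ty * tz +
    at(i1, j1, k1) * tx * ty * tz
  as.numeric(v)
}

#' Resample a 3-D array onto a new grid (trilinear)
#'
#' @param arr source array.
#' @param g source `grid3d`.
#' @param target target `grid3d`; must lie within the source voxel-center box.
#' @return array with `dim == target$dims`.
#' @export
resample_grid <- function(arr, g, target) {
  xs <- grid_axis(target, 1); ys <- grid_axis(target, 2); zs <- grid_axis(target, 3)
  ext <- grid_extent(g)
  tlo <- c(min(xs), min(ys), min(zs)); thi <- c(max(xs), max(ys), max(zs))
  clo <- g$origin; chi <- g$origin + (g$dims - 1) * g$spacing
  if (any(tlo < clo - 1e-6) || any(thi > chi + 1e-6)) {
    stop(sprintf(paste0(
      "resample_grid: target grid outside source voxel-center extent; ",
      "source centers x[%.1f,%.1f] y[%.1f,%.1f] z[%.1f,%.1f] mm, ",
      "target centers x[%.1f,%.1f] y[%.1f,%.1f] z[%.1f,%.1f] mm"),
      clo[1], chi[1], clo[2], chi[2], clo[3], chi[3],
      tlo[1], thi[1], tlo[2], thi[2], tlo[3], thi[3]))
  }
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  array(interp_trilinear(arr, g, pts), dim = target$dims)
}

#' @keywords internal
vnorm <- function(v) sqrt(sum(v * v))
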