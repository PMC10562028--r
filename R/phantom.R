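#' Default HU-to-material/density assignment table
#'
#' Four contiguous Hounsfield-unit intervals (Air, Lung, Tissue, Bone), each
#' mapped linearly onto a mass-density interval. Densities are continuous at
#' the interior boundaries (0.044, 0.302 and 1.101 g/cm3), so the mapped
#' density is a continuous, monotone non-decreasing function of HU.
#'
#' @return data.frame with columns `material`, `hu_min`, `hu_max`,
#'   `density_min`, `density_max`.
#' @export
hu_material_table <- function() {
  data.frame(
    material    = c("Air", "Lung", "Tissue", "Bone"),
    hu_min      = c(-1050, -950, -700, 125),
    hu_max      = c(-950, -700, 125, 2000),
    density_min = c(0.001, 0.044, 0.302, 1.101),
    density_max = c(0.044, 0.302, 1.101, 2.088),
    stringsAsFactors = FALSE
  )
}

validate_hu_table <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  need <- c("material", "hu_min", "hu_max", "density_min", "density_max")
  if (!all(need %in% names(table))) stop("HU table: missing columns")
  if (any(table$hu_max <= table$hu_min)) stop("HU table: empty HU interval")
  if (any(table$density_min <= 0) || any(table$density_max <= 0))
    stop("HU table: densities must be strictly positive")
  n <- nrow(table)
  if (n > 1L) {
    if (any(abs(table$hu_min[-1] - table$hu_max[-n]) > 1e-9))
      stop("HU table: HU intervals must be contiguous and ordered")
    if (any(abs(table$density_min[-1] - table$density_max[-n]) > 1e-9))
      stop("HU table: density must be continuous at interior boundaries")
  }
  invisible(table)
}

#' Map Hounsfield units to (material, density)
#'
#' Intervals are half-open `[hu_min, hu_max)` with the final row closed at
#' its upper end; within each interval density is interpolated linearly
#' between the row's density endpoints. Because interior boundary densities
#' match, the density is continuous in HU; only the material label depends on
#' the half-open convention. HU outside the table clamp to the extreme row's
#' extreme density.
#'
#' @param hu numeric vector of Hounsfield units.
#' @param table assignment table, default [hu_material_table()].
#' @return list with integer vector `material` (row index into `table`) and
#'   numeric vector `density` (g/cm3).
#' @export
map_hu <- function(hu, table = hu_material_table()) {
  validate_hu_table(table)
  hu <- as.numeric(hu)
  n <- nrow(table)
  hu_cl <- pmin(pmax(hu, table$hu_min[1]), table$hu_max[n])
  # half-open [min,max): findInterval on the interior boundaries
  mat <- findInterval(hu_cl, table$hu_min, left.open = FALSE) # 1..n
  mat <- pmin(pmax(mat, 1L), n)
  frac <- (hu_cl - table$hu_min[mat]) / (table$hu_max[mat] - table$hu_min[mat])
  dens <- table$density_min[mat] + frac * (table$density_max[mat] - table$density_min[mat])
  list(material = as.integer(mat), density = dens)
}

#' Voxel phantom container
#'
#' @param material 3-D integer array, row indices into `table`.
#' @param density 3-D numeric array, g/cm3.
#' @param grid a [grid3d()].
#' @param table the HU/material table the phantom was built from.
#' @return object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(material, density, grid, table = hu_material_table()) {
  stopifnot(identical(dim(material), dim(density)),
            identical(as.integer(dim(material)), grid$dims))
  if (any(density <= 0)) stop("voxel_phantom: densities must be positive")
  structure(list(material = material, density = density, grid = grid,
                 table = table),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("Voxel phantom:", format(x$grid), "\n")
  tab <- table(factor(x$table$material[x$material], levels = x$table$material))
  cat("  materials:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Build a voxel phantom from a CT volume
#'
#' HU are resampled (trilinear) onto the target grid first, then mapped
#' voxel-wise with [map_hu()]. Resampling first avoids averaging the
#' categorical material index.
#'
#' @param ct a [ct_volume()].
#' @param table HU/material table.
#' @param spacing target voxel size, mm (scalar or length 3); `NULL` keeps
#'   the CT grid.
#' @return a [voxel_phantom()].
#' @export
build_phantom <- function(ct, table = hu_material_table(), spacing = NULL) {
  stopifnot(inherits(ct, "ct_volume"))
  if (is.null(spacing)) {
    g <- ct$grid
    hu <- ct$hu
  } else {
    spacing <- rep(as.numeric(spacing), length.out = 3)
    # largest centered grid with the requested spacing inside the CT extent
    span <- (ct$grid$dims - 1) * ct$grid$spacing
    dims <- pmax(1L, as.integer(floor(span / spacing)) + 1L)
    ctr <- ct$grid$origin + span / 2
    g <- grid3d(ctr - (dims - 1) * spacing / 2, spacing, dims)
    hu <- resample_grid(ct$hu, ct$grid, g)
  }
  m <- map_hu(hu, table)
  voxel_phantom(array(m$material, dim = g$dims),
                array(m$density, dim = g$dims), g, table)
}

#' Uniform water phantom
#'
#' Tissue-material voxels with density overridden to 1.000 g/cm3, used for
#' the calibration reference condition (calibration is defined in water, not
#' in the HU-0 table density of ~0.98).
#'
#' @param side_mm cube side, mm.
#' @param spacing_mm voxel size, mm.
#' @param origin origin of the first voxel center, mm.
#' @return a [voxel_phantom()].
#' @export
water_phantom <- function(side_mm = 400, spacing_mm = 4,
                          origin = NULL) {
  n <- max(1L, as.integer(round(side_mm / spacing_mm)))
  if (is.null(origin))
    origin <- rep(-(n - 1) * spacing_mm / 2, 3)
  g <- grid3d(origin, rep(spacing_mm, 3), rep(n, 3L))
  tab <- hu_material_table()
  itissue <- match("Tissue", tab$material)
  voxel_phantom(array(itissue, dim = g$dims),
                array(1.0, dim = g$dims), g, tab)
}

#' Export a phantom in an egsphant-style text layout
#'
#' Material index grid plus density grid with voxel-boundary lists (cm), for
#' interoperability with EGSnrc-style tooling.
#'
#' @param phantom a [voxel_phantom()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_egsphant <- function(phantom, path) {
  g <- phantom$grid
  con <- file(path, "w")
  on.exit(close(con))
  tab <- phantom$table
  writeLines(as.character(nrow(tab)), con)
  writeLines(tab$material, con)
  writeLines(paste(g$dims, collapse = " "), con)
  for (ax in 1:3) {
    b <- (g$origin[ax] - g$spacing[ax] / 2 +
            (0:g$dims[ax]) * g$spacing[ax]) / 10 # cm
    writeLines(paste(format(b, trim = TRUE), collapse = " "), con)
  }
  writeLines(paste(as.integer(phantom$material), collapse = ""), con)
  writeLines(paste(format(phantom$density, digits = 6, trim = TRUE),
                   collapse = " "), con)
  invisible(path)
}
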