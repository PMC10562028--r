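# Shared in-code fixtures: small water boxes, open-field segments and
# scenes used across the transport, calibration and acceptance tests.

water_box <- function(npx = 20, spacing_mm = 10) {
  n <- rep(as.integer(npx), 3)
  g <- grid3d(rep(-(npx - 1) * spacing_mm / 2, 3), rep(spacing_mm, 3), n)
  voxel_phantom(array(3L, n), array(1.0, n), g)
}

open_segment <- function(half_mm = 40, gantry_deg = 0, iso = c(0, 0, 0),
                         transmission = 0) {
  ap <- aperture(c(-half_mm, half_mm, -half_mm, half_mm),
                 c(-half_mm, half_mm), -half_mm, half_mm,
                 transmission = transmission)
  list(gantry_deg = gantry_deg, aperture = ap, mu = 1, mu_frac = 1, iso = iso)
}

open_water_scene <- function(npx = 20, spacing_mm = 10, half_mm = 40,
                             energy = "6X") {
  mc_scene(water_box(npx, spacing_mm), list(open_segment(half_mm)),
           beam_source(energy))
}

# water slab phantom: thickness along +y starting at y = 0 (beam direction
# for gantry 0), generous lateral extent
water_slab_scene <- function(thick_mm = 100, spacing_mm = 4,
                             spectrum = data.frame(energy = 1, prob = 1)) {
  nxz <- 10L
  ny <- as.integer(round(thick_mm / spacing_mm))
  n <- c(nxz, ny, nxz)
  g <- grid3d(c(-(nxz - 1) * spacing_mm / 2, spacing_mm / 2,
                -(nxz - 1) * spacing_mm / 2),
              rep(spacing_mm, 3), n)
  ph <- voxel_phantom(array(3L, n), array(1.0, n), g)
  # pencil: zero-area sampling rectangle on the central axis
  ap <- aperture(c(0, 0, 0, 0), c(-5, 5), -5, 5)
  seg <- list(gantry_deg = 0, aperture = ap, mu = 1, mu_frac = 1,
              iso = c(0, 0, 0))
  mc_scene(ph, list(seg), beam_source("6X", spectrum = spectrum))
}

# interpolated-point standard error from a merged dose result, assuming
# independent voxels (used only for nearest-voxel reads in tests)
voxel_sigma <- function(res, pt) {
  i <- vapply(1:3, function(ax)
    which.min(abs(grid_axis(res$grid, ax) - pt[ax])), integer(1))
  res$rel_uncertainty[i[1], i[2], i[3]] * res$dose[i[1], i[2], i[3]]
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(abs(actual - expected), tol * max(abs(expected), 1e-300))
}
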