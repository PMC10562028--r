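test_that("radiological depth reproduces hand-computed path integrals", {
  n <- c(25L, 25L, 25L); g <- grid3d(rep(-48, 3), rep(4, 3), n)
  water <- voxel_phantom(array(3L, n), array(1.0, n), g)
  src <- c(0, -1000, 0)
  # homogeneous water: radiological equals geometric depth (exact)
  for (y in c(-20, 0, 30, 48)) {
    expect_equal(radiological_depth(water, src, c(0, y, 0)), (y + 50) / 10,
                 tolerance = 1e-9)
  }
  # 4.8 cm water then lung at 0.25: 4.8 + 0.25 * remaining path
  dens <- array(1.0, n); dens[, 13:25, ] <- 0.25
  mixed <- voxel_phantom(array(3L, n), dens, g)
  expect_equal(radiological_depth(mixed, src, c(0, 48, 0)),
               4.8 + 0.25 * 5.0, tolerance = 1e-9)
  # exact half-and-half slab: 5 cm water + 5 cm lung = 6.25 cm
  n2 <- c(5L, 20L, 5L); g2 <- grid3d(c(-10, 2.5, -10), rep(5, 3), n2)
  dens2 <- array(1.0, n2); dens2[, 11:20, ] <- 0.25
  ph2 <- voxel_phantom(array(3L, n2), dens2, g2)
  expect_equal(radiological_depth(ph2, c(0, -1000, 0), c(0, 100, 0)), 6.25,
               tolerance = 1e-9)
  # oblique 45-degree ray through the cube corner-to-center
  expect_equal(radiological_depth(water, c(-1000, -1000, 0), c(0, 0, 0)),
               5 * sqrt(2), tolerance = 1e-9)
  expect_error(radiological_depth(water, src, c(0, 500, 0)), "outside")
})

test_that("circular-field sector term equals S(r) exactly for any sector count", {
  tab <- make_tables("6X")
  for (r_mm in c(15, 30, 55)) {
    ap <- circular_aperture(c(0, 0), r_mm)
    for (ns in c(12, 36, 360)) {
      rs <- sector_radii(ap, 0, 0, ns)
      expect_equal(rs, rep(r_mm / 10, ns), tolerance = 1e-12)
      expect_equal(mean(scatter_factor(tab, rs)),
                   scatter_factor(tab, r_mm / 10), tolerance = 1e-12)
    }
  }
})

test_that("half-beam sector term approaches (S(r)+S(0))/2 at O(1/n)", {
  tab <- make_tables("6X")
  ap <- circular_aperture(c(0, 0), 50, half_blocked = TRUE)
  limit <- (scatter_factor(tab, 5) + scatter_factor(tab, 0)) / 2
  v360 <- mean(scatter_factor(tab, sector_radii(ap, 0, 0, 360)))
  expect_lt(abs(v360 - limit) / limit, 0.005)
  # convergence order measured on off-center probes against a dense reference
  pts <- cbind(c(3.7, -5, 8, 2, -9), c(2.1, 4, -3, 7, 1))
  merr <- function(ns) mean(vapply(seq_len(nrow(pts)), function(i) {
    ref <- mean(scatter_factor(tab, sector_radii(ap, pts[i, 1], pts[i, 2], 5760)))
    abs(mean(scatter_factor(tab, sector_radii(ap, pts[i, 1], pts[i, 2], ns))) - ref)
  }, numeric(1)))
  e18 <- merr(18); e144 <- merr(144)
  expect_lt(e144, e18 / 4) # at least first-order decay over an 8x refinement
})

test_that("commissioning tables satisfy their shape invariants", {
  tab <- make_tables("6FFF")
  d <- seq(1, 40, by = 0.5)
  expect_true(all(diff(tmr_lookup(tab, d)) < 0))
  r <- seq(0, 20, by = 0.1)
  expect_true(all(diff(scatter_factor(tab, r)) > 0))
  # raw saturating form: S(0) = 0 and S(r -> infinity) -> 1
  expect_equal(scatter_factor(tab, 0, normalized = FALSE), 0)
  expect_equal(scatter_factor(tab, 1e4, normalized = FALSE), 1)
  expect_error(tmr_lookup(tab, 60), "outside table range")
  # text round trip
  p <- withr::local_tempfile()
  write_tables(tab, p)
  tab2 <- read_tables(p)
  expect_equal(tab2$mu_eff, tab$mu_eff)
  expect_equal(tab2$ref_output_cgy_per_mu, tab$ref_output_cgy_per_mu)
})

test_that("Clarkson plan dose: zero-MU plans and aperture-centered circles", {
  n <- c(15L, 15L, 15L); g <- grid3d(rep(-56, 3), rep(8, 3), n)
  water <- voxel_phantom(array(3L, n), array(1.0, n), g)
  tab <- make_tables("6X")
  cps <- list(control_point(0, c(-30, 30, -30, 30), -30, 30, 0),
              control_point(0, c(-30, 30, -30, 30), -30, 30, 1))
  plan0 <- vmat_plan(list(arc_beam("6X", 0, cps, c(-30, 30))))
  expect_equal(clarkson_point_dose(plan0, water, c(0, 0, 0), tab), 0)
  # single segment against the closed-form product
  seg <- list(gantry_deg = 0,
              aperture = circular_aperture(c(0, 0), 40), iso = c(0, 0, 0))
  d <- clarkson_segment_dose_per_mu(seg, water, c(0, 20, 0), tab)
  d_eff <- (20 + 56 + 4) / 10 # depth from phantom surface, cm
  spd <- 1020
  expected <- tab$ref_output_cgy_per_mu * 0.01 *
    tmr_lookup(tab, d_eff) * scatter_factor(tab, 4) * (1000 / spd)^2
  expect_equal(d, expected, tolerance = 1e-9)
})

test_that("equivalent square side uses the equal-area convention", {
  ap <- aperture(c(-50, 50, -50, 50), c(-50, 50), -50, 50)
  expect_equal(equivalent_square_cm(ap), 10)
  expect_equal(equivalent_square_cm(circular_aperture(c(0, 0), 50)),
               sqrt(pi * 5^2)) # sqrt(pi r^2) with r in cm
})
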