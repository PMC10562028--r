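test_that("CT generation is deterministic and recipes map to the right materials", {
  d <- withr::local_tempdir()
  # water cube: all HU exactly 0
  wc <- make_ct(phantom_recipe(extent_mm = c(40, 40, 40), spacing_mm = 4))
  expect_true(all(wc$hu == 0))
  # thorax-like recipe yields exactly four distinct materials
  th <- make_ct(thorax_recipe(spacing_mm = 8), seed = 7)
  ph <- build_phantom(th)
  expect_setequal(unique(as.integer(ph$material)), 1:4)
  # noisy series is byte-identical under a fixed seed
  rec <- phantom_recipe(extent_mm = c(40, 40, 40), spacing_mm = 4,
                        noise_sd = 20)
  make_ct(rec, seed = 9, dir = file.path(d, "a"))
  make_ct(rec, seed = 9, dir = file.path(d, "b"))
  fa <- list.files(file.path(d, "a"), full.names = TRUE)
  fb <- list.files(file.path(d, "b"), full.names = TRUE)
  for (i in seq_along(fa))
    expect_identical(readBin(fa[i], raw(), file.size(fa[i])),
                     readBin(fb[i], raw(), file.size(fb[i])))
  # different seed changes the noise
  make_ct(rec, seed = 10, dir = file.path(d, "c"))
  fc <- list.files(file.path(d, "c"), full.names = TRUE)
  expect_false(identical(readBin(fa[1], raw(), file.size(fa[1])),
                         readBin(fc[1], raw(), file.size(fc[1]))))
})

test_that("plan recipes produce the requested arc structure", {
  p3 <- make_plan(plan_recipe(n_arcs = 3, n_cp = 114, energy = "6FFF"))
  expect_length(p3$beams, 3)
  expect_true(all(vapply(p3$beams, function(b)
    length(b$control_points), integer(1)) == 114L))
  p2 <- make_plan(plan_recipe(n_arcs = 2, n_cp = 178, energy = "10X",
                              beam_mu = 333))
  expect_length(p2$beams, 2)
  expect_equal(p2$beams[[1]]$energy, "10X")
  expect_equal(p2$beams[[2]]$beam_mu, 333)
  expect_length(p2$beams[[2]]$control_points, 178)
  # degenerate static pair with a square 10x10 field (calibration-style)
  ps <- make_plan(plan_recipe(n_arcs = 1, n_cp = 2, aperture = "square",
                              field_mm = 100, gantry_start = 0,
                              gantry_end = 0))
  cp <- ps$beams[[1]]$control_points[[1]]
  expect_equal(cp$jaws, c(x1 = -50, x2 = 50, y1 = -50, y2 = 50))
  open <- cp$mlc_b - cp$mlc_a > 0
  expect_true(all(cp$mlc_b[open] == 50))
  # sphere-conformal aperture opens the chord of the target per leaf pair
  psph <- make_plan(plan_recipe(n_arcs = 1, n_cp = 2, aperture = "sphere",
                                target_radius_mm = 25))
  cps <- psph$beams[[1]]$control_points[[1]]
  edges <- psph$beams[[1]]$leaf_edges
  yc <- (edges[-1] + edges[-length(edges)]) / 2
  expect_equal(cps$mlc_b, sqrt(pmax(0, 25^2 - yc^2)))
})

test_that("analytic TPS dose follows the closed-form exponential", {
  rec <- phantom_recipe(extent_mm = c(40, 80, 40), spacing_mm = 4)
  ph <- build_phantom(make_ct(rec))
  plan <- make_plan(plan_recipe(n_arcs = 1, n_cp = 2))
  td <- make_tps_dose(plan, ph, mode = "analytic", mu_eff = 0.056)
  ys <- grid_axis(ph$grid, 2)
  depth_cm <- (ys - (ph$grid$origin[2] - ph$grid$spacing[2] / 2)) / 10
  expect_equal(td$dose[3, , 3], exp(-0.056 * depth_cm), tolerance = 1e-12)
  # perturbation multiplies inside the mask only
  m <- array(FALSE, ph$grid$dims); m[, 1:5, ] <- TRUE
  tp <- make_tps_dose(plan, ph, mode = "analytic",
                      perturbation = list(mask = m, factor = 1.07))
  expect_equal(tp$dose[3, 1:5, 3], 1.07 * td$dose[3, 1:5, 3])
  expect_equal(tp$dose[3, 6:20, 3], td$dose[3, 6:20, 3])
})

test_that("mc-proxy TPS dose with zero perturbation self-compares to zero", {
  rec <- phantom_recipe(extent_mm = c(80, 80, 80), spacing_mm = 8)
  ph <- build_phantom(make_ct(rec))
  plan <- make_plan(plan_recipe(n_arcs = 1, n_cp = 6, aperture = "square",
                                field_mm = 40, beam_mu = 100))
  fcal <- compute_fcal(reference_measurement(0.8, 100, 4e-17, "6FFF"))
  tps <- make_tps_dose(plan, ph, fcal, mode = "mc-proxy",
                       histories_per_arc = 2e4, base_seed = 5)
  ver <- simulate_plan_dose(plan, ph, fcal, histories_per_arc = 2e4,
                            base_seed = 5)
  pts <- cbind(c(0, 4, -4), c(0, 0, 4), c(0, 4, 0))
  rep <- compare_doses(tps, ver, pts)
  expect_equal(rep$points$diff_percent, rep(0, 3))
})

test_that("phase-space generation: empty, sparse, and populated files parse cleanly", {
  d <- withr::local_tempdir()
  ps <- make_phase_space(file.path(d, "p.phsp"), 500, energy = "10FFF",
                         seed = 3)
  expect_equal(nrow(ps$records), 500)
  expect_true(all(abs(ps$records$u^2 + ps$records$v^2 + ps$records$w^2 - 1)
                  < 1e-6))
  expect_true(all(ps$records$w > 0))
  sp <- make_phase_space(file.path(d, "s.phsp"), 5e7, sparse = TRUE)
  expect_equal(sp$count, 5e7)
  expect_null(sp$records)
})
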