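test_that("phase-space files round-trip and concatenate with count arithmetic", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.phsp"); f2 <- file.path(d, "b.phsp")
  ps1 <- make_phase_space(f1, 3, energy = "6X", seed = 1)
  ps2 <- make_phase_space(f2, 4, energy = "6X", seed = 2)
  expect_equal(nrow(ps1$records), 3)
  expect_equal(ps1$count, 3)
  # order preserved on concatenation
  cc <- concatenate_phase_space(list(ps1, ps2))
  expect_equal(cc$count, 7)
  expect_equal(cc$records$energy, c(ps1$records$energy, ps2$records$energy))
  # identity
  one <- concatenate_phase_space(list(ps1))
  expect_equal(one$records, ps1$records)
  # five sparse headers of 5e7 -> 2.5e8 declared
  sparse <- lapply(1:5, function(i)
    make_phase_space(file.path(d, sprintf("s%d.phsp", i)), 5e7,
                     energy = "6FFF", sparse = TRUE))
  expect_equal(concatenate_phase_space(sparse)$count, 2.5e8)
  # mismatched energy rejected
  f3 <- file.path(d, "c.phsp")
  ps3 <- make_phase_space(f3, 2, energy = "10X", seed = 3)
  expect_error(concatenate_phase_space(list(ps1, ps3)), "mismatched")
  # empty file is valid but samplers reject it
  f0 <- file.path(d, "e.phsp")
  ps0 <- make_phase_space(f0, 0)
  expect_equal(ps0$count, 0)
  expect_error(sample_source(beam_source("6X", phase_space = ps0), 5), "empty")
})

test_that("parametric source sampling follows the spectrum", {
  # degenerate spectrum: every draw at 1 MeV
  s1 <- beam_source("6X", spectrum = data.frame(energy = 1, prob = 1))
  r <- sample_source(s1, 100, rng_seed = 4)
  expect_true(all(r$energy == 1))
  expect_equal(max(abs(r$u^2 + r$v^2 + r$w^2 - 1)), 0, tolerance = 1e-12)
  expect_true(all(r$w > 0))
  # two-line spectrum: fraction at 6 MeV within 3 sigma binomial of 0.7
  s2 <- beam_source("6X", spectrum = data.frame(energy = c(2, 6),
                                                prob = c(0.3, 0.7)))
  n <- 1e5
  r2 <- sample_source(s2, n, rng_seed = 5)
  frac <- mean(r2$energy == 6)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.3 * 0.7 / n))
  # invalid spectra rejected
  expect_error(beam_source("6X", spectrum = data.frame(energy = 1, prob = 0.5)),
               "sum to 1")
})

test_that("phase-space sampling is cyclic with reshuffled reuse", {
  d <- withr::local_tempdir()
  ps <- make_phase_space(file.path(d, "p.phsp"), 10, seed = 9)
  src <- beam_source("6X", phase_space = ps)
  r <- sample_source(src, 25, rng_seed = 1)
  counts <- table(r$energy + 1e6 * r$x) # records identified by their fields
  expect_true(all(counts %in% c(2, 3)))
  expect_equal(attr(r, "reuse_passes"), 2L)
})

test_that("collimation projects to the isocenter plane and never raises weight", {
  ap <- aperture(c(-50, 50, -50, 50), c(-50, 50), -50, 50)
  central <- data.frame(x = 0, y = 0, u = 0, v = 0, w = 1, energy = 1,
                        weight = 1)
  expect_equal(collimate(central, ap)$weight, 1)
  # ray aimed 1 mm outside a closed aperture, transmission 0 -> absorbed
  closed <- aperture(c(-50, 50, -50, 50), c(-50, 50), 0, 0)
  off <- data.frame(x = 0, y = 0, u = 1 / sqrt(1 + 500^2 / 1^2), v = 0,
                    w = 500 / sqrt(500^2 + 1), energy = 1, weight = 1)
  expect_equal(collimate(off, closed)$weight, 0)
  # transmission multiplies blocked weight
  leaky <- aperture(c(-50, 50, -50, 50), c(-50, 50), 0, 0,
                    transmission = 0.015)
  expect_equal(collimate(off, leaky)$weight, 0.015)
  # property: weights never increase over random rays
  src <- beam_source("6X")
  r <- sample_source(src, 2000, field_mm = c(-80, 80, -80, 80), rng_seed = 6)
  out <- collimate(r, aperture(c(-30, 30, -30, 30), c(-30, 30), -30, 30,
                               transmission = 0.1))
  expect_true(all(out$weight <= r$weight + 1e-15))
})

test_that("open-field transmission equals the open-area fraction", {
  # jaw rect 100x100, MLC opens the central 40x100 band
  ap <- aperture(c(-50, 50, -50, 50), c(-50, 50), -20, 20)
  src <- beam_source("6X")
  n <- 2e4
  r <- sample_source(src, n, field_mm = c(-50, 50, -50, 50), rng_seed = 7)
  out <- collimate(r, ap)
  p <- aperture_area(ap) / (100 * 100)
  expect_equal(p, 0.4)
  expect_lt(abs(mean(out$weight > 0) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("meterset differencing telescopes exactly", {
  mk_arc <- function(w, mu = 200) {
    cps <- lapply(seq_along(w), function(i)
      control_point(10 * i, c(-50, 50, -50, 50), -50, 50, w[i]))
    arc_beam("6X", mu, cps, c(-50, 50))
  }
  expect_equal(differential_mu(mk_arc(c(0, 0.5, 1)))[[1]], c(100, 100))
  # 98 control points, uniform weights: 97 equal segments summing exactly
  w <- (0:97) / 97
  mus <- differential_mu(mk_arc(w, mu = 317.3))[[1]]
  expect_length(mus, 97)
  expect_equal(sum(mus), 317.3)
  expect_lt(diff(range(mus)), 1e-10)
  # zero-MU leading segment is legal
  expect_equal(differential_mu(mk_arc(c(0, 0, 1)))[[1]], c(0, 200))
  # property: random non-decreasing weights always sum to beam_mu
  for (s in 1:5) {
    u <- cumsum(muv_runif(s, 20)); u <- c(0, u / max(u))
    expect_equal(sum(differential_mu(mk_arc(u, mu = 123.456))[[1]]), 123.456)
  }
})

test_that("beam basis follows the gantry convention", {
  b0 <- beam_basis(0)
  expect_equal(b0$src, c(0, -1000, 0))
  expect_equal(b0$w, c(0, 1, 0))
  b90 <- beam_basis(90) # source at patient left
  expect_equal(b90$src, c(1000, 0, 0), tolerance = 1e-12)
  expect_equal(b90$w, c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(b90$yb, c(0, 0, 1))
})

test_that("arc segmentation uses midpoint gantry and aperture", {
  cps <- list(control_point(350, c(-50, 50, -50, 50), -10, 10, 0),
              control_point(10, c(-30, 30, -30, 30), -20, 20, 1))
  b <- arc_beam("6X", 100, cps, c(-50, 50))
  segs <- arc_segments(b)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$gantry_deg, 0) # circular mean across 360
  expect_equal(segs[[1]]$aperture$jaws, c(-40, 40, -40, 40),
               ignore_attr = TRUE)
  expect_equal(segs[[1]]$aperture$leaf_a, -15)
  expect_equal(segs[[1]]$mu, 100)
})

test_that("plan containers enforce their invariants", {
  cps <- list(control_point(0, c(-50, 50, -50, 50), -10, 10, 0),
              control_point(10, c(-50, 50, -50, 50), -10, 10, 1))
  expect_error(arc_beam("6X", 100, cps[1], c(-50, 50)), ">= 2 control points")
  expect_error(control_point(0, c(-50, 50, -50, 50), 10, -10, 0),
               "crossed leaves at pair")
  expect_error(control_point(0, c(50, -50, -50, 50), -10, 10, 0), "jaws")
  bad <- list(control_point(0, c(-50, 50, -50, 50), -10, 10, 0.5),
              control_point(10, c(-50, 50, -50, 50), -10, 10, 1))
  expect_error(arc_beam("6X", 100, bad, c(-50, 50)), "from 0 to 1")
})
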