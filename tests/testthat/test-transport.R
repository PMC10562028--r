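test_that("job splitting follows the remainder rule and rejects bad requests", {
  s <- split_job(1e7, 100, base_seed = 5)
  expect_length(s, 100)
  expect_true(all(vapply(s, `[[`, numeric(1), "histories") == 1e5))
  expect_equal(vapply(s, `[[`, numeric(1), "seed"), 5 + 0:99)
  expect_equal(vapply(split_job(10, 3), `[[`, numeric(1), "histories"),
               c(4, 3, 3))
  s320 <- split_job(1e9, 320)
  expect_true(all(vapply(s320, `[[`, numeric(1), "histories") == 3125000))
  expect_error(split_job(2, 3), "n_jobs")
  # offsets tile the global history range
  offs <- vapply(s320, `[[`, numeric(1), "offset")
  expect_equal(offs, cumsum(c(0, rep(3125000, 319))))
})

test_that("run_job is deterministic and respects zero-MU segments", {
  scene <- open_water_scene(npx = 12, spacing_mm = 10)
  sp <- job_spec(5e3, base_seed = 11)
  a <- run_job(scene, sp)
  b <- run_job(scene, sp)
  expect_identical(a$sum, b$sum)
  expect_identical(a$sumsq, b$sumsq)
  # zero-MU segment receives zero histories and contributes nothing
  seg0 <- open_segment(40); seg0$mu <- 0; seg0$mu_frac <- 0
  seg1 <- open_segment(40); # identical geometry takes all histories
  scene2 <- mc_scene(scene$phantom, list(seg0, seg1), scene$source)
  c2 <- run_job(scene2, sp)
  expect_identical(c2$sum, a$sum)
})

test_that("merging weights by histories and equals the unsplit run", {
  scene <- open_water_scene(npx = 12, spacing_mm = 10)
  # single part: dose = sums / histories
  p <- run_job(scene, job_spec(4e3, base_seed = 3))
  r1 <- merge_partials(list(p))
  expect_equal(r1$dose, p$sum / 4e3)
  # split/merge equivalence at <= 1e-12 relative per voxel
  specs <- split_job(2e4, 2, base_seed = 42)
  merged <- merge_partials(lapply(specs, function(s) run_job(scene, s)))
  single <- merge_partials(list(run_job(scene, job_spec(2e4, base_seed = 42))))
  rel <- abs(merged$dose - single$dose) / pmax(single$dose, 1e-300)
  expect_lt(max(rel[single$dose > 0]), 1e-12)
  # histories-weighted, not file-count-weighted
  pa <- run_job(scene, job_spec(1e4, 42, offset = 0, total = 1e5, seed = 1))
  pb <- run_job(scene, job_spec(9e4, 42, offset = 1e4, total = 1e5, seed = 2))
  m <- merge_partials(list(pa, pb))
  expect_equal(m$dose, (pa$sum + pb$sum) / 1e5)
  # geometry and seed guards
  other <- open_water_scene(npx = 10, spacing_mm = 10)
  q <- run_job(other, job_spec(1e3, base_seed = 3))
  expect_error(merge_partials(list(p, q)), "geometry mismatch")
  expect_error(merge_partials(list(p, p)), "duplicate job seeds")
})

test_that("uncertainty estimation matches the history-by-history definition", {
  # constant per-history deposit: sigma is exactly zero
  g <- grid3d(c(0, 0, 0), c(10, 10, 10), c(2L, 2L, 2L))
  n <- 100; d <- 3e-15
  part <- structure(list(sum = array(n * d, dim = g$dims),
                         sumsq = array(n * d^2, dim = g$dims),
                         histories = n, grid = g, seed = 1),
                    class = "partial_dose")
  expect_true(all(estimate_uncertainty(part) == 0))
  # never-hit voxel flagged NA, not zero
  part$sum[2, 2, 2] <- 0; part$sumsq[2, 2, 2] <- 0
  expect_true(is.na(estimate_uncertainty(part)[2, 2, 2]))
  # hand-computed two-history case
  part2 <- part
  part2$histories <- 2
  part2$sum[] <- 5e-15; part2$sumsq[] <- 13e-30 # deposits 2e-15 and 3e-15
  m <- 2.5e-15
  expect_equal(estimate_uncertainty(part2)[1, 1, 1],
               sqrt((13e-30 / 2 - m^2) / 1) / m)
})

test_that("energy bookkeeping never creates energy", {
  scene <- open_water_scene(npx = 10, spacing_mm = 12)
  for (seed in c(1, 77, 301)) {
    p <- run_job(scene, job_spec(2e3, base_seed = seed))
    expect_lte(p$energy_deposited_mev, p$energy_launched_mev)
    expect_gt(p$energy_deposited_mev, 0)
  }
})

test_that("mirror-symmetric geometry gives mirror-symmetric dose within 3 sigma", {
  scene <- open_water_scene(npx = 14, spacing_mm = 10, half_mm = 50)
  r <- simulate_scene(scene, 2e5, base_seed = 13)
  nx <- r$grid$dims[1]
  d <- r$dose; s <- r$rel_uncertainty * d
  dm <- d[nx:1, , ]; sm <- s[nx:1, , ]
  use <- d > 0.2 * max(d) & dm > 0.2 * max(d) & !is.na(s) & !is.na(sm)
  z <- (d[use] - dm[use]) / sqrt(s[use]^2 + sm[use]^2)
  expect_gt(mean(abs(z) < 3), 0.985)
})

test_that("Compton sampling matches the Klein-Nishina oracle", {
  e <- 1.0
  smp <- muvr:::sample_compton_cpp(e, 1e5, seed = 17)
  eps <- smp[, "eprime"] / e
  # kinematic floor and forward limit
  expect_gte(min(eps), 1 / (1 + 2 * e / 0.51099895) - 1e-12)
  expect_lte(max(eps), 1 + 1e-12)
  # mean scattered fraction within 3 sigma of the numerically integrated value
  oracle <- kn_mean_scatter_fraction(e)
  se <- stats::sd(eps) / sqrt(length(eps))
  expect_lt(abs(mean(eps) - oracle), 3 * se)
  # energy-angle consistency: eps = 1 / (1 + a (1 - cos theta)) exactly
  a <- e / 0.51099895
  expect_lt(max(abs(eps - 1 / (1 + a * (1 - smp[, "costheta"])))), 1e-12)
})

test_that("pardose and 3ddose files round-trip", {
  d <- withr::local_tempdir()
  scene <- open_water_scene(npx = 8, spacing_mm = 12)
  p <- run_job(scene, job_spec(2e3, base_seed = 9))
  f <- file.path(d, "j.pardose")
  write_pardose(p, f)
  p2 <- read_pardose(f)
  expect_equal(p2$sum, p$sum)
  expect_equal(p2$sumsq, p$sumsq)
  expect_equal(p2$histories, p$histories)
  r <- merge_partials(list(p))
  f3 <- file.path(d, "j.3ddose")
  write_3ddose(r, f3)
  r2 <- read_3ddose(f3)
  expect_equal(r2$dose, r$dose, tolerance = 1e-6)
  expect_equal(r2$grid$spacing, r$grid$spacing, tolerance = 1e-9)
})

test_that("cross sections are internally consistent", {
  for (m in c("Air", "Lung", "Tissue", "Bone")) {
    xs <- cross_section_table(m)
    expect_true(all(xs$mu_rho > 0))
    expect_lt(max(abs(xs$mu_rho - (xs$pe + xs$compton + xs$pair)) / xs$mu_rho),
              0.01)
    expect_true(all(diff(xs$energy) > 0))
    expect_true(all(xs$mu_tr_rho <= xs$mu_rho))
  }
  # water total at 1 MeV is the Compton-dominated 0.0707 cm2/g
  mu <- xs_lookup(cross_section_table("Tissue"), 1.0)
  expect_equal(mu, 0.0707, tolerance = 0.01)
})
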