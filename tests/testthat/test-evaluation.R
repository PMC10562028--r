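sphere_mask <- function(grid, center, radius) {
  co <- expand.grid(x = grid_axis(grid, 1), y = grid_axis(grid, 2),
                    z = grid_axis(grid, 3))
  array((co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2
        <= radius^2, dim = grid$dims)
}

test_that("reference points: centroid plus four offsets, axis rule, pull-in", {
  g <- grid3d(rep(-39, 3), rep(2, 3), rep(40L, 3))
  m <- sphere_mask(g, c(0, 0, 0), 20)
  rp <- select_reference_points(m, g)
  expect_equal(nrow(rp$points), 5)
  expect_equal(rp$points[1, ], c(0, 0, 0), tolerance = 0.5) # centroid
  # tall enough sphere: superior-inferior axis used first
  expect_equal(rp$axes[1], 3L)
  expect_true(all(abs(rp$points[2:3, 3]) == 7.5))
  # all points inside the PTV
  ins <- interp_trilinear(m + 0, g, rp$points)
  expect_true(all(ins > 0))
  expect_false(any(rp$pulled_inward))
  # flat disc: sup-inf extent 6 mm forces lateral axes
  md <- sphere_mask(g, c(0, 0, 0), 25)
  md[, , c(1:18, 22:40)] <- FALSE
  rpd <- select_reference_points(md, g)
  expect_equal(sort(rpd$axes), c(1L, 2L))
  # small sphere: offsets pulled inward along their axes and flagged
  ms <- sphere_mask(g, c(0, 0, 0), 6)
  rps <- select_reference_points(ms, g)
  expect_true(any(rps$pulled_inward))
  expect_true(all(abs(rps$points[, 3]) <= 6))
  expect_error(select_reference_points(array(FALSE, g$dims), g), "empty PTV")
})

test_that("percent differences, strict action limit and summary statistics", {
  g <- grid3d(c(0, 0, 0), c(10, 10, 10), c(8L, 8L, 8L))
  tps <- tps_dose(array(2, dim = g$dims), g$origin, g$spacing)
  pts <- cbind(10 + 10 * (0:4), 30, 30)
  # secondary as point values: diffs {+3, -3, +8, -8, 0}
  sec <- 2 * (1 + c(3, -3, 8, -8, 0) / 100)
  rep <- compare_doses(tps, sec, pts)
  expect_equal(rep$points$diff_percent, c(3, -3, 8, -8, 0))
  expect_equal(rep$summary$mean, 0)
  expect_equal(rep$summary$mean_abs, 4.4)
  expect_equal(rep$summary$fraction_exceeding, 0.4)
  expect_equal(rep$summary$quartiles, c(-3, 0, 3))
  # boundary +5.0% does not flag (strict inequality)
  rep5 <- compare_doses(tps, rep(2.1, 5), pts)
  expect_equal(rep$summary$action_limit_percent, 5)
  expect_equal(rep5$points$diff_percent, rep(5, 5))
  expect_equal(rep5$summary$n_exceeding, 0)
  # identical doses: all zero, no flags
  rep0 <- compare_doses(tps, tps, pts)
  expect_true(all(rep0$points$diff_percent == 0))
  expect_false(any(rep0$points$exceeds_limit))
  # sign flip when the roles are swapped
  sec_grid <- tps_dose(array(2.08, dim = g$dims), g$origin, g$spacing)
  fwd <- compare_doses(tps, sec_grid, pts)
  bwd <- compare_doses(sec_grid, tps, pts)
  expect_true(all(sign(bwd$points$diff_percent) ==
                    -sign(fwd$points$diff_percent)))
  # permutation invariance of the summaries
  perm <- compare_doses(tps, sec[c(3, 1, 5, 2, 4)], pts[c(3, 1, 5, 2, 4), ])
  expect_equal(perm$summary[c("mean", "mean_abs", "sd", "quartiles")],
               rep$summary[c("mean", "mean_abs", "sd", "quartiles")])
  # zero TPS dose: point excluded with warning
  tz <- tps_dose(array(c(0, rep(2, prod(g$dims) - 1)), dim = g$dims),
                 g$origin, g$spacing)
  expect_warning(repz <- compare_doses(tz, rep(2, 5),
                                       rbind(c(0, 0, 0), pts[1:4, ])),
                 "zero TPS dose")
  expect_equal(repz$summary$n, 4)
})

test_that("study pooling: 37 arcs x 5 points = 185 and count-weighted fractions", {
  g <- grid3d(c(0, 0, 0), c(10, 10, 10), c(4L, 4L, 4L))
  tps <- tps_dose(array(2, dim = g$dims), g$origin, g$spacing)
  pts <- cbind(5 + 5 * (0:4), 15, 15)
  mk_report <- function(diffs)
    compare_doses(tps, 2 * (1 + diffs / 100), pts)
  roster <- study_roster()
  expect_equal(nrow(roster), 13)
  expect_equal(sum(roster$arcs), 37)
  expect_true(all(unlist(roster$cp_per_arc) %in% c(98, 114, 178)))
  expect_true(all(roster$dose_grid_mm %in% c(1.25, 2.0)))
  # one report per arc, lung arcs exceeding at one point each
  reports <- list(); site <- character(0)
  for (i in seq_len(nrow(roster))) for (a in seq_len(roster$arcs[i])) {
    diffs <- if (roster$site[i] == "lung") c(8, 0, 0, 0, 0) else rep(0, 5)
    reports[[length(reports) + 1L]] <- mk_report(diffs)
    site <- c(site, roster$site[i])
  }
  ss <- study_summary(reports, site = site)
  expect_equal(ss$n_points, 185)
  expect_equal(ss$n_arcs, 37)
  # 4 lung plans x 3 arcs x 1 point
  expect_equal(ss$n_exceeding, 12)
  expect_equal(ss$fraction_exceeding, 12 / 185)
  # pooled fraction equals the count-weighted mean of per-arc fractions
  per_arc <- vapply(reports, function(r) r$summary$fraction_exceeding,
                    numeric(1))
  n_arc <- vapply(reports, function(r) r$summary$n, numeric(1))
  expect_equal(ss$fraction_exceeding,
               sum(per_arc * n_arc) / sum(n_arc))
  # single arc with 1/5 exceeding
  one <- study_summary(list(mk_report(c(9, 0, 0, 0, 0))))
  expect_equal(one$fraction_exceeding, 0.2)
  lungrow <- ss$per_group[ss$per_group$site == "lung", ]
  expect_equal(lungrow$fraction_exceeding, 12 / 60)
})
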