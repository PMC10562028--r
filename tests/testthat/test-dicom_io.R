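test_that("CT series round-trips byte-exactly with HU rescale applied", {
  d <- withr::local_tempdir()
  ct <- make_ct(thorax_recipe(spacing_mm = 8), seed = 5,
                dir = file.path(d, "ct"))
  ct2 <- read_ct_series(file.path(d, "ct"))
  expect_identical(ct$hu, ct2$hu)
  expect_equal(ct$grid$origin, ct2$grid$origin)
  expect_equal(ct$grid$spacing, ct2$grid$spacing)
  # rescale identity: stored value 24 with intercept -1024 means HU -1000
  raw_ds <- muvr:::read_dicom(file.path(d, "ct", "CT.001.dcm"))
  px <- muvr:::dcm_get(raw_ds, "PixelData")
  stored <- readBin(px, integer(), 4, size = 2, endian = "little")
  expect_equal(stored[1], 24)
  expect_equal(ct2$hu[1, 1, 1], -1000)
})

test_that("missing slices and mixed series are rejected with diagnostics", {
  d <- withr::local_tempdir()
  make_ct(phantom_recipe(extent_mm = c(40, 40, 80), spacing_mm = 4),
          seed = 2, dir = file.path(d, "ct"))
  unlink(file.path(d, "ct", "CT.007.dcm"))
  expect_error(read_ct_series(file.path(d, "ct")), "gap of 8.000 mm")
  # a slice from another series (different seed -> different series UID)
  d2 <- withr::local_tempdir()
  make_ct(phantom_recipe(extent_mm = c(40, 40, 80), spacing_mm = 4),
          seed = 3, dir = d2)
  file.copy(file.path(d2, "CT.001.dcm"), file.path(d, "ct", "CT.099.dcm"))
  expect_error(read_ct_series(file.path(d, "ct")), "mixed series")
})

test_that("RT Plan round-trips a 98-control-point arc and flags bad plans", {
  d <- withr::local_tempdir()
  f <- file.path(d, "plan.dcm")
  plan <- make_plan(plan_recipe(n_arcs = 2, n_cp = 98, energy = "10FFF",
                                beam_mu = c(210)), isocenter = c(1, -2, 3),
                    path = f)
  p2 <- read_rtplan(f)
  expect_length(p2$beams, 2)
  b <- p2$beams[[1]]
  expect_equal(b$energy, "10FFF")
  expect_equal(b$beam_mu, 210)
  expect_length(b$control_points, 98)
  expect_equal(b$control_points[[1]]$cum_weight, 0)
  expect_equal(b$control_points[[98]]$cum_weight, 1)
  expect_equal(p2$isocenter, c(1, -2, 3))
  # full per-control-point equality against the in-memory plan
  for (ci in c(1, 25, 98)) {
    a <- plan$beams[[2]]$control_points[[ci]]
    bb <- p2$beams[[2]]$control_points[[ci]]
    expect_equal(a$gantry_deg, bb$gantry_deg, tolerance = 1e-8)
    expect_equal(a$mlc_a, bb$mlc_a, tolerance = 1e-8)
    expect_equal(a$cum_weight, bb$cum_weight, tolerance = 1e-9)
  }
  # crossed leaves at control point 5 name beam, CP and pair
  ds <- muvr:::read_dicom(f)
  for (j in seq_along(ds)) {
    if (ds[[j]]$keyword == "BeamSequence") {
      cps <- ds[[j]]$value[[1]]
      for (k in seq_along(cps[[1]])) NULL
      for (k in seq_along(ds[[j]]$value[[1]])) {
        if (ds[[j]]$value[[1]][[k]]$keyword == "ControlPointSequence") {
          cp5 <- ds[[j]]$value[[1]][[k]]$value[[6]]
          for (m in seq_along(cp5)) {
            if (cp5[[m]]$keyword == "BeamLimitingDevicePositionSequence") {
              mlc <- cp5[[m]]$value[[3]]
              pos <- muvr:::dcm_get(mlc, "LeafJawPositions")
              n <- length(pos) / 2
              pos[3] <- pos[n + 3] + 5 # cross pair 3
              cp5[[m]]$value[[3]] <- muvr:::dcm_set(mlc, "LeafJawPositions", pos)
            }
          }
          ds[[j]]$value[[1]][[k]]$value[[6]] <- cp5
        }
      }
    }
  }
  f2 <- file.path(d, "bad.dcm")
  muvr:::write_dicom(ds, f2)
  expect_error(read_rtplan(f2), "beam 1 control point 5.*pair.* 3")
})

test_that("structure masks match analytic volumes and empty ROIs warn", {
  d <- withr::local_tempdir()
  ct <- make_ct(phantom_recipe(extent_mm = c(60, 60, 60), spacing_mm = 2),
                seed = 4)
  f <- file.path(d, "ss.dcm")
  write_rtstruct(list(PTV = sphere_contours(c(0, 0, 0), 20, ct$grid),
                      Empty = list()), f)
  expect_warning(ss <- read_structures(f, ct), "no contours")
  vol <- sum(ss$rois$PTV$mask) * prod(ct$grid$spacing)
  expect_lt(abs(vol - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3), 0.05)
  expect_equal(sum(ss$rois$Empty$mask), 0)
})

test_that("RT Dose round-trips within one quantization step", {
  d <- withr::local_tempdir()
  g <- grid3d(c(0, 0, 0), c(2, 2, 2), c(6L, 5L, 4L))
  dose <- array(2, dim = g$dims)
  f <- file.path(d, "dose.dcm")
  write_rtdose(dose, g, f)
  rt <- read_rtdose(f)
  expect_lte(max(abs(rt$dose - 2)), 2 / 65535)
  expect_equal(rt$grid$dims, g$dims)
  # zero dose encodes all-zero pixels
  write_rtdose(array(0, dim = g$dims), g, f)
  expect_true(all(read_rtdose(f)$dose == 0))
  # second read is bitwise identical (stored scaled integers are stable)
  write_rtdose(array(muv_runif(8, prod(g$dims)), dim = g$dims), g, f)
  a <- read_rtdose(f)
  f2 <- file.path(d, "dose2.dcm")
  write_rtdose(a$dose, a$grid, f2)
  expect_identical(read_rtdose(f2)$dose, a$dose)
  expect_error(write_rtdose(array(-1, dim = g$dims), g, f), "non-negative")
})

test_that("dose grids finer than the CT load with separate geometry", {
  d <- withr::local_tempdir()
  ct <- make_ct(phantom_recipe(extent_mm = c(40, 40, 40), spacing_mm = 2),
                seed = 6)
  gd <- grid3d(c(-10, -10, -10), c(1.25, 1.25, 1.25), c(16L, 16L, 16L))
  f <- file.path(d, "dose.dcm")
  write_rtdose(array(1, dim = gd$dims), gd, f)
  td <- read_rtdose(f)
  expect_equal(td$grid$spacing, rep(1.25, 3))
  expect_equal(ct$grid$spacing, rep(2, 3))
})

test_that("strip_identifiers anonymizes, remaps UIDs consistently and is idempotent", {
  d <- withr::local_tempdir()
  plan <- make_plan(plan_recipe(n_arcs = 1, n_cp = 4),
                    path = file.path(d, "plan.dcm"), seed = 8)
  write_rtdose(array(1, dim = c(3, 3, 3)), grid3d(c(0, 0, 0), c(2, 2, 2),
                                                  c(3L, 3L, 3L)),
               file.path(d, "dose.dcm"), seed = 8)
  out <- strip_identifiers(file.path(d, c("plan.dcm", "dose.dcm")),
                           file.path(d, "anon"))
  a <- muvr:::read_dicom(out[1]); b <- muvr:::read_dicom(out[2])
  expect_equal(muvr:::dcm_get(a, "PatientName"), "ANON^ANON")
  # shared study UID remapped to the same value in both outputs
  expect_identical(muvr:::dcm_get(a, "StudyInstanceUID"),
                   muvr:::dcm_get(b, "StudyInstanceUID"))
  expect_false(identical(muvr:::dcm_get(a, "StudyInstanceUID"),
                         muvr:::muv_uid(8, 1)))
  # distinct inputs stay distinct (bijective remap on this set)
  expect_false(identical(muvr:::dcm_get(a, "SOPInstanceUID"),
                         muvr:::dcm_get(b, "SOPInstanceUID")))
  # idempotence: stripping a stripped file changes nothing
  out2 <- strip_identifiers(out[1], file.path(d, "anon2"))
  expect_identical(readBin(out[1], raw(), file.size(out[1])),
                   readBin(out2[1], raw(), file.size(out2[1])))
  # stripped plan still parses
  expect_length(read_rtplan(out[1])$beams, 1)
})
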