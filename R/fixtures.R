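# Synthetic-input generators: CT volumes with geometric HU regions, toy
# VMAT plans, structure contours, TPS-like dose grids, phase-space files
# and the study roster fixture. Everything is deterministic under a fixed
# seed so the full pipeline is testable with no external data.

#' Phantom recipe
#'
#' @param extent_mm physical extent per axis, mm.
#' @param spacing_mm voxel size, mm.
#' @param background_hu HU outside all regions.
#' @param regions list of region lists; each has `shape` (`"slab"`,
#'   `"sphere"`, `"cylinder"` or `"box"`), an `hu` value, and shape
#'   parameters: slab: `axis`, `from`, `to` (mm); sphere: `center`,
#'   `radius`; cylinder: `axis`, `center` (3-vector; the axis component is
#'   ignored), `radius`, `from`, `to`; box: `lo`, `hi` (3-vectors, mm).
#' @param noise_sd optional Gaussian HU noise, HU.
#' @return object of class `phantom_recipe`.
#' @export
phantom_recipe <- function(extent_mm = c(200, 200, 100), spacing_mm = 4,
                           background_hu = 0, regions = list(),
                           noise_sd = 0) {
  structure(list(extent_mm = rep(extent_mm, length.out = 3),
                 spacing_mm = rep(spacing_mm, length.out = 3),
                 background_hu = background_hu, regions = regions,
                 noise_sd = noise_sd),
            class = "phantom_recipe")
}

#' Thorax-like phantom recipe
#'
#' Tissue block with two lung cylinders (HU -750) and a bone rod (HU 700),
#' surrounded by air: a small-scale stand-in for a lung SBRT anatomy with
#' multiple soft-tissue/lung interfaces.
#'
#' @param spacing_mm voxel size, mm.
#' @return a [phantom_recipe()].
#' @export
thorax_recipe <- function(spacing_mm = 4) {
  phantom_recipe(
    extent_mm = c(240, 160, 120), spacing_mm = spacing_mm,
    background_hu = -1000,
    regions = list(
      list(shape = "cylinder", axis = 3, center = c(0, 0, 0), radius = 75,
           from = -60, to = 60, hu = 0),                    # body
      list(shape = "cylinder", axis = 3, center = c(-42, -8, 0), radius = 28,
           from = -60, to = 60, hu = -750),                 # right lung
      list(shape = "cylinder", axis = 3, center = c(42, -8, 0), radius = 28,
           from = -60, to = 60, hu = -750),                 # left lung
      list(shape = "cylinder", axis = 3, center = c(0, 48, 0), radius = 10,
           from = -60, to = 60, hu = 700)                   # vertebral bone
    ))
}

#' Lung/tissue interface recipe
#'
#' Tissue body cylinder containing a rectangular lung block whose medial
#' face sits between voxel columns, so a PTV straddling the interface
#' yields reference points that interpolate cleanly from one material only.
#' Used by the end-to-end evaluation fixture.
#'
#' @param spacing_mm voxel size, mm.
#' @return a [phantom_recipe()].
#' @export
interface_recipe <- function(spacing_mm = 4) {
  phantom_recipe(
    extent_mm = c(240, 160, 120), spacing_mm = spacing_mm,
    background_hu = -1000,
    regions = list(
      list(shape = "cylinder", axis = 3, center = c(0, 0, 0), radius = 75,
           from = -60, to = 60, hu = 0),
      list(shape = "box", lo = c(-70, -40, -48), hi = c(-12.1, 24, 48),
           hu = -750)))
}

#' Generate a CT volume from a recipe
#'
#' Deterministic given `seed`; later regions overwrite earlier ones.
#'
#' @param recipe a [phantom_recipe()].
#' @param seed noise seed.
#' @param dir optional directory: when given the series is also written as
#'   DICOM files via [write_ct_series()].
#' @return a [ct_volume()]; when `dir` is given, attribute `files` lists the
#'   slice paths.
#' @export
make_ct <- function(recipe, seed = 1, dir = NULL) {
  dims <- pmax(2L, as.integer(round(recipe$extent_mm / recipe$spacing_mm)))
  g <- grid3d(-(dims - 1) * recipe$spacing_mm / 2, recipe$spacing_mm, dims)
  xs <- grid_axis(g, 1); ys <- grid_axis(g, 2); zs <- grid_axis(g, 3)
  hu <- array(recipe$background_hu, dim = dims)
  co <- expand.grid(x = xs, y = ys, z = zs)
  for (r in recipe$regions) {
    inside <- switch(r$shape,
      slab = {
        ax <- c("x", "y", "z")[r$axis]
        co[[ax]] >= r$from & co[[ax]] <= r$to
      },
      sphere = {
        (co$x - r$center[1])^2 + (co$y - r$center[2])^2 +
          (co$z - r$center[3])^2 <= r$radius^2
      },
      cylinder = {
        perp <- setdiff(1:3, r$axis)
        ax <- c("x", "y", "z")
        d2 <- (co[[ax[perp[1]]]] - r$center[perp[1]])^2 +
          (co[[ax[perp[2]]]] - r$center[perp[2]])^2
        d2 <= r$radius^2 & co[[ax[r$axis]]] >= r$from & co[[ax[r$axis]]] <= r$to
      },
      box = {
        co$x >= r$lo[1] & co$x <= r$hi[1] &
          co$y >= r$lo[2] & co$y <= r$hi[2] &
          co$z >= r$lo[3] & co$z <= r$hi[3]
      },
      stop("make_ct: unknown shape ", r$shape))
    hu[inside] <- r$hu
  }
  if (recipe$noise_sd > 0) {
    u <- muv_runif(seed, length(hu))
    hu <- hu + stats::qnorm(u) * recipe$noise_sd
  }
  # out-of-table HU are kept (clamp tests rely on them); the CT writer
  # rejects anything outside its signed-16-bit storable range
  hu <- round(hu)
  ct <- ct_volume(hu, g$origin, g$spacing)
  if (!is.null(dir)) attr(ct, "files") <- write_ct_series(ct, dir, seed = seed)
  ct
}

#' Plan recipe
#'
#' @param n_arcs number of arcs.
#' @param n_cp control points per arc (e.g. 98, 114 or 178); scalar or
#'   vector of length `n_arcs`.
#' @param energy energy label.
#' @param beam_mu MU per arc.
#' @param gantry_start,gantry_end arc span, degrees.
#' @param aperture `"sphere"` (leaves conform to a target sphere per gantry
#'   angle) or `"square"`.
#' @param target_radius_mm sphere-conformal target radius.
#' @param field_mm square field side.
#' @param n_pairs,leaf_width_mm MLC bank layout.
#' @param dose_grid_mm TPS dose-grid resolution carried as plan metadata
#'   (1.25 or 2.0).
#' @return object of class `plan_recipe`.
#' @export
plan_recipe <- function(n_arcs = 3, n_cp = 114, energy = "6FFF",
                        beam_mu = 400, gantry_start = 181, gantry_end = 179,
                        aperture = c("sphere", "square"),
                        target_radius_mm = 25, field_mm = 100,
                        n_pairs = 40, leaf_width_mm = 5,
                        dose_grid_mm = 2.0) {
  structure(list(n_arcs = n_arcs, n_cp = rep(n_cp, length.out = n_arcs),
                 energy = match.arg(energy, supported_energies()),
                 beam_mu = beam_mu, gantry_start = gantry_start,
                 gantry_end = gantry_end, aperture = match.arg(aperture),
                 target_radius_mm = target_radius_mm, field_mm = field_mm,
                 n_pairs = n_pairs, leaf_width_mm = leaf_width_mm,
                 dose_grid_mm = dose_grid_mm),
            class = "plan_recipe")
}

#' Generate a VMAT plan from a recipe
#'
#' Cumulative meterset weights are uniform; the sphere-conformal aperture
#' opens each leaf pair to the chord of the target sphere at the pair's
#' y-position (gantry-independent for a sphere at isocenter, which is the
#' point: a simple, exactly-known aperture program).
#'
#' @param recipe a [plan_recipe()].
#' @param isocenter patient-space isocenter, mm.
#' @param path optional RT Plan output path (DICOM written when given).
#' @param seed UID seed for the DICOM writer.
#' @return a [vmat_plan()]; attribute `path` when written.
#' @export
make_plan <- function(recipe, isocenter = c(0, 0, 0), path = NULL, seed = 1) {
  np <- recipe$n_pairs
  half_span <- np * recipe$leaf_width_mm / 2
  edges <- seq(-half_span, half_span, by = recipe$leaf_width_mm)
  ycent <- (edges[-1] + edges[-length(edges)]) / 2
  beams <- vector("list", recipe$n_arcs)
  for (a in seq_len(recipe$n_arcs)) {
    ncp <- recipe$n_cp[a]
    # alternate rotation direction per arc like clinical multi-arc plans
    gs <- if (a %% 2 == 1) recipe$gantry_start else recipe$gantry_end
    ge <- if (a %% 2 == 1) recipe$gantry_end else recipe$gantry_start
    span <- ((ge - gs) %% 360); if (span == 0) span <- 360
    if (a %% 2 == 0) span <- -((gs - ge) %% 360)
    gantry <- (gs + span * (seq_len(ncp) - 1) / (ncp - 1)) %% 360
    w <- (seq_len(ncp) - 1) / (ncp - 1)
    cps <- vector("list", ncp)
    for (ci in seq_len(ncp)) {
      if (recipe$aperture == "sphere") {
        r <- recipe$target_radius_mm
        chord <- sqrt(pmax(0, r^2 - ycent^2))
        a1 <- -chord; a2 <- chord
        jaws <- c(-r, r, -r, r)
      } else {
        h <- recipe$field_mm / 2
        open <- abs(ycent) < h
        a1 <- ifelse(open, -h, 0); a2 <- ifelse(open, h, 0)
        jaws <- c(-h, h, -h, h)
      }
      cps[[ci]] <- control_point(gantry[ci], jaws, a1, a2, w[ci])
    }
    beams[[a]] <- arc_beam(recipe$energy, recipe$beam_mu, cps, edges)
  }
  plan <- vmat_plan(beams, isocenter = isocenter,
                    plan_label = sprintf("%s-%darc", recipe$energy,
                                         recipe$n_arcs))
  if (!is.null(path)) {
    write_rtplan(plan, path, seed = seed)
    attr(plan, "path") <- path
  }
  plan
}

#' Sphere contours for a PTV
#'
#' Closed planar polygons per CT slice intersecting the sphere, for the
#' RT Structure Set writer.
#'
#' @param center,radius sphere, mm.
#' @param grid the CT [grid3d()] (slice positions).
#' @param n_vertices polygon vertices per slice.
#' @return list of n x 3 matrices.
#' @export
sphere_contours <- function(center, radius, grid, n_vertices = 72) {
  zs <- grid_axis(grid, 3)
  out <- list()
  for (z in zs) {
    dz <- z - center[3]
    if (abs(dz) >= radius) next
    r <- sqrt(radius^2 - dz^2)
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    out[[length(out) + 1L]] <-
      cbind(center[1] + r * cos(th), center[2] + r * sin(th), z)
  }
  out
}

#' Run the MC pipeline for a whole plan and return calibrated dose
#'
#' Simulates every arc of the plan through the engine, applies the
#' per-energy calibration factor and the arc MU, and sums the arcs.
#'
#' @param plan a [vmat_plan()].
#' @param phantom a [voxel_phantom()].
#' @param fcal a `calibration_factor` for the plan energy.
#' @param histories_per_arc engine histories per arc.
#' @param base_seed run seed (each arc uses `base_seed + 1000 * arc`).
#' @param n_jobs jobs per arc.
#' @param transmission MLC transmission.
#' @return a `dose_result` with `dose` in Gy.
#' @export
simulate_plan_dose <- function(plan, phantom, fcal, histories_per_arc = 2e5,
                               base_seed = 1, n_jobs = 1, transmission = 0) {
  total <- NULL
  for (a in seq_along(plan$beams)) {
    b <- plan$beams[[a]]
    segs <- arc_segments(b, iso = plan$isocenter, transmission = transmission)
    scene <- mc_scene(phantom, segs, beam_source(b$energy))
    res <- simulate_scene(scene, histories_per_arc, n_jobs = n_jobs,
                          base_seed = base_seed + 1000 * a)
    cal <- apply_calibration(res, fcal, mu = b$beam_mu, energy = b$energy)
    if (is.null(total)) total <- cal
    else {
      total$dose <- total$dose + cal$dose
      total$histories <- total$histories + cal$histories
    }
  }
  total
}

#' Synthetic TPS dose for a plan
#'
#' `mc-proxy` mode runs the package's own engine at the requested histories
#' and relabels the calibrated result as TPS truth, optionally multiplied by
#' a perturbation field to manufacture known disagreement patterns (e.g.
#' +7% inside the lung mask). `analytic` mode returns a closed-form
#' exponential pencil-beam dose for the square-field recipe, usable for
#' closed-form checks. The proxy is deliberately circular (documented): it
#' exercises the evaluation logic, not TPS fidelity.
#'
#' @param plan a [vmat_plan()].
#' @param phantom a [voxel_phantom()].
#' @param fcal calibration factor (mc-proxy mode).
#' @param mode `"mc-proxy"` or `"analytic"`.
#' @param perturbation optional list `(mask, factor)`: logical array on the
#'   phantom grid and the multiplicative factor applied inside it.
#' @param histories_per_arc engine histories (mc-proxy).
#' @param base_seed run seed.
#' @param mu_eff analytic-mode effective attenuation, 1/cm.
#' @return a [tps_dose()].
#' @export
make_tps_dose <- function(plan, phantom, fcal = NULL,
                          mode = c("mc-proxy", "analytic"),
                          perturbation = NULL, histories_per_arc = 2e5,
                          base_seed = 1, mu_eff = 0.056) {
  mode <- match.arg(mode)
  g <- phantom$grid
  if (mode == "mc-proxy") {
    stopifnot(!is.null(fcal))
    res <- simulate_plan_dose(plan, phantom, fcal,
                              histories_per_arc = histories_per_arc,
                              base_seed = base_seed)
    dose <- res$dose
  } else {
    # single-beam exponential pencil dose from gantry 0: exp(-mu * depth)
    ys <- grid_axis(g, 2)
    depth_cm <- pmax(0, (ys - (g$origin[2] - g$spacing[2] / 2)) / 10)
    prof <- exp(-mu_eff * depth_cm)
    dose <- array(rep(prof, each = g$dims[1]), dim = g$dims)
  }
  if (!is.null(perturbation))
    dose <- dose * ifelse(perturbation$mask, perturbation$factor, 1)
  tps_dose(dose, g$origin, g$spacing)
}

#' Synthetic phase-space file
#'
#' Deterministic given `seed`. `sparse = TRUE` writes a header-only file
#' with the declared count (no records), for count-arithmetic tests that
#' would otherwise need hundreds of millions of records.
#'
#' @param path output file.
#' @param n declared particle count.
#' @param energy energy label.
#' @param seed sampling seed.
#' @param plane_z source plane, mm.
#' @param sparse header-only mode.
#' @return the written `phase_space` (re-read), invisibly.
#' @export
make_phase_space <- function(path, n, energy = "6X", seed = 1,
                             plane_z = -500, sparse = FALSE) {
  if (sparse || n == 0) {
    write_phase_space(path, NULL, energy, plane_z, count = n)
  } else {
    u <- matrix(muv_runif(seed, 5L * n), ncol = 5)
    spec <- toy_spectrum(energy)
    cdf <- cumsum(spec$prob)
    e <- spec$energy[findInterval(u[, 1], c(0, cdf), rightmost.closed = TRUE)]
    x <- (u[, 2] - 0.5) * 100; y <- (u[, 3] - 0.5) * 100
    ux <- (u[, 4] - 0.5) * 0.2; uy <- (u[, 5] - 0.5) * 0.2
    uz <- sqrt(1 - ux^2 - uy^2)
    recs <- data.frame(x = x, y = y, u = ux, v = uy, w = uz,
                       energy = e, weight = 1)
    write_phase_space(path, recs, energy, plane_z, count = n)
  }
  invisible(read_phase_space(path, header_only = sparse || n == 0))
}

#' Study roster fixture
#'
#' Thirteen plans spanning abdominal, brain, head & neck, lung and prostate
#' sites with the control-point counts, arc counts, energies and dose-grid
#' resolutions of a realistic clinical VMAT study (one brain plan mixes 178-
#' and 98-control-point arcs).
#'
#' @return data.frame with one row per plan and a `cp_per_arc` list column.
#' @export
study_roster <- function() {
  df <- data.frame(
    plan = c("Abdominal 1", "Abdominal 2", "Brain 1", "Brain 2",
             "Head & Neck 1", "Head & Neck 2", "Lung 1", "Lung 2", "Lung 3",
             "Lung 4", "Prostate 1", "Prostate 2", "Prostate 3"),
    site = c("abdomen", "abdomen", "brain", "brain", "head_neck", "head_neck",
             "lung", "lung", "lung", "lung", "prostate", "prostate",
             "prostate"),
    energy = c("6FFF", "10FFF", "6FFF", "6X", "10FFF", "6FFF", "6FFF", "6FFF",
               "6FFF", "6FFF", "10X", "10X", "6X"),
    arcs = c(3, 3, 3, 4, 3, 3, 3, 3, 3, 3, 2, 2, 2),
    dose_grid_mm = c(1.25, 1.25, 1.25, 2.0, 1.25, 1.25, 1.25, 1.25, 1.25,
                     1.25, 2.0, 2.0, 2.0),
    stringsAsFactors = FALSE)
  df$cp_per_arc <- lapply(seq_len(nrow(df)), function(i)
    switch(df$plan[i],
           "Brain 2" = c(178, 178, 98, 98),
           "Brain 1" = , "Lung 3" = rep(98, df$arcs[i]),
           "Head & Neck 1" = , "Head & Neck 2" = ,
           "Prostate 1" = , "Prostate 2" = ,
           "Prostate 3" = rep(178, df$arcs[i]),
           rep(114, df$arcs[i])))
  df
}
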