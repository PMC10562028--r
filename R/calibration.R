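# Per-energy calibration of engine output (Gy/particle) to absolute dose.
#
# The calibration factor links the TPS reference output (cGy/MU) and the
# engine dose per launched particle under the reference condition (10 x 10
# cm2 open field, 100 cm SSD, 40 cm water cube, scoring at 10 cm depth on
# the central axis):
#
#   F_cal = D_tps[Gy/MU] / D_mc[Gy/particle]     (particles per MU)
#
# and absolute dose is D[Gy] = D_mc[Gy/particle] * F_cal * MU. The printed
# clinical convention quotes the TPS output in cGy/MU; the factor of 100 is
# applied explicitly here so everything downstream is in Gy.

#' Reference measurement pair for one energy
#'
#' @param d_tps_cgy_per_mu TPS dose per MU at the reference point, cGy/MU.
#' @param mu_ref monitor units of the reference calculation (cancels in the
#'   factor; kept for provenance and the closure identity).
#' @param d_mc_gy_per_particle engine dose at the same point, Gy/particle.
#' @param energy energy label.
#' @return object of class `reference_measurement`.
#' @export
reference_measurement <- function(d_tps_cgy_per_mu, mu_ref,
                                  d_mc_gy_per_particle, energy) {
  energy <- match.arg(energy, supported_energies())
  vals <- c(d_tps_cgy_per_mu, mu_ref, d_mc_gy_per_particle)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("reference_measurement: all inputs must be strictly positive")
  structure(list(d_tps_cgy_per_mu = d_tps_cgy_per_mu,
                 mu_ref = mu_ref,
                 d_mc_gy_per_particle = d_mc_gy_per_particle,
                 energy = energy),
            class = "reference_measurement")
}

#' Compute the per-energy calibration factor
#'
#' @param ref a [reference_measurement()].
#' @param provenance free-text description of the reference setup.
#' @return object of class `calibration_factor` with `value` in
#'   particles/MU.
#' @export
compute_fcal <- function(ref, provenance = "10x10 cm, SSD 100, water, d = 10 cm") {
  stopifnot(inherits(ref, "reference_measurement"))
  value <- (ref$d_tps_cgy_per_mu * 0.01) / ref$d_mc_gy_per_particle
  structure(list(value = value, energy = ref$energy, provenance = provenance),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf("F_cal[%s] = %.6g particles/MU  (%s)\n",
              x$energy, x$value, x$provenance))
  invisible(x)
}

#' Apply a calibration factor to an engine dose result
#'
#' `dose_Gy = dose_per_particle * F_cal * MU` voxel-wise; relative
#' uncertainties are unchanged by the scaling.
#'
#' @param result a `dose_result` (Gy/particle).
#' @param fcal a `calibration_factor`.
#' @param mu monitor units of the arc (>= 0).
#' @param energy energy label of the arc; must match the factor's.
#' @return a `dose_result` with `dose` in Gy and `calibrated = TRUE`.
#' @export
apply_calibration <- function(result, fcal, mu, energy = fcal$energy) {
  stopifnot(inherits(fcal, "calibration_factor"))
  if (!identical(energy, fcal$energy))
    stop(sprintf("apply_calibration: arc energy %s does not match factor energy %s",
                 energy, fcal$energy))
  if (mu < 0) stop("apply_calibration: negative MU")
  out <- result
  out$dose <- result$dose * fcal$value * mu
  out$calibrated <- TRUE
  out
}

#' Calibration registry: one factor per energy
#'
#' @return an environment-backed registry with `$add(fcal)` (rejects
#'   duplicate energies), `$get(energy)` and `$energies()`.
#' @export
calibration_registry <- function() {
  store <- new.env(parent = emptyenv())
  list(
    add = function(fcal) {
      stopifnot(inherits(fcal, "calibration_factor"))
      if (!is.null(store[[fcal$energy]]))
        stop(sprintf("calibration_registry: factor for %s already registered",
                     fcal$energy))
      store[[fcal$energy]] <- fcal
      invisible(fcal)
    },
    get = function(energy) {
      f <- store[[energy]]
      if (is.null(f)) stop(sprintf("calibration_registry: no factor for %s", energy))
      f
    },
    energies = function() ls(store)
  )
}

#' Write / read a calibration registry as a text file
#'
#' One record per line: `label value provenance` (tab-separated).
#' @param reg a [calibration_registry()].
#' @param path file path.
#' @return `path` / a registry.
#' @export
write_calibration <- function(reg, path) {
  lines <- vapply(reg$energies(), function(e) {
    f <- reg$get(e)
    paste(f$energy, format(f$value, digits = 12), f$provenance, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  reg <- calibration_registry()
  for (ln in readLines(path)) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    reg$add(structure(list(value = as.numeric(p[2]), energy = p[1],
                           provenance = p[3]),
                      class = "calibration_factor"))
  }
  reg
}

#' Reference condition: water cube, static 10 x 10 field, SSD 100
#'
#' Emits the calibration geometry: a 40 x 40 x 40 cm water phantom whose
#' entrance surface sits at the isocenter plane (SSD 100 = SAD), a single
#' static open 10 x 10 cm field (gantry 0), and the central-axis scoring
#' point at 10 cm depth.
#'
#' @param spacing_mm phantom voxel size, mm.
#' @param field_mm field side at isocenter, mm.
#' @param depth_mm scoring depth below the entrance surface, mm.
#' @return list with `phantom`, `segments` (single open segment),
#'   `scoring_point` (mm) and `field_mm`.
#' @export
reference_setup <- function(spacing_mm = 5, field_mm = 100, depth_mm = 100) {
  n <- as.integer(round(400 / spacing_mm))
  # beam travels +y (gantry 0); entrance surface at y = 0 (isocenter plane)
  origin <- c(-(n - 1) * spacing_mm / 2, spacing_mm / 2,
              -(n - 1) * spacing_mm / 2)
  g <- grid3d(origin, rep(spacing_mm, 3), rep(n, 3L))
  tab <- hu_material_table()
  ph <- voxel_phantom(array(match("Tissue", tab$material), dim = g$dims),
                      array(1.0, dim = g$dims), g, tab)
  half <- field_mm / 2
  ap <- aperture(jaws = c(-half, half, -half, half),
                 leaf_edges = c(-half, half),
                 leaf_a = -half, leaf_b = half, transmission = 0)
  seg <- list(gantry_deg = 0, aperture = ap, mu = 1, mu_frac = 1,
              iso = c(0, 0, 0))
  list(phantom = ph, segments = list(seg),
       scoring_point = c(0, depth_mm, 0), field_mm = field_mm)
}

#' Run the reference simulation and derive a calibration factor
#'
#' Simulates the reference condition, reads the engine dose at the scoring
#' point (trilinear), and forms the factor against the supplied TPS
#' reference output.
#'
#' @param energy energy label.
#' @param d_tps_cgy_per_mu TPS reference output, cGy/MU.
#' @param histories engine histories.
#' @param seed run seed.
#' @param spacing_mm reference phantom voxel size, mm.
#' @return list with `fcal` (a `calibration_factor`), the reference
#'   `result`, `setup` and the measured `d_mc` (Gy/particle).
#' @export
calibrate_energy <- function(energy, d_tps_cgy_per_mu = 0.85,
                             histories = 2e5, seed = 1, spacing_mm = 5) {
  setup <- reference_setup(spacing_mm = spacing_mm)
  scene <- mc_scene(setup$phantom, setup$segments, beam_source(energy))
  res <- simulate_scene(scene, histories, n_jobs = 1, base_seed = seed)
  d_mc <- interp_trilinear(res$dose, res$grid,
                           matrix(setup$scoring_point, ncol = 3))
  ref <- reference_measurement(d_tps_cgy_per_mu, mu_ref = 100,
                               d_mc_gy_per_particle = d_mc, energy = energy)
  list(fcal = compute_fcal(ref), result = res, setup = setup, d_mc = d_mc)
}
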