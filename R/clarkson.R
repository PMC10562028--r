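# Modified Clarkson sector-integration point-dose calculator: the
# representative of the simple commercial secondary-check algorithm class.
# Heterogeneities are handled only through the effective (radiological)
# depth along the source-to-point line; tissue off that line is invisible to
# the algorithm by construction, which is exactly the failure mode the
# Monte Carlo engine is meant to expose.

#' Radiological (water-equivalent) depth along a ray
#'
#' Exact voxel ray tracing (Siddon-style): the segment from `source` to
#' `point` is cut at every voxel-face crossing and the geometric length in
#' each voxel is weighted by that voxel's density relative to water.
#'
#' @param phantom a [voxel_phantom()].
#' @param source ray start, mm (typically the beam focal spot).
#' @param point ray end, mm; must lie inside the phantom.
#' @return water-equivalent depth, cm.
#' @export
radiological_depth <- function(phantom, source, point) {
  g <- phantom$grid
  ext <- grid_extent(g)
  if (any(point < ext["lower", ] - 1e-9) || any(point > ext["upper", ] + 1e-9))
    stop("radiological_depth: point outside the phantom")
  d <- point - source
  L <- vnorm(d)
  if (L < 1e-12) return(0)
  dir <- d / L
  # parametric t in [0, L] (mm); collect crossings of all voxel faces
  ts <- c(0, L)
  for (ax in 1:3) {
    if (abs(dir[ax]) < 1e-12) next
    faces <- ext["lower", ax] + (0:g$dims[ax]) * g$spacing[ax]
    t <- (faces - source[ax]) / dir[ax]
    ts <- c(ts, t[t > 0 & t < L])
  }
  # clip to phantom entry
  t0 <- 0; t1 <- L
  for (ax in 1:3) {
    if (abs(dir[ax]) < 1e-12) {
      if (source[ax] < ext["lower", ax] || source[ax] > ext["upper", ax])
        return(0)
    } else {
      ta <- (ext["lower", ax] - source[ax]) / dir[ax]
      tb <- (ext["upper", ax] - source[ax]) / dir[ax]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  ts <- sort(unique(pmin(pmax(ts, t0), t1)))
  if (length(ts) < 2) return(0)
  mid <- (ts[-1] + ts[-length(ts)]) / 2
  len <- diff(ts)
  pts <- sweep(outer(mid, dir), 2, source, `+`)
  idx <- sapply(1:3, function(ax)
    pmin(pmax(floor((pts[, ax] - ext["lower", ax]) / g$spacing[ax]) + 1, 1),
         g$dims[ax]))
  dens <- phantom$density[cbind(idx[, 1], idx[, 2], idx[, 3])]
  sum(len * dens) / 10  # mm -> cm, densities relative to water (1 g/cm3)
}

# ---- commissioning tables ---------------------------------------------------

#' Analytic toy commissioning tables for one energy
#'
#' Tissue-maximum ratio `TMR(d) = exp(-mu_eff * (d - d_ref))` (field-size
#' independent in the toy model) and a saturating circular-field scatter
#' factor `S(r) = 1 - exp(-r / r0)` normalized at the reference field's
#' equivalent circular radius, so `S_norm(r_ref) = 1`. The reference output
#' (cGy/MU at 10 cm depth, 10 x 10 cm field, 100 cm source-point distance)
#' defaults to a nominal clinical value and is replaced during commissioning
#' against the engine.
#'
#' @param energy energy label.
#' @param mu_eff effective attenuation, 1/cm.
#' @param r0 scatter saturation radius, cm.
#' @param ref_output_cgy_per_mu reference output, cGy/MU.
#' @param d_ref reference depth, cm.
#' @param ref_field_cm reference square field side, cm.
#' @return object of class `commissioning_tables`.
#' @export
make_tables <- function(energy = "6X",
                        mu_eff = if (startsWith(energy, "10")) 0.044 else 0.056,
                        r0 = 2.0, ref_output_cgy_per_mu = 85,
                        d_ref = 10, ref_field_cm = 10) {
  energy <- match.arg(energy, supported_energies())
  r_ref <- ref_field_cm * sqrt(1 / pi)  # equivalent circular radius of ref square
  structure(list(energy = energy, mu_eff = mu_eff, r0 = r0,
                 ref_output_cgy_per_mu = ref_output_cgy_per_mu,
                 d_ref = d_ref, ref_field_cm = ref_field_cm, r_ref = r_ref,
                 s_norm = 1 - exp(-r_ref / r0)),
            class = "commissioning_tables")
}

#' Scatter factor for a circular field of radius r (cm)
#' @param tables a [make_tables()] object.
#' @param r_cm radius, cm (vectorized).
#' @param normalized when `TRUE` (default) the factor is scaled to 1 at the
#'   reference field's equivalent circular radius; the raw saturating form
#'   `1 - exp(-r/r0)` runs from 0 at r = 0 to 1 as r grows.
#' @return scatter factor.
#' @export
scatter_factor <- function(tables, r_cm, normalized = TRUE) {
  s <- 1 - exp(-pmax(r_cm, 0) / tables$r0)
  if (normalized) s / tables$s_norm else s
}

#' Tissue-maximum ratio at water-equivalent depth d (cm)
#' @param tables a [make_tables()] object.
#' @param d_cm depth, cm.
#' @param field_cm equivalent square side, cm (unused by the toy model;
#'   kept in the signature for the lookup contract).
#' @return TMR value.
#' @export
tmr_lookup <- function(tables, d_cm, field_cm = tables$ref_field_cm) {
  if (any(d_cm < 0) || any(d_cm > 50))
    stop(sprintf("tmr_lookup: depth %.1f cm outside table range [0, 50]",
                 max(d_cm)))
  exp(-tables$mu_eff * (d_cm - tables$d_ref))
}

#' Write / read commissioning tables as plain text
#' @param tables a `commissioning_tables`.
#' @param path file path.
#' @return `path` / tables.
#' @export
write_tables <- function(tables, path) {
  keys <- c("energy", "mu_eff", "r0", "ref_output_cgy_per_mu", "d_ref",
            "ref_field_cm")
  writeLines(vapply(keys, function(k)
    paste(k, format(tables[[k]], digits = 12), sep = "\t"), character(1)), path)
  invisible(path)
}

#' @rdname write_tables
#' @export
read_tables <- function(path) {
  kv <- do.call(rbind, strsplit(readLines(path), "\t", fixed = TRUE))
  v <- stats::setNames(kv[, 2], kv[, 1])
  make_tables(energy = v[["energy"]], mu_eff = as.numeric(v[["mu_eff"]]),
              r0 = as.numeric(v[["r0"]]),
              ref_output_cgy_per_mu = as.numeric(v[["ref_output_cgy_per_mu"]]),
              d_ref = as.numeric(v[["d_ref"]]),
              ref_field_cm = as.numeric(v[["ref_field_cm"]]))
}

# ---- sector integration -----------------------------------------------------

#' Sector radii from a point to the aperture boundary
#'
#' For each of `n_sectors` equally spaced directions at the projected point,
#' the radius is the distance to the first exit from the aperture's open
#' region (fine radial marching, 0.25 mm). Points outside the open region
#' get radius 0 in every sector.
#'
#' @param ap an [aperture()].
#' @param px,py point projected to the isocenter plane, mm.
#' @param n_sectors number of sectors (default 36).
#' @param r_max_mm maximum search radius, mm.
#' @return radii in cm, length `n_sectors`.
#' @export
sector_radii <- function(ap, px, py, n_sectors = 36, r_max_mm = 250) {
  phi <- (seq_len(n_sectors) - 0.5) * 2 * pi / n_sectors
  if (!aperture_contains(ap, px, py)) return(rep(0, n_sectors))
  if (ap$type == "circle") {
    # analytic: first crossing of the circle (and the blocking half-plane)
    dx <- px - ap$center[1]; dy <- py - ap$center[2]
    return(vapply(phi, function(a) {
      ca <- cos(a); sa <- sin(a)
      b <- dx * ca + dy * sa
      t_circ <- -b + sqrt(max(0, b^2 - (dx^2 + dy^2 - ap$radius^2)))
      t <- t_circ
      if (isTRUE(ap$half_blocked) && ca < 0) {
        t_half <- -dx / ca # crossing of x = center x
        if (t_half >= 0) t <- min(t, t_half)
      }
      t / 10
    }, numeric(1)))
  }
  step <- 0.25
  rs <- seq(step, r_max_mm, by = step)
  vapply(phi, function(a) {
    xs <- px + rs * cos(a); ys <- py + rs * sin(a)
    inside <- aperture_contains(ap, xs, ys)
    first_out <- which(!inside)[1]
    r_mm <- if (is.na(first_out)) r_max_mm
    else if (first_out == 1L) 0            # blocked at the point itself
    else (first_out - 0.5) * step
    r_mm / 10
  }, numeric(1))
}

#' Modified Clarkson point dose for a VMAT plan
#'
#' Per control-point segment: the point is projected to the isocenter plane
#' along the ray from the segment's source position; sector radii against
#' the segment aperture give the mean scatter factor; the effective depth
#' along the source-to-point line enters the TMR; an inverse-square factor
#' references the source-point distance to 100 cm. The segment dose per MU
#' is `RO * TMR(d_eff) * mean(S(r_sector)) * (100 / spd_cm)^2` and the plan
#' dose sums `segment_MU * dose_per_MU` over all segments and arcs.
#'
#' @param plan a [vmat_plan()] (or [arc_beam()]).
#' @param phantom a [voxel_phantom()].
#' @param point calculation point, mm.
#' @param tables [make_tables()] object.
#' @param n_sectors sectors for the Clarkson integration.
#' @return dose, Gy.
#' @export
clarkson_point_dose <- function(plan, phantom, point, tables,
                                n_sectors = 36) {
  beams <- if (inherits(plan, "arc_beam")) list(plan) else plan$beams
  iso <- if (inherits(plan, "vmat_plan")) plan$isocenter else c(0, 0, 0)
  total <- 0
  for (b in beams) {
    segs <- arc_segments(b, iso = iso)
    for (s in segs) {
      if (s$mu <= 0) next
      total <- total + s$mu *
        clarkson_segment_dose_per_mu(s, phantom, point, tables, n_sectors)
    }
  }
  total
}

#' Clarkson dose per MU for a single segment
#' @inheritParams clarkson_point_dose
#' @param segment one element of [arc_segments()] (or a compatible list with
#'   `gantry_deg`, `aperture`, `iso`).
#' @return dose per MU, Gy/MU.
#' @export
clarkson_segment_dose_per_mu <- function(segment, phantom, point, tables,
                                         n_sectors = 36) {
  bb <- beam_basis(segment$gantry_deg, iso = segment$iso)
  spd_mm <- vnorm(point - bb$src)
  # project the point to the isocenter plane along the source ray
  t <- SAD_MM / sum((point - bb$src) * bb$w)
  proj <- bb$src + t * (point - bb$src)
  px <- sum((proj - bb$iso) * bb$xb)
  py <- sum((proj - bb$iso) * bb$yb)
  d_eff <- radiological_depth(phantom, bb$src, point)
  rs <- sector_radii(segment$aperture, px, py, n_sectors)
  sbar <- mean(scatter_factor(tables, rs))
  ro_gy <- tables$ref_output_cgy_per_mu * 0.01
  ro_gy * tmr_lookup(tables, d_eff) * sbar * (1000 / spd_mm)^2
}

#' Commission the reference output against the Monte Carlo engine
#'
#' Replaces the nominal reference output so that the Clarkson calculator
#' reproduces a supplied reference point dose per MU (typically the
#' calibrated engine dose under the reference condition). This mirrors
#' clinical commissioning, where the simple algorithm's tables are tuned to
#' measured reference data.
#'
#' @param tables a `commissioning_tables`.
#' @param segment reference segment (open 10 x 10 field at gantry 0).
#' @param phantom reference phantom (water cube).
#' @param point reference scoring point, mm.
#' @param dose_per_mu_gy measured dose per MU at `point`, Gy/MU.
#' @param n_sectors sectors.
#' @return tables with `ref_output_cgy_per_mu` replaced.
#' @export
commission_reference_output <- function(tables, segment, phantom, point,
                                        dose_per_mu_gy, n_sectors = 36) {
  cur <- clarkson_segment_dose_per_mu(segment, phantom, point, tables,
                                      n_sectors)
  tables$ref_output_cgy_per_mu <- tables$ref_output_cgy_per_mu *
    dose_per_mu_gy / cur
  tables
}

#' Equivalent square side from aperture area
#'
#' Circular-to-square equivalence convention: `side = sqrt(area)` (the
#' equal-area square of the aperture opening), used for TMR field-size
#' lookups.
#'
#' @param ap an [aperture()].
#' @return side, cm.
#' @export
equivalent_square_cm <- function(ap) sqrt(aperture_area(ap)) / 10
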