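# Photon source and collimation: phase-space file handling, a parametric
# source emulator per energy label, ideal-aperture collimation at the
# isocenter plane, and meterset-weight differencing.

SAD_MM <- 1000  # source-axis distance

#' Beam-geometry basis vectors for a gantry angle
#'
#' Gantry rotates in the axial (x-y) patient plane about the isocenter:
#' at 0 degrees the source is anterior (-y side, beam travels towards +y);
#' at 90 degrees the source is at the patient's left (+x). Beam's-eye-view
#' axes: `xb` is the MLC leaf-travel (crossplane, X-jaw) direction, `yb` the
#' leaf-stacking (inplane, Y-jaw) direction = patient superior, `w` the beam
#' direction. No collimator or couch rotation.
#'
#' @param gantry_deg gantry angle, degrees.
#' @param iso isocenter, mm.
#' @param sad source-axis distance, mm.
#' @return list with `src` (source position, mm), unit vectors `xb`, `yb`,
#'   `w`, and `iso`.
#' @export
beam_basis <- function(gantry_deg, iso = c(0, 0, 0), sad = SAD_MM) {
  g <- gantry_deg * pi / 180
  src <- iso + sad * c(sin(g), -cos(g), 0)
  list(src = src,
       xb = c(cos(g), sin(g), 0),
       yb = c(0, 0, 1),
       w = c(-sin(g), cos(g), 0),
       iso = iso)
}

# ---- phase space ------------------------------------------------------------

PHSP_MAGIC <- "MUVPHSP1"

#' Write a phase-space file
#'
#' Fixed-width binary layout: 8-byte magic `"MUVPHSP1"`, little-endian
#' float64 particle count, 8-byte space-padded energy label, float64 source
#' plane z (mm); then one record per particle: 7 little-endian float32
#' (x, y, u, v, w, energy MeV, weight) + 1 byte particle type (0 = photon).
#' `records` may be `NULL` with a nonzero declared `count` ("sparse" mode:
#' header-only files used for count arithmetic without materializing
#' records).
#'
#' @param path output file.
#' @param records data.frame with columns `x`, `y`, `u`, `v`, `w`, `energy`,
#'   `weight`, or `NULL` for sparse mode.
#' @param energy energy label.
#' @param plane_z source plane z, mm.
#' @param count declared count; defaults to `nrow(records)`.
#' @return `path`, invisibly.
#' @export
write_phase_space <- function(path, records, energy, plane_z = -500,
                              count = if (is.null(records)) 0 else nrow(records)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(PHSP_MAGIC), con)
  writeBin(as.numeric(count), con, size = 8, endian = "little")
  lab <- substr(sprintf("%-8s", energy), 1, 8)
  writeBin(charToRaw(lab), con)
  writeBin(as.numeric(plane_z), con, size = 8, endian = "little")
  if (!is.null(records) && nrow(records)) {
    m <- t(as.matrix(records[, c("x", "y", "u", "v", "w", "energy", "weight")]))
    # interleave: per record 7 float32 + 1 type byte
    f <- writeBin(as.numeric(m), raw(), size = 4, endian = "little")
    fm <- matrix(f, nrow = 28)
    typ <- as.raw(rep(0, ncol(fm)))
    writeBin(as.vector(rbind(fm, matrix(typ, nrow = 1))), con)
  }
  invisible(path)
}

#' Read a phase-space file
#'
#' @param path file written by [write_phase_space()] (or the same layout).
#' @param header_only skip record payload.
#' @return object of class `phase_space`: list with `count`, `energy`,
#'   `plane_z`, `records` (data.frame, or `NULL` if header-only/sparse).
#' @export
read_phase_space <- function(path, header_only = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), 8))
  if (!identical(magic, PHSP_MAGIC))
    stop("read_phase_space: bad magic '", magic, "'")
  count <- readBin(con, numeric(), 1, size = 8, endian = "little")
  energy <- trimws(rawToChar(readBin(con, raw(), 8)))
  plane_z <- readBin(con, numeric(), 1, size = 8, endian = "little")
  recs <- NULL
  if (!header_only) {
    body <- raw(0)
    repeat {
      chunk <- readBin(con, raw(), n = 29 * 2^20)
      if (!length(chunk)) break
      body <- c(body, chunk)
    }
    if (length(body)) {
      if (length(body) %% 29 != 0)
        stop("read_phase_space: truncated record payload")
      n <- length(body) %/% 29
      bm <- matrix(body, nrow = 29)
      vals <- readBin(as.vector(bm[1:28, , drop = FALSE]), numeric(),
                      n = 7 * n, size = 4, endian = "little")
      vm <- matrix(vals, nrow = 7)
      recs <- data.frame(x = vm[1, ], y = vm[2, ], u = vm[3, ], v = vm[4, ],
                         w = vm[5, ], energy = vm[6, ], weight = vm[7, ])
      if (n != count)
        stop(sprintf("read_phase_space: declared count %g but %d records read",
                     count, n))
      bad <- abs(recs$u^2 + recs$v^2 + recs$w^2 - 1) > 1e-6 |
        recs$w <= 0 | recs$energy <= 0 | recs$weight <= 0
      if (any(bad))
        stop(sprintf("read_phase_space: %d invalid record(s)", sum(bad)))
    }
  }
  structure(list(count = count, energy = energy, plane_z = plane_z,
                 records = recs, path = path),
            class = "phase_space")
}

#' Concatenate phase-space files
#'
#' All inputs must share the energy label and source plane; records are
#' concatenated in input order and the declared count is the sum of the
#' declared input counts (sparse header-only inputs contribute counts only).
#'
#' @param sets list of `phase_space` objects.
#' @return a merged `phase_space` object (not written to disk).
#' @export
concatenate_phase_space <- function(sets) {
  stopifnot(length(sets) >= 1L)
  e0 <- sets[[1]]$energy; z0 <- sets[[1]]$plane_z
  for (s in sets) {
    if (!identical(s$energy, e0) || abs(s$plane_z - z0) > 1e-9)
      stop(sprintf("concatenate_phase_space: mismatched energy/plane (%s@%g vs %s@%g)",
                   s$energy, s$plane_z, e0, z0))
  }
  recs <- do.call(rbind, Filter(Negate(is.null), lapply(sets, `[[`, "records")))
  structure(list(count = sum(vapply(sets, `[[`, numeric(1), "count")),
                 energy = e0, plane_z = z0, records = recs, path = NA),
            class = "phase_space")
}

# ---- parametric source ------------------------------------------------------

#' Toy photon spectrum for an energy label
#'
#' Packaged two-parameter histogram spectra: flattened beams peak near a
#' third of the nominal accelerating potential; FFF beams are softer (more
#' low-energy fluence) because the flattening filter is absent. These are
#' shape stand-ins for commissioning data, adequate for contract and
#' statistics tests; absolute dose scale is absorbed by the calibration
#' factor.
#'
#' @param energy energy label.
#' @return data.frame with `energy` (MeV, ascending) and `prob` (sums to 1).
#' @export
toy_spectrum <- function(energy = supported_energies()) {
  energy <- match.arg(energy)
  emax <- if (startsWith(energy, "6")) 6 else 10
  soft <- endsWith(energy, "FFF")
  e <- seq(0.25, emax, by = 0.25)
  # gamma-like fluence shape; FFF softer
  shape <- if (soft) 1.6 else 2.4
  p <- e^(shape - 1) * exp(-e / (emax / 6))
  data.frame(energy = e, prob = p / sum(p))
}

#' Parametric or phase-space-backed beam source
#'
#' @param energy energy label.
#' @param spectrum data.frame `energy`/`prob` (parametric mode); defaults to
#'   [toy_spectrum()].
#' @param phase_space optional `phase_space` object; when given, sampling
#'   draws cyclically from its records (phase-space mode).
#' @param plane_z source plane z relative to isocenter along the beam axis,
#'   mm (negative = upstream).
#' @return object of class `beam_source`.
#' @export
beam_source <- function(energy, spectrum = NULL, phase_space = NULL,
                        plane_z = -500) {
  energy <- match.arg(energy, supported_energies())
  mode <- if (is.null(phase_space)) "parametric" else "phase_space"
  if (is.null(spectrum)) spectrum <- toy_spectrum(energy)
  if (abs(sum(spectrum$prob) - 1) > 1e-9)
    stop("beam_source: spectrum probabilities must sum to 1")
  if (is.unsorted(spectrum$energy, strictly = TRUE))
    stop("beam_source: spectrum energies must be ascending")
  structure(list(energy = energy, spectrum = spectrum,
                 phase_space = phase_space, plane_z = plane_z, mode = mode,
                 draws = 0L),
            class = "beam_source")
}

#' Sample particles from a beam source
#'
#' Parametric mode: energies drawn from the spectrum; each ray aims from the
#' focal point at the source plane towards a uniformly sampled point inside
#' `field_mm` on the isocenter plane (divergent fan; the angular spread is
#' set by the field size over the SAD). Phase-space mode: records are
#' consumed cyclically; on exhaustion the read position restarts with a
#' seeded reshuffle and the number of reuse passes is recorded (latent
#' variance reporting).
#'
#' @param source a [beam_source()].
#' @param n number of particles.
#' @param field_mm `c(x1,x2,y1,y2)` sampling rectangle at the isocenter
#'   plane, mm (parametric mode).
#' @param rng_seed integer seed for the package's own stream (does not touch
#'   R's global RNG).
#' @return data.frame of phase-space records (beam frame: x,y at the source
#'   plane, direction cosines u,v,w with w > 0 towards the patient) with
#'   attribute `reuse_passes` in phase-space mode.
#' @export
sample_source <- function(source, n, field_mm = c(-50, 50, -50, 50),
                          rng_seed = 1L) {
  stopifnot(inherits(source, "beam_source"), n >= 1)
  if (source$mode == "phase_space") {
    recs <- source$phase_space$records
    if (is.null(recs) || !nrow(recs))
      stop("sample_source: empty phase-space source")
    m <- nrow(recs)
    idx <- integer(0); passes <- 0L
    take <- n
    while (take > 0) {
      ord <- if (passes == 0L) seq_len(m)
      else order(muv_runif(rng_seed + passes, m))
      k <- min(take, m)
      idx <- c(idx, ord[seq_len(k)])
      take <- take - k
      if (take > 0) passes <- passes + 1L
    }
    out <- recs[idx, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "reuse_passes") <- passes
    return(out)
  }
  u <- matrix(muv_runif(rng_seed, 3L * n), ncol = 3)
  cdf <- cumsum(source$spectrum$prob)
  e <- source$spectrum$energy[findInterval(u[, 1], c(0, cdf),
                                           rightmost.closed = TRUE)]
  ax <- field_mm[1] + u[, 2] * (field_mm[2] - field_mm[1])
  ay <- field_mm[3] + u[, 3] * (field_mm[4] - field_mm[3])
  # focal point on the axis at the source plane; aim point on iso plane
  dz <- -source$plane_z   # distance from source plane to iso plane, mm
  d <- cbind(ax, ay, dz)
  len <- sqrt(rowSums(d^2))
  data.frame(x = 0, y = 0,
             u = d[, 1] / len, v = d[, 2] / len, w = d[, 3] / len,
             energy = e, weight = 1)
}

# ---- aperture ---------------------------------------------------------------

#' Beam aperture at the isocenter plane
#'
#' Ideal 2-D aperture: jaw rectangle intersected with the union of per-leaf-
#' pair open intervals; rays hitting blocked area keep a configurable global
#' transmission fraction (default 0 = absorbed).
#'
#' @param jaws `c(x1,x2,y1,y2)`, mm at isocenter.
#' @param leaf_edges leaf-pair boundaries along y, mm, ascending, length
#'   `n_pairs + 1`.
#' @param leaf_a,leaf_b per-pair leaf-tip positions (bank A <= bank B), mm.
#' @param transmission fraction in `[0, 1)` for blocked rays.
#' @return object of class `aperture`.
#' @export
aperture <- function(jaws, leaf_edges, leaf_a, leaf_b, transmission = 0) {
  jaws <- as.numeric(jaws)
  if (transmission < 0 || transmission >= 1)
    stop("aperture: transmission must lie in [0, 1)")
  if (any(leaf_a > leaf_b + 1e-9)) stop("aperture: crossed leaves")
  structure(list(type = "mlc", jaws = jaws,
                 leaf_edges = as.numeric(leaf_edges),
                 leaf_a = as.numeric(leaf_a), leaf_b = as.numeric(leaf_b),
                 transmission = transmission),
            class = "aperture")
}

#' Circular test aperture
#' @param center `c(x, y)` mm at isocenter.
#' @param radius mm.
#' @param transmission blocked-ray transmission.
#' @param half_blocked when `TRUE`, the half-plane `x < center[1]` is
#'   blocked (half-beam fixture for sector-integration limits).
#' @return an `aperture` of type `"circle"`.
#' @export
circular_aperture <- function(center, radius, transmission = 0,
                              half_blocked = FALSE) {
  structure(list(type = "circle", center = as.numeric(center),
                 radius = radius, transmission = transmission,
                 half_blocked = half_blocked),
            class = "aperture")
}

#' Is a point inside the open part of an aperture?
#' @param ap an [aperture()].
#' @param x,y coordinates at the isocenter plane, mm (vectorized).
#' @return logical vector.
#' @export
aperture_contains <- function(ap, x, y) {
  if (ap$type == "circle") {
    inside <- (x - ap$center[1])^2 + (y - ap$center[2])^2 <= ap$radius^2
    if (isTRUE(ap$half_blocked)) inside <- inside & x >= ap$center[1]
    return(inside)
  }
  inside_jaw <- x >= ap$jaws[1] & x <= ap$jaws[2] &
    y >= ap$jaws[3] & y <= ap$jaws[4]
  np <- length(ap$leaf_a)
  pair <- findInterval(y, ap$leaf_edges, rightmost.closed = TRUE)
  ok <- inside_jaw & pair >= 1 & pair <= np
  pair_cl <- pmin(pmax(pair, 1L), np)
  open <- x >= ap$leaf_a[pair_cl] & x <= ap$leaf_b[pair_cl]
  ok & open
}

#' Open area of an aperture, mm^2
#' @param ap an [aperture()].
#' @return area, mm^2.
#' @export
aperture_area <- function(ap) {
  if (ap$type == "circle") return(pi * ap$radius^2)
  np <- length(ap$leaf_a)
  tot <- 0
  for (i in seq_len(np)) {
    h <- min(ap$leaf_edges[i + 1], ap$jaws[4]) - max(ap$leaf_edges[i], ap$jaws[3])
    w <- min(ap$leaf_b[i], ap$jaws[2]) - max(ap$leaf_a[i], ap$jaws[1])
    if (h > 0 && w > 0) tot <- tot + h * w
  }
  tot
}

#' Collimate phase-space records through an aperture
#'
#' Each ray is projected from the source plane to the isocenter plane along
#' its direction; rays inside the open region pass unchanged, blocked rays
#' have their weight multiplied by the aperture transmission (weight 0 means
#' absorbed). Weights never increase.
#'
#' @param records data.frame from [sample_source()].
#' @param ap an [aperture()].
#' @param plane_z source plane z relative to the isocenter plane, mm.
#' @return records with updated `weight` (absorbed rows kept, weight 0).
#' @export
collimate <- function(records, ap, plane_z = -500) {
  dz <- -plane_z
  t <- dz / records$w
  px <- records$x + t * records$u
  py <- records$y + t * records$v
  open <- aperture_contains(ap, px, py)
  records$weight <- records$weight * ifelse(open, 1, ap$transmission)
  records
}

# ---- meterset differencing and segments ------------------------------------

#' Per-segment monitor units for a plan
#'
#' Segment k spans control points k..k+1 and carries
#' `beam_mu * (cum_weight[k+1] - cum_weight[k])`; per-arc segment MUs sum to
#' the arc MU exactly (compensated summation not needed: the telescoping sum
#' is exact).
#'
#' @param plan a [vmat_plan()] or single [arc_beam()].
#' @return list (one per arc) of numeric segment-MU vectors.
#' @export
differential_mu <- function(plan) {
  beams <- if (inherits(plan, "arc_beam")) list(plan) else plan$beams
  lapply(beams, function(b) {
    w <- vapply(b$control_points, `[[`, numeric(1), "cum_weight")
    dw <- diff(w)
    if (any(dw < -1e-12))
      stop("differential_mu: decreasing cumulative meterset weight")
    dw[dw < 0] <- 0
    b$beam_mu * dw
  })
}

#' Decompose an arc into transport segments
#'
#' Each segment uses the midpoint convention: gantry angle is the circular
#' mean and jaw/leaf positions the linear mean of its two bounding control
#' points.
#'
#' @param beam an [arc_beam()].
#' @param iso isocenter, mm.
#' @param transmission MLC transmission for blocked rays.
#' @return list of segments: `gantry_deg`, [aperture()], `mu`, `mu_frac`.
#' @export
arc_segments <- function(beam, iso = c(0, 0, 0), transmission = 0) {
  cps <- beam$control_points
  mus <- differential_mu(beam)[[1]]
  total <- sum(mus)
  lapply(seq_len(length(cps) - 1L), function(k) {
    a <- cps[[k]]; b <- cps[[k + 1]]
    # circular mean of the two gantry angles
    ga <- a$gantry_deg * pi / 180; gb <- b$gantry_deg * pi / 180
    gm <- atan2(mean(sin(c(ga, gb))), mean(cos(c(ga, gb)))) * 180 / pi
    ap <- aperture(jaws = (a$jaws + b$jaws) / 2,
                   leaf_edges = beam$leaf_edges,
                   leaf_a = (a$mlc_a + b$mlc_a) / 2,
                   leaf_b = (a$mlc_b + b$mlc_b) / 2,
                   transmission = transmission)
    gm <- gm %% 360
    if (gm > 360 - 1e-9) gm <- 0
    list(gantry_deg = gm, aperture = ap, mu = mus[k],
         mu_frac = if (total > 0) mus[k] / total else 0,
         iso = iso)
  })
}
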