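# Job orchestration around the C++ engine: history allocation, job
# splitting, partial-dose merging, uncertainty estimation and the
# EGSnrc-convention pardose/3ddose interchange files.

#' Deterministic package-internal uniform stream
#'
#' Seeded independently of R's global RNG (splitmix64 keyed by the seed), so
#' sampling inside the pipeline never perturbs user code.
#'
#' @param seed integer-valued seed.
#' @param n number of deviates.
#' @return numeric vector in (0, 1).
#' @export
muv_runif <- function(seed, n) muv_runif_cpp(as.numeric(seed), as.integer(n))

#' Simulation scene: phantom + per-segment geometry + source spectrum
#'
#' Bundles everything a transport job needs. Histories are allocated to
#' segments proportionally to differential MU by largest remainder, over the
#' run's *total* history count, so that any partition of the history range
#' into jobs reproduces the identical per-history streams.
#'
#' @param phantom a [voxel_phantom()].
#' @param segments list from [arc_segments()], or a single-segment list for
#'   static fields.
#' @param source a [beam_source()].
#' @return object of class `mc_scene`.
#' @export
mc_scene <- function(phantom, segments, source) {
  stopifnot(inherits(phantom, "voxel_phantom"), length(segments) >= 1L,
            inherits(source, "beam_source"))
  structure(list(phantom = phantom, segments = segments, source = source),
            class = "mc_scene")
}

# largest-remainder integer allocation of n over weights w (sums to n)
largest_remainder <- function(n, w) {
  if (sum(w) <= 0) return(rep(0, length(w)))
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Transport job specification
#'
#' A job covers the contiguous global history index range
#' `[offset, offset + histories)` of a run with `total` histories and a
#' shared `base_seed`; `seed` (= base_seed + job index) identifies the job.
#'
#' @param histories histories this job simulates (> 0).
#' @param base_seed run-level seed shared by all jobs of the run.
#' @param offset first global history index (0-based).
#' @param total total histories of the parent run.
#' @param seed job identifier seed (uniqueness is enforced at merge).
#' @return object of class `job_spec`.
#' @export
job_spec <- function(histories, base_seed, offset = 0, total = histories,
                     seed = base_seed) {
  stopifnot(histories > 0, total >= histories, offset >= 0,
            offset + histories <= total)
  structure(list(histories = histories, base_seed = base_seed,
                 offset = offset, total = total, seed = seed),
            class = "job_spec")
}

#' Split a run into parallelizable jobs
#'
#' Per-job history counts differ by at most one and sum to the total; job k
#' receives seed `base_seed + k - 1` and the k-th contiguous slice of the
#' global history range. Because the engine keys its random stream on
#' (base_seed, global history index), merging the partial doses of any split
#' reproduces the unsplit run exactly.
#'
#' @param total_histories total histories (>= n_jobs).
#' @param n_jobs number of jobs.
#' @param base_seed run seed.
#' @return list of [job_spec()]s.
#' @export
split_job <- function(total_histories, n_jobs, base_seed = 1) {
  if (n_jobs < 1 || n_jobs > total_histories)
    stop("split_job: need 1 <= n_jobs <= total_histories")
  base <- total_histories %/% n_jobs
  extra <- total_histories %% n_jobs
  counts <- rep(base, n_jobs) + c(rep(1, extra), rep(0, n_jobs - extra))
  offs <- cumsum(c(0, counts[-n_jobs]))
  lapply(seq_len(n_jobs), function(k)
    job_spec(counts[k], base_seed, offset = offs[k], total = total_histories,
             seed = base_seed + k - 1))
}

# engine segment descriptors with global history ranges
scene_engine_segments <- function(scene, total_histories) {
  segs <- scene$segments
  w <- vapply(segs, function(s) s$mu_frac, numeric(1))
  if (sum(w) <= 0) w <- rep(1, length(segs)) # static field: uniform
  counts <- largest_remainder(total_histories, w)
  bounds <- cumsum(c(0, counts))
  lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    bb <- beam_basis(s$gantry_deg, iso = s$iso)
    ap <- s$aperture
    list(src = bb$src, xb = bb$xb, yb = bb$yb, iso = bb$iso,
         rect = ap$jaws, leaf_edges = ap$leaf_edges,
         leaf_a = ap$leaf_a, leaf_b = ap$leaf_b,
         transmission = ap$transmission,
         h_lo = bounds[i], h_hi = bounds[i + 1])
  })
}

#' Run one transport job
#'
#' Deterministic given the job spec: running the same spec twice yields
#' bitwise-identical partial doses.
#'
#' @param scene an [mc_scene()].
#' @param spec a [job_spec()].
#' @param attenuation_only logical; primaries terminate at their first real
#'   interaction and no dose is scored (narrow-beam transmission mode, used
#'   by the closed-form oracle).
#' @return object of class `partial_dose`: per-voxel dose sum and
#'   sum-of-squares (Gy/particle basis), history count, geometry, and the
#'   engine's energy/transmission bookkeeping.
#' @export
run_job <- function(scene, spec, attenuation_only = FALSE) {
  stopifnot(inherits(scene, "mc_scene"), inherits(spec, "job_spec"))
  ph <- scene$phantom
  spect <- scene$source$spectrum
  esegs <- scene_engine_segments(scene, spec$total)
  res <- mc_run_cpp(
    mat = as.integer(ph$material), dens = as.numeric(ph$density),
    dims = ph$grid$dims, origin = ph$grid$origin, spacing = ph$grid$spacing,
    xs_list = xs_engine_pack(),
    seg_list = esegs,
    spec_e = spect$energy, spec_cdf = cumsum(spect$prob),
    base_seed = spec$base_seed, hist_offset = spec$offset,
    n_hist = spec$histories, attenuation_only = attenuation_only)
  structure(list(
    sum = array(res$sum, dim = ph$grid$dims),
    sumsq = array(res$sumsq, dim = ph$grid$dims),
    histories = res$histories, grid = ph$grid, seed = spec$seed,
    n_entered = res$n_entered,
    n_transmitted_primary = res$n_transmitted_primary,
    energy_launched_mev = res$energy_launched_mev,
    energy_deposited_mev = res$energy_deposited_mev),
    class = "partial_dose")
}

#' Merge partial doses into a dose result
#'
#' Weighted by histories (dose = sum of per-history deposits over total
#' histories), not by file count; geometries must match and job seeds must
#' be distinct.
#'
#' @param parts list of `partial_dose` objects.
#' @return object of class `dose_result`: `dose` (Gy/particle),
#'   `rel_uncertainty` (NA where no dose was scored), `histories`, `grid`.
#' @export
merge_partials <- function(parts) {
  stopifnot(length(parts) >= 1L)
  g <- parts[[1]]$grid
  for (p in parts[-1])
    if (!grids_equal(g, p$grid))
      stop("merge_partials: geometry mismatch between partial doses")
  seeds <- vapply(parts, `[[`, numeric(1), "seed")
  if (anyDuplicated(seeds))
    stop("merge_partials: duplicate job seeds")
  s <- Reduce(`+`, lapply(parts, `[[`, "sum"))
  s2 <- Reduce(`+`, lapply(parts, `[[`, "sumsq"))
  n <- sum(vapply(parts, `[[`, numeric(1), "histories"))
  merged <- structure(list(sum = s, sumsq = s2, histories = n, grid = g,
                           seed = seeds[1]),
                      class = "partial_dose")
  structure(list(dose = s / n,
                 rel_uncertainty = estimate_uncertainty(merged),
                 histories = n, grid = g),
            class = "dose_result")
}

#' History-by-history relative uncertainty
#'
#' `sigma_rel = sqrt((<d^2> - <d>^2) / (N - 1)) / <d>` per voxel, from the
#' accumulated sum and sum-of-squares of per-history deposits. Voxels never
#' hit are flagged `NA` (undefined), not zero.
#'
#' @param part a `partial_dose` (or merged accumulator).
#' @return array of relative standard errors; NA where mean dose is 0.
#' @export
estimate_uncertainty <- function(part) {
  n <- part$histories
  if (n < 2) stop("estimate_uncertainty: need >= 2 histories")
  m <- part$sum / n
  v <- (part$sumsq / n - m^2) / (n - 1)
  v[v < 0] <- 0
  out <- sqrt(v) / m
  out[part$sum <= 0] <- NA_real_
  out
}

#' Simulate a scene with job-level parallel structure (serial execution)
#'
#' @param scene an [mc_scene()].
#' @param histories total histories.
#' @param n_jobs number of jobs to split into.
#' @param base_seed run seed.
#' @return a `dose_result` (merged over jobs).
#' @export
simulate_scene <- function(scene, histories, n_jobs = 1, base_seed = 1) {
  specs <- split_job(histories, n_jobs, base_seed)
  merge_partials(lapply(specs, function(sp) run_job(scene, sp)))
}

# ---- pardose / 3ddose interchange -------------------------------------------

#' Write a partial dose (pardose) binary file
#'
#' Layout: magic `"MUVPARD1"`, little-endian float64 geometry hash, dims
#' (3 x int32), origin + spacing (6 x float64), histories (float64), then
#' the per-voxel dose-sum and sum-of-squares arrays as float64.
#'
#' @param part a `partial_dose`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pardose <- function(part, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MUVPARD1"), con)
  g <- part$grid
  writeBin(geometry_hash(g), con, size = 8, endian = "little")
  writeBin(as.integer(g$dims), con, size = 4, endian = "little")
  writeBin(as.numeric(c(g$origin, g$spacing)), con, size = 8, endian = "little")
  writeBin(as.numeric(c(part$histories, part$seed)), con, size = 8,
           endian = "little")
  writeBin(as.numeric(part$sum), con, size = 8, endian = "little")
  writeBin(as.numeric(part$sumsq), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a pardose file
#' @param path file written by [write_pardose()].
#' @return a `partial_dose`.
#' @export
read_pardose <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), 8))
  if (!identical(magic, "MUVPARD1")) stop("read_pardose: bad magic")
  hash <- readBin(con, numeric(), 1, size = 8, endian = "little")
  dims <- readBin(con, integer(), 3, size = 4, endian = "little")
  geo <- readBin(con, numeric(), 6, size = 8, endian = "little")
  hs <- readBin(con, numeric(), 2, size = 8, endian = "little")
  g <- grid3d(geo[1:3], geo[4:6], dims)
  if (abs(hash - geometry_hash(g)) > 1e-6)
    stop("read_pardose: geometry hash mismatch")
  nv <- prod(dims)
  s <- array(readBin(con, numeric(), nv, size = 8, endian = "little"), dims)
  s2 <- array(readBin(con, numeric(), nv, size = 8, endian = "little"), dims)
  structure(list(sum = s, sumsq = s2, histories = hs[1], grid = g,
                 seed = hs[2]),
            class = "partial_dose")
}

geometry_hash <- function(g) {
  sum(c(g$dims, g$origin, g$spacing) * (1:9)) # cheap order-sensitive digest
}

#' Write a dose result in the EGSnrc 3ddose text convention
#'
#' Line 1: nx ny nz; then the x, y and z voxel-boundary lists (n+1 values
#' each, cm); then the nx*ny*nz dose values (x fastest); then the relative
#' errors (0 where undefined).
#'
#' @param result a `dose_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_3ddose <- function(result, path) {
  g <- result$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(g$dims, collapse = " "), con)
  for (ax in 1:3) {
    b <- (g$origin[ax] - g$spacing[ax] / 2 + (0:g$dims[ax]) * g$spacing[ax]) / 10
    writeLines(paste(format(b, digits = 8, trim = TRUE), collapse = " "), con)
  }
  writeLines(paste(format(as.numeric(result$dose), digits = 8, trim = TRUE),
                   collapse = " "), con)
  err <- result$rel_uncertainty
  err[is.na(err)] <- 0
  writeLines(paste(format(as.numeric(err), digits = 6, trim = TRUE),
                   collapse = " "), con)
  invisible(path)
}

#' Read a 3ddose text file
#' @param path file in the layout of [write_3ddose()].
#' @return a `dose_result` (histories unknown, set to NA).
#' @export
read_3ddose <- function(path) {
  tok <- scan(path, what = numeric(), quiet = TRUE)
  dims <- as.integer(tok[1:3]); i <- 4
  bnds <- list()
  for (ax in 1:3) { bnds[[ax]] <- tok[i:(i + dims[ax])]; i <- i + dims[ax] + 1 }
  nv <- prod(dims)
  dose <- array(tok[i:(i + nv - 1)], dims); i <- i + nv
  err <- array(tok[i:(i + nv - 1)], dims)
  spacing <- vapply(bnds, function(b) mean(diff(b)) * 10, numeric(1))
  origin <- c(bnds[[1]][1] * 10 + spacing[1] / 2,
              bnds[[2]][1] * 10 + spacing[2] / 2,
              bnds[[3]][1] * 10 + spacing[3] / 2)
  err[err == 0 & dose == 0] <- NA_real_
  structure(list(dose = dose, rel_uncertainty = err, histories = NA_real_,
                 grid = grid3d(origin, spacing, dims)),
            class = "dose_result")
}
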