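# Readers and writers for the four DICOM-RT objects the workflow touches.
# Geometry convention: patient coordinates in mm, identity orientation,
# voxel values at voxel centers, 0-based voxel (0,0,0) center at the image
# position of the first slice. Gantry angles are stored as in the plan
# (degrees, vendor convention) wrapped to [0, 360).

default_patient_module <- function() {
  list(dcm_el("SpecificCharacterSet", "ISO_IR 100"),
       dcm_el("PatientName", "PHANTOM^MUV"),
       dcm_el("PatientID", "MUV000"),
       dcm_el("PatientBirthDate", ""),
       dcm_el("PatientSex", "O"),
       dcm_el("StudyDate", "20240101"),
       dcm_el("StudyTime", "120000"),
       dcm_el("AccessionNumber", ""),
       dcm_el("ReferringPhysicianName", ""),
       dcm_el("Manufacturer", "muvr"),
       dcm_el("StudyID", "1"))
}

# ---- CT ---------------------------------------------------------------------

#' Write a CT volume as a DICOM series (one file per slice)
#'
#' HU are stored as signed 16-bit with rescale slope 1 / intercept -1024.
#'
#' @param ct a [ct_volume()].
#' @param dir output directory (created if needed).
#' @param seed UID seed (fixture determinism).
#' @return character vector of file paths, invisibly.
#' @export
write_ct_series <- function(ct, dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- ct$grid
  study_uid <- muv_uid(seed, 1); series_uid <- muv_uid(seed, 2)
  for_uid <- muv_uid(seed, 3)
  stored <- ct$hu + 1024
  if (any(stored < -32768 | stored > 32767))
    stop("write_ct_series: HU out of representable range")
  paths <- character(g$dims[3])
  for (k in seq_len(g$dims[3])) {
    z <- grid_axis(g, 3)[k]
    px <- writeBin(as.integer(as.vector(stored[, , k])), raw(), size = 2,
                   endian = "little")
    ds <- c(default_patient_module(), list(
      dcm_el("SOPClassUID", UID_SOP_CT),
      dcm_el("SOPInstanceUID", muv_uid(seed, 100 + k)),
      dcm_el("Modality", "CT"),
      dcm_el("StudyInstanceUID", study_uid),
      dcm_el("SeriesInstanceUID", series_uid),
      dcm_el("FrameOfReferenceUID", for_uid),
      dcm_el("SeriesNumber", 1),
      dcm_el("InstanceNumber", k),
      dcm_el("ImagePositionPatient", c(g$origin[1], g$origin[2], z)),
      dcm_el("ImageOrientationPatient", c(1, 0, 0, 0, 1, 0)),
      dcm_el("SliceThickness", g$spacing[3]),
      dcm_el("PixelSpacing", c(g$spacing[2], g$spacing[1])), # row, column
      dcm_el("SamplesPerPixel", 1L),
      dcm_el("PhotometricInterpretation", "MONOCHROME2"),
      dcm_el("Rows", g$dims[2]),
      dcm_el("Columns", g$dims[1]),
      dcm_el("BitsAllocated", 16L),
      dcm_el("BitsStored", 16L),
      dcm_el("HighBit", 15L),
      dcm_el("PixelRepresentation", 1L),
      dcm_el("RescaleIntercept", -1024),
      dcm_el("RescaleSlope", 1),
      dcm_el("PixelData", px)))
    paths[k] <- file.path(dir, sprintf("CT.%03d.dcm", k))
    write_dicom(ds, paths[k])
  }
  invisible(paths)
}

#' Read a DICOM CT series
#'
#' Slices are sorted by position along the slice axis; the rescale
#' slope/intercept is applied so returned values are HU. Mixed series and
#' non-uniform slice spacing (missing slices) are rejected.
#'
#' @param dir directory containing the slice files of one series.
#' @return a [ct_volume()].
#' @export
read_ct_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("read_ct_series: no .dcm files in ", dir)
  slices <- lapply(files, read_dicom)
  series <- vapply(slices, function(s)
    dcm_require(s, "SeriesInstanceUID", "CT slice"), character(1))
  if (length(unique(series)) != 1L)
    stop("read_ct_series: mixed series in directory (",
         paste(unique(series), collapse = ", "), ")")
  ipp <- t(vapply(slices, function(s)
    dcm_require(s, "ImagePositionPatient", "CT slice"), numeric(3)))
  ord <- order(ipp[, 3])
  slices <- slices[ord]; ipp <- ipp[ord, , drop = FALSE]
  zs <- ipp[, 3]
  if (length(zs) > 1) {
    dz <- diff(zs)
    if (any(dz <= 0)) stop("read_ct_series: duplicate or non-monotone slice positions")
    if (max(dz) - min(dz) > 1e-3 * stats::median(dz) + 1e-6) {
      gap <- which.max(dz)
      stop(sprintf(
        "read_ct_series: non-uniform slice spacing; gap of %.3f mm between z = %.3f and z = %.3f (expected %.3f mm)",
        max(dz), zs[gap], zs[gap + 1], stats::median(dz)))
    }
  }
  s1 <- slices[[1]]
  nx <- dcm_require(s1, "Columns", "CT slice")
  ny <- dcm_require(s1, "Rows", "CT slice")
  psp <- dcm_require(s1, "PixelSpacing", "CT slice") # (row, col) = (dy, dx)
  dz <- if (length(zs) > 1) stats::median(diff(zs)) else
    dcm_get(s1, "SliceThickness") %||% 1
  hu <- array(0, dim = c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    slope <- dcm_get(s, "RescaleSlope") %||% 1
    inter <- dcm_get(s, "RescaleIntercept") %||% 0
    px <- dcm_require(s, "PixelData", "CT slice")
    v <- readBin(px, integer(), nx * ny, size = 2, signed = TRUE,
                 endian = "little")
    hu[, , k] <- v * slope + inter
  }
  ct_volume(hu, origin = c(ipp[1, 1], ipp[1, 2], zs[1]),
            spacing = c(psp[2], psp[1], dz))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- RT Dose ----------------------------------------------------------------

#' Write an RT Dose file
#'
#' Dose is encoded as unsigned 16-bit scaled integers with the scale stored
#' in DoseGridScaling; the round trip is exact to within one quantization
#' step (`scaling`).
#'
#' @param dose 3-D array, Gy, finite and non-negative.
#' @param grid the [grid3d()] of the dose array.
#' @param path output file.
#' @param plan_sop_uid SOP Instance UID of the plan this dose belongs to
#'   (referenced; optional).
#' @param seed UID seed.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(dose, grid, path, plan_sop_uid = NULL, seed = 1) {
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("write_rtdose: dose must be finite and non-negative")
  mx <- max(dose)
  scaling <- if (mx > 0) mx / 65535 else 1
  stored <- as.integer(round(dose / scaling))
  if (any(stored > 65535))
    stop("write_rtdose: dose exceeds representable range after scaling")
  g <- grid
  px <- writeBin(stored, raw(), size = 2, endian = "little")
  ds <- c(default_patient_module(), list(
    dcm_el("SOPClassUID", UID_SOP_RTDOSE),
    dcm_el("SOPInstanceUID", muv_uid(seed, 20001)),
    dcm_el("Modality", "RTDOSE"),
    dcm_el("StudyInstanceUID", muv_uid(seed, 1)),
    dcm_el("SeriesInstanceUID", muv_uid(seed, 21)),
    dcm_el("FrameOfReferenceUID", muv_uid(seed, 3)),
    dcm_el("SeriesNumber", 2),
    dcm_el("ImagePositionPatient", g$origin),
    dcm_el("ImageOrientationPatient", c(1, 0, 0, 0, 1, 0)),
    dcm_el("PixelSpacing", c(g$spacing[2], g$spacing[1])),
    dcm_el("NumberOfFrames", g$dims[3]),
    dcm_el("GridFrameOffsetVector", (seq_len(g$dims[3]) - 1) * g$spacing[3]),
    dcm_el("SamplesPerPixel", 1L),
    dcm_el("PhotometricInterpretation", "MONOCHROME2"),
    dcm_el("Rows", g$dims[2]),
    dcm_el("Columns", g$dims[1]),
    dcm_el("BitsAllocated", 16L),
    dcm_el("BitsStored", 16L),
    dcm_el("HighBit", 15L),
    dcm_el("PixelRepresentation", 0L),
    dcm_el("DoseUnits", "GY"),
    dcm_el("DoseType", "PHYSICAL"),
    dcm_el("DoseSummationType", "PLAN"),
    dcm_el("DoseGridScaling", scaling),
    dcm_el("PixelData", px)))
  if (!is.null(plan_sop_uid))
    ds <- c(ds, list(dcm_el("ReferencedRTPlanSequence", list(list(
      dcm_el("ReferencedSOPClassUID", UID_SOP_RTPLAN),
      dcm_el("ReferencedSOPInstanceUID", plan_sop_uid))))))
  write_dicom(ds, path)
  invisible(path)
}

#' Read an RT Dose file
#' @param path file path.
#' @return a [tps_dose()].
#' @export
read_rtdose <- function(path) {
  ds <- read_dicom(path)
  nx <- dcm_require(ds, "Columns", "RT Dose")
  ny <- dcm_require(ds, "Rows", "RT Dose")
  nz <- dcm_require(ds, "NumberOfFrames", "RT Dose")
  psp <- dcm_require(ds, "PixelSpacing", "RT Dose")
  ipp <- dcm_require(ds, "ImagePositionPatient", "RT Dose")
  gfo <- dcm_require(ds, "GridFrameOffsetVector", "RT Dose")
  scaling <- dcm_require(ds, "DoseGridScaling", "RT Dose")
  px <- dcm_require(ds, "PixelData", "RT Dose")
  v <- readBin(px, integer(), nx * ny * nz, size = 2, signed = FALSE,
               endian = "little")
  dz <- if (nz > 1) stats::median(diff(gfo)) else 1
  tps_dose(array(v * scaling, dim = c(nx, ny, nz)),
           origin = ipp, spacing = c(psp[2], psp[1], dz))
}

# ---- RT Plan ----------------------------------------------------------------

energy_to_tags <- function(energy) {
  list(nominal = if (startsWith(energy, "6")) 6 else 10,
       fff = endsWith(energy, "FFF"))
}

#' Write a VMAT plan as an RT Plan file
#'
#' @param plan a [vmat_plan()].
#' @param path output file.
#' @param seed UID seed.
#' @return `path`, invisibly; attribute `sop_uid` carries the instance UID.
#' @export
write_rtplan <- function(plan, path, seed = 1) {
  beams <- list()
  frx_beams <- list()
  for (bi in seq_along(plan$beams)) {
    b <- plan$beams[[bi]]
    en <- energy_to_tags(b$energy)
    cps <- list()
    for (ci in seq_along(b$control_points)) {
      cp <- b$control_points[[ci]]
      bld <- list(
        list(dcm_el("RTBeamLimitingDeviceType", "ASYMX"),
             dcm_el("LeafJawPositions", cp$jaws[c("x1", "x2")])),
        list(dcm_el("RTBeamLimitingDeviceType", "ASYMY"),
             dcm_el("LeafJawPositions", cp$jaws[c("y1", "y2")])),
        list(dcm_el("RTBeamLimitingDeviceType", "MLCX"),
             dcm_el("LeafJawPositions", c(cp$mlc_a, cp$mlc_b))))
      item <- list(
        dcm_el("ControlPointIndex", ci - 1L),
        dcm_el("GantryAngle", cp$gantry_deg),
        dcm_el("GantryRotationDirection", if (b$is_arc) "CW" else "NONE"),
        dcm_el("CumulativeMetersetWeight", cp$cum_weight),
        dcm_el("BeamLimitingDevicePositionSequence", bld))
      if (ci == 1L) {
        item <- c(item, list(
          dcm_el("NominalBeamEnergy", en$nominal),
          dcm_el("BeamLimitingDeviceAngle", 0),
          dcm_el("PatientSupportAngle", 0),
          dcm_el("IsocenterPosition", plan$isocenter)))
      }
      cps[[ci]] <- item
    }
    npairs <- length(b$control_points[[1]]$mlc_a)
    beams[[bi]] <- list(
      dcm_el("BeamNumber", bi),
      dcm_el("BeamName", paste0("ARC", bi)),
      dcm_el("BeamType", if (b$is_arc) "DYNAMIC" else "STATIC"),
      dcm_el("RadiationType", "PHOTON"),
      dcm_el("PrimaryFluenceModeSequence", list(list(
        dcm_el("FluenceMode", if (en$fff) "NON_STANDARD" else "STANDARD"),
        dcm_el("FluenceModeID", if (en$fff) "FFF" else "")))),
      dcm_el("BeamLimitingDeviceSequence", list(
        list(dcm_el("RTBeamLimitingDeviceType", "ASYMX")),
        list(dcm_el("RTBeamLimitingDeviceType", "ASYMY")),
        list(dcm_el("RTBeamLimitingDeviceType", "MLCX"),
             dcm_el("NumberOfLeafJawPairs", npairs),
             dcm_el("LeafPositionBoundaries", b$leaf_edges)))),
      dcm_el("FinalCumulativeMetersetWeight", 1),
      dcm_el("NumberOfControlPoints", length(b$control_points)),
      dcm_el("ControlPointSequence", cps))
    frx_beams[[bi]] <- list(
      dcm_el("ReferencedBeamNumber", bi),
      dcm_el("BeamMeterset", b$beam_mu))
  }
  sop_uid <- muv_uid(seed, 10001)
  ds <- c(default_patient_module(), list(
    dcm_el("SOPClassUID", UID_SOP_RTPLAN),
    dcm_el("SOPInstanceUID", sop_uid),
    dcm_el("Modality", "RTPLAN"),
    dcm_el("StudyInstanceUID", muv_uid(seed, 1)),
    dcm_el("SeriesInstanceUID", muv_uid(seed, 11)),
    dcm_el("FrameOfReferenceUID", muv_uid(seed, 3)),
    dcm_el("SeriesNumber", 3),
    dcm_el("RTPlanLabel", plan$plan_label),
    dcm_el("RTPlanGeometry", "PATIENT"),
    dcm_el("FractionGroupSequence", list(c(
      list(dcm_el("NumberOfFractionsPlanned", 1L),
           dcm_el("NumberOfBeams", length(plan$beams))),
      list(dcm_el("ReferencedBeamSequence", frx_beams))))),
    dcm_el("BeamSequence", beams)))
  write_dicom(ds, path)
  invisible(structure(path, sop_uid = sop_uid))
}

#' Read an RT Plan file into a VMAT plan
#'
#' Populates per-control-point gantry, jaws, MLC and cumulative weight;
#' rejects beams without an MLC position sequence and decreasing cumulative
#' weights; static (non-arc) beams are flagged via `is_arc = FALSE`.
#'
#' @param path file path.
#' @return a [vmat_plan()].
#' @export
read_rtplan <- function(path) {
  ds <- read_dicom(path)
  beam_items <- dcm_require(ds, "BeamSequence", "RT Plan")
  if (!length(beam_items)) stop("read_rtplan: plan has no beams")
  # MU per beam from the fraction group
  mus <- list()
  fg <- dcm_get(ds, "FractionGroupSequence")
  if (!is.null(fg) && length(fg)) {
    for (rb in dcm_get(fg[[1]], "ReferencedBeamSequence") %||% list())
      mus[[as.character(dcm_get(rb, "ReferencedBeamNumber"))]] <-
        dcm_get(rb, "BeamMeterset")
  }
  iso <- c(0, 0, 0)
  beams <- vector("list", length(beam_items))
  for (bi in seq_along(beam_items)) {
    bd <- beam_items[[bi]]
    bn <- dcm_get(bd, "BeamNumber") %||% bi
    mu <- mus[[as.character(bn)]] %||% 0
    # energy label
    nominal <- NULL
    cpitems <- dcm_require(bd, "ControlPointSequence",
                           sprintf("beam %d", bn))
    if (length(cpitems) < 2L)
      stop(sprintf("read_rtplan: beam %d has fewer than 2 control points", bn))
    nominal <- dcm_get(cpitems[[1]], "NominalBeamEnergy") %||% 6
    pfm <- dcm_get(bd, "PrimaryFluenceModeSequence")
    fff <- !is.null(pfm) && length(pfm) &&
      identical(dcm_get(pfm[[1]], "FluenceMode"), "NON_STANDARD")
    energy <- paste0(round(nominal), if (fff) "FFF" else "X")
    # leaf boundaries
    leaf_edges <- NULL
    for (bld in dcm_get(bd, "BeamLimitingDeviceSequence") %||% list())
      if (identical(dcm_get(bld, "RTBeamLimitingDeviceType"), "MLCX"))
        leaf_edges <- dcm_get(bld, "LeafPositionBoundaries")
    cpl <- vector("list", length(cpitems))
    final_w <- dcm_get(bd, "FinalCumulativeMetersetWeight") %||% 1
    prev_w <- -Inf
    jaws <- c(x1 = -200, x2 = 200, y1 = -200, y2 = 200)
    mlc_a <- NULL; mlc_b <- NULL
    for (ci in seq_along(cpitems)) {
      cpd <- cpitems[[ci]]
      if (ci == 1L) {
        ip <- dcm_get(cpd, "IsocenterPosition")
        if (!is.null(ip)) iso <- ip
      }
      saw_mlc <- FALSE
      for (p in dcm_get(cpd, "BeamLimitingDevicePositionSequence") %||% list()) {
        typ <- dcm_get(p, "RTBeamLimitingDeviceType")
        pos <- dcm_get(p, "LeafJawPositions")
        if (typ %in% c("ASYMX", "X")) jaws[c("x1", "x2")] <- pos
        else if (typ %in% c("ASYMY", "Y")) jaws[c("y1", "y2")] <- pos
        else if (typ %in% c("MLCX", "MLCY")) {
          n <- length(pos) / 2
          mlc_a <- pos[seq_len(n)]; mlc_b <- pos[n + seq_len(n)]
          saw_mlc <- TRUE
        }
      }
      if (ci == 1L && !saw_mlc)
        stop(sprintf("read_rtplan: beam %d has no MLC position sequence", bn))
      w <- (dcm_get(cpd, "CumulativeMetersetWeight") %||% 0) / final_w
      if (w < prev_w - 1e-9)
        stop(sprintf("read_rtplan: beam %d control point %d: decreasing cumulative meterset weight",
                     bn, ci - 1L))
      prev_w <- w
      ga <- dcm_get(cpd, "GantryAngle") %||% 0
      cpl[[ci]] <- tryCatch(
        control_point(ga, jaws, mlc_a, mlc_b, w),
        error = function(e)
          stop(sprintf("read_rtplan: beam %d control point %d: %s",
                       bn, ci - 1L, conditionMessage(e)), call. = FALSE))
    }
    if (is.null(leaf_edges)) {
      n <- length(cpl[[1]]$mlc_a)
      leaf_edges <- seq(-n * 2.5, n * 2.5, by = 5)
    }
    is_arc <- !identical(dcm_get(bd, "BeamType"), "STATIC")
    beams[[bi]] <- arc_beam(energy, mu, cpl, leaf_edges, is_arc = is_arc)
  }
  vmat_plan(beams, isocenter = iso,
            plan_label = dcm_get(ds, "RTPlanLabel") %||% "plan")
}

# ---- RT Structure Set -------------------------------------------------------

#' Write an RT Structure Set
#'
#' @param rois named list; each element is a list of contours, each an
#'   n x 3 matrix of closed planar polygon vertices, mm.
#' @param path output file.
#' @param seed UID seed.
#' @return `path`, invisibly.
#' @export
write_rtstruct <- function(rois, path, seed = 1) {
  ssr <- list(); rcs <- list()
  for (i in seq_along(rois)) {
    ssr[[i]] <- list(dcm_el("ROINumber", i),
                     dcm_el("ReferencedFrameOfReferenceUID", muv_uid(seed, 3)),
                     dcm_el("ROIName", names(rois)[i]))
    contours <- lapply(rois[[i]], function(m) {
      m <- matrix(as.numeric(m), ncol = 3)
      list(dcm_el("ContourGeometricType", "CLOSED_PLANAR"),
           dcm_el("NumberOfContourPoints", nrow(m)),
           dcm_el("ContourData", as.numeric(t(m))))
    })
    rcs[[i]] <- list(dcm_el("ReferencedROINumber", i),
                     dcm_el("ContourSequence", contours))
  }
  ds <- c(default_patient_module(), list(
    dcm_el("SOPClassUID", UID_SOP_RTSTRUCT),
    dcm_el("SOPInstanceUID", muv_uid(seed, 30001)),
    dcm_el("Modality", "RTSTRUCT"),
    dcm_el("StudyInstanceUID", muv_uid(seed, 1)),
    dcm_el("SeriesInstanceUID", muv_uid(seed, 31)),
    dcm_el("SeriesNumber", 4),
    dcm_el("StructureSetLabel", "muvr structures"),
    dcm_el("StructureSetROISequence", ssr),
    dcm_el("ROIContourSequence", rcs)))
  write_dicom(ds, path)
  invisible(path)
}

# ray-casting point-in-polygon, vectorized over points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Read an RT Structure Set and rasterize onto the CT grid
#'
#' Contours are assigned to the nearest CT slice and filled by ray-casting;
#' an ROI without contours yields an empty mask with a warning.
#'
#' @param path file path.
#' @param ct a [ct_volume()] providing the rasterization grid.
#' @return a [structure_set()].
#' @export
read_structures <- function(path, ct) {
  ds <- read_dicom(path)
  g <- ct$grid
  ssr <- dcm_require(ds, "StructureSetROISequence", "RT Structure Set")
  names_by_num <- list()
  for (item in ssr)
    names_by_num[[as.character(dcm_get(item, "ROINumber"))]] <-
      dcm_get(item, "ROIName")
  xs <- grid_axis(g, 1); ys <- grid_axis(g, 2); zs <- grid_axis(g, 3)
  rois <- list()
  for (item in dcm_require(ds, "ROIContourSequence", "RT Structure Set")) {
    num <- as.character(dcm_get(item, "ReferencedROINumber"))
    nm <- names_by_num[[num]] %||% paste0("ROI", num)
    contours <- lapply(dcm_get(item, "ContourSequence") %||% list(),
                       function(cs) matrix(dcm_get(cs, "ContourData"),
                                           ncol = 3, byrow = TRUE))
    mask <- array(FALSE, dim = g$dims)
    if (!length(contours)) {
      warning(sprintf("read_structures: ROI '%s' has no contours; empty mask", nm))
    } else {
      for (m in contours) {
        k <- which.min(abs(zs - m[1, 3]))
        if (abs(zs[k] - m[1, 3]) > g$spacing[3]) next # contour off-grid
        grid_pts <- expand.grid(x = xs, y = ys)
        inside <- point_in_polygon(grid_pts$x, grid_pts$y, m[, 1], m[, 2])
        mask[, , k] <- mask[, , k] | matrix(inside, nrow = g$dims[1])
      }
    }
    rois[[nm]] <- list(contours = contours, mask = mask)
  }
  structure_set(rois, g)
}

# ---- anonymization ----------------------------------------------------------

IDENTIFYING_TAGS <- c("PatientName", "PatientID", "PatientBirthDate",
                      "PatientSex", "AccessionNumber",
                      "ReferringPhysicianName", "StudyDescription",
                      "SeriesDescription", "StudyDate", "StudyTime",
                      "StudyID")
INSTANCE_UID_TAGS <- c("SOPInstanceUID", "StudyInstanceUID",
                       "SeriesInstanceUID", "FrameOfReferenceUID",
                       "ReferencedSOPInstanceUID",
                       "ReferencedFrameOfReferenceUID")
ANON_UID_PREFIX <- paste0(MUV_UID_ROOT, ".9.")

# stable digest of a UID string -> digits (consistency without shared state)
uid_digest <- function(uid) {
  h <- 0
  for (cc in utf8ToInt(uid)) h <- (h * 131 + cc) %% 999999937
  as.integer(h)
}

remap_uid <- function(uid) {
  if (startsWith(uid, ANON_UID_PREFIX)) uid # idempotent
  else paste0(ANON_UID_PREFIX, uid_digest(uid))
}

strip_dataset <- function(ds) {
  for (j in seq_along(ds)) {
    kw <- ds[[j]]$keyword
    if (kw %in% IDENTIFYING_TAGS) {
      ds[[j]]$value <- switch(kw,
                              PatientName = "ANON^ANON",
                              PatientID = "ANON",
                              PatientSex = "O",
                              StudyDate = "19000101",
                              StudyTime = "000000",
                              "")
    } else if (kw %in% INSTANCE_UID_TAGS) {
      ds[[j]]$value <- remap_uid(ds[[j]]$value)
    } else if (ds[[j]]$vr == "SQ") {
      ds[[j]]$value <- lapply(ds[[j]]$value, strip_dataset)
    }
  }
  ds
}

#' Strip identifying metadata from a set of DICOM files
#'
#' Identifying tags are replaced by placeholders and instance-level UIDs are
#' remapped deterministically (same input UID, same output UID), so
#' cross-references between the CT, plan, structures and dose of one case
#' stay consistent. Already-stripped files pass through unchanged
#' (idempotent). Missing tags are skipped.
#'
#' @param paths input DICOM files.
#' @param out_dir output directory.
#' @return character vector of output paths, invisibly.
#' @export
strip_identifiers <- function(paths, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(length(paths))
  for (i in seq_along(paths)) {
    ds <- strip_dataset(read_dicom(paths[i]))
    out[i] <- file.path(out_dir, basename(paths[i]))
    write_dicom(ds, out[i])
  }
  invisible(out)
}

# ---- case container ---------------------------------------------------------

#' Load a case directory (CT series + plan + structures + dose)
#'
#' The case container is a plain directory: CT slices under `ct/`, and
#' `plan.dcm`, `structures.dcm`, `dose.dcm` at the top level (missing
#' members are returned as `NULL`).
#'
#' @param dir case directory.
#' @return list with `ct`, `plan`, `structures`, `dose`.
#' @export
read_case <- function(dir) {
  ct <- if (dir.exists(file.path(dir, "ct"))) read_ct_series(file.path(dir, "ct"))
  plan <- if (file.exists(file.path(dir, "plan.dcm")))
    read_rtplan(file.path(dir, "plan.dcm"))
  structures <- if (!is.null(ct) && file.exists(file.path(dir, "structures.dcm")))
    read_structures(file.path(dir, "structures.dcm"), ct)
  dose <- if (file.exists(file.path(dir, "dose.dcm")))
    read_rtdose(file.path(dir, "dose.dcm"))
  list(ct = ct, plan = plan, structures = structures, dose = dose)
}
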