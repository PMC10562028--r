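# Minimal DICOM codec: explicit-VR little-endian read/write of the tag
# subset the four RT objects need. A dataset is a list of elements, each
# `list(group, element, vr, value)`; SQ values are lists of nested
# datasets. This is deliberately not a conformant toolkit -- it exists so
# the pipeline can exchange standards-shaped CT / RT Plan / RT Structure
# Set / RT Dose files with itself (and with pydicom-class readers) without
# an external dependency.

dcm_dictionary <- function() {
  # keyword, group, element, vr
  m <- matrix(c(
    "FileMetaInformationGroupLength", "0002", "0000", "UL",
    "FileMetaInformationVersion",     "0002", "0001", "OB",
    "MediaStorageSOPClassUID",        "0002", "0002", "UI",
    "MediaStorageSOPInstanceUID",     "0002", "0003", "UI",
    "TransferSyntaxUID",              "0002", "0010", "UI",
    "ImplementationClassUID",         "0002", "0012", "UI",
    "SpecificCharacterSet", "0008", "0005", "CS",
    "SOPClassUID",          "0008", "0016", "UI",
    "SOPInstanceUID",       "0008", "0018", "UI",
    "StudyDate",            "0008", "0020", "DA",
    "StudyTime",            "0008", "0030", "TM",
    "AccessionNumber",      "0008", "0050", "SH",
    "Modality",             "0008", "0060", "CS",
    "Manufacturer",         "0008", "0070", "LO",
    "ReferringPhysicianName", "0008", "0090", "PN",
    "StudyDescription",     "0008", "1030", "LO",
    "SeriesDescription",    "0008", "103E", "LO",
    "ReferencedSOPClassUID", "0008", "1150", "UI",
    "ReferencedSOPInstanceUID", "0008", "1155", "UI",
    "PatientName",          "0010", "0010", "PN",
    "PatientID",            "0010", "0020", "LO",
    "PatientBirthDate",     "0010", "0030", "DA",
    "PatientSex",           "0010", "0040", "CS",
    "SliceThickness",       "0018", "0050", "DS",
    "StudyInstanceUID",     "0020", "000D", "UI",
    "SeriesInstanceUID",    "0020", "000E", "UI",
    "StudyID",              "0020", "0010", "SH",
    "SeriesNumber",         "0020", "0011", "IS",
    "InstanceNumber",       "0020", "0013", "IS",
    "ImagePositionPatient", "0020", "0032", "DS",
    "ImageOrientationPatient", "0020", "0037", "DS",
    "FrameOfReferenceUID",  "0020", "0052", "UI",
    "SamplesPerPixel",      "0028", "0002", "US",
    "PhotometricInterpretation", "0028", "0004", "CS",
    "NumberOfFrames",       "0028", "0008", "IS",
    "Rows",                 "0028", "0010", "US",
    "Columns",              "0028", "0011", "US",
    "PixelSpacing",         "0028", "0030", "DS",
    "BitsAllocated",        "0028", "0100", "US",
    "BitsStored",           "0028", "0101", "US",
    "HighBit",              "0028", "0102", "US",
    "PixelRepresentation",  "0028", "0103", "US",
    "RescaleIntercept",     "0028", "1052", "DS",
    "RescaleSlope",         "0028", "1053", "DS",
    "PrimaryFluenceModeSequence", "3002", "0050", "SQ",
    "FluenceMode",          "3002", "0051", "CS",
    "FluenceModeID",        "3002", "0052", "SH",
    "DoseUnits",            "3004", "0002", "CS",
    "DoseType",             "3004", "0004", "CS",
    "DoseSummationType",    "3004", "000A", "CS",
    "GridFrameOffsetVector", "3004", "000C", "DS",
    "DoseGridScaling",      "3004", "000E", "DS",
    "StructureSetLabel",    "3006", "0002", "SH",
    "StructureSetROISequence", "3006", "0020", "SQ",
    "ROINumber",            "3006", "0022", "IS",
    "ReferencedFrameOfReferenceUID", "3006", "0024", "UI",
    "ROIName",              "3006", "0026", "LO",
    "ROIContourSequence",   "3006", "0039", "SQ",
    "ContourSequence",      "3006", "0040", "SQ",
    "ContourGeometricType", "3006", "0042", "CS",
    "NumberOfContourPoints", "3006", "0046", "IS",
    "ContourData",          "3006", "0050", "DS",
    "ReferencedROINumber",  "3006", "0084", "IS",
    "RTPlanLabel",          "300A", "0002", "SH",
    "RTPlanGeometry",       "300A", "000C", "CS",
    "FractionGroupSequence", "300A", "0070", "SQ",
    "NumberOfFractionsPlanned", "300A", "0078", "IS",
    "NumberOfBeams",        "300A", "0080", "IS",
    "BeamMeterset",         "300A", "0086", "DS",
    "BeamSequence",         "300A", "00B0", "SQ",
    "BeamLimitingDeviceSequence", "300A", "00B6", "SQ",
    "RTBeamLimitingDeviceType", "300A", "00B8", "CS",
    "NumberOfLeafJawPairs", "300A", "00BC", "IS",
    "LeafPositionBoundaries", "300A", "00BE", "DS",
    "BeamNumber",           "300A", "00C0", "IS",
    "BeamName",             "300A", "00C2", "LO",
    "BeamType",             "300A", "00C4", "CS",
    "RadiationType",        "300A", "00C6", "CS",
    "FinalCumulativeMetersetWeight", "300A", "010E", "DS",
    "NumberOfControlPoints", "300A", "0110", "IS",
    "ControlPointSequence", "300A", "0111", "SQ",
    "ControlPointIndex",    "300A", "0112", "IS",
    "NominalBeamEnergy",    "300A", "0114", "DS",
    "BeamLimitingDevicePositionSequence", "300A", "011A", "SQ",
    "LeafJawPositions",     "300A", "011C", "DS",
    "GantryAngle",          "300A", "011E", "DS",
    "GantryRotationDirection", "300A", "011F", "CS",
    "BeamLimitingDeviceAngle", "300A", "0120", "DS",
    "PatientSupportAngle",  "300A", "0122", "DS",
    "IsocenterPosition",    "300A", "012C", "DS",
    "CumulativeMetersetWeight", "300A", "0134", "DS",
    "ReferencedRTPlanSequence", "300C", "0002", "SQ",
    "ReferencedBeamSequence", "300C", "0004", "SQ",
    "ReferencedBeamNumber", "300C", "0006", "IS",
    "PixelData",            "7FE0", "0010", "OW"
  ), ncol = 4, byrow = TRUE)
  data.frame(keyword = m[, 1], group = strtoi(m[, 2], 16L),
             element = strtoi(m[, 3], 16L), vr = m[, 4],
             stringsAsFactors = FALSE)
}

.dcm_dict <- NULL
dcm_dict <- function() {
  if (is.null(.dcm_dict)) {
    d <- dcm_dictionary()
    utils::assignInMyNamespace(".dcm_dict", d)
  }
  .dcm_dict
}

# construct an element from a keyword
dcm_el <- function(keyword, value) {
  d <- dcm_dict()
  i <- match(keyword, d$keyword)
  if (is.na(i)) stop("dcm_el: unknown keyword ", keyword)
  list(group = d$group[i], element = d$element[i], vr = d$vr[i],
       value = value, keyword = keyword)
}

# find an element's value in a dataset by keyword; NULL when absent
dcm_get <- function(ds, keyword) {
  d <- dcm_dict()
  i <- match(keyword, d$keyword)
  for (el in ds)
    if (el$group == d$group[i] && el$element == d$element[i]) return(el$value)
  NULL
}

dcm_require <- function(ds, keyword, context = "dataset") {
  v <- dcm_get(ds, keyword)
  if (is.null(v))
    stop(sprintf("missing required DICOM tag %s in %s", keyword, context))
  v
}

dcm_set <- function(ds, keyword, value) {
  d <- dcm_dict()
  i <- match(keyword, d$keyword)
  for (j in seq_along(ds))
    if (ds[[j]]$group == d$group[i] && ds[[j]]$element == d$element[i]) {
      ds[[j]]$value <- value
      return(ds)
    }
  c(ds, list(dcm_el(keyword, value)))
}

# sort elements by (group, element) as the standard requires
dcm_sort <- function(ds) {
  key <- vapply(ds, function(e) e$group * 65536 + e$element, numeric(1))
  ds[order(key)]
}

STRING_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
                "SH", "ST", "TM", "UI", "UT")

uint16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_raw <- function(x) {
  # writeBin has no unsigned 32-bit; lengths stay below 2^31 here
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

encode_value <- function(vr, value) {
  if (vr %in% STRING_VRS) {
    s <- if (is.numeric(value)) paste(sprintf("%.10g", value), collapse = "\\")
    else paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2 == 1)
      b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
    b
  } else if (vr == "US") {
    writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "UL") {
    writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr == "FL") {
    writeBin(as.numeric(value), raw(), size = 4, endian = "little")
  } else if (vr == "FD") {
    writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    b <- as.raw(value)
    if (length(b) %% 2 == 1) b <- c(b, as.raw(0))
    b
  } else stop("encode_value: unsupported VR ", vr)
}

encode_element <- function(el) {
  vr <- el$vr
  head <- c(uint16_raw(el$group), uint16_raw(el$element), charToRaw(vr))
  if (vr == "SQ") {
    items <- lapply(el$value, function(item_ds) {
      body <- encode_dataset(item_ds)
      c(uint16_raw(0xFFFE), uint16_raw(0xE000), as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)),
        body,
        uint16_raw(0xFFFE), uint16_raw(0xE00D), uint32_raw(0))
    })
    c(head, as.raw(c(0, 0)), as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)),
      do.call(c, c(items, list(raw(0)))),
      uint16_raw(0xFFFE), uint16_raw(0xE0DD), uint32_raw(0))
  } else {
    body <- encode_value(vr, el$value)
    if (vr %in% c("OB", "OW", "UT", "UN")) {
      c(head, as.raw(c(0, 0)), uint32_raw(length(body)), body)
    } else {
      if (length(body) > 65534) stop("encode_element: value too long for short VR ", vr)
      c(head, uint16_raw(length(body)), body)
    }
  }
}

encode_dataset <- function(ds) {
  do.call(c, c(lapply(dcm_sort(ds), encode_element), list(raw(0))))
}

MUV_UID_ROOT <- "1.2.826.0.1.3680043.10.1442"
UID_SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_SOP_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
UID_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

#' Deterministic UID generator
#'
#' UIDs under a fixed private root, derived from a seed and counter so
#' fixture output is byte-reproducible.
#'
#' @param seed integer.
#' @param counter integer.
#' @return a UID string.
#' @export
muv_uid <- function(seed, counter) {
  sprintf("%s.%d.%d", MUV_UID_ROOT, as.integer(seed) %% 1000000000L,
          as.integer(counter))
}

#' Write a DICOM dataset to file
#'
#' Explicit-VR little-endian with the standard 128-byte preamble, "DICM"
#' marker and file meta group.
#'
#' @param ds dataset (list of elements built with internal constructors).
#' @param path output path.
#' @param sop_class_uid SOP Class UID for the meta group; defaults to the
#'   dataset's SOPClassUID element.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(ds, path, sop_class_uid = dcm_get(ds, "SOPClassUID")) {
  sop_inst <- dcm_get(ds, "SOPInstanceUID")
  meta <- list(
    dcm_el("FileMetaInformationVersion", as.raw(c(0, 1))),
    dcm_el("MediaStorageSOPClassUID", sop_class_uid),
    dcm_el("MediaStorageSOPInstanceUID", sop_inst),
    dcm_el("TransferSyntaxUID", UID_TS_EXPLICIT_LE),
    dcm_el("ImplementationClassUID", paste0(MUV_UID_ROOT, ".0.1"))
  )
  meta_body <- encode_dataset(meta)
  group_len <- dcm_el("FileMetaInformationGroupLength", length(meta_body))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 128)), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(encode_element(group_len), con)
  writeBin(meta_body, con)
  writeBin(encode_dataset(ds), con)
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

decode_value <- function(vr, bytes) {
  if (vr %in% STRING_VRS) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    s <- sub("[ ]+$", "", s)
    parts <- if (nzchar(s)) strsplit(s, "\\", fixed = TRUE)[[1]] else character(0)
    if (vr %in% c("DS", "IS")) as.numeric(parts) else trimws(parts)
  } else if (vr == "US") {
    readBin(bytes, integer(), length(bytes) / 2, size = 2, signed = FALSE,
            endian = "little")
  } else if (vr == "UL") {
    readBin(bytes, integer(), length(bytes) / 4, size = 4, endian = "little")
  } else if (vr == "FL") {
    readBin(bytes, numeric(), length(bytes) / 4, size = 4, endian = "little")
  } else if (vr == "FD") {
    readBin(bytes, numeric(), length(bytes) / 8, size = 8, endian = "little")
  } else {
    bytes # OB/OW/unknown: raw
  }
}

# cursor-based parser over a raw vector
dcm_parse <- function(buf, pos, end, depth = 0) {
  ds <- list()
  d <- dcm_dict()
  while (pos + 7 <= end) {
    grp <- readBin(buf[pos:(pos + 1)], integer(), 1, size = 2, signed = FALSE,
                   endian = "little")
    ele <- readBin(buf[(pos + 2):(pos + 3)], integer(), 1, size = 2,
                   signed = FALSE, endian = "little")
    pos <- pos + 4
    if (grp == 0xFFFE) { # delimiter items handled by caller
      len <- readBin(buf[pos:(pos + 3)], integer(), 1, size = 4, endian = "little")
      pos <- pos + 4
      if (ele == 0xE00D || ele == 0xE0DD)
        return(list(ds = ds, pos = pos, delim = ele))
      stop("dcm_parse: unexpected item tag outside sequence")
    }
    vr <- rawToChar(buf[pos:(pos + 1)])
    pos <- pos + 2
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      pos <- pos + 2 # reserved
      len <- readBin(buf[pos:(pos + 3)], integer(), 1, size = 4, endian = "little")
      pos <- pos + 4
    } else {
      len <- readBin(buf[pos:(pos + 1)], integer(), 1, size = 2, signed = FALSE,
                     endian = "little")
      pos <- pos + 2
    }
    undefined <- (len == -1L)
    if (vr == "SQ") {
      items <- list()
      item_end <- if (undefined) end else pos + len
      while (pos + 7 <= item_end) {
        ig <- readBin(buf[pos:(pos + 1)], integer(), 1, size = 2,
                      signed = FALSE, endian = "little")
        ie <- readBin(buf[(pos + 2):(pos + 3)], integer(), 1, size = 2,
                      signed = FALSE, endian = "little")
        il <- readBin(buf[(pos + 4):(pos + 7)], integer(), 1, size = 4,
                      endian = "little")
        pos <- pos + 8
        if (ig != 0xFFFE) stop("dcm_parse: malformed sequence item tag")
        if (ie == 0xE0DD) break
        if (ie != 0xE000) stop("dcm_parse: unexpected tag in sequence")
        if (il == -1L) {
          r <- dcm_parse(buf, pos, item_end, depth + 1)
          if (is.null(r$delim) || r$delim != 0xE00D)
            stop("dcm_parse: unterminated sequence item")
          items[[length(items) + 1L]] <- r$ds
          pos <- r$pos
        } else {
          r <- dcm_parse(buf, pos, pos + il, depth + 1)
          items[[length(items) + 1L]] <- r$ds
          pos <- pos + il
        }
      }
      value <- items
    } else {
      if (undefined) stop("dcm_parse: undefined length on non-SQ element")
      value <- decode_value(vr, if (len > 0) buf[pos:(pos + len - 1)] else raw(0))
      pos <- pos + len
    }
    i <- which(d$group == grp & d$element == ele)
    kw <- if (length(i)) d$keyword[i[1]] else sprintf("(%04X,%04X)", grp, ele)
    ds[[length(ds) + 1L]] <- list(group = grp, element = ele, vr = vr,
                                  value = value, keyword = kw)
  }
  list(ds = ds, pos = pos, delim = NULL)
}

#' Read a DICOM file
#'
#' Explicit-VR little-endian only (the transfer syntax this package
#' writes); returns the parsed main dataset.
#'
#' @param path file path.
#' @return dataset: list of elements with `keyword`, `vr`, `value`.
#' @export
read_dicom <- function(path) {
  buf <- readBin(path, raw(), file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("read_dicom: not a DICOM part-10 file: ", path)
  pos <- 133
  # file meta group: first element gives the group length
  r0 <- dcm_parse(buf, pos, pos + 12 - 1)
  gl_el <- r0$ds[[1]]
  if (gl_el$keyword != "FileMetaInformationGroupLength")
    stop("read_dicom: missing file meta group length")
  meta_end <- r0$pos + gl_el$value
  meta <- dcm_parse(buf, r0$pos, meta_end)$ds
  ts <- dcm_get(meta, "TransferSyntaxUID")
  if (!identical(ts, UID_TS_EXPLICIT_LE))
    stop("read_dicom: unsupported transfer syntax ", ts)
  dcm_parse(buf, meta_end, length(buf))$ds
}
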