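# Minimal DICOM Part 10 codec: explicit VR, little endian, uncompressed.
#
# Covers what the workflow needs — reading pixel spacing and rescale
# metadata, stripping identifying elements without touching pixel bytes, and
# writing well-formed single-frame secondary-capture files for fixtures.
# Sequences (SQ) are carried as opaque byte ranges when their length is
# defined; undefined-length sequences and compressed transfer syntaxes are
# out of scope and rejected up front.

EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
SC_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.7"  # secondary capture

# Tags the workflow understands by name. group/element in hex.
DICOM_DICT <- list(
  FileMetaInformationVersion = c(0x0002, 0x0001),
  MediaStorageSOPClassUID    = c(0x0002, 0x0002),
  MediaStorageSOPInstanceUID = c(0x0002, 0x0003),
  TransferSyntaxUID          = c(0x0002, 0x0010),
  ImplementationClassUID     = c(0x0002, 0x0012),
  StudyDate            = c(0x0008, 0x0020), SeriesDate   = c(0x0008, 0x0021),
  AcquisitionDate      = c(0x0008, 0x0022), ContentDate  = c(0x0008, 0x0023),
  StudyTime            = c(0x0008, 0x0030), SeriesTime   = c(0x0008, 0x0031),
  AcquisitionTime      = c(0x0008, 0x0032), ContentTime  = c(0x0008, 0x0033),
  AccessionNumber      = c(0x0008, 0x0050),
  SOPClassUID          = c(0x0008, 0x0016), SOPInstanceUID = c(0x0008, 0x0018),
  Modality             = c(0x0008, 0x0060),
  InstitutionName      = c(0x0008, 0x0080),
  ReferringPhysicianName = c(0x0008, 0x0090),
  OperatorsName        = c(0x0008, 0x1070),
  PatientName          = c(0x0010, 0x0010), PatientID      = c(0x0010, 0x0020),
  PatientBirthDate     = c(0x0010, 0x0030), PatientSex     = c(0x0010, 0x0040),
  OtherPatientIDs      = c(0x0010, 0x1000),
  ImagerPixelSpacing   = c(0x0018, 0x1164),
  StudyID              = c(0x0020, 0x0010),
  SamplesPerPixel      = c(0x0028, 0x0002),
  PhotometricInterpretation = c(0x0028, 0x0004),
  NumberOfFrames       = c(0x0028, 0x0008),
  Rows                 = c(0x0028, 0x0010), Columns        = c(0x0028, 0x0011),
  PixelSpacing         = c(0x0028, 0x0030),
  BitsAllocated        = c(0x0028, 0x0100), BitsStored     = c(0x0028, 0x0101),
  HighBit              = c(0x0028, 0x0102), PixelRepresentation = c(0x0028, 0x0103),
  RescaleIntercept     = c(0x0028, 0x1052), RescaleSlope   = c(0x0028, 0x1053),
  PixelData            = c(0x7FE0, 0x0010)
)

DICOM_VR <- c(
  FileMetaInformationVersion = "OB",
  MediaStorageSOPClassUID = "UI", MediaStorageSOPInstanceUID = "UI",
  TransferSyntaxUID = "UI", ImplementationClassUID = "UI",
  StudyDate = "DA", SeriesDate = "DA", AcquisitionDate = "DA", ContentDate = "DA",
  StudyTime = "TM", SeriesTime = "TM", AcquisitionTime = "TM", ContentTime = "TM",
  AccessionNumber = "SH", SOPClassUID = "UI", SOPInstanceUID = "UI",
  Modality = "CS", InstitutionName = "LO", ReferringPhysicianName = "PN",
  OperatorsName = "PN", PatientName = "PN", PatientID = "LO",
  PatientBirthDate = "DA", PatientSex = "CS", OtherPatientIDs = "LO",
  ImagerPixelSpacing = "DS", StudyID = "SH",
  SamplesPerPixel = "US", PhotometricInterpretation = "CS", NumberOfFrames = "IS",
  Rows = "US", Columns = "US", PixelSpacing = "DS",
  BitsAllocated = "US", BitsStored = "US", HighBit = "US", PixelRepresentation = "US",
  RescaleIntercept = "DS", RescaleSlope = "DS", PixelData = "OW"
)

#' Default DICOM identification denylist
#'
#' Element names removed from the observer-facing view of any DICOM file:
#' patient demographics, acquisition/study/series/content timestamps,
#' institution and personnel names, accession/study identifiers. All private
#' (odd-group) elements are removed as well, independent of this list.
#'
#' @return character vector of element names.
#' @export
dicom_denylist_default <- function() c(
  "PatientName", "PatientID", "PatientBirthDate", "PatientSex", "OtherPatientIDs",
  "AcquisitionDate", "AcquisitionTime", "StudyDate", "StudyTime",
  "SeriesDate", "SeriesTime", "ContentDate", "ContentTime",
  "InstitutionName", "ReferringPhysicianName", "OperatorsName",
  "AccessionNumber", "StudyID"
)

STRING_VRS <- c("AE","AS","CS","DA","DS","DT","IS","LO","LT","PN","SH","ST","TM","UI","UT")
LONG_LEN_VRS <- c("OB","OW","OF","SQ","UT","UN")

u16le <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
u32le <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))
w16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))
w32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

is_dicom <- function(payload) {
  length(payload) > 132L && rawToChar(payload[129:132]) == "DICM"
}

encode_element <- function(group, element, vr, value) {
  body <- if (vr %in% STRING_VRS) {
    v <- charToRaw(paste(as.character(value), collapse = "\\"))
    if (length(v) %% 2L == 1L) v <- c(v, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    v
  } else if (vr == "US") {
    do.call(c, lapply(as.integer(value), w16le))
  } else if (vr == "UL") {
    do.call(c, lapply(value, w32le))
  } else if (vr %in% c("OB", "OW")) {
    v <- as.raw(value)
    if (length(v) %% 2L == 1L) v <- c(v, as.raw(0L))
    v
  } else {
    bs_abort("validation", sprintf("unsupported VR '%s' for writing", vr))
  }
  head <- c(w16le(group), w16le(element), charToRaw(vr))
  if (vr %in% LONG_LEN_VRS) {
    c(head, as.raw(c(0L, 0L)), w32le(length(body)), body)
  } else {
    bs_check(length(body) <= 65535, "validation", "element too long for short VR")
    c(head, w16le(length(body)), body)
  }
}

#' Write a DICOM Part 10 file
#'
#' Produces an explicit-VR little-endian secondary-capture file around a
#' 16-bit grayscale pixel matrix. Used by the fixtures module; real-world
#' writing is limited to re-serializing a parsed file (see [dcm_anonymize()]).
#'
#' @param pixels integer matrix (rows x columns) of stored values in
#'   \[0, 65535\].
#' @param elements named list of extra string elements (names from
#'   [dicom_denylist_default()] and the package's tag dictionary), e.g.
#'   `list(PatientName = "Doe^Jane", PixelSpacing = c(0.1, 0.1))`.
#' @return raw vector with the full file.
#' @export
dcm_write <- function(pixels, elements = list()) {
  bs_check(is.matrix(pixels), "validation", "pixels must be a matrix")
  storage.mode(pixels) <- "integer"
  bs_check(all(pixels >= 0L & pixels <= 65535L), "validation",
           "stored pixel values must be within [0, 65535]")
  sop_uid <- paste0("2.25.", paste(sample.int(9, 30, replace = TRUE) - 1L, collapse = ""))

  meta_names <- c("FileMetaInformationVersion", "MediaStorageSOPClassUID",
                  "MediaStorageSOPInstanceUID", "TransferSyntaxUID",
                  "ImplementationClassUID")
  meta_vals <- list(as.raw(c(0L, 1L)), SC_SOP_CLASS, sop_uid, EXPLICIT_VR_LE,
                    "2.25.84058958401")
  meta_body <- raw()
  for (i in seq_along(meta_names)) {
    tg <- DICOM_DICT[[meta_names[i]]]
    meta_body <- c(meta_body, encode_element(tg[1], tg[2], DICOM_VR[[meta_names[i]]],
                                             meta_vals[[i]]))
  }
  group_len <- encode_element(0x0002, 0x0000, "UL", length(meta_body))

  ds <- list(
    SOPClassUID = SC_SOP_CLASS, SOPInstanceUID = sop_uid, Modality = "OT",
    SamplesPerPixel = 1L, PhotometricInterpretation = "MONOCHROME2",
    Rows = nrow(pixels), Columns = ncol(pixels),
    BitsAllocated = 16L, BitsStored = 16L, HighBit = 15L, PixelRepresentation = 0L
  )
  for (nm in names(elements)) {
    bs_check(nm %in% names(DICOM_DICT), "validation",
             sprintf("unknown DICOM element name '%s'", nm))
    val <- elements[[nm]]
    if (DICOM_VR[[nm]] == "DS") val <- format(as.numeric(val), digits = 10)
    ds[[nm]] <- val
  }
  ord <- order(vapply(names(ds), function(nm) {
    tg <- DICOM_DICT[[nm]]; tg[1] * 65536 + tg[2]
  }, numeric(1)))
  body <- raw()
  for (nm in names(ds)[ord]) {
    tg <- DICOM_DICT[[nm]]
    body <- c(body, encode_element(tg[1], tg[2], DICOM_VR[[nm]], ds[[nm]]))
  }
  # Pixel data: row-major, 16-bit little endian.
  px <- as.vector(t(pixels))
  px_bytes <- as.raw(rbind(px %% 256L, px %/% 256L))
  body <- c(body, encode_element(0x7FE0, 0x0010, "OW", px_bytes))

  c(as.raw(rep(0L, 128L)), charToRaw("DICM"), group_len, meta_body, body)
}

#' Parse a DICOM Part 10 file
#'
#' @param payload raw vector with the file bytes.
#' @return a `bs_dicom`: data frame of elements (`group`, `element`, `vr`,
#'   `name` when known) with a parallel list column of value bytes, plus
#'   decoded convenience accessors via [dcm_get()].
#' @export
dcm_read <- function(payload) {
  bs_check(is.raw(payload) && is_dicom(payload), "unsupported_media",
           "not a DICOM Part 10 file (missing DICM preamble)")
  pos <- 133L
  n <- length(payload)
  groups <- integer(); elems <- integer(); vrs <- character(); vals <- list()
  ts <- EXPLICIT_VR_LE
  while (pos + 7L <= n) {
    g <- u16le(payload[pos:(pos + 1L)]); e <- u16le(payload[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(payload[(pos + 4L):(pos + 5L)])
    bs_check(grepl("^[A-Z]{2}$", vr), "unsupported_media",
             "element without explicit VR: only explicit-VR little-endian files are supported")
    if (vr %in% LONG_LEN_VRS) {
      len <- u32le(payload[(pos + 8L):(pos + 11L)])
      bs_check(len != 4294967295, "unsupported_media",
               "undefined-length element (encapsulated/sequence) not supported")
      val_start <- pos + 12L
    } else {
      len <- u16le(payload[(pos + 6L):(pos + 7L)])
      val_start <- pos + 8L
    }
    bs_check(val_start + len - 1L <= n, "unsupported_media", "truncated DICOM element")
    groups <- c(groups, g); elems <- c(elems, e); vrs <- c(vrs, vr)
    vals <- c(vals, list(if (len > 0) payload[val_start:(val_start + len - 1L)] else raw()))
    if (g == 0x0002 && e == 0x0010) ts <- trimws(rawToChar(vals[[length(vals)]]))
    pos <- val_start + len
  }
  bs_check(ts == EXPLICIT_VR_LE, "unsupported_media",
           sprintf("transfer syntax '%s' not supported", ts))
  name_of <- function(g, e) {
    hit <- names(DICOM_DICT)[vapply(DICOM_DICT, function(t) t[1] == g && t[2] == e, logical(1))]
    if (length(hit)) hit[1] else NA_character_
  }
  tab <- data.frame(group = groups, element = elems, vr = vrs,
                    name = mapply(name_of, groups, elems), stringsAsFactors = FALSE)
  structure(list(elements = tab, values = vals), class = "bs_dicom")
}

#' @export
print.bs_dicom <- function(x, ...) {
  cat("<bs_dicom> ", nrow(x$elements), " elements\n", sep = "")
  invisible(x)
}

#' Read one element's decoded value
#'
#' @param dcm a `bs_dicom` from [dcm_read()].
#' @param name element name from the package's tag dictionary.
#' @return decoded value (character split on `\\` for strings, numeric for
#'   DS/IS/US/UL, raw for pixel/other data), or `NULL` when absent.
#' @export
dcm_get <- function(dcm, name) {
  i <- which(dcm$elements$name == name)
  if (!length(i)) return(NULL)
  i <- i[length(i)]  # dataset value shadows any file-meta duplicate
  vr <- dcm$elements$vr[i]
  v <- dcm$values[[i]]
  if (vr %in% c("DS", "IS")) {
    as.numeric(strsplit(trimws(rawToChar(v)), "\\\\")[[1]])
  } else if (vr %in% STRING_VRS) {
    v <- v[v != as.raw(0L)]  # UI values are NUL-padded to even length
    sub(" +$", "", strsplit(rawToChar(v), "\\\\")[[1]])
  } else if (vr == "US") {
    vapply(seq_len(length(v) %/% 2L), function(k) u16le(v[(2L * k - 1L):(2L * k)]), integer(1))
  } else if (vr == "UL") {
    vapply(seq_len(length(v) %/% 4L), function(k) u32le(v[(4L * k - 3L):(4L * k)]), numeric(1))
  } else {
    v
  }
}

#' Decode the pixel matrix of a parsed DICOM file
#'
#' @param dcm a `bs_dicom`.
#' @return integer matrix (rows x columns) of stored values.
#' @export
dcm_pixels <- function(dcm) {
  rows <- dcm_get(dcm, "Rows"); cols <- dcm_get(dcm, "Columns")
  bits <- dcm_get(dcm, "BitsAllocated") %||% 16L
  raw_px <- dcm_get(dcm, "PixelData")
  bs_check(!is.null(rows) && !is.null(cols) && !is.null(raw_px),
           "unsupported_media", "DICOM file has no decodable pixel data")
  if (bits == 16L) {
    lo <- as.integer(raw_px[seq(1L, length(raw_px), by = 2L)])
    hi <- as.integer(raw_px[seq(2L, length(raw_px), by = 2L)])
    px <- lo + 256L * hi
  } else if (bits == 8L) {
    px <- as.integer(raw_px)
  } else {
    bs_abort("unsupported_media", sprintf("BitsAllocated %d not supported", bits))
  }
  matrix(px[seq_len(rows * cols)], nrow = rows, ncol = cols, byrow = TRUE)
}

#' Strip identifying elements from a DICOM file
#'
#' Removes every element on the denylist and every private (odd-group)
#' element, then re-serializes. Pixel data bytes are copied verbatim — the
#' stored image is untouched. Pixel spacing, rescale and image-geometry
#' elements are retained, since the measurement tools need them.
#'
#' @param payload raw DICOM bytes.
#' @param denylist element names to remove; defaults to
#'   [dicom_denylist_default()].
#' @return raw vector with the anonymized file.
#' @export
dcm_anonymize <- function(payload, denylist = dicom_denylist_default()) {
  dcm <- dcm_read(payload)
  el <- dcm$elements
  drop <- (!is.na(el$name) & el$name %in% denylist) |
          (el$group %% 2L == 1L) |                # private groups
          (el$element == 0x0000 & el$group != 0x0002)  # retired group lengths
  keep <- which(!drop)
  meta <- keep[el$group[keep] == 0x0002 & el$element[keep] != 0x0000]
  body_idx <- keep[el$group[keep] != 0x0002]
  enc <- function(i) {
    vr <- el$vr[i]
    head <- c(w16le(el$group[i]), w16le(el$element[i]), charToRaw(vr))
    v <- dcm$values[[i]]
    if (vr %in% LONG_LEN_VRS) c(head, as.raw(c(0L, 0L)), w32le(length(v)), v)
    else c(head, w16le(length(v)), v)
  }
  meta_body <- do.call(c, c(list(raw()), lapply(meta, enc)))
  body <- do.call(c, c(list(raw()), lapply(body_idx, enc)))
  c(as.raw(rep(0L, 128L)), charToRaw("DICM"),
    encode_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body, body)
}
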