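#' Detect the media kind of an uploaded payload
#'
#' Detection is by content signature, never by extension alone: PNG and JPEG
#' magic bytes, the `DICM` marker at offset 128 for DICOM Part 10, the MP4
#' `ftyp` box, and the zip local-file signature (a zip upload is a stack of
#' frames). The declared filename is consulted only as a tie-breaker for
#' payloads whose sniffing is ambiguous (none of the supported kinds are).
#'
#' @param payload raw vector of file bytes.
#' @param declared_name the filename the uploader supplied.
#' @return one of `"png"`, `"jpg"`, `"mp4"`, `"dicom"`, `"stack"`.
#' @export
detect_media <- function(payload, declared_name = "") {
  bs_check(is.raw(payload) && length(payload) > 0L, "validation", "payload is empty")
  starts_with <- function(sig) length(payload) >= length(sig) &&
    identical(payload[seq_along(sig)], as.raw(sig))
  if (starts_with(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))) return("png")
  if (starts_with(c(0xFF, 0xD8, 0xFF))) return("jpg")
  if (is_dicom(payload)) return("dicom")
  if (starts_with(c(0x50, 0x4B, 0x03, 0x04)) || starts_with(c(0x50, 0x4B, 0x05, 0x06)))
    return("stack")
  if (length(payload) >= 12L && rawToChar(payload[5:8]) == "ftyp") return("mp4")
  bs_abort("unsupported_media",
           sprintf("cannot identify media in upload '%s'", declared_name))
}

#' Expand a zip stack into ordered frames
#'
#' Entries are ordered by natural sort of their names (`img2` before
#' `img10`); entries that are not decodable images are skipped with a
#' warning. A zip with no supported entry at all is rejected.
#'
#' @param zip_payload raw bytes of a zip archive.
#' @return list of `list(name, payload, kind)` in presentation order.
#' @export
expand_stack <- function(zip_payload) {
  tmp <- tempfile(fileext = ".zip")
  on.exit(unlink(tmp), add = TRUE)
  writeBin(zip_payload, tmp)
  entries <- tryCatch(zip::zip_list(tmp)$filename,
                      error = function(e) bs_abort("unsupported_media", "not a valid zip archive"))
  entries <- entries[!grepl("/$", entries)]
  exdir <- tempfile("stack")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  zip::unzip(tmp, exdir = exdir)
  frames <- list()
  for (nm in natural_sort(entries)) {
    bytes <- readBin(file.path(exdir, nm), "raw", file.size(file.path(exdir, nm)))
    kind <- tryCatch(detect_media(bytes, nm), bs_unsupported_media_error = function(e) NA)
    if (is.na(kind) || kind %in% c("stack", "mp4")) {
      warning(sprintf("stack entry '%s' is not a supported image; skipped", nm))
      next
    }
    frames[[length(frames) + 1L]] <- list(name = nm, payload = bytes, kind = kind)
  }
  bs_check(length(frames) >= 1L, "unsupported_media",
           "zip stack contains no supported image entries")
  frames
}

# --- metadata stripping -----------------------------------------------------

# PNG: copy only structural/rendering chunks, dropping every text-capable
# chunk (tEXt/zTXt/iTXt/eXIf/tIME/iCCP/...). IDAT bytes pass through
# untouched, so decoded pixels are identical by construction.
PNG_CHUNK_ALLOW <- c("IHDR", "PLTE", "IDAT", "IEND", "tRNS", "gAMA", "sRGB",
                     "sBIT", "bKGD", "pHYs")

strip_png_metadata <- function(payload) {
  n <- length(payload)
  bs_check(n > 8L, "unsupported_media", "truncated PNG")
  out <- payload[1:8]
  pos <- 9L
  while (pos + 7L <= n) {
    len <- u32be(payload[pos:(pos + 3L)])
    type <- rawToChar(payload[(pos + 4L):(pos + 7L)])
    chunk_end <- pos + 12L + len - 1L
    bs_check(chunk_end <= n, "unsupported_media", "truncated PNG chunk")
    if (type %in% PNG_CHUNK_ALLOW) out <- c(out, payload[pos:chunk_end])
    if (type == "IEND") break
    pos <- chunk_end + 1L
  }
  out
}

u32be <- function(raw4) sum(as.numeric(raw4) * c(16777216, 65536, 256, 1))

# JPEG: drop APP1..APP15 (EXIF, XMP, ...) and COM segments; keep APP0/JFIF,
# tables and entropy-coded data verbatim.
strip_jpeg_metadata <- function(payload) {
  n <- length(payload)
  bs_check(n > 4L, "unsupported_media", "truncated JPEG")
  out <- payload[1:2]  # SOI
  pos <- 3L
  repeat {
    bs_check(pos + 3L <= n, "unsupported_media", "truncated JPEG segment")
    marker <- as.integer(payload[pos + 1L])
    seg_len <- u16be(payload[(pos + 2L):(pos + 3L)])
    seg_end <- pos + 1L + seg_len
    drop <- (marker >= 0xE1 && marker <= 0xEF) || marker == 0xFE
    if (marker == 0xDA) {  # SOS: rest of the stream is entropy-coded data
      out <- c(out, payload[pos:n])
      break
    }
    if (!drop) out <- c(out, payload[pos:seg_end])
    pos <- seg_end + 1L
  }
  out
}

u16be <- function(raw2) 256L * as.integer(raw2[1]) + as.integer(raw2[2])

#' Strip identifying metadata for the observer-facing view
#'
#' DICOM files go through [dcm_anonymize()]; PNG loses all text-capable
#' chunks; JPEG loses APPn (EXIF/XMP) and comment segments. Pixel bytes are
#' never re-encoded. MP4 payloads pass through unchanged (video is stored
#' and served only).
#'
#' @param payload raw media bytes.
#' @param kind media kind from [detect_media()].
#' @param denylist DICOM element denylist.
#' @return raw vector with the stripped payload.
#' @export
anonymize_media <- function(payload, kind, denylist = dicom_denylist_default()) {
  switch(kind,
    dicom = dcm_anonymize(payload, denylist),
    png = strip_png_metadata(payload),
    jpg = strip_jpeg_metadata(payload),
    payload)
}

#' Extract physical pixel spacing from a DICOM file
#'
#' Looks for `PixelSpacing` (preferred) or `ImagerPixelSpacing`. DICOM
#' stores spacing as (row spacing, column spacing) in mm.
#'
#' @param dicom_payload raw DICOM bytes.
#' @return `NULL` when no spacing element exists or it is malformed
#'   (malformed raises a warning); otherwise a list with `mm_per_px` (the
#'   isotropic value, or the row value when anisotropic), `row_mm`,
#'   `col_mm`, `anisotropic`, and `source_element`.
#' @export
extract_pixel_spacing <- function(dicom_payload) {
  dcm <- if (inherits(dicom_payload, "bs_dicom")) dicom_payload else dcm_read(dicom_payload)
  for (nm in c("PixelSpacing", "ImagerPixelSpacing")) {
    v <- tryCatch(dcm_get(dcm, nm), error = function(e) NULL)
    if (is.null(v)) next
    if (length(v) != 2L || any(!is.finite(v)) || any(v <= 0)) {
      warning(sprintf("malformed %s element; treated as absent", nm))
      return(NULL)
    }
    return(list(mm_per_px = v[1], row_mm = v[1], col_mm = v[2],
                anisotropic = !isTRUE(all.equal(v[1], v[2])), source_element = nm))
  }
  NULL
}

# --- frame decoding ---------------------------------------------------------

#' Decode a media payload into a pixel frame
#'
#' @param payload raw bytes of a single png/jpg/dicom frame.
#' @param kind media kind.
#' @return a `bs_frame`: `pixels` (rows x cols matrix for grayscale, or
#'   rows x cols x 3 array for RGB, values 0-255 for png/jpg or stored values
#'   for DICOM), plus `rescale_slope`/`rescale_intercept` for DICOM.
#' @export
decode_frame <- function(payload, kind) {
  if (kind == "png" || kind == "jpg") {
    img <- if (kind == "png") png::readPNG(payload) else jpeg::readJPEG(payload)
    if (length(dim(img)) == 3L && dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE]
    px <- round(img * 255)
    storage.mode(px) <- "integer"
    structure(list(pixels = px, kind = kind, value_units = "intensity"),
              class = "bs_frame")
  } else if (kind == "dicom") {
    dcm <- dcm_read(payload)
    slope <- dcm_get(dcm, "RescaleSlope")
    inter <- dcm_get(dcm, "RescaleIntercept")
    structure(list(pixels = dcm_pixels(dcm), kind = "dicom",
                   rescale_slope = if (is.null(slope)) NULL else slope[1],
                   rescale_intercept = if (is.null(inter)) NULL else inter[1],
                   value_units = "stored"),
              class = "bs_frame")
  } else {
    bs_abort("unsupported_media", sprintf("cannot decode '%s' into pixels", kind))
  }
}

#' @export
print.bs_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<bs_frame:", x$kind, "> ", d[2], "x", d[1],
      if (length(d) == 3L) " RGB" else " gray", "\n", sep = "")
  invisible(x)
}

# Render a frame to an 8-bit PNG for the browser viewer. DICOM stored values
# are window-normalized to the frame's own min/max.
render_frame_png <- function(frame) {
  px <- frame$pixels
  if (frame$kind == "dicom") {
    rng <- range(px)
    px <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  } else {
    px <- px / 255
  }
  png::writePNG(px)
}

frame_dims <- function(payload, kind) {
  if (kind == "png") {
    # IHDR starts at byte 17: width, height as 32-bit big endian.
    list(w = as.integer(u32be(payload[17:20])), h = as.integer(u32be(payload[21:24])))
  } else if (kind == "jpg") {
    d <- dim(jpeg::readJPEG(payload))
    list(w = d[2], h = d[1])
  } else if (kind == "dicom") {
    dcm <- dcm_read(payload)
    list(w = as.integer(dcm_get(dcm, "Columns")), h = as.integer(dcm_get(dcm, "Rows")))
  } else {
    list(w = 0L, h = 0L)
  }
}

#' Ingest an uploaded file into a project
#'
#' Runs the full intake pipeline: content-based kind detection, zip-stack
#' expansion, metadata stripping for the observer view, viewer-PNG
#' rendering, DICOM pixel-spacing extraction, and assignment of a fresh
#' opaque image id (random, never derived from name or content — the same
#' payload ingested twice gets two unrelated ids). The original payload and
#' filename are retained master-side only.
#'
#' @param store a `bs_store`.
#' @param project_id target project.
#' @param payload raw file bytes.
#' @param declared_name the uploaded filename (master-visible only).
#' @param data_group optional data-group label; must be one of the project's.
#' @return the new image record (one row, as in `get_project()$images`).
#' @export
ingest_image <- function(store, project_id, payload, declared_name,
                         data_group = NULL) {
  proj <- get_project(store, project_id)
  if (!is.null(data_group)) {
    bs_check(data_group %in% proj$data_groups, "validation",
             sprintf("'%s' is not a data group of this project", data_group))
  }
  kind <- detect_media(payload, declared_name)
  frames <- if (kind == "stack") expand_stack(payload)
            else list(list(name = declared_name, payload = payload, kind = kind))

  spacing <- NULL
  for (fr in frames) {
    if (fr$kind == "dicom" && is.null(spacing)) {
      spacing <- extract_pixel_spacing(fr$payload)
    }
  }
  first <- frames[[1L]]
  dims <- frame_dims(first$payload, first$kind)

  image_id <- new_id()
  DBI::dbWithTransaction(store$con, {
    pos <- DBI::dbGetQuery(store$con,
      "SELECT COALESCE(MAX(pos), 0) + 1 AS p FROM images WHERE project_id = ?",
      params = list(project_id))$p
    DBI::dbExecute(store$con,
      "INSERT INTO images (image_id, project_id, pos, original_name, media_kind,
         data_group, n_frames, width_px, height_px, spacing_row_mm, spacing_col_mm,
         spacing_source, original_blob) VALUES (?,?,?,?,?,?,?,?,?,?,?,?,?)",
      params = list(image_id, project_id, pos, declared_name, kind,
                    data_group %||% NA_character_, length(frames),
                    dims$w, dims$h,
                    if (is.null(spacing)) NA_real_ else spacing$row_mm,
                    if (is.null(spacing)) NA_real_ else spacing$col_mm,
                    if (is.null(spacing)) NA_character_ else "dicom_metadata",
                    list(payload)))
    for (i in seq_along(frames)) {
      fr <- frames[[i]]
      anon <- anonymize_media(fr$payload, fr$kind)
      rendered <- if (fr$kind %in% c("png", "jpg", "dicom")) {
        render_frame_png(decode_frame(anon, fr$kind))
      } else NULL
      DBI::dbExecute(store$con,
        "INSERT INTO frames (image_id, frame_index, media_kind, anon_blob, render_png)
         VALUES (?,?,?,?,?)",
        params = list(image_id, i, fr$kind, list(anon), list(rendered)))
    }
  })
  DBI::dbGetQuery(store$con,
    "SELECT image_id, original_name, media_kind, data_group, n_frames,
            width_px, height_px, spacing_row_mm, spacing_col_mm, spacing_source
     FROM images WHERE image_id = ?", params = list(image_id))
}

#' Set an image's pixel spacing from a master-side calibration
#'
#' @param store a `bs_store`.
#' @param image_id image to calibrate.
#' @param cal a [calibration()].
#' @return invisibly, the image id.
#' @export
set_image_calibration <- function(store, image_id, cal) {
  bs_check(inherits(cal, "bs_calibration"), "validation", "cal must be a bs_calibration")
  n <- DBI::dbExecute(store$con,
    "UPDATE images SET spacing_row_mm = ?, spacing_col_mm = ?, spacing_source = ?
     WHERE image_id = ?",
    params = list(cal$row_mm_per_px, cal$col_mm_per_px, cal$source, image_id))
  bs_check(n == 1L, "not_found", sprintf("no image '%s'", image_id))
  invisible(image_id)
}

#' Load a stored frame for measurement
#'
#' Decodes the observer-facing (anonymized) payload of one frame of an
#' ingested image.
#'
#' @param store a `bs_store`.
#' @param image_id image identifier.
#' @param frame_index 1-based frame number.
#' @return a `bs_frame` (see [decode_frame()]).
#' @export
load_frame <- function(store, image_id, frame_index = 1L) {
  row <- DBI::dbGetQuery(store$con,
    "SELECT media_kind, anon_blob FROM frames WHERE image_id = ? AND frame_index = ?",
    params = list(image_id, frame_index))
  bs_check(nrow(row) == 1L, "not_found",
           sprintf("no frame %d for image '%s'", frame_index, image_id))
  decode_frame(row$anon_blob[[1]], row$media_kind)
}

#' Assemble the observer-facing (anonymized) view of an image
#'
#' The view carries only what an observer may see: the opaque id, geometry,
#' frame count and pixel spacing. It never includes the original filename,
#' the data group, or any denylisted DICOM value.
#'
#' @param store a `bs_store`.
#' @param image_id image identifier.
#' @return a list (`image_id`, `width_px`, `height_px`, `n_frames`,
#'   `pixel_spacing_mm_per_px` possibly NULL).
#' @export
anonymized_view <- function(store, image_id) {
  row <- DBI::dbGetQuery(store$con,
    "SELECT image_id, n_frames, width_px, height_px, spacing_row_mm, spacing_col_mm
     FROM images WHERE image_id = ?", params = list(image_id))
  bs_check(nrow(row) == 1L, "not_found", sprintf("no image '%s'", image_id))
  list(image_id = row$image_id,
       width_px = row$width_px, height_px = row$height_px,
       n_frames = row$n_frames,
       pixel_spacing_mm_per_px = if (is.na(row$spacing_row_mm)) NULL else row$spacing_row_mm,
       pixel_spacing_col_mm_per_px = if (is.na(row$spacing_col_mm)) NULL else row$spacing_col_mm)
}
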