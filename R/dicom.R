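# Minimal DICOM series reader: single-frame, uncompressed, little-endian
# (implicit 1.2.840.10008.1.2 or explicit 1.2.840.10008.1.2.1 transfer
# syntax). Covers what a CT series directory needs — stored values, rescale
# slope/intercept, geometry tags — nothing more. Compressed transfer
# syntaxes, sequences with undefined length and multiframe objects are
# rejected with a format error.

DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_IMPLICIT_LE <- "1.2.840.10008.1.2"

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
dcm_u32 <- function(raw, pos) {
  # as double: lengths can exceed .Machine$integer.max/2 in theory
  sum(as.double(raw[pos:(pos + 3L)]) * 256^(0:3))
}
dcm_str <- function(raw, pos, len) {
  if (len == 0) return("")
  bytes <- raw[pos:(pos + len - 1L)]
  bytes <- bytes[bytes != as.raw(0L)]   # strip padding nulls
  trimws(rawToChar(bytes))
}

# VRs that use the 4-byte length form in explicit VR encoding
DCM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parse one data element starting at pos; returns list(group, elem, vr,
# value_pos, value_len, next_pos). vr is NA under implicit VR.
dcm_element <- function(raw, pos, explicit, file) {
  if (pos + 7L > length(raw))
    stop_format("DICOM %s: truncated element at byte %d", file, pos)
  group <- dcm_u16(raw, pos); elem <- dcm_u16(raw, pos + 2L)
  if (explicit) {
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% DCM_LONG_VRS) {
      len <- dcm_u32(raw, pos + 8L); vpos <- pos + 12L
    } else {
      len <- dcm_u16(raw, pos + 6L); vpos <- pos + 8L
    }
  } else {
    vr <- NA_character_
    len <- dcm_u32(raw, pos + 4L); vpos <- pos + 8L
  }
  if (len == 0xFFFFFFFF)
    stop_format("DICOM %s: undefined-length element (%04x,%04x) unsupported",
                file, group, elem)
  if (vpos + len - 1L > length(raw))
    stop_format("DICOM %s: element (%04x,%04x) overruns file", file, group, elem)
  list(group = group, elem = elem, vr = vr,
       value_pos = vpos, value_len = len, next_pos = vpos + len)
}

# Read one DICOM file; returns the tags the reader needs.
read_dicom_file <- function(file) {
  raw <- readBin(file, "raw", n = file.info(file)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop_format("DICOM %s: missing DICM magic (not a part-10 file)", file)
  pos <- 133L
  # file meta group (0002,xxxx) is always explicit VR little endian
  tsuid <- NULL
  meta_end <- NA
  e <- dcm_element(raw, pos, explicit = TRUE, file)
  if (e$group == 0x0002 && e$elem == 0x0000) {
    meta_end <- e$next_pos + dcm_u32(raw, e$value_pos)
    pos <- e$next_pos
  }
  while (pos <= length(raw)) {
    e <- dcm_element(raw, pos, explicit = TRUE, file)
    if (e$group != 0x0002) break
    if (e$elem == 0x0010) tsuid <- dcm_str(raw, e$value_pos, e$value_len)
    pos <- e$next_pos
    if (!is.na(meta_end) && pos >= meta_end) break
  }
  if (is.null(tsuid))
    stop_format("DICOM %s: no TransferSyntaxUID in file meta", file)
  explicit <- switch(tsuid,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2"   = FALSE,
    stop_format("DICOM %s: unsupported transfer syntax %s", file, tsuid))
  tags <- list()
  while (pos < length(raw)) {
    e <- dcm_element(raw, pos, explicit = explicit, file)
    key <- sprintf("%04x,%04x", e$group, e$elem)
    tags[[key]] <- e
    pos <- e$next_pos
  }
  get_str <- function(key) {
    e <- tags[[key]]
    if (is.null(e)) NULL else dcm_str(raw, e$value_pos, e$value_len)
  }
  get_u16 <- function(key) {
    e <- tags[[key]]
    if (is.null(e)) NULL else dcm_u16(raw, e$value_pos)
  }
  need <- function(x, what) {
    if (is.null(x) || (is.character(x) && !nzchar(x)))
      stop_format("DICOM %s: missing required tag: %s", file, what)
    x
  }
  rows <- need(get_u16("0028,0010"), "Rows (0028,0010)")
  cols <- need(get_u16("0028,0011"), "Columns (0028,0011)")
  bits <- need(get_u16("0028,0100"), "BitsAllocated (0028,0100)")
  if (bits != 16L)
    stop_format("DICOM %s: only 16-bit pixel data supported (BitsAllocated=%d)",
                file, bits)
  pixrep <- get_u16("0028,0103"); if (is.null(pixrep)) pixrep <- 0L
  slope <- need(get_str("0028,1053"), "RescaleSlope (0028,1053)")
  intercept <- need(get_str("0028,1052"), "RescaleIntercept (0028,1052)")
  series <- need(get_str("0020,000e"), "SeriesInstanceUID (0020,000E)")
  ipp <- get_str("0020,0032")
  ipp_z <- if (is.null(ipp)) NA_real_ else {
    parts <- as.numeric(strsplit(ipp, "\\\\")[[1]])
    if (length(parts) != 3L || anyNA(parts))
      stop_format("DICOM %s: malformed ImagePositionPatient '%s'", file, ipp)
    parts[3]
  }
  psp <- get_str("0028,0030")
  pixel_spacing <- if (is.null(psp)) c(1, 1) else {
    v <- as.numeric(strsplit(psp, "\\\\")[[1]])
    if (length(v) != 2L || anyNA(v)) c(1, 1) else v
  }
  thick <- suppressWarnings(as.numeric(get_str("0018,0050")))
  pe <- tags[["7fe0,0010"]]
  if (is.null(pe)) stop_format("DICOM %s: no PixelData (7FE0,0010)", file)
  n_px <- rows * cols
  if (pe$value_len < 2 * n_px)
    stop_format("DICOM %s: PixelData too short for %dx%d", file, rows, cols)
  stored <- readBin(raw[pe$value_pos:(pe$value_pos + 2L * n_px - 1L)],
                    "integer", n = n_px, size = 2L,
                    signed = (pixrep == 1L), endian = "little")
  # PixelData is row-major (row after row)
  pixels <- matrix(stored, nrow = rows, ncol = cols, byrow = TRUE)
  list(file = file, series_uid = series, ipp_z = ipp_z,
       rows = rows, cols = cols,
       slope = as.numeric(slope), intercept = as.numeric(intercept),
       pixel_spacing = pixel_spacing,
       slice_thickness = if (length(thick) == 1 && !is.na(thick)) thick else NA_real_,
       pixels = pixels)
}

read_dicom_dir <- function(path) {
  if (!dir.exists(path))
    stop_input("read_volume: not a directory: %s", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop_input("read_volume: empty DICOM directory: %s", path)
  slices <- lapply(sort(files), read_dicom_file)
  uids <- vapply(slices, `[[`, "", "series_uid")
  if (length(unique(uids)) > 1L) {
    bad <- slices[[which(uids != uids[1])[1]]]$file
    stop_format("read_volume: mixed SeriesInstanceUIDs in %s (e.g. %s)",
                path, bad)
  }
  shp <- vapply(slices, function(s) c(s$rows, s$cols), integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
    bad <- slices[[which(shp[1, ] != shp[1, 1] | shp[2, ] != shp[2, 1])[1]]]$file
    stop_format("read_volume: inconsistent slice shapes in %s (e.g. %s)",
                path, bad)
  }
  z <- vapply(slices, `[[`, 0, "ipp_z")
  ord <- if (anyNA(z)) seq_along(slices) else order(z)
  slices <- slices[ord]
  z <- z[ord]
  vox <- array(0, dim = c(length(slices), slices[[1]]$rows, slices[[1]]$cols))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    vox[i, , ] <- s$pixels * s$slope + s$intercept
  }
  dz <- if (length(z) >= 2L && !anyNA(z)) {
    d <- diff(z)
    if (all(d > 0)) mean(d) else NA_real_
  } else NA_real_
  if (is.na(dz)) dz <- slices[[1]]$slice_thickness
  if (is.na(dz) || dz <= 0) dz <- 1
  ct_volume(vox,
            spacing = c(dz, slices[[1]]$pixel_spacing),
            origin_note = paste0("dicom:", path))
}
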