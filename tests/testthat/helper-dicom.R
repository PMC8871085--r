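# Writes minimal explicit-VR little-endian DICOM files for fixtures.
# Generated programmatically at test time; nothing binary ships in the repo.

dcm_pad <- function(s, pad = " ") {
  if (nchar(s) %% 2 == 1) paste0(s, pad) else s
}

write_test_dicom <- function(path, stored, slope = 1, intercept = -1024,
                             series_uid = "1.2.3.4", ipp = c(0, 0, 0),
                             pixel_spacing = c(0.5, 0.5),
                             slice_thickness = 1,
                             pixel_representation = 0L,
                             omit = character()) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wstr <- function(s) writeBin(charToRaw(s), con)
  short_el <- function(group, elem, vr, value_raw) {
    w16(group); w16(elem); wstr(vr); w16(length(value_raw))
    writeBin(value_raw, con)
  }
  str_el <- function(group, elem, vr, s, pad = " ")
    short_el(group, elem, vr, charToRaw(dcm_pad(s, pad)))
  us_el <- function(group, elem, x)
    short_el(group, elem, "US",
             writeBin(as.integer(x), raw(), size = 2, endian = "little"))
  # preamble + magic
  writeBin(raw(128), con); wstr("DICM")
  # file meta: group length + transfer syntax (explicit VR LE)
  ts <- dcm_pad("1.2.840.10008.1.2.1", " ")
  ts_el_len <- 8L + nchar(ts)
  short_el(0x0002, 0x0000, "UL",
           writeBin(as.integer(ts_el_len), raw(), size = 4, endian = "little"))
  str_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1", " ")
  # dataset, ascending tag order
  str_el(0x0018, 0x0050, "DS", format(slice_thickness))
  str_el(0x0020, 0x000E, "UI", series_uid, " ")
  str_el(0x0020, 0x0032, "DS", paste(ipp, collapse = "\\"))
  us_el(0x0028, 0x0010, nrow(stored))
  us_el(0x0028, 0x0011, ncol(stored))
  str_el(0x0028, 0x0030, "DS", paste(pixel_spacing, collapse = "\\"))
  us_el(0x0028, 0x0100, 16L)
  us_el(0x0028, 0x0101, 16L)
  us_el(0x0028, 0x0102, 15L)
  us_el(0x0028, 0x0103, pixel_representation)
  if (!"intercept" %in% omit) str_el(0x0028, 0x1052, "DS", format(intercept))
  if (!"slope" %in% omit) str_el(0x0028, 0x1053, "DS", format(slope))
  # pixel data: OW, 4-byte length form, row-major
  w16(0x7FE0); w16(0x0010); wstr("OW"); w16(0)
  w32(2L * length(stored))
  writeBin(as.integer(as.vector(t(stored))), con, size = 2, endian = "little")
  invisible(path)
}

# a small DICOM series directory; z positions deliberately written shuffled
write_test_series <- function(dir, slices, zs = seq_along(slices), ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ord <- rev(seq_along(slices))  # file order != z order
  for (i in ord)
    write_test_dicom(file.path(dir, sprintf("img%03d.dcm", i)),
                     slices[[i]], ipp = c(0, 0, zs[i]), ...)
  dir
}
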