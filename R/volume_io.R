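#' CT volume container
#'
#' A `ct_volume` holds a 3D scalar field in Hounsfield units together with its
#' voxel spacing. Axes are ordered (slice, row, column): `voxels[i, , ]` is the
#' i-th axial slice. All indices in the package are 1-based.
#'
#' @param voxels 3D numeric array of HU values, dimensions
#'   (slices, rows, columns). All values must be finite.
#' @param spacing numeric length-3 vector, (slice_mm, row_mm, col_mm), all > 0.
#' @param origin_note free-text provenance string.
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `origin_note`.
#' @examples
#' vol <- ct_volume(array(35, dim = c(4, 8, 8)), spacing = c(1, 0.5, 0.5))
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin_note = "") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop_input("ct_volume: voxels must be a 3D array, got %d dims",
               length(dim(voxels)))
  if (!is.numeric(voxels) || anyNA(voxels) || any(!is.finite(voxels)))
    stop_input("ct_volume: voxels must be finite numeric (no NaN/Inf)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_input("ct_volume: spacing must be 3 positive reals")
  structure(list(voxels = voxels, spacing = spacing,
                 origin_note = as.character(origin_note)[1]),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d slices x %d rows x %d cols, spacing %s mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  if (nzchar(x$origin_note)) cat("  origin: ", x$origin_note, "\n", sep = "")
  invisible(x)
}

#' Read a CT volume from NIfTI or a DICOM series directory
#'
#' NIfTI voxel values are taken as already being in HU (beyond the format's
#' own scl slope/intercept, which the reader applies); the first array axis is
#' treated as the slice axis in file order. For a DICOM directory, every file
#' must belong to one series, slices are sorted by ascending patient-z
#' (ImagePositionPatient), and stored values are rescaled to
#' HU = stored * RescaleSlope + RescaleIntercept.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom_dir"`.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = c("nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_input("read_volume: path does not exist: %s", path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    vox <- as.array(img)
    if (length(dim(vox)) == 4L && dim(vox)[4] == 1L)
      vox <- array(vox, dim = dim(vox)[1:3])
    if (length(dim(vox)) != 3L)
      stop_format("read_volume: %s is not a 3D volume", path)
    sp <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
    ct_volume(vox, spacing = sp, origin_note = paste0("nifti:", path))
  } else {
    read_dicom_dir(path)
  }
}

#' Write a CT volume to NIfTI
#'
#' Values are stored as 32-bit float, which represents integer HU exactly, so
#' `write_volume` then [read_volume()] round-trips integer phantoms
#' voxel-identically.
#'
#' @param vol a [ct_volume()].
#' @param path output `.nii` or `.nii.gz` path; the parent directory must
#'   exist and be writable.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_io("write_volume: directory does not exist: %s", dir)
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = "float")
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop_io("write_volume: could not write %s", path)
  invisible(path)
}

#' Extract one axial slice from a volume
#'
#' @param vol a [ct_volume()].
#' @param index 1-based slice index.
#' @return A `slice_image`: list with `pixels` (rows x cols HU matrix) and
#'   `slice_index`.
#' @export
extract_slice <- function(vol, index) {
  stopifnot(inherits(vol, "ct_volume"))
  n <- dim(vol$voxels)[1]
  if (!is.numeric(index) || length(index) != 1L || index != round(index) ||
      index < 1L || index > n)
    stop_input("extract_slice: index %s out of range [1, %d]",
               format(index), n)
  structure(list(pixels = vol$voxels[index, , ], slice_index = as.integer(index)),
            class = "slice_image")
}

slice_image <- function(pixels, slice_index = 1L) {
  structure(list(pixels = as.matrix(pixels), slice_index = as.integer(slice_index)),
            class = "slice_image")
}

# Accept either a slice_image or a bare matrix wherever a slice is expected.
as_slice_pixels <- function(slice) {
  if (inherits(slice, "slice_image")) slice$pixels
  else if (is.matrix(slice)) slice
  else stop_input("expected a slice_image or matrix")
}

#' Read or write a binary mask volume as NIfTI
#'
#' Masks are stored with values {0, 1}. Any nonzero voxel reads back as TRUE.
#'
#' @param mask logical array (2D or 3D).
#' @param path NIfTI path.
#' @return `read_mask` returns a logical array; `write_mask` returns the path
#'   invisibly.
#' @export
write_mask <- function(mask, path) {
  write_volume(ct_volume(array(as.double(mask), dim = dim(mask)),
                         origin_note = "mask"), path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  vol <- read_volume(path, "nifti")
  array(vol$voxels != 0, dim = dim(vol$voxels))
}
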