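#' Pipeline configuration
#'
#' Collects every tunable of the metal-preserving BS-CTA method.
#'
#' @param threshold_hu global metal threshold on the non-contrast slice
#'   (default 3500 HU).
#' @param alpha ROI enlargement factor (default 1.5).
#' @param center_mode `"midpoint"` or `"half_extent"` (see
#'   [component_center()]).
#' @param roi_mode `"per_component"` (one ROI per connected component,
#'   default) or `"global"` (one ROI around all supra-threshold pixels).
#' @param connectivity 8 (default) or 4.
#' @param otsu_bins histogram bins for ROI thresholding (default 256).
#' @param merge_mode `"replace_noncontrast"` (default; masked voxels take the
#'   non-contrast value — the metal's own image information) or `"max_union"`
#'   (masked voxels take `max(subtracted, non-contrast)`).
#' @param degenerate_fallback see [segment_metal()].
#' @param slice_range optional inclusive `(first, last)` slice interval to
#'   process; `NULL` (default) processes every slice.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_hu = 3500, alpha = 1.5,
                            center_mode = c("midpoint", "half_extent"),
                            roi_mode = c("per_component", "global"),
                            connectivity = 8, otsu_bins = 256,
                            merge_mode = c("replace_noncontrast", "max_union"),
                            degenerate_fallback = c("global_threshold", "skip"),
                            slice_range = NULL) {
  if (!is.finite(threshold_hu)) stop_input("pipeline_config: threshold_hu must be finite")
  if (alpha <= 0) stop_input("pipeline_config: alpha must be > 0")
  if (otsu_bins < 2) stop_input("pipeline_config: otsu_bins must be >= 2")
  if (!is.null(slice_range)) {
    slice_range <- as.integer(slice_range)
    if (length(slice_range) != 2L || slice_range[1] > slice_range[2])
      stop_input("pipeline_config: slice_range must be (first, last)")
  }
  structure(list(threshold_hu = threshold_hu, alpha = alpha,
                 center_mode = match.arg(center_mode),
                 roi_mode = match.arg(roi_mode),
                 connectivity = as.integer(connectivity),
                 otsu_bins = as.integer(otsu_bins),
                 merge_mode = match.arg(merge_mode),
                 degenerate_fallback = match.arg(degenerate_fallback),
                 slice_range = slice_range),
            class = "pipeline_config")
}

#' Subtract the non-contrast volume from the contrast volume
#'
#' Plain BS-CTA: the voxelwise signed difference `contrast - noncontrast`,
#' with no clamping. Inputs are assumed co-registered; a shape or spacing
#' mismatch raises a registration-assumption error rather than resampling.
#'
#' @param contrast,noncontrast [ct_volume()] pair.
#' @return A [ct_volume()] of differences.
#' @export
subtract_volumes <- function(contrast, noncontrast) {
  stopifnot(inherits(contrast, "ct_volume"), inherits(noncontrast, "ct_volume"))
  if (!identical(dim(contrast$voxels), dim(noncontrast$voxels)))
    stop_registration(
      "subtract_volumes: shape mismatch (%s vs %s); inputs must be co-registered",
      paste(dim(contrast$voxels), collapse = "x"),
      paste(dim(noncontrast$voxels), collapse = "x"))
  if (max(abs(contrast$spacing - noncontrast$spacing)) > 1e-6)
    stop_registration(
      "subtract_volumes: spacing mismatch; inputs must be co-registered")
  ct_volume(contrast$voxels - noncontrast$voxels,
            spacing = contrast$spacing, origin_note = "bscta:subtraction")
}

#' Re-incorporate metal voxels into a subtracted slice
#'
#' Subtraction removes implants because they appear in both scans; this puts
#' them back. `replace_noncontrast` sets masked pixels to the non-contrast
#' value (the implant's own image information, incorporated without further
#' blending); `max_union` sets them to the larger of the subtracted and
#' non-contrast values. Unmasked pixels are untouched.
#'
#' @param bs_slice subtracted slice (matrix or `slice_image`).
#' @param nc_slice matching non-contrast slice.
#' @param metal logical mask of the same shape.
#' @param mode `"replace_noncontrast"` or `"max_union"`.
#' @return HU matrix.
#' @export
preserve_metal <- function(bs_slice, nc_slice, metal,
                           mode = c("replace_noncontrast", "max_union")) {
  mode <- match.arg(mode)
  bs <- as_slice_pixels(bs_slice)
  nc <- as_slice_pixels(nc_slice)
  if (!all(dim(bs) == dim(nc)) || !all(dim(bs) == dim(metal)))
    stop_input("preserve_metal: shape mismatch")
  out <- bs
  if (mode == "replace_noncontrast") out[metal] <- nc[metal]
  else out[metal] <- pmax(bs[metal], nc[metal])
  out
}

#' Run the metal-preserving BS-CTA pipeline
#'
#' For each slice: threshold the *non-contrast* slice at the global metal
#' threshold (metal is detected on the non-contrast scan, where
#' contrast-filled vessels cannot be confused with implants), label connected
#' components, build an ROI per component, re-threshold each ROI by Otsu's
#' method, and write the resulting metal voxels back into the subtracted
#' slice. Slices with no supra-threshold pixel pass through as plain
#' subtraction.
#'
#' @param noncontrast,contrast co-registered [ct_volume()] pair.
#' @param cfg a [pipeline_config()].
#' @return List of class `pipeline_result`:
#'   \describe{
#'     \item{bscta}{[ct_volume()], subtraction with metal re-incorporated.}
#'     \item{metal_mask}{3D logical array of preserved voxels.}
#'     \item{per_slice_log}{data.frame (slice, n_components, n_metal_pixels).}
#'   }
#' @export
run_pipeline <- function(noncontrast, contrast, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  bs <- subtract_volumes(contrast, noncontrast)
  dims <- dim(bs$voxels)
  metal_mask <- array(FALSE, dim = dims)
  out <- bs$voxels
  slices <- if (is.null(cfg$slice_range)) seq_len(dims[1])
            else max(1L, cfg$slice_range[1]):min(dims[1], cfg$slice_range[2])
  log_rows <- vector("list", length(slices))
  for (j in seq_along(slices)) {
    i <- slices[j]
    nc_px <- noncontrast$voxels[i, , ]
    cand <- threshold_metal(nc_px, cfg$threshold_hu)
    n_comp <- 0L; n_metal <- 0L
    if (any(cand)) {
      sr <- slice_rois(cand, connectivity = cfg$connectivity,
                       alpha = cfg$alpha, center_mode = cfg$center_mode,
                       roi_mode = cfg$roi_mode)
      n_comp <- nrow(sr$components)
      metal <- segment_metal(nc_px, sr$rois, n_bins = cfg$otsu_bins,
                             degenerate_fallback = cfg$degenerate_fallback,
                             threshold_hu = cfg$threshold_hu)
      n_metal <- sum(metal)
      if (n_metal > 0L) {
        out[i, , ] <- preserve_metal(out[i, , ], nc_px, metal, cfg$merge_mode)
        metal_mask[i, , ] <- metal
      }
    }
    log_rows[[j]] <- data.frame(slice = i, n_components = n_comp,
                                n_metal_pixels = n_metal)
  }
  structure(list(
    bscta = ct_volume(out, spacing = bs$spacing,
                      origin_note = "bscta:metal-preserved"),
    metal_mask = metal_mask,
    per_slice_log = do.call(rbind, log_rows)),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  d <- dim(x$bscta$voxels)
  n_slices_with_metal <- sum(x$per_slice_log$n_metal_pixels > 0)
  cat(sprintf("pipeline_result: %dx%dx%d volume, %d metal voxels on %d slice(s)\n",
              d[1], d[2], d[3], sum(x$metal_mask), n_slices_with_metal))
  invisible(x)
}

#' Maximum-intensity projection
#'
#' Per-pixel maximum along one axis; a cheap preview standing in for full 3D
#' vessel rendering.
#'
#' @param vol a [ct_volume()] or 3D array.
#' @param axis 1 (slice axis, default), 2 or 3.
#' @return Numeric matrix of maxima.
#' @export
mip_preview <- function(vol, axis = 1) {
  v <- if (inherits(vol, "ct_volume")) vol$voxels else as.array(vol)
  if (length(dim(v)) != 3L) stop_input("mip_preview: need a 3D volume")
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop_input("mip_preview: axis must be 1, 2 or 3")
  apply(v, setdiff(1:3, axis), max)
}
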