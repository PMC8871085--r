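#' Intensity histogram of ROI pixels
#'
#' Equal-width bins spanning the pixels' [min, max] HU range; maximum-valued
#' pixels fall in the last bin. Class probabilities sum to 1.
#'
#' @param roi_pixels numeric HU values (any shape; flattened).
#' @param n_bins number of bins, >= 2; default 256 (the 8-bit convention of
#'   common reference implementations, applied directly to HU).
#' @return List of class `intensity_histogram` with `probs` (length
#'   `n_bins`), `edges` (length `n_bins + 1`, strictly increasing) and `L`.
#' @export
build_histogram <- function(roi_pixels, n_bins = 256) {
  x <- as.numeric(roi_pixels)
  if (length(x) == 0L) stop_input("build_histogram: empty ROI")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop_input("build_histogram: n_bins must be >= 2")
  mn <- min(x); mx <- max(x)
  if (mx == mn)
    stop_degenerate("build_histogram: constant ROI (all pixels %.6g HU)", mn)
  bin <- pmin(n_bins, floor((x - mn) / (mx - mn) * n_bins) + 1L)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(probs = counts / length(x),
                 edges = seq(mn, mx, length.out = n_bins + 1L),
                 L = n_bins),
            class = "intensity_histogram")
}

#' Otsu threshold selection by between-class variance
#'
#' Scans every candidate split k (foreground = bins above k) and selects the
#' k maximizing the between-class variance
#' \deqn{\sigma_{BC}^2(k) = \frac{(m_G P(k) - m(k))^2}{P(k)\,(1 - P(k))},}
#' where \eqn{P(k)} is the cumulative class probability through bin k,
#' \eqn{m(k)} the cumulative first moment and \eqn{m_G} the global mean
#' intensity level. Splits with \eqn{P(k) \in \{0, 1\}} are skipped (the
#' ratio is undefined there); plateaus are broken toward the smallest k.
#'
#' @param hist an `intensity_histogram` from [build_histogram()].
#' @return List of class `otsu_result`: `k_star` (selected bin index),
#'   `threshold_hu` (upper edge of bin `k_star`), `sigma_bc2`, `m_g`.
#' @export
otsu_threshold <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  p <- hist$probs
  L <- hist$L
  if (sum(p > 0) < 2L)
    stop_degenerate("otsu_threshold: fewer than two occupied bins")
  i <- seq_len(L)                       # intensity levels (affine-invariant)
  P <- cumsum(p)
  m <- cumsum(p * i)
  m_g <- m[L]
  k <- seq_len(L - 1L)
  Pk <- P[k]
  valid <- Pk > 0 & Pk < 1
  sigma <- rep(-Inf, L - 1L)
  sigma[valid] <- (m_g * Pk[valid] - m[k][valid])^2 /
    (Pk[valid] * (1 - Pk[valid]))
  k_star <- which.max(sigma)            # first max = smallest k on plateaus
  structure(list(k_star = as.integer(k_star),
                 threshold_hu = hist$edges[k_star + 1L],
                 sigma_bc2 = sigma[k_star],
                 m_g = m_g),
            class = "otsu_result")
}

#' Binarize a slice inside an ROI at a chosen threshold
#'
#' Pixels strictly above `result$threshold_hu` and inside `roi` are TRUE;
#' everything outside the ROI is FALSE.
#'
#' @param slice a `slice_image` or HU matrix.
#' @param roi an [roi_box()].
#' @param result an `otsu_result` (or any list with `threshold_hu`).
#' @return Logical matrix of the slice's shape.
#' @export
binarize_roi <- function(slice, roi, result) {
  px <- as_slice_pixels(slice)
  if (roi$r_lo < 1L || roi$c_lo < 1L ||
      roi$r_hi > nrow(px) || roi$c_hi > ncol(px))
    stop_input("binarize_roi: roi outside frame")
  mask <- matrix(FALSE, nrow(px), ncol(px))
  rr <- roi$r_lo:roi$r_hi
  cc <- roi$c_lo:roi$c_hi
  mask[rr, cc] <- px[rr, cc] > result$threshold_hu
  mask
}

#' Segment metal inside a set of ROIs by per-ROI Otsu thresholding
#'
#' Each ROI is binarized at its own Otsu threshold and the per-ROI masks are
#' unioned. A degenerate (constant-intensity) ROI cannot be Otsu-thresholded;
#' per `degenerate_fallback`, it is either binarized at the global metal
#' threshold (`"global_threshold"`, default — a constant ROI makes histogram
#' splitting moot but the slice must not abort) or skipped (`"skip"`).
#'
#' @param slice a `slice_image` or HU matrix.
#' @param rois list of [roi_box()] objects (may be empty).
#' @param n_bins histogram bins; default 256.
#' @param degenerate_fallback `"global_threshold"` or `"skip"`.
#' @param threshold_hu global threshold used by the fallback; default 3500.
#' @return Logical matrix: union of per-ROI metal masks (all-FALSE when
#'   `rois` is empty).
#' @export
segment_metal <- function(slice, rois, n_bins = 256,
                          degenerate_fallback = c("global_threshold", "skip"),
                          threshold_hu = 3500) {
  degenerate_fallback <- match.arg(degenerate_fallback)
  px <- as_slice_pixels(slice)
  mask <- matrix(FALSE, nrow(px), ncol(px))
  for (roi in rois) {
    roi_px <- px[roi$r_lo:roi$r_hi, roi$c_lo:roi$c_hi]
    res <- tryCatch(
      otsu_threshold(build_histogram(roi_px, n_bins)),
      clipkeep_degenerate_histogram_error = function(e) NULL)
    if (is.null(res)) {
      if (degenerate_fallback == "skip") next
      res <- list(threshold_hu = threshold_hu)
    }
    mask <- mask | binarize_roi(px, roi, res)
  }
  mask
}
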