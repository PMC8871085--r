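#' Threshold a slice for candidate metal pixels
#'
#' Marks every pixel strictly above `threshold_hu`. Clips and coils (titanium
#' or cobalt alloys) sit well above skull bone on the HU scale, so a single
#' global threshold separates them; 3500 HU is the default.
#'
#' @param slice a `slice_image` or bare HU matrix.
#' @param threshold_hu global HU threshold; default 3500.
#' @return Logical matrix of the slice's shape. An all-FALSE mask simply means
#'   no metal on this slice, not an error.
#' @examples
#' m <- matrix(35, 8, 8); m[3, 4] <- 4000
#' sum(threshold_metal(m))
#' @export
threshold_metal <- function(slice, threshold_hu = 3500) {
  px <- as_slice_pixels(slice)
  if (!is.finite(threshold_hu))
    stop_input("threshold_metal: threshold_hu must be finite")
  px > threshold_hu
}

# Sparse BFS connected-component labelling over the TRUE pixels of a logical
# matrix. Returns an integer vector of labels parallel to which(mask).
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  labels <- integer(length(idx))
  if (length(idx) == 0L) return(list(idx = idx, labels = labels))
  pos <- integer(nr * nc)       # map linear index -> rank in idx (0 = bg)
  pos[idx] <- seq_along(idx)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L,  0L, 0L,  1L, 1L, 1L)
    dc <- c(-1L,  0L,  1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L,  0L, 0L)
    dc <- c( 0L, 0L, -1L, 1L)
  }
  lab <- 0L
  for (seed in seq_along(idx)) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    queue <- idx[seed]
    labels[seed] <- lab
    while (length(queue) > 0L) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      nbr_r <- r + dr; nbr_c <- cc + dc
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      nb <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
      ranks <- pos[nb]
      ranks <- ranks[ranks != 0L]
      new <- ranks[labels[ranks] == 0L]
      if (length(new) > 0L) {
        labels[new] <- lab
        queue <- c(queue, idx[new])
      }
    }
  }
  list(idx = idx, labels = labels)
}

#' Connected components of a binary mask with bounding boxes
#'
#' Labels the TRUE pixels of a 2D mask (8- or 4-connectivity) and returns one
#' record per component with its exact inclusive bounding box and pixel count,
#' sorted by descending pixel count (ties by row then column of the box's
#' upper-left corner).
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return A data.frame with columns `r_min`, `r_max`, `c_min`, `c_max`,
#'   `n_pixels` (one row per component; zero rows for an empty mask).
#' @export
extract_components <- function(mask, connectivity = 8) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop_input("extract_components: mask must be a logical matrix")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop_input("extract_components: connectivity must be 4 or 8")
  lab <- label_components(mask, connectivity)
  if (length(lab$idx) == 0L)
    return(data.frame(r_min = integer(0), r_max = integer(0),
                      c_min = integer(0), c_max = integer(0),
                      n_pixels = integer(0)))
  nr <- nrow(mask)
  rows <- ((lab$idx - 1L) %% nr) + 1L
  cols <- ((lab$idx - 1L) %/% nr) + 1L
  comp <- data.frame(
    r_min = as.integer(tapply(rows, lab$labels, min)),
    r_max = as.integer(tapply(rows, lab$labels, max)),
    c_min = as.integer(tapply(cols, lab$labels, min)),
    c_max = as.integer(tapply(cols, lab$labels, max)),
    n_pixels = as.integer(tapply(rows, lab$labels, length)))
  comp[order(-comp$n_pixels, comp$r_min, comp$c_min), , drop = FALSE]
}

# round half away from zero (nonnegative coordinates in practice)
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Center coordinate of a detected component
#'
#' The default `midpoint` mode returns the midpoint of the inclusive bounding
#' box, `((r_min + r_max)/2, (c_min + c_max)/2)`, rounded half away from zero
#' — the only reading under which an ROI built around the "center" encloses
#' the component. `half_extent` mode evaluates the half-extent form
#' `((r_max − r_min)/2, (c_max − c_min)/2)` instead — not a location, but
#' retained for auditability of the center definition.
#'
#' @param comp one-row data.frame (or list) with `r_min`, `r_max`, `c_min`,
#'   `c_max`.
#' @param mode `"midpoint"` (default) or `"half_extent"`.
#' @return Numeric length-2 vector `(cc_row, cc_col)`.
#' @export
component_center <- function(comp, mode = c("midpoint", "half_extent")) {
  mode <- match.arg(mode)
  if (comp$r_min > comp$r_max || comp$c_min > comp$c_max)
    stop_input("component_center: invalid bounds")
  if (mode == "midpoint") {
    c(cc_row = round_half_away((comp$r_min + comp$r_max) / 2),
      cc_col = round_half_away((comp$c_min + comp$c_max) / 2))
  } else {
    c(cc_row = (comp$r_max - comp$r_min) / 2,
      cc_col = (comp$c_max - comp$c_min) / 2)
  }
}

#' Build a rectangular ROI around a component center
#'
#' Half-extents are `ceiling(alpha * (r_max - cc_row))` rows and
#' `ceiling(alpha * (c_max - cc_col))` columns, each floored at 1 pixel, so
#' the full ROI spans `2*alpha*(r_max - cc_row)` by `2*alpha*(c_max - cc_col)`
#' around the center; `alpha >= 1` with midpoint centers guarantees the ROI
#' contains the component's bounding box. Bounds are clipped to the frame.
#'
#' @param comp component record (bounding box), as from
#'   [extract_components()].
#' @param center `(cc_row, cc_col)` from [component_center()].
#' @param alpha positive enlargement factor; default 1.5.
#' @param frame `(rows, cols)` of the slice.
#' @return List with inclusive 1-based bounds `r_lo`, `r_hi`, `c_lo`, `c_hi`
#'   and `alpha`, of class `roi_box`.
#' @export
roi_box <- function(comp, center, alpha = 1.5, frame) {
  if (alpha <= 0) stop_input("roi_box: alpha must be > 0")
  frame <- as.integer(frame)
  if (length(frame) != 2L || any(frame < 1L))
    stop_input("roi_box: degenerate frame")
  # distance from the center to the farther box bound: with a midpoint center
  # this is (extent-1)/2 up to rounding, and taking the max of both sides
  # keeps the whole bounding box inside the ROI for alpha >= 1 even when the
  # rounded center sits off the exact midpoint (even extents)
  h_r <- max(1L, as.integer(ceiling(alpha * max(comp$r_max - center[[1]],
                                                center[[1]] - comp$r_min))))
  h_c <- max(1L, as.integer(ceiling(alpha * max(comp$c_max - center[[2]],
                                                center[[2]] - comp$c_min))))
  structure(list(
    r_lo = max(1L, as.integer(round_half_away(center[[1]])) - h_r),
    r_hi = min(frame[1], as.integer(round_half_away(center[[1]])) + h_r),
    c_lo = max(1L, as.integer(round_half_away(center[[2]])) - h_c),
    c_hi = min(frame[2], as.integer(round_half_away(center[[2]])) + h_c),
    alpha = alpha), class = "roi_box")
}

# All ROIs for one slice mask under the configured mode.
slice_rois <- function(mask, connectivity = 8, alpha = 1.5,
                       center_mode = "midpoint",
                       roi_mode = c("per_component", "global")) {
  roi_mode <- match.arg(roi_mode)
  comps <- extract_components(mask, connectivity)
  if (nrow(comps) == 0L) return(list(rois = list(), components = comps))
  frame <- dim(mask)
  if (roi_mode == "global") {
    box <- data.frame(r_min = min(comps$r_min), r_max = max(comps$r_max),
                      c_min = min(comps$c_min), c_max = max(comps$c_max),
                      n_pixels = sum(comps$n_pixels))
    ctr <- component_center(box, center_mode)
    return(list(rois = list(roi_box(box, ctr, alpha, frame)),
                components = comps))
  }
  rois <- lapply(seq_len(nrow(comps)), function(i) {
    comp <- comps[i, ]
    roi_box(comp, component_center(comp, center_mode), alpha, frame)
  })
  list(rois = rois, components = comps)
}
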