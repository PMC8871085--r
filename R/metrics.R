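#' Dice similarity coefficient
#'
#' `DSC(X, Y) = 2 |X intersect Y| / (|X| + |Y|)`: volumetric overlap between a
#' reference mask X and a predicted mask Y, in [0, 1], 1 iff the masks are
#' set-equal.
#'
#' @param reference,predicted logical arrays of identical shape.
#' @return DSC in [0, 1]. Both masks empty is undefined and raises an
#'   undefined-metric error.
#' @examples
#' x <- matrix(FALSE, 4, 4); x[1, 1:4] <- TRUE
#' y <- matrix(FALSE, 4, 4); y[1, 1:3] <- TRUE; y[2, 1] <- TRUE
#' dsc(x, y)  # 2*3 / (4+4) = 0.75
#' @export
dsc <- function(reference, predicted) {
  if (!all(dim(reference) == dim(predicted)))
    stop_input("dsc: mask shapes differ")
  nx <- sum(reference); ny <- sum(predicted)
  if (nx + ny == 0)
    stop_undefined_metric("dsc: both masks are empty")
  2 * sum(reference & predicted) / (nx + ny)
}

# coordinates (in voxel index units, optionally scaled by spacing) of the
# TRUE cells of a 2D/3D logical array, one row per point
mask_points <- function(mask, spacing = NULL) {
  pts <- which(mask, arr.ind = TRUE)
  if (is.vector(pts)) pts <- matrix(pts, ncol = 1)
  pts <- matrix(as.numeric(pts), nrow = NROW(pts))
  if (!is.null(spacing)) pts <- sweep(pts, 2, spacing, `*`)
  pts
}

# exact nearest-neighbour distances via chunked cross-distance algebra
min_dists <- function(A, B) {
  nb2 <- rowSums(B * B)
  out <- numeric(nrow(A))
  chunk <- max(1L, floor(2e7 / nrow(B)))
  for (s in seq(1L, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ai <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ai * Ai), nb2, `+`) - 2 * Ai %*% t(B)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Directed Hausdorff distance between two masks
#'
#' `hd(A, B) = max over a in A of min over b in B of ||a - b||` (Euclidean),
#' in voxel index units by default. Directed distances are asymmetric:
#' `hd(A, B) != hd(B, A)` in general.
#'
#' @param A,B logical masks (2D or 3D) of identical shape, or numeric point
#'   matrices (one point per row).
#' @param spacing optional per-axis scale to measure in millimetres instead
#'   of voxels.
#' @return Nonnegative real. An empty point set raises an undefined-metric
#'   error.
#' @export
directed_hd <- function(A, B, spacing = NULL) {
  pa <- if (is.logical(A)) mask_points(A, spacing) else as.matrix(A)
  pb <- if (is.logical(B)) mask_points(B, spacing) else as.matrix(B)
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    stop_undefined_metric("directed_hd: empty point set")
  max(min_dists(pa, pb))
}

#' Bidirectional Hausdorff distance
#'
#' `HD(X, Y) = max(hd(X, Y), hd(Y, X))`: the larger of the two directed
#' distances, 0 iff the masks are set-equal.
#'
#' @inheritParams directed_hd
#' @param X,Y logical masks of identical shape (or point matrices).
#' @return Nonnegative real.
#' @export
hausdorff <- function(X, Y, spacing = NULL) {
  max(directed_hd(X, Y, spacing), directed_hd(Y, X, spacing))
}

#' Summary statistics with a t-based 95% confidence interval
#'
#' Mean, sample SD (n-1 denominator), median, min, max and the 95% CI
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)`. With a single value, SD and CI
#' are reported as NA.
#'
#' @param values numeric vector, length >= 1.
#' @return List of class `summary_stats` with `mean`, `sd`, `median`, `min`,
#'   `max`, `ci95_lo`, `ci95_hi`, `n`.
#' @examples
#' s <- summarize_values(c(1, 2, 3))
#' c(s$ci95_lo, s$ci95_hi)  # approximately (-0.484, 4.484)
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop_input("summarize_values: empty input")
  n <- length(values)
  m <- mean(values)
  if (n >= 2L) {
    s <- stats::sd(values)
    half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
    ci <- c(m - half, m + half)
  } else {
    s <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  structure(list(mean = m, sd = s, median = stats::median(values),
                 min = min(values), max = max(values),
                 ci95_lo = ci[1], ci95_hi = ci[2], n = n),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("Mean±SD            %.4g±%.4g\n", x$mean, x$sd))
  cat(sprintf("Median             %.4g\n", x$median))
  cat(sprintf("(minimum, maximum) (%.4g, %.4g)\n", x$min, x$max))
  cat(sprintf("95%% CI             (%.4g, %.4g)\n", x$ci95_lo, x$ci95_hi))
  invisible(x)
}

#' Evaluate a predicted metal mask against a reference mask
#'
#' `per_slice` scope computes DSC and bidirectional HD on every axial slice
#' where either mask is nonempty, then summarizes each metric (mean, SD,
#' median, min, max, 95% CI); `volume` scope computes both metrics once in
#' 3D. HD is in voxel index units.
#'
#' @param reference,predicted 3D logical arrays of identical shape.
#' @param scope `"per_slice"` (default) or `"volume"`.
#' @return List of class `metrics_report` with `per_slice` (data.frame:
#'   slice, dsc, hd), `dsc_summary`, `hd_summary`, `scope`.
#' @export
evaluate_volume <- function(reference, predicted,
                            scope = c("per_slice", "volume")) {
  scope <- match.arg(scope)
  if (!all(dim(reference) == dim(predicted)))
    stop_input("evaluate_volume: mask shapes differ")
  if (scope == "volume") {
    if (sum(reference) + sum(predicted) == 0)
      stop_undefined_metric("evaluate_volume: both volumes empty")
    per <- data.frame(slice = NA_integer_,
                      dsc = dsc(reference, predicted),
                      hd = hausdorff(reference, predicted))
  } else {
    keep <- which(apply(reference, 1, any) | apply(predicted, 1, any))
    if (length(keep) == 0L)
      stop_undefined_metric("evaluate_volume: no slice has a nonempty mask")
    per <- do.call(rbind, lapply(keep, function(i) {
      data.frame(slice = i,
                 dsc = dsc(reference[i, , ], predicted[i, , ]),
                 hd = hausdorff(reference[i, , ], predicted[i, , ]))
    }))
  }
  structure(list(per_slice = per,
                 dsc_summary = summarize_values(per$dsc),
                 hd_summary = summarize_values(per$hd),
                 scope = scope),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Parameters          DSC      HD\n")
  for (i in seq_len(nrow(x$per_slice))) {
    r <- x$per_slice[i, ]
    lbl <- if (is.na(r$slice)) "volume" else sprintf("slice %d", r$slice)
    cat(sprintf("%-18s %7.4f %7.4f\n", lbl, r$dsc, r$hd))
  }
  fmt <- function(a, b) sprintf("%.4g±%.4g", a, b)
  cat(sprintf("%-18s %s %s\n", "Mean±SD",
              fmt(x$dsc_summary$mean, x$dsc_summary$sd),
              fmt(x$hd_summary$mean, x$hd_summary$sd)))
  cat(sprintf("%-18s %.4g %.4g\n", "Median",
              x$dsc_summary$median, x$hd_summary$median))
  cat(sprintf("%-18s (%.4g, %.4g) (%.4g, %.4g)\n", "(minimum, maximum)",
              x$dsc_summary$min, x$dsc_summary$max,
              x$hd_summary$min, x$hd_summary$max))
  cat(sprintf("%-18s (%.4g, %.4g) (%.4g, %.4g)\n", "95% CI",
              x$dsc_summary$ci95_lo, x$dsc_summary$ci95_hi,
              x$hd_summary$ci95_lo, x$hd_summary$ci95_hi))
  invisible(x)
}
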