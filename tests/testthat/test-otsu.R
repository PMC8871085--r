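test_that("build_histogram bins, normalizes and flags degenerate input", {
  h <- build_histogram(c(0, 0, 100, 100), n_bins = 2)
  expect_equal(h$probs, c(0.5, 0.5))
  expect_equal(h$edges, c(0, 50, 100))
  expect_error(build_histogram(rep(7, 10), 256),
               class = "clipkeep_degenerate_histogram_error")
  expect_error(build_histogram(numeric(0), 2), class = "clipkeep_input_error")
  set.seed(404)
  for (rep in 1:10) {
    h <- build_histogram(stats::rnorm(200, 0, 300), sample(c(16, 64, 256), 1))
    expect_equal(sum(h$probs), 1, tolerance = 1e-9)
    expect_true(all(diff(h$edges) > 0))
  }
})

test_that("two-spike histogram: plateau of equal variance, tie broken at smallest k", {
  p <- numeric(256); p[10] <- 0.5; p[200] <- 0.5
  h <- make_hist(p)
  res <- otsu_threshold(h)
  expect_equal(res$k_star, 10L)
  expect_equal(res$k_star, oracle_otsu_k(h$probs))
  # recompute sigma at a few plateau positions: all equal the reported max
  sig_at <- function(k) {
    i <- seq_len(256); P <- sum(h$probs[1:k]); m <- sum(i[1:k] * h$probs[1:k])
    (sum(i * h$probs) * P - m)^2 / (P * (1 - P))
  }
  for (k in c(10, 100, 199))
    expect_equal(sig_at(k), res$sigma_bc2, tolerance = 1e-9)
})

test_that("single occupied bin is degenerate", {
  p <- numeric(64); p[30] <- 1
  expect_error(otsu_threshold(make_hist(p)),
               class = "clipkeep_degenerate_histogram_error")
})

test_that("selected split maximizes between-class variance on random histograms", {
  set.seed(505)
  for (rep in 1:300) {
    L <- sample(c(16, 64, 256), 1)
    p <- stats::rexp(L) * (stats::runif(L) < 0.3)
    if (sum(p > 0) < 2) p[sample(L, 2)] <- 1
    h <- make_hist(p)
    expect_identical(otsu_threshold(h)$k_star, oracle_otsu_k(h$probs))
  }
})

test_that("maximizing sigma_bc2 equals minimizing within-class variance", {
  set.seed(606)
  for (rep in 1:50) {
    p <- stats::rexp(64); p <- p / sum(p)
    h <- make_hist(p)
    k_bc <- otsu_threshold(h)$k_star
    wcv <- vapply(1:63, function(k) oracle_within_class_var(h$probs, k), 0)
    expect_identical(k_bc, which.min(wcv))
  }
})

test_that("Otsu split is invariant under affine HU rescaling", {
  set.seed(707)
  x <- c(stats::rnorm(150, 35, 15), stats::rnorm(60, 4000, 15))
  r1 <- otsu_threshold(build_histogram(x, 256))
  a <- 2.5; b <- -300
  r2 <- otsu_threshold(build_histogram(a * x + b, 256))
  expect_identical(r1$k_star, r2$k_star)
  expect_equal(r2$threshold_hu, a * r1$threshold_hu + b, tolerance = 1e-8)
})

test_that("binarize_roi thresholds inside the ROI only", {
  px <- matrix(100, 20, 20); px[8:10, 8:10] <- 4000
  roi <- structure(list(r_lo = 5L, r_hi = 14L, c_lo = 5L, c_hi = 14L,
                        alpha = 1.5), class = "roi_box")
  m <- binarize_roi(px, roi, list(threshold_hu = 2000))
  expect_equal(sum(m), 9)
  expect_true(all(which(m, arr.ind = TRUE)[, 1] %in% 8:10))
  # threshold above the ROI max -> empty
  expect_false(any(binarize_roi(px, roi, list(threshold_hu = 5000))))
  # mask always inside the ROI footprint
  full <- binarize_roi(px, roi, list(threshold_hu = -1e5))
  out <- matrix(TRUE, 20, 20); out[5:14, 5:14] <- FALSE
  expect_false(any(full & out))
})

test_that("segment_metal unions per-ROI masks and handles edge cases", {
  px <- matrix(35, 40, 40)
  px[5:7, 5:7] <- 4000; px[30:32, 30:33] <- 4000
  cand <- threshold_metal(px, 3500)
  comps <- extract_components(cand, 8)
  rois <- lapply(seq_len(nrow(comps)), function(i) {
    cm <- comps[i, ]
    roi_box(cm, component_center(cm, "midpoint"), 1.5, dim(px))
  })
  m <- segment_metal(px, rois)
  expect_identical(m, px > 3500)           # exact recovery, noise-free
  expect_false(any(segment_metal(px, list())))
  # overlapping ROIs never double-count
  m2 <- segment_metal(px, c(rois, rois))
  expect_identical(m2, m)
})

test_that("degenerate ROI falls back to the global threshold or is skipped", {
  px <- matrix(4000, 10, 10)   # constant: Otsu inapplicable
  roi <- structure(list(r_lo = 1L, r_hi = 10L, c_lo = 1L, c_hi = 10L,
                        alpha = 1.5), class = "roi_box")
  m <- segment_metal(px, list(roi), degenerate_fallback = "global_threshold",
                     threshold_hu = 3500)
  expect_true(all(m))          # constant 4000 > 3500 everywhere in ROI
  expect_false(any(segment_metal(px, list(roi),
                                 degenerate_fallback = "skip")))
})

test_that("bone adjacent to metal in the ROI is segmented with it", {
  # the method's documented failure mode: a bone-rich ROI pulls the Otsu
  # split below bone, so the mask strictly contains non-metal voxels
  px <- matrix(35, 40, 40)
  px[22:36, 8:36] <- 1500                       # skull band
  truth <- matrix(FALSE, 40, 40)
  for (i in 0:8) truth[16 + i, 14 + i] <- TRUE  # oblique blade, tip in bone
  px[truth] <- 4000
  cand <- threshold_metal(px, 3500)
  comps <- extract_components(cand, 8)
  roi <- roi_box(comps[1, ], component_center(comps[1, ], "midpoint"),
                 1.5, dim(px))
  m <- segment_metal(px, list(roi))
  expect_true(all(m[truth]))                    # metal fully recovered
  expect_gt(sum(m & !truth), 0)                 # plus bone: strict superset
  expect_lt(dsc(truth, m), 1)
})
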