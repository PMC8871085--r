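test_that("dsc matches direct voxel counting", {
  x <- matrix(FALSE, 8, 8); x[1, 1:4] <- TRUE
  expect_equal(dsc(x, x), 1.0)
  y <- matrix(FALSE, 8, 8); y[5, 1:3] <- TRUE
  expect_equal(dsc(x, y), 0.0)                       # disjoint
  y2 <- matrix(FALSE, 8, 8); y2[1, 1:3] <- TRUE; y2[2, 1] <- TRUE
  expect_equal(dsc(x, y2), 0.75)                     # 2*3/(4+4)
  expect_equal(dsc(x, y2), dsc(y2, x))               # symmetry
  empty <- matrix(FALSE, 8, 8)
  expect_error(dsc(empty, empty), class = "clipkeep_undefined_metric_error")
  expect_equal(dsc(x, empty), 0.0)
})

test_that("directed Hausdorff distances: worked values and asymmetry", {
  a <- matrix(FALSE, 12, 12); a[1, 1] <- TRUE
  b <- matrix(FALSE, 12, 12); b[4, 5] <- TRUE
  expect_equal(directed_hd(a, b), 5.0)               # 3-4-5 triangle
  expect_equal(directed_hd(a, a), 0.0)
  A <- matrix(FALSE, 12, 12); A[1, 1] <- TRUE; A[11, 1] <- TRUE
  B <- matrix(FALSE, 12, 12); B[1, 1] <- TRUE
  expect_equal(directed_hd(A, B), 10.0)
  expect_equal(directed_hd(B, A), 0.0)               # asymmetric
  expect_equal(hausdorff(A, B), 10.0)                # max of both directions
  expect_equal(hausdorff(A, A), 0.0)
  expect_error(directed_hd(A, matrix(FALSE, 12, 12)),
               class = "clipkeep_undefined_metric_error")
})

test_that("hausdorff equals the all-pairs brute-force oracle on random masks", {
  set.seed(808)
  for (rep in 1:60) {
    A <- random_mask(24, 24, stats::runif(1, 0.02, 0.3))
    B <- random_mask(24, 24, stats::runif(1, 0.02, 0.3))
    expect_equal(hausdorff(A, B), oracle_hausdorff(A, B))
    expect_equal(directed_hd(A, B), oracle_directed_hd(A, B))
  }
})

test_that("bidirectional HD is a metric on mask space", {
  set.seed(909)
  for (rep in 1:30) {
    X <- random_mask(16, 16, 0.1); Y <- random_mask(16, 16, 0.1)
    Z <- random_mask(16, 16, 0.1)
    expect_equal(hausdorff(X, Y), hausdorff(Y, X))
    expect_lte(hausdorff(X, Z), hausdorff(X, Y) + hausdorff(Y, Z) + 1e-12)
    expect_identical(hausdorff(X, X) == 0, TRUE)
  }
})

test_that("HD respects anisotropic spacing when requested", {
  a <- matrix(FALSE, 4, 4); a[1, 1] <- TRUE
  b <- matrix(FALSE, 4, 4); b[1, 3] <- TRUE
  expect_equal(hausdorff(a, b), 2)                       # voxel units
  expect_equal(hausdorff(a, b, spacing = c(1, 0.5)), 1)  # mm
})

test_that("summarize_values reproduces the closed-form t-interval", {
  s <- summarize_values(c(1, 2, 3))
  expect_equal(s$mean, 2); expect_equal(s$sd, 1); expect_equal(s$median, 2)
  expect_equal(s$min, 1); expect_equal(s$max, 3)
  # mean +/- t(0.975, 2) * sd/sqrt(3) = 2 -/+ 4.3027 * 0.5774
  expect_equal(s$ci95_lo, -0.484, tolerance = 5e-4)
  expect_equal(s$ci95_hi, 4.484, tolerance = 5e-4)

  k <- summarize_values(rep(5, 4))
  expect_equal(k$sd, 0); expect_equal(c(k$ci95_lo, k$ci95_hi), c(5, 5))

  one <- summarize_values(3.2)
  expect_true(is.na(one$sd) && is.na(one$ci95_lo))
  expect_error(summarize_values(numeric(0)), class = "clipkeep_input_error")

  set.seed(1010)
  for (rep in 1:20) {
    v <- stats::rnorm(sample(2:30, 1))
    st <- summarize_values(v)
    expect_true(st$min <= st$median && st$median <= st$max)
    expect_true(st$ci95_lo <= st$mean && st$mean <= st$ci95_hi)
  }
})

test_that("confidence interval width shrinks as 1/sqrt(n)", {
  set.seed(1111)
  width <- function(n) {
    w <- replicate(200, { s <- summarize_values(stats::rnorm(n))
                          s$ci95_hi - s$ci95_lo })
    mean(w)
  }
  w25 <- width(25); w400 <- width(400)
  expect_equal(w25 / w400, 4, tolerance = 0.25)   # sqrt(400/25) = 4
})

test_that("evaluate_volume computes per-slice metrics matching 2D recomputation", {
  set.seed(1212)
  ref <- array(FALSE, c(6, 20, 20)); pred <- ref
  for (i in 2:5) {
    ref[i, 5:9, 5:9] <- TRUE
    pred[i, 5:9, 5:9] <- TRUE
  }
  pred[3, 5, 5] <- FALSE; pred[3, 12, 12] <- TRUE
  rep1 <- evaluate_volume(ref, pred, "per_slice")
  expect_equal(nrow(rep1$per_slice), 4)
  expect_equal(rep1$per_slice$slice, 2:5)
  for (j in seq_len(4)) {
    i <- rep1$per_slice$slice[j]
    expect_equal(rep1$per_slice$dsc[j], dsc(ref[i, , ], pred[i, , ]))
    expect_equal(rep1$per_slice$hd[j], hausdorff(ref[i, , ], pred[i, , ]))
  }
  expect_equal(rep1$dsc_summary$n, 4)
  # identical masks: all DSC 1, all HD 0, sd 0
  same <- evaluate_volume(ref, ref, "per_slice")
  expect_true(all(same$per_slice$dsc == 1) && all(same$per_slice$hd == 0))
  expect_equal(same$dsc_summary$sd, 0)
  # volume scope computes once in 3D
  vol <- evaluate_volume(ref, pred, "volume")
  expect_equal(nrow(vol$per_slice), 1)
  expect_equal(vol$per_slice$dsc, dsc(ref, pred))
  expect_error(evaluate_volume(array(FALSE, c(2, 4, 4)),
                               array(FALSE, c(2, 4, 4))),
               class = "clipkeep_undefined_metric_error")
})

test_that("metrics report prints the descriptive-statistics table layout", {
  ref <- array(FALSE, c(3, 10, 10)); ref[2, 3:5, 3:5] <- TRUE
  out <- capture.output(print(evaluate_volume(ref, ref)))
  expect_true(any(grepl("Mean±SD", out)))
  expect_true(any(grepl("Median", out)))
  expect_true(any(grepl("(minimum, maximum)", out, fixed = TRUE)))
  expect_true(any(grepl("95% CI", out)))
})
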