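# Independent oracles used across the suite. Each deliberately uses a
# different algorithm from the package implementation it checks.

# Connected components by dense min-label propagation iterated to a fixed
# point (the package uses sparse BFS instead).
oracle_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  shifts <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  repeat {
    old <- lab
    for (sh in shifts) {
      src_r <- max(1, 1 + sh[1]):min(nr, nr + sh[1])
      dst_r <- max(1, 1 - sh[1]):min(nr, nr - sh[1])
      src_c <- max(1, 1 + sh[2]):min(nc, nc + sh[2])
      dst_c <- max(1, 1 - sh[2]):min(nc, nc - sh[2])
      nb <- lab[src_r, src_c, drop = FALSE]
      cur <- lab[dst_r, dst_c, drop = FALSE]
      both <- nb > 0L & cur > 0L
      cur[both] <- pmin(cur[both], nb[both])
      lab[dst_r, dst_c] <- cur
    }
    if (identical(lab, old)) break
  }
  ids <- sort(unique(lab[lab > 0L]))
  comps <- do.call(rbind, lapply(ids, function(id) {
    ix <- which(lab == id, arr.ind = TRUE)
    data.frame(r_min = min(ix[, 1]), r_max = max(ix[, 1]),
               c_min = min(ix[, 2]), c_max = max(ix[, 2]),
               n_pixels = nrow(ix))
  }))
  comps[order(-comps$n_pixels, comps$r_min, comps$c_min), , drop = FALSE]
}

# Otsu by explicit two-class means at every split: sigma_bc2(k) =
# P(1-P) (mu1 - mu0)^2, computed from scratch per k (the package uses the
# cumulative-moment form).
oracle_otsu_k <- function(probs) {
  L <- length(probs)
  i <- seq_len(L)
  best_k <- NA_integer_; best_s <- -Inf
  for (k in 1:(L - 1)) {
    P <- sum(probs[1:k])
    if (P <= 0 || P >= 1) next
    mu0 <- sum(i[1:k] * probs[1:k]) / P
    mu1 <- sum(i[(k + 1):L] * probs[(k + 1):L]) / (1 - P)
    s <- P * (1 - P) * (mu1 - mu0)^2
    if (s > best_s + 1e-12) { best_s <- s; best_k <- k }
  }
  best_k
}

# within-class variance at split k, for the sigma_total = sigma_bc + sigma_w
# decomposition check
oracle_within_class_var <- function(probs, k) {
  L <- length(probs); i <- seq_len(L)
  P <- sum(probs[1:k])
  v0 <- if (P > 0) {
    mu0 <- sum(i[1:k] * probs[1:k]) / P
    sum(probs[1:k] * (i[1:k] - mu0)^2)
  } else 0
  v1 <- if (P < 1) {
    mu1 <- sum(i[(k + 1):L] * probs[(k + 1):L]) / (1 - P)
    sum(probs[(k + 1):L] * (i[(k + 1):L] - mu1)^2)
  } else 0
  v0 + v1
}

# Directed Hausdorff by per-point scan (the package uses one cross-distance
# matrix).
oracle_directed_hd <- function(A, B) {
  pa <- which(A, arr.ind = TRUE); pb <- which(B, arr.ind = TRUE)
  worst <- 0
  for (i in seq_len(nrow(pa))) {
    d <- sqrt(min(rowSums(sweep(pb, 2, pa[i, ])^2)))
    if (d > worst) worst <- d
  }
  worst
}

oracle_hausdorff <- function(A, B) {
  max(oracle_directed_hd(A, B), oracle_directed_hd(B, A))
}

# random logical matrix with at least one TRUE cell
random_mask <- function(nr, nc, p = 0.15) {
  m <- matrix(stats::runif(nr * nc) < p, nr, nc)
  if (!any(m)) m[sample(nr, 1), sample(nc, 1)] <- TRUE
  m
}

make_hist <- function(probs, edges = seq(0, length(probs), by = 1)) {
  structure(list(probs = probs / sum(probs), edges = edges,
                 L = length(probs)),
            class = "intensity_histogram")
}
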