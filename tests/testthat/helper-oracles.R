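# Independent brute-force oracles used to cross-check the implementation.
# Each oracle takes a different computational route from the function it
# checks (exhaustive search, direct enumeration, closed form, or a separate
# library), and is deliberately slow and simple.

# Exhaustive Otsu: minimize within-class variance directly on the raw 8-bit
# pixel values over all 256 candidate thresholds (foreground strictly > t).
oracle_otsu_8bit <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  popvar <- function(v) if (length(v) > 1L) mean((v - mean(v))^2) else 0
  wcv <- vapply(0:255, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (length(lo) == 0L || length(hi) == 0L) return(Inf)
    (length(lo) * popvar(lo) + length(hi) * popvar(hi)) / n
  }, numeric(1))
  # ties (identical partitions) averaged, mirroring the documented tie rule
  mean((0:255)[wcv == min(wcv)])
}

# Brute-force DBSCAN facts from the pairwise distance matrix:
# core status, the partition of core points into density-connected
# components, and the noise set. Border points (non-core within eps of a
# core) are not assigned by the oracle since standard DBSCAN leaves their
# cluster ambiguous; the checker verifies their assignment is admissible.
oracle_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  d <- unname(as.matrix(stats::dist(pts)))
  nb <- d <= eps
  core <- unname(rowSums(nb) >= min_pts)
  core_comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in which(core)) {
    if (!is.na(core_comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (!is.na(core_comp[v])) next
      core_comp[v] <- cur
      stack <- c(stack, which(core & nb[v, ] & is.na(core_comp)))
    }
  }
  border <- !core & vapply(seq_len(n), function(i) any(nb[i, ] & core), logical(1))
  list(core = core, core_comp = core_comp, border = border,
       noise = !core & !border, nb = nb)
}

# Check a cluster_labeling against the DBSCAN oracle facts.
check_dbscan_against_oracle <- function(labels, pts, eps, min_pts) {
  o <- oracle_dbscan(pts, eps, min_pts)
  # noise set identical
  expect_identical(is.na(labels), o$noise)
  # core points: same partition (labels constant on oracle components,
  # distinct across components)
  if (any(o$core)) {
    map <- tapply(labels[o$core], o$core_comp[o$core], unique)
    expect_true(all(lengths(map) == 1L))
    expect_equal(length(unique(unlist(map))), length(map))
  }
  # border points: assigned to a cluster owning a core point within eps
  for (i in which(o$border)) {
    owners <- unique(labels[o$core & o$nb[i, ]])
    expect_true(labels[i] %in% owners)
  }
}

# Peak merging via an independent route: connected components from
# single-linkage hierarchical clustering cut just below delta_m, averaged,
# iterated to a fixed point.
oracle_merge <- function(pts, delta_m) {
  pts <- as.data.frame(pts)
  repeat {
    if (nrow(pts) <= 1L) break
    hc <- stats::hclust(stats::dist(pts), method = "single")
    comp <- stats::cutree(hc, h = delta_m * (1 - 1e-12))
    if (max(comp) == nrow(pts)) break
    pts <- data.frame(row = as.numeric(tapply(pts$row, comp, mean)),
                      col = as.numeric(tapply(pts$col, comp, mean)))
  }
  pts <- pts[order(pts$row, pts$col), ]
  rownames(pts) <- NULL
  pts
}

# Direct dense Gaussian convolution with pointwise symmetric reflection
# indexing (valid while the kernel radius does not exceed the image size).
oracle_gaussian <- function(x, sd) {
  r <- max(1L, as.integer(ceiling(4 * sd)))
  k1 <- exp(-(-r:r)^2 / (2 * sd^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  h <- nrow(x); w <- ncol(x)
  refl <- function(i, n) ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- refl(i + (-r:r), h); cj <- refl(j + (-r:r), w)
    out[i, j] <- sum(k2 * x[ri, cj])
  }
  out
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(y, x) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  yhat <- ic + sl * x
  list(slope = sl, intercept = ic,
       r_squared = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
}

# Direct shifted-NB log-likelihood from the pmf.
oracle_nb_loglik <- function(k, r, p) {
  sum(lchoose(k + r - 1, k) + r * log(p) + k * log(1 - p))
}

# Small synthetic image with Gaussian blobs at given 0-based centers.
blob_image <- function(shape, centers, amp = 180, bg = 10, sd_px = 4, rho = 1.5442) {
  img <- matrix(bg, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(shape[1]) - 1 - centers[i, 1])^2,
                (seq_len(shape[2]) - 1 - centers[i, 2])^2, "+")
    img <- img + amp * exp(-d2 / (2 * sd_px^2))
  }
  intensity_image(img, rho)
}

full_mask <- function(img) binarize(img, -1)
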