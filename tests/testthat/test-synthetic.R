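# Synthetic fixtures: layout sampling, rendering, and scoring.

small_params <- function(...) {
  fixture_params(image_shape = c(512L, 512L), n_ganglia = 3L,
                 size_law = list(type = "fixed", sizes = c(3L, 5L, 8L)),
                 n_extraganglionic = 2L, seed = 5L, ...)
}

test_that("a requested layout is honored exactly and is seed-deterministic", {
  p <- fixture_params(image_shape = c(900L, 900L), n_ganglia = 4L,
                      size_law = list(type = "fixed", sizes = c(3L, 5L, 8L, 13L)),
                      n_extraganglionic = 2L, seed = 3L)
  gt <- sample_layout(p)
  expect_equal(nrow(gt$neurons), 31L)
  expect_equal(sort(as.integer(table(gt$neurons$cluster_label))), c(3L, 5L, 8L, 13L))
  expect_equal(sum(is.na(gt$neurons$cluster_label)), 2L)
  gt2 <- sample_layout(p)
  expect_identical(gt$neurons, gt2$neurons)
  img1 <- render_image(gt, p); img2 <- render_image(gt2, p)
  expect_identical(img1$pixels, img2$pixels)
})

test_that("planted layouts respect the separation geometry", {
  p <- small_params()
  gt <- sample_layout(p)
  eps_px <- default_eps(p$rho)
  soma_px <- p$soma_radius_um * p$rho
  pos <- as.matrix(gt$neurons[, c("row", "col")])
  lab <- gt$neurons$cluster_label
  d <- as.matrix(dist(pos)); diag(d) <- Inf
  # no soma overlap anywhere
  expect_gt(min(d), 2 * soma_px * 0.95)
  for (g in unique(na.omit(lab))) {
    in_g <- which(!is.na(lab) & lab == g)
    # intra-ganglion nearest-neighbor distance below eps_m
    expect_lt(max(apply(d[in_g, in_g, drop = FALSE], 1, min)), eps_px)
    # gaps to every other neuron exceed separation_factor * eps_m
    out_g <- setdiff(seq_len(nrow(pos)), in_g)
    expect_gt(min(d[in_g, out_g]), p$separation_factor * eps_px)
  }
  # all somata inside the border margin
  expect_true(all(pos >= soma_px))
  expect_true(all(pos[, 1] <= p$image_shape[1] - 1 - soma_px))
  expect_true(all(pos[, 2] <= p$image_shape[2] - 1 - soma_px))
})

test_that("ganglion sizes drawn from the shifted NB law have the expected mean", {
  p <- fixture_params(image_shape = c(7000L, 7000L), n_ganglia = 400L,
                      n_extraganglionic = 0L, seed = 11L)
  gt <- sample_layout(p)
  sizes <- as.integer(table(gt$neurons$cluster_label))
  expect_true(all(sizes >= 3L))
  law_mean <- 0.58 * (1 - 0.035) / 0.035 + 3
  expect_lt(abs(mean(sizes) - law_mean), 1.5)
})

test_that("an oversubscribed image raises a capacity error", {
  p <- fixture_params(image_shape = c(220L, 220L), n_ganglia = 12L,
                      size_law = list(type = "fixed", sizes = rep(8L, 12L)),
                      n_extraganglionic = 0L, seed = 1L)
  expect_error(sample_layout(p), "capacity")
})

test_that("rendering is constant without neurons and peaks at a planted soma", {
  p0 <- fixture_params(image_shape = c(64L, 64L), n_ganglia = 0L,
                       size_law = list(type = "fixed", sizes = integer(0)),
                       n_extraganglionic = 0L, noise_sd = 0, seed = 2L)
  img0 <- render_image(sample_layout(p0), p0)
  expect_true(all(img0$pixels == p0$background_intensity))
  p1 <- fixture_params(image_shape = c(128L, 128L), n_ganglia = 0L,
                       size_law = list(type = "fixed", sizes = integer(0)),
                       n_extraganglionic = 1L, noise_sd = 0, seed = 2L)
  gt1 <- sample_layout(p1)
  img1 <- render_image(gt1, p1)
  peak_px <- which(img1$pixels == max(img1$pixels), arr.ind = TRUE)
  expect_lt(sqrt((peak_px[1, 1] - 1 - gt1$neurons$row)^2 +
                 (peak_px[1, 2] - 1 - gt1$neurons$col)^2), 1.5)
})

test_that("detection scoring handles perfect, empty, and mixed matchings", {
  p <- small_params()
  gt <- sample_layout(p)
  n <- nrow(gt$neurons)
  exact <- peak_set(gt$neurons[, c("row", "col")], p$image_shape, 2.5)
  s <- score_detection(gt, exact)
  expect_equal(s$precision, 1); expect_equal(s$recall, 1)
  none <- peak_set(data.frame(row = numeric(0), col = numeric(0)), p$image_shape, 2.5)
  s0 <- score_detection(gt, none)
  expect_true(is.na(s0$precision)); expect_equal(s0$recall, 0)
  # drop one true neuron, add one spurious far-away peak: 0.9 / 0.9 on 10
  gt10 <- gt; gt10$neurons <- gt$neurons[1:10, ]
  det <- rbind(gt$neurons[1:9, c("row", "col")], data.frame(row = 1, col = 1))
  s9 <- score_detection(gt10, peak_set(det, p$image_shape, 2.5))
  expect_equal(s9$precision, 0.9); expect_equal(s9$recall, 0.9)
  expect_equal(s9$n_matched, 9L)
})

test_that("co-clustering agreement enumerates pairs correctly", {
  p <- small_params()
  gt <- sample_layout(p)
  # build a 4-neuron truth with one cluster; predict two 2-clusters
  gt4 <- gt
  gt4$neurons <- data.frame(row = c(0, 0, 1, 1), col = c(0, 1, 0, 1),
                            cluster_label = c(1L, 1L, 1L, 1L))
  matching <- data.frame(peak_idx = 1:4, truth_idx = 1:4, distance = 0)
  lab <- structure(list(labels = c(1L, 1L, 2L, 2L), eps = 5, min_pts = 2,
                        n_ganglia = 2L, n_extraganglionic = 0L),
                   class = "cluster_labeling")
  expect_equal(score_clustering(gt4, lab, matching), 2 / 6)
  ident <- structure(list(labels = c(1L, 1L, 1L, 1L), eps = 5, min_pts = 2,
                          n_ganglia = 1L, n_extraganglionic = 0L),
                     class = "cluster_labeling")
  expect_equal(score_clustering(gt4, ident, matching), 1)
  expect_true(is.na(score_clustering(gt4, ident, matching[1, ])))
})

test_that("recall degrades gracefully (non-increasing) along a noise ladder", {
  rec <- sapply(c(0, 40, 90), function(ns) {
    mean(sapply(1:2, function(sd) {
      p <- fixture_params(image_shape = c(400L, 400L), n_ganglia = 2L,
                          size_law = list(type = "fixed", sizes = c(4L, 6L)),
                          n_extraganglionic = 1L, noise_sd = ns, seed = 100L + sd)
      gt <- sample_layout(p)
      res <- count_plexus(render_image(gt, p), segment = FALSE)
      suppressWarnings(score_detection(gt, res$peaks)$recall)
    }))
  })
  expect_true(all(diff(rec) <= 1e-9))
})
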