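test_that("DBSCAN handles the canonical block fixtures", {
  expect_equal(cluster_dbscan(pixel_set(), 1.5, 4)$clusters, list())

  # 5x5 solid block: one cluster, no noise
  res <- cluster_dbscan(px_block(0, 0, 5, 5), 1.5, 4)
  expect_length(res$clusters, 1)
  expect_equal(nrow(res$clusters[[1]]$pixels), 25)
  expect_equal(nrow(res$noise), 0)

  # two 3x3 blocks 10 px apart plus one isolated pixel
  px <- px_block(0, 0, 3, 3)
  far <- px_block(13, 0, 3, 3)
  iso <- data.frame(col = 30L, row = 30L, intensity = 200L)
  allpx <- pixel_set(c(px$col, far$col, iso$col), c(px$row, far$row, iso$row),
                     c(px$intensity, far$intensity, iso$intensity))
  res2 <- cluster_dbscan(allpx, 1.5, 4)
  expect_length(res2$clusters, 2)
  expect_equal(sort(vapply(res2$clusters, function(cl) nrow(cl$pixels), numeric(1))),
               c(9, 9))
  expect_equal(nrow(res2$noise), 1)
  expect_equal(res2$noise$col, 30)
})

test_that("DBSCAN partitions: clusters plus noise cover the input exactly once", {
  for (s in c(11, 12, 13)) {
    px <- random_px(s)
    res <- cluster_dbscan(px, 2, 5)
    n_in <- sum(vapply(res$clusters, function(cl) nrow(cl$pixels), numeric(1))) +
      nrow(res$noise)
    expect_equal(n_in, nrow(px))
    lab <- partition_labels(res, px)
    expect_false(anyNA(lab))      # every pixel accounted for exactly once
  }
})

test_that("DBSCAN agrees with the quadratic oracle on random instances", {
  for (s in 1:12) {
    px <- random_px(s)
    for (eps in c(1.5, 3)) for (mp in c(3, 5)) {
      a <- partition_labels(cluster_dbscan(px, eps, mp), px)
      b <- partition_labels(brute_force_components(px, eps, mp), px)
      expect_identical(a, b)
    }
  }
})

test_that("oracle degenerate cases follow the core-point definition", {
  # min_pts = 1: every point is core, noise empty, clusters = eps-components
  px <- random_px(99)
  res <- brute_force_components(px, 1.5, 1)
  expect_equal(nrow(res$noise), 0)

  # single pixel below min_pts is noise
  one <- pixel_set(5L, 5L, 100L)
  res1 <- brute_force_components(one, 2, 2)
  expect_length(res1$clusters, 0)
  expect_equal(nrow(res1$noise), 1)
})

test_that("K-means recovers separated blocks at the analytic WCSS optimum", {
  a <- px_block(0, 0, 4, 4)
  b <- px_block(40, 0, 4, 4)
  px <- pixel_set(c(a$col, b$col), c(a$row, b$row), c(a$intensity, b$intensity))
  res <- cluster_kmeans(px, 2, seed = 1L)
  sizes <- sort(vapply(res$clusters, function(cl) nrow(cl$pixels), numeric(1)))
  expect_equal(sizes, c(16, 16))
  # analytic optimum: per-block variance around its own centroid
  blk <- cbind(a$col, a$row)
  wcss_block <- sum(scale(blk, scale = FALSE)^2)
  expect_equal(attr(res, "wcss"), 2 * wcss_block, tolerance = 1e-12)
  # and different seeds agree on this well-separated input
  res2 <- cluster_kmeans(px, 2, seed = 77L)
  expect_equal(attr(res2, "wcss"), attr(res, "wcss"), tolerance = 1e-12)
})

test_that("K-means is deterministic, validates k, and k=1 gives the mean", {
  px <- random_px(5)
  r1 <- cluster_kmeans(px, 4, seed = 3L)
  r2 <- cluster_kmeans(px, 4, seed = 3L)
  expect_identical(partition_labels(r1, px), partition_labels(r2, px))
  expect_error(cluster_kmeans(px, nrow(px) + 1L), "at least k")

  r3 <- cluster_kmeans(px, 1, seed = 0L)
  expect_length(r3$clusters, 1)
  expect_equal(unname(r3$clusters[[1]]$centroid),
               c(mean(px$col), mean(px$row)))
})

test_that("K-means WCSS is no worse than twice the stats::kmeans optimum", {
  # independent cross-check: same objective, library implementation
  px <- random_px(21)
  X <- cbind(px$col, px$row)
  ours <- attr(cluster_kmeans(px, 5, seed = 2L), "wcss")
  set.seed(2)
  ref <- stats::kmeans(X, centers = 5, nstart = 10)$tot.withinss
  expect_gte(ours, ref * 0.999)     # cannot beat a well-restarted optimum
  expect_lte(ours, ref * 2)         # single-start Lloyd lands near it
})

test_that("HAC equals sub-threshold connected components", {
  # every pixel its own cluster below unit spacing
  px <- random_px(31)
  res <- cluster_hac(px, 1.0)
  expect_length(res$clusters, nrow(px))

  # 1-px-wide diagonal line: one cluster at threshold 1.5
  diag_px <- pixel_set(0:9, 0:9, rep(200L, 10))
  expect_length(cluster_hac(diag_px, 1.5)$clusters, 1)

  # two strips separated by 3 px: two clusters at threshold 1.5
  s1 <- px_block(0, 0, 6, 2)
  s2 <- px_block(0, 5, 6, 2)
  both <- pixel_set(c(s1$col, s2$col), c(s1$row, s2$row),
                    c(s1$intensity, s2$intensity))
  expect_length(cluster_hac(both, 1.5)$clusters, 2)
})

test_that("HAC matches hclust single linkage and DBSCAN with min_pts 1", {
  for (s in c(41, 42)) {
    px <- random_px(s, n_max = 200L)
    thr <- 2.5
    # no pairwise distance exactly at the threshold on this integer lattice
    res <- cluster_hac(px, thr)
    hl <- stats::hclust(stats::dist(cbind(px$col, px$row)), method = "single")
    ref <- stats::cutree(hl, h = thr - 1e-9)
    expect_equal(length(res$clusters), length(unique(ref)))
    # same partition up to relabeling
    lab <- partition_labels(res, px)
    expect_equal(length(unique(paste(lab, ref))), length(unique(ref)))

    # DBSCAN with min_pts 1 and eps just under the threshold
    dl <- partition_labels(cluster_dbscan(px, thr - 1e-9, 1), px)
    expect_equal(length(unique(paste(lab, dl))), length(unique(dl)))
  }
})

test_that("cluster_pixels dispatches and defaults k to the DBSCAN count", {
  px <- random_px(8)
  res_d <- cluster_pixels(px, cluster_params(method = "dbscan"))
  res_k <- cluster_pixels(px, cluster_params(method = "kmeans"), frame_index = 4L)
  expect_equal(length(res_k$clusters), max(1L, length(res_d$clusters)))
  res_h <- cluster_pixels(px, cluster_params(method = "hac", link_threshold = 2))
  expect_gt(length(res_h$clusters), 0)
})
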