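test_that("corner points are the exhaustive rotated-diagonal extremes", {
  # single pixel: all corners coincide
  one <- as_cluster(pixel_set(3L, 4L, 100L))
  co <- corner_points(one)
  expect_true(all(vapply(co, function(p) all(p == c(3, 4)), logical(1))))

  # axis-aligned 3x5 rectangle at the origin (3 rows, 5 cols)
  rect <- as_cluster(px_block(0, 0, 5, 3))
  co2 <- corner_points(rect)
  expect_equal(co2$LU, c(col = 0, row = 0))
  expect_equal(co2$RD, c(col = 4, row = 2))
  expect_equal(co2$RU, c(col = 4, row = 0))
  expect_equal(co2$LD, c(col = 0, row = 2))

  # exhaustive argmin/argmax oracle on a random blob
  set.seed(3)
  blob <- random_px(17)
  cb <- corner_points(as_cluster(blob))
  s <- blob$col + blob$row; d <- blob$col - blob$row
  expect_equal(unname(cb$LU[1] + cb$LU[2]), min(s))
  expect_equal(unname(cb$RD[1] + cb$RD[2]), max(s))
  expect_equal(unname(cb$RU[1] - cb$RU[2]), max(d))
  expect_equal(unname(cb$LD[1] - cb$LD[2]), min(d))
})

test_that("pixel corners of a rotated rectangle sit within 1 px of its vertices", {
  ang <- 20; L <- 60; t <- 5
  px <- px_rect(ang, L, t)
  co <- corner_points(as_cluster(px))
  th <- ang * pi / 180
  ctr <- c((300 - 1) / 2, (200 - 1) / 2)
  d <- c(cos(th), -sin(th)); n <- c(sin(th), cos(th))
  vertices <- list(LU = ctr - L / 2 * d - t / 2 * n,
                   RD = ctr + L / 2 * d + t / 2 * n,
                   LD = ctr - L / 2 * d + t / 2 * n,
                   RU = ctr + L / 2 * d - t / 2 * n)
  # member-pixel corners land near the vertices (lattice jitter allowed)
  for (nm in names(vertices)) {
    expect_lt(sqrt(sum((co[[nm]] - vertices[[nm]])^2)), 2)
  }
  # the sub-pixel bounding-box corners localize them within a pixel
  bb <- cluster_angle(as_cluster(px))$bbox
  for (nm in names(vertices)) {
    expect_lt(sqrt(sum((bb[[nm]] - vertices[[nm]])^2)), 1.01)
  }
})

test_that("cluster_angle reproduces canonical orientations", {
  # horizontal 1x20 strip: exact zeros from the member-pixel corners, and
  # the default sub-pixel corners agree on the mean
  strip <- as_cluster(px_block(0, 5, 20, 1))
  ocp <- cluster_angle(strip, corner_method = "pixel")
  expect_equal(ocp$alpha1_deg, 0)
  expect_equal(ocp$alpha2_deg, 0)
  expect_equal(ocp$angle_deg, 0)
  expect_equal(cluster_angle(strip)$angle_deg, 0)

  # perfect diagonal from (0,10) to (10,0): +45 degrees by symmetry
  diag45 <- as_cluster(pixel_set(0:10, 10:0, rep(200L, 11)))
  expect_equal(cluster_angle(diag45, corner_method = "pixel")$angle_deg, 45)
  expect_equal(cluster_angle(diag45)$angle_deg, 45, tolerance = 1e-6)

  # 3-px strip along row = 0.3 col (falls to the right): about -16.70 deg
  base_r <- round(0.3 * (0:59))
  cols <- rep(0:59, each = 3); rows <- rep(base_r, each = 3) + 0:2
  strip3 <- as_cluster(pixel_set(cols, rows, rep(200L, length(cols))))
  expect_equal(cluster_angle(strip3)$angle_deg, -atan(0.3) * 180 / pi,
               tolerance = 0.5)

  # invariant: the reported angle is exactly the mean of the two diagonals
  oc3 <- cluster_angle(strip3)
  expect_identical(oc3$angle_deg, (oc3$alpha1_deg + oc3$alpha2_deg) / 2)
  expect_lte(abs(oc3$angle_deg), 90)

  # single pixel: degenerate, angle 0
  oc1 <- cluster_angle(as_cluster(pixel_set(2L, 2L, 9L)))
  expect_true(oc1$degenerate)
  expect_equal(oc1$angle_deg, 0)
})

test_that("orientation of solid rotated rectangles tracks the rotation angle", {
  for (ang in c(0, 7.5, 17.5, 30)) {
    px <- px_rect(ang, 60, 4)
    expect_equal(cluster_angle(as_cluster(px))$angle_deg, ang, tolerance = 0.7)
  }
  # the sub-pixel corners beat the single-pixel corners on short tubes
  errs <- sapply(c(22.5, 27.5), function(ang) {
    px <- px_rect(ang, 40, 6)
    c(obb = abs(cluster_angle(as_cluster(px))$angle_deg - ang),
      pixel = abs(cluster_angle(as_cluster(px), "pixel")$angle_deg - ang))
  })
  expect_true(all(errs["obb", ] <= errs["pixel", ] + 1e-9))
})

test_that("connection_angle requires strict lateral order and hits the arctangent", {
  # single-pixel clusters: centroids are the stated endpoints
  left <- cluster_angle(as_cluster(pixel_set(10L, 10L, 100L)))
  right <- cluster_angle(as_cluster(pixel_set(20L, 5L, 100L)))
  expect_equal(connection_angle(left, right), atan2(5, 10) * 180 / pi)

  # collinear segments on the row = -col line: 45 degrees throughout
  l45 <- cluster_angle(as_cluster(pixel_set(0:5, 20:15, rep(200L, 6))))
  r45 <- cluster_angle(as_cluster(pixel_set(10:15, 10:5, rep(200L, 6))))
  expect_equal(connection_angle(l45, r45), 45)
  expect_equal(l45$angle_deg, 45, tolerance = 1e-6)

  # overlapping clusters are not candidates
  a <- cluster_angle(as_cluster(px_block(0, 0, 10, 2)))
  b <- cluster_angle(as_cluster(px_block(5, 4, 10, 2)))
  expect_true(is.na(connection_angle(a, b)))
})

test_that("merge_pass joins collinear fragments and respects tolerances", {
  p <- merge_params(angle_tol_deg = 5, connect_tol_deg = 5, max_gap_px = 20)

  # single cluster: fixpoint
  one <- list(cluster_angle(as_cluster(px_rect(12, 50, 3))))
  expect_length(merge_pass(one, p), 1)

  # two collinear 12-degree segments with an 8 px gap merge to within 1 degree
  mk_seg <- function(c0, c1) {
    cols <- c0:c1
    rows <- round(-tan(12 * pi / 180) * cols) + 60L
    all_c <- rep(cols, each = 3); all_r <- rep(rows, each = 3) + 0:2
    cluster_angle(as_cluster(pixel_set(all_c, all_r, rep(200L, length(all_c)))))
  }
  segs <- list(mk_seg(0L, 40L), mk_seg(49L, 89L))
  merged <- merge_pass(segs, p)
  expect_length(merged, 1)
  expect_equal(merged[[1]]$angle_deg, 12, tolerance = 1)

  # pixel conservation and idempotence
  expect_equal(nrow(merged[[1]]$pixels),
               nrow(segs[[1]]$pixels) + nrow(segs[[2]]$pixels))
  again <- merge_pass(merged, p)
  expect_equal(length(again), 1)
  expect_identical(again[[1]]$angle_deg, merged[[1]]$angle_deg)

  # 10 vs 40 degrees: angle tolerance blocks the merge
  s10 <- cluster_angle(as_cluster(px_rect(10, 40, 3, canvas = c(100, 120))))
  far <- px_rect(40, 40, 3, canvas = c(100, 120))
  far$col <- far$col + 130L
  s40 <- cluster_angle(as_cluster(far))
  expect_length(merge_pass(list(s10, s40), p), 2)

  # a gap beyond max_gap_px blocks an otherwise valid merge
  segs_far <- list(mk_seg(0L, 40L), mk_seg(70L, 110L))
  expect_length(merge_pass(segs_far, merge_params(max_gap_px = 20)), 2)
})

test_that("fragmented synthetic fascicles are rebuilt with the generating angle", {
  for (fa in c(5, 17.5, 30)) for (nf in c(2, 4)) {
    sp <- scene_spec(frame_shape = c(200, 300), fascicle_angle_deg = fa,
                     aponeurosis_angle_deg = -2, speckle_sigma = 0,
                     fascicle_fragments = nf, fragment_gap_px = 12,
                     fascicle_halfspan_px = 70)
    mf <- make_frame(sp)
    px <- denoise(trim(mf$frame, mf$truth$roi)$top, 100, "top")
    oc <- orient_clusters(cluster_dbscan(px, 2, 5)$clusters)
    expect_gte(length(oc), nf)
    m <- merge_pass(oc, merge_params())
    expect_length(m, 1)
    expect_equal(m[[1]]$angle_deg, fa, tolerance = 1)
    # conservation through merging
    expect_equal(nrow(m[[1]]$pixels),
                 sum(vapply(oc, function(x) nrow(x$pixels), numeric(1))))
  }
})

test_that("plausibility filtering applies the slope and flatness rules", {
  rising <- cluster_angle(as_cluster(px_rect(15, 50, 3)))    # right end shallower
  falling <- cluster_angle(as_cluster(px_rect(-15, 50, 3)))  # left end shallower

  p_right <- merge_params(fascicle_rises = "right")
  kept <- plausibility_filter(list(rising, falling), "top", p_right)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$angle_deg, rising$angle_deg)

  # the published convention: most-left pixel higher than most-right
  p_left <- merge_params(fascicle_rises = "left")
  kept2 <- plausibility_filter(list(rising, falling), "top", p_left)
  expect_length(kept2, 1)
  expect_lt(kept2[[1]]$p_left[["row"]], kept2[[1]]$p_right[["row"]])

  # bottom ROI: a 45-degree cluster is no aponeurosis under a 15-degree bound
  steep <- cluster_angle(as_cluster(pixel_set(0:10, 10:0, rep(200L, 11))))
  flat <- cluster_angle(as_cluster(px_block(0, 5, 30, 2)))
  kept3 <- plausibility_filter(list(steep, flat), "bottom",
                               merge_params(apo_max_angle_deg = 15))
  expect_length(kept3, 1)
  expect_equal(kept3[[1]]$angle_deg, flat$angle_deg)

  # disabled filter keeps everything
  off <- merge_params(plausibility = FALSE)
  expect_length(plausibility_filter(list(rising, falling), "top", off), 2)
})

test_that("orient_clusters drops clusters below the minimum size", {
  small <- as_cluster(px_block(0, 0, 3, 3), id = 1L)      # 9 px
  big <- as_cluster(px_block(10, 10, 10, 3), id = 2L)     # 30 px
  oc <- orient_clusters(list(small, big), min_px = 15L)
  expect_length(oc, 1)
  expect_equal(oc[[1]]$id, 2L)
})
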