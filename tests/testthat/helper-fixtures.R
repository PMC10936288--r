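# shared fixture builders; everything is generated in code at test time

# pixel_set from a matrix of 0/1 occupancy (row 1 = depth 0)
px_from_mask <- function(mask, intensity = 200L) {
  idx <- which(mask > 0, arr.ind = TRUE)
  pixel_set(col = idx[, 2] - 1L, row = idx[, 1] - 1L,
            intensity = rep(intensity, nrow(idx)))
}

# solid axis-aligned block of pixels
px_block <- function(col0, row0, ncol_, nrow_, intensity = 200L) {
  g <- expand.grid(col = col0:(col0 + ncol_ - 1L), row = row0:(row0 + nrow_ - 1L))
  pixel_set(g$col, g$row, rep(intensity, nrow(g)))
}

# hard-rasterized rotated rectangle (pixel centers inside), centered in a canvas
px_rect <- function(angle_deg, length_px, thickness_px,
                    canvas = c(200, 300), intensity = 200L) {
  th <- angle_deg * pi / 180
  d <- c(cos(th), -sin(th)); n <- c(sin(th), cos(th))
  cc <- expand.grid(col = 0:(canvas[2] - 1L), row = 0:(canvas[1] - 1L))
  dx <- cc$col - (canvas[2] - 1) / 2
  dy <- cc$row - (canvas[1] - 1) / 2
  tl <- dx * d[1] + dy * d[2]
  s <- dx * n[1] + dy * n[2]
  keep <- abs(tl) <= length_px / 2 & abs(s) <= thickness_px / 2
  pixel_set(cc$col[keep], cc$row[keep], rep(intensity, sum(keep)))
}

# anti-aliased strip rendered by the scene painter, thresholded like the pipeline
px_strip_aa <- function(angle_deg, length_px, thickness_px,
                        canvas = c(120, 300), threshold = 100) {
  m <- matrix(20, canvas[1], canvas[2])
  m <- pennate:::.paint_strip(m, (canvas[2] - 1) / 2, (canvas[1] - 1) / 2,
                              angle_deg, thickness_px,
                              -length_px / 2, length_px / 2, 200)
  denoise(us_frame(round(m)), threshold, "top")
}

as_cluster <- function(px, id = 1L) {
  structure(list(id = as.integer(id), pixels = px), class = "us_cluster")
}

# canonical partition representation: cluster label per pixel in (col,row) order
partition_labels <- function(res, px) {
  key <- paste(px$col, px$row)
  lab <- integer(nrow(px))
  for (cl in res$clusters) {
    lab[match(paste(cl$pixels$col, cl$pixels$row), key)] <- cl$id
  }
  lab
}

# random scattered pixel set for property tests
random_px <- function(seed, n_max = 500L, extent = 60L) {
  set.seed(seed)
  n <- sample(30:n_max, 1)
  pts <- unique(data.frame(col = sample(0:extent, n, TRUE),
                           row = sample(0:extent, n, TRUE)))
  pixel_set(pts$col, pts$row, rep(150L, nrow(pts)))
}

# skew-normal draws via the delta representation (independent of the package)
rskewnorm <- function(n, xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  z <- delta * abs(rnorm(n)) + sqrt(1 - delta^2) * rnorm(n)
  xi + omega * z
}
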