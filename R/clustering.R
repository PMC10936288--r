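#' Clustering parameters
#'
#' @param method \code{"dbscan"} (default), \code{"kmeans"} or \code{"hac"}.
#' @param eps DBSCAN neighborhood radius in pixels.
#' @param min_pts DBSCAN core-point count (the point itself counts).
#' @param k number of K-means clusters; \code{NA} means "use the number of
#'   clusters DBSCAN finds on the same input".
#' @param max_iter K-means iteration cap.
#' @param seed K-means initialization seed; \code{NA} means "use the frame
#'   index".
#' @param link_threshold single-linkage merge distance for HAC (strict
#'   \code{<}).
#' @return object of class \code{cluster_params}.
#' @export
cluster_params <- function(method = c("dbscan", "kmeans", "hac"),
                           eps = 2.0, min_pts = 5L, k = NA_integer_,
                           max_iter = 100L, seed = NA_integer_,
                           link_threshold = 2.0) {
  method <- match.arg(method)
  stopifnot(eps > 0, min_pts >= 1, is.na(k) || k >= 1, link_threshold > 0)
  structure(list(method = method, eps = eps, min_pts = as.integer(min_pts),
                 k = as.integer(k), max_iter = as.integer(max_iter),
                 seed = as.integer(seed), link_threshold = link_threshold),
            class = "cluster_params")
}

# row-major scan order: by row (depth), then col
.scan_order <- function(px) order(px$row, px$col)

# subset a pixel_set, keeping attributes
.px_subset <- function(px, idx) {
  out <- px[idx, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("origin_roi", "offset", "class")] <-
    attributes(px)[c("origin_roi", "offset", "class")]
  out
}

.make_clusters <- function(px, labels) {
  ids <- sort(unique(labels[labels > 0L]))
  lapply(seq_along(ids), function(i) {
    structure(list(id = i, pixels = .px_subset(px, which(labels == ids[i]))),
              class = "us_cluster")
  })
}

#' @export
print.us_cluster <- function(x, ...) {
  cat(sprintf("<us_cluster #%d: %d px>\n", x$id, nrow(x$pixels)))
  invisible(x)
}

# neighbor lists (self included) within eps, via grid buckets of size eps
.neighbor_lists <- function(col, row, eps) {
  n <- length(col)
  cx <- floor(col / eps); cy <- floor(row / eps)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  env <- list2env(buckets, hash = TRUE, size = max(16L, length(buckets)))
  e2 <- eps^2
  lapply(seq_len(n), function(i) {
    ks <- paste(rep(cx[i] + (-1:1), each = 3), rep(cy[i] + (-1:1), times = 3))
    cand <- unlist(mget(ks, envir = env, ifnotfound = list(integer(0))),
                   use.names = FALSE)
    cand[(col[cand] - col[i])^2 + (row[cand] - row[i])^2 <= e2]
  })
}

# shared cluster construction from core flags + core-adjacency neighbor lists.
# Components are discovered in scan order of their earliest core point; border
# points (non-core with a core neighbor) join the first-discovered such
# cluster; everything else is noise.
.assign_from_neighbors <- function(n, nbrs, core) {
  labels <- integer(n)              # 0 = unassigned/noise
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cid <- cid + 1L
    frontier <- i
    labels[i] <- cid
    while (length(frontier)) {
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[core[nxt] & labels[nxt] == 0L]
      labels[nxt] <- cid
      frontier <- nxt
    }
  }
  # border points: first-discovered (smallest id) cluster among core neighbors
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    cn <- nbrs[[i]]
    cn <- cn[core[cn]]
    if (length(cn)) labels[i] <- min(labels[cn])
  }
  labels
}

#' DBSCAN pixel clustering
#'
#' Density-based clustering of foreground pixels on their \code{(col, row)}
#' coordinates (intensity is not a clustering coordinate; it enters later via
#' the value function). A pixel is a core point when at least \code{min_pts}
#' pixels (itself included) lie within Euclidean distance \code{eps}; clusters
#' are the density-connected groups of core points plus the border points
#' reachable from them; everything else is noise. Border points reachable from
#' several clusters go to the first cluster discovered under row-major pixel
#' scan order, which makes the output deterministic.
#'
#' @param px a [pixel_set()].
#' @param eps neighborhood radius (pixels).
#' @param min_pts core-point threshold (\code{>= 1}).
#' @return \code{list(clusters = list of us_cluster, noise = pixel_set)}.
#' @seealso [brute_force_components()] for the quadratic reference
#'   implementation used in the test suite.
#' @export
cluster_dbscan <- function(px, eps, min_pts) {
  stopifnot(inherits(px, "pixel_set"), eps > 0, min_pts >= 1)
  n <- nrow(px)
  if (n == 0L) {
    return(list(clusters = list(), noise = .px_subset(px, integer(0))))
  }
  ord <- .scan_order(px)
  sp <- .px_subset(px, ord)
  nbrs <- .neighbor_lists(sp$col, sp$row, eps)
  core <- lengths(nbrs) >= min_pts
  labels <- .assign_from_neighbors(n, nbrs, core)
  list(clusters = .make_clusters(sp, labels),
       noise = .px_subset(sp, which(labels == 0L)))
}

#' Quadratic reference implementation of the density clustering
#'
#' A literal O(N^2) transcription of the core-point / density-reachability
#' definition, computing the full pairwise distance matrix. It exists as an
#' independent oracle for [cluster_dbscan()] and is only suitable for small
#' inputs (a few thousand pixels).
#'
#' @inheritParams cluster_dbscan
#' @return same structure as [cluster_dbscan()].
#' @export
brute_force_components <- function(px, eps, min_pts) {
  stopifnot(inherits(px, "pixel_set"))
  n <- nrow(px)
  if (n == 0L) {
    return(list(clusters = list(), noise = .px_subset(px, integer(0))))
  }
  ord <- .scan_order(px)
  sp <- .px_subset(px, ord)
  d2 <- outer(sp$col, sp$col, "-")^2 + outer(sp$row, sp$row, "-")^2
  within <- d2 <= eps^2                   # self row included (diagonal 0)
  nbrs <- apply(within, 1L, which, simplify = FALSE)
  core <- rowSums(within) >= min_pts
  labels <- .assign_from_neighbors(n, nbrs, core)
  list(clusters = .make_clusters(sp, labels),
       noise = .px_subset(sp, which(labels == 0L)))
}

#' K-means pixel clustering
#'
#' Lloyd iteration on \code{(col, row)} coordinates: random pixel centers,
#' nearest-center assignment, mean update, repeated until the assignment is a
#' fixpoint or \code{max_iter} is reached. Deterministic for a given seed;
#' clusters that lose all members are dropped. The within-cluster sum of
#' squares is non-increasing over iterations and is cross-checked against
#' \code{stats::kmeans} in the test suite.
#'
#' @param px a [pixel_set()] with at least \code{k} pixels.
#' @param k number of clusters.
#' @param max_iter iteration cap.
#' @param seed RNG seed for center initialization.
#' @return \code{list(clusters =, noise =)} with empty noise; each cluster
#'   additionally reports its \code{centroid} and the final \code{wcss} is
#'   attached as an attribute of the cluster list.
#' @export
cluster_kmeans <- function(px, k, max_iter = 100L, seed = 0L) {
  stopifnot(inherits(px, "pixel_set"), k >= 1)
  n <- nrow(px)
  if (n < k) stop(sprintf("need at least k = %d pixels, got %d", k, n))
  sp <- .px_subset(px, .scan_order(px))
  X <- cbind(sp$col, sp$row)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  centers <- X[sample.int(n, k), , drop = FALSE]
  assign_px <- function(ctr) {
    # squared distance of every pixel to every center
    d2 <- outer(X[, 1], ctr[, 1], "-")^2 + outer(X[, 2], ctr[, 2], "-")^2
    max.col(-d2, ties.method = "first")
  }
  lab <- assign_px(centers)
  for (it in seq_len(max_iter)) {
    centers <- do.call(rbind, lapply(sort(unique(lab)), function(g) {
      colMeans(X[lab == g, , drop = FALSE])
    }))
    lab <- match(lab, sort(unique(lab)))   # compact after empty-cluster drop
    new_lab <- assign_px(centers)
    if (all(new_lab == lab)) break
    lab <- new_lab
  }
  wcss <- sum((X - centers[lab, , drop = FALSE])^2)
  clusters <- .make_clusters(sp, lab)
  for (i in seq_along(clusters)) {
    g <- clusters[[i]]$pixels
    clusters[[i]]$centroid <- c(col = mean(g$col), row = mean(g$row))
  }
  structure(list(clusters = clusters, noise = .px_subset(sp, integer(0))),
            wcss = wcss)
}

#' Single-linkage agglomerative pixel clustering
#'
#' Every pixel starts as its own cluster; clusters absorb each other whenever
#' some cross-pair of pixels is at Euclidean distance strictly less than the
#' link threshold. The result equals the connected components of the graph
#' joining pixel pairs at distance \code{< link_threshold}, computed here by
#' union-find over grid-bucketed candidate pairs.
#'
#' @param px a [pixel_set()].
#' @param link_threshold merge distance (strict).
#' @return \code{list(clusters =, noise =)} with empty noise.
#' @export
cluster_hac <- function(px, link_threshold) {
  stopifnot(inherits(px, "pixel_set"), link_threshold > 0)
  n <- nrow(px)
  if (n == 0L) {
    return(list(clusters = list(), noise = .px_subset(px, integer(0))))
  }
  sp <- .px_subset(px, .scan_order(px))
  nbrs <- .neighbor_lists(sp$col, sp$row, link_threshold)
  t2 <- link_threshold^2
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in nbrs[[i]]) {
      if (j <= i) next
      if ((sp$col[i] - sp$col[j])^2 + (sp$row[i] - sp$row[j])^2 < t2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))    # scan-order discovery ids
  list(clusters = .make_clusters(sp, labels),
       noise = .px_subset(sp, integer(0)))
}

#' Dispatch clustering by configured method
#'
#' @param px a [pixel_set()].
#' @param params a [cluster_params()].
#' @param frame_index used as the default K-means seed.
#' @return \code{list(clusters =, noise =)}.
#' @export
cluster_pixels <- function(px, params, frame_index = 0L) {
  stopifnot(inherits(params, "cluster_params"))
  switch(params$method,
    dbscan = cluster_dbscan(px, params$eps, params$min_pts),
    kmeans = {
      k <- params$k
      if (is.na(k)) {
        k <- max(1L, length(cluster_dbscan(px, params$eps, params$min_pts)$clusters))
      }
      seed <- if (is.na(params$seed)) as.integer(frame_index) else params$seed
      if (nrow(px) < k) {
        list(clusters = list(), noise = .px_subset(px, seq_len(nrow(px))))
      } else {
        cluster_kmeans(px, k, params$max_iter, seed)
      }
    },
    hac = cluster_hac(px, params$link_threshold)
  )
}
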