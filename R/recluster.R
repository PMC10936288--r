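# Angle convention used throughout: degrees from horizontal, measured on
# screen coordinates where rows grow downward. angle = atan2(-drow, dcol), so
# a positive angle means the structure is shallower (higher on screen) at its
# right end.
.segment_angle <- function(p_from, p_to) {
  dc <- p_to[["col"]] - p_from[["col"]]
  dr <- p_to[["row"]] - p_from[["row"]]
  if (dc == 0 && dr == 0) return(NA_real_)
  atan2(-dr, dc) * 180 / pi
}

# deterministic argopt: among rows attaining the extreme of `score`, pick the
# one with smallest col, then smallest row
.pick_extreme <- function(px, score, max = FALSE) {
  s <- if (max) -score else score
  cand <- which(s == min(s))
  cand <- cand[order(px$col[cand], px$row[cand])]
  c(col = px$col[cand[1]], row = px$row[cand[1]])
}

#' Corner points of a tubular cluster
#'
#' The four "corners" of a cluster are the pixels extreme along the two
#' diagonal directions: left-up minimizes \code{col + row}, right-down
#' maximizes it, right-up maximizes \code{col - row}, left-down minimizes it.
#' Ties are broken toward smaller column then smaller row, so the corners are
#' deterministic.
#'
#' @param cl a \code{us_cluster} (or any data frame with \code{col, row}).
#' @return \code{list(LU =, LD =, RU =, RD =)} of named \code{c(col, row)}
#'   pairs, each an actual member pixel.
#' @export
corner_points <- function(cl) {
  px <- if (inherits(cl, "us_cluster")) cl$pixels else cl
  stopifnot(nrow(px) >= 1)
  list(LU = .pick_extreme(px, px$col + px$row),
       RD = .pick_extreme(px, px$col + px$row, max = TRUE),
       RU = .pick_extreme(px, px$col - px$row, max = TRUE),
       LD = .pick_extreme(px, px$col - px$row))
}

# sub-pixel corners: vertices of the oriented bounding box whose axis is the
# intensity-weighted principal axis of the pixel cloud, expanded by the
# half-pixel footprint. Returns NULL for degenerate (single-point) clusters.
.obb_corners <- function(px) {
  X <- cbind(px$col, px$row)
  if (nrow(X) < 2L) return(NULL)
  w <- pmax(px$intensity - min(px$intensity), 1)
  ctr <- colSums(X * w) / sum(w)
  Xc <- sweep(X, 2, ctr)
  C <- crossprod(Xc * sqrt(w)) / sum(w)
  if (sum(abs(C)) < 1e-12) return(NULL)
  ev <- eigen(C, symmetric = TRUE)
  u <- ev$vectors[, 1]
  if (u[1] < 0) u <- -u
  v <- c(-u[2], u[1])
  pu <- Xc %*% u; pv <- Xc %*% v
  vtx <- function(a, b) {
    p <- ctr + a * u + b * v
    c(col = p[1], row = p[2])
  }
  u0 <- min(pu) - 0.5; u1 <- max(pu) + 0.5
  v0 <- min(pv) - 0.5; v1 <- max(pv) + 0.5
  # label vertices by tube end (left/right along the axis, u[1] >= 0 so +u
  # points rightward or straight down) and by side (shallower row = "up");
  # this stays well defined when the axis lies exactly on +-45 degrees,
  # where a col+row labeling of the vertices degenerates
  ends <- list(left = list(vtx(u0, v0), vtx(u0, v1)),
               right = list(vtx(u1, v0), vtx(u1, v1)))
  pick <- function(pair, up) {
    rows <- c(pair[[1]][["row"]], pair[[2]][["row"]])
    pair[[if (up) which.min(rows) else which.max(rows)]]
  }
  list(LU = pick(ends$left, TRUE), LD = pick(ends$left, FALSE),
       RU = pick(ends$right, TRUE), RD = pick(ends$right, FALSE))
}

#' Orient a cluster by its corner diagonals
#'
#' Draws the two lines joining opposite corners (L1: left-up to right-down,
#' L2: left-down to right-up), takes each line's inclination from horizontal,
#' and averages them. For a tubular (elongated, thin) cluster this mean
#' estimates the tube's orientation.
#'
#' Two corner localizations are available. The default, \code{"obb"}, places
#' the corners at the vertices of the cluster's oriented bounding box (axis =
#' intensity-weighted principal axis of the pixel cloud, expanded by the
#' half-pixel footprint): corners are then sub-pixel quantities and the
#' diagonal mean tracks the true orientation to a fraction of a degree even
#' on 40-pixel tubes. \code{"pixel"} uses the literal extreme member pixels
#' of [corner_points()]; its single-pixel rounding costs roughly 1–2 degrees
#' on short tubes, but it involves no moment computation. Also records the
#' most-left and most-right member pixels, used later for merging and
#' plausibility checks.
#'
#' @param cl a \code{us_cluster}.
#' @param corner_method \code{"obb"} (default) or \code{"pixel"}.
#' @return object of class \code{oriented_cluster}: list with \code{id},
#'   \code{pixels}, \code{corners} (the member-pixel corners of
#'   [corner_points()]), \code{bbox} (the sub-pixel corners actually used
#'   when \code{corner_method = "obb"}), \code{alpha1_deg}, \code{alpha2_deg},
#'   \code{angle_deg} (their mean), \code{p_left}, \code{p_right} and a
#'   \code{degenerate} flag (angle forced to 0 for single-point clusters).
#' @export
cluster_angle <- function(cl, corner_method = c("obb", "pixel")) {
  stopifnot(inherits(cl, "us_cluster"))
  corner_method <- match.arg(corner_method)
  px <- cl$pixels
  co <- corner_points(cl)
  bbox <- NULL
  if (corner_method == "obb") {
    bbox <- .obb_corners(px)
    src <- if (is.null(bbox)) co else bbox
  } else {
    src <- co
  }
  a1 <- .segment_angle(src$LU, src$RD)
  a2 <- .segment_angle(src$LD, src$RU)
  degenerate <- is.na(a1) || is.na(a2)
  # a diagonal collapses to a point when the tube lies exactly on +-45 deg;
  # the surviving diagonal then carries the orientation. Single pixel: 0.
  if (is.na(a1) && is.na(a2)) {
    a1 <- a2 <- 0
  } else if (is.na(a1)) {
    a1 <- a2
  } else if (is.na(a2)) {
    a2 <- a1
  }
  structure(list(id = cl$id, pixels = px, corners = co, bbox = bbox,
                 alpha1_deg = a1, alpha2_deg = a2,
                 angle_deg = (a1 + a2) / 2,
                 p_left = .pick_extreme(px, px$col),
                 p_right = .pick_extreme(px, px$col, max = TRUE),
                 degenerate = degenerate),
            class = "oriented_cluster")
}

#' @export
print.oriented_cluster <- function(x, ...) {
  cat(sprintf("<oriented_cluster #%d: %d px, angle %.2f deg>\n",
              x$id, nrow(x$pixels), x$angle_deg))
  invisible(x)
}

#' Orient a list of clusters, dropping tiny ones
#'
#' Clusters below \code{min_px} members are discarded before orientation:
#' corner diagonals of single-digit-pixel blobs carry no directional
#' information.
#'
#' @param clusters list of \code{us_cluster}.
#' @param min_px minimum member count (default 15).
#' @param corner_method passed to [cluster_angle()].
#' @return list of [cluster_angle()] results.
#' @export
orient_clusters <- function(clusters, min_px = 15L, corner_method = "obb") {
  keep <- Filter(function(cl) nrow(cl$pixels) >= min_px, clusters)
  lapply(keep, cluster_angle, corner_method = corner_method)
}

#' Re-clustering tolerances
#'
#' @param angle_tol_deg maximum difference between the two cluster angles for
#'   a pair to be a merge candidate.
#' @param connect_tol_deg maximum difference between the connection angle and
#'   the mean of the two cluster angles.
#' @param max_gap_px maximum lateral gap between the left cluster's right end
#'   and the right cluster's left end (caps long-range collinear merges).
#' @param plausibility apply the fascicle-slope plausibility rule.
#' @param fascicle_rises which end of a plausible fascicle is shallower:
#'   \code{"right"} (positive inclination) or \code{"left"} (the mirror
#'   orientation; which applies depends on probe placement).
#' @param apo_max_angle_deg bottom-ROI clusters steeper than this are
#'   implausible aponeuroses.
#' @return object of class \code{merge_params}.
#' @export
merge_params <- function(angle_tol_deg = 5, connect_tol_deg = 5,
                         max_gap_px = 40, plausibility = TRUE,
                         fascicle_rises = c("right", "left"),
                         apo_max_angle_deg = 15) {
  stopifnot(angle_tol_deg >= 0, connect_tol_deg >= 0, max_gap_px >= 0,
            apo_max_angle_deg >= 0)
  structure(list(angle_tol_deg = angle_tol_deg,
                 connect_tol_deg = connect_tol_deg,
                 max_gap_px = max_gap_px,
                 plausibility = isTRUE(plausibility),
                 fascicle_rises = match.arg(fascicle_rises),
                 apo_max_angle_deg = apo_max_angle_deg),
            class = "merge_params")
}

#' Connection angle between two laterally ordered clusters
#'
#' The inclination of the segment joining a point of the left cluster to a
#' point of the right cluster, compared with the pair's mean cluster angle to
#' decide whether the two are fragments of one tube. Each cluster is anchored
#' at its pixel centroid: for collinear tube fragments the centroids lie on
#' the common centerline, so the connection angle equals the tube angle
#' exactly, and — unlike single corner pixels, whose one-pixel rasterization
#' jitter tilts the short connecting segment by several degrees — the
#' centroid averages that noise away. Defined only when one cluster is
#' strictly to the right of the other.
#'
#' @param left,right \code{oriented_cluster}s with
#'   \code{right$p_left["col"] > left$p_right["col"]}.
#' @return connection angle in degrees, or \code{NA} when the clusters are
#'   not strictly ordered (not a merge candidate).
#' @export
connection_angle <- function(left, right) {
  if (right$p_left[["col"]] <= left$p_right[["col"]]) return(NA_real_)
  .segment_angle(c(col = mean(left$pixels$col), row = mean(left$pixels$row)),
                 c(col = mean(right$pixels$col), row = mean(right$pixels$row)))
}

.merge_two <- function(a, b) {
  px <- rbind(a$pixels, b$pixels)
  rownames(px) <- NULL
  attributes(px)[c("origin_roi", "offset", "class")] <-
    attributes(a$pixels)[c("origin_roi", "offset", "class")]
  cluster_angle(structure(list(id = min(a$id, b$id), pixels = px),
                          class = "us_cluster"))
}

#' Merge collinear cluster fragments
#'
#' Repeatedly scans cluster pairs ordered by lateral position and merges any
#' strictly left/right pair whose cluster angles agree within
#' \code{angle_tol_deg}, whose connection angle agrees with their mean angle
#' within \code{connect_tol_deg}, and whose lateral gap is at most
#' \code{max_gap_px}. The merged cluster is the pixel union with freshly
#' derived corners and angle. Runs to a fixpoint (applying it again changes
#' nothing); member pixels are conserved.
#'
#' @param clusters list of \code{oriented_cluster}.
#' @param p a [merge_params()].
#' @return list of \code{oriented_cluster}, at most as long as the input.
#' @export
merge_pass <- function(clusters, p) {
  stopifnot(inherits(p, "merge_params"))
  cl <- clusters
  repeat {
    if (length(cl) < 2L) break
    cl <- cl[order(vapply(cl, function(x) x$p_left[["col"]], numeric(1)),
                   vapply(cl, function(x) x$id, numeric(1)))]
    merged <- FALSE
    for (i in seq_len(length(cl) - 1L)) {
      for (j in (i + 1L):length(cl)) {
        a <- cl[[i]]; b <- cl[[j]]
        lr <- if (b$p_left[["col"]] > a$p_right[["col"]]) list(a, b)
              else if (a$p_left[["col"]] > b$p_right[["col"]]) list(b, a)
              else next
        left <- lr[[1]]; right <- lr[[2]]
        gap <- right$p_left[["col"]] - left$p_right[["col"]]
        if (gap > p$max_gap_px) next
        if (abs(left$angle_deg - right$angle_deg) > p$angle_tol_deg) next
        beta <- connection_angle(left, right)
        if (is.na(beta)) next
        if (abs(beta - (left$angle_deg + right$angle_deg) / 2) >
              p$connect_tol_deg) next
        cl[[i]] <- .merge_two(left, right)
        cl[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  cl
}

#' Plausibility filtering of oriented clusters
#'
#' Applies anatomy-based rules: in the top ROI a genuine fascicle runs
#' obliquely, with one fixed end shallower than the other (which end depends
#' on probe orientation; see \code{fascicle_rises} in [merge_params()]). In
#' the bottom ROI the aponeurosis is near horizontal, so clusters steeper
#' than \code{apo_max_angle_deg} are dropped.
#'
#' @param clusters list of \code{oriented_cluster}.
#' @param roi \code{"top"} or \code{"bottom"}.
#' @param p a [merge_params()].
#' @return filtered list.
#' @export
plausibility_filter <- function(clusters, roi = c("top", "bottom"), p) {
  roi <- match.arg(roi)
  stopifnot(inherits(p, "merge_params"))
  if (!p$plausibility) return(clusters)
  keep <- vapply(clusters, function(x) {
    if (roi == "top") {
      if (p$fascicle_rises == "right") {
        x$p_right[["row"]] < x$p_left[["row"]]   # right end shallower
      } else {
        x$p_left[["row"]] < x$p_right[["row"]]   # left end shallower
      }
    } else {
      abs(x$angle_deg) <= p$apo_max_angle_deg
    }
  }, logical(1))
  clusters[keep]
}
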