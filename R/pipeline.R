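#' Full pipeline configuration
#'
#' Bundles every stage's parameters. The no-augmentation (identity) path is
#' always run; additional elliptical augmentation filters each contribute one
#' candidate angle per frame, fused by the viscosity-weighted average before
#' temporal smoothing.
#'
#' @param roi an [roi_spec()] (one ROI specification per trial).
#' @param denoise_threshold brightness cut in \code{[0, 256]}.
#' @param augmentation_filters list of [ellipse_filter()] applied to the top
#'   sub-image (possibly empty).
#' @param clustering a [cluster_params()].
#' @param merge a [merge_params()].
#' @param value a [value_weights()].
#' @param viscosity a [viscosity_params()] for across-frame smoothing.
#' @param fusion a [fusion_params()] for within-frame filter fusion.
#' @param min_cluster_px clusters smaller than this are dropped before
#'   orientation.
#' @param smooth \code{TRUE} to apply temporal viscosity smoothing.
#' @param frame_rate Hz.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(roi,
                            denoise_threshold = 100,
                            augmentation_filters = list(),
                            clustering = cluster_params(),
                            merge = merge_params(),
                            value = value_weights(),
                            viscosity = viscosity_params(),
                            fusion = fusion_params(),
                            min_cluster_px = 15L,
                            smooth = TRUE,
                            frame_rate = 20) {
  stopifnot(inherits(roi, "roi_spec"),
            denoise_threshold >= 0, denoise_threshold <= 256,
            inherits(clustering, "cluster_params"),
            inherits(merge, "merge_params"),
            inherits(value, "value_weights"),
            inherits(viscosity, "viscosity_params"),
            inherits(fusion, "fusion_params"))
  for (f in augmentation_filters) stopifnot(inherits(f, "ellipse_filter"))
  structure(list(roi = roi, denoise_threshold = denoise_threshold,
                 augmentation_filters = augmentation_filters,
                 clustering = clustering, merge = merge, value = value,
                 viscosity = viscosity, fusion = fusion,
                 min_cluster_px = as.integer(min_cluster_px),
                 smooth = isTRUE(smooth),
                 frame_rate = frame_rate),
            class = "pipeline_config")
}

# one ROI -> candidate oriented clusters, after the full spatial chain
.detect_candidates <- function(sub, origin_roi, cfg, frame_index) {
  px <- denoise(sub, cfg$denoise_threshold, origin_roi = origin_roi)
  if (nrow(px) == 0L) return(list())
  res <- cluster_pixels(px, cfg$clustering, frame_index = frame_index)
  oriented <- orient_clusters(res$clusters, min_px = cfg$min_cluster_px)
  merged <- merge_pass(oriented, cfg$merge)
  plausibility_filter(merged, roi = origin_roi, p = cfg$merge)
}

# detect fascicle angle in (possibly augmented) top sub-image
.detect_fascicle <- function(top, cfg, frame_index) {
  cand <- .detect_candidates(top, "top", cfg, frame_index)
  select_target(cand, cfg$value)
}

#' Track the pennation angle through a frame sequence
#'
#' Runs the stream pipeline per frame: trim into the two ROIs; for the
#' identity path and each configured augmentation filter, threshold-denoise,
#' cluster, re-cluster and select the target fascicle; detect the aponeurosis
#' once per frame from the bottom ROI; form each filter's raw PA; fuse the
#' per-filter PAs with viscosity weights against the previous final PA; then
#' blend with the temporal prediction via the viscosity function. Frames with
#' no detection inherit the previous final PA (\code{status = "fallback"});
#' frames before the first success are \code{"no_detection"}.
#'
#' @param frames list of [us_frame()] in temporal order.
#' @param cfg a [pipeline_config()].
#' @param verbose print a per-frame summary line.
#' @return data.frame of class \code{angle_estimates} with columns
#'   \code{frame, time_s, fascicle_deg, aponeurosis_deg, pa_raw_deg,
#'   pa_final_deg, weight_used, status}. \code{pa_raw_deg} is the
#'   identity-path (no augmentation, no temporal information) PA.
#' @export
track_sequence <- function(frames, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (length(frames) == 0L) stop("need at least one frame")
  n <- length(frames)
  out <- data.frame(frame = vapply(frames, attr, integer(1), "frame_index"),
                    time_s = vapply(frames, attr, numeric(1), "time_s"),
                    fascicle_deg = NA_real_, aponeurosis_deg = NA_real_,
                    pa_raw_deg = NA_real_, pa_final_deg = NA_real_,
                    weight_used = NA_real_, status = "no_detection",
                    stringsAsFactors = FALSE)
  prev1 <- NA_real_; prev2 <- NA_real_
  n_success <- 0L
  # the no-augmentation path always runs; configured gain-1 filters are the
  # identity and would only duplicate it (shifting the epsilon bias)
  filters <- c(list(identity_filter()),
               Filter(function(f) f$gain > 1, cfg$augmentation_filters))
  for (i in seq_len(n)) {
    fi <- out$frame[i]
    rois <- trim(frames[[i]], cfg$roi)
    apo <- select_target(
      .detect_candidates(rois$bottom, "bottom", cfg, fi), cfg$value)
    pas <- rep(NA_real_, length(filters))
    fasc_id <- NULL
    for (k in seq_along(filters)) {
      top_k <- augment(rois$top, filters[[k]])
      fasc <- .detect_fascicle(top_k, cfg, fi)
      if (k == 1L) fasc_id <- fasc
      if (fasc$status == "ok" && apo$status == "ok") {
        pas[k] <- compute_pa(fasc$angle_deg, apo$angle_deg)
      }
    }
    out$fascicle_deg[i] <- fasc_id$angle_deg
    out$aponeurosis_deg[i] <- apo$angle_deg
    out$pa_raw_deg[i] <- pas[1]

    if (!cfg$smooth) {
      det <- pas[is.finite(pas)]
      if (length(det)) {
        out$pa_final_deg[i] <- det[1]
        out$status[i] <- "ok"
      } else if (is.finite(prev1)) {
        out$pa_final_deg[i] <- prev1
        out$status[i] <- "fallback"
      }
    } else {
      fused <- fuse_filters(pas, prev1, cfg$fusion)
      if (fused$status == "no_detection") {
        # nothing detected and no history yet
      } else if (fused$status == "fallback") {
        out$pa_final_deg[i] <- fused$angle_deg
        out$status[i] <- "fallback"
      } else if (n_success < 2L) {
        # bootstrap: first two successful frames pass the fused angle through
        out$pa_final_deg[i] <- fused$angle_deg
        out$weight_used[i] <- 1
        out$status[i] <- "ok"
        n_success <- n_success + 1L
      } else {
        sm <- smooth_angle(fused$angle_deg, prev1, prev2, cfg$viscosity)
        out$pa_final_deg[i] <- sm$angle_deg
        out$weight_used[i] <- sm$lambda
        out$status[i] <- "ok"
      }
    }
    if (is.finite(out$pa_final_deg[i])) {
      prev2 <- if (is.finite(prev1)) prev1 else out$pa_final_deg[i]
      prev1 <- out$pa_final_deg[i]
    }
    if (verbose) {
      message(sprintf("frame %3d: raw %6.2f final %6.2f [%s]",
                      fi, out$pa_raw_deg[i], out$pa_final_deg[i],
                      out$status[i]))
    }
  }
  class(out) <- c("angle_estimates", "data.frame")
  out
}

#' Write per-frame angle estimates to CSV
#'
#' @param estimates result of [track_sequence()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(estimates, path) {
  df <- as.data.frame(estimates)[, c("frame", "time_s", "fascicle_deg",
                                     "aponeurosis_deg", "pa_raw_deg",
                                     "pa_final_deg", "status")]
  for (cn in c("fascicle_deg", "aponeurosis_deg", "pa_raw_deg", "pa_final_deg")) {
    df[[cn]] <- sprintf("%.2f", df[[cn]])
    df[[cn]][df[[cn]] == "NA"] <- ""
  }
  df$status <- tolower(df$status)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- YAML config ----------------------------------------------------------

#' Read a pipeline configuration from YAML
#'
#' The config file is a flat YAML document; see
#' \code{system.file("extdata", "example_config.yaml", package = "pennate")}
#' for a complete commented example. All angles are degrees, all lengths
#' pixels.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  grab <- function(lst, defaults) {
    args <- defaults
    for (nm in names(lst)) args[[nm]] <- lst[[nm]]
    args
  }
  roi <- roi_spec(top_rows = unlist(y$roi$top_rows),
                  top_cols = unlist(y$roi$top_cols),
                  bottom_rows = unlist(y$roi$bottom_rows),
                  bottom_cols = unlist(y$roi$bottom_cols))
  filters <- lapply(y$augmentation_filters, function(f) {
    ellipse_filter(center = unlist(f$center), semi_major = f$semi_major,
                   semi_minor = f$semi_minor,
                   rotation_deg = f$rotation_deg %||% 0,
                   gain = f$gain %||% 1)
  })
  clustering <- do.call(cluster_params, grab(y$clustering, list()))
  merge <- do.call(merge_params, grab(y$merge, list()))
  value <- do.call(value_weights, grab(y$value, list()))
  viscosity <- do.call(viscosity_params, grab(y$viscosity, list()))
  fusion <- fusion_params(
    epsilon = y$fusion$epsilon %||% 1e-6,
    lambda_floor = y$fusion$lambda_floor %||% 1e-3,
    viscosity = do.call(viscosity_params,
                        grab(y$fusion$viscosity, list())))
  pipeline_config(roi = roi,
                  denoise_threshold = y$denoise_threshold %||% 100,
                  augmentation_filters = filters,
                  clustering = clustering, merge = merge, value = value,
                  viscosity = viscosity, fusion = fusion,
                  min_cluster_px = y$min_cluster_px %||% 15L,
                  smooth = y$smooth %||% TRUE,
                  frame_rate = y$frame_rate %||% 20)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
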