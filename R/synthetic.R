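#' Synthetic B-mode scene specification
#'
#' Describes a synthetic ultrasound frame with known geometry: a bright
#' tubular fascicle strip (optionally split into collinear fragments) in the
#' top half, a near-horizontal bright aponeurosis band in the bottom half,
#' additive Gaussian speckle, optional bright distractor blobs and an
#' optional low-contrast shadow band. The ground-truth pennation angle is
#' recomputable from the spec alone.
#'
#' Angles follow the package convention (positive = rising to the right);
#' with a positive fascicle inclination and a non-positive aponeurosis
#' inclination the pennation angle is the sum of the magnitudes.
#'
#' @param frame_shape \code{c(rows, cols)}; the frame is split into a top ROI
#'   (fascicle, upper half) and bottom ROI (aponeurosis, lower half).
#' @param fascicle_angle_deg ground-truth fascicle inclination (degrees).
#' @param fascicle_thickness_px,fascicle_intensity strip geometry/brightness.
#' @param fascicle_fragments number of collinear fragments the strip is split
#'   into (\code{>= 1}), separated by \code{fragment_gap_px} lateral gaps.
#' @param fragment_gap_px lateral gap between fragments (pixels).
#' @param fascicle_halfspan_px half of the fascicle's lateral extent.
#' @param aponeurosis_angle_deg,aponeurosis_thickness_px,aponeurosis_intensity
#'   aponeurosis band geometry/brightness.
#' @param background_mean mean background intensity.
#' @param speckle_sigma standard deviation of the additive Gaussian speckle.
#' @param distractor_blobs number of bright circular distractor blobs in the
#'   top ROI.
#' @param distractor_intensity,distractor_radius_px blob brightness/size.
#' @param shadow_band optional \code{list(cols = c(from, to), attenuation =)}
#'   multiplying intensities in a column band by \code{attenuation} in
#'   \code{(0, 1]} (a shadowed, low-contrast region).
#' @param seed RNG seed; frames are bit-identical for identical spec + seed.
#' @return object of class \code{scene_spec}.
#' @export
scene_spec <- function(frame_shape = c(128, 256),
                       fascicle_angle_deg = 12,
                       fascicle_thickness_px = 4,
                       fascicle_intensity = 200,
                       fascicle_fragments = 1L,
                       fragment_gap_px = 10,
                       fascicle_halfspan_px = 56,
                       aponeurosis_angle_deg = -2,
                       aponeurosis_thickness_px = 5,
                       aponeurosis_intensity = 220,
                       background_mean = 20,
                       speckle_sigma = 10,
                       distractor_blobs = 0L,
                       distractor_intensity = 240,
                       distractor_radius_px = 6,
                       shadow_band = NULL,
                       seed = 0L) {
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 16),
            fascicle_thickness_px >= 1, aponeurosis_thickness_px >= 1,
            fascicle_fragments >= 1,
            fascicle_intensity >= 0, fascicle_intensity <= 255,
            aponeurosis_intensity >= 0, aponeurosis_intensity <= 255,
            background_mean >= 0, background_mean <= 255,
            speckle_sigma >= 0, distractor_blobs >= 0)
  if (!is.null(shadow_band)) {
    stopifnot(length(shadow_band$cols) == 2,
              shadow_band$attenuation > 0, shadow_band$attenuation <= 1)
  }
  structure(list(frame_shape = as.integer(frame_shape),
                 fascicle_angle_deg = fascicle_angle_deg,
                 fascicle_thickness_px = fascicle_thickness_px,
                 fascicle_intensity = fascicle_intensity,
                 fascicle_fragments = as.integer(fascicle_fragments),
                 fragment_gap_px = fragment_gap_px,
                 fascicle_halfspan_px = fascicle_halfspan_px,
                 aponeurosis_angle_deg = aponeurosis_angle_deg,
                 aponeurosis_thickness_px = aponeurosis_thickness_px,
                 aponeurosis_intensity = aponeurosis_intensity,
                 background_mean = background_mean,
                 speckle_sigma = speckle_sigma,
                 distractor_blobs = as.integer(distractor_blobs),
                 distractor_intensity = distractor_intensity,
                 distractor_radius_px = distractor_radius_px,
                 shadow_band = shadow_band,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# default ROI split of a synthetic frame: top half / bottom half
.scene_roi <- function(spec) {
  nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
  roi_spec(top_rows = c(0, nr %/% 2), top_cols = c(0, nc),
           bottom_rows = c(nr %/% 2, nr), bottom_cols = c(0, nc))
}

# paint an anti-aliased tubular strip onto matrix m (0-based pixel centers).
# Centerline passes through (c0, r0) at `angle_deg`, longitudinal extent
# [t0, t1] along the tube axis. Coverage-weighted blend toward `intensity`.
.paint_strip <- function(m, c0, r0, angle_deg, thickness, t0, t1, intensity) {
  nr <- nrow(m); nc <- ncol(m)
  th <- angle_deg * pi / 180
  d <- c(cos(th), -sin(th))               # tube axis in (col, row)
  cols <- matrix(rep(0:(nc - 1L), each = nr), nr, nc) - c0
  rows <- matrix(rep(0:(nr - 1L), times = nc), nr, nc) - r0
  t_len <- cols * d[1] + rows * d[2]      # longitudinal coordinate
  s_perp <- cols * -d[2] + rows * d[1]    # signed perpendicular distance
  cov <- pmin(1, pmax(0, thickness / 2 + 0.5 - abs(s_perp))) *
         pmin(1, pmax(0, pmin(t_len - t0, t1 - t_len) + 0.5))
  pmax(m, m + cov * (intensity - m))
}

.paint_disc <- function(m, c0, r0, radius, intensity) {
  nr <- nrow(m); nc <- ncol(m)
  cols <- matrix(rep(0:(nc - 1L), each = nr), nr, nc) - c0
  rows <- matrix(rep(0:(nr - 1L), times = nc), nr, nc) - r0
  cov <- pmin(1, pmax(0, radius + 0.5 - sqrt(cols^2 + rows^2)))
  pmax(m, m + cov * (intensity - m))
}

# check a strip stays inside [row_lo, row_hi) rows given its extent
.strip_fits <- function(r0, angle_deg, halfspan, thickness, row_lo, row_hi) {
  exc <- abs(halfspan * tan(angle_deg * pi / 180)) + thickness / 2 + 1
  (r0 - exc) >= row_lo && (r0 + exc) <= (row_hi - 1)
}

#' Generate one synthetic frame with ground truth
#'
#' Rasterizes the scene with coverage-weighted (anti-aliased) strips,
#' quantizes to 8 bits, and adds clipped Gaussian speckle. Deterministic for
#' a given spec (the spec's seed drives all randomness).
#'
#' @param spec a [scene_spec()].
#' @param frame_index,frame_rate frame metadata.
#' @return \code{list(frame = us_frame, truth = list(fascicle_angle_deg,
#'   aponeurosis_angle_deg, pa_deg, roi))}.
#' @export
make_frame <- function(spec, frame_index = 0L, frame_rate = 20) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
  roi <- .scene_roi(spec)
  split_row <- roi$bottom_rows[1]

  # fascicle: centered in the top ROI
  fc0 <- (nc - 1) / 2
  fr0 <- split_row / 2
  if (!.strip_fits(fr0, spec$fascicle_angle_deg, spec$fascicle_halfspan_px,
                   spec$fascicle_thickness_px, 0, split_row)) {
    stop("fascicle geometry does not fit inside the top ROI")
  }
  # aponeurosis: centered in the bottom ROI
  ac0 <- (nc - 1) / 2
  ar0 <- (split_row + nr) / 2
  a_halfspan <- nc / 2 - 8
  if (!.strip_fits(ar0, spec$aponeurosis_angle_deg, a_halfspan,
                   spec$aponeurosis_thickness_px, split_row, nr)) {
    stop("aponeurosis geometry does not fit inside the bottom ROI")
  }

  m <- matrix(spec$background_mean, nr, nc)
  # fascicle fragments: split the longitudinal extent, gaps between fragments
  cth <- cos(spec$fascicle_angle_deg * pi / 180)
  t_half <- spec$fascicle_halfspan_px / cth
  nfrag <- spec$fascicle_fragments
  gap <- spec$fragment_gap_px
  seg_len <- (2 * t_half - (nfrag - 1) * gap) / nfrag
  if (seg_len <= 2) stop("fascicle fragments too short; reduce fragments or gap")
  for (i in seq_len(nfrag)) {
    t0 <- -t_half + (i - 1) * (seg_len + gap)
    m <- .paint_strip(m, fc0, fr0, spec$fascicle_angle_deg,
                      spec$fascicle_thickness_px, t0, t0 + seg_len,
                      spec$fascicle_intensity)
  }
  m <- .paint_strip(m, ac0, ar0, spec$aponeurosis_angle_deg,
                    spec$aponeurosis_thickness_px, -a_halfspan / 1, a_halfspan,
                    spec$aponeurosis_intensity)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  if (spec$distractor_blobs > 0L) {
    # distractors model distinct bright tissue echoes (separate clusters),
    # so they are kept clear of the fascicle band: a blob fused to the
    # fascicle would change the cluster whose angle is the ground truth
    fth <- spec$fascicle_angle_deg * pi / 180
    fn <- c(sin(fth), cos(fth))             # fascicle normal in (col, row)
    clearance <- spec$fascicle_thickness_px / 2 + spec$distractor_radius_px + 5
    for (i in seq_len(spec$distractor_blobs)) {
      for (try in 1:50) {
        bc <- stats::runif(1, spec$distractor_radius_px + 2,
                           nc - spec$distractor_radius_px - 3)
        br <- stats::runif(1, spec$distractor_radius_px + 2,
                           split_row - spec$distractor_radius_px - 3)
        d_perp <- abs((bc - fc0) * fn[1] + (br - fr0) * fn[2])
        if (d_perp > clearance) break
      }
      m <- .paint_disc(m, bc, br, spec$distractor_radius_px,
                       spec$distractor_intensity)
    }
  }
  if (!is.null(spec$shadow_band)) {
    cs <- spec$shadow_band$cols
    m[, (cs[1] + 1L):cs[2]] <- m[, (cs[1] + 1L):cs[2]] * spec$shadow_band$attenuation
  }
  m <- round(m)
  if (spec$speckle_sigma > 0) {
    m <- m + round(stats::rnorm(length(m), 0, spec$speckle_sigma))
  }
  m <- pmin(pmax(m, 0L), 255L)

  truth <- list(fascicle_angle_deg = spec$fascicle_angle_deg,
                aponeurosis_angle_deg = spec$aponeurosis_angle_deg,
                pa_deg = compute_pa(spec$fascicle_angle_deg,
                                    spec$aponeurosis_angle_deg),
                roi = roi)
  list(frame = us_frame(m, frame_index = frame_index,
                        time_s = frame_index / frame_rate),
       truth = truth)
}

#' Generate a synthetic frame sequence with a PA trajectory
#'
#' The aponeurosis inclination is held fixed while the fascicle inclination
#' varies frame-to-frame to realize the requested pennation-angle trajectory.
#' Corrupted frames emulate a fascicle that barely shows: its intensity drops
#' to 10%, and (in the default \code{"distractor"} mode) a bright wrong-angle
#' strip is drawn instead — the high-value distractor case — so the raw
#' detection locks onto a grossly wrong angle that temporal smoothing must
#' reject. In \code{"dim"} mode the fascicle merely fades, yielding a missing
#' detection instead of a wrong one.
#'
#' @param base a [scene_spec()]; its fascicle angle is overridden per frame.
#' @param n_frames number of frames.
#' @param pa_trajectory ground-truth PA per frame (length \code{n_frames}).
#' @param corrupt_frames 0-based indices of corrupted frames.
#' @param corrupt_mode \code{"distractor"} or \code{"dim"}.
#' @param corrupt_offset_deg angular offset of the distractor strip from the
#'   true fascicle.
#' @param frame_rate Hz.
#' @return \code{list(frames = list of us_frame, truth = data.frame(frame,
#'   time_s, fascicle_angle_deg, aponeurosis_angle_deg, pa_deg, corrupted),
#'   roi = roi_spec)}.
#' @export
make_sequence <- function(base, n_frames, pa_trajectory,
                          corrupt_frames = integer(),
                          corrupt_mode = c("distractor", "dim"),
                          corrupt_offset_deg = 25,
                          frame_rate = 20) {
  stopifnot(inherits(base, "scene_spec"))
  corrupt_mode <- match.arg(corrupt_mode)
  if (length(pa_trajectory) != n_frames) {
    stop("pa_trajectory must have one PA per frame")
  }
  roi <- .scene_roi(base)
  frames <- vector("list", n_frames)
  truth <- data.frame(frame = seq_len(n_frames) - 1L,
                      time_s = (seq_len(n_frames) - 1L) / frame_rate,
                      fascicle_angle_deg = NA_real_,
                      aponeurosis_angle_deg = base$aponeurosis_angle_deg,
                      pa_deg = pa_trajectory,
                      corrupted = FALSE)
  for (i in seq_len(n_frames)) {
    idx <- i - 1L
    spec_i <- base
    spec_i$fascicle_angle_deg <- pa_trajectory[i] + base$aponeurosis_angle_deg
    spec_i$seed <- base$seed + idx
    truth$fascicle_angle_deg[i] <- spec_i$fascicle_angle_deg
    corrupted <- idx %in% corrupt_frames
    truth$corrupted[i] <- corrupted
    if (!corrupted) {
      frames[[i]] <- make_frame(spec_i, frame_index = idx,
                                frame_rate = frame_rate)$frame
      next
    }
    spec_i$fascicle_intensity <- round(0.1 * base$fascicle_intensity)
    fr <- make_frame(spec_i, frame_index = idx, frame_rate = frame_rate)$frame
    if (corrupt_mode == "distractor") {
      m <- matrix(as.numeric(fr), nrow(fr), ncol(fr))
      wrong <- spec_i$fascicle_angle_deg + corrupt_offset_deg
      halfspan <- 28
      t_half <- halfspan / cos(wrong * pi / 180)
      m <- .paint_strip(m, (ncol(fr) - 1) / 2, roi$bottom_rows[1] / 2, wrong,
                        base$fascicle_thickness_px, -t_half, t_half,
                        base$fascicle_intensity)
      m <- pmin(pmax(round(m), 0L), 255L)
      fr2 <- us_frame(m, frame_index = idx, time_s = idx / frame_rate)
      fr <- fr2
    }
    frames[[i]] <- fr
  }
  list(frames = frames, truth = truth, roi = roi)
}

#' Write a synthetic sequence to disk
#'
#' Writes 8-bit grayscale PNG frames (\code{frame_0000.png}, ...) plus a
#' \code{truth.csv} with the generating geometry; the frames round-trip
#' through [load_frames()] bit-exactly.
#'
#' @param seq_out result of [make_sequence()].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic <- function(seq_out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(seq_out$frames)) {
    fr <- seq_out$frames[[i]]
    png::writePNG(matrix(as.numeric(fr) / 255, nrow(fr), ncol(fr)),
                  file.path(dir, sprintf("frame_%04d.png", i - 1L)))
  }
  utils::write.csv(seq_out$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
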