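#' Foreground pixel set
#'
#' The pixels of one sub-image that survive brightness thresholding, as a
#' data frame with 0-based ROI-local coordinates. Carries the ROI origin and
#' the full-frame offset as attributes.
#'
#' @param col,row integer 0-based coordinates (col = lateral, row = depth).
#' @param intensity integer echo intensities in \code{[0, 255]}.
#' @param origin_roi \code{"top"} or \code{"bottom"}.
#' @param offset 0-based \code{c(row, col)} of the ROI within the full frame.
#' @return data.frame of class \code{pixel_set} with columns
#'   \code{col, row, intensity}.
#' @export
pixel_set <- function(col = integer(), row = integer(), intensity = integer(),
                      origin_roi = "top", offset = c(row = 0L, col = 0L)) {
  if (anyDuplicated(cbind(col, row))) stop("duplicate (col, row) pixels")
  origin_roi <- match.arg(origin_roi, c("top", "bottom"))
  structure(data.frame(col = as.integer(col), row = as.integer(row),
                       intensity = as.integer(intensity)),
            origin_roi = origin_roi,
            offset = offset,
            class = c("pixel_set", "data.frame"))
}

#' Map a pixel set to full-frame coordinates
#'
#' @param px a [pixel_set()].
#' @return data.frame with \code{col, row} translated by the stored offset.
#' @export
frame_coords <- function(px) {
  off <- attr(px, "offset")
  data.frame(col = px$col + off[["col"]], row = px$row + off[["row"]],
             intensity = px$intensity)
}

#' Threshold-denoise a sub-image
#'
#' Removes every pixel whose brightness is lower than the threshold; pixels
#' with intensity equal to the threshold are kept. This is the only denoising
#' step of the pipeline: speckle that stays below the threshold never reaches
#' the clustering stage.
#'
#' @param sub an [us_frame()] sub-image.
#' @param threshold intensity cut in \code{[0, 256]}; 0 keeps everything,
#'   256 removes everything.
#' @param origin_roi which ROI the sub-image came from.
#' @return a [pixel_set()] of the surviving pixels (possibly empty), in
#'   ROI-local 0-based coordinates.
#' @export
denoise <- function(sub, threshold, origin_roi = c("top", "bottom")) {
  stopifnot(inherits(sub, "us_frame"), threshold >= 0, threshold <= 256)
  origin_roi <- match.arg(origin_roi)
  keep <- which(unclass(sub) >= threshold, arr.ind = TRUE)
  pixel_set(col = keep[, 2] - 1L, row = keep[, 1] - 1L,
            intensity = unclass(sub)[keep],
            origin_roi = origin_roi, offset = attr(sub, "offset"))
}

#' Elliptical augmentation filter
#'
#' A user-positioned ellipse inside which pixel brightness is multiplied by a
#' gain (clipped to 255), used to highlight a faint or shadowed fascicle
#' before thresholding. Parameterized by center, semi-axes and rotation
#' (interconvertible with a focus/vertex parameterization).
#'
#' @param center 0-based \code{c(col, row)} of the ellipse center, in the
#'   coordinates of the sub-image it will be applied to.
#' @param semi_major,semi_minor semi-axis lengths in pixels,
#'   \code{semi_major >= semi_minor > 0}.
#' @param rotation_deg rotation of the major axis from horizontal, positive =
#'   rising to the right (same sign convention as all angles in the package).
#' @param gain multiplicative brightness factor, \code{>= 1}.
#' @return object of class \code{ellipse_filter}.
#' @export
ellipse_filter <- function(center, semi_major, semi_minor,
                           rotation_deg = 0, gain = 1) {
  stopifnot(length(center) == 2, semi_minor > 0, semi_major >= semi_minor,
            gain >= 1)
  structure(list(center = as.numeric(center), semi_major = semi_major,
                 semi_minor = semi_minor, rotation_deg = rotation_deg,
                 gain = gain),
            class = "ellipse_filter")
}

#' The identity augmentation (gain 1)
#' @return an [ellipse_filter()] that leaves any image unchanged.
#' @export
identity_filter <- function() {
  ellipse_filter(center = c(0, 0), semi_major = 1, semi_minor = 1, gain = 1)
}

#' Augment an elliptical region of a sub-image
#'
#' Pixels whose center lies inside the ellipse get intensity
#' \code{min(255, round(gain * original))}; all other pixels are untouched.
#'
#' @param sub an [us_frame()] sub-image.
#' @param filt an [ellipse_filter()].
#' @return the augmented [us_frame()] (same offset and metadata).
#' @export
augment <- function(sub, filt) {
  stopifnot(inherits(sub, "us_frame"), inherits(filt, "ellipse_filter"))
  if (filt$gain == 1) return(sub)
  nr <- nrow(sub); nc <- ncol(sub)
  # pixel centers at 0-based integer coordinates
  dx <- matrix(rep(0:(nc - 1L), each = nr), nr, nc) - filt$center[1]
  dy <- matrix(rep(0:(nr - 1L), times = nc), nr, nc) - filt$center[2]
  phi <- filt$rotation_deg * pi / 180
  # major-axis direction (cos phi, -sin phi) in (col, row): row grows downward
  u <- dx * cos(phi) - dy * sin(phi)
  v <- dx * sin(phi) + dy * cos(phi)
  inside <- (u / filt$semi_major)^2 + (v / filt$semi_minor)^2 <= 1
  m <- unclass(sub)
  m[inside] <- pmin(255, round(filt$gain * m[inside]))
  out <- sub
  out[] <- as.integer(m)
  out
}
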