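#' Ultrasound frame
#'
#' A single grayscale B-mode frame: an integer matrix of echo intensities in
#' \code{[0, 255]} with rows indexing depth (downward) and columns indexing
#' lateral position (rightward). All pixel coordinates used in this package
#' are 0-based: pixel \code{(col, row)} sits at matrix entry
#' \code{[row + 1, col + 1]}.
#'
#' @param intensities numeric or integer matrix; values must lie in
#'   \code{[0, 255]}.
#' @param frame_index non-negative integer frame number within a sequence.
#' @param time_s acquisition time in seconds (\code{frame_index / frame_rate}).
#' @return An object of class \code{us_frame}: the intensity matrix (integer
#'   storage) with attributes \code{frame_index}, \code{time_s} and
#'   \code{offset} (the 0-based \code{c(row, col)} position of the top-left
#'   pixel within the full frame; \code{c(0, 0)} for an untrimmed frame).
#' @seealso [trim()], [load_frames()]
#' @export
us_frame <- function(intensities, frame_index = 0L, time_s = 0) {
  m <- as.matrix(intensities)
  if (length(m) == 0L) stop("frame must be non-empty")
  if (anyNA(m) || any(m < 0) || any(m > 255)) {
    stop("intensities must lie in [0, 255]")
  }
  storage.mode(m) <- "integer"
  structure(m,
            frame_index = as.integer(frame_index),
            time_s = as.numeric(time_s),
            offset = c(row = 0L, col = 0L),
            class = "us_frame")
}

#' @export
print.us_frame <- function(x, ...) {
  cat(sprintf("<us_frame %d x %d, frame %d, t = %.3f s, offset (%d,%d)>\n",
              nrow(x), ncol(x), attr(x, "frame_index"), attr(x, "time_s"),
              attr(x, "offset")[["row"]], attr(x, "offset")[["col"]]))
  invisible(x)
}

#' Region-of-interest specification
#'
#' Splits a frame into a shallow "top" sub-image expected to contain the
#' target fascicle and a deeper "bottom" sub-image expected to contain the
#' (near-horizontal) aponeurosis. Intervals are 0-based and half-open:
#' \code{rows = c(r0, r1)} selects rows \code{r0 .. r1 - 1}.
#'
#' @param top_rows,top_cols,bottom_rows,bottom_cols length-2 integer vectors,
#'   half-open \code{[from, to)} intervals.
#' @return An object of class \code{roi_spec}.
#' @export
roi_spec <- function(top_rows, top_cols, bottom_rows, bottom_cols) {
  chk <- function(iv, nm) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || iv[1] < 0L || iv[2] <= iv[1]) {
      stop(sprintf("%s must be a half-open interval [from, to) with to > from >= 0", nm))
    }
    iv
  }
  spec <- list(top_rows = chk(top_rows, "top_rows"),
               top_cols = chk(top_cols, "top_cols"),
               bottom_rows = chk(bottom_rows, "bottom_rows"),
               bottom_cols = chk(bottom_cols, "bottom_cols"))
  if (spec$top_rows[2] > spec$bottom_rows[1]) {
    stop("top ROI must end at or above the start of the bottom ROI")
  }
  structure(spec, class = "roi_spec")
}

# map a frame read as [0,1] doubles (png) or raw integers (tiff as.is) to 0-255
.to_uint8 <- function(m) {
  if (length(dim(m)) == 3L) {           # colour: Rec.601 luminance
    nch <- dim(m)[3]
    m <- if (nch >= 3L) {
      0.299 * m[, , 1] + 0.587 * m[, , 2] + 0.114 * m[, , 3]
    } else {
      m[, , 1]
    }
  }
  mx <- max(m)
  if (mx <= 1) {                        # normalized reader output
    m <- m * 255
  } else if (mx > 255) {                # >8-bit integer samples: max-normalize
    m <- m / mx * 255
  }
  round(m)
}

.read_image <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    list(.to_uint8(png::readPNG(path)))
  } else if (grepl("\\.(tif|tiff)$", lower)) {
    imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    lapply(imgs, .to_uint8)
  } else {
    stop(sprintf("unsupported image format: %s (PNG/TIFF only)", path))
  }
}

#' Load an ordered frame sequence
#'
#' Reads a directory of numbered PNG/TIFF images (sorted by filename), a
#' single image, or a multi-frame TIFF. Colour input is converted to grayscale
#' by Rec.601 luminance; samples deeper than 8 bits are max-normalized so the
#' brightest pixel maps to 255.
#'
#' @param path directory of numbered images, or a PNG/TIFF file.
#' @param frame_rate acquisition rate in Hz; sets \code{time_s = index / rate}.
#' @return List of [us_frame()] objects in temporal order.
#' @export
load_frames <- function(path, frame_rate = 20) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
    if (length(files) == 0L) stop(sprintf("no PNG/TIFF frames found in %s", path))
    mats <- unlist(lapply(files, .read_image), recursive = FALSE)
  } else if (file.exists(path)) {
    mats <- .read_image(path)
  } else {
    stop(sprintf("path does not exist: %s", path))
  }
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("frames have inconsistent dimensions")
  }
  lapply(seq_along(mats), function(i) {
    us_frame(mats[[i]], frame_index = i - 1L, time_s = (i - 1L) / frame_rate)
  })
}

.crop <- function(frame, rows, cols) {
  if (rows[2] > nrow(frame) || cols[2] > ncol(frame)) {
    stop("ROI exceeds frame bounds")
  }
  sub <- unclass(frame)[(rows[1] + 1L):rows[2], (cols[1] + 1L):cols[2], drop = FALSE]
  out <- us_frame(sub, frame_index = attr(frame, "frame_index"),
                  time_s = attr(frame, "time_s"))
  off <- attr(frame, "offset")
  attr(out, "offset") <- c(row = off[["row"]] + rows[1], col = off[["col"]] + cols[1])
  out
}

#' Trim a frame into fascicle and aponeurosis sub-images
#'
#' Cuts the frame into the two ROIs of a [roi_spec()]. Each sub-image keeps a
#' recorded 0-based offset so that positions and angles measured in ROI
#' coordinates can be mapped back to the full frame.
#'
#' @param frame an [us_frame()].
#' @param roi an [roi_spec()].
#' @return \code{list(top =, bottom =)} of [us_frame()] crops.
#' @export
trim <- function(frame, roi) {
  stopifnot(inherits(frame, "us_frame"), inherits(roi, "roi_spec"))
  list(top = .crop(frame, roi$top_rows, roi$top_cols),
       bottom = .crop(frame, roi$bottom_rows, roi$bottom_cols))
}
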