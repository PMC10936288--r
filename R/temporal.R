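#' Viscosity (temporal smoothing) parameters
#'
#' The viscosity weight is a skew-Gaussian function of the increment between
#' the currently measured angle and the angle predicted from recent frames.
#' Increments near the typical frame-to-frame change get weight close to
#' \code{amplitude} (the current measurement dominates); far-tail increments
#' get weight near 0, so the previous estimate is held — which is how an
#' investigator treats a frame where the fascicle barely shows.
#'
#' @param location_deg skew-normal location \eqn{\xi} (degrees).
#' @param scale_deg skew-normal scale \eqn{\omega > 0} (degrees).
#' @param shape skew-normal shape \eqn{\alpha} (0 = symmetric Gaussian).
#' @param amplitude peak weight in \code{(0, 1]}, attained at the mode.
#' @param predictor \code{"previous"} (hold: predicted = last final angle) or
#'   \code{"linear_extrapolation"} (predicted = \code{2*prev1 - prev2}).
#' @return object of class \code{viscosity_params}.
#' @export
viscosity_params <- function(location_deg = 0, scale_deg = 2, shape = 0,
                             amplitude = 1,
                             predictor = c("previous", "linear_extrapolation")) {
  stopifnot(scale_deg > 0, amplitude > 0, amplitude <= 1)
  structure(list(location_deg = location_deg, scale_deg = scale_deg,
                 shape = shape, amplitude = amplitude,
                 predictor = match.arg(predictor)),
            class = "viscosity_params")
}

# skew-normal density 2/w * phi((x-xi)/w) * Phi(a (x-xi)/w), vectorized
.sn_density <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

# mode of the skew-normal (numeric; closed form does not exist for alpha != 0)
.sn_mode <- function(xi, omega, alpha) {
  if (alpha == 0) return(xi)
  opt <- stats::optimize(function(x) .sn_density(x, xi, omega, alpha),
                         interval = c(xi - omega, xi + omega), maximum = TRUE,
                         tol = 1e-10)
  opt$maximum
}

#' Skew-Gaussian viscosity weight
#'
#' Evaluates the skew-normal density at the angle increment and normalizes it
#' so the mode maps to \code{amplitude}; the returned weight therefore lies in
#' \code{[0, amplitude]} and decays to 0 in both tails. Log-space evaluation
#' keeps deep-tail ratios (e.g. a 30-degree outlier under a 2-degree scale)
#' finite instead of underflowing to 0/0.
#'
#' @param increment_deg measured angle minus predicted angle (degrees); may be
#'   a vector.
#' @param vp a [viscosity_params()].
#' @return weight(s) in \code{[0, amplitude]}.
#' @export
viscosity_weight <- function(increment_deg, vp) {
  stopifnot(inherits(vp, "viscosity_params"))
  xi <- vp$location_deg; omega <- vp$scale_deg; alpha <- vp$shape
  z <- (increment_deg - xi) / omega
  zm <- (.sn_mode(xi, omega, alpha) - xi) / omega
  logf <- function(z) {
    stats::dnorm(z, log = TRUE) + stats::pnorm(alpha * z, log.p = TRUE)
  }
  vp$amplitude * exp(logf(z) - logf(zm))
}

#' Blend a measured angle with its temporal prediction
#'
#' The final angle is \code{lambda * measured + (1 - lambda) * predicted},
#' where \code{lambda} is the viscosity weight of the increment
#' \code{measured - predicted}. A normal increment gives \code{lambda} near
#' the amplitude so the measurement dominates; an outlier gives
#' \code{lambda} near 0 so the prediction (previous estimate) is held.
#'
#' @param measured_deg current raw angle.
#' @param prev1_deg,prev2_deg final angles of the two preceding frames
#'   (\code{prev2_deg} only used by the linear-extrapolation predictor; pass
#'   \code{prev1_deg} again during bootstrap).
#' @param vp a [viscosity_params()].
#' @return \code{list(angle_deg =, lambda =)}.
#' @export
smooth_angle <- function(measured_deg, prev1_deg, prev2_deg, vp) {
  stopifnot(inherits(vp, "viscosity_params"))
  predicted <- switch(vp$predictor,
    previous = prev1_deg,
    linear_extrapolation = 2 * prev1_deg - prev2_deg)
  lambda <- viscosity_weight(measured_deg - predicted, vp)
  list(angle_deg = lambda * measured_deg + (1 - lambda) * predicted,
       lambda = lambda)
}

#' Calibrate the viscosity weight from angle increments
#'
#' Fits a skew-normal to observed frame-to-frame angle increments by the
#' method of moments (mean, standard deviation, skewness), then inflates the
#' fitted scale by \code{span_factor} so the viscosity span is strictly wider
#' than the empirical spread — the weight then suppresses only outliers, not
#' normal motion.
#'
#' @param increment_samples numeric vector of observed increments (degrees),
#'   at least 20.
#' @param span_factor scale inflation, \code{>= 1} (default 2).
#' @param amplitude,predictor passed through to the result.
#' @return a [viscosity_params()] with the inflated scale; the uninflated
#'   moment fit is attached as attribute \code{"fit"}
#'   (\code{c(location, scale, shape)}).
#' @export
calibrate_viscosity <- function(increment_samples, span_factor = 2,
                                amplitude = 1, predictor = "previous") {
  x <- increment_samples[is.finite(increment_samples)]
  if (length(x) < 20L) stop("need at least 20 increment samples to calibrate")
  stopifnot(span_factor >= 1)
  m <- mean(x); s <- stats::sd(x)
  if (s < 1e-8) {
    warning("degenerate increment samples (zero spread); using minimum-scale floor")
    fit <- c(location = m, scale = 0.1, shape = 0)
  } else {
    g1 <- mean((x - m)^3) / s^3
    # moment inversion: skewness -> delta -> (shape, scale, location)
    g1max <- 0.5 * (4 - pi) * (2 / (pi - 2))^1.5   # ~0.9953, attained as shape -> Inf
    g1c <- sign(g1) * min(abs(g1), 0.99 * g1max)
    a13 <- abs(g1c)^(2 / 3)
    delta <- sign(g1c) * sqrt((pi / 2) * a13 / (a13 + ((4 - pi) / 2)^(2 / 3)))
    shape <- delta / sqrt(1 - delta^2)
    omega <- s / sqrt(1 - 2 * delta^2 / pi)
    xi <- m - omega * delta * sqrt(2 / pi)
    fit <- c(location = xi, scale = omega, shape = shape)
  }
  vp <- viscosity_params(location_deg = fit[["location"]],
                         scale_deg = fit[["scale"]] * span_factor,
                         shape = fit[["shape"]],
                         amplitude = amplitude, predictor = predictor)
  attr(vp, "fit") <- fit
  vp
}

#' Fusion parameters for multiple augmentation filters
#'
#' @param epsilon small positive guard added to the weight sum so the
#'   weighted average cannot blow up when all weights are tiny.
#' @param lambda_floor when every filter's weight falls below this, the frame
#'   is treated as undetectable and the previous final angle is held
#'   (\code{status = "fallback"}).
#' @param viscosity a [viscosity_params()] used to weight each filter's angle
#'   against the previous final angle.
#' @return object of class \code{fusion_params}.
#' @export
fusion_params <- function(epsilon = 1e-6, lambda_floor = 1e-3,
                          viscosity = viscosity_params()) {
  stopifnot(epsilon > 0, lambda_floor >= 0,
            inherits(viscosity, "viscosity_params"))
  structure(list(epsilon = epsilon, lambda_floor = lambda_floor,
                 viscosity = viscosity),
            class = "fusion_params")
}

#' Fuse per-filter angle detections within one frame
#'
#' Each augmentation filter yields one candidate angle; filters suited to the
#' frame produce angles near the previous final angle and receive viscosity
#' weight near the amplitude, while unsuitable filters are rolled out by
#' near-zero weight. The fused angle is
#' \code{sum(lambda * theta) / (sum(lambda) + epsilon)}. If every weight is
#' below \code{lambda_floor} the previous final angle is held. On the first
#' frame (no previous angle) the median detection is returned.
#'
#' @param per_filter_angles numeric vector of detected angles (degrees), one
#'   per filter; \code{NA}s (filters with no detection) are dropped.
#' @param prev_final_deg previous frame's final angle, or \code{NA} on the
#'   first frame.
#' @param fp a [fusion_params()].
#' @return \code{list(angle_deg =, status =)} with status \code{"ok"},
#'   \code{"fallback"} or \code{"no_detection"}.
#' @export
fuse_filters <- function(per_filter_angles, prev_final_deg, fp) {
  stopifnot(inherits(fp, "fusion_params"))
  th <- per_filter_angles[is.finite(per_filter_angles)]
  if (length(th) == 0L) {
    if (is.finite(prev_final_deg)) {
      return(list(angle_deg = prev_final_deg, status = "fallback"))
    }
    return(list(angle_deg = NA_real_, status = "no_detection"))
  }
  if (!is.finite(prev_final_deg)) {
    return(list(angle_deg = stats::median(th), status = "ok"))
  }
  lambda <- viscosity_weight(th - prev_final_deg, fp$viscosity)
  if (all(lambda < fp$lambda_floor)) {
    return(list(angle_deg = prev_final_deg, status = "fallback"))
  }
  list(angle_deg = sum(lambda * th) / (sum(lambda) + fp$epsilon),
       status = "ok")
}
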