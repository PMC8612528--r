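#' Trajectory kinematics
#'
#' Converts raw center-of-mass + snout trajectories into the kinematic
#' observables of the analysis: instantaneous linear velocity in body lengths
#' per second, unwrapped heading of the center-of-mass -> snout vector, and
#' signed angular velocity. Sign convention: positive angular velocity is a
#' rightward (clockwise) rotation in the de-mirrored ventral view with x
#' rightward and y up.
#'
#' @name kinematics
NULL

#' Centered moving average with shrunken edge windows
#'
#' Window must be odd; at the edges the window shrinks symmetrically so the
#' output has the same length as the input. `window = 1` is the identity.
#'
#' @param x numeric vector.
#' @param window odd integer >= 1, in samples.
#' @return smoothed numeric vector, same length as `x`.
#' @export
smooth_series <- function(x, window) {
  if (length(window) != 1 || window < 1 || window %% 2 == 0)
    stop("`window` must be an odd integer >= 1")
  if (window == 1 || length(x) == 1) return(x)
  n <- length(x)
  half <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1)
  hi <- pmin(i + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Instantaneous linear velocity in body lengths per second
#'
#' Frame-to-frame displacement of the center of mass, scaled by frame rate
#' and body length. The last sample is repeated so the series has the same
#' length as the trajectory.
#'
#' @param traj a `trajectory` object (see [trajectory()]).
#' @param specimen a `specimen` object (see [specimen()]); supplies body
#'   length in cm.
#' @param smooth_window odd window (frames) applied to positions before
#'   differencing; default 5. Use 1 for raw positions.
#' @return numeric vector of speeds, BL/s, same length as the trajectory.
#' @export
instantaneous_velocity <- function(traj, specimen, smooth_window = 5) {
  stopifnot(inherits(traj, "trajectory"))
  if (specimen$body_length <= 0) stop("body length must be positive")
  n <- length(traj$t)
  if (n < 2) stop("need at least 2 frames")
  x <- smooth_series(traj$com_x, smooth_window)
  y <- smooth_series(traj$com_y, smooth_window)
  d <- sqrt(diff(x)^2 + diff(y)^2)
  v <- d * traj$frame_rate / specimen$body_length
  c(v, v[n - 1])
}

#' Unwrapped heading of the center-of-mass -> snout vector
#'
#' @param traj a `trajectory` with snout coordinates.
#' @param smooth_window odd window (frames) applied to positions first;
#'   default 1 (none), preserving fast S-bend peaks.
#' @return heading in degrees, unwrapped (no +-180 jumps).
#' @export
heading_series <- function(traj, smooth_window = 1) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$snout_x)) stop("snout channel absent; heading undefined")
  sx <- smooth_series(traj$snout_x, smooth_window) - smooth_series(traj$com_x, smooth_window)
  sy <- smooth_series(traj$snout_y, smooth_window) - smooth_series(traj$com_y, smooth_window)
  r <- sqrt(sx^2 + sy^2)
  if (any(r < 1e-9)) stop("snout coincident with center of mass; heading undefined")
  h <- atan2(sy, sx) * 180 / pi
  # unwrap
  dh <- diff(h)
  dh <- dh - 360 * round(dh / 360)
  c(h[1], h[1] + cumsum(dh))
}

#' Signed angular velocity of the head vector
#'
#' Centered finite differences of the unwrapped heading (forward/backward at
#' the edges), scaled by frame rate. Positive = rightward (clockwise) turn in
#' the de-mirrored ventral view; a left turn gives negative values.
#'
#' Note the sampling caveat: a half-sine angular-velocity pulse of peak P and
#' duration d sampled at 30 Hz recovers a peak of at least
#' `P * sin(pi/2 * (1 - 1/(d * rate)))`; pulses near 1000 deg/s lasting ~0.1 s
#' are close to the sampling limit and their peaks are underestimated.
#'
#' @inheritParams heading_series
#' @return angular velocity, deg/s, same length as the trajectory.
#' @export
angular_velocity <- function(traj, smooth_window = 1) {
  h <- heading_series(traj, smooth_window)
  n <- length(h)
  if (n < 2) stop("need at least 2 frames")
  dh <- numeric(n)
  if (n > 2) dh[2:(n - 1)] <- (h[3:n] - h[1:(n - 2)]) / 2
  dh[1] <- h[2] - h[1]
  dh[n] <- h[n] - h[n - 1]
  -dh * traj$frame_rate  # heading decreases during a clockwise (rightward) turn
}

#' Full kinematic series for one trajectory
#'
#' @inheritParams instantaneous_velocity
#' @param heading_window smoothing window for the heading channel (default 1,
#'   none: fast S-bend peaks must not be eroded).
#' @return a `kinematic_series` data.frame with columns `t`, `temp`, `v_lin`
#'   (BL/s), `heading` (deg, unwrapped), `v_ang` (deg/s, signed).
#' @export
kinematic_series <- function(traj, specimen, smooth_window = 5, heading_window = 1) {
  ks <- data.frame(
    t = traj$t,
    temp = traj$temp,
    v_lin = instantaneous_velocity(traj, specimen, smooth_window),
    heading = heading_series(traj, heading_window),
    v_ang = angular_velocity(traj, heading_window)
  )
  attr(ks, "frame_rate") <- traj$frame_rate
  class(ks) <- c("kinematic_series", "data.frame")
  ks
}

#' Elongation ratio of a specimen
#'
#' Body length over body width; elongate bottom-dwelling morphs (high ratio)
#' are the ones that display withdrawal-like startles.
#'
#' @param specimen a `specimen` object, or a body length in cm if
#'   `body_width` is given.
#' @param body_width body width in cm (only when `specimen` is numeric).
#' @return dimensionless ratio.
#' @export
elongation_ratio <- function(specimen, body_width = NULL) {
  if (is.numeric(specimen)) {
    len <- specimen
    wid <- body_width
  } else {
    len <- specimen$body_length
    wid <- specimen$body_width
  }
  if (is.null(wid) || wid <= 0) stop("body width must be positive")
  if (len <= 0) stop("body length must be positive")
  len / wid
}
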