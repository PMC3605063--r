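#' Angle utilities on the ring
#'
#' `wrapAngle` wraps angles into `[0, 2*pi)`; `wrapSigned` wraps a difference
#' into `(-pi, pi]`; `angularSeparation` is the unsigned ring distance
#' `min(|d|, 2*pi - |d|)` in `[0, pi]`. Positive angles run anti-clockwise,
#' so a clockwise-moving individual has decreasing theta.
#'
#' @param theta angle(s) in radians
#' @return wrapped angle(s)
#' @examples
#' wrapAngle(6.38)                 # 0.0968...
#' wrapSigned(6.25 - 0.05)         # -0.0832...
#' angularSeparation(0.1, 6.2)     # 0.1832...
#' @export
wrapAngle <- function(theta) theta %% (2 * pi)

#' @rdname wrapAngle
#' @export
wrapSigned <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  ## map the boundary -pi (from exact multiples of 2*pi shifted) onto +pi
  w[w <= -pi] <- pi
  w
}

#' @rdname wrapAngle
#' @param a,b angles in radians
#' @export
angularSeparation <- function(a, b) {
  ## |a - b| first, then wrap: exact for small separations, so zone
  ## boundaries compare cleanly
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Signed per-frame angular displacements
#'
#' Wrapped signed difference of consecutive frames, in `(-pi, pi]`; positive
#' means anti-clockwise movement. These are the observations fed to the
#' orientation HMM.
#'
#' @param traj a [TrialTrajectory-class] with at least 2 frames
#' @return a (T-1) x N matrix of signed steps in radians/frame
#' @export
displacements <- function(traj) {
  th <- thetaMatrix(traj)
  if (nrow(th) < 2) stop("need at least 2 frames to form displacements")
  wrapSigned(th[-1, , drop = FALSE] - th[-nrow(th), , drop = FALSE])
}
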