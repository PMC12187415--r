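# Swimming kinematics: linear and angular speed, low-pass filtering.

#' Linear speed from a trajectory
#'
#' First-order forward differences of position divided by the time step;
#' speed is the Euclidean norm of the velocity components. Translation
#' invariant.
#'
#' @param traj a [trajectory_series()].
#' @param dt time step in seconds (default 1/30).
#' @return numeric vector of speeds in cm s^-1, length `l - 1` for an
#'   `l`-sample trajectory.
#' @examples
#' tr <- trajectory_series("f1", c(0, 0.1), c(0, 0))
#' linear_speed(tr, dt = 1 / 30)  # 3 cm/s
#' @export
linear_speed <- function(traj, dt = 1 / 30) {
  if (length(traj$x) < 2L)
    fs_abort("need at least 2 samples for a forward difference",
             "insufficient_data")
  if (dt <= 0) fs_abort("dt must be > 0", "parameter_error")
  sqrt(diff(traj$x)^2 + diff(traj$y)^2) / dt
}

#' Absolute angular speed from a trajectory
#'
#' The default (`position_vectors`) applies
#' `omega(t) = atan2(|det[p(t), p(t+1)]|, p(t) . p(t+1)) / dt`
#' to successive tank-centred *position* vectors, i.e. the angle subtended at
#' the tank centre per unit time. `velocity_vectors` applies the same formula
#' to successive velocity vectors, measuring the turning rate of the heading.
#' Both are invariant under global rotation; only the velocity mode is
#' invariant under translation. Samples where an operand vector has zero
#' length are undefined and returned as `NA` (excluded from summaries rather
#' than biasing them towards zero).
#'
#' @param traj a [trajectory_series()] with tank-centred coordinates.
#' @param dt time step in seconds (default 1/30).
#' @param mode `"position_vectors"` (default) or `"velocity_vectors"`.
#' @return numeric vector of non-negative angular speeds in rad s^-1
#'   (length `l - 1` for position mode, `l - 2` for velocity mode), with `NA`
#'   at undefined samples.
#' @export
angular_speed <- function(traj, dt = 1 / 30,
                          mode = c("position_vectors", "velocity_vectors")) {
  mode <- match.arg(mode)
  if (dt <= 0) fs_abort("dt must be > 0", "parameter_error")
  n_min <- if (mode == "position_vectors") 2L else 3L
  if (length(traj$x) < n_min)
    fs_abort(sprintf("need at least %d samples for mode '%s'", n_min, mode),
             "insufficient_data")
  if (mode == "position_vectors") {
    ux <- traj$x[-length(traj$x)]; uy <- traj$y[-length(traj$y)]
    vx <- traj$x[-1]; vy <- traj$y[-1]
  } else {
    dx <- diff(traj$x); dy <- diff(traj$y)
    ux <- dx[-length(dx)]; uy <- dy[-length(dy)]
    vx <- dx[-1]; vy <- dy[-1]
  }
  det <- ux * vy - uy * vx
  dot <- ux * vx + uy * vy
  w <- atan2(abs(det), dot) / dt
  zero <- (ux == 0 & uy == 0) | (vx == 0 & vy == 0)
  w[zero] <- NA_real_
  w
}

# steady-state initial conditions for a direct-form-II-transposed filter,
# so that a constant input produces a constant output from the first sample
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[-1] / a[1]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(comp), B)
}

df2t_filter <- function(b, a, x, zi) {
  n <- length(a) - 1L
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 1) for (k in 1:(n - 1)) z[k] <- b[k + 1] * xi + z[k + 1] - a[k + 1] * yi
    z[n] <- b[n + 1] * xi - a[n + 1] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter with [signal::butter()] and applies
#' it forward and backward (zero phase, so filtering introduces no lag that
#' would distort increment-based drift/diffusion estimates). The cutoff is
#' given in rad s^-1 and converted to Hz as `cutoff / (2*pi)` before
#' normalisation by the Nyquist frequency. The two passes use odd-reflection
#' padding and steady-state initial conditions; at very low normalised
#' cutoffs (the default 0.1 rad s^-1 at 30 Hz gives 0.001 of Nyquist) this is
#' required for a well-behaved response -- a naive zero-initialised pass does
#' not even preserve a constant input there.
#'
#' @param series numeric series to filter.
#' @param order filter order (default 4).
#' @param cutoff cutoff frequency in rad s^-1 (default 0.1).
#' @param fs sampling rate in Hz (default 30).
#' @param padlen reflection padding length; default `3 * (order + 1)` capped
#'   at `length(series) - 1`.
#' @return the filtered series, same length as the input.
#' @export
butterworth_lowpass <- function(series, order = 4, cutoff = 0.1, fs = 30,
                                padlen = NULL) {
  if (order < 1) fs_abort("order must be >= 1", "parameter_error")
  fc <- cutoff / (2 * pi)
  if (fc <= 0 || fc >= fs / 2)
    fs_abort(sprintf(
      "cutoff %.4g rad/s (%.4g Hz) must lie in (0, Nyquist = %.4g Hz)",
      cutoff, fc, fs / 2), "parameter_error")
  n <- length(series)
  if (n < 2L) return(series)
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  b <- bf$b * (sum(bf$a) / sum(bf$b))  # pin DC gain to exactly 1
  a <- bf$a
  padlen <- min(n - 1L, padlen %||% (3L * (order + 1L)))
  ext <- c(2 * series[1] - series[(padlen + 1):2],
           series,
           2 * series[n] - series[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- df2t_filter(b, a, ext, zi * ext[1])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Heading angles from a trajectory
#'
#' Heading of the velocity vector (forward differences). Frames with zero
#' displacement inherit the previous defined heading.
#'
#' @param traj a [trajectory_series()].
#' @return numeric vector of headings in rad, length `l - 1`.
#' @export
heading_series <- function(traj) {
  dx <- diff(traj$x); dy <- diff(traj$y)
  h <- atan2(dy, dx)
  zero <- dx == 0 & dy == 0
  if (any(zero)) {
    h[zero] <- NA_real_
    # carry the last defined heading forward (then backward for a leading run)
    for (i in seq_along(h)) if (is.na(h[i]) && i > 1) h[i] <- h[i - 1]
    for (i in rev(seq_along(h))) if (is.na(h[i]) && i < length(h)) h[i] <- h[i + 1]
    h[is.na(h)] <- 0
  }
  h
}
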