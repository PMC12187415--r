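# Interindividual distance and intermittent exploration episodes.

#' Interindividual distance series
#'
#' Container for the state variable of the stochastic model: the Euclidean
#' distance between two fish, or for triads the mean of the three pairwise
#' distances, sampled at a fixed rate.
#'
#' @param x non-negative numeric distance series in cm.
#' @param dt sampling interval in s.
#' @param trial_id trial identifier.
#' @param illumination optional condition label carried through to summaries.
#' @param group_size optional group size carried through to summaries.
#' @return an object of class `distance_series`.
#' @export
distance_series <- function(x, dt, trial_id = NA_character_,
                            illumination = NA_character_,
                            group_size = NA_integer_) {
  if (any(!is.finite(x)) || any(x < 0))
    fs_abort("distance series must be finite and non-negative",
             "integrity_error")
  if (dt <= 0) fs_abort("dt must be > 0", "parameter_error")
  structure(list(x = as.numeric(x), dt = dt, trial_id = trial_id,
                 illumination = illumination,
                 group_size = as.integer(group_size)),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series '%s'> %d samples at dt = %.4g s, range [%.2f, %.2f] cm\n",
              x$trial_id, length(x$x), x$dt, min(x$x), max(x$x)))
  invisible(x)
}

#' Interindividual distance of a trial
#'
#' Dyads: the per-frame Euclidean distance between the two fish. Triads: the
#' per-frame mean of the three pairwise distances, the quantity modelled by
#' the 1-D stochastic differential equation.
#'
#' @param x a [trial()] with at least 2 fish.
#' @return a [distance_series()].
#' @export
interindividual_distance <- function(x) {
  if (x$group_size < 2L)
    fs_abort("interindividual distance is undefined for a single fish",
             "not_applicable")
  pairs <- utils::combn(x$group_size, 2)
  n <- length(x$fish[[1]]$x)
  m <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- x$fish[[pairs[1, k]]]; b <- x$fish[[pairs[2, k]]]
    sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  }, numeric(n))
  d <- rowMeans(matrix(m, nrow = n))
  distance_series(d, 1 / x$frame_rate, trial_id = x$trial_id,
                  illumination = x$illumination, group_size = x$group_size)
}

#' Detect intermittent exploration episodes
#'
#' An exploration episode is a maximal run of consecutive frames with
#' distance strictly greater than `threshold` (default 3 BL = 9 cm) that
#' lasts strictly longer than `min_duration` (default 3 s) *and* is preceded
#' by at least one frame at or below the threshold -- the fish must have been
#' in close proximity before leaving. At 30 Hz the strict duration inequality
#' means an episode needs at least 91 frames; a 90-frame (exactly 3 s) run is
#' rejected. A series that starts above threshold and never dips below yields
#' no episodes.
#'
#' @param x a [distance_series()].
#' @param threshold distance threshold in cm (default 9).
#' @param min_duration minimum duration in s, strict (default 3).
#' @param amplitude_mode `"mean"` (default) or `"median"` distance over the
#'   episode, see [episode_amplitude()].
#' @return a data.frame of class `episodes` with columns `trial_id`,
#'   `start_frame`, `end_frame` (0-based, half-open), `duration_s`,
#'   `amplitude_cm`, in temporal order; zero rows if none.
#' @export
detect_episodes <- function(x, threshold = 9, min_duration = 3,
                            amplitude_mode = c("mean", "median")) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (threshold <= 0) fs_abort("threshold must be > 0", "parameter_error")
  empty <- data.frame(trial_id = character(0), start_frame = integer(0),
                      end_frame = integer(0), duration_s = numeric(0),
                      amplitude_cm = numeric(0))
  class(empty) <- c("episodes", "data.frame")
  attr(empty, "dt") <- x$dt
  if (length(x$x) == 0L) return(empty)
  above <- x$x > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values &
    (r$lengths * x$dt) > min_duration &
    starts > 1L  # maximal run not at series start => previous frame <= threshold
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  ep <- data.frame(trial_id = x$trial_id,
                   start_frame = starts - 1L,
                   end_frame = ends,  # half-open [start, end)
                   duration_s = (ends - starts + 1L) * x$dt)
  ep$amplitude_cm <- vapply(seq_len(nrow(ep)), function(i)
    episode_amplitude(x, ep[i, ], mode = amplitude_mode), numeric(1))
  class(ep) <- c("episodes", "data.frame")
  attr(ep, "dt") <- x$dt
  ep
}

#' Episode amplitude
#'
#' Amplitude of an exploration episode: the average (default) or median
#' interindividual distance over the episode's frames. Both conventions are
#' in use for this quantity, so the mode is explicit.
#'
#' @param x the [distance_series()] the episode was detected in.
#' @param ep a single-row episode (with 0-based half-open `start_frame`,
#'   `end_frame`).
#' @param mode `"mean"` (default) or `"median"`.
#' @return amplitude in cm.
#' @export
episode_amplitude <- function(x, ep, mode = c("mean", "median")) {
  mode <- match.arg(mode)
  idx <- (ep$start_frame + 1L):ep$end_frame
  if (ep$end_frame <= ep$start_frame || ep$end_frame > length(x$x))
    fs_abort("episode out of series bounds or empty", "parameter_error")
  if (mode == "mean") mean(x$x[idx]) else stats::median(x$x[idx])
}

#' Per-trial exploration-episode statistics
#'
#' One row per trial with the number of episodes and the trial means of
#' episode duration and amplitude. Trials with zero episodes keep `NA` means
#' and are flagged (`has_episodes = FALSE`) so downstream ANOVA can exclude
#' them explicitly.
#'
#' @param x a list of [trial()] objects (distance computed internally) or of
#'   [distance_series()] objects.
#' @param threshold,min_duration,amplitude_mode passed to [detect_episodes()].
#' @return a data.frame with columns `trial_id`, `illumination`, `group_size`,
#'   `n_episodes`, `mean_T`, `mean_A`, `has_episodes`.
#' @export
trial_episode_stats <- function(x, threshold = 9, min_duration = 3,
                                amplitude_mode = c("mean", "median")) {
  amplitude_mode <- match.arg(amplitude_mode)
  rows <- lapply(x, function(tr) {
    ds <- if (inherits(tr, "distance_series")) tr
          else interindividual_distance(tr)
    ep <- detect_episodes(ds, threshold = threshold,
                          min_duration = min_duration,
                          amplitude_mode = amplitude_mode)
    data.frame(trial_id = ds$trial_id,
               illumination = ds$illumination,
               group_size = ds$group_size,
               n_episodes = nrow(ep),
               mean_T = if (nrow(ep)) mean(ep$duration_s) else NA_real_,
               mean_A = if (nrow(ep)) mean(ep$amplitude_cm) else NA_real_,
               has_episodes = nrow(ep) > 0L)
  })
  do.call(rbind, rows)
}
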