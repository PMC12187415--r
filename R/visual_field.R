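# Visual-cue metrics: visual-field opacity and optic flow.
#
# Conspecific bodies are modelled as discs of diameter 1 BL centred on the
# tracked centroid. Each disc subtends an angular interval ("shade") in the
# focal fish's local frame (0 = heading). Opacity is the measure of the
# union of shades inside the visible field, normalised by the visible-field
# width 2*pi - gamma; overlapping conspecifics are therefore never counted
# twice. Angular sets are kept as non-wrapping closed intervals inside
# [-pi, pi]; intervals that cross the branch cut are split.

#' Visual-field configuration
#'
#' @param blind_angle blind angle gamma in rad (default 21 degrees, the
#'   reported zebrafish blind area).
#' @param fish_radius conspecific body radius in cm (default 1.5, i.e. a disc
#'   of diameter 1 BL = 3 cm).
#' @param blind_zone_centre `"rear"` (default; anatomically the blind area is
#'   behind the fish) or `"front"` (the literal reading of the indicator-set
#'   definition, which excludes `(-gamma/2, gamma/2)` around the heading).
#' @param overlap what to do when a conspecific disc overlaps the focal
#'   position (`d <= radius`): `"error"` (default) or `"clamp"` to treat the
#'   conspecific as occluding the whole visible field.
#' @return an object of class `visual_field_config`.
#' @export
visual_field_config <- function(blind_angle = 21 * pi / 180, fish_radius = 1.5,
                                blind_zone_centre = c("rear", "front"),
                                overlap = c("error", "clamp")) {
  blind_zone_centre <- match.arg(blind_zone_centre)
  overlap <- match.arg(overlap)
  if (!is.finite(blind_angle) || blind_angle < 0 || blind_angle >= 2 * pi)
    fs_abort("blind_angle must lie in [0, 2*pi)", "parameter_error")
  if (fish_radius <= 0) fs_abort("fish_radius must be > 0", "parameter_error")
  structure(list(blind_angle = blind_angle, fish_radius = fish_radius,
                 blind_zone_centre = blind_zone_centre, overlap = overlap),
            class = "visual_field_config")
}

#' Focal fish pose
#'
#' @param position length-2 numeric, cm.
#' @param heading heading angle in rad; wrapped to `(-pi, pi]`.
#' @return an object of class `focal_pose`.
#' @export
focal_pose <- function(position, heading) {
  structure(list(position = as.numeric(position),
                 heading = wrap_angle(heading)),
            class = "focal_pose")
}

# ---- angular interval machinery ---------------------------------------------
# a piece set is a 2-column matrix (lo, hi), lo <= hi, within [-pi, pi]

pieces_from_arc <- function(centre, halfwidth) {
  if (halfwidth >= pi) return(cbind(-pi, pi))
  lo <- centre - halfwidth
  hi <- centre + halfwidth
  if (lo < -pi) rbind(c(lo + 2 * pi, pi), c(-pi, hi))
  else if (hi > pi) rbind(c(lo, pi), c(-pi, hi - 2 * pi))
  else cbind(lo, hi)
}

pieces_union <- function(pieces) {
  if (is.null(pieces) || nrow(pieces) == 0L) return(pieces)
  pieces <- pieces[order(pieces[, 1]), , drop = FALSE]
  out <- pieces[1, , drop = FALSE]
  if (nrow(pieces) > 1) for (i in 2:nrow(pieces)) {
    k <- nrow(out)
    if (pieces[i, 1] <= out[k, 2]) out[k, 2] <- max(out[k, 2], pieces[i, 2])
    else out <- rbind(out, pieces[i, ])
  }
  out
}

pieces_measure <- function(pieces) {
  if (is.null(pieces) || nrow(pieces) == 0L) return(0)
  m <- pieces_union(pieces)
  sum(m[, 2] - m[, 1])
}

pieces_intersect <- function(a, b) {
  if (is.null(a) || is.null(b) || nrow(a) == 0L || nrow(b) == 0L)
    return(matrix(numeric(0), 0, 2))
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) out <- rbind(out, c(lo, hi))
  }
  out
}

# visible field as a piece set in the focal frame
visible_field_pieces <- function(cfg) {
  g2 <- cfg$blind_angle / 2
  if (cfg$blind_angle == 0) return(cbind(-pi, pi))
  if (cfg$blind_zone_centre == "rear") cbind(-pi + g2, pi - g2)
  else rbind(c(-pi, -g2), c(g2, pi))
}

# ---- shades -----------------------------------------------------------------

#' Angular shade subtended by a conspecific disc
#'
#' The disc of radius `radius` centred at `other_centre` subtends, in the
#' focal fish's local frame, an interval centred on the conspecific's bearing
#' with half-width `asin(radius / d)`.
#'
#' @param focal a [focal_pose()].
#' @param other_centre length-2 numeric, cm.
#' @param radius disc radius in cm.
#' @return a list of class `visual_shade` with fields `centre`, `halfwidth`
#'   (rad, focal frame) and `pieces` (branch-cut-split intervals).
#' @examples
#' sh <- subtended_shade(focal_pose(c(0, 0), 0), c(3, 0), 1.5)
#' sh$halfwidth  # asin(0.5) = pi/6
#' @export
subtended_shade <- function(focal, other_centre, radius) {
  dx <- other_centre[1] - focal$position[1]
  dy <- other_centre[2] - focal$position[2]
  d <- sqrt(dx^2 + dy^2)
  if (d <= radius)
    fs_abort(sprintf(
      "conspecific at distance %.3f cm overlaps the focal body (radius %.3f)",
      d, radius), "overlap_error")
  centre <- wrap_angle(atan2(dy, dx) - focal$heading)
  halfwidth <- asin(radius / d)
  structure(list(centre = centre, halfwidth = halfwidth,
                 source_id = NA_character_,
                 pieces = pieces_from_arc(centre, halfwidth)),
            class = "visual_shade")
}

others_matrix <- function(others) {
  if (is.null(others) || length(others) == 0L) return(matrix(numeric(0), 0, 2))
  if (is.data.frame(others)) return(cbind(others$x, others$y))
  if (is.matrix(others)) return(others)
  do.call(rbind, lapply(others, as.numeric))
}

#' Visual-field opacity
#'
#' Fraction of the visible angular field (the full circle minus the blind
#' angle) occupied by the union of conspecific shades:
#' `O = |union of shades intersected with visible field| / (2*pi - gamma)`.
#' `O = 0` means an empty visual field, `O = 1` a fully covered one.
#'
#' @param focal a [focal_pose()].
#' @param others conspecific centroids: a list of length-2 vectors, an n x 2
#'   matrix, or a data.frame with `x`, `y` columns. May be empty.
#' @param cfg a [visual_field_config()].
#' @return a scalar in `[0, 1]`.
#' @examples
#' cfg <- visual_field_config()
#' opacity(focal_pose(c(0, 0), 0), list(c(3, 0)), cfg)  # ~0.177
#' @export
opacity <- function(focal, others, cfg = visual_field_config()) {
  om <- others_matrix(others)
  vis <- visible_field_pieces(cfg)
  denom <- 2 * pi - cfg$blind_angle
  if (nrow(om) == 0L) return(0)
  pieces <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(om))) {
    sh <- tryCatch(subtended_shade(focal, om[i, ], cfg$fish_radius),
                   fishsde_overlap_error = function(e) {
                     if (cfg$overlap == "clamp") NULL else stop(e)
                   })
    pieces <- rbind(pieces, if (is.null(sh)) cbind(-pi, pi) else sh$pieces)
  }
  pieces_measure(pieces_intersect(pieces_union(pieces), vis)) / denom
}

#' Ray-cast reference implementation of opacity
#'
#' Discretises the visual field into `n_rays` uniformly spaced rays and counts
#' the rays inside the visible field that hit any conspecific disc, with the
#' same normalisation as [opacity()]. Converges to the analytic value as
#' `n_rays` grows; kept as an independent oracle for the interval-union
#' implementation.
#'
#' @inheritParams opacity
#' @param n_rays number of rays (>= 360).
#' @return a scalar in `[0, 1]`.
#' @export
opacity_raycast_oracle <- function(focal, others, cfg = visual_field_config(),
                                   n_rays = 36000L) {
  if (n_rays < 360L) fs_abort("n_rays must be >= 360", "parameter_error")
  om <- others_matrix(others)
  psi <- -pi + (seq_len(n_rays) - 0.5) * 2 * pi / n_rays
  g2 <- cfg$blind_angle / 2
  visible <- if (cfg$blind_zone_centre == "rear") abs(psi) <= pi - g2
             else abs(psi) >= g2
  hit <- rep(FALSE, n_rays)
  for (i in seq_len(nrow(om))) {
    dx <- om[i, 1] - focal$position[1]
    dy <- om[i, 2] - focal$position[2]
    d <- sqrt(dx^2 + dy^2)
    if (d <= cfg$fish_radius) {
      if (cfg$overlap == "clamp") hit <- hit | TRUE
      else fs_abort("conspecific overlaps the focal body", "overlap_error")
      next
    }
    bearing <- wrap_angle(atan2(dy, dx) - focal$heading)
    hit <- hit | (abs(wrap_angle(psi - bearing)) <= asin(cfg$fish_radius / d))
  }
  sum(hit & visible) * (2 * pi / n_rays) / (2 * pi - cfg$blind_angle)
}

#' Optic flow across the visible field
#'
#' For each conspecific `j`, the angular velocity of its shade is the wrapped
#' displacement of the shade centre (its bearing in the focal frame) between
#' two consecutive time steps, divided by `dt`. The optic flow is the sum over
#' conspecifics of `|W_j|` times the width of the shade's intersection with
#' the visible field at time `t`; rays hitting no conspecific contribute
#' nothing. Non-negative by construction and even under time reversal.
#'
#' @param focal_t,focal_t1 [focal_pose()] at times `t` and `t + dt`.
#' @param others_t,others_t1 conspecific centroids at the two times, as
#'   data.frames with `id`, `x`, `y` columns (ids must match) or matrices /
#'   lists matched by position.
#' @param cfg a [visual_field_config()].
#' @param dt time step in s.
#' @return optic flow in rad^2 s^-1.
#' @export
optic_flow <- function(focal_t, focal_t1, others_t, others_t1,
                       cfg = visual_field_config(), dt = 1 / 30) {
  if (dt <= 0) fs_abort("dt must be > 0", "parameter_error")
  if (is.data.frame(others_t) && is.data.frame(others_t1)) {
    if (!identical(sort(as.character(others_t$id)),
                   sort(as.character(others_t1$id))))
      fs_abort("conspecific ids differ between time steps", "integrity_error")
    others_t <- others_t[order(others_t$id), ]
    others_t1 <- others_t1[order(others_t1$id), ]
  }
  m0 <- others_matrix(others_t)
  m1 <- others_matrix(others_t1)
  if (nrow(m0) != nrow(m1))
    fs_abort("conspecific counts differ between time steps", "integrity_error")
  if (nrow(m0) == 0L) return(0)
  vis <- visible_field_pieces(cfg)
  total <- 0
  for (j in seq_len(nrow(m0))) {
    sh0 <- subtended_shade(focal_t, m0[j, ], cfg$fish_radius)
    sh1 <- subtended_shade(focal_t1, m1[j, ], cfg$fish_radius)
    W <- wrap_angle(sh1$centre - sh0$centre) / dt
    width <- pieces_measure(pieces_intersect(sh0$pieces, vis))
    total <- total + abs(W) * width
  }
  total
}

#' Per-frame visual-cue series for every fish in a trial
#'
#' Headings are taken from the velocity vector ([heading_series()]). Opacity
#' is computed at every frame; optic flow needs two consecutive frames and is
#' `NA` at the final frame.
#'
#' @param x a [trial()].
#' @param cfg a [visual_field_config()].
#' @return a data.frame `trial_id, fish_id, frame, opacity, optic_flow`
#'   (frame 0-based), one row per frame per fish. Single-fish trials get
#'   zero opacity and optic flow.
#' @export
visual_cue_series <- function(x, cfg = visual_field_config()) {
  dt <- 1 / x$frame_rate
  n <- length(x$fish[[1]]$x)
  ids <- vapply(x$fish, `[[`, character(1), "fish_id")
  out <- vector("list", length(ids))
  headings <- lapply(x$fish, heading_series)
  for (k in seq_along(ids)) {
    f <- x$fish[[k]]
    O <- numeric(n); FL <- rep(NA_real_, n)
    oth <- x$fish[-k]
    for (i in seq_len(n)) {
      h_i <- headings[[k]][min(i, n - 1L)]
      pose <- focal_pose(c(f$x[i], f$y[i]), h_i)
      centres <- lapply(oth, function(o) c(o$x[i], o$y[i]))
      O[i] <- opacity(pose, centres, cfg)
      if (i < n && length(oth)) {
        h_i1 <- headings[[k]][min(i + 1L, n - 1L)]
        pose1 <- focal_pose(c(f$x[i + 1], f$y[i + 1]), h_i1)
        centres1 <- lapply(oth, function(o) c(o$x[i + 1], o$y[i + 1]))
        FL[i] <- optic_flow(pose, pose1, centres, centres1, cfg, dt)
      } else if (i < n) FL[i] <- 0
    }
    out[[k]] <- data.frame(trial_id = x$trial_id, fish_id = ids[k],
                           frame = seq_len(n) - 1L, opacity = O,
                           optic_flow = FL)
  }
  do.call(rbind, out)
}
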