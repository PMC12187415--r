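# Synthetic data: every input the pipeline needs, generated in code.
#
# The generator emulates the recording setup (30 Hz, 18000 frames, 60 cm
# circular arena, 3 cm fish, groups of 1-3) and drives the interindividual
# distance with the bistable SDE, then embeds that distance process into 2-D
# group trajectories. Regime parameters are synthetic defaults chosen to
# mirror the qualitative bright/dark contrast (bright: stronger bias toward
# the near well and a higher barrier; dark: reduced tilt, lower barrier,
# farther exploration well); they are NOT calibrated to any animal data.

#' Synthetic bright/dark SDE regimes
#'
#' Default, clearly non-authorial parameter sets for the two illumination
#' regimes. Both share a parabolic diffusion with negative curvature (noise
#' largest at intermediate distances); the bright regime has a stronger tilt
#' toward the close-proximity well and a higher barrier, the dark regime a
#' weaker tilt, a lower barrier and a farther exploration well, so dark
#' trials show longer and larger exploration episodes.
#'
#' @param diffusion diffusion coefficients `c(b0, b1, b2)` shared by both
#'   regimes.
#' @return named list with `bright` and `dark` [sde_model()]s.
#' @export
default_regimes <- function(diffusion = c(0.53125, 0.075, -0.003)) {
  list(
    bright = sde_model(potential_params(alpha = -0.10, beta = -1.2e-3,
                                        xl = 4, xh = 12),
                       diffusion = diffusion),
    dark = sde_model(potential_params(alpha = -0.015, beta = -5e-4,
                                      xl = 5, xh = 16),
                     diffusion = diffusion)
  )
}

#' Synthetic-data specification
#'
#' @param regimes named list of bright/dark [sde_model()]s
#'   (default [default_regimes()]).
#' @param group_size 1, 2 or 3 fish.
#' @param frame_rate Hz (default 30).
#' @param n_frames samples per trial (default 18000).
#' @param arena an [arena_config()].
#' @param sigma_pos positional jitter bound in cm: every embedded coordinate
#'   is perturbed by a uniform draw in `[-sigma_pos, sigma_pos]` (default
#'   0.05, a fraction of a body length of tracking noise; bounded like
#'   pixel-quantisation error).
#' @param heading_smooth s.d. of the group-axis rotation increments in
#'   rad s^-1/2 (default 0.3); smaller values give straighter group motion.
#' @param seed master seed.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(regimes = default_regimes(), group_size = 2L,
                       frame_rate = 30, n_frames = 18000L,
                       arena = arena_config(), sigma_pos = 0.05,
                       heading_smooth = 0.3, seed = 1L) {
  if (!group_size %in% 1:3)
    fs_abort("group_size must be 1, 2 or 3", "parameter_error")
  if (frame_rate <= 0 || n_frames < 2L || sigma_pos < 0 || heading_smooth < 0)
    fs_abort("spec fields must be positive", "parameter_error")
  structure(list(regimes = regimes, group_size = as.integer(group_size),
                 frame_rate = frame_rate, n_frames = as.integer(n_frames),
                 arena = arena, sigma_pos = sigma_pos,
                 heading_smooth = heading_smooth, seed = seed),
            class = "synth_spec")
}

#' Generate interindividual-distance paths for a condition
#'
#' Seeded Euler-Maruyama paths from the condition's regime model. Pure
#' function of (spec, condition, n_trials): the per-trial streams derive
#' from `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @param condition `"bright"` or `"dark"`.
#' @param n_trials number of trials (default 10).
#' @return list of [distance_series()] labelled with the condition.
#' @export
generate_distance_paths <- function(spec, condition = c("bright", "dark"),
                                    n_trials = 10L) {
  condition <- match.arg(condition)
  model <- spec$regimes[[condition]]
  cfg <- sim_config(dt = 1 / spec$frame_rate, n_steps = spec$n_frames,
                    n_trials = n_trials)
  offset <- if (condition == "bright") 0L else 104729L
  simulate_trials(model, cfg, master_seed = spec$seed + offset,
                  trial_prefix = paste0("synth_", condition),
                  illumination = condition, group_size = spec$group_size)
}

#' Embed a distance path into 2-D group trajectories
#'
#' Builds trajectories whose realized interindividual distance reproduces
#' `x_path`. The group centroid follows a smooth mean-reverting random walk
#' inside the arena and the group axis rotates smoothly. Dyads are placed at
#' centroid +/- x/2 along the axis; triads on an equilateral triangle of side
#' `x` (circumradius `x / sqrt(3)`), whose mean pairwise distance equals `x`
#' -- the modelled quantity; matching all three pairwise distances would be
#' under-determined. Bounded uniform jitter of half-width `sigma_pos` is
#' added to every coordinate, so the reconstructed distance matches `x_path`
#' to within `2*sqrt(2)*sigma_pos` by the triangle inequality.
#'
#' @param x_path a [distance_series()].
#' @param spec a [synth_spec()] with `group_size >= 2`.
#' @param seed seed for the embedding's randomness (default derived from
#'   `spec$seed` and the trial id).
#' @return a [trial()] with `spec$group_size` fish.
#' @export
embed_trajectories <- function(x_path, spec, seed = NULL) {
  g <- spec$group_size
  if (g < 2L) fs_abort("embedding needs group_size >= 2", "parameter_error")
  x <- x_path$x
  n <- length(x)
  R <- spec$arena$arena_diameter / 2
  margin <- 1
  # separation of the farthest fish from the centroid
  sep <- if (g == 2L) x / 2 else x / sqrt(3)
  if (max(sep) > R - margin)
    fs_abort(sprintf(
      "distance path (max %.1f cm) does not fit in the arena", max(x)),
      "infeasible_embedding")
  if (is.null(seed))
    seed <- (spec$seed + sum(utf8ToInt(x_path$trial_id))) %% .Machine$integer.max
  set.seed(seed)
  dt <- 1 / spec$frame_rate
  # mean-reverting centroid walk, clamped so all fish stay inside
  kappa <- 0.05; sig_c <- 1.5
  cx <- cy <- numeric(n)
  for (k in 2:n) {
    cx[k] <- cx[k - 1] - kappa * cx[k - 1] * dt + sig_c * sqrt(dt) * rnorm(1)
    cy[k] <- cy[k - 1] - kappa * cy[k - 1] * dt + sig_c * sqrt(dt) * rnorm(1)
    rmax <- R - margin - sep[k]
    rr <- sqrt(cx[k]^2 + cy[k]^2)
    if (rmax <= 0) { cx[k] <- 0; cy[k] <- 0 }
    else if (rr > rmax) { cx[k] <- cx[k] * rmax / rr; cy[k] <- cy[k] * rmax / rr }
  }
  phi <- cumsum(c(runif(1, -pi, pi), spec$heading_smooth * sqrt(dt) * rnorm(n - 1)))
  # bounded (uniform) per-coordinate jitter: tracking noise is bounded by
  # pixel quantisation, and |jitter| <= sigma_pos per coordinate guarantees
  # the reconstructed distance stays within 2*sqrt(2)*sigma_pos of the path
  jit <- function() runif(n, -spec$sigma_pos, spec$sigma_pos)
  fish <- if (g == 2L) {
    list(
      trajectory_series("f1", cx + sep * cos(phi) + jit(),
                        cy + sep * sin(phi) + jit()),
      trajectory_series("f2", cx - sep * cos(phi) + jit(),
                        cy - sep * sin(phi) + jit()))
  } else {
    lapply(1:3, function(m) {
      a <- phi + (m - 1) * 2 * pi / 3
      trajectory_series(paste0("f", m), cx + sep * cos(a) + jit(),
                        cy + sep * sin(a) + jit())
    })
  }
  trial(x_path$trial_id, fish, illumination = x_path$illumination,
        frame_rate = spec$frame_rate, arena = spec$arena,
        arena_tol = max(0.5, 6 * spec$sigma_pos))
}

#' Generate a condition's worth of synthetic trials
#'
#' Convenience wrapper: distance paths for the condition, embedded into 2-D
#' trajectories.
#'
#' @inheritParams generate_distance_paths
#' @return list of [trial()] objects.
#' @export
generate_trials <- function(spec, condition = c("bright", "dark"),
                            n_trials = 10L) {
  paths <- generate_distance_paths(spec, condition, n_trials)
  lapply(paths, embed_trajectories, spec = spec)
}

#' Random geometric fixtures for the visual-cue oracle
#'
#' Seed-reproducible random focal/conspecific poses in the arena, each with
#' the opacity computed by the 36000-ray ray-cast oracle, for regression
#' tests of the analytic interval-union implementation.
#'
#' @param n number of fixtures.
#' @param seed seed.
#' @param cfg a [visual_field_config()].
#' @param arena an [arena_config()].
#' @param n_others number of conspecifics per fixture (recycled; default
#'   alternates 1 and 2, i.e. dyads and triads).
#' @param n_rays rays for the oracle (default 36000).
#' @return list of fixtures: `focal` ([focal_pose()]), `others` (matrix),
#'   `expected_opacity`.
#' @export
generate_visual_fixtures <- function(n, seed = 1L,
                                     cfg = visual_field_config(),
                                     arena = arena_config(),
                                     n_others = NULL, n_rays = 36000L) {
  if (n < 1L) fs_abort("n must be >= 1", "parameter_error")
  set.seed(seed)
  n_others <- rep_len(n_others %||% c(1L, 2L), n)
  lapply(seq_len(n), function(i) {
    focal <- focal_pose(runif(2, -10, 10), runif(1, -pi, pi))
    k <- n_others[i]
    others <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      repeat {
        d <- runif(1, 2.2 * cfg$fish_radius, arena$arena_diameter / 2)
        a <- runif(1, -pi, pi)
        cand <- focal$position + d * c(cos(a), sin(a))
        if (sqrt(sum(cand^2)) <= arena$arena_diameter / 2) break
      }
      others[j, ] <- cand
    }
    list(focal = focal, others = others,
         expected_opacity = opacity_raycast_oracle(focal, others, cfg,
                                                   n_rays = n_rays))
  })
}
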