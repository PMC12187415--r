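# Euler-Maruyama integration and the in-silico experiment harness.

#' Simulation configuration
#'
#' @param dt integration step in s (default 1/30, the recording rate).
#' @param n_steps number of samples per path, including the initial state
#'   (default 18000, one recorded trial).
#' @param x0 initial state in cm; `NULL` (default) draws it uniformly from
#'   between the model's wells (or the middle half of the domain when the
#'   drift has no bistable well pair).
#' @param domain working domain `c(lo, hi)` in cm; default `c(0, 57)`, the
#'   tank diameter minus one body length, since the interindividual distance
#'   is non-negative and bounded by the tank.
#' @param boundary `"reflect"` (default; excursions fold back into the
#'   domain) or `"absorb_error"` (leaving the domain raises an error).
#' @param seed seed for the path's random stream.
#' @param n_trials number of trials for ensemble runs (default 10, the
#'   per-condition trial count of the experimental design).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt = 1 / 30, n_steps = 18000L, x0 = NULL,
                       domain = c(0, 57),
                       boundary = c("reflect", "absorb_error"),
                       seed = NULL, n_trials = 10L) {
  boundary <- match.arg(boundary)
  if (dt <= 0) fs_abort("dt must be > 0", "parameter_error")
  if (n_steps < 2L) fs_abort("n_steps must be >= 2", "parameter_error")
  if (domain[1] >= domain[2]) fs_abort("domain must have lo < hi",
                                       "parameter_error")
  if (!is.null(x0) && (x0 < domain[1] || x0 > domain[2]))
    fs_abort("x0 must lie inside the domain", "parameter_error")
  structure(list(dt = dt, n_steps = as.integer(n_steps), x0 = x0,
                 domain = as.numeric(domain), boundary = boundary,
                 seed = seed, n_trials = as.integer(n_trials)),
            class = "sim_config")
}

x0_range_of <- function(model, cfg) {
  if (!is.null(model$potential)) c(model$potential$xl, model$potential$xh)
  else cfg$domain[1] + c(0.25, 0.75) * diff(cfg$domain)
}

reflect_into <- function(x, lo, hi) {
  # fold excursions back; loop handles multi-width overshoots
  while (any(bad <- (x < lo | x > hi))) {
    x[x < lo] <- 2 * lo - x[x < lo]
    x[x > hi] <- 2 * hi - x[x > hi]
  }
  x
}

em_core <- function(model, cfg, x0, Z) {
  # Z: (n_steps - 1) x n_paths matrix of standard normals
  Ffun <- drift_fun(model)
  Gfun <- diffusion_fun(model)
  dt <- cfg$dt
  sqdt <- sqrt(dt)
  lo <- cfg$domain[1]; hi <- cfg$domain[2]
  n <- cfg$n_steps
  X <- matrix(NA_real_, n, length(x0))
  X[1, ] <- x0
  x <- x0
  for (k in seq_len(n - 1L)) {
    x <- x + Ffun(x) * dt + Gfun(x) * sqdt * Z[k, ]
    if (any(!is.finite(x)))
      fs_abort(sprintf("integration diverged at step %d", k),
               "integration_error")
    if (cfg$boundary == "reflect") {
      x <- reflect_into(x, lo, hi)
    } else if (any(x < lo | x > hi)) {
      fs_abort(sprintf("path left the domain at step %d", k),
               "integration_error")
    }
    X[k + 1L, ] <- x
  }
  X
}

#' Euler-Maruyama integration of an SDE model
#'
#' First-order scheme `x[k+1] = x[k] + F(x[k]) dt + G(x[k]) sqrt(dt) z[k]`
#' with standard-normal `z[k]` from the seeded generator and reflecting
#' boundaries by default. With a fixed seed the path is bit-identical across
#' runs.
#'
#' @param model an [sde_model()].
#' @param cfg a [sim_config()].
#' @param trial_id identifier for the returned series.
#' @return a [distance_series()] of length `cfg$n_steps`.
#' @export
euler_maruyama <- function(model, cfg = sim_config(), trial_id = "sim") {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  x0 <- cfg$x0 %||% {
    r <- x0_range_of(model, cfg)
    runif(1, r[1], r[2])
  }
  Z <- matrix(rnorm(cfg$n_steps - 1L), ncol = 1)
  X <- em_core(model, cfg, x0, Z)
  distance_series(X[, 1], cfg$dt, trial_id = trial_id)
}

# per-trial streams derived from one master seed: trial i is reproducible
# from (master_seed, i) alone and identical whether simulated singly or as
# part of the vectorised ensemble
trial_seeds <- function(master_seed, n_trials) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n_trials)
}

#' Simulate an ensemble of trials from one model
#'
#' Integrates `n_trials` independent paths. Each trial has its own random
#' stream derived from the master seed; trial `i` is bit-identical to
#' `euler_maruyama()` run with `seed = trial_seeds(master_seed, n)[i]`. The
#' stepping is vectorised across trials.
#'
#' @param model an [sde_model()].
#' @param cfg a [sim_config()]; `cfg$n_trials` paths are produced.
#' @param master_seed master seed for the per-trial streams.
#' @param trial_prefix prefix for trial ids.
#' @param illumination,group_size labels attached to the returned series.
#' @return a list of [distance_series()].
#' @export
simulate_trials <- function(model, cfg = sim_config(), master_seed = 1L,
                            trial_prefix = "sim", illumination = NA_character_,
                            group_size = NA_integer_) {
  n_tr <- cfg$n_trials
  seeds <- trial_seeds(master_seed, n_tr)
  x0r <- x0_range_of(model, cfg)
  x0 <- numeric(n_tr)
  Z <- matrix(NA_real_, cfg$n_steps - 1L, n_tr)
  for (i in seq_len(n_tr)) {
    set.seed(seeds[i])
    x0[i] <- cfg$x0 %||% runif(1, x0r[1], x0r[2])
    Z[, i] <- rnorm(cfg$n_steps - 1L)
  }
  X <- em_core(model, cfg, x0, Z)
  lapply(seq_len(n_tr), function(i)
    distance_series(X[, i], cfg$dt,
                    trial_id = sprintf("%s_%02d", trial_prefix, i),
                    illumination = illumination, group_size = group_size))
}

#' In-silico experimental design
#'
#' One simulated condition per illumination x group-size cell, matching the
#' experimental layout (Dyads-Bright, Dyads-Dark, Triads-Bright,
#' Triads-Dark) with the same number of trials per condition. By default the
#' same illumination-specific model is used for dyads and triads.
#'
#' @param models named list with `bright` and `dark` [sde_model()]s (e.g.
#'   [default_regimes()] or fitted models).
#' @param n_trials trials per condition (default 10).
#' @param group_sizes group sizes to include (default `c(2, 3)`).
#' @return a list of condition specs (class `insilico_design`).
#' @export
insilico_design <- function(models = default_regimes(), n_trials = 10L,
                            group_sizes = c(2L, 3L)) {
  if (!all(c("bright", "dark") %in% names(models)))
    fs_abort("models must contain 'bright' and 'dark'", "parameter_error")
  if (n_trials < 1L) fs_abort("n_trials must be >= 1", "parameter_error")
  design <- list()
  for (g in group_sizes) for (ill in c("bright", "dark")) {
    design[[sprintf("%s_%s", c("2" = "dyads", "3" = "triads")[as.character(g)],
                    ill)]] <-
      list(model = models[[ill]], n_trials = as.integer(n_trials),
           illumination = ill, group_size = as.integer(g))
  }
  structure(design, class = "insilico_design")
}

#' Run the in-silico validation experiment
#'
#' Simulates every condition of the design, detects exploration episodes on
#' each path, summarises them per trial, removes outlier trials with the
#' interquartile-range rule (Tukey fences, applied per response variable),
#' and runs a two-way ANOVA (Illumination x Number of Individuals, with
#' eta-squared effect sizes) on the mean episode duration and amplitude.
#' Trials without episodes are flagged and excluded from the ANOVA.
#'
#' @param design an [insilico_design()].
#' @param cfg a [sim_config()] shared by all conditions.
#' @param master_seed master seed; condition `j` uses `master_seed + j - 1`
#'   offsets within [trial_seeds()] streams.
#' @param threshold,min_duration,amplitude_mode episode detection settings,
#'   see [detect_episodes()].
#' @return a list of class `insilico_result` with `stats` (the per-trial
#'   table, including `outlier_T`/`outlier_A` flags), `anova` (per-response
#'   [two_way_anova()] results, `NULL` with a diagnostic when a whole
#'   condition produced no episodes) and `diagnostics`.
#' @export
run_insilico <- function(design, cfg = sim_config(), master_seed = 1L,
                         threshold = 9, min_duration = 3,
                         amplitude_mode = c("mean", "median")) {
  amplitude_mode <- match.arg(amplitude_mode)
  stats_rows <- list()
  for (j in seq_along(design)) {
    cond <- design[[j]]
    cond_cfg <- cfg
    cond_cfg$n_trials <- cond$n_trials
    paths <- simulate_trials(cond$model, cond_cfg,
                             master_seed = master_seed + j - 1L,
                             trial_prefix = names(design)[j],
                             illumination = cond$illumination,
                             group_size = cond$group_size)
    stats_rows[[j]] <- trial_episode_stats(paths, threshold = threshold,
                                           min_duration = min_duration,
                                           amplitude_mode = amplitude_mode)
  }
  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL

  diagnostics <- character(0)
  cond_label <- interaction(stats$illumination, stats$group_size, drop = TRUE)
  dead <- tapply(stats$has_episodes, cond_label, function(z) !any(z))
  if (any(dead)) {
    diagnostics <- sprintf(
      "condition(s) without any episode: %s; ANOVA skipped",
      paste(names(dead)[dead], collapse = ", "))
    fs_log(diagnostics, "warn")
  }

  with_ep <- stats[stats$has_episodes, , drop = FALSE]
  filt_T <- iqr_outlier_filter(with_ep$mean_T)
  filt_A <- iqr_outlier_filter(with_ep$mean_A)
  stats$outlier_T <- stats$outlier_A <- FALSE
  stats$outlier_T[stats$has_episodes][filt_T$removed_idx] <- TRUE
  stats$outlier_A[stats$has_episodes][filt_A$removed_idx] <- TRUE

  anova <- list(duration = NULL, amplitude = NULL)
  if (!any(dead)) {
    dT <- with_ep[!stats$outlier_T[stats$has_episodes], , drop = FALSE]
    dA <- with_ep[!stats$outlier_A[stats$has_episodes], , drop = FALSE]
    anova$duration <- two_way_anova(dT$mean_T, dT$illumination,
                                    factor(dT$group_size),
                                    factor_names = c("illumination",
                                                     "group_size"))
    anova$amplitude <- two_way_anova(dA$mean_A, dA$illumination,
                                     factor(dA$group_size),
                                     factor_names = c("illumination",
                                                      "group_size"))
  }
  structure(list(stats = stats, anova = anova, diagnostics = diagnostics),
            class = "insilico_result")
}
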