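# Pipeline orchestration: run any stage end-to-end from one configuration,
# with plain CSV/JSON artifacts so every intermediate can be inspected or
# replaced. All stochastic stages are deterministic given (config, seed).

#' Pipeline configuration
#'
#' Nested configuration for the pipeline stages. Any field may be overridden
#' via `...`; unknown fields are rejected.
#'
#' @param input_dir,output_dir file-system locations for stage inputs and
#'   artifacts.
#' @param seed master seed used by every stochastic stage.
#' @param log_level `"debug"`, `"info"`, `"warn"` or `"quiet"`.
#' @param ... overrides for the nested groups `arena`, `visual`, `episode`,
#'   `inference`, `simulation`, `synth` (named lists merged over defaults).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = ".", output_dir = ".", seed = 1L,
                            log_level = "warn", ...) {
  base <- list(
    input_dir = input_dir, output_dir = output_dir, seed = seed,
    log_level = log_level,
    arena = list(arena_diameter = 60, body_length = 3, px_per_cm = 34.13),
    visual = list(blind_angle = 21 * pi / 180, fish_radius = 1.5,
                  blind_zone_centre = "rear"),
    episode = list(threshold = 9, min_duration = 3, amplitude_mode = "mean"),
    inference = list(max_degree = 5, K = 5, prune_threshold = 1e-3,
                     bin_width = 0.1, min_count = 10, filter = FALSE),
    simulation = list(dt = 1 / 30, n_steps = 18000, domain = c(0, 57),
                      n_trials = 10),
    synth = list(group_size = 2, n_trials = 10, sigma_pos = 0.05,
                 conditions = c("bright", "dark"),
                 # optional per-condition model override:
                 # list(bright = list(alpha=, beta=, xl=, xh=, diffusion=), ...)
                 regimes = NULL)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad))
    fs_abort(sprintf("unknown config field(s): %s",
                     paste(bad, collapse = ", ")), "parameter_error")
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]][names(over[[nm]])] <- over[[nm]]
    else base[[nm]] <- over[[nm]]
  }
  structure(base, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` (needs the yaml package) or `.json` file
#'   whose top-level fields are [pipeline_config()] arguments.
#' @return a [pipeline_config()].
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      fs_abort("the yaml package is required for YAML configs", "io_error")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

cfg_arena <- function(config) do.call(arena_config, config$arena)
cfg_visual <- function(config) do.call(visual_field_config, config$visual)
cfg_simulation <- function(config) {
  s <- config$simulation
  sim_config(dt = s$dt, n_steps = s$n_steps, domain = unlist(s$domain),
             n_trials = s$n_trials)
}
cfg_ssr <- function(config) {
  i <- config$inference
  ssr_config(max_degree = i$max_degree, K = i$K,
             prune_threshold = i$prune_threshold, seed = config$seed)
}

write_manifest <- function(config, stage, outputs) {
  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass_deep(unclass(config)), cfg_json,
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    stage = stage,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fishsde")),
    config_hash = unname(tools::md5sum(cfg_json)),
    config = jsonlite::read_json(cfg_json),
    outputs = basename(outputs))
  unlink(cfg_json)
  path <- file.path(config$output_dir, paste0(stage, "_manifest.json"))
  write_results(manifest, path)
  path
}

read_stage_trials <- function(config) {
  meta_path <- file.path(config$input_dir, "metadata.csv")
  metadata <- if (file.exists(meta_path)) read_results(meta_path) else NULL
  traj <- file.path(config$input_dir, "trajectories")
  src <- if (dir.exists(traj)) traj else config$input_dir
  read_trials(src, arena = cfg_arena(config), metadata = metadata)
}

#' Run one pipeline stage
#'
#' Stages: `synth` (write synthetic trajectory CSVs and a ground-truth
#' manifest), `metrics` (visual-cue and kinematic series per trial),
#' `episodes` (distance series, episode table, per-trial stats), `infer`
#' (SDE identification per illumination condition, model JSON + binned KM
#' CSV), `potential` (potential curve and bistability report from a model
#' JSON), `simulate` (Euler-Maruyama paths from a model JSON) and `insilico`
#' (the full validation experiment: simulations, episode stats, IQR outlier
#' rule, two-way ANOVA). Every stage writes its artifacts plus a manifest
#' with the configuration, seed and package version into
#' `config$output_dir`.
#'
#' @param stage stage name (see above).
#' @param config a [pipeline_config()].
#' @return invisibly, a character vector of artifact paths.
#' @export
run_stage <- function(stage = c("synth", "metrics", "episodes", "infer",
                                "potential", "simulate", "insilico"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  old <- options(fishsde.verbose = config$log_level)
  on.exit(options(old))
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  out <- switch(stage,
    synth = stage_synth(config),
    metrics = stage_metrics(config),
    episodes = stage_episodes(config),
    infer = stage_infer(config),
    potential = stage_potential(config),
    simulate = stage_simulate(config),
    insilico = stage_insilico(config))
  manifest <- write_manifest(config, stage, out)
  fs_log(sprintf("stage '%s' wrote %d artifact(s)", stage, length(out)),
         "info")
  invisible(c(out, manifest))
}

stage_synth <- function(config) {
  sdir <- file.path(config$output_dir, "trajectories")
  if (!dir.exists(sdir)) dir.create(sdir)
  outs <- character(0)
  meta <- list()
  truth <- list()
  regimes <- default_regimes()
  if (!is.null(config$synth$regimes)) {
    for (cond in names(config$synth$regimes)) {
      r <- config$synth$regimes[[cond]]
      regimes[[cond]] <- sde_model(
        potential_params(r$alpha, r$beta, r$xl, r$xh),
        diffusion = unlist(r$diffusion %||% c(0.53125, 0.075, -0.003)))
    }
  }
  for (cond in config$synth$conditions) {
    spec <- synth_spec(regimes = regimes,
                       group_size = config$synth$group_size,
                       arena = cfg_arena(config),
                       n_frames = config$simulation$n_steps,
                       sigma_pos = config$synth$sigma_pos,
                       seed = config$seed)
    trials <- generate_trials(spec, cond, n_trials = config$synth$n_trials)
    for (tr in trials) {
      p <- file.path(sdir, paste0(tr$trial_id, ".csv"))
      write_trial_csv(tr, p)
      outs <- c(outs, p)
      meta[[length(meta) + 1L]] <- data.frame(trial_id = tr$trial_id,
                                              illumination = cond)
    }
    m <- spec$regimes[[cond]]
    truth[[cond]] <- list(drift = m$drift$coefficients,
                          diffusion = m$diffusion$coefficients,
                          potential = m$potential)
  }
  meta_path <- file.path(config$output_dir, "metadata.csv")
  write_results(do.call(rbind, meta), meta_path)
  truth_path <- file.path(config$output_dir, "ground_truth.json")
  write_results(truth, truth_path)
  c(outs, meta_path, truth_path)
}

stage_metrics <- function(config) {
  trials <- read_stage_trials(config)
  vcfg <- cfg_visual(config)
  cues <- do.call(rbind, lapply(trials, visual_cue_series, cfg = vcfg))
  kin <- do.call(rbind, lapply(trials, function(tr) {
    dt <- 1 / tr$frame_rate
    do.call(rbind, lapply(tr$fish, function(f)
      data.frame(trial_id = tr$trial_id, fish_id = f$fish_id,
                 frame = seq_len(length(f$x) - 1L) - 1L,
                 linear_speed = linear_speed(f, dt),
                 angular_speed = angular_speed(f, dt))))
  }))
  p1 <- file.path(config$output_dir, "visual_cues.csv")
  p2 <- file.path(config$output_dir, "kinematics.csv")
  write_results(cues, p1)
  write_results(kin, p2)
  c(p1, p2)
}

stage_episodes <- function(config) {
  trials <- read_stage_trials(config)
  ds <- lapply(trials, interindividual_distance)
  dist_tab <- do.call(rbind, lapply(ds, function(d)
    data.frame(trial_id = d$trial_id, frame = seq_along(d$x) - 1L,
               distance_cm = d$x)))
  eps <- do.call(rbind, lapply(ds, function(d)
    detect_episodes(d, threshold = config$episode$threshold,
                    min_duration = config$episode$min_duration,
                    amplitude_mode = config$episode$amplitude_mode)))
  stats <- trial_episode_stats(ds, threshold = config$episode$threshold,
                               min_duration = config$episode$min_duration,
                               amplitude_mode = config$episode$amplitude_mode)
  paths <- file.path(config$output_dir,
                     c("distance.csv", "episodes.csv", "episode_stats.csv"))
  write_results(dist_tab, paths[1])
  write_results(as.data.frame(eps), paths[2])
  write_results(stats, paths[3])
  paths
}

stage_infer <- function(config) {
  trials <- read_stage_trials(config)
  ds <- lapply(trials, interindividual_distance)
  conds <- split(ds, vapply(ds, function(d)
    d$illumination %||% NA_character_, character(1)))
  outs <- character(0)
  for (cond in names(conds)) {
    fit <- identify_sde(conds[[cond]], cfg = cfg_ssr(config),
                        bin_width = config$inference$bin_width,
                        min_count = config$inference$min_count,
                        filter = isTRUE(config$inference$filter))
    mp <- file.path(config$output_dir, sprintf("model_%s.json", cond))
    bp <- file.path(config$output_dir, sprintf("binned_km_%s.csv", cond))
    write_results(list(
      condition = cond,
      drift = list(target = "drift", degree = fit$drift_fit$model$degree,
                   coefficients = fit$drift_fit$model$coefficients,
                   cv_error = fit$drift_fit$cv_error),
      diffusion = list(target = "diffusion",
                       degree = fit$diffusion_fit$model$degree,
                       coefficients = fit$diffusion_fit$model$coefficients,
                       cv_error = fit$diffusion_fit$cv_error),
      domain = fit$model$domain,
      potential = fit$model$potential), mp)
    write_results(as.data.frame(fit$binned), bp)
    outs <- c(outs, mp, bp)
  }
  outs
}

model_from_json <- function(path) {
  m <- read_results(path)
  sde_model(drift = unlist(m$drift$coefficients),
            diffusion = unlist(m$diffusion$coefficients),
            domain = unlist(m$domain))
}

stage_potential <- function(config) {
  models <- list.files(config$input_dir, pattern = "^model_.*\\.json$",
                       full.names = TRUE)
  if (!length(models))
    fs_abort("no model_*.json files in input_dir", "io_error")
  outs <- character(0)
  for (mp in models) {
    cond <- sub("^model_(.*)\\.json$", "\\1", basename(mp))
    model <- model_from_json(mp)
    xs <- seq(model$domain[1], model$domain[2], by = 0.1)
    Vfun <- function(x) {
      cf <- model$drift$coefficients
      -polyval_asc(c(0, cf[1], cf[2] / 2, cf[3] / 3, cf[4] / 4), x)
    }
    curve_path <- file.path(config$output_dir,
                            sprintf("potential_%s.csv", cond))
    write_results(data.frame(x = xs, V = Vfun(xs) - Vfun(xs[1])), curve_path)
    rep_path <- file.path(config$output_dir,
                          sprintf("bistability_%s.json", cond))
    write_results(bistability_report(model), rep_path)
    outs <- c(outs, curve_path, rep_path)
  }
  outs
}

stage_simulate <- function(config) {
  models <- list.files(config$input_dir, pattern = "^model_.*\\.json$",
                       full.names = TRUE)
  if (!length(models))
    fs_abort("no model_*.json files in input_dir", "io_error")
  outs <- character(0)
  for (mp in models) {
    cond <- sub("^model_(.*)\\.json$", "\\1", basename(mp))
    model <- model_from_json(mp)
    paths <- simulate_trials(model, cfg_simulation(config),
                             master_seed = config$seed,
                             trial_prefix = paste0("sim_", cond),
                             illumination = cond)
    tab <- do.call(rbind, lapply(paths, function(d)
      data.frame(trial_id = d$trial_id, frame = seq_along(d$x) - 1L,
                 distance_cm = d$x)))
    p <- file.path(config$output_dir, sprintf("simulated_%s.csv", cond))
    write_results(tab, p)
    outs <- c(outs, p)
  }
  outs
}

stage_insilico <- function(config) {
  model_files <- list.files(config$input_dir, pattern = "^model_.*\\.json$",
                            full.names = TRUE)
  models <- if (length(model_files)) {
    setNames(lapply(model_files, model_from_json),
             sub("^model_(.*)\\.json$", "\\1", basename(model_files)))
  } else default_regimes()
  design <- insilico_design(models, n_trials = config$simulation$n_trials)
  res <- run_insilico(design, cfg_simulation(config),
                      master_seed = config$seed,
                      threshold = config$episode$threshold,
                      min_duration = config$episode$min_duration)
  p1 <- file.path(config$output_dir, "insilico_stats.csv")
  p2 <- file.path(config$output_dir, "insilico_anova.json")
  write_results(res$stats, p1)
  write_results(list(
    duration = if (!is.null(res$anova$duration))
      as.data.frame(res$anova$duration),
    amplitude = if (!is.null(res$anova$amplitude))
      as.data.frame(res$anova$amplitude),
    diagnostics = res$diagnostics), p2)
  c(p1, p2)
}
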