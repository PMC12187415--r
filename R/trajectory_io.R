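# Trajectory containers and file I/O.
#
# Trajectories follow a long CSV dialect (AnimalTA-like export):
# columns `trial_id,fish_id,frame,x,y`, frame 0-based, gap-free, one file per
# trial or one long file. Coordinates are Cartesian, origin at the tank
# centre; raw exports with a different origin can be shifted on read.

#' Arena and recording geometry
#'
#' Describes the experimental setup: a circular tank, the body length of the
#' tracked fish and the camera calibration used to convert pixels to
#' centimetres. Defaults match a 60 cm tank, 3 cm adult zebrafish and a
#' calibration of 34.13 pixels per cm.
#'
#' @param arena_diameter tank diameter in cm.
#' @param body_length fish body length (BL) in cm.
#' @param px_per_cm pixel-to-centimetre calibration ratio.
#' @return an object of class `arena_config`.
#' @examples
#' arena_config()
#' @export
arena_config <- function(arena_diameter = 60, body_length = 3,
                         px_per_cm = 34.13) {
  for (v in c(arena_diameter, body_length, px_per_cm))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      fs_abort("arena_config fields must be strictly positive scalars",
               "parameter_error")
  structure(list(arena_diameter = arena_diameter, body_length = body_length,
                 px_per_cm = px_per_cm), class = "arena_config")
}

#' Single-fish trajectory
#'
#' @param fish_id fish identifier (string).
#' @param x,y equal-length numeric position series in cm, tank-centred.
#' @return an object of class `trajectory_series`.
#' @export
trajectory_series <- function(fish_id, x, y) {
  if (length(x) != length(y))
    fs_abort(sprintf("fish '%s': x and y series differ in length (%d vs %d)",
                     fish_id, length(x), length(y)), "integrity_error")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    fs_abort(sprintf("fish '%s': non-finite coordinates", fish_id),
             "integrity_error")
  structure(list(fish_id = as.character(fish_id),
                 x = as.numeric(x), y = as.numeric(y)),
            class = "trajectory_series")
}

#' A trial: synchronized group trajectories plus metadata
#'
#' @param trial_id trial identifier.
#' @param fish list of [trajectory_series()] objects (1-3 fish), equal length.
#' @param illumination `"bright"`, `"dark"` or `NA` if unknown.
#' @param frame_rate sampling rate in Hz (default 30).
#' @param arena an [arena_config()]; used to check positions stay in the tank.
#' @param arena_tol tolerance in cm beyond the arena radius before a position
#'   is treated as a tracking error.
#' @return an object of class `trial` with fields `trial_id`, `illumination`,
#'   `group_size`, `frame_rate`, `fish`.
#' @export
trial <- function(trial_id, fish, illumination = NA_character_,
                  frame_rate = 30, arena = arena_config(), arena_tol = 0.5) {
  if (!length(fish) %in% 1:3)
    fs_abort(sprintf("trial '%s': group size must be 1-3, got %d",
                     trial_id, length(fish)), "integrity_error")
  if (!all(vapply(fish, inherits, logical(1), "trajectory_series")))
    fs_abort("fish must be a list of trajectory_series", "parameter_error")
  lens <- vapply(fish, function(f) length(f$x), integer(1))
  if (length(unique(lens)) != 1L)
    fs_abort(sprintf("trial '%s': fish series lengths differ (%s)",
                     trial_id, paste(lens, collapse = ", ")),
             "integrity_error")
  if (!is.na(illumination) && !illumination %in% c("bright", "dark"))
    fs_abort("illumination must be 'bright', 'dark' or NA", "parameter_error")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    fs_abort("frame_rate must be > 0", "parameter_error")
  r_max <- arena$arena_diameter / 2 + arena_tol
  for (f in fish) {
    rr <- sqrt(f$x^2 + f$y^2)
    if (any(rr > r_max))
      fs_abort(sprintf(
        "trial '%s', fish '%s': position %.2f cm from centre exceeds arena radius %.2f + %.2f cm",
        trial_id, f$fish_id, max(rr), arena$arena_diameter / 2, arena_tol),
        "integrity_error")
  }
  fish <- unname(fish[order(vapply(fish, `[[`, character(1), "fish_id"))])
  structure(list(trial_id = as.character(trial_id),
                 illumination = illumination,
                 group_size = length(fish),
                 frame_rate = frame_rate,
                 fish = fish),
            class = "trial")
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf("<trial '%s'> %d fish, %d frames at %g Hz, illumination: %s\n",
              x$trial_id, x$group_size, length(x$fish[[1]]$x), x$frame_rate,
              x$illumination))
  invisible(x)
}

required_traj_cols <- c("trial_id", "fish_id", "frame", "x", "y")

#' Read trajectory CSV files into trials
#'
#' Reads one file, or every `*.csv` in a directory, in the long dialect
#' `trial_id,fish_id,frame,x,y` (0-based, gap-free frames). Pixel coordinates
#' are converted to cm with `arena$px_per_cm`; positions are then shifted by
#' `origin` so that the tank centre is at (0, 0). Missing frames are an error,
#' never interpolated: downstream derivatives assume a uniform time step.
#'
#' @param path a CSV file or a directory of CSV files.
#' @param arena an [arena_config()].
#' @param units `"cm"` or `"px"` for the coordinates in the file.
#' @param metadata optional data.frame with columns `trial_id` and
#'   `illumination` (and optionally `frame_rate`).
#' @param origin length-2 numeric: coordinates (in `units`) of the tank centre
#'   in the file's frame, subtracted on read.
#' @param frame_rate sampling rate in Hz for all trials (default 30).
#' @param arena_tol passed to [trial()].
#' @return a list of [trial()] objects, ordered by trial id.
#' @export
read_trials <- function(path, arena = arena_config(), units = c("cm", "px"),
                        metadata = NULL, origin = c(0, 0), frame_rate = 30,
                        arena_tol = 0.5) {
  units <- match.arg(units)
  if (!file.exists(path))
    fs_abort(sprintf("path does not exist: %s", path), "io_error")
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.csv$", full.names = TRUE) else path
  if (length(files) == 0L)
    fs_abort(sprintf("no CSV files under %s", path), "io_error")
  dat <- do.call(rbind, lapply(files, function(f) {
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    missing <- setdiff(required_traj_cols, names(d))
    if (length(missing))
      fs_abort(sprintf("file %s: missing column '%s'", basename(f),
                       missing[1]), "format_error")
    d[required_traj_cols]
  }))
  scale <- if (units == "px") 1 / arena$px_per_cm else 1
  dat$x <- (dat$x - origin[1]) * scale
  dat$y <- (dat$y - origin[2]) * scale

  out <- lapply(split(dat, dat$trial_id), function(td) {
    fish <- lapply(split(td, td$fish_id), function(fd) {
      o <- order(fd$frame)
      fd <- fd[o, ]
      if (any(duplicated(fd$frame)) || any(diff(fd$frame) <= 0))
        fs_abort(sprintf("trial '%s', fish '%s': non-monotone frame index",
                         td$trial_id[1], fd$fish_id[1]), "integrity_error")
      if (!identical(as.integer(fd$frame),
                     seq.int(0L, length.out = nrow(fd))))
        fs_abort(sprintf("trial '%s', fish '%s': frames not 0-based gap-free",
                         td$trial_id[1], fd$fish_id[1]), "integrity_error")
      trajectory_series(fd$fish_id[1], fd$x, fd$y)
    })
    illum <- NA_character_
    fr <- frame_rate
    if (!is.null(metadata)) {
      row <- metadata[metadata$trial_id == td$trial_id[1], , drop = FALSE]
      if (nrow(row)) {
        illum <- as.character(row$illumination[1])
        if ("frame_rate" %in% names(row)) fr <- row$frame_rate[1]
      }
    }
    trial(td$trial_id[1], fish, illumination = illum, frame_rate = fr,
          arena = arena, arena_tol = arena_tol)
  })
  out[order(names(out))]
}

#' Write a trial back to the trajectory CSV dialect
#'
#' @param x a [trial()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trial_csv <- function(x, path) {
  rows <- do.call(rbind, lapply(x$fish, function(f)
    data.frame(trial_id = x$trial_id, fish_id = f$fish_id,
               frame = seq_along(f$x) - 1L, x = f$x, y = f$y)))
  write_results(rows, path)
}

#' Write result tables and model objects to disk
#'
#' Data frames go to CSV; lists and model objects go to JSON with full float
#' precision, so a read-back with [read_results()] reproduces the object up to
#' float text formatting.
#'
#' @param object a data.frame (CSV) or list-like result (JSON).
#' @param path destination; extension selects the format (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path) {
  if (!dir.exists(dirname(path)))
    fs_abort(sprintf("parent directory does not exist: %s", dirname(path)),
             "io_error")
  ext <- tolower(tools::file_ext(path))
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", ext))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  if (is.data.frame(object) || ext == "csv") {
    utils::write.csv(as.data.frame(object), tmp, row.names = FALSE)
  } else {
    jsonlite::write_json(unclass_deep(object), tmp, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  }
  if (!file.rename(tmp, path))
    fs_abort(sprintf("cannot write to %s", path), "io_error")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, unclass_deep)
  }
  x
}

#' Read back results written by [write_results()]
#'
#' @param path a `.csv` or `.json` file.
#' @return a data.frame (CSV) or list (JSON).
#' @export
read_results <- function(path) {
  if (!file.exists(path))
    fs_abort(sprintf("path does not exist: %s", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Convert between centimetres and pixels
#'
#' Linear, invertible calibration transforms.
#'
#' @param x numeric values.
#' @param arena an [arena_config()] holding `px_per_cm`.
#' @return converted values.
#' @export
cm_to_px <- function(x, arena = arena_config()) x * arena$px_per_cm

#' @rdname cm_to_px
#' @export
px_to_cm <- function(x, arena = arena_config()) x / arena$px_per_cm
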