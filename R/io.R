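#' Read and write tracking traces
#'
#' Trace CSVs have columns `time_s`, `x_cm`, `y_cm` and optionally `zone`;
#' a header is required. Reading validates monotone times and grid
#' uniformity, then runs [trace_qc()], attaching the gap/out-of-bounds
#' summary.
#'
#' @param path CSV path.
#' @param arena An [arena_geometry()] (or arena kind string).
#' @param sample_rate Samples per second; inferred from the median time
#'   step when `NULL`.
#' @param lightcycle Optional [light_cycle()].
#' @param qc Run [trace_qc()] after reading.
#' @param ... Passed to [trace_qc()].
#' @return A `phenocage_trace`.
#' @export
read_trace <- function(path, arena, sample_rate = NULL, lightcycle = NULL,
                       qc = TRUE, ...) {
  if (!file.exists(path)) stop_input("trace file not found: %s", path)
  if (is.character(arena)) arena <- arena_geometry(arena)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "x_cm", "y_cm")
  if (!all(need %in% names(df))) {
    stop_input("trace CSV %s lacks column(s): %s", path,
               paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop_input("trace times in %s are not strictly increasing", path)
  }
  if (is.null(sample_rate)) {
    sample_rate <- 1 / median(diff(df$time_s))
  }
  tr <- tracking_trace(df$time_s, df$x_cm, df$y_cm, sample_rate = sample_rate,
                       arena = arena, lightcycle = lightcycle,
                       zone = if ("zone" %in% names(df)) df$zone,
                       validate = FALSE)
  if (qc) tr <- trace_qc(tr, ...)
  tr
}

#' @rdname read_trace
#' @param trace A `phenocage_trace`.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace), path, progress = FALSE)
  invisible(path)
}

#' Read and write keypoint tables
#'
#' Keypoint CSVs use the tidy long pose-estimation export layout:
#' `frame`, `bodypart`, `x_cm`, `y_cm`, `confidence`.
#'
#' @param path CSV path.
#' @param sample_rate Samples per second.
#' @return Keypoint tibble with `sample_rate` attribute.
#' @export
read_keypoints <- function(path, sample_rate) {
  if (!file.exists(path)) stop_input("keypoint file not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("frame", "bodypart", "x_cm", "y_cm", "confidence")
  if (!all(need %in% names(df))) {
    stop_input("keypoint CSV lacks column(s): %s",
               paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(df$confidence < 0 | df$confidence > 1)) {
    stop_input("keypoint confidence outside [0, 1]")
  }
  attr(df, "sample_rate") <- sample_rate
  class(df) <- c("phenocage_keypoints", class(df))
  df
}

#' @rdname read_keypoints
#' @param kp A keypoint tibble.
#' @export
write_keypoints <- function(kp, path) {
  readr::write_csv(tibble::as_tibble(kp), path, progress = FALSE)
  invisible(path)
}

#' Read and write cognition-wall entry logs
#'
#' Entry-log CSVs have columns `time_s` and `hole`.
#'
#' @param path CSV path.
#' @param schedule A [target_schedule()].
#' @return A `phenocage_entrylog`.
#' @export
read_entry_log <- function(path, schedule) {
  if (!file.exists(path)) stop_input("entry log not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "hole") %in% names(df))) {
    stop_input("entry log CSV needs columns time_s, hole")
  }
  entry_log(df$time_s, df$hole, schedule)
}

#' @rdname read_entry_log
#' @param log A `phenocage_entrylog`.
#' @export
write_entry_log <- function(log, path) {
  readr::write_csv(tibble::as_tibble(log)[, c("time_s", "hole")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' Run configurations are plain-text key-value (YAML) files listing the
#' animals (id, group, optional own-WT assignment, trace and entry-log
#' paths), the arena and light cycle, the entry schedule and the
#' segmentation/phenotype/statistics parameters. Relative paths are
#' resolved against the config file's directory.
#'
#' @param path Config file path.
#' @return A validated `phenocage_runconfig` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$animals) || length(cfg$animals) == 0) {
    stop_input("config lists no animals")
  }
  arena_kinds <- c("open_field", "phenotyper", "barnes", "water_maze",
                   "three_chamber", "t_maze", "darklight")
  if (is.null(cfg$arena)) cfg$arena <- "phenotyper"
  if (!cfg$arena %in% arena_kinds) {
    stop_input("unknown arena kind '%s' in config field `arena`", cfg$arena)
  }
  if (is.null(cfg$sample_rate)) stop_input("config field `sample_rate` is required")
  check_pos(cfg$sample_rate, "sample_rate")
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (is.null(cfg$control_group)) cfg$control_group <- "WT"
  resolve <- function(p) {
    if (is.null(p) || is.null(cfg$base_dir)) return(p)
    if (file.exists(p)) p else file.path(cfg$base_dir, p)
  }
  for (i in seq_along(cfg$animals)) {
    a <- cfg$animals[[i]]
    if (is.null(a$id) || is.null(a$group)) {
      stop_input("animal %d lacks id or group", i)
    }
    a$trace <- resolve(a$trace)
    a$entry_log <- resolve(a$entry_log)
    if (!is.null(a$trace) && !file.exists(a$trace)) {
      stop_input("trace file for %s not found: %s", a$id, a$trace)
    }
    if (!is.null(a$entry_log) && !file.exists(a$entry_log)) {
      stop_input("entry log for %s not found: %s", a$id, a$entry_log)
    }
    cfg$animals[[i]] <- a
  }
  structure(cfg, class = "phenocage_runconfig")
}

config_lightcycle <- function(cfg) {
  lc <- cfg$lightcycle
  if (is.null(lc)) return(light_cycle())
  light_cycle(lights_on = lc$lights_on %||% "07:00",
              lights_off = lc$lights_off %||% "19:00",
              t0 = lc$t0 %||% "19:00")
}

config_segmentation <- function(cfg) {
  do.call(segmentation_config, cfg$segmentation %||% list())
}

config_phenotype <- function(cfg) {
  do.call(phenotype_config, cfg$phenotype %||% list())
}
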