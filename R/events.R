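#' Behavioral event logs
#'
#' An event log is a tibble of ordered behavioral events with columns
#' `layer` (`"locomotor"`, `"shelter"`, `"activity"`), `kind` (`"movement"`,
#' `"arrest"`, `"shelter_visit"`, `"activity_bout"`), `start`, `end`
#' (seconds, end-exclusive) and `distance` (cm, movements only, `NA`
#' otherwise). Within a layer events are time-sorted and non-overlapping.
#' Logs produced by the synthetic generator are exact ground truth.
#'
#' @param layer,kind,start,end,distance Event columns.
#' @param duration Total span of the underlying recording (s).
#' @param lightcycle Optional [light_cycle()].
#' @return A `phenocage_events` tibble.
#' @export
event_log <- function(layer, kind, start, end, distance = NULL,
                      duration = NULL, lightcycle = NULL) {
  n <- length(start)
  if (is.null(distance)) distance <- rep(NA_real_, n)
  out <- tibble::tibble(layer = as.character(layer), kind = as.character(kind),
                        start = as.double(start), end = as.double(end),
                        distance = as.double(distance))
  if (any(out$end <= out$start)) stop_input("event end must exceed start")
  if (any(!is.na(out$distance) & out$distance < 0)) stop_input("negative movement distance")
  out <- dplyr::arrange(out, .data$layer, .data$start)
  for (ly in unique(out$layer)) {
    ev <- out[out$layer == ly, ]
    if (nrow(ev) > 1 && any(ev$start[-1] < ev$end[-nrow(ev)] - 1e-9)) {
      stop_input("overlapping events in layer '%s'", ly)
    }
  }
  if (is.null(duration)) duration <- max(out$end, 0)
  structure(out, class = c("phenocage_events", class(out)),
            duration = duration, lightcycle = lightcycle)
}

#' @export
print.phenocage_events <- function(x, ...) {
  cat(sprintf("<phenocage_events> %d events over %.1f s\n",
              nrow(x), attr(x, "duration")))
  NextMethod()
}

events_layer <- function(events, layer) {
  events[events$layer == layer, , drop = FALSE]
}

events_kind <- function(events, kind) {
  events[events$kind == kind, , drop = FALSE]
}

#' Segmentation configuration
#'
#' Velocity and duration thresholds for event segmentation. The tracking
#' thresholds used by commercial software are not standardized, so all of
#' them are exposed here; downstream metrics either fix or are agnostic to
#' them.
#'
#' @param v_move Speed threshold for movement (cm/s).
#' @param v_freeze Speed below which a frame counts as frozen (cm/s).
#' @param min_move_dur Minimum movement duration (s).
#' @param min_freeze_dur Minimum freezing duration (s).
#' @param merge_gap Sub-threshold gap bridged inside a movement (s).
#' @param activity_merge_gap Gap between movements bridged inside an
#'   activity bout (s).
#' @param proximity_radius Interaction radius beyond an object boundary (cm).
#' @param min_conf Minimum keypoint confidence.
#' @param max_gap Longest tracking gap interpolated by QC (s).
#' @param max_missing Maximum tolerated missing-frame fraction.
#' @return A list of class `phenocage_segcfg`.
#' @export
segmentation_config <- function(v_move = 2, v_freeze = 1, min_move_dur = 0.5,
                                min_freeze_dur = 1, merge_gap = 0.5,
                                activity_merge_gap = 5, proximity_radius = 2,
                                min_conf = 0.6, max_gap = 1, max_missing = 0.2) {
  check_pos(c(v_move, v_freeze, min_move_dur, min_freeze_dur), "thresholds")
  check_pos(c(merge_gap, activity_merge_gap, proximity_radius), "gaps")
  check_prob(min_conf, "min_conf")
  structure(list(v_move = v_move, v_freeze = v_freeze,
                 min_move_dur = min_move_dur, min_freeze_dur = min_freeze_dur,
                 merge_gap = merge_gap, activity_merge_gap = activity_merge_gap,
                 proximity_radius = proximity_radius, min_conf = min_conf,
                 max_gap = max_gap, max_missing = max_missing),
            class = "phenocage_segcfg")
}

# Merge (start,end) index runs separated by gaps of at most `gap_frames`
# frames, then drop runs shorter than `min_frames`.
merge_runs <- function(runs, gap_frames, min_frames = 1L) {
  if (nrow(runs) == 0) return(runs)
  keep <- list(runs[1, ])
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs[i, 1] - last[2] - 1L <= gap_frames) {
        keep[[length(keep)]][2] <- runs[i, 2]
      } else {
        keep[[length(keep) + 1L]] <- runs[i, ]
      }
    }
  }
  out <- do.call(rbind, keep)
  out[out[, 2] - out[, 1] + 1L >= min_frames, , drop = FALSE]
}

#' Segment a trace into behavioral events
#'
#' Produces the three event layers of home-cage phenotyping: the shelter
#' layer (maximal runs with the body center inside the shelter zone), the
#' locomotor layer, which partitions non-shelter time into movements (speed
#' at least `v_move` sustained for `min_move_dur`, bridged across
#' sub-threshold gaps up to `merge_gap`) and arrests (the complement), and
#' the activity layer (movements merged across gaps up to
#' `activity_merge_gap`). Event times are end-exclusive on the frame grid,
#' so shelter + non-shelter time equals the trace duration and movement +
#' arrest time equals the non-shelter time exactly.
#'
#' @param trace A [tracking_trace()]; run [trace_qc()] first if it may
#'   contain gaps.
#' @param cfg A [segmentation_config()].
#' @param shelter_zone Zone treated as the shelter; defaults to the arena's
#'   `shelter` zone if present.
#' @return A [event_log()] with an attached `lightcycle` when the trace has
#'   one.
#' @export
segment_events <- function(trace, cfg = segmentation_config(),
                           shelter_zone = NULL) {
  stopifnot(inherits(trace, "phenocage_trace"))
  if (anyNA(trace$x_cm) || anyNA(trace$y_cm)) {
    stop_input("trace contains missing coordinates; run trace_qc() first")
  }
  rate <- trace_rate(trace)
  dt <- 1 / rate
  n <- nrow(trace)
  if (n < 2) stop_input("trace too short to segment")
  if (is.null(shelter_zone)) shelter_zone <- trace_arena(trace)$zones$shelter

  t0 <- trace$time_s
  in_shelter <- if (is.null(shelter_zone)) rep(FALSE, n) else {
    zone_contains(shelter_zone, trace$x_cm, trace$y_cm)
  }
  speed <- trace_speed(trace)
  steps <- trace_steps(trace)

  ev <- list()
  sh_runs <- logical_runs(in_shelter)
  if (nrow(sh_runs) > 0) {
    ev$shelter <- tibble::tibble(layer = "shelter", kind = "shelter_visit",
                                 start = t0[sh_runs[, 1]],
                                 end = t0[sh_runs[, 2]] + dt,
                                 distance = NA_real_)
  }

  # Locomotor segmentation runs independently within each non-shelter span so
  # shelter visits (and long QC gaps encoded as shelter-breaks upstream)
  # always split movements.
  out_runs <- logical_runs(!in_shelter)
  mv <- list()
  if (nrow(out_runs) > 0) {
    for (r in seq_len(nrow(out_runs))) {
      i0 <- out_runs[r, 1]; i1 <- out_runs[r, 2]
      moving <- speed[i0:i1] >= cfg$v_move
      # the final displacement of a span either crosses into the shelter or
      # is undefined at the trace end; neither is locomotor time
      moving[length(moving)] <- FALSE
      runs <- logical_runs(moving)
      runs <- merge_runs(runs, gap_frames = as.integer(round(cfg$merge_gap * rate)),
                         min_frames = as.integer(round(cfg$min_move_dur * rate)))
      if (nrow(runs) > 0) {
        runs <- runs + i0 - 1L
        dist <- vapply(seq_len(nrow(runs)), function(k) {
          sum(steps[runs[k, 1]:runs[k, 2]])
        }, numeric(1))
        mv[[length(mv) + 1L]] <- tibble::tibble(
          layer = "locomotor", kind = "movement",
          start = t0[runs[, 1]], end = t0[runs[, 2]] + dt, distance = dist)
      }
    }
  }
  movements <- if (length(mv)) dplyr::bind_rows(mv) else NULL

  # Arrests: complement of movements within each non-shelter span.
  ar <- list()
  if (nrow(out_runs) > 0) {
    for (r in seq_len(nrow(out_runs))) {
      s <- t0[out_runs[r, 1]]; e <- t0[out_runs[r, 2]] + dt
      inside <- if (is.null(movements)) movements else {
        movements[movements$start >= s - 1e-9 & movements$end <= e + 1e-9, ]
      }
      bounds <- c(s, if (!is.null(inside)) rbind(inside$start, inside$end), e)
      starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
      ends <- bounds[seq(2, length(bounds), by = 2)]
      keep <- ends - starts > dt / 2
      if (any(keep)) {
        ar[[length(ar) + 1L]] <- tibble::tibble(
          layer = "locomotor", kind = "arrest",
          start = starts[keep], end = ends[keep], distance = NA_real_)
      }
    }
  }

  # Activity layer: movements merged across gaps <= activity_merge_gap.
  act <- NULL
  if (!is.null(movements) && nrow(movements) > 0) {
    m <- dplyr::arrange(movements, .data$start)
    grp <- cumsum(c(1, (m$start[-1] - m$end[-nrow(m)]) > cfg$activity_merge_gap + 1e-9))
    act <- dplyr::summarise(dplyr::group_by(tibble::tibble(grp = grp,
                                                           start = m$start,
                                                           end = m$end), grp),
                            start = min(.data$start), end = max(.data$end),
                            .groups = "drop")
    act <- tibble::tibble(layer = "activity", kind = "activity_bout",
                          start = act$start, end = act$end, distance = NA_real_)
  }

  all_ev <- dplyr::bind_rows(c(ev, list(movements = movements,
                                        arrests = if (length(ar)) dplyr::bind_rows(ar),
                                        activity = act)))
  if (nrow(all_ev) == 0) {
    all_ev <- tibble::tibble(layer = character(), kind = character(),
                             start = double(), end = double(),
                             distance = double())
    return(structure(all_ev, class = c("phenocage_events", class(all_ev)),
                     duration = n * dt, lightcycle = attr(trace, "lightcycle")))
  }
  event_log(all_ev$layer, all_ev$kind, all_ev$start, all_ev$end,
            all_ev$distance, duration = n * dt,
            lightcycle = attr(trace, "lightcycle"))
}

#' Freezing detection
#'
#' Freezing is the absence of movement: frames with speed below `v_freeze`
#' sustained for at least `min_freeze_dur` seconds. The percentage of time
#' frozen is reported per 60-s bin, the convention for unconditioned-fear
#' scoring; a trailing partial bin is reported with its own duration.
#'
#' @param trace A [tracking_trace()].
#' @param cfg A [segmentation_config()].
#' @param bin_s Bin width in seconds.
#' @return List with `intervals` (tibble start/end) and `bins` (tibble
#'   `bin`, `start_s`, `duration_s`, `percent_frozen`).
#' @export
detect_freezing <- function(trace, cfg = segmentation_config(), bin_s = 60) {
  stopifnot(inherits(trace, "phenocage_trace"))
  n <- nrow(trace)
  if (n < 2) stop_input("trace too short for freezing analysis")
  rate <- trace_rate(trace)
  frozen <- trace_speed(trace) < cfg$v_freeze
  runs <- logical_runs(frozen)
  runs <- runs[runs[, 2] - runs[, 1] + 1L >= round(cfg$min_freeze_dur * rate), ,
               drop = FALSE]
  frozen_ok <- rep(FALSE, n)
  for (r in seq_len(nrow(runs))) frozen_ok[runs[r, 1]:runs[r, 2]] <- TRUE
  intervals <- tibble::tibble(start = trace$time_s[runs[, 1]],
                              end = trace$time_s[runs[, 2]] + 1 / rate)
  bin <- floor((trace$time_s - trace$time_s[1]) / bin_s)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, frozen = frozen_ok), bin),
    duration_s = dplyr::n() / rate,
    percent_frozen = 100 * mean(.data$frozen), .groups = "drop")
  bins <- tibble::tibble(bin = agg$bin + 1L,
                         start_s = trace$time_s[1] + agg$bin * bin_s,
                         duration_s = agg$duration_s,
                         percent_frozen = agg$percent_frozen)
  list(intervals = intervals, bins = bins)
}
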