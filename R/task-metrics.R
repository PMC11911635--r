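#' Discrimination index
#'
#' Novel-target interaction time divided by total interaction time, the
#' common preference measure across recognition tests: novel object /
#' (novel + old objects), novel arm / (novel + familiar arm), stranger /
#' (stranger + object). Chance level is 0.5.
#'
#' @param novel_seconds Interaction time with the novel target (s).
#' @param familiar_seconds Interaction time(s) with the familiar
#'   target(s); a vector is summed.
#' @return List with `di` (in `[0, 1]`, `NA` when undefined) and
#'   `undefined` flag (total interaction zero).
#' @export
discrimination_index <- function(novel_seconds, familiar_seconds) {
  if (any(c(novel_seconds, familiar_seconds) < 0)) {
    stop_input("interaction times must be non-negative")
  }
  denom <- novel_seconds + sum(familiar_seconds)
  if (denom == 0) return(list(di = NA_real_, undefined = TRUE))
  list(di = novel_seconds / denom, undefined = FALSE)
}

#' Alternation percentage
#'
#' Percentage of animals whose first entry in the test trial was the
#' target (previously blocked) arm.
#'
#' @param first_entries Character vector of per-animal first arm choices.
#' @param target The target arm label.
#' @return Percentage in `[0, 100]`.
#' @export
alternation <- function(first_entries, target) {
  n <- length(first_entries)
  if (n == 0) stop_input("no animals")
  100 * sum(first_entries == target) / n
}

#' Build an entry log from times and holes
#'
#' @param time_s Ascending entry times (s from task start).
#' @param hole Hole per entry (`left`/`middle`/`right`).
#' @param schedule A [target_schedule()].
#' @return A `phenocage_entrylog` tibble.
#' @export
entry_log <- function(time_s, hole, schedule) {
  stopifnot(inherits(schedule, "phenocage_schedule"))
  if (is.unsorted(time_s)) stop_input("entry times must be ascending")
  if (!all(hole %in% c("left", "middle", "right"))) {
    stop_input("holes must be left/middle/right")
  }
  out <- tibble::tibble(time_s = as.double(time_s), hole = as.character(hole))
  attr(out, "schedule") <- schedule
  class(out) <- c("phenocage_entrylog", class(out))
  out
}

# Classify every entry as correct / perseverative / neutral against the
# schedule. Perseverative = previous day's target after a reversal; on days
# with no distinct previous target (day 1, or repeat target) errors are
# neutral.
classify_entries <- function(log, schedule = attr(log, "schedule")) {
  if (nrow(log) == 0) stop_input("empty entry log")
  day <- floor(log$time_s / 86400) + 1
  if (any(!day %in% schedule$day)) {
    stop_input("entries on day(s) without a scheduled target")
  }
  target <- schedule$target[day]
  prev <- previous_target(schedule, day)
  prev[!is.na(prev) & prev == target] <- NA_character_
  cls <- ifelse(log$hole == target, "correct",
                ifelse(!is.na(prev) & log$hole == prev, "perseverative",
                       "neutral"))
  tibble::tibble(time_s = log$time_s, hole = log$hole, day = day,
                 target = target, class = cls)
}

#' Cognition-wall learning curves
#'
#' Entries are classified as correct, perseverative (the previous day's
#' target after a reversal) or neutral (the remaining hole); on the first
#' day no perseverative class exists and errors are neutral. Fractions of
#' each class are computed in consecutive, non-overlapping bins of
#' `bin_size` entries (the learning curve is per amount of entries, not
#' time, adjusting for activity differences); the trailing partial bin is
#' reported with its own size. Per-hour entry counts are returned
#' alongside.
#'
#' @param log An entry log ([entry_log()] or [simulate_entry_log()]).
#' @param bin_size Entries per bin (50 by convention).
#' @param per_day Also split bins within each day (restarting the bin
#'   count at each target switch, as the per-reversal-day curves are
#'   plotted); default `FALSE` bins over the whole log.
#' @return List with `curve` (tibble `day` (if `per_day`), `bin`,
#'   `n_entries`, `frac_correct`, `frac_perseverative`, `frac_neutral`)
#'   and `entries_per_hour` (tibble `hour`, `n_entries`).
#' @export
learning_curves <- function(log, bin_size = 50, per_day = FALSE) {
  schedule <- attr(log, "schedule")
  if (is.null(schedule)) stop_input("entry log lacks a schedule")
  cls <- classify_entries(log, schedule)
  bin_of <- function(i) (i - 1L) %/% bin_size + 1L
  if (per_day) {
    cls <- dplyr::group_by(cls, .data$day)
    cls <- dplyr::mutate(cls, bin = bin_of(dplyr::row_number()))
  } else {
    cls$bin <- bin_of(seq_len(nrow(cls)))
    cls <- dplyr::group_by(cls)
  }
  curve <- dplyr::summarise(
    dplyr::group_by(cls, .data$bin, .add = TRUE),
    n_entries = dplyr::n(),
    frac_correct = mean(.data$class == "correct"),
    frac_perseverative = mean(.data$class == "perseverative"),
    frac_neutral = mean(.data$class == "neutral"),
    .groups = "drop")
  eph <- dplyr::count(
    tibble::tibble(hour = floor(log$time_s / 3600) + 1), .data$hour,
    name = "n_entries")
  list(curve = curve, entries_per_hour = eph)
}

#' Average learning curves over animals
#'
#' Per-bin group mean of the correct fraction over the animals still
#' contributing to that bin. Curves are conventionally displayed only
#' while more than `min_n` animals contribute; bins at or below the
#' cutoff are retained but flagged.
#'
#' @param curves Named list of per-animal `curve` tibbles from
#'   [learning_curves()].
#' @param min_n Display cutoff (curves shown while `n > min_n`).
#' @return Tibble `bin`, `n_animals`, `mean_correct`,
#'   `mean_perseverative`, `mean_neutral`, `display`.
#' @export
average_learning_curves <- function(curves, min_n = 3) {
  all <- dplyr::bind_rows(curves, .id = "animal")
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$bin),
    n_animals = dplyr::n(),
    mean_correct = mean(.data$frac_correct),
    mean_perseverative = mean(.data$frac_perseverative),
    mean_neutral = mean(.data$frac_neutral),
    .groups = "drop")
  out$display <- out$n_animals > min_n
  out
}

#' Replay the pellet reward schedule
#'
#' One pellet is dispensed after each fifth cumulative correct entry
#' through the day's target; correct entries need not be consecutive. The
#' counter resets at each daily target switch by default (rewards are tied
#' to the day's target entrance); set `carry_over = TRUE` to keep the
#' remainder across days.
#'
#' @param log An entry log with a schedule.
#' @param per_pellet Correct entries per pellet.
#' @param carry_over Keep the correct-entry remainder across day
#'   boundaries.
#' @return Tibble of pellet events: `time_s`, `day`, `entry_index` (index
#'   of the entry that triggered the pellet).
#' @export
replay_reward_schedule <- function(log, per_pellet = 5, carry_over = FALSE) {
  cls <- classify_entries(log, attr(log, "schedule"))
  counter <- 0L
  out <- list()
  cur_day <- cls$day[1]
  for (i in seq_len(nrow(cls))) {
    if (!carry_over && cls$day[i] != cur_day) {
      counter <- 0L
      cur_day <- cls$day[i]
    }
    if (cls$class[i] == "correct") {
      counter <- counter + 1L
      if (counter == per_pellet) {
        out[[length(out) + 1L]] <- tibble::tibble(time_s = cls$time_s[i],
                                                  day = cls$day[i],
                                                  entry_index = i)
        counter <- 0L
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(time_s = double(), day = double(),
                          entry_index = integer()))
  }
  dplyr::bind_rows(out)
}

#' Probe-trial metrics
#'
#' The memory readouts of a probe trial: relative path length and time per
#' quadrant (chance 0.25 over four equal quadrants), cumulative path
#' length to the first entry into the target zone, and, when a keypoint
#' session is supplied, interaction seconds with the target holes.
#'
#' @param trace A [tracking_trace()] on a quadrant-divided arena.
#' @param target Name of the target quadrant.
#' @param target_zone Optional target zone (platform/hole) for the
#'   distance-to-first-entry readout.
#' @param kp,hole_targets Optional keypoint session and hole zones for
#'   interaction scoring.
#' @param cfg A [segmentation_config()].
#' @return List with `quadrants` (zone metrics restricted to the
#'   quadrants, plus `is_target`), `distance_to_target` and
#'   `hole_interactions` (or `NULL`).
#' @export
probe_metrics <- function(trace, target, target_zone = NULL, kp = NULL,
                          hole_targets = NULL, cfg = segmentation_config()) {
  arena <- trace_arena(trace)
  quads <- arena$zones[names(arena$zones) %in% c("NE", "NW", "SW", "SE")]
  if (length(quads) != 4) stop_input("arena has no quadrant partition")
  if (!target %in% names(quads)) stop_input("unknown target quadrant '%s'", target)
  qm <- zone_metrics(trace, quads, cfg)
  qm$is_target <- qm$zone == target
  dte <- if (!is.null(target_zone)) distance_to_first_entry(trace, target_zone)
  hi <- if (!is.null(kp) && !is.null(hole_targets)) {
    score_interactions(kp, hole_targets, cfg)
  }
  list(quadrants = qm, distance_to_target = dte, hole_interactions = hi)
}
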