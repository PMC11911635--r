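#' Per-zone occupancy and locomotion metrics
#'
#' For each zone: time inside (s), path length inside (cm), relative path
#' length (fraction of the total), entry count, mean speed (cm/s) and the
#' fraction of inside frames spent moving. Zone membership is decided on
#' the point position of each sample (closed zones, boundary counts as
#' inside); each inter-frame displacement is attributed to the zone of its
#' starting sample, so over a partition of the arena the relative
#' distances sum to exactly 1.
#'
#' @param trace A [tracking_trace()].
#' @param zones Named list of zones; defaults to the arena's zones.
#' @param cfg A [segmentation_config()] (for the moving threshold).
#' @return Tibble with one row per zone: `zone`, `time_s`, `time_fraction`,
#'   `distance_cm`, `relative_distance`, `entries`, `mean_speed`,
#'   `moving_fraction`.
#' @export
zone_metrics <- function(trace, zones = NULL, cfg = segmentation_config()) {
  stopifnot(inherits(trace, "phenocage_trace"))
  arena <- trace_arena(trace)
  if (is.null(zones)) zones <- arena$zones
  if (length(zones) == 0) stop_input("no zones to score")
  if (is.null(names(zones))) stop_input("zones must be named")
  n <- nrow(trace)
  dt <- 1 / trace_rate(trace)
  steps <- trace_steps(trace)
  speed <- trace_speed(trace)
  total_dist <- sum(steps)
  total_time <- n * dt
  rows <- lapply(names(zones), function(zn) {
    z <- zones[[zn]]
    inside <- zone_contains(z, trace$x_cm, trace$y_cm)
    entries <- sum(diff(inside) == 1L) + as.integer(inside[1])
    tibble::tibble(
      zone = zn,
      time_s = sum(inside) * dt,
      time_fraction = sum(inside) / n,
      distance_cm = sum(steps[inside]),
      relative_distance = if (total_dist > 0) sum(steps[inside]) / total_dist else NA_real_,
      entries = entries,
      mean_speed = if (any(inside)) mean(speed[inside]) else NA_real_,
      moving_fraction = if (any(inside)) mean(speed[inside] >= cfg$v_move) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Path length until first entry into a target zone
#'
#' Cumulative path length from the trace start to the first sample inside
#' the target; the standard replacement for latency when groups differ in
#' locomotion speed. If the target is never reached the total path length
#' is returned with `reached = FALSE`.
#'
#' @param trace A [tracking_trace()].
#' @param target A zone.
#' @return List with `distance_cm` and `reached`.
#' @export
distance_to_first_entry <- function(trace, target) {
  stopifnot(inherits(trace, "phenocage_trace"))
  inside <- zone_contains(target, trace$x_cm, trace$y_cm)
  steps <- trace_steps(trace)
  first <- match(TRUE, inside)
  if (is.na(first)) {
    return(list(distance_cm = sum(steps), reached = FALSE))
  }
  if (first == 1L) return(list(distance_cm = 0, reached = TRUE))
  list(distance_cm = sum(steps[seq_len(first - 1L)]), reached = TRUE)
}

#' Score object/hole interactions from pose keypoints
#'
#' Interaction is defined as the nose being in close proximity to the
#' object or hole: within `proximity_radius` of the target boundary.
#' Frames whose nose confidence falls below `min_conf` are excluded from
#' both numerator and denominator; interaction seconds are in-proximity
#' valid frames divided by the sample rate.
#'
#' @param kp A keypoint tibble in long format (`frame`, `bodypart`,
#'   `x_cm`, `y_cm`, `confidence`) with attribute `sample_rate`, as
#'   produced by [simulate_interaction_session()] or [read_keypoints()].
#' @param targets Named list of disc/rect zones.
#' @param cfg A [segmentation_config()] (`proximity_radius`, `min_conf`).
#' @param min_valid_fraction Minimum fraction of frames with usable nose
#'   confidence; below it the session errors out.
#' @return Tibble `target`, `interaction_s`, `valid_frames`,
#'   `valid_fraction`.
#' @export
score_interactions <- function(kp, targets, cfg = segmentation_config(),
                               min_valid_fraction = 0.5) {
  stopifnot(is.data.frame(kp))
  rate <- attr(kp, "sample_rate")
  if (is.null(rate)) stop_input("keypoint table lacks a sample_rate attribute")
  nose <- kp[kp$bodypart == "nose", ]
  if (nrow(nose) == 0) stop_input("no nose keypoints in session")
  valid <- nose$confidence >= cfg$min_conf
  if (mean(valid) < min_valid_fraction) {
    stop_input("only %.0f%% of frames have nose confidence >= %.2f",
               100 * mean(valid), cfg$min_conf)
  }
  nose <- nose[valid, ]
  rows <- lapply(names(targets), function(tn) {
    d <- zone_distance(targets[[tn]], nose$x_cm, nose$y_cm)
    near <- d <= cfg$proximity_radius
    tibble::tibble(target = tn, interaction_s = sum(near) / rate,
                   valid_frames = nrow(nose),
                   valid_fraction = mean(valid))
  })
  dplyr::bind_rows(rows)
}
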