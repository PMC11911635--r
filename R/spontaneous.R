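#' Hourly activity profile
#'
#' Seconds of activity-bout time per clock hour, organized per light
#' phase: hour 1 is the first hour of each 12-h phase, and the phase
#' baseline used by the switch indices is the mean of hours 8, 9 and 10 of
#' the phase. Bout time is apportioned to hours by exact interval overlap.
#'
#' @param events A [event_log()] with an `activity` layer and an attached
#'   light cycle (or pass `lightcycle`).
#' @param lightcycle Optional [light_cycle()] override.
#' @return Tibble `phase`, `phase_index`, `hour`, `activity_s` (12 hours
#'   per observed phase).
#' @export
hourly_activity_profile <- function(events, lightcycle = NULL) {
  lc <- if (!is.null(lightcycle)) lightcycle else attr(events, "lightcycle")
  if (is.null(lc)) stop_input("no light cycle available")
  total <- attr(events, "duration")
  bouts <- events_kind(events, "activity_bout")
  ph <- phase_windows(lc, total)
  rows <- lapply(seq_len(nrow(ph)), function(i) {
    hstarts <- ph$start[i] + 3600 * (0:11)
    act <- vapply(hstarts, function(h0) {
      sum(overlap_len(bouts$start, bouts$end, h0, h0 + 3600))
    }, numeric(1))
    observed <- pmin(hstarts + 3600, total) - hstarts
    tibble::tibble(phase = ph$phase[i], phase_index = ph$phase_index[i],
                   hour = 1:12, activity_s = act,
                   observed_s = pmax(observed, 0))
  })
  dplyr::bind_rows(rows)
}

profile_phase_total <- function(profile, phase, index) {
  sel <- profile$phase == phase & profile$phase_index == index
  if (!any(sel)) return(NA_real_)
  if (any(profile$observed_s[sel] < 3600 - 1e-6)) return(NA_real_)
  sum(profile$activity_s[sel])
}

#' Habituation index
#'
#' Total activity during the third dark phase divided by total activity
#' during the first: 1 means equal activity (no habituation), values
#' below 1 mean lower activity on the third dark phase.
#'
#' @param profile An [hourly_activity_profile()] covering at least three
#'   dark phases.
#' @param phase Phase over which the index is formed (`"dark"` is the
#'   reported registry parameter).
#' @return The ratio, or `NA_real_` (missing flag) when phase 1 or 3 is
#'   unobserved or phase-1 activity is zero.
#' @export
habituation_index <- function(profile, phase = "dark") {
  a1 <- profile_phase_total(profile, phase, 1)
  a3 <- profile_phase_total(profile, phase, 3)
  if (is.na(a1) || is.na(a3) || a1 <= 0) return(NA_real_)
  a3 / a1
}

#' Activity change around a light switch
#'
#' Mean hourly activity during the 2-h window on either side of a light
#' switch minus the baseline of the original phase (the mean of its
#' hours 8, 9 and 10). Anticipation uses the last 2 h of the original
#' phase, response the first 2 h of the next phase.
#'
#' @param profile An [hourly_activity_profile()].
#' @param switch `"to_dark"` or `"to_light"`.
#' @param window `"anticipation"` or `"response"`.
#' @param day Which switch: the one leading into that day's dark
#'   (`to_dark`) or light (`to_light`) phase. Day-3 switches are the
#'   reported registry parameters.
#' @return Activity change in s/h, or `NA_real_` when any needed hour is
#'   unobserved.
#' @export
switch_delta <- function(profile, switch = c("to_dark", "to_light"),
                         window = c("anticipation", "response"), day = 3) {
  switch <- match.arg(switch)
  window <- match.arg(window)
  # recordings start at lights-off, so dark phase d precedes light phase d
  if (switch == "to_dark") {
    orig <- list(phase = "light", index = day - 1)
    nxt <- list(phase = "dark", index = day)
  } else {
    orig <- list(phase = "dark", index = day)
    nxt <- list(phase = "light", index = day)
  }
  hour_val <- function(ph, idx, hours) {
    sel <- profile$phase == ph$phase & profile$phase_index == ph$index &
      profile$hour %in% hours
    if (sum(sel) != length(hours)) return(rep(NA_real_, length(hours)))
    if (any(profile$observed_s[sel] < 3600 - 1e-6)) return(rep(NA_real_, length(hours)))
    profile$activity_s[sel]
  }
  baseline <- mean(hour_val(orig, NULL, 8:10))
  win <- if (window == "anticipation") {
    mean(hour_val(orig, NULL, 11:12))
  } else {
    mean(hour_val(nxt, NULL, 1:2))
  }
  if (is.na(baseline) || is.na(win)) return(NA_real_)
  win - baseline
}

# The 20-parameter spontaneous-behavior registry. `completed` marks
# parameters added to complete the published count of 20 beyond the ~14
# the study names explicitly.
phenotype_registry <- function() {
  tibble::tibble(
    parameter = c(
      "total_activity_dark", "total_activity_light",
      "mean_bout_duration_dark", "habituation_index_dark",
      "dark_light_activity_index",
      "anticipation_dark_delta", "response_dark_delta",
      "anticipation_light_delta", "response_light_delta",
      "n_shelter_visits_dark", "short_shelter_threshold",
      "long_shelter_threshold", "cum_short_visit_duration",
      "cum_long_visit_duration", "shelter_time_fraction_dark",
      "long_movement_threshold", "fraction_long_movements",
      "long_arrest_threshold", "mean_long_arrest_duration",
      "n_long_arrests"),
    units = c("s", "s", "s", "ratio", "fraction",
              "s/h", "s/h", "s/h", "s/h",
              "count", "log2_s", "log2_s", "s", "s", "fraction",
              "log2_cm", "fraction", "s", "s", "count"),
    phase = c("dark", "light", "dark", "dark", "both",
              "dark", "dark", "light", "light",
              "dark", "both", "both", "both", "both", "dark",
              "both", "both", "both", "both", "both"),
    registry_completed = c(FALSE, TRUE, FALSE, FALSE, TRUE,
                           FALSE, FALSE, FALSE, FALSE,
                           TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
                           FALSE, TRUE, FALSE, FALSE, TRUE)
  )
}

#' Phenotype configuration
#'
#' @param mixture_seed Seed for the EM restarts.
#' @param min_points Minimum events for a mixture fit.
#' @param pool_days Fit thresholds on events pooled over all days (`TRUE`,
#'   default: more points for EM) or day-3 events only.
#' @param day Day whose dark/light phases scope the count/total
#'   parameters.
#' @param arrest_q Percentile for the long arrest threshold.
#' @return List of class `phenocage_phenocfg`.
#' @export
phenotype_config <- function(mixture_seed = 1, min_points = 30,
                             pool_days = TRUE, day = 3, arrest_q = 0.9) {
  structure(list(mixture_seed = mixture_seed, min_points = min_points,
                 pool_days = pool_days, day = day, arrest_q = arrest_q),
            class = "phenocage_phenocfg")
}

#' Compute the 20-parameter spontaneous-behavior registry
#'
#' Emits exactly the 20 registry parameters for one animal from its event
#' log. Count, total and switch parameters are scoped to the dark/light
#' phases of `cfg$day` (day 3 by default, minimizing novel-environment
#' effects); mixture and percentile thresholds are fitted per animal on
#' events pooled over all days unless `cfg$pool_days` is `FALSE`. The
#' shelter thresholds come from a 3-component mixture of log2 visit
#' durations (short = 90th percentile of the first component, long =
#' intersection of the second and third), the movement threshold from the
#' intersection of a 2-component mixture of log2 distances, and the
#' arrest threshold from the 90th percentile of raw arrest durations.
#' Parameters whose inputs are unavailable (too few events, unobserved
#' phases) are flagged missing rather than dropped.
#'
#' @param events A [event_log()] with a light cycle.
#' @param lightcycle Optional [light_cycle()] override.
#' @param cfg A [phenotype_config()].
#' @return A tibble with exactly 20 rows: `parameter`, `value`, `units`,
#'   `phase`, `missing`, `registry_completed`.
#' @export
compute_phenotype_vector <- function(events, lightcycle = NULL,
                                     cfg = phenotype_config()) {
  lc <- if (!is.null(lightcycle)) lightcycle else attr(events, "lightcycle")
  if (is.null(lc)) stop_input("no light cycle available")
  total <- attr(events, "duration")
  day <- cfg$day
  ph <- phase_windows(lc, total)
  # fall back to the last fully observed day when the log is shorter
  full_dark <- ph$phase_index[ph$phase == "dark" & ph$end - ph$start >= 43200 - 1e-6]
  if (!day %in% full_dark && length(full_dark) > 0) day <- max(full_dark)

  win <- function(phase, index) {
    sel <- ph$phase == phase & ph$phase_index == index
    if (!any(sel)) return(NULL)
    c(ph$start[sel], ph$end[sel])
  }
  dark_w <- win("dark", day)
  light_w <- win("light", day)
  in_window <- function(ev, w) {
    if (is.null(w) || nrow(ev) == 0) return(ev[0, ])
    ev[ev$start >= w[1] - 1e-9 & ev$start < w[2], , drop = FALSE]
  }

  bouts <- events_kind(events, "activity_bout")
  visits <- events_kind(events, "shelter_visit")
  movements <- events_kind(events, "movement")
  arrests <- events_kind(events, "arrest")
  day_window <- if (!is.null(dark_w) && !is.null(light_w)) {
    c(min(dark_w[1], light_w[1]), max(dark_w[2], light_w[2]))
  } else {
    dark_w %||% light_w
  }
  scope <- function(ev) {
    if (cfg$pool_days || is.null(day_window)) ev else in_window(ev, day_window)
  }

  profile <- hourly_activity_profile(events, lc)
  act_dark <- if (is.null(dark_w)) NA_real_ else {
    sum(overlap_len(bouts$start, bouts$end, dark_w[1], dark_w[2]))
  }
  act_light <- if (is.null(light_w)) NA_real_ else {
    sum(overlap_len(bouts$start, bouts$end, light_w[1], light_w[2]))
  }
  dark_bouts <- in_window(bouts, dark_w)
  mean_bout_dark <- if (nrow(dark_bouts)) mean(dark_bouts$end - dark_bouts$start) else NA_real_
  dli <- if (!is.na(act_dark) && !is.na(act_light) && act_dark + act_light > 0) {
    act_dark / (act_dark + act_light)
  } else {
    NA_real_
  }

  # thresholds
  sfit <- fit_log2_mixture(scope(visits)$end - scope(visits)$start, k = 3,
                           min_points = cfg$min_points, seed = cfg$mixture_seed)
  short_thr <- long_thr <- NA_real_
  if (!sfit$missing && sfit$converged) {
    short_thr <- component_percentile(c(sfit$means[1], sfit$sds[1]), 0.9)
    long_thr <- gaussian_intersection(
      c(sfit$weights[2], sfit$means[2], sfit$sds[2]),
      c(sfit$weights[3], sfit$means[3], sfit$sds[3]))$threshold
  }
  mfit <- fit_log2_mixture(scope(movements)$distance, k = 2,
                           min_points = cfg$min_points, seed = cfg$mixture_seed)
  move_thr <- NA_real_
  if (!mfit$missing && mfit$converged) {
    move_thr <- gaussian_intersection(
      c(mfit$weights[1], mfit$means[1], mfit$sds[1]),
      c(mfit$weights[2], mfit$means[2], mfit$sds[2]))$threshold
  }
  arrest_dur <- scope(arrests)$end - scope(arrests)$start
  arrest_thr <- empirical_percentile_threshold(arrest_dur, q = cfg$arrest_q)

  # day-scoped derived quantities
  day_visits <- in_window(visits, day_window)
  vis_dur <- day_visits$end - day_visits$start
  cum_long <- if (is.na(long_thr)) NA_real_ else sum(vis_dur[log2(vis_dur) > long_thr])
  cum_short <- if (is.na(short_thr)) NA_real_ else sum(vis_dur[log2(vis_dur) <= short_thr])
  dark_visits <- in_window(visits, dark_w)
  shelter_dark <- if (is.null(dark_w)) NA_real_ else {
    sum(overlap_len(visits$start, visits$end, dark_w[1], dark_w[2])) /
      (dark_w[2] - dark_w[1])
  }
  day_moves <- in_window(movements, day_window)
  frac_long_mv <- if (is.na(move_thr) || nrow(day_moves) == 0) NA_real_ else {
    mean(log2(day_moves$distance) > move_thr)
  }
  day_arr <- in_window(arrests, day_window)
  day_arr_dur <- day_arr$end - day_arr$start
  long_arr <- if (is.na(arrest_thr)) numeric(0) else day_arr_dur[day_arr_dur > arrest_thr]
  mean_long_arr <- if (is.na(arrest_thr)) NA_real_ else {
    if (length(long_arr)) mean(long_arr) else 0
  }
  n_long_arr <- if (is.na(arrest_thr)) NA_real_ else length(long_arr)

  values <- c(
    total_activity_dark = act_dark,
    total_activity_light = act_light,
    mean_bout_duration_dark = mean_bout_dark,
    habituation_index_dark = habituation_index(profile, "dark"),
    dark_light_activity_index = dli,
    anticipation_dark_delta = switch_delta(profile, "to_dark", "anticipation", day),
    response_dark_delta = switch_delta(profile, "to_dark", "response", day),
    anticipation_light_delta = switch_delta(profile, "to_light", "anticipation", day),
    response_light_delta = switch_delta(profile, "to_light", "response", day),
    n_shelter_visits_dark = as.double(nrow(dark_visits)),
    short_shelter_threshold = short_thr,
    long_shelter_threshold = long_thr,
    cum_short_visit_duration = cum_short,
    cum_long_visit_duration = cum_long,
    shelter_time_fraction_dark = shelter_dark,
    long_movement_threshold = move_thr,
    fraction_long_movements = frac_long_mv,
    long_arrest_threshold = arrest_thr,
    mean_long_arrest_duration = mean_long_arr,
    n_long_arrests = n_long_arr
  )
  reg <- phenotype_registry()
  out <- dplyr::left_join(reg,
                          tibble::tibble(parameter = names(values),
                                         value = unname(values)),
                          by = "parameter")
  out$missing <- !is.finite(out$value)
  out[, c("parameter", "value", "units", "phase", "missing",
          "registry_completed")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
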