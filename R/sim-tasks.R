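#' Target schedule for the cognition-wall task
#'
#' Per-day target holes for the discrimination/serial-reversal task. The
#' standard protocol is 2 days of discrimination learning on the left hole
#' followed by daily reversals in the pattern right, left, middle, right,
#' left.
#'
#' @param targets Character vector of per-day targets, each one of
#'   `"left"`, `"middle"`, `"right"`.
#' @return A `phenocage_schedule` tibble with `day` and `target`.
#' @export
target_schedule <- function(targets = c("left", "left", "right", "left",
                                        "middle", "right", "left")) {
  if (length(targets) == 0) stop_input("schedule must cover at least one day")
  if (!all(targets %in% c("left", "middle", "right"))) {
    stop_input("targets must be one of left/middle/right")
  }
  out <- tibble::tibble(day = seq_along(targets), target = targets)
  structure(out, class = c("phenocage_schedule", class(out)))
}

# Target of the previous *different-target* day; NA on day 1. A reversal is
# a change of target, so the perseverative hole on day d is the target of
# day d-1 (which may equal the current target during multi-day
# discrimination, in which case there is no distinct perseverative hole).
previous_target <- function(schedule, day) {
  ifelse(day <= 1, NA_character_, schedule$target[pmax(day - 1, 1)])
}

#' Behavioral agent specification for the cognition wall
#'
#' A stochastic agent producing hole entries: with probability `p_correct`
#' the current target, otherwise an error split between the previous day's
#' target (probability mass `perseveration_weight` of errors, when a
#' distinct previous target exists) and the neutral hole.
#'
#' @param p_correct Probability an entry is through the current target.
#' @param perseveration_weight Fraction of errors directed at the previous
#'   day's target.
#' @param entries_per_hour_profile Entry rate by hour of day (scalar or
#'   length-24 vector, entries/h).
#' @param seed Required integer seed.
#' @return A `phenocage_agentspec`.
#' @export
agent_spec <- function(p_correct = 0.5, perseveration_weight = 0.5,
                       entries_per_hour_profile = 15, seed) {
  if (missing(seed) || is.null(seed)) stop_input("`seed` is required")
  check_prob(p_correct, "p_correct")
  check_prob(perseveration_weight, "perseveration_weight")
  check_pos(entries_per_hour_profile, "entries_per_hour_profile", strict = FALSE)
  if (!length(entries_per_hour_profile) %in% c(1L, 24L)) {
    stop_input("entries_per_hour_profile must be length 1 or 24")
  }
  structure(list(p_correct = p_correct,
                 perseveration_weight = perseveration_weight,
                 entries_per_hour_profile = entries_per_hour_profile,
                 seed = seed), class = "phenocage_agentspec")
}

#' Simulate an entry log for the cognition-wall task
#'
#' Entry times follow an inhomogeneous Poisson process with the agent's
#' hourly rate profile; holes follow the agent's correctness and
#' perseveration parameters against the schedule.
#'
#' @param agent An [agent_spec()].
#' @param schedule A [target_schedule()].
#' @return An entry-log tibble (`time_s`, `hole`) with the schedule
#'   attached as attribute `schedule`.
#' @export
simulate_entry_log <- function(agent, schedule) {
  stopifnot(inherits(agent, "phenocage_agentspec"),
            inherits(schedule, "phenocage_schedule"))
  if (nrow(schedule) == 0) stop_input("empty schedule")
  holes <- c("left", "middle", "right")
  with_local_seed(agent$seed, {
    prof <- agent$entries_per_hour_profile
    if (length(prof) == 1L) prof <- rep(prof, 24)
    times <- unlist(lapply(seq_len(nrow(schedule)), function(day) {
      unlist(lapply(0:23, function(h) {
        k <- rpois(1, prof[h + 1])
        if (k == 0) return(numeric(0))
        sort((day - 1) * 86400 + h * 3600 + runif(k, 0, 3600))
      }))
    }))
    times <- sort(times)
    day <- floor(times / 86400) + 1
    target <- schedule$target[day]
    prev <- previous_target(schedule, day)
    hole <- character(length(times))
    for (i in seq_along(times)) {
      if (runif(1) < agent$p_correct) {
        hole[i] <- target[i]
      } else {
        others <- setdiff(holes, target[i])
        if (!is.na(prev[i]) && prev[i] != target[i]) {
          neutral <- setdiff(others, prev[i])
          hole[i] <- if (runif(1) < agent$perseveration_weight) prev[i] else neutral
        } else {
          hole[i] <- sample(others, 1)
        }
      }
    }
    out <- tibble::tibble(time_s = times, hole = hole)
    attr(out, "schedule") <- schedule
    class(out) <- c("phenocage_entrylog", class(out))
    out
  })
}

#' Simulate a scripted keypoint session
#'
#' Builds a pose-keypoint trace for an object-interaction session (novel
#' object recognition, object placement, three-chamber) in which the
#' nose-in-proximity time per target is scripted exactly: during a scripted
#' approach the nose sits at the target center, otherwise all keypoints sit
#' at a neutral home position away from every target. Body keypoints trail
#' the nose at fixed offsets.
#'
#' @param targets Named list of disc/rect zones (the objects).
#' @param script Tibble with `target`, `start`, `end` (s): when the nose is
#'   at each target. Intervals must not overlap.
#' @param duration Session length (s).
#' @param sample_rate Samples per second.
#' @param confidence Keypoint confidence value for all frames (scalar), or
#'   a vector recycled over frames.
#' @param home Neutral nose position, away from all proximity radii.
#' @return A keypoint tibble in long format (`frame`, `time_s`, `bodypart`,
#'   `x_cm`, `y_cm`, `confidence`) with attribute `sample_rate`.
#' @export
simulate_interaction_session <- function(targets, script, duration = 300,
                                         sample_rate = 20, confidence = 0.95,
                                         home = c(25, 25)) {
  if (is.null(names(targets)) || any(names(targets) == "")) {
    stop_input("targets must be a named list of zones")
  }
  for (i in seq_along(targets)) {
    for (j in seq_along(targets)) {
      if (i < j) {
        ci <- target_center(targets[[i]]); cj <- target_center(targets[[j]])
        ri <- target_radius(targets[[i]]); rj <- target_radius(targets[[j]])
        if (sqrt(sum((ci - cj)^2)) <= ri + rj) stop_input("target zones overlap")
      }
    }
  }
  if (nrow(script) > 0) {
    if (any(script$start < 0 | script$end > duration | script$end <= script$start)) {
      stop_input("script times must lie within the session")
    }
    o <- order(script$start)
    if (any(script$start[o][-1] < script$end[o][-nrow(script)])) {
      stop_input("script intervals overlap")
    }
    if (!all(script$target %in% names(targets))) stop_input("unknown script target")
  }
  n <- as.integer(round(duration * sample_rate))
  tt <- (seq_len(n) - 1) / sample_rate
  nose <- matrix(rep(home, each = n), ncol = 2)
  for (i in seq_len(nrow(script))) {
    idx <- tt >= script$start[i] & tt < script$end[i]
    ctr <- target_center(targets[[script$target[i]]])
    nose[idx, 1] <- ctr[1]; nose[idx, 2] <- ctr[2]
  }
  parts <- c(nose = 0, head = 1, ear_left = 1.5, ear_right = 1.5,
             shoulders = 2.5, back = 4, tail = 7)
  kp <- dplyr::bind_rows(lapply(names(parts), function(pn) {
    tibble::tibble(frame = seq_len(n), time_s = tt, bodypart = pn,
                   x_cm = nose[, 1] - parts[[pn]], y_cm = nose[, 2],
                   confidence = rep_len(confidence, n))
  }))
  kp <- dplyr::arrange(kp, .data$frame, .data$bodypart)
  attr(kp, "sample_rate") <- sample_rate
  class(kp) <- c("phenocage_keypoints", class(kp))
  kp
}

target_center <- function(zone) {
  switch(zone$kind,
    disc = c(zone$cx, zone$cy),
    rect = c((zone$x0 + zone$x1) / 2, (zone$y0 + zone$y1) / 2),
    stop_input("interaction targets must be disc or rect zones"))
}

target_radius <- function(zone) {
  switch(zone$kind,
    disc = zone$radius,
    rect = sqrt((zone$x1 - zone$x0)^2 + (zone$y1 - zone$y0)^2) / 2,
    stop_input("interaction targets must be disc or rect zones"))
}

#' Simulate unbiased probe-trial trajectories
#'
#' Correlated random walks in a circular arena with a reflective boundary:
#' isotropic by construction (uniform initial heading, symmetric turning,
#' start at the center), so the expected relative path length in any of
#' the four equal quadrants is the chance level 0.25. All trials are
#' stepped together, vectorized across trials.
#'
#' @param n_trials Number of probe trials.
#' @param duration Trial length (s); probe trials are conventionally 60 s.
#' @param sample_rate Samples per second.
#' @param arena A circular-arena [arena_geometry()] (`water_maze` or
#'   `barnes`).
#' @param speed Swim/walk speed (cm/s).
#' @param turn_sd Per-frame heading change (radians, sd).
#' @param seed Required integer seed.
#' @return List of [tracking_trace()] objects, one per trial.
#' @export
simulate_probe_trials <- function(n_trials, duration = 60, sample_rate = 20,
                                  arena = arena_geometry("water_maze"),
                                  speed = 20, turn_sd = 0.5, seed) {
  if (missing(seed) || is.null(seed)) stop_input("`seed` is required")
  if (arena$bounds$kind != "disc") stop_input("probe simulation needs a circular arena")
  R <- arena$bounds$radius - 1e-6
  n <- as.integer(round(duration * sample_rate))
  step <- speed / sample_rate
  with_local_seed(seed, {
    x <- matrix(0, nrow = n, ncol = n_trials)
    y <- matrix(0, nrow = n, ncol = n_trials)
    theta <- runif(n_trials, 0, 2 * pi)
    px <- rep(0, n_trials); py <- rep(0, n_trials)
    for (i in seq_len(n)) {
      x[i, ] <- px; y[i, ] <- py
      theta <- theta + rnorm(n_trials, 0, turn_sd)
      nx <- px + step * cos(theta)
      ny <- py + step * sin(theta)
      r <- sqrt(nx^2 + ny^2)
      out <- r > R
      if (any(out)) {
        # reflect radially and bounce the heading off the tangent
        phi <- atan2(ny[out], nx[out])
        r2 <- pmax(2 * R - r[out], 0)
        nx[out] <- r2 * cos(phi)
        ny[out] <- r2 * sin(phi)
        theta[out] <- 2 * phi + pi - theta[out]
      }
      px <- nx; py <- ny
    }
    lapply(seq_len(n_trials), function(j) {
      tracking_trace((seq_len(n) - 1) / sample_rate, x[, j], y[, j],
                     sample_rate = sample_rate, arena = arena,
                     validate = FALSE)
    })
  })
}
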