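#' Specification for a synthetic home-cage recording
#'
#' Defines the generative model for a continuous home-cage recording with
#' exact ground truth. The animal alternates between shelter visits, whose
#' durations are drawn from a 3-component Gaussian mixture on log2 seconds,
#' and out-of-shelter periods in which activity bouts arrive as a Poisson
#' process whose rate depends on the light phase and is multiplicatively
#' modulated in the 2-h windows before (anticipation) and after (response)
#' each light switch. A bout is a run of movements, with distances drawn
#' from a 2-component mixture on log2 cm, separated by short arrests; long
#' arrests fill the remaining out-of-shelter time. All event boundaries are
#' snapped to the sample grid and margins around shelter entries and
#' between bouts are enforced so that segmentation at the default
#' thresholds recovers the ground-truth log exactly on jitter-free output.
#'
#' @param duration_days Days of continuous recording (the standard
#'   protocol uses 3), starting at the first lights-off.
#' @param sample_rate Samples per second (20 for the video setup; reduce
#'   for fast tests).
#' @param lightcycle A [light_cycle()].
#' @param arena A home-cage [arena_geometry()] with a `shelter` zone.
#' @param activity_bout_rate_per_phase Bout arrival rate (bouts/h of
#'   out-of-shelter time), named `dark`/`light`.
#' @param activity_bout_duration Lognormal `c(meanlog, sdlog)` of target
#'   bout duration (s).
#' @param anticipation_response_modulation List with elements `to_dark` and
#'   `to_light`, each `c(anticipation = , response = )` multiplicative
#'   factors applied to the bout rate in the last/first 2 h around the
#'   switch.
#' @param shelter_entry_rate_per_h Rate of shelter entries (1/h of
#'   out-of-shelter time), named `dark`/`light`.
#' @param shelter_visit_log2_mixture List `weights`, `means`, `sds`: the
#'   3-component mixture of log2 visit durations (log2 s).
#' @param movement_log2_mixture List `weights`, `means`, `sds`: the
#'   2-component mixture of log2 movement distances (log2 cm).
#' @param arrest_duration `c(min, max)` of the uniform short-arrest gaps
#'   inside a bout (s); must lie strictly between the segmentation
#'   `merge_gap` and `activity_merge_gap` for exact recovery.
#' @param movement_speed Nominal movement speed (cm/s).
#' @param min_movement_cm Smallest movement distance generated (mixture
#'   draws below it are redrawn), keeping movements above the detection
#'   floor.
#' @param jitter_sd Gaussian positional jitter (cm) added to the trace;
#'   0 (default) keeps segmentation exact.
#' @param seed Required integer seed; the generator never touches global
#'   RNG state.
#' @return A `phenocage_simspec` list.
#' @export
homecage_sim_spec <- function(duration_days = 3,
                              sample_rate = 20,
                              lightcycle = light_cycle(),
                              arena = arena_geometry("phenotyper"),
                              activity_bout_rate_per_phase = c(dark = 16, light = 5),
                              activity_bout_duration = c(meanlog = log(40), sdlog = 0.6),
                              anticipation_response_modulation = list(
                                to_dark = c(anticipation = 1.5, response = 1.5),
                                to_light = c(anticipation = 1.3, response = 0.6)),
                              shelter_entry_rate_per_h = c(dark = 4, light = 7),
                              shelter_visit_log2_mixture = list(
                                weights = c(0.3, 0.4, 0.3),
                                means = c(4, 7, 11),
                                sds = c(0.5, 0.5, 0.5)),
                              movement_log2_mixture = list(
                                weights = c(0.6, 0.4),
                                means = c(2.5, 5.5),
                                sds = c(0.7, 0.7)),
                              arrest_duration = c(min = 0.75, max = 4.5),
                              movement_speed = 8,
                              min_movement_cm = 4,
                              jitter_sd = 0,
                              seed) {
  if (missing(seed) || is.null(seed)) stop_input("`seed` is required")
  if (!is.numeric(duration_days) || duration_days < 1) {
    stop_input("duration_days must be >= 1")
  }
  check_pos(sample_rate, "sample_rate")
  check_mix <- function(mx, k, name) {
    if (length(mx$weights) != k || length(mx$means) != k || length(mx$sds) != k) {
      stop_input("`%s` must have %d components", name, k)
    }
    if (abs(sum(mx$weights) - 1) > 1e-9) stop_input("`%s` weights must sum to 1", name)
    if (any(mx$weights < 0)) stop_input("`%s` weights must be non-negative", name)
    check_pos(mx$sds, paste0(name, "$sds"))
  }
  check_mix(shelter_visit_log2_mixture, 3, "shelter_visit_log2_mixture")
  check_mix(movement_log2_mixture, 2, "movement_log2_mixture")
  check_pos(activity_bout_rate_per_phase, "activity_bout_rate_per_phase", strict = FALSE)
  check_pos(shelter_entry_rate_per_h, "shelter_entry_rate_per_h")
  check_pos(movement_speed, "movement_speed")
  if (arrest_duration[1] >= arrest_duration[2]) stop_input("arrest_duration min must be < max")
  structure(list(
    duration_days = duration_days, sample_rate = sample_rate,
    lightcycle = lightcycle, arena = arena,
    activity_bout_rate_per_phase = activity_bout_rate_per_phase,
    activity_bout_duration = activity_bout_duration,
    anticipation_response_modulation = anticipation_response_modulation,
    shelter_entry_rate_per_h = shelter_entry_rate_per_h,
    shelter_visit_log2_mixture = shelter_visit_log2_mixture,
    movement_log2_mixture = movement_log2_mixture,
    arrest_duration = arrest_duration, movement_speed = movement_speed,
    min_movement_cm = min_movement_cm, jitter_sd = jitter_sd,
    seed = seed), class = "phenocage_simspec")
}

#' Draw from a Gaussian mixture on the log2 scale
#'
#' @param n Number of draws.
#' @param mixture List `weights`, `means`, `sds` on the log2 scale.
#' @param min_value Optional floor on the raw value; draws below it are
#'   redrawn from the same component (truncation).
#' @return Tibble with `value` (raw scale) and `component` (the generating
#'   component, ground truth for recovery tests).
#' @export
sample_log2_mixture <- function(n, mixture, min_value = NULL) {
  comp <- sample.int(length(mixture$weights), n, replace = TRUE,
                     prob = mixture$weights)
  val <- 2^rnorm(n, mixture$means[comp], mixture$sds[comp])
  if (!is.null(min_value)) {
    bad <- which(val < min_value)
    guard <- 0L
    while (length(bad) > 0 && guard < 100L) {
      val[bad] <- 2^rnorm(length(bad), mixture$means[comp[bad]],
                          mixture$sds[comp[bad]])
      bad <- bad[val[bad] < min_value]
      guard <- guard + 1L
    }
    val <- pmax(val, min_value)
  }
  tibble::tibble(value = val, component = comp)
}

# Bout-rate modulation factor at time t (s since recording start). Hours
# 1-2 of a phase carry the response factor of the switch into that phase,
# hours 11-12 the anticipation factor of the upcoming switch.
switch_modulation <- function(spec, t) {
  ph <- light_phase(spec$lightcycle, t)
  hour <- floor((t %% 43200) / 3600) + 1
  mod <- spec$anticipation_response_modulation
  f <- rep(1, length(t))
  resp <- ifelse(ph == "dark", mod$to_dark[["response"]], mod$to_light[["response"]])
  anti <- ifelse(ph == "dark", mod$to_light[["anticipation"]], mod$to_dark[["anticipation"]])
  f[hour <= 2] <- resp[hour <= 2]
  f[hour >= 11] <- anti[hour >= 11]
  f
}

#' Simulate the ground-truth event log of a home-cage recording
#'
#' The event-level core of [simulate_homecage_trace()]: returns the exact
#' event log without building per-frame positions (fast enough for large
#' cohort simulations). Attributes `truth_shelter` and `truth_movements`
#' carry the generating mixture component of every shelter visit and
#' movement.
#'
#' @param spec A [homecage_sim_spec()].
#' @return A [event_log()] covering `[0, duration_days * 86400)`.
#' @export
simulate_homecage_events <- function(spec) {
  stopifnot(inherits(spec, "phenocage_simspec"))
  with_local_seed(spec$seed, simulate_homecage_events_impl(spec))
}

simulate_homecage_events_impl <- function(spec) {
  rate <- spec$sample_rate
  dt <- 1 / rate
  snap <- function(t) round(t * rate) / rate
  total <- spec$duration_days * 86400
  margin <- 1                      # rest margin around shelter entries (s)
  min_gap_bout <- 5 + 3 * dt       # keeps activity bouts separate (> merge gap)
  mv_frames_min <- ceiling(0.5 * rate) + 1L
  smix <- spec$shelter_visit_log2_mixture
  mmix <- spec$movement_log2_mixture

  shel <- list(); moves <- list(); bouts <- list()
  t <- 0
  while (t < total - dt) {
    phase <- light_phase(spec$lightcycle, t)
    out_dur <- snap(max(rexp(1, spec$shelter_entry_rate_per_h[[phase]] / 3600),
                        2 * margin + dt))
    out_end <- min(snap(t + out_dur), total)

    # Activity bouts inside (t + margin, out_end - margin)
    s <- t + margin
    repeat {
      base <- spec$activity_bout_rate_per_phase[[light_phase(spec$lightcycle, s)]]
      r_s <- base * switch_modulation(spec, s) / 3600
      if (r_s <= 0) break
      gap <- rexp(1, r_s)
      s <- snap(s + max(gap, if (length(bouts)) min_gap_bout else 0))
      if (s >= out_end - margin - dt) break
      target <- rlnorm(1, spec$activity_bout_duration[["meanlog"]],
                       spec$activity_bout_duration[["sdlog"]])
      bout_start <- s
      bout_mvs <- list()
      cur <- s
      repeat {
        d <- sample_log2_mixture(1, mmix, min_value = spec$min_movement_cm)
        f <- max(ceiling(d$value * rate / spec$movement_speed), mv_frames_min)
        if (cur + f * dt > out_end - margin) break
        bout_mvs[[length(bout_mvs) + 1L]] <-
          c(start = cur, end = cur + f * dt, distance = d$value,
            component = d$component)
        cur <- cur + f * dt
        if (cur - bout_start >= target) break
        gapf <- round(runif(1, spec$arrest_duration[[1]],
                            spec$arrest_duration[[2]]) * rate)
        cur <- cur + gapf * dt
        if (cur >= out_end - margin) break
      }
      if (length(bout_mvs) > 0) {
        bm <- do.call(rbind, lapply(bout_mvs, unname))
        colnames(bm) <- c("start", "end", "distance", "component")
        moves[[length(moves) + 1L]] <- bm
        bouts[[length(bouts) + 1L]] <- c(start = unname(bm[1, "start"]),
                                         end = unname(bm[nrow(bm), "end"]))
        s <- unname(bm[nrow(bm), "end"]) + min_gap_bout
      }
      if (s >= out_end - margin) break
    }
    t <- out_end
    if (t >= total - dt) break

    comp <- sample.int(3L, 1L, prob = smix$weights)
    dur <- snap(max(2^rnorm(1, smix$means[comp], smix$sds[comp]), dt))
    end <- min(t + dur, total)
    shel[[length(shel) + 1L]] <- c(start = t, end = end, component = comp)
    t <- end
  }

  shelter_df <- if (length(shel)) {
    m <- do.call(rbind, shel)
    tibble::tibble(start = m[, "start"], end = m[, "end"],
                   component = as.integer(m[, "component"]))
  } else {
    tibble::tibble(start = double(), end = double(), component = integer())
  }
  move_df <- if (length(moves)) {
    m <- do.call(rbind, moves)
    tibble::tibble(start = m[, "start"], end = m[, "end"],
                   distance = m[, "distance"],
                   component = as.integer(m[, "component"]))
  } else {
    tibble::tibble(start = double(), end = double(), distance = double(),
                   component = integer())
  }
  bout_df <- if (length(bouts)) {
    m <- do.call(rbind, bouts)
    tibble::tibble(start = m[, "start"], end = m[, "end"])
  } else {
    tibble::tibble(start = double(), end = double())
  }

  # Arrests: complement of movements within out-of-shelter spans.
  occupied <- rbind(cbind(shelter_df$start, shelter_df$end),
                    cbind(move_df$start, move_df$end))
  arr <- complement_intervals(occupied, total)

  ev <- dplyr::bind_rows(
    if (nrow(shelter_df)) tibble::tibble(layer = "shelter", kind = "shelter_visit",
                                         start = shelter_df$start,
                                         end = shelter_df$end, distance = NA_real_),
    if (nrow(move_df)) tibble::tibble(layer = "locomotor", kind = "movement",
                                      start = move_df$start, end = move_df$end,
                                      distance = move_df$distance),
    if (nrow(arr)) tibble::tibble(layer = "locomotor", kind = "arrest",
                                  start = arr[, 1], end = arr[, 2],
                                  distance = NA_real_),
    if (nrow(bout_df)) tibble::tibble(layer = "activity", kind = "activity_bout",
                                      start = bout_df$start, end = bout_df$end,
                                      distance = NA_real_)
  )
  out <- event_log(ev$layer, ev$kind, ev$start, ev$end, ev$distance,
                   duration = total, lightcycle = spec$lightcycle)
  attr(out, "truth_shelter") <- shelter_df
  attr(out, "truth_movements") <- move_df
  attr(out, "sim_spec") <- spec
  out
}

# Complement of a set of disjoint [start, end) intervals within [0, total).
complement_intervals <- function(iv, total) {
  if (is.null(iv) || nrow(iv) == 0) return(cbind(0, total))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  starts <- c(0, iv[, 2])
  ends <- c(iv[, 1], total)
  keep <- ends - starts > 1e-9
  cbind(starts[keep], ends[keep])
}

#' Simulate a full home-cage tracking trace with ground truth
#'
#' Builds the per-frame position trace realizing the event log of
#' [simulate_homecage_events()]: the shelter center during visits, a
#' constant rest position during arrests, and during movements a bounded
#' correlated random walk whose every frame step has length exactly
#' `distance / frames`, so the observed path length equals the drawn
#' movement distance and the per-frame speed stays constant above the
#' detection threshold (for which `sample_rate >= 2` is required at the
#' default thresholds).
#'
#' @param spec A [homecage_sim_spec()].
#' @return List with `trace` (a [tracking_trace()] of exactly
#'   `duration_days * 86400 * sample_rate` samples) and `events` (the
#'   ground-truth [event_log()]).
#' @export
simulate_homecage_trace <- function(spec) {
  stopifnot(inherits(spec, "phenocage_simspec"))
  with_local_seed(spec$seed, {
    events <- simulate_homecage_events_impl(spec)
    trace <- build_trace_from_events(spec, events)
    list(trace = trace, events = events)
  })
}

build_trace_from_events <- function(spec, events) {
  rate <- spec$sample_rate
  dt <- 1 / rate
  total <- spec$duration_days * 86400
  n <- as.integer(round(total * rate))
  times <- (seq_len(n) - 1) * dt
  shelter <- spec$arena$zones$shelter
  sc <- c((shelter$x0 + shelter$x1) / 2, (shelter$y0 + shelter$y1) / 2)
  # rest point just outside the shelter wall, used when leaving the shelter
  exit_pt <- c(shelter$x1 + 1.5, (shelter$y0 + shelter$y1) / 2)
  bounds <- spec$arena$bounds
  x <- numeric(n); y <- numeric(n)

  mv <- events[events$kind == "movement", ]
  sh <- events[events$kind == "shelter_visit", ]
  chg <- dplyr::bind_rows(
    if (nrow(mv)) tibble::tibble(kind = "movement", start = mv$start,
                                 end = mv$end, distance = mv$distance),
    if (nrow(sh)) tibble::tibble(kind = "shelter", start = sh$start,
                                 end = sh$end, distance = NA_real_)
  )
  chg <- if (is.null(chg) || nrow(chg) == 0) {
    tibble::tibble(kind = character(), start = double(), end = double(),
                   distance = double())
  } else {
    dplyr::arrange(chg, .data$start)
  }

  p <- c(20, 10)  # initial rest position away from the shelter corner
  cursor <- 1L    # next frame to fill
  idx_of <- function(t) as.integer(round(t * rate)) + 1L
  for (i in seq_len(nrow(chg))) {
    i0 <- idx_of(chg$start[i])
    i1 <- min(idx_of(chg$end[i]) - 1L, n)
    if (i0 > cursor) {
      x[cursor:(i0 - 1L)] <- p[1]; y[cursor:(i0 - 1L)] <- p[2]
    }
    if (chg$kind[i] == "shelter") {
      x[i0:i1] <- sc[1]; y[i0:i1] <- sc[2]
      p <- exit_pt
    } else {
      f <- i1 - i0 + 1L  # moving frames; positions path[1..f], rest at path[f+1]
      path <- movement_path(p, chg$distance[i], f, bounds, shelter)
      x[i0:i1] <- path$x[seq_len(f)]
      y[i0:i1] <- path$y[seq_len(f)]
      p <- c(path$x[f + 1L], path$y[f + 1L])
    }
    cursor <- i1 + 1L
  }
  if (cursor <= n) {
    x[cursor:n] <- p[1]; y[cursor:n] <- p[2]
  }
  if (spec$jitter_sd > 0) {
    x <- x + rnorm(n, 0, spec$jitter_sd)
    y <- y + rnorm(n, 0, spec$jitter_sd)
  }
  tracking_trace(times, x, y, sample_rate = rate, arena = spec$arena,
                 lightcycle = spec$lightcycle, validate = FALSE)
}

# Correlated random walk from `p` of exactly f steps of length d/f inside
# `bounds` (with a wall margin) avoiding `shelter` (expanded by 0.5 cm).
# Every frame step has length exactly d/f, so the observed path length of
# the movement equals the drawn distance and the per-frame speed is
# constant. Returns f+1 points (start + one per step). First a vectorized
# proposal; if it clips a wall or the shelter, a frame-stepped walk that
# redraws the heading at obstacles.
movement_path <- function(p, d, f, bounds, shelter, wall_margin = 1.5,
                          turn_sd = 0.4) {
  step <- d / f
  ex <- if (!is.null(shelter)) {
    list(x0 = shelter$x0 - 0.5, y0 = shelter$y0 - 0.5,
         x1 = shelter$x1 + 0.5, y1 = shelter$y1 + 0.5)
  } else {
    NULL
  }
  lo <- c(bounds$x0 + wall_margin, bounds$y0 + wall_margin)
  hi <- c(bounds$x1 - wall_margin, bounds$y1 - wall_margin)
  valid <- function(x, y) {
    ok <- x >= lo[1] & x <= hi[1] & y >= lo[2] & y <= hi[2]
    if (!is.null(ex)) {
      ok <- ok & !(x >= ex$x0 & x <= ex$x1 & y >= ex$y0 & y <= ex$y1)
    }
    ok
  }
  for (attempt in 1:10) {
    theta <- cumsum(c(runif(1, -pi, pi), rnorm(f - 1, 0, turn_sd)))
    xs <- p[1] + cumsum(step * cos(theta))
    ys <- p[2] + cumsum(step * sin(theta))
    if (all(valid(xs, ys))) {
      return(list(x = c(p[1], xs), y = c(p[2], ys)))
    }
  }
  # frame-stepped fallback near obstacles
  xs <- numeric(f); ys <- numeric(f)
  cx <- p[1]; cy <- p[2]
  th <- runif(1, -pi, pi)
  for (i in seq_len(f)) {
    th <- th + rnorm(1, 0, turn_sd)
    for (try in 1:100) {
      nx <- cx + step * cos(th)
      ny <- cy + step * sin(th)
      if (valid(nx, ny)) break
      th <- runif(1, -pi, pi)
    }
    cx <- nx; cy <- ny
    xs[i] <- cx; ys[i] <- cy
  }
  list(x = c(p[1], xs), y = c(p[2], ys))
}
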