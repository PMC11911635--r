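# Shared fixture builders. Everything is generated in code at test time.

# A trace from explicit coordinates on a uniform grid.
make_trace <- function(x, y, rate = 20, arena = arena_geometry("open_field"),
                       lightcycle = NULL) {
  n <- length(x)
  tracking_trace((seq_len(n) - 1) / rate, x, y, sample_rate = rate,
                 arena = arena, lightcycle = lightcycle)
}

# A stationary trace at a point.
const_trace <- function(duration_s, rate = 20, pos = c(25, 25),
                        arena = arena_geometry("open_field")) {
  n <- as.integer(duration_s * rate)
  make_trace(rep(pos[1], n), rep(pos[2], n), rate = rate, arena = arena)
}

# Small fast home-cage spec for event/trace tests.
small_homecage_spec <- function(seed, days = 1, rate = 2, ...) {
  homecage_sim_spec(duration_days = days, sample_rate = rate, seed = seed, ...)
}

# Hourly activity profile built directly (phase-major, 12 hours per phase).
make_profile <- function(dark = list(), light = list()) {
  mk <- function(lst, phase) {
    dplyr::bind_rows(lapply(seq_along(lst), function(i) {
      tibble::tibble(phase = phase, phase_index = i, hour = 1:12,
                     activity_s = lst[[i]], observed_s = 3600)
    }))
  }
  dplyr::bind_rows(mk(dark, "dark"), mk(light, "light"))
}

# Independent frame-level freezing oracle: frames whose forward speed is
# below `v` within a run of at least `min_dur` seconds.
trace_frozen_oracle <- function(trace, v = 1, min_dur = 1) {
  rate <- attr(trace, "sample_rate")
  d <- sqrt(diff(trace$x_cm)^2 + diff(trace$y_cm)^2) * rate
  slow <- c(d, d[length(d)]) < v
  r <- rle(slow)
  keep <- r$values & r$lengths >= round(min_dur * rate)
  inverse.rle(list(values = keep, lengths = r$lengths))
}

# Entry log with entries spread over days at fixed spacing.
make_entry_log <- function(holes_by_day, schedule) {
  times <- unlist(lapply(seq_along(holes_by_day), function(d) {
    k <- length(holes_by_day[[d]])
    (d - 1) * 86400 + seq_len(k) * 60
  }))
  entry_log(times, unlist(holes_by_day), schedule)
}
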