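#' Tracking traces
#'
#' A tracking trace is a tibble of uniformly sampled 2-D positions
#' (`time_s`, `x_cm`, `y_cm`, optional `zone`) carrying the arena, light
#' cycle and sample rate as attributes. Times must sit on a uniform grid at
#' the stated rate; gaps up to `max_gap` seconds are linearly interpolated
#' by [trace_qc()], longer ones are reported and split events downstream.
#'
#' @param time_s,x_cm,y_cm Numeric vectors of equal length.
#' @param sample_rate Samples per second (20 for the standard video setup).
#' @param arena A [arena_geometry()].
#' @param lightcycle A [light_cycle()] (optional outside the home cage).
#' @param zone Optional per-sample zone label.
#' @param validate Check grid uniformity and finiteness.
#' @return A `phenocage_trace` tibble.
#' @export
tracking_trace <- function(time_s, x_cm, y_cm, sample_rate, arena,
                           lightcycle = NULL, zone = NULL, validate = TRUE) {
  n <- length(time_s)
  if (length(x_cm) != n || length(y_cm) != n) stop_input("coordinate lengths differ")
  check_pos(sample_rate, "sample_rate")
  stopifnot(inherits(arena, "phenocage_arena"))
  if (validate && n > 1) {
    dt <- diff(time_s)
    if (any(dt <= 0)) stop_input("trace times must be strictly increasing")
    if (any(abs(dt - 1 / sample_rate) > 1e-6 / sample_rate + 1e-9)) {
      stop_input("trace times are not on a uniform 1/sample_rate grid")
    }
  }
  out <- tibble::tibble(time_s = as.double(time_s),
                        x_cm = as.double(x_cm), y_cm = as.double(y_cm))
  if (!is.null(zone)) out$zone <- zone
  structure(out,
            class = c("phenocage_trace", class(out)),
            sample_rate = sample_rate, arena = arena, lightcycle = lightcycle)
}

#' @export
print.phenocage_trace <- function(x, ...) {
  cat(sprintf("<phenocage_trace> %d samples @ %g/s, arena '%s'\n",
              nrow(x), attr(x, "sample_rate"), attr(x, "arena")$kind))
  NextMethod()
}

trace_rate <- function(trace) attr(trace, "sample_rate")
trace_arena <- function(trace) attr(trace, "arena")

# Per-frame speed (cm/s): displacement from frame i to i+1 times the rate;
# the final frame repeats the previous value so the vector matches nrow.
trace_speed <- function(trace) {
  n <- nrow(trace)
  if (n < 2) return(rep(0, n))
  d <- sqrt(diff(trace$x_cm)^2 + diff(trace$y_cm)^2)
  c(d, d[length(d)]) * trace_rate(trace)
}

# Per-frame step length (cm) attributed to the starting frame; last frame 0.
trace_steps <- function(trace) {
  n <- nrow(trace)
  if (n < 2) return(rep(0, n))
  c(sqrt(diff(trace$x_cm)^2 + diff(trace$y_cm)^2), 0)
}

#' Trace quality control
#'
#' Linearly interpolates missing coordinates across gaps of at most
#' `max_gap` seconds and reports longer gaps and out-of-bounds samples.
#' Fails when more than `max_missing` of the frames are lost.
#'
#' @param trace A [tracking_trace()] (may contain `NA` coordinates).
#' @param max_gap Longest gap (s) bridged by interpolation.
#' @param max_missing Maximum tolerated fraction of lost frames.
#' @return The trace with short gaps filled, plus a `qc` attribute:
#'   tibble of gaps (`start_s`, `end_s`, `filled`) and the out-of-bounds
#'   count.
#' @export
trace_qc <- function(trace, max_gap = 1, max_missing = 0.2) {
  miss <- !complete.cases(trace$x_cm, trace$y_cm)
  frac <- mean(miss)
  if (frac > max_missing) {
    runs <- logical_runs(miss)
    spans <- paste(sprintf("[%.2f, %.2f]", trace$time_s[runs[, 1]],
                           trace$time_s[runs[, 2]]), collapse = ", ")
    stop_input("trace QC failed: %.1f%% of frames missing (spans %s)",
               100 * frac, spans)
  }
  gaps <- tibble::tibble(start_s = double(), end_s = double(), filled = logical())
  if (any(miss)) {
    runs <- logical_runs(miss)
    dur <- (runs[, 2] - runs[, 1] + 1) / trace_rate(trace)
    fill <- dur <= max_gap
    gaps <- tibble::tibble(start_s = trace$time_s[runs[, 1]],
                           end_s = trace$time_s[runs[, 2]], filled = fill)
    idx <- seq_len(nrow(trace))
    ok <- !miss
    for (col in c("x_cm", "y_cm")) {
      v <- trace[[col]]
      interp <- stats::approx(idx[ok], v[ok], xout = idx, rule = 2)$y
      do_fill <- miss
      for (r in which(!fill)) do_fill[runs[r, 1]:runs[r, 2]] <- FALSE
      v[do_fill] <- interp[do_fill]
      trace[[col]] <- v
    }
  }
  ok <- complete.cases(trace$x_cm, trace$y_cm)
  oob <- sum(!zone_contains(trace_arena(trace)$bounds, trace$x_cm[ok], trace$y_cm[ok]))
  attr(trace, "qc") <- list(gaps = gaps, out_of_bounds = oob,
                            missing_fraction = frac)
  trace
}
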