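test_that("segmentation handles still, sheltered and scripted traces", {
  # constant position outside the shelter: one arrest, nothing else
  arena <- arena_geometry("phenotyper")
  tr <- const_trace(60, rate = 20, pos = c(20, 10), arena = arena)
  ev <- segment_events(tr)
  expect_equal(sum(ev$kind == "movement"), 0)
  arr <- ev[ev$kind == "arrest", ]
  expect_equal(nrow(arr), 1)
  expect_equal(arr$end - arr$start, 60)

  # entirely inside the shelter: one full-span visit, empty locomotor layer
  tr2 <- const_trace(60, rate = 20, pos = c(5, 25), arena = arena)
  ev2 <- segment_events(tr2)
  expect_equal(nrow(ev2[ev2$layer == "locomotor", ]), 0)
  sh <- ev2[ev2$kind == "shelter_visit", ]
  expect_equal(nrow(sh), 1)
  expect_equal(c(sh$start, sh$end), c(0, 60))
})

test_that("segmentation reproduces generator ground truth exactly on jitter-free output", {
  spec <- small_homecage_spec(seed = 101, rate = 2)
  sim <- simulate_homecage_trace(spec)
  seg <- segment_events(sim$trace)
  dt <- 1 / 2
  for (k in c("movement", "arrest", "shelter_visit", "activity_bout")) {
    truth <- sim$events[sim$events$kind == k, ]
    got <- seg[seg$kind == k, ]
    expect_equal(nrow(got), nrow(truth), info = k)
    expect_lt(max(abs(got$start - truth$start)), dt, label = paste(k, "starts"))
    expect_lt(max(abs(got$end - truth$end)), dt, label = paste(k, "ends"))
  }
  mv_t <- sim$events[sim$events$kind == "movement", ]
  mv_g <- seg[seg$kind == "movement", ]
  expect_equal(mv_g$distance, mv_t$distance, tolerance = 1e-8)
})

test_that("segmented layers conserve time", {
  spec <- small_homecage_spec(seed = 55, rate = 2)
  sim <- simulate_homecage_trace(spec)
  seg <- segment_events(sim$trace)
  total <- attr(seg, "duration")
  dur <- function(k) sum(seg$end[seg$kind == k] - seg$start[seg$kind == k])
  expect_equal(dur("shelter_visit") + dur("movement") + dur("arrest"), total)
})

test_that("freezing percentages per 60-s bin match scripted stillness", {
  # still for 600 s: 100% frozen in each of 10 bins
  tr <- const_trace(600, rate = 10)
  fz <- detect_freezing(tr)
  expect_equal(nrow(fz$bins), 10)
  expect_equal(fz$bins$percent_frozen, rep(100, 10))

  # steady 5 cm/s walk: 0% in all bins
  n <- 600 * 10
  step <- 5 / 10
  xs <- 5 + (seq_len(n) %% 80) * step  # shuttling line, always moving
  tr2 <- make_trace(xs, rep(25, n), rate = 10)
  fz2 <- detect_freezing(tr2)
  expect_true(all(fz2$bins$percent_frozen <= 100 * 2 / 600))  # turnaround frames only

  # alternating 30 s still / 30 s moving: ~50% per bin
  rate <- 10
  blocks <- rep(rep(c(0, 1), 10), each = 30 * rate)
  xs3 <- 5 + cumsum(blocks * step)
  tr3 <- make_trace(xs3, rep(25, length(xs3)), rate = rate)
  fz3 <- detect_freezing(tr3)
  frozen_frames <- sum(trace_frozen_oracle(tr3, v = 1, min_dur = 1))
  expect_equal(mean(fz3$bins$percent_frozen), 100 * frozen_frames / length(xs3),
               tolerance = 1e-6)
  expect_true(all(abs(fz3$bins$percent_frozen - 50) < 2))

  # partial final bin is reported with its own duration
  tr4 <- const_trace(90, rate = 10)
  fz4 <- detect_freezing(tr4)
  expect_equal(fz4$bins$duration_s, c(60, 30))
})

test_that("zone metrics agree with a per-sample brute-force oracle and sum over partitions", {
  arena <- arena_geometry("open_field")
  set.seed(21)
  n <- 2000
  xs <- cumsum(rnorm(n, 0, 0.5)); ys <- cumsum(rnorm(n, 0, 0.5))
  xs <- 25 + 20 * sin(xs / 10); ys <- 25 + 20 * sin(ys / 7)
  tr <- make_trace(xs, ys, rate = 20, arena = arena)
  zm <- zone_metrics(tr)

  # independent oracle: per-sample assignment and step attribution
  steps <- c(sqrt(diff(xs)^2 + diff(ys)^2), 0)
  inner <- xs >= 5 & xs <= 45 & ys >= 5 & ys <= 45
  expect_equal(zm$distance_cm[zm$zone == "inner"], sum(steps[inner]))
  expect_equal(zm$distance_cm[zm$zone == "outer"], sum(steps[!inner]))
  expect_equal(zm$time_s[zm$zone == "inner"], sum(inner) / 20)
  expect_equal(sum(zm$relative_distance), 1, tolerance = 1e-9)
  expect_equal(sum(zm$time_fraction), 1, tolerance = 1e-9)

  # wholly inside the inner zone
  tr_in <- const_trace(10, rate = 20, pos = c(25, 25), arena = arena)
  zm_in <- zone_metrics(tr_in)
  expect_equal(zm_in$time_fraction[zm_in$zone == "inner"], 1)
  expect_equal(zm_in$time_fraction[zm_in$zone == "outer"], 0)

  # rigid translation of trace and zones together leaves metrics unchanged
  zones <- list(box = zone_rect(10, 10, 30, 30))
  shifted <- list(box = zone_rect(15, 12, 35, 32))
  tr_s <- make_trace(xs + 5, ys + 2, rate = 20, arena = arena)
  a <- zone_metrics(tr, zones)
  b <- zone_metrics(tr_s, shifted)
  expect_equal(a$distance_cm, b$distance_cm, tolerance = 1e-9)
  expect_equal(a$time_s, b$time_s)
  expect_equal(a$entries, b$entries)
})

test_that("quadrant relative distances over a circular arena sum to one", {
  tr <- simulate_probe_trials(3, duration = 30, sample_rate = 10, seed = 9)
  for (t in tr) {
    qm <- zone_metrics(t)
    quads <- qm[qm$zone %in% c("NE", "NW", "SW", "SE"), ]
    expect_equal(sum(quads$relative_distance), 1, tolerance = 1e-9)
  }
})

test_that("distance to first target entry matches the cumulative-sum oracle", {
  arena <- arena_geometry("barnes")
  target <- zone_disc(48, 0, 5.25)
  # straight-line approach from 40 cm away from the boundary
  rate <- 20
  xs <- seq(48 - 5.25 - 40, 48, by = 0.5)
  tr <- make_trace(xs, rep(0, length(xs)), rate = rate, arena = arena)
  d <- distance_to_first_entry(tr, target)
  expect_true(d$reached)
  expect_equal(d$distance_cm, 40, tolerance = 0.5)  # within one step

  # start inside the target
  tr0 <- const_trace(5, rate = rate, pos = c(48, 0), arena = arena)
  d0 <- distance_to_first_entry(tr0, target)
  expect_true(d0$reached)
  expect_equal(d0$distance_cm, 0)

  # arbitrary path: equals the brute-force cumulative sum oracle
  set.seed(3)
  n <- 1500
  ang <- cumsum(rnorm(n, 0, 0.2))
  px <- pmin(pmax(cumsum(cos(ang)) * 0.8 - 30, -55), 55)
  py <- pmin(pmax(cumsum(sin(ang)) * 0.8, -55), 55)
  tr2 <- make_trace(px, py, rate = rate, arena = arena)
  d2 <- distance_to_first_entry(tr2, target)
  inside <- (px - 48)^2 + py^2 <= 5.25^2
  steps <- c(sqrt(diff(px)^2 + diff(py)^2), 0)
  first <- match(TRUE, inside)
  oracle <- if (is.na(first)) sum(steps) else sum(steps[seq_len(first - 1)])
  expect_equal(d2$distance_cm, oracle)
  expect_equal(d2$reached, !is.na(first))

  # never reached: total path length, reached = FALSE
  tr3 <- const_trace(5, rate = rate, pos = c(0, 0), arena = arena)
  d3 <- distance_to_first_entry(tr3, target)
  expect_false(d3$reached)
})

test_that("interaction scoring excludes low-confidence frames and errors on bad sessions", {
  targets <- list(A = zone_disc(10, 10, 3))
  kp <- simulate_interaction_session(
    targets, tibble::tibble(target = "A", start = 0, end = 100),
    duration = 200, sample_rate = 20)
  # push half the nose frames below the confidence threshold
  nose_rows <- which(kp$bodypart == "nose")
  drop <- nose_rows[seq(1, length(nose_rows), by = 2)]
  kp$confidence[drop] <- 0.1
  out <- score_interactions(kp, targets)
  # half the in-proximity frames survive: 100 s scripted -> 50 s counted
  expect_equal(out$interaction_s, 50)
  expect_equal(out$valid_fraction, 0.5)

  kp$confidence[kp$bodypart == "nose"] <- 0.1
  expect_error(score_interactions(kp, targets), "confidence")
})

test_that("trace QC interpolates short gaps and reports long ones", {
  n <- 200
  xs <- seq(5, 45, length.out = n); ys <- rep(25, n)
  xs[50:55] <- NA; ys[50:55] <- NA          # 0.3 s gap at 20/s: filled
  xs[100:131] <- NA; ys[100:131] <- NA      # 1.6 s gap: reported, not filled
  tr <- make_trace(xs, ys, rate = 20)
  out <- trace_qc(tr, max_gap = 1)
  qc <- attr(out, "qc")
  expect_equal(nrow(qc$gaps), 2)
  expect_equal(qc$gaps$filled, c(TRUE, FALSE))
  expect_false(anyNA(out$x_cm[50:55]))
  expect_true(anyNA(out$x_cm[100:145]))
  expect_error(trace_qc(tr, max_missing = 0.1), "QC failed")
})
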