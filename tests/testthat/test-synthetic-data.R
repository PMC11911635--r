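test_that("trace length follows duration and rate, and zero bout rate gives a still animal", {
  spec <- small_homecage_spec(seed = 1, rate = 2)
  sim <- simulate_homecage_trace(spec)
  expect_equal(nrow(sim$trace), 1 * 86400 * 2)

  still <- small_homecage_spec(
    seed = 2, rate = 2,
    activity_bout_rate_per_phase = c(dark = 0, light = 0))
  sim2 <- simulate_homecage_trace(still)
  expect_equal(sum(sim2$events$kind == "movement"), 0)
  # outside the shelter the position never changes
  sh <- sim2$events[sim2$events$kind == "shelter_visit", ]
  in_shelter <- rep(FALSE, nrow(sim2$trace))
  for (i in seq_len(nrow(sh))) {
    idx <- sim2$trace$time_s >= sh$start[i] & sim2$trace$time_s < sh$end[i]
    in_shelter[idx] <- TRUE
  }
  out_xy <- unique(cbind(sim2$trace$x_cm[!in_shelter],
                         sim2$trace$y_cm[!in_shelter]))
  expect_lte(nrow(out_xy), 2)  # initial rest point and the shelter exit point
})

test_that("shelter-visit durations match their generating mixture components", {
  mix <- list(weights = c(0.3, 0.4, 0.3), means = c(4, 7, 11),
              sds = c(0.5, 0.5, 0.5))
  set.seed(11)
  d <- sample_log2_mixture(5000, mix)
  for (k in 1:3) {
    expect_lt(abs(mean(log2(d$value[d$component == k])) - mix$means[k]), 0.1)
  }
  expect_gt(min(table(d$component)), 1000)
})

test_that("simulated home-cage output is seed-deterministic and internally consistent", {
  spec <- small_homecage_spec(seed = 31, rate = 2)
  a <- simulate_homecage_trace(spec)
  b <- simulate_homecage_trace(spec)
  expect_identical(a$trace$x_cm, b$trace$x_cm)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))

  ev <- a$events
  # events time-sorted and non-overlapping within each layer
  for (ly in unique(ev$layer)) {
    e <- ev[ev$layer == ly, ]
    expect_true(all(diff(e$start) >= 0))
    if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)] - 1e-9))
  }
  # no movement overlaps a shelter visit
  mv <- ev[ev$kind == "movement", ]
  sh <- ev[ev$kind == "shelter_visit", ]
  for (i in seq_len(nrow(sh))) {
    expect_false(any(mv$start < sh$end[i] & mv$end > sh$start[i]))
  }
})

test_that("invalid home-cage specs are rejected", {
  expect_error(homecage_sim_spec(seed = 1, shelter_visit_log2_mixture = list(
    weights = c(0.5, 0.4, 0.3), means = c(4, 7, 11), sds = c(0.5, 0.5, 0.5))),
    "sum to 1")
  expect_error(homecage_sim_spec(seed = 1, movement_log2_mixture = list(
    weights = c(0.6, 0.4), means = c(2, 5), sds = c(0.7, -0.1))), "positive")
  expect_error(homecage_sim_spec(seed = 1, duration_days = 0.5), ">= 1")
  expect_error(homecage_sim_spec())  # missing seed
})

test_that("entry-log agents respect correctness and perseveration settings", {
  sched <- target_schedule(c("left", "right"))
  perfect <- simulate_entry_log(
    agent_spec(p_correct = 1, seed = 5), sched)
  day <- floor(perfect$time_s / 86400) + 1
  expect_true(all(perfect$hole == sched$target[day]))

  persev <- simulate_entry_log(
    agent_spec(p_correct = 0, perseveration_weight = 1, seed = 6), sched)
  day2 <- persev[floor(persev$time_s / 86400) + 1 == 2, ]
  expect_gt(nrow(day2), 0)
  expect_true(all(day2$hole == "left"))  # day-1 target

  # 0.7-correct agent: overall fraction within 3 binomial s.e.
  long_sched <- target_schedule(rep(c("left", "right", "middle"), 4))
  ag <- agent_spec(p_correct = 0.7, entries_per_hour_profile = 8, seed = 7)
  log <- simulate_entry_log(ag, long_sched)
  expect_gt(nrow(log), 2000)
  dayl <- floor(log$time_s / 86400) + 1
  frac <- mean(log$hole == long_sched$target[dayl])
  se <- sqrt(0.7 * 0.3 / nrow(log))
  expect_lt(abs(frac - 0.7), 3 * se)

  expect_error(simulate_entry_log(ag, target_schedule(character(0))))
})

test_that("scripted interaction sessions carry exact nose-in-proximity ground truth", {
  targets <- list(A = zone_disc(10, 10, 3), B = zone_disc(40, 40, 3))
  script <- tibble::tibble(target = c("A", "B"),
                           start = c(0, 100), end = c(60, 140))
  kp <- simulate_interaction_session(targets, script, duration = 300,
                                     sample_rate = 20)
  out <- score_interactions(kp, targets)
  expect_equal(out$interaction_s[out$target == "A"], 60)
  expect_equal(out$interaction_s[out$target == "B"], 40)

  # nose never near any target -> zero everywhere
  kp0 <- simulate_interaction_session(targets, script[0, ], duration = 300)
  out0 <- score_interactions(kp0, targets)
  expect_equal(out0$interaction_s, c(0, 0))

  # full-session dwell equals the session length
  kp_full <- simulate_interaction_session(
    targets["A"], tibble::tibble(target = "A", start = 0, end = 300),
    duration = 300)
  expect_equal(score_interactions(kp_full, targets["A"])$interaction_s, 300)

  expect_error(simulate_interaction_session(
    list(A = zone_disc(10, 10, 3), B = zone_disc(11, 10, 3)), script),
    "overlap")
})

test_that("cohorts recover injected group effects and are reproducible", {
  base <- small_homecage_spec(seed = 1, rate = 2)
  groups <- tibble::tibble(
    label = c("A", "B"), n = c(8, 8),
    effects = list(list(), list(activity_rate_factor = c(dark = 2))))
  cs <- cohort_spec(groups, base, seed = 77)
  co <- simulate_cohort(cs)
  expect_equal(nrow(co$animals), 16)
  co2 <- simulate_cohort(cs)
  expect_identical(
    lapply(co$events, function(e) as.data.frame(e)),
    lapply(co2$events, function(e) as.data.frame(e)))

  dark_activity <- function(ev) {
    b <- ev[ev$kind == "activity_bout", ]
    ph <- light_phase(attr(ev, "lightcycle"), b$start)
    sum((b$end - b$start)[ph == "dark"])
  }
  act <- vapply(co$events, dark_activity, numeric(1))
  ga <- act[co$animals$group[match(names(act), co$animals$animal_id)] == "A"]
  gb <- act[co$animals$group[match(names(act), co$animals$animal_id)] == "B"]
  expect_gt(mean(gb), mean(ga))  # doubled dark bout rate

  # zero-offset groups do not differ beyond sampling noise (~3 s.e.)
  groups0 <- tibble::tibble(label = c("A", "B"), n = c(8, 8),
                            effects = list(list(), list()))
  co0 <- simulate_cohort(cohort_spec(groups0, base, seed = 42))
  act0 <- vapply(co0$events, dark_activity, numeric(1))
  g <- co0$animals$group[match(names(act0), co0$animals$animal_id)]
  se <- sqrt(var(act0[g == "A"]) / 8 + var(act0[g == "B"]) / 8)
  expect_lt(abs(mean(act0[g == "A"]) - mean(act0[g == "B"])), 3 * se)
})
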