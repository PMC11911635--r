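test_that("discrimination index follows its formula and flags degenerate input", {
  expect_equal(discrimination_index(30, 30)$di, 0.5)
  expect_equal(discrimination_index(60, 40)$di, 0.6)
  expect_equal(discrimination_index(60, c(20, 20))$di, 0.6)
  z <- discrimination_index(0, 0)
  expect_true(z$undefined)
  expect_true(is.na(z$di))
  expect_error(discrimination_index(-1, 5), "non-negative")
  # strictly increasing in novel time for fixed familiar time
  dis <- vapply(seq(0, 100, by = 10), function(nv) {
    discrimination_index(nv, 40)$di
  }, numeric(1))
  expect_true(all(diff(dis) > 0))
})

test_that("alternation is the percentage choosing the target arm", {
  expect_equal(alternation(rep("left", 10), "left"), 100)
  expect_equal(alternation(c(rep("left", 8), rep("right", 8)), "left"), 50)
  set.seed(1)
  arms <- sample(c("left", "right"), 20, replace = TRUE)
  expect_equal(alternation(arms, "left"), alternation(sample(arms), "left"))
  expect_error(alternation(character(0), "left"), "no animals")
})

# Independent brute-force classifier used as the oracle for the curves.
brute_classify <- function(times, holes, targets) {
  day <- floor(times / 86400) + 1
  out <- character(length(times))
  for (i in seq_along(times)) {
    tgt <- targets[day[i]]
    prev <- if (day[i] > 1) targets[day[i] - 1] else NA
    out[i] <- if (holes[i] == tgt) "correct"
    else if (!is.na(prev) && prev != tgt && holes[i] == prev) "perseverative"
    else "neutral"
  }
  out
}

test_that("learning-curve classification matches the brute-force oracle on random logs", {
  sched <- target_schedule()  # left,left,right,left,middle,right,left
  set.seed(8)
  for (rep in 1:5) {
    n <- 400
    times <- sort(runif(n, 0, 7 * 86400))
    holes <- sample(c("left", "middle", "right"), n, replace = TRUE)
    log <- entry_log(times, holes, sched)
    got <- phenocage:::classify_entries(log)
    expect_identical(got$class, brute_classify(times, holes, sched$target))
  }
})

test_that("learning curves bin entries by 50 and their class fractions sum to one", {
  sched <- target_schedule(c("left", "right"))
  log <- make_entry_log(list(rep("left", 120), rep("right", 55)), sched)
  lc <- learning_curves(log)
  expect_equal(lc$curve$n_entries, c(50, 50, 50, 25))
  expect_equal(lc$curve$frac_correct, rep(1, 4))
  expect_equal(lc$curve$frac_correct + lc$curve$frac_perseverative +
                 lc$curve$frac_neutral, rep(1, 4))

  # mixed log keeps the partition property
  set.seed(9)
  holes <- sample(c("left", "middle", "right"), 230, replace = TRUE)
  logm <- make_entry_log(split(holes, rep(1:2, c(115, 115))), sched)
  c2 <- learning_curves(logm)$curve
  expect_equal(c2$frac_correct + c2$frac_perseverative + c2$frac_neutral,
               rep(1, nrow(c2)))

  # a 0.7-correct Bernoulli agent stays within 3 binomial s.e. of 0.7
  ag <- agent_spec(p_correct = 0.7, entries_per_hour_profile = 15, seed = 10)
  long_sched <- target_schedule(rep(c("left", "right", "middle"), 3))
  elog <- simulate_entry_log(ag, long_sched)
  expect_gt(nrow(elog), 2000)
  cv <- learning_curves(elog)$curve
  full <- cv[cv$n_entries == 50, ]
  est <- mean(full$frac_correct)
  expect_lt(abs(est - 0.7), 3 * sqrt(0.7 * 0.3 / (50 * nrow(full))))

  expect_error(learning_curves(make_entry_log(
    list(rep("left", 5), rep("left", 5), rep("left", 5)), sched)),
    "without a scheduled target")
})

test_that("the per-group average curve honors the n>3 display cutoff", {
  sched <- target_schedule(c("left", "right"))
  curves <- lapply(1:5, function(i) {
    k <- c(260, 260, 120, 120, 60)[i]
    learning_curves(make_entry_log(list(rep("left", k)), sched))$curve
  })
  names(curves) <- paste0("m", 1:5)
  avg <- average_learning_curves(curves)
  # 260 entries -> 6 bins, 120 -> 3 bins, 60 -> 2 bins
  expect_equal(avg$n_animals, c(5, 5, 4, 2, 2, 2))
  expect_equal(avg$display, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("pellet replay releases one pellet per five cumulative correct entries", {
  sched <- target_schedule(c("left", "right"))
  # 25 correct entries in a day -> 5 pellets
  log <- make_entry_log(list(rep("left", 25)), sched)
  expect_equal(nrow(replay_reward_schedule(log)), 5)
  # 4 correct entries -> none
  log4 <- make_entry_log(list(rep("left", 4)), sched)
  expect_equal(nrow(replay_reward_schedule(log4)), 0)
  # non-consecutive rule: C,E,C,E,C,E,C,E,C -> pellet after the 9th entry
  pat <- c("left", "right", "left", "right", "left", "right", "left",
           "right", "left")
  logp <- make_entry_log(list(pat), sched)
  pel <- replay_reward_schedule(logp)
  expect_equal(nrow(pel), 1)
  expect_equal(pel$entry_index, 9L)
  # counter resets at the daily switch: 7 correct day 1 + 3 correct day 2
  logr <- make_entry_log(list(rep("left", 7), rep("right", 3)), sched)
  expect_equal(nrow(replay_reward_schedule(logr)), 1)
  expect_equal(nrow(replay_reward_schedule(logr, carry_over = TRUE)), 2)
  # pellet count equals floor(day correct / 5) under the reset convention
  set.seed(2)
  holes <- list(sample(c("left", "right"), 63, replace = TRUE),
                sample(c("left", "right"), 41, replace = TRUE))
  logf <- make_entry_log(holes, sched)
  expect_equal(nrow(replay_reward_schedule(logf)),
               sum(floor(c(sum(holes[[1]] == "left"),
                           sum(holes[[2]] == "right")) / 5)))
})

test_that("probe metrics combine quadrant shares, target approach and chance symmetry", {
  # trace confined to one quadrant
  arena <- arena_geometry("water_maze")
  n <- 600
  xs <- 20 + 10 * sin(seq_len(n) / 20); ys <- 20 + 10 * cos(seq_len(n) / 30)
  tr <- make_trace(xs, ys, rate = 20, arena = arena)
  pm <- probe_metrics(tr, target = "NE",
                      target_zone = arena$zones$platform)
  q <- pm$quadrants
  expect_equal(q$relative_distance[q$zone == "NE"], 1)
  expect_equal(sum(q$relative_distance), 1, tolerance = 1e-9)
  expect_true(pm$distance_to_target$reached)

  expect_error(probe_metrics(tr, target = "UP"), "unknown target")
  of <- const_trace(2, arena = arena_geometry("open_field"))
  expect_error(probe_metrics(of, target = "NE"), "quadrant")
})
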