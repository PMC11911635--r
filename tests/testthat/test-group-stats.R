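test_that("the normality gate routes to the parametric or rank path", {
  set.seed(30)
  normal <- list(WT = rnorm(12, 10), a = rnorm(12, 10), b = rnorm(12, 12))
  cmp <- compare_groups(normal, control = "WT")
  expect_equal(cmp$path, "anova_tukey")
  expect_equal(cmp$transform, "none")

  heavy <- list(WT = rcauchy(15), a = rcauchy(15), b = rcauchy(15) + 40)
  cmp2 <- compare_groups(heavy, control = "WT", try_log10 = FALSE)
  expect_equal(cmp2$path, "kruskal_mannwhitney")

  # lognormal data pass after the one-shot log10 transform
  ln <- list(WT = exp(rnorm(20, 1, 1.2)), a = exp(rnorm(20, 1, 1.2)),
             b = exp(rnorm(20, 2, 1.2)))
  cmp3 <- compare_groups(ln, control = "WT")
  expect_equal(cmp3$transform, "log10")
  expect_equal(cmp3$path, "anova_tukey")

  expect_error(compare_groups(list(a = rnorm(10))), "at least 2")
  expect_error(compare_groups(list(a = rnorm(10), b = rnorm(2))), "n >= 3")
  const <- compare_groups(list(a = rep(1, 5), b = rep(1, 5)))
  expect_true(const$degenerate)
  expect_equal(const$omnibus_p, 1)
})

test_that("the pairing rule gates model-vs-model comparisons on a control difference", {
  set.seed(31)
  # no model differs from control: only control pairs reported
  null_g <- list(WT = rcauchy(12), m1 = rcauchy(12), m2 = rcauchy(12))
  cmp <- compare_groups(null_g, control = "WT", try_log10 = FALSE)
  if (cmp$omnibus_p < 0.05 && nrow(cmp$pairwise) > 0 &&
      all(cmp$pairwise$p[cmp$pairwise$group1 == "WT" |
                           cmp$pairwise$group2 == "WT"] >= 0.05)) {
    expect_true(all(cmp$pairwise$group1 == "WT" | cmp$pairwise$group2 == "WT"))
  }
  # a clear model-vs-control difference opens the model-model comparisons
  shift <- list(WT = rcauchy(15), m1 = rcauchy(15) + 50, m2 = rcauchy(15))
  cmp2 <- compare_groups(shift, control = "WT", try_log10 = FALSE)
  expect_equal(cmp2$path, "kruskal_mannwhitney")
  expect_true(any(cmp2$pairwise$group1 != "WT" & cmp2$pairwise$group2 != "WT"))

  # strong shift with normal data: omnibus extremely significant
  pw <- list(WT = rnorm(15), m1 = rnorm(15) + 5, m2 = rnorm(15))
  cmp3 <- compare_groups(pw, control = "WT")
  expect_lt(cmp3$omnibus_p, 1e-6)
})

test_that("every ladder test agrees with the base statistical backend", {
  set.seed(32)
  for (i in 1:100) {
    g <- list(a = rnorm(10 + i %% 5, sd = 1 + i %% 3),
              b = rexp(12), c = rnorm(11, 2))
    cmp <- compare_groups(g, try_log10 = FALSE)
    vals <- unlist(g, use.names = FALSE)
    grp <- factor(rep(names(g), lengths(g)), levels = names(g))
    if (cmp$path == "anova_tukey") {
      ref <- summary(aov(vals ~ grp))[[1]][["Pr(>F)"]][1]
    } else {
      ref <- kruskal.test(vals, grp)$p.value
    }
    expect_equal(cmp$omnibus_p, ref, tolerance = 1e-8)

    x <- rnorm(8 + i %% 7, mean = 0.5 + 0.1 * (i %% 3), sd = 0.2)
    ct <- chance_test(x, 0.5, normal = TRUE)
    expect_equal(ct$p, t.test(x, mu = 0.5)$p.value, tolerance = 1e-8)
    ctw <- chance_test(x, 0.5, normal = FALSE)
    expect_equal(ctw$p,
                 suppressWarnings(wilcox.test(x, mu = 0.5)$p.value),
                 tolerance = 1e-8)

    tab <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(alternation_chisq(tab)$p,
                 suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
                 tolerance = 1e-8)
  }
})

test_that("chance tests behave under the null, under shifts and on degenerate data", {
  # symmetric around chance: large p
  sym <- c(0.20, 0.30, 0.22, 0.28, 0.15, 0.35, 0.25, 0.25)
  expect_gt(chance_test(sym, 0.25)$p, 0.5)
  # constant shift of +1: overwhelming evidence
  expect_lt(chance_test(0.5 + 1 + rnorm(10, 0, 1e-3), 0.5)$p, 0.001)
  # all values exactly at chance: degenerate, p = 1
  d <- chance_test(rep(0.5, 6), 0.5)
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
  # the signed-rank test only uses signs and ranks of |x - chance|
  x <- c(0.1, 0.45, 0.6, 0.9, 0.2, 0.7)
  y <- 0.5 + sign(x - 0.5) * rank(abs(x - 0.5)) / 10
  expect_equal(chance_test(x, 0.5, normal = FALSE)$p,
               chance_test(y, 0.5, normal = FALSE)$p)
  expect_error(chance_test(c(1, 2), 0.5), "n >= 3")
})

test_that("chi-square on alternation counts matches the textbook formula", {
  same <- alternation_chisq(matrix(c(10, 10, 5, 5), 2, byrow = TRUE))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  O <- matrix(c(15, 1, 8, 8), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(alternation_chisq(O)$statistic, sum((O - E)^2 / E))
  expect_equal(alternation_chisq(O)$statistic,
               alternation_chisq(O[2:1, ])$statistic)
  zed <- alternation_chisq(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(zed$degenerate)
  expect_error(alternation_chisq(matrix(-1, 2, 2)), "non-negative")
})

test_that("FDR adjustment matches the Benjamini-Hochberg step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    running <- Inf
    for (i in m:1) {
      running <- min(running, m * p[o[i]] / i)
      adj[o[i]] <- min(running, 1)
    }
    adj
  }
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(33)
  for (i in 1:50) {
    p <- runif(sample(2:25, 1))^sample(1:3, 1)
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the WT-pooling filter excludes pooled-only significances and retains the rest", {
  mk <- function(wt_means, model_shift, n = 10, sd = 0.6, seed = 1) {
    set.seed(seed)
    wt <- dplyr::bind_rows(lapply(seq_along(wt_means), function(i) {
      tibble::tibble(value = rnorm(n, wt_means[i], sd), group = "WT",
                     wt_of = paste0("m", i))
    }))
    models <- dplyr::bind_rows(lapply(seq_along(wt_means), function(i) {
      tibble::tibble(value = rnorm(n, wt_means[i] + model_shift[i], sd),
                     group = paste0("m", i), wt_of = NA_character_)
    }))
    dplyr::bind_rows(wt, models)
  }
  # identical WT subgroups, no effects: retain (checked over replicates)
  retains <- vapply(1:20, function(r) {
    d <- mk(c(0, 0, 0), c(0, 0, 0), seed = 100 + r)
    wt_consistency_filter(d)$decision == "retain"
  }, logical(1))
  expect_gte(mean(retains), 0.95)

  # one WT subgroup shifted far off: pooled-vs-model fires, own-WT does not
  d2 <- mk(c(0, 0, 6), c(0, 0, 0), seed = 7)
  f2 <- wt_consistency_filter(d2)
  expect_true(f2$wt_subgroups_differ)
  expect_true(f2$pooled_significant)
  expect_false(f2$own_wt_significant)
  expect_equal(f2$decision, "exclude")

  # subgroups differ mildly but nothing is pooled-significant: retain
  d3 <- mk(c(0, 0, 1.2), c(0.35, 0.35, -0.65), seed = 9)
  f3 <- wt_consistency_filter(d3)
  if (!f3$pooled_significant) expect_equal(f3$decision, "retain")

  # a real effect also visible against own WTs: retain
  d4 <- mk(c(0, 0, 1.5), c(4, 0, 0), seed = 11)
  f4 <- wt_consistency_filter(d4)
  expect_equal(f4$decision, "retain")
  expect_true(f4$own_wt_significant)

  bad <- tibble::tibble(value = rnorm(12), group = rep(c("WT", "m1"), 6),
                        wt_of = rep(c("m2", NA), 6))
  expect_error(wt_consistency_filter(bad), "own-WT")
})
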