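#' Normality-gated group comparison
#'
#' The study's statistical ladder for a single parameter across groups.
#' Each group is assessed for normality (Shapiro-Wilk at `alpha_normal`);
#' if any group fails and all values are positive, a log10 transform is
#' attempted once. If all groups are (then) normal, a one-way ANOVA with
#' Tukey post-hoc is used; otherwise a Kruskal-Wallis omnibus followed, and
#' only when the omnibus is significant, by pairwise Mann-Whitney tests
#' (reported unadjusted, as in the described procedure; set
#' `adjust_pairwise` for BH adjustment). When a `control` group is named,
#' the pairwise set follows the study's pairing rule: every model group is
#' compared against the control, and model-vs-model comparisons are
#' included only if at least one model differed significantly from the
#' control. The gate never changes the data, only the test path.
#'
#' @param values_by_group Named list of numeric vectors (one per group),
#'   each with at least 3 observations.
#' @param control Optional control group label (the pooled wild-type
#'   group).
#' @param alpha Significance level driving the omnibus gate and the
#'   pairing rule.
#' @param alpha_normal Level of the per-group normality test.
#' @param try_log10 Attempt a log10 transform when normality fails.
#' @param adjust_pairwise Apply BH adjustment to the pairwise p-values.
#' @return A `phenocage_comparison` list: `path`
#'   (`"anova_tukey"`/`"kruskal_mannwhitney"`), `transform` (`"none"` or
#'   `"log10"`), `omnibus_p`, `pairwise` (tibble `group1`, `group2`, `p`,
#'   `p_adj`), `normality` (tibble `group`, `p`), `degenerate`.
#' @export
compare_groups <- function(values_by_group, control = NULL, alpha = 0.05,
                           alpha_normal = 0.05, try_log10 = TRUE,
                           adjust_pairwise = FALSE) {
  if (!is.list(values_by_group) || length(values_by_group) < 2) {
    stop_input("need at least 2 groups")
  }
  labels <- names(values_by_group)
  if (is.null(labels) || any(labels == "")) stop_input("groups must be named")
  ns <- lengths(values_by_group)
  if (any(ns < 3)) {
    stop_input("every group needs n >= 3 (got %s)",
               paste(labels[ns < 3], collapse = ", "))
  }
  if (!is.null(control) && !control %in% labels) {
    stop_input("control group '%s' not present", control)
  }
  vals <- unlist(values_by_group, use.names = FALSE)
  grp <- factor(rep(labels, ns), levels = labels)
  if (any(!is.finite(vals))) stop_input("non-finite values")

  if (sd(vals) < 1e-12) {
    return(structure(list(path = "degenerate", transform = "none",
                          omnibus_p = 1,
                          pairwise = tibble::tibble(group1 = character(),
                                                    group2 = character(),
                                                    p = double(),
                                                    p_adj = double()),
                          normality = tibble::tibble(group = labels,
                                                     p = NA_real_),
                          degenerate = TRUE),
                     class = "phenocage_comparison"))
  }

  shapiro_p <- function(x) {
    if (sd(x) < 1e-12) return(0)  # constant within group: treat as non-normal
    shapiro.test(x)$p.value
  }
  norm_p <- vapply(values_by_group, shapiro_p, numeric(1))
  transform <- "none"
  if (any(norm_p < alpha_normal) && try_log10 && all(vals > 0)) {
    logged <- lapply(values_by_group, log10)
    norm_p2 <- vapply(logged, shapiro_p, numeric(1))
    if (all(norm_p2 >= alpha_normal)) {
      values_by_group <- logged
      vals <- unlist(logged, use.names = FALSE)
      norm_p <- norm_p2
      transform <- "log10"
    }
  }
  normal <- all(norm_p >= alpha_normal)

  pair_rows <- function(p_by_pair) {
    pw <- p_by_pair
    if (!is.null(control)) {
      ctrl <- pw$group1 == control | pw$group2 == control
      any_sig <- any(pw$p[ctrl] < alpha)
      pw <- pw[ctrl | any_sig, , drop = FALSE]
    }
    pw$p_adj <- if (adjust_pairwise) fdr_adjust(pw$p) else pw$p
    pw
  }

  if (normal) {
    fit <- aov(vals ~ grp)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$grp
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pw <- pair_rows(tibble::tibble(group1 = pairs[, 2], group2 = pairs[, 1],
                                   p = unname(tk[, "p adj"])))
    path <- "anova_tukey"
  } else {
    omnibus_p <- kruskal.test(vals, grp)$p.value
    pw <- tibble::tibble(group1 = character(), group2 = character(),
                         p = double(), p_adj = double())
    if (is.finite(omnibus_p) && omnibus_p < alpha) {
      cmb <- utils::combn(labels, 2)
      raw <- tibble::tibble(
        group1 = cmb[1, ], group2 = cmb[2, ],
        p = vapply(seq_len(ncol(cmb)), function(i) {
          suppressWarnings(wilcox.test(values_by_group[[cmb[1, i]]],
                                       values_by_group[[cmb[2, i]]])$p.value)
        }, numeric(1)))
      pw <- pair_rows(raw)
    }
    path <- "kruskal_mannwhitney"
  }
  structure(list(path = path, transform = transform, omnibus_p = omnibus_p,
                 pairwise = pw,
                 normality = tibble::tibble(group = labels, p = norm_p),
                 degenerate = FALSE),
            class = "phenocage_comparison")
}

#' @export
print.phenocage_comparison <- function(x, ...) {
  cat(sprintf("<phenocage_comparison> path=%s transform=%s omnibus p=%.4g\n",
              x$path, x$transform, x$omnibus_p))
  if (nrow(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Chance-level test
#'
#' One-sample comparison of a group's values against a chance constant
#' (0.5 for discrimination indices, 0.25 for quadrant metrics): one-sample
#' t-test when the data are normal, one-sample Wilcoxon signed-rank
#' otherwise. When `normal` is not supplied it is decided by Shapiro-Wilk
#' at `alpha_normal`.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param chance The chance constant.
#' @param normal Logical, or `NULL` to gate on Shapiro-Wilk.
#' @param alpha_normal Level of the normality gate.
#' @return A `phenocage_chancetest` list: `test`, `chance`, `estimate`
#'   (mean or pseudo-median location), `p`, `degenerate`.
#' @export
chance_test <- function(values, chance, normal = NULL, alpha_normal = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop_input("need n >= 3")
  if (sd(values) < 1e-12) {
    return(structure(list(test = "degenerate", chance = chance,
                          estimate = mean(values),
                          p = if (abs(mean(values) - chance) < 1e-12) 1 else 0,
                          degenerate = TRUE),
                     class = "phenocage_chancetest"))
  }
  if (is.null(normal)) normal <- shapiro.test(values)$p.value >= alpha_normal
  if (normal) {
    tt <- t.test(values, mu = chance)
    out <- list(test = "one_sample_t", chance = chance,
                estimate = unname(tt$estimate), p = tt$p.value,
                degenerate = FALSE)
  } else {
    wt <- suppressWarnings(wilcox.test(values, mu = chance, conf.int = FALSE))
    out <- list(test = "wilcoxon_signed_rank", chance = chance,
                estimate = median(values), p = wt$p.value,
                degenerate = FALSE)
  }
  structure(out, class = "phenocage_chancetest")
}

#' Chi-square test on alternation counts
#'
#' Group differences in T-maze alternation tested on a 2x2 table of
#' target / non-target first entries (textbook Pearson chi-square, no
#' continuity correction).
#'
#' @param counts 2x2 matrix: rows = groups, columns = target/non-target
#'   counts.
#' @return List `statistic`, `df`, `p`, `degenerate` (zero-margin table).
#' @export
alternation_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop_input("counts must be 2x2")
  if (any(counts < 0)) stop_input("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    return(list(statistic = NA_real_, df = 1L, p = NA_real_,
                degenerate = TRUE))
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values for the spontaneous-behavior parameter
#' family: monotone in the ranks, capped at 1, never below the raw
#' p-value.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) stop_input("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Wild-type pooling consistency filter
#'
#' The control-pooling sanity check for parameters tested against a pooled
#' wild-type group assembled from several littermate subgroups. A
#' parameter is excluded exactly when (i) the WT subgroups differ among
#' themselves, (ii) some model group is significant against the pooled WT,
#' and (iii) no such model group is significant against its own WT
#' littermates - the pattern of a pooled-control false positive.
#'
#' @param data Tibble with columns `value`, `group` (model label or the
#'   control label) and `wt_of` (for control animals: the model whose
#'   littermates they are; ignored for model animals). A `parameter`
#'   column may be present to filter several parameters at once.
#' @param control The control group label.
#' @param alpha Significance level.
#' @return Tibble of decisions: one row per parameter with
#'   `wt_subgroups_differ`, `pooled_significant`, `own_wt_significant`,
#'   `decision` (`"retain"`/`"exclude"`) and the per-model p-values in a
#'   list-column `detail`.
#' @export
wt_consistency_filter <- function(data, control = "WT", alpha = 0.05) {
  data <- tibble::as_tibble(data)
  if (!all(c("value", "group", "wt_of") %in% names(data))) {
    stop_input("data needs columns value, group, wt_of")
  }
  if (!"parameter" %in% names(data)) data$parameter <- "parameter"
  out <- lapply(split(data, data$parameter), function(d) {
    wt <- d[d$group == control, ]
    models <- setdiff(unique(d$group), control)
    if (nrow(wt) == 0 || length(models) == 0) {
      stop_input("need both control and model groups")
    }
    if (any(!models %in% wt$wt_of)) {
      stop_input("missing own-WT subgroup for model(s): %s",
                 paste(setdiff(models, wt$wt_of), collapse = ", "))
    }
    sub_vals <- split(wt$value, wt$wt_of)
    differ_p <- two_or_more_group_p(sub_vals)
    differs <- is.finite(differ_p) && differ_p < alpha
    detail <- lapply(models, function(m) {
      mv <- d$value[d$group == m]
      pooled_p <- two_group_p(mv, wt$value)
      own_p <- two_group_p(mv, wt$value[wt$wt_of == m])
      tibble::tibble(model = m, pooled_p = pooled_p, own_p = own_p)
    })
    detail <- dplyr::bind_rows(detail)
    sig <- detail$pooled_p < alpha
    pooled_sig <- any(sig)
    own_sig <- pooled_sig && any(detail$own_p[sig] < alpha)
    exclude <- differs && pooled_sig && !own_sig
    tibble::tibble(parameter = d$parameter[1],
                   wt_subgroups_differ = differs,
                   pooled_significant = pooled_sig,
                   own_wt_significant = own_sig,
                   decision = if (exclude) "exclude" else "retain",
                   detail = list(detail))
  })
  dplyr::bind_rows(out)
}

# Two-sample p with the normality gate: Welch t when both samples pass
# Shapiro-Wilk, Mann-Whitney otherwise.
two_group_p <- function(a, b, alpha_normal = 0.05) {
  if (length(a) < 3 || length(b) < 3) return(NA_real_)
  if (sd(c(a, b)) < 1e-12) return(1)
  normal <- all(vapply(list(a, b), function(x) {
    if (sd(x) < 1e-12) return(0)
    shapiro.test(x)$p.value
  }, numeric(1)) >= alpha_normal)
  if (normal) t.test(a, b)$p.value else {
    suppressWarnings(wilcox.test(a, b)$p.value)
  }
}

# Omnibus p across >= 2 samples with the same gate.
two_or_more_group_p <- function(groups, alpha_normal = 0.05) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) return(NA_real_)
  vals <- unlist(groups, use.names = FALSE)
  if (sd(vals) < 1e-12) return(1)
  if (length(groups) == 2) return(two_group_p(groups[[1]], groups[[2]]))
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  normal <- all(vapply(groups, function(x) {
    if (length(x) < 3 || sd(x) < 1e-12) return(0)
    shapiro.test(x)$p.value
  }, numeric(1)) >= alpha_normal)
  if (normal) {
    summary(aov(vals ~ grp))[[1]][["Pr(>F)"]][1]
  } else {
    kruskal.test(vals, grp)$p.value
  }
}
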