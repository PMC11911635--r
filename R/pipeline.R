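#' Run the full phenotyping pipeline
#'
#' End-to-end orchestration from raw tables to a report: per animal, read
#' and QC the trace, segment events, compute the 20-parameter phenotype
#' registry; read entry logs and compute learning curves where present;
#' then run the statistical ladder per parameter (normality-gated omnibus
#' and pairwise comparisons against the control group), adjust the
#' omnibus p-values by FDR across parameters, and apply the WT-pooling
#' consistency filter when own-WT subgroup labels are available. A failing
#' animal is reported with its stage and skipped; the remaining animals
#' are still processed. Deterministic given the config and its seed.
#'
#' @param config A `phenocage_runconfig`, a config file path, or a plain
#'   list in the same shape.
#' @return A `phenocage_report` list: `phenotypes` (tidy per-animal
#'   parameter table), `learning` (per-animal curves and per-group
#'   averages), `stats` (parameter comparisons with FDR), `filter`
#'   (WT-pooling decisions or `NULL`), `errors`, `provenance`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else {
    if (!inherits(config, "phenocage_runconfig")) validate_run_config(config)
    else config
  }
  arena <- arena_geometry(cfg$arena)
  lc <- config_lightcycle(cfg)
  seg <- config_segmentation(cfg)
  pheno_cfg <- config_phenotype(cfg)
  schedule <- target_schedule(cfg$entry_schedule %||%
                                c("left", "left", "right", "left", "middle",
                                  "right", "left"))
  errors <- list()
  note_error <- function(stage, id, e) {
    errors[[length(errors) + 1L]] <<- tibble::tibble(
      stage = stage, animal_id = id, message = conditionMessage(e))
  }

  pheno_rows <- list()
  curves <- list()
  groups <- character()
  wt_of <- character()
  for (a in cfg$animals) {
    groups[a$id] <- a$group
    wt_of[a$id] <- a$wt_of %||% NA_character_
    if (!is.null(a$trace)) {
      pv <- tryCatch({
        tr <- read_trace(a$trace, arena = arena, sample_rate = cfg$sample_rate,
                         lightcycle = lc, max_gap = seg$max_gap,
                         max_missing = seg$max_missing)
        ev <- segment_events(tr, seg)
        compute_phenotype_vector(ev, lc, pheno_cfg)
      }, error = function(e) {
        note_error("phenotype", a$id, e)
        NULL
      })
      if (!is.null(pv)) {
        pv$animal_id <- a$id
        pv$group <- a$group
        pheno_rows[[a$id]] <- pv
      }
    }
    if (!is.null(a$entry_log)) {
      lcv <- tryCatch({
        log <- read_entry_log(a$entry_log, schedule)
        learning_curves(log)$curve
      }, error = function(e) {
        note_error("learning", a$id, e)
        NULL
      })
      if (!is.null(lcv)) curves[[a$id]] <- lcv
    }
  }
  phenotypes <- if (length(pheno_rows)) dplyr::bind_rows(pheno_rows) else NULL

  learning <- NULL
  if (length(curves)) {
    by_group <- split(names(curves), groups[names(curves)])
    averages <- dplyr::bind_rows(lapply(by_group, function(ids) {
      average_learning_curves(curves[ids])
    }), .id = "group")
    learning <- list(per_animal = dplyr::bind_rows(curves, .id = "animal_id"),
                     group_average = averages)
  }

  stats_tbl <- NULL
  filter_tbl <- NULL
  if (!is.null(phenotypes)) {
    stats_tbl <- ladder_over_parameters(phenotypes, control = cfg$control_group)
    wt_map <- wt_of[!is.na(wt_of)]
    if (length(wt_map) > 0) {
      filter_tbl <- tryCatch({
        fd <- phenotypes[!phenotypes$missing, ]
        fd$wt_of <- wt_of[fd$animal_id]
        feasible <- all(table(fd$wt_of[fd$group == cfg$control_group &
                                         fd$parameter == fd$parameter[1]]) >= 3)
        if (!feasible) NULL else {
          wt_consistency_filter(fd[, c("parameter", "value", "group", "wt_of")],
                                control = cfg$control_group)
        }
      }, error = function(e) {
        note_error("wt_filter", "(all)", e)
        NULL
      })
    }
  }

  structure(list(
    phenotypes = phenotypes, learning = learning, stats = stats_tbl,
    filter = filter_tbl,
    errors = if (length(errors)) dplyr::bind_rows(errors) else NULL,
    provenance = list(
      config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "base_dir")]),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("phenocage")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "phenocage_report")
}

# Run the gated ladder for every parameter with enough data, then BH-adjust
# the omnibus p-values across parameters.
ladder_over_parameters <- function(phenotypes, control, alpha = 0.05) {
  params <- unique(phenotypes$parameter)
  rows <- lapply(params, function(p) {
    d <- phenotypes[phenotypes$parameter == p & !phenotypes$missing, ]
    byg <- split(d$value, d$group)
    byg <- byg[lengths(byg) >= 3]
    if (length(byg) < 2) {
      return(tibble::tibble(parameter = p, path = "insufficient",
                            transform = NA_character_, omnibus_p = NA_real_,
                            degenerate = NA, comparison = list(NULL)))
    }
    cmp <- compare_groups(byg, control = if (control %in% names(byg)) control,
                          alpha = alpha)
    tibble::tibble(parameter = p, path = cmp$path, transform = cmp$transform,
                   omnibus_p = cmp$omnibus_p, degenerate = cmp$degenerate,
                   comparison = list(cmp))
  })
  out <- dplyr::bind_rows(rows)
  out$omnibus_p_fdr <- NA_real_
  ok <- is.finite(out$omnibus_p)
  out$omnibus_p_fdr[ok] <- fdr_adjust(out$omnibus_p[ok])
  out
}

#' Write a pipeline report to disk
#'
#' Tidy CSVs per table plus a JSON index with the provenance record.
#'
#' @param report A `phenocage_report`.
#' @param dir Output directory (created if needed).
#' @return The index JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "phenocage_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  put <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(df, path, progress = FALSE)
    files[[name]] <<- basename(path)
  }
  put(report$phenotypes, "phenotypes")
  if (!is.null(report$learning)) {
    put(report$learning$per_animal, "learning_per_animal")
    put(report$learning$group_average, "learning_group_average")
  }
  if (!is.null(report$stats)) {
    flat <- report$stats[, setdiff(names(report$stats), "comparison")]
    put(flat, "stats_omnibus")
    pw <- dplyr::bind_rows(lapply(seq_len(nrow(report$stats)), function(i) {
      cmp <- report$stats$comparison[[i]]
      if (is.null(cmp) || nrow(cmp$pairwise) == 0) return(NULL)
      d <- cmp$pairwise
      d$parameter <- report$stats$parameter[i]
      d
    }))
    if (!is.null(pw) && nrow(pw)) put(pw, "stats_pairwise")
  }
  if (!is.null(report$filter)) {
    put(report$filter[, setdiff(names(report$filter), "detail")], "wt_filter")
  }
  put(report$errors, "errors")
  index <- list(tables = files, provenance = report$provenance)
  index_path <- file.path(dir, "report_index.json")
  jsonlite::write_json(index, index_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(index_path)
}

#' Generate a bundled miniature synthetic cohort on disk
#'
#' Writes a small fully synthetic cohort - four groups of four animals,
#' one simulated day at a reduced sample rate - with traces, cognition-wall
#' entry logs, ground-truth JSON sidecars and a ready-to-run config,
#' exercising every reader in the package.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param sample_rate Trace sample rate (reduced from the 20/s acquisition
#'   rate to keep the fixture small).
#' @param duration_days Simulated days.
#' @param n_per_group Animals per group.
#' @return The config file path, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1, sample_rate = 2,
                              duration_days = 1, n_per_group = 4) {
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "entries"), showWarnings = FALSE)
  base <- homecage_sim_spec(duration_days = duration_days,
                            sample_rate = sample_rate, seed = seed)
  groups <- tibble::tibble(
    label = c("WT", "mdx5cv", "mdx52", "DMDnull"),
    n = n_per_group,
    effects = list(list(),
                   list(),
                   list(activity_rate_factor = 1.2),
                   list(bout_duration_factor = 0.7,
                        shelter_mean_shift = c(0, 0, -0.5))))
  cohort <- simulate_cohort(cohort_spec(groups, base, seed = seed),
                            include_trace = TRUE)
  schedule <- target_schedule()
  animals <- list()
  truth <- list()
  for (i in seq_len(nrow(cohort$animals))) {
    id <- cohort$animals$animal_id[i]
    grp <- cohort$animals$group[i]
    trace_path <- file.path("traces", paste0(id, ".csv"))
    write_trace(cohort$traces[[id]], file.path(dir, trace_path))
    agent <- agent_spec(p_correct = if (grp == "WT") 0.6 else 0.5,
                        perseveration_weight = 0.5,
                        entries_per_hour_profile = 12,
                        seed = child_seed(seed, 1000 + i))
    elog <- simulate_entry_log(agent, schedule)
    entry_path <- file.path("entries", paste0(id, ".csv"))
    write_entry_log(elog, file.path(dir, entry_path))
    animals[[i]] <- list(id = id, group = grp,
                         wt_of = if (grp == "WT") {
                           c("mdx5cv", "mdx52", "DMDnull")[(i - 1) %% 3 + 1]
                         },
                         trace = trace_path, entry_log = entry_path)
    ev <- cohort$events[[id]]
    truth[[id]] <- list(
      n_events = nrow(ev),
      n_movements = sum(ev$kind == "movement"),
      n_shelter_visits = sum(ev$kind == "shelter_visit"),
      group = grp)
  }
  cfg <- list(seed = seed, arena = "phenotyper", sample_rate = sample_rate,
              control_group = "WT",
              lightcycle = list(lights_on = "07:00", lights_off = "19:00",
                                t0 = "19:00"),
              entry_schedule = as.list(schedule$target),
              animals = animals)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg_path)
}
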