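#' Run the full instrumented-ARAT analysis
#'
#' End-to-end orchestration: segmentation of every task recording,
#' duration/jerk metrics, z-scores against the control cohort, section
#' summaries, the nonparametric comparison battery (control vs MS per
#' section and per phase; Friedman across sections on the
#' manipulation/transport/release z-scores with Holm post-hocs;
#' Kruskal-Wallis across impairment sub-groups on the subject-level
#' Z_Duration/Z_Jerk with Holm post-hocs; Spearman validity correlations
#' against ARAT, peg-test rate and intention tremor) and the clinical
#' clustering. Per-task failures are collected per (subject, item) without
#' aborting the cohort. With `tasks = NULL` and a supplied `clinical`
#' table, only the clinical blocks are produced and the sensor blocks are
#' marked absent; with neither, a cohort is simulated.
#'
#' @param tasks Tibble with columns `subject`, `group`, `item` and
#'   list-column `rec` (see [simulate_cohort()] or [read_imu_dir()]), or
#'   `NULL`.
#' @param clinical Clinical records tibble (see [ms_clinical()] /
#'   [simulate_cohort()]), or `NULL`.
#' @param n,items,seed Simulation settings used when `tasks` is `NULL` and
#'   no `clinical` table is given.
#' @param cfg A [segmentation_config()].
#' @param controls Group label of the control cohort.
#' @param k Number of impairment clusters.
#' @param out_dir Optional directory; writes `metrics.csv`, `z.csv`,
#'   `clusters.csv` and `report.json`.
#' @return An `arat_report` list.
#' @export
run_analysis <- function(tasks = NULL, clinical = NULL,
                         n = c(control = 12, mild = 12, moderate = 5,
                               severe = 4),
                         items = c(1, 5, 7, 11, 14, 17), seed = 1,
                         cfg = segmentation_config(), controls = "control",
                         k = 3, out_dir = NULL) {
  if (is.null(tasks) && is.null(clinical)) {
    sim <- simulate_cohort(n = n, items = items, seed = seed)
    tasks <- sim$tasks
    clinical <- sim$clinical
  }
  report <- list(
    config = list(
      theta = cfg$theta, omega_max_scope = cfg$omega_max_scope,
      gyro_cutoff = cfg$gyro_cutoff, merge_gap = cfg$merge_gap,
      peak_prominence = cfg$peak_prominence,
      accel_cutoff = cfg$accel_cutoff, interp = cfg$interp,
      jerk_log_base = "natural", seed = seed, k = k, controls = controls
    ),
    sensor_blocks_absent = is.null(tasks)
  )

  if (!is.null(tasks)) {
    seg_res <- map(seq_len(nrow(tasks)), function(i) {
      tryCatch(
        list(seg = segment_task(tasks$rec[[i]], cfg), error = NULL),
        iarat_error = function(e) list(seg = NULL, error = conditionMessage(e))
      )
    })
    failed <- map_chr(seg_res, ~ .x$error %||% NA_character_)
    report$errors <- tibble(
      subject = tasks$subject, item = tasks$item, message = failed
    ) |> filter(!is.na(.data$message))
    ok <- is.na(failed)
    tasks_ok <- tasks[ok, ]
    tasks_ok$seg <- map(seg_res[ok], "seg")
    metrics <- cohort_metrics(tasks_ok, cfg)
    ztab <- zscore_table(metrics, controls = controls)
    subj_z <- subject_zscores(metrics, controls = controls)
    sect <- section_summary(metrics, controls = controls)
    report$metrics <- metrics
    report$zscores <- ztab
    report$subject_zscores <- subj_z
    report$section_summary <- sect
    report$group_comparison <- compare_groups_by_section(sect, controls)
    report$phase_comparison <- compare_groups_by_phase(subj_z, controls)
    report$friedman_sections <- friedman_across_sections(sect, controls)
    report$subgroup_comparison <- compare_subgroups(subj_z, controls)
    if (!is.null(clinical)) {
      report$validity <- validity_correlations(subj_z, clinical, controls)
    }
  }

  if (!is.null(clinical)) {
    ms <- filter(clinical, .data$group != controls | !("group" %in% names(clinical)))
    feats <- intersect(c("arat", "nhpt_rate", "ftrs_sum"), names(ms))
    report$clustering <- cluster_impairment(ms, k = k, features = feats)
    by_col <- if ("impairment" %in% names(ms)) "impairment" else NULL
    report$clinical_summary <- cohort_summary(ms, by = by_col,
                                              variables = feats)
  }

  report <- structure(report, class = "arat_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

compare_groups_by_section <- function(sect, controls) {
  sect |>
    filter(.data$phase == "task") |>
    mutate(cohort = ifelse(.data$group == controls, "control", "ms")) |>
    group_by(.data$section, .data$parameter) |>
    summarise(
      test = list(mann_whitney(.data$mean_value[.data$cohort == "control"],
                               .data$mean_value[.data$cohort == "ms"])),
      .groups = "drop"
    ) |>
    tidy_test_column()
}

compare_groups_by_phase <- function(subj_z, controls) {
  subj_z |>
    filter(.data$phase != "task") |>
    mutate(cohort = ifelse(.data$group == controls, "control", "ms")) |>
    group_by(.data$phase, .data$parameter) |>
    summarise(
      test = list(mann_whitney(.data$mean_value[.data$cohort == "control"],
                               .data$mean_value[.data$cohort == "ms"])),
      .groups = "drop"
    ) |>
    tidy_test_column()
}

friedman_across_sections <- function(sect, controls) {
  ms <- filter(sect, .data$group != controls,
               .data$phase %in% c("manipulation", "transport", "release"))
  combos <- distinct(ms, .data$phase, .data$parameter)
  pmap(combos, function(phase, parameter) {
    wide <- ms |>
      filter(.data$phase == !!phase, .data$parameter == !!parameter) |>
      select("subject", "section", "z") |>
      tidyr::pivot_wider(names_from = "section", values_from = "z") |>
      select(-"subject")
    wide <- wide[, colSums(is.na(wide)) == 0, drop = FALSE]
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    # a within-subject comparison needs >= 2 sections and >= 2 subjects
    if (ncol(wide) < 2 || nrow(wide) < 2) return(NULL)
    ft <- friedman(wide)
    posthoc <- if (ft$p.value < 0.05 && ncol(wide) > 2) {
      pairs <- utils::combn(names(wide), 2)
      ph <- map(seq_len(ncol(pairs)), function(j) {
        sub <- friedman(wide[, pairs[, j]])
        tibble(group1 = pairs[1, j], group2 = pairs[2, j],
               p.value = sub$p.value)
      }) |> list_rbind()
      ph$p.adjusted <- holm_adjust(ph$p.value)
      ph
    } else {
      NULL
    }
    tibble(phase = phase, parameter = parameter,
           statistic = unname(ft$statistic), p.value = ft$p.value,
           n_blocks = unname(ft$n["n_blocks"]), k = unname(ft$n["k"]),
           posthoc = list(posthoc))
  }) |> list_rbind()
}

compare_subgroups <- function(subj_z, controls) {
  ms <- filter(subj_z, .data$group != controls, .data$phase == "task")
  combos <- distinct(ms, .data$parameter)
  pmap(combos, function(parameter) {
    sub <- filter(ms, .data$parameter == !!parameter)
    groups <- split(sub$z, sub$group)
    if (length(groups) < 2) return(NULL)
    kt <- kruskal_wallis(groups)
    posthoc <- if (kt$p.value < 0.05) pairwise_posthoc(groups) else NULL
    tibble(parameter = parameter, statistic = unname(kt$statistic),
           p.value = kt$p.value, posthoc = list(posthoc))
  }) |> list_rbind()
}

validity_correlations <- function(subj_z, clinical, controls) {
  ms_z <- subj_z |>
    filter(.data$group != controls) |>
    inner_join(clinical, by = c("subject", "group"))
  task_rows <- filter(ms_z, .data$phase == "task")
  manip_jerk <- filter(ms_z, .data$phase == "manipulation",
                       .data$parameter == "jerk")
  specs <- list(
    list(z = "duration", target = "arat"),
    list(z = "jerk", target = "arat"),
    list(z = "duration", target = "nhpt_rate"),
    list(z = "jerk", target = "nhpt_rate")
  )
  out <- map(specs, function(s) {
    sub <- filter(task_rows, .data$parameter == s$z)
    tst <- spearman(sub$z, sub[[s$target]])
    tibble(parameter = paste0("Z_", s$z), clinical_scale = s$target,
           r = unname(tst$statistic), p.value = tst$p.value,
           n = unname(tst$n))
  }) |> list_rbind()
  trem <- spearman(manip_jerk$z, manip_jerk$ftrs_intention)
  bind_rows(out, tibble(
    parameter = "Z_jerk_manipulation", clinical_scale = "ftrs_intention",
    r = unname(trem$statistic), p.value = trem$p.value,
    n = unname(trem$n)
  ))
}

tidy_test_column <- function(df) {
  df |>
    mutate(statistic = map_dbl(.data$test, ~ unname(.x$statistic)),
           p.value = map_dbl(.data$test, "p.value")) |>
    select(-"test")
}

#' @export
print.arat_report <- function(x, ...) {
  cat("<arat_report>\n")
  cat("  config: theta =", x$config$theta, "| scope =",
      x$config$omega_max_scope, "| seed =", x$config$seed, "\n")
  if (!is.null(x$metrics)) {
    cat("  tasks analysed:", nrow(distinct(x$metrics, .data$subject)),
        "subjects\n")
  }
  if (!is.null(x$errors) && nrow(x$errors) > 0) {
    cat("  failed cells:", nrow(x$errors), "\n")
  }
  if (!is.null(x$clustering)) {
    cat("  clusters:", paste(sort(table(x$clustering$labels$cluster),
                                  decreasing = TRUE), collapse = "/"), "\n")
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$metrics)) {
    readr::write_csv(report$metrics, file.path(out_dir, "metrics.csv"))
    readr::write_csv(as_tibble(report$zscores), file.path(out_dir, "z.csv"))
  }
  if (!is.null(report$clustering)) {
    readr::write_csv(report$clustering$labels,
                     file.path(out_dir, "clusters.csv"))
  }
  json <- report
  json$clustering <- if (!is.null(report$clustering)) {
    list(k = report$clustering$k, features = report$clustering$features,
         labels = report$clustering$labels,
         merge_heights = report$clustering$tree$height)
  }
  json$zscores <- NULL  # large; already on disk as z.csv
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(out_dir)
}
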