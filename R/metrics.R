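#' Normalized log-jerk smoothness index
#'
#' Dimensionless smoothness measure over a time window of gravity-free
#' global acceleration `a(t)`:
#' `JI = ln( mean||da/dt|| / mean||a|| * D )`,
#' where `D` is the window duration and the derivative is computed by
#' central finite differences (one-sided at the window edges). The ratio of
#' mean jerk to mean acceleration magnitude makes the index invariant to
#' amplitude scaling; multiplying by the duration makes it dimensionless.
#' Higher values indicate less smooth movement. Optional pre-smoothing of
#' the acceleration at `accel_cutoff` Hz is off by default.
#'
#' @param accel Tibble from [free_acceleration()] (columns `t`, `ax`, `ay`,
#'   `az`).
#' @param window Numeric `c(start, end)` in seconds.
#' @param accel_cutoff Optional low-pass cut-off (Hz) applied to each
#'   acceleration axis before differentiation.
#' @param rate Sampling rate, Hz; taken from the `rate` attribute of
#'   `accel` when available.
#' @return The jerk index (dimensionless scalar).
#' @export
#' @examples
#' # a pure 2 Hz sinusoid over 2 s has JI = ln(2*pi*2*2) = ln(8*pi)
#' t <- seq(0, 2, by = 0.02)
#' a <- tibble::tibble(t = t, ax = 0, ay = 0, az = sin(2 * pi * 2 * t))
#' jerk_index(a, c(0, 2), rate = 50)
jerk_index <- function(accel, window, accel_cutoff = NULL, rate = NULL) {
  rate <- rate %||% attr(accel, "rate")
  idx <- which(accel$t >= window[1] - 1e-12 & accel$t <= window[2] + 1e-12)
  if (length(idx) < 3) {
    iarat_abort("window must contain at least 3 samples",
                class = "iarat_length_error")
  }
  a <- as.matrix(accel[idx, c("ax", "ay", "az")])
  if (!is.null(accel_cutoff)) {
    a <- lowpass_zero_lag(a, rate = rate, cutoff = accel_cutoff, order = 4)
  }
  t <- accel$t[idx]
  jerk <- apply(a, 2, finite_diff, t = t)
  mean_j <- mean(sqrt(rowSums(jerk^2)))
  mean_a <- mean(sqrt(rowSums(a^2)))
  if (mean_a == 0) {
    iarat_abort("undefined jerk index: mean acceleration magnitude is zero",
                class = "iarat_undefined_metric_error")
  }
  D <- t[length(t)] - t[1]
  log(mean_j / mean_a * D)
}

# central differences, one-sided at the edges
finite_diff <- function(x, t) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d
}

#' Duration and jerk index per phase and whole task
#'
#' Computes, for every segmented sub-movement and for the whole task
#' (first onset to return termination), the duration and the
#' [jerk_index()]. Zero-length (or shorter than 3 samples) manipulation or
#' release phases get duration as segmented and an `NA` jerk index; they
#' are excluded from aggregates downstream.
#'
#' @param rec An [imu_recording()].
#' @param seg A `phase_segmentation` from [segment_task()].
#' @param cfg A [segmentation_config()]; `accel_cutoff` is forwarded to the
#'   jerk computation.
#' @return Tibble with columns `item`, `phase` (sub-movements plus
#'   `"task"`), `duration` (s), `jerk_index`.
#' @export
compute_metrics <- function(rec, seg, cfg = segmentation_config()) {
  fa <- attr(seg, "free_accel") %||% free_acceleration(rec)
  rate <- imu_rate(rec)
  ji_safe <- function(w) {
    if (diff(w) < 2.5 / rate) return(NA_real_)
    tryCatch(
      jerk_index(fa, w, accel_cutoff = cfg$accel_cutoff, rate = rate),
      iarat_error = function(e) NA_real_
    )
  }
  phases <- tibble(
    item = seg$item,
    phase = as.character(seg$phase),
    duration = seg$offset - seg$onset,
    jerk_index = map_dbl(seq_len(nrow(seg)),
                         ~ ji_safe(c(seg$onset[.x], seg$offset[.x])))
  )
  task_window <- c(min(seg$onset), max(seg$offset))
  bind_rows(
    phases,
    tibble(item = seg$item[1], phase = "task",
           duration = diff(task_window),
           jerk_index = ji_safe(task_window))
  )
}

#' Z-scores against control-group normative statistics
#'
#' For each cell (parameter, item, phase), the control cohort defines a
#' mean and standard deviation (n-1 denominator); every subject's value is
#' expressed as `Z = (value - control mean) / control SD`, the deviation
#' from normative data. A control cohort scored against itself therefore
#' has per-cell mean 0 and SD 1.
#'
#' @param cohort Long tibble with columns `subject`, `group`, `item`,
#'   `phase`, `parameter` (`"duration"` or `"jerk"`), `value` (see
#'   [cohort_metrics()]).
#' @param controls Group label identifying the control cohort.
#' @return The cohort tibble with an added `z` column; the per-cell control
#'   statistics are attached as attribute `control_stats` (a tibble with
#'   `parameter`, `item`, `phase`, `ctrl_mean`, `ctrl_sd`, `n_controls`).
#' @export
zscore_table <- function(cohort, controls = "control") {
  stats_tbl <- cohort |>
    filter(.data$group == controls, !is.na(.data$value)) |>
    group_by(.data$parameter, .data$item, .data$phase) |>
    summarise(ctrl_mean = mean(.data$value), ctrl_sd = stats::sd(.data$value),
              n_controls = dplyr::n(), .groups = "drop")
  degenerate <- filter(stats_tbl, .data$ctrl_sd == 0 | .data$n_controls < 2)
  if (nrow(degenerate) > 0) {
    iarat_abort(
      paste0("degenerate normative cell(s) (SD = 0 or n < 2): ",
             paste(sprintf("(%s, item %s, %s)", degenerate$parameter,
                           degenerate$item, degenerate$phase),
                   collapse = "; ")),
      class = "iarat_degenerate_normative_error"
    )
  }
  out <- cohort |>
    left_join(stats_tbl, by = c("parameter", "item", "phase")) |>
    mutate(z = (.data$value - .data$ctrl_mean) / .data$ctrl_sd) |>
    select(-"ctrl_mean", -"ctrl_sd", -"n_controls")
  structure(out, control_stats = stats_tbl,
            class = c("zscore_table", class(tibble())))
}

#' Subject-level aggregate z-scores
#'
#' For each subject, parameter and phase, the parameter is first averaged
#' across items (mean-then-z) and the mean is then z-scored against the
#' distribution of the same per-subject mean in the control cohort. The
#' `"task"` phase rows give the overall Z_Duration and Z_Jerk used in the
#' validity analysis.
#'
#' @inheritParams zscore_table
#' @return Tibble with columns `subject`, `group`, `phase`, `parameter`,
#'   `mean_value`, `z`.
#' @export
subject_zscores <- function(cohort, controls = "control") {
  means <- cohort |>
    filter(!is.na(.data$value)) |>
    group_by(.data$subject, .data$group, .data$phase, .data$parameter) |>
    summarise(mean_value = mean(.data$value), .groups = "drop")
  norms <- means |>
    filter(.data$group == controls) |>
    group_by(.data$phase, .data$parameter) |>
    summarise(ctrl_mean = mean(.data$mean_value),
              ctrl_sd = stats::sd(.data$mean_value), .groups = "drop")
  if (any(norms$ctrl_sd == 0)) {
    iarat_abort("degenerate normative SD in subject-level aggregation",
                class = "iarat_degenerate_normative_error")
  }
  means |>
    left_join(norms, by = c("phase", "parameter")) |>
    mutate(z = (.data$mean_value - .data$ctrl_mean) / .data$ctrl_sd) |>
    select(-"ctrl_mean", -"ctrl_sd")
}

#' Per-section summary of metrics or z-scores
#'
#' Adds the ARAT section (Grasp/Grip/Pinch/Gross) of each item and averages
#' the parameter over the section's member items, per subject, phase and
#' parameter; the section mean is then z-scored against the control
#' cohort's distribution of the same section mean. Sections with missing
#' items are averaged over the available items (their count is reported).
#'
#' @inheritParams zscore_table
#' @return Tibble with columns `subject`, `group`, `section`, `phase`,
#'   `parameter`, `mean_value`, `n_items`, `z`.
#' @export
section_summary <- function(cohort, controls = "control") {
  means <- cohort |>
    filter(!is.na(.data$value)) |>
    mutate(section = arat_section(.data$item)) |>
    group_by(.data$subject, .data$group, .data$section, .data$phase,
             .data$parameter) |>
    summarise(mean_value = mean(.data$value), n_items = dplyr::n_distinct(.data$item),
              .groups = "drop")
  norms <- means |>
    filter(.data$group == controls) |>
    group_by(.data$section, .data$phase, .data$parameter) |>
    summarise(ctrl_mean = mean(.data$mean_value),
              ctrl_sd = stats::sd(.data$mean_value), .groups = "drop")
  means |>
    left_join(norms, by = c("section", "phase", "parameter")) |>
    mutate(z = (.data$mean_value - .data$ctrl_mean) / .data$ctrl_sd) |>
    select(-"ctrl_mean", -"ctrl_sd")
}

#' Long-format cohort metrics table
#'
#' Stacks per-task [compute_metrics()] outputs for a whole cohort into the
#' long format consumed by [zscore_table()], [subject_zscores()] and
#' [section_summary()].
#'
#' @param tasks Tibble with columns `subject`, `group`, `item` and a
#'   list-column `metrics` of [compute_metrics()] outputs (or list-columns
#'   `rec` plus `seg` to compute them here).
#' @param cfg A [segmentation_config()], used when metrics must be computed.
#' @return Long tibble with columns `subject`, `group`, `item`, `phase`,
#'   `parameter`, `value`.
#' @export
cohort_metrics <- function(tasks, cfg = segmentation_config()) {
  if (!"metrics" %in% names(tasks)) {
    tasks$metrics <- map2(tasks$rec, tasks$seg,
                          ~ compute_metrics(.x, .y, cfg))
  }
  tasks |>
    select("subject", "group", "metrics") |>
    tidyr::unnest("metrics") |>
    tidyr::pivot_longer(c("duration", "jerk_index"), names_to = "parameter",
                        values_to = "value") |>
    mutate(parameter = ifelse(.data$parameter == "jerk_index", "jerk",
                              .data$parameter))
}
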