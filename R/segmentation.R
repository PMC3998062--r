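#' Segmentation configuration
#'
#' Parameters controlling threshold-based segmentation of one ARAT task.
#'
#' @param theta Relative threshold as a fraction of the maximum angular
#'   speed; the calibrated operating value is 0.25, from the family
#'   {0.15, 0.20, 0.25, 0.30}.
#' @param gyro_cutoff Low-pass cut-off for the gyroscope axes, Hz.
#' @param omega_max_scope `"global"` (threshold anchored to the task-wide
#'   maximum of the angular-speed norm) or `"per_portion"` (each movement
#'   window uses its own maximum).
#' @param merge_gap Runs of supra-threshold samples closer than this gap
#'   (seconds) are merged before lobe selection.
#' @param peak_prominence Minimum prominence (m/s^2) for the vertical
#'   acceleration peak that terminates the return phase.
#' @param manual_windows Optional data frame with columns `start`, `end`:
#'   a user-supplied rough partition that overrides automatic lobe
#'   detection (the semi-automated mode).
#' @param interp Use sub-sample linear interpolation of threshold crossings
#'   (default). `FALSE` snaps onsets/offsets to the first sample beyond the
#'   threshold, which adds up to one sample of systematic bias.
#' @param accel_cutoff Optional low-pass cut-off (Hz) applied to the
#'   gravity-free acceleration before jerk computation; `NULL` (default)
#'   disables smoothing.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(theta = 0.25, gyro_cutoff = 2.5,
                                omega_max_scope = c("global", "per_portion"),
                                merge_gap = 0.05, peak_prominence = 0.5,
                                manual_windows = NULL, interp = TRUE,
                                accel_cutoff = NULL) {
  if (!(theta > 0 && theta < 1)) {
    iarat_abort("theta must be in (0, 1)", class = "iarat_parameter_error")
  }
  if (merge_gap < 0) {
    iarat_abort("merge_gap must be >= 0", class = "iarat_parameter_error")
  }
  structure(
    list(theta = theta, gyro_cutoff = gyro_cutoff,
         omega_max_scope = match.arg(omega_max_scope),
         merge_gap = merge_gap, peak_prominence = peak_prominence,
         manual_windows = manual_windows, interp = interp,
         accel_cutoff = accel_cutoff),
    class = "segmentation_config"
  )
}

# runs of consecutive TRUE values -> tibble(start_idx, end_idx)
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(start_idx = starts[r$values], end_idx = ends[r$values])
}

#' Detect movement windows from the angular-speed profile
#'
#' Automated replacement of the manual rough tri-partition: samples with
#' angular speed above `theta * max(omega)` form runs; runs separated by
#' less than `merge_gap` seconds are merged; the `n_lobes` longest runs
#' (ties broken toward the earlier run) are kept in temporal order and each
#' is expanded to the midpoint between neighbouring retained runs (the
#' first to the recording start, the last to its end). A user-supplied
#' `manual_windows` in the config overrides detection.
#'
#' @param omega Tibble from [angular_speed()].
#' @param cfg A [segmentation_config()].
#' @param n_lobes Number of movement lobes expected: 3 for items 1-16,
#'   2 for items 17-19.
#' @return Tibble with columns `window`, `start`, `end`, `run_start`,
#'   `run_end` (seconds).
#' @export
detect_movement_windows <- function(omega, cfg = segmentation_config(),
                                    n_lobes = 3) {
  if (!is.null(cfg$manual_windows)) {
    mw <- as_tibble(cfg$manual_windows)
    return(tibble(window = seq_len(nrow(mw)), start = mw$start, end = mw$end,
                  run_start = mw$start, run_end = mw$end))
  }
  t <- omega$t
  w <- omega$omega
  thr <- cfg$theta * max(w)
  runs <- true_runs(w > thr)
  if (nrow(runs) > 1) {
    # merge runs whose inter-run gap is shorter than merge_gap
    keep <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      gap <- t[runs$start_idx[i]] - t[last$end_idx]
      if (gap < cfg$merge_gap) {
        keep[[length(keep)]]$end_idx <- runs$end_idx[i]
      } else {
        keep[[length(keep) + 1]] <- runs[i, ]
      }
    }
    runs <- list_rbind(keep)
  }
  if (nrow(runs) < n_lobes) {
    iarat_abort(
      sprintf("insufficient movement lobes: found %d supra-threshold run(s), need %d",
              nrow(runs), n_lobes),
      class = "iarat_segmentation_error"
    )
  }
  dur <- t[runs$end_idx] - t[runs$start_idx]
  sel <- order(-dur, runs$start_idx)[seq_len(n_lobes)]
  runs <- runs[sort(sel), ]
  rs <- t[runs$start_idx]
  re <- t[runs$end_idx]
  start <- c(t[1], (re[-n_lobes] + rs[-1]) / 2)
  end <- c((re[-n_lobes] + rs[-1]) / 2, t[length(t)])
  tibble(window = seq_len(n_lobes), start = start, end = end,
         run_start = rs, run_end = re)
}

#' Onset/offset of one movement lobe within a window
#'
#' The onset is where the angular speed first exceeds `threshold` inside the
#' window and the offset where it next falls below it. By default both
#' instants are refined by linear interpolation between the bracketing
#' samples; with `interp = FALSE` they snap to the first sample beyond the
#' threshold. When the signal never falls back below the threshold the
#' offset is clamped to the window end with a warning.
#'
#' @param omega Tibble from [angular_speed()].
#' @param window Numeric `c(start, end)` in seconds (or a one-row window
#'   tibble from [detect_movement_windows()]).
#' @param threshold Absolute threshold, deg/s.
#' @param interp Sub-sample interpolation of the crossing (default `TRUE`).
#' @return Named numeric `c(onset, offset)` in seconds.
#' @export
phase_boundaries <- function(omega, window, threshold, interp = TRUE) {
  if (is.data.frame(window)) window <- c(window$start[1], window$end[1])
  idx <- which(omega$t >= window[1] - 1e-12 & omega$t <= window[2] + 1e-12)
  if (length(idx) == 0) {
    iarat_abort("empty window", class = "iarat_parameter_error")
  }
  t <- omega$t[idx]
  w <- omega$omega[idx]
  i0 <- which(w > threshold)[1]
  if (is.na(i0)) {
    iarat_abort(
      sprintf("phase_below_threshold: no sample above %.4g deg/s in window [%.3f, %.3f]",
              threshold, window[1], window[2]),
      class = c("iarat_phase_below_threshold", "iarat_segmentation_error"),
      window = window
    )
  }
  cross_time <- function(i_after, rising) {
    if (!interp || i_after == 1) return(t[i_after])
    y0 <- w[i_after - 1]
    y1 <- w[i_after]
    if ((rising && y0 > threshold) || (!rising && y0 < threshold) || y1 == y0) {
      return(t[i_after])
    }
    t[i_after - 1] + (threshold - y0) / (y1 - y0) * (t[i_after] - t[i_after - 1])
  }
  onset <- cross_time(i0, rising = TRUE)
  below <- which(w < threshold & seq_along(w) > i0)
  if (length(below) == 0) {
    iarat_warn(sprintf(
      "angular speed never fell below threshold before window end; offset clamped to %.3f s",
      window[2]
    ))
    offset <- t[length(t)]
  } else {
    offset <- cross_time(below[1], rising = FALSE)
  }
  c(onset = onset, offset = offset)
}

# local maxima of y with topographic prominence >= prom; returns indices
peaks_with_prominence <- function(y, prom) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    h <- y[i]
    left <- y[1:i]
    hi_l <- which(left > h)
    lmin <- if (length(hi_l) == 0) min(left) else min(left[max(hi_l):i])
    right <- y[i:n]
    hi_r <- which(right > h)
    rmin <- if (length(hi_r) == 0) min(right) else min(right[1:min(hi_r)])
    keep[k] <- (h - max(lmin, rmin)) >= prom
  }
  cand[keep]
}

#' Termination of the return phase from the vertical acceleration
#'
#' The hand-table contact closing the task is taken as the last local
#' maximum of the gravity-free vertical acceleration, with prominence at
#' least `cfg$peak_prominence`, occurring after the return onset. If no
#' qualifying peak exists the supplied `fallback` (normally the threshold
#' offset of the return lobe) is returned with a warning.
#'
#' @param vertical Tibble from [free_acceleration()] (uses the `vertical`
#'   column), or any tibble with columns `t` and `vertical`.
#' @param return_onset Onset of the return phase, seconds.
#' @param cfg A [segmentation_config()].
#' @param fallback Time to return when no qualifying peak is found.
#' @return Time of the contact instant, seconds.
#' @export
return_termination <- function(vertical, return_onset,
                               cfg = segmentation_config(), fallback = NA_real_) {
  idx <- which(vertical$t >= return_onset - 1e-12)
  if (length(idx) == 0) {
    iarat_abort("return_onset is beyond the recording",
                class = "iarat_parameter_error")
  }
  y <- vertical$vertical[idx]
  pk <- peaks_with_prominence(y, cfg$peak_prominence)
  if (length(pk) == 0) {
    iarat_warn("no vertical-acceleration peak after return onset; falling back to threshold offset")
    return(fallback)
  }
  vertical$t[idx[pk[length(pk)]]]
}

#' Segment one ARAT task into sub-movements
#'
#' Composes [angular_speed()], [free_acceleration()],
#' [detect_movement_windows()], [phase_boundaries()] and
#' [return_termination()]. Items 1-16 yield the five phases reaching,
#' manipulation, transport, release and return, with manipulation filling
#' the gap between reaching offset and transport onset and release the gap
#' between transport offset and return onset. Items 17-19 (Gross section)
#' yield transport and return only, with the dwell at the target absorbed
#' into transport so the two phases stay contiguous. The return phase ends
#' at the last vertical-acceleration peak (hand-table contact).
#'
#' @param rec An [imu_recording()] whose metadata carries the item number.
#' @param cfg A [segmentation_config()].
#' @return A `phase_segmentation`: tibble with columns `item`, `phase`,
#'   `onset`, `offset` (seconds), carrying the angular-speed and
#'   free-acceleration series and the config as attributes.
#' @export
segment_task <- function(rec, cfg = segmentation_config()) {
  item <- imu_meta(rec)$item
  if (is.na(item)) {
    iarat_abort("recording has no ARAT item metadata",
                class = "iarat_parameter_error")
  }
  n_lobes <- if (item >= 17) 2L else 3L
  omega <- angular_speed(rec, cfg)
  fa <- free_acceleration(rec)
  res <- tryCatch(
    segment_task_impl(omega, fa, item, n_lobes, cfg),
    iarat_segmentation_error = function(e) {
      iarat_abort(paste0("item ", item, ": ", conditionMessage(e)),
                  class = class(e)[1])
    }
  )
  structure(
    res,
    item = item, config = cfg, omega = omega, free_accel = fa,
    class = c("phase_segmentation", class(tibble()))
  )
}

segment_task_impl <- function(omega, fa, item, n_lobes, cfg) {
  windows <- detect_movement_windows(omega, cfg, n_lobes)
  omega_max <- max(omega$omega)
  bounds <- map(seq_len(n_lobes), function(i) {
    wmax <- if (cfg$omega_max_scope == "global") {
      omega_max
    } else {
      max(omega$omega[omega$t >= windows$start[i] & omega$t <= windows$end[i]])
    }
    phase_boundaries(omega, c(windows$start[i], windows$end[i]),
                     threshold = cfg$theta * wmax, interp = cfg$interp)
  })
  on <- map_dbl(bounds, 1)
  off <- map_dbl(bounds, 2)
  term <- return_termination(fa, on[n_lobes], cfg, fallback = off[n_lobes])
  if (n_lobes == 3L) {
    tibble(
      item = item,
      phase = factor(phase_levels(), levels = phase_levels()),
      onset = c(on[1], off[1], on[2], off[2], on[3]),
      offset = c(off[1], on[2], off[2], on[3], term)
    )
  } else {
    tibble(
      item = item,
      phase = factor(c("transport", "return"), levels = phase_levels()),
      onset = c(on[1], on[2]),
      offset = c(on[2], term)
    )
  }
}

phase_levels <- function() {
  c("reaching", "manipulation", "transport", "release", "return")
}

#' Validate a phase segmentation
#'
#' Checks phase order, contiguity and non-overlap; manipulation and release
#' may have zero length, every other phase must have onset < offset.
#'
#' @param seg A `phase_segmentation` (or a tibble with columns `phase`,
#'   `onset`, `offset`).
#' @return `seg`, invisibly; aborts on violation.
#' @export
validate_segmentation <- function(seg) {
  expected <- intersect(phase_levels(), as.character(seg$phase))
  if (!identical(as.character(seg$phase), expected)) {
    iarat_abort("phases out of order", class = "iarat_validation_error")
  }
  zero_ok <- seg$phase %in% c("manipulation", "release")
  if (any(seg$offset < seg$onset - 1e-9)) {
    iarat_abort("phase offset precedes onset", class = "iarat_validation_error")
  }
  if (any(!zero_ok & (seg$offset - seg$onset) <= 0)) {
    iarat_abort("zero-length phase outside manipulation/release",
                class = "iarat_validation_error")
  }
  if (nrow(seg) > 1 &&
      max(abs(seg$onset[-1] - seg$offset[-nrow(seg)])) > 1e-9) {
    iarat_abort("phases are not contiguous", class = "iarat_validation_error")
  }
  invisible(seg)
}

#' Extract the five comparison instants from a segmentation
#'
#' Returns the onset (T0) and termination (T1) instants that the accuracy
#' analysis compares against an external reference: T0/T1 of reaching and
#' transport and T0 of return (transport and return only for Gross items).
#'
#' @param seg A `phase_segmentation`.
#' @return Tibble with columns `instant`, `time`.
#' @export
segmentation_instants <- function(seg) {
  ph <- function(p, col) seg[[col]][seg$phase == p]
  if ("reaching" %in% seg$phase) {
    tibble(
      instant = c("T0_reaching", "T1_reaching", "T0_transport",
                  "T1_transport", "T0_return"),
      time = c(ph("reaching", "onset"), ph("reaching", "offset"),
               ph("transport", "onset"), ph("transport", "offset"),
               ph("return", "onset"))
    )
  } else {
    tibble(
      instant = c("T0_transport", "T0_return"),
      time = c(ph("transport", "onset"), ph("return", "onset"))
    )
  }
}

#' Timing-error analysis across the threshold family
#'
#' Summarizes absolute timing errors between segmentation instants and
#' reference instants, per instant type and threshold, in the layout of the
#' sensor-vs-gold-standard comparison: mean and SD of `|t_imu - t_ref|`
#' plus an `All instants` row per threshold. The threshold minimizing the
#' all-instants mean error is reported as an attribute (`best_threshold`)
#' — the selection rule that fixes the operating threshold.
#'
#' @param paired Tibble with columns `threshold`, `instant`, `t_imu`,
#'   `t_ref` (one row per compared instant).
#' @return Tibble of class `error_table` with columns `instant`,
#'   `threshold`, `mean_abs_error`, `sd_abs_error`, `n`.
#' @export
threshold_error_analysis <- function(paired) {
  if (!is.data.frame(paired) || nrow(paired) == 0) {
    iarat_abort("empty pairing", class = "iarat_parameter_error")
  }
  paired <- mutate(paired, abs_err = abs(.data$t_imu - .data$t_ref))
  per <- paired |>
    group_by(.data$instant, .data$threshold) |>
    summarise(mean_abs_error = mean(.data$abs_err),
              sd_abs_error = stats::sd(.data$abs_err),
              n = dplyr::n(), .groups = "drop")
  all <- paired |>
    group_by(.data$threshold) |>
    summarise(mean_abs_error = mean(.data$abs_err),
              sd_abs_error = stats::sd(.data$abs_err),
              n = dplyr::n(), .groups = "drop") |>
    mutate(instant = "All instants", .before = 1)
  out <- bind_rows(per, all)
  best <- all$threshold[which.min(all$mean_abs_error)]
  structure(out, best_threshold = best,
            class = c("error_table", class(tibble())))
}

#' Segment a set of tasks under each threshold and pair with references
#'
#' Convenience wrapper building the input of [threshold_error_analysis()]:
#' every task is segmented once per threshold and its instants are joined
#' with the task's reference instants (e.g. from
#' [simulate_marker_oracle()]).
#'
#' @param tasks Tibble with list-columns `rec` ([imu_recording()]) and
#'   `ref` (tibble `instant`, `time`).
#' @param cfg Base [segmentation_config()]; `theta` is overridden per
#'   threshold.
#' @param thresholds Numeric vector of threshold fractions.
#' @return Tibble with columns `task`, `threshold`, `instant`, `t_imu`,
#'   `t_ref`.
#' @export
sweep_thresholds <- function(tasks, cfg = segmentation_config(),
                             thresholds = c(0.15, 0.20, 0.25, 0.30)) {
  grid <- tidyr::expand_grid(task = seq_len(nrow(tasks)), theta = thresholds)
  pmap(grid, function(task, theta) {
    cfg_t <- cfg
    cfg_t$theta <- theta
    seg <- segment_task(tasks$rec[[task]], cfg_t)
    inst <- segmentation_instants(seg)
    ref <- tasks$ref[[task]]
    inner_join(inst, ref, by = "instant", suffix = c("_imu", "_ref")) |>
      mutate(task = task, threshold = theta, .before = 1) |>
      rename(t_imu = "time_imu", t_ref = "time_ref")
  }) |>
    list_rbind()
}
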