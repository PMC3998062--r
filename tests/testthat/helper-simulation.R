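# shared simulation settings for the test suite

# sensor noise and tremor off; kinematic draws still random
noise_free_spec <- function(group = "control", ...) {
  simulation_spec(group, noise_accel = 0, noise_gyro = 0, tremor_amp = 0, ...)
}

# fully deterministic reference movement: group means, no noise, no tremor
deterministic_spec <- function(group = "control", ...) {
  sp <- simulation_spec(group, noise_accel = 0, noise_gyro = 0,
                        tremor_amp = 0, ...)
  sp$phase_duration_sd[] <- 0
  sp
}

# a minimal hand-built recording: stationary sensor, identity orientation
stationary_recording <- function(n = 50, rate = 50, item = 1) {
  imu_recording(
    tibble::tibble(
      t = (seq_len(n) - 1) / rate,
      ax = 0, ay = 0, az = 9.81,
      gx = 0, gy = 0, gz = 0,
      r11 = 1, r12 = 0, r13 = 0,
      r21 = 0, r22 = 1, r23 = 0,
      r31 = 0, r32 = 0, r33 = 1
    ),
    rate = rate, item = item, group = "control", subject = "T01"
  )
}

# replace the gyro/accel streams of a template recording
with_signals <- function(rec, gx = NULL, gy = NULL, gz = NULL, az = NULL) {
  d <- tibble::as_tibble(rec)
  if (!is.null(gx)) d$gx <- gx
  if (!is.null(gy)) d$gy <- gy
  if (!is.null(gz)) d$gz <- gz
  if (!is.null(az)) d$az <- az
  meta <- imu_meta(rec)
  imu_recording(d, rate = imu_rate(rec), subject = meta$subject,
                group = meta$group, arm = meta$arm, item = meta$item)
}

# expected instants of a 3-lobe ground truth at a given threshold/scope
expected_instants <- function(gt, theta, scope = "global") {
  ac <- analytic_crossings(gt, theta, scope)
  if (nrow(ac) == 3) {
    c(ac$onset[1], ac$offset[1], ac$onset[2], ac$offset[2], ac$onset[3])
  } else {
    c(ac$onset[1], ac$onset[2])
  }
}

segment_cohort <- function(tasks, cfg = segmentation_config()) {
  tasks$seg <- lapply(tasks$rec, function(r) {
    suppressWarnings(segment_task(r, cfg))
  })
  tasks
}
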