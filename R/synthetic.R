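# minimum-jerk speed bell: shape(tau) = 16 tau^2 (1-tau)^2, peak 1 at tau = 1/2
mj_shape <- function(tau) ifelse(tau > 0 & tau < 1, 16 * tau^2 * (1 - tau)^2, 0)

# analytic d shape / d tau
mj_dshape <- function(tau) {
  ifelse(tau > 0 & tau < 1, 32 * tau * (1 - tau) * (1 - 2 * tau), 0)
}

# fraction of the lobe before the theta-crossing: solve 16 t^2 (1-t)^2 = c
mj_crossing_fraction <- function(c) (1 - sqrt(1 - sqrt(c))) / 2

K_ON <- mj_crossing_fraction(0.25)        # 0.1464466
K_WIDTH <- 1 - 2 * K_ON                   # 0.7071068: crossing-to-crossing span

#' Simulation specification for one severity group
#'
#' Defines the kinematic and sensor parameters of the synthetic ARAT task
#' generator. Phase-duration means are expressed in "segmented" time: the
#' generator sizes each movement lobe so that its 0.25-threshold
#' crossing-to-crossing span matches the target, and places the inter-lobe
#' dwells so the manipulation/release gaps match theirs. Control defaults
#' are the published control phase durations (reaching 0.45 s,
#' manipulation 0.14 s, transport 0.66 s, release 0.21 s, return 0.67 s);
#' impaired groups scale the dwell-dominated phases most (severe
#' manipulation 2.74x control, matching the reported 174% median duration
#' increase) and add intention tremor.
#'
#' @param group `"control"`, `"mild"`, `"moderate"` or `"severe"`.
#' @param phase_duration Named means (s) for reaching, manipulation,
#'   transport, release, return.
#' @param phase_duration_sd Named within-subject SDs (s); default 10% of
#'   the mean.
#' @param peak_speed Named peak angular speeds (deg/s) of the reaching,
#'   transport and return lobes.
#' @param dwell_gross Dwell (s) between the two lobes of Gross items.
#' @param tremor_freq Tremor band, Hz.
#' @param tremor_amp Tremor acceleration amplitude, m/s^2; an intention
#'   envelope ramps it in over the last 30% of each object-directed lobe
#'   and holds it through the manipulation and release dwells.
#' @param noise_accel,noise_gyro Sensor noise SDs (m/s^2, deg/s).
#' @param impact_amp Amplitude of the vertical hand-table impact
#'   transient, m/s^2.
#' @param subject_sd Between-subject multiplicative SD on phase-duration
#'   means (log scale), used by [simulate_cohort()].
#' @param speed_scale Hand speed per unit angular speed, (m/s)/(deg/s).
#' @param rate Sampling rate, Hz.
#' @return A list of class `simulation_spec`.
#' @export
#' @examples
#' simulation_spec("severe")$phase_duration
simulation_spec <- function(group = c("control", "mild", "moderate", "severe"),
                            phase_duration = NULL, phase_duration_sd = NULL,
                            peak_speed = NULL, dwell_gross = 0.20,
                            tremor_freq = c(3.5, 5), tremor_amp = NULL,
                            noise_accel = 0.05, noise_gyro = 1.0,
                            impact_amp = 8, subject_sd = 0.08,
                            speed_scale = 0.0035, rate = 50) {
  group <- match.arg(group)
  ctrl <- c(reaching = 0.45, manipulation = 0.14, transport = 0.66,
            release = 0.21, return = 0.67)
  mult <- switch(group,
    control  = c(1, 1, 1, 1, 1),
    # mild = the published sub-movement durations of MS subjects with a
    # maximum (normal) ARAT score
    mild     = c(0.46, 0.30, 0.77, 0.28, 0.68) / ctrl,
    moderate = c(1.10, 2.40, 1.30, 1.50, 1.10),
    severe   = c(1.20, 2.74, 1.50, 1.80, 1.25)
  )
  phase_duration <- phase_duration %||% setNames(ctrl * mult, names(ctrl))
  phase_duration_sd <- phase_duration_sd %||% 0.10 * phase_duration
  speed_mult <- switch(group, control = 1, mild = 0.95, moderate = 0.85,
                       severe = 0.75)
  peak_speed <- peak_speed %||%
    (c(reaching = 250, transport = 200, return = 250) * speed_mult)
  tremor_amp <- tremor_amp %||%
    switch(group, control = 0, mild = 0.3, moderate = 0.8, severe = 1.5)
  if (any(phase_duration < 0) || any(phase_duration_sd < 0)) {
    iarat_abort("durations must be positive and SDs non-negative",
                class = "iarat_parameter_error")
  }
  structure(
    list(group = group, phase_duration = phase_duration,
         phase_duration_sd = phase_duration_sd, peak_speed = peak_speed,
         dwell_gross = dwell_gross, tremor_freq = tremor_freq,
         tremor_amp = tremor_amp, noise_accel = noise_accel,
         noise_gyro = noise_gyro, impact_amp = impact_amp,
         subject_sd = subject_sd, speed_scale = speed_scale, rate = rate),
    class = "simulation_spec"
  )
}

# positive draw; dwells may be exactly 0 only when sd == 0
draw_duration <- function(mean, sd, floor = 0.02) {
  if (sd == 0) return(mean)
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x > floor) return(list(value = x, resampled = i - 1L))
  }
  iarat_abort("could not draw a positive phase duration",
              class = "iarat_parameter_error")
}

#' Simulate one ARAT task recording with ground truth
#'
#' Builds the angular-speed profile as 3 (items 1-16) or 2 (items 17-19)
#' minimum-jerk speed lobes separated by manipulation/release dwells,
#' integrates it into a consistent wrist orientation trajectory (rotation
#' about the global x axis, so the gyroscope reading and the rotation
#' matrices describe the same motion exactly), constructs a matching
#' gravity-free global acceleration with a hand-table impact transient at
#' the end of the return lobe, adds intention tremor and sensor noise, and
#' maps everything into the sensor frame with gravity added back.
#'
#' @param spec A [simulation_spec()].
#' @param item ARAT item number, 1-19.
#' @param seed Optional integer; when given the output is a deterministic
#'   function of (spec, item, seed).
#' @param subject,arm Metadata forwarded to the recording.
#' @return List with elements `rec` (an [imu_recording()]) and `gt` (a
#'   `ground_truth` list: lobe geometry, phase boundaries in segmented
#'   time, impact time, tremor parameters).
#' @export
#' @examples
#' sim <- simulate_task(simulation_spec("control"), item = 1, seed = 42)
#' sim$gt$boundaries
simulate_task <- function(spec, item = 1, seed = NULL, subject = NA_character_,
                          arm = "dominant") {
  if (!is.null(seed)) set.seed(seed)
  item <- as.integer(item)
  if (item < 1 || item > 19) {
    iarat_abort("item must be in 1..19", class = "iarat_parameter_error")
  }
  gross <- item >= 17L
  resampled <- 0L
  dd <- function(p) {
    d <- draw_duration(spec$phase_duration[[p]], spec$phase_duration_sd[[p]])
    if (is.list(d)) {
      resampled <<- resampled + d$resampled
      d$value
    } else {
      d
    }
  }
  rate <- spec$rate
  if (!gross) {
    D <- c(reaching = dd("reaching"), manipulation = dd("manipulation"),
           transport = dd("transport"), release = dd("release"),
           return = dd("return"))
    lobe_names <- c("reaching", "transport", "return")
    peaks <- spec$peak_speed[c("reaching", "transport", "return")]
    signs <- c(1, 1, -1)
    dirs <- rbind(c(0.5, 0, 0.8660254),   # reach: up and forward
                  c(0.8660254, 0, 0.5),   # transport: mostly forward
                  c(0.5, 0, -0.8660254))  # return: down and back
  } else {
    D <- c(transport = dd("transport"), return = dd("return"))
    lobe_names <- c("transport", "return")
    peaks <- spec$peak_speed[c("transport", "return")]
    signs <- c(1, -1)
    dirs <- rbind(c(0.5, 0, 0.8660254), c(0.5, 0, -0.8660254))
  }
  amp <- unname(pmax(peaks * (1 + stats::rnorm(length(peaks), 0, 0.05)), 1))
  # lobe geometry is laid out in segmented time at the operating threshold
  # (0.25 of the task-global peak): each lobe's crossing fraction depends on
  # its own peak relative to the largest one, so the drawn phase durations
  # are exactly what default segmentation measures
  frac <- mj_crossing_fraction(pmin(0.25 * max(amp) / amp, 0.999))
  if (!gross) {
    L <- c(D[["reaching"]] / (1 - 2 * frac[1]),
           D[["transport"]] / (1 - 2 * frac[2]),
           D[["return"]] / (1 - frac[3]))
    # dwell targets are the pauses between lobe supports: the speed norm
    # rests near zero for that long, so it dips cleanly below every
    # threshold in the family and crossings stay uncontaminated by the
    # neighbouring lobe. (The segmented manipulation/release durations
    # additionally include the sub-threshold lobe tails.) An explicitly
    # requested zero dwell instead collapses the two crossings onto each
    # other, the degenerate contiguity case.
    dwell_target <- c(D[["manipulation"]], D[["release"]])
    gap_collapse <- c(-frac[1] * L[1] - frac[2] * L[2],
                      -frac[2] * L[2] - frac[3] * L[3])
    gap <- ifelse(dwell_target > 0, dwell_target, gap_collapse)
  } else {
    L <- c(D[["transport"]] / (1 - 2 * frac[1]),
           D[["return"]] / (1 - frac[2]))
    gap <- spec$dwell_gross
  }
  start <- 0.5 + c(0, cumsum(L[-length(L)] + gap))
  t_impact <- start[length(L)] + L[length(L)]
  n <- ceiling((t_impact + 0.5) * rate) + 1
  t <- (seq_len(n) - 1) / rate

  # signed angular speed about the global x axis, plus its hand kinematics
  omega_signed <- numeric(n)
  accel <- matrix(0, n, 3)
  for (l in seq_along(L)) {
    tau <- (t - start[l]) / L[l]
    omega_signed <- omega_signed + signs[l] * amp[l] * mj_shape(tau)
    dvdt <- spec$speed_scale * amp[l] * mj_dshape(tau) / L[l]
    accel <- accel + outer(dvdt, dirs[l, ])
  }
  # hand-table contact: narrow vertical transient at the return lobe end
  accel[, 3] <- accel[, 3] +
    spec$impact_amp * exp(-(t - t_impact)^2 / (2 * 0.03^2))

  # analytic 0.25 crossings define the segmented-time phase boundaries
  on <- start + frac * L
  off <- start + (1 - frac) * L
  if (!gross) {
    boundaries <- tibble(
      phase = phase_levels(),
      onset = c(on[1], off[1], on[2], off[2], on[3]),
      offset = c(off[1], on[2], off[2], on[3], t_impact)
    )
  } else {
    boundaries <- tibble(
      phase = c("transport", "return"),
      onset = c(on[1], on[2]),
      offset = c(on[2], t_impact)
    )
  }

  # intention tremor: ramp over the last 30% of each object-directed lobe,
  # full amplitude through the following dwell
  tremor_freq <- stats::runif(1, spec$tremor_freq[1], spec$tremor_freq[2])
  tremor_phase <- stats::runif(1, 0, 2 * pi)
  if (spec$tremor_amp > 0) {
    env <- numeric(n)
    n_dwell <- length(L) - 1
    for (l in seq_len(n_dwell)) {
      ramp0 <- start[l] + 0.7 * L[l]
      ramp1 <- start[l] + L[l]
      env <- pmax(env, pmin(pmax((t - ramp0) / (ramp1 - ramp0), 0), 1) *
                    (t < on[l + 1]))
    }
    u <- c(0.6, 0.3, 0.7416198)  # fixed oblique unit vector
    trem <- spec$tremor_amp * env *
      sin(2 * pi * tremor_freq * t + tremor_phase)
    accel <- accel + outer(trem, u)
  }

  # orientation: rotation about the global x axis by the integrated angle,
  # so gyro (sensor frame) = (omega_signed, 0, 0) exactly
  phi <- cumsum(omega_signed) / rate * pi / 180
  cphi <- cos(phi)
  sphi <- sin(phi)
  f_global <- accel
  f_global[, 3] <- f_global[, 3] + GRAVITY
  # f_sensor = R' f_global with R = Rx(phi)
  fx <- f_global[, 1]
  fy <- cphi * f_global[, 2] + sphi * f_global[, 3]
  fz <- -sphi * f_global[, 2] + cphi * f_global[, 3]
  gyro <- cbind(omega_signed, 0, 0)
  if (spec$noise_accel > 0) {
    fx <- fx + stats::rnorm(n, 0, spec$noise_accel)
    fy <- fy + stats::rnorm(n, 0, spec$noise_accel)
    fz <- fz + stats::rnorm(n, 0, spec$noise_accel)
  }
  if (spec$noise_gyro > 0) {
    gyro <- gyro + matrix(stats::rnorm(3 * n, 0, spec$noise_gyro), n, 3)
  }
  rec <- imu_recording(
    tibble(
      t = t, ax = fx, ay = fy, az = fz,
      gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
      r11 = 1, r12 = 0, r13 = 0,
      r21 = 0, r22 = cphi, r23 = -sphi,
      r31 = 0, r32 = sphi, r33 = cphi
    ),
    rate = rate, subject = subject, group = spec$group, arm = arm, item = item
  )
  gt <- structure(
    list(
      item = item, group = spec$group,
      lobes = tibble(lobe = lobe_names, start = start, duration = L,
                     peak = unname(amp), sign = signs),
      boundaries = boundaries, impact = t_impact,
      tremor_amp = spec$tremor_amp, tremor_freq = tremor_freq,
      accel_global = tibble(t = t, ax = accel[, 1], ay = accel[, 2],
                            az = accel[, 3]),
      resampled_draws = resampled
    ),
    class = "ground_truth"
  )
  list(rec = rec, gt = gt)
}

#' Analytic threshold-crossing times of the simulated lobes
#'
#' Closed-form onset/offset times where a lobe's speed crosses
#' `theta * omega_max`: solving `16 tau^2 (1 - tau)^2 = c` gives
#' `tau = (1 -/+ sqrt(1 - sqrt(c))) / 2`. With `scope = "global"` the
#' threshold is anchored to the largest lobe peak; with `"per_portion"`
#' each lobe uses its own peak (`c = theta`). Lobes whose peak falls below
#' the global threshold get `NA` crossings.
#'
#' @param gt A `ground_truth` from [simulate_task()].
#' @param theta Threshold fraction.
#' @param scope `"global"` or `"per_portion"`.
#' @return Tibble with columns `lobe`, `onset`, `offset`.
#' @export
analytic_crossings <- function(gt, theta = 0.25,
                               scope = c("global", "per_portion")) {
  scope <- match.arg(scope)
  lobes <- gt$lobes
  cc <- if (scope == "global") {
    theta * max(lobes$peak) / lobes$peak
  } else {
    rep(theta, nrow(lobes))
  }
  frac <- ifelse(cc < 1, mj_crossing_fraction(pmin(cc, 1)), NA_real_)
  tibble(
    lobe = lobes$lobe,
    onset = lobes$start + frac * lobes$duration,
    offset = lobes$start + (1 - frac) * lobes$duration
  )
}

#' Reference instants from a simulated optoelectronic gold standard
#'
#' Synthesizes the wrist-speed trace implied by the ground-truth lobe
#' kinematics at the motion-capture rate (200 Hz), low-pass filters it
#' (order 5, zero-lag, 6 Hz) and applies the gold-standard rule — first
#' crossings above/below 20% of each bell's peak speed, evaluated per
#' movement portion — returning the reference T0/T1 instants that the
#' sensor-derived instants are scored against.
#'
#' @param gt A `ground_truth` from [simulate_task()].
#' @param noise SD of additive speed noise (m/s; mm-scale marker noise
#'   differentiates to roughly this magnitude). Default 0.
#' @param rate Marker sampling rate, Hz.
#' @return Tibble with columns `instant`, `time` (empty for zero-motion
#'   ground truth).
#' @export
simulate_marker_oracle <- function(gt, noise = 0, rate = 200) {
  lobes <- gt$lobes
  if (nrow(lobes) == 0 || all(lobes$peak <= 0)) {
    return(tibble(instant = character(0), time = numeric(0)))
  }
  t_end <- gt$impact + 0.5
  t <- seq(0, t_end, by = 1 / rate)
  speed <- numeric(length(t))
  for (l in seq_len(nrow(lobes))) {
    tau <- (t - lobes$start[l]) / lobes$duration[l]
    speed <- speed + 0.0035 * lobes$peak[l] * mj_shape(tau)
  }
  if (noise > 0) speed <- speed + stats::rnorm(length(t), 0, noise)
  speed <- lowpass_zero_lag(speed, rate = rate, cutoff = 6, order = 5)
  # portion limits: midpoints between consecutive lobe supports
  edges <- c(0, (lobes$start[-1] + c(lobes$start + lobes$duration)[-nrow(lobes)]) / 2,
             t_end)
  inst <- map(seq_len(nrow(lobes)), function(l) {
    idx <- which(t >= edges[l] & t <= edges[l + 1])
    w <- speed[idx]
    thr <- 0.2 * max(w)
    i0 <- which(w > thr)[1]
    j0 <- which(w < thr & seq_along(w) > which.max(w))[1]
    interp <- function(i) {
      if (is.na(i) || i == 1) return(t[idx[i]])
      t0 <- t[idx[i - 1]]
      t[idx[i]] - (w[i] - thr) / (w[i] - w[i - 1]) * (t[idx[i]] - t0)
    }
    tibble(lobe = lobes$lobe[l], T0 = interp(i0), T1 = interp(j0))
  }) |> list_rbind()
  out <- tibble(
    instant = c(paste0("T0_", inst$lobe), paste0("T1_", inst$lobe)),
    time = c(inst$T0, inst$T1)
  )
  keep <- if (nrow(lobes) == 3) {
    c("T0_reaching", "T1_reaching", "T0_transport", "T1_transport",
      "T0_return")
  } else {
    c("T0_transport", "T0_return")
  }
  out[match(keep, out$instant), ]
}

#' Simulate a full cohort of recordings and clinical records
#'
#' Draws per-subject phase-duration means around each severity group's
#' means (log-normal between-subject variation), simulates every requested
#' item per subject, and generates clinical scores consistent with the
#' severity grade: controls at the ARAT ceiling with healthy peg-test
#' times (about 19 +/- 2 s); impaired groups drawn uniformly within their
#' cluster's published non-outlier ranges (two of the severe subjects
#' drawn as unable to complete the peg test).
#'
#' @param n Named counts per group, e.g.
#'   `c(control = 12, mild = 12, moderate = 5, severe = 4)` (the study's
#'   12 controls and 21 MS subjects split by impairment).
#' @param items Items to simulate per subject.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param specs Optional named list of [simulation_spec()] overrides.
#' @return List with `tasks` (tibble `subject`, `group`, `item`,
#'   list-columns `rec`, `gt`) and `clinical` (one row per subject with
#'   `severity` grade 0-3 and ARAT/9HPT/FTRS scores).
#' @export
simulate_cohort <- function(n = c(control = 12, mild = 12, moderate = 5,
                                  severe = 4),
                            items = 1:19, seed = 1, specs = NULL) {
  if (any(n <= 0)) {
    iarat_abort("group sizes must be positive", class = "iarat_parameter_error")
  }
  set.seed(seed)
  groups <- names(n)
  tasks <- list()
  clin <- list()
  sid <- 0
  for (g in groups) {
    base <- specs[[g]] %||% simulation_spec(g)
    for (s in seq_len(n[[g]])) {
      sid <- sid + 1
      subject <- sprintf("%s%02d", g, s)
      spec_s <- base
      spec_s$phase_duration <- base$phase_duration *
        exp(stats::rnorm(length(base$phase_duration), 0, base$subject_sd))
      sims <- map(items, ~ simulate_task(spec_s, item = .x, subject = subject))
      tasks[[length(tasks) + 1]] <- tibble(
        subject = subject, group = g, item = items,
        rec = map(sims, "rec"), gt = map(sims, "gt")
      )
      clin[[length(clin) + 1]] <- simulate_clinical_record(subject, g, sid)
    }
  }
  list(tasks = list_rbind(tasks), clinical = list_rbind(clin))
}

simulate_clinical_record <- function(subject, group, sid) {
  severity <- match(group, c("control", "mild", "moderate", "severe")) - 1L
  rec <- switch(group,
    control = {
      t9 <- max(stats::rnorm(1, 19, 2), 12)
      tibble(arat = 57, nhpt_s = t9, ftrs_sum = 0L)
    },
    mild = tibble(
      arat = sample(54:57, 1), nhpt_s = stats::runif(1, 25.0, 37.5),
      ftrs_sum = sample(0:3, 1)
    ),
    moderate = tibble(
      arat = sample(39:51, 1), nhpt_s = stats::runif(1, 40.9, 59.6),
      ftrs_sum = sample(1:4, 1)
    ),
    severe = {
      unable <- sid %% 2 == 0  # half of severe subjects cannot complete it
      tibble(
        arat = sample(34:39, 1),
        nhpt_s = if (unable) NA_real_ else stats::runif(1, 105.9, 159.5),
        ftrs_sum = sample(3:5, 1)
      )
    }
  )
  rec |>
    mutate(
      subject = subject, group = group, severity = severity,
      nhpt_rate = pegs_per_minute(.data$nhpt_s),
      ftrs_postural = pmin(.data$ftrs_sum %/% 2L, 2L),
      ftrs_intention = .data$ftrs_sum - pmin(.data$ftrs_sum %/% 2L, 2L),
      .before = 1
    )
}
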