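#' Zero-lag low-pass Butterworth filtering
#'
#' Applies an order-`order` low-pass Butterworth filter forward and backward
#' (zero phase, squared magnitude response). The series is extended at both
#' ends with `3 * order` samples of odd (point-symmetric) reflection before
#' filtering, which is benign for recordings that start and end at rest and
#' makes the output bit-reproducible.
#'
#' @param x Numeric vector, or matrix/data frame whose columns are filtered
#'   independently.
#' @param rate Sampling rate, Hz.
#' @param cutoff Cut-off frequency, Hz; must be below the Nyquist rate.
#' @param order Filter order for each pass (default 4).
#' @return Filtered object with the same dimensions as `x`.
#' @export
#' @examples
#' t <- seq(0, 4, by = 0.02)
#' x <- sin(2 * pi * 1 * t)
#' y <- lowpass_zero_lag(x, rate = 50, cutoff = 2.5)
lowpass_zero_lag <- function(x, rate, cutoff, order = 4) {
  if (cutoff >= rate / 2) {
    iarat_abort("cutoff must be below the Nyquist frequency (rate/2)",
                class = "iarat_parameter_error")
  }
  if (is.data.frame(x)) {
    x[] <- lapply(x, lowpass_zero_lag, rate = rate, cutoff = cutoff,
                  order = order)
    return(x)
  }
  if (is.matrix(x)) {
    return(apply(x, 2, lowpass_zero_lag, rate = rate, cutoff = cutoff,
                 order = order))
  }
  n <- length(x)
  pad <- 3 * order
  if (n <= pad) {
    iarat_abort(
      sprintf("series too short for zero-lag filtering: need > %d samples, got %d",
              pad, n),
      class = "iarat_length_error"
    )
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]),
          x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  # subtract the starting level before each causal pass (unit DC gain puts
  # it back): the filter state then starts at its steady state, so the
  # start-up transient vanishes for signals that begin at rest
  one_pass <- function(v) {
    v0 <- v[1]
    as.numeric(signal::filter(bf, v - v0)) + v0
  }
  y <- rev(one_pass(rev(one_pass(xp))))
  y[(pad + 1):(pad + n)]
}

#' Angular-speed norm of the gyroscope signals
#'
#' Each gyroscope axis is smoothed with a zero-lag low-pass Butterworth
#' filter (default order 4, cut-off 2.5 Hz) and the Euclidean norm of the
#' three filtered axes is taken, yielding the non-negative angular speed
#' profile used for movement segmentation. Filtering is per axis, before
#' the norm, so the zero-lag property holds on each component.
#'
#' @param rec An [imu_recording()].
#' @param cfg A [segmentation_config()]; `gyro_cutoff` and filter order are
#'   taken from it.
#' @return Tibble with columns `t` and `omega` (deg/s); attributes
#'   `filtered = TRUE` and `cutoff`.
#' @export
angular_speed <- function(rec, cfg = segmentation_config()) {
  validate_recording(rec)
  rate <- imu_rate(rec)
  g <- lowpass_zero_lag(as.matrix(as_tibble(rec)[c("gx", "gy", "gz")]),
                        rate = rate, cutoff = cfg$gyro_cutoff, order = 4)
  out <- tibble(t = rec$t, omega = sqrt(rowSums(g^2)))
  attr(out, "filtered") <- TRUE
  attr(out, "cutoff") <- cfg$gyro_cutoff
  attr(out, "rate") <- rate
  out
}

#' Gravity-free acceleration in the global frame
#'
#' Rotates the sensor-frame specific force into the global frame with the
#' per-sample rotation matrix and subtracts the gravity component
#' `(0, 0, g)` (z vertical, up; g = 9.81 m/s^2). The `vertical` column is
#' the z component, the signal whose last acceleration peak marks the
#' hand-table contact at the end of the return phase.
#'
#' @param rec An [imu_recording()].
#' @return Tibble with columns `t`, `ax`, `ay`, `az` (gravity-free global
#'   acceleration, m/s^2) and `vertical` (equal to `az`).
#' @export
free_acceleration <- function(rec) {
  validate_recording(rec)
  d <- as_tibble(rec)
  ax <- d$r11 * d$ax + d$r12 * d$ay + d$r13 * d$az
  ay <- d$r21 * d$ax + d$r22 * d$ay + d$r23 * d$az
  az <- d$r31 * d$ax + d$r32 * d$ay + d$r33 * d$az - GRAVITY
  out <- tibble(t = d$t, ax = ax, ay = ay, az = az, vertical = az)
  attr(out, "rate") <- imu_rate(rec)
  out
}
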