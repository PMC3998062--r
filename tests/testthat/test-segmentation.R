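make_omega <- function(lobes, n = 300, rate = 50) {
  # lobes: tibble(start, duration, peak); unfiltered synthetic profile
  t <- (seq_len(n) - 1) / rate
  w <- numeric(n)
  for (i in seq_len(nrow(lobes))) {
    tau <- (t - lobes$start[i]) / lobes$duration[i]
    w <- w + lobes$peak[i] * ifelse(tau > 0 & tau < 1,
                                    16 * tau^2 * (1 - tau)^2, 0)
  }
  tibble::tibble(t = t, omega = w)
}

test_that("three separated lobes give three windows, one peak each", {
  lobes <- tibble::tibble(start = c(0.5, 2, 3.5), duration = 1, peak = 100)
  om <- make_omega(lobes)
  w <- detect_movement_windows(om, segmentation_config(), n_lobes = 3)
  expect_equal(nrow(w), 3)
  peaks <- lobes$start + lobes$duration / 2
  for (i in 1:3) {
    inside <- peaks >= w$start[i] & peaks <= w$end[i]
    expect_equal(sum(inside), 1)
    expect_true(inside[i])
  }
  # windows tile the recording
  expect_equal(w$start[1], om$t[1])
  expect_equal(w$end[3], om$t[nrow(om)])
  expect_equal(w$end[-3], w$start[-1])
})

test_that("requesting two lobes keeps the two longest in time order", {
  lobes <- tibble::tibble(start = c(0.5, 2, 3.5),
                          duration = c(1.0, 0.4, 0.8), peak = 100)
  om <- make_omega(lobes)
  w <- detect_movement_windows(om, segmentation_config(), n_lobes = 2)
  # brute-force oracle: enumerate supra-threshold runs directly
  thr <- 0.25 * max(om$omega)
  r <- rle(om$omega > thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = om$t[starts[r$values]],
                     end = om$t[ends[r$values]])
  runs$dur <- runs$end - runs$start
  keep <- sort(order(-runs$dur)[1:2])
  expect_equal(w$run_start, runs$start[keep])
  expect_equal(w$run_end, runs$end[keep])
  expect_true(all(diff(w$start) > 0))
})

test_that("a flat signal yields the insufficient-lobes error", {
  om <- tibble::tibble(t = (0:99) / 50, omega = rep(0, 100))
  expect_error(detect_movement_windows(om, segmentation_config(), 3),
               regexp = "insufficient movement lobes",
               class = "iarat_segmentation_error")
})

test_that("equal-duration runs break ties toward the earlier run", {
  lobes <- tibble::tibble(start = c(0.5, 2, 3.5), duration = c(1, 1, 1),
                          peak = c(100, 100, 100))
  om <- make_omega(lobes)
  w <- detect_movement_windows(om, segmentation_config(), n_lobes = 2)
  expect_lt(w$run_start[1], 2)  # the first of the tied runs is kept
})

test_that("manual windows override automatic detection", {
  om <- make_omega(tibble::tibble(start = 1, duration = 1, peak = 100))
  mw <- data.frame(start = c(0, 2), end = c(2, 4))
  cfg <- segmentation_config(manual_windows = mw)
  w <- detect_movement_windows(om, cfg, n_lobes = 2)
  expect_equal(w$start, mw$start)
  expect_equal(w$end, mw$end)
})

test_that("lobe boundaries land on the closed-form threshold crossings", {
  # speed proportional to 30 tau^2 (1-tau)^2: theta = 0.25 of its own peak
  # crosses at tau = 0.14645 and 0.85355 of the lobe duration
  L <- 0.8
  lobes <- tibble::tibble(start = 1, duration = L, peak = 120)
  om <- make_omega(lobes, n = 200)
  b <- phase_boundaries(om, c(0, 4), threshold = 0.25 * 120)
  tau <- (1 - sqrt(1 - sqrt(0.25))) / 2
  expect_lte(abs(b[["onset"]] - (1 + tau * L)), 0.02)
  expect_lte(abs(b[["offset"]] - (1 + (1 - tau) * L)), 0.02)
})

test_that("constant supra-threshold signal clamps the offset with a warning", {
  om <- tibble::tibble(t = (0:49) / 50, omega = rep(80, 50))
  expect_warning(
    b <- phase_boundaries(om, c(0, 0.98), threshold = 20),
    regexp = "clamped"
  )
  expect_equal(b[["onset"]], 0)
  expect_equal(b[["offset"]], 0.98)
})

test_that("a window that never crosses the threshold raises phase_below_threshold", {
  om <- make_omega(tibble::tibble(start = 1, duration = 1, peak = 10))
  expect_error(phase_boundaries(om, c(0, 4), threshold = 50),
               class = "iarat_phase_below_threshold")
})

test_that("the return ends at the planted impact transient", {
  sim <- simulate_task(noise_free_spec(), item = 1, seed = 21)
  seg <- segment_task(sim$rec)
  expect_lte(abs(seg$offset[seg$phase == "return"] - sim$gt$impact), 0.02)
})

test_that("with two impact transients the later one terminates the return", {
  t <- (0:199) / 50
  vert <- tibble::tibble(
    t = t,
    vertical = 5 * exp(-(t - 2)^2 / (2 * 0.03^2)) +
      4 * exp(-(t - 3)^2 / (2 * 0.03^2))
  )
  hit <- return_termination(vert, return_onset = 1, segmentation_config())
  expect_lte(abs(hit - 3), 0.02)
})

test_that("monotone decay falls back to the threshold offset with a warning", {
  t <- (0:99) / 50
  vert <- tibble::tibble(t = t, vertical = exp(-t))
  expect_warning(
    hit <- return_termination(vert, 0.5, segmentation_config(),
                              fallback = 1.23),
    regexp = "falling back"
  )
  expect_equal(hit, 1.23)
})

test_that("a noise-free item recovers all five phases at the analytic crossings", {
  sim <- simulate_task(deterministic_spec(), item = 1, seed = 1)
  seg <- segment_task(sim$rec)
  expect_equal(as.character(seg$phase),
               c("reaching", "manipulation", "transport", "release", "return"))
  validate_segmentation(seg)
  # contiguity: phases tile [first onset, return termination]
  expect_equal(seg$onset[-1], seg$offset[-5], tolerance = 1e-9)
  want <- expected_instants(sim$gt, 0.25)
  got <- segmentation_instants(seg)$time
  expect_lte(max(abs(got - want)), 0.02)
})

test_that("boundary error stays within one sample for the whole threshold family", {
  for (item in c(1, 9, 13, 18)) {
    sim <- simulate_task(deterministic_spec(), item = item, seed = 1)
    for (theta in c(0.15, 0.20, 0.25, 0.30)) {
      seg <- segment_task(sim$rec, segmentation_config(theta = theta))
      got <- segmentation_instants(seg)$time
      expect_lte(max(abs(got - expected_instants(sim$gt, theta))), 0.02)
    }
  }
})

test_that("per-portion thresholds recover each lobe's own crossings", {
  sim <- simulate_task(deterministic_spec(), item = 1, seed = 1)
  cfg <- segmentation_config(omega_max_scope = "per_portion")
  seg <- segment_task(sim$rec, cfg)
  want <- expected_instants(sim$gt, 0.25, scope = "per_portion")
  expect_lte(max(abs(segmentation_instants(seg)$time - want)), 0.02)
})

test_that("gross items segment into exactly two contiguous phases", {
  sim <- simulate_task(noise_free_spec(), item = 18, seed = 4)
  seg <- segment_task(sim$rec)
  expect_equal(as.character(seg$phase), c("transport", "return"))
  expect_equal(seg$offset[1], seg$onset[2])
  validate_segmentation(seg)
})

test_that("a zero-dwell ground truth has coincident manipulation crossings", {
  sp <- deterministic_spec()
  sp$phase_duration[["manipulation"]] <- 0
  sp$phase_duration[["release"]] <- 0
  sim <- simulate_task(sp, item = 1, seed = 1)
  b <- sim$gt$boundaries
  expect_equal(b$onset[b$phase == "manipulation"],
               b$offset[b$phase == "manipulation"])
  # zero-length manipulation/release are legal segmentations
  validate_segmentation(
    tibble::tibble(item = 1, phase = b$phase, onset = b$onset,
                   offset = b$offset)
  )
})

test_that("segmentation is invariant to gyro amplitude scaling", {
  sim <- simulate_task(noise_free_spec(), item = 1, seed = 13)
  d <- tibble::as_tibble(sim$rec)
  d$gx <- d$gx / 4; d$gy <- d$gy / 4; d$gz <- d$gz / 4
  rec2 <- imu_recording(d, rate = 50, item = 1)
  s1 <- segment_task(sim$rec)
  s2 <- segment_task(rec2)
  expect_equal(s1$onset, s2$onset, tolerance = 1e-9)
  expect_equal(s1$offset, s2$offset, tolerance = 1e-9)
})

test_that("time-shifting a recording shifts every boundary by the shift", {
  sim <- simulate_task(noise_free_spec(), item = 1, seed = 17)
  d <- tibble::as_tibble(sim$rec)
  d$t <- d$t + 5
  rec2 <- imu_recording(d, rate = 50, item = 1)
  s1 <- segment_task(sim$rec)
  s2 <- segment_task(rec2)
  expect_equal(s2$onset, s1$onset + 5, tolerance = 1e-9)
  expect_equal(s2$offset, s1$offset + 5, tolerance = 1e-9)
})

test_that("error analysis summarizes |t_imu - t_ref| and finds the best threshold", {
  # identical instants give an all-zero table
  paired0 <- tidyr::expand_grid(
    threshold = c(0.15, 0.25), instant = c("T0_reaching", "T0_return"),
    t_imu = 1, t_ref = 1
  )
  tab0 <- threshold_error_analysis(paired0)
  expect_true(all(tab0$mean_abs_error == 0))
  expect_equal(nrow(tab0), 6)  # 2 instants x 2 thresholds + 2 'All instants'
  expect_true("All instants" %in% tab0$instant)

  expect_error(threshold_error_analysis(tibble::tibble()),
               class = "iarat_parameter_error")

  # sensor-vs-oracle sweep over simulated tasks: every cell must equal a
  # direct re-average of the stored instants
  tasks <- purrr::map(1:12, function(s) {
    sim <- simulate_task(noise_free_spec(), item = (s %% 3) * 4 + 1, seed = s)
    tibble::tibble(rec = list(sim$rec),
                   ref = list(simulate_marker_oracle(sim$gt)))
  }) |> purrr::list_rbind()
  paired <- sweep_thresholds(tasks)
  tab <- threshold_error_analysis(paired)
  for (i in seq_len(nrow(tab))) {
    sel <- paired$threshold == tab$threshold[i] &
      (tab$instant[i] == "All instants" | paired$instant == tab$instant[i])
    expect_equal(tab$mean_abs_error[i],
                 mean(abs(paired$t_imu[sel] - paired$t_ref[sel])),
                 tolerance = 1e-12)
  }
  all_rows <- tab[tab$instant == "All instants", ]
  expect_equal(attr(tab, "best_threshold"),
               all_rows$threshold[which.min(all_rows$mean_abs_error)])
})
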