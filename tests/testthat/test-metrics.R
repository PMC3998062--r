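sine_accel <- function(f = 2, D = 2, rate = 50, A = 1) {
  t <- seq(0, D, by = 1 / rate)
  tibble::tibble(t = t, ax = 0, ay = 0, az = A * sin(2 * pi * f * t))
}

test_that("jerk index of a sinusoid matches ln(2 pi f D)", {
  a <- sine_accel(f = 2, D = 2)
  expect_equal(jerk_index(a, c(0, 2), rate = 50), log(8 * pi),
               tolerance = 0.02 * log(8 * pi))
})

test_that("jerk index is invariant to amplitude scaling", {
  a1 <- sine_accel(A = 1)
  a2 <- sine_accel(A = 137.5)
  expect_equal(jerk_index(a1, c(0, 2), rate = 50),
               jerk_index(a2, c(0, 2), rate = 50), tolerance = 1e-9)
})

test_that("jerk index rejects degenerate windows", {
  a <- sine_accel()
  expect_error(jerk_index(a, c(0, 0.02), rate = 50),
               class = "iarat_length_error")
  flat <- tibble::tibble(t = (0:9) / 50, ax = 0, ay = 0, az = 0)
  expect_error(jerk_index(flat, c(0, 0.18), rate = 50),
               class = "iarat_undefined_metric_error")
})

test_that("healthy task jerk magnitudes land in the natural-log range", {
  # printed healthy whole-task values sit near 3.0 at ~2 s tasks; a log10
  # convention would land near 1.3 instead
  set.seed(42)
  ji <- replicate(15, {
    sim <- simulate_task(simulation_spec("control"), item = 1)
    m <- compute_metrics(sim$rec, segment_task(sim$rec))
    m$jerk_index[m$phase == "task"]
  })
  expect_gt(median(ji), 2.0)
  expect_lt(median(ji), 4.5)
})

test_that("phase durations are offset minus onset and the task spans all phases", {
  seg <- structure(
    tibble::tibble(
      item = 1L,
      phase = factor(c("reaching", "manipulation", "transport", "release",
                       "return"),
                     levels = c("reaching", "manipulation", "transport",
                                "release", "return")),
      onset = c(0.0, 0.5, 0.8, 1.5, 1.7),
      offset = c(0.5, 0.8, 1.5, 1.7, 2.4)
    ),
    class = c("phase_segmentation", class(tibble::tibble()))
  )
  rec <- stationary_recording(n = 121)
  d <- tibble::as_tibble(rec)
  d$ax <- sin(2 * pi * 1.5 * d$t)  # arbitrary non-zero movement content
  rec <- imu_recording(d, rate = 50, item = 1)
  m <- compute_metrics(rec, seg)
  expect_equal(m$duration, c(0.5, 0.3, 0.7, 0.2, 0.7, 2.4))
  expect_equal(m$phase, c("reaching", "manipulation", "transport", "release",
                          "return", "task"))
})

test_that("task-level jerk equals jerk_index called on the whole window", {
  sim <- simulate_task(simulation_spec("control"), item = 1, seed = 31)
  seg <- segment_task(sim$rec)
  m <- compute_metrics(sim$rec, seg)
  direct <- jerk_index(free_acceleration(sim$rec),
                       c(min(seg$onset), max(seg$offset)), rate = 50)
  expect_equal(m$jerk_index[m$phase == "task"], direct, tolerance = 1e-12)
})

test_that("zero-length phases get duration zero and an undefined jerk", {
  seg <- structure(
    tibble::tibble(
      item = 1L,
      phase = factor(c("reaching", "manipulation", "transport"),
                     levels = c("reaching", "manipulation", "transport",
                                "release", "return")),
      onset = c(0.0, 0.5, 0.5),
      offset = c(0.5, 0.5, 1.2)
    ),
    class = c("phase_segmentation", class(tibble::tibble()))
  )
  d <- tibble::as_tibble(stationary_recording(n = 100))
  d$ax <- sin(2 * pi * 1.5 * d$t)
  rec <- imu_recording(d, rate = 50, item = 1)
  m <- compute_metrics(rec, seg)
  expect_equal(m$duration[m$phase == "manipulation"], 0)
  expect_true(is.na(m$jerk_index[m$phase == "manipulation"]))
})

test_that("median segmented reaching duration recovers the 0.45 s target", {
  set.seed(7)
  d <- replicate(100, {
    sim <- simulate_task(simulation_spec("control"), item = 1)
    seg <- segment_task(sim$rec)
    seg$offset[seg$phase == "reaching"] - seg$onset[seg$phase == "reaching"]
  })
  expect_lt(abs(median(d) - 0.45), 0.10 * 0.45)
})

make_cohort <- function(values) {
  # values: named list group -> vector of per-subject values for one cell
  purrr::imap(values, function(v, g) {
    tibble::tibble(
      subject = paste0(g, seq_along(v)), group = g, item = 1L,
      phase = "task", parameter = "duration", value = v
    )
  }) |> purrr::list_rbind()
}

test_that("z-scores follow the normative-deviation definition", {
  # hand-checkable: controls {1,2,3}, patient at 4 -> Z = (4-2)/1 = 2
  cohort <- make_cohort(list(control = c(1, 2, 3), ms = 4))
  z <- zscore_table(cohort)
  expect_equal(z$z[z$group == "ms"], 2.0)
  # a subject exactly at the control mean scores zero
  cohort0 <- make_cohort(list(control = c(1, 2, 3), ms = 2))
  expect_equal(zscore_table(cohort0)$z[4], 0)
})

test_that("control cohort scored against itself standardizes to mean 0, sd 1", {
  set.seed(12)
  cohort <- purrr::map(1:8, function(s) {
    tibble::tibble(
      subject = paste0("C", s), group = "control",
      item = rep(1:3, each = 2), phase = "task",
      parameter = rep(c("duration", "jerk"), 3),
      value = rnorm(6, mean = 2)
    )
  }) |> purrr::list_rbind()
  z <- zscore_table(cohort)
  cells <- dplyr::group_by(z, item, parameter) |>
    dplyr::summarise(m = mean(z), s = sd(z), .groups = "drop")
  expect_lt(max(abs(cells$m)), 1e-9)
  expect_lt(max(abs(cells$s - 1)), 1e-9)
})

test_that("degenerate normative cells are refused by name", {
  cohort <- make_cohort(list(control = c(2, 2, 2), ms = 4))
  expect_error(zscore_table(cohort), regexp = "duration",
               class = "iarat_degenerate_normative_error")
})

test_that("z-scores are equivariant under a common shift of one cell", {
  set.seed(3)
  cohort <- make_cohort(list(control = rnorm(6), ms = rnorm(4)))
  shifted <- dplyr::mutate(cohort, value = value + 17.3)
  expect_equal(zscore_table(cohort)$z, zscore_table(shifted)$z,
               tolerance = 1e-9)
})

test_that("subject aggregates are mean-then-z against the control means", {
  set.seed(4)
  cohort <- purrr::map(1:6, function(s) {
    g <- if (s <= 4) "control" else "ms"
    tibble::tibble(subject = paste0(g, s), group = g, item = 1:5,
                   phase = "task", parameter = "duration",
                   value = rnorm(5, mean = ifelse(g == "ms", 3, 2)))
  }) |> purrr::list_rbind()
  sz <- subject_zscores(cohort)
  # brute force for one MS subject
  subj_means <- tapply(cohort$value, cohort$subject, mean)
  ctrl_means <- subj_means[paste0("control", 1:4)]
  want <- (subj_means[["ms5"]] - mean(ctrl_means)) / sd(ctrl_means)
  expect_equal(sz$z[sz$subject == "ms5"], want, tolerance = 1e-12)
})

test_that("section summaries average over exactly the member items", {
  cohort <- tibble::tibble(
    subject = "S1", group = "ms", item = 1:19, phase = "task",
    parameter = "duration", value = as.numeric(1:19)
  )
  ctrl <- purrr::map(1:3, function(s) {
    tibble::tibble(subject = paste0("C", s), group = "control", item = 1:19,
                   phase = "task", parameter = "duration",
                   value = as.numeric(1:19) + s / 10)
  }) |> purrr::list_rbind()
  sect <- section_summary(dplyr::bind_rows(cohort, ctrl))
  s1 <- sect[sect$subject == "S1", ]
  expect_equal(s1$mean_value[s1$section == "Grasp"], mean(1:6))
  expect_equal(s1$mean_value[s1$section == "Grip"], mean(7:10))
  expect_equal(s1$mean_value[s1$section == "Pinch"], mean(11:16))
  expect_equal(s1$mean_value[s1$section == "Gross"], mean(17:19))
  # identical metric on all items collapses to that value
  flat <- dplyr::mutate(dplyr::bind_rows(cohort, ctrl),
                        value = ifelse(group == "ms", 5, value))
  sf <- section_summary(flat)
  expect_true(all(sf$mean_value[sf$subject == "S1"] == 5))
})

test_that("mean manipulation jerk rises monotonically with tremor amplitude", {
  amps <- c(0, 0.5, 1, 2)
  set.seed(9)
  mean_ji <- vapply(amps, function(a) {
    sp <- simulation_spec("control", tremor_amp = a)
    mean(replicate(30, {
      sim <- simulate_task(sp, item = 1)
      m <- compute_metrics(sim$rec, segment_task(sim$rec))
      m$jerk_index[m$phase == "manipulation"]
    }))
  }, numeric(1))
  expect_true(all(diff(mean_ji) > 0))
  expect_gt(unname(spearman(amps, mean_ji)$statistic), 0.9)
})
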