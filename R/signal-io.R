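#' IMU recording container
#'
#' An `imu_recording` is a tibble with one row per sample and columns
#' `t` (seconds), `ax, ay, az` (specific force in the sensor frame, m/s^2),
#' `gx, gy, gz` (angular velocity, deg/s) and `r11 ... r33` (the row-major
#' 3x3 rotation matrix mapping the sensor frame to a global frame whose z
#' axis points vertically up). Sampling-rate and task metadata travel as
#' attributes so the object still behaves as an ordinary data frame.
#'
#' Validation enforces the physical contract of the wrist-worn sensor:
#' a strictly uniform time base at `rate` Hz, orthonormal rotation matrices
#' (determinant +1), accelerations within the +/- 5 g range and angular
#' velocities within +/- 1200 deg/s.
#'
#' @param data Data frame with the 16 signal columns described above.
#' @param rate Sampling rate in Hz; inferred from `t` when `NULL`.
#' @param subject,group,arm,item Metadata: subject identifier, cohort label
#'   (`"control"` or `"MS"`), tested arm, and ARAT item number (1-19).
#' @param validate Run the full invariant check (default `TRUE`).
#'
#' @return An `imu_recording` tibble.
#' @export
#' @examples
#' rec <- imu_recording(
#'   tibble::tibble(
#'     t = seq(0, 0.04, by = 0.02),
#'     ax = 0, ay = 0, az = 9.81,
#'     gx = 0, gy = 0, gz = 0,
#'     r11 = 1, r12 = 0, r13 = 0,
#'     r21 = 0, r22 = 1, r23 = 0,
#'     r31 = 0, r32 = 0, r33 = 1
#'   ),
#'   item = 1, group = "control", subject = "C01"
#' )
#' imu_rate(rec)
imu_recording <- function(data, rate = NULL, subject = NA_character_,
                          group = NA_character_, arm = NA_character_,
                          item = NA_integer_, validate = TRUE) {
  data <- as_tibble(data)
  missing <- setdiff(imu_columns(), names(data))
  if (length(missing) > 0) {
    iarat_abort(
      paste0("missing signal column(s): ", paste(missing, collapse = ", ")),
      class = "iarat_format_error"
    )
  }
  data <- data[imu_columns()]
  if (is.null(rate)) {
    if (nrow(data) < 2) {
      iarat_abort("cannot infer rate from fewer than 2 samples",
                  class = "iarat_validation_error")
    }
    rate <- 1 / stats::median(diff(data$t))
  }
  rec <- structure(
    data,
    rate = rate,
    meta = list(
      subject = as.character(subject), group = as.character(group),
      arm = as.character(arm),
      item = if (is.na(item)) NA_integer_ else as.integer(item)
    ),
    class = c("imu_recording", class(tibble()))
  )
  if (validate) validate_recording(rec)
  rec
}

imu_columns <- function() {
  c("t", "ax", "ay", "az", "gx", "gy", "gz",
    "r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33")
}

#' @rdname imu_recording
#' @param rec An `imu_recording`.
#' @export
imu_rate <- function(rec) attr(rec, "rate")

#' @rdname imu_recording
#' @export
imu_meta <- function(rec) attr(rec, "meta")

#' @rdname imu_recording
#' @export
validate_recording <- function(rec) {
  data <- as_tibble(rec)
  rate <- imu_rate(rec)
  n <- nrow(data)
  if (n < 2) {
    iarat_abort("recording must contain at least 2 samples",
                class = "iarat_validation_error")
  }
  step <- diff(data$t)
  if (any(step <= 0) || max(abs(step - 1 / rate)) > 1e-9) {
    iarat_abort(
      sprintf("time base is not uniform at %.6g Hz (max step deviation %.3g s)",
              rate, max(abs(step - 1 / rate))),
      class = "iarat_validation_error"
    )
  }
  bad <- which(rotation_error(data) > 1e-6)
  if (length(bad) > 0) {
    iarat_abort(
      sprintf("non-orthonormal rotation matrix at sample index(es): %s",
              paste(utils::head(bad, 10), collapse = ", ")),
      class = "iarat_validation_error",
      indices = bad
    )
  }
  if (max(abs(c(data$ax, data$ay, data$az))) > 5 * GRAVITY + 1e-9) {
    iarat_abort("acceleration outside the +/-5 g sensor range",
                class = "iarat_validation_error")
  }
  if (max(abs(c(data$gx, data$gy, data$gz))) > 1200 + 1e-9) {
    iarat_abort("angular velocity outside the +/-1200 deg/s sensor range",
                class = "iarat_validation_error")
  }
  invisible(rec)
}

# per-sample deviation from orthonormality: max |R'R - I| entry and |det - 1|
rotation_error <- function(data) {
  r <- as.matrix(data[c("r11", "r12", "r13", "r21", "r22", "r23",
                        "r31", "r32", "r33")])
  g <- function(i, j) {
    # (R'R)[i,j] = sum_k R[k,i] R[k,j]; columns of R are (r1i, r2i, r3i)
    r[, paste0("r", 1:3, i), drop = FALSE] * r[, paste0("r", 1:3, j), drop = FALSE]
  }
  dot <- function(i, j) rowSums(g(i, j))
  err <- pmax(
    abs(dot(1, 1) - 1), abs(dot(2, 2) - 1), abs(dot(3, 3) - 1),
    abs(dot(1, 2)), abs(dot(1, 3)), abs(dot(2, 3))
  )
  det <- r[, "r11"] * (r[, "r22"] * r[, "r33"] - r[, "r23"] * r[, "r32"]) -
    r[, "r12"] * (r[, "r21"] * r[, "r33"] - r[, "r23"] * r[, "r31"]) +
    r[, "r13"] * (r[, "r21"] * r[, "r32"] - r[, "r22"] * r[, "r31"])
  pmax(err, abs(det - 1))
}

#' @export
print.imu_recording <- function(x, ...) {
  meta <- imu_meta(x)
  cat(sprintf(
    "<imu_recording> %d samples @ %g Hz | subject %s, group %s, item %s\n",
    nrow(x), imu_rate(x), meta$subject, meta$group,
    ifelse(is.na(meta$item), "?", meta$item)
  ))
  NextMethod()
}

#' ARAT section membership
#'
#' Maps an ARAT item number (1-19) to its section: Grasp (items 1-6),
#' Grip (7-10), Pinch (11-16) or Gross (17-19).
#'
#' @param item Integer vector of item numbers in 1-19.
#' @return Factor with levels Grasp, Grip, Pinch, Gross.
#' @export
#' @examples
#' arat_section(c(1, 7, 11, 17))
arat_section <- function(item) {
  item <- as.integer(item)
  if (any(is.na(item)) || any(item < 1L | item > 19L)) {
    iarat_abort("ARAT item numbers must be integers in 1..19",
                class = "iarat_parameter_error")
  }
  cut(item, breaks = c(0, 6, 10, 16, 19),
      labels = c("Grasp", "Grip", "Pinch", "Gross"))
}

# ---------------------------------------------------------------------------
# CSV dialect: comma separated, one header row (t, ax..az, gx..gz, r11..r33,
# rotation row-major), one row per sample; JSON sidecar <name>.meta.json with
# subject/group/arm/item/rate and optional unit declarations.
# ---------------------------------------------------------------------------

sidecar_path <- function(path) sub("\\.csv$", ".meta.json", path)

#' Read an IMU recording from the package CSV dialect
#'
#' Reads `<path>` (columns `t, ax, ay, az, gx, gy, gz, r11..r33`) together
#' with its JSON metadata sidecar `<name>.meta.json`, converts to canonical
#' units (m/s^2, deg/s) if the sidecar declares `accel_units = "g"` or
#' `gyro_units = "rad/s"`, and validates the result.
#'
#' @param path CSV file location.
#' @param meta Optional named list overriding/replacing the sidecar
#'   (fields `subject`, `group`, `arm`, `item`, `rate`, `accel_units`,
#'   `gyro_units`).
#' @return A validated [imu_recording()].
#' @export
read_imu_csv <- function(path, meta = NULL) {
  if (!file.exists(path)) {
    iarat_abort(paste0("file not found: ", path), class = "iarat_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(imu_columns(), names(data))
  if (length(missing) > 0) {
    iarat_abort(
      paste0("malformed header, missing column(s): ",
             paste(missing, collapse = ", ")),
      class = "iarat_format_error"
    )
  }
  side <- sidecar_path(path)
  file_meta <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    list()
  }
  file_meta[names(meta)] <- meta
  meta <- file_meta
  if (identical(meta$accel_units, "g")) {
    data[c("ax", "ay", "az")] <- data[c("ax", "ay", "az")] * GRAVITY
  }
  if (identical(meta$gyro_units, "rad/s")) {
    data[c("gx", "gy", "gz")] <- data[c("gx", "gy", "gz")] * 180 / pi
  }
  imu_recording(
    data,
    rate = meta$rate %||% NULL,
    subject = meta$subject %||% NA_character_,
    group = meta$group %||% NA_character_,
    arm = meta$arm %||% NA_character_,
    item = meta$item %||% NA_integer_
  )
}

#' Write an IMU recording in the package CSV dialect
#'
#' Serializes the signal table with full double precision (>= 9 significant
#' digits) and writes the JSON metadata sidecar next to it, so that
#' [read_imu_csv()] reproduces the recording within 1e-9 on every stream.
#'
#' @param rec A valid [imu_recording()].
#' @param path Output CSV location (sidecar written as `<name>.meta.json`).
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  validate_recording(rec)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    iarat_abort(paste0("directory does not exist: ", dir),
                class = "iarat_io_error")
  }
  readr::write_csv(as_tibble(rec), path, progress = FALSE)
  meta <- imu_meta(rec)
  meta$rate <- imu_rate(rec)
  meta$accel_units <- "m/s^2"
  meta$gyro_units <- "deg/s"
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a directory of `<subject>_<item>.csv` recordings
#'
#' @param dir Directory containing recordings in the package CSV dialect.
#' @return Tibble with columns `subject`, `group`, `item`, `path` and a
#'   list-column `rec` of [imu_recording()] objects.
#' @export
read_imu_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) {
    iarat_abort(paste0("no .csv recordings found in ", dir),
                class = "iarat_io_error")
  }
  recs <- map(files, read_imu_csv)
  tibble(
    subject = map_chr(recs, ~ imu_meta(.x)$subject),
    group = map_chr(recs, ~ imu_meta(.x)$group),
    item = map_int(recs, ~ imu_meta(.x)$item),
    path = files,
    rec = recs
  )
}

#' @importFrom purrr map_chr map_int
#' @importFrom rlang %||%
NULL
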