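#' Clinical assessment of the 21-subject MS cohort
#'
#' Embedded transcription of the published clinical assessment table:
#' ARAT total (0-57), Nine Hole Peg Test time (seconds, `NA` for the two
#' subjects unable to complete the test) and its pegs-per-minute
#' conversion, and Fahn's Tremor Rating Scale postural and intention
#' components with their sum. The `impairment` column records the
#' mild/moderate/severe sub-group each subject was assigned to. All values
#' are stored as printed, including the one pegs-per-minute entry (S18)
#' that the conversion rule does not reproduce.
#'
#' @return Tibble with one row per MS subject: `subject`, `impairment`,
#'   `arat`, `nhpt_s`, `nhpt_rate`, `ftrs_sum`, `ftrs_postural`,
#'   `ftrs_intention`.
#' @export
#' @examples
#' ms_clinical()
ms_clinical <- function() {
  tibble(
    subject = paste0("S", c(1:4, 10:12, 15:17, 19, 21,
                            6, 8, 9, 13, 14,
                            5, 7, 18, 20)),
    impairment = factor(rep(c("mild", "moderate", "severe"), c(12, 5, 4)),
                        levels = c("mild", "moderate", "severe")),
    arat = c(57, 56, 57, 57, 55, 57, 55, 57, 57, 54, 55, 56,
             51, 39, 40, 49, 44,
             34, 37, 34, 39),
    nhpt_s = c(37.5, 25.0, 27.3, 28.2, 32.4, 32.8, 31.2, 30.7, 36.2, 31.0,
               33.1, 30.5,
               49.9, 40.9, 44.9, 59.6, 44.9,
               NA, NA, 105.9, 159.5),
    nhpt_rate = c(14.4, 21.6, 19.8, 19.2, 16.8, 16.2, 17.4, 17.4, 15.0,
                  17.4, 16.2, 18.0,
                  10.8, 13.2, 12.0, 9.0, 12.0,
                  0.0, 0.0, 5.4, 3.6),
    ftrs_sum = c(1, 2, 1, 0, 0, 0, 0, 1, 1, 3, 2, 2,
                 3, 2, 4, 2, 1,
                 4, 3, 5, 5),
    ftrs_postural = c(0, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1, 1,
                      2, 1, 2, 1, 0,
                      1, 1, 2, 1),
    ftrs_intention = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 2, 1, 1,
                       1, 1, 2, 1, 1,
                       3, 2, 3, 4)
  )
}

#' Demographic and disease characteristics of the MS cohort
#'
#' Embedded transcription of the published demographics table: age, sex,
#' MS course (relapsing-remitting, primary or secondary progressive), time
#' since diagnosis and EDSS for the 21 MS subjects.
#'
#' @return Tibble with columns `subject`, `age`, `sex`, `ms_type`,
#'   `disease_duration`, `edss`.
#' @export
ms_demographics <- function() {
  tibble(
    subject = paste0("S", 1:21),
    age = c(69, 43, 57, 44, 51, 45, 58, 25, 51, 40, 39, 38, 44, 55, 50,
            38, 54, 46, 61, 45, 43),
    sex = c("F", "M", "F", "M", "M", "M", "M", "F", "F", "M", "F", "F",
            "F", "M", "M", "M", "F", "F", "M", "M", "M"),
    ms_type = c("RR", "RR", "RR", "RR", "SP", "PP", "SP", "RR", "SP", "RR",
                "SP", "RR", "SP", "PP", "PP", "RR", "RR", "PP", "SP", "SP",
                "RR"),
    disease_duration = c(31, 15, 32, 1, 29, 4, 14, 3, 25, 1, 23, 5, 23,
                         33, 18, 5, 27, 8, 31, 9, 2),
    edss = c(6, 4.5, 6.5, 6.5, 7.5, 6, 7, 2.5, 7.5, 2, 8, 6.5, 8.5, 6,
             6.5, 6, 6, 7.5, 5.5, 6.5, 6.5)
  )
}

#' Convert a Nine Hole Peg Test time to pegs moved per minute
#'
#' One trial moves 9 pegs; the per-second rate `9 / time` is rounded to
#' two decimals and scaled to a minute: `rate = 60 * round(9 / time, 2)`.
#' Subjects unable to complete the test (`NA` or `"unable"`) are assigned
#' a rate of 0, which keeps the score defined for the whole cohort.
#'
#' @param time Completion time(s) in seconds; `NA` (or the string
#'   `"unable"`) encodes an incomplete test.
#' @return Pegs per minute (numeric vector).
#' @export
#' @examples
#' pegs_per_minute(c(25.0, 37.5, NA))
pegs_per_minute <- function(time) {
  if (is.character(time)) {
    time <- ifelse(tolower(time) == "unable", NA_character_, time)
    time <- as.numeric(time)
  }
  if (any(!is.na(time) & time <= 0)) {
    iarat_abort("time must be positive (or NA/'unable')",
                class = "iarat_parameter_error")
  }
  ifelse(is.na(time), 0, 60 * round(9 / time, 2))
}

#' Impairment sub-groups by hierarchical clustering of clinical scores
#'
#' Standardizes the clinical features (default: ARAT total, 9HPT pegs per
#' minute and the FTRS postural+intention sum — the representations
#' defined for every subject, including those unable to complete the peg
#' test) across the cohort, computes Euclidean distances and builds the
#' UPGMA (average linkage) agglomerative tree; cluster labels come from
#' cutting the tree at `k` clusters. `stats::hclust` breaks merge ties
#' deterministically by merge order.
#'
#' @param records Tibble of clinical records (see [ms_clinical()]).
#' @param k Number of clusters to cut at.
#' @param features Column names entering the clustering.
#' @return An `impairment_clustering`: list with `labels` (tibble
#'   `subject`, `cluster`), the `hclust` tree, `k` and `features`.
#' @export
#' @examples
#' cl <- cluster_impairment(ms_clinical(), k = 3)
#' table(cl$labels$cluster)
cluster_impairment <- function(records, k = 3,
                               features = c("arat", "nhpt_rate", "ftrs_sum")) {
  if (nrow(records) < k) {
    iarat_abort("need at least k records", class = "iarat_parameter_error")
  }
  x <- as.matrix(records[features])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    iarat_abort(
      paste0("constant feature(s), cannot standardize: ",
             paste(features[sds == 0], collapse = ", ")),
      class = "iarat_standardization_error"
    )
  }
  xs <- scale(x)
  tree <- stats::hclust(stats::dist(xs), method = "average")
  cl <- stats::cutree(tree, k = k)
  structure(
    list(
      labels = tibble(subject = records$subject, cluster = unname(cl)),
      tree = tree, k = k, features = features
    ),
    class = "impairment_clustering"
  )
}

#' @export
print.impairment_clustering <- function(x, ...) {
  cat(sprintf("<impairment_clustering> k = %d on (%s)\n", x$k,
              paste(x$features, collapse = ", ")))
  print(table(cluster = x$labels$cluster))
  invisible(x)
}

#' Median and range summary of clinical variables
#'
#' Per (optional) group and numeric variable: median (average of the two
#' central order statistics for even n), minimum, maximum and the count of
#' non-missing values. Missing values (e.g. peg-test times of subjects
#' unable to complete it) are skipped, with the skip count retained in
#' `n` versus `n_total`.
#'
#' @param records Tibble of clinical records.
#' @param by Optional grouping column name (e.g. `"impairment"`).
#' @param variables Columns to summarize; defaults to every numeric column.
#' @return Long tibble with columns (`group`,) `variable`, `median`,
#'   `min`, `max`, `n`, `n_total`.
#' @export
#' @examples
#' cohort_summary(ms_clinical(), by = "impairment")
cohort_summary <- function(records, by = NULL, variables = NULL) {
  if (nrow(records) == 0) {
    iarat_abort("empty cohort", class = "iarat_parameter_error")
  }
  if (is.null(variables)) {
    variables <- names(records)[vapply(records, is.numeric, logical(1))]
    variables <- setdiff(variables, by)
  }
  long <- records[unique(c(by, variables))] |>
    tidyr::pivot_longer(dplyr::all_of(variables), names_to = "variable",
                        values_to = "value")
  if (!is.null(by)) names(long)[1] <- "group"
  grp <- if (is.null(by)) "variable" else c("group", "variable")
  long |>
    group_by(dplyr::across(dplyr::all_of(grp))) |>
    summarise(
      median = stats::median(.data$value, na.rm = TRUE),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      n = sum(!is.na(.data$value)),
      n_total = dplyr::n(),
      .groups = "drop"
    )
}
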