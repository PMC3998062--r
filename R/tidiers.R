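#' Tidy a phase segmentation
#'
#' @param x A `phase_segmentation`.
#' @param ... Unused.
#' @return Tibble with columns `item`, `phase`, `onset`, `offset`,
#'   `duration`.
#' @export
tidy.phase_segmentation <- function(x, ...) {
  as_tibble(x) |>
    mutate(phase = as.character(.data$phase),
           duration = .data$offset - .data$onset)
}

#' @export
glance.phase_segmentation <- function(x, ...) {
  tibble(
    item = attr(x, "item"),
    n_phases = nrow(x),
    task_duration = max(x$offset) - min(x$onset),
    theta = attr(x, "config")$theta,
    omega_max_scope = attr(x, "config")$omega_max_scope
  )
}

#' Tidy an impairment clustering
#'
#' @param x An `impairment_clustering`.
#' @param ... Unused.
#' @return Tibble with columns `subject`, `cluster`, `cluster_size`.
#' @export
tidy.impairment_clustering <- function(x, ...) {
  x$labels |>
    add_count(.data$cluster, name = "cluster_size")
}

#' @export
glance.impairment_clustering <- function(x, ...) {
  sizes <- sort(table(x$labels$cluster), decreasing = TRUE)
  tibble(
    k = x$k,
    n = nrow(x$labels),
    largest_cluster = as.integer(sizes[1]),
    max_merge_height = max(x$tree$height)
  )
}

#' @export
print.segmentation_config <- function(x, ...) {
  cat(sprintf(
    "<segmentation_config> theta = %.2f (%s), gyro cutoff = %g Hz, merge gap = %g s\n",
    x$theta, x$omega_max_scope, x$gyro_cutoff, x$merge_gap
  ))
  invisible(x)
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("<simulation_spec> group = %s, tremor = %g m/s^2 @ %g-%g Hz\n",
              x$group, x$tremor_amp, x$tremor_freq[1], x$tremor_freq[2]))
  print(round(x$phase_duration, 3))
  invisible(x)
}
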