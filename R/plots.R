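#' Plot a segmented task
#'
#' Angular-speed profile with the detected sub-movements shaded and the
#' threshold line drawn; the gravity-free vertical acceleration is shown
#' underneath with the return-termination instant marked.
#'
#' @param object A `phase_segmentation` from [segment_task()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_segmentation <- function(object, ...) {
  omega <- attr(object, "omega")
  cfg <- attr(object, "config")
  seg <- as_tibble(object)
  thr <- cfg$theta * max(omega$omega)
  ggplot() +
    geom_rect(
      data = mutate(seg, phase = factor(.data$phase, phase_levels())),
      aes(xmin = .data$onset, xmax = .data$offset, ymin = -Inf, ymax = Inf,
          fill = .data$phase),
      alpha = 0.25
    ) +
    geom_line(data = omega, aes(x = .data$t, y = .data$omega)) +
    geom_hline(yintercept = thr, linetype = "dashed", colour = "grey40") +
    labs(
      x = "time [s]", y = expression(Omega ~ "[deg/s]"), fill = "phase",
      title = sprintf("Item %d segmentation (theta = %.2f)",
                      attr(object, "item"), cfg$theta)
    ) +
    theme_minimal()
}

#' Boxplot of subject-level z-scores by group
#'
#' @param subject_z Output of [subject_zscores()].
#' @param phase Phase to display (default `"task"`).
#' @return A ggplot object.
#' @export
plot_zscores <- function(subject_z, phase = "task") {
  dat <- filter(subject_z, .data$phase == !!phase)
  ggplot(dat, aes(x = .data$group, y = .data$z, fill = .data$group)) +
    geom_boxplot(outlier.shape = 21) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    facet_wrap(~parameter, scales = "free_y",
               labeller = labeller(parameter = c(duration = "Z Duration",
                                                 jerk = "Z Jerk"))) +
    labs(x = NULL, y = "z-score vs controls") +
    theme_minimal() +
    theme(legend.position = "none")
}

# dendrogram segment coordinates from an hclust object
dendro_segments <- function(tree) {
  n <- length(tree$order)
  leaf_x <- numeric(n)
  leaf_x[tree$order] <- seq_len(n)
  node_x <- numeric(nrow(tree$merge))
  node_h <- tree$height
  segs <- vector("list", nrow(tree$merge))
  child <- function(id) {
    if (id < 0) c(x = leaf_x[-id], h = 0) else c(x = node_x[id], h = node_h[id])
  }
  for (i in seq_len(nrow(tree$merge))) {
    a <- child(tree$merge[i, 1])
    b <- child(tree$merge[i, 2])
    node_x[i] <- (a["x"] + b["x"]) / 2
    segs[[i]] <- tibble(
      x = c(a[["x"]], b[["x"]], a[["x"]]),
      xend = c(a[["x"]], b[["x"]], b[["x"]]),
      y = c(a[["h"]], b[["h"]], node_h[i]),
      yend = c(node_h[i], node_h[i], node_h[i])
    )
  }
  list_rbind(segs)
}

#' Dendrogram of the impairment clustering
#'
#' @param object An `impairment_clustering` from [cluster_impairment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.impairment_clustering <- function(object, ...) {
  tree <- object$tree
  n <- length(tree$order)
  leaves <- tibble(
    x = seq_len(n),
    subject = object$labels$subject[tree$order],
    cluster = factor(object$labels$cluster[tree$order])
  )
  ggplot() +
    geom_segment(data = dendro_segments(tree),
                 aes(x = .data$x, xend = .data$xend, y = .data$y,
                     yend = .data$yend)) +
    geom_text(data = leaves,
              aes(x = .data$x, y = -0.02, label = .data$subject,
                  colour = .data$cluster),
              angle = 90, hjust = 1, size = 3) +
    scale_y_continuous(expand = expansion(mult = c(0.25, 0.05))) +
    labs(x = NULL, y = "UPGMA merge height", colour = "cluster") +
    theme_minimal() +
    theme(axis.text.x = element_blank(), panel.grid.major.x = element_blank())
}
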