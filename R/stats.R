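new_arat_test <- function(statistic, p.value, method, n, exact = NA,
                          degenerate = FALSE) {
  structure(
    list(statistic = statistic, p.value = p.value, method = method,
         n = n, exact = exact, degenerate = degenerate),
    class = "arat_test"
  )
}

#' @export
print.arat_test <- function(x, ...) {
  cat(sprintf("<arat_test> %s\n  %s = %.6g, p = %.4g%s%s\n",
              x$method, names(x$statistic)[1], x$statistic, x$p.value,
              if (isTRUE(x$exact)) " (exact)" else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
tidy.arat_test <- function(x, ...) {
  tibble(statistic = unname(x$statistic), p.value = x$p.value,
         method = x$method, exact = x$exact, degenerate = x$degenerate)
}

#' @export
glance.arat_test <- function(x, ...) {
  bind_cols(tidy(x), tibble(!!!as.list(x$n)))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midrank ties. The U statistic counts, over
#' all pairs, how often an `x` value exceeds a `y` value (ties count 1/2).
#' For small samples (total n <= 16, or `mode = "exact"`) the p-value is
#' computed by full enumeration of all group assignments of the pooled
#' midranks, which remains valid under ties; otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return An `arat_test` (statistic `U`, two-sided `p.value`).
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    iarat_abort("both samples must be non-empty",
                class = "iarat_parameter_error")
  }
  nx <- length(x)
  ny <- length(y)
  N <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  n_out <- c(n_x = nx, n_y = ny)
  if (length(unique(pooled)) == 1) {
    return(new_arat_test(c(U = U), 1, "Mann-Whitney U test", n_out,
                         exact = NA, degenerate = TRUE))
  }
  exact <- mode == "exact" || (mode == "auto" && N <= 16)
  if (exact) {
    sets <- utils::combn(N, nx)
    base <- nx * (nx + 1) / 2
    Us <- colSums(matrix(r[sets], nrow = nx)) - base
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
  } else {
    ties <- table(pooled)
    sigma2 <- nx * ny / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      return(new_arat_test(c(U = U), 1, "Mann-Whitney U test", n_out,
                           exact = FALSE, degenerate = TRUE))
    }
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  new_arat_test(c(U = U), p, "Mann-Whitney U test", n_out, exact = exact)
}

#' Kruskal-Wallis test
#'
#' Rank test for location differences among two or more independent
#' groups, with tie correction; p from the chi-square distribution with
#' g - 1 degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param groups List of numeric samples.
#' @return An `arat_test` (statistic `H`).
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))  # H = 32/7
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(lengths(groups) == 0)) {
    iarat_abort("need >= 2 non-empty groups", class = "iarat_parameter_error")
  }
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  n_out <- setNames(lengths(groups), paste0("n_", seq_along(groups)))
  if (length(unique(values)) == 1) {
    return(new_arat_test(c(H = 0), 1, "Kruskal-Wallis test", n_out,
                         degenerate = TRUE))
  }
  kt <- stats::kruskal.test(values, g)
  new_arat_test(c(H = unname(kt$statistic)), kt$p.value,
                "Kruskal-Wallis test", n_out)
}

#' Friedman test
#'
#' Within-block rank test for k related treatments over n complete blocks
#' (via [stats::friedman.test()] on the blocks-by-treatments matrix).
#'
#' @param blocked Numeric matrix or data frame, rows = blocks,
#'   columns = treatments; no missing values.
#' @return An `arat_test` (statistic `chi_squared`).
#' @export
friedman <- function(blocked) {
  m <- as.matrix(blocked)
  if (ncol(m) < 2 || anyNA(m)) {
    iarat_abort("need a complete block design with k >= 2 treatments",
                class = "iarat_parameter_error")
  }
  if (all(apply(m, 1, function(row) length(unique(row)) == 1))) {
    return(new_arat_test(c(chi_squared = 0), 1, "Friedman test",
                         c(n_blocks = nrow(m), k = ncol(m)),
                         degenerate = TRUE))
  }
  ft <- stats::friedman.test(m)
  new_arat_test(c(chi_squared = unname(ft$statistic)), ft$p.value,
                "Friedman test", c(n_blocks = nrow(m), k = ncol(m)))
}

#' Holm step-down adjustment
#'
#' Bonferroni-Holm multiple-testing correction: sort p-values ascending,
#' take the running maximum of `(m - i + 1) * p_(i)`, cap at 1, and return
#' in the original order (via [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03, 0.06, 0.06
holm_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    iarat_abort("p-values must lie in [0, 1]", class = "iarat_parameter_error")
  }
  stats::p.adjust(pvalues, method = "holm")
}

# all permutations of 1..n as an n! x n matrix (n <= 9)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- sub
    m[m >= i] <- m[m >= i] + 1L
    out[[i]] <- cbind(rep(i, nrow(sub)), m, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. For n <= 9 (or `mode = "exact"`) the
#' two-sided p-value comes from full enumeration of all permutations of
#' one rank vector; otherwise from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom.
#'
#' @param x,y Numeric samples of equal length >= 3.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return An `arat_test` (statistic `r`).
#' @export
spearman <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  n <- length(x)
  if (length(y) != n || n < 3) {
    iarat_abort("x and y must have equal length >= 3",
                class = "iarat_parameter_error")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    iarat_abort("undefined correlation: zero rank variance",
                class = "iarat_undefined_metric_error")
  }
  r <- stats::cor(rx, ry)
  exact <- mode == "exact" || (mode == "auto" && n <= 9)
  if (exact) {
    perms <- permutations_of(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rs <- (matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rs) >= abs(r) - 1e-12)
  } else {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  new_arat_test(c(r = r), p, "Spearman rank correlation", c(n = n),
                exact = exact)
}

#' Pairwise post-hoc comparisons with Holm adjustment
#'
#' All pairwise Mann-Whitney comparisons between the supplied groups, with
#' Holm-adjusted p-values — the post-hoc pattern applied after a
#' significant Kruskal-Wallis (independent groups) result.
#'
#' @param groups Named list of numeric samples.
#' @return Tibble with columns `group1`, `group2`, `statistic`, `p.value`,
#'   `p.adjusted`.
#' @export
pairwise_posthoc <- function(groups) {
  nm <- names(groups) %||% as.character(seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    tst <- mann_whitney(groups[[i1]], groups[[i2]])
    tibble(group1 = nm[i1], group2 = nm[i2],
           statistic = unname(tst$statistic), p.value = tst$p.value)
  }) |> list_rbind()
  res$p.adjusted <- holm_adjust(res$p.value)
  res
}
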