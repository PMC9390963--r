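#' Per-cell transcriptional momentum
#'
#' The squared L2 norm of each cell's two-dimensional embedding velocity
#' vector: `vx^2 + vy^2`. Rotation-invariant and always non-negative.
#'
#' @param velocities tibble with columns `cell_id`, `vx`, `vy` and
#'   (optionally) `group`.
#' @return the input tibble with a `momentum` column appended.
#' @export
momentum <- function(velocities) {
  need <- c("cell_id", "vx", "vy")
  if (!all(need %in% names(velocities))) {
    abort("velocities must have columns cell_id, vx, vy")
  }
  bad <- !is.finite(velocities$vx) | !is.finite(velocities$vy)
  if (any(bad)) {
    abort(paste("non-finite velocity component for cell(s):",
                paste(velocities$cell_id[bad], collapse = ", ")))
  }
  mutate(velocities, momentum = .data$vx^2 + .data$vy^2)
}

#' Compare momentum distributions across groups
#'
#' Per-group summaries, pairwise two-sided Wilcoxon rank-sum tests, and
#' Gaussian kernel densities evaluated on a shared grid (Scott's rule
#' bandwidth by default).
#'
#' @param momenta tibble with columns `group` and `momentum`
#'   (from [momentum()]).
#' @param bw kernel bandwidth; default Scott's rule on the pooled momenta.
#' @param n_grid grid resolution for the shared density grid.
#' @return a `momentum_comparison` list: `summary` (tibble group / n / mean /
#'   median), `tests` (tibble group_a / group_b / statistic / p_value),
#'   `density` (tibble group / momentum / density).
#' @export
compare_momentum <- function(momenta, bw = NULL, n_grid = 512) {
  if (!all(c("group", "momentum") %in% names(momenta))) {
    abort("momenta must have columns group and momentum")
  }
  groups <- unique(momenta$group)
  if (length(groups) < 2) abort("need at least 2 groups")
  sizes <- table(momenta$group)
  if (any(sizes < 3)) abort("every group needs at least 3 cells")

  summary_tbl <- momenta |>
    group_by(.data$group) |>
    summarise(n = n(), mean = mean(.data$momentum),
              median = median(.data$momentum), .groups = "drop")

  pairs <- utils::combn(as.character(groups), 2)
  tests <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- momenta$momentum[momenta$group == pairs[1, j]]
    b <- momenta$momentum[momenta$group == pairs[2, j]]
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                       exact = FALSE, correct = TRUE))
    tibble(group_a = pairs[1, j], group_b = pairs[2, j],
           statistic = unname(wt$statistic), p_value = wt$p.value)
  }) |> bind_rows()

  if (is.null(bw)) {
    pooled <- momenta$momentum
    bw <- if (sd(pooled) > 0) bw.nrd(pooled) else 1
  }
  grid <- seq(min(momenta$momentum), max(momenta$momentum), length.out = n_grid)
  if (grid[1] == grid[n_grid]) grid <- grid[1] + seq(-1, 1, length.out = n_grid)
  dens <- purrr::map(as.character(groups), function(g) {
    v <- momenta$momentum[momenta$group == g]
    if (sd(v) == 0) {
      warn(sprintf("group '%s' has constant momenta; density is degenerate", g))
    }
    d <- density(v, bw = bw, from = grid[1], to = grid[n_grid], n = n_grid)
    tibble(group = g, momentum = d$x, density = d$y)
  }) |> bind_rows()

  structure(list(summary = summary_tbl, tests = tests, density = dens,
                 bw = bw),
            class = "momentum_comparison")
}

#' @export
print.momentum_comparison <- function(x, ...) {
  cat("<momentum_comparison>\n")
  print(x$summary)
  print(x$tests)
  invisible(x)
}
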