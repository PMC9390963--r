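#' Tree-ensemble gene regulatory network inference
#'
#' GENIE3-style inference: each target gene's expression, standardized to
#' unit variance, is regressed on the candidate regulators with a random
#' forest (`k_mode` features tried per split), and each regulator's edge
#' importance is its total variance-reduction (node-impurity decrease)
#' importance averaged over trees. Samples are treated as i.i.d. observations.
#'
#' @param matrix gene x sample expression matrix (>= 5 samples).
#' @param regulators candidate regulator gene ids; default all genes.
#' @param n_trees trees per forest.
#' @param k_mode features per split: `"sqrt"`, `"all"`, or an integer.
#' @param seed integer seed (per-target forests get independent derived
#'   seeds, so fits are order-independent).
#' @param targets genes to fit as targets; default all genes.
#' @return an `importance_network` list with `edges`
#'   (tibble: regulator, target, importance, sorted by importance),
#'   `regulators`, `n_trees`, `k_mode`, `seed`.
#' @export
infer_network <- function(matrix, regulators = rownames(matrix),
                          n_trees = 1000, k_mode = "sqrt", seed = 42L,
                          targets = rownames(matrix)) {
  check_expression_matrix(matrix)
  if (ncol(matrix) < 5) abort("network inference needs at least 5 samples")
  missing_reg <- setdiff(regulators, rownames(matrix))
  if (length(missing_reg)) {
    abort(paste("regulators absent from the matrix:",
                paste(missing_reg, collapse = ", ")))
  }
  # Canonicalize sample order: samples are exchangeable rows, so results must
  # not depend on the column order of the input matrix.
  x <- t(matrix[, order(colnames(matrix)), drop = FALSE])  # samples x genes
  # Derive one sub-seed per target so per-target fits are independent and
  # identical whether run sequentially or not.
  target_seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                             length(targets)))
  edge_list <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    tgt <- targets[ti]
    preds <- setdiff(regulators, tgt)
    if (length(preds) < 2) {
      warn(sprintf("target '%s' has fewer than 2 candidate regulators; skipped", tgt))
      next
    }
    y <- x[, tgt]
    if (sd(y) == 0) {
      warn(sprintf("target '%s' is constant; importances set to 0", tgt))
      edge_list[[ti]] <- tibble(regulator = preds, target = tgt, importance = 0)
      next
    }
    y <- y / sd(y)  # unit-variance standardization of the target
    mtry <- switch(as.character(k_mode),
                   sqrt = max(1L, floor(sqrt(length(preds)))),
                   all = length(preds),
                   {
                     k <- suppressWarnings(as.integer(k_mode))
                     if (is.na(k) || k < 1) abort("k_mode must be 'sqrt', 'all' or a positive integer")
                     min(k, length(preds))
                   })
    imp <- with_seed(target_seeds[ti], {
      rf <- randomForest::randomForest(
        x = x[, preds, drop = FALSE], y = y,
        ntree = n_trees, mtry = mtry, importance = FALSE
      )
      # IncNodePurity: total RSS decrease per predictor, summed within trees
      # and averaged over trees -- GENIE3's variance-reduction importance.
      rf$importance[, "IncNodePurity"] / n_trees
    })
    edge_list[[ti]] <- tibble(regulator = preds, target = tgt,
                              importance = unname(imp))
  }
  edges <- bind_rows(edge_list)
  edges <- arrange(edges, desc(.data$importance))
  structure(
    list(edges = edges, regulators = regulators, n_trees = n_trees,
         k_mode = k_mode, seed = seed),
    class = "importance_network"
  )
}

#' @export
print.importance_network <- function(x, ...) {
  cat(sprintf("<importance_network> %d edges, %d candidate regulators, %d trees (k = %s)\n",
              nrow(x$edges), length(x$regulators), x$n_trees, x$k_mode))
  invisible(x)
}

#' Rank regulators by summed outgoing importance
#'
#' @param net an `importance_network` (or a bare edge tibble with columns
#'   regulator / target / importance).
#' @param top_n how many regulators to retain.
#' @return tibble: gene, outgoing_sum, rank; sorted by outgoing sum
#'   descending, ties broken lexicographically by gene id.
#' @export
rank_regulators <- function(net, top_n = 100) {
  edges <- if (inherits(net, "importance_network")) net$edges else net
  if (nrow(edges) == 0) abort("network has no edges")
  ranking <- edges |>
    group_by(gene = .data$regulator) |>
    summarise(outgoing_sum = sum(.data$importance), .groups = "drop") |>
    arrange(desc(.data$outgoing_sum), .data$gene)
  if (top_n > nrow(ranking)) {
    warn(sprintf("top_n = %d exceeds the %d regulators; returning all",
                 top_n, nrow(ranking)))
    top_n <- nrow(ranking)
  }
  ranking <- head(ranking, top_n)
  ranking$rank <- seq_len(nrow(ranking))
  ranking
}

#' Group ranked regulators into dynamic modules by k-means
#'
#' k-means on the z-scored time profiles of the ranked regulators
#' (k-means++ seeding, deterministic for a fixed seed).
#'
#' @param ranking tibble from [rank_regulators()] (column `gene`).
#' @param profiles `profile_matrix` covering every ranked gene.
#' @param k number of modules.
#' @param seed integer seed.
#' @param nstart k-means restarts (best of).
#' @return tibble: gene, module.
#' @export
group_regulator_profiles <- function(ranking, profiles, k = 4, seed = 17L,
                                     nstart = 25) {
  genes <- ranking$gene
  missing <- setdiff(genes, rownames(profiles))
  if (length(missing)) {
    abort(paste("ranked genes without profiles:", paste(missing, collapse = ", ")))
  }
  if (length(genes) < k) abort("fewer ranked genes than modules k")
  z <- row_zscore(unclass(profiles)[genes, , drop = FALSE])$values
  km <- with_seed(seed, kmeans(z, centers = k, nstart = nstart, iter.max = 100))
  tibble(gene = genes, module = unname(km$cluster[genes]))
}
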