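#' Run the full synthetic analysis pipeline
#'
#' Chains the five analysis stages on one configuration:
#' simulate (time course + annotations with ground truth), cluster (fuzzy
#' c-means per model on responder profiles, trend matching across models),
#' grn (tree-ensemble network per model on responder samples), signature
#' (fast-on/off ISG derivation from responder time courses, consistent
#' across both models) and prune (promoter-window direct connections plus
#' the hive-quadrant statistic). All randomness flows from the seeds
#' recorded in the manifest; rerunning with the same config reproduces
#' identical outputs.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, every intermediate
#'   artifact (TSV / BED6 / GMT / JSON manifest) is written there.
#' @param k_clusters fuzzy c-means cluster count.
#' @param r_min minimum Pearson correlation declaring matched clusters.
#' @param n_trees trees per random forest in the GRN stage.
#' @param grn_seed seed of the GRN stage.
#' @param window_up,window_down promoter window extents, bp.
#' @param signature_k k for the fast/slow ISG split.
#' @param quantile quantile level of the hive-quadrant statistic.
#' @param early_timepoint_index named integer vector: per-model column index
#'   of the early timepoint used to label the fast ISG cluster (default
#'   first timepoint for the first model, second for the second, mirroring
#'   the per-model upregulation days).
#' @param verbose emit one log line per stage.
#' @return an `onoffgrn_run` list; see Details.
#'
#' @details The returned list carries `sim` (the `sim_timecourse`),
#'   `annotations`, `clusterings` (per model), `matches` (cross-model trend
#'   matches), `fast_onoff_match` (the matched pair with the on/fast-off
#'   centroid shape, if any), `networks` (per model), `signature` (per-model
#'   fast/slow tables), `fast_genes` (genes fast in every model),
#'   `direct` (per-model pruned networks), `quadrant` (per-model hive
#'   statistics) and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = NULL,
                         k_clusters = 6, r_min = 0.8,
                         n_trees = 100, grn_seed = 42L,
                         window_up = 400, window_down = 300,
                         signature_k = 2, quantile = 0.9,
                         early_timepoint_index = NULL,
                         verbose = TRUE) {
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  t_all <- Sys.time()
  models <- config$models
  if (is.null(early_timepoint_index)) {
    early_timepoint_index <- setNames(pmin(seq_along(models), 2L), models)
  }

  # -- stage 1: simulate ------------------------------------------------
  sim <- simulate_timecourse(config)
  annotations <- simulate_annotations(sim$truth, window_up = window_up,
                                      window_down = window_down,
                                      seed = config$seed + 1L)
  say("simulate", "%d genes x %d samples, %d true edges (%d direct)",
      nrow(sim$counts), ncol(sim$counts), nrow(sim$truth$edges),
      sum(sim$truth$edges$direct))

  # -- stage 2: cluster -------------------------------------------------
  # Time profiles are built on the log2(count + 1) scale: the dynamic shapes
  # live on the log scale and count noise is variance-stabilized there.
  log_counts <- log_transform(sim$counts)
  clusterings <- list()
  profiles <- list()
  for (m in models) {
    prof <- average_replicates(log_counts, sim$meta, m, "responder")
    profiles[[m]] <- prof
    clusterings[[m]] <- fuzzy_cmeans(znormalize(prof), k = k_clusters,
                                     seed = config$seed)
  }
  matches <- if (length(models) >= 2) {
    match_clusters(clusterings[[1]], clusterings[[2]], r_min = r_min)
  } else {
    tibble(cluster_a = integer(), cluster_b = integer(), pearson_r = double())
  }
  fast_match <- NULL
  for (i in seq_len(nrow(matches))) {
    ca <- clusterings[[1]]$centroids[matches$cluster_a[i], ]
    cb <- clusterings[[2]]$centroids[matches$cluster_b[i], ]
    if (is_fast_onoff_shape(ca) && is_fast_onoff_shape(cb)) {
      fast_match <- matches[i, ]
      break
    }
  }
  say("cluster", "k = %d per model; %d matched pairs at r >= %.2f",
      k_clusters, nrow(matches), r_min)

  # -- stage 3: grn -----------------------------------------------------
  networks <- list()
  for (m in models) {
    ids <- sim$meta$sample_id[sim$meta$model == m &
                                sim$meta$response == "responder"]
    networks[[m]] <- infer_network(sim$counts[, ids, drop = FALSE],
                                   regulators = sim$truth$tf_genes,
                                   n_trees = n_trees, seed = grn_seed,
                                   targets = rownames(sim$counts))
    say("grn", "%s: %d edges from %d responder samples (%d trees)",
        m, nrow(networks[[m]]$edges), length(ids), n_trees)
  }

  # -- stage 4: signature -----------------------------------------------
  isg_candidates <- names(sim$truth$isg_class)
  signatures <- list()
  for (m in models) {
    signatures[[m]] <- extract_fast_onoff(
      profiles[[m]], isg_candidates, k = signature_k,
      early_timepoint_index = early_timepoint_index[[m]],
      seed = config$seed, isg_class = sim$truth$isg_class
    )
  }
  fast_per_model <- purrr::map(signatures, ~ .x$gene[.x$fast])
  fast_genes <- purrr::reduce(fast_per_model, intersect)
  say("signature", "%d fast-on/off genes consistent across %d model(s)",
      length(fast_genes), length(models))

  # -- stage 5: prune + quadrant ---------------------------------------
  direct <- list()
  quadrant <- list()
  for (m in models) {
    direct[[m]] <- prune_direct(
      networks[[m]], annotations$tss, annotations$tfbs,
      de_genes = sim$truth$de_genes, tf_list = sim$truth$tf_genes,
      up = window_up, down = window_down,
      fast_isgs = fast_genes
    )
    quadrant[[m]] <- hive_quadrant_stats(direct[[m]], quantile = quantile)
    say("prune", "%s: %d direct edges; top-decile TF-to-ISG fraction %.3f",
        m, nrow(direct[[m]]$edges),
        quadrant[[m]]$fraction_in_tf_to_isg_quadrant)
  }

  manifest <- list(
    package = "onoffgrn",
    version = as.character(utils::packageVersion("onoffgrn")),
    stages = c("simulate", "cluster", "grn", "signature", "prune"),
    seeds = list(simulate = config$seed, annotations = config$seed + 1L,
                 cluster = config$seed, grn = grn_seed,
                 signature = config$seed),
    parameters = list(
      n_genes = config$n_genes, n_tfs = config$n_tfs,
      n_isg_fast = config$n_isg_fast, k_clusters = k_clusters,
      r_min = r_min, n_trees = n_trees, window_up = window_up,
      window_down = window_down, signature_k = signature_k,
      quantile = quantile,
      early_timepoint_index = as.list(early_timepoint_index)
    )
  )

  run <- structure(
    list(sim = sim, annotations = annotations, clusterings = clusterings,
         matches = matches, fast_onoff_match = fast_match,
         networks = networks, signature = signatures,
         fast_genes = fast_genes, direct = direct, quadrant = quadrant,
         manifest = manifest),
    class = "onoffgrn_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  say("done", "pipeline finished in %.1f s",
      as.numeric(difftime(Sys.time(), t_all, units = "secs")))
  run
}

# Persist every intermediate artifact of a pipeline run as plain text.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_matrix(run$sim$counts, p("counts.tsv"))
  readr::write_tsv(run$sim$meta, p("meta.tsv"), progress = FALSE)
  write_tss_bed(run$annotations$tss, p("tss.bed"))
  write_tfbs_bed(run$annotations$tfbs, p("tfbs.bed"))
  writeLines(run$sim$truth$de_genes, p("de_genes.txt"))
  writeLines(run$sim$truth$tf_genes, p("tf_list.txt"))
  cls <- run$sim$truth$isg_class
  write_gmt(list(
    ISG_ALPHA_BETA = names(cls)[cls %in% c("alpha_beta", "both")],
    ISG_GAMMA = names(cls)[cls %in% c("gamma", "both")],
    FAST_ISG_TRUTH = run$sim$truth$fast_isg_genes
  ), p("gene_sets.gmt"))
  jsonlite::write_json(
    list(edges = run$sim$truth$edges,
         archetype = as.list(run$sim$truth$archetype),
         fast_isg_genes = run$sim$truth$fast_isg_genes,
         de_genes = run$sim$truth$de_genes),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  for (m in names(run$networks)) {
    readr::write_tsv(run$networks[[m]]$edges,
                     p(sprintf("edges_%s.tsv", m)), progress = FALSE)
    readr::write_tsv(run$direct[[m]]$edges,
                     p(sprintf("direct_edges_%s.tsv", m)), progress = FALSE)
    readr::write_tsv(run$signature[[m]],
                     p(sprintf("signature_%s.tsv", m)), progress = FALSE)
    readr::write_tsv(run$quadrant[[m]],
                     p(sprintf("quadrant_%s.tsv", m)), progress = FALSE)
    m_idx <- match(m, names(run$clusterings))
    readr::write_tsv(
      as_tibble(run$clusterings[[m]]$membership, rownames = "gene"),
      p(sprintf("membership_%s.tsv", m)), progress = FALSE)
    readr::write_tsv(
      as_tibble(run$clusterings[[m]]$centroids, rownames = "cluster"),
      p(sprintf("centroids_%s.tsv", m)), progress = FALSE)
  }
  readr::write_tsv(run$matches, p("cluster_matches.tsv"), progress = FALSE)
  writeLines(run$fast_genes, p("fast_onoff_genes.txt"))
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.onoffgrn_run <- function(x, ...) {
  cat("<onoffgrn_run>\n")
  cat(sprintf("  models: %s\n", paste(names(x$networks), collapse = ", ")))
  cat(sprintf("  %d cross-model cluster matches; %d fast-on/off genes\n",
              nrow(x$matches), length(x$fast_genes)))
  for (m in names(x$quadrant)) {
    cat(sprintf("  %s: %d direct edges, TF-to-ISG quadrant fraction %.3f\n",
                m, nrow(x$direct[[m]]$edges),
                x$quadrant[[m]]$fraction_in_tf_to_isg_quadrant))
  }
  invisible(x)
}
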