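#' Simulate the checkpoint-blockade expression time course with known truth
#'
#' Draws a gene x sample negative-binomial count matrix for every cell of the
#' design (model x response x timepoint x replicate), together with sample
#' metadata and the generating ground truth: the TF-to-target edge set, each
#' gene's dynamic archetype, the promoter-proximal ("direct") edge subset, the
#' differentially expressed gene set and the fast interferon-stimulated gene
#' set. The noiseless mean model follows the archetype templates exactly: in
#' responders, on/fast-off genes peak at the first timepoint and fall below
#' half of their peak by the last, while in non-responders they rise
#' monotonically.
#'
#' @param config a [sim_config()].
#'
#' @return a `sim_timecourse` list with elements
#'   `counts` (gene x sample matrix, layer `"counts"`),
#'   `meta` (tibble: sample_id, model, timepoint_day, response, mouse_id,
#'   replicate, lib_factor),
#'   `truth` (a `ground_truth` list, see below),
#'   `log2_mean` (list of gene x timepoint noiseless log2-mean matrices per
#'   arm) and `config`.
#'
#'   `truth` carries: `edges` (tibble regulator / target / weight / direct),
#'   `archetype` (named character, every gene), `tf_genes`, `ifn_tf_genes`,
#'   `fast_isg_genes` (non-TF on/fast-off genes), `de_genes` (genes whose
#'   responder and non-responder mean profiles differ), `isg_class` (named
#'   character over the ISG signature candidates: `alpha_beta`, `gamma` or
#'   `both`) and `baseline` (named numeric, log2).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, {
    truth <- draw_ground_truth(config)
    log2_mean <- archetype_mean_model(truth, config)
    truth$de_genes <- attr(log2_mean, "de_genes")

    nt <- length(config$timepoints)
    grid <- tidyr::expand_grid(
      model = config$models,
      response = c("responder", "non_responder"),
      timepoint_day = config$timepoints,
      replicate = seq_len(config$replicates_per_cell)
    )
    grid$sample_id <- sprintf(
      "%s_%s_d%g_r%d", grid$model,
      ifelse(grid$response == "responder", "R", "NR"),
      grid$timepoint_day, grid$replicate
    )
    grid$mouse_id <- sprintf(
      "m_%s_%s_d%g_%d", grid$model,
      ifelse(grid$response == "responder", "R", "NR"),
      grid$timepoint_day, grid$replicate
    )
    grid$lib_factor <- runif(nrow(grid), config$libsize_range[1],
                             config$libsize_range[2])

    genes <- names(truth$archetype)
    mu <- matrix(NA_real_, length(genes), nrow(grid),
                 dimnames = list(genes, grid$sample_id))
    for (i in seq_len(nrow(grid))) {
      ti <- match(grid$timepoint_day[i], config$timepoints)
      mu[, i] <- 2^log2_mean[[grid$response[i]]][, ti]
    }
    counts <- draw_nb_counts(mu, grid$lib_factor, config$dispersion)
    counts <- set_expr_layer(counts, "counts")

    structure(
      list(counts = counts,
           meta = as_tibble(grid[, c("sample_id", "model", "timepoint_day",
                                     "response", "mouse_id", "replicate",
                                     "lib_factor")]),
           truth = truth,
           log2_mean = log2_mean,
           config = config),
      class = "sim_timecourse"
    )
  })
}

#' Draw negative-binomial counts around a mean matrix
#'
#' `counts[g, s] ~ NB(mu = lib_factors[s] * mu_matrix[g, s],
#' size = 1/dispersion)`, so the expected column sum scales linearly with the
#' library factor.
#'
#' @param mu_matrix gene x sample matrix of noiseless means (linear scale).
#' @param lib_factors per-sample multiplicative library-size factors.
#' @param dispersion negative-binomial dispersion (> 0).
#' @return integer-valued matrix with the dimnames of `mu_matrix`.
#' @export
draw_nb_counts <- function(mu_matrix, lib_factors, dispersion) {
  stopifnot(length(lib_factors) == ncol(mu_matrix), dispersion > 0)
  mu <- sweep(mu_matrix, 2, lib_factors, `*`)
  out <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
                nrow(mu), ncol(mu), dimnames = dimnames(mu_matrix))
  out
}

# Archetype assignment, edge structure and per-gene baselines.
draw_ground_truth <- function(config) {
  n_targets <- config$n_genes - config$n_tfs
  tf_genes <- character(config$n_tfs)
  ifn_names <- c("Irf1", "Stat1", "Stat2", "Irf7", "Irf9")
  n_ifn <- min(5L, config$n_tfs)
  tf_genes[seq_len(n_ifn)] <- ifn_names[seq_len(n_ifn)]
  if (config$n_tfs > n_ifn) {
    tf_genes[(n_ifn + 1):config$n_tfs] <-
      sprintf("Tf%02d", (n_ifn + 1):config$n_tfs)
  }
  target_genes <- sprintf("G%04d", seq_len(n_targets))

  # TF archetypes: IFN TFs are on/fast-off; the rest cycle over the gradual
  # archetypes so every target archetype has at least one driver when
  # n_tfs >= 8.
  other_arch <- c("grad_up", "grad_up_resp", "grad_down")
  tf_archetype <- c(
    rep("on_fast_off", n_ifn),
    if (config$n_tfs > n_ifn) {
      other_arch[((seq_len(config$n_tfs - n_ifn) - 1) %% 3) + 1]
    }
  )
  names(tf_archetype) <- tf_genes

  # Target archetypes: the fast ISG block first, then the configured mix.
  props <- config$archetype_props / sum(config$archetype_props)
  n_rest <- n_targets - config$n_isg_fast
  rest_arch <- rep(names(props), times = diff(round(cumsum(c(0, props)) * n_rest)))
  if (length(rest_arch) < n_rest) {
    rest_arch <- c(rest_arch, rep("flat", n_rest - length(rest_arch)))
  }
  target_archetype <- c(rep("on_fast_off", config$n_isg_fast), rest_arch)
  names(target_archetype) <- target_genes

  archetype <- c(tf_archetype, target_archetype)
  genes <- names(archetype)

  # Couple every non-flat target to TFs of its own archetype.
  edges <- list()
  for (g in target_genes) {
    a <- target_archetype[[g]]
    if (a == "flat") next
    drivers <- tf_genes[tf_archetype == a]
    if (length(drivers) == 0) next  # degenerate configs: template used directly
    k <- min(config$n_regulators_per_target, length(drivers))
    regs <- sample(drivers, k)
    edges[[g]] <- tibble(
      regulator = regs, target = g,
      weight = runif(k, config$coupling_range[1], config$coupling_range[2])
    )
  }
  edges <- bind_rows(edges)
  edges$direct <- runif(nrow(edges)) < config$direct_prob

  baseline <- setNames(
    runif(length(genes), config$baseline_log2_range[1],
          config$baseline_log2_range[2]),
    genes
  )

  fast_isg <- target_genes[target_archetype == "on_fast_off"]
  # ISG signature candidates: the fast set plus the slow responder-specific
  # risers (both land in the curated alpha/beta and gamma interferon sets).
  slow_isg <- target_genes[target_archetype == "grad_up_resp"]
  cand <- c(fast_isg, slow_isg)
  isg_class <- setNames(
    sample(c("alpha_beta", "gamma", "both"), length(cand), replace = TRUE,
           prob = c(0.4, 0.4, 0.2)),
    cand
  )

  structure(
    list(edges = edges,
         archetype = archetype,
         tf_genes = tf_genes,
         ifn_tf_genes = tf_genes[seq_len(n_ifn)],
         fast_isg_genes = fast_isg,
         de_genes = character(0),   # filled from the mean model below
         isg_class = isg_class,
         baseline = baseline),
    class = "ground_truth"
  )
}

# Noiseless log2 mean matrices (gene x timepoint) per arm; also finalizes
# truth$de_genes from the realized mean model.
archetype_mean_model <- function(truth, config) {
  nt <- length(config$timepoints)
  genes <- names(truth$archetype)
  out <- list()
  for (arm in c("responder", "non_responder")) {
    m <- matrix(NA_real_, length(genes), nt,
                dimnames = list(genes, paste0("d", config$timepoints)))
    tpl_key <- if (arm == "responder") "responder" else "non_responder"
    # TFs and unregulated genes follow their template directly.
    regulated <- unique(truth$edges$target)
    for (g in genes) {
      if (g %in% regulated) next
      tpl <- config$templates[[truth$archetype[[g]]]][[tpl_key]]
      m[g, ] <- truth$baseline[[g]] + config$amplitude * tpl
    }
    # Regulated targets: baseline + weighted regulator deviations.
    for (g in intersect(genes, regulated)) {
      e <- truth$edges[truth$edges$target == g, ]
      dev <- rep(0, nt)
      for (j in seq_len(nrow(e))) {
        r <- e$regulator[j]
        dev <- dev + e$weight[j] * (m[r, ] - truth$baseline[[r]])
      }
      # Normalize by total weight so target dynamic range stays comparable.
      m[g, ] <- truth$baseline[[g]] + dev / sum(e$weight)
    }
    out[[arm]] <- m
  }
  de <- genes[apply(abs(out$responder - out$non_responder), 1, max) > 1e-9]
  # write back into the enclosing truth via the caller
  assign_de(out, de)
}

assign_de <- function(mean_list, de) {
  attr(mean_list, "de_genes") <- de
  mean_list
}

#' @export
print.sim_timecourse <- function(x, ...) {
  cat("<sim_timecourse>\n")
  cat(sprintf("  %d genes x %d samples (%s)\n", nrow(x$counts), ncol(x$counts),
              paste(x$config$models, collapse = " + ")))
  cat(sprintf("  %d true edges (%d direct), %d fast ISGs, %d DE genes\n",
              nrow(x$truth$edges), sum(x$truth$edges$direct),
              length(x$truth$fast_isg_genes), length(x$truth$de_genes)))
  invisible(x)
}

#' Log-transform an expression matrix
#'
#' `log2(x + pseudocount)` variance stabilization, the conventional scale for
#' time-profile clustering of count data.
#'
#' @param matrix gene x sample non-negative matrix.
#' @param pseudocount added before the log.
#' @return transformed matrix; the layer tag gains a `"log2_"` prefix.
#' @export
log_transform <- function(matrix, pseudocount = 1) {
  check_expression_matrix(matrix)
  set_expr_layer(log2(matrix + pseudocount),
                 paste0("log2_", expr_layer(matrix)))
}

#' Convert gene-level counts to TPM (transcripts per million)
#'
#' Gene-level simulation carries no transcript lengths, so TPM here is column
#' normalization to one million.
#'
#' @param counts gene x sample count matrix.
#' @return matrix with layer `"TPM"`; columns sum to 1e6.
#' @export
counts_to_tpm <- function(counts) {
  check_expression_matrix(counts, "counts")
  cs <- colSums(counts)
  if (any(cs == 0)) abort("cannot TPM-normalize a sample with zero total counts")
  set_expr_layer(sweep(counts, 2, cs, `/`) * 1e6, "TPM")
}
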