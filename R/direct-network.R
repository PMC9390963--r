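#' Promoter window around a transcription start site
#'
#' Strand-oriented window (upstream means 5' of the gene): 400 bp upstream /
#' 300 bp downstream by default. Coordinates are 0-based half-open (BED
#' convention) and clipped at 0.
#'
#' @param tss 0-based TSS position.
#' @param strand `"+"` or `"-"`; ignored when `ignore_strand = TRUE`.
#' @param up,down upstream / downstream extents in bp.
#' @param ignore_strand treat every gene as `+` strand (symmetric behaviour
#'   of a strand-unaware window operation).
#' @return list with `start` and `end` (half-open).
#' @export
promoter_window <- function(tss, strand, up = 400, down = 300,
                            ignore_strand = FALSE) {
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  if (ignore_strand || strand == "+") {
    list(start = max(0, tss - up), end = tss + down)
  } else {
    list(start = max(0, tss - down), end = tss + up)
  }
}

#' Prune an inferred network to promoter-proximal direct connections
#'
#' An edge (regulator, target) is retained iff the regulator is in `tf_list`,
#' the target is differentially expressed, and at least one binding site of
#' that TF overlaps (by >= 1 bp) the target's promoter window on the target's
#' chromosome. Node classes for the retained subgraph are assigned as
#' `ifn_tf` (interferon-related TFs), `other_tf`, `fast_isg`, `other`.
#'
#' @param net an `importance_network` (or bare edge tibble).
#' @param tss tibble: gene, chrom, tss, strand. Duplicate TSS entries for a
#'   gene are resolved to the first listed, with a warning.
#' @param tfbs tibble: tf, chrom, start, end (0-based half-open).
#' @param de_genes differentially expressed gene ids (eligible targets).
#' @param tf_list transcription-factor gene ids (eligible sources).
#' @param up,down promoter window extents, bp.
#' @param ignore_strand see [promoter_window()].
#' @param ifn_tfs TFs forming the interferon axis (default Irf1, Stat1,
#'   Stat2, Irf7, Irf9).
#' @param fast_isgs genes forming the fast-ISG axis (for node classes).
#' @return a `direct_network` list: `edges` (tibble regulator / target /
#'   importance), `node_class` (named character), `window` (parameters),
#'   `dropped` (counts of edges dropped for missing TSS / missing TFBS).
#' @export
prune_direct <- function(net, tss, tfbs, de_genes, tf_list,
                         up = 400, down = 300, ignore_strand = FALSE,
                         ifn_tfs = c("Irf1", "Stat1", "Stat2", "Irf7", "Irf9"),
                         fast_isgs = character(0)) {
  edges <- if (inherits(net, "importance_network")) net$edges else net
  if (anyDuplicated(tss$gene)) {
    warn("duplicate TSS records; keeping the first per gene")
    tss <- tss[!duplicated(tss$gene), , drop = FALSE]
  }

  cand <- edges[edges$regulator %in% tf_list & edges$target %in% de_genes, ,
                drop = FALSE]
  n_missing_tss <- sum(!cand$target %in% tss$gene)
  if (n_missing_tss > 0) {
    warn(sprintf("%d candidate edges dropped: target has no TSS record",
                 n_missing_tss))
    cand <- cand[cand$target %in% tss$gene, , drop = FALSE]
  }
  no_site_tfs <- setdiff(unique(cand$regulator), unique(tfbs$tf))
  if (length(no_site_tfs)) {
    warn(paste("TFs with no binding site anywhere; their edges dropped:",
               paste(no_site_tfs, collapse = ", ")))
  }

  keep <- logical(nrow(cand))
  if (nrow(cand) > 0) {
    ti <- match(cand$target, tss$gene)
    win <- t(vapply(seq_len(nrow(cand)), function(i) {
      w <- promoter_window(tss$tss[ti[i]], tss$strand[ti[i]],
                           up = up, down = down,
                           ignore_strand = ignore_strand)
      c(w$start, w$end)
    }, numeric(2)))
    # Interval joins per (TF, chrom) using IRanges; half-open coords are
    # converted to closed 1-based internally.
    key <- paste(cand$regulator, tss$chrom[ti])
    site_key <- paste(tfbs$tf, tfbs$chrom)
    for (kk in unique(key)) {
      rows <- which(key == kk)
      sites <- tfbs[site_key == kk, , drop = FALSE]
      if (nrow(sites) == 0) next
      q <- IRanges::IRanges(start = win[rows, 1] + 1, end = win[rows, 2])
      s <- IRanges::IRanges(start = sites$start + 1, end = sites$end)
      keep[rows] <- IRanges::overlapsAny(q, s, minoverlap = 1)
    }
  }
  retained <- cand[keep, , drop = FALSE]

  nodes <- unique(c(retained$regulator, retained$target))
  node_class <- setNames(rep("other", length(nodes)), nodes)
  node_class[nodes %in% tf_list] <- "other_tf"
  node_class[nodes %in% ifn_tfs & nodes %in% tf_list] <- "ifn_tf"
  node_class[nodes %in% fast_isgs & !(nodes %in% tf_list)] <- "fast_isg"

  structure(
    list(edges = as_tibble(retained[, c("regulator", "target", "importance")]),
         node_class = node_class,
         window = list(up = up, down = down, ignore_strand = ignore_strand),
         dropped = list(missing_tss = n_missing_tss,
                        tf_without_tfbs = no_site_tfs)),
    class = "direct_network"
  )
}

#' @export
print.direct_network <- function(x, ...) {
  cat(sprintf("<direct_network> %d retained edges, %d nodes (window -%d/+%d bp%s)\n",
              nrow(x$edges), length(x$node_class), x$window$up, x$window$down,
              if (x$window$ignore_strand) ", strand-unaware" else ""))
  invisible(x)
}

#' TF-to-ISG importance score matrix
#'
#' Importance of each retained TF -> ISG edge; absent pairs are 0.
#'
#' @param direct a `direct_network`.
#' @param tfs row genes (TFs).
#' @param isgs column genes (ISGs).
#' @return tfs x isgs numeric matrix.
#' @export
tf_to_isg_matrix <- function(direct, tfs, isgs) {
  m <- matrix(0, length(tfs), length(isgs), dimnames = list(tfs, isgs))
  e <- direct$edges
  e <- e[e$regulator %in% tfs & e$target %in% isgs, , drop = FALSE]
  if (nrow(e)) m[cbind(e$regulator, e$target)] <- e$importance
  m
}

#' Top-edge quadrant statistic of the direct network
#'
#' The hive-plot quadrant summary: the empirical `quantile` (linear
#' interpolation) of the edge importances is the threshold; top edges are
#' those with importance strictly above it; the statistic is the fraction of
#' top edges running from an interferon-related TF to a fast-ISG.
#'
#' @param direct a `direct_network` with node classes assigned.
#' @param quantile quantile level for the threshold.
#' @return tibble: threshold, n_top_edges, fraction_in_tf_to_isg_quadrant.
#' @export
hive_quadrant_stats <- function(direct, quantile = 0.9) {
  e <- direct$edges
  if (nrow(e) < 10) abort("need at least 10 edges for the quadrant statistic")
  thr <- stats::quantile(e$importance, probs = quantile, type = 7, names = FALSE)
  top <- e[e$importance > thr, , drop = FALSE]
  if (nrow(top) == 0) {
    warn("all importances equal at/below the threshold; no top edges")
    return(tibble(threshold = thr, n_top_edges = 0L,
                  fraction_in_tf_to_isg_quadrant = NA_real_))
  }
  src <- direct$node_class[top$regulator]
  tgt <- direct$node_class[top$target]
  frac <- mean(src == "ifn_tf" & tgt == "fast_isg")
  tibble(threshold = thr, n_top_edges = nrow(top),
         fraction_in_tf_to_isg_quadrant = frac)
}
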