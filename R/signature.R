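#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then members. Member order is
#' preserved; duplicated members within a set are stored once with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions kept in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("malformed GMT line %d: need name, description and >= 1 member", i))
    }
    nm <- fields[1]
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warn(sprintf("set '%s': duplicate members de-duplicated", nm))
      members <- unique(members)
    }
    sets[[nm]] <- members
    descs[nm] <- fields[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("every gene set must be named")
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Derive the fast-on/off ISG subset from responder time courses
#'
#' k-means (k = 2) on the z-scored responder time profiles of the
#' interferon-stimulated genes; the "fast" cluster is the one whose centroid
#' is higher at the designated early timepoint (the first post-baseline
#' design timepoint of the model), making the rule invariant to cluster
#' label swaps.
#'
#' @param responder_profiles `profile_matrix` of responder time courses
#'   (layer `"mean"` or `"zscore"`; mean profiles are z-scored internally).
#' @param isg_genes candidate ISG ids; absent genes dropped with a warning.
#' @param k number of clusters (2 = fast vs slow).
#' @param early_timepoint_index column index of the early timepoint used to
#'   label the fast cluster.
#' @param seed integer seed.
#' @param isg_class optional named character giving each gene's source set
#'   (`alpha_beta`, `gamma`, `both`).
#' @return an `isg_signature` tibble: gene, class, fast; with derivation
#'   parameters in attributes.
#' @export
extract_fast_onoff <- function(responder_profiles, isg_genes, k = 2,
                               early_timepoint_index = 1, seed = 17L,
                               isg_class = NULL) {
  present <- intersect(isg_genes, rownames(responder_profiles))
  if (length(present) < length(isg_genes)) {
    warn(sprintf("%d ISG(s) absent from the profiles; dropped",
                 length(isg_genes) - length(present)))
  }
  if (length(present) < 2 * k) {
    abort(sprintf("need at least %d ISG profiles for k = %d", 2 * k, k))
  }
  x <- unclass(responder_profiles)[present, , drop = FALSE]
  if (!identical(attr(responder_profiles, "layer"), "zscore")) {
    x <- row_zscore(x)$values
  }
  if (nrow(unique(x)) < k) abort("profiles are not distinct enough to cluster")
  km <- with_seed(seed, kmeans(x, centers = k, nstart = 25, iter.max = 100))
  fast_cluster <- which.max(km$centers[, early_timepoint_index])
  fast <- unname(km$cluster == fast_cluster)
  cls <- if (is.null(isg_class)) rep(NA_character_, length(present)) else
    unname(isg_class[present])
  out <- tibble(gene = present, class = cls, fast = fast)
  attr(out, "derivation") <- list(k = k, seed = seed,
                                  early_timepoint_index = early_timepoint_index)
  class(out) <- c("isg_signature", class(out))
  out
}

#' Score samples for a gene signature
#'
#' Per-sample mean of the signature genes' z-scores (each gene standardized
#' across samples) -- the "average expression" signature summary.
#'
#' @param matrix gene x sample expression matrix.
#' @param signature_genes signature gene ids; missing ones are dropped with
#'   a warning.
#' @return tibble: sample_id, score.
#' @export
score_signature <- function(matrix, signature_genes) {
  check_expression_matrix(matrix)
  present <- intersect(signature_genes, rownames(matrix))
  missing <- setdiff(signature_genes, rownames(matrix))
  if (length(present) == 0) {
    abort(paste("no signature gene found in the matrix; missing:",
                paste(missing, collapse = ", ")))
  }
  if (length(missing)) {
    warn(sprintf("%d signature gene(s) absent from the matrix; dropped",
                 length(missing)))
  }
  z <- row_zscore(matrix[present, , drop = FALSE])$values
  tibble(sample_id = colnames(matrix), score = unname(colMeans(z)))
}
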