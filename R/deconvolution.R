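#' Build a population reference by collapsing labelled samples
#'
#' Column `p` of the reference is the per-gene mean of the samples labelled
#' `p`.
#'
#' @param samples gene x sample expression matrix.
#' @param population_labels per-sample population labels, either a named
#'   character vector (names = sample ids) or in column order.
#' @return gene x population `ReferenceMatrix`, layer inherited.
#' @export
build_reference <- function(samples, population_labels) {
  check_expression_matrix(samples, "samples")
  if (!is.null(names(population_labels))) {
    missing <- setdiff(colnames(samples), names(population_labels))
    if (length(missing)) {
      abort(paste("unlabelled sample(s):", paste(missing, collapse = ", ")))
    }
    population_labels <- population_labels[colnames(samples)]
  }
  if (length(population_labels) != ncol(samples) || anyNA(population_labels)) {
    abort("every sample needs a population label")
  }
  pops <- unique(population_labels)
  ref <- vapply(pops, function(p) {
    rowMeans(samples[, population_labels == p, drop = FALSE])
  }, numeric(nrow(samples)))
  dimnames(ref) <- list(rownames(samples), pops)
  set_expr_layer(ref, expr_layer(samples))
}

#' Filter genes by TPM prevalence
#'
#' Keeps genes with a TPM strictly greater than `min_tpm` in at least
#' `min_samples` samples (the prevalence rule tied to the smallest
#' experimental group size).
#'
#' @param matrix gene x sample matrix with layer `"TPM"`.
#' @param min_tpm strict lower TPM bound.
#' @param min_samples minimum number of qualifying samples.
#' @return filtered matrix, layer `"TPM"`.
#' @export
filter_genes_tpm <- function(matrix, min_tpm = 0.3, min_samples = 8) {
  check_expression_matrix(matrix)
  if (!identical(expr_layer(matrix), "TPM")) {
    abort("filter_genes_tpm expects a TPM-layer matrix")
  }
  keep <- rowSums(matrix > min_tpm) >= min_samples
  set_expr_layer(matrix[keep, , drop = FALSE], "TPM")
}

#' Estimate mixture fractions of reference populations in bulk samples
#'
#' Non-negative least squares of each sample on the reference columns over
#' the shared genes, with the fractions renormalized to sum to one. This
#' NNLS solver replaces the nu-SVR used by the CIBERSORT family: on exact
#' mixtures both estimate the same mixing fractions, and NNLS has no
#' undocumented tuning internals. No quantile normalization is applied.
#'
#' @param mixtures gene x sample matrix of bulk profiles (a single named
#'   vector is treated as one sample).
#' @param reference gene x population reference matrix.
#' @return a `mixture_estimate` tibble: sample_id, one column per population,
#'   residual (Euclidean norm of the NNLS residual).
#' @export
deconvolve <- function(mixtures, reference) {
  if (is.null(dim(mixtures))) {
    mixtures <- matrix(mixtures, ncol = 1,
                       dimnames = list(names(mixtures), "S1"))
  }
  shared <- intersect(rownames(mixtures), rownames(reference))
  if (length(shared) < ncol(reference)) {
    abort(sprintf("only %d shared genes for %d populations",
                  length(shared), ncol(reference)))
  }
  unmatched <- setdiff(rownames(reference), shared)
  if (length(unmatched)) {
    warn(sprintf("%d reference gene(s) not present in the mixtures",
                 length(unmatched)))
  }
  A <- reference[shared, , drop = FALSE]
  if (qr(A)$rank < ncol(A)) {
    warn("reference matrix is rank-deficient; fractions may not be unique")
  }
  res <- purrr::map(seq_len(ncol(mixtures)), function(j) {
    b <- mixtures[shared, j]
    fit <- pracma::lsqnonneg(A, b)
    w <- fit$x
    total <- sum(w)
    frac <- if (total > 0) w / total else rep(1 / ncol(A), ncol(A))
    c(frac, residual = sqrt(sum((A %*% w - b)^2)))
  })
  out <- as_tibble(do.call(rbind, res), .name_repair = "minimal")
  names(out) <- c(colnames(reference), "residual")
  out <- dplyr::bind_cols(tibble(sample_id = colnames(mixtures)), out)
  class(out) <- c("mixture_estimate", class(out))
  out
}
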