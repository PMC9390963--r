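#' Average replicates into a per-gene time profile matrix
#'
#' Collapses samples of one experimental arm (model, response) to the
#' arithmetic mean per (gene, timepoint).
#'
#' @param matrix gene x sample expression matrix.
#' @param meta sample metadata tibble with columns `sample_id`, `model`,
#'   `timepoint_day`, `response`.
#' @param model,response arm selector.
#' @return a `profile_matrix`: gene x timepoint matrix with attributes
#'   `timepoints`, `arm`, and `layer = "mean"`.
#' @export
average_replicates <- function(matrix, meta, model, response) {
  check_expression_matrix(matrix)
  keep <- meta$model == model & meta$response == response
  sub <- meta[keep, , drop = FALSE]
  if (nrow(sub) == 0) abort(sprintf("no samples for arm (%s, %s)", model, response))
  tps <- sort(unique(meta$timepoint_day))
  prof <- matrix(NA_real_, nrow(matrix), length(tps),
                 dimnames = list(rownames(matrix), paste0("d", tps)))
  for (i in seq_along(tps)) {
    ids <- sub$sample_id[sub$timepoint_day == tps[i]]
    if (length(ids) == 0) {
      abort(sprintf("arm (%s, %s) has no sample at timepoint %g",
                    model, response, tps[i]))
    }
    prof[, i] <- rowMeans(matrix[, ids, drop = FALSE])
  }
  structure(prof, timepoints = tps, arm = c(model = model, response = response),
            layer = "mean", class = c("profile_matrix", "matrix", "array"))
}

#' Z-normalize time profiles gene-wise
#'
#' Standardizes each gene's profile across timepoints (sd with denominator
#' n-1). Constant profiles become all-zero and are flagged in the
#' `constant_genes` attribute.
#'
#' @param profiles a `profile_matrix` with layer `"mean"`.
#' @return a `profile_matrix` with layer `"zscore"`.
#' @export
znormalize <- function(profiles) {
  if (!identical(attr(profiles, "layer"), "mean")) {
    abort("znormalize expects a profile matrix with layer 'mean'")
  }
  z <- row_zscore(unclass(profiles))
  structure(z$values,
            timepoints = attr(profiles, "timepoints"),
            arm = attr(profiles, "arm"),
            layer = "zscore",
            constant_genes = rownames(profiles)[z$constant],
            class = c("profile_matrix", "matrix", "array"))
}

#' Estimate the fuzzy c-means fuzzifier
#'
#' Schwaemmle-Jensen rule based on the data dimension `D` (timepoints) and
#' the number of profiles `N`:
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`.
#'
#' @param n_profiles number of (non-constant) gene profiles.
#' @param n_timepoints profile dimension.
#' @return fuzzifier m > 1.
#' @export
estimate_fuzzifier <- function(n_profiles, n_timepoints) {
  N <- n_profiles
  D <- n_timepoints
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fuzzy c-means clustering of time profiles
#'
#' Standard FCM alternating updates (membership proportional to
#' `(1/d^2)^(1/(m-1))`, centroids as membership^m-weighted means), run from a
#' k-means++ centroid seeding so results are deterministic for a fixed seed.
#' All-zero flagged constant profiles are excluded with a warning.
#'
#' @param profiles `profile_matrix` with layer `"zscore"`.
#' @param k number of clusters (>= 2).
#' @param m fuzzifier; default is the Schwaemmle-Jensen estimate
#'   ([estimate_fuzzifier()]).
#' @param tol convergence tolerance on the objective.
#' @param max_iter iteration cap.
#' @param seed seed for the centroid seeding.
#' @return an `fcm_clustering` list: `centroids` (k x timepoint),
#'   `membership` (gene x k, rows sum to 1), `objective`, `k`, `m`, `seed`,
#'   `n_iter`, `excluded_genes`, `timepoints`.
#' @export
fuzzy_cmeans <- function(profiles, k = 6, m = NULL, tol = 1e-9,
                         max_iter = 200, seed = 17L) {
  if (!identical(attr(profiles, "layer"), "zscore")) {
    abort("fuzzy_cmeans expects z-scored profiles (run znormalize() first)")
  }
  x <- unclass(profiles)
  excluded <- attr(profiles, "constant_genes") %||% character(0)
  if (length(excluded)) {
    warn(sprintf("excluding %d constant (all-zero) profiles from clustering",
                 length(excluded)))
    x <- x[!rownames(x) %in% excluded, , drop = FALSE]
  }
  if (k < 2) abort("k must be >= 2")
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    abort(sprintf("k = %d exceeds the %d distinct profiles", k, n_distinct))
  }
  if (is.null(m)) m <- estimate_fuzzifier(nrow(x), ncol(x))
  if (m <= 1) abort("fuzzifier m must be > 1")

  fit <- with_seed(seed, {
    centers <- kmeanspp_centers(x, k)
    e1071::cmeans(x, centers = centers, m = m, iter.max = max_iter,
                  method = "cmeans", control = list(reltol = tol))
  })
  membership <- fit$membership
  dimnames(membership) <- list(rownames(x), paste0("C", seq_len(k)))
  centroids <- fit$centers
  dimnames(centroids) <- list(paste0("C", seq_len(k)), colnames(x))
  structure(
    list(centroids = centroids, membership = membership,
         objective = fcm_objective(x, centroids, membership, m),
         k = k, m = m, seed = seed, n_iter = fit$iter,
         excluded_genes = excluded,
         timepoints = attr(profiles, "timepoints"),
         arm = attr(profiles, "arm")),
    class = "fcm_clustering"
  )
}

# Within-cluster membership^m-weighted SSE.
fcm_objective <- function(x, centroids, membership, m) {
  d2 <- matrix(0, nrow(x), nrow(centroids))
  for (c in seq_len(nrow(centroids))) {
    d2[, c] <- rowSums((x - matrix(centroids[c, ], nrow(x), ncol(x),
                                   byrow = TRUE))^2)
  }
  sum(membership^m * d2)
}

#' @export
print.fcm_clustering <- function(x, ...) {
  cat(sprintf("<fcm_clustering> k = %d, m = %.3f, %d genes, objective %.6g (%d iter)\n",
              x$k, x$m, nrow(x$membership), x$objective, x$n_iter))
  invisible(x)
}

#' Hard cluster assignment from a fuzzy clustering
#'
#' Argmax membership per gene; ties go to the lowest cluster index.
#'
#' @param clustering an `fcm_clustering`.
#' @return named integer vector of cluster indices.
#' @export
hard_assignment <- function(clustering) {
  apply(clustering$membership, 1, which.max)
}

#' Match cluster trends between two clusterings
#'
#' All cluster pairs whose centroid trend lines have a Pearson correlation of
#' at least `r_min`, sorted by correlation (descending). Pairs involving a
#' constant centroid are skipped with a warning.
#'
#' @param a,b `fcm_clustering` objects with equally many timepoints.
#' @param r_min minimum Pearson correlation to declare a match.
#' @return tibble: cluster_a, cluster_b, pearson_r.
#' @export
match_clusters <- function(a, b, r_min = 0.8) {
  if (ncol(a$centroids) != ncol(b$centroids)) {
    abort("clusterings have different timepoint counts")
  }
  rows <- list()
  for (i in seq_len(nrow(a$centroids))) {
    for (j in seq_len(nrow(b$centroids))) {
      ca <- a$centroids[i, ]; cb <- b$centroids[j, ]
      if (sd(ca) == 0 || sd(cb) == 0) {
        warn(sprintf("constant centroid in pair (%d, %d); skipped", i, j))
        next
      }
      r <- cor(ca, cb)
      if (r >= r_min) {
        rows[[length(rows) + 1]] <- tibble(cluster_a = i, cluster_b = j,
                                           pearson_r = r)
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(cluster_a = integer(), cluster_b = integer(), pearson_r = double())
  arrange(out, desc(.data$pearson_r))
}

#' Genes shared by two matched clusters
#'
#' Intersection of the hard-assigned gene sets of cluster `cluster_a` in `a`
#' and `cluster_b` in `b`.
#'
#' @param a,b `fcm_clustering` objects.
#' @param cluster_a,cluster_b cluster indices of the matched pair.
#' @return character vector of shared genes.
#' @export
overlap_genes <- function(a, b, cluster_a, cluster_b) {
  ha <- hard_assignment(a)
  hb <- hard_assignment(b)
  intersect(names(ha)[ha == cluster_a], names(hb)[hb == cluster_b])
}

#' Does a centroid display the on/fast-off shape?
#'
#' Rule used to single out the fast interferon cluster among matched cluster
#' pairs: the profile peaks within the first two timepoints with a peak of at
#' least `min_peak` z-units (excluding low-amplitude noise centroids), ends
#' below half of its peak, and completes at least `drop_frac` of its
#' peak-to-final drop by the penultimate timepoint. The default `drop_frac`
#' of 0.75 sits midway between a linear decline (which completes ~2/3 of its
#' drop by the penultimate point) and a rapid shut-off (> 0.8), so gradual
#' down-trending clusters are rejected.
#'
#' @param centroid numeric centroid profile (z-units).
#' @param min_peak minimum peak height, z-units.
#' @param drop_frac minimum fraction of the peak-to-final drop completed by
#'   the penultimate timepoint.
#' @return logical.
#' @export
is_fast_onoff_shape <- function(centroid, min_peak = 0.5, drop_frac = 0.75) {
  n <- length(centroid)
  if (n < 3) return(FALSE)
  peak_at <- which.max(centroid)
  if (peak_at > 2) return(FALSE)
  peak <- centroid[peak_at]
  final <- centroid[n]
  if (peak < min_peak) return(FALSE)
  if (!(final < 0.5 * peak)) return(FALSE)
  drop_total <- peak - final
  if (drop_total <= 0) return(FALSE)
  drop_by_penult <- peak - min(centroid[peak_at:(n - 1)])
  drop_by_penult / drop_total >= drop_frac
}
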