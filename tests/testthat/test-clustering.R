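make_profiles <- function(values, timepoints = c(0, 2, 4, 6),
                          layer = "mean") {
  structure(values, timepoints = timepoints,
            arm = c(model = "AB1", response = "responder"), layer = layer,
            class = c("profile_matrix", "matrix", "array"))
}

test_that("replicate averaging is an arithmetic mean and order-invariant", {
  counts <- matrix(c(4, 6, 10, 2, 8, 12), nrow = 1,
                   dimnames = list("g1", sprintf("s%d", 1:6)))
  counts <- rbind(counts, g2 = c(1, 3, 5, 7, 9, 11))
  meta <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    model = "AB1", response = "responder",
    timepoint_day = c(0, 0, 2, 2, 4, 4)
  )
  # a design timepoint with no sample in the arm is an error naming it
  meta_gap <- meta
  meta_gap$response[meta_gap$timepoint_day == 0] <- "non_responder"
  expect_error(average_replicates(counts, meta_gap, "AB1", "responder"),
               "timepoint 0")
  prof <- average_replicates(counts, meta, "AB1", "responder")
  expect_equal(unname(prof["g1", ]), c(5, 6, 10))
  perm <- sample(ncol(counts))
  prof2 <- average_replicates(counts[, perm], meta, "AB1", "responder")
  expect_equal(prof, prof2)
  # single replicate: profile equals that sample's column
  meta1 <- meta[c(1, 3, 5), ]
  prof1 <- average_replicates(counts[, c(1, 3, 5)], meta1, "AB1", "responder")
  expect_equal(unname(prof1["g2", ]), unname(counts["g2", c(1, 3, 5)]))
})

test_that("z-normalization standardizes rows and flags constant profiles", {
  prof <- make_profiles(matrix(c(1, 2, 3, 4,
                                 5, 5, 5, 5), 2, 4, byrow = TRUE,
                               dimnames = list(c("g1", "g2"), NULL)))
  z <- znormalize(prof)
  expect_equal(unname(z["g1", ]),
               c(-1.1618950, -0.3872983, 0.3872983, 1.1618950),
               tolerance = 1e-6)
  expect_equal(unname(z["g2", ]), rep(0, 4))
  expect_identical(attr(z, "constant_genes"), "g2")
  expect_equal(mean(z["g1", ]), 0, tolerance = 1e-12)
  expect_equal(sd(z["g1", ]), 1, tolerance = 1e-12)
  expect_error(znormalize(z), "layer 'mean'")
})

test_that("near-hard fuzzifier separates well-separated groups crisply", {
  set.seed(4)
  a <- matrix(rep(c(2, 1, -1, -2), each = 10), 10, 4) + rnorm(40, sd = 0.05)
  b <- matrix(rep(c(-2, -1, 1, 2), each = 10), 10, 4) + rnorm(40, sd = 0.05)
  x <- rbind(a, b)
  rownames(x) <- sprintf("g%02d", 1:20)
  prof <- make_profiles(x)
  fit <- fuzzy_cmeans(znormalize(prof), k = 2, m = 1.05, seed = 1)
  top <- apply(fit$membership, 1, max)
  expect_true(all(top > 0.99))
  grp <- hard_assignment(fit)
  expect_length(unique(grp[1:10]), 1)
  expect_length(unique(grp[11:20]), 1)
  expect_false(grp[[1]] == grp[[11]])
})

test_that("membership rows sum to one and duplicated genes get identical rows", {
  sim <- simulate_timecourse(small_config())
  prof <- average_replicates(sim$counts, sim$meta, "AB1", "responder")
  z <- znormalize(prof)
  dup <- unclass(z)
  dup <- rbind(dup, dup_copy = dup[1, ])
  zdup <- make_profiles(dup, layer = "zscore")
  attr(zdup, "constant_genes") <- attr(z, "constant_genes")
  fit <- suppressWarnings(fuzzy_cmeans(zdup, k = 4, seed = 17))
  expect_equal(unname(rowSums(fit$membership)),
               rep(1, nrow(fit$membership)), tolerance = 1e-8)
  expect_equal(unname(fit$membership["dup_copy", ]),
               unname(fit$membership[rownames(dup)[1], ]), tolerance = 1e-8)
})

test_that("fuzzy c-means reaches the multi-restart optimum on small data", {
  set.seed(7)
  centers <- matrix(c(2, 1, -1, -2,
                      -2, -1, 1, 2,
                      1, -2, 2, -1), 3, 4, byrow = TRUE)
  x <- centers[rep(1:3, length.out = 36), ] + matrix(rnorm(36 * 4, sd = 0.3), 36, 4)
  rownames(x) <- sprintf("g%02d", 1:36)
  m <- 1.25
  fit <- fuzzy_cmeans(make_profiles(row_z <- t(scale(t(x))), layer = "zscore"),
                      k = 3, m = m, seed = 17)
  set.seed(99)
  oracle <- best_fcm_objective(t(scale(t(x))), k = 3, m = m, restarts = 200)
  expect_lt(abs(fit$objective - oracle), 1e-6)
})

test_that("cluster trend matching follows Pearson correlation of centroids", {
  mk <- function(centroids) {
    structure(list(centroids = centroids,
                   membership = matrix(1, 1, nrow(centroids)),
                   k = nrow(centroids), m = 1.5, timepoints = c(0, 2, 4, 6)),
              class = "fcm_clustering")
  }
  a <- mk(matrix(c(0, 1, 2, 3,
                   3, 2, 1, 0), 2, 4, byrow = TRUE))
  b <- mk(matrix(c(1, 3, 5, 7,
                   0, -1, -2, -3), 2, 4, byrow = TRUE))
  m <- match_clusters(a, b, r_min = 0.8)
  # affine transforms correlate perfectly; negations are excluded
  expect_equal(m$pearson_r[m$cluster_a == 1 & m$cluster_b == 1], 1.0)
  expect_equal(m$pearson_r[m$cluster_a == 2 & m$cluster_b == 2], 1.0)
  expect_false(any(m$cluster_a == 1 & m$cluster_b == 2))
  # symmetric in arguments (mirrored pairs)
  m2 <- match_clusters(b, a, r_min = 0.8)
  expect_setequal(paste(m$cluster_a, m$cluster_b),
                  paste(m2$cluster_b, m2$cluster_a))
  # constant centroid: every pair involving it is skipped with a warning
  cc <- mk(matrix(c(1, 1, 1, 1, 0, 1, 2, 3), 2, 4, byrow = TRUE))
  w <- testthat::capture_warnings(match_clusters(cc, a, r_min = 0.8))
  expect_length(w, 2)
  expect_match(w, "constant centroid", all = TRUE)
})

test_that("matched on/fast-off clusters recover the fast ISG genes", {
  # study-scale replication (the surgical design had 8-12 tumours per
  # model/response/timepoint cell); four clusters for the four archetypes;
  # profiles clustered on the log2 scale where the dynamic shapes live
  cfg <- sim_config(n_genes = 120, n_tfs = 8, n_isg_fast = 25,
                    replicates_per_cell = 9, seed = 19)
  sim <- simulate_timecourse(cfg)
  log_counts <- log_transform(sim$counts)
  fits <- lapply(cfg$models, function(m) {
    fuzzy_cmeans(znormalize(average_replicates(log_counts, sim$meta,
                                               m, "responder")),
                 k = 4, seed = 17)
  })
  matches <- match_clusters(fits[[1]], fits[[2]], r_min = 0.8)
  fast_pairs <- which(
    vapply(seq_len(nrow(matches)), function(i) {
      is_fast_onoff_shape(fits[[1]]$centroids[matches$cluster_a[i], ]) &&
        is_fast_onoff_shape(fits[[2]]$centroids[matches$cluster_b[i], ])
    }, logical(1))
  )
  # exactly one matched pair has the on/fast-off shape, and its gene overlap
  # recovers the fast ISG truth
  expect_length(fast_pairs, 1)
  top <- fast_pairs[1]
  ov <- overlap_genes(fits[[1]], fits[[2]],
                      matches$cluster_a[top], matches$cluster_b[top])
  recovered <- length(intersect(ov, sim$truth$fast_isg_genes)) /
    length(sim$truth$fast_isg_genes)
  expect_gte(recovered, 0.9)
})

test_that("results are invariant to cluster relabeling", {
  sim <- simulate_timecourse(small_config())
  z <- znormalize(average_replicates(sim$counts, sim$meta, "AB1", "responder"))
  fit <- fuzzy_cmeans(z, k = 3, seed = 17)
  perm <- c(3, 1, 2)
  relabeled <- fit
  relabeled$centroids <- fit$centroids[perm, , drop = FALSE]
  relabeled$membership <- fit$membership[, perm, drop = FALSE]
  other <- fuzzy_cmeans(znormalize(average_replicates(sim$counts, sim$meta,
                                                      "Renca", "responder")),
                        k = 3, seed = 17)
  m1 <- match_clusters(fit, other, r_min = 0.8)
  m2 <- match_clusters(relabeled, other, r_min = 0.8)
  expect_setequal(
    paste(m1$cluster_a, m1$cluster_b),
    paste(perm[m2$cluster_a], m2$cluster_b)
  )
  expect_equal(sort(m1$pearson_r), sort(m2$pearson_r))
})

test_that("fuzzifier estimate exceeds one and shrinks with dimension", {
  m4 <- estimate_fuzzifier(100, 4)
  m10 <- estimate_fuzzifier(100, 10)
  expect_gt(m4, 1)
  expect_gt(m10, 1)
  expect_gt(m4, m10)
})
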