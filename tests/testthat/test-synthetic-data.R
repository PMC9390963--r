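test_that("config validation rejects degenerate designs", {
  expect_error(sim_config(timepoints = c(0, 2, 2, 6)), "strictly increasing")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(n_tfs = 50, n_genes = 50), "n_tfs")
  expect_error(sim_config(n_isg_fast = 400), "n_isg_fast")
})

test_that("noiseless mean model obeys the archetype shape constraints", {
  sim <- simulate_timecourse(small_config())
  truth <- sim$truth
  fast <- truth$fast_isg_genes
  expect_gt(length(fast), 0)
  for (g in c(fast, truth$ifn_tf_genes)) {
    resp <- sim$log2_mean$responder[g, ]
    nonresp <- sim$log2_mean$non_responder[g, ]
    peak_at <- which.max(resp)
    expect_lte(peak_at, 2)
    # strictly decreasing after the peak in responders
    expect_true(all(diff(resp[peak_at:length(resp)]) < 0))
    # below half of the peak dynamic range at the last timepoint
    base <- truth$baseline[[g]]
    expect_lt(resp[length(resp)] - base, 0.5 * (max(resp) - base))
    # monotone non-decreasing in non-responders
    expect_true(all(diff(nonresp) >= 0))
  }
})

test_that("ground truth is internally consistent on every draw", {
  for (seed in c(1, 2, 3)) {
    truth <- simulate_timecourse(small_config(seed = seed))$truth
    # direct edges are a subset of true edges by construction
    expect_true(all(truth$edges$direct %in% c(TRUE, FALSE)))
    expect_setequal(
      truth$fast_isg_genes,
      setdiff(names(truth$archetype)[truth$archetype == "on_fast_off"],
              truth$tf_genes)
    )
    expect_true(all(truth$fast_isg_genes %in% truth$de_genes))
    expect_true(all(truth$edges$regulator %in% truth$tf_genes))
    expect_false(any(truth$edges$regulator == truth$edges$target))
  }
})

test_that("simulation is bitwise reproducible and leaves the RNG untouched", {
  cfg <- small_config(seed = 5)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  a <- simulate_timecourse(cfg)
  after <- runif(1)
  b <- simulate_timecourse(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$edges, b$truth$edges)
  expect_identical(before, after)  # generator restored the RNG state
})

test_that("expected column sums scale linearly with library factors", {
  cfg <- small_config()
  sim <- simulate_timecourse(cfg)
  mu <- matrix(50, 40, 4, dimnames = list(sprintf("g%d", 1:40),
                                          sprintf("s%d", 1:4)))
  lib <- c(0.5, 1, 1.5, 2)
  set.seed(42)
  draws1 <- replicate(200, colSums(draw_nb_counts(mu, lib, cfg$dispersion)))
  draws2 <- replicate(200, colSums(draw_nb_counts(mu, 2 * lib, cfg$dispersion)))
  ratio <- rowMeans(draws2) / rowMeans(draws1)
  expect_true(all(abs(ratio - 2) < 2 * 0.05))
})

test_that("TPM conversion normalizes columns to one million", {
  sim <- simulate_timecourse(small_config())
  tpm <- counts_to_tpm(sim$counts)
  expect_equal(unname(colSums(tpm)), rep(1e6, ncol(tpm)))
})

test_that("annotations put TFBS inside windows for direct edges only", {
  sim <- simulate_timecourse(small_config())
  ann <- simulate_annotations(sim$truth, seed = 3)
  tss_of <- setNames(ann$tss$tss, ann$tss$gene)
  strand_of <- setNames(ann$tss$strand, ann$tss$gene)
  for (i in seq_len(nrow(sim$truth$edges))) {
    e <- sim$truth$edges[i, ]
    w <- promoter_window(tss_of[[e$target]], strand_of[[e$target]])
    sites <- ann$tfbs[ann$tfbs$tf == e$regulator, ]
    hit <- any(sites$start < w$end & sites$end > w$start &
                 sites$start >= tss_of[[e$target]] - 1000 &
                 sites$start <= tss_of[[e$target]] + 1000)
    expect_identical(hit, e$direct)
  }
})

test_that("pruning a complete candidate graph recovers exactly the direct edges", {
  sim <- simulate_timecourse(small_config(seed = 21))
  truth <- sim$truth
  ann <- simulate_annotations(truth, seed = 22)
  genes <- names(truth$archetype)
  complete <- tidyr::expand_grid(regulator = truth$tf_genes, target = genes) |>
    dplyr::filter(regulator != target) |>
    dplyr::mutate(importance = 1)
  pruned <- prune_direct(complete, ann$tss, ann$tfbs,
                         de_genes = truth$de_genes, tf_list = truth$tf_genes)
  want <- truth$edges[truth$edges$direct & truth$edges$target %in% truth$de_genes, ]
  expect_setequal(paste(pruned$edges$regulator, pruned$edges$target),
                  paste(want$regulator, want$target))
})

test_that("mixture simulation honours identity, linearity and validation", {
  ref <- simulate_reference_matrix(n_genes = 30, seed = 2)
  k <- ncol(ref)
  onehot <- matrix(0, k, 1, dimnames = list(colnames(ref), "s1"))
  onehot[3, 1] <- 1
  m <- simulate_mixtures(ref, onehot, noise_sd = 0)
  expect_equal(unname(m[, 1]), unname(ref[, 3]))
  unif <- matrix(1 / k, k, 1, dimnames = list(colnames(ref), "s1"))
  m2 <- simulate_mixtures(ref, unif, noise_sd = 0)
  expect_equal(unname(m2[, 1]), unname(rowMeans(ref)))
  bad <- unif * 1.2
  expect_error(simulate_mixtures(ref, bad), "sum to 1")
  expect_error(simulate_mixtures(ref, -unif), "non-negative")
})

test_that("intended growth-curve outcomes map onto the matching calls", {
  curves <- simulate_growth_curves(
    rep(c("progression", "complete_regression", "partial"), each = 4),
    seed = 9
  )
  calls <- classify_response(curves)
  joined <- dplyr::left_join(calls, dplyr::distinct(curves, mouse_id, intended),
                             by = "mouse_id")
  map <- c(progression = "non_responder",
           complete_regression = "responder",
           partial = "intermediate")
  expect_identical(joined$call, unname(map[joined$intended]))
})

test_that("survival generator matches its exponential model", {
  # Same-law groups under HR = 1
  d <- simulate_survival(hazard_ratio = 1, n_per_group = 10000, seed = 31)
  ks <- suppressWarnings(stats::ks.test(d$time[d$group == "control"],
                                        d$time[d$group == "experimental"]))
  expect_gt(ks$p.value, 0.01)
  # Control median ~= 35 within 2%
  big <- simulate_survival(hazard_ratio = 5, n_per_group = 100000, seed = 32)
  expect_lt(abs(median(big$time[big$group == "control"]) - 35) / 35, 0.02)
  # Experimental median scales with 1/hazard: 35 * 5 = 175
  expect_lt(abs(median(big$time[big$group == "experimental"]) - 175) / 175, 0.02)
  expect_error(simulate_survival(hazard_ratio = 0), "positive")
  expect_error(simulate_survival(control_median_days = -2), "positive")
})

test_that("velocity embedding has the stated isotropic-Gaussian moments", {
  v <- simulate_velocity_embedding(
    c(hi = 50000, lo = 50000, still = 100),
    c(hi = 2, lo = 1, still = 0), seed = 8
  )
  mom <- momentum(v)
  means <- tapply(mom$momentum, mom$group, mean)
  expect_equal(unname(means[["still"]]), 0)
  # E|v|^2 = 2 sigma^2, so a 2x scale gives a 4x mean momentum
  expect_lt(abs(means[["hi"]] / means[["lo"]] - 4), 4 * 0.05)
  v2 <- simulate_velocity_embedding(
    c(hi = 50000, lo = 50000, still = 100),
    c(hi = 2, lo = 1, still = 0), seed = 8
  )
  expect_identical(v, v2)
})
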