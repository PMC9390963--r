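test_that("promoter windows follow the stated strand-aware offsets", {
  expect_equal(promoter_window(10000, "+"), list(start = 9600, end = 10300))
  expect_equal(promoter_window(10000, "-"), list(start = 9700, end = 10400))
  expect_equal(promoter_window(200, "+"), list(start = 0, end = 500))
  expect_equal(promoter_window(10000, "-", ignore_strand = TRUE),
               list(start = 9600, end = 10300))
  expect_error(promoter_window(100, "x"), "strand")
})

test_that("edges are retained iff a binding site overlaps the promoter window", {
  tss <- tibble::tibble(gene = "G1", chrom = "chr1", tss = 10000, strand = "+")
  edges <- tibble::tibble(regulator = "T1", target = "G1", importance = 0.5)
  inside <- tibble::tibble(tf = "T1", chrom = "chr1", start = 9650, end = 9661)
  outside <- tibble::tibble(tf = "T1", chrom = "chr1", start = 10500, end = 10511)
  kept <- prune_direct(edges, tss, inside, de_genes = "G1", tf_list = "T1")
  expect_equal(nrow(kept$edges), 1)
  dropped <- prune_direct(edges, tss, outside, de_genes = "G1", tf_list = "T1")
  expect_equal(nrow(dropped$edges), 0)
  # 1-bp overlap at the half-open boundary counts; touching does not
  touching <- tibble::tibble(tf = "T1", chrom = "chr1", start = 10300, end = 10310)
  expect_equal(nrow(prune_direct(edges, tss, touching, de_genes = "G1",
                                 tf_list = "T1")$edges), 0)
  grazing <- tibble::tibble(tf = "T1", chrom = "chr1", start = 10299, end = 10310)
  expect_equal(nrow(prune_direct(edges, tss, grazing, de_genes = "G1",
                                 tf_list = "T1")$edges), 1)
})

test_that("pruning matches a brute-force interval scan on random networks", {
  for (seed in c(3, 9)) {
    set.seed(seed)
    genes <- sprintf("G%02d", 1:12)
    tfs <- sprintf("T%d", 1:4)
    all_genes <- c(tfs, genes)
    tss <- tibble::tibble(
      gene = all_genes, chrom = sample(c("chr1", "chr2"), 16, replace = TRUE),
      tss = sample(1000:50000, 16), strand = sample(c("+", "-"), 16, TRUE)
    )
    tfbs <- tibble::tibble(
      tf = sample(tfs, 60, TRUE), chrom = sample(c("chr1", "chr2"), 60, TRUE),
      start = sample(500:50500, 60)
    )
    tfbs$end <- tfbs$start + sample(5:20, 60, TRUE)
    edges <- tidyr::expand_grid(regulator = tfs, target = all_genes) |>
      dplyr::filter(regulator != target) |>
      dplyr::mutate(importance = runif(dplyr::n()))
    de <- sample(all_genes, 10)
    got <- suppressWarnings(
      prune_direct(edges, tss, tfbs, de_genes = de, tf_list = tfs)
    )
    want <- brute_force_prune(edges, tss, tfbs, de_genes = de, tf_list = tfs)
    expect_setequal(paste(got$edges$regulator, got$edges$target),
                    paste(want$regulator, want$target))
    # record-order invariance
    got2 <- suppressWarnings(
      prune_direct(edges[sample(nrow(edges)), ], tss,
                   tfbs[sample(nrow(tfbs)), ], de_genes = de, tf_list = tfs)
    )
    expect_setequal(paste(got$edges$regulator, got$edges$target),
                    paste(got2$edges$regulator, got2$edges$target))
    # monotone in window size: enlarging never removes a retained edge
    wider <- suppressWarnings(
      prune_direct(edges, tss, tfbs, de_genes = de, tf_list = tfs,
                   up = 1000, down = 800)
    )
    expect_true(all(paste(got$edges$regulator, got$edges$target) %in%
                      paste(wider$edges$regulator, wider$edges$target)))
  }
})

test_that("missing TSS and site-less TFs drop edges with warnings", {
  tss <- tibble::tibble(gene = "G1", chrom = "chr1", tss = 10000, strand = "+")
  edges <- tibble::tibble(regulator = c("T1", "T2"), target = c("G1", "G2"),
                          importance = c(0.5, 0.4))
  tfbs <- tibble::tibble(tf = "T1", chrom = "chr1", start = 9700, end = 9710)
  expect_warning(
    out <- prune_direct(edges, tss, tfbs, de_genes = c("G1", "G2"),
                        tf_list = c("T1", "T2")),
    "no TSS"
  )
  expect_equal(out$dropped$missing_tss, 1L)
  expect_equal(out$edges$regulator, "T1")
})

test_that("TF-to-ISG score matrices agree with direct summation", {
  dn <- structure(list(
    edges = tibble::tibble(
      regulator = c("Irf1", "Irf1", "Stat1", "Tf9"),
      target = c("IsgA", "IsgB", "IsgA", "Other1"),
      importance = c(0.7, 0.2, 0.4, 0.9)
    ),
    node_class = c(Irf1 = "ifn_tf", Stat1 = "ifn_tf", Tf9 = "other_tf",
                   IsgA = "fast_isg", IsgB = "fast_isg", Other1 = "other")
  ), class = "direct_network")
  m <- tf_to_isg_matrix(dn, c("Irf1", "Stat1"), c("IsgA", "IsgB"))
  expect_equal(m["Irf1", "IsgA"], 0.7)
  expect_equal(m["Stat1", "IsgB"], 0)
  for (tf in rownames(m)) {
    manual <- sum(dn$edges$importance[dn$edges$regulator == tf &
                                        dn$edges$target %in% colnames(m)])
    expect_equal(sum(m[tf, ]), manual)
  }
  empty <- tf_to_isg_matrix(dn, "Stat2", "IsgC")
  expect_true(all(empty == 0))
})

test_that("hive quadrant statistic is a checked exceedance fraction", {
  mk_direct <- function(importance, src_class, tgt_class) {
    n <- length(importance)
    regs <- sprintf("s%d", seq_len(n))
    tgts <- sprintf("t%d", seq_len(n))
    structure(list(
      edges = tibble::tibble(regulator = regs, target = tgts,
                             importance = importance),
      node_class = c(setNames(src_class, regs), setNames(tgt_class, tgts))
    ), class = "direct_network")
  }
  # unique maximum is an ifn_tf -> fast_isg edge: fraction 1 at quantile 0.9
  d1 <- mk_direct(c(10, 1:9 / 10), c("ifn_tf", rep("other_tf", 9)),
                  c("fast_isg", rep("other", 9)))
  s1 <- hive_quadrant_stats(d1, quantile = 0.9)
  expect_equal(s1$fraction_in_tf_to_isg_quadrant, 1.0)
  # maximum from other_tf -> other: fraction 0
  d2 <- mk_direct(c(10, 1:9 / 10), c("other_tf", rep("ifn_tf", 9)),
                  c("other", rep("fast_isg", 9)))
  expect_equal(hive_quadrant_stats(d2, quantile = 0.9)$fraction_in_tf_to_isg_quadrant, 0.0)
  # equals a brute-force recount and is scale invariant, on random networks
  for (seed in c(1, 5)) {
    set.seed(seed)
    n <- 40
    cls_src <- sample(c("ifn_tf", "other_tf"), n, TRUE)
    cls_tgt <- sample(c("fast_isg", "other"), n, TRUE)
    imp <- round(runif(n), 2)  # duplicates exercise the strict exceedance
    d <- mk_direct(imp, cls_src, cls_tgt)
    s <- hive_quadrant_stats(d, quantile = 0.9)
    thr <- quantile(imp, 0.9, type = 7, names = FALSE)
    top <- which(imp > thr)
    expect_equal(s$n_top_edges, length(top))
    expect_equal(s$fraction_in_tf_to_isg_quadrant,
                 mean(cls_src[top] == "ifn_tf" & cls_tgt[top] == "fast_isg"))
    expect_gte(s$fraction_in_tf_to_isg_quadrant, 0)
    expect_lte(s$fraction_in_tf_to_isg_quadrant, 1)
    d_scaled <- mk_direct(imp * 17, cls_src, cls_tgt)
    expect_equal(hive_quadrant_stats(d_scaled, 0.9)$fraction_in_tf_to_isg_quadrant,
                 s$fraction_in_tf_to_isg_quadrant)
  }
  # degenerate: all importances equal
  d_eq <- mk_direct(rep(0.5, 12), rep("ifn_tf", 12), rep("fast_isg", 12))
  expect_warning(s_eq <- hive_quadrant_stats(d_eq, 0.9), "no top edges")
  expect_equal(s_eq$n_top_edges, 0L)
  expect_equal(s_eq$threshold, 0.5)
})
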