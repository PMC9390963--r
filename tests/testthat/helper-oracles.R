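# Independent oracle implementations used across tests. These deliberately
# re-derive results by brute force / naive iteration, separate from the
# package's code paths.

# Naive fuzzy c-means: random membership initialization, plain alternating
# updates, run to convergence. Returns the objective.
naive_fcm_objective <- function(x, k, m, n_iter = 300, tol = 1e-12) {
  n <- nrow(x)
  u <- matrix(runif(n * k), n, k)
  u <- u / rowSums(u)
  obj_old <- Inf
  for (it in seq_len(n_iter)) {
    um <- u^m
    centers <- (t(um) %*% x) / colSums(um)
    d2 <- matrix(0, n, k)
    for (c in seq_len(k)) {
      d2[, c] <- rowSums((x - matrix(centers[c, ], n, ncol(x), byrow = TRUE))^2)
    }
    d2 <- pmax(d2, 1e-300)
    w <- d2^(-1 / (m - 1))
    u <- w / rowSums(w)
    obj <- sum(u^m * d2)
    if (abs(obj_old - obj) < tol) break
    obj_old <- obj
  }
  obj
}

best_fcm_objective <- function(x, k, m, restarts = 200) {
  min(vapply(seq_len(restarts), function(i) naive_fcm_objective(x, k, m),
             numeric(1)))
}

# Naive Lloyd k-means from random centers; returns within-cluster SSE.
naive_kmeans_sse <- function(x, k, n_iter = 100) {
  centers <- x[sample.int(nrow(x), k), , drop = FALSE]
  for (it in seq_len(n_iter)) {
    d2 <- vapply(seq_len(k), function(c) {
      rowSums((x - matrix(centers[c, ], nrow(x), ncol(x), byrow = TRUE))^2)
    }, numeric(nrow(x)))
    assign <- max.col(-d2)
    for (c in seq_len(k)) {
      if (any(assign == c)) centers[c, ] <- colMeans(x[assign == c, , drop = FALSE])
    }
  }
  d2 <- vapply(seq_len(k), function(c) {
    rowSums((x - matrix(centers[c, ], nrow(x), ncol(x), byrow = TRUE))^2)
  }, numeric(nrow(x)))
  sum(d2[cbind(seq_len(nrow(x)), max.col(-d2))])
}

# Exhaustive best 2-partition by within-cluster SSE over all non-trivial
# splits of <= ~15 rows.
exhaustive_best_2partition <- function(x) {
  n <- nrow(x)
  best <- Inf
  best_side <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    side <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2)))))
    if (all(side) || !any(side)) next
    sse <- 0
    for (s in list(side, !side)) {
      xs <- x[s, , drop = FALSE]
      mu <- colMeans(xs)
      sse <- sse + sum((xs - matrix(mu, nrow(xs), ncol(xs), byrow = TRUE))^2)
    }
    if (sse < best) {
      best <- sse
      best_side <- side
    }
  }
  list(sse = best, side = best_side)
}

# Brute-force promoter-window edge scan: all-pairs loop over edges and sites.
brute_force_prune <- function(edges, tss, tfbs, de_genes, tf_list,
                              up = 400, down = 300) {
  kept <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    r <- edges$regulator[i]
    g <- edges$target[i]
    if (!(r %in% tf_list) || !(g %in% de_genes)) next
    ti <- which(tss$gene == g)[1]
    if (is.na(ti)) next
    if (tss$strand[ti] == "+") {
      ws <- max(0, tss$tss[ti] - up); we <- tss$tss[ti] + down
    } else {
      ws <- max(0, tss$tss[ti] - down); we <- tss$tss[ti] + up
    }
    sites <- tfbs[tfbs$tf == r & tfbs$chrom == tss$chrom[ti], , drop = FALSE]
    for (j in seq_len(nrow(sites))) {
      if (sites$start[j] < we && sites$end[j] > ws) {  # half-open overlap
        kept[i] <- TRUE
        break
      }
    }
  }
  edges[kept, , drop = FALSE]
}

# Mann-Whitney U by exhaustive pair enumeration (ties counted 0.5).
brute_force_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# AUROC of a score vector against binary labels (probability a random
# positive outranks a random negative, ties 0.5).
auroc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  brute_force_u(pos, neg) / (length(pos) * length(neg))
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sij <- choose2(as.vector(tab))
  si <- choose2(rowSums(tab))
  sj <- choose2(colSums(tab))
  n2 <- choose2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Small fixture: a linear TF -> target network expression matrix.
# Returns list(matrix, true_edges tibble, regulators).
sim_linear_network <- function(n_regulators = 6, n_targets = 14,
                               n_true_edges = 10, n_samples = 200,
                               noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  regs <- sprintf("R%02d", seq_len(n_regulators))
  tgts <- sprintf("T%02d", seq_len(n_targets))
  x <- matrix(rnorm(n_samples * n_regulators), n_regulators, n_samples,
              dimnames = list(regs, sprintf("s%03d", seq_len(n_samples))))
  pairs <- expand.grid(regulator = regs, target = tgts,
                       stringsAsFactors = FALSE)
  pick <- sample.int(nrow(pairs), n_true_edges)
  true_edges <- pairs[pick, ]
  y <- matrix(rnorm(n_targets * n_samples, sd = noise_sd), n_targets,
              n_samples, dimnames = list(tgts, colnames(x)))
  for (i in seq_len(nrow(true_edges))) {
    w <- runif(1, 0.8, 1.5)
    y[true_edges$target[i], ] <- y[true_edges$target[i], ] +
      w * x[true_edges$regulator[i], ]
  }
  m <- rbind(x, y)
  m <- m - min(m)  # shift non-negative (scale-irrelevant for the trees)
  list(matrix = m, true_edges = true_edges, regulators = regs,
       targets = tgts)
}

# Small default simulation config for desk-scale tests.
small_config <- function(seed = 11, ...) {
  sim_config(n_genes = 60, n_tfs = 8, n_isg_fast = 10,
             replicates_per_cell = 2, seed = seed, ...)
}
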