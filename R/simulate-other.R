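#' Simulate TSS and TF binding-site annotations consistent with the truth
#'
#' Places every gene on a single synthetic chromosome (`chrS`), TSS every
#' 50 kb on alternating strands, and emits binding sites so that each
#' promoter-proximal ("direct") ground-truth edge has a TF binding site
#' inside the target's promoter window, while every indirect true edge gets
#' only a decoy site well outside any promoter window (so pruning on these
#' annotations recovers the direct edges exactly).
#'
#' @param truth a `ground_truth` object from [simulate_timecourse()].
#' @param window_up,window_down promoter window extent upstream / downstream
#'   of the TSS, in bp.
#' @param tfbs_width width of the emitted binding sites, bp.
#' @param seed integer seed.
#' @return list with `tss` (tibble: gene, chrom, tss, strand) and `tfbs`
#'   (tibble: tf, chrom, start, end; 0-based half-open intervals).
#' @export
simulate_annotations <- function(truth, window_up = 400, window_down = 300,
                                 tfbs_width = 10, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  with_seed(seed, {
    genes <- names(truth$archetype)
    tss <- tibble(
      gene = genes,
      chrom = "chrS",
      tss = 50000L * seq_along(genes),
      strand = rep_len(c("+", "-"), length(genes))
    )
    tss_of <- setNames(tss$tss, tss$gene)
    strand_of <- setNames(tss$strand, tss$gene)

    rows <- vector("list", nrow(truth$edges))
    for (i in seq_len(nrow(truth$edges))) {
      e <- truth$edges[i, ]
      g <- e$target
      win <- promoter_window(tss_of[[g]], strand_of[[g]],
                             up = window_up, down = window_down)
      if (isTRUE(e$direct)) {
        start <- floor(runif(1, win$start, win$end - tfbs_width))
      } else {
        # Decoy: 2-5 kb past the TSS, outside every promoter window (genes
        # are 50 kb apart, windows span < 1 kb).
        start <- tss_of[[g]] + floor(runif(1, 2000, 5000))
      }
      rows[[i]] <- tibble(tf = e$regulator, chrom = "chrS",
                          start = start, end = start + tfbs_width)
    }
    list(tss = tss, tfbs = bind_rows(rows))
  })
}

#' Simulate a cytokine-stimulation reference expression matrix
#'
#' A gene x population non-negative matrix with a marker-gene block per
#' population (default populations mirror the seven collapsed
#' cytokine-induced T cell states: IFN-beta stimulated, resting, Th17, Th2,
#' Th1, Th0, iTreg), well-conditioned for mixture-fraction recovery.
#'
#' @param n_genes number of genes; at least one marker gene per population.
#' @param populations population labels.
#' @param marker_boost expression added to a population's marker block.
#' @param seed integer seed.
#' @return gene x population matrix, layer `"TPM"`.
#' @export
simulate_reference_matrix <- function(n_genes = 70,
                                      populations = c("IFNb", "Resting", "Th17",
                                                      "Th2", "Th1", "Th0", "iTreg"),
                                      marker_boost = 30,
                                      seed = 1L) {
  k <- length(populations)
  stopifnot(n_genes >= k)
  with_seed(seed, {
    vals <- matrix(rgamma(n_genes * k, shape = 2, rate = 0.5), n_genes, k,
                   dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                   populations))
    block <- rep_len(seq_len(k), n_genes)
    for (j in seq_len(k)) vals[block == j, j] <- vals[block == j, j] + marker_boost
    set_expr_layer(vals, "TPM")
  })
}

#' Simulate bulk mixtures of a reference matrix
#'
#' Each sample is `reference %*% proportions + noise`, with Gaussian noise
#' truncated at zero. Proportion vectors must be non-negative and sum to one.
#'
#' @param reference gene x population matrix.
#' @param proportions population x sample matrix of mixing fractions (a
#'   single vector is treated as one sample); each column must sum to 1
#'   within 1e-8.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed.
#' @return gene x sample matrix, layer `"TPM"`.
#' @export
simulate_mixtures <- function(reference, proportions, noise_sd = 0, seed = 1L) {
  if (is.null(dim(proportions))) {
    proportions <- matrix(proportions, ncol = 1,
                          dimnames = list(names(proportions), "S1"))
  }
  if (nrow(proportions) != ncol(reference)) {
    abort("proportions must have one row per reference population")
  }
  if (any(proportions < 0)) abort("proportions must be non-negative")
  bad <- abs(colSums(proportions) - 1) > 1e-8
  if (any(bad)) {
    abort(sprintf("proportion vectors must sum to 1 (offending sample(s): %s)",
                  paste(colnames(proportions)[bad], collapse = ", ")))
  }
  if (is.null(colnames(proportions))) {
    colnames(proportions) <- sprintf("S%d", seq_len(ncol(proportions)))
  }
  with_seed(seed, {
    mix <- reference %*% proportions
    if (noise_sd > 0) {
      mix <- pmax(mix + matrix(rnorm(length(mix), sd = noise_sd),
                               nrow(mix), ncol(mix)), 0)
    }
    set_expr_layer(mix, "TPM")
  })
}

#' Simulate per-mouse tumour growth curves with intended outcomes
#'
#' Deterministic-by-construction curves: `"progression"` curves cross
#' 100 mm2 before day 28, `"complete_regression"` curves reach 0 mm2 and stay
#' there, `"partial"` curves do neither. Tumours start near 9 mm2, matching
#' the size at surgery.
#'
#' @param outcomes character vector of intended outcomes per mouse, values in
#'   `"complete_regression"`, `"progression"`, `"partial"`.
#' @param cage_ids optional per-mouse cage labels (default: five mice per
#'   cage in input order).
#' @param days measurement days since treatment start.
#' @param seed integer seed.
#' @return long tibble: mouse_id, cage_id, day, area_mm2, intended.
#' @export
simulate_growth_curves <- function(outcomes, cage_ids = NULL,
                                   days = seq(0, 28, by = 2), seed = 1L) {
  ok <- c("complete_regression", "progression", "partial")
  if (!all(outcomes %in% ok)) {
    abort(paste("outcomes must be one of:", paste(ok, collapse = ", ")))
  }
  n <- length(outcomes)
  if (is.null(cage_ids)) cage_ids <- sprintf("cage%d", ceiling(seq_len(n) / 5))
  stopifnot(length(cage_ids) == n)
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      a0 <- runif(1, 8, 10)
      area <- switch(
        outcomes[i],
        progression = {
          cross_day <- runif(1, 12, 22)
          r <- log(120 / a0) / cross_day
          pmax(a0 * exp(r * days) * runif(length(days), 0.92, 1.08), 0.5)
        },
        complete_regression = {
          regress_day <- runif(1, 6, 14)
          a <- pmax(0, a0 * (1 - days / regress_day)) *
            runif(length(days), 0.9, 1.1)
          a[days >= regress_day] <- 0
          a
        },
        partial = {
          # decline towards ~3 mm2 then regrow, capped well below 100
          a <- ifelse(days <= 10, a0 - (a0 - 3) * days / 10,
                      3 + 57 * (days - 10) / 18)
          pmin(pmax(a * runif(length(days), 0.9, 1.1), 1), 95)
        }
      )
      out[[i]] <- tibble(
        mouse_id = sprintf("mouse%02d", i), cage_id = cage_ids[i],
        day = days, area_mm2 = area, intended = outcomes[i]
      )
    }
    bind_rows(out)
  })
}

#' Simulate two-arm exponential survival data
#'
#' Control times are exponential with the given median; the experimental
#' hazard is the control hazard divided by `hazard_ratio` (a control vs
#' experimental hazard ratio above 1 means experimental animals survive
#' longer). All events are observed unless an administrative censoring day is
#' set.
#'
#' @param hazard_ratio control-vs-experimental hazard ratio (> 0).
#' @param n_per_group animals per arm (>= 2).
#' @param control_median_days median control survival, days.
#' @param admin_censor_day optional administrative censoring day.
#' @param seed integer seed.
#' @return tibble: group (`"control"`/`"experimental"`), time, event (0/1).
#' @export
simulate_survival <- function(hazard_ratio = 5, n_per_group = 10,
                              control_median_days = 35,
                              admin_censor_day = NULL, seed = 1L) {
  if (!is.finite(hazard_ratio) || hazard_ratio <= 0) {
    abort("hazard_ratio must be positive")
  }
  if (!is.finite(control_median_days) || control_median_days <= 0) {
    abort("control_median_days must be positive")
  }
  if (n_per_group < 2) abort("n_per_group must be at least 2")
  with_seed(seed, {
    rate_c <- log(2) / control_median_days
    rate_e <- rate_c / hazard_ratio
    d <- tibble(
      group = rep(c("control", "experimental"), each = n_per_group),
      time = c(rexp(n_per_group, rate_c), rexp(n_per_group, rate_e)),
      event = 1L
    )
    if (!is.null(admin_censor_day)) {
      d$event <- as.integer(d$time <= admin_censor_day)
      d$time <- pmin(d$time, admin_censor_day)
    }
    d
  })
}

#' Simulate a two-dimensional embedding-velocity fixture
#'
#' Per-cell velocity vectors drawn from an isotropic Gaussian with a
#' group-specific scale, for exercising the transcriptional-momentum
#' statistic (for which `E[|v|^2] = 2 * scale^2`).
#'
#' @param n_cells_per_group named integer vector: cells per group.
#' @param group_scales named numeric vector of non-negative per-group scales
#'   (same names as `n_cells_per_group`).
#' @param seed integer seed.
#' @return tibble: cell_id, group, vx, vy.
#' @export
simulate_velocity_embedding <- function(n_cells_per_group, group_scales,
                                        seed = 1L) {
  groups <- names(n_cells_per_group)
  if (is.null(groups) || !setequal(groups, names(group_scales))) {
    abort("n_cells_per_group and group_scales must share group names")
  }
  if (any(group_scales < 0)) abort("scales must be non-negative")
  with_seed(seed, {
    out <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      g <- groups[i]
      n <- n_cells_per_group[[g]]
      s <- group_scales[[g]]
      out[[i]] <- tibble(
        cell_id = sprintf("%s_c%05d", g, seq_len(n)),
        group = g,
        vx = rnorm(n, sd = s) * (s > 0),
        vy = rnorm(n, sd = s) * (s > 0)
      )
    }
    bind_rows(out)
  })
}
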