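#' Simulation configuration for the synthetic checkpoint-blockade time course
#'
#' Bundles the design of the synthetic experiment: a two-model (AB1, Renca),
#' four-timepoint (days 0, 2, 4, 6), two-arm (responder / non-responder)
#' layout in which transcription factors (TFs) drive downstream targets, and a
#' subset of interferon-stimulated genes (ISGs) follows on/fast-off kinetics
#' in responders only.
#'
#' Gene dynamics are built from per-archetype, per-arm template profiles on
#' the log2 scale: `log2 mean = baseline + amplitude * template`. The five
#' archetypes are `on_fast_off` (high at/near treatment start in responders,
#' rapid shut-off; slow monotone rise in non-responders), `grad_up` (gradual
#' rise in both arms), `grad_up_resp` (gradual rise, larger amplitude in
#' responders), `grad_down` (gradual decline in both arms) and `flat`.
#' Target genes do not get a template directly: their log2 mean is
#' `baseline + sum(w * (regulator log2 mean - regulator baseline))` over their
#' regulators, with coupling weights drawn uniformly from `coupling_range`,
#' so the regulatory structure is recoverable by tree-ensemble inference.
#'
#' @param n_genes total number of genes (TFs included).
#' @param n_tfs number of transcription factors; the first `min(5, n_tfs)` are
#'   the interferon-related TFs Irf1, Stat1, Stat2, Irf7, Irf9 and carry the
#'   on/fast-off archetype.
#' @param n_isg_fast number of non-TF genes assigned on/fast-off dynamics
#'   (the ground-truth fast ISG set).
#' @param timepoints strictly increasing day offsets of the sampling design.
#' @param replicates_per_cell biological replicates per
#'   (model, response, timepoint) cell.
#' @param models tumour-model labels.
#' @param dispersion negative-binomial dispersion of the count noise
#'   (`Var = mu + dispersion * mu^2`); must be positive.
#' @param libsize_range interval of multiplicative per-sample library-size
#'   factors, drawn uniformly.
#' @param baseline_log2_range interval of per-gene baseline log2 expression.
#' @param amplitude dynamic range of the archetype templates, log2 units.
#' @param coupling_range interval of regulator-to-target coupling weights.
#' @param n_regulators_per_target how many TFs drive each regulated target.
#' @param direct_prob probability that a true regulatory edge is
#'   promoter-proximal ("direct", i.e. backed by a TF binding site in the
#'   target's promoter window).
#' @param archetype_props proportions of the non-fast, non-TF genes assigned
#'   to the `grad_up`, `grad_up_resp`, `grad_down` and `flat` archetypes.
#' @param templates named list of per-archetype templates; each entry is a
#'   list with `responder` and `non_responder` numeric vectors of length
#'   `length(timepoints)`.
#' @param seed integer seed making every draw reproducible.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 300,
                       n_tfs = 10,
                       n_isg_fast = 40,
                       timepoints = c(0, 2, 4, 6),
                       replicates_per_cell = 3,
                       models = c("AB1", "Renca"),
                       dispersion = 0.1,
                       libsize_range = c(0.8, 1.25),
                       baseline_log2_range = c(4, 8),
                       amplitude = 3,
                       coupling_range = c(0.5, 1.5),
                       n_regulators_per_target = 2,
                       direct_prob = 0.6,
                       archetype_props = c(grad_up = 0.25, grad_up_resp = 0.2,
                                           grad_down = 0.25, flat = 0.3),
                       templates = default_archetype_templates(length(timepoints)),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
    n_isg_fast = as.integer(n_isg_fast), timepoints = as.numeric(timepoints),
    replicates_per_cell = as.integer(replicates_per_cell),
    models = as.character(models), dispersion = as.numeric(dispersion),
    libsize_range = as.numeric(libsize_range),
    baseline_log2_range = as.numeric(baseline_log2_range),
    amplitude = as.numeric(amplitude),
    coupling_range = as.numeric(coupling_range),
    n_regulators_per_target = as.integer(n_regulators_per_target),
    direct_prob = as.numeric(direct_prob),
    archetype_props = archetype_props,
    templates = templates,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 2 || cfg$n_tfs < 1) abort("need n_genes >= 2 and n_tfs >= 1")
  if (cfg$n_tfs >= cfg$n_genes) abort("n_tfs must be smaller than n_genes")
  if (cfg$n_isg_fast > cfg$n_genes - cfg$n_tfs) {
    abort("n_isg_fast cannot exceed n_genes - n_tfs")
  }
  if (any(diff(cfg$timepoints) <= 0)) {
    abort("timepoints must be strictly increasing")
  }
  if (!is.finite(cfg$dispersion) || cfg$dispersion <= 0) {
    abort("dispersion must be > 0")
  }
  if (length(cfg$libsize_range) != 2 || any(cfg$libsize_range <= 0) ||
      diff(cfg$libsize_range) < 0) {
    abort("libsize_range must be a positive increasing interval")
  }
  nt <- length(cfg$timepoints)
  needed <- c("on_fast_off", "grad_up", "grad_up_resp", "grad_down", "flat")
  if (!all(needed %in% names(cfg$templates))) {
    abort(paste("templates must define:", paste(needed, collapse = ", ")))
  }
  for (a in needed) {
    tpl <- cfg$templates[[a]]
    if (length(tpl$responder) != nt || length(tpl$non_responder) != nt) {
      abort(sprintf("template '%s' must have %d values per arm", a, nt))
    }
  }
  cfg
}

#' Default per-archetype, per-arm dynamic templates
#'
#' Fractions of the dynamic amplitude at each design timepoint. The
#' on/fast-off responder template peaks at the first timepoint and falls below
#' half of its peak by the last; its non-responder counterpart rises
#' monotonically (the slower, less intense chronic activation).
#'
#' @param n_timepoints number of design timepoints (templates are defined for
#'   the default four; other designs must supply their own).
#' @return named list of archetype templates.
#' @export
default_archetype_templates <- function(n_timepoints = 4) {
  if (n_timepoints != 4) {
    abort("default templates are defined for 4 timepoints; supply `templates`")
  }
  list(
    on_fast_off = list(responder     = c(1.00, 0.90, 0.30, 0.15),
                       non_responder = c(0.20, 0.40, 0.60, 0.80)),
    grad_up     = list(responder     = c(0.20, 0.47, 0.73, 1.00),
                       non_responder = c(0.20, 0.47, 0.73, 1.00)),
    grad_up_resp = list(responder    = c(0.40, 0.93, 1.47, 2.00),
                        non_responder = c(0.20, 0.47, 0.73, 1.00)),
    grad_down   = list(responder     = c(1.00, 0.73, 0.47, 0.20),
                       non_responder = c(1.00, 0.73, 0.47, 0.20)),
    flat        = list(responder     = rep(0.5, 4),
                       non_responder = rep(0.5, 4))
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes (%d TFs, %d fast ISGs); models: %s\n",
              x$n_genes, x$n_tfs, x$n_isg_fast, paste(x$models, collapse = ", ")))
  cat(sprintf("  timepoints (days): %s; %d replicates per cell\n",
              paste(x$timepoints, collapse = ", "), x$replicates_per_cell))
  cat(sprintf("  NB dispersion %.3g; seed %d\n", x$dispersion, x$seed))
  invisible(x)
}

# Evaluate code with a temporarily fixed RNG state, restoring it afterwards,
# so generators are pure functions of (config, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
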