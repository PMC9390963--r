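# onoffgrn

Analysis toolkit for time-course tumour transcriptomics under immune
checkpoint blockade (ICB). Preclinical bilateral-tumour studies showed that
mice responding to anti-CTLA4/anti-PD-L1 therapy display **on/fast-off
kinetics of type-I-interferon signalling**: interferon-stimulated genes
(ISGs) are highly expressed at treatment start and shut off within days,
while non-responders activate them slowly and chronically. `onoffgrn`
packages the computational route to that finding — from raw time-course
expression matrices to the fast-on/off ISG signature and the regulatory
network behind it — for anyone analysing multi-timepoint
responder/non-responder designs, plus a synthetic-data generator with
embedded ground truth so every stage is testable without any download.

## What it computes

- **Time-course clustering** — replicate-averaged, z-normalised gene
  profiles clustered by fuzzy c-means (memberships `u_gc ∝ (1/d²)^{1/(m−1)}`,
  fuzzifier `m` estimated by the Schwämmle–Jensen rule), with cluster trends
  matched between tumour models by the Pearson correlation of centroid trend
  lines and their gene overlap extracted.
- **Regulatory network inference** — GENIE3-style tree ensembles: each
  target gene (standardised to unit variance) is regressed on candidate
  regulators with a random forest (`√p` features per split), and edge
  importance is the total variance-reduction importance averaged over trees.
  Regulators rank by summed outgoing importance.
- **Direct-connection pruning** — a TF→gene edge is kept only when the gene
  is differentially expressed and a binding site of that TF falls in the
  strand-oriented promoter window 400 bp upstream / 300 bp downstream of
  the gene's TSS (0-based half-open BED semantics, ≥ 1 bp overlap); the
  hive-quadrant statistic reports what fraction of the top-decile edges run
  from interferon-related TFs (Irf1, Stat1, Stat2, Irf7, Irf9) to fast ISGs.
- **Fast-on/off signature** — k-means (k = 2) on z-scored responder time
  courses of curated ISG sets; the cluster with the higher centroid at the
  model's early timepoint is the fast set. Samples are scored by the mean
  z-score of signature genes.
- **Supporting statistics** — non-negative least-squares deconvolution of
  cytokine-stimulation signatures (7 collapsed T-cell states, TPM > 0.3 in
  ≥ 8 samples prevalence filter); per-cell transcriptional momentum
  `‖v‖² = v_x² + v_y²` of embedding velocities with rank-sum group
  comparisons; deterministic growth-curve response calls (non-responder:
  ≥ 100 mm² within 28 days; responder: sustained complete regression) with
  the cage dichotomy filter; and log-rank (Mantel–Cox) testing with
  Monte-Carlo power for the study design (control median 35 days, hazard
  ratio 5, n = 10 per arm) against the Schoenfeld closed form
  `Φ(√(d/4)·|log HR| − z_{1−α/2})`.
- **Synthetic data** — negative-binomial counts over a 2-model ×
  4-timepoint × 2-arm design in which TF archetype templates drive coupled
  targets, with matching TSS/TFBS annotations, mixtures, growth curves,
  survival times and velocity embeddings, all pure functions of
  `(config, seed)`.

## Worked example

```r
library(onoffgrn)

cfg <- sim_config(seed = 7)   # 300 genes, 10 TFs, 40 fast ISGs, 2 models
run <- run_pipeline(cfg, n_trees = 100)
#> [simulate] 300 genes x 48 samples, 367 true edges (232 direct)
#> [cluster] k = 6 per model; 10 matched pairs at r >= 0.80
#> [grn] AB1: 2990 edges from 12 responder samples (100 trees)
#> [grn] Renca: 2990 edges from 12 responder samples (100 trees)
#> [signature] 40 fast-on/off genes consistent across 2 model(s)
#> [prune] AB1: 114 direct edges; top-decile TF-to-ISG fraction 0.167
#> [prune] Renca: 114 direct edges; top-decile TF-to-ISG fraction 0.333

run
#> <onoffgrn_run>
#>   models: AB1, Renca
#>   10 cross-model cluster matches; 40 fast-on/off genes
#>   AB1: 114 direct edges, TF-to-ISG quadrant fraction 0.167
#>   Renca: 114 direct edges, TF-to-ISG quadrant fraction 0.333
```

The 48 samples are 2 models × 2 response arms × 4 timepoints × 3
replicates. The derived fast set recovers the generator's truth exactly here
(Jaccard 1.0), and the 114 pruned edges per model are exactly the
promoter-proximal true edges into differentially expressed targets.
Individual stages compose with the pipe:

```r
rank_regulators(run$networks$AB1, top_n = 5)
#> # A tibble: 5 × 3
#>   gene  outgoing_sum  rank
#>   <chr>        <dbl> <int>
#> 1 Tf08          3.71     1
#> 2 Tf07          3.57     2
#> 3 Tf10          3.26     3
#> 4 Irf7          2.75     4
#> 5 Tf06          2.70     5

simulate_power(power_spec(hazard_ratio = 5, n_per_group = 10, reps = 2000,
                          seed = 1))[, 1:4]
#> # A tibble: 1 × 4
#>   power_estimate   mc_se  reps n_events_mean
#>            <dbl>   <dbl> <int>         <dbl>
#> 1          0.893 0.00691  2000            20
```

The Monte-Carlo power of the study's survival design comfortably exceeds
the planned 0.8. Fitted objects have `tidy()`, `glance()` and `autoplot()`
methods (`autoplot(run$clusterings$AB1)` draws the centroid trends;
`plot_growth_curves()` and `plot_tf_isg_scores()` cover the other result
types).

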