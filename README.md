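# faconnectome

Graph-theoretical analysis of FA-weighted white-matter structural
connectomes for three-group case–control studies (healthy controls vs.
frontal-tumor vs. temporal-tumor patients), with a seeded synthetic cohort
generator for validation and power analysis.

## The problem

Deterministic DTI tractography yields, per subject, a pair of symmetric
90 × 90 matrices over the AAL atlas regions: a streamline-count matrix and
a mean fractional-anisotropy (FA) matrix. Connectome studies of focal brain
lesions ask whether a patient group's network topology differs from
controls — globally (small-world organization, efficiency), regionally
(nodal path length, degree, betweenness, nodal efficiency), and in its
rich-club core — and whether those differences track cognitive decline.
This package implements that full analysis chain for researchers working
with such matrix pairs:

1. **Network construction** — an edge is kept iff its streamline count is
   ≥ a threshold (default 3); its weight is the mean FA of the connection.
2. **Sparsity sweep** — each network is thresholded to the strongest
   `⌊s·N(N−1)/2⌋` edges for s = 0.05 … 0.50 (step 0.05), and every metric
   is summarized as the trapezoidal area under its metric-vs-sparsity
   curve (AUC), removing the dependence on any single threshold.
3. **Graph metrics** — with edge length 1/w (strong connections are short):
   * global: clustering coefficient `Cp` (Onnela geometric-mean formula,
     weights max-normalized), characteristic path length `Lp`, global and
     local efficiency `Eglob`, `Eloc`;
   * small-world ratios against degree-preserving random nulls
     (Maslov–Sneppen rewiring, weights reshuffled):
     `γ = Cp/Cp_rand`, `λ = Lp/Lp_rand`, `σ = γ/λ`;
   * nodal: shortest path `NLp`, degree `K`, betweenness `B` (Brandes,
     fractional tie credit), nodal efficiency `E_nodal`.
4. **Rich club** — hubs are the top 15% of nodes by cohort-averaged
   degree; `φ(k)` is the edge density among nodes of degree > k,
   normalized by null ensembles; every edge is classed rich (hub–hub),
   feeder (hub–peripheral) or local (peripheral–peripheral) and class FA
   strengths are summed.
5. **Statistics** — ANOVA/χ² on demographics (including ANOVA
   reconstructed from printed group means/SDs/ns), ANCOVA-style group
   comparisons of metric AUCs controlling age, sex and education (partial
   F for the group block, adjusted means, post hoc pairwise t),
   Benjamini–Hochberg FDR within each nodal-metric family, and
   brain–behavior partial correlations.

Because clinical imaging data of this kind are rarely shareable, the
package ships a **synthetic cohort generator**: a seeded FA-weighted
template (ring-band lattice plus a 13-hub overlay; small-world and
rich-club by construction) from which control subjects are jittered copies
and tumor-group subjects get reduced/deleted peripheral connectivity,
boosted hub–hub connectivity, and cognitive scores calibrated to target
correlations with local-efficiency AUC. Everything is reproducible from a
`cohort_spec(seed = …)`.

## Worked example

```r
library(faconnectome)

co <- generate_cohort(cohort_spec(c(CN = 6, FTumor = 6, TTumor = 6), seed = 7))
nets <- lapply(co$subjects, function(s)
  build_connectome(connectome_pair(s$count_matrix, s$fa_matrix),
                   streamline_threshold = 3))
nets[[1]]
#> FA-weighted connectome: 90 nodes, 2348 edges, density 0.586

# global metrics across the sparsity sweep, 100 nulls per sparsity
sw <- sweep_metrics(nets[[1]], sparsity_grid(0.05, 0.50, 0.05),
                    n_nulls = 100, seed = 1)
round(sw$global_auc, 3)
#>     Cp     Lp  Eglob   Eloc  gamma lambda  sigma
#>  0.195  1.298  0.177  0.216  0.928  0.487  0.855
```

These are areas under each metric's curve over the 0.45-wide sparsity
range; dividing by 0.45 gives grid-averaged values, e.g. σ = 0.855/0.45 ≈
1.9 > 1: this subject's network clusters far more than degree-matched
random graphs (γ ≈ 2.1) at near-random path length (λ ≈ 1.1) — a
small-world architecture.

```r
hubs <- select_hubs(nets, fraction = 0.15)     # 13 hubs (15% of 90)
strengths <- t(sapply(nets, classify_and_sum, hub_labels = hubs))
aggregate(strengths, list(group = co$table$group), mean)
#>    group rich feeder local
#> 1     CN 53.9  333.9 814.3
#> 2 FTumor 59.2  334.5 696.3
#> 3 TTumor 59.2  334.0 697.0
```

Both tumor groups show the injected rich-club strengthening (53.9 → 59.2)
and peripheral weakening (814 → 696). Covariate-adjusted group inference
on the local-efficiency AUC:

```r
res <- adjusted_group_test(co$table$eloc_auc, co$table$group,
                           co$table[, c("age", "sex", "education")])
round(c(F = res$F, p = res$p), 4)
#>      F      p
#> 1.5017 0.2618
round(res$adjusted_means, 4)
#>     CN FTumor TTumor
#> 0.2172 0.2162 0.2160
```

The adjusted means order as designed (controls highest), though n = 6 per
group is far too small for significance — at the generator's default
effect size the deficit is reliably detected from about n = 30 per group.
Summary-table statistics work from printed values alone:

```r
chisq_independence(rbind(male = c(6, 5, 10), female = c(8, 8, 8)))
#> $chi2
#> [1] 1.00471
#> $p
#> [1] 0.6051041
```

An end-to-end run (simulate → build → metrics → rich club → statistics,
with CSV tables and a checksum manifest) is a single call:

```r
res <- run_pipeline(run_config(
  synthetic = cohort_spec(c(CN = 14, FTumor = 13, TTumor = 18), seed = 1),
  out_dir = "results/run1"))
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/connectome-pipeline.R`
(`run-all`, `simulate`, `sensitivity`, `init-config` subcommands, YAML
config).

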