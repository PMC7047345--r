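---
title: "Methods: FA-weighted connectome analysis and its synthetic validation cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FA-weighted connectome analysis and its synthetic validation cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices, numerical
conventions and known limitations of the package. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## 1. From matrix pairs to weighted networks

The unit of input is a per-subject pair of symmetric 90 × 90 matrices over
an AAL-style parcellation: non-negative integer streamline counts and mean
FA per connection (dimensionless, in [0, 1]). Validation rejects
asymmetry beyond 1e-9, nonzero diagonals, FA outside [0, 1], and FA
present where the count is zero, naming the offending indices.

**Streamline threshold.** An edge survives iff its count is **at least**
the threshold (inclusive reading of "connected through a certain number of
streamlines"); default 3, the conventional choice for deterministic
tractography. `threshold_sensitivity()` quantifies how little the
downstream AUCs move across thresholds 1–5 (Spearman rank correlation of
subject AUCs against the baseline, computed for the four null-free global
metrics; the small-world ratios are excluded there because a 5-threshold ×
cohort × 100-null sweep would dominate runtime while answering a question
about the count cutoff, not the null model). Tractography parameters
themselves (FA > 0.2, 45° turning angle) are upstream provenance, recorded
but never recomputed.

**Sparsity thresholding.** At sparsity *s* the strongest
`floor(s·N(N−1)/2)` FA edges are kept — `floor` guarantees density ≤ s.
Ties in FA are broken by ascending (i, j) node index, which makes the
selection deterministic and the edge sets nested along any grid. The
default grid is 0.05–0.50 in steps of 0.05: the range over which
whole-brain structural networks remain sparse yet mostly connected; the
step is a discretization choice only — the test suite checks that halving
it moves smooth metric AUCs by under 2%. Thresholding is applied
**per subject** (required for subject-level AUC statistics), not to
group-averaged matrices.

## 2. Graph metrics

All path-based quantities use edge length `1/w` for FA weight `w`; with
unit weights every metric reduces to its binary counterpart (tested). The
`1 − w` alternative is not used: reciprocal length is the standard
transform for FA weights and keeps efficiencies in [0, 1] when weights
are ≤ 1. A `binary = TRUE` option on the path-length functions covers the
binarized-λ variant.

* **Distances** are exact Floyd–Warshall (compiled C++); disconnected
  pairs are `Inf`. `Lp` and `NLp` average the *finite* distances and
  report the count of infinite pairs alongside — disconnection is a value,
  not an error, and this convention keeps the metrics finite at sparse
  thresholds without restricting to the giant component. A node with no
  finite distances has undefined `NLp` (`NA` with a warning), and its
  nodal AUC is propagated as `NA` rather than invented.
* **Efficiencies** count `1/∞` as 0. `Eloc(i)` is the global efficiency of
  the subgraph induced by `i`'s neighbors with original weights; degree <2
  contributes 0.
* **Clustering** is the Onnela geometric-mean triangle formula on weights
  normalized by the network maximum — the default of the GRETNA/PANDA
  toolbox lineage; `Cp` averages over all nodes with degree <2 contributing
  0.
* **Betweenness** is Brandes' algorithm with fractional credit for tied
  shortest paths and endpoints excluded (via igraph).
* **Small-world ratios.** Nulls are degree-preserving double-edge-swap
  rewirings (10×|E| rewiring trials through igraph's C implementation)
  with the original FA weights randomly reassigned to the rewired edges;
  100 nulls by default. γ and λ divide by the **ensemble means** of
  `Cp_rand` and `Lp_rand` (matching their definitions), not by per-null
  ratios; σ = γ/λ, defined only for positive ensemble means.
* **AUC** is the trapezoidal integral over the grid; exact for curves
  linear in *s*. Where a single dimensionless summary is reported (e.g.
  the acceptance script's σ and γ), the AUC is divided by the grid range
  (0.45) so the value sits on the same scale as the per-sparsity ratios.

Correctness is anchored by brute-force oracles: exhaustive simple-path
enumeration for distances, betweenness and efficiencies, explicit
neighbor-subgraph materialization for local efficiency, and direct
definition-recounting for φ(k), all on ≤ 7-node graphs to 1e-9, plus
igraph cross-checks and scale/unit-weight reduction properties.

## 3. Rich-club analysis

Hubs are the top `floor(0.15·N)` nodes (13 of 90) by nodal degree averaged
over **all** subjects, groups pooled, on the streamline-filtered (not
sparsity-thresholded) networks; ties break by higher mean strength, then
node index. φ(k) is the **binary** density among nodes of degree > k
("density of connections"); a weighted variant is available but
non-default. φ_norm(k) divides by the null-ensemble mean φ, and is `NA`
where fewer than two nodes exceed k (reported missing, never 0).
Edge classes partition the edge set — rich (hub–hub), feeder (one hub),
local (no hub) — so class strengths (summed FA) always add to total
network strength (tested to 1e-9). Which k values to test for group
differences is left to the user; the full curve is returned.

## 4. Statistical layer

"ANOVA controlling for age, sex and education" is read as the standard
ANCOVA general linear model: `outcome ~ group + covariates`, with a
partial F test for the group block, adjusted group means at the covariate
means, and post hoc pairwise contrasts computed from the same fitted model
(t on the residual df, two-sided). With no covariates this reduces exactly
to one-way ANOVA (tested to 1e-6). Incomplete cases are dropped listwise
with a message; collinear covariates raise an error naming the columns.

`anova_from_summary()` reconstructs the one-way F from printed group
means/SDs/ns (between-SS about the size-weighted grand mean, within-SS
`Σ(nᵢ−1)sᵢ²`) and equals raw-data ANOVA whenever the summaries are exact.
The χ² test is Pearson **without** continuity correction. FDR is
Benjamini–Hochberg, applied within one family per nodal metric (each
metric's 90 node tests form one family); global and strength tests are few
and reported unadjusted. Brain–behavior association is the partial
correlation of the covariate-residualized metric and score, with a
two-sided p on `n − 2 − k` df; at least 10 complete cases are required.

## 5. The synthetic cohort generator

The generator exists because subject-level imaging matrices of this kind
are typically not depositable. It emulates the *statistical structure* the
analysis assumes, not the imaging physics.

**Template** (`make_template_network`, seeded). Nodes sit on a ring and
connect within a band of width `0.28·(n−1)` (density ≈ 0.59, so the full
0.05–0.50 sweep is always feasible). FA decays smoothly with ring
distance: `w = 0.2 + 0.6 · proximity^0.75 · Beta(10, 2)`, capped at 0.8 —
a plausible white-matter FA range with adjacent-node means near 0.7.
Because weight orders by proximity, thresholding at *any* sparsity yields
a lattice-like, highly clustered topology: the template is small-world by
construction at every grid point. The 13 designated hubs form a strong
clique (`0.2 + 0.6·Beta(12, 3)`) and send two strong spokes
(`0.2 + 0.6·Beta(10, 3)`) into each of six ring segments, guaranteeing
both the highest degrees (top-13 by construction; tested) and a detectable
rich club.

**Subjects.** Controls are the template with N(0, 0.02) FA jitter on
existing edges (clipped into [0.01, 1] to preserve the edge pattern; any
clipping is logged). Tumor-group subjects first have local-class edge
weights multiplied by `eloc_reduction` (default 0.90), a fraction
`local_edge_dropout` (default 0.05) of local edges deleted, and hub–hub
weights multiplied by `richclub_boost` (default 1.10) — encoding the
peripheral-weakening / core-strengthening pattern the analysis is meant to
detect. Streamline counts are `Poisson(50·w) + 1`, giving the count filter
realistic variation. Demographics (age, education: clipped normals; sex:
Bernoulli) and cognitive score means/SDs are calibrated to the published
three-group summary table. Scores are Gaussian and deliberately not
truncated at 0 — truncation would distort the calibrated correlations.

**Cognition calibration.** For each configured (group, score) pair the
score is `m + s·(r·z + sqrt(1−r²)·ε)` where `z` is the group-standardized
local-efficiency AUC and ε is standardized noise **orthogonalized against
z**, so the realized within-group Pearson correlation equals the target
`r` exactly rather than up to sampling error; the covariate-adjusted
partial correlation then deviates only through the (independent)
covariates. Defaults target r = 0.503 (temporal group, memory) and
r = 0.49 (frontal group, DSST). A `missing_score_fraction` parameter
blanks patient scores at random (default 0), since published cohorts often
lack cognition for some patients.

**Known behavior of the effect dial.** The CN-vs-tumor Eloc AUC gap grows
with the local-weight reduction over the designed regime (factors
1.0 → 0.90) but saturates for much stronger reductions: once local weights
fall below the feeder/background weight ranks, top-k sparsity selection
recruits replacement edges and the thresholded topology adapts. The
monotonicity property is therefore asserted within the designed regime.

**What the generator does not emulate**: tumor location, hemisphere or
grade; lesion-induced node loss; spatial embedding or image-space noise
(no NIfTI); realistic inter-regional FA covariance structure; floor/
ceiling effects in test scores. Passing tests therefore demonstrate that
the *pipeline* recovers known injected structure under realistic noise —
not that real glioma cohorts behave this way.

## 6. Reproducibility and problem sizes

Every stochastic step is seeded: a `cohort_spec` reproduces its cohort
bit-identically, null ensembles reproduce under their seed, and the
pipeline writes a manifest of config hash and per-file checksums
(identical configs reproduce identical table checksums; tested). The
analysis scales chosen for the shipped checks are desk-scale by design:
oracle suites run on ≤ 7-node graphs; small-world recovery uses the
published group sizes (14/13/18) with 100 nulls per sparsity; calibrated
correlation recovery uses n = 500 per tumor group; type-I error control is
checked with 1000 group-label permutations on a null-effect cohort at
n = 15 per group (rejection rate required within 0.05 ± 0.02).

## 7. Limitations

* The ANCOVA reading of "ANOVA after controlling for covariates" is the
  standard one, but residualize-then-ANOVA variants exist and will differ
  slightly in unbalanced designs.
* The null model preserves degree exactly but not strength sequences; a
  strength-preserving null would change γ and φ_norm quantitatively.
* Rich-club hub selection at a single fraction (0.15) follows the study
  design it mirrors; the φ(k) curves themselves are fraction-free and
  should be preferred when the hub count is contentious.
* `Lp`/`NLp` exclusion of infinite pairs makes group comparisons at very
  sparse thresholds subtly dependent on disconnection rates; the count of
  infinite pairs is always reported so users can check.
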