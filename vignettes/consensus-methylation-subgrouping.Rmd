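---
title: "Consensus methylation subgrouping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus methylation subgrouping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models each
stage assumes, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The subgrouping model

The core object is a probes × samples matrix of β-values,
β = M / (M + U + offset), with the offset defaulting to 100 as is
conventional for Infinium arrays. Methylation subgroups are treated as
latent sample classes that express themselves as coordinated β
differences over many CpGs. Nothing in the pipeline assumes a
parametric β distribution; the clustering operates on a sample-by-sample
distance,

d(i, j) = 1 − r_w(i, j),

where r_w is the Pearson correlation between sample columns with
per-probe weights. The weights are the probes' standard deviations by
default, so probes that vary across the cohort dominate the comparison;
uniform weights are available and reduce d exactly to the ordinary
Pearson correlation distance. The weighting scheme is a documented
choice: the underlying protocol used a weighted Pearson distance without
stating its weights, and SD weighting is the choice most consistent with
the SD-based probe selection that precedes it.

### Consensus clustering and stability

A single t-SNE/k-means run is not a stable partition: t-SNE is seeded
and k-means is greedy. The pipeline therefore treats the *resampling
distribution* of partitions as the object of interest:

1. For each (dimension, k) cell of the grid (dimensions {2, 3},
   k = 2…10), the full-cohort embedding and k-means partition define a
   fixed **reference**.
2. Each of `n_iter` iterations draws ⌊0.8 n⌋ samples without
   replacement, embeds the subsampled distance matrix by exact t-SNE
   (θ = 0, perplexity 30), partitions each embedding with k-means, and
   maps the result back to the full cohort: a held-out sample inherits
   the label of its nearest sampled neighbour under the original
   distance. (An alternative, scoring a sample only over the iterations
   that contain it, is available via `map_back = "observed"`.)
3. Labels are aligned to the reference by maximum-weight bipartite
   matching (Hungarian algorithm) on the contingency table; alignment
   renames labels and never changes the partition.
4. A sample's **modal score** is the fraction of iterations assigning it
   to its modal label; a cell's **reproducibility** is the mean modal
   score; the silhouette of the modal partition is computed on the
   original distance matrix (not on any embedding), because stability
   should be judged in data space rather than in a particular 2-D or 3-D
   projection.

The cell maximising the rank sum of reproducibility and mean silhouette
is selected; exact ties go to the smaller k and then the smaller
dimension, favouring the more parsimonious model. The grid is reported
in full so that both axes of the trade-off are visible.

A sample is **classifiable** iff its modal score strictly exceeds 0.70
and its silhouette is strictly positive. Non-classifiable samples are
excluded from all per-subgroup analyses (enrichment, DMRs, survival).

Anchoring the alignment to the full-data reference per cell is a
convention, not a law of nature: some protocols align consecutive
iterations to each other instead. A fixed anchor makes modal scores
well-defined and independent of iteration order, which is why it was
chosen. Cluster labels are 1-based integers following R convention.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tsne_perplexity` | 30 | neighbourhood size; must satisfy perplexity < (n−1)/3 for the smallest embedded set (the 80% subsample) |
| `tsne_max_iter` | 5000 | gradient iterations; for cohorts of ~100–150 samples the embedding is stationary long before this, and the experiments in this package run 1500 |
| `n_iter` | 256 | resampling iterations; the recovery experiments use 64, which already gives modal-score resolution of 1/64 |
| `subsample_frac` | 0.8 | resampling fraction |
| `k_grid`, `dims_grid` | 2…10, {2, 3} | model grid |
| `modal_threshold` | 0.70 | classifiability cutoff (strict) |
| `kmeans_restarts` | 10 | best-inertia restarts per partition |

Seeding is hierarchical: one master seed, with every unit of work
(iteration r, dimension, k) using a seed derived by a fixed integer
mixing function, so any cell can be reproduced in isolation.

## Copy number from array intensities

Combined intensities M + U are proportional to local DNA amount, so
copy-number change appears as a multiplicative intensity shift. Each
sample is scaled so its median total matches the reference median
(removing array-level brightness), and per-probe log2 ratios are taken
against the per-probe median of a copy-neutral reference set. Probes are
then combined into bins per chromosome arm by a greedy left-to-right
rule: a bin closes as soon as it spans ≥ 50,000 bases *and* holds ≥ 15
probes; a trailing fragment merges into its left neighbour; arms with
fewer than 15 probes yield no bins. Bin value is the median probe ratio.

Event logic on top of the bins:

* **arm call**: median bin value beyond ±0.1;
* **WCA** (whole-chromosome aberration): both arms called in the same
  non-neutral direction; acrocentric chromosomes (13, 14, 15, 21, 22),
  which have no p-arm probes, are called on the q arm alone;
* **SCA** (segmental aberration): a maximal run of ≥ 3 consecutive
  same-direction aberrant bins on an arm of a chromosome *without* a
  WCA — so a chromosome's WCA and SCA calls are mutually exclusive by
  construction;
* **focal**: any bin overlapping a listed gene beyond ±1.0 log2.

The binning minima are the only calling constants inherited from the
established workflow; the ±0.1 arm and ±1.0 focal thresholds are this
package's documented defaults (the upstream tool leaves calling to the
analyst) and are configurable. Unlike the clustering path, the CNA path
consumes the unfiltered manifest: X/Y probes are retained.

## Cluster-specific DMRs

For each subgroup, a one-vs-rest contrast over classifiable samples
computes per-CpG Δβ (cluster minus rest), a Welch unequal-variance t
statistic, and Benjamini–Hochberg FDR across tested CpGs (CpGs constant
in both groups are flagged and skipped). Significant CpGs sharing the
Δβ sign are grouped greedily along each chromosome with inter-CpG gaps
≤ 1 kb; groups of ≥ 2 CpGs whose |mean Δβ| strictly exceeds 0.3 become
regions, which are then linked to the nearest annotated gene when within
20 kb (interval distance, 0 if overlapping; ties resolved to the
lexicographically smallest name). The transparent grouping rule is a
deliberate stand-in for kernel-smoothing region callers: the protocol
being followed specifies only the Δβ > 0.3 selection, and a rule whose
every step is checkable is preferred here to a reimplementation of a
particular smoother. The 0.3 threshold is intentionally strict: planted
blocks at Δβ = 0.25 must yield nothing.

## The inferential layer

Cluster-feature association uses Pearson's χ² (no continuity correction
by default — configurable, and none of the package's conclusions depend
on the choice), both as a K-cluster test and per-cluster one-vs-rest
2×2 tests, with unknown statuses excluded per feature. "Infant" is
operationalised as age < 1.5 years at diagnosis, boundary exclusive.
Survival uses the Kaplan–Meier product-limit estimator with a 5-year
extractor and the standard unweighted log-rank test. Spearman
correlation (average ranks, t-approximation p) is provided for
methylation–expression checks.

## What the generator emulates — and what it does not

`sim_config()`/`generate_cohort()` produce a full synthetic study:

* a 450k-like manifest over the autosomes (plus a small X/Y fraction so
  the sex-chromosome filter has work), with ~70% of probes in
  CpG-island-like runs spaced 50–800 bp — without this clustering of
  probe positions, DMR blocks of consecutive CpGs would be megabases
  wide and no gap-based region caller could see them; probes are also
  anchored inside the canonical neuroblastoma loci (MYCN, TERT, PTPRD,
  CDKN2A/B) the way a real array targets cancer-gene promoters;
* a bimodal β baseline shared by all subgroups, with per-cluster
  archetypes shifted by ±Δβ over planted blocks, and per-sample β drawn
  from a Beta distribution with mean equal to the archetype and
  concentration `beta_precision` (default 50, i.e. SD ≈ 0.07 at
  β = 0.5), keeping support in [0, 1];
* intensities whose per-probe affinity is a *fixed array property*
  (drawn from a manifest-keyed stream, so reference cohorts on the same
  manifest share it and reference normalisation cancels it), a
  per-cell lognormal noise, and planted CNA events applied
  multiplicatively to M and U jointly — so β is copy-neutral to first
  order and the clustering is insensitive to copy number;
* ambiguous samples as convex mixtures of two archetypes with weight
  ~ U(0.35, 0.65), the synthetic analogue of non-classifiable tumours;
* clinical covariates (infant age, MYCN status, INSS stage, COG risk)
  drawn per cluster from a Table-2-like model, and exponential PFS with
  independent exponential censoring (default hazards 0.2/yr for
  high-risk-like clusters and 0.055/yr for the infant-like cluster,
  i.e. 5-year PFS ≈ 37% vs ≈ 76%; censoring 0.08/yr).

Because emitted β is recomputed from the emitted intensities, the
identity β = M/(M+U+offset) holds to machine precision, and the planted
Δβ is attenuated by the factor S/(S+offset) ≈ 0.98 — worth remembering
when planting effects near a strict threshold.

Not emulated: idat-level chemistry and background ('noob' correction is
upstream of this pipeline's inputs), batch effects, tumour purity and
stromal contamination, probe-type (I/II) bias, and realistic linkage
between clinical covariates and the planted CNAs (covariates are drawn
from the cluster model independently of the intensity events). Passing
tests on this generator therefore demonstrates that the machinery
recovers structure *of the planted kind* at realistic noise levels — not
that real tumour cohorts contain such structure, nor that the defaults
are optimal for real arrays. The synthetic array is also ~20× sparser
than a real 450k (20,000 probes by default), which is why planted focal
amplicons default to 10 Mb spans: at real probe density the same logic
operates at conumee's usual sub-megabase scale.

## Problem sizes used by the experiments

The recovery experiments run 10 replicate cohorts of n = 120 samples ×
20,000 probes (Δβ = 0.35, no ambiguity) through the full grid
(dims {2, 3} × k 2…8) at 64 resampling iterations and 1500 t-SNE
iterations; classifiability experiments average three replicate cohorts
per ambiguity level in {0, 0.1, 0.2}; CNA recovery uses 50 carriers of a
whole-chr7 gain (log2 0.4) and a focal MYCN amplification (log2 1.5);
DMR recovery plants 8 blocks × 8 CpGs per replicate over 10 replicates.
These sizes were chosen so the whole battery runs in a few minutes on a
single CPU while leaving each check statistically meaningful.

## Known limitations

* The cohort-level numbers of the original study (retained-probe count,
  per-cluster DMR counts, cluster sizes) depend on the real arrays, the
  published cross-reactive probe list and the cited region caller's
  internals; they are context for this package, not reproducible
  targets.
* Silhouette is undefined for a single cluster, so the model grid starts
  at k = 2 even though one may wish to test "no structure"; the
  reproducibility axis at small k is informative there.
* The log-rank p-value is asymptotic; in cohorts of a dozen samples per
  group it can deviate from the exact permutation p by a few percent.
* Greedy binning and greedy DMR grouping are order-dependent by design;
  both are deterministic and contract-checked, but neither is a global
  optimiser.
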