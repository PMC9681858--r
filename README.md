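# nbmethclust

Consensus DNA-methylation subgrouping of neuroblastoma, with
methylation-derived copy number, cluster-specific DMRs and survival
comparison — plus a synthetic cohort generator that makes every stage
testable against known ground truth.

## The problem

Neuroblastoma lacks clearly defined molecular subgroups: risk is
stratified by age, stage and single markers (*MYCN* amplification, 11q
deletion), but tumours with the same marker can behave differently.
Genome-wide DNA methylation, measured on Infinium 450k-style arrays as
per-CpG β-values (β = M / (M + U + offset) ∈ [0, 1]), captures
cell-state differences that single markers miss. This package implements
a resampling-consensus clustering pipeline over β-value profiles that
partitions tumours into methylation subgroups, scores how stably each
sample maps to its subgroup, and then characterises the subgroups by
copy-number profile, differentially methylated regions (DMRs), clinical
covariates and progression-free survival (PFS).

## The method

1. **Probe QC** — remove probes failing detection (p > 0.01 in ≥ 50% of
   samples), cross-reactive probes, X/Y probes, and probes with a SNP
   within 2 bp at MAF ≥ 5%; keep the 10,000 most variable probes by SD.
2. **Distance** — d(i, j) = 1 − r_w(i, j), the weighted Pearson
   correlation distance between sample columns with per-probe weights
   (SD by default; uniform reduces to ordinary Pearson).
3. **Consensus embedding/clustering** — exact t-SNE (θ = 0, perplexity
   30) of the precomputed distance into 2 and 3 dimensions, k-means for
   k = 2…10; 256 iterations resample 80% of samples, embed, cluster, map
   held-out samples to their nearest sampled neighbour, and align labels
   to the full-data reference partition by Hungarian matching. Each
   sample's **modal score** is the fraction of iterations agreeing with
   its modal label; each (dimension, k) cell is scored by
   reproducibility (mean modal score) and mean silhouette, and the cell
   maximising the rank sum is selected.
4. **Classifiability** — a sample is classifiable iff modal score > 0.70
   and silhouette > 0; others are excluded from per-subgroup analyses.
5. **Copy number** — combined M+U intensities normalised against a
   reference set, binned per arm (≥ 50 kb and ≥ 15 probes per bin), then
   arm calls (|log2| > 0.1), whole-chromosome aberrations (both arms,
   WCA), segmental aberrations (≥ 3 consecutive aberrant bins on
   non-WCA chromosomes, SCA), and focal amplifications/deletions
   (|log2| ≥ 1 over listed genes).
6. **DMRs** — per-CpG one-vs-rest Welch t tests with BH correction;
   significant same-sign CpGs grouped within 1 kb, ≥ 2 CpGs, kept when
   |mean Δβ| > 0.3; linked to the nearest gene within 20 kb.
7. **Inference** — χ² cluster-feature enrichment (Table-2 style),
   Spearman correlation, Kaplan–Meier PFS and log-rank comparison.

## Worked example

```r
library(nbmethclust)

cfg    <- sim_config(n_samples = 60, n_probes = 8000, seed = 42)
cohort <- generate_cohort(cfg)
pip <- subgroup_pipeline(cohort$beta, cohort$manifest, cohort$detp,
                         preprocess_params(top_k = 8000),
                         cluster_params(dims_grid = 2, k_grid = 3:7,
                                        n_iter = 32, tsne_max_iter = 1000,
                                        tsne_perplexity = 12, seed = 1))
res <- pip$consensus
res$grid[, c("dim", "k", "reproducibility", "avg_silhouette")]
#>   dim k reproducibility avg_silhouette
#> 1   2 3           0.688          0.447
#> 2   2 4           0.743          0.604
#> 3   2 5           0.990          0.765
#> 4   2 6           0.911          0.765
#> 5   2 7           0.831          0.765
res$selected
#> dim   k
#>   2   5
head(res$assignments, 4)
#>   sample modal_cluster modal_score silhouette classifiable
#> 1   S001             2     0.96875  0.7594149         TRUE
#> 2   S002             3     1.00000  0.7685781         TRUE
#> 3   S003             2     0.96875  0.7625596         TRUE
#> 4   S004             4     0.96875  0.7650862         TRUE
mclust::adjustedRandIndex(res$assignments$modal_cluster,
                          cohort$truth$true_cluster)
#> [1] 1
```

The grid shows that the five planted subgroups are found at k = 5 with
near-perfect stability (reproducibility 0.99) and the highest
silhouette; the selected solution recovers the planted partition exactly
(adjusted Rand index 1), and every sample passes the modal-score /
silhouette classifiability rule.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on a simulated
120-sample cohort and write their tables to `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | simulate the cohort (five subgroups, planted DMR blocks, CNA events, clinical covariates, survival) |
| `02_cluster.R`  | QC, consensus clustering, model selection, classifiability |
| `03_cna.R`      | reference-normalised binned copy number; arm/WCA/SCA/focal calls |
| `04_dmr.R`      | cluster-specific DMRs and nearest-gene linkage |
| `05_survival_assoc.R` | enrichment report, Kaplan–Meier and log-rank |

On the bundled configuration the pipeline selects k = 5, classifies
120/120 samples with adjusted Rand index 1 against the planted truth,
recovers all 200 planted DMR blocks, and the best-prognosis subgroup
shows 5-year PFS 0.61 vs 0.39 for the rest (log-rank p = 0.012).

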