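#!/usr/bin/env Rscript
# Simulate the study cohort: 120 tumours on a 20,000-probe 450k-like
# array, five planted methylation subgroups with subgroup-specific DMR
# blocks, the canonical neuroblastoma copy-number lesions, cluster-linked
# clinical covariates and progression-free survival.

library(nbmethclust)

seed <- 20260928L
cfg <- sim_config(seed = seed)
cohort <- generate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")

sizes <- table(cohort$truth$true_cluster)
cat("cohort written to results/cohort\n")
cat("samples:", ncol(cohort$beta), " probes:", nrow(cohort$beta), "\n")
cat("planted cluster sizes:", paste(sizes, collapse = "/"), "\n")
cat("planted DMR blocks:", nrow(cohort$truth$planted_dmrs), "\n")
cat("planted CNA events:", length(cohort$truth$cna_events), "\n")
cat("infants (<1.5y):", sum(cohort$sample_sheet$age_years < 1.5), "\n")
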