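#' One planted-subgroup recovery run of the full pipeline
#'
#' Generates a synthetic cohort under the generator defaults (five planted
#' subgroups), runs QC, probe selection, the weighted Pearson distance and
#' the resampling consensus, and returns the cohort together with the
#' consensus result. Used by the recovery and classifiability experiments.
#'
#' @param seed master seed for this replicate.
#' @param n_samples cohort size.
#' @param dmr_delta planted between-cluster beta shift.
#' @param ambiguous_fraction fraction of archetype-mixture samples.
#' @param dims_grid,k_grid,n_iter,tsne_max_iter,tsne_perplexity consensus
#'   settings (see [cluster_params()]); `tsne_max_iter = 1500` is ample for
#'   cohorts of this size.
#' @return list with `cohort` (an `nb_cohort`) and `pipeline` (the
#'   [subgroup_pipeline()] output).
#' @export
consensus_recovery_run <- function(seed, n_samples = 120, dmr_delta = 0.35,
                                   ambiguous_fraction = 0,
                                   dims_grid = c(2, 3), k_grid = 2:8,
                                   n_iter = 64, tsne_max_iter = 1500,
                                   tsne_perplexity = 30) {
  cfg <- sim_config(n_samples = n_samples, dmr_delta = dmr_delta,
                    ambiguous_fraction = ambiguous_fraction, seed = seed)
  co <- generate_cohort(cfg)
  cp <- cluster_params(dims_grid = dims_grid, k_grid = k_grid,
                       n_iter = n_iter, tsne_max_iter = tsne_max_iter,
                       tsne_perplexity = tsne_perplexity,
                       seed = derive_seed(seed, 7))
  pip <- subgroup_pipeline(co$beta, co$manifest, co$detp,
                           preprocess_params(), cp)
  list(cohort = co, pipeline = pip)
}

#' Planted CNA detection experiment
#'
#' Simulates carriers of a whole-chromosome-7 gain and a focal MYCN
#' amplification, a copy-neutral reference set, and reports the fraction
#' of carriers in which each event is called, plus the number of emitted
#' bins violating the size/probe contract.
#'
#' @param seed master seed.
#' @param n_carriers number of carrier samples.
#' @param wca_shift log2 shift of the whole-chromosome gain.
#' @param focal_shift log2 shift of the focal amplification.
#' @param n_probes synthetic array size.
#' @return list with `wca_rate`, `focal_rate`, `bin_violations`, `n`.
#' @export
cna_recovery_experiment <- function(seed, n_carriers = 50,
                                    wca_shift = 0.4, focal_shift = 1.5,
                                    n_probes = 12000) {
  evs <- list(cna_event("whole", 7, "gain", wca_shift, 1:5, 1.0),
              cna_event("focal", 2, "amplification", focal_shift, 1:5,
                        1.0, gene = "MYCN"))
  cfg <- sim_config(n_samples = n_carriers, n_probes = n_probes,
                    cna_events = evs, seed = seed)
  co <- generate_cohort(cfg)
  ref <- generate_cohort(sim_config(n_samples = 10, n_probes = n_probes,
                                    cna_events = list(),
                                    seed = derive_seed(seed, 11)),
                         manifest = co$manifest)
  profs <- cna_profiles(co$M, co$U, co$manifest, ref$M + ref$U,
                        gene_map = default_genes())
  viol <- sum(vapply(profs, function(p) {
    sum(p$bins$n_probes < 15 | (p$bins$end - p$bins$start + 1) < 50000)
  }, numeric(1)))
  list(
    wca_rate = mean(vapply(profs, function(p)
      any(p$wca$chrom == "7" & p$wca$direction == "gain"), logical(1))),
    focal_rate = mean(vapply(profs, function(p)
      any(p$focal$gene == "MYCN" &
            p$focal$direction == "amplification"), logical(1))),
    bin_violations = viol, n = n_carriers)
}

#' Planted DMR recovery experiment
#'
#' Plants `n_blocks` 8-CpG blocks of the given delta between two groups of
#' 40 samples on a dense synthetic manifest, over `n_reps` replicates, and
#' reports sensitivity (fraction of planted blocks overlapped by a call)
#' and the false-discovery proportion among calls.
#'
#' @param seed master seed.
#' @param delta planted group difference in beta.
#' @param n_reps replicates.
#' @param n_blocks planted blocks per replicate.
#' @param n_probes CpGs per replicate.
#' @return list with `sensitivity`, `fdp`, `n_calls`, `n`.
#' @export
dmr_recovery_experiment <- function(seed, delta = 0.4, n_reps = 10,
                                    n_blocks = 8, n_probes = 3000) {
  man <- data.frame(probe_id = sprintf("cg%08d", seq_len(n_probes)),
                    chrom = "1", pos = 1e6 + 500 * (seq_len(n_probes) - 1),
                    arm = "q", cross_reactive = FALSE,
                    snp_dist_bp = NA_integer_, snp_maf = NA_real_)
  hits <- 0; total <- 0; fp <- 0; calls <- 0
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, 13, r))
    blocks <- lapply(seq_len(n_blocks) - 1,
                     function(i) (i * 350 + 51):(i * 350 + 58))
    beta <- matrix(stats::rnorm(n_probes * 80, 0.5, 0.05), n_probes, 80)
    for (b in blocks) {
      beta[b, 1:40] <- stats::rnorm(length(b) * 40, 0.5 + delta / 2, 0.05)
      beta[b, 41:80] <- stats::rnorm(length(b) * 40, 0.5 - delta / 2, 0.05)
    }
    beta <- pmin(pmax(beta, 0.001), 0.999)
    rownames(beta) <- man$probe_id
    st <- cpg_stats(beta, rep(1:2, c(40, 40)), 1)
    d <- call_dmrs(st, man)
    total <- total + n_blocks
    calls <- calls + nrow(d)
    rng <- vapply(blocks, function(b)
      c(man$pos[b[1]], man$pos[b[length(b)]]), numeric(2))
    for (j in seq_len(nrow(d))) {
      if (!any(d$start[j] <= rng[2, ] & d$end[j] >= rng[1, ]))
        fp <- fp + 1
    }
    hits <- hits + sum(vapply(seq_len(n_blocks), function(i)
      any(d$start <= rng[2, i] & d$end >= rng[1, i]), logical(1)))
  }
  list(sensitivity = hits / total, fdp = fp / max(calls, 1),
       n_calls = calls, n = n_reps)
}

#' Null-calibration experiment for the inferential layer
#'
#' (1) Per-CpG one-vs-rest testing on a cohort with no planted signal:
#' fraction of CpGs reaching FDR < 0.05. (2) Log-rank type-I error over
#' `n_sims` two-group comparisons with identical hazards.
#'
#' @param seed master seed.
#' @param n_cpgs CpGs in the null methylation matrix.
#' @param n_sims null survival simulations.
#' @return list with `cpg_fdr_fraction`, `logrank_type1`, `n`.
#' @export
null_calibration_experiment <- function(seed, n_cpgs = 5000,
                                        n_sims = 200) {
  set.seed(derive_seed(seed, 17))
  beta <- matrix(stats::rbeta(n_cpgs * 40, 5, 5), n_cpgs, 40,
                 dimnames = list(sprintf("cg%08d", seq_len(n_cpgs)), NULL))
  st <- cpg_stats(beta, rep(1:2, each = 20), 1)
  frac <- mean(st$fdr < 0.05, na.rm = TRUE)
  rej <- vapply(seq_len(n_sims), function(s) {
    sv <- generate_survival(rep(1L, 100), 0.2, 0.08,
                            seed = derive_seed(seed, 19, s))
    logrank_test(sv$time, sv$event, rep(1:2, each = 50))$p < 0.05
  }, logical(1))
  list(cpg_fdr_fraction = frac, logrank_type1 = mean(rej), n = n_sims)
}
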