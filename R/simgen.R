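#' Simulation configuration for a synthetic methylation cohort
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' defaults describe a 450k-like cohort of five methylation subgroups with
#' subgroup-specific DMR blocks, Table-2-style copy-number events, cluster-
#' correlated clinical covariates and cluster-dependent progression-free
#' survival with independent exponential censoring.
#'
#' @param n_samples number of tumour samples.
#' @param n_probes number of CpG probes on the synthetic array (>= 100).
#' @param n_clusters number of planted methylation subgroups.
#' @param cluster_proportions probability vector over clusters (sums to 1).
#' @param n_dmr_blocks_per_cluster planted DMR blocks owned by each cluster.
#' @param dmr_block_size CpGs per planted block.
#' @param dmr_delta beta shift of a planted block in its owner cluster,
#'   in (0, 1).
#' @param beta_precision concentration of the Beta noise around each
#'   archetype beta (larger = less noisy; array-like at ~50).
#' @param cna_events list of [cna_event()] objects; `default_cna_events()`
#'   plants the canonical neuroblastoma lesions.
#' @param clinical_model per-cluster covariate model; see
#'   `default_clinical_model()`.
#' @param hazard_per_cluster event rate per year for each cluster.
#' @param censor_rate independent exponential censoring rate per year.
#' @param ambiguous_fraction fraction of samples drawn as convex mixtures of
#'   two cluster archetypes (the non-classifiable analogue), in [0, 1).
#' @param island_fraction fraction of probes laid down in CpG-island-like
#'   tight clusters (50-800 bp spacing); the rest are open-sea singletons.
#' @param sex_fraction fraction of probes placed on X/Y.
#' @param cross_reactive_fraction fraction of probes flagged cross-reactive.
#' @param snp_fraction fraction of probes with a filter-triggering SNP.
#' @param failed_probe_fraction fraction of probes with failed detection.
#' @param failed_sample_fraction fraction of samples in which a failed probe
#'   has a high detection p-value.
#' @param beta_offset intensity offset used when writing beta from M/U.
#' @param focal_span_bp width of the region scaled by a focal event. The
#'   synthetic manifest is much sparser than a real 450k array, so focal
#'   amplicons span proportionally wider windows to carry enough probes per
#'   bin.
#' @param seed master RNG seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 120,
                       n_probes = 20000,
                       n_clusters = 5,
                       cluster_proportions = NULL,
                       n_dmr_blocks_per_cluster = 40,
                       dmr_block_size = 8,
                       dmr_delta = 0.35,
                       beta_precision = 50,
                       cna_events = default_cna_events(),
                       clinical_model = default_clinical_model(n_clusters),
                       hazard_per_cluster = default_hazards(n_clusters),
                       censor_rate = 0.08,
                       ambiguous_fraction = 0,
                       island_fraction = 0.7,
                       sex_fraction = 0.02,
                       cross_reactive_fraction = 0.03,
                       snp_fraction = 0.03,
                       failed_probe_fraction = 0.005,
                       failed_sample_fraction = 0.6,
                       beta_offset = 100,
                       focal_span_bp = 1e7,
                       seed = 1L) {
  if (is.null(cluster_proportions))
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  assert_that(n_samples >= 2 && n_probes >= 100,
              "invalid n_samples / n_probes")
  assert_that(length(cluster_proportions) == n_clusters,
              "cluster_proportions length must equal n_clusters")
  assert_that(abs(sum(cluster_proportions) - 1) < 1e-8,
              "cluster_proportions must sum to 1")
  assert_that(dmr_delta >= 0 && dmr_delta < 1,
              "dmr_delta must be in [0,1)")  # 0 = null cohort
  assert_that(beta_precision > 0, "beta_precision must be > 0")
  assert_that(all(hazard_per_cluster > 0) && censor_rate > 0,
              "all rates must be > 0")
  assert_that(length(hazard_per_cluster) == n_clusters,
              "hazard_per_cluster length must equal n_clusters")
  assert_that(ambiguous_fraction >= 0 && ambiguous_fraction < 1,
              "ambiguous_fraction must be in [0,1)")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Define a planted copy-number event
#'
#' @param target one of `"whole"`, `"arm"`, `"segment"`, `"focal"`.
#' @param chrom chromosome label (`"1"`..`"22"`, `"X"`, `"Y"`).
#' @param direction `"gain"`, `"loss"`, `"amplification"` or `"deletion"`.
#' @param log2_shift signed log2 intensity shift applied to carrier samples
#'   over the targeted probes. Amplification/deletion require |shift| >= 1;
#'   gain/loss require |shift| in (0, 1).
#' @param carrier_clusters integer cluster ids eligible to carry the event.
#' @param penetrance probability that an eligible sample carries the event.
#' @param arm `"p"` or `"q"` for arm events.
#' @param start,end 1-based segment bounds for segment events.
#' @param gene gene symbol for focal events (must exist in the gene table).
#' @return list of class `cna_event`.
#' @export
cna_event <- function(target, chrom, direction, log2_shift,
                      carrier_clusters, penetrance,
                      arm = NULL, start = NULL, end = NULL, gene = NULL) {
  assert_that(target %in% c("whole", "arm", "segment", "focal"),
              "unknown CNA target type")
  assert_that(direction %in% c("gain", "loss", "amplification", "deletion"),
              "unknown CNA direction")
  mag <- abs(log2_shift)
  if (direction %in% c("amplification", "deletion"))
    assert_that(mag >= 1, "amplification/deletion shift must be >= 1")
  else
    assert_that(mag > 0 && mag < 1, "gain/loss shift must be in (0,1)")
  assert_that(penetrance >= 0 && penetrance <= 1,
              "penetrance must be in [0,1]")
  if (direction %in% c("loss", "deletion"))
    assert_that(log2_shift < 0, "loss/deletion shift must be negative")
  else
    assert_that(log2_shift > 0, "gain/amplification shift must be positive")
  if (target == "arm") assert_that(arm %in% c("p", "q"), "arm must be p or q")
  if (target == "segment")
    assert_that(!is.null(start) && !is.null(end) && start <= end,
                "segment needs start <= end")
  if (target == "focal") assert_that(!is.null(gene), "focal needs a gene")
  structure(list(target = target, chrom = as.character(chrom),
                 direction = direction, log2_shift = log2_shift,
                 carrier_clusters = as.integer(carrier_clusters),
                 penetrance = penetrance, arm = arm, start = start,
                 end = end, gene = gene),
            class = "cna_event")
}

#' Canonical neuroblastoma gene loci (hg19) used for focal events and
#' focal-call lookup
#' @return data.frame with `gene`, `chrom`, `start`, `end`.
#' @export
default_genes <- function() {
  data.frame(
    gene = c("MYCN", "TERT", "PTPRD", "CDKN2A", "CDKN2B"),
    chrom = c("2", "5", "9", "9", "9"),
    start = c(16080683, 1253287, 8314246, 21967751, 22002902),
    end = c(16087129, 1295162, 10612723, 21995300, 22009280),
    stringsAsFactors = FALSE
  )
}

#' Default planted copy-number events
#'
#' Mirrors the canonical neuroblastoma lesion spectrum: 1p loss and MYCN
#' amplification in the MYCN cluster (2), 11q loss / 17q gain / whole-chr7
#' gain and segmental 2p+, 3p-, 4p- in the 11q cluster (3), partial 11q/17q
#' involvement of cluster 5, and numerical (whole-chromosome) changes
#' concentrated in clusters 1 and 4.
#' @return list of [cna_event()] objects.
#' @export
default_cna_events <- function() {
  list(
    cna_event("arm", 1, "loss", -0.3, 2, 0.88, arm = "p"),
    cna_event("arm", 17, "gain", 0.3, 2, 0.77, arm = "q"),
    cna_event("arm", 17, "gain", 0.3, 3, 0.90, arm = "q"),
    cna_event("arm", 17, "gain", 0.3, 5, 0.53, arm = "q"),
    cna_event("arm", 11, "loss", -0.3, 3, 0.95, arm = "q"),
    cna_event("arm", 11, "loss", -0.3, 5, 0.50, arm = "q"),
    cna_event("arm", 2, "gain", 0.3, 3, 0.26, arm = "p"),
    cna_event("arm", 3, "loss", -0.3, 3, 0.69, arm = "p"),
    cna_event("arm", 4, "loss", -0.3, 3, 0.50, arm = "p"),
    cna_event("whole", 7, "gain", 0.4, 3, 0.48),
    cna_event("whole", 6, "gain", 0.4, c(1, 4), 0.60),
    cna_event("whole", 13, "gain", 0.4, c(1, 4), 0.55),
    cna_event("whole", 18, "loss", -0.4, c(1, 4), 0.50),
    cna_event("whole", 12, "gain", 0.4, 1:5, 0.12),
    cna_event("focal", 2, "amplification", 1.5, 2, 0.90, gene = "MYCN"),
    cna_event("focal", 9, "deletion", -1.2, 2, 0.30, gene = "PTPRD"),
    cna_event("focal", 9, "deletion", -1.2, 2, 0.28, gene = "CDKN2A"),
    cna_event("focal", 5, "amplification", 1.2, 1:5, 0.02, gene = "TERT")
  )
}

#' Default per-cluster clinical covariate model
#'
#' Cluster 4 is the infant cluster (90% diagnosed below 1.5 years, low/
#' intermediate COG risk, INSS stage 4s/1); the other clusters are
#' predominantly older, high-risk, stage-4 disease; MYCN amplification
#' concentrates in cluster 2.
#' @param n_clusters number of clusters (the defaults describe 5).
#' @return list with one sub-list per cluster.
#' @export
default_clinical_model <- function(n_clusters = 5) {
  mk <- function(p_infant, p_mycn, inss, cog) {
    list(p_infant = p_infant, p_mycn = p_mycn, inss = inss, cog = cog)
  }
  inss_hr <- c("1" = 0.03, "2b" = 0.00, "3" = 0.03, "4" = 0.94, "4s" = 0.00)
  cog_hr <- c(high = 0.94, intermediate = 0.03, low = 0.03)
  inss_inf <- c("1" = 0.28, "2b" = 0.02, "3" = 0.06, "4" = 0.05, "4s" = 0.59)
  cog_inf <- c(high = 0.13, intermediate = 0.23, low = 0.64)
  base <- mk(0.08, 0.05, inss_hr, cog_hr)
  out <- rep(list(base), n_clusters)
  if (n_clusters >= 2) out[[2]] <- mk(0.05, 0.91, inss_hr, cog_hr)
  if (n_clusters >= 3) out[[3]] <- mk(0.02, 0.01, inss_hr, cog_hr)
  if (n_clusters >= 4) out[[4]] <- mk(0.90, 0.01, inss_inf, cog_inf)
  out
}

#' Default per-cluster progression hazards (events per year)
#'
#' Chosen so that 5-year progression-free survival is roughly 37% for the
#' high-risk clusters and ~76% for the infant cluster.
#' @param n_clusters number of clusters.
#' @return numeric vector.
#' @export
default_hazards <- function(n_clusters = 5) {
  h <- rep(0.2, n_clusters)
  if (n_clusters >= 4) h[4] <- 0.055
  h
}

#' Simulate survival times with independent exponential censoring
#'
#' @param labels integer cluster label per sample.
#' @param hazards event rate per year, one per cluster (or one per sample).
#' @param censor_rate censoring rate per year (> 0).
#' @param seed RNG seed.
#' @return data.frame with `time` (years) and `event` (1 = progression).
#' @export
generate_survival <- function(labels, hazards, censor_rate, seed = 1L) {
  assert_that(all(hazards > 0), "hazards must be > 0")
  assert_that(censor_rate > 0, "censor_rate must be > 0")
  n <- length(labels)
  rate <- if (length(hazards) == n) hazards else hazards[labels]
  assert_that(all(!is.na(rate)), "label outside hazard table")
  set.seed(seed)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::rexp(n, censor_rate)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

# place non-overlapping planted DMR blocks on autosomal manifest rows
plant_dmr_blocks <- function(manifest, config) {
  auto <- which(manifest$chrom %in% as.character(1:22) &
                  !manifest$cross_reactive & is.na(manifest$snp_dist_bp))
  bs <- config$dmr_block_size
  used <- logical(nrow(manifest))
  blocks <- list()
  for (cl in seq_len(config$n_clusters)) {
    placed <- 0
    guard <- 0
    while (placed < config$n_dmr_blocks_per_cluster && guard < 50000) {
      guard <- guard + 1
      i0 <- sample(auto[auto <= nrow(manifest) - bs + 1], 1)
      idx <- i0:(i0 + bs - 1)
      if (any(used[idx])) next
      if (length(unique(manifest$chrom[idx])) != 1) next
      # blocks must be compact, like a real island-hosted DMR
      if (max(diff(manifest$pos[idx])) > 1000) next
      used[idx] <- TRUE
      placed <- placed + 1
      dir <- sample(c(1, -1), 1)
      blocks[[length(blocks) + 1]] <- list(cluster = cl, rows = idx,
                                           direction = dir)
    }
  }
  blocks
}

#' Generate a full synthetic methylation cohort with ground truth
#'
#' Draws per-cluster archetype beta profiles from a bimodal baseline,
#' shifts planted DMR blocks by +/- `dmr_delta` in their owner cluster,
#' draws per-sample beta around the archetype with Beta noise, converts
#' beta to methylated/unmethylated intensities whose totals carry the
#' planted copy-number shifts, and draws detection p-values, clinical
#' covariates and survival. The emitted beta matrix is computed from the
#' emitted intensities via `M / (M + U + offset)`, so the intensity/beta
#' identity holds exactly.
#'
#' @param config a [sim_config()].
#' @param manifest optional pre-generated manifest (defaults to
#'   [generate_manifest()] under the config seed).
#' @return list of class `nb_cohort` with elements `manifest`, `M`, `U`,
#'   `beta`, `detp`, `sample_sheet`, `genes`, `truth`, `config`.
#' @export
generate_cohort <- function(config, manifest = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(manifest)) manifest <- generate_manifest(config)
  n <- config$n_samples
  p <- nrow(manifest)
  K <- config$n_clusters

  set.seed(derive_seed(config$seed, 202))

  # cluster sizes: largest-remainder rounding of the proportions
  sizes <- floor(config$cluster_proportions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- config$cluster_proportions * n - sizes
    sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  assert_that(all(sizes >= 0) && sum(sizes) == n,
              "cluster proportions inconsistent with n_clusters")
  labels <- sample(rep(seq_len(K), sizes))

  # bimodal baseline beta per probe, shared by all clusters
  comp <- sample(1:3, p, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  baseline <- ifelse(comp == 1, stats::rbeta(p, 2, 12),
                     ifelse(comp == 2, stats::rbeta(p, 12, 2),
                            stats::rbeta(p, 5, 5)))

  # planted DMR blocks: rebase the block so the +/- delta shift stays in range
  blocks <- plant_dmr_blocks(manifest, config)
  delta <- config$dmr_delta
  arch <- matrix(rep(baseline, K), nrow = p)
  for (b in blocks) {
    b0 <- if (b$direction > 0) stats::runif(1, 0.08, 0.95 - delta)
          else stats::runif(1, 0.05 + delta, 0.92)
    arch[b$rows, ] <- b0
    arch[b$rows, b$cluster] <- b0 + b$direction * delta
  }
  arch <- pmin(pmax(arch, 0.02), 0.98)

  # ambiguous samples: convex archetype mixtures
  n_amb <- round(config$ambiguous_fraction * n)
  amb_flag <- logical(n)
  amb_flag[sample.int(n, n_amb)] <- TRUE
  mix_partner <- rep(NA_integer_, n)
  mix_weight <- rep(NA_real_, n)

  mean_beta <- arch[, labels, drop = FALSE]
  for (i in which(amb_flag)) {
    partner <- sample(setdiff(seq_len(K), labels[i]), 1)
    w <- stats::runif(1, 0.35, 0.65)
    mix_partner[i] <- partner
    mix_weight[i] <- w
    mean_beta[, i] <- w * arch[, labels[i]] + (1 - w) * arch[, partner]
  }

  # per-sample beta noise: Beta with mean = archetype, conc = beta_precision
  pr <- config$beta_precision
  beta_target <- matrix(stats::rbeta(p * n, mean_beta * pr,
                                     (1 - mean_beta) * pr), nrow = p)

  # intensities: per-probe lognormal affinity, small per-cell noise,
  # multiplicative copy-number shifts on the total. Probe affinity is a
  # fixed property of the array, not of the cohort: it is drawn from a
  # manifest-size-keyed stream so that any cohort on the same manifest
  # (e.g. a copy-neutral reference set) shares it and reference
  # normalisation cancels it per probe.
  rs <- .Random.seed
  set.seed(derive_seed(977, p))
  total0 <- stats::rlnorm(p, log(4000), 0.2)
  assign(".Random.seed", rs, envir = globalenv())
  total <- total0 * matrix(stats::rlnorm(p * n, 0, 0.05), nrow = p)

  events <- config$cna_events
  carriers <- matrix(FALSE, length(events), n)
  genes <- default_genes()
  for (e in seq_along(events)) {
    ev <- events[[e]]
    eligible <- labels %in% ev$carrier_clusters
    carry <- eligible & stats::runif(n) < ev$penetrance
    carriers[e, ] <- carry
    if (!any(carry)) next
    rows <- event_probe_rows(ev, manifest, genes, config$focal_span_bp)
    if (length(rows) == 0) next
    total[rows, carry] <- total[rows, carry] * 2^ev$log2_shift
  }

  M <- beta_target * total
  U <- (1 - beta_target) * total
  sample_ids <- sprintf("S%03d", seq_len(n))
  dimnames(M) <- dimnames(U) <- list(manifest$probe_id, sample_ids)
  beta <- compute_beta(M, U, offset = config$beta_offset)

  # detection p-values: good probes near 0; a failed-probe tranche is high
  # in a fraction of samples
  detp <- matrix(stats::runif(p * n, 0, 0.005), nrow = p,
                 dimnames = list(manifest$probe_id, sample_ids))
  n_fail <- round(config$failed_probe_fraction * p)
  if (n_fail > 0) {
    fp <- sample.int(p, n_fail)
    for (j in fp) {
      bad <- stats::runif(n) < config$failed_sample_fraction
      detp[j, bad] <- stats::runif(sum(bad), 0.02, 1)
    }
  }

  # clinical covariates per cluster model
  cm <- config$clinical_model
  age <- mycn <- inss <- cog <- rep(NA_character_, n)
  age <- numeric(n)
  for (i in seq_len(n)) {
    m <- cm[[labels[i]]]
    age[i] <- if (stats::runif(1) < m$p_infant) stats::runif(1, 0, 1.5)
              else stats::runif(1, 1.5, 12)
    mycn[i] <- if (stats::runif(1) < m$p_mycn) "amp" else "normal"
    inss[i] <- sample(names(m$inss), 1, prob = m$inss)
    cog[i] <- sample(names(m$cog), 1, prob = m$cog)
  }
  mycn[sample.int(n, max(0, round(0.02 * n)))] <- NA

  surv <- generate_survival(labels, config$hazard_per_cluster,
                            config$censor_rate,
                            seed = derive_seed(config$seed, 303))

  sheet <- data.frame(sample_id = sample_ids, age_years = age, mycn = mycn,
                      inss = inss, cog_risk = cog, pfs_years = surv$time,
                      event = surv$event, stringsAsFactors = FALSE)

  planted_dmrs <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(cluster = b$cluster, chrom = manifest$chrom[b$rows[1]],
               start = manifest$pos[b$rows[1]],
               end = manifest$pos[b$rows[length(b$rows)]],
               n_cpgs = length(b$rows),
               delta = b$direction * delta,
               probe_first = manifest$probe_id[b$rows[1]],
               stringsAsFactors = FALSE)
  }))

  truth <- list(true_cluster = labels, ambiguous_flag = amb_flag,
                mix_partner = mix_partner, mix_weight = mix_weight,
                planted_dmrs = planted_dmrs, cna_carriers = carriers,
                cna_events = events,
                true_hazard = config$hazard_per_cluster[labels])

  structure(list(manifest = manifest, M = M, U = U, beta = beta,
                 detp = detp, sample_sheet = sheet, genes = genes,
                 truth = truth, config = config),
            class = "nb_cohort")
}

# manifest rows targeted by a planted CNA event
event_probe_rows <- function(ev, manifest, genes, focal_span_bp = 4e6) {
  if (ev$target == "whole") {
    which(manifest$chrom == ev$chrom)
  } else if (ev$target == "arm") {
    which(manifest$chrom == ev$chrom & manifest$arm == ev$arm)
  } else if (ev$target == "segment") {
    which(manifest$chrom == ev$chrom & manifest$pos >= ev$start &
            manifest$pos <= ev$end)
  } else {
    g <- genes[genes$gene == ev$gene, ]
    assert_that(nrow(g) == 1, paste("unknown focal gene", ev$gene))
    mid <- (g$start + g$end) / 2
    which(manifest$chrom == g$chrom &
            manifest$pos >= mid - focal_span_bp / 2 &
            manifest$pos <= mid + focal_span_bp / 2)
  }
}

#' Generate a synthetic gene annotation track
#'
#' Emits the canonical loci from [default_genes()] plus `n_random` synthetic
#' genes tiled over the autosomes, for exercising DMR-gene linkage.
#'
#' @param manifest probe manifest (bounds the coordinate range).
#' @param n_random number of synthetic genes.
#' @param seed RNG seed.
#' @return data.frame with `gene`, `chrom`, `start`, `end`.
#' @export
generate_genes <- function(manifest, n_random = 300, seed = 1L) {
  set.seed(derive_seed(seed, 404))
  info <- chrom_info()
  info <- info[info$chrom %in% as.character(1:22), ]
  k <- pmax(1, round(n_random * info$length / sum(info$length)))
  rows <- lapply(seq_len(nrow(info)), function(i) {
    st <- sort(sample.int(info$length[i] - 2e5, k[i]))
    data.frame(gene = sprintf("GENE_%s_%03d", info$chrom[i], seq_len(k[i])),
               chrom = info$chrom[i], start = st,
               end = st + sample(2e3:2e5, k[i], replace = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- rbind(default_genes(), do.call(rbind, rows))
  out[order(match(out$chrom, c(as.character(1:22), "X", "Y")), out$start), ]
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits the TSV dialects used throughout the pipeline: beta matrix,
#' M/U intensity matrices, detection p-values, probe manifest, sample sheet
#' and a ground-truth JSON.
#'
#' @param cohort an `nb_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nb_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$beta, file.path(dir, "beta.tsv"))
  write_matrix_tsv(cohort$M, file.path(dir, "intensities.M.tsv"))
  write_matrix_tsv(cohort$U, file.path(dir, "intensities.U.tsv"))
  write_matrix_tsv(cohort$detp, file.path(dir, "detp.tsv"))
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$sample_sheet, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$cna_carriers <- unname(split(truth$cna_carriers,
                                     row(truth$cna_carriers)))
  truth$cna_events <- lapply(truth$cna_events, unclass)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
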