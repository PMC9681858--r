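#' DMR calling parameters
#'
#' @param fdr_alpha per-CpG FDR threshold for region membership.
#' @param max_gap_bp maximum gap between consecutive member CpGs.
#' @param min_cpgs minimum CpGs per region.
#' @param min_abs_delta regions must have |mean delta beta| strictly above
#'   this (default 0.30).
#' @param gene_max_dist_bp maximum DMR-to-gene distance for linkage.
#' @return list of class `dmr_params`.
#' @export
dmr_params <- function(fdr_alpha = 0.05, max_gap_bp = 1000, min_cpgs = 2,
                       min_abs_delta = 0.30, gene_max_dist_bp = 20000) {
  assert_that(min_abs_delta > 0 && min_abs_delta < 1,
              "min_abs_delta must be in (0,1)")
  assert_that(fdr_alpha > 0 && max_gap_bp > 0 && min_cpgs > 0 &&
                gene_max_dist_bp > 0, "all parameters must be positive")
  structure(list(fdr_alpha = fdr_alpha, max_gap_bp = max_gap_bp,
                 min_cpgs = min_cpgs, min_abs_delta = min_abs_delta,
                 gene_max_dist_bp = gene_max_dist_bp),
            class = "dmr_params")
}

#' Per-CpG one-vs-rest differential methylation statistics
#'
#' For each CpG: delta = mean beta(cluster) - mean beta(rest), a Welch
#' (unequal-variance) two-sample t statistic, and Benjamini-Hochberg FDR
#' across the tested CpGs. CpGs that are constant in both groups are
#' flagged (`tested = FALSE`) and excluded from the FDR adjustment.
#'
#' @param beta probes x samples beta matrix.
#' @param labels per-sample cluster labels (NA = excluded).
#' @param cluster the cluster to contrast against the rest.
#' @param min_n minimum samples per group (default 3).
#' @return data.frame: `probe_id`, `delta`, `t`, `df`, `p`, `fdr`,
#'   `tested`.
#' @export
cpg_stats <- function(beta, labels, cluster, min_n = 3) {
  in_c <- which(!is.na(labels) & labels == cluster)
  out_c <- which(!is.na(labels) & labels != cluster)
  n1 <- length(in_c)
  n2 <- length(out_c)
  assert_that(n1 >= min_n && n2 >= min_n,
              "each group needs at least min_n samples")
  x <- beta[, in_c, drop = FALSE]
  y <- beta[, out_c, drop = FALSE]
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- matrixStats::rowVars(x)
  v2 <- matrixStats::rowVars(y)
  delta <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  tested <- se2 > 0
  tstat <- ifelse(tested, delta / sqrt(se2), NA_real_)
  df <- ifelse(tested,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               NA_real_)
  p <- 2 * stats::pt(-abs(tstat), df)
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(probe_id = rownames(beta), delta = delta, t = tstat, df = df,
             p = p, fdr = fdr, tested = tested, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Group significant CpGs into differentially methylated regions
#'
#' Significant CpGs (FDR < `fdr_alpha`) sharing the delta sign are grouped
#' greedily along each chromosome with inter-CpG gaps <= `max_gap_bp`;
#' groups with >= `min_cpgs` members whose mean delta strictly exceeds
#' `min_abs_delta` in absolute value become regions.
#'
#' @param stats data.frame from [cpg_stats()].
#' @param manifest probe manifest (coordinates for the tested probes).
#' @param params a [dmr_params()].
#' @param cluster optional cluster label recorded on each region.
#' @return data.frame of regions: `cluster`, `chrom`, `start`, `end`,
#'   `n_cpgs`, `mean_delta`, `direction`, `min_fdr`.
#' @export
call_dmrs <- function(stats, manifest, params = dmr_params(),
                      cluster = NA) {
  man <- manifest[match(stats$probe_id, manifest$probe_id), ]
  assert_that(!anyNA(man$probe_id), "stats not aligned to manifest")
  sig <- which(stats$tested & !is.na(stats$fdr) &
                 stats$fdr < params$fdr_alpha)
  empty <- data.frame(cluster = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_cpgs = integer(), mean_delta = numeric(),
                      direction = character(), min_fdr = numeric())
  if (!length(sig)) return(empty)
  df <- data.frame(chrom = man$chrom[sig], pos = man$pos[sig],
                   delta = stats$delta[sig], fdr = stats$fdr[sig],
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), ]
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    brk <- c(TRUE, diff(d$pos) > params$max_gap_bp |
               sign(d$delta[-1]) != sign(d$delta[-nrow(d)]))
    grp <- cumsum(brk)
    for (g in split(d, grp)) {
      if (nrow(g) < params$min_cpgs) next
      md <- mean(g$delta)
      if (abs(md) <= params$min_abs_delta) next
      out[[length(out) + 1]] <- data.frame(
        cluster = cluster, chrom = ch, start = min(g$pos),
        end = max(g$pos), n_cpgs = nrow(g), mean_delta = md,
        direction = if (md > 0) "hyper" else "hypo",
        min_fdr = min(g$fdr), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Link regions to their nearest annotated gene
#'
#' Nearest gene by minimal interval distance (0 when overlapping; disjoint
#' intervals are separated by the number of bases strictly between them).
#' Regions farther than `max_dist` from every gene get `nearest_gene = NA`.
#' Distance ties go to the lexicographically smallest gene name.
#'
#' @param dmrs data.frame from [call_dmrs()].
#' @param genes gene annotation (`gene`, `chrom`, `start`, `end`).
#' @param max_dist maximum linkage distance in bp (default 20,000).
#' @return `dmrs` with `nearest_gene` and `gene_distance` columns.
#' @export
link_genes <- function(dmrs, genes, max_dist = 20000) {
  dmrs$nearest_gene <- rep(NA_character_, nrow(dmrs))
  dmrs$gene_distance <- rep(NA_real_, nrow(dmrs))
  if (!nrow(dmrs) || is.null(genes) || !nrow(genes)) return(dmrs)
  for (i in seq_len(nrow(dmrs))) {
    g <- genes[genes$chrom == dmrs$chrom[i], ]
    if (!nrow(g)) next
    d <- pmax(0, pmax(g$start - dmrs$end[i], dmrs$start[i] - g$end) - 1)
    best <- min(d)
    if (best > max_dist) next
    cand <- sort(g$gene[d == best])
    dmrs$nearest_gene[i] <- cand[1]
    dmrs$gene_distance[i] <- best
  }
  dmrs
}

#' Cluster-specific DMRs for every cluster
#'
#' Runs [cpg_stats()], [call_dmrs()] and [link_genes()] one-vs-rest for
#' each cluster label, using classifiable samples only when a
#' classifiability mask is supplied.
#'
#' @param beta probes x samples beta matrix.
#' @param labels per-sample cluster labels.
#' @param manifest probe manifest.
#' @param genes optional gene annotation for linkage.
#' @param params a [dmr_params()].
#' @param classifiable optional logical mask; non-classifiable samples are
#'   excluded from the contrasts.
#' @return data.frame of all regions across clusters.
#' @export
cluster_dmrs <- function(beta, labels, manifest, genes = NULL,
                         params = dmr_params(), classifiable = NULL) {
  if (!is.null(classifiable)) labels[!classifiable] <- NA
  out <- lapply(sort(unique(labels[!is.na(labels)])), function(cl) {
    st <- cpg_stats(beta, labels, cl)
    link_genes(call_dmrs(st, manifest, params, cluster = cl), genes,
               params$gene_max_dist_bp)
  })
  do.call(rbind, out)
}

#' Write DMRs as BED (0-based half-open) plus a full-field TSV
#' @param dmrs data.frame from [cluster_dmrs()] / [call_dmrs()].
#' @param bed_path,tsv_path output files (either may be NULL).
#' @export
write_dmrs <- function(dmrs, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = paste0("chr", dmrs$chrom),
                      start = dmrs$start - 1, end = dmrs$end,
                      name = paste0("cluster", dmrs$cluster, "_",
                                    dmrs$direction))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path))
    utils::write.table(dmrs, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(dmrs)
}
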