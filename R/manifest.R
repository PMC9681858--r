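#' Chromosome sizes and centromere positions (hg19)
#'
#' Approximate hg19 chromosome lengths and centromere midpoints used to lay
#' out synthetic probe manifests and to assign chromosome arms. Acrocentric
#' chromosomes (13, 14, 15, 21, 22) are flagged so the simulator places
#' probes on their q arms only, as on real arrays.
#'
#' @return data.frame with columns `chrom`, `length`, `centromere`,
#'   `acrocentric`.
#' @export
chrom_info <- function() {
  data.frame(
    chrom = c(as.character(1:22), "X", "Y"),
    length = c(249250621, 243199373, 198022430, 191154276, 180915260,
               171115067, 159138663, 146364022, 141213431, 135534747,
               135006516, 133851895, 115169878, 107349540, 102531392,
               90354753, 81195210, 78077248, 59128983, 63025520,
               48129895, 51304566, 155270560, 59373566),
    centromere = c(125.0e6, 93.3e6, 91.0e6, 50.4e6, 48.4e6, 61.0e6,
                   59.9e6, 45.6e6, 49.0e6, 40.2e6, 53.7e6, 35.8e6,
                   17.9e6, 17.6e6, 19.0e6, 36.6e6, 24.0e6, 17.2e6,
                   26.5e6, 27.5e6, 13.2e6, 14.7e6, 60.6e6, 12.5e6),
    acrocentric = c(rep(FALSE, 12), TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic Infinium-style probe manifest
#'
#' Lays `n_probes` CpG probes over the autosomes (plus, optionally, a
#' fraction on X/Y so the sex-chromosome filter has work to do), with
#' 1-based positions sorted within each chromosome, arm assignment from the
#' centromere table, a fixed fraction of probes flagged cross-reactive, and
#' a fraction annotated with a proximal SNP (distance <= 2 bp, MAF >= 0.05)
#' plus an equal fraction with non-qualifying SNP annotations (so that the
#' SNP filter is exercised for specificity as well as sensitivity).
#'
#' @param config a [sim_config()] list (fields `n_probes`, `sex_fraction`,
#'   `cross_reactive_fraction`, `snp_fraction`, `seed` are used).
#' @return data.frame with columns `probe_id`, `chrom`, `pos`, `arm`,
#'   `cross_reactive`, `snp_dist_bp`, `snp_maf`.
#' @export
generate_manifest <- function(config) {
  n <- config$n_probes
  assert_that(is.numeric(n) && n >= 100, "n_probes must be >= 100")
  info <- chrom_info()
  sex_frac <- config$sex_fraction %||% 0
  assert_that(sex_frac >= 0 && sex_frac < 1, "sex_fraction must be in [0,1)")

  set.seed(derive_seed(config$seed, 101))

  # probes per chromosome, proportional to placeable length
  placeable <- ifelse(info$acrocentric, info$length - info$centromere,
                      info$length)
  auto <- info$chrom %in% as.character(1:22)
  n_sex <- round(sex_frac * n)
  n_auto <- n - n_sex
  alloc <- integer(nrow(info))
  alloc[auto] <- diff(c(0, round(cumsum(placeable[auto] /
                                          sum(placeable[auto])) * n_auto)))
  if (n_sex > 0) {
    alloc[info$chrom == "X"] <- ceiling(n_sex * 0.7)
    alloc[info$chrom == "Y"] <- n_sex - ceiling(n_sex * 0.7)
  }

  # positions mix CpG-island-like clusters (tightly spaced runs, as on a
  # real array) with open-sea singletons, so that DMR blocks of
  # consecutive probes are physically compact
  island_frac <- config$island_fraction %||% 0.7
  gen_positions <- function(k, lo, hi) {
    pos <- numeric(0)
    while (length(pos) < k * island_frac) {
      m <- 4 + stats::rpois(1, 4)
      start <- stats::runif(1, lo, hi)
      pos <- c(pos, start + cumsum(c(0, stats::runif(m - 1, 50, 800))))
    }
    if (length(pos) < k)
      pos <- c(pos, stats::runif(k - length(pos), lo, hi))
    pos <- sort(unique(round(pos)))
    pos <- pos[pos >= lo & pos <= hi]
    while (length(pos) < k) {
      pos <- sort(unique(c(pos, round(stats::runif(k - length(pos),
                                                   lo, hi)))))
      pos <- pos[pos >= lo & pos <= hi]
    }
    if (length(pos) > k) pos <- sort(sample(pos, k))
    pos
  }
  rows <- lapply(seq_len(nrow(info)), function(i) {
    k <- alloc[i]
    if (k == 0) return(NULL)
    lo <- if (info$acrocentric[i]) info$centromere[i] + 1 else 1
    pos <- gen_positions(k, lo, info$length[i])
    data.frame(chrom = info$chrom[i], pos = pos,
               arm = ifelse(pos <= info$centromere[i], "p", "q"),
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)

  # real arrays target the promoters/bodies of recurrent cancer genes;
  # anchor a run of probes inside each canonical locus so focal events
  # always have on-gene coverage
  anchors <- default_genes()
  cen_of <- info$centromere[match(man$chrom, info$chrom)]
  moved <- integer(0)
  for (i in seq_len(nrow(anchors))) {
    g <- anchors[i, ]
    idx <- setdiff(which(man$chrom == g$chrom), moved)
    if (length(idx) < 8) next
    mid <- (g$start + g$end) / 2
    near <- idx[order(abs(man$pos[idx] - mid))][1:6]
    man$pos[near] <- round(seq(g$start, g$end, length.out = 6))
    moved <- c(moved, near)
  }
  man$arm <- ifelse(man$pos <= cen_of, "p", "q")
  man <- man[order(match(man$chrom, info$chrom), man$pos), ]
  # enforce strictly increasing positions after anchoring
  for (ch in unique(man$chrom)) {
    j <- which(man$chrom == ch)
    while (any(dup <- duplicated(man$pos[j]))) {
      man$pos[j][dup] <- man$pos[j][dup] + 1L
      man <- man[order(match(man$chrom, info$chrom), man$pos), ]
      j <- which(man$chrom == ch)
    }
  }
  rownames(man) <- NULL
  man$probe_id <- sprintf("cg%08d", seq_len(nrow(man)))
  man <- man[, c("probe_id", "chrom", "pos", "arm")]

  xr_frac <- config$cross_reactive_fraction %||% 0.03
  n_xr <- round(xr_frac * nrow(man))
  man$cross_reactive <- FALSE
  man$cross_reactive[sample.int(nrow(man), n_xr)] <- TRUE

  snp_frac <- config$snp_fraction %||% 0.03
  n_snp <- round(snp_frac * nrow(man))
  man$snp_dist_bp <- NA_integer_
  man$snp_maf <- NA_real_
  free <- which(is.na(man$snp_dist_bp))
  hit <- sample(free, min(n_snp, length(free)))
  man$snp_dist_bp[hit] <- sample(0:2, length(hit), replace = TRUE)
  man$snp_maf[hit] <- stats::runif(length(hit), 0.05, 0.5)
  # an equal tranche of annotations that must NOT trigger the filter
  free <- setdiff(which(is.na(man$snp_dist_bp)), hit)
  miss <- sample(free, min(n_snp, length(free)))
  far <- sample(c(TRUE, FALSE), length(miss), replace = TRUE)
  man$snp_dist_bp[miss] <- ifelse(far, sample(3:50, length(miss), TRUE),
                                  sample(0:2, length(miss), TRUE))
  man$snp_maf[miss] <- ifelse(far, stats::runif(length(miss), 0.05, 0.5),
                              stats::runif(length(miss), 0.001, 0.049))
  rownames(man) <- man$probe_id
  man
}
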