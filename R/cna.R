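#' Copy-number calling parameters
#'
#' @param min_bin_bases minimum genomic span of a bin (default 50,000).
#' @param min_bin_probes minimum probes per bin (default 15).
#' @param call_threshold |log2| beyond which a bin/arm is gained or lost.
#' @param amp_threshold log2 above which a focal bin is an amplification.
#' @param homdel_threshold log2 below which a focal bin is a deletion.
#' @param min_seg_bins minimum consecutive aberrant bins forming a
#'   segmental (SCA) call.
#' @return list of class `cna_params`.
#' @export
cna_params <- function(min_bin_bases = 50000, min_bin_probes = 15,
                       call_threshold = 0.1, amp_threshold = 1.0,
                       homdel_threshold = -1.0, min_seg_bins = 3) {
  assert_that(homdel_threshold < -call_threshold &&
                call_threshold > 0 && call_threshold < amp_threshold,
              "thresholds must satisfy homdel < -call < 0 < call < amp")
  structure(list(min_bin_bases = min_bin_bases,
                 min_bin_probes = min_bin_probes,
                 call_threshold = call_threshold,
                 amp_threshold = amp_threshold,
                 homdel_threshold = homdel_threshold,
                 min_seg_bins = min_seg_bins),
            class = "cna_params")
}

#' Normalise combined intensities against a reference set
#'
#' Scales each sample so that its median total intensity matches the
#' median of the reference profile, then returns per-probe
#' `log2(sample / reference)` where the reference is the per-probe median
#' over the reference samples.
#'
#' @param sample_total per-probe total (M + U) intensities: a vector or a
#'   probes x samples matrix.
#' @param reference_totals probes x m matrix of reference totals (m >= 1).
#' @return log2 ratios, same shape as `sample_total`.
#' @export
normalize_to_reference <- function(sample_total, reference_totals) {
  ref <- as.matrix(reference_totals)
  assert_that(ncol(ref) >= 1, "need at least one reference sample")
  x <- as.matrix(sample_total)
  assert_that(nrow(x) == nrow(ref), "probe dimension mismatch")
  assert_that(all(x > 0) && all(ref > 0),
              "intensities must be strictly positive")
  ref_profile <- matrixStats::rowMedians(ref)
  ref_med <- stats::median(ref_profile)
  scale <- ref_med / matrixStats::colMedians(x)
  scaled <- sweep(x, 2, scale, `*`)
  out <- log2(scaled / ref_profile)
  if (is.null(dim(sample_total))) out[, 1] else out
}

# greedy per-arm bin boundaries; returns list of integer row-index vectors
greedy_bins <- function(pos, min_bases, min_probes) {
  n <- length(pos)
  if (n < min_probes) return(list())
  bins <- list()
  start <- 1
  i <- 1
  while (i <= n) {
    count <- i - start + 1
    span <- pos[i] - pos[start] + 1
    if (count >= min_probes && span >= min_bases) {
      bins[[length(bins) + 1]] <- start:i
      start <- i + 1
    }
    i <- i + 1
  }
  if (start <= n) {  # trailing incomplete bin: merge left, or drop
    if (length(bins)) {
      last <- length(bins)
      bins[[last]] <- c(bins[[last]], start:n)
    }
  }
  bins
}

#' Bin per-probe log2 ratios along the genome
#'
#' Greedy left-to-right binning within each chromosome arm: the current
#' bin is extended until it spans at least `min_bin_bases` bases AND
#' contains at least `min_bin_probes` probes, then closed. A trailing bin
#' failing either minimum is merged into its left neighbour, or dropped
#' when the arm has produced none. Bin value = median probe ratio. Arms
#' with fewer than `min_bin_probes` probes yield no bins.
#'
#' @param ratios per-probe log2 ratio vector, aligned with `manifest` rows
#'   (names, when present, must match `manifest$probe_id`).
#' @param manifest probe manifest (sorted by position within chromosome).
#' @param params a [cna_params()].
#' @return data.frame of bins: `chrom`, `arm`, `start`, `end`, `n_probes`,
#'   `log2` plus the covered manifest row range.
#' @export
bin_genome <- function(ratios, manifest, params = cna_params()) {
  assert_that(length(ratios) == nrow(manifest),
              "ratios must align with the manifest")
  chroms <- c(as.character(1:22), "X", "Y")
  out <- list()
  for (ch in intersect(chroms, unique(manifest$chrom))) {
    for (a in c("p", "q")) {
      rows <- which(manifest$chrom == ch & manifest$arm == a)
      if (!length(rows)) next
      rows <- rows[order(manifest$pos[rows])]
      idx <- greedy_bins(manifest$pos[rows], params$min_bin_bases,
                         params$min_bin_probes)
      for (b in idx) {
        r <- rows[b]
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, arm = a,
          start = manifest$pos[r[1]], end = manifest$pos[r[length(r)]],
          n_probes = length(r), log2 = stats::median(ratios[r]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), arm = character(),
                      start = numeric(), end = numeric(),
                      n_probes = integer(), log2 = numeric()))
  do.call(rbind, out)
}

#' Derive arm, whole-chromosome, segmental and focal calls from bins
#'
#' Arm call: median bin log2 against +/- `call_threshold`. WCA: both arms
#' of a chromosome share a non-neutral direction (acrocentric chromosomes,
#' with no p-arm probes, are called on the q arm alone). SCA: a maximal
#' run of >= `min_seg_bins` consecutive same-direction aberrant bins on an
#' arm of a chromosome that carries no WCA. Focal: any bin overlapping a
#' listed gene beyond the amplification/deletion thresholds.
#'
#' @param bins data.frame from [bin_genome()].
#' @param manifest probe manifest (for acrocentric bookkeeping).
#' @param params a [cna_params()].
#' @param gene_map optional data.frame (`gene`, `chrom`, `start`, `end`)
#'   of loci to screen for focal events.
#' @return list of class `cna_profile`: `bins`, `arm_calls`, `wca`, `sca`,
#'   `focal`, `n_wca`, `has_sca`.
#' @export
call_events <- function(bins, manifest, params = cna_params(),
                        gene_map = NULL) {
  thr <- params$call_threshold
  dir_of <- function(x) ifelse(x > thr, "gain", ifelse(x < -thr, "loss",
                                                       "neutral"))
  arm_calls <- do.call(rbind, lapply(
    split(bins, paste(bins$chrom, bins$arm)), function(b) {
      data.frame(chrom = b$chrom[1], arm = b$arm[1],
                 median_log2 = stats::median(b$log2),
                 call = dir_of(stats::median(b$log2)),
                 stringsAsFactors = FALSE)
    }))
  rownames(arm_calls) <- NULL

  # whole-chromosome aberrations
  wca <- list()
  for (ch in unique(arm_calls$chrom)) {
    ac <- arm_calls[arm_calls$chrom == ch, ]
    present_arms <- sort(unique(manifest$arm[manifest$chrom == ch]))
    if (length(present_arms) == 2) {
      if (nrow(ac) == 2 && ac$call[1] != "neutral" &&
          ac$call[1] == ac$call[2])
        wca[[length(wca) + 1]] <- data.frame(chrom = ch,
                                             direction = ac$call[1])
    } else if (nrow(ac) >= 1 && ac$call[1] != "neutral") {
      # acrocentric: q arm alone decides
      wca[[length(wca) + 1]] <- data.frame(chrom = ch,
                                           direction = ac$call[1])
    }
  }
  wca <- if (length(wca)) do.call(rbind, wca)
         else data.frame(chrom = character(), direction = character())

  # segmental aberrations on arms of non-WCA chromosomes
  sca <- list()
  for (key in unique(paste(bins$chrom, bins$arm))) {
    b <- bins[paste(bins$chrom, bins$arm) == key, ]
    b <- b[order(b$start), ]
    if (b$chrom[1] %in% wca$chrom) next
    d <- dir_of(b$log2)
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$values)) {
      if (r$values[j] == "neutral" || r$lengths[j] < params$min_seg_bins)
        next
      sca[[length(sca) + 1]] <- data.frame(
        chrom = b$chrom[1], arm = b$arm[1],
        start = b$start[starts[j]], end = b$end[ends[j]],
        n_bins = r$lengths[j], direction = r$values[j],
        stringsAsFactors = FALSE)
    }
  }
  sca <- if (length(sca)) do.call(rbind, sca)
         else data.frame(chrom = character(), arm = character(),
                         start = numeric(), end = numeric(),
                         n_bins = integer(), direction = character())

  # focal events over listed genes
  focal <- data.frame(gene = character(), direction = character(),
                      log2 = numeric())
  if (!is.null(gene_map) && nrow(bins)) {
    hits <- list()
    for (i in seq_len(nrow(gene_map))) {
      g <- gene_map[i, ]
      ov <- bins$chrom == g$chrom & bins$start <= g$end & bins$end >= g$start
      if (!any(ov)) next
      lg <- bins$log2[ov]
      if (any(lg >= params$amp_threshold))
        hits[[length(hits) + 1]] <- data.frame(
          gene = g$gene, direction = "amplification", log2 = max(lg))
      else if (any(lg <= params$homdel_threshold))
        hits[[length(hits) + 1]] <- data.frame(
          gene = g$gene, direction = "deletion", log2 = min(lg))
    }
    if (length(hits)) focal <- do.call(rbind, hits)
  }

  structure(list(bins = bins, arm_calls = arm_calls, wca = wca, sca = sca,
                 focal = focal, n_wca = nrow(wca), has_sca = nrow(sca) > 0),
            class = "cna_profile")
}

#' Full methylation-intensity copy-number profile for one or more samples
#'
#' Convenience wrapper: normalises totals against the reference, bins the
#' genome once per manifest, and derives calls per sample.
#'
#' @param M,U intensity matrices (probes x samples).
#' @param manifest probe manifest aligned with the rows.
#' @param reference_totals probes x m matrix of reference (M + U) totals.
#' @param params a [cna_params()].
#' @param gene_map optional focal gene table.
#' @return named list of `cna_profile` objects, one per sample.
#' @export
cna_profiles <- function(M, U, manifest, reference_totals,
                         params = cna_params(), gene_map = NULL) {
  ratios <- normalize_to_reference(M + U, reference_totals)
  ratios <- as.matrix(ratios)
  out <- lapply(seq_len(ncol(ratios)), function(j) {
    bins <- bin_genome(ratios[, j], manifest, params)
    call_events(bins, manifest, params, gene_map)
  })
  names(out) <- colnames(M)
  out
}

#' Write per-sample bins as a SEG-style TSV
#'
#' Columns: sample, chrom, start, end, n_probes, log2 (1-based inclusive
#' coordinates).
#' @param profiles named list of `cna_profile` objects.
#' @param path output file.
#' @export
write_seg <- function(profiles, path) {
  seg <- do.call(rbind, lapply(names(profiles), function(s) {
    b <- profiles[[s]]$bins
    if (!nrow(b)) return(NULL)
    data.frame(sample = s, b[, c("chrom", "start", "end", "n_probes",
                                 "log2")])
  }))
  utils::write.table(seg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
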