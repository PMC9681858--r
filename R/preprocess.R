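#' Preprocessing parameters
#'
#' @param beta_offset intensity offset in the beta denominator.
#' @param det_alpha detection p-value threshold above which a measurement
#'   counts as failed.
#' @param det_frac fraction of failing samples at which a probe is removed
#'   (inclusive).
#' @param snp_maf_min minimum minor-allele frequency for the SNP filter
#'   (inclusive).
#' @param snp_dist_max maximum CpG-to-SNP distance for the SNP filter
#'   (inclusive).
#' @param drop_sex_chroms remove X/Y probes before clustering.
#' @param top_k number of most-variable probes to keep.
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(beta_offset = 100, det_alpha = 0.01,
                              det_frac = 0.5, snp_maf_min = 0.05,
                              snp_dist_max = 2, drop_sex_chroms = TRUE,
                              top_k = 10000) {
  assert_that(det_alpha > 0 && det_alpha < 1, "det_alpha must be in (0,1)")
  assert_that(det_frac >= 0 && det_frac <= 1, "det_frac must be in [0,1]")
  assert_that(top_k >= 2, "top_k must be >= 2")
  structure(list(beta_offset = beta_offset, det_alpha = det_alpha,
                 det_frac = det_frac, snp_maf_min = snp_maf_min,
                 snp_dist_max = snp_dist_max,
                 drop_sex_chroms = drop_sex_chroms, top_k = top_k),
            class = "preprocess_params")
}

#' Compute beta-values from methylated/unmethylated intensities
#'
#' beta = M / (M + U + offset), elementwise; always in [0, 1].
#'
#' @param M,U nonnegative intensity matrices of identical shape.
#' @param offset nonnegative intensity offset (default 100, the array
#'   convention).
#' @return matrix of beta-values with the dimnames of `M`.
#' @export
compute_beta <- function(M, U, offset = 100) {
  assert_that(all(dim(M) == dim(U)), "M and U must have the same shape")
  assert_that(all(M >= 0) && all(U >= 0) && offset >= 0,
              "intensities and offset must be nonnegative")
  M / (M + U + offset)
}

#' Apply probe-level quality filters
#'
#' Removes, in order: (1) probes whose detection p-value exceeds
#' `det_alpha` in at least `det_frac` of samples; (2) cross-reactive
#' probes; (3) X/Y probes; (4) probes with a proximal SNP (distance <=
#' `snp_dist_max` and MAF >= `snp_maf_min`, both inclusive). Each removed
#' probe is counted under the first rule that removes it.
#'
#' @param beta probes x samples beta matrix (rownames = probe ids).
#' @param manifest probe manifest covering the rows of `beta`.
#' @param detp optional detection p-value matrix aligned with `beta`; when
#'   `NULL` the detection filter is skipped.
#' @param params a [preprocess_params()].
#' @return list with `beta` (filtered matrix) and `report` (named removal
#'   counts plus `retained`).
#' @export
filter_probes <- function(beta, manifest, detp = NULL,
                          params = preprocess_params()) {
  ids <- rownames(beta)
  assert_that(!is.null(ids), "beta must have probe ids as rownames")
  man <- manifest[match(ids, manifest$probe_id), ]
  assert_that(!anyNA(man$probe_id), "manifest missing probes present in beta")

  removed <- rep(NA_character_, length(ids))
  if (!is.null(detp)) {
    assert_that(all(dim(detp) == dim(beta)), "detp shape mismatch")
    fail_frac <- rowMeans(detp > params$det_alpha)
    removed[is.na(removed) & fail_frac >= params$det_frac] <- "detection"
  }
  removed[is.na(removed) & man$cross_reactive] <- "cross_reactive"
  if (params$drop_sex_chroms)
    removed[is.na(removed) & man$chrom %in% c("X", "Y")] <- "sex_chrom"
  snp_hit <- !is.na(man$snp_dist_bp) & !is.na(man$snp_maf) &
    man$snp_dist_bp <= params$snp_dist_max & man$snp_maf >= params$snp_maf_min
  removed[is.na(removed) & snp_hit] <- "snp_proximal"

  keep <- is.na(removed)
  report <- c(detection = sum(removed == "detection", na.rm = TRUE),
              cross_reactive = sum(removed == "cross_reactive", na.rm = TRUE),
              sex_chrom = sum(removed == "sex_chrom", na.rm = TRUE),
              snp_proximal = sum(removed == "snp_proximal", na.rm = TRUE),
              retained = sum(keep))
  list(beta = beta[keep, , drop = FALSE], report = report)
}

#' Select the most variable probes by standard deviation
#'
#' Ranks probes by across-sample standard deviation (n - 1 denominator),
#' keeps the top `k`, preserving the original probe order within the
#' selection; rank ties are broken by lexicographic probe id.
#'
#' @param beta probes x samples beta matrix with probe-id rownames.
#' @param k number of probes to keep (<= nrow(beta)).
#' @return the row-subset beta matrix.
#' @export
select_top_variable <- function(beta, k = 10000) {
  assert_that(k <= nrow(beta), "k exceeds the number of probes")
  sds <- matrixStats::rowSds(beta)
  ord <- order(-sds, rownames(beta))
  keep <- sort(ord[seq_len(k)])
  beta[keep, , drop = FALSE]
}
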