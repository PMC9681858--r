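#' Run the full subgrouping pipeline on a beta matrix
#'
#' Probe filtering, top-variable selection, weighted Pearson distance and
#' resampling-consensus clustering in one call.
#'
#' @param beta probes x samples beta matrix.
#' @param manifest probe manifest covering the rows.
#' @param detp optional detection p-value matrix.
#' @param pparams a [preprocess_params()].
#' @param cparams a [cluster_params()].
#' @return list with `filtered` (beta after QC), `top` (top-variable
#'   subset), `dist`, `consensus` (a `consensus_result`), and
#'   `filter_report`.
#' @export
subgroup_pipeline <- function(beta, manifest, detp = NULL,
                              pparams = preprocess_params(),
                              cparams = cluster_params()) {
  fp <- filter_probes(beta, manifest, detp, pparams)
  top <- select_top_variable(fp$beta, min(pparams$top_k, nrow(fp$beta)))
  D <- weighted_pearson_distance(top, cparams$probe_weights)
  res <- consensus_resample(D, cparams)
  list(filtered = fp$beta, top = top, dist = D, consensus = res,
       filter_report = fp$report)
}
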