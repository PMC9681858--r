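#' Weighted Pearson distance between samples
#'
#' Computes the pairwise sample distance `1 - r_w`, where `r_w` is the
#' weighted Pearson correlation between sample columns with per-probe
#' weights `w` (weighted means, variances and covariances with weight
#' normalisation). With uniform weights this reduces exactly to the
#' ordinary Pearson correlation distance.
#'
#' @param beta probes x samples matrix.
#' @param weights per-probe weight vector (nonnegative, not all zero), or
#'   one of `"sd"` (per-probe standard deviation, the default used by the
#'   clustering pipeline) / `"uniform"`.
#' @return samples x samples symmetric distance matrix with zero diagonal,
#'   entries in [0, 2].
#' @export
weighted_pearson_distance <- function(beta, weights = "sd") {
  assert_that(nrow(beta) >= 2, "need at least 2 probes")
  if (is.character(weights)) {
    weights <- switch(match.arg(weights, c("sd", "uniform")),
                      sd = matrixStats::rowSds(beta),
                      uniform = rep(1, nrow(beta)))
  }
  assert_that(length(weights) == nrow(beta), "weights length mismatch")
  assert_that(all(weights >= 0) && sum(weights) > 0,
              "weights must be nonnegative and not all zero")
  w <- weights / sum(weights)
  mu <- colSums(w * beta)
  xc <- sweep(beta, 2, mu)
  cov <- crossprod(xc, w * xc)
  v <- diag(cov)
  if (any(v <= 0)) {
    stop("zero weighted variance for sample(s): ",
         paste(colnames(beta)[v <= 0], collapse = ", "), call. = FALSE)
  }
  r <- cov / sqrt(outer(v, v))
  d <- 1 - r
  d <- (d + t(d)) / 2
  diag(d) <- 0
  pmin(pmax(d, 0), 2)
}
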