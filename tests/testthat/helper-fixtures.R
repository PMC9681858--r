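# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk.

# small cohort cached per (distinctive) configuration to keep the suite fast
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(key = "default", ...) {
  if (!exists(key, .fixture_env)) {
    cfg <- sim_config(...)
    assign(key, generate_cohort(cfg), .fixture_env)
  }
  get(key, .fixture_env)
}

# manifest for hand-built beta matrices: one chromosome, evenly spaced CpGs
flat_manifest <- function(n, spacing = 500, chrom = "1", arm = "q",
                          start = 1e6) {
  data.frame(probe_id = sprintf("cg%08d", seq_len(n)), chrom = chrom,
             pos = start + spacing * (seq_len(n) - 1), arm = arm,
             cross_reactive = FALSE, snp_dist_bp = NA_integer_,
             snp_maf = NA_real_, stringsAsFactors = FALSE)
}

# beta matrix with a planted one-vs-rest block: group means differ by
# `delta` over `block` rows; gaussian noise truncated to [0,1]
block_beta <- function(n_probes, n1, n2, block, delta, sd = 0.05,
                       base = 0.5, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  m <- matrix(stats::rnorm(n_probes * n, base, sd), n_probes, n)
  m[block, seq_len(n1)] <- stats::rnorm(length(block) * n1,
                                        base + delta / 2, sd)
  m[block, n1 + seq_len(n2)] <- stats::rnorm(length(block) * n2,
                                             base - delta / 2, sd)
  m <- pmin(pmax(m, 0.001), 0.999)
  rownames(m) <- sprintf("cg%08d", seq_len(n_probes))
  colnames(m) <- sprintf("S%03d", seq_len(n))
  m
}

# distance matrix of two tight, well-separated sample groups
two_group_dist <- function(n_per = 20, gap = 1.6, jitter = 0.01,
                           seed = 1) {
  set.seed(seed)
  x <- c(stats::rnorm(n_per, 0, jitter), stats::rnorm(n_per, gap, jitter))
  as.matrix(stats::dist(cbind(x)))
}

# textbook (unweighted) Pearson distance, written independently of the
# package implementation
pearson_dist_oracle <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- m[, i]; xj <- m[, j]
      r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
        sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
      d[i, j] <- 1 - r
    }
  }
  diag(d) <- 0
  d
}

# per-definition silhouette, looped, independent of cluster::silhouette
silhouette_oracle <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# best label-permutation overlap by exhaustive search (k <= 6)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

best_overlap_oracle <- function(labels, reference) {
  ks <- sort(unique(labels))
  best <- 0
  for (p in perms(seq_along(ks))) {
    mapped <- ks[p][match(labels, ks)]
    best <- max(best, sum(mapped == reference))
  }
  best
}
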