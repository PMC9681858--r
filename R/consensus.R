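#' Consensus clustering parameters
#'
#' Defaults reproduce the published protocol: exact t-SNE (theta = 0,
#' 5000 iterations, perplexity 30) on a precomputed 1 - weighted-Pearson
#' distance, 256 resampling iterations at 80% of the cohort, k-means over
#' k = 2..10 in 2 and 3 embedding dimensions, and the >70% modal-score
#' classifiability rule.
#'
#' @param probe_weights `"sd"` or `"uniform"` probe weighting for the
#'   distance (only used by convenience wrappers; the distance itself is an
#'   input to [consensus_resample()]).
#' @param dims_grid embedding dimensions to scan.
#' @param k_grid cluster numbers to scan (min >= 2).
#' @param n_iter number of resampling iterations.
#' @param subsample_frac fraction of samples drawn per iteration, in (0,1).
#' @param tsne_theta Barnes-Hut angle; 0 = exact t-SNE.
#' @param tsne_max_iter t-SNE gradient iterations.
#' @param tsne_perplexity t-SNE perplexity (must satisfy
#'   perplexity < (n - 1) / 3 for the smallest embedded set).
#' @param kmeans_restarts k-means restarts (best inertia kept).
#' @param modal_threshold classifiability cutoff on the modal score
#'   (strict inequality).
#' @param map_back `"nearest"`: held-out samples inherit the label of their
#'   nearest sampled neighbour under the distance; `"observed"`: held-out
#'   samples stay unlabelled and modal scores are computed over the
#'   iterations that contain the sample.
#' @param seed master seed; every iteration/cell derives its own seed from
#'   it.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(probe_weights = "sd", dims_grid = c(2, 3),
                           k_grid = 2:10, n_iter = 256,
                           subsample_frac = 0.8, tsne_theta = 0,
                           tsne_max_iter = 5000, tsne_perplexity = 30,
                           kmeans_restarts = 10, modal_threshold = 0.70,
                           map_back = c("nearest", "observed"), seed = 1L) {
  assert_that(subsample_frac > 0 && subsample_frac < 1,
              "subsample_frac must be in (0,1)")
  assert_that(min(k_grid) >= 2, "k_grid minimum must be >= 2")
  assert_that(all(dims_grid %in% c(2, 3)), "dims_grid must be within {2,3}")
  structure(list(probe_weights = probe_weights, dims_grid = sort(dims_grid),
                 k_grid = sort(k_grid), n_iter = n_iter,
                 subsample_frac = subsample_frac, tsne_theta = tsne_theta,
                 tsne_max_iter = tsne_max_iter,
                 tsne_perplexity = tsne_perplexity,
                 kmeans_restarts = kmeans_restarts,
                 modal_threshold = modal_threshold,
                 map_back = match.arg(map_back), seed = as.integer(seed)),
            class = "cluster_params")
}

#' Exact t-SNE embedding of a precomputed distance matrix
#'
#' @param dist samples x samples distance matrix.
#' @param dim embedding dimension (2 or 3).
#' @param params a [cluster_params()] (theta, max_iter, perplexity).
#' @param seed RNG seed; same seed and input give identical coordinates.
#' @return n x dim coordinate matrix.
#' @export
tsne_embed <- function(dist, dim = 2, params = cluster_params(), seed = 1L) {
  D <- as.matrix(dist)
  n <- nrow(D)
  assert_that(dim %in% c(2, 3), "dim must be 2 or 3")
  if (params$tsne_perplexity >= (n - 1) / 3) {
    stop("perplexity ", params$tsne_perplexity, " too large for n = ", n,
         " (requires perplexity < (n-1)/3)", call. = FALSE)
  }
  set.seed(seed)
  Rtsne::Rtsne(D, dims = dim, theta = params$tsne_theta,
               max_iter = params$tsne_max_iter,
               perplexity = params$tsne_perplexity, pca = FALSE,
               is_distance = TRUE, check_duplicates = FALSE,
               verbose = FALSE)$Y
}

#' Best-of-restarts k-means partition of an embedding
#'
#' @param embedding n x dim coordinate matrix.
#' @param k number of clusters (<= n).
#' @param restarts random restarts; the lowest-inertia solution is kept.
#' @param seed RNG seed.
#' @return integer vector of labels in 1..k.
#' @export
kmeans_partition <- function(embedding, k, restarts = 10, seed = 1L) {
  n <- nrow(embedding)
  assert_that(k <= n, "k exceeds the number of samples")
  if (k == n) return(seq_len(n))  # each point its own cluster, zero inertia
  set.seed(seed)
  fit <- suppressWarnings(stats::kmeans(embedding, centers = k,
                                        nstart = restarts, iter.max = 100))
  as.integer(fit$cluster)
}

#' Align a partition's labels to a reference by Hungarian matching
#'
#' Finds the label permutation maximising the overlap with the reference
#' via maximum-weight bipartite matching (Hungarian algorithm) on the
#' contingency table. When the partition has more labels than the
#' reference, unmatched labels receive fresh ids. The partition itself is
#' never changed, only the label names.
#'
#' @param labels integer partition (NA = sample absent).
#' @param reference integer reference partition over the same samples.
#' @return relabelled `labels`.
#' @export
align_labels <- function(labels, reference) {
  assert_that(length(labels) == length(reference),
              "partitions must cover the same samples")
  ok <- !is.na(labels) & !is.na(reference)
  assert_that(any(ok), "no overlapping samples between the partitions")
  ll <- sort(unique(labels[!is.na(labels)]))
  rl <- sort(unique(reference[ok]))
  C <- as.matrix(table(factor(labels[ok], levels = ll),
                       factor(reference[ok], levels = rl)))
  d <- max(length(ll), length(rl))
  Cp <- matrix(0, d, d)
  Cp[seq_along(ll), seq_along(rl)] <- C
  asg <- as.integer(clue::solve_LSAP(Cp, maximum = TRUE))
  new_id <- integer(length(ll))
  fresh <- max(rl)
  for (i in seq_along(ll)) {
    if (asg[i] <= length(rl)) {
      new_id[i] <- rl[asg[i]]
    } else {
      fresh <- fresh + 1
      new_id[i] <- fresh
    }
  }
  out <- labels
  out[!is.na(labels)] <- new_id[match(labels[!is.na(labels)], ll)]
  out
}

#' Per-sample and average silhouette on a precomputed distance
#'
#' Standard silhouette s(i) = (b - a) / max(a, b) on the given distance
#' matrix; singleton clusters get s = 0. Errors when fewer than two
#' non-empty clusters are present.
#'
#' @param dist samples x samples distance matrix.
#' @param labels integer cluster labels.
#' @return list with `widths` (per-sample) and `average`.
#' @export
silhouette_scores <- function(dist, labels) {
  assert_that(length(unique(labels)) >= 2,
              "silhouette requires at least 2 non-empty clusters")
  si <- cluster::silhouette(as.integer(factor(labels)),
                            dmatrix = as.matrix(dist))
  w <- si[, "sil_width"]
  list(widths = as.numeric(w), average = mean(w))
}

#' Resampling-consensus t-SNE/k-means clustering
#'
#' For every (dimension, k) cell of the grid: the full-cohort embedding and
#' k-means partition define the reference; each of `n_iter` iterations
#' draws `floor(subsample_frac * n)` samples without replacement, embeds
#' their sub-distance-matrix, partitions with k-means, maps the labels back
#' to the full cohort (held-out samples inherit the label of their nearest
#' sampled neighbour under the distance), and aligns the labels to the
#' reference by Hungarian matching. Per-sample modal labels and modal
#' scores (fraction of iterations agreeing with the modal label), the cell
#' reproducibility (average modal score), and the silhouette of the modal
#' partition under the original distance are then computed per cell. Cells
#' with fewer than 90% successful iterations are marked invalid.
#'
#' @param dist samples x samples distance matrix (e.g. from
#'   [weighted_pearson_distance()]).
#' @param params a [cluster_params()].
#' @return object of class `consensus_result`: `grid` (one row per cell
#'   with reproducibility, average silhouette, validity), `cells` (per-cell
#'   reference, aligned label matrix, modal labels/scores, silhouettes),
#'   `selected` (dim, k chosen by [select_solution()]), `assignments`
#'   (per-sample modal cluster, modal score, silhouette and classifiable
#'   flag at the selected cell), and `params`.
#' @export
consensus_resample <- function(dist, params = cluster_params()) {
  D <- as.matrix(dist)
  n <- nrow(D)
  m <- floor(params$subsample_frac * n)
  assert_that(params$tsne_perplexity < (m - 1) / 3,
              "perplexity too large for the subsampled cohort")
  dims <- params$dims_grid
  ks <- params$k_grid
  seed <- params$seed
  cell_id <- function(d, k) paste0("d", d, "_k", k)

  cells <- list()
  for (d in dims) {
    full_emb <- tsne_embed(D, d, params, seed = derive_seed(seed, 0, d, 0))
    for (k in ks) {
      ref <- kmeans_partition(full_emb, k, params$kmeans_restarts,
                              seed = derive_seed(seed, 0, d, k))
      cells[[cell_id(d, k)]] <- list(
        dim = d, k = k, reference = ref,
        labels = matrix(NA_integer_, params$n_iter, n),
        embedding = full_emb)
    }
  }

  for (r in seq_len(params$n_iter)) {
    set.seed(derive_seed(seed, r))
    idx <- sample.int(n, m)
    hold <- setdiff(seq_len(n), idx)
    # nearest sampled neighbour of each held-out sample
    nn_pos <- if (length(hold))
      apply(D[hold, idx, drop = FALSE], 1, which.min) else integer(0)
    for (d in dims) {
      emb <- tryCatch(
        tsne_embed(D[idx, idx], d, params,
                   seed = derive_seed(seed, r, d, 0)),
        error = function(e) NULL)
      if (is.null(emb)) next  # all cells of this (r, d) stay NA
      for (k in ks) {
        lab_sub <- tryCatch(
          kmeans_partition(emb, k, params$kmeans_restarts,
                           seed = derive_seed(seed, r, d, k)),
          error = function(e) NULL)
        if (is.null(lab_sub)) next
        full <- rep(NA_integer_, n)
        full[idx] <- lab_sub
        if (params$map_back == "nearest" && length(hold))
          full[hold] <- lab_sub[nn_pos]
        cl <- cells[[cell_id(d, k)]]
        cells[[cell_id(d, k)]]$labels[r, ] <-
          align_labels(full, cl$reference)
      }
    }
  }

  grid <- do.call(rbind, lapply(cells, function(cl) {
    n_ok <- sum(apply(!is.na(cl$labels), 1, any))
    denom <- if (params$map_back == "observed")
      colSums(!is.na(cl$labels)) else rep(params$n_iter, n)
    modal <- apply(cl$labels, 2, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(c(NA_integer_, 0))
      tb <- table(x)
      lab <- as.integer(names(tb)[which.max(tb)])
      c(lab, max(tb))
    })
    modal_label <- as.integer(modal[1, ])
    modal_score <- as.numeric(modal[2, ]) / pmax(denom, 1)
    sil <- tryCatch(silhouette_scores(D, modal_label),
                    error = function(e) list(widths = rep(NA_real_, n),
                                             average = NA_real_))
    cells[[cell_id(cl$dim, cl$k)]]$modal_label <<- modal_label
    cells[[cell_id(cl$dim, cl$k)]]$modal_score <<- modal_score
    cells[[cell_id(cl$dim, cl$k)]]$silhouette <<- sil$widths
    data.frame(dim = cl$dim, k = cl$k,
               reproducibility = mean(modal_score),
               avg_silhouette = sil$average,
               n_ok_iter = n_ok,
               valid = n_ok >= 0.9 * params$n_iter &&
                 !is.na(sil$average))
  }))
  rownames(grid) <- NULL

  res <- structure(list(grid = grid, cells = cells, params = params,
                        n = n), class = "consensus_result")
  res$selected <- select_solution(res)
  sel <- cells[[cell_id(res$selected["dim"], res$selected["k"])]]
  res$assignments <- data.frame(
    sample = colnames(D) %||% seq_len(n),
    modal_cluster = sel$modal_label,
    modal_score = sel$modal_score,
    silhouette = sel$silhouette,
    classifiable = classify_samples(res, params$modal_threshold),
    stringsAsFactors = FALSE)
  res
}

#' Select the consensus grid cell with the best rank-sum of
#' reproducibility and silhouette
#'
#' Over valid cells, ranks cells by reproducibility and by average
#' silhouette (higher is better for both) and selects the cell maximising
#' the rank sum; ties go to the smaller k, then the smaller dimension.
#'
#' @param result a `consensus_result`.
#' @return named vector `c(dim, k)`.
#' @export
select_solution <- function(result) {
  g <- result$grid[result$grid$valid, , drop = FALSE]
  assert_that(nrow(g) > 0, "no valid consensus cells")
  score <- rank(g$reproducibility) + rank(g$avg_silhouette)
  g <- g[order(-score, g$k, g$dim), ]
  c(dim = g$dim[1], k = g$k[1])
}

#' Per-sample classifiability at the selected consensus cell
#'
#' A sample is classifiable iff its modal score strictly exceeds the
#' threshold (default 0.70) and its silhouette is strictly positive.
#'
#' @param result a `consensus_result` with a selected cell.
#' @param modal_threshold stability cutoff (strict).
#' @return logical vector.
#' @export
classify_samples <- function(result, modal_threshold = 0.70) {
  sel <- result$cells[[paste0("d", result$selected["dim"],
                              "_k", result$selected["k"])]]
  sel$modal_score > modal_threshold & sel$silhouette > 0
}
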