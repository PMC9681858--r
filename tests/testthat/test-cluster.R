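test_that("label alignment recovers permutations exactly", {
  ref <- c(1, 1, 2, 2, 3, 3)
  lab <- c(3, 3, 1, 1, 2, 2)  # a pure relabelling
  expect_equal(align_labels(lab, ref), ref)
  expect_equal(align_labels(c(1, 1, 0, 0), c(0, 0, 1, 1)), c(0, 0, 1, 1))
  # alignment never changes the partition, only the names
  set.seed(8)
  lab2 <- sample(1:4, 40, replace = TRUE)
  ref2 <- sample(1:4, 40, replace = TRUE)
  al <- align_labels(lab2, ref2)
  expect_equal(mclust::adjustedRandIndex(lab2, al), 1)
})

test_that("alignment overlap equals the exhaustive-permutation optimum", {
  for (seed in 1:4) {
    set.seed(seed)
    ref <- sample(1:5, 60, replace = TRUE)
    lab <- sample(1:5, 60, replace = TRUE)
    al <- align_labels(lab, ref)
    expect_equal(sum(al == ref), best_overlap_oracle(lab, ref))
  }
})

test_that("alignment handles missing samples and extra labels", {
  ref <- c(1, 1, 2, 2, 3, 3)
  lab <- c(2, 2, NA, NA, 1, 1)
  al <- align_labels(lab, ref)
  expect_equal(al, c(1, 1, NA, NA, 3, 3))
  # more labels than the reference: unmatched labels get fresh ids
  lab3 <- c(1, 2, 1, 2, 3, 4)
  al3 <- align_labels(lab3, c(1, 1, 1, 1, 2, 2))
  expect_equal(mclust::adjustedRandIndex(al3, lab3), 1)
  expect_true(all(!is.na(al3)))
  expect_error(align_labels(c(NA, NA), c(1, 2)), "overlap")
})

test_that("silhouette matches its definition", {
  # two clusters, within-distance 0, between-distance 1
  D <- matrix(1, 4, 4) - diag(4)
  D[1, 2] <- D[2, 1] <- 0
  D[3, 4] <- D[4, 3] <- 0
  s <- silhouette_scores(D, c(1, 1, 2, 2))
  expect_equal(s$widths, rep(1, 4))
  # a sample exactly equidistant (a = b) scores 0
  De <- as.matrix(stats::dist(c(0, 1, 2)))
  se <- silhouette_scores(De, c(1, 2, 2))
  expect_equal(se$widths[2], 0)
  # 6-sample toy equals the per-definition oracle
  set.seed(9)
  X <- matrix(stats::rnorm(12), 6, 2)
  Dt <- as.matrix(stats::dist(X))
  lab <- c(1, 1, 2, 2, 3, 3)
  st <- silhouette_scores(Dt, lab)
  expect_lt(max(abs(st$widths - silhouette_oracle(Dt, lab))), 1e-12)
  expect_equal(st$average, mean(silhouette_oracle(Dt, lab)))
  expect_error(silhouette_scores(Dt, rep(1, 6)), "2 non-empty")
})

test_that("single-iteration consensus gives modal score 1 by definition", {
  D <- two_group_dist(n_per = 15, gap = 1.6)
  p <- cluster_params(dims_grid = 2, k_grid = 2:3, n_iter = 1,
                      tsne_perplexity = 7, tsne_max_iter = 500, seed = 2)
  res <- consensus_resample(D, p)
  for (cell in res$cells) expect_true(all(cell$modal_score == 1))
})

test_that("consensus recovers planted subgroups with perfect stability", {
  cfg <- sim_config(n_samples = 100, n_probes = 8000, dmr_delta = 0.4,
                    ambiguous_fraction = 0, seed = 31)
  co <- generate_cohort(cfg)
  fp <- filter_probes(co$beta, co$manifest, co$detp)
  top <- select_top_variable(fp$beta, min(10000, nrow(fp$beta)))
  D <- weighted_pearson_distance(top, "sd")
  p <- cluster_params(dims_grid = 2, k_grid = 5, n_iter = 64,
                      tsne_max_iter = 1500, tsne_perplexity = 25, seed = 17)
  res <- consensus_resample(D, p)
  cell <- res$cells[["d2_k5"]]
  expect_true(all(cell$modal_score > 0.9))
  expect_equal(mclust::adjustedRandIndex(cell$modal_label,
                                         co$truth$true_cluster), 1)
  # modal scores live in (0, 1] and reproducibility is their mean
  expect_true(all(cell$modal_score > 0 & cell$modal_score <= 1))
  expect_equal(res$grid$reproducibility[res$grid$k == 5],
               mean(cell$modal_score))
})

test_that("ambiguous samples are less stable than clean ones", {
  cfg <- sim_config(n_samples = 80, n_probes = 6000, dmr_delta = 0.35,
                    ambiguous_fraction = 0.15, seed = 37)
  co <- generate_cohort(cfg)
  fp <- filter_probes(co$beta, co$manifest, co$detp)
  top <- select_top_variable(fp$beta, min(10000, nrow(fp$beta)))
  D <- weighted_pearson_distance(top, "sd")
  p <- cluster_params(dims_grid = 2, k_grid = 5, n_iter = 32,
                      tsne_max_iter = 1000, tsne_perplexity = 20,
                      seed = 19)
  res <- consensus_resample(D, p)
  cell <- res$cells[["d2_k5"]]
  amb <- co$truth$ambiguous_flag
  expect_lt(mean(cell$modal_score[amb]), mean(cell$modal_score[!amb]))
})

fake_result <- function(grid, cells = NULL, selected = NULL) {
  r <- structure(list(grid = grid, cells = cells), class = "consensus_result")
  if (!is.null(selected)) r$selected <- selected
  r
}

test_that("model selection maximises the rank sum with k-then-dim ties", {
  g <- data.frame(dim = c(2, 2, 3), k = c(4, 5, 5),
                  reproducibility = c(0.7, 0.9, 0.8),
                  avg_silhouette = c(0.3, 0.6, 0.5),
                  n_ok_iter = 10, valid = TRUE)
  expect_equal(unname(select_solution(fake_result(g))), c(2, 5))
  # exact rank-sum tie between k = 4 and k = 6: smaller k wins
  g2 <- data.frame(dim = 2, k = c(4, 6),
                   reproducibility = c(0.9, 0.7),
                   avg_silhouette = c(0.3, 0.6),
                   n_ok_iter = 10, valid = TRUE)
  expect_equal(unname(select_solution(fake_result(g2))["k"]), 4)
  # dim tie-break after k
  g3 <- data.frame(dim = c(3, 2), k = 5,
                   reproducibility = c(0.8, 0.8),
                   avg_silhouette = c(0.5, 0.5),
                   n_ok_iter = 10, valid = TRUE)
  expect_equal(unname(select_solution(fake_result(g3))["dim"]), 2)
  # invalid cells are ignored; no valid cells is an error
  g4 <- g
  g4$valid <- FALSE
  expect_error(select_solution(fake_result(g4)), "valid")
})

test_that("classifiability uses strict thresholds on both criteria", {
  cells <- list(d2_k2 = list(
    modal_score = c(0.70, 0.95, 1.0, 0.71),
    silhouette = c(0.5, -0.01, 0.5, 0.0)))
  r <- fake_result(NULL, cells, selected = c(dim = 2, k = 2))
  expect_equal(classify_samples(r, 0.70), c(FALSE, FALSE, TRUE, FALSE))
})
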