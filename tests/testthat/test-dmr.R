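test_that("per-CpG statistics are calibrated under the null", {
  set.seed(51)
  beta <- matrix(stats::rbeta(5000 * 40, 5, 5), 5000, 40,
                 dimnames = list(sprintf("cg%08d", 1:5000), NULL))
  labels <- rep(1:2, each = 20)
  st <- cpg_stats(beta, labels, 1)
  expect_lte(mean(st$fdr < 0.05, na.rm = TRUE), 0.06)
})

test_that("a strong planted block is fully significant", {
  beta <- block_beta(2000, 40, 40, block = 101:108, delta = 0.4,
                     sd = 0.05, seed = 52)
  st <- cpg_stats(beta, rep(1:2, c(40, 40)), 1)
  expect_true(all(st$fdr[101:108] < 0.05))
  expect_true(all(abs(st$delta[101:108] - 0.4) < 0.05))
})

test_that("constant CpGs are flagged and skipped", {
  beta <- block_beta(50, 5, 5, block = 1:2, delta = 0.3, seed = 53)
  beta[10, ] <- 0.5
  st <- cpg_stats(beta, rep(1:2, c(5, 5)), 1)
  expect_false(st$tested[10])
  expect_true(is.na(st$p[10]) && is.na(st$fdr[10]))
  expect_equal(st$delta[10], 0)
  expect_error(cpg_stats(beta, rep(c(1, 2), c(2, 8)), 1), "min_n")
})

test_that("DMR calling recovers a planted block and honours the 0.3 rule", {
  man <- flat_manifest(2000)
  beta <- block_beta(2000, 40, 40, block = 101:108, delta = 0.4,
                     sd = 0.05, seed = 54)
  st <- cpg_stats(beta, rep(1:2, c(40, 40)), 1)
  dmrs <- call_dmrs(st, man, cluster = 1)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, man$pos[101])
  expect_equal(dmrs$end, man$pos[108])
  expect_equal(dmrs$n_cpgs, 8)
  expect_equal(dmrs$direction, "hyper")
  # a block below the delta threshold yields nothing
  beta2 <- block_beta(2000, 40, 40, block = 101:108, delta = 0.25,
                      sd = 0.05, seed = 55)
  st2 <- cpg_stats(beta2, rep(1:2, c(40, 40)), 1)
  expect_equal(nrow(call_dmrs(st2, man)), 0)
})

test_that("the gap rule splits distant CpGs into droppable singletons", {
  man <- flat_manifest(10, spacing = 5000)  # 5 kb apart, gap limit 1 kb
  beta <- block_beta(10, 30, 30, block = 4:5, delta = 0.5, sd = 0.03,
                     seed = 56)
  st <- cpg_stats(beta, rep(1:2, c(30, 30)), 1)
  expect_true(all(st$fdr[4:5] < 0.05))
  expect_equal(nrow(call_dmrs(st, man)), 0)  # two 1-CpG groups, both dropped
})

test_that("raising the delta threshold never adds DMRs and output regions
           never overlap", {
  man <- flat_manifest(3000)
  set.seed(57)
  blocks <- lapply(0:9, function(i) (i * 250 + 21):(i * 250 + 28))
  beta <- matrix(stats::rnorm(3000 * 60, 0.5, 0.05), 3000, 60)
  for (b in blocks) {
    beta[b, 1:30] <- stats::rnorm(length(b) * 30, 0.72, 0.05)
    beta[b, 31:60] <- stats::rnorm(length(b) * 30, 0.32, 0.05)
  }
  beta <- pmin(pmax(beta, 0.001), 0.999)
  rownames(beta) <- man$probe_id
  st <- cpg_stats(beta, rep(1:2, c(30, 30)), 1)
  counts <- vapply(c(0.2, 0.3, 0.39), function(th) {
    nrow(call_dmrs(st, man, dmr_params(min_abs_delta = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  d <- call_dmrs(st, man, dmr_params(min_abs_delta = 0.3))
  if (nrow(d) > 1) {
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
})

test_that("planted blocks are recovered with high sensitivity and low FDP", {
  man <- flat_manifest(3000)
  hits <- 0; total <- 0; false_calls <- 0; all_calls <- 0
  for (rep in 1:10) {
    set.seed(60 + rep)
    blocks <- lapply(0:7, function(i) (i * 350 + 51):(i * 350 + 58))
    beta <- matrix(stats::rnorm(3000 * 80, 0.5, 0.05), 3000, 80)
    for (b in blocks) {
      beta[b, 1:40] <- stats::rnorm(length(b) * 40, 0.7, 0.05)
      beta[b, 41:80] <- stats::rnorm(length(b) * 40, 0.3, 0.05)
    }
    beta <- pmin(pmax(beta, 0.001), 0.999)
    rownames(beta) <- man$probe_id
    st <- cpg_stats(beta, rep(1:2, c(40, 40)), 1)
    d <- call_dmrs(st, man)
    total <- total + length(blocks)
    all_calls <- all_calls + nrow(d)
    for (b in blocks) {
      ov <- d$start <= man$pos[b[length(b)]] & d$end >= man$pos[b[1]]
      if (any(ov)) hits <- hits + 1
    }
    if (nrow(d)) {
      planted_rng <- vapply(blocks, function(b)
        c(man$pos[b[1]], man$pos[b[length(b)]]), numeric(2))
      fp <- vapply(seq_len(nrow(d)), function(j) {
        !any(d$start[j] <= planted_rng[2, ] & d$end[j] >= planted_rng[1, ])
      }, logical(1))
      false_calls <- false_calls + sum(fp)
    }
  }
  expect_gte(hits / total, 0.9)
  expect_lte(false_calls / max(all_calls, 1), 0.1)
})

test_that("gene linkage picks the nearest gene with deterministic ties", {
  genes <- data.frame(
    gene = c("GENE_B", "GENE_A", "FARAWAY"),
    chrom = c("1", "1", "2"),
    start = c(2e6, 960000, 5e6),
    end = c(2.1e6, 980000, 5.1e6), stringsAsFactors = FALSE)
  dmr_in <- data.frame(cluster = 1, chrom = "1", start = 2.05e6,
                       end = 2.06e6, n_cpgs = 5, mean_delta = 0.4,
                       direction = "hyper", min_fdr = 1e-5)
  linked <- link_genes(dmr_in, genes)
  expect_equal(linked$nearest_gene, "GENE_B")  # inside the gene body
  expect_equal(linked$gene_distance, 0)
  # 25 kb from the only gene on its chromosome: unlinked
  dmr_far <- dmr_in
  dmr_far$chrom <- "2"
  dmr_far$start <- 5.1e6 + 25001
  dmr_far$end <- 5.1e6 + 26000
  expect_true(is.na(link_genes(dmr_far, genes)$nearest_gene))
  # exactly equidistant between GENE_A and GENE_B: lexicographic winner
  gap <- 10000
  dmr_tie <- dmr_in
  dmr_tie$start <- 980000 + gap + 1
  dmr_tie$end <- 2e6 - gap - 1
  linked_tie <- link_genes(dmr_tie, genes)
  expect_equal(linked_tie$gene_distance, gap)
  expect_equal(linked_tie$nearest_gene, "GENE_A")
  # empty annotation: everything unlinked
  expect_true(is.na(link_genes(dmr_in,
                               genes[0, ])$nearest_gene))
})

test_that("planted cohort blocks are recovered end to end", {
  cfg <- sim_config(n_samples = 60, n_probes = 8000, dmr_delta = 0.4,
                    n_dmr_blocks_per_cluster = 20, cna_events = list(),
                    seed = 78)
  co <- generate_cohort(cfg)
  pd <- co$truth$planted_dmrs
  expect_equal(nrow(pd), 100)
  d <- cluster_dmrs(co$beta, co$truth$true_cluster, co$manifest)
  hit <- vapply(seq_len(nrow(pd)), function(i) {
    any(d$cluster == pd$cluster[i] & d$chrom == pd$chrom[i] &
          d$start <= pd$end[i] & d$end >= pd$start[i])
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  fp <- vapply(seq_len(nrow(d)), function(j) {
    !any(pd$chrom == d$chrom[j] & pd$start <= d$end[j] &
           pd$end >= d$start[j])
  }, logical(1))
  expect_lte(mean(fp), 0.1)
})

test_that("cluster_dmrs restricts contrasts to classifiable samples", {
  man <- flat_manifest(500)
  beta <- block_beta(500, 30, 30, block = 11:18, delta = 0.45, sd = 0.05,
                     seed = 70)
  labels <- rep(1:2, c(30, 30))
  cls <- rep(TRUE, 60)
  d <- cluster_dmrs(beta, labels, man, classifiable = cls)
  expect_true(nrow(d) >= 2)  # block appears in both one-vs-rest contrasts
  expect_setequal(unique(d$cluster), 1:2)
  # opposite signs in the two contrasts
  expect_lt(prod(d$mean_delta[d$cluster == 1][1],
                 d$mean_delta[d$cluster == 2][1]), 0)
})
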