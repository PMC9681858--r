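# independent re-implementation of the greedy binning rule, kept naive
greedy_oracle <- function(pos, min_bases, min_probes) {
  bins <- list()
  cur <- integer(0)
  for (i in seq_along(pos)) {
    cur <- c(cur, i)
    if (length(cur) >= min_probes &&
        (pos[cur[length(cur)]] - pos[cur[1]] + 1) >= min_bases) {
      bins[[length(bins) + 1]] <- cur
      cur <- integer(0)
    }
  }
  if (length(cur) && length(bins))
    bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
  bins
}

test_that("reference normalisation removes global scale", {
  set.seed(4)
  ref <- matrix(stats::rlnorm(500 * 5, log(4000), 0.2), 500, 5)
  target <- matrixStats::rowMedians(ref)
  r0 <- normalize_to_reference(target, ref)
  expect_lt(max(abs(r0)), 1e-9)
  r2 <- normalize_to_reference(target * 2, ref)
  expect_lt(max(abs(r2)), 1e-9)
  expect_error(normalize_to_reference(-target, ref), "positive")
})

test_that("planted arm gain is recovered in the normalised ratios", {
  ev <- cna_event("arm", 17, "gain", 0.4, 1:5, 1.0, arm = "q")
  cfg <- sim_config(n_samples = 20, n_probes = 6000, cna_events = list(ev),
                    seed = 41)
  co <- generate_cohort(cfg)
  ref_cfg <- sim_config(n_samples = 10, n_probes = 6000,
                        cna_events = list(), seed = 42)
  ref <- generate_cohort(ref_cfg, manifest = co$manifest)
  ratios <- normalize_to_reference(co$M + co$U, ref$M + ref$U)
  rows <- co$manifest$chrom == "17" & co$manifest$arm == "q"
  med <- stats::median(ratios[rows, ])
  expect_lt(abs(med - 0.4), 0.1)
})

test_that("greedy binning meets both minima and conserves probes", {
  man <- flat_manifest(30, spacing = 200000 / 29)
  bins <- bin_genome(stats::rnorm(30, 0, 0.01), man)
  expect_true(all(bins$n_probes >= 15))
  expect_true(all(bins$end - bins$start + 1 >= 50000))
  expect_equal(sum(bins$n_probes), 30)
  # bins tile the arm without overlap
  expect_true(all(diff(bins$start) > 0))
  expect_true(all(bins$start[-1] > bins$end[-nrow(bins)]))
  # 14 probes on an arm: minimum unreachable, no bins
  man14 <- flat_manifest(14, spacing = 10000)
  expect_equal(nrow(bin_genome(stats::rnorm(14), man14)), 0)
})

test_that("bin boundaries equal the brute-force greedy oracle", {
  set.seed(11)
  pos <- sort(sample.int(3e6, 45))
  man <- flat_manifest(45)
  man$pos <- pos
  bins <- bin_genome(stats::rnorm(45), man)
  oracle <- greedy_oracle(pos, 50000, 15)
  expect_equal(nrow(bins), length(oracle))
  for (j in seq_along(oracle)) {
    expect_equal(bins$start[j], pos[oracle[[j]][1]])
    expect_equal(bins$end[j], pos[oracle[[j]][length(oracle[[j]])]])
    expect_equal(bins$n_probes[j], length(oracle[[j]]))
  }
})

test_that("neutral bins yield no calls and WCA excludes SCA", {
  man <- rbind(flat_manifest(45, spacing = 5000, arm = "p", start = 1e6),
               flat_manifest(90, spacing = 5000, arm = "q", start = 130e6))
  man$probe_id <- sprintf("cg%08d", seq_len(nrow(man)))
  bins0 <- bin_genome(rep(0, nrow(man)), man)
  prof0 <- call_events(bins0, man)
  expect_true(all(prof0$arm_calls$call == "neutral"))
  expect_equal(prof0$n_wca, 0)
  expect_false(prof0$has_sca)
  expect_equal(nrow(prof0$focal), 0)
  # both arms gained: a WCA, and no SCA reported for that chromosome
  prof1 <- call_events(bin_genome(rep(0.4, nrow(man)), man), man)
  expect_equal(prof1$wca$chrom, "1")
  expect_equal(prof1$wca$direction, "gain")
  expect_false(prof1$has_sca)
  # one arm gained only: SCA, not WCA
  prof2 <- call_events(bin_genome(c(rep(0, 45), rep(0.4, 90)), man), man)
  expect_equal(prof2$n_wca, 0)
  expect_true(prof2$has_sca)
  expect_equal(prof2$sca$arm, "q")
})

test_that("whole-chromosome and focal events are recovered from simulation", {
  evs <- list(cna_event("whole", 7, "gain", 0.4, 1:5, 1.0),
              cna_event("focal", 2, "amplification", 1.5, 1:5, 1.0,
                        gene = "MYCN"))
  cfg <- sim_config(n_samples = 12, n_probes = 12000, cna_events = evs,
                    seed = 43)
  co <- generate_cohort(cfg)
  ref <- generate_cohort(sim_config(n_samples = 8, n_probes = 12000,
                                    cna_events = list(), seed = 44),
                         manifest = co$manifest)
  profs <- cna_profiles(co$M, co$U, co$manifest, ref$M + ref$U,
                        gene_map = default_genes())
  wca_hit <- vapply(profs, function(p)
    any(p$wca$chrom == "7" & p$wca$direction == "gain"), logical(1))
  mycn_hit <- vapply(profs, function(p)
    any(p$focal$gene == "MYCN" & p$focal$direction == "amplification"),
    logical(1))
  expect_true(all(wca_hit))
  expect_true(all(mycn_hit))
})

test_that("detection rate is monotone in the planted shift", {
  rates <- vapply(c(0.1, 0.2, 0.4), function(sh) {
    ev <- cna_event("whole", 7, "gain", sh, 1:5, 1.0)
    cfg <- sim_config(n_samples = 10, n_probes = 8000,
                      cna_events = list(ev), seed = 47)
    co <- generate_cohort(cfg)
    ref <- generate_cohort(sim_config(n_samples = 6, n_probes = 8000,
                                      cna_events = list(), seed = 48),
                           manifest = co$manifest)
    profs <- cna_profiles(co$M, co$U, co$manifest, ref$M + ref$U)
    mean(vapply(profs, function(p)
      any(p$wca$chrom == "7" & p$wca$direction == "gain"), logical(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[3], 1)
})
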