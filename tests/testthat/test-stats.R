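test_that("chi-square matches the direct sum over cells", {
  # exactly proportional table: independence, statistic 0
  tb0 <- outer(c(10, 20), c(3, 7)) / 10
  r0 <- chi_square_test(tb0)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)
  # random 3x4 table against sum((O - E)^2 / E)
  set.seed(71)
  tb <- matrix(rpois(12, 20) + 1, 3, 4)
  r <- chi_square_test(tb)
  E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  expect_lt(abs(r$statistic - sum((tb - E)^2 / E)), 1e-10)
  expect_equal(r$df, 6)
  expect_equal(r$p, stats::pchisq(sum((tb - E)^2 / E), 6,
                                  lower.tail = FALSE))
  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("published MYCN-by-cluster counts give an extreme chi-square", {
  # cluster 2 vs rest by MYCN amplification: 39/43 vs 8/161
  tb <- matrix(c(39, 4, 8, 153), 2, byrow = TRUE)
  expect_lt(chi_square_test(tb)$p, 1e-4)
  # continuity correction does not change the conclusion
  expect_lt(chi_square_test(tb, continuity = TRUE)$p, 1e-4)
})

test_that("Spearman correlation handles monotone data and ties", {
  x <- 1:10
  expect_equal(spearman_correlation(x, x^3)$rho, 1)
  expect_equal(spearman_correlation(x, -x - 5)$rho, -1)
  # 10-point toy with a tie equals rank-then-Pearson by hand
  set.seed(72)
  y <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  xr <- rank(x); yr <- rank(y)
  rho_manual <- sum((xr - mean(xr)) * (yr - mean(yr))) /
    sqrt(sum((xr - mean(xr))^2) * sum((yr - mean(yr))^2))
  r <- spearman_correlation(x, y)
  expect_lt(abs(r$rho - rho_manual), 1e-12)
  tstat <- rho_manual * sqrt((10 - 2) / (1 - rho_manual^2))
  expect_equal(r$p, 2 * stats::pt(-abs(tstat), 8), tolerance = 1e-10)
  expect_error(spearman_correlation(x, rep(1, 10)), "constant")
})

test_that("Kaplan-Meier equals the hand-computed product limit", {
  # 8 subjects with interleaved censoring
  time <- c(1, 2, 2, 3, 4, 5, 6, 7)
  event <- c(1, 1, 0, 1, 0, 1, 0, 1)
  km <- km_estimate(time, event)
  # hand product-limit: t=1: 7/8; t=2: *6/7; t=3: *4/5; t=5: *2/3; t=7: *0
  s <- summary(km$fit)
  expect_equal(s$time, c(1, 2, 3, 5, 7))
  expect_equal(s$surv,
               c(7 / 8, 7 / 8 * 6 / 7, 7 / 8 * 6 / 7 * 4 / 5,
                 7 / 8 * 6 / 7 * 4 / 5 * 2 / 3, 0),
               tolerance = 1e-12)
  expect_equal(unname(km$surv_at(4.5)), 7 / 8 * 6 / 7 * 4 / 5,
               tolerance = 1e-12)
  # no censoring: empirical survivor function
  km2 <- km_estimate(1:4, rep(1, 4))
  expect_equal(summary(km2$fit)$surv, c(3, 2, 1, 0) / 4)
  # all censored: flat at 1
  km3 <- km_estimate(1:4, rep(0, 4))
  expect_equal(unname(km3$surv_at(10)), 1)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "nonnegative")
})

test_that("log-rank is null on identical groups and matches permutation",
{
  time <- c(1, 2, 3, 4, 5)
  lr0 <- logrank_test(rep(time, 2), rep(1, 10), rep(1:2, each = 5))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # small two-group toy against a label-permutation null
  set.seed(73)
  t10 <- c(0.8, 1.2, 1.6, 2.5, 3.1, 0.4, 0.9, 1.1, 4.2, 5.0)
  e10 <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  g10 <- rep(1:2, each = 5)
  obs <- logrank_test(t10, e10, g10)$statistic
  B <- 20000
  null_stats <- vapply(seq_len(B), function(b) {
    logrank_test(t10, e10, sample(g10))$statistic
  }, numeric(1))
  p_perm <- (1 + sum(null_stats >= obs)) / (B + 1)
  p_asym <- logrank_test(t10, e10, g10)$p
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(p_asym - p_perm), mc_err + 0.05)
  expect_error(logrank_test(t10, e10, rep(1, 10)), "2 groups")
})

test_that("log-rank separates different planted hazards", {
  reject <- vapply(1:10, function(r) {
    s1 <- generate_survival(rep(1L, 200), 0.1, 0.05, seed = 100 + r)
    s2 <- generate_survival(rep(1L, 200), 0.4, 0.05, seed = 200 + r)
    lr <- logrank_test(c(s1$time, s2$time), c(s1$event, s2$event),
                       rep(1:2, each = 200))
    lr$p < 0.001
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("enrichment report counts, margins and skipping behave", {
  set.seed(74)
  n <- 150
  labels <- sample(1:5, n, replace = TRUE)
  sheet <- data.frame(
    age_years = ifelse(labels == 4, stats::runif(n, 0, 1.4),
                       stats::runif(n, 2, 10)),
    mycn = ifelse(labels == 2 & stats::runif(n) < 0.9, "amp", "normal"),
    stringsAsFactors = FALSE)
  sheet$mycn[1:3] <- NA
  rep_tab <- enrichment_report(labels, sheet)
  expect_setequal(rep_tab$feature, c("infant", "mycn_amp"))
  my <- rep_tab[rep_tab$feature == "mycn_amp", ]
  # counts conserve the classifiable samples with known status
  expect_equal(my$n_known, sum(!is.na(sheet$mycn)))
  expect_equal(sum(my[paste0("n_", 1:5)]), my$n_pos)
  expect_lt(my$p_2, 0.001)
  expect_lt(rep_tab$p_4[rep_tab$feature == "infant"], 0.001)
  # a feature with zero positives is skipped
  sheet2 <- sheet
  sheet2$mycn[!is.na(sheet2$mycn)] <- "normal"
  rep2 <- enrichment_report(labels, sheet2)
  expect_false("mycn_amp" %in% rep2$feature)
})
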