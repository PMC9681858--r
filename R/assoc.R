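#' Pearson chi-square test of independence on a contingency table
#'
#' @param table r x c nonnegative integer matrix (at least 2x2, no zero
#'   row/column margins).
#' @param continuity apply the Yates continuity correction (2x2 only;
#'   off by default).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(table, continuity = FALSE) {
  tb <- as.matrix(table)
  assert_that(nrow(tb) >= 2 && ncol(tb) >= 2, "table must be at least 2x2")
  assert_that(all(tb >= 0), "table entries must be nonnegative")
  assert_that(all(rowSums(tb) > 0) && all(colSums(tb) > 0),
              "zero row/column margin")
  ht <- suppressWarnings(stats::chisq.test(tb, correct = continuity))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Average ranks are used for ties; the p-value comes from the asymptotic
#' t approximation.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 4,
              "need equal-length vectors of at least 4 values")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "constant vector has no rank correlation")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time nonnegative event/censoring times in years.
#' @param event event indicator (1 = event, 0 = censored).
#' @param group optional group labels (one curve per group).
#' @return list with the `survival::survfit` object (`fit`) and
#'   `surv_at(t)`, returning the estimated survival at time `t` per group.
#' @export
km_estimate <- function(time, event, group = NULL) {
  assert_that(all(time >= 0) && all(is.finite(time)),
              "times must be finite and nonnegative")
  df <- data.frame(time = time, event = event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
  } else {
    df$group <- group
    fit <- survival::survfit(survival::Surv(time, event) ~ group,
                             data = df)
  }
  surv_at <- function(t) {
    s <- summary(fit, times = t, extend = TRUE)
    if (is.null(s$strata)) {
      stats::setNames(s$surv, "all")
    } else {
      stats::setNames(s$surv, sub("^group=", "", as.character(s$strata)))
    }
  }
  list(fit = fit, surv_at = surv_at)
}

#' Log-rank test across K groups
#'
#' Standard (unweighted) log-rank; df = K - 1.
#'
#' @param time,event survival outcome per sample.
#' @param group group label per sample (>= 2 non-empty groups).
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  assert_that(nlevels(g) >= 2, "log-rank requires at least 2 groups")
  df <- data.frame(time = time, event = event, group = g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df,
                           rho = 0)
  k <- nlevels(g)
  list(statistic = unname(sd$chisq), df = k - 1,
       p = stats::pchisq(sd$chisq, k - 1, lower.tail = FALSE))
}

#' Cluster-feature enrichment report (Table-2 style)
#'
#' For each binary feature (infant diagnosis below `infant_age` years,
#' MYCN amplification, per-arm gains/losses, whole-chromosome aberration
#' burden "at least 1" / "2 or more", and focal events), reports the per-
#' cluster positive counts, the K-cluster chi-square p-value, and the per-
#' cluster one-vs-rest 2x2 p-values. Samples with unknown status are
#' excluded per feature; features with no positive samples are skipped.
#'
#' @param labels per-sample cluster labels (classifiable samples only;
#'   NA = excluded).
#' @param sample_sheet data.frame with `age_years`, `mycn`.
#' @param profiles optional named list of `cna_profile` objects aligned
#'   with the samples.
#' @param infant_age infancy cutoff in years (strict; default 1.5).
#' @param continuity passed to [chi_square_test()].
#' @return data.frame: `feature`, per-cluster counts `n_<cluster>`,
#'   `n_pos`, `p_overall` and per-cluster `p_<cluster>`.
#' @export
enrichment_report <- function(labels, sample_sheet, profiles = NULL,
                              infant_age = 1.5, continuity = FALSE) {
  keep <- !is.na(labels)
  labels <- labels[keep]
  sheet <- sample_sheet[keep, , drop = FALSE]
  if (!is.null(profiles)) profiles <- profiles[keep]
  clusters <- sort(unique(labels))

  features <- list(
    infant = sheet$age_years < infant_age,
    mycn_amp = sheet$mycn == "amp"
  )
  if (!is.null(profiles)) {
    arm_key <- unique(do.call(rbind, lapply(profiles, function(p) {
      ac <- p$arm_calls[p$arm_calls$call != "neutral", c("chrom", "arm",
                                                         "call")]
      ac
    })))
    if (!is.null(arm_key) && nrow(arm_key)) {
      for (i in seq_len(nrow(arm_key))) {
        nm <- sprintf("chr%s%s%s", arm_key$chrom[i], arm_key$arm[i],
                      if (arm_key$call[i] == "gain") "+" else "-")
        features[[nm]] <- vapply(profiles, function(p) {
          any(p$arm_calls$chrom == arm_key$chrom[i] &
                p$arm_calls$arm == arm_key$arm[i] &
                p$arm_calls$call == arm_key$call[i])
        }, logical(1))
      }
    }
    features$wca_at_least_1 <- vapply(profiles, function(p) p$n_wca >= 1,
                                      logical(1))
    features$wca_2_or_more <- vapply(profiles, function(p) p$n_wca >= 2,
                                     logical(1))
    focal_genes <- unique(unlist(lapply(profiles,
                                        function(p) p$focal$gene)))
    for (g in focal_genes) {
      features[[paste0("focal_", g)]] <- vapply(profiles, function(p) {
        g %in% p$focal$gene
      }, logical(1))
    }
  }

  rows <- list()
  for (nm in names(features)) {
    f <- features[[nm]]
    known <- !is.na(f)
    if (!any(f[known])) next  # feature absent: row skipped
    lab <- labels[known]
    ff <- f[known]
    counts <- vapply(clusters, function(cl) sum(ff[lab == cl]), integer(1))
    tb <- rbind(pos = counts,
                neg = vapply(clusters, function(cl) sum(!ff[lab == cl]),
                             integer(1)))
    p_overall <- tryCatch(chi_square_test(tb, continuity)$p,
                          error = function(e) NA_real_)
    p_cl <- vapply(clusters, function(cl) {
      t2 <- matrix(c(sum(ff[lab == cl]), sum(!ff[lab == cl]),
                     sum(ff[lab != cl]), sum(!ff[lab != cl])), 2)
      tryCatch(chi_square_test(t2, continuity)$p,
               error = function(e) NA_real_)
    }, numeric(1))
    row <- data.frame(feature = nm, t(counts), n_pos = sum(ff),
                      n_known = length(ff), p_overall = p_overall,
                      t(p_cl))
    names(row) <- c("feature", paste0("n_", clusters), "n_pos", "n_known",
                    "p_overall", paste0("p_", clusters))
    rows[[nm]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
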