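# Pseudotime-association statistics: resampled correlation screen,
# competitive gene-set test, mutation/CNA association, survival
# stratification and fold-change concordance.

test_that("the -10log10 FDR scale places 0.05 at 13.01", {
  expect_equal(round(neglog_fdr(0.05), 2), 13.01)
  expect_equal(neglog_fdr(1), 0)
  expect_equal(round(neglog_fdr(0.5), 4), 3.0103)
  expect_error(neglog_fdr(0), "\\(0, 1\\]")
  expect_error(neglog_fdr(-0.1), "\\(0, 1\\]")
})

pt_fixture <- function(n = 30, seed = 1) {
  set.seed(seed)
  setNames(sort(runif(n, 0, 250)), sprintf("s%03d", seq_len(n)))
}

test_that("resampled correlation reduces to plain Pearson when keep_frac = 1", {
  ptv <- pt_fixture(40)
  set.seed(2)
  X <- rbind(lin = ptv * 0.02 + rnorm(40, sd = 0.1),
             noise = rnorm(40))
  colnames(X) <- names(ptv)
  res <- pseudotime_gene_correlation(X, ptv, n_reps = 10, keep_frac = 1)
  expect_equal(res$statistic[res$feature_id == "lin"],
               unname(cor(X["lin", ], ptv)), tolerance = 1e-12)
  expect_equal(res$statistic[res$feature_id == "noise"],
               unname(cor(X["noise", ], ptv)), tolerance = 1e-12)
})

test_that("an exact linear gene scores mean r of 1 in every subset", {
  ptv <- pt_fixture(30)
  X <- rbind(lin = 3 + 0.5 * ptv, other = rnorm(30))
  colnames(X) <- names(ptv)
  res <- pseudotime_gene_correlation(X, ptv, n_reps = 10, keep_frac = 2/3)
  expect_equal(res$statistic[res$feature_id == "lin"], 1, tolerance = 1e-12)
  expect_error(pseudotime_gene_correlation(X[, 1:20], ptv[1:10]), "missing")
})

test_that("the null screen is calibrated against the plain-Pearson oracle", {
  n <- 300
  ptv <- pt_fixture(n, seed = 3)
  set.seed(4)
  X <- matrix(rnorm(400 * n), 400, n,
              dimnames = list(sprintf("g%03d", 1:400), names(ptv)))
  res <- pseudotime_gene_correlation(X, ptv, n_reps = 10, keep_frac = 2/3,
                                     seed = 5)
  full_r <- as.numeric(cor(t(X), ptv))
  expect_lt(mean(abs(res$statistic - full_r)), 0.05)
  expect_lte(mean(res$q_fdr < 0.05), 0.07)
  # BH oracle: hand-computed step-up adjustment
  p <- res$p_raw
  bh <- rev(cummin(rev(sort(p) * length(p) / seq_along(p))))[rank(p)]
  expect_equal(res$q_fdr, pmin(1, bh), tolerance = 1e-12)
  # q monotone in p, bounded, and above p
  expect_true(all(res$q_fdr >= res$p_raw - 1e-15))
  expect_true(all(res$q_fdr > 0 & res$q_fdr <= 1))
  expect_equal(res$neg10log10_q, -10 * log10(res$q_fdr))
})

test_that("gene-set z equals the extreme-configuration Wilcoxon oracle", {
  set.seed(6)
  N <- 100; m <- 10
  stats <- setNames(sort(rnorm(N)), sprintf("g%03d", 1:N))
  top <- names(stats)[(N - m + 1):N]      # the m top-ranked genes
  sets <- list(top = top,
               mid = names(stats)[41:60],
               rand = sample(names(stats), 20))
  res <- preranked_gene_set_test(stats, sets, rho = 0)
  # oracle: z of the rank-sum for the most extreme configuration
  W_max <- sum((N - m + 1):N)
  z_oracle <- (W_max - m * (N + 1) / 2) / sqrt(m * (N - m) * (N + 1) / 12)
  expect_equal(res$z[res$set == "top"], z_oracle, tolerance = 1e-12)
  # it is minimal among all same-size sets by construction
  expect_true(res$p_raw[res$set == "top"] <= min(res$p_raw))
  expect_identical(res$direction[res$set == "top"], "Up")
  # rho = 0 reduces the inflation factor to 1: doubling rho must not
  rho_res <- preranked_gene_set_test(stats, sets["top"], rho = 0.05)
  expect_gt(rho_res$p_raw, res$p_raw[res$set == "top"])
})

test_that("random gene sets yield approximately uniform p values", {
  set.seed(7)
  N <- 500
  stats <- setNames(rnorm(N), sprintf("g%04d", 1:N))
  sets <- lapply(1:1000, function(i) sample(names(stats), 25))
  names(sets) <- paste0("set", 1:1000)
  res <- preranked_gene_set_test(stats, sets, rho = 0)
  ks <- suppressWarnings(ks.test(res$p_raw, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("gene-set ranking agrees with the established competitive test", {
  skip_if_not_installed("limma")
  set.seed(8)
  N <- 300
  stats <- setNames(rnorm(N), sprintf("g%03d", 1:N))
  stats[1:30] <- stats[1:30] + 2
  sets <- list(shifted = names(stats)[1:30],
               null1 = names(stats)[31:80],
               null2 = names(stats)[81:130])
  res <- preranked_gene_set_test(stats, sets, rho = 0.01)
  idx <- lapply(sets, function(s) which(names(stats) %in% s))
  cam <- limma::cameraPR(stats, idx, use.ranks = TRUE, inter.gene.cor = 0.01,
                         sort = FALSE)
  # same top set, same directions, p values within an order of magnitude
  expect_identical(res$set[which.min(res$p_raw)], "shifted")
  expect_identical(rownames(cam)[which.min(cam$PValue)], "shifted")
  expect_identical(res$direction[match(rownames(cam), res$set)],
                   as.character(cam$Direction))
  expect_lt(max(abs(log10(res$p_raw[match(rownames(cam), res$set)]) -
                    log10(cam$PValue))), 1)
})

test_that("mutation screen filters recurrence and approximates the exact test", {
  ptv <- pt_fixture(12, seed = 9)
  # 6v6, complete separation, no ties
  mut_sep <- matrix(0L, 2, 12,
                    dimnames = list(c("sep", "five"), names(ptv)))
  mut_sep["sep", 7:12] <- 1L      # mutants hold the 6 highest pseudotimes
  mut_sep["five", 1:5] <- 1L      # only 5 mutated individuals: filtered out
  res <- mutation_association(mut_sep, ptv, min_mutated = 6)
  expect_false("five" %in% res$feature_id)
  # exact two-sided enumeration oracle: 2 / choose(12, 6)
  p_exact <- 2 / choose(12, 6)
  expect_equal(round(p_exact, 5), 0.00216)
  p_norm <- res$p_raw[res$feature_id == "sep"]
  expect_lt(max(p_norm / p_exact, p_exact / p_norm), 2)
})

test_that("mutation screen handles strata and degenerate pseudotime", {
  ptv <- pt_fixture(40, seed = 10)
  set.seed(11)
  mut <- matrix(rbinom(3 * 40, 1, 0.4), 3, 40,
                dimnames = list(c("a", "b", "c"), names(ptv)))
  strata <- setNames(rep(c("early", "late"), each = 20), names(ptv))
  res <- mutation_association(mut, ptv, min_mutated = 3, strata = strata)
  expect_setequal(unique(res$stratum), c("early", "late"))
  # BH applied within stratum
  for (st in c("early", "late")) {
    sub <- res[res$stratum == st, ]
    expect_equal(sub$q_fdr, p.adjust(sub$p_raw, "BH"))
  }
  # constant pseudotime: p = 1 by convention
  flat <- setNames(rep(5, 40), names(ptv))
  res_flat <- mutation_association(mut, flat, min_mutated = 3)
  expect_true(all(res_flat$p_raw == 1))
})

test_that("CNA association matches perfect monotone fixtures and the null", {
  pt5 <- setNames(c(0, 10, 20, 30, 40), paste0("s", 1:5))
  cna <- matrix(c(-2, -1, 0, 1, 2), 1, 5,
                dimnames = list("up", names(pt5)))
  expect_equal(cna_association(cna, pt5)$statistic, 1, tolerance = 1e-12)
  pt_rev <- setNames(rev(pt5), names(pt5))
  expect_equal(cna_association(cna, pt_rev)$statistic, -1, tolerance = 1e-12)
  # constant CNA -> NA, reported
  cna2 <- rbind(cna, flat = rep(0L, 5))
  res <- cna_association(cna2, pt5)
  expect_true(is.na(res$statistic[res$feature_id == "flat"]))
  # null: |r| < 0.1 with high probability at n = 500
  set.seed(12)
  hits <- vapply(1:200, function(i) {
    x <- sample(-2:2, 500, replace = TRUE)
    y <- runif(500)
    abs(cor(x, y)) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.97)
})

test_that("quartile stratification reproduces the printed tier sizes", {
  pt79 <- setNames(runif(79), sprintf("p%02d", 1:79))
  tiers <- stratify_quartiles(pt79)
  expect_equal(unname(table(tiers$tier)), c(20L, 20L, 20L, 19L),
               ignore_attr = TRUE)
  expect_equal(unname(table(stratify_quartiles(setNames(runif(8), letters[1:8]))$tier)),
               rep(2L, 4), ignore_attr = TRUE)
  expect_equal(unname(table(stratify_quartiles(setNames(runif(9), letters[1:9]))$tier)),
               c(3L, 2L, 2L, 2L), ignore_attr = TRUE)
  # tiers follow ascending pseudotime
  expect_true(all(diff(tiers$pseudotime) >= 0))
  expect_error(stratify_quartiles(setNames(runif(3), letters[1:3])), "fewer")
})

test_that("per-patient deduplication keeps the higher-pseudotime sample", {
  pt <- setNames(c(10, 50, 30, 20), paste0("s", 1:4))
  patient <- setNames(c("A", "A", "B", "C"), names(pt))
  tiers <- stratify_quartiles(pt, n_tiers = 3, patient = patient)
  expect_false("s1" %in% tiers$sample_id)   # lower-pseudotime duplicate dropped
  expect_true("s2" %in% tiers$sample_id)
  expect_equal(nrow(tiers), 3L)
})

test_that("log-rank test matches a hand-rolled observed/expected tabulation", {
  # oracle: literal hypergeometric tabulation over distinct event times
  logrank_oracle <- function(time, event, group) {
    groups <- sort(unique(group))
    O <- E <- setNames(numeric(length(groups)), groups)
    V <- 0
    for (tt in sort(unique(time[event == 1]))) {
      at_risk <- time >= tt
      n <- sum(at_risk)
      d <- sum(event == 1 & time == tt)
      for (g in groups) {
        n_g <- sum(at_risk & group == g)
        O[g] <- O[g] + sum(event == 1 & time == tt & group == g)
        E[g] <- E[g] + d * n_g / n
      }
      g1 <- sum(at_risk & group == groups[1])
      if (n > 1) V <- V + d * (g1 / n) * (1 - g1 / n) * (n - d) / (n - 1)
    }
    ((O[1] - E[1])^2) / V
  }
  surv <- data.frame(sample_id = paste0("s", 1:6),
                     time = c(1, 2, 3, 4, 5, 6),
                     event = rep(1L, 6))
  groups <- setNames(rep(c("A", "B"), each = 3), surv$sample_id)
  res <- logrank_test(surv, groups)
  expect_equal(res$chi_square,
               unname(logrank_oracle(surv$time, surv$event, groups)),
               tolerance = 1e-10)
  expect_equal(res$df, 1L)

  # identical groups: chi-square 0, p 1
  surv2 <- data.frame(sample_id = paste0("t", 1:8),
                      time = rep(c(1, 3, 5, 7), 2),
                      event = rep(c(1L, 0L, 1L, 1L), 2))
  g2 <- setNames(rep(c("A", "B"), each = 4), surv2$sample_id)
  res2 <- logrank_test(surv2, g2)
  expect_equal(res2$chi_square, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1, tolerance = 1e-12)

  # a fully censored group contributes no events but keeps df = k - 1
  surv3 <- data.frame(sample_id = paste0("u", 1:6),
                      time = c(1, 2, 3, 0.5, 0.5, 0.5),
                      event = c(1L, 1L, 1L, 0L, 0L, 0L))
  g3 <- setNames(rep(c("A", "B"), each = 3), surv3$sample_id)
  res3 <- logrank_test(surv3, g3)
  expect_equal(res3$df, 1L)
  expect_true(is.finite(res3$chi_square))
  # no events at all -> error
  surv4 <- surv3; surv4$event <- 0L
  expect_error(logrank_test(surv4, g3), "no events")
})

test_that("permuted log-rank p values are approximately uniform", {
  set.seed(13)
  n <- 60
  surv <- data.frame(sample_id = sprintf("s%03d", 1:n),
                     time = rexp(n, 0.1),
                     event = rbinom(n, 1, 0.8))
  p <- vapply(1:2000, function(i) {
    g <- setNames(sample(rep(c("A", "B"), each = n / 2)), surv$sample_id)
    logrank_test(surv, g)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fold-change concordance counts the gene intersection", {
  fc_a <- setNames(rnorm(10), sprintf("g%02d", 1:10))
  expect_equal(fc_concordance(fc_a, fc_a)$r, 1, tolerance = 1e-12)
  expect_equal(fc_concordance(fc_a, -fc_a)$r, -1, tolerance = 1e-12)
  res <- fc_concordance(fc_a, fc_a[1:7])
  expect_identical(res$n_common, 7L)
  expect_error(fc_concordance(fc_a[1:2], fc_a[1:2]), "fewer than 3")
})

test_that("log2 fold changes are group-mean differences on the log scale", {
  X <- toy_counts(1:12, 3, 4)
  fc <- log2_fold_change(X, c("s01", "s02"), c("s03", "s04"))
  expect_equal(unname(fc), rowMeans(X[, 1:2]) - rowMeans(X[, 3:4]),
               ignore_attr = TRUE)
})
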