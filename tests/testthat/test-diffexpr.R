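sim_matrix <- function(n = 200, d0 = 4, s02 = 0.04, n_diff = 0, effect = 0,
                       seed = 1) {
  set.seed(seed)
  s2 <- s02 * d0 / rchisq(n, d0)
  X <- matrix(rnorm(n * 6, 0, sqrt(s2)), n, 6,
              dimnames = list(sprintf("P%03d", 1:n), NULL))
  if (n_diff > 0) X[1:n_diff, 4:6] <- X[1:n_diff, 4:6] + effect
  X
}

test_that("moderated t reduces to the ordinary t when the prior vanishes", {
  X <- sim_matrix(seed = 2)
  mt <- moderated_ttest(X, 1:3, 4:6, prior_df = 0)
  ref_t <- apply(X, 1, function(r)
    unname(t.test(r[4:6], r[1:3], var.equal = TRUE)$statistic))
  expect_equal(mt$t, ref_t, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(mt$df_total, rep(4, nrow(X)))
})

test_that("identical sample variances shrink to themselves", {
  # equal per-protein variance patterns: replicate deviations identical
  dev <- c(-1, 0, 1) * 0.3
  X <- rbind(c(5 + dev, 7 + dev), c(8 + dev, 8.5 + dev),
             c(3 + dev, 2 + dev))
  mt <- moderated_ttest(X, 1:3, 4:6)
  expect_equal(mt$s_tilde, mt$s, tolerance = 1e-12)
  ref_t <- apply(X, 1, function(r)
    unname(t.test(r[4:6], r[1:3], var.equal = TRUE)$statistic))
  expect_equal(mt$t, ref_t, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("moderated statistics agree with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  X <- sim_matrix(n = 400, seed = 5, n_diff = 15, effect = 1.5)
  mt <- moderated_ttest(X, 1:3, 4:6)
  fit <- limma::eBayes(limma::lmFit(X, cbind(1, c(0, 0, 0, 1, 1, 1))))
  expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(mt, "s02"), fit$s2.prior, tolerance = 1e-8)
  expect_equal(mt$t, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(mt$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("hyperparameter estimates recover a known prior on average", {
  d0s <- s02s <- numeric(40)
  for (s in seq_along(d0s)) {
    X <- sim_matrix(n = 500, d0 = 4, s02 = 0.04, seed = 1000 + s)
    mt <- moderated_ttest(X, 1:3, 4:6)
    d0s[s] <- attr(mt, "d0"); s02s[s] <- attr(mt, "s02")
  }
  expect_lt(abs(mean(d0s) - 4) / 4, 0.15)
  expect_lt(abs(mean(s02s) - 0.04) / 0.04, 0.15)
})

test_that("moderated t approaches a z-like statistic as the prior dominates", {
  X <- sim_matrix(seed = 7)
  mt_inf <- moderated_ttest(X, 1:3, 4:6, prior_df = Inf)
  # fixed variance: every protein shares the same s_tilde
  expect_equal(length(unique(round(mt_inf$s_tilde, 12))), 1L)
  expect_true(all(is.infinite(mt_inf$df_total)))
  # continuity: large finite prior df is close to the limit
  mt_big <- moderated_ttest(X, 1:3, 4:6, prior_df = 1e8)
  expect_equal(mt_big$t, mt_inf$t, tolerance = 1e-4)
})

test_that("BH adjustment matches the textbook step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(11)
  p <- runif(1000)
  adj <- bh_adjust(p)
  expect_equal(adj, bh_loop(p))
  # never decreases, preserves order
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("significance curve honors both boundary conditions", {
  pr <- significance_curve_params(curvature = 0.4)
  expect_identical(significance_threshold(1, pr), 0)
  expect_identical(significance_threshold(0.5, pr), 0)
  expect_equal(significance_threshold(50, pr), 0.05, tolerance = 1e-9)
  # a vanishing p-value at exactly |log2fc| = 1 is still not significant
  expect_false(significance_curve(1.0, 1e-9, pr))
  expect_false(significance_curve(0.5, 0.001, pr))
  expect_true(significance_curve(50, 0.049, pr))
  expect_false(significance_curve(50, 0.051, pr))
  # monotone threshold in |log2fc|
  fc <- seq(1, 10, by = 0.1)
  expect_true(all(diff(significance_threshold(fc, pr)) > 0))
  # monotone significance at fixed adjusted p
  sig <- significance_curve(fc, rep(0.03, length(fc)), pr)
  expect_true(all(diff(as.integer(sig)) >= 0))
  expect_error(significance_curve_params(curvature = 0), "positive")
})

test_that("consensus keeps only proteins significant in every cycle", {
  # protein-level geometry of the synthetic study: log2 levels near 23,
  # between-protein spread 2, replicate spread 0.3, MNAR dropout at 19.5
  set.seed(12)
  n <- 400
  X <- matrix(rnorm(n * 6, 0, 0.3), n, 6) + rnorm(n, 23, 2)
  rownames(X) <- sprintf("P%03d", 1:n)
  X[1:5, 4:6] <- X[1:5, 4:6] + 3
  pm <- plogis((19.5 - X) / 0.8)
  X[matrix(runif(n * 6), n, 6) < pm] <- NA
  cs <- consensus_significance(X, 1:3, 4:6, groups = list(1:3, 4:6),
                               n_cycles = 20, seed = 77)
  expect_setequal(cs$significant,
                  names(cs$cycles_significant)[cs$cycles_significant == 20])
  # planted strong effects survive all cycles
  expect_equal(sum(sprintf("P%03d", 1:5) %in% cs$significant), 5)
  # anything else the consensus keeps is MNAR-driven: dropout truncation
  # or downshift imputation on a protein with missing values
  extra <- setdiff(cs$significant, sprintf("P%03d", 1:5))
  mnar <- rownames(X)[rowSums(is.na(X)) > 0]
  expect_true(all(extra %in% mnar))
  # determinism of the whole consensus under the master seed
  cs2 <- consensus_significance(X, 1:3, 4:6, groups = list(1:3, 4:6),
                                n_cycles = 20, seed = 77)
  expect_identical(cs$cycles_significant, cs2$cycles_significant)
})

test_that("null data yields an essentially empty consensus set", {
  # imputation-cycle stochasticity must not manufacture significance: the
  # only calls the consensus may retain on null data are MNAR on-off
  # proteins whose detection asymmetry the downshift rule treats as signal
  empty <- logical(25); worst <- 0; stray <- 0
  for (s in seq_along(empty)) {
    set.seed(3000 + s)
    n <- 300
    X <- matrix(rnorm(n * 6, 0, 0.3), n, 6) + rnorm(n, 23, 2)
    rownames(X) <- sprintf("P%03d", 1:n)
    pm <- plogis((19.5 - X) / 0.8)
    X[matrix(runif(n * 6), n, 6) < pm] <- NA
    cs <- consensus_significance(X, 1:3, 4:6, groups = list(1:3, 4:6),
                                 n_cycles = 20, seed = 3000 + s)
    empty[s] <- length(cs$significant) == 0
    worst <- max(worst, length(cs$significant))
    downshifted <- rownames(X)[rowSums(is.na(X[, 1:3])) >= 2 |
                                 rowSums(is.na(X[, 4:6])) >= 2]
    stray <- stray + sum(!cs$significant %in% downshifted)
  }
  expect_gte(mean(empty), 0.85)
  expect_lte(worst, 3)
  expect_equal(stray, 0)
})

test_that("Welch test matches the textbook formula and conventions", {
  w0 <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  wc <- welch_ttest(c(2, 2, 2), c(2, 2))
  expect_equal(wc$p, 1)                      # zero variance, equal means
  expect_equal(welch_ttest(c(0, 0, 0), c(10, 10, 10.0001))$p, 0,
               tolerance = 1e-6)
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(5 + i %% 4); b <- rnorm(7, 0.5, 2)
    w <- welch_ttest(a, b)
    o <- welch_loop(a, b)
    expect_equal(w$t, o$t, tolerance = 1e-12)
    expect_equal(w$df, o$df, tolerance = 1e-12)
    expect_equal(w$p, o$p, tolerance = 1e-12)
  }
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
})

test_that("Tukey HSD matches a studentized-range oracle", {
  v <- rep(5, 8); g <- rep(c("a", "b", "c", "d"), each = 2)
  tk0 <- tukey_hsd(v, g)
  expect_true(all(tk0$adj_p == 1))
  set.seed(14)
  v2 <- c(rnorm(5, 0, 0.1), rnorm(5, 0.1, 0.1), rnorm(5, 10, 0.1),
          rnorm(5, 0.05, 0.1))
  g2 <- rep(c("a", "b", "c", "d"), each = 5)
  tk2 <- tukey_hsd(v2, g2)
  expect_lt(tk2$adj_p[tk2$pair == "c-a"], 0.001)
  o <- tukey_loop(v2, g2)
  expect_equal(setNames(tk2$adj_p, tk2$pair), o[tk2$pair],
               tolerance = 1e-6)
  expect_error(tukey_hsd(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})
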