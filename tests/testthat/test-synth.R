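small_cfg <- function(...) {
  synth_config(proteome = utils::modifyList(
    synth_config()$proteome,
    utils::modifyList(list(n_donors = 2, n_proteins = 40,
                           peptides_per_protein = 4), list(...))))
}

test_that("generators are fully deterministic under a fixed seed", {
  expect_identical(gen_accel_trace("PTS", seed = 5),
                   gen_accel_trace("PTS", seed = 5))
  expect_identical(gen_size_distribution(seed = 5),
                   gen_size_distribution(seed = 5))
  p1 <- gen_proteome(small_cfg(), seed = 5)
  p2 <- gen_proteome(small_cfg(), seed = 5)
  expect_identical(p1$peptides$intensity, p2$peptides$intensity)
  expect_identical(gen_blood_counts(seed = 5), gen_blood_counts(seed = 5))
  expect_false(identical(gen_blood_counts(seed = 5),
                         gen_blood_counts(seed = 6)))
})

test_that("carrier traces carry the configured gait line", {
  tr <- gen_accel_trace("C", seed = 21)
  gf <- ground_frequency(tr, c(60, 120))
  expect_lt(abs(gf - 4.0), 0.1)
  m <- summarize_transport(tr)
  expect_lt(m$max_amplitude, 2.4)
  expect_gt(m$median_amplitude, 0.05)
  expect_lt(m$median_amplitude, 0.5)
  expect_equal(m$duration, 5.5, tolerance = 0.01)
})

test_that("pneumatic-tube traces produce the expected shock regime", {
  counts <- vapply(1:8, function(s)
    summarize_transport(gen_accel_trace("PTS", seed = s))$shock_count,
    numeric(1))
  expect_lt(abs(mean(counts) - 116), 3 * sqrt(116))
  m <- summarize_transport(gen_accel_trace("PTS", seed = 1))
  expect_gt(m$max_amplitude, 3)
  expect_equal(m$duration, 2.4, tolerance = 0.01)
  # per-axis clipping respected by construction
  tr <- gen_accel_trace("PTS", seed = 2)
  expect_lte(max(abs(c(tr$ax, tr$ay, tr$az))), 16)
})

test_that("zero-amplitude carrier config yields null metrics", {
  cfg <- synth_config(carrier = list(
    duration_min = 1, ground_freq = 4, amp_fund = 0, amp_harm = 0,
    amp_lateral = 0, phase_jitter = 0, noise_sd = 0))
  m <- summarize_transport(gen_accel_trace("C", cfg, seed = 1))
  expect_equal(c(m$tk, m$rms, m$vdv, m$shock_count), c(0, 0, 0, 0))
})

test_that("size-distribution generator hits its configured targets", {
  d <- gen_size_distribution(seed = 1, noise_sd = 0, total = 3e9)
  f <- distribution_features(d)
  expect_equal(f$auc, 3e9, tolerance = 0.01)        # quadrature error only
  expect_lte(abs(f$mode_size - 100), 10)
  # wider-configured group has larger sd in every seed
  wide_wins <- vapply(1:20, function(s) {
    narrow <- distribution_features(
      gen_size_distribution(seed = s, gsd = 1.4))$sd_size
    wide <- distribution_features(
      gen_size_distribution(seed = 1000 + s, gsd = 2.0))$sd_size
    wide > narrow
  }, logical(1))
  expect_true(all(wide_wins))
})

test_that("noise-free proteome flows to constant Top3 and a null test", {
  cfg <- small_cfg(donor_sd = 0, rep_sd = 0, inj_sd = 0,
                   miss_mid = -100, n_diff = 0, n_corr = 0)
  pr <- gen_proteome(cfg, seed = 3, plasma = "PFP")
  expect_false(anyNA(pr$peptides$intensity))
  pm <- sum_injections(pr$peptides)
  # no noise to stabilize: feed plain log2 intensities straight to Top3
  tq <- top3(peptide_matrix(log2(pm$intensity), pm$protein, pm$samples))
  # without any noise the protein profile is identical in every sample
  expect_lt(max(apply(tq$log2, 1, function(r) diff(range(r)))), 1e-9)
  # hence no fold change anywhere, and Welch reports p = 1 by convention
  smp <- tq$samples
  ca <- which(smp$donor == "D01" & smp$transport == "C")
  cb <- which(smp$donor == "D01" & smp$transport == "PTS")
  fc <- rowMeans(tq$log2[, cb]) - rowMeans(tq$log2[, ca])
  expect_true(all(abs(fc) < 1e-9))
  expect_equal(welch_ttest(tq$log2[1, ca], tq$log2[1, cb])$p, 1)
})

test_that("missingness matches the logistic dropout model", {
  pr <- gen_proteome(small_cfg(n_proteins = 150), seed = 9)
  obs_frac <- mean(is.na(pr$peptides$intensity))
  expect_lt(abs(obs_frac - pr$truth$expected_missing), 0.02)
})

test_that("planted differential proteins shift PTS intensities", {
  cfg <- small_cfg(n_proteins = 60, n_diff = 5, diff_effect = 3)
  pr <- gen_proteome(cfg, seed = 4, plasma = "PFP")
  pm <- pr$peptides
  lx <- log2(pm$intensity)
  pts <- pm$samples$transport == "PTS"
  planted <- pm$protein %in% pr$truth$differential
  shift <- mean(lx[planted, pts], na.rm = TRUE) -
    mean(lx[planted, !pts], na.rm = TRUE)
  null_shift <- mean(lx[!planted, pts], na.rm = TRUE) -
    mean(lx[!planted, !pts], na.rm = TRUE)
  # MNAR dropout truncates the low tail, so the realized shift is
  # attenuated; it must still clearly separate from the null background
  expect_gt(shift - null_shift, 1.5)
  expect_lt(abs(null_shift), 0.3)
})

test_that("blood counts stay in range and couple red cells to hemoglobin", {
  cfg <- synth_config()
  for (s in 1:100) {
    b <- gen_blood_counts(cfg, seed = s)
    for (ct in names(cfg$blood$ranges)) {
      expect_true(all(b[[ct]] >= cfg$blood$ranges[[ct]][1] &
                        b[[ct]] <= cfg$blood$ranges[[ct]][2]))
    }
  }
  rho <- vapply(1:20, function(s) {
    b <- gen_blood_counts(cfg, seed = s)
    cor(b$Ec, b$HGB, method = "spearman")
  }, numeric(1))
  expect_gte(mean(rho >= 0.6), 0.95)
})

test_that("a complete synthetic study flows through every pipeline stage", {
  cfg <- synth_config(proteome = utils::modifyList(
    synth_config()$proteome,
    list(n_donors = 4, n_proteins = 60, peptides_per_protein = 4,
         n_diff = 5, n_corr = 5)))
  st <- gen_study(cfg, seed = 8)
  expect_length(st$traces, 8)
  expect_equal(nrow(st$metrics), 8)
  expect_length(st$distributions, 16)

  # particles stage
  feats <- do.call(rbind, lapply(st$distributions, distribution_features))
  expect_false(anyNA(feats$auc))

  # quant stage on PFP only
  pm <- st$proteome$peptides
  keep <- pm$samples$plasma == "PFP"
  pm <- peptide_matrix(pm$intensity[, keep], pm$protein,
                       pm$samples[keep, ])
  pm2 <- sum_injections(pm)
  pmn <- vsn_normalize(pm2, maxit = 12)
  tq <- top3(pmn)
  grp <- with(pmn$samples, paste(donor, transport))
  q <- impute(tq$log2, groups = grp, seed = 13, min_obs = 5)
  expect_false(anyNA(q$log2))

  # differential stage, one donor
  ca <- which(grp == "D01 C"); cb <- which(grp == "D01 PTS")
  cs <- consensus_significance(tq$log2, ca, cb,
                               groups = grp, n_cycles = 5, seed = 21,
                               min_obs = 5)
  expect_gte(length(cs$significant), 0)

  # gene products, metric correlation, ranking
  genes <- st$proteome$annotation$gene_name[
    match(rownames(q$log2), st$proteome$annotation$protein_id)]
  ga <- aggregate_gene_products(q, genes, groups = grp)
  met <- st$proteome$metrics
  mkey <- paste(met$donor, met$transport)
  vdvv <- met$vdv[match(colnames(ga$median_log2), mkey)]
  corr <- lapply(list(vdv = vdvv), function(v) {
    do.call(rbind, lapply(rownames(ga$median_log2), function(g) {
      r <- spearman_thresholded(ga$median_log2[g, ], v)
      data.frame(gene = g, rho = r$rho, p = r$p, recorded = r$recorded)
    }))
  })
  rl <- ranked_list(corr)
  expect_equal(nrow(rl), nrow(ga$median_log2))

  # selection stage
  y <- as.integer(grepl("PTS", colnames(ga$median_log2)))
  tm <- transport_markers(ga$median_log2, y, alpha = 1)
  expect_gte(tm$n_features, 1)
})
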