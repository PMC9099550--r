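toy_pm <- function(x, injections = TRUE) {
  nc <- ncol(x)
  smp <- if (injections)
    data.frame(donor = "D1", replicate = rep(seq_len(nc / 2), each = 2),
               injection = rep(1:2, nc / 2))
  else data.frame(donor = "D1", replicate = seq_len(nc))
  peptide_matrix(x, rep("P1", nrow(x)), smp)
}

test_that("injection summing follows the stated missingness convention", {
  x <- rbind(c(10, 14, NA, 14), c(NA, NA, 3, 5))
  out <- sum_injections(toy_pm(x))
  expect_equal(out$intensity[1, ], c(24, 14), ignore_attr = TRUE)
  expect_true(is.na(out$intensity[2, 1]))
  expect_equal(out$intensity[2, 2], 8, ignore_attr = TRUE)
  expect_equal(ncol(out$intensity), 2)
  odd <- peptide_matrix(x[, 1:3], rep("P1", 2),
                        data.frame(donor = "D1", replicate = c(1, 1, 2),
                                   injection = c(1, 2, 1)))
  expect_error(sum_injections(odd), "unpaired")

  # seeded matrix equals a naive column-pair loop
  set.seed(5)
  m <- matrix(exp(rnorm(200 * 8, 10, 2)), 200, 8)
  m[runif(1600) < 0.3] <- NA
  pm <- toy_pm(m)
  out2 <- sum_injections(pm)$intensity
  for (j in 1:4) {
    a <- m[, 2 * j - 1]; b <- m[, 2 * j]
    ref <- mapply(function(u, v)
      if (is.na(u) && is.na(v)) NA_real_ else sum(u, v, na.rm = TRUE),
      a, b)
    expect_equal(unname(out2[, j]), unname(ref))
  }
})

test_that("glog calibration aligns scale factors and identical samples", {
  set.seed(1)
  x1 <- exp(rnorm(800, 8, 1.5))
  H0 <- vsn_normalize(cbind(x1, x1))
  expect_lt(max(abs(H0[, 1] - H0[, 2])), 1e-9)
  # a pure scale factor is removed completely
  H <- vsn_normalize(cbind(x1, 2 * x1))
  expect_lt(max(abs(H[, 1] - H[, 2])), 1e-6)
  expect_error(vsn_normalize(cbind(x1)), "2 samples")
})

test_that("glog calibration stabilizes additive+multiplicative noise", {
  # additive + multiplicative error model, 2000 peptides, 3 replicates
  set.seed(1)
  mu <- exp(rnorm(2000, 7, 2))
  mk <- function() mu * exp(rnorm(2000, 0, 0.15)) + rnorm(2000, 0, 30)
  Y <- cbind(mk(), mk(), mk())
  Y[Y <= 0] <- 0.1
  H <- vsn_normalize(Y)
  dec <- cut(rank(rowMeans(H)), 10)
  sds <- tapply(H[, 1] - H[, 2], dec, sd)
  # intensity-independent spread: every decile within 25% of the mean SD
  expect_lt(max(abs(sds - mean(sds))) / mean(sds), 0.25)
  sds_raw <- tapply(log2(Y[, 1]) - log2(Y[, 2]), dec, sd)
  expect_gt(max(sds_raw) / min(sds_raw), 3)
})

test_that("Top3 sums the three most intense peptides per sample", {
  x <- log2(matrix(c(10, 5, 3, 1), 4, 1))
  pm <- peptide_matrix(x, rep("P1", 4), data.frame(run = "a"))
  expect_equal(top3(pm)$log2[1, 1], log2(18), ignore_attr = TRUE)

  x2 <- log2(matrix(c(4, 2, NA), 3, 1))
  pm2 <- peptide_matrix(x2, rep("P1", 3), data.frame(run = "a"))
  t2 <- top3(pm2)
  expect_equal(t2$log2[1, 1], log2(6), ignore_attr = TRUE)
  expect_true(t2$sub_top3[1, 1])

  # seeded matrix equals a sort-and-sum oracle per cell
  set.seed(7)
  m <- matrix(rnorm(60 * 4, 20, 2), 60, 4)
  m[runif(240) < 0.25] <- NA
  prot <- rep(sprintf("P%02d", 1:12), each = 5)
  tq <- top3(peptide_matrix(m, prot, data.frame(run = letters[1:4])))
  for (p in unique(prot)) for (s in 1:4) {
    v <- sort(2^m[prot == p, s], decreasing = TRUE)
    v <- v[!is.na(v)]
    ref <- if (!length(v)) NA_real_ else
      log2(sum(v[seq_len(min(3, length(v)))]))
    expect_equal(unname(tq$log2[p, s]), ref)
  }
})

test_that("Top3 is monotone in any contributing peptide", {
  set.seed(8)
  m <- matrix(rnorm(15 * 2, 20, 1), 15, 2)
  prot <- rep(c("A", "B", "C"), each = 5)
  base <- top3(peptide_matrix(m, prot, data.frame(run = 1:2)))$log2
  for (i in c(1, 6, 11)) {
    m2 <- m
    m2[i, 1] <- m2[i, 1] + 2
    up <- top3(peptide_matrix(m2, prot, data.frame(run = 1:2)))$log2
    expect_true(all(up >= base - 1e-12))
  }
})

test_that("imputation branches follow the stated distributions", {
  set.seed(2)
  X <- matrix(rnorm(4000 * 6, 20, 2), 4000, 6)
  X[1:3000, 1:3] <- NA                       # all-missing triplets
  X[3001:3200, 1] <- NA                      # exactly-one-missing rows
  q <- impute(X, groups = list(1:3, 4:6), seed = 11)
  expect_false(anyNA(q$log2))
  # mask conservation and branch bookkeeping
  expect_equal(sum(q$mask != ""), sum(is.na(X)))
  expect_equal(sum(q$mask == "gaussian"), 9000)
  expect_equal(sum(q$mask == "mle"), 200)
  # Monte-Carlo against the stated left-shifted Gaussian
  for (s in 1:3) {
    imp <- q$log2[1:3000, s]
    target_mean <- q$col_mean[s] - 2.5 * q$col_sd[s]
    target_sd <- 0.3 * q$col_sd[s]
    se <- target_sd / sqrt(3000)
    expect_lt(abs(mean(imp) - target_mean), 3 * se)
    expect_lt(abs(sd(imp) - target_sd) / target_sd, 0.05)
  }
  # untouched group stays identical
  expect_equal(q$log2[, 4:6][!is.na(X[, 4:6])], X[, 4:6][!is.na(X[, 4:6])])
  # no-missing input is returned unchanged with an empty mask
  X2 <- matrix(rnorm(60, 20, 2), 20, 3)
  q2 <- impute(X2, groups = list(1:3), seed = 1)
  expect_identical(q2$log2, X2)
  expect_true(all(q2$mask == ""))
})

test_that("single-missing imputation recovers the conditional-mean slope", {
  set.seed(3)
  S <- matrix(0.9, 3, 3); diag(S) <- 1
  Y <- matrix(rnorm(3000 * 3), 3000, 3) %*% chol(S) * 1.5 + 20
  miss <- cbind(sample(3000, 500), sample(1:3, 500, TRUE))
  Ym <- Y; Ym[miss] <- NA
  q <- impute(Ym, groups = list(1:3), seed = 5)
  # conditional mean of an equicorrelated trivariate normal:
  # slope rho/(1+rho) on each observed replicate
  idx <- which(q$mask == "mle", arr.ind = TRUE)
  imp <- q$log2[idx]
  obs <- t(vapply(seq_len(nrow(idx)), function(i)
    q$log2[idx[i, 1], setdiff(1:3, idx[i, 2])], numeric(2)))
  fit <- lm(imp ~ obs)
  expect_lt(max(abs(coef(fit)[2:3] - 0.9 / 1.9)), 0.1 * 0.9 / 1.9)
})

test_that("imputation is deterministic and stays below observed maxima", {
  set.seed(4)
  X <- matrix(rnorm(500 * 6, 20, 2), 500, 6)
  X[runif(3000) < 0.25] <- NA
  # keep >= 10 observed per column (true here); identical seeds agree
  q1 <- impute(X, groups = list(1:3, 4:6), seed = 99)
  q2 <- impute(X, groups = list(1:3, 4:6), seed = 99)
  expect_identical(q1$log2, q2$log2)
  q3 <- impute(X, groups = list(1:3, 4:6), seed = 100)
  expect_false(identical(q1$log2, q3$log2))
  # left-shifted draws essentially never exceed the observed column maximum
  for (s in 1:6) {
    drawn <- q1$log2[q1$mask[, s] == "gaussian", s]
    if (length(drawn))
      expect_lt(max(drawn), max(X[, s], na.rm = TRUE))
  }
  expect_error(impute(X[1:5, ], groups = list(1:3, 4:6), seed = 1),
               "insufficient")
})

test_that("gene-product aggregation sums linearly then takes medians", {
  # two protein groups of one gene, one replicate group
  x <- rbind(log2(c(100, 200, 400)), log2(c(50, 100, 200)))
  rownames(x) <- c("P1", "P2")
  g <- aggregate_gene_products(x, genes = c("G1", "G1"),
                               groups = list(rep = 1:3))
  expect_equal(unname(g$log2_sums["G1", 1]), log2(150))
  expect_equal(unname(g$median_log2["G1", 1]), median(log2(c(150, 300, 600))))
  # replicate medians: log2 values (5, 6, 10) -> 6
  x2 <- matrix(c(5, 6, 10), 1, 3, dimnames = list("P9", NULL))
  g2 <- aggregate_gene_products(x2, "G9", list(rep = 1:3))
  expect_equal(unname(g2$median_log2["G9", 1]), 6)
  # groups without any real detection in the replicate group are excluded
  mask <- matrix(c("", "", "", "gaussian", "gaussian", "gaussian"),
                 2, 3, byrow = TRUE)
  g3 <- aggregate_gene_products(x, c("G1", "G1"), list(rep = 1:3),
                                mask = mask)
  expect_equal(unname(g3$log2_sums["G1", 1]), log2(100))

  # seeded quant equals a group-sum-then-median oracle
  set.seed(6)
  q <- matrix(rnorm(30 * 6, 20, 1), 30, 6,
              dimnames = list(sprintf("P%02d", 1:30), NULL))
  genes <- rep(sprintf("G%02d", 1:10), each = 3)
  ga <- aggregate_gene_products(q, genes, list(a = 1:3, b = 4:6))
  for (gn in unique(genes)) for (k in 1:2) {
    cols <- list(1:3, 4:6)[[k]]
    ref <- median(log2(colSums(2^q[genes == gn, cols, drop = FALSE])))
    expect_equal(unname(ga$median_log2[gn, k]), ref)
  }
})

test_that("subclass intensities are member means with absent members skipped", {
  x <- rbind(A = c(4, 8), B = c(6, 2), C = c(10, 10))
  out <- subclass_intensity(x, list(ab = c("A", "B"), solo = "C"))
  expect_equal(unname(out["ab", ]), c(5, 5))
  expect_equal(unname(out["solo", ]), c(10, 10))
  expect_warning(
    out2 <- subclass_intensity(x, list(ab = c("A", "B"), gone = "Z")),
    "empty subclass")
  expect_equal(rownames(out2), "ab")
  # seeded data equals a direct mean oracle
  set.seed(9)
  y <- matrix(rnorm(40, 20, 2), 10, 4,
              dimnames = list(letters[1:10], NULL))
  mem <- list(m1 = c("a", "c", "f"), m2 = letters[1:10])
  oz <- subclass_intensity(y, mem)
  expect_equal(unname(oz["m1", ]), unname(colMeans(y[c("a", "c", "f"), ])))
  expect_equal(unname(oz["m2", ]), unname(colMeans(y)))
})

test_that("peptide TSV reader parses run metadata and zero-as-missing", {
  f <- tempfile(fileext = ".tsv")
  d <- data.frame(protein_group = c("P1", "P1", "P2"),
                  check.names = FALSE)
  d[["Intensity D01_PFP_C_1_1"]] <- c(100, 0, 50)
  d[["Intensity D01_PFP_C_1_2"]] <- c(120, 80, 0)
  write.table(d, f, sep = "\t", row.names = FALSE, quote = FALSE)
  pm <- read_peptides(f)
  expect_equal(dim(pm$intensity), c(3L, 2L))
  expect_true(is.na(pm$intensity[2, 1]))
  expect_equal(pm$samples$injection, c(1L, 2L))
  expect_equal(pm$samples$donor, c("D01", "D01"))
  unlink(f)
})
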