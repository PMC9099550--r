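# Independent naive-loop oracles used to cross-check the vectorized
# implementations. Deliberately written as plain element-wise loops.

tk_loop <- function(x) {
  s <- 0
  for (n in 2:(length(x) - 1)) s <- s + x[n]^2 - x[n - 1] * x[n + 1]
  s / (length(x) - 2)
}

rms_loop <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  sqrt(s / length(x))
}

vdv_loop <- function(x, dt) {
  s <- 0
  for (v in x) s <- s + v^4 * dt
  s^0.25
}

shocks_loop <- function(x, thr) {
  cnt <- 0L; inside <- FALSE
  for (v in x) {
    if (v > thr && !inside) { cnt <- cnt + 1L; inside <- TRUE }
    if (v <= thr) inside <- FALSE
  }
  cnt
}

# weighted-moment features of a binned distribution, direct summation
features_loop <- function(s, c_) {
  tot <- sum(c_)
  m <- sum(s * c_) / tot
  v <- sum(c_ * (s - m)^2) / tot
  sk <- if (v > 0) (sum(c_ * (s - m)^3) / tot) / v^1.5 else 0
  auc <- 0
  for (i in 2:length(s)) auc <- auc + (s[i] - s[i - 1]) * (c_[i] + c_[i - 1]) / 2
  list(auc = auc, mean = m, sd = sqrt(v), skew = sk,
       mode = s[which.max(c_)])
}

volume_loop <- function(s, c_, dil) {
  tot <- 0
  for (i in seq_along(s)) tot <- tot + c_[i] * 4 / 3 * pi * (s[i] / 2)^3
  tot * dil
}

# textbook BH step-up
bh_loop <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# textbook Welch statistic
welch_loop <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Tukey-Kramer pairwise p via the studentized range distribution
tukey_loop <- function(values, g) {
  g <- factor(g)
  k <- nlevels(g)
  ni <- tapply(values, g, length)
  mi <- tapply(values, g, mean)
  df <- length(values) - k
  mse <- sum((values - ave(values, g))^2) / df
  out <- c()
  lv <- levels(g)
  for (i in 2:k) for (j in 1:(i - 1)) {
    q <- abs(mi[i] - mi[j]) / sqrt(mse / 2 * (1 / ni[i] + 1 / ni[j]))
    out[paste(lv[i], lv[j], sep = "-")] <- 1 - ptukey(q, k, df)
  }
  out
}

# rank-then-Pearson Spearman with t-approximation p (n >= 10, no exact path)
spearman_loop <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * pt(-abs(t), n - 2))
}

# slow proximal-gradient (ISTA) solver of the elastic-net objective
#   (1/2n)||y - b0 - X b||^2 + lambda (alpha |b|_1 + (1-alpha)/2 |b|_2^2)
# X must already be centered/standardized; b0 = mean(y). The gaussian
# response is standardized to unit 1/n variance with lambda rescaled (and
# coefficients scaled back), the convention the penalized least-squares
# fitters use; the L1 path is invariant to it, the ridge term is not.
ista_enet <- function(X, y, alpha, lambda, maxit = 2e5, tol = 1e-13) {
  s <- sqrt(mean((y - mean(y))^2))
  out <- ista_enet_raw(X, y / s, alpha, lambda / s, maxit, tol)
  out$coef <- out$coef * s
  out$intercept <- out$intercept * s
  out
}

ista_enet_raw <- function(X, y, alpha, lambda, maxit = 2e5, tol = 1e-13) {
  n <- nrow(X)
  yc <- y - mean(y)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE,
                 only.values = TRUE)$values) + lambda * (1 - alpha)
  s <- 1 / L
  b <- rep(0, ncol(X))
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(maxit)) {
    grad <- -crossprod(X, yc - X %*% b) / n + lambda * (1 - alpha) * b
    bn <- soft(b - s * grad, s * lambda * alpha)
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn
  }
  list(intercept = mean(y), coef = as.numeric(b))
}

# planted 3-block recorded-rho matrix generator for clustering checks
planted_rho_matrix <- function(n_per = 6, noise = 0.15, seed = 1) {
  set.seed(seed)
  memb <- rep(1:3, each = n_per)
  m <- outer(memb, memb, function(a, b) ifelse(a == b, 0.8, 0))
  m <- m + matrix(rnorm(length(m), 0, noise), nrow(m))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  list(matrix = m, membership = memb)
}
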