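#' Inverse of the trigamma function
#'
#' Newton iteration for `trigamma(x) = y`, `y > 0`; used when matching
#' moments of log sample variances to a scaled-F prior.
#'
#' @param y Positive numeric vector.
#' @return `x` with `trigamma(x) = y` (Inf where `y <= 0`).
#' @keywords internal
trigamma_inverse <- function(y) {
  out <- rep(NA_real_, length(y))
  out[y <= 0] <- Inf
  todo <- which(is.finite(y) & y > 0)
  if (!length(todo)) return(out)
  yv <- y[todo]
  x <- 0.5 + 1 / yv
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / yv) / psigamma(x, deriv = 2)
    x <- x + dif
    x[x <= 0] <- 1e-8
    if (max(abs(dif) / x) < 1e-10) break
  }
  out[todo] <- x
  out
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Fits, per protein, the two-group model on log2 abundances and shrinks the
#' residual variances toward a common prior: the sample variances are
#' modeled as scaled-F distributed around a prior variance `s0^2` with prior
#' degrees of freedom `d0`, both estimated by moment matching on the log
#' sample variances (zero-variance proteins are excluded from the fit). The
#' moderated variance is the precision-weighted combination
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`, the moderated t is
#' `log2fc / (s_tilde * sqrt(1/n1 + 1/n2))`, and p-values use `d + d0`
#' degrees of freedom. `prior_df = 0` reproduces the ordinary t-test;
#' `prior_df = Inf` gives a fixed-variance z-like statistic.
#'
#' @param x Complete numeric log2 matrix (proteins x samples).
#' @param cols_a,cols_b Column indices of the two conditions (e.g. carrier
#'   and pneumatic-tube triplicates). `log2fc` is `mean(b) - mean(a)`.
#' @param prior_df `NULL` to estimate `d0` (default), or a fixed value.
#' @param adjust Apply [bh_adjust()] to the p-values (default TRUE).
#' @return `data.frame` (one row per protein): `log2fc`, `s`, `s_tilde`,
#'   `t`, `p`, `adj_p`, `df_total`; attributes `d0` and `s02`.
#' @export
moderated_ttest <- function(x, cols_a, cols_b, prior_df = NULL,
                            adjust = TRUE) {
  x <- as.matrix(x)
  a <- x[, cols_a, drop = FALSE]
  b <- x[, cols_b, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  d <- n1 + n2 - 2
  if (d <= 0)
    stop("cannot moderate: zero residual degrees of freedom", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("matrix must be complete (impute first)", call. = FALSE)
  ma <- rowMeans(a); mb <- rowMeans(b)
  ss <- (rowSums((a - ma)^2) + rowSums((b - mb)^2)) / d
  fc <- mb - ma
  if (is.null(prior_df)) {
    z <- log(ss[ss > 0])
    if (length(z) < 2)
      stop("cannot moderate: too few proteins with positive variance",
           call. = FALSE)
    evar <- stats::var(z) - trigamma(d / 2)
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
    } else {
      # no excess spread in the sample variances: degenerate prior at their
      # geometric mean (identical variances shrink to themselves)
      d0 <- Inf
      s02 <- exp(mean(z))
    }
  } else {
    d0 <- prior_df
    z <- log(ss[ss > 0])
    s02 <- if (length(z)) exp(mean(z)) else 1
    if (d0 == 0) s02 <- NA_real_
  }
  st2 <- if (is.infinite(d0)) rep(s02, length(ss)) else
    (d0 * s02 + d * ss) / (d0 + d)
  if (!is.null(prior_df) && prior_df == 0) st2 <- ss
  se <- sqrt(st2 * (1 / n1 + 1 / n2))
  tstat <- fc / se
  dftot <- d + d0
  p <- if (is.infinite(dftot)) 2 * stats::pnorm(-abs(tstat)) else
    2 * stats::pt(-abs(tstat), dftot)
  res <- data.frame(log2fc = fc, s = sqrt(ss), s_tilde = sqrt(st2),
                    t = tstat, p = p,
                    row.names = rownames(x))
  res$adj_p <- if (adjust) bh_adjust(p) else p
  res$df_total <- dftot
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Significance-curve parameters
#'
#' The significance rule couples the fold-change and FDR cutoffs: the
#' adjusted-p threshold is 0 at `|log2fc| = fc_min` and rises smoothly
#' (exponential saturation with curvature `c`) to `p_max` for asymptotically
#' large fold changes:
#' `threshold(fc) = p_max * (1 - exp(-(|fc| - fc_min)/c))` for
#' `|fc| > fc_min`, else 0.
#'
#' @param fc_min Fold-change cutoff in log2 units (default 1).
#' @param p_max Asymptotic adjusted-p cutoff (default 0.05).
#' @param curvature Positive curvature scale `c`; conventionally derived
#'   from the overall variance of the tested proteins, see
#'   [curvature_from_stats()].
#' @return Object of class `significance_curve_params`.
#' @export
significance_curve_params <- function(fc_min = 1, p_max = 0.05,
                                      curvature = 0.5) {
  if (!is.numeric(curvature) || curvature <= 0)
    stop("curvature must be positive", call. = FALSE)
  if (fc_min < 0 || p_max <= 0 || p_max > 1)
    stop("invalid fc_min or p_max", call. = FALSE)
  structure(list(fc_min = fc_min, p_max = p_max, curvature = curvature),
            class = "significance_curve_params")
}

#' Curvature from the overall variance of a test result
#'
#' The curve's transition scale is the median moderated SD across tested
#' proteins, so noisier datasets demand larger fold changes before the
#' adjusted-p threshold approaches its asymptote.
#'
#' @param stats A [moderated_ttest()] result.
#' @inheritParams significance_curve_params
#' @return A [significance_curve_params()].
#' @export
curvature_from_stats <- function(stats, fc_min = 1, p_max = 0.05) {
  cc <- stats::median(stats$s_tilde, na.rm = TRUE)
  if (!is.finite(cc) || cc <= 0) cc <- 0.5
  significance_curve_params(fc_min, p_max, cc)
}

#' Adjusted-p threshold of the significance curve
#'
#' @param log2fc Numeric log2 fold changes.
#' @param params A [significance_curve_params()].
#' @return Threshold values (0 where `|log2fc| <= fc_min`).
#' @export
significance_threshold <- function(log2fc, params) {
  stopifnot(inherits(params, "significance_curve_params"))
  afc <- abs(log2fc)
  ifelse(afc <= params$fc_min, 0,
         params$p_max * (1 - exp(-(afc - params$fc_min) /
                                   params$curvature)))
}

#' Fold-change-dependent significance call
#'
#' Significant iff `|log2fc| > fc_min` and the adjusted p-value lies at or
#' below the curve threshold (see [significance_threshold()]).
#'
#' @param log2fc Numeric log2 fold changes.
#' @param adj_p Adjusted p-values.
#' @param params A [significance_curve_params()].
#' @return Logical vector.
#' @export
significance_curve <- function(log2fc, adj_p, params) {
  abs(log2fc) > params$fc_min &
    adj_p <= significance_threshold(log2fc, params)
}

#' Consensus significance over repeated imputation
#'
#' Because imputation is stochastic, the impute / test / adjust / curve
#' pipeline is repeated `n_cycles` times with independent seeds, and only
#' proteins reported significant in every cycle are accepted.
#'
#' @param x Protein-by-sample log2 matrix with `NA`s (pre-imputation).
#' @param cols_a,cols_b Column indices of the two conditions.
#' @param groups Replicate-triplet column groups for [impute()].
#' @param n_cycles Number of imputation cycles (default 20).
#' @param seed Master seed; per-cycle seeds are derived from it.
#' @param params `NULL` (default) refits the curve per cycle via
#'   [curvature_from_stats()], or a fixed [significance_curve_params()].
#' @param ... Further arguments to [impute()].
#' @return List: `significant` (row names / indices significant in all
#'   cycles), `cycles_significant` (per-protein count), `n_cycles`,
#'   `per_cycle` (list of per-cycle significant sets), `stats` (result of
#'   the last cycle's test).
#' @export
consensus_significance <- function(x, cols_a, cols_b, groups,
                                   n_cycles = 20, seed,
                                   params = NULL, ...) {
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  x <- as.matrix(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  set.seed(as.integer(seed %% .Machine$integer.max))
  cycle_seeds <- sample.int(2^30, n_cycles)
  count <- stats::setNames(rep(0L, nrow(x)), ids)
  per_cycle <- vector("list", n_cycles)
  st <- NULL
  for (cy in seq_len(n_cycles)) {
    sig <- tryCatch({
      q <- impute(x, groups, seed = cycle_seeds[cy], ...)
      st <- moderated_ttest(q$log2, cols_a, cols_b)
      pr <- if (is.null(params)) curvature_from_stats(st) else params
      significance_curve(st$log2fc, st$adj_p, pr)
    }, error = function(e)
      stop("consensus cycle ", cy, " failed: ", conditionMessage(e),
           call. = FALSE))
    count <- count + sig
    per_cycle[[cy]] <- ids[sig]
  }
  list(significant = ids[count == n_cycles], cycles_significant = count,
       n_cycles = n_cycles, per_cycle = per_cycle, stats = st)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Satterthwaite degrees of freedom. When both
#' groups are constant: equal constants give `t = 0, p = 1` by convention;
#' different constants give an infinite statistic and `p = 0`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return Named list: `t`, `df`, `p`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = Inf, p = 1))
    return(list(t = sign(mean(b) - mean(a)) * Inf, df = Inf, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' One-way ANOVA followed by studentized-range pairwise tests; the standard
#' post-hoc for four-group plasma-type/transport panels (significance
#' typically read at p <= 0.01).
#'
#' @param values Numeric response vector.
#' @param group Group labels (coerced to factor), >= 2 groups, each n >= 2.
#' @return `data.frame` with columns `pair`, `diff`, `lwr`, `upr`, `adj_p`.
#' @export
tukey_hsd <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  fit <- stats::aov(values ~ group)
  tk <- stats::TukeyHSD(fit)$group
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    adj_p = tk[, "p adj"], row.names = NULL)
  # all-identical groups yield 0/0 statistics; report p = 1 by convention
  out$adj_p[is.nan(out$adj_p)] <- 1
  out
}
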