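#' Construct a peptide intensity matrix
#'
#' Rows are peptides, columns are mass-spectrometry runs. Missing peptide
#' observations are `NA`; observed intensities must be positive. Each peptide
#' maps to exactly one protein group, and column metadata identifies the
#' donor, plasma type, transport mode, technical replicate and injection of
#' every run.
#'
#' @param intensity Numeric matrix (peptides x runs), `NA` for missing.
#' @param protein Character vector of protein-group ids, one per row.
#' @param samples `data.frame` with one row per column of `intensity`;
#'   typically columns `donor`, `plasma`, `transport`, `replicate`,
#'   `injection`.
#' @return An object of class `peptide_matrix`.
#' @export
peptide_matrix <- function(intensity, protein, samples) {
  intensity <- as.matrix(intensity)
  if (length(protein) != nrow(intensity))
    stop("one protein-group id per peptide row required", call. = FALSE)
  if (nrow(samples) != ncol(intensity))
    stop("sample metadata must have one row per intensity column",
         call. = FALSE)
  if (any(intensity[!is.na(intensity)] < 0))
    stop("intensities must be non-negative", call. = FALSE)
  structure(list(intensity = intensity, protein = as.character(protein),
                 samples = as.data.frame(samples)),
            class = "peptide_matrix")
}

#' @export
print.peptide_matrix <- function(x, ...) {
  cat(sprintf("peptide_matrix: %d peptides x %d runs, %d protein groups, %.1f%% missing\n",
              nrow(x$intensity), ncol(x$intensity),
              length(unique(x$protein)),
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' Read a peptide table
#'
#' Tab-separated peptide report dialect: a protein-group id column (named
#' `protein_group`, `Proteins`, or `Leading.razor.protein`) and one intensity
#' column per run, named `Intensity <run>`. Zero intensities are treated as
#' missing, following the convention of peptide reports from search engines.
#'
#' @param path TSV path.
#' @param samples Optional run metadata `data.frame` (one row per intensity
#'   column, in column order). When absent, run names are parsed from
#'   `<donor>_<plasma>_<transport>_<replicate>_<injection>` column suffixes.
#' @return A [peptide_matrix()].
#' @export
read_peptides <- function(path, samples = NULL) {
  d <- utils::read.delim(path, check.names = TRUE)
  pcol <- intersect(c("protein_group", "Proteins", "Leading.razor.protein"),
                    names(d))[1]
  if (is.na(pcol))
    stop("no protein-group id column found", call. = FALSE)
  icols <- grep("^Intensity\\.", names(d), value = TRUE)
  if (!length(icols))
    stop("no 'Intensity <run>' columns found", call. = FALSE)
  m <- as.matrix(d[, icols, drop = FALSE])
  m[m == 0] <- NA
  run <- sub("^Intensity\\.", "", icols)
  if (is.null(samples)) {
    parts <- strsplit(run, "_", fixed = TRUE)
    if (all(lengths(parts) == 5L)) {
      samples <- data.frame(
        donor = vapply(parts, `[`, "", 1L),
        plasma = vapply(parts, `[`, "", 2L),
        transport = vapply(parts, `[`, "", 3L),
        replicate = as.integer(vapply(parts, `[`, "", 4L)),
        injection = as.integer(vapply(parts, `[`, "", 5L)))
    } else {
      samples <- data.frame(run = run)
    }
  }
  colnames(m) <- run
  peptide_matrix(m, d[[pcol]], samples)
}

#' Sum paired injections
#'
#' The two injections (mass-spectrometry replicates) of every digest are
#' summed into one run. A missing value is treated as 0 when its partner
#' injection was observed; when both injections are missing the sum stays
#' missing. Column count is halved and the `injection` metadata column is
#' dropped.
#'
#' @param pm A [peptide_matrix()] whose `samples` include an `injection`
#'   column and pairing metadata (all non-injection columns).
#' @return A [peptide_matrix()] with one column per digest.
#' @export
sum_injections <- function(pm) {
  stopifnot(inherits(pm, "peptide_matrix"))
  smp <- pm$samples
  if (is.null(smp$injection))
    stop("injection metadata missing", call. = FALSE)
  keycols <- setdiff(names(smp), "injection")
  key <- do.call(paste, c(smp[keycols], sep = "\r"))
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  if (any(lengths(groups) != 2L))
    stop("unpaired injection: every digest needs exactly 2 injections",
         call. = FALSE)
  first <- vapply(groups, `[`, integer(1), 1L)
  out <- vapply(groups, function(ix) {
    a <- pm$intensity[, ix[1]]; b <- pm$intensity[, ix[2]]
    s <- ifelse(is.na(a), 0, a) + ifelse(is.na(b), 0, b)
    s[is.na(a) & is.na(b)] <- NA
    s
  }, numeric(nrow(pm$intensity)))
  dimnames(out) <- list(rownames(pm$intensity),
                        do.call(paste, c(smp[first, keycols, drop = FALSE],
                                         sep = "_")))
  peptide_matrix(out, pm$protein, smp[first, keycols, drop = FALSE])
}

# glog2 transform h(x) = log2(z + sqrt(z^2 + 1)), z = (x - a)/b,
# and its derivative with respect to x.
.glog2 <- function(x, a, b) asinh((x - a) / b) / log(2)
.glog2_deriv <- function(x, a, b) {
  z <- (x - a) / b
  1 / (b * sqrt(z^2 + 1) * log(2))
}

#' Variance-stabilizing glog2 normalization
#'
#' Fits one affine-then-arsinh transform per sample,
#' `h_s(x) = glog2((x - a_s)/b_s)`, by maximum profile likelihood under the
#' model that every transformed peptide equals a peptide-specific level plus
#' Gaussian noise of constant variance. The criterion balances residual
#' spread against the Jacobian of the transform, which is what makes the
#' replicate spread intensity-independent (the classical additive +
#' multiplicative error model). Asymptotically
#' `h(x2) - h(x1) -> log2(x2/x1)`, so downstream differences read as log2
#' fold changes.
#'
#' Optimization is block-coordinate: per-sample `(a_s, log b_s)` by BFGS with
#' analytic gradients against the current reference profile, alternated with
#' reference/variance updates, until the profile likelihood stabilizes.
#'
#' @param x A [peptide_matrix()] or a numeric matrix (features x samples,
#'   `NA` missing, observed values positive).
#' @param maxit Outer block-coordinate iterations (default 50).
#' @param tol Relative profile-likelihood tolerance (default 1e-10).
#' @return Same shape as the input, with intensities on the glog2 scale;
#'   attribute `vsn_params` holds the fitted per-sample `a`, `b`.
#' @export
vsn_normalize <- function(x, maxit = 50, tol = 1e-10) {
  pm <- NULL
  if (inherits(x, "peptide_matrix")) { pm <- x; x <- pm$intensity }
  x <- as.matrix(x)
  S <- ncol(x)
  if (S < 2L) stop("normalization needs at least 2 samples", call. = FALSE)
  if (any(x[!is.na(x)] <= 0))
    stop("observed intensities must be positive", call. = FALSE)
  obs <- !is.na(x)
  nobs <- sum(obs)
  # init: no offset, scale from a low quantile so the linear region covers
  # the noise floor
  a <- rep(0, S)
  lb <- log(pmax(apply(x, 2, stats::quantile, 0.1, na.rm = TRUE), 1e-8))
  H <- matrix(NA_real_, nrow(x), S)
  for (s in seq_len(S)) H[, s] <- .glog2(x[, s], a[s], exp(lb[s]))
  nll_old <- Inf
  for (it in seq_len(maxit)) {
    mu <- rowMeans(H, na.rm = TRUE)
    R <- H - mu
    rss <- sum(R[obs]^2)
    sigma2 <- max(rss / nobs, 1e-300)
    for (s in seq_len(S)) {
      xs <- x[obs[, s], s]
      mus <- mu[obs[, s]]
      fn <- function(p) {
        b <- exp(p[2])
        h <- .glog2(xs, p[1], b)
        z <- (xs - p[1]) / b
        sum((h - mus)^2) / (2 * sigma2) -
          sum(-p[2] - 0.5 * log(z^2 + 1) - log(log(2)))
      }
      gr <- function(p) {
        b <- exp(p[2])
        z <- (xs - p[1]) / b
        h <- asinh(z) / log(2)
        r <- h - mus
        dh_da <- -1 / (b * sqrt(z^2 + 1) * log(2))
        dh_dlb <- -z / (sqrt(z^2 + 1) * log(2))
        dlj_da <- z / (b * (z^2 + 1))     # d log h' / da
        dlj_dlb <- -1 / (z^2 + 1)          # d log h' / d log b
        c(sum(r * dh_da) / sigma2 - sum(dlj_da),
          sum(r * dh_dlb) / sigma2 - sum(dlj_dlb))
      }
      o <- stats::optim(c(a[s], lb[s]), fn, gr, method = "BFGS",
                        control = list(maxit = 40))
      a[s] <- o$par[1]; lb[s] <- o$par[2]
      H[, s] <- .glog2(x[, s], a[s], exp(lb[s]))
    }
    mu <- rowMeans(H, na.rm = TRUE)
    rss <- sum((H - mu)[obs]^2)
    nll <- nobs / 2 * log(max(rss, 1e-300)) +
      sum(lb * colSums(obs)) +
      sum(0.5 * log(((x - rep(a, each = nrow(x))) /
                       rep(exp(lb), each = nrow(x)))^2 + 1)[obs])
    if (is.finite(nll_old) && abs(nll_old - nll) <
        tol * (abs(nll_old) + 1)) break
    if (nll > nll_old + 1e-6 * (abs(nll_old) + 1))
      break  # profile likelihood stalled; keep best-so-far parameters
    nll_old <- nll
  }
  if (any(!is.finite(exp(lb))) || any(exp(lb) <= 0))
    stop("glog calibration failed: non-positive scale estimate (b) for ",
         "sample(s) ", paste(which(exp(lb) <= 0), collapse = ", "),
         call. = FALSE)
  dimnames(H) <- dimnames(x)
  attr(H, "vsn_params") <- data.frame(a = a, b = exp(lb))
  if (!is.null(pm)) {
    out <- peptide_matrix(H, pm$protein, pm$samples)
    attr(out, "vsn_params") <- attr(H, "vsn_params")
    return(out)
  }
  H
}

#' Top3 protein quantification
#'
#' Per sample and protein group: back-transform the normalized peptide
#' values to the linear scale, sum the three most intense observed peptides
#' (all of them when fewer than 3 are observed -- flagged `sub_top3`), and
#' return the log2 of the sum. A protein with no observed peptide in a
#' sample stays missing there.
#'
#' @param pm A glog2-normalized [peptide_matrix()] (see [vsn_normalize()]).
#' @return List of class `top3_quant`: `log2` (protein x sample matrix),
#'   `n_used` (peptides summed), `sub_top3` (logical matrix), `samples`.
#' @export
top3 <- function(pm) {
  stopifnot(inherits(pm, "peptide_matrix"))
  prots <- unique(pm$protein)
  groups <- split(seq_along(pm$protein), factor(pm$protein, levels = prots))
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    warning("protein group(s) without mapped peptides excluded: ",
            paste(prots[empty], collapse = ", "))
    groups <- groups[!empty]; prots <- prots[!empty]
  }
  S <- ncol(pm$intensity)
  lin <- 2^pm$intensity
  out <- matrix(NA_real_, length(prots), S,
                dimnames = list(prots, colnames(pm$intensity)))
  nuse <- matrix(0L, length(prots), S, dimnames = dimnames(out))
  for (g in seq_along(groups)) {
    sub <- lin[groups[[g]], , drop = FALSE]
    for (s in seq_len(S)) {
      v <- sub[, s]
      v <- v[!is.na(v)]
      if (!length(v)) next
      k <- min(3L, length(v))
      out[g, s] <- log2(sum(sort(v, decreasing = TRUE)[seq_len(k)]))
      nuse[g, s] <- length(v)
    }
  }
  structure(list(log2 = out, n_used = nuse, sub_top3 = nuse > 0 & nuse < 3,
                 samples = pm$samples),
            class = "top3_quant")
}

# EM fit of a multivariate normal to rows with missing entries.
# y: n x k matrix with NA; returns list(mu, sigma).
.em_mvnorm <- function(y, maxit = 100, tol = 1e-8) {
  k <- ncol(y)
  use <- rowSums(!is.na(y)) > 0L
  y <- y[use, , drop = FALSE]
  n <- nrow(y)
  mu <- colMeans(y, na.rm = TRUE)
  sigma <- stats::cov(y, use = "pairwise.complete.obs")
  sigma[is.na(sigma)] <- 0
  diag(sigma)[diag(sigma) <= 0 | is.na(diag(sigma))] <-
    max(diag(sigma), 1e-4, na.rm = TRUE)
  # ensure positive definite start
  sigma <- sigma + diag(1e-6, k)
  pat <- apply(!is.na(y), 1, function(r) paste(as.integer(r), collapse = ""))
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    sum_y <- rep(0, k); sum_yy <- matrix(0, k, k); ll <- 0
    for (p in unique(pat)) {
      rows <- which(pat == p)
      o <- which(strsplit(p, "", fixed = TRUE)[[1]] == "1")
      m <- setdiff(seq_len(k), o)
      yo <- y[rows, o, drop = FALSE]
      if (length(m) == 0L) {
        sum_y <- sum_y + colSums(yo)
        sum_yy <- sum_yy + crossprod(yo)
        ll <- ll + sum(.dmvnorm_log(yo, mu, sigma))
        next
      }
      soo <- sigma[o, o, drop = FALSE]
      smo <- sigma[m, o, drop = FALSE]
      smm <- sigma[m, m, drop = FALSE]
      soo_inv <- solve(soo)
      cond_cov <- smm - smo %*% soo_inv %*% t(smo)
      dev <- sweep(yo, 2, mu[o])
      cond_mean <- matrix(mu[m], nrow(yo), length(m), byrow = TRUE) +
        dev %*% t(smo %*% soo_inv)
      full <- matrix(0, nrow(yo), k)
      full[, o] <- yo
      full[, m] <- cond_mean
      sum_y <- sum_y + colSums(full)
      cp <- crossprod(full)
      cp[m, m] <- cp[m, m, drop = FALSE] + nrow(yo) * cond_cov
      sum_yy <- sum_yy + cp
      ll <- ll + sum(.dmvnorm_log(yo, mu[o], soo))
    }
    mu_new <- sum_y / n
    sigma_new <- sum_yy / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2 + diag(1e-10, k)
    mu <- mu_new; sigma <- sigma_new
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma)
}

.dmvnorm_log <- function(y, mu, sigma) {
  k <- length(mu)
  ch <- chol(sigma)
  dev <- sweep(as.matrix(y), 2, mu)
  q <- colSums(backsolve(ch, t(dev), transpose = TRUE)^2)
  -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

#' Impute missing protein abundances (two-branch MNAR rule)
#'
#' Operates on a log2 abundance matrix with replicate-triplet column groups.
#' For each protein and group of three technical replicates:
#' \itemize{
#'   \item 2 or 3 missing values: the protein is treated as below the
#'     detection limit and each missing cell is drawn independently from a
#'     left-shifted Gaussian
#'     `Normal(col_mean - 2.5 * col_sd, (0.3 * col_sd)^2)`, where `col_mean`
#'     and `col_sd` are the observed-value mean and SD of that sample
#'     column.
#'   \item exactly 1 missing value: the value is plausibly missing at
#'     random, and is replaced by its conditional mean under a trivariate
#'     Gaussian across the replicate columns fitted by
#'     expectation-maximization (maximum-likelihood estimation).
#' }
#' The mask records which branch produced every imputed cell, and the whole
#' procedure is deterministic given `seed`.
#'
#' @param x Numeric protein (or peptide) by sample log2 matrix with `NA`s.
#' @param groups List of integer column triplets (technical replicates), or
#'   a factor/vector of group labels over columns.
#' @param seed Integer seed controlling the stochastic branch.
#' @param min_obs Minimum observed values per column for moment estimation
#'   (default 10).
#' @param em_maxit,em_tol EM iteration cap and log-likelihood tolerance.
#' @return Object of class `protein_quant`: list with `log2` (complete
#'   matrix), `mask` (character matrix, `""`, `"gaussian"` or `"mle"`), and
#'   the per-column `col_mean`, `col_sd` used by the stochastic branch.
#' @export
impute <- function(x, groups, seed, min_obs = 10,
                   em_maxit = 100, em_tol = 1e-8) {
  x <- as.matrix(x)
  if (!is.list(groups)) {
    f <- factor(groups, levels = unique(groups))
    groups <- split(seq_len(ncol(x)), f)
  }
  if (any(lengths(groups) != 3L))
    stop("replicate groups must be triplets of columns", call. = FALSE)
  if (length(unlist(groups)) != ncol(x) ||
      anyDuplicated(unlist(groups)))
    stop("groups must partition the columns", call. = FALSE)
  if (missing(seed)) stop("an imputation seed is required", call. = FALSE)
  nob <- colSums(!is.na(x))
  if (any(nob < min_obs))
    stop("insufficient data for moment estimation: column(s) ",
         paste(which(nob < min_obs), collapse = ", "),
         " have fewer than ", min_obs, " observed values", call. = FALSE)
  col_mean <- colMeans(x, na.rm = TRUE)
  col_sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  out <- x
  mask <- matrix("", nrow(x), ncol(x), dimnames = dimnames(x))
  set.seed(as.integer(seed %% .Machine$integer.max))
  for (g in groups) {
    miss <- is.na(x[, g, drop = FALSE])
    nmiss <- rowSums(miss)
    # left-shifted Gaussian branch (>= 2 missing in the triplet)
    rows2 <- which(nmiss >= 2L)
    for (i in rows2) {
      for (j in which(miss[i, ])) {
        s <- g[j]
        out[i, s] <- stats::rnorm(1, col_mean[s] - 2.5 * col_sd[s],
                                  0.3 * col_sd[s])
        mask[i, s] <- "gaussian"
      }
    }
    # conditional-mean (EM / MLE) branch (exactly 1 missing)
    rows1 <- which(nmiss == 1L)
    if (length(rows1)) {
      fit <- .em_mvnorm(x[, g, drop = FALSE], maxit = em_maxit,
                        tol = em_tol)
      for (i in rows1) {
        m <- which(miss[i, ])
        o <- setdiff(seq_along(g), m)
        smo <- fit$sigma[m, o, drop = FALSE]
        soo <- fit$sigma[o, o, drop = FALSE]
        out[i, g[m]] <- fit$mu[m] +
          smo %*% solve(soo, x[i, g[o]] - fit$mu[o])
        mask[i, g[m]] <- "mle"
      }
    }
  }
  structure(list(log2 = out, mask = mask, col_mean = col_mean,
                 col_sd = col_sd, seed = seed),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("protein_quant: %d x %d, %d imputed (%d gaussian, %d mle)\n",
              nrow(x$log2), ncol(x$log2), sum(x$mask != ""),
              sum(x$mask == "gaussian"), sum(x$mask == "mle")))
  invisible(x)
}

#' Collapse protein groups to gene products
#'
#' Protein groups annotated with the same gene name are summed on the linear
#' scale, per sample, excluding groups with no (pre-imputation) detection in
#' that replicate group; the per-donor/transport value is then the median
#' over the three technical replicates of the log2 sums.
#'
#' @param quant A [impute()] result (`protein_quant`), or a complete log2
#'   matrix (in which case `mask` may be given separately).
#' @param genes Character vector of gene names, one per protein row.
#' @param groups List (or label vector) of replicate-triplet column groups,
#'   as for [impute()].
#' @param mask Optional character/logical matrix marking imputed cells when
#'   `quant` is a plain matrix.
#' @return List of class `gene_product_matrix`: `median_log2` (gene x group
#'   matrix), `log2_sums` (gene x sample matrix).
#' @export
aggregate_gene_products <- function(quant, genes, groups, mask = NULL) {
  if (inherits(quant, "protein_quant")) {
    mask <- quant$mask != ""
    x <- quant$log2
  } else {
    x <- as.matrix(quant)
    mask <- if (is.null(mask)) matrix(FALSE, nrow(x), ncol(x))
            else mask != "" & mask != "FALSE"
  }
  if (!is.list(groups)) {
    f <- factor(groups, levels = unique(groups))
    groups <- split(seq_len(ncol(x)), f)
  }
  gnames <- unique(genes)
  gidx <- split(seq_along(genes), factor(genes, levels = gnames))
  sums <- matrix(NA_real_, length(gnames), ncol(x),
                 dimnames = list(gnames, colnames(x)))
  med <- matrix(NA_real_, length(gnames), length(groups),
                dimnames = list(gnames, names(groups)))
  lin <- 2^x
  for (gi in seq_along(gidx)) {
    rows <- gidx[[gi]]
    for (k in seq_along(groups)) {
      cols <- groups[[k]]
      # protein groups need >= 1 real detection within the replicate group
      keep <- rows[rowSums(!mask[rows, cols, drop = FALSE]) > 0L]
      if (!length(keep)) next
      s <- colSums(lin[keep, cols, drop = FALSE])
      sums[gi, cols] <- log2(s)
      med[gi, k] <- stats::median(log2(s))
    }
  }
  structure(list(median_log2 = med, log2_sums = sums),
            class = "gene_product_matrix")
}

#' Representative subclass intensities
#'
#' The representative intensity of a protein subclass (e.g. apolipoproteins,
#' platelet markers) in a sample is the arithmetic mean of the log2
#' abundances of its member rows, skipping members absent from the matrix or
#' missing in that sample. Empty subclasses are dropped with a warning.
#'
#' @param x Numeric log2 matrix (rows named by gene/protein) or a
#'   `gene_product_matrix` (its `median_log2` is used).
#' @param membership Named list: subclass -> member row names.
#' @return Matrix, one row per non-empty subclass.
#' @export
subclass_intensity <- function(x, membership) {
  if (inherits(x, "gene_product_matrix")) x <- x$median_log2
  x <- as.matrix(x)
  present <- lapply(membership, intersect, rownames(x))
  empty <- lengths(present) == 0L
  if (any(empty)) {
    warning("empty subclass(es) excluded: ",
            paste(names(membership)[empty], collapse = ", "))
    present <- present[!empty]
  }
  if (!length(present))
    stop("no subclass has any member in the matrix", call. = FALSE)
  t(vapply(present,
           function(m) colMeans(x[m, , drop = FALSE], na.rm = TRUE),
           numeric(ncol(x))))
}
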