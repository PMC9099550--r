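#' Complete-case gene-product matrix
#'
#' Feature selection uses only gene products quantified everywhere: rows
#' (gene products) with any missing entry are removed.
#'
#' @param x Gene-product by observation numeric matrix (may contain `NA`).
#' @return The matrix restricted to complete rows; attribute `n_retained`
#'   and `n_removed`.
#' @export
complete_case_filter <- function(x) {
  x <- as.matrix(x)
  keep <- rowSums(is.na(x)) == 0L
  if (!any(keep))
    stop("no complete-case rows survive the filter", call. = FALSE)
  out <- x[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

# log-spaced penalty path from lambda_max (all-zero solution) downward
.lambda_path <- function(X, y, alpha, nlambda = 100, min_ratio = 0.001) {
  tx <- t(X)
  n <- nrow(tx)
  sds <- sqrt(colMeans(sweep(tx, 2, colMeans(tx))^2))  # 1/n scaling
  sds[sds == 0] <- 1
  xs <- sweep(sweep(tx, 2, colMeans(tx)), 2, sds, "/")
  lmax <- max(abs(crossprod(xs, y - mean(y)))) / (n * max(alpha, 1e-3))
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' Penalized linear transport classifier (Lasso / elastic net)
#'
#' Fits the elastic-net penalized least-squares model of the 0/1 transport
#' label (0 = carrier, 1 = pneumatic tube) on standardized gene-product
#' intensities, by cyclic coordinate descent (via glmnet):
#' `(1/2n) sum (y - b0 - Xb)^2 + lambda (alpha |b|_1 + (1-alpha)/2 |b|_2^2)`.
#' `alpha = 1` is the pure Lasso (shortest selection), `alpha = 0.5` the
#' elastic net (retains groups of correlated features). Features are
#' standardized internally; coefficients are returned on the original
#' scale. At `lambda >= lambda_max` all coefficients are exactly zero.
#'
#' @param x Gene-product by observation matrix, no missing values (see
#'   [complete_case_filter()]).
#' @param y 0/1 labels, one per observation.
#' @param alpha Elastic-net mixing in (0, 1]; 1 = Lasso.
#' @param lambda Optional penalty value(s); default: a 100-point log-spaced
#'   path from `lambda_max` down to `0.001 * lambda_max`.
#' @return Object of class `lasso_fit`: `alpha`, `lambda` (path, decreasing),
#'   `intercept` and `coef` (feature x lambda matrix), `glmnet` (the
#'   underlying fit), `features`.
#' @export
elastic_net_fit <- function(x, y, alpha = 1, lambda = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("x must be complete; run complete_case_filter first",
                     call. = FALSE)
  if (alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  if (length(y) != ncol(x))
    stop("one label per observation column required", call. = FALSE)
  path <- .lambda_path(x, y, alpha)
  if (!is.null(lambda)) path <- rev(sort(unique(c(path, lambda))))
  fit <- glmnet::glmnet(t(x), y, family = "gaussian", alpha = alpha,
                        lambda = path, standardize = TRUE,
                        thresh = 1e-10, maxit = 1e5)
  cf <- as.matrix(fit$beta)
  rownames(cf) <- rownames(x)
  structure(list(alpha = alpha, lambda = fit$lambda,
                 intercept = as.numeric(fit$a0), coef = cf,
                 glmnet = fit, features = rownames(x)),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("lasso_fit: alpha %.2f, %d lambdas, %d features\n",
              x$alpha, length(x$lambda), nrow(x$coef)))
  invisible(x)
}

#' Coefficients at a penalty value
#'
#' @param fit A [elastic_net_fit()] result.
#' @param lambda Penalty value (nearest path point is used).
#' @return Named list `intercept`, `coef` (named vector).
#' @export
coef_at <- function(fit, lambda) {
  stopifnot(inherits(fit, "lasso_fit"))
  i <- which.min(abs(fit$lambda - lambda))
  list(intercept = fit$intercept[i], coef = fit$coef[, i])
}

#' Leave-one-out cross-validated penalty strength
#'
#' For every path lambda the model is refit n times on n-1 observations
#' (standardization redone inside each training fold by the fitter) and the
#' held-out sample is classified by thresholding the predicted response at
#' 0.5. The chosen lambda minimizes the mean misclassification error; ties
#' go to the largest (sparsest) lambda.
#'
#' @inheritParams elastic_net_fit
#' @param lambda Optional fixed path (default as in [elastic_net_fit()]).
#' @return List: `lambda_opt`, `lambda` (path), `error` (mean LOOCV
#'   misclassification per lambda), `per_obs` (n x nlambda 0/1 loss
#'   matrix), `fit` (the full-data [elastic_net_fit()]).
#' @export
loocv_lambda <- function(x, y, alpha = 1, lambda = NULL) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("labels are single-class; nothing to discriminate", call. = FALSE)
  path <- if (is.null(lambda)) .lambda_path(x, y, alpha) else
    rev(sort(unique(lambda)))
  loss <- matrix(NA_real_, n, length(path))
  for (i in seq_len(n)) {
    f <- glmnet::glmnet(t(x[, -i, drop = FALSE]), y[-i],
                        family = "gaussian", alpha = alpha, lambda = path,
                        standardize = TRUE, thresh = 1e-10, maxit = 1e5)
    pred <- stats::predict(f, newx = t(x[, i, drop = FALSE]), s = path)
    loss[i, ] <- as.numeric((pred >= 0.5) != y[i])
  }
  err <- colMeans(loss)
  best <- which(err == min(err))[1]  # path is decreasing: first = largest
  full <- elastic_net_fit(x, y, alpha, lambda = path)
  list(lambda_opt = path[best], lambda = path, error = err,
       per_obs = loss, fit = full)
}

#' Split selected markers by coefficient sign
#'
#' @param fit A [elastic_net_fit()] result (or list with `coef` vector).
#' @param lambda Penalty at which to read coefficients; defaults to the
#'   smallest path value if `fit` holds a path.
#' @return List `positive`, `negative`: named coefficient vectors ordered
#'   by decreasing absolute value.
#' @export
select_markers <- function(fit, lambda = NULL) {
  cf <- if (inherits(fit, "lasso_fit")) {
    if (is.null(lambda)) lambda <- min(fit$lambda)
    coef_at(fit, lambda)$coef
  } else fit$coef
  nz <- cf[cf != 0]
  pos <- nz[nz > 0]; neg <- nz[nz < 0]
  list(positive = pos[order(-abs(pos))], negative = neg[order(-abs(neg))])
}

#' One-call transport-marker selection
#'
#' Complete-case filtering, LOOCV penalty choice and marker extraction in
#' one step.
#'
#' @param x Gene-product by observation matrix (`NA` allowed; incomplete
#'   rows are dropped).
#' @param y 0/1 transport labels (0 = carrier, 1 = pneumatic tube).
#' @param alpha 1 for pure Lasso, 0.5 for elastic net.
#' @return List: `markers` (from [select_markers()]), `cv` (from
#'   [loocv_lambda()]), `n_features` retained.
#' @export
transport_markers <- function(x, y, alpha = 1) {
  xc <- complete_case_filter(x)
  cv <- loocv_lambda(xc, y, alpha)
  list(markers = select_markers(cv$fit, cv$lambda_opt), cv = cv,
       n_features = attr(xc, "n_retained"))
}
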