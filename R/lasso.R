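## column standardization with the 1/n variance convention; constant
## columns are flagged and their coefficients pinned at zero
standardize_cols <- function(X) {
  mu <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, mu)^2))
  ok <- s > 0
  Xs <- sweep(X, 2, mu)
  Xs[, ok] <- sweep(Xs[, ok, drop = FALSE], 2, s[ok], "/")
  Xs[, !ok] <- 0
  list(X = Xs, center = mu, scale = ifelse(ok, s, 1), ok = ok)
}

lambda_grid <- function(Xs, y, family, n_lambda, lambda_min_ratio) {
  n <- nrow(Xs)
  ybar <- mean(y)
  r0 <- y - ybar                      # null-model residual, both families
  lmax <- max(abs(crossprod(Xs, r0))) / n
  # nudge above the exact entry point: the argmax gene sits exactly on
  # the soft-threshold boundary and floating-point drift in the IRLS
  # refresh would otherwise let it enter with a ~1e-16 coefficient
  lmax <- max(lmax, 1e-10) * (1 + 1e-6)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' L1-penalized logistic (or squared-loss) regularization path
#'
#' Cyclic coordinate descent on the penalized objective
#' `-(1/n) loglik + lambda * ||beta||_1` over a log-spaced lambda grid
#' from `lambda_max` (the smallest penalty with an all-zero solution)
#' down to `lambda_min_ratio * lambda_max`, with warm starts. Columns
#' are standardized internally (mean 0, sd 1 with the 1/n convention);
#' coefficients are reported back on the input scale. The logistic
#' family wraps the descent in an iteratively reweighted quadratic
#' approximation. Convergence: max coefficient change < `tol`.
#'
#' @param X samples x genes numeric matrix.
#' @param y binary labels (0/1, logical, or two-level factor).
#' @param n_lambda grid size (default 100).
#' @param lambda_min_ratio ratio of smallest to largest lambda
#'   (default 0.01, the usual n < p choice).
#' @param family `"binomial"` (default) or `"gaussian"` (squared-loss
#'   check mode).
#' @param tol convergence tolerance on coefficient changes.
#' @return A `lasso_fit` list: `lambda` (decreasing), `beta`
#'   (genes x lambda, input scale), `a0` (intercepts), `lambda_max`,
#'   `family`, `levels` (for factor y).
#' @export
lasso_logistic_path <- function(X, y, n_lambda = 100L,
                                lambda_min_ratio = 0.01,
                                family = c("binomial", "gaussian"),
                                tol = 1e-7) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_param("X must be finite")
  lev <- NULL
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    lev <- levels(y)
    if (length(lev) != 2L) stop_param("y must have exactly two classes")
    y <- as.numeric(y == lev[2L])
  } else y <- as.numeric(y)
  if (family == "binomial" && length(unique(y)) < 2L)
    stop_param("y must contain both classes")

  sc <- standardize_cols(X)
  lam <- lambda_grid(sc$X, y, family, n_lambda, lambda_min_ratio)
  fit <- cd_path(sc$X, y, lam, if (family == "binomial") 1L else 0L,
                 tol, 1000L)
  beta <- fit$beta / sc$scale
  beta[!sc$ok, ] <- 0
  a0 <- fit$b0 - colSums(fit$beta * (sc$center / sc$scale))
  rownames(beta) <- colnames(X)
  structure(list(lambda = lam, beta = beta, a0 = a0,
                 lambda_max = lam[1L], family = family, levels = lev),
            class = "lasso_fit")
}

#' Predicted class probabilities from a lasso fit
#' @param object a `lasso_fit`.
#' @param newx samples x genes matrix.
#' @param ... unused.
#' @return samples x lambda matrix of probabilities (binomial) or
#'   linear predictors (gaussian).
#' @export
predict.lasso_fit <- function(object, newx, ...) {
  eta <- sweep(as.matrix(newx) %*% object$beta, 2, object$a0, "+")
  if (object$family == "binomial") plogis(eta) else eta
}

## stratified fold assignment; returns integer fold id per sample
stratified_folds <- function(y, n_folds, seed) {
  with_local_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

binomial_deviance <- function(y, phat, eps = 1e-5) {
  phat <- pmin(pmax(phat, eps), 1 - eps)
  -2 * mean(y * log(phat) + (1 - y) * log(1 - phat))
}

#' Cross-validated binomial deviance along the lambda path
#'
#' Stratified k-fold CV: each fold's training data is refit over the
#' full-data lambda grid, held-out samples are scored, and the mean
#' held-out binomial deviance per lambda (averaged over folds) selects
#' `lambda_star` (ties broken towards the larger penalty). If a
#' stratified training split ever ends up single-class the split is
#' redrawn from a shifted seed (logged).
#'
#' @param X,y as in [lasso_logistic_path()].
#' @param fit a `lasso_fit` on the full data (supplies the grid).
#' @param n_folds folds (default 10).
#' @param seed fixes the split.
#' @return `fit` with `cv_deviance`, `lambda_star`, `lambda_star_index`
#'   filled in.
#' @export
cv_deviance <- function(X, y, fit, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(fit, "lasso_fit"))
  X <- as.matrix(X)
  if (!is.null(fit$levels)) y <- as.numeric(factor(y, fit$levels) == fit$levels[2L])
  y <- as.numeric(y)
  for (attempt in 0:10) {
    fold <- stratified_folds(y, n_folds, seed + attempt * 1000003L)
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(y[fold != f])) == 2L, TRUE))
    if (ok) break
    message("refolding: single-class training split at seed ", seed)
  }
  dev <- matrix(NA_real_, n_folds, length(fit$lambda))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (!any(!tr)) next
    sc <- standardize_cols(X[tr, , drop = FALSE])
    sub <- cd_path(sc$X, y[tr], fit$lambda,
                   if (fit$family == "binomial") 1L else 0L, 1e-7, 1000L)
    beta <- sub$beta / sc$scale
    beta[!sc$ok, ] <- 0
    a0 <- sub$b0 - colSums(sub$beta * (sc$center / sc$scale))
    eta <- sweep(X[!tr, , drop = FALSE] %*% beta, 2, a0, "+")
    phat <- plogis(eta)
    dev[f, ] <- apply(phat, 2, function(pp) binomial_deviance(y[!tr], pp))
  }
  cvm <- colMeans(dev, na.rm = TRUE)
  if (any(!is.finite(cvm))) stop("non-finite CV deviance")
  best <- which(cvm == min(cvm))[1L]   # grid is decreasing: first = larger lambda
  fit$cv_deviance <- cvm
  fit$lambda_star <- fit$lambda[best]
  fit$lambda_star_index <- best
  fit$cv_seed <- seed
  fit
}

#' Stability selection by repeated cross-validated LASSO
#'
#' The signature-discovery procedure: the penalized logistic path is fit
#' once on the full data; then, `n_reps` times, a fresh random
#' stratified CV split picks `lambda_star` by minimum held-out binomial
#' deviance and the full-data coefficients at that penalty are recorded.
#' Genes selected (nonzero) in at least `threshold` of the repetitions
#' form the signature; each gene's weight is its coefficient averaged
#' across all repetitions (zeros from non-selecting runs included).
#' Every repetition's seed derives from the master seed, so any single
#' repetition is re-runnable in isolation.
#'
#' @param X samples x genes matrix (normalized log2 expression).
#' @param y two-class labels; coefficients are log-odds of the second
#'   level (e.g. MST when levels are `c("SN", "MST")`).
#' @param n_reps repetitions (default 500).
#' @param threshold minimum selection count (default 250).
#' @param seed master seed.
#' @param n_folds CV folds per repetition.
#' @param n_lambda,lambda_min_ratio path grid, see
#'   [lasso_logistic_path()].
#' @return A `signature_model` list: `gene_id`, `selection_count`,
#'   `mean_coef`, `n_reps`, `selection_threshold`, `signature_genes`,
#'   `signature_weights`, `rep_seeds`, `lambda_stars`, `fit`.
#' @export
stability_select <- function(X, y, n_reps = 500L, threshold = 250L,
                             seed = 1L, n_folds = 10L, n_lambda = 100L,
                             lambda_min_ratio = 0.01) {
  if (n_reps < threshold)
    stop_param("n_reps must be at least the selection threshold")
  X <- as.matrix(X)
  fit <- lasso_logistic_path(X, y, n_lambda = n_lambda,
                             lambda_min_ratio = lambda_min_ratio)
  rep_seeds <- derive_seeds(seed, n_reps)
  sel <- integer(ncol(X))
  coefsum <- numeric(ncol(X))
  lambda_stars <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cvfit <- cv_deviance(X, y, fit, n_folds = n_folds, seed = rep_seeds[r])
    b <- cvfit$beta[, cvfit$lambda_star_index]
    b[abs(b) < 1e-8] <- 0      # below solver tolerance: numerically zero
    sel <- sel + (b != 0)
    coefsum <- coefsum + b
    lambda_stars[r] <- cvfit$lambda_star
  }
  mean_coef <- coefsum / n_reps
  keep <- sel >= threshold & mean_coef != 0
  structure(list(gene_id = colnames(X),
                 selection_count = setNames(sel, colnames(X)),
                 mean_coef = setNames(mean_coef, colnames(X)),
                 n_reps = as.integer(n_reps),
                 selection_threshold = as.integer(threshold),
                 signature_genes = colnames(X)[keep],
                 signature_weights = setNames(mean_coef[keep],
                                              colnames(X)[keep]),
                 rep_seeds = rep_seeds,
                 lambda_stars = lambda_stars,
                 fit = fit),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: %d/%d repetitions required; %d gene(s) selected\n",
              x$selection_threshold, x$n_reps, length(x$signature_genes)))
  if (length(x$signature_genes)) {
    df <- data.frame(gene = x$signature_genes,
                     selection_count = x$selection_count[x$signature_genes],
                     weight = round(x$signature_weights, 4))
    rownames(df) <- NULL
    print(df)
  }
  invisible(x)
}
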