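#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: order the p-values, scale by n/rank, enforce
#' monotonicity from the largest p downwards and cap at 1. Ties are
#' handled by the stable sort, so the output is order-preserving with
#' the input.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return vector of q-values, same order as `p`.
#' @export
adjust_bh <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop_param("p-values must lie in (0, 1]")
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  q[o] <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q
}

## Newton inversion of the trigamma function (for the empirical-Bayes
## prior df); monotone decreasing on (0, Inf).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(0)
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-8) break
    }
    y
  }, 0)
}

## Fit a scaled inverse-chi-square prior to residual variances by moment
## matching on log(s2): returns s2_prior and df_prior.
squeeze_var_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(s2_prior = mean(s2[ok], na.rm = TRUE),
                                df_prior = 0))
  z <- log(s2[ok])
  d <- rep_len(df, length(s2))[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(emean)
  }
  list(s2_prior = s2_prior, df_prior = df_prior)
}

## exact t -> standard normal z, stable in the tails
t_to_z <- function(t, df) {
  if (!is.finite(df)) return(t)
  sign(t) * qnorm(pt(abs(t), df = df, lower.tail = FALSE, log.p = TRUE),
                  lower.tail = FALSE, log.p = TRUE)
}

## per-gene weighted least squares for a two-group design, vectorized
wls_two_group <- function(logexp, weights, j1, j2) {
  w1 <- weights[, j1, drop = FALSE]; w2 <- weights[, j2, drop = FALSE]
  x1 <- logexp[, j1, drop = FALSE]; x2 <- logexp[, j2, drop = FALSE]
  W1 <- rowSums(w1); W2 <- rowSums(w2)
  m1 <- rowSums(w1 * x1) / W1
  m2 <- rowSums(w2 * x2) / W2
  rss <- rowSums(w1 * (x1 - m1)^2) + rowSums(w2 * (x2 - m2)^2)
  df <- length(j1) + length(j2) - 2L
  list(logFC = m2 - m1, s2 = rss / df, df = df, varfac = 1 / W1 + 1 / W2)
}

#' Precision-weighted moderated-t contrast between two groups
#'
#' Fits, per gene, a weighted least-squares two-group model on the
#' samples of the two groups only; shrinks the residual variances with
#' an empirical-Bayes scaled inverse-chi-square prior fitted across all
#' genes (moment matching on the log variances); forms the moderated
#' t-statistic `logFC / moderated SE` on `df_residual + df_prior`
#' degrees of freedom; and attaches BH q-values.
#'
#' @param expr a [normalize_voom()] result.
#' @param cohort the matching [count_cohort()].
#' @param group1,group2 group labels; `logFC` is `group2 - group1`.
#' @param df_prior optional override of the prior degrees of freedom;
#'   `0` disables moderation (ordinary weighted t).
#' @return A `contrast_table` data.frame with columns `gene_id`,
#'   `logFC`, `ave_expr`, `t_mod`, `p`, `q`, and attributes `s2_prior`,
#'   `df_prior`, `df_total`, `contrast`.
#' @export
fit_contrast <- function(expr, cohort, group1, group2, df_prior = NULL) {
  stopifnot(inherits(expr, "weighted_expr"))
  grp <- expr$group
  j1 <- which(grp == group1); j2 <- which(grp == group2)
  if (length(j1) < 2L || length(j2) < 2L)
    stop_param("both groups need at least 2 samples (",
               group1, ": ", length(j1), ", ", group2, ": ", length(j2), ")")

  fit <- wls_two_group(expr$logexp, expr$weights, j1, j2)
  prior <- squeeze_var_prior(fit$s2, fit$df)
  if (!is.null(df_prior)) {
    prior$df_prior <- df_prior
    if (df_prior == 0) prior$s2_prior <- 1   # unused when weight is zero
  }
  d0 <- prior$df_prior
  s2_post <- if (is.finite(d0)) {
    (d0 * prior$s2_prior + fit$df * fit$s2) / (d0 + fit$df)
  } else rep(prior$s2_prior, length(fit$s2))
  se <- sqrt(s2_post * fit$varfac)
  t_mod <- ifelse(se > 0, fit$logFC / se, 0)
  df_total <- fit$df + d0
  p <- 2 * pt(-abs(t_mod), df = df_total)
  p[!is.finite(t_mod) | se == 0] <- 1
  t_mod[se == 0] <- 0
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  tab <- data.frame(
    gene_id = rownames(expr$logexp),
    logFC = unname(fit$logFC),
    ave_expr = unname(rowMeans(expr$logexp[, c(j1, j2), drop = FALSE])),
    t_mod = unname(t_mod),
    p = unname(p),
    q = adjust_bh(unname(p)),
    stringsAsFactors = FALSE)
  structure(tab,
            class = c("contrast_table", "data.frame"),
            s2_prior = prior$s2_prior, df_prior = d0,
            df_total = df_total, s2_resid = unname(fit$s2),
            contrast = c(group1, group2))
}

#' Significant genes of a contrast
#'
#' Applies both reported thresholds: raw `p < p_cut` and BH
#' `q <= q_cut`, and counts positive / negative log fold changes.
#'
#' @param table a [fit_contrast()] result.
#' @param p_cut raw p-value threshold (default 0.05).
#' @param q_cut BH q-value threshold (default 0.25).
#' @return list with `genes`, `n_up`, `n_down`, and the filtered `table`.
#' @export
significant_genes <- function(table, p_cut = 0.05, q_cut = 0.25) {
  stopifnot(nrow(table) > 0)
  keep <- table$p < p_cut & table$q <= q_cut
  sub <- table[keep, , drop = FALSE]
  list(genes = sub$gene_id,
       n_up = sum(sub$logFC > 0),
       n_down = sum(sub$logFC < 0),
       table = sub)
}

#' Row-wise scale and center for heatmaps
#'
#' Per-gene mean 0 / unit variance across samples. Constant rows map to
#' all zeros and are flagged in the `constant_rows` attribute.
#'
#' @param expr a [normalize_voom()] result or log-expression matrix.
#' @param genes gene ids to keep (default all).
#' @return scaled genes x samples matrix.
#' @export
scale_center <- function(expr, genes = NULL) {
  m <- if (inherits(expr, "weighted_expr")) expr$logexp else as.matrix(expr)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(m))
    if (length(miss)) stop_param("genes not in expression matrix: ",
                                 paste(miss, collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  out <- (m - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  attr(out, "constant_rows") <- rownames(m)[s == 0]
  out
}
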