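#' Library-size normalization with voom-style precision weights
#'
#' Converts counts to log2 counts-per-million using the total library
#' size as the per-sample scaling factor,
#' `log2((count + 0.5) / (libsize + 1) * 1e6)`, fits a per-gene linear
#' model on the group means, and estimates the mean-variance trend of
#' the log counts nonparametrically: lowess of the square root of the
#' residual standard deviation against the average log2 count size.
#' The trend evaluated at each observation's fitted log count gives an
#' inverse-variance precision weight, which downstream linear modeling
#' consumes. Offsets 0.5 / 1 and the lowess span follow the established
#' convention for this procedure.
#'
#' @param cohort a [count_cohort()] with at least two samples.
#' @param span lowess span for the mean-variance trend.
#' @param iter lowess robustifying iterations.
#' @return An object of class `weighted_expr`: list with `logexp`
#'   (genes x samples, log2 scale), `weights` (same shape, positive),
#'   `trend` (function: average log2 count -> sqrt residual sd),
#'   `group`, `gene_role`, `library_size`.
#' @export
normalize_voom <- function(cohort, span = 0.5, iter = 3L) {
  stopifnot(inherits(cohort, "count_cohort"))
  if (length(cohort$sample_ids) < 2L)
    stop_param("need at least 2 samples")
  lib <- cohort$library_size
  zero <- names(lib)[lib == 0]
  if (length(zero))
    stop_param("sample(s) with zero total counts: ",
               paste(zero, collapse = ", "))

  counts <- cohort$counts
  logexp <- log2(t(t(counts + 0.5) / (lib + 1)) * 1e6)

  ## group-mean fit (one-way layout over the sample groups)
  groups <- factor(cohort$group)
  fitted <- matrix(0, nrow(logexp), ncol(logexp), dimnames = dimnames(logexp))
  rss <- numeric(nrow(logexp))
  for (g in levels(groups)) {
    j <- which(groups == g)
    m <- rowMeans(logexp[, j, drop = FALSE])
    fitted[, j] <- m
    rss <- rss + rowSums((logexp[, j, drop = FALSE] - m)^2)
  }
  df_resid <- ncol(logexp) - nlevels(groups)
  if (df_resid < 1L)
    stop_param("no residual degrees of freedom: every group has one sample")
  sigma <- sqrt(rss / df_resid)

  ## mean-variance trend: sqrt-sd vs average log2 count size
  sx <- rowMeans(logexp) + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  lo <- lowess(sx, sy, f = span, iter = iter)
  floor_sy <- max(min(lo$y), 1e-4)   # keep weights finite and positive
  trend <- function(x) {
    y <- approx(lo$x, lo$y, xout = x, rule = 2, ties = "ordered")$y
    pmax(y, floor_sy)
  }

  fitted_count <- fitted + matrix(log2(lib + 1), nrow(fitted), ncol(fitted),
                                  byrow = TRUE) - log2(1e6)
  w <- 1 / trend(fitted_count)^4
  dim(w) <- dim(logexp); dimnames(w) <- dimnames(logexp)

  structure(list(logexp = logexp, weights = w, trend = trend,
                 group = cohort$group, gene_role = cohort$gene_role,
                 library_size = lib),
            class = "weighted_expr")
}

#' @export
print.weighted_expr <- function(x, ...) {
  cat(sprintf("weighted_expr: %d genes x %d samples (log2 CPM, voom-style weights)\n",
              nrow(x$logexp), ncol(x$logexp)))
  invisible(x)
}

## pairwise sample distance: root-mean-square of the top-`top` largest
## per-gene log-expression differences for that pair
pairwise_top_dist <- function(logexp, top = 500L) {
  n <- ncol(logexp)
  top <- min(top, nrow(logexp))
  d <- matrix(0, n, n, dimnames = list(colnames(logexp), colnames(logexp)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    dd <- (logexp[, i] - logexp[, j])^2
    dd <- sort(dd, decreasing = TRUE)[seq_len(top)]
    d[i, j] <- d[j, i] <- sqrt(mean(dd))
  }
  d
}

#' Classical MDS coordinates for QC
#'
#' Pairwise sample distances are the root-mean-square of the top 500
#' most different genes per pair (all genes when the panel is smaller),
#' embedded by classical multidimensional scaling and centered at zero.
#'
#' @param expr a [normalize_voom()] result, or a bare genes x samples
#'   log-expression matrix.
#' @param k number of dimensions (default 2).
#' @param top number of top genes per pair.
#' @return samples x k coordinate matrix.
#' @export
mds_coordinates <- function(expr, k = 2L, top = 500L) {
  logexp <- if (inherits(expr, "weighted_expr")) expr$logexp else as.matrix(expr)
  n <- ncol(logexp)
  if (k >= n) stop_param("k must be smaller than the number of samples")
  d <- pairwise_top_dist(logexp, top)
  cs <- cmdscale(as.dist(d), k = k)
  ## pad in case of degenerate (zero-eigenvalue) axes
  if (ncol(cs) < k)
    cs <- cbind(cs, matrix(0, nrow(cs), k - ncol(cs)))
  cs <- sweep(cs, 2, colMeans(cs))
  rownames(cs) <- colnames(logexp)
  colnames(cs) <- paste0("dim", seq_len(k))
  cs
}
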