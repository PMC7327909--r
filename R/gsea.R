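#' Competitive gene-set test with inter-gene correlation correction
#'
#' For a two-group contrast, converts each gene's moderated t to an
#' equivalent standard-normal z, then tests each gene set by a
#' two-sample comparison of member versus non-member z-scores in which
#' the member mean's variance is inflated by `VIF = 1 + (m - 1) * rho`,
#' with the mean inter-gene residual correlation `rho` estimated per set
#' from the standardized residual space of the member genes (after the
#' group means and precision weights are accounted for). Without this
#' inflation, correlated sets would look spuriously significant.
#'
#' @param expr a [normalize_voom()] result.
#' @param cohort the matching [count_cohort()].
#' @param contrast length-2 character vector `(group1, group2)`.
#' @param sets a [read_gmt()] collection or named list of gene ids;
#'   ids are matched to panel genes case-insensitively.
#' @param min_size sets with fewer panel members are skipped (warning).
#' @param rho_fixed optional fixed inter-gene correlation; `NULL`
#'   (default) estimates it per set.
#' @return A `gsea_result` data.frame with columns `set_name`,
#'   `n_genes`, `direction`, `rho_bar`, `vif`, `p`, `q` (BH across the
#'   tested sets), in the input set order.
#' @export
camera_test <- function(expr, cohort, contrast, sets,
                        min_size = 2L, rho_fixed = NULL) {
  stopifnot(inherits(expr, "weighted_expr"), length(contrast) == 2L)
  if (!length(sets)) stop_param("empty gene-set collection")
  grp <- expr$group
  j <- which(grp %in% contrast)
  groups2 <- factor(grp[j], levels = contrast)
  y <- expr$logexp[, j, drop = FALSE]
  w <- expr$weights[, j, drop = FALSE]
  G <- nrow(y); n <- ncol(y); p <- 2L
  df_resid <- n - p
  if (df_resid < 1L) stop_param("no residual degrees of freedom")

  design <- cbind(1, as.integer(groups2 == contrast[2L]))

  ## per-gene weighted QR: last effect is the (unscaled) contrast
  ## estimate, the trailing n-2 effects span the residual space
  U <- matrix(0, G, n - p)
  unscaledt <- numeric(G)
  sw <- sqrt(w)
  for (g in seq_len(G)) {
    xw <- design * sw[g, ]
    QR <- qr(xw)
    e <- qr.qty(QR, y[g, ] * sw[g, ])
    ut <- e[p]
    if (QR$qr[p, p] < 0) ut <- -ut
    unscaledt[g] <- ut
    U[g, ] <- e[-(1:p)]
  }
  sigma2 <- rowMeans(U^2)
  U <- U / sqrt(pmax(sigma2, 1e-8))
  prior <- squeeze_var_prior(sigma2, df_resid)
  d0 <- prior$df_prior
  s2_post <- if (is.finite(d0))
    (d0 * prior$s2_prior + df_resid * sigma2) / (d0 + df_resid)
  else rep(prior$s2_prior, G)
  modt <- unscaledt / sqrt(s2_post)
  df_total <- min(df_resid + d0, G * df_resid)
  z <- t_to_z(modt, df_total)

  ids <- toupper(rownames(y))
  if (!is.list(sets)) sets <- list(set1 = sets)
  idx <- lapply(sets, function(s) which(ids %in% toupper(as.character(s))))
  small <- lengths(idx) < min_size
  if (any(small)) {
    warning("skipping ", sum(small), " set(s) with fewer than ", min_size,
            " panel members: ", paste(names(sets)[small], collapse = ", "))
    idx <- idx[!small]
  }
  if (!length(idx)) stop_param("no testable sets after id matching")

  mean_z <- mean(z); var_z <- var(z)
  df_camera <- min(df_resid, G - 2L)
  res <- lapply(names(idx), function(nm) {
    iset <- idx[[nm]]
    m <- length(iset); m2 <- G - m
    if (!is.null(rho_fixed)) {
      rho <- rho_fixed
    } else {
      Uset <- U[iset, , drop = FALSE]
      vif_est <- m * mean(colMeans(Uset)^2)
      rho <- (vif_est - 1) / (m - 1)
    }
    rho <- max(rho, -1 / (m - 1) + 1e-3)   # keep vif strictly positive
    vif <- 1 + (m - 1) * rho
    mean_in <- mean(z[iset])
    delta <- G / m2 * (mean_in - mean_z)   # = mean_in - mean_out
    var_pooled <- ((G - 1) * var_z - delta^2 * m * m2 / G) / (G - 2)
    tt <- delta / sqrt(var_pooled * (vif / m + 1 / m2))
    data.frame(set_name = nm, n_genes = m,
               direction = if (tt >= 0) "Up" else "Down",
               rho_bar = rho, vif = vif,
               p = 2 * pt(-abs(tt), df = df_camera),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p <- pmin(pmax(out$p, .Machine$double.xmin), 1)
  out$q <- adjust_bh(out$p)
  class(out) <- c("gsea_result", "data.frame")
  attr(out, "contrast") <- contrast
  out
}

#' Rank gene sets by FDR
#'
#' Sorted ascending by q (ties broken by p, then set name); the top k
#' are returned with `-log10(q)` attached for bar-plot export.
#'
#' @param results a [camera_test()] result.
#' @param k how many sets to keep (default 10).
#' @return the top-k rows with an extra `neg_log10_q` column.
#' @export
rank_pathways <- function(results, k = 10L) {
  stopifnot(nrow(results) > 0)
  if (k <= 0) stop_param("k must be positive")
  o <- order(results$q, results$p, results$set_name)
  out <- results[o, , drop = FALSE][seq_len(min(k, nrow(results))), ,
                                    drop = FALSE]
  out$neg_log10_q <- -log10(out$q)
  rownames(out) <- NULL
  out
}
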