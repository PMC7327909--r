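#' Score all samples with a weighted gene signature
#'
#' Per sample, the raw score is the sum over signature genes of
#' `weight * normalized log2 expression`; scores are then min-max
#' transformed over the scored cohort to a 0-1 scale and called
#' low/high at the 0.4 cut (a score of exactly 0.4 is called low, per
#' the "< 0.4 is low" convention). Scoring is applied to every sample,
#' including groups that were not used for training (the AST group in
#' the intended use).
#'
#' @param model a [stability_select()] result, or a named numeric
#'   vector of gene weights.
#' @param expr a [normalize_voom()] result.
#' @param cohort the matching [count_cohort()] (supplies group labels);
#'   optional when `expr` carries them.
#' @param cut low/high threshold on the 0-1 scale (default 0.4).
#' @return A `score_table` data.frame: `sample_id`, `group`,
#'   `raw_score`, `score01`, `call`.
#' @export
score_samples <- function(model, expr, cohort = NULL, cut = 0.4) {
  w <- if (inherits(model, "signature_model")) model$signature_weights
       else model
  if (!length(w)) stop_param("empty signature: no genes to score")
  stopifnot(inherits(expr, "weighted_expr"))
  miss <- setdiff(names(w), rownames(expr$logexp))
  if (length(miss))
    stop_param("signature gene(s) missing from expression: ",
               paste(miss, collapse = ", "))
  raw <- colSums(expr$logexp[names(w), , drop = FALSE] * w)
  rng <- range(raw)
  if (rng[2] > rng[1]) {
    s01 <- (raw - rng[1]) / (rng[2] - rng[1])
  } else {
    warning("all raw scores identical; score01 set to 0")
    s01 <- rep(0, length(raw))
  }
  grp <- if (!is.null(cohort)) cohort$group else expr$group
  out <- data.frame(sample_id = colnames(expr$logexp),
                    group = unname(grp[colnames(expr$logexp)]),
                    raw_score = unname(raw),
                    score01 = unname(s01),
                    call = ifelse(s01 > cut, "high", "low"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("score_table", "data.frame"), cut = cut)
}

#' Per-group summary of signature scores
#'
#' @param scores a [score_samples()] result.
#' @param cut low/high threshold (defaults to the one used in scoring).
#' @return data.frame with one row per group: mean, min, max of
#'   `score01` and low/high counts.
#' @export
summarize_scores <- function(scores, cut = NULL) {
  stopifnot(nrow(scores) > 0)
  if (is.null(cut)) cut <- attr(scores, "cut") %||% 0.4
  groups <- unique(scores$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    s <- scores$score01[scores$group == g]
    data.frame(group = g, n = length(s),
               mean = mean(s), min = min(s), max = max(s),
               n_low = sum(s <= cut), n_high = sum(s > cut),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
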