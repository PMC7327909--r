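#' Pipeline configuration
#'
#' Collects paths, thresholds and tuning parameters for a full run.
#' Defaults equal the analysis constants of the intended study design:
#' raw p < 0.05 with BH q <= 0.25 for differential expression, q < 0.05
#' for gene-set enrichment, 500 LASSO repetitions with a 250-run
#' selection threshold and 10 CV folds, and the 0.4 low/high score cut.
#'
#' @param counts,samples,genes,gmt input file paths (`genes` optional).
#' @param outdir output directory.
#' @param p_cut,q_cut DE thresholds.
#' @param gsea_q GSEA FDR threshold.
#' @param score_cut low/high score threshold.
#' @param reps,threshold,folds,n_lambda,lambda_min_ratio signature
#'   parameters.
#' @param seed master seed for every stochastic stage.
#' @param contrasts list of 2-vectors of group labels; the first one is
#'   the signature training contrast.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts, samples, gmt, outdir,
                            genes = NULL,
                            p_cut = 0.05, q_cut = 0.25,
                            gsea_q = 0.05, score_cut = 0.4,
                            reps = 500L, threshold = 250L, folds = 10L,
                            n_lambda = 100L, lambda_min_ratio = 0.01,
                            seed = 1L,
                            contrasts = list(c("SN", "MST"),
                                             c("SN", "AST"),
                                             c("AST", "MST"))) {
  cfg <- as.list(environment())
  # CLI overrides arrive as strings
  for (f in c("p_cut", "q_cut", "gsea_q", "score_cut", "lambda_min_ratio"))
    cfg[[f]] <- as.numeric(cfg[[f]])
  for (f in c("reps", "threshold", "folds", "n_lambda", "seed"))
    cfg[[f]] <- as.integer(cfg[[f]])
  for (th in c("p_cut", "q_cut", "gsea_q", "score_cut"))
    if (cfg[[th]] <= 0 || cfg[[th]] >= 1)
      stop_param(th, " must lie in (0, 1)")
  if (cfg$reps < cfg$threshold) stop_param("reps must be >= threshold")
  for (f in c("counts", "samples", "gmt"))
    if (!file.exists(cfg[[f]])) stop_param(f, " file not found: ", cfg[[f]])
  if (!is.null(cfg$genes) && !file.exists(cfg$genes))
    stop_param("genes file not found: ", cfg$genes)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' normalize -> differential expression for each configured contrast ->
#' gene-set enrichment per contrast -> signature training on the first
#' contrast with scoring of all samples -> per-group score summary.
#' Every tabular artifact is written as TSV under `outdir` along with a
#' `manifest.tsv` of MD5 hashes; re-running the same config and seed
#' reproduces every artifact bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  cohort <- stage("read", read_counts(config$counts, config$samples,
                                      config$genes))
  sets <- stage("gsea", read_gmt(config$gmt))
  expr <- stage("normalize", normalize_voom(cohort))

  files <- c(files, stage("normalize", {
    ntab <- data.frame(gene_id = rownames(expr$logexp), expr$logexp,
                       check.names = FALSE)
    wtab <- data.frame(gene_id = rownames(expr$weights), expr$weights,
                       check.names = FALSE)
    mds <- mds_coordinates(expr, k = 2L)
    c(write_tsv(ntab, file.path(config$outdir, "normalized_log2cpm.tsv")),
      write_tsv(wtab, file.path(config$outdir, "voom_weights.tsv")),
      write_tsv(data.frame(sample_id = rownames(mds), mds),
                file.path(config$outdir, "mds.tsv")))
  }))

  de <- list(); gsea <- list(); de_counts <- list()
  for (ct in config$contrasts) {
    key <- paste(ct, collapse = "_vs_")
    tab <- stage("diffexpr", fit_contrast(expr, cohort, ct[1], ct[2]))
    sig <- significant_genes(tab, config$p_cut, config$q_cut)
    de[[key]] <- tab; de_counts[[key]] <- sig
    volcano <- data.frame(gene_id = tab$gene_id, logFC = tab$logFC,
                          neg_log10_p = -log10(tab$p),
                          significant = tab$gene_id %in% sig$genes)
    files <- c(files,
               write_tsv(tab, file.path(config$outdir,
                                        paste0("de_", key, ".tsv"))),
               write_tsv(volcano, file.path(config$outdir,
                                            paste0("volcano_", key, ".tsv"))))
    gs <- stage("gsea", camera_test(expr, cohort, ct, sets))
    gsea[[key]] <- gs
    files <- c(files,
               write_tsv(gs, file.path(config$outdir,
                                       paste0("gsea_", key, ".tsv"))),
               write_tsv(rank_pathways(gs, 10L),
                         file.path(config$outdir,
                                   paste0("gsea_top_", key, ".tsv"))))
  }

  train <- config$contrasts[[1L]]
  model <- stage("signature", {
    keep <- expr$group %in% train
    X <- t(expr$logexp[, keep, drop = FALSE])
    y <- factor(expr$group[keep], levels = train)
    stability_select(X, y, n_reps = config$reps,
                     threshold = config$threshold, seed = config$seed,
                     n_folds = config$folds, n_lambda = config$n_lambda,
                     lambda_min_ratio = config$lambda_min_ratio)
  })
  scores <- stage("signature", score_samples(model, expr, cohort,
                                             cut = config$score_cut))
  summary <- summarize_scores(scores)
  files <- c(files, stage("signature", {
    sigtab <- data.frame(gene_id = model$gene_id,
                         selection_count = unname(model$selection_count),
                         mean_coef = unname(model$mean_coef))
    hm <- if (length(model$signature_genes) >= 1L)
      scale_center(expr, model$signature_genes) else NULL
    out <- c(write_tsv(sigtab, file.path(config$outdir, "signature.tsv")),
             write_tsv(scores, file.path(config$outdir, "scores.tsv")),
             write_tsv(summary, file.path(config$outdir,
                                          "score_summary.tsv")))
    if (!is.null(hm))
      out <- c(out, write_tsv(
        data.frame(gene_id = rownames(hm), hm, check.names = FALSE),
        file.path(config$outdir, "signature_heatmap.tsv")))
    out
  }))

  inputs <- c(config$counts, config$samples, config$gmt, config$genes)
  manifest <- data.frame(
    file = c(basename(inputs), basename(files)),
    role = c(rep("input", length(inputs)), rep("output", length(files))),
    md5 = unname(tools::md5sum(c(inputs, files))),
    seed = config$seed,
    version = as.character(utils::packageVersion("spitzsig")),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))

  invisible(list(cohort = cohort, expr = expr, de = de,
                 de_significant = de_counts, gsea = gsea, model = model,
                 scores = scores, summary = summary, manifest = manifest))
}
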