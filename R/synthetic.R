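#' Configuration for the synthetic NanoString-like cohort generator
#'
#' The defaults state the simulated world once: a 51-sample cohort split
#' 27 SN / 10 AST / 14 MST over a 770-gene panel with 40 housekeeping
#' genes, log-normal library sizes whose median is about 3e5 total counts
#' and whose min/max span roughly the 1.9e4..7.9e5 range seen on FFPE
#' material, and negative-binomial gene counts with variance
#' mu + phi * mu^2.
#'
#' Planted structure (all on endogenous genes):
#' * `n_de_genes` genes carry a two-group log2 shift of `de_logfc`
#'   between SN and MST (alternating sign; AST sits at the SN level).
#' * `n_signature_genes` genes carry ordered group means
#'   baseline, baseline + step, baseline + 2*step across SN, AST, MST
#'   (sign alternating across the planted genes), so the intermediate
#'   position of AST is true by construction.
#' * housekeeping genes never carry a group effect.
#'
#' @param n_per_group integer triple: samples per group (SN, AST, MST).
#' @param n_genes total panel size.
#' @param n_housekeeping number of housekeeping genes.
#' @param n_de_genes number of planted two-group DE genes.
#' @param de_logfc planted log2 fold change (MST vs SN) of the DE genes.
#' @param n_signature_genes number of planted ordered-mean signature genes.
#' @param signature_step per-class log2 increment SN -> AST -> MST.
#' @param nb_dispersion negative-binomial dispersion phi (> 0).
#' @param libsize_log_mean,libsize_log_sd natural-log mean and sd of the
#'   log-normal library-size draw.
#' @param seed integer seed; the same seed gives a bit-identical cohort.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_group = c(SN = 27L, AST = 10L, MST = 14L),
                             n_genes = 770L,
                             n_housekeeping = 40L,
                             n_de_genes = 50L,
                             de_logfc = 2,
                             n_signature_genes = 6L,
                             signature_step = 1,
                             nb_dispersion = 0.1,
                             libsize_log_mean = log(3e5),
                             libsize_log_sd = 0.7,
                             seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_genes = as.integer(n_genes),
              n_housekeeping = as.integer(n_housekeeping),
              n_de_genes = as.integer(n_de_genes),
              de_logfc = de_logfc,
              n_signature_genes = as.integer(n_signature_genes),
              signature_step = signature_step,
              nb_dispersion = nb_dispersion,
              libsize_log_mean = libsize_log_mean,
              libsize_log_sd = libsize_log_sd,
              seed = as.integer(seed))
  if (length(cfg$n_per_group) != 3L || any(cfg$n_per_group < 1L))
    stop_param("invalid config: n_per_group must be three positive counts")
  if (is.null(names(cfg$n_per_group)) || !all(nzchar(names(cfg$n_per_group))))
    names(cfg$n_per_group) <- c("SN", "AST", "MST")
  if (cfg$n_genes < 1L || cfg$n_housekeeping < 0L ||
      cfg$n_de_genes < 0L || cfg$n_signature_genes < 0L)
    stop_param("invalid config: gene counts must be non-negative (n_genes positive)")
  if (cfg$n_housekeeping + cfg$n_de_genes + cfg$n_signature_genes > cfg$n_genes)
    stop_param("invalid config: n_housekeeping + n_de_genes + n_signature_genes ",
               "exceeds n_genes")
  if (!is.finite(cfg$nb_dispersion) || cfg$nb_dispersion <= 0)
    stop_param("invalid config: nb_dispersion must be > 0")
  if (!is.finite(cfg$libsize_log_sd) || cfg$libsize_log_sd < 0)
    stop_param("invalid config: libsize_log_sd must be >= 0")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic count cohort with known ground truth
#'
#' Draws per-sample library sizes log-normally, baseline relative gene
#' abundances log-normally (normalized to sum to one), applies the
#' planted group effects on the log2 scale and samples counts from a
#' negative binomial with mean `abundance * library size` and dispersion
#' `nb_dispersion`. Ground truth (gene roles, planted flags, true log
#' fold changes, signature signs) is stored in the cohort's `gene_info`.
#'
#' @param config a [synthetic_config()].
#' @return A [count_cohort()] whose `gene_info` carries columns
#'   `is_de`, `is_signature`, `true_logfc` (MST vs SN) and `sig_sign`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  with_local_seed(config$seed, {
    groups <- rep(names(config$n_per_group), config$n_per_group)
    n <- length(groups)
    sample_ids <- unlist(lapply(names(config$n_per_group), function(g)
      paste0(g, seq_len(config$n_per_group[[g]]))), use.names = FALSE)
    gene_ids <- sprintf("G%04d", seq_len(config$n_genes))

    ## gene roles and planted assignments: housekeeping first, then DE,
    ## then signature genes, rest null endogenous
    role <- rep("endogenous", config$n_genes)
    if (config$n_housekeeping > 0L) {
      hk <- seq_len(config$n_housekeeping)
      role[hk] <- "housekeeping"
      gene_ids[hk] <- sprintf("HK%03d", seq_along(hk))
    }
    de_idx <- seq_len(config$n_de_genes) + config$n_housekeeping
    sig_idx <- seq_len(config$n_signature_genes) +
      config$n_housekeeping + config$n_de_genes

    ## baseline relative abundances: log-normal spread, a few decades
    base <- exp(rnorm(config$n_genes, 0, 1.5))
    base <- base / sum(base)

    ## signature genes must be quantifiable: swap them into the upper
    ## half of the abundance draw (a diagnostic marker on a
    ## near-zero-count probe is undetectable by construction). DE genes
    ## keep their random abundances -- real DE spans the expressed
    ## range, and concentrating 50 large effects among the most
    ## abundant genes would distort the library composition. The
    ## overall abundance distribution is unchanged; only labels move.
    planted <- seq_len(config$n_signature_genes) +
      config$n_housekeeping + config$n_de_genes
    if (length(planted)) {
      upper <- order(base, decreasing = TRUE)[
        seq_len(ceiling(config$n_genes / 2))]
      need <- setdiff(planted, upper)
      pool <- setdiff(upper, planted)
      m <- min(length(need), length(pool))
      if (m > 0) {
        need <- need[seq_len(m)]
        donors <- pool[sample.int(length(pool), m)]
        tmp <- base[need]; base[need] <- base[donors]; base[donors] <- tmp
      }
    }

    ## per-group log2 offsets
    eff <- matrix(0, config$n_genes, 3,
                  dimnames = list(gene_ids, names(config$n_per_group)))
    true_logfc <- numeric(config$n_genes)
    if (length(de_idx)) {
      s <- rep_len(c(1, -1), length(de_idx))
      eff[de_idx, 3] <- s * config$de_logfc        # MST shifted vs SN/AST
      true_logfc[de_idx] <- s * config$de_logfc
    }
    sig_sign <- integer(config$n_genes)
    if (length(sig_idx)) {
      s <- rep_len(c(1, -1), length(sig_idx))
      eff[sig_idx, 2] <- s * config$signature_step
      eff[sig_idx, 3] <- s * 2 * config$signature_step
      true_logfc[sig_idx] <- s * 2 * config$signature_step
      sig_sign[sig_idx] <- s
    }

    lib <- pmax(1, round(rlnorm(n, config$libsize_log_mean,
                                config$libsize_log_sd)))
    gi <- match(groups, colnames(eff))
    mu <- (base * 2^eff[, gi, drop = FALSE]) *
      rep(lib, each = config$n_genes)
    counts <- matrix(as.integer(rnbinom(length(mu),
                                        size = 1 / config$nb_dispersion,
                                        mu = mu)),
                     nrow = config$n_genes,
                     dimnames = list(gene_ids, sample_ids))

    info <- data.frame(
      is_de = seq_len(config$n_genes) %in% de_idx,
      is_signature = seq_len(config$n_genes) %in% sig_idx,
      true_logfc = true_logfc,
      sig_sign = sig_sign,
      row.names = gene_ids)
    cohort <- count_cohort(counts, groups, gene_role = role, gene_info = info)
    attr(cohort, "config") <- config
    cohort
  })
}

#' Write a cohort as a TSV fixture set
#'
#' Emits `counts.tsv` (genes x samples), `samples.tsv` (`sample_id`,
#' `group`) and `genes.tsv` (`gene_id`, `role`, ground-truth columns) in
#' the dialects read back by [read_counts()]; the round trip is lossless.
#'
#' @param cohort a [count_cohort()].
#' @param directory output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_fixture <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  cpath <- file.path(directory, "counts.tsv")
  spath <- file.path(directory, "samples.tsv")
  gpath <- file.path(directory, "genes.tsv")
  ctab <- data.frame(gene_id = cohort$gene_ids, cohort$counts,
                     check.names = FALSE)
  write.table(ctab, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = cohort$sample_ids,
                         group = unname(cohort$group)),
              spath, sep = "\t", quote = FALSE, row.names = FALSE)
  gtab <- data.frame(gene_id = cohort$gene_ids,
                     role = unname(cohort$gene_role))
  if (!is.null(cohort$gene_info)) gtab <- cbind(gtab, cohort$gene_info)
  write.table(gtab, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = cpath, samples = spath, genes = gpath))
}
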