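make_gsea_fixture <- function(seed = 21L) {
  co <- null_cohort(seed = seed, n_genes = 300L)
  ex <- normalize_voom(co)
  list(cohort = co, expr = ex,
       sets = random_sets(co, n_sets = 25L, size = 20L, seed = seed))
}

test_that("camera results satisfy the structural invariants", {
  fx <- make_gsea_fixture()
  res <- camera_test(fx$expr, fx$cohort, c("SN", "MST"), fx$sets)
  expect_equal(nrow(res), 25L)
  expect_equal(res$vif, 1 + (res$n_genes - 1) * res$rho_bar, tolerance = 1e-12)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(res$direction %in% c("Up", "Down")))
  # reversing the contrast flips direction, keeps p
  rev_ <- camera_test(fx$expr, fx$cohort, c("MST", "SN"), fx$sets)
  expect_equal(rev_$p, res$p, tolerance = 1e-10)
  expect_true(all(rev_$direction != res$direction))
})

test_that("rho forced to 0 reduces to the unadjusted two-sample z test", {
  fx <- make_gsea_fixture(seed = 22L)
  res0 <- camera_test(fx$expr, fx$cohort, c("SN", "MST"), fx$sets,
                      rho_fixed = 0)
  expect_true(all(res0$vif == 1))
  resE <- camera_test(fx$expr, fx$cohort, c("SN", "MST"), fx$sets)
  # estimated-rho p differs but stays on the same side for strong sets
  expect_equal(cor(res0$p, resE$p, method = "spearman"), 1,
               tolerance = 0.25)
})

test_that("raising rho never decreases p (monotone correlation penalty)", {
  fx <- make_gsea_fixture(seed = 23L)
  rhos <- c(0, 0.02, 0.05, 0.1, 0.2)
  ps <- sapply(rhos, function(r)
    camera_test(fx$expr, fx$cohort, c("SN", "MST"), fx$sets,
                rho_fixed = r)$p)
  for (i in seq_len(nrow(ps))) expect_true(all(diff(ps[i, ]) >= -1e-12))
})

test_that("camera agrees with the limma reference implementation", {
  fx <- make_gsea_fixture(seed = 24L)
  res <- camera_test(fx$expr, fx$cohort, c("SN", "MST"), fx$sets)
  keep <- fx$cohort$group %in% c("SN", "MST")
  design <- model.matrix(~ factor(fx$cohort$group[keep], c("SN", "MST")))
  ref <- limma::camera(
    fx$expr$logexp[, keep],
    index = lapply(fx$sets, function(s) which(fx$cohort$gene_ids %in% s)),
    design = design, weights = fx$expr$weights[, keep],
    inter.gene.cor = NA, allow.neg.cor = TRUE, sort = FALSE)
  expect_equal(res$p, ref$PValue, tolerance = 1e-4)
  expect_equal(res$rho_bar, ref$Correlation, tolerance = 1e-6)
})

test_that("camera p ranks concord with a label-permutation oracle on a tiny instance", {
  # 12 genes, 8 samples (4 vs 4): exhaustive permutation of group labels
  set.seed(99)
  n_genes <- 12L; n <- 8L
  counts <- matrix(rnbinom(n_genes * n, mu = 400, size = 10), n_genes,
                   dimnames = list(paste0("g", 1:n_genes), paste0("s", 1:n)))
  # inject a group shift into a few genes so p-values spread out
  counts[1:3, 5:8] <- counts[1:3, 5:8] * 3L
  co <- count_cohort(counts, rep(c("SN", "MST"), each = 4))
  ex <- normalize_voom(co)
  sets <- list(A = c("g1", "g2", "g3"), B = c("g4", "g5", "g6"),
               C = c("g7", "g8", "g9"), D = c("g10", "g11", "g12"),
               E = c("g1", "g5", "g9"), F = c("g2", "g6", "g10"),
               G = c("g3", "g4", "g11"), H = c("g1", "g2", "g12"))
  res <- camera_test(ex, co, c("SN", "MST"), sets)

  # permutation null of the set statistic |mean z in set - mean z out|
  zstat <- function(grp) {
    cop <- count_cohort(counts, grp)
    tab <- fit_contrast(normalize_voom(cop), cop, "SN", "MST")
    df <- attr(tab, "df_total")
    spitzsig:::t_to_z(tab$t_mod, df)
  }
  combs <- combn(8, 4)
  stat_mat <- sapply(seq_len(ncol(combs)), function(k) {
    grp <- rep("MST", 8); grp[combs[, k]] <- "SN"
    z <- zstat(grp)
    vapply(sets, function(s) {
      i <- match(s, rownames(counts))
      abs(mean(z[i]) - mean(z[-i]))
    }, 0)
  })
  obs <- stat_mat[, 1]  # first combination is the observed labeling
  perm_p <- rowMeans(stat_mat >= obs - 1e-12)
  expect_gt(cor(res$p[match(names(sets), res$set_name)], perm_p,
                method = "spearman"), 0.9)
})

test_that("small sets are skipped with a warning; empty collections error", {
  fx <- make_gsea_fixture(seed = 25L)
  sets <- fx$sets[1:3]
  sets$TINY <- fx$cohort$gene_ids[1]
  expect_warning(res <- camera_test(fx$expr, fx$cohort, c("SN", "MST"), sets),
                 "TINY")
  expect_equal(nrow(res), 3L)
  expect_error(camera_test(fx$expr, fx$cohort, c("SN", "MST"), list()),
               "empty")
})

test_that("rank_pathways sorts by q with deterministic tie-breaks", {
  res <- structure(data.frame(
    set_name = c("B", "A", "C", "D"),
    n_genes = 10L, direction = "Up", rho_bar = 0, vif = 1,
    p = c(0.01, 0.01, 0.005, 0.5),
    q = c(0.02, 0.02, 0.02, 0.5)),
    class = c("gsea_result", "data.frame"))
  top <- rank_pathways(res, k = 10)
  expect_equal(top$set_name, c("C", "A", "B", "D"))  # p then name
  expect_equal(top$neg_log10_q, -log10(top$q))
  expect_equal(nrow(rank_pathways(res, k = 2)), 2L)
  expect_error(rank_pathways(res, k = 0), "positive")
})

test_that("a set holding all planted DE genes ranks first", {
  cfg <- synthetic_config(n_per_group = c(SN = 10L, AST = 2L, MST = 10L),
                          n_genes = 300L, n_housekeeping = 10L,
                          n_de_genes = 25L, de_logfc = 2,
                          n_signature_genes = 0L, seed = 26L)
  co <- generate_cohort(cfg)
  ex <- normalize_voom(co)
  # camera tests the mean member statistic, so the planted set must be
  # directional: use the up-regulated planted genes
  planted <- rownames(co$gene_info)[co$gene_info$is_de &
                                      co$gene_info$true_logfc > 0]
  sets <- c(list(PLANTED = planted),
            random_sets(co, n_sets = 15L, size = 25L, seed = 26L))
  res <- camera_test(ex, co, c("SN", "MST"), sets)
  expect_equal(rank_pathways(res, 1)$set_name, "PLANTED")
})
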