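test_that("all coefficients are zero at and above lambda_max", {
  set.seed(1)
  X <- matrix(rnorm(40 * 30), 40, 30, dimnames = list(NULL, paste0("g", 1:30)))
  y <- rbinom(40, 1, 0.5)
  fit <- lasso_logistic_path(X, y)
  expect_true(all(fit$beta[, 1] == 0))
  expect_equal(fit$lambda[1], fit$lambda_max)
  # and strictly some become nonzero further down the path
  expect_gt(sum(fit$beta[, length(fit$lambda)] != 0), 0)
})

test_that("orthonormal squared-loss design matches the soft-threshold closed form", {
  # columns with (1/n) X'X = I: entries +/-1, orthogonal, mean zero
  n <- 8L
  x1 <- rep(c(1, -1), 4)
  x2 <- rep(c(1, 1, -1, -1), 2)
  X <- cbind(a = x1, b = x2)
  set.seed(3)
  y <- 0.9 * x1 - 0.4 * x2 + rnorm(n, 0, 0.2)
  fit <- lasso_logistic_path(X, y, n_lambda = 50, family = "gaussian",
                             lambda_min_ratio = 0.05)
  b_uni <- crossprod(X, y - mean(y)) / n
  for (l in seq_along(fit$lambda)) {
    expected <- sign(b_uni) * pmax(abs(b_uni) - fit$lambda[l], 0)
    expect_equal(unname(fit$beta[, l]), c(expected), tolerance = 1e-6)
  }
})

test_that("at vanishing lambda the logistic fit matches the Newton MLE", {
  set.seed(5)
  n <- 80L
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  eta <- 0.5 + 0.8 * X[, 1] - 0.6 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  fit <- lasso_logistic_path(X, y, n_lambda = 60, lambda_min_ratio = 1e-6)
  ref <- glm(y ~ X, family = binomial())   # independent Newton/IRLS solver
  expect_equal(unname(fit$beta[, 60]), unname(coef(ref)[-1]),
               tolerance = 1e-4)
  expect_equal(fit$a0[60], unname(coef(ref)[1]), tolerance = 1e-4)
})

test_that("the path agrees with glmnet along the whole grid", {
  set.seed(6)
  n <- 41L; p <- 150L
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  y <- rbinom(n, 1, plogis(X[, 1] - X[, 2]))
  fit <- lasso_logistic_path(X, y)
  g <- glmnet::glmnet(X, y, family = "binomial", lambda = fit$lambda,
                      standardize = TRUE, thresh = 1e-12)
  cb <- as.matrix(coef(g))
  expect_lt(max(abs(fit$beta - cb[-1, ])), 5e-3)
  expect_lt(max(abs(fit$a0 - cb[1, ])), 5e-3)
})

test_that("coefficient paths are continuous in lambda", {
  set.seed(7)
  X <- matrix(rnorm(60 * 20), 60, 20, dimnames = list(NULL, paste0("g", 1:20)))
  y <- rbinom(60, 1, plogis(X[, 1]))
  coarse <- lasso_logistic_path(X, y, n_lambda = 100)
  fine <- lasso_logistic_path(X, y, n_lambda = 1000)
  gap <- function(fit) max(abs(fit$beta[, -1] - fit$beta[, -ncol(fit$beta)]))
  expect_lt(gap(fine), gap(coarse))
  expect_lt(gap(fine), 0.02)
})

test_that("single-class y and constant columns are handled", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(lasso_logistic_path(X, rep(1, 20)), "both classes")
  X2 <- cbind(X, const = 1)
  set.seed(8)
  y <- rbinom(20, 1, 0.5)
  fit <- lasso_logistic_path(X2, y)
  expect_true(all(fit$beta["const", ] == 0))
})

test_that("cv_deviance is deterministic in the seed and finds informative genes", {
  set.seed(9)
  n <- 60L; p <- 40L
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  y <- rbinom(n, 1, plogis(3 * X[, 7]))
  fit <- lasso_logistic_path(X, y)
  cv1 <- cv_deviance(X, y, fit, seed = 4)
  cv2 <- cv_deviance(X, y, fit, seed = 4)
  expect_identical(cv1$cv_deviance, cv2$cv_deviance)
  expect_true(all(is.finite(cv1$cv_deviance) & cv1$cv_deviance > 0))
  # the informative gene is in the selected model
  expect_true(fit$beta["g7", cv1$lambda_star_index] != 0)
  # with identical folds, the held-out deviance curve and the selected
  # penalty agree with the reference implementation (noise draws
  # included: the minimum-deviance rule may land anywhere on the path,
  # but both implementations must land in the same place)
  for (k in 1:3) {
    set.seed(100 + k)
    y0 <- rbinom(n, 1, 0.5)
    fit0 <- lasso_logistic_path(X, y0)
    cv0 <- cv_deviance(X, y0, fit0, seed = 5)
    fold <- spitzsig:::stratified_folds(y0, 10, 5)
    ref <- glmnet::cv.glmnet(X, y0, family = "binomial",
                             lambda = fit0$lambda, foldid = fold)
    expect_equal(cv0$cv_deviance, ref$cvm, tolerance = 0.02,
                 ignore_attr = TRUE)
    expect_equal(cv0$lambda_star, ref$lambda.min, tolerance = 1e-8)
  }
})

test_that("stability selection is invariant to gene and sample order", {
  co <- tiny_cohort(seed = 10L, n_per_group = c(SN = 8L, AST = 2L, MST = 8L))
  ex <- normalize_voom(co)
  keep <- ex$group %in% c("SN", "MST")
  X <- t(ex$logexp[, keep])
  y <- factor(ex$group[keep], c("SN", "MST"))
  ss1 <- stability_select(X, y, n_reps = 10, threshold = 5, seed = 3)
  gp <- sample(ncol(X))
  ss2 <- stability_select(X[, gp], y, n_reps = 10, threshold = 5, seed = 3)
  expect_equal(ss2$selection_count[colnames(X)],
               ss1$selection_count)
  # sweep order differs after permutation, so agreement is to the
  # solver tolerance, not bit-exact
  expect_equal(ss2$mean_coef[colnames(X)], ss1$mean_coef, tolerance = 1e-4)
  expect_error(stability_select(X, y, n_reps = 5, threshold = 10),
               "threshold")
})
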