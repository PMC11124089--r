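# response_imputation module: harmonization removes planted shifts, Box-Cox
# grid MLE, variance filter rules, ridge vs OLS oracle, penalty limits,
# planted-model recovery, and prediction contracts.

test_that("harmonization removes a planted additive batch shift", {
  set.seed(21)
  g <- 150
  n <- 100
  genes <- sprintf("g%03d", 1:g)
  base <- matrix(rnorm(g * n, 6), g, n, dimnames = list(genes, paste0("a", 1:n)))
  shifted <- matrix(rnorm(g * n, 6), g, n,
                    dimnames = list(genes, paste0("b", 1:n))) + 2
  h <- harmonize_expression(base, shifted, min_common = 50)
  # shrinkage leaves a small per-gene residual (~(1-w) * sampling noise); the
  # planted 2-unit shift must be reduced to < 0.1 on average across genes
  expect_lt(mean(abs(rowMeans(h$train) - rowMeans(h$target))), 0.1)
  expect_lt(max(abs(rowMeans(h$train) - rowMeans(h$target))), 0.3)
  expect_identical(rownames(h$train), rownames(h$target))
})

test_that("harmonization of identical-distribution batches is ~no-op", {
  set.seed(22)
  g <- 100
  genes <- sprintf("g%03d", 1:g)
  a <- matrix(rnorm(g * 200, 5, 2), g, 200, dimnames = list(genes, paste0("a", 1:200)))
  b <- matrix(rnorm(g * 200, 5, 2), g, 200, dimnames = list(genes, paste0("b", 1:200)))
  h <- harmonize_expression(a, b, min_common = 50)
  drift <- abs(rowMeans(h$train) - rowMeans(a))
  se <- apply(a, 1, sd) / sqrt(200)
  expect_true(all(drift < 3 * se))
  # disjoint universes error
  b2 <- b
  rownames(b2) <- sprintf("x%03d", 1:g)
  expect_error(harmonize_expression(a, b2), "disjoint")
  expect_error(harmonize_expression(a[, 1, drop = FALSE], b), ">= 2 samples")
})

test_that("Box-Cox grid MLE recovers log and identity transforms", {
  set.seed(31)
  logn <- exp(rnorm(500, 1, 0.6))
  pt <- power_transform_response(logn)
  expect_lte(abs(pt$exponent - 0), 0.2)
  # independent oracle: profile likelihood from MASS on the same grid
  skip_if_not_installed("MASS")
  bc <- MASS::boxcox(logn ~ 1, lambda = seq(-2, 2, 0.1), plotit = FALSE)
  expect_equal(pt$exponent, bc$x[which.max(bc$y)], tolerance = 1e-9)
  # positive, roughly normal sample with informative coefficient of variation
  norm_pos <- pmax(rnorm(2000, 8, 3), 0.3)
  pt2 <- power_transform_response(norm_pos)
  bc2 <- MASS::boxcox(norm_pos ~ 1, lambda = seq(-2, 2, 0.1), plotit = FALSE)
  expect_equal(pt2$exponent, bc2$x[which.max(bc2$y)], tolerance = 1e-9)
  # constant vector: identity with warning
  expect_warning(pc <- power_transform_response(rep(3, 12)), "constant")
  expect_equal(pc$values, rep(3, 12))
  expect_equal(pc$exponent, 1)
  expect_error(power_transform_response(c(1, 2, 3)), ">= 10")
  # shift makes values strictly positive
  neg <- rnorm(50, 0, 1)
  ptn <- power_transform_response(neg)
  expect_gt(min(neg) + ptn$shift, 0)
})

test_that("variance filter ranks, rounds up, breaks ties lexicographically", {
  expr <- rbind(g4 = c(0, 4, 8), g3 = c(0, 3, 6), g2 = c(0, 2, 4), g1 = c(0, 1, 2))
  colnames(expr) <- paste0("s", 1:3)
  expect_equal(select_variable_genes(expr, 0.5), c("g4", "g3"))
  expect_setequal(select_variable_genes(expr, 1), rownames(expr))
  # tie at the cut: lexicographically smaller id kept
  expr2 <- rbind(a = c(0, 2, 4), c = c(0, 1, 2), b = c(0, 1, 2))
  colnames(expr2) <- paste0("s", 1:3)
  expect_equal(select_variable_genes(expr2, 0.5), c("a", "b"))
  expect_error(select_variable_genes(expr2, 0), "fraction")
})

test_that("ridge at lambda -> 0 equals OLS; lambda -> Inf collapses to mean", {
  set.seed(41)
  n <- 60
  p <- 10
  x <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- 2 + x %*% beta + rnorm(n, 0, 0.1)
  expr <- t(x)
  dimnames(expr) <- list(sprintf("g%02d", 1:p), sprintf("s%02d", 1:n))
  resp <- setNames(as.vector(y), colnames(expr))
  m0 <- fit_ridge(expr, resp, lambda_grid = 1e-10, nfolds = 5, seed = 1)
  ols <- lm(y ~ scale(x))
  pred_ridge <- glycodrug:::predict_ridge(m0, expr)
  expect_equal(pred_ridge, unname(fitted(ols)), tolerance = 1e-6)
  mInf <- fit_ridge(expr, resp, lambda_grid = 1e12, nfolds = 5, seed = 1)
  expect_true(all(abs(mInf$coef) < 1e-6))
  expect_equal(glycodrug:::predict_ridge(mInf, expr),
               rep(mean(y), n), tolerance = 1e-4)
  # penalty path monotonicity: ||beta|| non-increasing in lambda
  norms <- vapply(10^seq(-3, 4, length.out = 10), function(l)
    sqrt(sum(fit_ridge(expr, resp, lambda_grid = l, nfolds = 5, seed = 1)$coef^2)),
    numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
  expect_error(fit_ridge(expr[, 1:5], resp[1:5]), "fewer than 10")
})

test_that("ridge recovers a planted linear model on held-out data", {
  set.seed(51)
  n <- 300
  p <- 100
  x <- matrix(rnorm(n * p), n, p)
  w <- rnorm(p, 0, 0.3)
  signal <- as.vector(x %*% w)
  y <- signal + rnorm(n, 0, 0.3 * sd(signal))
  train <- 1:200
  test <- 201:300
  expr <- t(x)
  dimnames(expr) <- list(sprintf("g%03d", 1:p), sprintf("s%03d", 1:n))
  resp <- setNames(y, colnames(expr))
  m <- fit_ridge(expr[, train], resp[train], seed = 3)
  pred <- glycodrug:::predict_ridge(m, expr[, test])
  expect_gte(cor(pred, signal[test]), 0.9)
})

test_that("fit-then-predict is invariant to gene and sample order", {
  set.seed(61)
  p <- 30
  n <- 40
  expr <- matrix(rnorm(p * n), p, n,
                 dimnames = list(sprintf("g%02d", 1:p), sprintf("s%02d", 1:n)))
  resp <- setNames(rnorm(n), colnames(expr))
  m1 <- fit_ridge(expr, resp, seed = 5)
  gp <- sample(p)
  m2 <- fit_ridge(expr[gp, ], resp, seed = 5)
  expect_equal(glycodrug:::predict_ridge(m1, expr),
               glycodrug:::predict_ridge(m2, expr[gp, ]), tolerance = 1e-8)
  sp <- sample(n)
  target <- matrix(rnorm(p * 7), p, 7,
                   dimnames = list(rownames(expr), paste0("t", 1:7)))
  m3 <- fit_ridge(expr[, sp], resp[sp], seed = 5)
  # fold assignment keys on sample ids, so column order cannot matter
  expect_equal(glycodrug:::predict_ridge(m1, target),
               glycodrug:::predict_ridge(m3, target), tolerance = 1e-8)
})

test_that("bundle training and imputation contracts", {
  cfg <- tiny_config(n_ccl = 80, n_genes = 150,
                     geneset_sizes = c(glycolysis = 10, oxphos = 20, ar = 6))
  st <- simulate_study(cfg)
  harm <- harmonize_expression(st$ccl$expr, st$cohorts$EC$expr, min_common = 50)
  auc <- st$ccl$auc
  auc[1:75, 2] <- NA # too few measured lines -> skipped
  expect_message(
    bundle <- train_imputation_models(harm$train, auc, seed = 9),
    "skipping")
  expect_false(st$ccl$metadata$drug_id[2] %in% names(bundle$models))
  expect_length(bundle$genes, ceiling(0.5 * nrow(harm$train)))
  imp <- impute_response(bundle, harm$target)
  expect_identical(rownames(imp), colnames(st$cohorts$EC$expr))
  expect_true(all(is.finite(imp)))
  # patient identical to a training line reproduces its fitted value
  m <- bundle$models[[1]]
  line1 <- harm$train[, 1, drop = FALSE]
  expect_equal(glycodrug:::predict_ridge(m, line1),
               glycodrug:::predict_ridge(m, harm$train)[1], tolerance = 1e-8)
  # missing model genes error, listing them
  expect_error(impute_response(bundle, harm$target[-(1:5), ]), "missing model genes")
  # all-zero coefficient model predicts its intercept
  m0 <- m
  m0$coef[] <- 0
  expect_equal(glycodrug:::predict_ridge(m0, harm$target),
               rep(m0$intercept, ncol(harm$target)))
})
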