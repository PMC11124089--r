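# Drug-response imputation: two-batch empirical-Bayes harmonization of
# expression, Box-Cox power transform of measured AUC, variance-based feature
# selection, per-drug ridge regression with seeded 10-fold CV over a log
# lambda grid, and prediction into patient tumors.

# ---- harmonization (two-batch parametric empirical-Bayes location/scale) ----

combat_two_batch <- function(y, batch, conv = 1e-4, max_iter = 200) {
  batches <- unique(batch)
  stopifnot(length(batches) == 2L)
  n_i <- vapply(batches, function(b) sum(batch == b), integer(1))
  n <- ncol(y)
  b_hat <- vapply(batches, function(b) rowMeans(y[, batch == b, drop = FALSE]),
                  numeric(nrow(y)))
  grand <- as.vector(b_hat %*% (n_i / n))
  fitted <- b_hat[, match(batch, batches), drop = FALSE]
  var_pooled <- rowSums((y - fitted)^2) / n
  s <- (y - grand) / sqrt(var_pooled)

  adj <- s
  for (k in seq_along(batches)) {
    sk <- s[, batch == batches[k], drop = FALSE]
    nk <- n_i[k]
    gamma_hat <- rowMeans(sk)
    delta_hat <- apply(sk, 1, stats::var)
    gamma_bar <- mean(gamma_hat)
    t2 <- stats::var(gamma_hat)
    m <- mean(delta_hat)
    s2 <- stats::var(delta_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    g_old <- gamma_hat
    d_old <- delta_hat
    for (it in seq_len(max_iter)) {
      g_new <- (nk * t2 * gamma_hat + d_old * gamma_bar) / (nk * t2 + d_old)
      sum2 <- rowSums((sk - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (nk / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new
      d_old <- d_new
      if (change < conv) break
    }
    adj[, batch == batches[k]] <- (sk - g_old) / sqrt(d_old)
  }
  adj * sqrt(var_pooled) + grand
}

#' Harmonize training and target expression matrices
#'
#' Restricts both matrices to their common genes and adjusts the combined
#' matrix with a two-batch empirical-Bayes location-scale procedure
#' (per-gene standardization, batch effects shrunk toward parametric priors,
#' data back-transformed), then splits the result back by source.
#'
#' @param train_expr,target_expr genes x samples matrices (>= 2 samples each).
#' @param min_common minimum acceptable number of common genes.
#' @return list with harmonized `train` and `target` matrices.
#' @export
harmonize_expression <- function(train_expr, target_expr, min_common = 100) {
  if (ncol(train_expr) < 2L || ncol(target_expr) < 2L) {
    stop("harmonize_expression: each source needs >= 2 samples")
  }
  common <- intersect(rownames(train_expr), rownames(target_expr))
  if (!length(common)) stop("harmonize_expression: disjoint gene universes")
  if (length(common) < min_common) {
    stop(sprintf("harmonize_expression: only %d common genes (< %d)",
                 length(common), min_common))
  }
  a <- train_expr[common, , drop = FALSE]
  b <- target_expr[common, , drop = FALSE]
  ok <- apply(a, 1, stats::sd) > 0 & apply(b, 1, stats::sd) > 0
  if (any(!ok)) {
    warning(sum(!ok), " zero-variance gene(s) excluded from harmonization")
    a <- a[ok, , drop = FALSE]
    b <- b[ok, , drop = FALSE]
  }
  if (!nrow(a)) stop("harmonize_expression: no usable genes left")
  batch <- rep(c("train", "target"), c(ncol(a), ncol(b)))
  adj <- combat_two_batch(cbind(a, b), batch)
  list(train = adj[, batch == "train", drop = FALSE],
       target = adj[, batch == "target", drop = FALSE])
}

# ---- response power transform (Box-Cox by grid MLE) ----

box_cox <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Power-transform a measured response vector
#'
#' Shifts the values to be strictly positive (`shift = max(0, eps - min)`),
#' then picks the Box-Cox exponent by maximum profile likelihood over a
#' bounded grid. A constant vector is returned unchanged with exponent 1 and
#' a warning.
#'
#' @param auc numeric vector with >= 10 finite values.
#' @param grid candidate exponents.
#' @param eps positivity margin for the shift.
#' @return list with `values` (transformed, NA kept in place), `shift`,
#'   `exponent`, class `power_transform`.
#' @export
power_transform_response <- function(auc, grid = seq(-2, 2, by = 0.1),
                                     eps = 1e-6) {
  ok <- is.finite(auc)
  x <- auc[ok]
  if (length(x) < 10L) stop("power_transform_response needs >= 10 finite values")
  if (stats::sd(x) == 0) {
    warning("constant response vector: identity transform applied")
    return(structure(list(values = auc, shift = 0, exponent = 1),
                     class = "power_transform"))
  }
  shift <- max(0, eps - min(x))
  y <- x + shift
  n <- length(y)
  slog <- sum(log(y))
  ll <- vapply(grid, function(l) {
    z <- box_cox(y, l)
    -n / 2 * log(mean((z - mean(z))^2)) + (l - 1) * slog
  }, numeric(1))
  lambda <- grid[which.max(ll)]
  out <- rep(NA_real_, length(auc))
  out[ok] <- box_cox(y, lambda)
  structure(list(values = out, shift = shift, exponent = lambda),
            class = "power_transform")
}

#' Select the most variable genes
#'
#' Genes ranked by variance across samples; the top `ceiling(fraction * G)`
#' are returned, ties broken by lexicographic gene id.
#'
#' @param expr genes x samples matrix.
#' @param fraction fraction of genes to keep, in (0, 1].
#' @return character vector of gene ids, in decreasing-variance order.
#' @export
select_variable_genes <- function(expr, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  v <- apply(expr, 1, stats::var)
  ord <- order(-v, rownames(expr), method = "radix")
  rownames(expr)[ord][seq_len(ceiling(fraction * nrow(expr)))]
}

# ---- ridge regression (exact, via eigen-decomposition of the Gram matrix) --

standardize_cols <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

# decomposition reusable across drugs sharing the same sample set
ridge_decomp <- function(x) {
  std <- standardize_cols(x)
  xs <- std$x
  n <- nrow(xs)
  p <- ncol(xs)
  if (n <= p) {
    e <- eigen(tcrossprod(xs), symmetric = TRUE)
    list(kind = "n", xs = xs, q = e$vectors, vals = pmax(e$values, 0),
         center = std$center, scale = std$scale)
  } else {
    e <- eigen(crossprod(xs), symmetric = TRUE)
    list(kind = "p", xs = xs, q = e$vectors, vals = pmax(e$values, 0),
         center = std$center, scale = std$scale)
  }
}

# coefficients (standardized scale) for one lambda
ridge_coefs <- function(dec, yc, lambda) {
  if (dec$kind == "n") {
    # beta = X' Q diag(1/(vals + lambda)) Q' y
    w <- crossprod(dec$q, yc) / (dec$vals + lambda)
    as.vector(crossprod(dec$xs, dec$q %*% w))
  } else {
    w <- crossprod(dec$q, crossprod(dec$xs, yc)) / (dec$vals + lambda)
    as.vector(dec$q %*% w)
  }
}

# Fold assignment is a function of the (sorted) sample ids, not of column
# order, so fit-then-predict is invariant to sample permutations.
make_cv_folds <- function(ids, nfolds, seed) {
  set.seed(seed)
  f <- sample(rep(seq_len(nfolds), length.out = length(ids)))
  f[match(ids, sort(ids))]
}

# per-fold decompositions for a fixed design matrix
ridge_fold_cache <- function(x, folds) {
  lapply(sort(unique(folds)), function(f) {
    dec <- ridge_decomp(x[folds != f, , drop = FALSE])
    xv <- sweep(sweep(x[folds == f, , drop = FALSE], 2, dec$center),
                2, dec$scale, "/")
    # validation predictor against the training eigenbasis
    gq <- if (dec$kind == "n") (xv %*% t(dec$xs)) %*% dec$q else xv %*% dec$q
    list(dec = dec, gq = gq, val = which(folds == f), train = which(folds != f))
  })
}

cv_fold_mse <- function(fold, y, lambda_grid) {
  dec <- fold$dec
  yt <- y[fold$train]
  yv <- y[fold$val]
  yc <- yt - mean(yt)
  vapply(lambda_grid, function(l) {
    if (dec$kind == "n") {
      w <- crossprod(dec$q, yc) / (dec$vals + l)
    } else {
      w <- crossprod(dec$q, crossprod(dec$xs, yc)) / (dec$vals + l)
    }
    pred <- as.vector(fold$gq %*% w) + mean(yt)
    mean((yv - pred)^2)
  }, numeric(1))
}

#' Fit a ridge model for one drug
#'
#' Coefficients minimize `||y - X b - b0||^2 + lambda ||b||^2` on
#' column-standardized predictors with an unpenalized intercept; `lambda` is
#' chosen by seeded 10-fold cross-validation over a logarithmic grid
#' minimizing mean squared error. Solved exactly through an
#' eigen-decomposition of the Gram matrix.
#'
#' @param expr genes x samples training expression (the model's gene list).
#' @param response named numeric response vector (transformed AUC), names =
#'   training sample ids; must align with `colnames(expr)`.
#' @param lambda_grid penalty grid (default 25 points, 1e-3 to 1e4).
#' @param nfolds CV folds.
#' @param seed fold-assignment seed.
#' @param .cache optional precomputed fold cache + full-data decomposition
#'   (internal; shared across drugs with identical training samples).
#' @return list with `genes`, `coef` (standardized scale), `center`, `scale`,
#'   `intercept`, `lambda`, `cv_mse`, `n`; class `ridge_model`.
#' @export
fit_ridge <- function(expr, response,
                      lambda_grid = 10^seq(-3, 4, length.out = 25),
                      nfolds = 10, seed = 1, .cache = NULL) {
  samples <- intersect(colnames(expr), names(response))
  if (length(samples) < 10L) {
    stop("fit_ridge: fewer than 10 aligned training samples")
  }
  x <- t(expr[, samples, drop = FALSE])
  y <- as.vector(response[samples])
  if (is.null(.cache)) {
    folds <- make_cv_folds(samples, nfolds, seed)
    .cache <- list(folds = ridge_fold_cache(x, folds), full = ridge_decomp(x))
  }
  mse_mat <- matrix(vapply(.cache$folds, cv_fold_mse,
                           numeric(length(lambda_grid)),
                           y = y, lambda_grid = lambda_grid),
                    nrow = length(lambda_grid))
  mse <- rowMeans(mse_mat)
  lambda <- lambda_grid[which.min(mse)]
  dec <- .cache$full
  beta <- ridge_coefs(dec, y - mean(y), lambda)
  structure(list(genes = colnames(x),
                 coef = stats::setNames(beta, colnames(x)),
                 center = dec$center, scale = dec$scale,
                 intercept = mean(y), lambda = lambda,
                 cv_mse = stats::setNames(mse, signif(lambda_grid, 3)),
                 n = length(y)),
            class = "ridge_model")
}

predict_ridge <- function(model, expr) {
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing)) {
    stop("missing model genes in expression matrix: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10))
  }
  xs <- (t(expr[model$genes, , drop = FALSE]) -
           matrix(model$center, ncol(expr), length(model$genes), byrow = TRUE)) /
    matrix(model$scale, ncol(expr), length(model$genes), byrow = TRUE)
  as.vector(xs %*% model$coef) + model$intercept
}

#' Train per-drug ridge imputation models
#'
#' Applies the variance-based feature filter to the harmonized training
#' matrix, power-transforms each drug's measured AUC, and fits a seeded
#' cross-validated ridge model per drug (complete-case per drug; drugs with
#' fewer than 10 measured lines are skipped with a message).
#'
#' @param train_expr harmonized genes x cell lines expression matrix.
#' @param auc cell lines x drugs measured AUC matrix.
#' @param fraction feature-selection fraction (default 0.5).
#' @param lambda_grid,nfolds,seed passed to [fit_ridge()].
#' @return list of class `ridge_model_bundle`: `models` (per drug), `genes`,
#'   `skipped` (named reasons).
#' @export
train_imputation_models <- function(train_expr, auc, fraction = 0.5,
                                    lambda_grid = 10^seq(-3, 4, length.out = 25),
                                    nfolds = 10, seed = 1) {
  lines <- intersect(colnames(train_expr), rownames(auc))
  if (length(lines) < 10L) stop("fewer than 10 cell lines shared by expression and AUC")
  genes <- select_variable_genes(train_expr[, lines, drop = FALSE], fraction)
  sub <- train_expr[genes, lines, drop = FALSE]
  x_full <- t(sub)
  folds_full <- make_cv_folds(lines, nfolds, sub_seed(seed, 101))
  cache_full <- NULL
  models <- list()
  skipped <- character(0)
  for (d in colnames(auc)) {
    y <- auc[lines, d]
    ok <- is.finite(y)
    if (sum(ok) < 10L) {
      skipped[d] <- sprintf("only %d measured responses (< 10)", sum(ok))
      message("skipping ", d, ": ", skipped[d])
      next
    }
    pt <- power_transform_response(y[ok])
    resp <- stats::setNames(pt$values, lines[ok])
    if (all(ok)) {
      if (is.null(cache_full)) {
        cache_full <- list(folds = ridge_fold_cache(x_full, folds_full),
                           full = ridge_decomp(x_full))
      }
      m <- fit_ridge(sub, resp, lambda_grid, nfolds,
                     seed = sub_seed(seed, 101), .cache = cache_full)
    } else {
      m <- fit_ridge(sub[, lines[ok], drop = FALSE], resp, lambda_grid, nfolds,
                     seed = sub_seed(seed, 101))
    }
    m$transform <- list(shift = pt$shift, exponent = pt$exponent)
    m$drug_id <- d
    models[[d]] <- m
  }
  structure(list(models = models, genes = genes, fraction = fraction,
                 lambda_grid = lambda_grid, seed = seed, skipped = skipped),
            class = "ridge_model_bundle")
}

#' Impute drug response in target samples
#'
#' Per drug, predicted response = intercept + sum(coef * standardized
#' expression); values stay on the transformed-AUC scale (lower = predicted
#' more sensitive). The target matrix must already be harmonized with the
#' training matrix.
#'
#' @param bundle a `ridge_model_bundle`.
#' @param target_expr harmonized genes x samples matrix.
#' @return samples x drugs numeric matrix.
#' @export
impute_response <- function(bundle, target_expr) {
  stopifnot(inherits(bundle, "ridge_model_bundle"))
  if (!length(bundle$models)) stop("bundle contains no trained models")
  out <- vapply(bundle$models, predict_ridge, numeric(ncol(target_expr)),
                expr = target_expr)
  out <- matrix(out, ncol = length(bundle$models),
                dimnames = list(colnames(target_expr), names(bundle$models)))
  out
}

#' Serialize a model bundle to JSON
#' @param bundle a `ridge_model_bundle`.
#' @param path output path.
#' @export
write_model_bundle_json <- function(bundle, path) {
  ser <- lapply(bundle$models, function(m) {
    list(drug_id = m$drug_id, genes = m$genes, coef = as.list(m$coef),
         center = as.list(stats::setNames(m$center, m$genes)),
         scale = as.list(stats::setNames(m$scale, m$genes)),
         intercept = m$intercept, lambda = m$lambda, n = m$n,
         transform = m$transform)
  })
  jsonlite::write_json(list(genes = bundle$genes, fraction = bundle$fraction,
                            seed = bundle$seed, models = ser),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
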