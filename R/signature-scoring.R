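# Per-sample gene-set variation scoring and AR/glycolysis stratification.
#
# The enrichment score follows the gene-set variation analysis recipe:
#  1. per gene, a Gaussian-kernel CDF statistic across samples with bandwidth
#     sd/4 (affine-invariant per gene);
#  2. per sample, genes are ranked by that statistic and the ranks are made
#     symmetric around zero, r = |p/2 - rank|;
#  3. a weighted Kolmogorov-Smirnov random walk (weight exponent tau = 1)
#     steps up by r^tau (normalized over the set) at set genes and down by
#     1/(p - m) elsewhere;
#  4. the score is the largest positive deviation minus the magnitude of the
#     largest negative deviation, hence lies in (-1, 1).

new_score_table <- function(sample_id, signature, score, scale) {
  structure(
    data.frame(sample_id = sample_id, signature = signature, score = score,
               stringsAsFactors = FALSE),
    scale = scale, class = c("score_table", "data.frame"))
}

#' Extract one signature's scores as a named vector
#' @param st a score table.
#' @param signature signature name.
#' @return named numeric vector (names = sample ids).
#' @export
score_vector <- function(st, signature) {
  sub <- st[st$signature == signature, , drop = FALSE]
  if (!nrow(sub)) stop("signature '", signature, "' not present in score table")
  stats::setNames(sub$score, sub$sample_id)
}

# Gaussian-kernel CDF statistic, one gene at a time.
kcdf_statistic <- function(expr, bw_div = 4) {
  z <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    h <- stats::sd(x) / bw_div
    z[i, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / h))
  }
  z
}

ks_walk_score <- function(weights, in_set) {
  m <- sum(in_set)
  p <- length(in_set)
  inc <- ifelse(in_set, weights / sum(weights[in_set]), -1 / (p - m))
  nu <- cumsum(inc)
  max(0, max(nu)) + min(0, min(nu))
}

#' Single-sample gene-set variation scores
#'
#' @param expr genes x samples log-scale expression matrix (>= 2 samples).
#' @param sets a [gene_set_collection()]; each set must overlap the
#'   expression gene universe in >= 2 genes after zero-variance genes are
#'   dropped.
#' @param tau weight exponent of the random walk (default 1).
#' @param bw_div kernel bandwidth divisor: bandwidth = per-gene sd / `bw_div`.
#' @return a score table (`sample_id`, `signature`, `score`) with scale
#'   `"raw"`; scores lie in (-1, 1).
#' @export
gsva_enrichment <- function(expr, sets, tau = 1, bw_div = 4) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2L) stop("gsva_enrichment needs >= 2 samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped before scoring")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  genes <- rownames(expr)
  matched <- list()
  for (nm in names(sets$sets)) {
    mg <- intersect(sets$sets[[nm]], genes)
    if (length(mg) < length(sets$sets[[nm]])) {
      warning(sprintf("set '%s': %d of %d genes matched the expression matrix",
                      nm, length(mg), length(sets$sets[[nm]])))
    }
    if (length(mg) < 2L) {
      stop("set '", nm, "' has fewer than 2 usable genes after filtering")
    }
    matched[[nm]] <- mg
  }
  z <- kcdf_statistic(expr, bw_div)
  p <- nrow(expr)
  out <- list()
  for (j in seq_len(ncol(expr))) {
    pos <- rank_by_score_desc(z[, j], genes) # 1 = highest statistic
    r <- abs(p / 2 - pos)
    ord <- order(pos)
    w_ord <- r[ord]^tau
    genes_ord <- genes[ord]
    for (nm in names(matched)) {
      in_set <- genes_ord %in% matched[[nm]]
      out[[length(out) + 1L]] <- list(
        sample_id = colnames(expr)[j], signature = nm,
        score = ks_walk_score(w_ord, in_set))
    }
  }
  df <- do.call(rbind.data.frame, out)
  new_score_table(df$sample_id, df$signature, df$score, "raw")
}

#' Rescale raw scores to the 0-100 convention
#'
#' Linear min-max map onto `[0, 100]`, applied per signature within the
#' cohort at hand; the order of samples is preserved and both endpoints are
#' attained.
#'
#' @param raw a raw score table (>= 2 distinct values per signature).
#' @return a score table with scale `"percent_0_100"`.
#' @export
rescale_scores <- function(raw) {
  stopifnot(inherits(raw, "score_table"))
  out <- raw
  for (nm in unique(raw$signature)) {
    i <- raw$signature == nm
    x <- raw$score[i]
    rng <- range(x)
    if (diff(rng) == 0) {
      stop("constant raw scores for signature '", nm, "': 0-100 scale undefined")
    }
    out$score[i] <- 100 * (x - rng[1]) / diff(rng)
  }
  attr(out, "scale") <- "percent_0_100"
  out
}

#' AR pathway activity score
#'
#' Each signature gene's expression is standardized to z-scores across
#' samples, z-scores are summed per sample, and the sums are min-max scaled
#' to `[0, 1]` (higher = higher AR pathway activity).
#'
#' @param expr genes x samples expression matrix (>= 2 samples).
#' @param ar_set character vector of AR signature gene ids.
#' @return a score table (signature `"ar_activity"`, scale `"unit_0_1"`).
#' @export
ar_activity <- function(expr, ar_set) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2L) stop("ar_activity needs >= 2 samples")
  present <- intersect(ar_set, rownames(expr))
  if (length(present) < length(ar_set)) {
    warning(sprintf("AR set: %d of %d genes matched the expression matrix",
                    length(present), length(ar_set)))
  }
  if (!length(present)) stop("no AR signature genes present in the matrix")
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance AR signature gene(s) dropped")
    sub <- sub[sds > 0, , drop = FALSE]
  }
  if (!nrow(sub)) stop("all AR signature genes have zero variance")
  z <- (sub - rowMeans(sub)) / apply(sub, 1, stats::sd)
  s <- colSums(z)
  rng <- range(s)
  if (diff(rng) == 0) stop("constant AR z-score sums: 0-1 scale undefined")
  new_score_table(colnames(expr), "ar_activity", (s - rng[1]) / diff(rng),
                  "unit_0_1")
}

#' Stratify samples into AR(low)Gly(high) versus other
#'
#' A sample is `AR_low_Gly_high` iff its AR score is strictly below the
#' median AR score and its glycolysis score strictly above the median
#' glycolysis score; everything else (including values at the median) is
#' `other`.
#'
#' @param ar AR activity score table.
#' @param gly glycolysis score table (signature `"glycolysis"`).
#' @return named character vector of labels, class `strata_labels`.
#' @export
stratify_ar_gly <- function(ar, gly) {
  a <- score_vector(ar, "ar_activity")
  g <- score_vector(gly, "glycolysis")
  if (!setequal(names(a), names(g))) {
    stop("stratify_ar_gly: AR and glycolysis tables cover different samples")
  }
  g <- g[names(a)]
  lab <- ifelse(a < stats::median(a) & g > stats::median(g),
                "AR_low_Gly_high", "other")
  structure(stats::setNames(lab, names(a)), class = "strata_labels")
}
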