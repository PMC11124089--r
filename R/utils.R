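# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed
#'
#' Deterministically maps a master seed plus an integer offset onto a seed
#' below 2^31, so that independent pipeline stages can be re-run in isolation
#' without sharing RNG state.
#'
#' @param seed master integer seed.
#' @param offset integer stage offset.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
sub_seed <- function(seed, offset) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.double(seed)) %% m)
  v <- (s * 48271 + as.double(offset) * 7919 + 1) %% m
  as.integer(v %/% 1 + 1)
}

#' Welch's unequal-variance t-test
#'
#' Plain textbook Welch test with a variance floor so that degenerate
#' zero-variance groups yield a finite statistic instead of a division error.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param alternative "two.sided", "greater" (mean x > mean y) or "less".
#' @param var_floor lower bound on the squared standard error.
#' @return list with `t`, `df`, `p`, `mean_x`, `mean_y`, `n_x`, `n_y`.
#' @examples
#' welch_test(rnorm(10), rnorm(10) + 1)$p
#' @export
welch_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                       var_floor = 1e-12) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) {
    stop("welch_test: both groups need at least 2 finite observations")
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  sex <- vx / nx
  sey <- vy / ny
  se2 <- max(sex + sey, var_floor)
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  denom <- sex^2 / (nx - 1) + sey^2 / (ny - 1)
  df <- if (denom <= 0) nx + ny - 2 else (sex + sey)^2 / denom
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(tt), df),
    greater   = stats::pt(tt, df, lower.tail = FALSE),
    less      = stats::pt(tt, df)
  )
  list(t = tt, df = df, p = p, mean_x = mean(x), mean_y = mean(y),
       n_x = nx, n_y = ny)
}

# Stable ordering of ids: pure lexicographic byte order independent of locale.
lex_order <- function(ids) order(method = "radix", ids)

# rank positions 1..p by decreasing score, ties broken by lexicographic id
rank_by_score_desc <- function(score, ids) {
  ord <- order(-score, ids, method = "radix")
  pos <- integer(length(score))
  pos[ord] <- seq_along(score)
  pos
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simple deterministic 31-bit polynomial string hash, for run manifests.
config_hash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
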