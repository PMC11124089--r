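# Kaplan-Meier product-limit estimation and the two-group log-rank test,
# plus the median-split survival comparison used for biomarker genes.
# Conventions: at a tied time, events are processed before censorings (both
# are at risk at that time); censored subjects leave the risk set after
# their time.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator `S(t) = prod_{ti <= t} (1 - di/ni)` over distinct
#' event times.
#'
#' @param clinical clinical table with `os_months` (> 0) and `os_event`
#'   (1 = death, 0 = censored).
#' @return data.frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `survival` (one row per distinct event time; empty if no events, in
#'   which case S(t) = 1 everywhere). Attribute `n` = number of subjects.
#' @export
km_curve <- function(clinical) {
  validate_clinical(clinical)
  time <- clinical$os_months
  event <- clinical$os_event
  if (!length(time)) stop("km_curve: empty clinical table")
  ev_times <- sort(unique(time[event == 1]))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
                       survival = surv),
            n = length(time), class = c("km_curve", "data.frame"))
}

#' Two-group log-rank test
#'
#' Observed minus expected events in group 1 summed over distinct event
#' times, variance by the hypergeometric formula;
#' `chi2 = (O - E)^2 / V` with 1 degree of freedom.
#'
#' @param clinical clinical table (`sample_id`, `os_months`, `os_event`).
#' @param groups labels (2 levels) named by sample id, or aligned with the
#'   clinical rows.
#' @return list: `chi2`, `p`, `observed`, `expected` (per group), `groups`.
#' @export
log_rank_test <- function(clinical, groups) {
  validate_clinical(clinical)
  if (!is.null(names(groups))) {
    groups <- groups[clinical$sample_id]
  }
  g <- factor(as.vector(groups))
  if (nlevels(g) != 2L) stop("log_rank_test: exactly two groups required")
  if (any(table(g) == 0)) stop("log_rank_test: one group is empty")
  time <- clinical$os_months
  event <- clinical$os_event
  if (sum(event) == 0) {
    warning("log_rank_test: no events; p set to 1")
    return(list(chi2 = 0, p = 1,
                observed = stats::setNames(c(0, 0), levels(g)),
                expected = stats::setNames(c(0, 0), levels(g)),
                groups = levels(g)))
  }
  is1 <- g == levels(g)[1]
  ev_times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & is1)
    dj <- sum(time == t & event == 1)
    d1j <- sum(time == t & event == 1 & is1)
    o1 <- o1 + d1j
    e1 <- e1 + dj * n1j / nj
    if (nj > 1) {
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  d_total <- sum(event)
  list(chi2 = chi2, p = p,
       observed = stats::setNames(c(o1, d_total - o1), levels(g)),
       expected = stats::setNames(c(e1, d_total - e1), levels(g)),
       groups = levels(g))
}

#' Median-split survival comparison for a biomarker gene
#'
#' Samples with expression strictly above the median are labeled `high`,
#' the rest (including values at the median) `low`; Kaplan-Meier curves and
#' the log-rank comparison are returned.
#'
#' @param expr genes x samples expression matrix.
#' @param gene gene id (must be present).
#' @param clinical clinical table with matching `sample_id`s.
#' @return list: `curves` (named list low/high of [km_curve()]s), `test`
#'   (log-rank result), `labels` (named character vector).
#' @export
median_split_survival <- function(expr, gene, clinical) {
  if (!gene %in% rownames(expr)) stop("gene '", gene, "' not in matrix")
  shared <- intersect(clinical$sample_id, colnames(expr))
  if (length(shared) < 2L) stop("median_split_survival: < 2 matched samples")
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  x <- expr[gene, shared]
  if (stats::sd(x) == 0) stop("all-equal expression for '", gene, "': split undefined")
  lab <- ifelse(x > stats::median(x), "high", "low")
  labels <- stats::setNames(lab, shared)
  curves <- lapply(c(low = "low", high = "high"), function(l)
    km_curve(cl[lab == l, , drop = FALSE]))
  test <- log_rank_test(cl, labels)
  list(curves = curves, test = test, labels = labels)
}
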