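# Score-response association screening, BH-FDR control, Drug_HG/Drug_DE set
# formation with cross-cohort intersection, primary-MOA summary, and the
# four-filter candidate cascade.
#
# Per drug, ordinary least squares of the metabolic score on the predicted
# response:
#   GlycolysisScore = b0 + b1 * PredictedDrugResponse
#   OXPHOSScore     = b0 + b1 * PredictedDrugResponse + b2 * AgeAtProcurement
# A significantly negative b1 (BH-FDR < alpha) in every cohort nominates the
# drug: high-score tumors are predicted more sensitive (lower AUC).

#' Associate metabolic scores with imputed drug responses
#'
#' Ordinary least squares of the score on the predicted response for each
#' drug; for OXPHOS, age at procurement is added as a covariate when at
#' least 3 non-missing ages are available. Complete-case per model. Drugs
#' with a constant predicted response get `beta1 = 0, p = 1` with a warning.
#'
#' @param scores a score table containing the signature named by `score_type`.
#' @param imputed samples x drugs imputed-response matrix.
#' @param clinical optional clinical table (for `age_at_procurement`).
#' @param score_type `"glycolysis"` or `"oxphos"`.
#' @param cohort,source labels stored with each record.
#' @return data.frame of class `association_records`: drug_id, score_type,
#'   cohort, source, beta0, beta1, beta2, p_value, n.
#' @export
score_response_association <- function(scores, imputed, clinical = NULL,
                                       score_type = c("glycolysis", "oxphos"),
                                       cohort = NA_character_,
                                       source = NA_character_) {
  score_type <- match.arg(score_type)
  sv <- score_vector(scores, score_type)
  samples <- intersect(rownames(imputed), names(sv))
  if (length(samples) < 3L) stop("fewer than 3 shared samples")
  age <- NULL
  if (score_type == "oxphos" && !is.null(clinical) &&
      "age_at_procurement" %in% names(clinical)) {
    a <- stats::setNames(clinical$age_at_procurement, clinical$sample_id)[samples]
    if (sum(is.finite(a)) >= 3L) age <- a
  }
  rows <- lapply(colnames(imputed), function(d) {
    resp <- imputed[samples, d]
    y <- sv[samples]
    keep <- is.finite(resp) & is.finite(y)
    if (!is.null(age)) keep <- keep & is.finite(age)
    resp <- resp[keep]; y <- y[keep]
    n <- length(resp)
    if (n < 3L || stats::sd(resp) == 0) {
      if (n >= 3L) warning("constant predicted response for ", d, "; p set to 1")
      return(data.frame(drug_id = d, score_type = score_type, cohort = cohort,
                        source = source, beta0 = if (n) mean(y) else NA_real_,
                        beta1 = 0, beta2 = NA_real_, p_value = 1, n = n,
                        stringsAsFactors = FALSE))
    }
    fit <- if (is.null(age)) stats::lm(y ~ resp) else
      stats::lm(y ~ resp + a2, data = data.frame(y = y, resp = resp,
                                                 a2 = age[keep]))
    sm <- summary(fit)$coefficients
    data.frame(drug_id = d, score_type = score_type, cohort = cohort,
               source = source, beta0 = sm[1, 1], beta1 = sm[2, 1],
               beta2 = if (nrow(sm) >= 3) sm[3, 1] else NA_real_,
               p_value = sm[2, 4], n = n, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("association_records", "data.frame"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same order as input, all in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("bh_adjust: p-values must be finite and in [0, 1]")
  }
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Add BH-FDR within each (cohort, source, score_type) family
#'
#' @param records association records (possibly several rbind-ed families).
#' @return records with an `fdr` column.
#' @export
adjust_associations <- function(records) {
  fam <- interaction(records$cohort, records$source, records$score_type,
                     drop = TRUE)
  records$fdr <- NA_real_
  for (f in levels(fam)) {
    i <- fam == f
    records$fdr[i] <- bh_adjust(records$p_value[i])
  }
  records
}

#' Form Drug_HG / Drug_OX / Drug_DE sets and cross-cohort intersections
#'
#' Within each (cohort, source): `Drug_HG` = drugs with `beta1 < 0` and
#' `fdr < alpha` for glycolysis; `Drug_OX` analogous for OXPHOS;
#' `Drug_DE` = their intersection. Cross-cohort sets (per source) intersect
#' over all cohorts present.
#'
#' @param assoc association records (fdr added if absent).
#' @param alpha FDR threshold (default 0.05).
#' @return list of class `nomination_sets` with `per_dataset`,
#'   `cross_cohort`, `cohorts`, `sources`, `alpha`.
#' @export
nominate_drug_sets <- function(assoc, alpha = 0.05) {
  if (is.null(assoc$fdr)) assoc <- adjust_associations(assoc)
  cohorts <- unique(assoc$cohort)
  sources <- unique(assoc$source)
  sel <- function(co, so, ty) {
    i <- assoc$cohort == co & assoc$source == so & assoc$score_type == ty &
      assoc$beta1 < 0 & assoc$fdr < alpha
    sort(unique(assoc$drug_id[i]))
  }
  per <- list()
  for (so in sources) {
    for (co in cohorts) {
      hg <- sel(co, so, "glycolysis")
      ox <- sel(co, so, "oxphos")
      per[[paste(co, so, sep = "|")]] <-
        list(hg = hg, ox = ox, de = intersect(hg, ox))
    }
  }
  cross <- list()
  for (so in sources) {
    pick <- function(what) Reduce(intersect, lapply(cohorts, function(co)
      per[[paste(co, so, sep = "|")]][[what]]))
    cross[[so]] <- list(hg = pick("hg"), ox = pick("ox"), de = pick("de"))
  }
  structure(list(per_dataset = per, cross_cohort = cross, cohorts = cohorts,
                 sources = sources, alpha = alpha),
            class = "nomination_sets")
}

#' @export
print.nomination_sets <- function(x, ...) {
  cat("<nomination_sets> alpha =", x$alpha, "\n")
  for (nm in names(x$per_dataset)) {
    s <- x$per_dataset[[nm]]
    cat(sprintf("  %-18s HG %3d  OX %3d  DE %3d\n", nm,
                length(s$hg), length(s$ox), length(s$de)))
  }
  for (so in names(x$cross_cohort)) {
    s <- x$cross_cohort[[so]]
    cat(sprintf("  cross-cohort %-6s HG %3d  OX %3d  DE %3d\n", so,
                length(s$hg), length(s$ox), length(s$de)))
  }
  invisible(x)
}

#' Summarize mechanisms of action among cross-cohort candidates
#'
#' Within each cohort the candidate drugs are ranked by the glycolysis-model
#' `beta1` p-value and the top 50% most significant kept; the cross-cohort
#' overlap of those halves is summarized by MOA, and MOAs appearing at least
#' twice are flagged primary. Missing MOA annotations count as "unknown".
#'
#' @param cross_cohort_hg character vector of cross-cohort Drug_HG ids.
#' @param metadata drug metadata (drug_id, moa).
#' @param assoc association records (glycolysis rows used).
#' @return data.frame moa / n_drugs / primary, plus attribute
#'   `overlap_drugs`.
#' @export
primary_moa_summary <- function(cross_cohort_hg, metadata, assoc) {
  gl <- assoc[assoc$score_type == "glycolysis" &
                assoc$drug_id %in% cross_cohort_hg, , drop = FALSE]
  if (!nrow(gl) || !length(cross_cohort_hg)) {
    return(structure(data.frame(moa = character(0), n_drugs = integer(0),
                                primary = logical(0)),
                     overlap_drugs = character(0)))
  }
  halves <- lapply(unique(gl$cohort), function(co) {
    sub <- gl[gl$cohort == co, , drop = FALSE]
    sub <- sub[order(sub$p_value, sub$drug_id, method = "radix"), ]
    utils::head(sub$drug_id, ceiling(nrow(sub) / 2))
  })
  overlap <- Reduce(intersect, halves)
  moa <- stats::setNames(metadata$moa, metadata$drug_id)[overlap]
  moa[is.na(moa) | moa == ""] <- "unknown"
  tab <- sort(table(moa), decreasing = TRUE)
  structure(data.frame(moa = names(tab), n_drugs = as.integer(tab),
                       primary = as.integer(tab) >= 2, row.names = NULL,
                       stringsAsFactors = FALSE),
            overlap_drugs = overlap)
}

# per-drug slopes of CCL scores on measured AUC (filter 3)
measured_trend_slopes <- function(ccl_scores, auc, drug) {
  if (!drug %in% colnames(auc)) return(NULL)
  y <- auc[, drug]
  out <- list()
  for (ty in c("glycolysis", "oxphos")) {
    sv <- score_vector(ccl_scores, ty)
    shared <- intersect(names(sv), rownames(auc))
    yy <- y[shared]
    keep <- is.finite(yy)
    if (sum(keep) < 3L) return(NULL)
    fit <- stats::lm(sv[shared][keep] ~ yy[keep])
    out[[ty]] <- list(slope = unname(stats::coef(fit)[2]),
                      p = summary(fit)$coefficients[2, 4])
  }
  out
}

#' Run the four-filter candidate cascade
#'
#' Filter 1 keeps drugs with development status approved or clinical.
#' Filter 2 removes drugs with a significantly opposing association
#' (`beta1 > 0`, `fdr < alpha`) in any (cohort, source, score) record.
#' Filter 3 regresses cell-line glycolysis and OXPHOS scores on measured AUC
#' per drug and keeps drugs with both slopes negative (sign only; slopes and
#' p-values are recorded in the trail).
#' Filter 4 scores pre/post perturbation replicates and removes drugs whose
#' glycolysis or OXPHOS score significantly increases after treatment
#' (one-sided Welch, p < 0.05); drugs without perturbation data pass with
#' reason "no data".
#'
#' @param candidates character vector of candidate drug ids.
#' @param metadata drug metadata (drug_id, moa, status).
#' @param all_assoc association records across all datasets (fdr added if
#'   absent).
#' @param ccl_expr cell-line expression matrix.
#' @param ccl_measured cell lines x drugs measured AUC matrix.
#' @param perturb a `perturbation_set` (may cover only some drugs).
#' @param sets gene-set collection with glycolysis and oxphos sets.
#' @param alpha significance threshold reused from nomination.
#' @param ccl_scores optional precomputed rescaled cell-line score table
#'   (computed from `ccl_expr` if NULL).
#' @return list of class `filter_trail`: `stages`, `trail` (drug x stage
#'   pass/fail with reasons), `surviving` (nested sets after each stage).
#' @export
run_filter_cascade <- function(candidates, metadata, all_assoc, ccl_expr,
                               ccl_measured, perturb, sets, alpha = 0.05,
                               ccl_scores = NULL) {
  if (!length(candidates)) stop("run_filter_cascade: empty candidate set")
  if (is.null(all_assoc$fdr)) all_assoc <- adjust_associations(all_assoc)
  stages <- c("development_status", "cross_dataset_consistency",
              "measured_response_trend", "perturbation_metabolic_activation")
  trail <- list()
  note <- function(drug, stage, pass, reason) {
    trail[[length(trail) + 1L]] <<- data.frame(
      drug_id = drug, stage = stage, pass = pass, reason = reason,
      stringsAsFactors = FALSE)
  }
  surviving <- list(initial = sort(candidates))

  status <- stats::setNames(metadata$status, metadata$drug_id)
  keep <- character(0)
  for (d in surviving$initial) {
    ok <- isTRUE(status[d] %in% c("approved", "clinical"))
    note(d, stages[1], ok,
         if (ok) sprintf("status %s", status[d]) else
           sprintf("status %s not approved/clinical", status[d] %||% "missing"))
    if (ok) keep <- c(keep, d)
  }
  surviving[[stages[1]]] <- keep

  keep2 <- character(0)
  for (d in surviving[[stages[1]]]) {
    opp <- all_assoc$drug_id == d & all_assoc$beta1 > 0 & all_assoc$fdr < alpha
    ok <- !any(opp)
    note(d, stages[2], ok,
         if (ok) "consistent across datasets" else {
           r <- all_assoc[which(opp)[1], ]
           sprintf("opposing %s association in %s/%s (fdr %.3g)",
                   r$score_type, r$cohort, r$source, r$fdr)
         })
    if (ok) keep2 <- c(keep2, d)
  }
  surviving[[stages[2]]] <- keep2

  if (is.null(ccl_scores) && length(surviving[[stages[2]]])) {
    gm <- gene_set_collection(sets$sets[c("glycolysis", "oxphos")])
    ccl_scores <- rescale_scores(gsva_enrichment(ccl_expr, gm))
  }
  keep3 <- character(0)
  for (d in surviving[[stages[2]]]) {
    sl <- measured_trend_slopes(ccl_scores, ccl_measured, d)
    if (is.null(sl)) {
      note(d, stages[3], FALSE, "no measured data")
      next
    }
    ok <- sl$glycolysis$slope < 0 && sl$oxphos$slope < 0
    note(d, stages[3], ok,
         sprintf("slopes gly %.3g (p %.3g), oxphos %.3g (p %.3g)",
                 sl$glycolysis$slope, sl$glycolysis$p,
                 sl$oxphos$slope, sl$oxphos$p))
    if (ok) keep3 <- c(keep3, d)
  }
  surviving[[stages[3]]] <- keep3

  keep4 <- character(0)
  for (d in surviving[[stages[3]]]) {
    if (!d %in% names(perturb)) {
      note(d, stages[4], TRUE, "no data")
      keep4 <- c(keep4, d)
      next
    }
    pp <- perturb[[d]]
    combined <- cbind(pp$pre, pp$post)
    gm <- gene_set_collection(sets$sets[c("glycolysis", "oxphos")])
    sc <- gsva_enrichment(combined, gm)
    arm <- rep(c("pre", "post"), c(ncol(pp$pre), ncol(pp$post)))
    worst <- list(p = 1, sig = "none")
    for (ty in c("glycolysis", "oxphos")) {
      sv <- score_vector(sc, ty)
      w <- welch_test(sv[arm == "post"], sv[arm == "pre"],
                      alternative = "greater")
      if (w$p < worst$p) worst <- list(p = w$p, sig = ty)
    }
    ok <- worst$p >= 0.05
    note(d, stages[4], ok,
         if (ok) sprintf("no significant activation (min p %.3g)", worst$p)
         else sprintf("%s score increases post-treatment (p %.3g)",
                      worst$sig, worst$p))
    if (ok) keep4 <- c(keep4, d)
  }
  surviving[[stages[4]]] <- keep4

  structure(list(stages = stages, trail = do.call(rbind, trail),
                 surviving = surviving),
            class = "filter_trail")
}

#' @export
print.filter_trail <- function(x, ...) {
  cat("<filter_trail>\n")
  for (nm in names(x$surviving)) {
    cat(sprintf("  %-36s %d drugs\n", nm, length(x$surviving[[nm]])))
  }
  invisible(x)
}
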