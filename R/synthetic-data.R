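# Synthetic-data generators. Every pipeline input (cell-line panel, two tumor
# cohorts, drug metadata, PPI edges, perturbation profiles) is generated from
# one latent metabolic program with planted ground truth, so downstream stages
# have a known answer to recover.
#
# Generative model, shared by cell lines and patients:
#   (g_s, o_s) ~ bivariate standard normal with correlation prog_corr
#   a_s        ~ standard normal, independent (AR program)
#   x_gs = baseline_g + loading_g * latent_{prog(g), s} + N(0, sd_g)
# where prog(g) assigns each signature gene to its program and off-signature
# genes have loading 0. Patient cohorts add a cohort-wide batch shift.
# Drug response: AUC_d(s) = alpha_d + gamma_d g_s + delta_d o_s + N(0, noise_sd),
# gamma_d < 0 for planted Drug_HG, gamma_d and delta_d < 0 for planted Drug_DE,
# both 0 for null drugs (lower AUC = more sensitive).

#' Synthetic study configuration
#'
#' Defaults are the stated conditions of the validation suite: 2000 genes,
#' 300 cell lines, two cohorts of 120 tumors, 60 drugs of which 8 are planted
#' glycolysis-targeting (Drug_HG) and 4 dual-effect (Drug_DE), a standardized
#' AUC-on-glycolysis slope of -0.5 with residual sd 0.15 (= 0.3 x |slope|),
#' a 2 log-unit cohort batch shift, latent glycolysis/OXPHOS correlation 0.5,
#' a log-hazard of 0.8 per sd of marker-gene expression and 20% censoring.
#'
#' @param n_genes,n_ccl,n_patients_per_cohort,n_drugs panel dimensions.
#' @param n_planted_hg,n_planted_de planted drug counts.
#' @param geneset_sizes named sizes for the glycolysis / oxphos / ar sets.
#' @param effect_size_gamma standardized slope of AUC on latent glycolysis
#'   for planted drugs (negative).
#' @param noise_sd residual sd of measured AUC around its linear predictor.
#' @param batch_shift additive per-cohort offset (log units); the WC cohort
#'   receives 1.5x this shift to emulate a different unit convention.
#' @param prog_corr correlation of latent glycolysis and OXPHOS activities.
#' @param survival_beta log-hazard per unit standardized marker expression.
#' @param censor_rate independent censoring fraction in `[0, 1)`.
#' @param age_oxphos_slope optional dependence of age on latent OXPHOS
#'   (0 = independent), to exercise the age-adjusted association model.
#' @param n_hub_genes,hub_partners planted PPI hub structure.
#' @param perturb_replicates replicates per arm in perturbation profiles.
#' @param seed master seed; all generators derive sub-streams from it.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000, n_ccl = 300,
                         n_patients_per_cohort = 120, n_drugs = 60,
                         n_planted_hg = 8, n_planted_de = 4,
                         geneset_sizes = c(glycolysis = 40, oxphos = 200, ar = 20),
                         effect_size_gamma = -0.5, noise_sd = 0.15,
                         batch_shift = 2, prog_corr = 0.5,
                         survival_beta = 0.8, censor_rate = 0.2,
                         age_oxphos_slope = 0,
                         n_hub_genes = 5, hub_partners = 30,
                         perturb_replicates = 5, seed = 1) {
  cfg <- list(n_genes = n_genes, n_ccl = n_ccl,
              n_patients_per_cohort = n_patients_per_cohort, n_drugs = n_drugs,
              n_planted_hg = n_planted_hg, n_planted_de = n_planted_de,
              geneset_sizes = geneset_sizes,
              effect_size_gamma = effect_size_gamma, noise_sd = noise_sd,
              batch_shift = batch_shift, prog_corr = prog_corr,
              survival_beta = survival_beta, censor_rate = censor_rate,
              age_oxphos_slope = age_oxphos_slope,
              n_hub_genes = n_hub_genes, hub_partners = hub_partners,
              perturb_replicates = perturb_replicates, seed = seed)
  counts <- c(n_genes, n_ccl, n_patients_per_cohort, n_drugs)
  if (any(counts <= 0)) stop("synth_config: all counts must be positive")
  if (n_planted_hg < 0 || n_planted_de < 0) {
    stop("synth_config: planted counts must be non-negative")
  }
  if (n_planted_hg + n_planted_de > n_drugs) {
    stop("synth_config: n_planted_hg + n_planted_de exceeds n_drugs")
  }
  if (is.null(names(geneset_sizes)) ||
      !all(c("glycolysis", "oxphos", "ar") %in% names(geneset_sizes))) {
    stop("synth_config: geneset_sizes must name glycolysis, oxphos and ar")
  }
  if (sum(geneset_sizes) > n_genes) {
    stop("synth_config: gene set sizes exceed the gene universe")
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("synth_config: censor_rate must be in [0, 1)")
  }
  if (abs(prog_corr) > 1) stop("synth_config: |prog_corr| must be <= 1")
  structure(cfg, class = "synth_config")
}

gene_universe <- function(config) sprintf("g%05d", seq_len(config$n_genes))
drug_ids <- function(config) sprintf("drug%03d", seq_len(config$n_drugs))

#' Generate disjoint signature gene sets
#'
#' Draws the glycolysis, OXPHOS and AR signature gene sets without
#' replacement from the gene universe, so the sets are pairwise disjoint.
#' Empty requested sets are returned empty with a warning (degenerate).
#'
#' @param config a [synth_config()].
#' @return a [gene_set_collection()].
#' @export
generate_gene_sets <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(sub_seed(config$seed, 1))
  pool <- gene_universe(config)
  sets <- list()
  for (nm in names(config$geneset_sizes)) {
    k <- config$geneset_sizes[[nm]]
    if (k > length(pool)) stop("gene set '", nm, "' exceeds remaining universe")
    if (k == 0) {
      warning("gene set '", nm, "' requested with size 0 (degenerate)")
      sets[[nm]] <- character(0)
      next
    }
    sets[[nm]] <- sort(sample(pool, k))
    pool <- setdiff(pool, sets[[nm]])
  }
  gene_set_collection(sets, stats::setNames(
    paste0("synthetic ", names(sets), " signature"), names(sets)))
}

# latent draws: bivariate (g, o) with correlation rho, plus independent a
draw_latents <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  data.frame(g = z1, o = rho * z1 + sqrt(1 - rho^2) * z2, a = stats::rnorm(n))
}

# per-gene generative parameters, fixed once per study
draw_gene_params <- function(config, sets) {
  genes <- gene_universe(config)
  program <- rep(NA_character_, length(genes))
  names(program) <- genes
  for (nm in names(sets$sets)) program[sets$sets[[nm]]] <- nm
  data.frame(
    gene_id = genes,
    program = unname(program),
    baseline = stats::rnorm(length(genes), 6, 1.5),
    loading = ifelse(is.na(program), 0, stats::runif(length(genes), 0.6, 1.4)),
    noise_sd = stats::runif(length(genes), 0.5, 1.5),
    stringsAsFactors = FALSE
  )
}

# expression from gene params + latents (+ per-cohort shift)
draw_expression <- function(gene_params, latents, sample_ids, shift = 0) {
  nG <- nrow(gene_params)
  n <- nrow(latents)
  lat <- rbind(glycolysis = latents$g, oxphos = latents$o, ar = latents$a)
  prog_row <- match(gene_params$program, rownames(lat)) # NA for off-signature
  sig <- matrix(0, nG, n)
  has <- !is.na(prog_row)
  sig[has, ] <- gene_params$loading[has] * lat[prog_row[has], , drop = FALSE]
  noise <- matrix(stats::rnorm(nG * n), nG, n) * gene_params$noise_sd
  m <- gene_params$baseline + sig + noise + shift
  dimnames(m) <- list(gene_params$gene_id, sample_ids)
  m
}

#' Generate the synthetic cell-line panel
#'
#' Cell-line expression, measured per-drug AUCs, drug metadata (MOA and
#' development status) and the ground-truth record. Planted Drug_HG drugs
#' depend negatively on latent glycolysis; planted Drug_DE drugs depend
#' negatively on both latent programs; the remaining drugs are null.
#'
#' @param config a [synth_config()].
#' @return list with `expr` (genes x cell lines), `auc` (cell lines x drugs),
#'   `metadata` (drug_id/moa/status), `gene_sets` and `truth`. `truth` holds
#'   latents, per-drug coefficients, planted drug sets, the noiseless AUC
#'   matrix, the survival marker gene, planted hub genes and the gene-level
#'   generative parameters.
#' @export
generate_ccl_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sets <- generate_gene_sets(config)
  set.seed(sub_seed(config$seed, 2))
  gp <- draw_gene_params(config, sets)
  ids <- sprintf("ccl%04d", seq_len(config$n_ccl))
  lat <- draw_latents(config$n_ccl, config$prog_corr)
  rownames(lat) <- ids
  expr <- draw_expression(gp, lat, ids)

  drugs <- drug_ids(config)
  hg <- drugs[seq_len(config$n_planted_hg)]
  de <- drugs[config$n_planted_hg + seq_len(config$n_planted_de)]
  gamma <- stats::setNames(rep(0, config$n_drugs), drugs)
  delta <- gamma
  gamma[hg] <- config$effect_size_gamma
  gamma[de] <- config$effect_size_gamma
  delta[de] <- config$effect_size_gamma
  alpha <- stats::setNames(stats::rnorm(config$n_drugs, 10, 1), drugs)

  true_auc <- outer(lat$g, gamma) + outer(lat$o, delta) +
    matrix(alpha, config$n_ccl, config$n_drugs, byrow = TRUE)
  dimnames(true_auc) <- list(ids, drugs)
  auc <- true_auc + matrix(stats::rnorm(length(true_auc), 0, config$noise_sd),
                           nrow(true_auc))

  planted <- c(hg, de)
  moa_pool <- c("CDK inhibitor", "HSP90 inhibitor", "aurora kinase inhibitor",
                "mTOR inhibitor")
  moa <- stats::setNames(sprintf("moa_%03d", seq_along(drugs)), drugs)
  if (length(planted)) {
    moa[planted] <- rep(moa_pool, length.out = length(planted))
  }
  status <- stats::setNames(
    sample(c("approved", "clinical", "preclinical"), config$n_drugs,
           replace = TRUE, prob = c(0.3, 0.3, 0.4)), drugs)
  # planted drugs are late-stage compounds so the development-status filter is
  # informative but does not erase the planted signal
  if (length(planted)) {
    status[planted] <- rep(c("approved", "clinical"), length.out = length(planted))
  }
  if (config$n_planted_hg >= 3) status[hg[3]] <- "preclinical"

  sig_genes <- unlist(sets$sets[c("glycolysis", "oxphos")], use.names = FALSE)
  off <- setdiff(gp$gene_id, unlist(sets$sets, use.names = FALSE))
  marker <- if (length(off)) off[1] else gp$gene_id[1]
  hubs <- sort(sample(sig_genes, min(config$n_hub_genes, length(sig_genes))))

  truth <- list(
    latents = list(ccl = lat),
    drugs = data.frame(drug_id = drugs, alpha = unname(alpha),
                       gamma = unname(gamma), delta = unname(delta),
                       planted = ifelse(drugs %in% de, "drug_de",
                                        ifelse(drugs %in% hg, "drug_hg", "null")),
                       stringsAsFactors = FALSE),
    planted_hg_drugs = hg, planted_de_drugs = de,
    null_drugs = setdiff(drugs, planted),
    true_auc = true_auc, marker_gene = marker, planted_hub_genes = hubs,
    gene_params = gp
  )
  list(expr = expr, auc = auc,
       metadata = data.frame(drug_id = drugs, moa = unname(moa),
                             status = unname(status), stringsAsFactors = FALSE),
       gene_sets = sets, truth = truth)
}

#' Generate a synthetic patient cohort
#'
#' Same generative program as the cell-line panel plus a cohort-wide additive
#' batch shift on every gene (the "WC" cohort is shifted 1.5x to emulate a
#' different unit convention). The clinical table carries age at procurement
#' (uniform 45-85 unless `age_oxphos_slope` != 0), overall-survival time from
#' an exponential hazard proportional to
#' `exp(survival_beta * standardized marker-gene expression)` and independent
#' censoring at `censor_rate`.
#'
#' @param config a [synth_config()].
#' @param truth ground truth from [generate_ccl_panel()].
#' @param cohort_id `"EC"` or `"WC"`.
#' @return list with `expr`, `clinical`, `latents` and `true_auc`
#'   (noiseless patient x drug linear predictor).
#' @export
generate_patient_cohort <- function(config, truth, cohort_id) {
  stopifnot(inherits(config, "synth_config"))
  idx <- match(cohort_id, c("EC", "WC"))
  if (is.na(idx)) stop("unknown cohort_id '", cohort_id, "' (expected EC or WC)")
  set.seed(sub_seed(config$seed, 10 + idx))
  n <- config$n_patients_per_cohort
  ids <- sprintf("%s_p%04d", cohort_id, seq_len(n))
  lat <- draw_latents(n, config$prog_corr)
  rownames(lat) <- ids
  shift <- config$batch_shift * c(1, 1.5)[idx]
  expr <- draw_expression(truth$gene_params, lat, ids, shift = shift)

  age <- stats::runif(n, 45, 85)
  if (config$age_oxphos_slope != 0) {
    age <- age + config$age_oxphos_slope * lat$o
  }
  mk <- expr[truth$marker_gene, ]
  z <- if (stats::sd(mk) > 0) (mk - mean(mk)) / stats::sd(mk) else mk * 0
  rate <- log(2) / 36 * exp(config$survival_beta * z)
  t_event <- stats::rexp(n, rate)
  event <- stats::rbinom(n, 1, 1 - config$censor_rate)
  time <- ifelse(event == 1, t_event, t_event * stats::runif(n))
  clinical <- data.frame(sample_id = ids, age_at_procurement = age,
                         os_months = pmax(time, 1e-6), os_event = event,
                         stringsAsFactors = FALSE)

  dr <- truth$drugs
  true_auc <- outer(lat$g, stats::setNames(dr$gamma, dr$drug_id)) +
    outer(lat$o, stats::setNames(dr$delta, dr$drug_id)) +
    matrix(dr$alpha, n, nrow(dr), byrow = TRUE)
  dimnames(true_auc) <- list(ids, dr$drug_id)
  list(expr = expr, clinical = clinical, latents = lat, true_auc = true_auc)
}

#' Generate a STRING-style PPI edge table with planted hubs
#'
#' Undirected edges with integer confidence in `[150, 999]`. Planted hub
#' genes are wired to `hub_partners` signature genes at confidence >= 700;
#' background edges are sparse with mixed confidence. No self-loops; a
#' duplicate undirected pair is collapsed to one edge keeping the maximum
#' confidence. Output is sorted, so a fixed seed yields a byte-identical
#' table.
#'
#' @param config a [synth_config()].
#' @param truth ground truth from [generate_ccl_panel()].
#' @return data.frame protein1/protein2/combined_score.
#' @export
generate_ppi_edges <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  if (!length(truth$planted_hub_genes)) stop("planted_hub_genes is empty")
  set.seed(sub_seed(config$seed, 20))
  genes <- truth$gene_params$gene_id
  sig <- truth$gene_params$gene_id[!is.na(truth$gene_params$program)]
  p1 <- character(0); p2 <- character(0); sc <- integer(0)
  for (hub in truth$planted_hub_genes) {
    partners <- sample(setdiff(sig, hub),
                       min(config$hub_partners, length(sig) - 1))
    p1 <- c(p1, rep(hub, length(partners)))
    p2 <- c(p2, partners)
    sc <- c(sc, sample(750:980, length(partners), replace = TRUE))
  }
  n_bg <- 3 * config$n_genes
  b1 <- sample(genes, n_bg, replace = TRUE)
  b2 <- sample(genes, n_bg, replace = TRUE)
  keep <- b1 != b2
  p1 <- c(p1, b1[keep]); p2 <- c(p2, b2[keep])
  sc <- c(sc, sample(150:999, sum(keep), replace = TRUE))
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  df <- data.frame(protein1 = lo, protein2 = hi, combined_score = sc,
                   stringsAsFactors = FALSE)
  df <- df[order(df$protein1, df$protein2, -df$combined_score, method = "radix"), ]
  df <- df[!duplicated(df[c("protein1", "protein2")]), ]
  rownames(df) <- NULL
  df
}

#' Generate pre/post drug perturbation expression profiles
#'
#' For each drug, `r` replicate pre-treatment and `r` replicate
#' post-treatment profiles of one cell-line context; post profiles shift the
#' named signature genes' means by the stated per-drug amount (negative =
#' metabolic suppression, positive = activation).
#'
#' @param config a [synth_config()].
#' @param truth ground truth from [generate_ccl_panel()].
#' @param drug_effects named list: drug id -> named numeric vector of
#'   signature shifts, e.g. `list(drug001 = c(glycolysis = 1))`.
#' @param r replicates per arm (>= 2).
#' @return list of class `perturbation_set`; one element per drug with
#'   `pre` and `post` expression matrices and the applied `shifts`.
#' @export
generate_perturbation_profiles <- function(config, truth, drug_effects,
                                           r = config$perturb_replicates) {
  stopifnot(inherits(config, "synth_config"))
  if (r < 2) stop("perturbation profiles need r >= 2 replicates per arm")
  bad <- setdiff(names(drug_effects), drug_ids(config))
  if (length(bad)) stop("unknown drug id(s) in drug_effects: ",
                        paste(bad, collapse = ", "))
  set.seed(sub_seed(config$seed, 30))
  gp <- truth$gene_params
  sets <- split(gp$gene_id, gp$program)
  out <- list()
  for (d in names(drug_effects)) {
    shifts <- drug_effects[[d]]
    base <- function(arm) {
      m <- gp$baseline +
        matrix(stats::rnorm(nrow(gp) * r), nrow(gp)) * gp$noise_sd
      dimnames(m) <- list(gp$gene_id, sprintf("%s_%s_%d", d, arm, seq_len(r)))
      m
    }
    pre <- base("pre")
    post <- base("post")
    for (sig in names(shifts)) {
      members <- sets[[sig]]
      if (is.null(members)) stop("unknown signature '", sig, "' in drug_effects")
      post[members, ] <- post[members, ] + shifts[[sig]]
    }
    out[[d]] <- list(pre = pre, post = post, shifts = shifts)
  }
  structure(out, class = "perturbation_set")
}

#' Simulate the full synthetic study
#'
#' Runs every generator with sub-streams of the master seed and returns the
#' complete input bundle. The default perturbation design gives the first
#' planted Drug_HG a glycolysis activation of +1 (to be caught by filter 4),
#' the second a suppression of -1, the first Drug_DE an OXPHOS suppression,
#' and one null drug a zero shift; all other drugs have no perturbation data.
#'
#' @param config a [synth_config()].
#' @param drug_effects optional override of the perturbation design.
#' @return list with `config`, `gene_sets`, `ccl` (expr/auc/metadata),
#'   `cohorts` (EC and WC), `ppi`, `perturb` and `truth`.
#' @export
simulate_study <- function(config = synth_config(), drug_effects = NULL) {
  panel <- generate_ccl_panel(config)
  truth <- panel$truth
  cohorts <- list(EC = generate_patient_cohort(config, truth, "EC"),
                  WC = generate_patient_cohort(config, truth, "WC"))
  truth$latents$EC <- cohorts$EC$latents
  truth$latents$WC <- cohorts$WC$latents
  if (is.null(drug_effects)) {
    drug_effects <- list()
    hg <- truth$planted_hg_drugs
    de <- truth$planted_de_drugs
    nul <- truth$null_drugs
    if (length(hg) >= 1) drug_effects[[hg[1]]] <- c(glycolysis = 1.0)
    if (length(hg) >= 2) drug_effects[[hg[2]]] <- c(glycolysis = -1.0)
    if (length(de) >= 1) drug_effects[[de[1]]] <- c(oxphos = -0.5)
    if (length(nul) >= 1) drug_effects[[nul[1]]] <- c(glycolysis = 0)
  }
  perturb <- generate_perturbation_profiles(config, truth, drug_effects)
  ppi <- generate_ppi_edges(config, truth)
  list(config = config, gene_sets = panel$gene_sets,
       ccl = list(expr = panel$expr, auc = panel$auc,
                  metadata = panel$metadata),
       cohorts = cohorts, ppi = ppi, perturb = perturb, truth = truth)
}

#' Write a simulated study to disk in the pipeline's file formats
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named list of file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    gene_sets = file.path(dir, "gene_sets.gmt"),
    ccl_expr = file.path(dir, "ccl_expression.tsv"),
    ccl_auc = file.path(dir, "ccl_auc.csv"),
    drug_metadata = file.path(dir, "drug_metadata.csv"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_gmt(study$gene_sets, paths$gene_sets)
  write_expression_tsv(study$ccl$expr, paths$ccl_expr)
  write_auc_csv(study$ccl$auc, paths$ccl_auc)
  write_drug_metadata_csv(study$ccl$metadata, paths$drug_metadata)
  write_string_tsv(study$ppi, paths$ppi)
  for (cid in names(study$cohorts)) {
    pe <- file.path(dir, sprintf("%s_expression.tsv", cid))
    pc <- file.path(dir, sprintf("%s_clinical.csv", cid))
    write_expression_tsv(study$cohorts[[cid]]$expr, pe)
    write_clinical_csv(study$cohorts[[cid]]$clinical, pc)
    paths[[paste0(cid, "_expr")]] <- pe
    paths[[paste0(cid, "_clinical")]] <- pc
  }
  for (d in names(study$perturb)) {
    pp <- file.path(dir, sprintf("perturb_%s.tsv", d))
    write_expression_tsv(cbind(study$perturb[[d]]$pre, study$perturb[[d]]$post), pp)
    paths[[paste0("perturb_", d)]] <- pp
  }
  tr <- study$truth
  jsonlite::write_json(
    list(planted_hg_drugs = tr$planted_hg_drugs,
         planted_de_drugs = tr$planted_de_drugs,
         null_drugs = tr$null_drugs,
         marker_gene = tr$marker_gene,
         planted_hub_genes = tr$planted_hub_genes,
         drugs = tr$drugs),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
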