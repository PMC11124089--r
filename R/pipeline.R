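# Configuration, input loading/validation, and orchestration of the full
# analysis: scoring -> imputation -> association/nomination -> filter
# cascade -> biomarker discovery -> survival stratification.

#' Pipeline configuration
#'
#' Collects every numeric convention of the analysis with its default:
#' nomination FDR threshold `alpha` (0.05), feature-selection fraction (0.5),
#' biomarker preselection correlation threshold (0.4), PPI confidence floor
#' (700 on the 0-1000 scale), per-method hub list size `k` (50), consensus
#' threshold `min_methods` (6 of 12), EPC replicates `epc_R` (1000), and the
#' master seed from which all stage sub-streams derive.
#'
#' @param input_dir directory holding the input files (layout as written by
#'   [write_study()]).
#' @param out_dir directory for per-stage artifacts.
#' @param cohorts cohort labels (expression/clinical file prefixes).
#' @param source_label name of the drug-screen training source.
#' @param alpha FDR threshold for nomination and filter 2.
#' @param fraction variance-filter fraction.
#' @param preselect_threshold biomarker preselection |Spearman rho| cut-off.
#' @param min_conf PPI confidence floor (0-1000).
#' @param k per-method hub list size.
#' @param min_methods consensus tier threshold.
#' @param epc_R EPC Monte-Carlo replicates.
#' @param min_common harmonization common-gene floor.
#' @param filters logical vector of length 4 toggling the cascade stages.
#' @param n_biomarker_drugs how many surviving candidates get biomarker
#'   discovery.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            cohorts = c("EC", "WC"),
                            source_label = "SYN_SCREEN",
                            alpha = 0.05, fraction = 0.5,
                            preselect_threshold = 0.4, min_conf = 700,
                            k = 50, min_methods = 6, epc_R = 1000,
                            min_common = 100,
                            filters = rep(TRUE, 4),
                            n_biomarker_drugs = 1, seed = 1) {
  stopifnot(alpha > 0, alpha <= 1, fraction > 0, fraction <= 1,
            preselect_threshold >= 0, min_conf >= 0, min_conf <= 1000,
            k >= 1, min_methods >= 1, min_methods <= 12, epc_R >= 1,
            length(filters) == 4)
  structure(list(input_dir = input_dir, out_dir = out_dir, cohorts = cohorts,
                 source_label = source_label, alpha = alpha,
                 fraction = fraction,
                 preselect_threshold = preselect_threshold,
                 min_conf = min_conf, k = k, min_methods = min_methods,
                 epc_R = epc_R, min_common = min_common, filters = filters,
                 n_biomarker_drugs = n_biomarker_drugs, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file with fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Load and validate all pipeline inputs
#'
#' Reads the expression/clinical/AUC/metadata/GMT/PPI/perturbation files from
#' `config$input_dir`, aligns matrices by shared identifiers, and errors with
#' the file name and violation on malformed input.
#'
#' @param config a [pipeline_config()].
#' @return validated in-memory bundle (same shape as [simulate_study()]
#'   output, without `truth`).
#' @export
load_inputs <- function(config) {
  dir <- config$input_dir
  need <- function(p) {
    if (!file.exists(p)) stop("missing input file: ", p)
    p
  }
  gene_sets <- read_gmt(need(file.path(dir, "gene_sets.gmt")))
  ccl_expr <- read_expression_tsv(need(file.path(dir, "ccl_expression.tsv")))
  auc <- read_auc_csv(need(file.path(dir, "ccl_auc.csv")))
  metadata <- read_drug_metadata_csv(need(file.path(dir, "drug_metadata.csv")))
  ppi <- read_string_tsv(need(file.path(dir, "ppi_edges.tsv")))
  if (!ncol(auc)) stop("empty drug library in ccl_auc.csv")
  shared_lines <- intersect(colnames(ccl_expr), rownames(auc))
  if (length(shared_lines) < 10L) {
    stop("fewer than 10 cell lines shared by expression and AUC tables")
  }
  cohorts <- list()
  for (cid in config$cohorts) {
    expr <- read_expression_tsv(need(file.path(dir, sprintf("%s_expression.tsv", cid))))
    clin <- read_clinical_csv(need(file.path(dir, sprintf("%s_clinical.csv", cid))))
    dropped <- setdiff(clin$sample_id, colnames(expr))
    if (length(dropped)) {
      message(cid, ": ", length(dropped), " clinical sample(s) lack expression, dropped")
      clin <- clin[clin$sample_id %in% colnames(expr), , drop = FALSE]
    }
    cohorts[[cid]] <- list(expr = expr, clinical = clin)
  }
  perturb <- list()
  for (f in list.files(dir, pattern = "^perturb_.*\\.tsv$", full.names = TRUE)) {
    d <- sub("^perturb_(.*)\\.tsv$", "\\1", basename(f))
    m <- read_expression_tsv(f)
    pre <- m[, grepl("_pre_", colnames(m)), drop = FALSE]
    post <- m[, grepl("_post_", colnames(m)), drop = FALSE]
    if (!ncol(pre) || !ncol(post)) {
      stop("perturbation file ", f, " lacks _pre_/_post_ replicate columns")
    }
    perturb[[d]] <- list(pre = pre, post = post)
  }
  list(gene_sets = gene_sets,
       ccl = list(expr = ccl_expr, auc = auc, metadata = metadata),
       cohorts = cohorts, ppi = ppi,
       perturb = structure(perturb, class = "perturbation_set"))
}

score_cohort <- function(expr, gene_sets) {
  gm <- gene_set_collection(gene_sets$sets[c("glycolysis", "oxphos")])
  rescale_scores(gsva_enrichment(expr, gm))
}

#' Run the full analysis pipeline
#'
#' Executes scoring, imputation, association/nomination, the filter cascade,
#' biomarker discovery and survival stratification in order, writing
#' per-stage artifacts, the filter trail, a run manifest and a summary of the
#' nomination set counts to `config$out_dir`. Stages can be cut short with
#' `last_stage` (used by the CLI subcommands).
#'
#' @param config a [pipeline_config()].
#' @param bundle optional in-memory input bundle (e.g. from
#'   [simulate_study()]); read from disk via [load_inputs()] when NULL.
#' @param last_stage one of "score", "impute", "nominate", "filter",
#'   "biomarkers", "survive" (default: run everything).
#' @return invisibly, a list of stage results.
#' @export
run_all <- function(config, bundle = NULL, last_stage = "survive") {
  stages <- c("score", "impute", "nominate", "filter", "biomarkers", "survive")
  last <- match(match.arg(last_stage, stages), stages)
  if (is.null(bundle)) bundle <- load_inputs(config)
  if (!ncol(bundle$ccl$auc)) stop("empty drug library; aborting before imputation")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  stage_failed <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  # -- stage 1: signature scoring --------------------------------------------
  res$scores <- tryCatch({
    scores <- lapply(bundle$cohorts, function(co) score_cohort(co$expr, bundle$gene_sets))
    ccl_scores <- score_cohort(bundle$ccl$expr, bundle$gene_sets)
    ar <- lapply(bundle$cohorts, function(co)
      ar_activity(co$expr, bundle$gene_sets$sets$ar))
    for (cid in names(scores)) {
      write_score_csv(scores[[cid]], file.path(config$out_dir,
                                               sprintf("scores_%s.csv", cid)))
      write_score_csv(ar[[cid]], file.path(config$out_dir,
                                           sprintf("ar_scores_%s.csv", cid)))
    }
    write_score_csv(ccl_scores, file.path(config$out_dir, "scores_ccl.csv"))
    list(cohort = scores, ccl = ccl_scores, ar = ar)
  }, error = function(e) stage_failed("score", e))
  if (last == 1L) return(write_manifest(config, res))

  # -- stage 2: response imputation ------------------------------------------
  res$imputed <- tryCatch({
    imputed <- list()
    for (cid in names(bundle$cohorts)) {
      harm <- harmonize_expression(bundle$ccl$expr, bundle$cohorts[[cid]]$expr,
                                   min_common = config$min_common)
      models <- train_imputation_models(
        harm$train, bundle$ccl$auc, fraction = config$fraction,
        seed = sub_seed(config$seed, 200 + match(cid, names(bundle$cohorts))))
      imp <- impute_response(models, harm$target)
      utils::write.csv(data.frame(sample_id = rownames(imp), imp,
                                  check.names = FALSE),
                       file.path(config$out_dir, sprintf("imputed_%s_%s.csv",
                                                         config$source_label, cid)),
                       row.names = FALSE, quote = FALSE)
      imputed[[cid]] <- imp
    }
    imputed
  }, error = function(e) stage_failed("impute", e))
  if (last == 2L) return(write_manifest(config, res))

  # -- stage 3: association + nomination -------------------------------------
  res$nomination <- tryCatch({
    recs <- list()
    for (cid in names(bundle$cohorts)) {
      for (ty in c("glycolysis", "oxphos")) {
        recs[[length(recs) + 1L]] <- score_response_association(
          res$scores$cohort[[cid]], res$imputed[[cid]],
          clinical = bundle$cohorts[[cid]]$clinical, score_type = ty,
          cohort = cid, source = config$source_label)
      }
    }
    assoc <- adjust_associations(do.call(rbind, recs))
    utils::write.csv(assoc, file.path(config$out_dir, "associations.csv"),
                     row.names = FALSE, quote = FALSE)
    noms <- nominate_drug_sets(assoc, alpha = config$alpha)
    moa <- primary_moa_summary(noms$cross_cohort[[config$source_label]]$hg,
                               bundle$ccl$metadata, assoc)
    utils::write.csv(moa, file.path(config$out_dir, "moa_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    write_nomination_summary(noms, file.path(config$out_dir,
                                             "nomination_summary.csv"))
    jsonlite::write_json(
      list(per_dataset = noms$per_dataset, cross_cohort = noms$cross_cohort,
           alpha = noms$alpha),
      file.path(config$out_dir, "nominations.json"), auto_unbox = TRUE,
      digits = NA)
    list(assoc = assoc, sets = noms, moa = moa)
  }, error = function(e) stage_failed("nominate", e))
  if (last == 3L) return(write_manifest(config, res))

  # -- stage 4: filter cascade -----------------------------------------------
  res$filter <- tryCatch({
    cross <- res$nomination$sets$cross_cohort[[config$source_label]]
    candidates <- union(cross$hg, cross$de)
    if (!length(candidates)) {
      message("no cross-cohort candidates; skipping cascade")
      NULL
    } else {
      trail <- run_filter_cascade(candidates, bundle$ccl$metadata,
                                  res$nomination$assoc, bundle$ccl$expr,
                                  bundle$ccl$auc, bundle$perturb,
                                  bundle$gene_sets, alpha = config$alpha,
                                  ccl_scores = res$scores$ccl)
      utils::write.csv(trail$trail, file.path(config$out_dir, "filter_trail.csv"),
                       row.names = FALSE)
      trail
    }
  }, error = function(e) stage_failed("filter", e))
  if (last == 4L) return(write_manifest(config, res))

  # -- stage 5: biomarker discovery ------------------------------------------
  res$biomarkers <- tryCatch({
    survivors <- if (is.null(res$filter)) character(0) else
      res$filter$surviving[[utils::tail(res$filter$stages, 1)]]
    if (!length(survivors)) {
      message("no surviving candidates; skipping biomarker discovery")
      NULL
    } else {
      # strongest cross-cohort glycolysis association first
      gl <- res$nomination$assoc
      gl <- gl[gl$score_type == "glycolysis" & gl$drug_id %in% survivors, ]
      strength <- stats::aggregate(p_value ~ drug_id, gl, max)
      strength <- strength[order(strength$p_value, strength$drug_id), ]
      picks <- utils::head(strength$drug_id, config$n_biomarker_drugs)
      cid <- names(bundle$cohorts)[1]
      out <- list()
      for (d in picks) {
        genes <- preselect_correlated_genes(
          bundle$cohorts[[cid]]$expr, res$imputed[[cid]][, d],
          threshold = config$preselect_threshold)
        if (length(genes) < 2L) {
          message("drug ", d, ": fewer than 2 preselected genes, skipped")
          next
        }
        graph <- build_ppi_subnetwork(bundle$ppi, genes, min_conf = config$min_conf)
        tab <- centrality_table(graph, seed = sub_seed(config$seed, 300),
                                R = config$epc_R)
        cons <- consensus_hubs(tab, k = config$k, min_methods = config$min_methods)
        filt <- if (d %in% colnames(bundle$ccl$auc) && length(cons$selected)) {
          spearman_biomarker_filter(bundle$ccl$expr, bundle$ccl$auc[, d],
                                    cons$selected)
        } else NULL
        strata <- lapply(names(bundle$cohorts), function(cc)
          stratify_ar_gly(res$scores$ar[[cc]], res$scores$cohort[[cc]]))
        names(strata) <- names(bundle$cohorts)
        strat_tests <- lapply(names(strata), function(cc)
          tryCatch(stratum_response_test(res$imputed[[cc]][, d], strata[[cc]]),
                   error = function(e) NULL))
        names(strat_tests) <- names(strata)
        utils::write.csv(
          data.frame(gene_id = names(cons$counts), methods_count = cons$counts,
                     row.names = NULL),
          file.path(config$out_dir, sprintf("consensus_%s.csv", d)),
          row.names = FALSE)
        if (!is.null(filt)) {
          utils::write.csv(filt, file.path(config$out_dir,
                                           sprintf("biomarkers_%s.csv", d)),
                           row.names = FALSE)
        }
        out[[d]] <- list(preselected = genes, graph = graph, consensus = cons,
                         biomarkers = filt, strata = strata,
                         strat_tests = strat_tests)
      }
      out
    }
  }, error = function(e) stage_failed("biomarkers", e))
  if (last == 5L) return(write_manifest(config, res))

  # -- stage 6: survival stratification --------------------------------------
  res$survival <- tryCatch({
    if (is.null(res$biomarkers) || !length(res$biomarkers)) {
      message("no biomarkers; skipping survival analysis")
      NULL
    } else {
      cid <- names(bundle$cohorts)[1]
      out <- list()
      for (d in names(res$biomarkers)) {
        filt <- res$biomarkers[[d]]$biomarkers
        if (is.null(filt) || !any(filt$selected)) next
        sel <- filt[filt$selected, ]
        gene <- sel$gene_id[which.min(sel$rho)]
        ms <- median_split_survival(bundle$cohorts[[cid]]$expr, gene,
                                    bundle$cohorts[[cid]]$clinical)
        utils::write.csv(as.data.frame(ms$curves$high),
                         file.path(config$out_dir,
                                   sprintf("km_high_%s_%s.csv", d, gene)),
                         row.names = FALSE)
        utils::write.csv(as.data.frame(ms$curves$low),
                         file.path(config$out_dir,
                                   sprintf("km_low_%s_%s.csv", d, gene)),
                         row.names = FALSE)
        jsonlite::write_json(
          list(drug = d, gene = gene, cohort = cid,
               chi2 = ms$test$chi2, p = ms$test$p),
          file.path(config$out_dir, sprintf("survival_%s_%s.json", d, gene)),
          auto_unbox = TRUE, digits = NA)
        out[[d]] <- list(gene = gene, result = ms)
      }
      out
    }
  }, error = function(e) stage_failed("survive", e))
  write_manifest(config, res)
}

# Table-1-style count summary of the nomination sets
write_nomination_summary <- function(noms, path) {
  rows <- list()
  for (nm in names(noms$per_dataset)) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    s <- noms$per_dataset[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      scope = "per_dataset", cohort = parts[1], source = parts[2],
      drug_hg = length(s$hg), drug_ox = length(s$ox), drug_de = length(s$de))
  }
  for (so in names(noms$cross_cohort)) {
    s <- noms$cross_cohort[[so]]
    rows[[length(rows) + 1L]] <- data.frame(
      scope = "cross_cohort", cohort = paste(noms$cohorts, collapse = "^"),
      source = so, drug_hg = length(s$hg), drug_ox = length(s$ox),
      drug_de = length(s$de))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_manifest <- function(config, res) {
  cfg <- unclass(config)
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "glycodrug",
                   version = as.character(utils::packageVersion("glycodrug")),
                   config = cfg, config_hash = config_hash(as.character(js)),
                   seed = config$seed,
                   stages_run = setdiff(names(res), "config"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic study),
#' `score`, `impute`, `nominate`, `filter`, `biomarkers`, `survive`
#' (run the pipeline up to that stage) and `run-all`.
#' Common flags: `--input DIR --out DIR --seed N`; `simulate` also accepts
#' `--n-drugs`, `--n-ccl`, `--n-patients`, `--n-genes`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the subcommand's result.
#' @export
glycodrug_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: glycodrug <simulate|score|impute|nominate|filter|biomarkers|survive|run-all> [--input DIR] [--out DIR] [--seed N]")
  }
  cmd <- args[1]
  opts <- list(input = "inputs", out = "results", seed = 1,
               `n-drugs` = 60, `n-ccl` = 300, `n-patients` = 120,
               `n-genes` = 2000)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts)) stop("unknown option --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  seed <- as.integer(opts$seed)
  if (cmd == "simulate") {
    ng <- as.integer(opts$`n-genes`)
    # scale the default signature sizes down with small gene universes
    sizes <- pmax(round(c(glycolysis = 40, oxphos = 200, ar = 20) *
                          min(1, ng / 2000)), 4)
    cfg <- synth_config(geneset_sizes = sizes,
                        n_genes = as.integer(opts$`n-genes`),
                        n_ccl = as.integer(opts$`n-ccl`),
                        n_patients_per_cohort = as.integer(opts$`n-patients`),
                        n_drugs = as.integer(opts$`n-drugs`), seed = seed)
    paths <- write_study(simulate_study(cfg), opts$input)
    message("wrote ", length(paths), " input files to ", opts$input)
    return(invisible(paths))
  }
  stage_map <- c(score = "score", impute = "impute", nominate = "nominate",
                 filter = "filter", biomarkers = "biomarkers",
                 survive = "survive", `run-all` = "survive")
  if (!cmd %in% names(stage_map)) stop("unknown subcommand '", cmd, "'")
  cfg <- pipeline_config(input_dir = opts$input, out_dir = opts$out, seed = seed)
  invisible(run_all(cfg, last_stage = stage_map[[cmd]]))
}
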