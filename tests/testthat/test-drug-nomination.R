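# drug_nomination module: association OLS, BH arithmetic, set formation,
# MOA summary and filter cascade contracts.

mk_score <- function(ids, vals, sig = "glycolysis") {
  glycodrug:::new_score_table(ids, sig, vals, "percent_0_100")
}

test_that("exact linear relation recovers beta1 with ~zero p", {
  ids <- sprintf("s%02d", 1:20)
  resp <- matrix(seq(0, 1, length.out = 20), 20, 1,
                 dimnames = list(ids, "drugA"))
  sc <- mk_score(ids, 10 - 2 * resp[, 1])
  rec <- suppressWarnings( # lm warns on an essentially perfect fit
    score_response_association(sc, resp, score_type = "glycolysis",
                               cohort = "EC", source = "S"))
  expect_equal(rec$beta1, -2, tolerance = 1e-10)
  expect_lt(rec$p_value, 1e-20)
  # constant response -> p = 1 with warning
  resp2 <- cbind(resp, drugB = rep(0.5, 20))
  expect_warning(
    rec2 <- withCallingHandlers(
      score_response_association(sc, resp2, score_type = "glycolysis"),
      warning = function(w) {
        if (grepl("perfect fit", conditionMessage(w))) invokeRestart("muffleWarning")
      }),
    "constant")
  expect_equal(rec2$p_value[rec2$drug_id == "drugB"], 1)
})

test_that("null association p-values are uniform; age covariate is harmless", {
  set.seed(71)
  n <- 150
  ids <- sprintf("s%03d", 1:n)
  sc <- mk_score(ids, runif(n, 0, 100))
  resp <- matrix(rnorm(n * 200), n, 200,
                 dimnames = list(ids, sprintf("d%03d", 1:200)))
  rec <- score_response_association(sc, resp, score_type = "glycolysis")
  ks <- suppressWarnings(ks.test(rec$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  # adding an irrelevant age covariate leaves beta1 ~unchanged
  set.seed(72)
  g <- rnorm(n)
  resp1 <- matrix(g * -0.7 + rnorm(n, 0, 0.4), n, 1,
                  dimnames = list(ids, "dX"))
  sco <- mk_score(ids, 50 + 10 * g + rnorm(n), sig = "oxphos")
  clin <- data.frame(sample_id = ids, age_at_procurement = runif(n, 45, 85))
  r_no <- score_response_association(sco, resp1, NULL, "oxphos")
  r_age <- score_response_association(sco, resp1, clin, "oxphos")
  expect_false(is.na(r_age$beta2))
  se <- abs(r_no$beta1 / qt(r_no$p_value / 2, df = n - 2, lower.tail = FALSE))
  expect_lt(abs(r_age$beta1 - r_no$beta1), 3 * se)
})

test_that("bh_adjust matches hand arithmetic and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  # monotone w.r.t. raw p order
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

mk_assoc <- function(drug, ty, cohort, source, beta1, fdr, p = fdr / 2) {
  data.frame(drug_id = drug, score_type = ty, cohort = cohort, source = source,
             beta0 = 0, beta1 = beta1, beta2 = NA_real_, p_value = p, n = 50,
             fdr = fdr, stringsAsFactors = FALSE)
}

test_that("nomination sets apply sign, FDR, and intersection rules", {
  assoc <- rbind(
    mk_assoc("d1", "glycolysis", "EC", "S", -1, 0.04),
    mk_assoc("d1", "glycolysis", "WC", "S", -1, 0.20),
    mk_assoc("d2", "glycolysis", "EC", "S", 1, 0.001),
    mk_assoc("d2", "glycolysis", "WC", "S", 1, 0.001),
    mk_assoc("d3", "glycolysis", "EC", "S", -1, 0.01),
    mk_assoc("d3", "glycolysis", "WC", "S", -1, 0.01),
    mk_assoc("d3", "oxphos", "EC", "S", -1, 0.01),
    mk_assoc("d3", "oxphos", "WC", "S", -1, 0.01))
  noms <- nominate_drug_sets(assoc, alpha = 0.05)
  expect_equal(noms$per_dataset[["EC|S"]]$hg, c("d1", "d3"))
  expect_equal(noms$cross_cohort$S$hg, "d3") # d1 fails WC, d2 fails sign
  expect_equal(noms$cross_cohort$S$de, "d3")
  # alpha = 1 keeps all negative-slope drugs; alpha ~ 0 keeps none
  noms1 <- nominate_drug_sets(assoc, alpha = 1)
  expect_setequal(noms1$per_dataset[["EC|S"]]$hg, c("d1", "d3"))
  noms0 <- nominate_drug_sets(assoc, alpha = 1e-9)
  expect_length(noms0$cross_cohort$S$hg, 0)
  # Drug_DE is always the intersection of HG and OX
  for (nm in names(noms$per_dataset)) {
    s <- noms$per_dataset[[nm]]
    expect_setequal(s$de, intersect(s$hg, s$ox))
  }
})

test_that("primary MOA summary implements the top-50%-overlap rule", {
  assoc <- rbind(
    mk_assoc(c("d1", "d2", "d3", "d4"), "glycolysis", "EC", "S", -1,
             0.01, p = c(0.001, 0.002, 0.03, 0.04)),
    mk_assoc(c("d1", "d2", "d3", "d4"), "glycolysis", "WC", "S", -1,
             0.01, p = c(0.001, 0.002, 0.03, 0.04)))
  meta <- data.frame(drug_id = c("d1", "d2", "d3", "d4"),
                     moa = c("CDK inhibitor", "CDK inhibitor", "x", "y"),
                     status = "approved")
  ms <- primary_moa_summary(c("d1", "d2", "d3", "d4"), meta, assoc)
  expect_true(ms$primary[ms$moa == "CDK inhibitor"])
  expect_equal(ms$n_drugs[ms$moa == "CDK inhibitor"], 2)
  # drug top-50% in one cohort only is excluded from the overlap
  assoc2 <- assoc
  assoc2$p_value[assoc2$cohort == "WC"] <- c(0.04, 0.03, 0.002, 0.001)
  ms2 <- primary_moa_summary(c("d1", "d2", "d3", "d4"), meta, assoc2)
  expect_length(attr(ms2, "overlap_drugs"), 0)
  # all-unique MOAs -> nothing primary
  meta3 <- data.frame(drug_id = c("d1", "d2"), moa = c("a", "b"),
                      status = "approved")
  ms3 <- primary_moa_summary(c("d1", "d2"), meta3,
                             assoc[assoc$drug_id %in% c("d1", "d2"), ])
  expect_false(any(ms3$primary))
})

test_that("filter cascade applies the four rules and stays nested", {
  cfg <- tiny_config(n_drugs = 8, n_planted_hg = 4, n_planted_de = 2, seed = 13)
  st <- simulate_study(cfg)
  hg <- st$truth$planted_hg_drugs
  meta <- st$ccl$metadata
  # candidates: all planted drugs
  cand <- c(hg, st$truth$planted_de_drugs)
  # build associations: all fine except one drug with an opposing record
  assoc <- do.call(rbind, lapply(cand, function(d) rbind(
    mk_assoc(d, "glycolysis", "EC", "S", -1, 0.01),
    mk_assoc(d, "oxphos", "EC", "S", -1, 0.01))))
  assoc$beta1[assoc$drug_id == hg[4] & assoc$score_type == "oxphos"] <- 1
  meta$status[meta$drug_id == hg[3]] <- "preclinical"
  trail <- run_filter_cascade(cand, meta, assoc, st$ccl$expr, st$ccl$auc,
                              st$perturb, st$gene_sets)
  tr <- trail$trail
  expect_false(tr$pass[tr$drug_id == hg[3] & tr$stage == "development_status"])
  expect_false(tr$pass[tr$drug_id == hg[4] &
                         tr$stage == "cross_dataset_consistency"])
  # planted +1 glycolysis activation (hg[1]) is removed at filter 4
  expect_false(tr$pass[tr$drug_id == hg[1] &
                         tr$stage == "perturbation_metabolic_activation"])
  # drugs without perturbation data pass filter 4 with reason "no data"
  no_pert <- setdiff(trail$surviving$measured_response_trend, names(st$perturb))
  for (d in no_pert) {
    row <- tr[tr$drug_id == d & tr$stage == "perturbation_metabolic_activation", ]
    expect_true(row$pass)
    expect_equal(row$reason, "no data")
  }
  # nesting of survivors
  s <- trail$surviving
  for (i in 2:length(s)) expect_true(all(s[[i]] %in% s[[i - 1]]))
  # missing measured AUC -> fails filter 3 with "no measured data"
  auc2 <- st$ccl$auc[, setdiff(colnames(st$ccl$auc), hg[2]), drop = FALSE]
  trail2 <- run_filter_cascade(cand, meta, assoc, st$ccl$expr, auc2,
                               st$perturb, st$gene_sets)
  tr2 <- trail2$trail
  expect_equal(tr2$reason[tr2$drug_id == hg[2] &
                            tr2$stage == "measured_response_trend"],
               "no measured data")
  expect_error(run_filter_cascade(character(0), meta, assoc, st$ccl$expr,
                                  st$ccl$auc, st$perturb, st$gene_sets),
               "empty candidate")
})
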