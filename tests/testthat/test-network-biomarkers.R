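# network_biomarkers module: closed-form centrality values, brute-force oracle
# agreement, consensus rules, preselection/biomarker filters, Welch strata
# test.

test_that("triangle, path, star closed forms hold exactly", {
  k3 <- named_graph(cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(centrality(k3, "Degree"), c(a = 2, b = 2, c = 2))
  expect_equal(centrality(k3, "Betweenness"), c(a = 0, b = 0, c = 0))
  expect_equal(centrality(k3, "ClusteringCoefficient"), c(a = 1, b = 1, c = 1))
  expect_equal(centrality(k3, "MCC"), c(a = 2, b = 2, c = 2)) # (3-1)! = 2

  path <- named_graph(cbind(c("a", "b"), c("b", "c")))
  expect_equal(centrality(path, "Betweenness")[["b"]], 1)
  expect_equal(centrality(path, "Stress")[["b"]], 1)
  expect_equal(centrality(path, "Closeness")[["a"]], 1.5) # 1 + 1/2
  expect_equal(centrality(path, "EcCentricity")[["a"]], 0.5)

  star <- named_graph(cbind("hub", c("l1", "l2", "l3", "l4")))
  expect_equal(centrality(star, "Stress")[["hub"]], 6) # C(4,2) leaf pairs
  expect_equal(centrality(star, "MNC")[["hub"]], 1)
  expect_equal(centrality(star, "DMNC")[["hub"]], 0)
  expect_equal(centrality(star, "MCC")[["hub"]], 4) # edgeless nbhd -> degree
  expect_equal(centrality(star, "Bottleneck")[["hub"]], 4)

  # complete graph K4: everyone equivalent
  k4 <- named_graph(t(combn(c("a", "b", "c", "d"), 2)))
  expect_equal(unname(centrality(k4, "MCC")), rep(6, 4)) # (4-1)!
  expect_equal(unname(centrality(k4, "Radiality")), rep(1, 4))
  expect_equal(unname(centrality(k4, "MNC")), rep(3, 4))
  expect_equal(unname(centrality(k4, "DMNC")), rep(3 / 3^1.7, 4))
  expect_error(centrality(k4, "NotAMethod"), "unknown centrality")
})

test_that("deterministic centralities match the brute-force oracle", {
  det <- setdiff(CENTRALITY_METHODS, "EPC")
  for (i in 1:6) {
    tg <- random_test_graph(n = sample(8:18, 1), p = runif(1, 0.15, 0.45),
                            seed = 100 + i)
    oracle <- oracle_centralities(tg$A, rownames(tg$A))
    for (m in det) {
      expect_equal(centrality(tg$graph, m), oracle[[m]], tolerance = 1e-9,
                   info = sprintf("method %s graph %d", m, i))
    }
  }
})

test_that("centralities are isomorphism-invariant (id-independent methods)", {
  tg <- random_test_graph(n = 14, p = 0.3, seed = 222)
  set.seed(5)
  perm <- sample(14)
  A2 <- tg$A[perm, perm]
  oracle1 <- oracle_centralities(tg$A, rownames(tg$A))
  oracle2 <- oracle_centralities(A2, rownames(A2))
  for (m in c("Degree", "Betweenness", "Stress", "Closeness", "EcCentricity",
              "Radiality", "ClusteringCoefficient", "MNC", "DMNC", "MCC")) {
    expect_equal(oracle2[[m]][names(oracle1[[m]])], oracle1[[m]],
                 tolerance = 1e-9, info = m)
  }
})

test_that("EPC: certain edges give exact component size; MC matches oracle", {
  tg <- random_test_graph(n = 12, p = 0.35, seed = 321)
  g <- tg$graph
  igraph::E(g)$confidence <- 1000
  cm <- igraph::components(g)
  expect_equal(unname(centrality(g, "EPC", seed = 4, R = 5)),
               unname(cm$csize[cm$membership]))
  # unweighted (p = 0.5): two independent Monte-Carlo implementations agree
  epc <- centrality(tg$graph, "EPC", seed = 11, R = 1000)
  orc <- oracle_epc(tg$A, conf = NULL, R = 1000, seed = 99)
  se <- sqrt(orc$var / 1000 + orc$var / 1000) + 1e-9
  expect_true(all(abs(epc - orc$mean) < 4 * se + 0.05))
})

test_that("subnetwork construction honors confidence and interactor rules", {
  edges <- data.frame(protein1 = c("a", "a", "b", "c", "a"),
                      protein2 = c("b", "c", "c", "d", "b"),
                      combined_score = c(699, 700, 800, 950, 720))
  g <- build_ppi_subnetwork(edges, c("a", "b", "c", "e"), min_conf = 700)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c", "e")) # e isolated, kept
  el <- igraph::as_edgelist(g)
  # a-b at 699 dropped, duplicate a-b at 720 kept (max confidence rule)
  expect_equal(nrow(el), 3)
  expect_true(all(igraph::E(g)$confidence >= 700))
  ab <- igraph::E(g)$confidence[igraph::get_edge_ids(g, c("a", "b"))]
  expect_equal(ab, 720)
  # d outside the supplied list is absent (max interactors = 0)
  expect_false("d" %in% igraph::V(g)$name)
})

test_that("consensus counting, tie-breaks and monotonicity", {
  set.seed(77)
  tg <- random_test_graph(n = 30, p = 0.25, seed = 777)
  tab <- centrality_table(tg$graph, seed = 3, R = 50)
  expect_equal(dim(tab), c(30, 12))
  # k >= node count: every node in every list
  cons_all <- consensus_hubs(tab, k = 50, min_methods = 6)
  expect_true(all(cons_all$counts == 12))
  cons <- consensus_hubs(tab, k = 5, min_methods = 6)
  expect_true(all(cons$counts <= 12))
  expect_setequal(cons$selected, names(cons$counts)[cons$counts >= 6])
  # raising min_methods never adds genes
  cons8 <- consensus_hubs(tab, k = 5, min_methods = 8)
  expect_true(all(cons8$selected %in% cons$selected))
  # a gene counted 5 times is excluded at min_methods = 6
  if (any(cons$counts == 5)) {
    expect_false(names(cons$counts)[cons$counts == 5][1] %in% cons$selected)
  }
  # deterministic tie-break: equal scores resolved lexicographically
  tab2 <- matrix(1, 4, 2, dimnames = list(c("d", "b", "a", "c"), c("m1", "m2")))
  c2 <- consensus_hubs(tab2, k = 2, min_methods = 2)
  expect_setequal(c2$selected, c("a", "b"))
})

test_that("preselection threshold behavior and degenerate genes", {
  set.seed(88)
  n <- 100
  ids <- sprintf("s%03d", 1:n)
  resp <- setNames(rnorm(n), ids)
  expr <- rbind(
    mono = setNames(resp^3, ids),            # exact monotone transform
    anti = -resp + rnorm(n, 0, 1e-8),        # near-perfect anti-correlation
    flat = rep(1, n),                        # constant -> excluded
    noise = rnorm(n))
  colnames(expr) <- ids
  expect_warning(sel <- preselect_correlated_genes(expr, resp, 0.4),
                 "constant")
  expect_true(all(c("mono", "anti") %in% sel))
  expect_false("flat" %in% sel)
  # unattainable threshold -> empty
  expect_warning(sel2 <- preselect_correlated_genes(expr, resp, 1.01))
  expect_length(sel2, 0)
  # null genes selected with probability < 0.01 at threshold 0.4, n = 100
  set.seed(89)
  noise_expr <- matrix(rnorm(500 * n), 500, n,
                       dimnames = list(sprintf("g%03d", 1:500), ids))
  hits <- length(preselect_correlated_genes(noise_expr, resp, 0.4))
  expect_lt(hits / 500, 0.01)
})

test_that("spearman biomarker filter applies sign and significance rules", {
  set.seed(91)
  n <- 50
  lines <- sprintf("c%02d", 1:n)
  auc <- setNames(rnorm(n, 10), lines)
  expr <- rbind(neg = -auc, pos = auc, null = rnorm(n))
  colnames(expr) <- lines
  res <- spearman_biomarker_filter(expr, auc, c("neg", "pos", "null"))
  expect_equal(res$rho[res$gene_id == "neg"], -1)
  expect_true(res$selected[res$gene_id == "neg"])
  expect_false(res$selected[res$gene_id == "pos"]) # rho = +1, sign rule
  expect_warning(spearman_biomarker_filter(expr, auc, c("neg", "ghost")),
                 "missing")
  # null calibration: one-sided tail ~ 2.5%
  set.seed(92)
  null_expr <- matrix(rnorm(400 * n), 400, n,
                      dimnames = list(sprintf("g%03d", 1:400), lines))
  resn <- spearman_biomarker_filter(null_expr, auc, rownames(null_expr))
  expect_lt(mean(resn$selected), 0.06)
  expect_gt(mean(resn$selected), 0.002)
})

test_that("stratum response test matches Welch formulas; degenerate variance safe", {
  s <- structure(setNames(c(rep("AR_low_Gly_high", 3), rep("other", 3)),
                          sprintf("s%d", 1:6)), class = "strata_labels")
  imp <- setNames(c(1, 2, 3, 1, 2, 3), sprintf("s%d", 1:6))
  r <- stratum_response_test(imp, s)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # textbook Welch oracle evaluated inline
  set.seed(93)
  x <- rnorm(12)
  y <- rnorm(15, 1)
  imp2 <- setNames(c(x, y), sprintf("s%02d", 1:27))
  s2 <- structure(setNames(rep(c("AR_low_Gly_high", "other"), c(12, 15)),
                           names(imp2)), class = "strata_labels")
  r2 <- stratum_response_test(imp2, s2)
  se2 <- var(x) / 12 + var(y) / 15
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 12)^2 / 11 + (var(y) / 15)^2 / 14)
  expect_equal(r2$t, t_hand, tolerance = 1e-10)
  expect_equal(r2$df, df_hand, tolerance = 1e-10)
  expect_equal(r2$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  # zero-variance groups: finite statistic, p -> 0
  s3 <- structure(setNames(rep(c("AR_low_Gly_high", "other"), each = 2),
                           sprintf("s%d", 1:4)), class = "strata_labels")
  imp3 <- setNames(c(0, 0, 1, 1), sprintf("s%d", 1:4))
  r3 <- stratum_response_test(imp3, s3)
  expect_true(is.finite(r3$t))
  expect_lt(r3$p, 1e-6)
  expect_error(stratum_response_test(imp3[1:3], s3), ">= 2 samples")
})
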