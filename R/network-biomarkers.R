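# Per-drug biomarker nomination: correlation preselection, PPI subnetwork
# construction, 12 topological centrality rankings (cytoHubba-style), tiered
# consensus, Spearman response filter, and the stratified-response test.
#
# Centrality definitions (d(u,v) = shortest-path length, sigma_st = number of
# shortest s-t paths, sigma_st(v) = those through v):
#   Degree                 |N(v)|
#   Betweenness            sum over unordered pairs s<t (s,t != v) of
#                          sigma_st(v)/sigma_st
#   Stress                 sum sigma_st(v) (raw counts)
#   Closeness (harmonic)   sum over reachable w != v of 1/d(v,w)
#   EcCentricity           1 / max_{w in comp(v)} d(v,w); isolated -> 0
#   Radiality              sum over w in comp(v), w != v of
#                          (diam(comp)+1-d(v,w)) / (|comp|-1); singleton -> 0
#   ClusteringCoefficient  2 e(N(v)) / (deg (deg-1)); deg < 2 -> 0
#   MNC                    size of largest connected component M of the
#                          induced subgraph on N(v)
#   DMNC                   |E(M)| / |V(M)|^1.7; |V(M)| <= 1 -> 0
#   MCC                    sum over maximal cliques C (|C| >= 2) containing v
#                          of (|C|-1)!; equals deg(v) when N(v) is edgeless
#   Bottleneck             number of roots s != v whose canonical BFS
#                          shortest-path tree gives v a subtree (v included)
#                          of size > |tree|/4
#   EPC                    mean over R seeded replicates, each edge retained
#                          independently with probability confidence/1000
#                          (0.5 if unweighted), of |comp(v)|

CENTRALITY_METHODS <- c("Betweenness", "Bottleneck", "Closeness",
                        "ClusteringCoefficient", "Degree", "DMNC",
                        "EcCentricity", "EPC", "MCC", "MNC", "Radiality",
                        "Stress")

#' Preselect genes correlated with a drug's imputed response
#'
#' @param expr genes x samples expression matrix (>= 5 samples).
#' @param imputed_drug named numeric vector of imputed responses.
#' @param threshold absolute Spearman correlation cut-off (default 0.4).
#' @return character vector of selected gene ids.
#' @export
preselect_correlated_genes <- function(expr, imputed_drug, threshold = 0.4) {
  samples <- intersect(colnames(expr), names(imputed_drug))
  if (length(samples) < 5L) stop("preselect_correlated_genes needs >= 5 samples")
  x <- expr[, samples, drop = FALSE]
  const <- apply(x, 1, function(r) stats::sd(r) == 0)
  if (any(const)) {
    warning(sum(const), " constant gene(s) excluded (correlation undefined)")
    x <- x[!const, , drop = FALSE]
  }
  rr <- rank(imputed_drug[samples])
  gr <- t(apply(x, 1, rank))
  rho <- as.vector(stats::cor(rr, t(gr)))
  rownames(x)[!is.na(rho) & abs(rho) >= threshold]
}

#' Build the PPI subnetwork induced on a gene list
#'
#' Induced subgraph on exactly the supplied genes (maximum interactors = 0),
#' keeping edges with confidence >= `min_conf` (0-1000 scale); isolated
#' supplied genes are retained as nodes. Duplicate undirected pairs collapse
#' to one edge with the maximum confidence.
#'
#' @param edges data.frame protein1/protein2/combined_score.
#' @param genes character vector of node ids.
#' @param min_conf minimum combined score (default 700, i.e. 0.7).
#' @return an igraph undirected graph with edge attribute `confidence`.
#' @export
build_ppi_subnetwork <- function(edges, genes, min_conf = 700) {
  if (!length(genes)) stop("build_ppi_subnetwork: empty gene list")
  genes <- sort(unique(genes))
  keep <- edges$combined_score >= min_conf &
    edges$protein1 %in% genes & edges$protein2 %in% genes &
    edges$protein1 != edges$protein2
  e <- edges[keep, , drop = FALSE]
  if (nrow(e)) {
    lo <- pmin(e$protein1, e$protein2)
    hi <- pmax(e$protein1, e$protein2)
    key <- paste(lo, hi, sep = "\r")
    o <- order(key, -e$combined_score, method = "radix")
    e <- data.frame(from = lo[o], to = hi[o],
                    confidence = e$combined_score[o],
                    stringsAsFactors = FALSE)
    e <- e[!duplicated(paste(e$from, e$to, sep = "\r")), ]
  } else {
    e <- data.frame(from = character(0), to = character(0),
                    confidence = numeric(0))
  }
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = genes))
}

# ---- shortest-path machinery (adjacency lists, BFS with path counts) -------

graph_adjlist <- function(graph) {
  al <- igraph::as_adj_list(graph, mode = "all")
  lapply(al, function(v) sort(as.integer(v)))
}

bfs_paths <- function(adj, s, n) {
  d <- rep(NA_integer_, n)
  sigma <- numeric(n)
  d[s] <- 0L
  sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (w in adj[[u]]) {
        if (is.na(d[w])) {
          d[w] <- d[u] + 1L
          nxt <- c(nxt, w)
        }
        if (!is.na(d[w]) && d[w] == d[u] + 1L) sigma[w] <- sigma[w] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(d = d, sigma = sigma)
}

all_pairs_paths <- function(adj, n) {
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    b <- bfs_paths(adj, s, n)
    fin <- !is.na(b$d)
    d[s, fin] <- b$d[fin]
    sigma[s, ] <- b$sigma
  }
  list(d = d, sigma = sigma)
}

centrality_stress <- function(adj, n) {
  ap <- all_pairs_paths(adj, n)
  d <- ap$d
  sg <- ap$sigma
  out <- numeric(n)
  for (v in seq_len(n)) {
    through <- outer(d[, v], d[v, ], "+") == d & is.finite(d)
    cnt <- outer(sg[, v], sg[v, ]) * through
    cnt[v, ] <- 0
    cnt[, v] <- 0
    out[v] <- sum(cnt[upper.tri(cnt)])
  }
  out
}

centrality_bottleneck <- function(adj, n) {
  counts <- numeric(n)
  for (s in seq_len(n)) {
    parent <- rep(NA_integer_, n)
    d <- rep(NA_integer_, n)
    d[s] <- 0L
    queue <- s
    order_visited <- s
    head <- 1L
    while (head <= length(queue)) {
      u <- queue[head]
      head <- head + 1L
      for (w in adj[[u]]) { # adj lists are pre-sorted: canonical tree
        if (is.na(d[w])) {
          d[w] <- d[u] + 1L
          parent[w] <- u
          queue <- c(queue, w)
          order_visited <- c(order_visited, w)
        }
      }
    }
    tree <- order_visited
    nt <- length(tree)
    size <- rep(1, n)
    for (u in rev(tree)) {
      if (!is.na(parent[u])) size[parent[u]] <- size[parent[u]] + size[u]
    }
    for (v in tree) {
      if (v != s && size[v] > nt / 4) counts[v] <- counts[v] + 1
    }
  }
  counts
}

centrality_epc <- function(graph, R = 1000, seed = 1) {
  n <- igraph::vcount(graph)
  if (n == 0) return(numeric(0))
  el <- igraph::as_edgelist(graph, names = FALSE)
  conf <- igraph::edge_attr(graph, "confidence")
  prob <- if (is.null(conf)) rep(0.5, nrow(el)) else conf / 1000
  set.seed(seed)
  acc <- numeric(n)
  for (r in seq_len(R)) {
    keep <- stats::runif(nrow(el)) < prob
    sg <- igraph::subgraph_from_edges(graph, which(keep), delete.vertices = FALSE)
    cm <- igraph::components(sg)
    acc <- acc + cm$csize[cm$membership]
  }
  acc / R
}

centrality_mcc <- function(graph) {
  n <- igraph::vcount(graph)
  out <- numeric(n)
  if (n == 0) return(out)
  cl <- igraph::max_cliques(graph, min = 2)
  for (cq in cl) {
    idx <- as.integer(cq)
    out[idx] <- out[idx] + factorial(length(idx) - 1)
  }
  out
}

# largest neighbourhood component; ties: more edges, then smallest node id
neighbourhood_component <- function(graph, v) {
  nb <- as.integer(igraph::neighbors(graph, v))
  if (!length(nb)) return(list(nv = 0L, ne = 0L))
  sub <- igraph::induced_subgraph(graph, nb)
  cm <- igraph::components(sub)
  best <- NULL
  for (k in seq_len(cm$no)) {
    members <- which(cm$membership == k)
    nv <- length(members)
    ne <- igraph::ecount(igraph::induced_subgraph(sub, members))
    id <- min(igraph::V(sub)$name[members])
    cand <- list(nv = nv, ne = ne, id = id)
    if (is.null(best) || nv > best$nv ||
        (nv == best$nv && (ne > best$ne || (ne == best$ne && id < best$id)))) {
      best <- cand
    }
  }
  best
}

#' Topological centrality scores
#'
#' Computes one of the 12 hub-ranking methods (see the definitions at the top
#' of this file). All methods except EPC are deterministic; EPC is a seeded
#' Monte-Carlo mean over `R` edge-percolation replicates.
#'
#' @param graph igraph graph from [build_ppi_subnetwork()] (or any undirected
#'   simple graph with named vertices).
#' @param method one of Betweenness, Bottleneck, Closeness,
#'   ClusteringCoefficient, Degree, DMNC, EcCentricity, EPC, MCC, MNC,
#'   Radiality, Stress.
#' @param seed RNG seed for EPC.
#' @param R EPC replicate count.
#' @return named numeric vector of per-node scores.
#' @export
centrality <- function(graph, method, seed = 1, R = 1000) {
  if (!method %in% CENTRALITY_METHODS) {
    stop("unknown centrality method '", method, "'")
  }
  n <- igraph::vcount(graph)
  if (n == 0) stop("centrality: empty graph")
  nm <- igraph::V(graph)$name
  adj <- graph_adjlist(graph)
  dmat <- function() igraph::distances(graph)
  sc <- switch(method,
    Degree = as.numeric(igraph::degree(graph)),
    Betweenness = as.numeric(igraph::betweenness(graph, directed = FALSE)),
    Stress = centrality_stress(adj, n),
    Closeness = {
      d <- dmat()
      h <- 1 / d
      diag(h) <- 0
      rowSums(h)
    },
    EcCentricity = {
      d <- dmat()
      apply(d, 1, function(r) {
        mx <- max(r[is.finite(r)])
        if (mx == 0) 0 else 1 / mx
      })
    },
    Radiality = {
      d <- dmat()
      cm <- igraph::components(graph)
      out <- numeric(n)
      for (k in seq_len(cm$no)) {
        members <- which(cm$membership == k)
        if (length(members) == 1L) { out[members] <- 0; next }
        dk <- d[members, members, drop = FALSE]
        diam <- max(dk)
        nc <- length(members)
        out[members] <- (rowSums(diam + 1 - dk) - (diam + 1)) / (nc - 1)
      }
      out
    },
    ClusteringCoefficient = {
      cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
      deg <- igraph::degree(graph)
      cc[deg < 2] <- 0
      as.numeric(cc)
    },
    MNC = vapply(seq_len(n), function(v)
      as.numeric(neighbourhood_component(graph, v)$nv), numeric(1)),
    DMNC = vapply(seq_len(n), function(v) {
      m <- neighbourhood_component(graph, v)
      if (m$nv <= 1) 0 else m$ne / m$nv^1.7
    }, numeric(1)),
    MCC = centrality_mcc(graph),
    Bottleneck = centrality_bottleneck(adj, n),
    EPC = centrality_epc(graph, R = R, seed = seed)
  )
  stats::setNames(as.numeric(sc), nm)
}

#' All 12 centralities as a gene x method table
#'
#' @param graph igraph graph.
#' @param methods subset of the 12 method names (default all).
#' @param seed,R passed to EPC.
#' @return numeric matrix, genes x methods, class `centrality_table`.
#' @export
centrality_table <- function(graph, methods = CENTRALITY_METHODS, seed = 1,
                             R = 1000) {
  cols <- lapply(methods, function(m) centrality(graph, m, seed = seed, R = R))
  tab <- do.call(cbind, cols)
  colnames(tab) <- methods
  structure(tab, class = c("centrality_table", class(tab)))
}

#' Tiered consensus over per-method top-k hub lists
#'
#' Per method, the `k` highest-scoring genes are listed (ties broken by
#' lexicographic gene id; all genes listed when the graph has fewer than `k`
#' nodes); each gene is counted by the number of methods listing it, and the
#' selected set contains genes counted by at least `min_methods` methods.
#'
#' @param tab a `centrality_table`.
#' @param k per-method list size (default 50).
#' @param min_methods consensus threshold (e.g. 6 or 8 of 12).
#' @return list of class `consensus_table`: `counts` (named, all genes),
#'   `selected`, `tiers` (distinct counts, descending), `k`, `min_methods`.
#' @export
consensus_hubs <- function(tab, k = 50, min_methods = 6) {
  stopifnot(k >= 1, min_methods >= 1, min_methods <= ncol(tab))
  genes <- rownames(tab)
  counts <- stats::setNames(integer(length(genes)), genes)
  for (m in colnames(tab)) {
    ord <- order(-tab[, m], genes, method = "radix")
    top <- genes[ord][seq_len(min(k, length(genes)))]
    counts[top] <- counts[top] + 1L
  }
  tiers <- sort(unique(counts[counts > 0]), decreasing = TRUE)
  tier_df <- data.frame(
    methods_count = tiers,
    n_genes = vapply(tiers, function(t) sum(counts == t), integer(1)))
  structure(list(counts = counts,
                 selected = sort(names(counts)[counts >= min_methods]),
                 tiers = tier_df, k = k, min_methods = min_methods),
            class = "consensus_table")
}

#' Spearman biomarker filter against measured drug response
#'
#' Per candidate gene, Spearman rank correlation (and two-sided p) between
#' cell-line expression and measured AUC; selected iff rho < 0 and p < 0.05
#' (higher expression, lower AUC, more sensitive).
#'
#' @param ccl_expr genes x cell lines expression matrix.
#' @param measured_auc named numeric vector of measured AUCs.
#' @param candidates character vector of candidate genes.
#' @return data.frame gene_id / rho / p_value / selected.
#' @export
spearman_biomarker_filter <- function(ccl_expr, measured_auc, candidates) {
  present <- intersect(candidates, rownames(ccl_expr))
  if (length(present) < length(candidates)) {
    warning(length(candidates) - length(present),
            " candidate gene(s) missing from the expression matrix, dropped")
  }
  lines <- intersect(colnames(ccl_expr), names(measured_auc))
  lines <- lines[is.finite(measured_auc[lines])]
  if (length(lines) < 5L) stop("spearman_biomarker_filter needs >= 5 cell lines")
  y <- measured_auc[lines]
  rows <- lapply(present, function(g) {
    ct <- suppressWarnings(
      stats::cor.test(ccl_expr[g, lines], y, method = "spearman",
                      exact = FALSE))
    data.frame(gene_id = g, rho = unname(ct$estimate),
               p_value = ct$p.value,
               selected = unname(ct$estimate) < 0 & ct$p.value < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Welch test of imputed response between strata
#'
#' Two-sided Welch's unequal-variance t-test of the imputed response between
#' the `AR_low_Gly_high` stratum and all others; group means are reported so
#' the direction (more sensitive = lower predicted response) is explicit.
#'
#' @param imputed_drug named numeric vector of imputed responses.
#' @param strata `strata_labels` from [stratify_ar_gly()].
#' @return list: `t`, `df`, `p`, `mean_target`, `mean_other`, `n_target`,
#'   `n_other`.
#' @export
stratum_response_test <- function(imputed_drug, strata) {
  shared <- intersect(names(imputed_drug), names(strata))
  g1 <- imputed_drug[shared[strata[shared] == "AR_low_Gly_high"]]
  g2 <- imputed_drug[shared[strata[shared] == "other"]]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("stratum_response_test: each stratum needs >= 2 samples")
  }
  w <- welch_test(g1, g2)
  list(t = w$t, df = w$df, p = w$p, mean_target = w$mean_x,
       mean_other = w$mean_y, n_target = w$n_x, n_other = w$n_y)
}
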