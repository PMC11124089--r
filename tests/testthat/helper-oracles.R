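# Independent brute-force centrality oracle. Deliberately shares no code with
# the package: distances via Floyd-Warshall, path counts via DP over levels,
# cliques via plain Bron-Kerbosch, BFS trees derived from the distance matrix,
# percolation components via union-find.

oracle_fw_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    S[s, s] <- 1
    ds <- D[s, ]
    for (dist in sort(unique(ds[is.finite(ds) & ds > 0]))) {
      for (t in which(ds == dist)) {
        preds <- which(A[, t] == 1 & ds == dist - 1)
        S[s, t] <- sum(S[s, preds])
      }
    }
  }
  S
}

oracle_bron_kerbosch <- function(A) {
  n <- nrow(A)
  cliques <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      cliques[[length(cliques) + 1L]] <<- R
      return(invisible())
    }
    for (v in P) {
      nb <- which(A[v, ] == 1)
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques
}

# canonical BFS tree from the distance matrix: discovery order within a level
# follows the parents' order, each parent claiming its unassigned neighbours
# in ascending node index
oracle_bottleneck <- function(A, D) {
  n <- nrow(A)
  counts <- numeric(n)
  for (s in seq_len(n)) {
    lev <- D[s, ]
    if (all(!is.finite(lev[-s]))) next
    parent <- rep(NA_integer_, n)
    order_now <- s
    tree <- s
    L <- 0
    repeat {
      nxt <- integer(0)
      members <- which(lev == L + 1)
      if (!length(members)) break
      assigned <- logical(n)
      for (u in order_now) {
        for (w in sort(which(A[u, ] == 1))) {
          if (lev[w] == L + 1 && !assigned[w]) {
            assigned[w] <- TRUE
            parent[w] <- u
            nxt <- c(nxt, w)
          }
        }
      }
      tree <- c(tree, nxt)
      order_now <- nxt
      L <- L + 1
    }
    nt <- length(tree)
    size <- rep(1, n)
    for (w in rev(tree)) {
      if (!is.na(parent[w])) size[parent[w]] <- size[parent[w]] + size[w]
    }
    for (v in tree) if (v != s && size[v] > nt / 4) counts[v] <- counts[v] + 1
  }
  counts
}

oracle_components_sub <- function(A, members) {
  # components of the induced subgraph on `members`; list of index vectors
  remaining <- members
  comps <- list()
  while (length(remaining)) {
    comp <- remaining[1]
    repeat {
      grow <- setdiff(remaining[colSums(A[comp, remaining, drop = FALSE]) > 0], comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

# all 11 deterministic centralities, named by method
oracle_centralities <- function(A, node_names) {
  n <- nrow(A)
  D <- oracle_fw_dist(A)
  S <- oracle_path_counts(A, D)
  deg <- rowSums(A)

  btw <- numeric(n)
  str_ <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t]) {
          cnt <- S[s, v] * S[v, t]
          str_[v] <- str_[v] + cnt
          btw[v] <- btw[v] + cnt / S[s, t]
        }
      }
    }
  }

  clo <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    sum(1 / d[is.finite(d)])
  }, numeric(1))

  ecc <- vapply(seq_len(n), function(v) {
    mx <- max(D[v, ][is.finite(D[v, ])])
    if (mx == 0) 0 else 1 / mx
  }, numeric(1))

  rad <- numeric(n)
  for (comp in oracle_components_sub(A, seq_len(n))) {
    if (length(comp) == 1L) next
    dk <- D[comp, comp, drop = FALSE]
    diam <- max(dk)
    for (i in seq_along(comp)) {
      rad[comp[i]] <- sum(diam + 1 - dk[i, -i]) / (length(comp) - 1)
    }
  }

  cc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1)) # = edges among neighbours / C(k, 2)
  }, numeric(1))

  mnc <- numeric(n)
  dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    if (!length(nb)) next
    comps <- oracle_components_sub(A, nb)
    best <- NULL
    for (cp in comps) {
      nv <- length(cp)
      ne <- sum(A[cp, cp]) / 2
      id <- node_names[min(cp)]
      if (is.null(best) || nv > best$nv ||
          (nv == best$nv && (ne > best$ne || (ne == best$ne && id < best$id)))) {
        best <- list(nv = nv, ne = ne, id = id)
      }
    }
    mnc[v] <- best$nv
    if (best$nv > 1) dmnc[v] <- best$ne / best$nv^1.7
  }

  mcc <- numeric(n)
  for (cq in oracle_bron_kerbosch(A)) {
    if (length(cq) < 2) next
    mcc[cq] <- mcc[cq] + factorial(length(cq) - 1)
  }

  out <- list(Betweenness = btw, Stress = str_, Closeness = clo,
              EcCentricity = ecc, Radiality = rad,
              ClusteringCoefficient = cc, Degree = deg, MNC = mnc,
              DMNC = dmnc, MCC = mcc,
              Bottleneck = oracle_bottleneck(A, D))
  lapply(out, function(x) stats::setNames(x, node_names))
}

# second, independent EPC Monte-Carlo: rbinom edge draws + union-find
oracle_epc <- function(A, conf = NULL, R = 1000, seed = 1) {
  n <- nrow(A)
  el <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  prob <- if (is.null(conf)) rep(0.5, nrow(el)) else conf / 1000
  find <- function(par, x) {
    while (par[x] != x) x <- par[x]
    x
  }
  set.seed(seed)
  acc <- numeric(n)
  est2 <- numeric(n)
  for (r in seq_len(R)) {
    keep <- stats::rbinom(nrow(el), 1, prob) == 1
    par <- seq_len(n)
    for (e in which(keep)) {
      a <- find(par, el[e, 1])
      b <- find(par, el[e, 2])
      if (a != b) par[a] <- b
    }
    roots <- vapply(seq_len(n), function(x) find(par, x), integer(1))
    sz <- table(roots)
    cs <- as.numeric(sz[as.character(roots)])
    acc <- acc + cs
    est2 <- est2 + cs^2
  }
  list(mean = acc / R, var = est2 / R - (acc / R)^2)
}

# seeded Erdos-Renyi graph with named vertices, optional edge confidence
random_test_graph <- function(n, p, seed, with_conf = FALSE) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(stats::runif(length(up)) < p)
  A <- A + t(A)
  names <- sprintf("n%02d", seq_len(n))
  dimnames(A) <- list(names, names)
  el <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  conf <- if (with_conf) sample(150:999, nrow(el), replace = TRUE) else NULL
  df <- data.frame(from = names[el[, 1]], to = names[el[, 2]])
  if (!is.null(conf)) df$confidence <- conf
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = names))
  list(graph = g, A = A, conf = conf)
}
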