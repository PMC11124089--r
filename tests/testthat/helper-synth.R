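# Shared fixtures: small synthetic worlds used across module tests.

tiny_config <- function(seed = 7, ...) {
  args <- list(n_genes = 200, n_ccl = 60, n_patients_per_cohort = 40,
               n_drugs = 12, n_planted_hg = 3, n_planted_de = 2,
               geneset_sizes = c(glycolysis = 15, oxphos = 30, ar = 8),
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

# clinical table builder for survival tests
make_clinical <- function(time, event, ids = sprintf("s%02d", seq_along(time)),
                          age = NA_real_) {
  data.frame(sample_id = ids, age_at_procurement = age,
             os_months = time, os_event = event, stringsAsFactors = FALSE)
}

# path graph a-b-c..., as igraph with named vertices
named_graph <- function(edges, vertices = NULL) {
  df <- data.frame(from = edges[, 1], to = edges[, 2])
  if (is.null(vertices)) vertices <- sort(unique(c(df$from, df$to)))
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = vertices))
}
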