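# Readers and writers for the plain-text interchange formats used by the
# pipeline: expression TSV (genes x samples), GMT gene sets, clinical CSV,
# drug AUC CSV, drug metadata CSV, STRING-style PPI edge TSV, score CSV.

#' Gene set collection
#'
#' @param sets named list of character vectors (gene ids).
#' @param description optional named character vector of set descriptions.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("gene sets must be named")
  }
  for (nm in names(sets)) {
    if (anyDuplicated(sets[[nm]])) {
      stop("duplicate gene ids within set '", nm, "'")
    }
  }
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, description = description),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection>", length(x$sets), "sets\n")
  for (nm in names(x$sets)) cat(" ", nm, ":", length(x$sets[[nm]]), "genes\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT '%s' line %d: expected >= 3 tab-separated fields, got %d",
                   path, i, length(fields)))
    }
    sets[[fields[1]]] <- fields[-(1:2)]
    desc[fields[1]] <- fields[2]
  }
  gene_set_collection(sets, desc)
}

#' Write a GMT gene-set file
#' @param gsc a [gene_set_collection()].
#' @param path file path.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$description[[nm]] %||% "", gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' First column `gene_id`, remaining columns one per sample; values are
#' log-scale expression (e.g. log2(FPKM + 1)).
#'
#' @param path file path.
#' @return numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "gene_id") {
    stop(sprintf("malformed expression TSV '%s': first column must be 'gene_id'", path))
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicated gene ids in '%s': %s", path,
                 paste(utils::head(dups, 5), collapse = ", ")))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix TSV
#' @param mat genes x samples numeric matrix with dimnames.
#' @param path file path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table CSV
#'
#' Columns: `sample_id`, `age_at_procurement` (years; may be NA),
#' `os_months` (> 0), `os_event` (1 = death observed, 0 = censored).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_months", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("malformed clinical CSV '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in ", path)
  validate_clinical(df)
  df
}

validate_clinical <- function(df) {
  if (any(!is.finite(df$os_months)) || any(df$os_months <= 0)) {
    stop("clinical table: os_months must be finite and > 0")
  }
  if (!all(df$os_event %in% c(0, 1))) {
    stop("clinical table: os_event must be 0/1")
  }
  invisible(df)
}

#' Write a clinical table CSV
#' @param df clinical data.frame.
#' @param path file path.
#' @export
write_clinical_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measured drug-response AUC CSV
#'
#' First column `cell_line_id`, one column per drug; lower AUC = more
#' sensitive. Missing entries allowed (NA).
#'
#' @param path file path.
#' @return numeric matrix cell lines x drugs.
#' @export
read_auc_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "cell_line_id") {
    stop(sprintf("malformed AUC CSV '%s': first column must be 'cell_line_id'", path))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a measured drug-response AUC CSV
#' @param mat cell lines x drugs matrix.
#' @param path file path.
#' @export
write_auc_csv <- function(mat, path) {
  df <- data.frame(cell_line_id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read drug metadata CSV (`drug_id`, `moa`, `status`)
#' @param path file path.
#' @return data.frame.
#' @export
read_drug_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "moa", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("malformed drug metadata CSV '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  df
}

#' Write drug metadata CSV
#' @param df data.frame with drug_id, moa, status.
#' @param path file path.
#' @export
write_drug_metadata_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a STRING-style PPI edge TSV
#'
#' Columns `protein1`, `protein2`, `combined_score`; scores are integers on
#' the 0-1000 confidence scale used by STRING exports.
#'
#' @param path file path.
#' @return data.frame with the three columns.
#' @export
read_string_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("malformed PPI TSV '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  sc <- df$combined_score
  bad <- which(!is.finite(sc) | sc < 0 | sc > 1000 | sc != round(sc))
  if (length(bad)) {
    stop(sprintf("malformed PPI TSV '%s': combined_score out of 0-1000 at data row(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")))
  }
  df[need]
}

#' Write a STRING-style PPI edge TSV
#' @param edges data.frame protein1/protein2/combined_score.
#' @param path file path.
#' @export
write_string_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a score table CSV (`sample_id`, `signature`, `score`, `scale`)
#' @param st a score table (see [gsva_enrichment()]).
#' @param path file path.
#' @export
write_score_csv <- function(st, path) {
  df <- as.data.frame(st)
  df$scale <- attr(st, "scale") %||% "raw"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
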