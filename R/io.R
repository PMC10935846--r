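# Plain-text interchange: TSV matrices (first column = row id, header =
# column ids, empty or "NA" = missing), 3-column edge lists, one-set-per-
# line gene-set files, and JSON ground-truth side-channels.

#' Read a TSV matrix (first column = row ids)
#'
#' @param path TSV file; header row holds column ids, the first column
#'   row ids; empty cells or "NA" are missing.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"),
                        comment = "#")
  as_value_matrix(df, path)
}

#' Write a matrix as TSV (first column = row ids)
#'
#' @param matrix Numeric matrix with dimnames.
#' @param path Output file.
#' @param id_name Header of the id column (default "id").
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path, id_name = "id") {
  m <- as_value_matrix(matrix, "matrix")
  df <- as_tibble(m, rownames = id_name)
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' Read a 3-column edge-list TSV (gene_a, gene_b, confidence)
#' @param path TSV file with a header row.
#' @return Tibble: gene_a, gene_b, confidence.
#' @export
read_edges_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (ncol(df) < 3) abort("Edge file needs 3 columns: gene_a, gene_b, confidence.")
  tibble(gene_a = as.character(df[[1]]), gene_b = as.character(df[[2]]),
         confidence = as.numeric(df[[3]]))
}

#' Write an edge list as 3-column TSV
#' @param edges Tibble gene_a/gene_b/confidence.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(edges, path) {
  readr::write_tsv(edges[, c("gene_a", "gene_b", "confidence")], path)
  invisible(path)
}

#' Read gene sets from a one-set-per-line tab-separated file
#'
#' Each line: set name, description, then member gene ids, all
#' tab-separated (the GMT convention).
#'
#' @param path Gene-set file.
#' @return Named list of character vectors; descriptions kept in a
#'   `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descr <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort("Each gene-set line needs name, description and >= 1 member.")
    sets[[parts[1]]] <- unique(parts[-(1:2)])
    descr[parts[1]] <- parts[2]
  }
  attr(sets, "descriptions") <- descr
  sets
}

#' Write gene sets in one-set-per-line tab-separated format
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional named descriptions (default "na").
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a planted synthetic object's data files plus ground truth
#'
#' Writes the pipeline-facing data files of a `gen_*()` object under
#' `dir` with the given base `name`, and the planted ground truth to
#' `<name>.truth.json`. Pipeline stages read only the data files.
#'
#' @param x A `planted_phenome`, `planted_expression`, `planted_cross`,
#'   `planted_network` or `planted_drug_panel`.
#' @param dir Output directory (created if needed).
#' @param name File base name.
#' @return Named character vector of the files written, invisibly.
#' @export
write_planted <- function(x, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(suffix) file.path(dir, paste0(name, suffix))
  files <- c()
  truth <- list()
  if (inherits(x, "planted_phenome")) {
    write_matrix_tsv(x$matrix, p(".tsv"), id_name = "strain")
    files["matrix"] <- p(".tsv")
    truth <- x[c("block_assignment", "clade_label", "strain_axis", "params")]
  } else if (inherits(x, "planted_expression")) {
    write_matrix_tsv(x$matrix, p(".tsv"), id_name = "gene")
    files["matrix"] <- p(".tsv")
    truth <- x[c("true_signature", "batch_label", "dialect", "params")]
  } else if (inherits(x, "planted_cross")) {
    write_matrix_tsv(x$genotypes, p(".genotypes.tsv"), id_name = "segregant")
    readr::write_tsv(x$marker_pos, p(".markers.tsv"))
    readr::write_tsv(x$trait, p(".trait.tsv"))
    files <- c(genotypes = p(".genotypes.tsv"), markers = p(".markers.tsv"),
               trait = p(".trait.tsv"))
    truth <- x[c("qtl_markers", "params")]
  } else if (inherits(x, "planted_network")) {
    write_edges_tsv(x$edges, p(".edges.tsv"))
    readr::write_tsv(x$gene_intervals, p(".genes.tsv"))
    files <- c(edges = p(".edges.tsv"), genes = p(".genes.tsv"))
    truth <- list(module_genes = x$module_genes, params = x$params)
  } else if (inherits(x, "planted_drug_panel")) {
    write_matrix_tsv(x$expression, p(".expression.tsv"), id_name = "gene")
    write_matrix_tsv(x$resistance, p(".resistance.tsv"), id_name = "cell_line")
    write_gene_sets(list(PS = x$ps_genes, NS = x$ns_genes), p(".sets.tsv"))
    files <- c(expression = p(".expression.tsv"),
               resistance = p(".resistance.tsv"), sets = p(".sets.tsv"))
    truth <- x["params"]
  } else {
    abort("Unknown planted object.")
  }
  jsonlite::write_json(truth, p(".truth.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  files["truth"] <- p(".truth.json")
  invisible(files)
}
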