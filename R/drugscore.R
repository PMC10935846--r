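# PS/NS gene-set scoring of cell-line expression and correlation with
# drug resistance (normalized IC50 Z-scores; higher = more resistant).

#' Map a yeast gene set to human genes through an ortholog table
#'
#' Takes the union of the human targets of every set member; duplicates
#' collapse, unmapped members are counted and reported via a message.
#'
#' @param gene_set Character vector of yeast gene ids.
#' @param ortholog_map Two-column data frame (yeast, human); one yeast
#'   gene may map to several human genes.
#' @return Character vector of human gene ids (sorted, unique).
#' @export
map_orthologs <- function(gene_set, ortholog_map) {
  om <- as.data.frame(ortholog_map)
  if (nrow(om) == 0) abort("`ortholog_map` is empty.")
  yeast <- as.character(om[[1]])
  human <- as.character(om[[2]])
  hit <- yeast %in% gene_set
  unmapped <- sum(!gene_set %in% yeast)
  if (unmapped > 0) {
    inform(sprintf("map_orthologs: %d of %d gene(s) had no ortholog and were dropped.",
                   unmapped, length(gene_set)))
  }
  out <- sort(unique(human[hit]))
  if (length(out) == 0) abort("No gene of the set maps to a human ortholog.")
  out
}

#' PS/NS median scores per cell line
#'
#' Gene-wise mean-centers the expression matrix, then scores every cell
#' line with the median centered expression of the PS genes and of the NS
#' genes present in the matrix, plus their difference. Genes belonging to
#' both sets (possible through many-to-one orthology) are excluded from
#' both with a warning. The even-count median is the midpoint of the two
#' central order statistics.
#'
#' @param expression Complete genes x cell-lines matrix.
#' @param ps_set,ns_set Character vectors of (human) PS and NS gene ids.
#' @return Class `cell_line_scores`: tibble with cell_line, ps_score,
#'   ns_score, diff_score (= ps - ns), and `n_ps`/`n_ns` attributes for
#'   the intersecting set sizes.
#' @export
score_cell_lines <- function(expression, ps_set, ns_set) {
  m <- as_value_matrix(expression, "expression")
  assert_complete(m, "score_cell_lines")
  overlap <- intersect(ps_set, ns_set)
  if (length(overlap) > 0) {
    warn(sprintf("score_cell_lines: %d gene(s) in both PS and NS sets excluded from both.",
                 length(overlap)))
    ps_set <- setdiff(ps_set, overlap)
    ns_set <- setdiff(ns_set, overlap)
  }
  ps <- intersect(ps_set, rownames(m))
  ns <- intersect(ns_set, rownames(m))
  if (length(ps) == 0 || length(ns) == 0) {
    abort("PS or NS set has no gene in the expression matrix.")
  }
  cm <- sweep(m, 1, rowMeans(m))  # gene-wise centering
  ps_score <- apply(cm[ps, , drop = FALSE], 2, median)
  ns_score <- apply(cm[ns, , drop = FALSE], 2, median)
  structure(
    tibble(cell_line = colnames(m),
           ps_score = unname(ps_score),
           ns_score = unname(ns_score),
           diff_score = unname(ps_score - ns_score)),
    n_ps = length(ps), n_ns = length(ns),
    class = c("cell_line_scores", class(tibble()))
  )
}

#' Spearman correlation of PS/NS/diff scores with drug resistance
#'
#' For every drug, correlates each score type with the resistance
#' measure (e.g. GDSC Z_SCORE; higher = more resistant) across the cell
#' lines shared between the score table and that drug's non-missing
#' resistance values. Missing entries are pairwise-deleted per drug;
#' drugs with fewer than `min_cell_lines` usable lines are skipped with a
#' warning.
#'
#' @param scores A `cell_line_scores` tibble.
#' @param resistance_table Cell-lines x drugs matrix (or data frame with
#'   a cell-line id column); `NA` allowed.
#' @param min_cell_lines Minimum shared lines per drug (default 10).
#' @return Class `drug_cor_table`: tibble with drug, n_cell_lines, and
#'   rho/p for ps, ns and diff.
#' @export
correlate_with_resistance <- function(scores, resistance_table, min_cell_lines = 10) {
  stopifnot(is.data.frame(scores), all(c("cell_line", "ps_score", "ns_score", "diff_score") %in% names(scores)))
  res <- resistance_table
  if (is.data.frame(res)) res <- as_value_matrix(res, "resistance_table") else
    res <- as_value_matrix(res, "resistance_table")
  shared_lines <- intersect(scores$cell_line, rownames(res))
  sc <- scores[match(shared_lines, scores$cell_line), ]
  res <- res[shared_lines, , drop = FALSE]
  rows <- list()
  skipped <- 0L
  for (drug in colnames(res)) {
    ok <- !is.na(res[, drug])
    if (sum(ok) < min_cell_lines) {
      skipped <- skipped + 1L
      next
    }
    r <- res[ok, drug]
    ps <- spearman_test(sc$ps_score[ok], r)
    ns <- spearman_test(sc$ns_score[ok], r)
    df <- spearman_test(sc$diff_score[ok], r)
    rows[[drug]] <- tibble(drug = drug, n_cell_lines = sum(ok),
                           rho_ps = ps$rho, p_ps = ps$p,
                           rho_ns = ns$rho, p_ns = ns$p,
                           rho_diff = df$rho, p_diff = df$p)
  }
  if (skipped > 0) {
    warn(sprintf("correlate_with_resistance: %d drug(s) below %d shared cell lines skipped.",
                 skipped, min_cell_lines))
  }
  if (length(rows) == 0) abort("No drug meets the minimum cell-line count.")
  structure(bind_rows(rows), class = c("drug_cor_table", class(tibble())))
}

#' Summarize drug correlations per score type
#'
#' Median and quartiles of the per-drug Spearman correlations for each
#' score type, plus a two-sided sign test (exact binomial on the sign of
#' nonzero correlations) of whether the median correlation differs from
#' 0 across drugs.
#'
#' @param table A `drug_cor_table`.
#' @return Tibble: score_type, n_drugs, median_rho, q25, q75, sign_p.
#' @export
summarize_correlations <- function(table) {
  stopifnot(is.data.frame(table))
  if (nrow(table) < 1) abort("Need at least 1 drug.")
  one <- function(type, rho) {
    nz <- rho[rho != 0 & !is.na(rho)]
    sign_p <- if (length(nz) == 0) 1 else
      binom.test(sum(nz > 0), length(nz), 0.5)$p.value
    tibble(score_type = type, n_drugs = sum(!is.na(rho)),
           median_rho = median(rho, na.rm = TRUE),
           q25 = unname(quantile(rho, 0.25, na.rm = TRUE)),
           q75 = unname(quantile(rho, 0.75, na.rm = TRUE)),
           sign_p = sign_p)
  }
  bind_rows(one("ps", table$rho_ps), one("ns", table$rho_ns),
            one("diff", table$rho_diff))
}
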