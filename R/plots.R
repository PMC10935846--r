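# ggplot2 views of the result objects.

#' PAC curve across cluster numbers
#' @param object A `consensus_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consensus_result <- function(object, ...) {
  ggplot2::ggplot(object$pac, ggplot2::aes(x = .data$K, y = .data$pac)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = object$pac$K) +
    ggplot2::labs(x = "Number of clusters K",
                  y = "Proportion of ambiguous clustering (PAC)",
                  title = "Consensus clustering model selection") +
    ggplot2::theme_minimal()
}

#' Consensus matrix heatmap at one K
#' @param result A `consensus_result`.
#' @param K Which cluster number to show (default: minimum-PAC K).
#' @return A ggplot.
#' @export
plot_consensus_matrix <- function(result, K = NULL) {
  stopifnot(inherits(result, "consensus_result"))
  K <- K %||% optimal_k(result)[1]
  cm <- result$consensus[[as.character(K)]]
  if (is.null(cm)) abort(sprintf("K = %s was not scanned.", K))
  ord <- hcluster(1 - cm, K = K)
  lv <- ord$item[order(ord$cluster)]
  df <- as_tibble(cm, rownames = "a") |>
    tidyr::pivot_longer(-"a", names_to = "b", values_to = "index") |>
    mutate(a = factor(.data$a, levels = lv), b = factor(.data$b, levels = lv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$index)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Consensus",
                  title = sprintf("Consensus matrix, K = %d", K)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Signature score distribution, split by sign consistency
#' @param object A `recurrent_signature`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recurrent_signature <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$consistent)) +
    ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Gene signature score (first eigenarray)", y = "Genes",
                  fill = "Sign-consistent",
                  title = sprintf("Recurrent signature (%s)", object$source_tag)) +
    ggplot2::theme_minimal()
}

#' LOD score plot along the genome
#' @param object A `lod_scan`.
#' @param ... Unused.
#' @return A ggplot; the permutation threshold is drawn when present.
#' @export
autoplot.lod_scan <- function(object, ...) {
  df <- object$scan
  df$x <- if ("start" %in% names(df)) df$start else seq_len(nrow(df))
  p <- ggplot2::ggplot(df[!is.na(df$lod), ], ggplot2::aes(x = .data$x, y = .data$lod)) +
    ggplot2::geom_point(size = 0.8, colour = "#2b5d8a") +
    ggplot2::labs(x = if ("start" %in% names(df)) "Position" else "Marker index",
                  y = "LOD score", title = "Genotype-overall growth linkage") +
    ggplot2::theme_minimal()
  if ("chrom" %in% names(df) && length(unique(df$chrom)) > 1) {
    p <- p + ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                                 scales = "free_x", space = "free_x")
  }
  if (!is.null(object$threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = object$threshold,
                                 linetype = 2, colour = "red")
  }
  p
}

#' Observed vs null LCC size along the gene ranking
#' @param object An `lcc_curve`.
#' @param ... Unused.
#' @return A ggplot with the null mean +/- 1 SD ribbon.
#' @export
autoplot.lcc_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$null_mean - .data$null_sd,
                                      ymax = .data$null_mean + .data$null_sd),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed_lcc), colour = "#b2182b") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_lcc), colour = "#b2182b") +
    ggplot2::labs(x = "Top-ranked genes analyzed",
                  y = "Largest connected component size",
                  title = "Functional connectedness of top-associated genes") +
    ggplot2::theme_minimal()
}

#' Per-drug correlation distributions by score type
#' @param object A `drug_cor_table`.
#' @param ... Unused.
#' @return A ggplot boxplot of Spearman correlations.
#' @export
autoplot.drug_cor_table <- function(object, ...) {
  df <- tidy(object)
  df$score_type <- factor(df$score_type, levels = c("ps", "ns", "diff"),
                          labels = c("PS", "NS", "PS - NS"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score_type, y = .data$rho)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Cell-line score", y = "Spearman correlation with resistance",
                  title = "Signature scores vs drug resistance") +
    ggplot2::theme_minimal()
}

#' Gene-set score distributions as boxplots
#' @param dist Output of [gene_set_score_distribution()].
#' @return A ggplot.
#' @export
plot_gene_set_scores <- function(dist) {
  stopifnot(is.list(dist), "scores" %in% names(dist))
  ggplot2::ggplot(dist$scores, ggplot2::aes(x = .data$set, y = .data$score)) +
    ggplot2::geom_boxplot(fill = "grey90", outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Gene signature score",
                  title = "Signature scores across gene sets") +
    ggplot2::theme_minimal()
}
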