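# broom-style tidy()/glance() methods for the package's result objects.

#' @export
tidy.consensus_result <- function(x, ...) x$pac

#' @export
glance.consensus_result <- function(x, ...) {
  best <- optimal_k(x)
  tibble(best_K = best[1], n_tied = length(best),
         min_pac = min(x$pac$pac),
         n_iterations = x$n_iterations,
         resample_fraction = x$resample_fraction)
}

#' @export
tidy.recurrent_signature <- function(x, ...) {
  tibble(gene = names(x$score), score = unname(x$score),
         consistent = unname(x$consistent[names(x$score)]))
}

#' @export
glance.recurrent_signature <- function(x, ...) {
  tibble(n_genes = length(x$score),
         n_consistent = sum(x$consistent),
         n_positive = sum(x$score > 0 & x$consistent),
         n_negative = sum(x$score < 0 & x$consistent),
         n_iterations = x$n_iterations,
         noise_sd = x$noise_sd,
         source_tag = x$source_tag)
}

#' @export
tidy.lod_scan <- function(x, ...) x$scan

#' @export
glance.lod_scan <- function(x, ...) {
  ok <- !is.na(x$scan$lod)
  peak <- which.max(x$scan$lod)
  tibble(n_segregants = x$n,
         n_markers = nrow(x$scan),
         n_skipped = x$n_skipped,
         max_lod = max(x$scan$lod[ok]),
         peak_marker = x$scan$marker[peak],
         threshold = x$threshold %||% NA_real_,
         n_permutations = x$n_permutations)
}

#' @export
tidy.lowrank_phenome <- function(x, ...) {
  tibble(component = seq_along(x$d), singular_value = x$d,
         kept = seq_along(x$d) <= x$rank_used)
}

#' @export
glance.lowrank_phenome <- function(x, ...) {
  tibble(rank_used = x$rank_used, frob_error = x$frob_error,
         var_captured = sum(x$d[seq_len(x$rank_used)]^2) / sum(x$d^2))
}

#' @export
tidy.lcc_test <- function(x, ...) {
  tibble(observed_lcc_size = x$observed_lcc_size,
         null_mean = x$null_mean, null_sd = x$null_sd,
         empirical_p = x$empirical_p,
         n_iterations = x$n_iterations,
         n_genes_selected = x$n_genes_selected)
}

#' @export
glance.lcc_test <- tidy.lcc_test

#' @export
tidy.drug_cor_table <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x),
                      cols = c("rho_ps", "rho_ns", "rho_diff"),
                      names_to = "score_type", names_prefix = "rho_",
                      values_to = "rho")[, c("drug", "n_cell_lines", "score_type", "rho")]
}

#' @export
glance.drug_cor_table <- function(x, ...) {
  s <- summarize_correlations(x)
  tidyr::pivot_wider(s[, c("score_type", "median_rho")],
                     names_from = "score_type", values_from = "median_rho",
                     names_prefix = "median_rho_") |>
    mutate(n_drugs = nrow(x))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> K in {%s}, %d iterations at %.0f%% resampling\n",
              paste(x$pac$K, collapse = ", "), x$n_iterations,
              100 * x$resample_fraction))
  print(x$pac)
  invisible(x)
}

#' @export
print.lod_scan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<lod_scan> %d markers x %d segregants; max LOD %.2f at %s",
              g$n_markers, g$n_segregants, g$max_lod, g$peak_marker))
  if (!is.na(g$threshold)) cat(sprintf(" (threshold %.2f)", g$threshold))
  cat("\n")
  invisible(x)
}

#' @export
print.lcc_test <- function(x, ...) {
  cat(sprintf("<lcc_test> observed LCC %d vs null %.2f +/- %.2f (%d draws of %d genes), p = %.4g\n",
              x$observed_lcc_size, x$null_mean, x$null_sd,
              x$n_iterations, x$n_genes_selected, x$empirical_p))
  invisible(x)
}
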