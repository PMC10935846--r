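# Recurrent gene-expression signatures: first eigenarrays stabilized by
# noise perturbation and sign-consistency filtering, PS/NS gene sets, and
# the downstream characterization analyses.

new_signature <- function(score, consistent, n_iterations, noise_sd,
                          source_tag = "other", flip_count = 0L) {
  structure(list(
    score = score,              # named numeric, unit-norm eigenarray
    consistent = consistent,    # named logical, same names
    n_iterations = n_iterations,
    noise_sd = noise_sd,
    source_tag = source_tag,
    flip_count = flip_count
  ), class = "recurrent_signature")
}

#' @export
print.recurrent_signature <- function(x, ...) {
  cat(sprintf("<recurrent_signature> %d genes (%d sign-consistent), tag '%s', %d iteration(s)\n",
              length(x$score), sum(x$consistent), x$source_tag, x$n_iterations))
  invisible(x)
}

#' Zero-center each sample column
#'
#' Sample-wise zero-center scaling: subtracts each sample's mean so every
#' column sums to zero. No variance scaling is applied.
#'
#' @param matrix Complete genes x samples matrix or data frame.
#' @return Centered matrix.
#' @export
scale_samples <- function(matrix) {
  m <- as_value_matrix(matrix, "matrix")
  if (length(m) == 0) abort("`matrix` is empty.")
  assert_complete(m, "scale_samples")
  sweep(m, 2, colMeans(m))
}

#' Subtract the gene-wise mean from each gene row
#'
#' Puts absolute-scale data (counts/intensities) on the same footing as
#' relative two-colour ratios, whose values are already deviations from a
#' pooled reference. Intended call order: `center_genes()` then
#' [scale_samples()]. Refuses relative-dialect input, which is already
#' reference-normalized.
#'
#' @param matrix Complete genes x samples matrix.
#' @param dialect `"absolute"` (default) or `"relative"` (error).
#' @return Row-centered matrix.
#' @export
center_genes <- function(matrix, dialect = c("absolute", "relative")) {
  dialect <- match.arg(dialect)
  if (dialect == "relative") {
    abort("center_genes() is for absolute-scale data; relative (two-colour) values are already reference-normalized.")
  }
  m <- as_value_matrix(matrix, "matrix")
  assert_complete(m, "center_genes")
  sweep(m, 1, rowMeans(m))
}

# First left-singular vector, sign-oriented; errors when the top singular
# pair is degenerate (the eigenarray would not be identifiable).
.first_u <- function(m) {
  s <- svd(m, nu = 2, nv = 0)
  if (length(s$d) > 1 && (s$d[1] - s$d[2]) <= 1e-9 * max(s$d[1], 1)) {
    abort("Top singular values are degenerate; the first eigenarray is not identifiable.")
  }
  setNames(orient_vector(s$u[, 1]), rownames(m))
}

#' First eigenarray of an expression matrix
#'
#' The unit-norm first left-singular vector of the sample-scaled matrix:
#' each gene's entry is its gene signature score on the most influential
#' cellular state. The sign is oriented so the gene of largest magnitude
#' scores positive.
#'
#' @param matrix Complete, sample-scaled genes x samples matrix.
#' @param source_tag Optional provenance label stored on the result.
#' @return A `recurrent_signature` with all genes marked consistent.
#' @export
first_eigenarray <- function(matrix, source_tag = "other") {
  m <- as_value_matrix(matrix, "matrix")
  assert_complete(m, "first_eigenarray")
  u <- .first_u(m)
  new_signature(u, setNames(rep(TRUE, length(u)), names(u)),
                n_iterations = 1L, noise_sd = 0, source_tag = source_tag)
}

#' Robust recurrent signature via noise-perturbed SVD
#'
#' Re-extracts the first eigenarray `n_iterations` times after adding
#' i.i.d. Gaussian noise (default mean 0, SD 1) to every expression
#' value. Each perturbed eigenarray is orientation-matched to the
#' unperturbed one (flipped when their inner product is negative; flips
#' are counted). A gene is sign-consistent when its score keeps the same
#' nonzero sign across the unperturbed run and all perturbed iterations.
#' The reported score is the unperturbed eigenarray value.
#'
#' @param matrix Complete, sample-scaled genes x samples matrix.
#' @param n_iterations Number of noise perturbations (default 1000).
#' @param noise_mean,noise_sd Gaussian noise parameters.
#' @param seed Integer seed.
#' @param source_tag Provenance label.
#' @return A `recurrent_signature`.
#' @export
robust_signature <- function(matrix, n_iterations = 1000, noise_mean = 0,
                             noise_sd = 1, seed = 1, source_tag = "other") {
  m <- as_value_matrix(matrix, "matrix")
  assert_complete(m, "robust_signature")
  if (n_iterations < 1) abort("`n_iterations` must be >= 1.")
  base <- .first_u(m)
  consistent <- sign(base) != 0
  flip_count <- 0L
  set.seed(seed)
  for (it in seq_len(n_iterations)) {
    pert <- m + matrix(rnorm(length(m), noise_mean, noise_sd), nrow(m))
    u <- svd(pert, nu = 1, nv = 0)$u[, 1]
    if (sum(u * base) < 0) {
      u <- -u
      flip_count <- flip_count + 1L
    }
    consistent <- consistent & (sign(u) == sign(base))
  }
  new_signature(base, consistent, n_iterations = n_iterations,
                noise_sd = noise_sd, source_tag = source_tag,
                flip_count = flip_count)
}

#' Integrate expression datasets on shared genes with batch adjustment
#'
#' Restricts each matrix to the genes present in all datasets,
#' batch-adjusts by per-batch per-gene mean subtraction (a location-only
#' adjustment that removes additive batch offsets), and concatenates the
#' samples. Sample ids are prefixed with their batch label.
#'
#' @param matrices Named list of >= 2 complete genes x samples matrices;
#'   names become batch labels (defaults to batch_1, batch_2, ...).
#' @return Matrix of shared genes x all samples with a `batch` attribute
#'   (character vector, one entry per sample).
#' @export
integrate_datasets <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2) {
    abort("`matrices` must be a list of at least 2 expression matrices.")
  }
  mats <- lapply(matrices, as_value_matrix)
  labs <- names(mats) %||% paste0("batch_", seq_along(mats))
  labs[labs == ""] <- paste0("batch_", which(labs == ""))
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) == 0) abort("No genes shared across all datasets.")
  parts <- vector("list", length(mats))
  batch <- character()
  for (i in seq_along(mats)) {
    sub <- mats[[i]][shared, , drop = FALSE]
    assert_complete(sub, "integrate_datasets")
    sub <- sweep(sub, 1, rowMeans(sub))  # per-batch gene-wise centering
    colnames(sub) <- paste(labs[i], colnames(sub), sep = ".")
    parts[[i]] <- sub
    batch <- c(batch, rep(labs[i], ncol(sub)))
  }
  out <- do.call(cbind, parts)
  attr(out, "batch") <- setNames(batch, colnames(out))
  out
}

#' Integrate two recurrent signatures into one
#'
#' Orients `sig_b` against `sig_a` (flipped when their Spearman
#' correlation over shared genes is negative; an absolute correlation
#' below 0.05 is refused as non-identifiable), keeps the shared
#' sign-consistent genes whose scores agree in sign after orientation,
#' and averages the two scores.
#'
#' @param sig_a,sig_b `recurrent_signature` objects.
#' @return A `recurrent_signature` with `source_tag = "integrated"`
#'   restricted to the agreeing genes.
#' @export
integrate_signatures <- function(sig_a, sig_b) {
  stopifnot(inherits(sig_a, "recurrent_signature"),
            inherits(sig_b, "recurrent_signature"))
  a <- sig_a$score[sig_a$consistent]
  b <- sig_b$score[sig_b$consistent]
  shared <- intersect(names(a), names(b))
  if (length(shared) < 2) abort("Too few shared consistent genes to integrate.")
  rho <- spearman(a[shared], b[shared])
  if (is.na(rho) || abs(rho) < 0.05) {
    abort("Signature orientation is ambiguous (|Spearman rho| < 0.05); cannot integrate.")
  }
  if (rho < 0) b <- -b
  agree <- shared[sign(a[shared]) == sign(b[shared]) & sign(a[shared]) != 0]
  if (length(agree) == 0) abort("No genes agree in sign after orientation.")
  score <- (a[agree] + b[agree]) / 2
  new_signature(score, setNames(rep(TRUE, length(agree)), agree),
                n_iterations = max(sig_a$n_iterations, sig_b$n_iterations),
                noise_sd = max(sig_a$noise_sd, sig_b$noise_sd),
                source_tag = "integrated")
}

#' Split a signature into positive- and negative-scored gene sets
#'
#' PS genes (positive scores) carry the growth program, NS genes
#' (negative scores) the survival/stress program. Only sign-consistent
#' genes are partitioned; zero scores are excluded with a message.
#'
#' @param signature A `recurrent_signature`.
#' @return Named list of two character vectors, `ps` and `ns`.
#' @export
split_ps_ns <- function(signature) {
  stopifnot(inherits(signature, "recurrent_signature"))
  sc <- signature$score[signature$consistent]
  zero <- sum(sc == 0)
  if (zero > 0) inform(sprintf("split_ps_ns: %d zero-scored gene(s) excluded.", zero))
  ps <- sort(names(sc)[sc > 0])
  ns <- sort(names(sc)[sc < 0])
  if (length(ps) == 0 || length(ns) == 0) {
    abort("One of the PS/NS sets is empty; the signature has a single-signed score vector.")
  }
  list(ps = ps, ns = ns)
}

#' Spearman comparison of two signatures over shared genes
#'
#' @param sig_a,sig_b `recurrent_signature` objects (or named numeric
#'   score vectors) with at least 10 shared genes.
#' @return One-row tibble: rho, p_value, n_genes.
#' @export
compare_signatures <- function(sig_a, sig_b) {
  a <- if (inherits(sig_a, "recurrent_signature")) sig_a$score else as_named_numeric(sig_a, "sig_a")
  b <- if (inherits(sig_b, "recurrent_signature")) sig_b$score else as_named_numeric(sig_b, "sig_b")
  shared <- intersect(names(a), names(b))
  if (length(shared) < 10) abort("Need at least 10 shared genes.")
  st <- spearman_test(a[shared], b[shared])
  tibble(rho = st$rho, p_value = st$p, n_genes = length(shared))
}

#' Signature-score distributions over predefined gene sets
#'
#' Returns each set's score distribution within the signature plus
#' two-sided Wilcoxon rank-sum tests for every set pair, with
#' Benjamini-Hochberg adjusted p-values alongside the raw ones. Sets with
#' no gene in the signature are skipped with a warning.
#'
#' @param signature A `recurrent_signature`.
#' @param gene_sets Named list of character vectors (e.g. ESR, UGRR,
#'   metabolic-cycle sets).
#' @return List with `scores` (tibble: set, gene, score) and `tests`
#'   (tibble: set_a, set_b, statistic, p_value, p_adj).
#' @export
gene_set_score_distribution <- function(signature, gene_sets) {
  stopifnot(inherits(signature, "recurrent_signature"))
  if (is.null(names(gene_sets))) abort("`gene_sets` must be a named list.")
  sc <- signature$score
  kept <- list()
  for (nm in names(gene_sets)) {
    members <- intersect(gene_sets[[nm]], names(sc))
    if (length(members) == 0) {
      warn(sprintf("Gene set '%s' shares no genes with the signature; skipped.", nm))
      next
    }
    kept[[nm]] <- tibble(set = nm, gene = members, score = unname(sc[members]))
  }
  if (length(kept) == 0) abort("No gene set intersects the signature.")
  scores <- bind_rows(kept)
  sets <- names(kept)
  tests <- NULL
  if (length(sets) >= 2) {
    pairs <- utils::combn(sets, 2)
    tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      x <- kept[[pairs[1, i]]]$score
      y <- kept[[pairs[2, i]]]$score
      wt <- suppressWarnings(wilcox.test(x, y))
      tibble(set_a = pairs[1, i], set_b = pairs[2, i],
             statistic = unname(wt$statistic), p_value = wt$p.value)
    })
    tests$p_adj <- p.adjust(tests$p_value, method = "BH")
  }
  list(scores = scores, tests = tests)
}

#' Correlate signature scores with a per-gene measurement
#'
#' Spearman correlation between the gene signature scores and any
#' external gene-level measurement (haploid KO fitness, expression noise,
#' mRNA half-life, abundance variability, ...) over the gene
#' intersection; missing measurements are dropped.
#'
#' @param signature A `recurrent_signature`.
#' @param measurement Named numeric vector or two-column data frame
#'   (gene, value); >= 10 genes must overlap.
#' @return One-row tibble: rho, p_value, n_genes.
#' @export
correlate_signature_with_measurement <- function(signature, measurement) {
  stopifnot(inherits(signature, "recurrent_signature"))
  mv <- as_named_numeric(measurement, "measurement")
  mv <- mv[!is.na(mv)]
  shared <- intersect(names(signature$score), names(mv))
  if (length(shared) < 10) abort("Fewer than 10 genes overlap the measurement.")
  st <- spearman_test(signature$score[shared], mv[shared])
  tibble(rho = st$rho, p_value = st$p, n_genes = length(shared))
}

#' Per-gene log2 fold change between two sample groups
#'
#' For each gene of `gene_set` present in the matrix, computes
#' `log2(mean(g1) / mean(g2))` on linear-scale data, or the difference of
#' group means when `pre_logged = TRUE`.
#'
#' @param matrix Complete genes x samples matrix on a positive linear
#'   scale (unless `pre_logged`).
#' @param group_labels Named vector (or two-column data frame) mapping
#'   each sample to one of exactly two groups; the first group sorted
#'   alphabetically is the numerator.
#' @param gene_set Character vector of genes (default: all genes).
#' @param pre_logged Set `TRUE` for already-logged data.
#' @return Tibble: gene, log2fc.
#' @export
group_log2fc <- function(matrix, group_labels, gene_set = NULL, pre_logged = FALSE) {
  m <- as_value_matrix(matrix, "matrix")
  assert_complete(m, "group_log2fc")
  gl <- if (is.data.frame(group_labels)) {
    setNames(as.character(group_labels[[2]]), as.character(group_labels[[1]]))
  } else setNames(as.character(group_labels), names(group_labels) %||% colnames(m))
  gl <- gl[intersect(colnames(m), names(gl))]
  groups <- sort(unique(gl))
  if (length(groups) != 2) abort("`group_labels` must define exactly 2 groups over the samples.")
  g1 <- names(gl)[gl == groups[1]]
  g2 <- names(gl)[gl == groups[2]]
  if (length(g1) == 0 || length(g2) == 0) abort("Both groups must be nonempty.")
  genes <- if (is.null(gene_set)) rownames(m) else intersect(gene_set, rownames(m))
  if (length(genes) == 0) abort("`gene_set` shares no genes with the matrix.")
  m1 <- rowMeans(m[genes, g1, drop = FALSE])
  m2 <- rowMeans(m[genes, g2, drop = FALSE])
  if (pre_logged) {
    fc <- m1 - m2
  } else {
    if (any(m1 <= 0) || any(m2 <= 0)) {
      abort("Non-positive group mean on linear scale; use `pre_logged = TRUE` for logged data.")
    }
    fc <- log2(m1 / m2)
  }
  tibble(gene = genes, log2fc = unname(fc))
}
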