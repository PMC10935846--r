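# Phenome preprocessing, low-rank reconstruction and clustering.

#' Drop rows and columns with too many missing values
#'
#' Applies the 10% missingness rule: any row whose missing fraction
#' exceeds `max_missing_frac` is removed, then any column, and the two
#' passes repeat until a fixed point (removing a row can rescue a column
#' and vice versa, so iteration makes the result order-insensitive).
#'
#' @param matrix Strains x conditions (or genes x samples) numeric matrix
#'   or data frame; `NA` marks missing cells.
#' @param max_missing_frac Maximum tolerated missing fraction per row or
#'   column (default 0.1).
#' @return The filtered matrix, original dimnames preserved.
#' @export
filter_missing <- function(matrix, max_missing_frac = 0.1) {
  m <- as_value_matrix(matrix, "matrix")
  if (length(m) == 0) abort("`matrix` is empty.")
  repeat {
    if (nrow(m) == 0 || ncol(m) == 0) {
      abort("filter_missing removed every row or column; matrix too sparse.")
    }
    bad_rows <- rowMeans(is.na(m)) > max_missing_frac
    if (any(bad_rows)) m <- m[!bad_rows, , drop = FALSE]
    if (nrow(m) == 0) abort("filter_missing removed every row; matrix too sparse.")
    bad_cols <- colMeans(is.na(m)) > max_missing_frac
    if (any(bad_cols)) m <- m[, !bad_cols, drop = FALSE]
    if (ncol(m) == 0) abort("filter_missing removed every column; matrix too sparse.")
    if (!any(bad_rows) && !any(bad_cols)) break
  }
  m
}

#' Impute missing cells by k-nearest-neighbour row averaging
#'
#' Each missing cell is replaced by the average of that column's observed
#' values over the `k` rows nearest to the target row. Row-row distance is
#' root-mean-square difference over mutually observed columns (i.e.
#' Euclidean distance rescaled by the number of shared columns); rows
#' sharing no observed column are excluded as neighbours. A cell with
#' fewer than `k` usable neighbours falls back to the column mean with a
#' warning. Observed values are never altered.
#'
#' @param matrix Numeric matrix/data frame with `NA` for missing cells;
#'   every row and column must retain at least one observed value.
#' @param k Number of neighbours (default 10).
#' @return Complete matrix of the same shape.
#' @export
impute_knn <- function(matrix, k = 10) {
  m <- as_value_matrix(matrix, "matrix")
  if (!anyNA(m)) return(m)
  if (any(rowSums(!is.na(m)) == 0) || any(colSums(!is.na(m)) == 0)) {
    abort("Every row and column must have at least one observed value; run filter_missing() first.")
  }
  obs <- !is.na(m)
  out <- m
  fallback <- FALSE
  for (i in which(rowSums(!obs) > 0)) {
    shared <- obs & matrix(obs[i, ], nrow(m), ncol(m), byrow = TRUE)
    n_shared <- rowSums(shared)
    d <- rep(NA_real_, nrow(m))
    for (j in seq_len(nrow(m))) {
      if (j == i || n_shared[j] == 0) next
      idx <- shared[j, ]
      d[j] <- sqrt(mean((m[i, idx] - m[j, idx])^2))
    }
    for (cc in which(!obs[i, ])) {
      cand <- which(obs[, cc] & !is.na(d))
      if (length(cand) < k) {
        out[i, cc] <- mean(m[, cc], na.rm = TRUE)
        fallback <- TRUE
      } else {
        nn <- cand[order(d[cand])][seq_len(k)]
        out[i, cc] <- mean(m[nn, cc])
      }
    }
  }
  if (fallback) {
    warn("impute_knn: some cells had fewer than `k` usable neighbours; column means used there.")
  }
  out
}

#' Standardize each condition column to mean 0, variance 1
#'
#' Sample-wise normalization of the growth phenome: every condition
#' column is centred and scaled to unit sample variance (n-1 denominator).
#'
#' @param matrix Complete numeric matrix (strains x conditions).
#' @return Standardized matrix.
#' @export
standardize_conditions <- function(matrix) {
  m <- as_value_matrix(matrix, "matrix")
  assert_complete(m, "standardize_conditions")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("Zero-variance condition(s): %s",
                  paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Rank-r reconstruction of a phenome matrix by truncated SVD
#'
#' Decomposes `M = U S V^T` and returns `sum_{k<=rank} S_k U_k V_k^T`,
#' discarding condition-specific minor components. Default rank 2 keeps
#' the overall-growth and trade-off axes. Singular vectors are
#' sign-oriented so the largest-magnitude entry of each right-singular
#' vector is positive, making the stored factors reproducible.
#'
#' @param matrix Complete numeric matrix.
#' @param rank Number of leading singular triplets kept.
#' @return Class `lowrank_phenome`: list with `values` (reconstruction),
#'   `rank_used`, oriented factors `u`, `d`, `v`, and `frob_error` (the
#'   root-sum-square of discarded singular values).
#' @export
svd_reconstruct <- function(matrix, rank = 2) {
  m <- as_value_matrix(matrix, "matrix")
  assert_complete(m, "svd_reconstruct")
  if (rank < 1 || rank > min(dim(m))) abort("`rank` must be in 1..min(dim).")
  s <- svd(m)
  for (j in seq_along(s$d)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  keep <- seq_len(rank)
  rec <- s$u[, keep, drop = FALSE] %*% diag(s$d[keep], rank) %*% t(s$v[, keep, drop = FALSE])
  dimnames(rec) <- dimnames(m)
  structure(list(
    values = rec,
    rank_used = rank,
    u = s$u, d = s$d, v = s$v,
    frob_error = sqrt(sum(s$d[-keep]^2))
  ), class = "lowrank_phenome")
}

#' Condition-condition Spearman correlation matrix
#'
#' @param matrix Complete numeric matrix with at least 3 strains (rows).
#' @return Symmetric correlation matrix with unit diagonal; ties handled
#'   by midranks.
#' @export
condition_correlation <- function(matrix) {
  m <- as_value_matrix(matrix, "matrix")
  assert_complete(m, "condition_correlation")
  if (nrow(m) < 3) abort("Need at least 3 strains for rank correlations.")
  cor(m, method = "spearman")
}

#' Average-linkage hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering (average linkage by default) cut at `K`
#' clusters. The canonical distance upstream is `1 - Spearman` from
#' [condition_correlation()].
#'
#' @param distance_matrix Symmetric matrix with zero diagonal, or a
#'   `dist` object.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param K Number of clusters.
#' @return Class `cluster_assignment`: tibble (item, cluster) with
#'   attributes `K`, `linkage_method` and the `hclust` tree.
#' @export
hcluster <- function(distance_matrix, linkage = "average", K = 2) {
  if (inherits(distance_matrix, "dist")) {
    d <- distance_matrix
    items <- attr(d, "Labels") %||% paste0("item_", seq_len(attr(d, "Size")))
  } else {
    dm <- as.matrix(distance_matrix)
    if (is.null(colnames(dm))) colnames(dm) <- rownames(dm) <- paste0("item_", seq_len(ncol(dm)))
    if (max(abs(dm - t(dm))) > 1e-8 || any(abs(diag(dm)) > 1e-8)) {
      abort("`distance_matrix` must be symmetric with zero diagonal.")
    }
    d <- as.dist(dm)
    items <- colnames(dm)
  }
  n <- attr(d, "Size")
  if (K > n) abort("`K` cannot exceed the number of items.")
  tree <- hclust(d, method = linkage)
  cl <- cutree(tree, k = K)
  structure(
    tibble(item = items, cluster = unname(cl)),
    K = K, linkage_method = linkage, tree = tree,
    class = c("cluster_assignment", class(tibble()))
  )
}

#' Chi-squared test of cluster composition against strain labels
#'
#' Pearson chi-squared (no continuity correction) on the cluster x label
#' contingency table, e.g. growth-cluster membership vs wild/domesticated
#' clade.
#'
#' @param strain_clusters Vector of cluster ids (or a
#'   `cluster_assignment`).
#' @param clade_labels Vector of class labels, same length/order.
#' @return One-row tibble: statistic, df, p_value, n.
#' @export
cluster_composition_test <- function(strain_clusters, clade_labels) {
  if (inherits(strain_clusters, "cluster_assignment")) {
    strain_clusters <- strain_clusters$cluster
  }
  if (is.data.frame(clade_labels)) clade_labels <- clade_labels[[ncol(clade_labels)]]
  tab <- table(cluster = strain_clusters, clade = clade_labels)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("Need at least 2 clusters and 2 label classes.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Empty cluster or label class after tabulation.")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, n = sum(tab))
}
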