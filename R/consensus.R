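# Consensus clustering over resampled hierarchical clusterings, and the
# proportion of ambiguous clustering (PAC) used to pick K.

#' Consensus clustering of conditions with resampling
#'
#' Repeatedly subsamples strains (features) and conditions (items)
#' without replacement, clusters the sampled conditions by average-linkage
#' hierarchical clustering on `1 - Spearman` distance, and records, for
#' every condition pair, how often it was co-clustered among the
#' iterations in which both conditions were sampled. The consensus index
#' of a pair is co-clustered count / co-sampled count: 1 for pairs that
#' cluster together whenever seen, 0 for pairs that never do. Pairs never
#' co-sampled (vanishingly rare at the defaults) get index 0 with a
#' message.
#'
#' @param matrix Complete strains x conditions matrix (raw or the rank-2
#'   reconstruction; both are valid entry points and the choice is
#'   recorded in the result).
#' @param K_range Integer vector of cluster numbers to scan (min >= 2).
#' @param n_iterations Resampling iterations (default 1000).
#' @param resample_fraction Fraction of conditions and of strains drawn
#'   each iteration (default 0.8), in (0, 1].
#' @param seed Integer seed.
#' @param linkage Agglomeration method (default "average").
#' @return Class `consensus_result`: list with `consensus` (named list of
#'   condition x condition matrices, one per K, symmetric with unit
#'   diagonal), `pac` (tibble: K, pac), `n_iterations`,
#'   `resample_fraction`, `seed`.
#' @export
consensus_cluster <- function(matrix, K_range = 2:6, n_iterations = 1000,
                              resample_fraction = 0.8, seed = 1,
                              linkage = "average") {
  m <- as_value_matrix(matrix, "matrix")
  assert_complete(m, "consensus_cluster")
  K_range <- sort(unique(as.integer(K_range)))
  if (min(K_range) < 2) abort("min(K_range) must be >= 2.")
  if (resample_fraction <= 0 || resample_fraction > 1) {
    abort("`resample_fraction` must be in (0, 1].")
  }
  n_cond <- ncol(m)
  n_strain <- nrow(m)
  if (max(K_range) > floor(resample_fraction * n_cond)) {
    abort("Largest K exceeds the number of sampled conditions per iteration.")
  }
  n_cs <- floor(resample_fraction * n_cond)
  n_ss <- floor(resample_fraction * n_strain)
  if (n_ss < 3) abort("Too few strains sampled per iteration for rank correlations.")

  conds <- colnames(m)
  co_sampled <- matrix(0, n_cond, n_cond, dimnames = list(conds, conds))
  co_clustered <- lapply(K_range, function(K) co_sampled)
  names(co_clustered) <- as.character(K_range)

  set.seed(seed)
  for (it in seq_len(n_iterations)) {
    cs <- sort(sample.int(n_cond, n_cs))
    ss <- sample.int(n_strain, n_ss)
    sub <- m[ss, cs, drop = FALSE]
    d <- 1 - suppressWarnings(cor(sub, method = "spearman"))
    tree <- hclust(as.dist(d), method = linkage)
    co_sampled[cs, cs] <- co_sampled[cs, cs] + 1
    for (K in K_range) {
      cl <- cutree(tree, k = K)
      same <- outer(cl, cl, "==")
      key <- as.character(K)
      co_clustered[[key]][cs, cs] <- co_clustered[[key]][cs, cs] + same
    }
  }

  never <- co_sampled == 0
  diag(never) <- FALSE
  if (any(never)) {
    inform(sprintf("consensus_cluster: %d condition pair(s) were never co-sampled; their index is set to 0.",
                   sum(never) / 2))
  }
  denom <- co_sampled
  denom[denom == 0] <- 1  # guarded pairs get 0/1 = 0
  consensus <- lapply(co_clustered, function(cc) {
    cm <- cc / denom
    diag(cm) <- 1
    cm
  })

  pac_tbl <- tibble(
    K = K_range,
    pac = vapply(consensus, pac, numeric(1))
  )
  structure(list(
    consensus = consensus,
    pac = pac_tbl,
    n_iterations = n_iterations,
    resample_fraction = resample_fraction,
    seed = seed,
    linkage = linkage
  ), class = "consensus_result")
}

#' Proportion of ambiguous clustering (PAC)
#'
#' The fraction of off-diagonal unordered condition pairs whose consensus
#' index lies strictly inside the ambiguity window `(lower, upper)`.
#' Lower PAC indicates a more robust cluster number.
#'
#' @param consensus_matrix Square matrix of consensus indices in `[0, 1]`.
#' @param lower,upper Ambiguity window bounds (default 0.1 and 0.9;
#'   strict inequalities).
#' @return PAC value in `[0, 1]`.
#' @export
pac <- function(consensus_matrix, lower = 0.1, upper = 0.9) {
  cm <- as.matrix(consensus_matrix)
  if (lower >= upper) abort("`lower` must be < `upper`.")
  if (any(cm < 0 | cm > 1)) abort("Consensus indices must lie in [0, 1].")
  x <- cm[upper.tri(cm)]
  if (length(x) == 0) abort("Consensus matrix has no off-diagonal pairs.")
  mean(x > lower & x < upper)
}

#' Pick the optimal K from a consensus result by minimum PAC
#'
#' @param result A `consensus_result`.
#' @param exclude_singletons If `TRUE`, K values whose full-data
#'   assignment contains a singleton cluster are excluded before taking
#'   the minimum (default `FALSE`). Requires the consensus matrices.
#' @return Integer vector of optimal K (length > 1 reports a PAC tie).
#' @export
optimal_k <- function(result, exclude_singletons = FALSE) {
  stopifnot(inherits(result, "consensus_result"))
  tbl <- result$pac
  if (exclude_singletons) {
    keep <- vapply(tbl$K, function(K) {
      cm <- result$consensus[[as.character(K)]]
      cl <- hcluster(1 - cm, linkage = result$linkage, K = K)
      all(table(cl$cluster) > 1)
    }, logical(1))
    if (any(keep)) tbl <- tbl[keep, ]
  }
  tbl$K[tbl$pac == min(tbl$pac)]
}
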