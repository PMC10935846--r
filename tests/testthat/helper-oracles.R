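# Independent brute-force oracles used to check the implementations.

# Largest connected component by breadth-first search over an edge list
# restricted to a node set (nodes absent from all edges are isolated).
lcc_oracle <- function(edges_a, edges_b, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edges_a)) {
    a <- edges_a[i]; b <- edges_b[i]
    if (a %in% nodes && b %in% nodes) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  best <- 0L
  for (start in nodes) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    best <- max(best, size)
  }
  best
}

# Average-linkage agglomeration by exhaustive pairwise-average updates;
# returns cluster memberships at K clusters.
average_linkage_oracle <- function(dm, K) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  d <- dm
  while (length(clusters) > K) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- mean(dm[clusters[[i]], clusters[[j]]])
      if (dij < best[1]) best <- c(dij, i, j)
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  out <- integer(n)
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k
  out
}

# Spearman correlation as rank-then-Pearson with midranks.
spearman_oracle <- function(x, y) {
  cor(rank(x), rank(y), method = "pearson")
}

# Exhaustive application of the 10% row/column filtering rule to a fixed
# point, rows first.
filter_oracle <- function(m, frac = 0.1) {
  repeat {
    changed <- FALSE
    br <- rowMeans(is.na(m)) > frac
    if (any(br)) { m <- m[!br, , drop = FALSE]; changed <- TRUE }
    bc <- colMeans(is.na(m)) > frac
    if (any(bc)) { m <- m[, !bc, drop = FALSE]; changed <- TRUE }
    if (!changed) break
  }
  m
}

# Same-partition check up to label permutation.
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

truth_vector <- function(planted_expr) {
  setNames(planted_expr$true_signature$score, planted_expr$true_signature$gene)
}
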