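# Locus-to-gene p-value mapping, cross-condition aggregation, and the
# largest-connected-component (LCC) permutation test on a
# confidence-weighted functional gene network.

# Normalize an edge input (tibble/data.frame gene_a, gene_b, confidence,
# or planted_network, or igraph) to a clean undirected simple edge tibble
# plus the node universe.
normalize_network <- function(network) {
  if (inherits(network, "planted_network")) {
    edges <- network$edges
    nodes <- network$all_genes %||% union(edges$gene_a, edges$gene_b)
  } else if (inherits(network, "igraph")) {
    el <- igraph::as_data_frame(network, what = "edges")
    conf <- el$confidence %||% el$weight %||% rep(1, nrow(el))
    edges <- tibble(gene_a = el$from, gene_b = el$to, confidence = conf)
    nodes <- igraph::V(network)$name
  } else {
    df <- as.data.frame(network)
    if (ncol(df) < 3) abort("`network` needs columns gene_a, gene_b, confidence.")
    edges <- tibble(gene_a = as.character(df[[1]]), gene_b = as.character(df[[2]]),
                    confidence = as.numeric(df[[3]]))
    nodes <- union(edges$gene_a, edges$gene_b)
  }
  if (nrow(edges)) {
    if (any(edges$confidence < 0 | edges$confidence > 1)) {
      abort("Edge confidences must lie in [0, 1].")
    }
    loops <- edges$gene_a == edges$gene_b
    if (any(loops)) {
      inform(sprintf("Dropping %d self-loop(s).", sum(loops)))
      edges <- edges[!loops, ]
    }
    key <- paste(pmin(edges$gene_a, edges$gene_b), pmax(edges$gene_a, edges$gene_b))
    if (anyDuplicated(key)) {
      inform(sprintf("Collapsing %d duplicate edge(s), keeping the maximum confidence.",
                     sum(duplicated(key))))
      o <- order(key, -edges$confidence)
      edges <- edges[o, ][!duplicated(key[o]), ]
    }
  }
  list(edges = edges, nodes = nodes)
}

# igraph over the full node universe, keeping only edges with confidence
# strictly above the threshold (nodes with no surviving edge stay as
# isolated vertices).
threshold_graph <- function(net, min_confidence) {
  e <- net$edges[net$edges$confidence > min_confidence, , drop = FALSE]
  igraph::graph_from_data_frame(e[, c("gene_a", "gene_b")], directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Gene-level p-values from locus-level association p-values
#'
#' Assigns each gene the minimum p-value over the association loci whose
#' interval overlaps the gene body by at least 1 bp. Coordinates are
#' 1-based inclusive (overlap when `max(starts) <= min(ends)`); BED-style
#' 0-based half-open input is converted at parse time via
#' `coords = "bed"`. Genes intersected by no locus are omitted.
#'
#' @param locus_pvalues Data frame: chrom, start, end, p.
#' @param gene_intervals Data frame: gene, chrom, start, end.
#' @param coords `"one_based"` (default) or `"bed"`.
#' @return Tibble: gene, p.
#' @export
gene_pvalue_from_loci <- function(locus_pvalues, gene_intervals,
                                  coords = c("one_based", "bed")) {
  coords <- match.arg(coords)
  loci <- as.data.frame(locus_pvalues)
  genes <- as.data.frame(gene_intervals)
  names(loci)[1:4] <- c("chrom", "start", "end", "p")
  names(genes)[1:4] <- c("gene", "chrom", "start", "end")
  if (coords == "bed") {
    loci$start <- loci$start + 1L
    genes$start <- genes$start + 1L
  }
  if (any(loci$start > loci$end) || any(genes$start > genes$end)) {
    abort("Malformed interval: start > end.")
  }
  out <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    l <- loci[loci$chrom == ch, ]
    if (nrow(l) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = g$start, end = g$end),
      IRanges::IRanges(start = l$start, end = l$end)
    )
    if (length(hits) == 0) next
    hp <- tibble(gene = g$gene[S4Vectors::queryHits(hits)],
                 p = l$p[S4Vectors::subjectHits(hits)])
    out[[ch]] <- summarise(group_by(hp, .data$gene), p = min(.data$p), .groups = "drop")
  }
  if (length(out) == 0) return(tibble(gene = character(), p = numeric()))
  arrange(bind_rows(out), .data$gene)
}

#' Aggregate per-condition gene p-values
#'
#' Combines each gene's association p-values across condition sets (e.g.
#' the six GWA analyses over clades and condition families). The default
#' is Fisher's method, `-2 * sum(ln p)` against chi-squared with `2k`
#' degrees of freedom over the `k` conditions where the gene is scored;
#' `method = "min"` takes the minimum p instead. Zero p-values are
#' clamped to the smallest positive double with a warning.
#'
#' @param per_condition List of per-condition gene p-value tables
#'   (tibbles gene/p, or named numeric vectors).
#' @param method `"fisher"` (default) or `"min"`.
#' @return Tibble: gene, p, n_conditions — sorted by p.
#' @export
aggregate_pvalues <- function(per_condition, method = c("fisher", "min")) {
  method <- match.arg(method)
  if (!is.list(per_condition) || length(per_condition) == 0) {
    abort("`per_condition` must be a nonempty list of gene p-value tables.")
  }
  vecs <- lapply(per_condition, as_named_numeric, arg = "per_condition")
  long <- bind_rows(lapply(vecs, function(v) tibble(gene = names(v), p = unname(v))))
  if (any(long$p < 0 | long$p > 1)) abort("p-values must lie in (0, 1].")
  if (any(long$p == 0)) {
    warn("Zero p-values clamped to the smallest positive double.")
    long$p[long$p == 0] <- .Machine$double.xmin
  }
  agg <- if (method == "fisher") {
    summarise(group_by(long, .data$gene),
              p = pchisq(-2 * sum(log(.data$p)), df = 2 * dplyr::n(), lower.tail = FALSE),
              n_conditions = dplyr::n(), .groups = "drop")
  } else {
    summarise(group_by(long, .data$gene),
              p = min(.data$p), n_conditions = dplyr::n(), .groups = "drop")
  }
  arrange(agg, .data$p, .data$gene)
}

#' Top-ranked genes by aggregated p-value
#'
#' @param aggregated Tibble gene/p (output of [aggregate_pvalues()]) or
#'   named numeric vector.
#' @param k Number of genes (default 50).
#' @return Tibble: rank, gene, p. Ties are broken lexicographically by
#'   gene id; a tie spanning the rank-k boundary is reported via a
#'   message.
#' @export
top_genes <- function(aggregated, k = 50) {
  if (k <= 0) abort("`k` must be positive.")
  v <- as_named_numeric(aggregated, "aggregated")
  if (k > length(v)) abort("`k` exceeds the number of scored genes.")
  o <- order(v, names(v))
  v <- v[o]
  if (k < length(v) && v[k] == v[k + 1]) {
    inform(sprintf("top_genes: tie at the rank-%d boundary (p = %g); lexicographic inclusion.",
                   k, v[k]))
  }
  tibble(rank = seq_len(k), gene = names(v)[seq_len(k)], p = unname(v[seq_len(k)]))
}

#' Largest connected component of a gene set on the thresholded network
#'
#' Induces the subgraph of `gene_set` on the edges with confidence
#' strictly greater than `min_confidence` (0.4 = medium confidence) and
#' returns the node count of its largest connected component. Genes
#' absent from the network count as isolated nodes, so the result is at
#' least 1 for a nonempty set.
#'
#' @param network Edge table (gene_a, gene_b, confidence),
#'   `planted_network`, or igraph.
#' @param gene_set Character vector of gene ids.
#' @param min_confidence Strict lower bound on edge confidence.
#' @return Integer LCC size.
#' @export
lcc_size <- function(network, gene_set, min_confidence = 0.4) {
  if (length(gene_set) == 0) abort("`gene_set` is empty.")
  gene_set <- unique(as.character(gene_set))
  net <- normalize_network(network)
  e <- net$edges
  e <- e[e$confidence > min_confidence &
           e$gene_a %in% gene_set & e$gene_b %in% gene_set, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("gene_a", "gene_b")], directed = FALSE,
                                     vertices = data.frame(name = gene_set))
  as.integer(max(igraph::components(g)$csize))
}

#' LCC permutation null test for a gene selection
#'
#' Compares an observed LCC size against the null distribution obtained
#' by drawing the same number of genes uniformly without replacement from
#' the network's node universe `n_iterations` times. The empirical
#' p-value uses the add-one permutation estimator
#' `(1 + #{null >= observed}) / (n_iterations + 1)` and is never 0.
#'
#' @param network Edge table, `planted_network`, or igraph.
#' @param n_genes Number of genes drawn per null iteration.
#' @param observed_size Observed LCC size (e.g. from [lcc_size()]).
#' @param n_iterations Null samples (default 1000).
#' @param min_confidence Strict edge-confidence threshold.
#' @param seed Integer seed.
#' @return Class `lcc_test`: list with `observed_lcc_size`, `null_mean`,
#'   `null_sd`, `empirical_p`, `n_iterations`, `n_genes_selected`,
#'   `null_sizes`.
#' @export
lcc_null_test <- function(network, n_genes, observed_size, n_iterations = 1000,
                          min_confidence = 0.4, seed = 1) {
  if (n_iterations < 1) abort("`n_iterations` must be >= 1.")
  net <- normalize_network(network)
  if (n_genes > length(net$nodes)) abort("`n_genes` exceeds the network node count.")
  g <- threshold_graph(net, min_confidence)
  set.seed(seed)
  sizes <- vapply(seq_len(n_iterations), function(i) {
    vs <- sample(net$nodes, n_genes)
    max(igraph::components(igraph::induced_subgraph(g, vs))$csize)
  }, numeric(1))
  structure(list(
    observed_lcc_size = as.integer(observed_size),
    null_mean = mean(sizes),
    null_sd = sd(sizes),
    empirical_p = (1 + sum(sizes >= observed_size)) / (n_iterations + 1),
    n_iterations = n_iterations,
    n_genes_selected = n_genes,
    null_sizes = sizes
  ), class = "lcc_test")
}

#' Observed vs null LCC size along a gene ranking
#'
#' For each k in `k_grid`, computes the LCC size of the top-k ranked
#' genes and the matching resampling null (drawn independently per k).
#'
#' @param network Edge table, `planted_network`, or igraph.
#' @param ranked_genes Character vector in rank order (or the tibble from
#'   [top_genes()]).
#' @param k_grid Integer vector of ranking depths.
#' @param n_iterations Null samples per k.
#' @param min_confidence Strict edge-confidence threshold.
#' @param seed Integer seed (per-k seeds derived deterministically).
#' @return Class `lcc_curve`: tibble with k, observed_lcc, null_mean,
#'   null_sd, empirical_p.
#' @export
lcc_size_curve <- function(network, ranked_genes, k_grid, n_iterations = 1000,
                           min_confidence = 0.4, seed = 1) {
  if (length(k_grid) == 0) abort("`k_grid` is empty.")
  if (is.data.frame(ranked_genes)) ranked_genes <- ranked_genes$gene
  ranked_genes <- as.character(ranked_genes)
  if (max(k_grid) > length(ranked_genes)) abort("`k_grid` exceeds the ranking length.")
  rows <- lapply(sort(unique(as.integer(k_grid))), function(k) {
    obs <- lcc_size(network, ranked_genes[seq_len(k)], min_confidence)
    nt <- lcc_null_test(network, k, obs, n_iterations, min_confidence,
                        seed = derive_seed(seed, paste0("lcc_k", k)))
    tibble(k = k, observed_lcc = obs, null_mean = nt$null_mean,
           null_sd = nt$null_sd, empirical_p = nt$empirical_p)
  })
  structure(bind_rows(rows), class = c("lcc_curve", class(tibble())))
}
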