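# Locus-to-gene p-values, aggregation, and the LCC permutation null.

test_that("gene_pvalue_from_loci takes the minimum p over 1-based inclusive overlaps", {
  genes <- tibble::tibble(gene = c("gA", "gB"), chrom = "chr1",
                          start = c(101, 301), end = c(200, 400))
  loci <- tibble::tibble(chrom = "chr1", start = c(50, 150, 90),
                         end = c(150, 250, 100), p = c(0.5, 0.001, 0.2))
  res <- gene_pvalue_from_loci(loci, genes)
  expect_equal(res$p[res$gene == "gA"], 0.001)  # min over two intersecting loci
  expect_false("gB" %in% res$gene)              # no intersecting locus -> omitted

  # locus ending exactly one base before the gene start does not assign
  edge <- tibble::tibble(chrom = "chr1", start = 1, end = 100, p = 0.01)
  expect_false("gA" %in% gene_pvalue_from_loci(edge, genes)$gene)
  touch <- tibble::tibble(chrom = "chr1", start = 1, end = 101, p = 0.01)
  expect_equal(gene_pvalue_from_loci(touch, genes)$p, 0.01)

  # BED dialect converts at parse time: 0-based half-open [100, 101) is base 101
  bed <- tibble::tibble(chrom = "chr1", start = 100, end = 101, p = 0.02)
  genes_bed <- tibble::tibble(gene = "gA", chrom = "chr1", start = 100, end = 200)
  expect_equal(gene_pvalue_from_loci(bed, genes_bed, coords = "bed")$p, 0.02)

  expect_error(gene_pvalue_from_loci(
    tibble::tibble(chrom = "chr1", start = 10, end = 5, p = 0.1), genes), "Malformed")
})

test_that("aggregate_pvalues implements Fisher's method with a min alternative", {
  one <- list(cond1 = c(gA = 0.3))
  expect_equal(aggregate_pvalues(one)$p, 0.3, tolerance = 1e-12)

  two <- list(c(gA = 0.5), c(gA = 0.5))
  expect_equal(aggregate_pvalues(two)$p,
               pchisq(-2 * (log(0.5) + log(0.5)), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(aggregate_pvalues(two)$p, 0.5966, tolerance = 1e-4)

  expect_equal(aggregate_pvalues(list(c(gA = 0.5), c(gA = 0.01)), method = "min")$p, 0.01)

  # permutation-invariant across condition order
  conds <- list(c(gA = 0.2, gB = 0.7), c(gA = 0.05, gB = 0.9), c(gA = 0.8))
  expect_equal(aggregate_pvalues(conds), aggregate_pvalues(rev(conds)))

  expect_warning(res <- aggregate_pvalues(list(c(gA = 0))), "clamped")
  expect_gt(res$p, 0)
})

test_that("top_genes ranks by p with lexicographic ties", {
  v <- c(g5 = 0.01, g1 = 0.05, g3 = 0.05, g2 = 0.05, g4 = 0.9)
  tg <- suppressMessages(top_genes(v, k = 2))
  expect_identical(tg$gene, c("g5", "g1"))
  expect_message(top_genes(v, k = 2), "tie")
  expect_identical(top_genes(v, k = 5)$gene, c("g5", "g1", "g2", "g3", "g4"))
  expect_error(top_genes(v, k = 0), "positive")
  expect_error(top_genes(v, k = 9), "exceeds")
})

test_that("lcc_size matches the brute-force oracle, including the strict 0.4 boundary", {
  # path a-b-c plus isolated d; edge b-c at exactly 0.4 is excluded
  edges <- tibble::tibble(gene_a = c("a", "b"), gene_b = c("b", "c"),
                          confidence = c(0.9, 0.4))
  expect_identical(lcc_size(edges, c("a", "b", "c", "d")), 2L)
  expect_identical(lcc_size(edges, c("a", "b", "c"), min_confidence = 0.39), 3L)

  # no internal edges -> singleton LCC; absent genes count as isolated
  expect_identical(lcc_size(edges, c("x", "y", "z")), 1L)
  expect_error(lcc_size(edges, character()), "empty")

  # exhaustive check on random graphs with <= 12 nodes
  set.seed(23)
  for (i in 1:30) {
    n <- sample(2:12, 1)
    nodes <- paste0("n", seq_len(n))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.25
    conf <- runif(nrow(pairs))
    edges_i <- tibble::tibble(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                              confidence = conf[keep])
    sub <- sample(nodes, sample(seq_len(n), 1))
    strong <- edges_i[edges_i$confidence > 0.4, ]
    expect_identical(lcc_size(edges_i, sub),
                     as.integer(lcc_oracle(strong$gene_a, strong$gene_b, sub)))
  }

  # raising the threshold never increases the LCC
  nw <- gen_network(100, 8, 0.05, background_confidence = 0.6, seed = 24)
  gs <- sample(nw$all_genes, 30)
  sizes <- sapply(c(0.1, 0.4, 0.7, 0.95), function(th) lcc_size(nw, gs, th))
  expect_true(all(diff(sizes) <= 0))
})

test_that("duplicate and self edges are normalized with max confidence kept", {
  edges <- tibble::tibble(gene_a = c("a", "b", "a", "c"),
                          gene_b = c("b", "a", "a", "d"),
                          confidence = c(0.2, 0.8, 0.5, 0.9))
  expect_message(expect_message(
    res <- lcc_size(edges, c("a", "b")), "self-loop"), "duplicate")
  expect_identical(res, 2L)  # max(0.2, 0.8) = 0.8 > 0.4 keeps a-b connected
})

test_that("lcc_null_test is calibrated, deterministic and add-one protected", {
  nw <- gen_network(500, 10, 0.002, seed = 25)
  # observed = 1 can never beat the null
  t1 <- lcc_null_test(nw, 10, 1, n_iterations = 50, seed = 26)
  expect_equal(t1$empirical_p, 1)

  tm <- lcc_null_test(nw, 10, lcc_size(nw, nw$module_genes), n_iterations = 500, seed = 26)
  expect_lt(tm$empirical_p, 0.01)
  expect_gt(tm$empirical_p, 0)
  expect_identical(length(tm$null_sizes), 500L)

  tm2 <- lcc_null_test(nw, 10, 10, n_iterations = 500, seed = 26)
  expect_identical(tm$null_sizes, tm2$null_sizes)  # same seed, same null

  # random 10-gene draws from a sparse 1000-gene background barely connect
  nw2 <- gen_network(1000, 10, 0.001, seed = 27)
  null10 <- lcc_null_test(nw2, 10, 10, n_iterations = 1000, seed = 28)
  expect_lt(null10$null_mean, 3)

  expect_error(lcc_null_test(nw, 1000, 5), "node count")
})

test_that("lcc_size_curve is monotone in k and dominates the null on a planted ranking", {
  nw <- gen_network(400, 10, 0.002, seed = 29)
  ranked <- c(nw$module_genes, setdiff(nw$all_genes, nw$module_genes))
  curve <- lcc_size_curve(nw, ranked, k_grid = c(1, 5, 10, 20),
                          n_iterations = 200, seed = 30)
  expect_identical(curve$observed_lcc[curve$k == 1], 1L)
  expect_true(all(diff(curve$observed_lcc) >= 0))
  top <- curve[curve$k >= 10, ]
  expect_true(all(top$observed_lcc > top$null_mean + 2 * top$null_sd))
  expect_error(lcc_size_curve(nw, ranked, integer()), "empty")
  expect_error(lcc_size_curve(nw, ranked[1:5], 10), "ranking")
})
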