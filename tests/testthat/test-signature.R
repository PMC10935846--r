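# Eigenarray signatures: scaling, extraction, robustness, integration
# and the characterization analyses.

test_that("scale_samples zero-centers columns without variance scaling", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  out <- scale_samples(m)
  expect_equal(unname(out[, "a"]), c(-1, 0, 1))
  expect_equal(unname(out[, "b"]), c(0, 0, 0))
  expect_equal(scale_samples(out), out)  # idempotent on centered data
  expect_equal(colSums(out), c(a = 0, b = 0), tolerance = 1e-6)
})

test_that("center_genes row-centers absolute data and refuses relative data", {
  m <- rbind(g1 = c(2, 4, 6), g2 = c(0, 0, 0))
  out <- center_genes(m)
  expect_equal(unname(out["g1", ]), c(-2, 0, 2))
  expect_equal(unname(out["g2", ]), c(0, 0, 0))
  expect_error(center_genes(m, dialect = "relative"), "relative")

  # stepwise two-step oracle on a 2x2 matrix
  m2 <- rbind(g1 = c(s1 = 1, s2 = 3), g2 = c(s1 = 5, s2 = 7))
  step1 <- m2 - rowMeans(m2)           # both rows -> (-1, 1)
  step2 <- sweep(step1, 2, colMeans(step1))
  expect_equal(scale_samples(center_genes(m2)), step2)
  expect_equal(unname(step2), matrix(0, 2, 2))
})

test_that("first_eigenarray recovers a rank-1 factor up to scale and orients deterministically", {
  g <- c(gene_a = 3, gene_b = -2, gene_c = 1, gene_d = -1)
  t <- rnorm(8)
  m <- outer(g, t)
  sig <- first_eigenarray(m)
  expect_equal(abs(cor(sig$score, g)), 1, tolerance = 1e-9)
  expect_gt(sig$score[which.max(abs(sig$score))], 0)  # orientation rule
  expect_equal(sqrt(sum(sig$score^2)), 1, tolerance = 1e-9)
  expect_true(all(sig$consistent))

  # duplicated gene rows receive equal scores
  m2 <- rbind(m, gene_a2 = m["gene_a", ])
  sig2 <- first_eigenarray(m2)
  expect_equal(unname(sig2$score["gene_a"]), unname(sig2$score["gene_a2"]), tolerance = 1e-12)

  # scale invariance of the unit-norm signature
  expect_equal(first_eigenarray(5 * m)$score, sig$score, tolerance = 1e-9)

  # degenerate top pair is refused
  expect_error(first_eigenarray(diag(4)), "degenerate")
})

test_that("robust_signature recovers a planted signature and flags consistency", {
  ex <- gen_expression(500, 100, signature_sd = 3, noise_sd = 0.5, seed = 51)
  sig <- robust_signature(scale_samples(ex$matrix), n_iterations = 50, seed = 52)
  tr <- truth_vector(ex)
  rho <- cor(sig$score, tr[names(sig$score)], method = "spearman")
  expect_gt(abs(rho), 0.95)
  # strong-|score| genes are overwhelmingly sign-consistent
  strong <- abs(tr) > median(abs(tr))
  expect_gt(mean(sig$consistent[names(tr)[strong]]), 0.8)

  # pure noise: few consistent genes, and the recovered vector carries no
  # information about any given gene ordering (the planted truth is flat)
  ex0 <- gen_expression(500, 60, signature_sd = 0, noise_sd = 1, seed = 53)
  sig0 <- robust_signature(scale_samples(ex0$matrix), n_iterations = 100, seed = 54)
  expect_lt(mean(sig0$consistent), 0.2)
  expect_lt(abs(cor(sig0$score, tr[names(sig0$score)], method = "spearman")), 0.3)

  # zero perturbation: every nonzero-scored gene is consistent
  sigz <- robust_signature(scale_samples(ex$matrix[1:50, 1:20]), n_iterations = 3,
                           noise_sd = 0, seed = 55)
  expect_true(all(sigz$consistent[sigz$score != 0]))

  # determinism under the seed
  siga <- robust_signature(scale_samples(ex$matrix[1:60, 1:30]), n_iterations = 10, seed = 9)
  sigb <- robust_signature(scale_samples(ex$matrix[1:60, 1:30]), n_iterations = 10, seed = 9)
  expect_identical(siga, sigb)
})

test_that("recovery degrades monotonically with the noise-to-signal ratio", {
  grid <- c(0.2, 1, 3, 6, 12)
  ok <- 0L
  for (s in 1:3) {
    rhos <- sapply(seq_along(grid), function(i) {
      ex <- gen_expression(200, 40, signature_sd = 1, noise_sd = grid[i], seed = 60 + 10 * s + i)
      abs(cor(first_eigenarray(scale_samples(ex$matrix))$score,
              truth_vector(ex), method = "spearman"))
    })
    if (all(diff(rhos) <= 0.02)) ok <- ok + 1L
  }
  expect_gte(ok, 2L)
})

test_that("integrate_datasets removes additive batch offsets", {
  ex <- gen_expression(300, 60, signature_sd = 3, noise_sd = 0.5,
                       n_batches = 2, batch_sd = 4, seed = 71)
  batches <- split(ex$batch_label$sample, ex$batch_label$batch)
  mats <- lapply(batches, function(s) ex$matrix[, s])
  combined <- integrate_datasets(mats)
  expect_identical(ncol(combined), 60L)
  sig <- robust_signature(scale_samples(combined), n_iterations = 30, seed = 72)
  rho <- cor(sig$score, truth_vector(ex)[names(sig$score)], method = "spearman")
  expect_gt(abs(rho), 0.9)

  # two copies of one matrix: per-batch values identical after adjustment
  m <- ex$matrix[1:20, 1:10]
  cc <- integrate_datasets(list(x = m, y = m))
  expect_identical(ncol(cc), 20L)
  expect_equal(unname(cc[, 1:10]), unname(cc[, 11:20]))

  disjoint <- list(a = m, b = matrix(1, 2, 2, dimnames = list(c("zz1", "zz2"), c("s1", "s2"))))
  expect_error(integrate_datasets(disjoint), "shared")
})

test_that("integrate_signatures orients, filters sign conflicts and is symmetric", {
  sc <- c(g1 = 0.5, g2 = -0.4, g3 = 0.3, g4 = -0.2, g5 = 0.1)
  mk <- function(score) {
    ex <- outer(score, rnorm(12)) + matrix(rnorm(length(score) * 12, sd = 0.05), length(score))
    first_eigenarray(scale_samples(ex))
  }
  a <- mk(sc)
  b <- mk(sc)
  ab <- integrate_signatures(a, b)
  ba <- integrate_signatures(b, a)
  expect_equal(sort(names(ab$score)), sort(names(ba$score)))
  expect_equal(ab$score[sort(names(ab$score))], ba$score[sort(names(ba$score))], tolerance = 1e-12)
  expect_identical(ab$source_tag, "integrated")

  # self-integration restricted to consistent genes reproduces the input
  aa <- integrate_signatures(a, a)
  expect_equal(aa$score, a$score[names(aa$score)])

  # a gene with conflicting sign is excluded
  b2 <- b
  b2$score["g5"] <- -b2$score["g5"]
  expect_false("g5" %in% names(integrate_signatures(a, b2)$score))

  # two noisy recoveries integrate at least as well as either input
  ex1 <- gen_expression(400, 30, signature_sd = 1, noise_sd = 2, seed = 81)
  tr <- truth_vector(ex1)
  m1 <- outer(tr, rnorm(40)) + matrix(rnorm(400 * 40, sd = 2), 400)
  rownames(m1) <- names(tr)
  s1 <- robust_signature(scale_samples(ex1$matrix), 20, seed = 82)
  s2 <- robust_signature(scale_samples(m1), 20, seed = 83)
  si <- integrate_signatures(s1, s2)
  r <- function(s) abs(cor(s$score, tr[names(s$score)], method = "spearman"))
  expect_gte(r(si) + 0.02, max(r(s1), r(s2)))
})

test_that("split_ps_ns partitions nonzero consistent genes exhaustively", {
  sig <- growthtradeoff:::new_signature(
    c(g1 = 1, g2 = -1, g3 = 2), c(g1 = TRUE, g2 = TRUE, g3 = TRUE), 1L, 0)
  sets <- split_ps_ns(sig)
  expect_identical(sets$ps, c("g1", "g3"))
  expect_identical(sets$ns, "g2")

  allpos <- growthtradeoff:::new_signature(c(a = 1, b = 2), c(a = TRUE, b = TRUE), 1L, 0)
  expect_error(split_ps_ns(allpos), "empty")

  # planted arms recovered with high Jaccard
  ex <- gen_expression(500, 80, signature_sd = 3, noise_sd = 0.5, seed = 91)
  sig2 <- robust_signature(scale_samples(ex$matrix), n_iterations = 30, seed = 92)
  tr <- truth_vector(ex)
  if (cor(sig2$score, tr[names(sig2$score)], method = "spearman") < 0) {
    sig2$score <- -sig2$score
  }
  sets2 <- split_ps_ns(sig2)
  expect_gt(jaccard(sets2$ps, names(tr)[tr > 0]), 0.8)
  expect_gt(jaccard(sets2$ns, names(tr)[tr < 0]), 0.8)
})

test_that("compare_signatures and measurement correlations behave at the extremes", {
  sc <- setNames(rnorm(50), paste0("g", 1:50))
  sig <- growthtradeoff:::new_signature(sc, setNames(rep(TRUE, 50), names(sc)), 1L, 0)
  expect_equal(compare_signatures(sig, sig)$rho, 1)
  neg <- growthtradeoff:::new_signature(-sc, setNames(rep(TRUE, 50), names(sc)), 1L, 0)
  expect_equal(compare_signatures(sig, neg)$rho, -1)
  expect_error(compare_signatures(sig, growthtradeoff:::new_signature(
    c(zz = 1), c(zz = TRUE), 1L, 0)), "shared")

  # independent signatures are uncorrelated in most seeds
  hits <- 0L
  for (s in 1:100) {
    set.seed(100 + s)
    a <- setNames(rnorm(1000), paste0("g", 1:1000))
    b <- setNames(rnorm(1000), paste0("g", 1:1000))
    if (abs(cor(a, b, method = "spearman")) < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 90L)

  expect_equal(correlate_signature_with_measurement(sig, sc)$rho, 1)
  # permuted measurements decorrelate
  set.seed(7)
  mean_abs <- mean(replicate(100, {
    abs(correlate_signature_with_measurement(sig, setNames(sample(sc), names(sc)))$rho)
  }))
  expect_lt(mean_abs, 0.15)

  # midrank tie handling against the hand oracle on a 5-gene case
  sig5 <- growthtradeoff:::new_signature(
    c(a = 1, b = 2, c = 3, d = 4, e = 5) / 10,
    setNames(rep(TRUE, 5), letters[1:5]), 1L, 0)
  meas <- c(a = 1, b = 1, c = 2, d = 2, e = 3)
  got <- suppressWarnings(correlate_signature_with_measurement(
    growthtradeoff:::new_signature(
      c(sig5$score, f = 0.6, g = 0.7, h = 0.8, i = 0.9, j = 1.0),
      setNames(rep(TRUE, 10), c(letters[1:5], letters[6:10])), 1L, 0),
    c(meas, f = 3, g = 4, h = 4, i = 5, j = 6)))
  oracle <- spearman_oracle(1:10, c(1, 1, 2, 2, 3, 3, 4, 4, 5, 6))
  expect_equal(got$rho, oracle, tolerance = 1e-12)
})

test_that("gene_set_score_distribution separates planted arms and skips disjoint sets", {
  ex <- gen_expression(400, 60, signature_sd = 3, noise_sd = 0.5, seed = 93)
  sig <- robust_signature(scale_samples(ex$matrix), n_iterations = 20, seed = 94)
  tr <- truth_vector(ex)
  sets <- list(ns_like = names(sort(tr))[1:50],
               ps_like = names(sort(tr, decreasing = TRUE))[1:50])
  res <- gene_set_score_distribution(sig, sets)
  expect_lt(res$tests$p_value[1], 1e-4)
  expect_true(all(c("p_value", "p_adj") %in% names(res$tests)))

  expect_warning(
    res2 <- gene_set_score_distribution(sig, c(sets, list(alien = c("x1", "x2")))),
    "alien")
  expect_false("alien" %in% res2$scores$set)

  # a set against itself sits at the null center
  res3 <- gene_set_score_distribution(sig, list(all1 = names(tr), all2 = names(tr)))
  expect_gt(res3$tests$p_value[1], 0.9)
})

test_that("group_log2fc matches direct computation", {
  m <- rbind(g1 = c(2, 2, 1, 1), g2 = c(8, 8, 2, 2), g3 = c(3, 3, 3, 3))
  colnames(m) <- paste0("s", 1:4)
  labs <- setNames(c("a", "a", "b", "b"), colnames(m))
  fc <- group_log2fc(m, labs)
  expect_equal(fc$log2fc[fc$gene == "g1"], 1)
  expect_equal(fc$log2fc[fc$gene == "g2"], 2)
  expect_equal(fc$log2fc[fc$gene == "g3"], 0)

  # identical groups -> zero; pre-logged uses mean differences
  expect_equal(group_log2fc(m, setNames(c("a", "b", "a", "b"), colnames(m)),
                            gene_set = "g3")$log2fc, 0)
  expect_equal(group_log2fc(log2(m), labs, pre_logged = TRUE)$log2fc,
               c(1, 2, 0))
  m0 <- m; m0["g1", 1:2] <- 0
  expect_error(group_log2fc(m0, labs), "positive")
})
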