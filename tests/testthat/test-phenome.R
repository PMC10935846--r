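# Phenome preprocessing, SVD reconstruction and clustering.

test_that("filter_missing applies the 10% rule and iterates to a fixed point", {
  m <- matrix(1, 10, 10, dimnames = list(paste0("s", 1:10), paste0("c", 1:10)))
  m[1, 1:2] <- NA  # 20% of row 1
  out <- filter_missing(m)
  expect_identical(dim(out), c(9L, 10L))
  expect_false("s1" %in% rownames(out))

  full <- matrix(rnorm(30), 5, 6)
  expect_equal(unname(filter_missing(full)), full)  # fully observed -> identity

  # dropping a bad row rescues a column that would otherwise fail
  m2 <- matrix(rnorm(144), 12, 12, dimnames = list(paste0("s", 1:12), paste0("c", 1:12)))
  m2[1, 1:3] <- NA   # row 1: 25% missing -> dropped
  m2[2, 5] <- NA     # col 5: 2/12 = 16.7% before, 1/11 = 9.1% after row drop
  m2[1, 5] <- NA
  out2 <- filter_missing(m2)
  oracle <- filter_oracle(m2)
  expect_identical(dimnames(out2), dimnames(oracle))
  expect_true("c5" %in% colnames(out2))
  expect_false("s1" %in% rownames(out2))

  all_na <- matrix(NA_real_, 3, 3)
  expect_error(filter_missing(all_na), "sparse")
})

test_that("impute_knn matches a brute-force neighbour oracle and preserves observed cells", {
  expect_equal(impute_knn(matrix(1:12, 3, 4)), matrix(as.numeric(1:12), 3, 4),
               ignore_attr = TRUE)

  # identical rows: zero-distance neighbours supply the missing value
  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, NA))
  expect_equal(impute_knn(m, k = 2)[3, 3], 3)

  set.seed(99)
  m5 <- matrix(rnorm(15), 5, 3)
  m5[2, 1] <- NA
  m5[4, 3] <- NA
  out <- impute_knn(m5, k = 2)
  # oracle: RMS distance over mutually observed columns, k nearest rows
  # observed at the target column
  oracle_impute <- function(m, i, cc, k) {
    d <- sapply(seq_len(nrow(m)), function(j) {
      if (j == i) return(NA_real_)
      sh <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(sh)) return(NA_real_)
      sqrt(mean((m[i, sh] - m[j, sh])^2))
    })
    cand <- which(!is.na(m[, cc]) & !is.na(d))
    nn <- cand[order(d[cand])][seq_len(k)]
    mean(m[nn, cc])
  }
  expect_equal(out[2, 1], oracle_impute(m5, 2, 1, 2))
  expect_equal(out[4, 3], oracle_impute(m5, 4, 3, 2))
  expect_equal(out[!is.na(m5)], m5[!is.na(m5)])  # observed values untouched

  # too few neighbours -> column-mean fallback with a warning
  expect_warning(res <- impute_knn(m5, k = 10), "neighbours")
  expect_equal(res[2, 1], mean(m5[, 1], na.rm = TRUE))
})

test_that("standardize_conditions centers and scales with the n-1 convention", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  out <- standardize_conditions(m)
  expect_equal(unname(out[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(out), c(a = 0, b = 0), tolerance = 1e-8)
  expect_equal(apply(out, 2, sd), c(a = 1, b = 1), tolerance = 1e-8)
  expect_equal(standardize_conditions(out), out, tolerance = 1e-12)
  expect_error(standardize_conditions(cbind(a = c(1, 1, 1), b = 1:3)), "a")
  expect_error(standardize_conditions(cbind(a = c(1, NA, 3))), "missing")
})

test_that("svd_reconstruct satisfies Eckart-Young and full-rank identity", {
  set.seed(7)
  m <- matrix(rnorm(24), 6, 4)
  full <- svd_reconstruct(m, rank = 4)
  expect_equal(full$values, m, tolerance = 1e-8, ignore_attr = TRUE)

  r1 <- tcrossprod(rnorm(6), rnorm(4))
  expect_equal(svd_reconstruct(r1, 1)$values, r1, tolerance = 1e-8, ignore_attr = TRUE)

  rec <- svd_reconstruct(m, rank = 2)
  d <- svd(m)$d
  expect_equal(norm(m - rec$values, "F"), sqrt(d[3]^2 + d[4]^2), tolerance = 1e-9)
  expect_equal(rec$frob_error, sqrt(d[3]^2 + d[4]^2), tolerance = 1e-9)
  expect_lte(qr(rec$values)$rank, 2)
  expect_error(svd_reconstruct(m, 5), "rank")

  # no random rank-2 factorization beats the SVD truncation
  err <- norm(m - rec$values, "F")
  for (i in 1:100) {
    A <- matrix(rnorm(12), 6, 2)
    B <- matrix(rnorm(8), 2, 4)
    expect_gte(norm(m - A %*% B, "F"), err - 1e-12)
  }
})

test_that("condition_correlation is a midrank Spearman matrix", {
  m <- cbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4), z = c(4, 3, 2, 1))
  rho <- condition_correlation(m)
  expect_equal(unname(rho["x", "y"]), 0.8)
  expect_equal(unname(rho["x", "z"]), -1)
  expect_equal(unname(diag(rho)), rep(1, 3))
  expect_equal(rho, t(rho))
  expect_equal(unname(rho["x", "y"]), spearman_oracle(m[, "x"], m[, "y"]))
  expect_error(condition_correlation(m[1:2, ]), "3 strains")
})

test_that("hcluster recovers separated pairs and matches the average-linkage oracle", {
  pts <- c(0, 0.1, 10, 10.1)
  dm <- as.matrix(dist(pts))
  cl <- hcluster(dm, K = 2)
  expect_true(same_partition(cl$cluster, c(1, 1, 2, 2)))
  expect_identical(length(unique(cl$cluster)), 2L)

  cl4 <- hcluster(dm, K = 4)
  expect_identical(length(unique(cl4$cluster)), 4L)

  set.seed(3)
  p5 <- cumsum(runif(5, 0.5, 2))
  dm5 <- as.matrix(dist(p5))
  for (K in 2:4) {
    expect_true(same_partition(hcluster(dm5, K = K)$cluster,
                               average_linkage_oracle(dm5, K)))
  }
  expect_error(hcluster(dm, K = 5), "exceed")
  expect_error(hcluster(matrix(c(0, 1, 2, 0), 2, 2), K = 1), "symmetric")
})

test_that("cluster_composition_test is Pearson chi-squared without continuity correction", {
  # perfectly confounded 2x2 table: chi-squared = n = 20
  res <- cluster_composition_test(rep(1:2, each = 10), rep(c("wild", "dom"), each = 10))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)

  # null calibration: p roughly uniform when labels are independent
  set.seed(5)
  ps <- replicate(200, {
    cluster_composition_test(sample(1:2, 120, replace = TRUE),
                             sample(c("w", "d", "u"), 120, replace = TRUE))$p_value
  })
  expect_gt(median(ps), 0.35)
  expect_lt(median(ps), 0.65)

  expect_error(cluster_composition_test(rep(1, 10), rep(c("a", "b"), 5)), "2 clusters")
})

test_that("stage contracts refuse unpreprocessed input", {
  m <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(standardize_conditions(m), "filter_missing")
  expect_error(svd_reconstruct(m), "missing")
  expect_error(condition_correlation(m), "missing")
  expect_error(consensus_cluster(m, K_range = 2), "missing")
})
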