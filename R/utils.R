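# Internal helpers shared across modules.

# Coerce a matrix-like input (matrix or data frame of numerics, optionally
# with an explicit id column) to a numeric matrix with dimnames.
as_value_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    idcol <- which(!vapply(x, is.numeric, logical(1)))
    if (length(idcol) > 1) {
      abort(sprintf("`%s` has more than one non-numeric column.", arg))
    }
    if (length(idcol) == 1) {
      rn <- as.character(x[[idcol]])
      x <- x[, -idcol, drop = FALSE]
      m <- as.matrix(x)
      rownames(m) <- rn
    } else {
      m <- as.matrix(x)
    }
  } else if (is.matrix(x)) {
    m <- x
  } else {
    abort(sprintf("`%s` must be a matrix or data frame.", arg))
  }
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- paste0("row_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("col_", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort(sprintf("`%s` must have unique row and column ids.", arg))
  }
  m
}

assert_complete <- function(m, stage) {
  if (anyNA(m)) {
    abort(sprintf(
      "%s requires a complete matrix with no missing values; run filter_missing()/impute_knn() first.",
      stage
    ))
  }
  invisible(m)
}

# Named numeric from a 2-column data frame (id, value) or a named vector.
as_named_numeric <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) abort(sprintf("`%s` must have an id and a value column.", arg))
    num <- which(vapply(x, is.numeric, logical(1)))[1]
    id <- setdiff(seq_len(ncol(x)), num)[1]
    setNames(as.numeric(x[[num]]), as.character(x[[id]]))
  } else if (is.numeric(x)) {
    if (is.null(names(x))) abort(sprintf("`%s` must be named.", arg))
    x
  } else {
    abort(sprintf("`%s` must be a named numeric vector or a two-column data frame.", arg))
  }
}

# Deterministic per-stage seed stream: every stage of a run draws from
# seed * 131 + sum of the stage name's character codes, folded into the
# 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage))
  as.integer((abs(seed) * 131 + h) %% (.Machine$integer.max - 1L) + 1)
}

# Sign-orientation used for every singular/principal vector in the package:
# flip so the entry of largest absolute magnitude is positive (ties: first).
orient_vector <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

spearman <- function(x, y) {
  suppressWarnings(cor(x, y, method = "spearman", use = "pairwise.complete.obs"))
}

spearman_test <- function(x, y) {
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
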