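# Overall growth phenotype (PC1) and single-marker LOD linkage mapping.

#' Overall growth phenotype as PC1 of the phenome
#'
#' Principal component analysis of the preprocessed (filtered, imputed,
#' condition-standardized) phenome; the PC1 score of each strain is its
#' overall growth phenotype. The sign is oriented so that PC1 correlates
#' non-negatively (Spearman) with mean growth across conditions.
#'
#' @param phenome Complete strains x conditions matrix, already
#'   condition-standardized.
#' @return Tibble: strain, trait (PC1 score), with the condition
#'   `loadings` and `var_explained` (PC1 variance fraction) as attributes.
#' @export
overall_growth_pc1 <- function(phenome) {
  m <- as_value_matrix(phenome, "phenome")
  assert_complete(m, "overall_growth_pc1")
  if (ncol(m) < 2) abort("Need at least 2 conditions for PCA.")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  rho <- spearman(scores, rowMeans(m))
  if (!is.na(rho) && rho < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  out <- tibble(strain = rownames(m), trait = unname(scores))
  attr(out, "loadings") <- loadings
  attr(out, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out
}

#' LOD score of one marker against a quantitative trait
#'
#' The logarithm-of-odds linkage statistic
#' `LOD = -n * ln(1 - r^2) / (2 * ln 10)`, where `r` is the Pearson
#' correlation between the biallelic genotype (0/1 parental origin) and
#' the trait across the `n` segregants. Equivalent to
#' `n/2 * log10(SS_total / SS_residual)` of the single-marker regression.
#'
#' @param genotype_column Vector in `{0, 1}`; both alleles must occur.
#' @param trait Numeric trait vector of the same length, nonconstant.
#' @return LOD score (>= 0; 0 iff r = 0).
#' @export
lod_score <- function(genotype_column, trait) {
  g <- as.numeric(genotype_column)
  t <- as.numeric(trait)
  if (length(g) != length(t)) abort("Genotype and trait lengths differ.")
  if (anyNA(g) || anyNA(t)) abort("Missing genotypes or trait values are not allowed.")
  if (!all(g %in% c(0, 1))) abort("Genotypes must be coded 0/1.")
  if (length(unique(g)) < 2) abort("Monomorphic marker: correlation undefined.")
  if (sd(t) == 0) abort("Constant trait: correlation undefined.")
  n <- length(g)
  r <- cor(g, t)
  -n * log(1 - r^2) / (2 * log(10))
}

# Vectorized LOD over marker columns (shared by scan and permutations).
.lod_vec <- function(G, traits) {
  n <- nrow(G)
  r <- suppressWarnings(cor(G, traits))
  -n * log(1 - r^2) / (2 * log(10))
}

#' Genome-wide single-marker LOD scan
#'
#' Applies [lod_score()] to every marker column. Monomorphic markers are
#' skipped with a warning and reported as `NA`.
#'
#' @param genotypes Segregants x markers matrix in `{0, 1}` (a
#'   `planted_cross` is also accepted).
#' @param trait Numeric trait per segregant (named vector, two-column
#'   data frame, or omitted to use the cross's own trait).
#' @param marker_pos Optional tibble (marker, chrom, start/position) to
#'   annotate the scan.
#' @return Class `lod_scan`: list with `scan` (tibble: marker, lod and
#'   any coordinates), `n` segregants, `n_skipped`, and an optional
#'   `threshold` slot filled by [permutation_threshold()].
#' @export
lod_scan <- function(genotypes, trait = NULL, marker_pos = NULL) {
  if (inherits(genotypes, "planted_cross")) {
    cross <- genotypes
    genotypes <- cross$genotypes
    trait <- trait %||% cross$trait
    marker_pos <- marker_pos %||% cross$marker_pos
  }
  G <- as_value_matrix(genotypes, "genotypes")
  if (!all(G %in% c(0, 1))) abort("Genotypes must be coded 0/1 with no missing values.")
  tr <- if (is.numeric(trait) && is.null(names(trait))) {
    if (length(trait) != nrow(G)) abort("Trait length differs from the number of segregants.")
    setNames(as.numeric(trait), rownames(G))
  } else as_named_numeric(trait, "trait")
  tr <- tr[rownames(G)]
  if (anyNA(tr)) abort("Trait is missing for some segregants.")
  if (sd(tr) == 0) abort("Constant trait: correlation undefined.")
  poly <- apply(G, 2, function(x) length(unique(x)) > 1)
  if (!any(poly)) abort("All markers are monomorphic.")
  if (any(!poly)) {
    warn(sprintf("lod_scan: %d monomorphic marker(s) skipped.", sum(!poly)))
  }
  lod <- rep(NA_real_, ncol(G))
  lod[poly] <- drop(.lod_vec(G[, poly, drop = FALSE], tr))
  scan <- tibble(marker = colnames(G), lod = lod)
  if (!is.null(marker_pos)) {
    scan <- left_join(scan, as_tibble(marker_pos), by = "marker")
  }
  structure(list(scan = scan, n = nrow(G), n_skipped = sum(!poly),
                 threshold = NULL, n_permutations = 0L),
            class = "lod_scan")
}

#' Permutation significance threshold for a LOD scan
#'
#' Permutes the trait across segregants, records the genome-wide maximum
#' LOD of each permuted scan, and returns the empirical `1 - alpha`
#' quantile of those maxima as the genome-wide significance threshold.
#'
#' @param genotypes Segregants x markers matrix in `{0, 1}` (or a
#'   `planted_cross`).
#' @param trait Trait vector (as in [lod_scan()]).
#' @param alpha Genome-wide error rate in `(0, 1]`; `alpha = 1` returns
#'   the minimum of the null maxima.
#' @param n_permutations Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List: `threshold`, `alpha`, `n_permutations`, and the sorted
#'   `max_lods` null sample.
#' @export
permutation_threshold <- function(genotypes, trait = NULL, alpha = 0.05,
                                  n_permutations = 1000, seed = 1) {
  if (inherits(genotypes, "planted_cross")) {
    cross <- genotypes
    genotypes <- cross$genotypes
    trait <- trait %||% cross$trait
  }
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  if (n_permutations < 100) abort("Use at least 100 permutations.")
  G <- as_value_matrix(genotypes, "genotypes")
  tr <- if (is.numeric(trait) && is.null(names(trait))) {
    if (length(trait) != nrow(G)) abort("Trait length differs from the number of segregants.")
    setNames(as.numeric(trait), rownames(G))
  } else as_named_numeric(trait, "trait")
  tr <- tr[rownames(G)]
  if (anyNA(tr)) abort("Trait is missing for some segregants.")
  poly <- apply(G, 2, function(x) length(unique(x)) > 1)
  if (!any(poly)) abort("All markers are monomorphic.")
  Gp <- G[, poly, drop = FALSE]
  set.seed(seed)
  perms <- replicate(n_permutations, tr[sample.int(length(tr))])
  lods <- .lod_vec(Gp, perms)            # markers x permutations
  max_lods <- apply(lods, 2, max)
  threshold <- unname(quantile(max_lods, probs = 1 - alpha, type = 1))
  list(threshold = threshold, alpha = alpha,
       n_permutations = n_permutations, max_lods = sort(max_lods))
}

#' Attach a permutation threshold to a LOD scan
#'
#' @param scan A `lod_scan`.
#' @param threshold Result of [permutation_threshold()] (or a number).
#' @return The scan with `threshold` and `n_permutations` filled in.
#' @export
set_scan_threshold <- function(scan, threshold) {
  stopifnot(inherits(scan, "lod_scan"))
  if (is.list(threshold)) {
    scan$threshold <- threshold$threshold
    scan$n_permutations <- threshold$n_permutations
  } else {
    scan$threshold <- as.numeric(threshold)
  }
  scan
}
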