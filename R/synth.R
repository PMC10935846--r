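# Synthetic inputs with planted ground truth. Every generator is a pure
# function of its seed, and downstream stages only ever see the data
# members, never the planted truth.

#' Generate a phenome matrix with a planted two-block growth trade-off
#'
#' Strains get a latent trade-off axis position `a_s ~ N(0, 1)`; conditions
#' are split into two blocks, A (growth-favouring) and B (stress-like), and
#' the growth value of strain s under condition c is
#' `+/- tradeoff_strength * a_s + N(0, noise_sd^2)` with the sign set by the
#' block of c. Conditions within a block are therefore positively
#' correlated and any A-B pair is anti-correlated, emulating the dichotomy
#' between growth-preferring and stress-resistant phenotype programs.
#' Missing cells are planted uniformly at random at `missing_rate`.
#'
#' Strain clade labels (wild / domesticated / unassigned) are derived from
#' the latent axis (above +0.5, below -0.5, in between) so that
#' cluster-composition tests have plantable structure.
#'
#' @param n_strains,n_conditions Matrix dimensions (strains x conditions).
#' @param block_sizes Integer vector of length 2, sizes of condition blocks
#'   A and B; must sum to `n_conditions` and both be positive.
#' @param tradeoff_strength Non-negative scale of the planted axis signal;
#'   0 plants no structure.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian measurement
#'   noise.
#' @param missing_rate Fraction of cells set missing, in `[0, 1)`.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return An object of class `planted_phenome`: list with `matrix`
#'   (strains x conditions, `NA` for missing), `block_assignment` (tibble:
#'   condition, block), `clade_label` (tibble: strain, clade),
#'   `strain_axis` (tibble: strain, axis), `missing_mask` (logical matrix),
#'   and the generator parameters.
#' @export
gen_phenome <- function(n_strains, n_conditions,
                        block_sizes = c(ceiling(n_conditions / 2), floor(n_conditions / 2)),
                        tradeoff_strength = 5, noise_sd = 1,
                        missing_rate = 0, seed = 1) {
  if (n_strains < 1 || n_conditions < 1) abort("Dimensions must be positive.")
  if (length(block_sizes) != 2 || any(block_sizes < 1) || sum(block_sizes) != n_conditions) {
    abort("`block_sizes` must be two positive integers summing to `n_conditions`.")
  }
  if (tradeoff_strength < 0) abort("`tradeoff_strength` must be >= 0.")
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")

  set.seed(seed)
  strains <- sprintf("strain_%03d", seq_len(n_strains))
  conditions <- c(sprintf("A%02d", seq_len(block_sizes[1])),
                  sprintf("B%02d", seq_len(block_sizes[2])))
  block <- rep(c("A", "B"), block_sizes)

  axis <- rnorm(n_strains)
  sgn <- ifelse(block == "A", 1, -1)
  m <- tradeoff_strength * outer(axis, sgn) +
    matrix(rnorm(n_strains * n_conditions, sd = noise_sd), n_strains, n_conditions)
  dimnames(m) <- list(strains, conditions)

  mask <- matrix(FALSE, n_strains, n_conditions, dimnames = dimnames(m))
  n_miss <- round(missing_rate * length(m))
  if (n_miss > 0) {
    mask[sample(length(m), n_miss)] <- TRUE
    m[mask] <- NA_real_
  }

  clade <- ifelse(axis > 0.5, "domesticated", ifelse(axis < -0.5, "wild", "unassigned"))

  structure(list(
    matrix = m,
    block_assignment = tibble(condition = conditions, block = block),
    clade_label = tibble(strain = strains, clade = clade),
    strain_axis = tibble(strain = strains, axis = axis),
    missing_mask = mask,
    params = list(tradeoff_strength = tradeoff_strength, noise_sd = noise_sd,
                  missing_rate = missing_rate, seed = seed)
  ), class = "planted_phenome")
}

#' Generate an expression matrix with one planted two-arm signature
#'
#' Plants a single dominant expression program: sample activities
#' `t_j ~ N(0, 1)`, gene scores `g_i ~ N(0, signature_sd^2)`, and
#' `value_ij = g_i * t_j + batch_offset_ij + N(0, noise_sd^2)` where the
#' batch offset is a per-gene, per-batch constant with SD `batch_sd`.
#' Genes with positive and negative true scores are thus mutually
#' exclusive (anti-correlated) across samples. For `dialect = "absolute"`
#' a per-gene positive baseline (uniform on 5..15) is added, mimicking
#' count/intensity platforms; `"relative"` mimics two-colour log-ratios.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param signature_sd SD of the planted per-gene signature scores; 0
#'   plants no signature.
#' @param noise_sd SD of i.i.d. Gaussian noise.
#' @param n_batches Number of equal-size sample batches.
#' @param batch_sd SD of per-batch per-gene additive offsets (0 = none).
#' @param dialect `"relative"` or `"absolute"`.
#' @param seed Integer seed.
#'
#' @return Class `planted_expression`: list with `matrix` (genes x
#'   samples), `true_signature` (tibble: gene, score; zero-centered),
#'   `batch_label` (tibble: sample, batch), `dialect`, `params`.
#' @export
gen_expression <- function(n_genes, n_samples, signature_sd = 3, noise_sd = 0.5,
                           n_batches = 1, batch_sd = 0,
                           dialect = c("relative", "absolute"), seed = 1) {
  dialect <- match.arg(dialect)
  if (n_genes < 2 || n_samples < 2) abort("Need at least 2 genes and 2 samples.")
  set.seed(seed)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  samples <- sprintf("sample_%03d", seq_len(n_samples))
  batch <- rep_len(paste0("batch_", seq_len(n_batches)), n_samples)
  batch <- sort(batch)

  tj <- rnorm(n_samples)
  gi <- rnorm(n_genes, sd = signature_sd)
  gi <- gi - mean(gi)  # zero-centered planted scores

  m <- outer(gi, tj)
  if (batch_sd > 0 && n_batches > 1) {
    off <- matrix(rnorm(n_genes * n_batches, sd = batch_sd), n_genes, n_batches)
    m <- m + off[, match(batch, paste0("batch_", seq_len(n_batches)))]
  }
  m <- m + matrix(rnorm(n_genes * n_samples, sd = noise_sd), n_genes, n_samples)
  if (dialect == "absolute") {
    m <- m + runif(n_genes, 5, 15)  # per-gene positive baseline
  }
  dimnames(m) <- list(genes, samples)

  structure(list(
    matrix = m,
    true_signature = tibble(gene = genes, score = gi),
    batch_label = tibble(sample = samples, batch = batch),
    dialect = dialect,
    params = list(signature_sd = signature_sd, noise_sd = noise_sd,
                  n_batches = n_batches, batch_sd = batch_sd, seed = seed)
  ), class = "planted_expression")
}

#' Generate a biallelic segregant cross with planted additive QTLs
#'
#' Genotypes at every marker are independent fair coin flips in `{0, 1}`
#' (parental origin; no recombination map). The quantitative trait is the
#' sum of the planted additive marker effects plus Gaussian noise:
#' `trait_s = sum_k effect_k * (genotype_sk - 0.5) + N(0, noise_sd^2)`,
#' so an effect of 1 separates the two allele classes by one unit (one
#' noise SD when `noise_sd = 1`).
#'
#' @param n_segregants,n_markers Cross dimensions.
#' @param qtl List of `c(marker_index, effect)` pairs (or a 2-column
#'   matrix); empty list plants a null cross.
#' @param noise_sd Trait noise SD.
#' @param seed Integer seed.
#'
#' @return Class `planted_cross`: list with `genotypes` (segregants x
#'   markers, 0/1), `marker_pos` (tibble: marker, chrom, start, end;
#'   1-based inclusive), `qtl_markers` (tibble: marker, effect), `trait`
#'   (tibble: segregant, trait), `params`.
#' @export
gen_cross <- function(n_segregants, n_markers, qtl = list(), noise_sd = 1, seed = 1) {
  if (n_segregants < 2 || n_markers < 1) abort("Dimensions too small.")
  qtl_tbl <- if (length(qtl) == 0) {
    tibble(marker_index = integer(), effect = numeric())
  } else {
    qm <- do.call(rbind, lapply(qtl, function(x) c(x[1], x[2])))
    tibble(marker_index = as.integer(qm[, 1]), effect = as.numeric(qm[, 2]))
  }
  if (nrow(qtl_tbl) && any(qtl_tbl$marker_index < 1 | qtl_tbl$marker_index > n_markers)) {
    abort("QTL effect list references markers outside 1..n_markers.")
  }
  set.seed(seed)
  segregants <- sprintf("seg_%04d", seq_len(n_segregants))
  markers <- sprintf("m%05d", seq_len(n_markers))
  g <- matrix(rbinom(n_segregants * n_markers, 1, 0.5), n_segregants, n_markers,
              dimnames = list(segregants, markers))
  trait <- rnorm(n_segregants, sd = noise_sd)
  if (nrow(qtl_tbl)) {
    for (i in seq_len(nrow(qtl_tbl))) {
      trait <- trait + qtl_tbl$effect[i] * (g[, qtl_tbl$marker_index[i]] - 0.5)
    }
  }
  structure(list(
    genotypes = g,
    marker_pos = tibble(marker = markers, chrom = "chr1",
                        start = (seq_len(n_markers) - 1L) * 1000L + 1L,
                        end = (seq_len(n_markers) - 1L) * 1000L + 1L),
    qtl_markers = mutate(qtl_tbl, marker = markers[.data$marker_index]),
    trait = tibble(segregant = segregants, trait = trait),
    params = list(noise_sd = noise_sd, seed = seed)
  ), class = "planted_cross")
}

#' Generate a confidence-weighted gene network with one planted module
#'
#' The planted module is wired as a connected subgraph (random spanning
#' tree plus `module_size` extra random internal edges) with confidence
#' `module_confidence`; background edges are Erdos-Renyi with probability
#' `background_p` at `background_confidence`. Gene intervals tile one
#' synthetic chromosome: gene i occupies `[(i-1)*2000 + 1, (i-1)*2000 + 1000]`
#' (1-based inclusive, 1 kb genes spaced 1 kb apart).
#'
#' @param n_genes Total genes (nodes).
#' @param module_size Planted module size (<= `n_genes`).
#' @param background_p Background edge probability.
#' @param module_confidence,background_confidence Edge confidences in
#'   `[0, 1]`. A `module_confidence` at or below the conventional 0.4
#'   medium-confidence threshold triggers a warning (the module would
#'   vanish from the thresholded graph), not an error.
#' @param seed Integer seed.
#'
#' @return Class `planted_network`: list with `edges` (tibble: gene_a,
#'   gene_b, confidence), `module_genes` (character), `gene_intervals`
#'   (tibble: gene, chrom, start, end), `params`.
#' @export
gen_network <- function(n_genes, module_size = 10, background_p = 0.001,
                        module_confidence = 0.9, background_confidence = 0.2,
                        seed = 1) {
  if (module_size > n_genes) abort("`module_size` must be <= `n_genes`.")
  if (any(c(module_confidence, background_confidence) < 0) ||
      any(c(module_confidence, background_confidence) > 1)) {
    abort("Confidences must lie in [0, 1].")
  }
  if (module_size > 0 && module_confidence <= 0.4) {
    warn("module_confidence <= 0.4: the planted module vanishes at the medium-confidence threshold.")
  }
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  module <- if (module_size > 0) sample(genes, module_size) else character()

  edges <- list()
  if (module_size > 1) {
    # random spanning tree: attach each node to a uniformly chosen earlier one
    ord <- sample(module)
    to <- vapply(2:module_size, function(i) ord[sample.int(i - 1, 1)], character(1))
    tree <- tibble(gene_a = ord[-1], gene_b = to)
    extra <- tibble(gene_a = sample(module, module_size, replace = TRUE),
                    gene_b = sample(module, module_size, replace = TRUE))
    med <- bind_rows(tree, extra)
    med <- med[med$gene_a != med$gene_b, ]
    edges$module <- mutate(med, confidence = module_confidence)
  }
  if (background_p > 0 && n_genes > 1) {
    pairs <- which(upper.tri(matrix(TRUE, n_genes, n_genes)), arr.ind = TRUE)
    pick <- runif(nrow(pairs)) < background_p
    if (any(pick)) {
      edges$background <- tibble(gene_a = genes[pairs[pick, 1]],
                                 gene_b = genes[pairs[pick, 2]],
                                 confidence = background_confidence)
    }
  }
  edge_tbl <- if (length(edges)) bind_rows(edges) else
    tibble(gene_a = character(), gene_b = character(), confidence = numeric())
  # simple graph: one edge per unordered pair, max confidence wins
  if (nrow(edge_tbl)) {
    key <- paste(pmin(edge_tbl$gene_a, edge_tbl$gene_b),
                 pmax(edge_tbl$gene_a, edge_tbl$gene_b))
    o <- order(key, -edge_tbl$confidence)
    edge_tbl <- edge_tbl[o, ]
    edge_tbl <- edge_tbl[!duplicated(key[o]), ]
  }

  structure(list(
    edges = as_tibble(edge_tbl),
    module_genes = sort(module),
    gene_intervals = tibble(gene = genes, chrom = "chr1",
                            start = (seq_len(n_genes) - 1L) * 2000L + 1L,
                            end = (seq_len(n_genes) - 1L) * 2000L + 1000L),
    all_genes = genes,
    params = list(background_p = background_p, module_confidence = module_confidence,
                  background_confidence = background_confidence, seed = seed)
  ), class = "planted_network")
}

#' Generate a cell-line drug panel where resistance tracks the NS arm
#'
#' A designated signature pool of `2 * n_signature` genes is split into
#' disjoint PS and NS halves. Each cell line gets a latent state
#' `s_c ~ N(0, 1)`; NS genes express `+s_c`, PS genes `-s_c` (plus noise),
#' so the cell line's NS-minus-PS median score tracks `s_c`. Resistance of
#' every drug is `effect * s_c + N(0, noise_sd^2)` on a Z-score-like
#' scale, i.e. a monotone function of NS score minus PS score, so higher
#' NS (survival-program) expression predicts higher drug resistance.
#'
#' @param n_genes,n_cell_lines,n_drugs Panel dimensions.
#' @param n_signature Genes per arm (PS and NS each); default 20.
#' @param effect Non-negative planted correlation strength; 0 = null.
#' @param noise_sd Noise SD for both expression and resistance.
#' @param seed Integer seed.
#'
#' @return Class `planted_drug_panel`: list with `expression` (genes x
#'   cell lines), `resistance` (cell lines x drugs), `ps_genes`,
#'   `ns_genes` (character), `params`.
#' @export
gen_drug_panel <- function(n_genes, n_cell_lines, n_drugs, n_signature = 20,
                           effect = 2, noise_sd = 0.5, seed = 1) {
  if (n_drugs < 1) abort("`n_drugs` must be at least 1.")
  if (effect < 0) abort("`effect` must be >= 0.")
  if (2 * n_signature > n_genes) abort("Signature pool exceeds `n_genes`.")
  set.seed(seed)
  genes <- sprintf("HG%04d", seq_len(n_genes))
  lines <- sprintf("cell_%03d", seq_len(n_cell_lines))
  drugs <- sprintf("drug_%03d", seq_len(n_drugs))
  ps <- genes[seq_len(n_signature)]
  ns <- genes[n_signature + seq_len(n_signature)]

  s <- rnorm(n_cell_lines)
  expr <- matrix(rnorm(n_genes * n_cell_lines, sd = noise_sd), n_genes, n_cell_lines,
                 dimnames = list(genes, lines))
  expr[ns, ] <- sweep(expr[ns, , drop = FALSE], 2, s, "+")
  expr[ps, ] <- sweep(expr[ps, , drop = FALSE], 2, s, "-")

  res <- effect * matrix(s, n_cell_lines, n_drugs) +
    matrix(rnorm(n_cell_lines * n_drugs, sd = noise_sd), n_cell_lines, n_drugs)
  dimnames(res) <- list(lines, drugs)

  structure(list(
    expression = expr,
    resistance = res,
    ps_genes = ps,
    ns_genes = ns,
    params = list(effect = effect, noise_sd = noise_sd, seed = seed)
  ), class = "planted_drug_panel")
}
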