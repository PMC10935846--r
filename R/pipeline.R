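# Run configuration and end-to-end orchestration over the analysis
# stages, with a manifest proving which files each stage consumed.

#' Build a run configuration
#'
#' Collects the stage parameters, input paths and output directory for
#' [run_pipeline()]. The configuration round-trips losslessly through
#' JSON ([write_run_config()] / [read_run_config()]), and every run
#' writes its resolved configuration and seed next to its outputs.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; each stage derives its own stream from it
#'   (seed * 131 + character-code sum of the stage name, mod 2^31).
#' @param inputs Named list of input paths (see [run_pipeline()]).
#' @param rank SVD reconstruction rank for the phenome stage.
#' @param K_range Cluster numbers scanned by consensus clustering.
#' @param n_iterations Resampling/permutation/perturbation iterations
#'   shared by the stochastic stages.
#' @param resample_fraction Consensus resampling fraction.
#' @param noise_sd Signature perturbation noise SD.
#' @param alpha Genome-wide error rate for the LOD threshold.
#' @param k_grid Ranking depths for the LCC curve.
#' @param min_confidence Network edge-confidence threshold.
#' @param aggregation p-value aggregation rule ("fisher" or "min").
#' @param coords Coordinate dialect of interval files ("one_based" or
#'   "bed").
#' @param min_cell_lines Minimum shared cell lines per drug.
#' @param use_reconstruction Whether consensus clustering runs on the
#'   rank-r reconstruction (default) or the raw standardized matrix; the
#'   choice is recorded in the run log.
#' @return Class `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, inputs = list(), rank = 2,
                       K_range = 2:6, n_iterations = 1000,
                       resample_fraction = 0.8, noise_sd = 1, alpha = 0.05,
                       k_grid = c(10, 25, 50), min_confidence = 0.4,
                       aggregation = "fisher", coords = "one_based",
                       min_cell_lines = 10, use_reconstruction = TRUE) {
  structure(list(
    out_dir = out_dir, seed = seed, inputs = inputs, rank = rank,
    K_range = as.integer(K_range), n_iterations = n_iterations,
    resample_fraction = resample_fraction, noise_sd = noise_sd,
    alpha = alpha, k_grid = as.integer(k_grid),
    min_confidence = min_confidence, aggregation = aggregation,
    coords = coords, min_cell_lines = min_cell_lines,
    use_reconstruction = use_reconstruction
  ), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$K_range <- as.integer(x$K_range)
  x$k_grid <- as.integer(x$k_grid)
  x$inputs <- as.list(x$inputs)
  structure(x, class = "run_config")
}

#' Run the analysis pipeline over input files
#'
#' Executes the requested stages in dependency order
#' (phenome -> qtl -> network; signature -> drugscore), reading only the
#' declared input files, and writes every stage's outputs plus a
#' manifest (stage, file role, path, md5, seconds) and the resolved
#' configuration under `config$out_dir`.
#'
#' Recognized `config$inputs` entries:
#' \describe{
#'   \item{phenome}{strains x conditions growth TSV}
#'   \item{genotypes, trait}{segregant genotype TSV; optional trait TSV
#'     (defaults to PC1 of the processed phenome when the row sets
#'     match)}
#'   \item{edges, gene_intervals, loci}{network edge TSV, gene interval
#'     TSV, and one or more locus p-value TSVs (character vector)}
#'   \item{expression}{one or more expression TSVs (named character
#'     vector; names become batch labels)}
#'   \item{human_expression, resistance, orthologs}{cell-line expression
#'     TSV, resistance TSV, optional yeast-to-human ortholog TSV}
#' }
#'
#' @param config A [run_config()].
#' @param stages Stages to run (default: all whose inputs are present).
#' @return List of stage results, with the manifest as `$manifest`.
#' @export
run_pipeline <- function(config,
                         stages = c("phenome", "qtl", "network", "signature", "drugscore")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  ins <- config$inputs
  declared <- unlist(ins, use.names = FALSE)
  missing_in <- declared[!file.exists(declared)]
  if (length(missing_in)) {
    abort(sprintf("Missing input file(s): %s", paste(missing_in, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(config$out_dir, "run_config.json"))

  manifest <- list()
  note <- function(stage, role, path, secs) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, role = role, path = path,
      md5 = unname(tools::md5sum(path)), seconds = round(secs, 3))
  }
  res <- list()
  has <- function(...) all(c(...) %in% names(ins))
  outp <- function(f) file.path(config$out_dir, f)

  processed_phenome <- NULL
  if ("phenome" %in% stages && has("phenome")) {
    t0 <- proc.time()[3]
    m <- read_matrix_tsv(ins$phenome)
    m <- standardize_conditions(impute_knn(filter_missing(m)))
    rec <- svd_reconstruct(m, rank = config$rank)
    base <- if (config$use_reconstruction) rec$values else m
    cc <- consensus_cluster(base, K_range = config$K_range,
                            n_iterations = config$n_iterations,
                            resample_fraction = config$resample_fraction,
                            seed = derive_seed(config$seed, "phenome"))
    corr <- condition_correlation(base)
    cl <- hcluster(1 - corr, K = min(config$K_range))
    processed_phenome <- m
    write_matrix_tsv(rec$values, outp("phenome_reconstructed.tsv"), "strain")
    write_matrix_tsv(corr, outp("condition_correlation.tsv"), "condition")
    readr::write_tsv(cc$pac, outp("pac.tsv"))
    readr::write_tsv(cl, outp("condition_clusters.tsv"))
    for (K in names(cc$consensus)) {
      write_matrix_tsv(cc$consensus[[K]], outp(sprintf("consensus_K%s.tsv", K)), "condition")
    }
    secs <- proc.time()[3] - t0
    note("phenome", "input", ins$phenome, secs)
    for (f in c("phenome_reconstructed.tsv", "condition_correlation.tsv",
                "pac.tsv", "condition_clusters.tsv")) {
      note("phenome", "output", outp(f), secs)
    }
    res$phenome <- list(matrix = m, reconstruction = rec, consensus = cc,
                        correlation = corr, clusters = cl,
                        used_reconstruction = config$use_reconstruction)
  }

  if ("qtl" %in% stages && has("genotypes")) {
    t0 <- proc.time()[3]
    G <- read_matrix_tsv(ins$genotypes)
    trait <- if (has("trait")) {
      tr <- readr::read_tsv(ins$trait, show_col_types = FALSE)
      note_in <- ins$trait
      tr
    } else {
      if (is.null(processed_phenome)) abort("qtl stage needs a trait file or a phenome stage run.")
      note_in <- ins$phenome
      overall_growth_pc1(processed_phenome)
    }
    scan <- lod_scan(G, trait)
    thr <- permutation_threshold(G, trait, alpha = config$alpha,
                                 n_permutations = config$n_iterations,
                                 seed = derive_seed(config$seed, "qtl"))
    scan <- set_scan_threshold(scan, thr)
    readr::write_tsv(scan$scan, outp("lod_scan.tsv"))
    jsonlite::write_json(thr[c("threshold", "alpha", "n_permutations")],
                         outp("lod_threshold.json"), auto_unbox = TRUE, digits = NA)
    secs <- proc.time()[3] - t0
    note("qtl", "input", ins$genotypes, secs)
    note("qtl", "input", note_in, secs)
    note("qtl", "output", outp("lod_scan.tsv"), secs)
    note("qtl", "output", outp("lod_threshold.json"), secs)
    res$qtl <- list(scan = scan, threshold = thr)
  }

  if ("network" %in% stages && has("edges", "gene_intervals", "loci")) {
    t0 <- proc.time()[3]
    edges <- read_edges_tsv(ins$edges)
    gi <- readr::read_tsv(ins$gene_intervals, show_col_types = FALSE, comment = "#")
    per_cond <- lapply(ins$loci, function(f) {
      loci <- readr::read_tsv(f, show_col_types = FALSE, comment = "#")
      gene_pvalue_from_loci(loci, gi, coords = config$coords)
    })
    agg <- aggregate_pvalues(per_cond, method = config$aggregation)
    k_grid <- config$k_grid[config$k_grid <= nrow(agg)]
    ranked <- top_genes(agg, k = max(k_grid))
    curve <- lcc_size_curve(edges, ranked, k_grid,
                            n_iterations = config$n_iterations,
                            min_confidence = config$min_confidence,
                            seed = derive_seed(config$seed, "network"))
    readr::write_tsv(agg, outp("gene_pvalues_aggregated.tsv"))
    readr::write_tsv(ranked, outp("top_genes.tsv"))
    readr::write_tsv(curve, outp("lcc_curve.tsv"))
    secs <- proc.time()[3] - t0
    for (f in c(ins$edges, ins$gene_intervals, unlist(ins$loci))) note("network", "input", f, secs)
    for (f in c("gene_pvalues_aggregated.tsv", "top_genes.tsv", "lcc_curve.tsv")) {
      note("network", "output", outp(f), secs)
    }
    res$network <- list(aggregated = agg, ranked = ranked, curve = curve,
                        aggregation = config$aggregation)
  }

  signature_sets <- NULL
  if ("signature" %in% stages && has("expression")) {
    t0 <- proc.time()[3]
    paths <- ins$expression
    mats <- lapply(paths, read_matrix_tsv)
    names(mats) <- names(paths) %||% paste0("batch_", seq_along(mats))
    prep <- lapply(mats, function(m) scale_samples(impute_knn(filter_missing(m))))
    combined <- if (length(prep) > 1) integrate_datasets(prep) else prep[[1]]
    sig <- robust_signature(combined, n_iterations = config$n_iterations,
                            noise_sd = config$noise_sd,
                            seed = derive_seed(config$seed, "signature"))
    sets <- split_ps_ns(sig)
    readr::write_tsv(tidy(sig), outp("signature.tsv"))
    write_gene_sets(list(PS = sets$ps, NS = sets$ns), outp("ps_ns_sets.tsv"))
    signature_sets <- sets
    secs <- proc.time()[3] - t0
    for (f in paths) note("signature", "input", f, secs)
    note("signature", "output", outp("signature.tsv"), secs)
    note("signature", "output", outp("ps_ns_sets.tsv"), secs)
    res$signature <- list(signature = sig, sets = sets)
  }

  if ("drugscore" %in% stages && has("human_expression", "resistance")) {
    t0 <- proc.time()[3]
    expr <- read_matrix_tsv(ins$human_expression)
    resm <- read_matrix_tsv(ins$resistance)
    sets <- if (has("sets")) {
      gs <- read_gene_sets(ins$sets)
      list(ps = gs$PS, ns = gs$NS)
    } else signature_sets
    if (is.null(sets)) abort("drugscore stage needs a `sets` input or a signature stage run.")
    if (has("orthologs")) {
      om <- readr::read_tsv(ins$orthologs, show_col_types = FALSE)
      sets <- list(ps = map_orthologs(sets$ps, om), ns = map_orthologs(sets$ns, om))
    }
    sc <- score_cell_lines(expr, sets$ps, sets$ns)
    ct <- correlate_with_resistance(sc, resm, min_cell_lines = config$min_cell_lines)
    sm <- summarize_correlations(ct)
    readr::write_tsv(sc, outp("cell_line_scores.tsv"))
    readr::write_tsv(ct, outp("drug_correlations.tsv"))
    readr::write_tsv(sm, outp("drug_correlation_summary.tsv"))
    secs <- proc.time()[3] - t0
    note("drugscore", "input", ins$human_expression, secs)
    note("drugscore", "input", ins$resistance, secs)
    for (f in c("cell_line_scores.tsv", "drug_correlations.tsv",
                "drug_correlation_summary.tsv")) {
      note("drugscore", "output", outp(f), secs)
    }
    res$drugscore <- list(scores = sc, correlations = ct, summary = sm)
  }

  res$manifest <- bind_rows(manifest)
  readr::write_tsv(res$manifest, file.path(config$out_dir, "manifest.tsv"))
  res
}
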