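#' Pipeline configuration
#'
#' A run is driven either by input files (`expression`, `design`,
#' `utr_fasta`, optional `gene_map`) or by a simulation block — exactly one
#' of the two. The simulation block pairs an expression simulator config
#' with per-class UTR G/C targets, so planted helicase-dependent
#' transcripts can be given the G/C-rich UTRs the biology predicts.
#'
#' @param expression,design,utr_fasta,gene_map input file paths (input
#'   mode).
#' @param simulation list with elements `expression` (a [sim_config()])
#'   and optionally `gc_dependent`, `gc_independent`, `gc_null`,
#'   `utr_length_range` (simulation mode). Defaults give dependent
#'   transcripts G/C-rich UTRs (0.65) versus 0.45/0.50 for the others.
#' @param prior a [prior_spec()].
#' @param threshold classification threshold (default 0.2).
#' @param fold_engine folding engine for UTR features.
#' @param seed integer seed for all run randomness.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression = NULL, design = NULL,
                            utr_fasta = NULL, gene_map = NULL,
                            simulation = NULL, prior = prior_spec(),
                            threshold = 0.2, fold_engine = "basepair",
                            seed = 1) {
  input_mode <- !is.null(expression) || !is.null(design) ||
    !is.null(utr_fasta)
  if (input_mode && !is.null(simulation))
    stop_bad_arg("provide input paths or a simulation block, not both")
  if (!input_mode && is.null(simulation))
    stop_bad_arg("provide either input paths or a simulation block")
  if (input_mode && (is.null(expression) || is.null(design)))
    stop_bad_arg("input mode needs at least expression and design paths")
  if (!is.null(simulation)) {
    if (is.null(simulation$expression))
      simulation$expression <- sim_config(seed = seed)
    stopifnot(inherits(simulation$expression, "sim_config"))
    simulation$gc_dependent <- simulation$gc_dependent %||% 0.65
    simulation$gc_independent <- simulation$gc_independent %||% 0.45
    simulation$gc_null <- simulation$gc_null %||% 0.50
    simulation$utr_length_range <- simulation$utr_length_range %||% c(50, 300)
  }
  structure(list(expression = expression, design = design,
                 utr_fasta = utr_fasta, gene_map = gene_map,
                 simulation = simulation, prior = prior,
                 threshold = threshold, fold_engine = fold_engine,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys mirror [pipeline_config()]: `inputs:` (expression,
#' design, utr_fasta, gene_map), `simulation:` (any [sim_config()] field
#' plus gc_dependent / gc_independent / gc_null / utr_length_range),
#' `prior:` (tau_intercept, tau_coef, sigma_scale, prior_complex),
#' `threshold`, `fold_engine`, `seed`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  prior <- do.call(prior_spec, y$prior %||% list())
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    utr_keys <- c("gc_dependent", "gc_independent", "gc_null",
                  "utr_length_range")
    expr_args <- s[setdiff(names(s), utr_keys)]
    if (is.null(expr_args$seed) && !is.null(y$seed))
      expr_args$seed <- y$seed
    sim <- c(list(expression = do.call(sim_config, expr_args)),
             s[intersect(names(s), utr_keys)])
  }
  pipeline_config(expression = y$inputs$expression,
                  design = y$inputs$design,
                  utr_fasta = y$inputs$utr_fasta,
                  gene_map = y$inputs$gene_map,
                  simulation = sim, prior = prior,
                  threshold = y$threshold %||% 0.2,
                  fold_engine = y$fold_engine %||% "basepair",
                  seed = y$seed %||% 1)
}

#' Validate pipeline input files
#'
#' Checks TSV schemas, value sanity (non-negative SDs, finite means),
#' design balance, FASTA alphabet and transcript-id join coverage.
#'
#' @param paths list with `expression`, `design` and optionally
#'   `utr_fasta`, `gene_map` file paths.
#' @return `data.frame` with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when everything is clean.
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  note <- function(level, ...) {
    issues[[length(issues) + 1L]] <<- data.frame(
      level = level, message = paste0(...), stringsAsFactors = FALSE)
  }
  for (p in c("expression", "design")) {
    if (is.null(paths[[p]]) || !file.exists(paths[[p]]))
      note("error", "missing required input file: ", p)
  }
  expr <- design <- NULL
  if (!length(issues)) {
    expr <- tryCatch(read_expression_tsv(paths$expression),
                     error = function(e) {
                       note("error", conditionMessage(e)); NULL })
    design <- tryCatch(read_design_tsv(paths$design),
                       error = function(e) {
                         note("error", conditionMessage(e)); NULL })
  }
  if (!is.null(expr)) {
    bad_sd <- which(!is.finite(expr$sd_log_expr) | expr$sd_log_expr < 0)
    if (length(bad_sd))
      note("error", "negative or non-finite sd_log_expr at row(s) ",
           paste(head(bad_sd, 5), collapse = ", "))
    bad_y <- which(!is.finite(expr$mean_log_expr))
    if (length(bad_y))
      note("error", "non-finite mean_log_expr at row(s) ",
           paste(head(bad_y, 5), collapse = ", "))
  }
  if (!is.null(expr) && !is.null(design)) {
    missing_samp <- setdiff(unique(expr$sample_id), design$sample_id)
    if (length(missing_samp))
      note("error", "expression samples absent from design: ",
           paste(head(missing_samp, 5), collapse = ", "))
    ok <- tryCatch({build_design_dod(design); TRUE},
                   error = function(e) {
                     note("error", "design unusable for DoD comparison: ",
                          conditionMessage(e)); FALSE })
    if (ok) {
      per_tx <- table(expr$transcript_id)
      if (length(unique(per_tx)) != 1L)
        note("error", "transcripts have unequal numbers of samples")
    }
  }
  if (!is.null(paths$utr_fasta)) {
    if (!file.exists(paths$utr_fasta)) {
      note("error", "UTR FASTA not found: ", paths$utr_fasta)
    } else {
      seqs <- tryCatch(read_utr_fasta(paths$utr_fasta),
                       error = function(e) {
                         note("error", "bad UTR FASTA: ",
                              conditionMessage(e)); NULL })
      if (!is.null(seqs) && !is.null(expr)) {
        lost <- setdiff(unique(expr$transcript_id), names(seqs))
        if (length(lost))
          note("warning", length(lost),
               " transcript(s) in expression lack a UTR sequence")
      }
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(level = character(), message = character(),
                  stringsAsFactors = FALSE)
}

simulate_pipeline_inputs <- function(config) {
  sim <- simulate_expression(config$simulation$expression)
  gc_by_class <- c(dependent = config$simulation$gc_dependent,
                   independent = config$simulation$gc_independent,
                   null = config$simulation$gc_null)
  sub_seeds <- derive_substreams(config$seed + 1L, 3L)
  seqs <- character(0)
  for (cl in names(gc_by_class)) {
    ids <- sim$truth$transcript_id[sim$truth$class_true == cl]
    if (!length(ids)) next
    spec <- utr_sim_spec(
      n_sequences = length(ids),
      length_range = config$simulation$utr_length_range,
      gc_target = gc_by_class[[cl]], ids = ids,
      seed = sub_seeds[match(cl, names(gc_by_class))])
    seqs <- c(seqs, simulate_utrs(spec)$sequences)
  }
  seqs <- seqs[sim$truth$transcript_id]
  gene_map <- data.frame(transcript_id = sim$truth$transcript_id,
                         gene_id = sim$truth$transcript_id,
                         stringsAsFactors = FALSE)
  list(expression = sim$expression, design = sim$design, utrs = seqs,
       gene_map = gene_map, truth = sim$truth)
}

#' Run the full translatome analysis pipeline
#'
#' Simulates or loads inputs, runs per-transcript model selection
#' (difference-of-difference), classifies transcripts, collapses to genes,
#' computes 5'UTR features on the longest UTR per gene, and compares the
#' dependent and independent classes. Writes all artifacts plus a JSON
#' manifest to `output_dir`; partial outputs are removed on failure, and a
#' fixed config + seed reproduces byte-identical outputs.
#'
#' Files written: `results.tsv` (per transcript), `genes.tsv` (collapsed),
#' `ranking.rnk`, `features.tsv`, `enrichment.json`, `manifest.json`, and
#' in simulation mode `truth.tsv`, `expression.tsv`, `design.tsv`,
#' `utrs.fasta`.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @param output_dir directory for artifacts (created if needed).
#' @return Invisibly, a list with `results`, `genes`, `features`,
#'   `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(fn, name) {
    path <- file.path(output_dir, name)
    fn(path)
    written <<- c(written, path)
    path
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written))

  if (is.null(config$simulation)) {
    report <- validate_inputs(config[c("expression", "design", "utr_fasta",
                                       "gene_map")])
    for (w in report$message[report$level == "warning"]) warning(w)
    if (any(report$level == "error"))
      stop_bad_arg("input validation failed:\n  ",
                   paste(report$message[report$level == "error"],
                         collapse = "\n  "))
    inputs <- list(expression = read_expression_tsv(config$expression),
                   design = read_design_tsv(config$design),
                   utrs = if (!is.null(config$utr_fasta))
                     read_utr_fasta(config$utr_fasta),
                   gene_map = if (!is.null(config$gene_map))
                     read_gene_map(config$gene_map),
                   truth = NULL)
  } else {
    inputs <- simulate_pipeline_inputs(config)
    emit(function(p) write_tsv(inputs$expression, p), "expression.tsv")
    emit(function(p) write_tsv(inputs$design, p), "design.tsv")
    emit(function(p) write_tsv(inputs$truth, p), "truth.tsv")
    emit(function(p) write_utr_fasta(inputs$utrs, p), "utrs.fasta")
  }
  if (is.null(inputs$gene_map))
    inputs$gene_map <- data.frame(
      transcript_id = unique(inputs$expression$transcript_id),
      gene_id = unique(inputs$expression$transcript_id),
      stringsAsFactors = FALSE)

  results <- run_model_selection(inputs$expression, inputs$design,
                                 prior = config$prior,
                                 threshold = config$threshold)
  genes <- collapse_to_gene(results, inputs$gene_map)
  emit(function(p) write_tsv(results, p), "results.tsv")
  emit(function(p) write_tsv(genes, p), "genes.tsv")
  emit(function(p) write_rnk(genes$gene_id, genes$rank_score, p),
       "ranking.rnk")

  features <- enrichment <- NULL
  if (!is.null(inputs$utrs)) {
    kept <- longest_utr_per_gene(inputs$utrs, inputs$gene_map)
    features <- utr_features(kept, engine = config$fold_engine)
    gene_of <- attr(kept, "gene_map")
    feat_class <- genes$class[match(
      gene_of$gene_id[match(features$utr_id, gene_of$transcript_id)],
      genes$gene_id)]
    emit(function(p) write_tsv(features, p), "features.tsv")
    if (sum(feat_class == "dependent", na.rm = TRUE) > 0 &&
        sum(feat_class == "independent", na.rm = TRUE) > 0) {
      enrichment <- enrichment_report(features, feat_class)
      emit(function(p) jsonlite::write_json(enrichment, p,
                                            auto_unbox = TRUE,
                                            digits = NA, pretty = TRUE),
           "enrichment.json")
    }
  }

  counts <- table(factor(results$class,
                         c("dependent", "independent", "unclassified")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("translatome")),
    seed = config$seed,
    threshold = config$threshold,
    prior = unclass(config$prior),
    fold_engine = if (is.function(config$fold_engine)) "custom"
                  else config$fold_engine,
    mode = if (is.null(config$simulation)) "input" else "simulation",
    n_transcripts = nrow(results),
    n_genes = nrow(genes),
    counts = as.list(counts),
    files = basename(written))
  emit(function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE,
                                        digits = NA, pretty = TRUE),
       "manifest.json")
  ok <- TRUE
  invisible(list(results = results, genes = genes, features = features,
                 enrichment = enrichment, manifest = manifest))
}
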