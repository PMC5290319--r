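#' Run the full analysis pipeline and write its artifacts
#'
#' Loads the count tables, applies the sample coverage filter, estimates or
#' loads purities, computes presence posteriors, builds and solves the
#' conflict graph, assigns variants, infers the tree, classifies putative
#' artifacts against the binary baseline, bootstraps branch support and
#' (optionally) detects subclones. Writes into `out_dir`:
#' `tree.nwk` (Newick with bootstrap labels), `branch_variants.tsv`,
#' `artifacts.tsv`, `binary_classification.tsv`, `presence.tsv`,
#' `conflict_graph.tsv` and `summary.json`. With fixed inputs and seed the
#' JSON summary is byte-identical across runs.
#'
#' @param mut_reads,coverage Paths to the paired count TSVs, or a prebuilt
#'   [variant_call_matrix()] as `mut_reads` (then `coverage` is ignored).
#' @param purity Optional purity TSV path or named vector.
#' @param out_dir Output directory (created if needed).
#' @param config A [patient_config()].
#' @param subclones Run subclone detection (conservative default `FALSE`).
#' @param patient_id Optional patient identifier.
#' @return Invisibly, a list with all intermediate objects and the summary.
#' @export
run_analysis <- function(mut_reads, coverage = NULL, purity = NULL,
                         out_dir = ".", config = patient_config(),
                         subclones = FALSE, patient_id = NULL) {
  x <- if (inherits(mut_reads, "variant_call_matrix")) mut_reads
  else read_count_tables(mut_reads, coverage, purity = purity,
                         patient_id = patient_id %||% NULL)
  if (!is.null(patient_id)) x$patient_id <- patient_id
  x <- filter_samples(x, config)
  purity_est <- estimate_purity(x, config)
  x$purity <- purity_est

  table <- presence_table(x, config)
  graph <- build_conflict_graph(table)
  solution <- solve_min_vertex_cover(graph)
  assignments <- assign_variants(solution, table)
  baseline <- binary_classification(x, config)
  artifacts <- classify_artifacts(assignments, baseline, x, table, config)
  n_incomp <- count_incompatible_variants(baseline)
  tree <- bootstrap_support(x, config, table = table,
                            reps = config$bootstrap_reps)
  sc <- NULL
  if (subclones)
    sc <- detect_subclones(graph, solution, table, config)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_newick(tree, fp("tree.nwk"))
  write_presence_table(table, fp("presence.tsv"))
  write_binary_classification(baseline, fp("binary_classification.tsv"))
  write_conflict_graph(graph, fp("conflict_graph.tsv"))
  utils::write.table(artifacts$cells, fp("artifacts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bv <- data.frame(
    branch = rep(names(tree$variants_by_branch),
                 lengths(tree$variants_by_branch)),
    variant = unlist(tree$variants_by_branch, use.names = FALSE))
  utils::write.table(bv, fp("branch_variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  summary <- list(
    patient = x$patient_id,
    n_samples = length(x$samples),
    n_variants = nrow(x$mut_reads),
    purity = as.list(round(purity_est, 4L)),
    config = config[c("c0", "e", "f_absent", "p_fpr", "fdr",
                      "min_median_coverage", "bootstrap_reps", "rng_seed",
                      "error_channel")],
    objective = solution$objective,
    proven_optimal = solution$proven_optimal,
    kept_patterns = mask_bitstring(solution$kept, length(x$samples)),
    incompatible_variants_binary = as.integer(n_incomp),
    artifact_counts = as.list(artifacts$counts),
    dropped_variants = tree$dropped_variants,
    newick = to_newick(tree),
    subclones = if (!is.null(sc)) lapply(sc$splits, identity) else NULL)
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = 8L, null = "null", pretty = TRUE)
  invisible(list(matrix = x, table = table, graph = graph,
                 solution = solution, assignments = assignments,
                 baseline = baseline, artifacts = artifacts, tree = tree,
                 subclones = sc, summary = summary,
                 incompatible_binary = n_incomp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `run` (full analysis), `simulate` (write a simulated count
#' table pair plus ground-truth JSON), `benchmark` (scenario grid to a tidy
#' TSV). See `inst/cli/metaphylo.R`, installed next to the package, for the
#' launcher; flags mirror the pipeline filters (`--fpr`, `--fdr`,
#' `--f-absent`, `--min-median-coverage`, `--boot`, `--subclones`,
#' `--seed`).
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: metaphylo <run|simulate|benchmark> [options]")
    return(invisible(1L))
  }
  cmd <- args[1L]; rest <- args[-1L]
  opt <- parse_cli_opts(rest)
  status <- 0L
  tryCatch({
    if (cmd == "run") {
      cfg <- patient_config(
        p_fpr = opt$fpr %||% 0.005, fdr = opt$fdr %||% 0.05,
        f_absent = opt$`f-absent` %||% 0.05,
        min_median_coverage = opt$`min-median-coverage` %||% 0,
        bootstrap_reps = opt$boot %||% 1000L,
        rng_seed = opt$seed %||% 1L)
      run_analysis(opt$`mut-reads`, opt$coverage, purity = opt$purity,
                   out_dir = opt$out %||% ".", config = cfg,
                   subclones = isTRUE(opt$subclones))
    } else if (cmd == "simulate") {
      sp <- sim_params(mean_depth = opt$depth %||% 400,
                       purity = opt$purity_frac %||% opt$purity %||% 0.75,
                       m_mets = opt$mets %||% 6L,
                       rng_seed = opt$seed %||% 1L)
      tumor <- simulate_tumor(sp)
      seqd <- sequence_samples(tumor, sp)
      out <- opt$out %||% "."
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_count_tables(seqd$matrix,
                         file.path(out, "sim_mut_reads.tsv"),
                         file.path(out, "sim_coverage.tsv"),
                         file.path(out, "sim_purity.tsv"))
      jsonlite::write_json(
        list(clades = seqd$truth$clades,
             seeding_times = seqd$truth$seeding_times,
             clonal = seqd$truth$clonal,
             A = seqd$truth$A),
        file.path(out, "sim_truth.json"), auto_unbox = TRUE, digits = 8L)
    } else if (cmd == "benchmark") {
      res <- run_benchmark(
        depths = opt$depths %||% c(25, 400),
        purities = opt$purities %||% c(0.15, 0.55, 0.95),
        replicates = opt$replicates %||% 5L,
        seed = opt$seed %||% 1L)
      utils::write.table(res, opt$out %||% "benchmark.tsv", sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else {
      message("unknown subcommand: ", cmd)
      status <- 1L
    }
  }, error = function(e) {
    message("error [", cmd, "]: ", conditionMessage(e))
    status <<- 1L
  })
  invisible(status)
}

parse_cli_opts <- function(args) {
  opt <- list()
  # --config file: key=value lines, overridden by explicit flags
  ci <- which(args == "--config")
  if (length(ci)) {
    lines <- readLines(args[ci[1L] + 1L], warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(trimws(lines), "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) next
      val <- trimws(kv[2L])
      num <- suppressWarnings(as.numeric(val))
      opt[[trimws(kv[1L])]] <- if (is.na(num)) val else num
    }
    args <- args[-c(ci[1L], ci[1L] + 1L)]
  }
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opt[[key]] <- TRUE
      i <- i + 1L
    } else {
      val <- args[i + 1L]
      vals <- strsplit(val, ",", fixed = TRUE)[[1L]]
      num <- suppressWarnings(as.numeric(vals))
      opt[[key]] <- if (anyNA(num)) val else
        if (length(num) > 1L) num else num
      if (key %in% c("depths", "purities")) opt[[key]] <- num
      i <- i + 2L
    }
  }
  opt
}
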