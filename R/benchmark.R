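#' Branching error of a reconstructed sample tree
#'
#' Fraction of the true coalescent events (non-root clades of the true
#' sample tree) that are missing from the reconstruction.
#'
#' @param true_tree True tree: a `seeding_tree`, `ape::phylo`, or list of
#'   clades (character vectors of sample names).
#' @param inferred_tree Reconstruction, same accepted forms.
#' @param leaves Optional character vector of the common leaf set; if
#'   supplied, both clade sets are checked against it.
#' @return Fraction in `[0, 1]`; `NA` when the true tree has no non-root
#'   clade.
#' @examples
#' branching_error(list(c("M1", "M2"), c("M3", "M4")),
#'                 list(c("M1", "M2")))  # 0.5
#' @export
branching_error <- function(true_tree, inferred_tree, leaves = NULL) {
  tc <- tree_clades(true_tree)
  ic <- tree_clades(inferred_tree)
  if (!is.null(leaves)) {
    all_l <- unique(unlist(c(tc, ic)))
    if (!all(all_l %in% leaves))
      stop("clades mention samples outside the stated leaf set: ",
           paste(setdiff(all_l, leaves), collapse = ", "))
  }
  if (!length(tc)) return(NA_real_)
  key <- function(cl) vapply(cl, paste, character(1L), collapse = "\r")
  mean(!(key(tc) %in% key(ic)))
}

#' Mutation matrix error score
#'
#' Normalized disagreement between the true parental matrix `A` (1 =
#' parental, 0.5 = same branch, 0 = otherwise) and a reconstruction
#' `A_hat` over the same mutation set:
#' `sum_{i != j} |A_hat[i,j] - A[i,j]| / (k (k - 1))`.
#' `NA` entries of `A_hat` (pairs about which the method provided no
#' information) are filled with `A[i,j] - 0.5`, so an uninformative method
#' scores exactly 0.5.
#'
#' @param true_A True `k x k` matrix.
#' @param inferred_A Reconstructed matrix; may contain `NA` and fractional
#'   values in `[0, 1]`.
#' @return The error score in `[0, 1]`; 0 for `k < 2`.
#' @export
mutation_matrix_error <- function(true_A, inferred_A) {
  if (!identical(dim(true_A), dim(inferred_A)))
    stop("matrix shapes differ")
  k <- nrow(true_A)
  if (k < 2L) return(0)
  fill <- is.na(inferred_A)
  inferred_A[fill] <- true_A[fill] - 0.5
  off <- row(true_A) != col(true_A)
  sum(abs(inferred_A[off] - true_A[off])) / (k * (k - 1))
}

#' Reconstructed parental matrix from pattern assignments
#'
#' Builds the analogue of [true_mutation_matrix()] from the inferred
#' per-variant pattern assignments: 1 when the assigned sample set of `i`
#' strictly contains `j`'s, 0.5 for identical sets, 0 otherwise. Mutations
#' in `mutation_ids` that the method did not place (undetected, or assigned
#' to the empty pattern) yield `NA` rows/columns, to be filled by
#' [mutation_matrix_error()]'s no-information rule.
#'
#' @param assignments Output of [assign_variants()] (named by variant id).
#' @param mutation_ids Character vector: the mutation set of the true matrix.
#' @return Numeric matrix with `NA` for no-information pairs.
#' @export
inferred_mutation_matrix <- function(assignments, mutation_ids) {
  k <- length(mutation_ids)
  A <- matrix(NA_real_, k, k, dimnames = list(mutation_ids, mutation_ids))
  masks <- assignments[match(mutation_ids, names(assignments))]
  known <- !is.na(masks) & masks != 0L
  for (i in which(known)) for (j in which(known)) {
    if (i == j) next
    ui <- masks[i]; uj <- masks[j]
    A[i, j] <- if (ui == uj) 0.5
    else if (bitwAnd(ui, uj) == uj && bitwAnd(uj, bitwNot(ui)) == 0L) 1
    else 0
  }
  A
}

#' Neighbour-joining baseline tree
#'
#' Classical baseline: threshold the Bayesian presence posteriors at
#' `p > 0.5` into binary profiles, compute pairwise Hamming distances
#' between samples, run neighbour joining, and root at an added all-zero
#' germline profile.
#'
#' @param table A [presence_table()] (at least 3 samples).
#' @return A rooted `ape::phylo` over the samples (germline tip removed).
#' @export
neighbour_joining_baseline <- function(table) {
  n <- ncol(table$p)
  if (n < 3L) stop("neighbour joining needs at least 3 samples")
  prof <- rbind(t(table$p > 0.5) * 1L, germline = 0L)
  rownames(prof) <- c(gsub("[ \t():,;]", "_", table$samples), "germline")
  D <- as.matrix(stats::dist(prof, method = "manhattan"))
  tr <- ape::nj(as.dist(D))
  tr <- ape::root(tr, outgroup = "germline", resolve.root = TRUE)
  tr <- ape::drop.tip(tr, "germline")
  orig <- stats::setNames(table$samples, gsub("[ \t():,;]", "_", table$samples))
  tr$tip.label <- unname(orig[tr$tip.label])
  tr
}

#' One-call phylogeny inference from a count matrix
#'
#' Convenience wrapper running posteriors, conflict graph, exact cover,
#' variant assignment and tree construction.
#'
#' @param x A [variant_call_matrix()].
#' @param config A [patient_config()].
#' @return List with `table`, `graph`, `solution`, `assignments`, `tree`.
#' @export
infer_tree <- function(x, config = patient_config()) {
  table <- presence_table(x, config)
  graph <- build_conflict_graph(table)
  solution <- solve_min_vertex_cover(graph)
  assignments <- assign_variants(solution, table)
  tree <- build_tree(assignments)
  list(table = table, graph = graph, solution = solution,
       assignments = assignments, tree = tree)
}

#' Benchmark one simulated phylogeny
#'
#' Simulates a tumour, sequences it, reconstructs with the Bayesian
#' pipeline and with the neighbour-joining baseline, and scores both
#' against the ground truth.
#'
#' @param params A [sim_params()].
#' @return One-row data frame: scenario descriptors, the branching error of
#'   both methods, the mutation matrix error of the Bayesian pipeline, the
#'   number of detected variants, and whether every true branch carried at
#'   least one detected variant (`covered`, the paper-style conditioning).
#' @export
benchmark_replicate <- function(params) {
  tumor <- simulate_tumor(params)
  seqd <- sequence_samples(tumor, params)
  truth <- seqd$truth
  fit <- infer_tree(seqd$matrix, patient_config(e = params$e_seq))
  nj <- neighbour_joining_baseline(fit$table)

  be <- branching_error(truth$clades, fit$tree)
  be_nj <- branching_error(truth$clades, nj)
  Ahat <- inferred_mutation_matrix(fit$assignments, rownames(truth$A))
  mme <- mutation_matrix_error(truth$A, Ahat)

  # conditioning: every true clade must have >= 1 detected variant with
  # exactly that clonal pattern
  det_clonal <- truth$clonal[truth$detected, , drop = FALSE]
  pat_key <- apply(det_clonal, 1L, function(rw) {
    paste(sort(colnames(det_clonal)[rw]), collapse = "\r")
  })
  clade_key <- vapply(truth$clades, paste, character(1L), collapse = "\r")
  covered <- all(clade_key %in% pat_key)

  data.frame(mean_depth = params$mean_depth, purity = params$purity,
             m_mets = params$m_mets,
             polyphyletic = params$polyphyletic_count,
             seed = params$rng_seed,
             n_variants = nrow(seqd$matrix$mut_reads),
             branching_error = be, branching_error_nj = be_nj,
             matrix_error = mme, covered = covered)
}

#' Benchmark grid over depths and purities
#'
#' @param depths,purities Scenario grid (defaults: a scaled-down version of
#'   the full 25-800x / 15-95% grid).
#' @param replicates Seeded replicates per scenario cell.
#' @param seed Base seed; replicate `k` of cell `c` uses a distinct seed
#'   derived from it.
#' @param ... Further arguments to [sim_params()].
#' @return Tidy data frame of [benchmark_replicate()] rows.
#' @export
run_benchmark <- function(depths = c(25, 400), purities = c(0.15, 0.55, 0.95),
                          replicates = 10L, seed = 1L, ...) {
  grid <- expand.grid(depth = depths, purity = purities)
  out <- vector("list", nrow(grid) * replicates)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    for (rep in seq_len(replicates)) {
      k <- k + 1L
      sp <- sim_params(mean_depth = grid$depth[g], purity = grid$purity[g],
                       rng_seed = (seed * 1000L + g * 100L + rep) %% 2147483647L,
                       ...)
      out[[k]] <- benchmark_replicate(sp)
    }
  }
  do.call(rbind, out)
}
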