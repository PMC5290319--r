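popcount <- function(mask) {
  vapply(mask, function(mk) sum(pattern_vector(mk, 30L)), integer(1L))
}

mask_bitstring <- function(mask, n) {
  vapply(mask, function(mk) paste(pattern_vector(mk, n), collapse = ""),
         character(1L))
}

#' Build the unique perfect-and-persistent phylogeny from compatible patterns
#'
#' Given the per-variant pattern assignments (a pairwise compatible, i.e.
#' laminar, pattern family), constructs the unique rooted tree whose
#' internal branches are the distinct non-empty patterns ordered by
#' containment. The founder (all-samples) pattern forms the trunk, singleton
#' patterns form the leaf branches, and every sample's root-to-leaf path
#' collects exactly its assigned variants. Variants assigned to the empty
#' pattern are reported separately (putative false-positive set), not placed
#' on the tree.
#'
#' @param assignments Named integer vector of pattern bitmasks as returned
#'   by [assign_variants()] (attributes `n` and `samples`), or a plain
#'   vector with `samples` supplied.
#' @param samples Character vector of sample names (overrides the
#'   attribute).
#' @return An object of class `seeding_tree`: list with `samples`,
#'   `branches` (data frame: mask, bitstring, size, parent mask, number of
#'   variants, support), `variants_by_branch`, and `dropped_variants`.
#' @export
build_tree <- function(assignments, samples = attr(assignments, "samples")) {
  if (is.null(samples)) stop("sample names are required")
  n <- length(samples)
  masks <- as.integer(assignments)
  vnames <- names(assignments)
  if (is.null(vnames)) vnames <- paste0("v", seq_along(masks))
  dropped <- vnames[masks == 0L]
  masks_on <- masks[masks != 0L]
  vnames_on <- vnames[masks != 0L]

  full <- as.integer(2^n - 1)
  branch_masks <- sort(unique(c(full, as.integer(2^(seq_len(n) - 1L)),
                                masks_on)))
  # laminarity check
  bm <- branch_masks
  for (i in seq_along(bm)) for (j in seq_len(i - 1L)) {
    if (incompatible(bm[i], bm[j], n = n))
      stop(sprintf("incompatible input patterns %s and %s",
                   mask_bitstring(bm[i], n), mask_bitstring(bm[j], n)))
  }
  sizes <- popcount(bm)
  ord <- order(sizes, decreasing = TRUE)
  bm <- bm[ord]; sizes <- sizes[ord]
  parent <- rep(NA_integer_, length(bm))
  for (i in seq_along(bm)) {
    if (bm[i] == full) next
    sup <- which(sizes > sizes[i] &
                   bitwAnd(bm, bm[i]) == bm[i])
    if (length(sup)) parent[i] <- bm[sup[which.min(sizes[sup])]]
  }
  nv <- vapply(bm, function(mk) sum(masks_on == mk), integer(1L))
  vb <- lapply(bm, function(mk) vnames_on[masks_on == mk])
  names(vb) <- mask_bitstring(bm, n)
  branches <- data.frame(mask = bm, bitstring = mask_bitstring(bm, n),
                         size = sizes, parent = parent, n_variants = nv,
                         support = NA_real_, stringsAsFactors = FALSE)
  structure(list(samples = samples, branches = branches,
                 variants_by_branch = vb, dropped_variants = dropped),
            class = "seeding_tree")
}

#' @export
print.seeding_tree <- function(x, ...) {
  cat(sprintf("seeding_tree: %d samples, %d branches, %d variants placed\n",
              length(x$samples), nrow(x$branches), sum(x$branches$n_variants)))
  cat(to_newick(x), "\n")
  invisible(x)
}

#' Clades (internal sample subsets) of a tree
#'
#' Returns the non-trivial clades — sample subsets of internal branches with
#' at least two and fewer than all samples. The root clade (all samples) is
#' excluded as it is trivially present in any rooted tree.
#'
#' @param tree A `seeding_tree`, an `ape::phylo`, or a list of character
#'   vectors of sample names.
#' @return List of sorted character vectors of sample names.
#' @export
tree_clades <- function(tree) {
  if (inherits(tree, "seeding_tree")) {
    n <- length(tree$samples)
    keep <- tree$branches$size >= 2L & tree$branches$size < n
    cl <- lapply(tree$branches$mask[keep], function(mk) {
      sort(tree$samples[pattern_vector(mk, n) == 1L])
    })
  } else if (inherits(tree, "phylo")) {
    pp <- ape::prop.part(tree)
    labs <- attr(pp, "labels")
    cl <- lapply(pp, function(idx) sort(labs[idx]))
    cl <- cl[vapply(cl, length, integer(1L)) < length(labs)]
    cl <- cl[vapply(cl, length, integer(1L)) >= 2L]
  } else {
    cl <- lapply(tree, function(s) sort(as.character(s)))
  }
  unique(cl)
}

#' Newick serialization of a seeding tree
#'
#' Internal node labels carry the bootstrap support (when available);
#' branch lengths are the number of variants acquired on the branch. Spaces
#' in sample names become underscores. The root edge is the trunk (founder
#' pattern).
#'
#' @param tree A `seeding_tree`.
#' @param digits Digits for support labels.
#' @return A Newick string.
#' @export
to_newick <- function(tree, digits = 2L) {
  n <- length(tree$samples)
  b <- tree$branches
  full <- as.integer(2^n - 1)
  safe <- gsub("[ \t():,;]", "_", tree$samples)
  rec <- function(mask) {
    i <- match(mask, b$mask)
    kids <- b$mask[!is.na(b$parent) & b$parent == mask]
    len <- b$n_variants[i]
    if (b$size[i] == 1L) {
      s <- which(pattern_vector(mask, n) == 1L)
      return(sprintf("%s:%d", safe[s], len))
    }
    sub <- paste(vapply(kids, rec, character(1L)), collapse = ",")
    lab <- if (is.na(b$support[i])) "" else
      formatC(b$support[i], digits = digits, format = "f")
    sprintf("(%s)%s:%d", sub, lab, len)
  }
  paste0(rec(full), ";")
}

#' @rdname to_newick
#' @param path Output file path.
#' @return `write_newick` invisibly returns `path`.
#' @export
write_newick <- function(tree, path, digits = 2L) {
  writeLines(to_newick(tree, digits), path)
  invisible(path)
}

#' Convert a seeding tree to an ape phylo object
#'
#' @param tree A `seeding_tree`.
#' @return An `ape::phylo`.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = to_newick(tree))
}

#' Compare Bayesian pattern assignments to the binary baseline
#'
#' Each (variant, sample) cell is concordant if the conventional binary
#' classification agrees with the presence state of the variant's assigned
#' evolutionarily compatible pattern. Discordant cells are putative
#' sequencing artifacts: a putative false-positive when the baseline calls
#' the variant present but the pattern says absent, and a putative
#' false-negative in the opposite case. False-negatives are split by
#' detection power: the probability that a clonal variant (true VAF
#' `gamma_s/2`) would reach the baseline's realized rejection threshold,
#' `P(X >= K*)` with `X ~ Binomial(N, theta(gamma_s/2))`; below 50% the cell
#' is an under-powered false-negative, otherwise well-powered.
#'
#' @param assignments Output of [assign_variants()].
#' @param baseline Logical presence matrix from [binary_classification()]
#'   (carries the realized BH cutoff as attribute).
#' @param x The [variant_call_matrix()].
#' @param table The [presence_table()] (for purities).
#' @param config A [patient_config()].
#' @return An object of class `artifact_report`: list with `cells` (data
#'   frame of discordant cells), `classification` (full character matrix)
#'   and `counts`.
#' @export
classify_artifacts <- function(assignments, baseline, x, table,
                               config = patient_config()) {
  n <- ncol(x$mut_reads); m <- nrow(x$mut_reads)
  pat <- t(vapply(as.integer(assignments), pattern_vector,
                  integer(n), n = n)) == 1L
  cutoff <- attr(baseline, "cutoff")
  if (is.null(cutoff)) cutoff <- config$fdr
  gamma <- table$purity
  theta <- theta_channel(gamma / 2, config$e, config$error_channel)
  cls <- matrix("concordant", m, n, dimnames = dimnames(x$mut_reads))
  fp <- baseline & !pat
  fn <- !baseline & pat
  cls[fp] <- "putative false-positive"
  if (any(fn)) {
    idx <- which(fn, arr.ind = TRUE)
    N <- x$coverage[fn]
    th <- theta[idx[, 2L]]
    kstar <- stats::qbinom(1 - cutoff, N, config$p_fpr) + 1
    power <- stats::pbinom(kstar - 1, N, th, lower.tail = FALSE)
    cls[fn] <- ifelse(power < 0.5, "under-powered false-negative",
                      "well-powered false-negative")
  }
  disc <- which(cls != "concordant", arr.ind = TRUE)
  cells <- data.frame(
    variant = rownames(cls)[disc[, 1L]],
    sample = colnames(cls)[disc[, 2L]],
    class = cls[disc],
    mut_reads = x$mut_reads[disc],
    coverage = x$coverage[disc],
    stringsAsFactors = FALSE)
  counts <- c(table(factor(cls, levels = c(
    "concordant", "putative false-positive",
    "under-powered false-negative", "well-powered false-negative"))))
  structure(list(cells = cells, classification = cls, counts = counts,
                 cutoff = cutoff),
            class = "artifact_report")
}

#' @export
print.artifact_report <- function(x, ...) {
  total <- sum(x$counts) - x$counts[["concordant"]]
  cat(sprintf("artifact_report: %d putative artifacts of %d cells\n",
              total, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Bootstrap support for the inferred branches
#'
#' Variants are resampled with replacement `reps` times; for each replicate
#' the presence posteriors of the drawn variants are pushed through the
#' conflict graph, the exact cover solver and the variant assignment, and a
#' branch of the original tree is counted as recovered when the replicate's
#' assigned patterns contain the same sample subset. Purity is held fixed
#' across replicates. Seeded via `config$rng_seed`.
#'
#' @param x A [variant_call_matrix()].
#' @param config A [patient_config()].
#' @param table Optional precomputed [presence_table()].
#' @param reps Number of replicates (defaults to `config$bootstrap_reps`).
#' @return The original `seeding_tree` with the `support` column filled
#'   (fraction of replicates containing each internal branch).
#' @export
bootstrap_support <- function(x, config = patient_config(), table = NULL,
                              reps = config$bootstrap_reps) {
  if (is.null(table)) table <- presence_table(x, config)
  graph <- build_conflict_graph(table)
  sol <- solve_min_vertex_cover(graph)
  asg <- assign_variants(sol, table)
  tree <- build_tree(asg)
  if (reps < 1L) return(tree)
  m <- nrow(table$p)
  L <- graph$L
  cap <- 1 - 1e-12
  logs <- log1p(-pmin(L, cap))
  withr_seed <- config$rng_seed
  set.seed(withr_seed)
  hit <- stats::setNames(numeric(nrow(tree$branches)), tree$branches$mask)
  for (b in seq_len(reps)) {
    idx <- sample.int(m, m, replace = TRUE)
    w <- -colMeans(logs[idx, , drop = FALSE])
    solb <- .laminar_cover_dp(w, graph$n)
    keptb <- as.integer(solb$kept)
    Lb <- L[idx, keptb + 1L, drop = FALSE]
    pick <- keptb[max.col(Lb, ties.method = "first")]
    present <- unique(pick[pick != 0L])
    hit <- hit + as.numeric(tree$branches$mask %in%
                              c(present, as.integer(2^graph$n - 1)))
  }
  tree$branches$support <- unname(hit / reps)
  # leaf branches and the trunk are structural, not inferential
  attr(tree, "bootstrap_reps") <- reps
  tree
}
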