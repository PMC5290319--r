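#' Detect polyphyletic samples and split them into subclones
#'
#' Evolutionarily incompatible mutation patterns whose reliability score is
#' higher than expected from noise indicate that a sample hosts subclones
#' with distinct evolutionary trajectories (polyclonal seeding or
#' reseeding). The noise threshold is the 95th percentile of removed-pattern
#' scores under a permutation null: each variant's per-sample presence
#' probabilities are shuffled across samples, the conflict graph is rebuilt
#' and re-solved, and the removed-pattern scores are pooled over `n_perm`
#' permutations.
#'
#' Removed patterns are visited in decreasing reliability. A removed
#' pattern `v` above the threshold that conflicts with a kept pattern `u`
#' is re-examined at the variant level: in every sample carried by both
#' patterns where each side has at least one supporting variant (maximum-
#' likelihood pattern equal to `v` resp. `u`) confidently present
#' (posterior `p > config$subclone_prob`), the two sides cannot descend
#' from one lineage, so the sample is split into two pseudo-samples
#' ("<sample> SC 1" for the kept side, "SC 2" for the conflicting side) and
#' `v` is re-homed to the second pseudo-sample. Supersets (ancestors) and
#' subsets (descendants) of `v` keep their containment relations through
#' the split. At most two subclones per sample and `max_iter` sweeps. This
#' is an admissible reconstruction of an algorithm whose detailed
#' pseudo-code is not public (see the methods vignette).
#'
#' @param graph A `conflict_graph` (full enumeration).
#' @param solution The [solve_min_vertex_cover()] solution for `graph`.
#' @param table The [presence_table()].
#' @param config A [patient_config()].
#' @param n_perm Permutations for the null distribution.
#' @param max_iter Maximal split sweeps.
#' @return An object of class `subclone_split`: list with `splits` (named
#'   list: sample -> pseudo-sample names), `split_of` (per-sample split
#'   flag), `patterns` (augmented 0/1 pattern matrix over pseudo-samples:
#'   kept patterns plus the rescued conflicting patterns), `threshold`, and
#'   `unresolved` (high-score removed patterns that could not be rescued).
#' @export
detect_subclones <- function(graph, solution, table,
                             config = patient_config(), n_perm = 100L,
                             max_iter = 5L) {
  stopifnot(inherits(graph, "conflict_graph"), graph$full_enumeration)
  n <- graph$n
  threshold <- subclone_noise_threshold(table, config, n_perm)

  rw <- solution$weights[as.character(solution$removed)]
  ord <- order(rw, decreasing = TRUE)
  removed <- solution$removed[ord]
  rw <- unname(rw[ord])
  kept <- solution$kept

  # variant-level support: each variant's ML pattern over all patterns
  ml <- graph$nodes[max.col(graph$L, ties.method = "first")]
  supporters <- function(mask) which(ml == mask)

  split_of <- stats::setNames(rep(FALSE, n), table$samples)
  side2 <- integer(0L)      # patterns re-homed to the "SC 2" side
  unresolved <- integer(0L)

  for (it in seq_len(max_iter)) {
    progressed <- FALSE
    for (ri in seq_along(removed)) {
      v <- removed[ri]
      if (rw[ri] <= threshold) break
      if (v %in% side2) next
      sv <- supporters(v)
      if (!length(sv)) next
      conflictors <- kept[vapply(kept, incompatible, logical(1L),
                                 v = v, n = n)]
      rescued <- FALSE
      for (u in conflictors) {
        shared <- which(pattern_vector(bitwAnd(u, v), n) == 1L)
        shared <- shared[!split_of[shared]]
        if (!length(shared)) { rescued <- TRUE; next }
        su <- supporters(u)
        ok <- vapply(shared, function(s) {
          length(su) > 0L &&
            max(table$p[sv, s]) > config$subclone_prob &&
            max(table$p[su, s]) > config$subclone_prob
        }, logical(1L))
        if (all(ok)) {
          split_of[shared] <- TRUE
          rescued <- TRUE
          progressed <- TRUE
        }
      }
      if (rescued) side2 <- union(side2, v)
      else unresolved <- union(unresolved, v)
    }
    if (!progressed) break
  }

  pseudo <- lapply(seq_len(n), function(s) {
    if (split_of[s]) paste(table$samples[s], "SC", 1:2) else table$samples[s]
  })
  names(pseudo) <- table$samples
  patterns <- augmented_patterns(kept, side2, split_of, pseudo, n)
  # sanity: the augmented family must be pairwise compatible
  for (a in seq_len(nrow(patterns))) for (b in seq_len(a - 1L)) {
    if (incompatible(patterns[a, ], patterns[b, ])) {
      unresolved <- union(unresolved, side2)
      break
    }
  }
  high <- removed[rw > threshold]
  structure(list(splits = pseudo[split_of], split_of = split_of,
                 patterns = patterns, threshold = threshold,
                 unresolved = setdiff(unresolved, side2),
                 rescued = side2),
            class = "subclone_split")
}

# Expand patterns over pseudo-samples.  In a split sample the rescued
# conflicting pattern occupies "SC 2" and a kept pattern occupies "SC 1" —
# unless it is an ancestor (superset) of a rescued pattern, in which case
# both subclone lineages carry it, or a descendant (subset), which belongs
# to the rescued lineage ("SC 2").
augmented_patterns <- function(kept, rescued, split_of, pseudo, n) {
  cols <- unlist(pseudo, use.names = FALSE)
  is_superset <- function(w, r) bitwAnd(w, r) == r
  is_subset <- function(w, r) bitwAnd(w, r) == w
  expand <- function(mask, side) {
    bits <- pattern_vector(mask, n)
    if (side == 1L && length(rescued)) {
      anc <- any(vapply(rescued, is_superset, logical(1L), w = mask))
      des <- !anc && any(vapply(rescued, is_subset, logical(1L), w = mask))
    } else anc <- des <- FALSE
    out <- unlist(lapply(seq_len(n), function(s) {
      if (!split_of[s]) bits[s]
      else if (bits[s] == 0L) c(0L, 0L)
      else if (side == 2L || des) c(0L, 1L)
      else if (anc) c(1L, 1L)
      else c(1L, 0L)
    }))
    stats::setNames(out, cols)
  }
  rows <- c(lapply(kept, expand, side = 1L),
            lapply(rescued, expand, side = 2L))
  mat <- do.call(rbind, rows)
  rownames(mat) <- c(sprintf("kept_%d", kept),
                     if (length(rescued)) sprintf("rescued_%d", rescued))
  mat
}

subclone_noise_threshold <- function(table, config, n_perm) {
  n <- ncol(table$p)
  set.seed(config$rng_seed + 7L)
  pooled <- numeric(0L)
  for (b in seq_len(n_perm)) {
    perm <- t(apply(table$p, 1L, sample))
    tab <- structure(list(p = perm, q = 1 - perm, samples = table$samples),
                     class = "presence_table")
    w <- reliability_scores(tab)
    sol <- .laminar_cover_dp(w, n)
    rem <- setdiff(seq_along(w) - 1L, as.integer(sol$kept))
    pooled <- c(pooled, w[rem + 1L])
  }
  if (!length(pooled)) return(Inf)
  stats::quantile(pooled, 0.95, names = FALSE)
}

#' @export
print.subclone_split <- function(x, ...) {
  if (!length(x$splits)) {
    cat("subclone_split: no sample required splitting (threshold ",
        format(x$threshold, digits = 3), ")\n", sep = "")
  } else {
    cat("subclone_split: threshold", format(x$threshold, digits = 3), "\n")
    for (s in names(x$splits))
      cat(" ", s, "->", paste(x$splits[[s]], collapse = " + "), "\n")
  }
  invisible(x)
}
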