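#' Solve the weighted minimum vertex cover of a conflict graph
#'
#' Finds the minimum-weight set of pattern nodes whose removal eliminates
#' every evolutionary incompatibility; the complement (the kept set) is the
#' maximum-reliability set of pairwise compatible mutation patterns. Two
#' exact backends are used behind one interface:
#'
#' * full pattern enumeration: an `O(3^n)` dynamic program over
#'   maximum-weight laminar families (the independent sets of the conflict
#'   graph are exactly the laminar pattern families);
#' * arbitrary node sets (restricted graphs, plain weighted graphs): an
#'   exact branch-and-bound maximum-weight independent set search.
#'
#' Both backends return proven optima and are deterministic; ties are broken
#' towards removing fewer nodes.
#'
#' @param graph A `conflict_graph` from [build_conflict_graph()], or a plain
#'   list with elements `weights` (numeric) and `edges` (two-column matrix
#'   of 1-based node indices).
#' @return An object of class `cover_solution`: list with `removed` and
#'   `kept` (for conflict graphs: pattern bitmasks; for plain graphs: node
#'   indices), `objective` (total removed weight), `proven_optimal`, and
#'   `n`/`samples` when available.
#' @examples
#' # a weighted triangle: the two cheapest nodes form the cover
#' g <- list(weights = c(1, 2, 3), edges = rbind(c(1, 2), c(1, 3), c(2, 3)))
#' solve_min_vertex_cover(g)$objective  # 3
#' @export
solve_min_vertex_cover <- function(graph) {
  if (inherits(graph, "conflict_graph")) {
    if (!all(is.finite(graph$weights))) stop("node weights must be finite")
    if (graph$full_enumeration) {
      sol <- .laminar_cover_dp(graph$weights, graph$n)
      kept_masks <- as.integer(sol$kept)
      removed_masks <- setdiff(graph$nodes, kept_masks)
      obj <- sum(graph$weights) - sol$kept_weight
    } else {
      ed <- conflict_edges(graph)
      sol <- .mwis_branch_bound(graph$weights, ed)
      kept_masks <- graph$nodes[sol$kept]
      removed_masks <- graph$nodes[-sol$kept]
      obj <- sum(graph$weights) - sol$kept_weight
    }
    structure(list(removed = removed_masks, kept = kept_masks,
                   objective = max(obj, 0), proven_optimal = TRUE,
                   n = graph$n, samples = graph$samples,
                   weights = stats::setNames(graph$weights, graph$nodes)),
              class = "cover_solution")
  } else {
    if (is.null(graph$weights)) stop("graph must provide node weights")
    ed <- graph$edges
    if (is.null(ed) || nrow(ed) == 0L)
      ed <- matrix(integer(0L), 0L, 2L)
    if (!all(is.finite(graph$weights))) stop("node weights must be finite")
    sol <- .mwis_branch_bound(graph$weights, ed)
    kept <- as.integer(sol$kept)
    structure(list(removed = setdiff(seq_along(graph$weights), kept),
                   kept = kept,
                   objective = max(sum(graph$weights) - sol$kept_weight, 0),
                   proven_optimal = TRUE, n = NULL, samples = NULL,
                   weights = graph$weights),
              class = "cover_solution")
  }
}

#' @export
print.cover_solution <- function(x, ...) {
  cat(sprintf("cover_solution: %d removed / %d kept, objective %.6g%s\n",
              length(x$removed), length(x$kept), x$objective,
              if (isTRUE(x$proven_optimal)) " (proven optimal)" else ""))
  invisible(x)
}

#' Assign every variant to its most likely surviving pattern
#'
#' Each variant is mapped to the kept pattern maximizing its pattern
#' likelihood; ties are broken towards the larger sample set, then the
#' lexicographically smallest bitstring.
#'
#' @param solution A `cover_solution` over pattern bitmasks.
#' @param table The [presence_table()] used to build the graph.
#' @return Integer vector of pattern bitmasks, named by variant, with
#'   attribute `"loglik"` carrying the per-variant log-likelihood of the
#'   chosen pattern.
#' @export
assign_variants <- function(solution, table) {
  n <- ncol(table$p)
  kept <- solution$kept
  if (!length(kept)) stop("kept pattern set is empty")
  lp <- log(pmax(table$p, 1e-300)); lq <- log(pmax(table$q, 1e-300))
  ll <- vapply(kept, function(mask) {
    bits <- pattern_vector(mask, n)
    rowSums(lp[, bits == 1L, drop = FALSE]) +
      rowSums(lq[, bits == 0L, drop = FALSE])
  }, numeric(nrow(table$p)))
  ll <- matrix(ll, nrow = nrow(table$p))
  sizes <- vapply(kept, function(mk) sum(pattern_vector(mk, n)), integer(1L))
  bitstr <- vapply(kept, function(mk) {
    paste(pattern_vector(mk, n), collapse = "")
  }, character(1L))
  ord_rank <- order(sizes, bitstr, decreasing = c(TRUE, FALSE),
                    method = "radix")
  pref <- integer(length(kept)); pref[ord_rank] <- seq_along(kept)
  pick <- apply(ll, 1L, function(row) {
    cand <- which(row >= max(row) - 1e-9)
    cand[which.min(pref[cand])]
  })
  out <- kept[pick]
  names(out) <- rownames(table$p)
  attr(out, "loglik") <- ll[cbind(seq_along(pick), pick)]
  attr(out, "n") <- n
  attr(out, "samples") <- table$samples
  out
}

#' Export the vertex-cover instance in LP format
#'
#' Writes the weighted minimum vertex cover integer program (minimize the
#' total removed weight subject to one covering constraint per conflict
#' edge, binary variables) in CPLEX LP format for debugging with external
#' solvers.
#'
#' @param graph A `conflict_graph` or a plain list with `weights`/`edges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cover_lp <- function(graph, path) {
  w <- graph$weights
  ed <- if (inherits(graph, "conflict_graph")) conflict_edges(graph)
        else graph$edges
  if (is.null(ed)) ed <- matrix(integer(0L), 0L, 2L)
  con <- file(path, "w")
  on.exit(close(con))
  terms <- paste(sprintf("%.12g x%d", w, seq_along(w)), collapse = " + ")
  writeLines(c("Minimize", paste(" obj:", terms), "Subject To"), con)
  if (nrow(ed)) {
    writeLines(sprintf(" e%d: x%d + x%d >= 1",
                       seq_len(nrow(ed)), ed[, 1L], ed[, 2L]), con)
  }
  writeLines(c("Binary", paste(sprintf(" x%d", seq_along(w)),
                               collapse = ""), "End"), con)
  invisible(path)
}
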