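# Mutation patterns are encoded as integer bitmasks over samples:
# sample i (1-based, in the order of table$samples) <-> bit 2^(i-1).

#' Convert between pattern bitmasks and logical sample vectors
#'
#' @param v Logical or 0/1 vector over samples.
#' @return `pattern_mask`: the integer bitmask; `pattern_vector`: the 0/1
#'   vector of length `n` for mask `mask`.
#' @export
pattern_mask <- function(v) {
  v <- as.logical(v)
  if (length(v) > 30L) stop("patterns support at most 30 samples")
  as.integer(sum(2^(which(v) - 1L)))
}

#' @rdname pattern_mask
#' @param mask Integer bitmask.
#' @param n Number of samples.
#' @export
pattern_vector <- function(mask, n) {
  as.integer(bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L))
}

#' Test evolutionary incompatibility of two mutation patterns
#'
#' Two patterns conflict with the perfect-and-persistent phylogeny
#' assumption if and only if some sample carries only the first, some sample
#' carries only the second, and some sample carries both (the germline
#' supplies the both-absent state). Nested or disjoint patterns never
#' conflict.
#'
#' @param u,v Patterns: 0/1 (or logical) vectors of equal length, or integer
#'   bitmasks if `n` is given.
#' @param n If supplied, `u` and `v` are interpreted as bitmasks over `n`
#'   samples.
#' @return `TRUE` iff the patterns are evolutionarily incompatible.
#' @examples
#' incompatible(c(1, 1, 0), c(0, 1, 1))  # TRUE: crossing
#' incompatible(c(1, 1, 0), c(1, 1, 1))  # FALSE: nested
#' @export
incompatible <- function(u, v, n = NULL) {
  if (is.null(n)) {
    if (length(u) != length(v)) stop("patterns must have equal length")
    u <- pattern_mask(u); v <- pattern_mask(v)
  }
  bitwAnd(u, bitwNot(v)) != 0L && bitwAnd(v, bitwNot(u)) != 0L &&
    bitwAnd(u, v) != 0L
}

#' Likelihood that a variant exhibits a given mutation pattern
#'
#' `L_mu(v) = prod_s (p[mu,s] if v_s = 1 else q[mu,s])`: the probability,
#' under the per-sample presence posteriors, that variant `mu` is present in
#' exactly the samples of pattern `v`. Over all `2^n` patterns these
#' likelihoods sum to one for each variant.
#'
#' @param table A [presence_table()].
#' @param variant Variant index or name.
#' @param v Pattern as 0/1 vector (or bitmask if `as_mask = TRUE`).
#' @param as_mask Interpret `v` as an integer bitmask.
#' @return The pattern likelihood.
#' @export
pattern_likelihood <- function(table, variant, v, as_mask = FALSE) {
  n <- ncol(table$p)
  bits <- if (as_mask) pattern_vector(v, n) else as.integer(as.logical(v))
  if (length(bits) != n) stop("pattern length must equal the number of samples")
  prod(ifelse(bits == 1L, table$p[variant, ], table$q[variant, ]))
}

#' Likelihoods of all 2^n patterns for every variant
#'
#' @param table A [presence_table()].
#' @return An `m x 2^n` matrix; column `j` corresponds to bitmask `j - 1`.
#' @export
pattern_likelihoods <- function(table) {
  n <- ncol(table$p)
  if (n > 14L) stop("full pattern enumeration is limited to 14 samples")
  L <- matrix(1, nrow(table$p), 1L)
  for (s in seq_len(n)) L <- cbind(L * table$q[, s], L * table$p[, s])
  rownames(L) <- rownames(table$p)
  L
}

#' Reliability score of a mutation pattern
#'
#' `omega_v = -(1/m) * sum_mu log(1 - L_mu(v))`: minus the normalized
#' log-likelihood that *no* variant exhibits pattern `v`. Likelihoods are
#' capped at `1 - 1e-12` to keep the score finite. Scores are in nats.
#'
#' @param v Pattern as 0/1 vector.
#' @param table A [presence_table()].
#' @return Non-negative reliability score.
#' @export
reliability_score <- function(v, table) {
  L <- vapply(seq_len(nrow(table$p)),
              function(mu) pattern_likelihood(table, mu, v), numeric(1L))
  -mean(log1p(-pmin(L, 1 - 1e-12)))
}

#' Reliability scores of all patterns
#'
#' Vectorized version of [reliability_score()] over the full enumeration.
#'
#' @param table A [presence_table()].
#' @param L Optional precomputed [pattern_likelihoods()] matrix.
#' @return Numeric vector of length `2^n`; entry `j` is the score of bitmask
#'   `j - 1`.
#' @export
reliability_scores <- function(table, L = pattern_likelihoods(table)) {
  -colMeans(log1p(-pmin(L, 1 - 1e-12)))
}

#' Build the evolutionary conflict graph
#'
#' Nodes are mutation patterns weighted by their reliability scores; edges
#' join evolutionarily incompatible pattern pairs. For `n <= 14` samples all
#' `2^n` patterns are enumerated (the empty and the founder pattern are
#' isolated by construction). For larger `n`, set `restricted = TRUE` to
#' limit the nodes to each variant's maximum-likelihood pattern, all
#' patterns within Hamming distance 1 of those, and the empty/full patterns.
#'
#' Edges are materialized eagerly only while the pair count is moderate;
#' otherwise they are computed on demand (`conflict_edges()`), since the
#' exact cover solver for the full enumeration does not need them.
#'
#' @param table A [presence_table()].
#' @param restricted Use the restricted node set (required for `n > 14`).
#' @param max_eager_pairs Materialize the edge list only if
#'   `choose(nodes, 2)` is at most this.
#' @return An object of class `conflict_graph`: list with `n`, `nodes`
#'   (integer bitmasks), `weights`, `edges` (two-column matrix of node
#'   indices or `NULL`), `full_enumeration` flag, and the likelihood matrix
#'   `L` (full enumeration only).
#' @export
build_conflict_graph <- function(table, restricted = FALSE,
                                 max_eager_pairs = 6e5) {
  n <- ncol(table$p)
  if (n > 14L && !restricted)
    stop("more than 14 samples: rerun with restricted = TRUE ",
         "(restricted pattern enumeration)")
  if (!restricted) {
    L <- pattern_likelihoods(table)
    nodes <- seq_len(2^n) - 1L
    weights <- reliability_scores(table, L)
  } else {
    ml <- apply(rbind(table$p), 1L, function(pr) {
      pattern_mask(pr > 0.5)
    })
    hood <- unique(c(0L, as.integer(2^n - 1), ml,
                     as.integer(outer(ml, as.integer(2^(seq_len(n) - 1L)),
                                      bitwXor))))
    nodes <- sort(hood)
    weights <- vapply(nodes, function(mask) {
      reliability_score(pattern_vector(mask, n), table)
    }, numeric(1L))
    L <- NULL
  }
  names(weights) <- nodes
  g <- structure(list(n = n, nodes = nodes, weights = unname(weights),
                      edges = NULL, full_enumeration = !restricted, L = L,
                      samples = table$samples),
                 class = "conflict_graph")
  if (choose(length(nodes), 2L) <= max_eager_pairs)
    g$edges <- conflict_edges(g)
  g
}

#' Edge list of a conflict graph
#'
#' @param graph A `conflict_graph`.
#' @return Two-column integer matrix of node indices (i < j), one row per
#'   incompatible pair.
#' @export
conflict_edges <- function(graph) {
  if (!is.null(graph$edges)) return(graph$edges)
  nodes <- graph$nodes
  idx <- which(outer(nodes, nodes, function(u, v) {
    bitwAnd(u, bitwNot(v)) != 0L & bitwAnd(v, bitwNot(u)) != 0L &
      bitwAnd(u, v) != 0L
  }), arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  colnames(idx) <- c("i", "j")
  unname(idx)
}

#' @export
print.conflict_graph <- function(x, ...) {
  ne <- if (is.null(x$edges)) NA_integer_ else nrow(x$edges)
  cat(sprintf("conflict_graph: %d samples, %d pattern nodes%s%s\n",
              x$n, length(x$nodes),
              if (is.na(ne)) "" else sprintf(", %d conflict edges", ne),
              if (x$full_enumeration) " (full enumeration)" else " (restricted)"))
  invisible(x)
}

#' Export a conflict graph as an edge-list TSV
#'
#' One row per node: pattern bitstring, reliability weight, and the
#' semicolon-separated bitstrings of its conflicting neighbours.
#'
#' @param graph A `conflict_graph`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_conflict_graph <- function(graph, path) {
  ed <- conflict_edges(graph)
  bits <- vapply(graph$nodes, function(mk) {
    paste(pattern_vector(mk, graph$n), collapse = "")
  }, character(1L))
  nbr <- rep("", length(graph$nodes))
  if (nrow(ed)) {
    adj <- split(c(ed[, 2L], ed[, 1L]), c(ed[, 1L], ed[, 2L]))
    for (k in names(adj))
      nbr[as.integer(k)] <- paste(bits[adj[[k]]], collapse = ";")
  }
  utils::write.table(
    data.frame(pattern = bits, weight = graph$weights, neighbors = nbr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
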