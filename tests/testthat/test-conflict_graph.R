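test_that("incompatibility is the three-witness condition", {
  expect_true(incompatible(c(1, 1, 0), c(0, 1, 1)))
  expect_false(incompatible(c(1, 1, 0), c(1, 1, 1)))  # nested
  expect_false(incompatible(c(1, 0, 0), c(0, 1, 0)))  # disjoint
  expect_error(incompatible(c(1, 0), c(1, 0, 1)), "equal length")
  # symmetry on random pairs
  set.seed(1)
  for (i in 1:50) {
    u <- stats::runif(6) < 0.5
    v <- stats::runif(6) < 0.5
    expect_identical(incompatible(u, v), incompatible(v, u))
  }
})

test_that("pattern likelihoods multiply posteriors and sum to one", {
  tab <- structure(list(
    p = matrix(c(0.9, 0.3), 1, 2, dimnames = list("v1", c("S1", "S2"))),
    q = matrix(c(0.1, 0.7), 1, 2, dimnames = list("v1", c("S1", "S2"))),
    samples = c("S1", "S2")), class = "presence_table")
  expect_equal(pattern_likelihood(tab, 1, c(1, 0)), 0.9 * 0.7)
  expect_equal(pattern_likelihood(tab, 1, c(1, 1)), 0.9 * 0.3)

  # degenerate posteriors concentrate all mass on one pattern
  tabd <- table_from_patterns(list(c("A", "C")), c("A", "B", "C"),
                              p_hi = 1 - 1e-15, p_lo = 1e-15)
  L <- pattern_likelihoods(tabd)
  expect_equal(unname(L[1, pattern_mask(c(1, 0, 1)) + 1L]), 1,
               tolerance = 1e-9)

  # normalization over all 2^n patterns, random rows, n up to 10
  set.seed(7)
  for (n in c(3L, 6L, 10L)) {
    p <- matrix(stats::runif(5 * n), 5, n)
    tabr <- structure(list(p = p, q = 1 - p,
                           samples = paste0("S", seq_len(n))),
                      class = "presence_table")
    expect_equal(rowSums(pattern_likelihoods(tabr)), rep(1, 5),
                 tolerance = 1e-9)
  }
})

test_that("reliability scores follow the -mean log(1 - L) definition", {
  # hand-computed oracle: m=2, L1=0.9, L2=0.5 -> -(1/2) ln(0.1*0.5)
  tab <- structure(list(
    p = matrix(c(0.9, 0.5), 2, 1), q = matrix(c(0.1, 0.5), 2, 1),
    samples = "S1"), class = "presence_table")
  # pattern {S1}: L1 = 0.9, L2 = 0.5
  expect_equal(reliability_score(1, tab), -0.5 * log(0.1 * 0.5),
               tolerance = 1e-12)
  # no support -> zero score
  expect_equal(reliability_score(c(0, 1), table_from_patterns(
    list("A"), c("A", "B"), p_hi = 1, p_lo = 0)), 0, tolerance = 1e-9)

  # adding a variant with L(v) = 0 keeps the sum, lowers the mean score
  tab3 <- structure(list(
    p = matrix(c(0.9, 0.5, 0), 3, 1), q = matrix(c(0.1, 0.5, 1), 3, 1),
    samples = "S1"), class = "presence_table")
  expect_equal(reliability_score(1, tab3),
               reliability_score(1, tab) * 2 / 3, tolerance = 1e-12)

  # likelihood capping keeps scores finite
  tabc <- table_from_patterns(list(c("A", "B")), c("A", "B"),
                              p_hi = 1, p_lo = 0)
  sc <- reliability_scores(tabc)
  expect_true(all(is.finite(sc)))

  # score dominates the best single-variant contribution
  set.seed(11)
  p <- matrix(stats::runif(40), 10, 4)
  tabr <- structure(list(p = p, q = 1 - p, samples = paste0("S", 1:4)),
                    class = "presence_table")
  L <- pattern_likelihoods(tabr)
  sc <- reliability_scores(tabr, L)
  lower <- apply(-log1p(-pmin(L, 1 - 1e-12)), 2L, max) / nrow(L)
  expect_true(all(sc >= lower - 1e-12))
})

test_that("conflict graph enumerates nodes, weights and exact edge set", {
  # n=3, uniform p=0.5: the three crossing pairs conflict
  p <- matrix(0.5, 2, 3, dimnames = list(c("v1", "v2"), c("A", "B", "C")))
  tab <- structure(list(p = p, q = 1 - p, samples = c("A", "B", "C")),
                   class = "presence_table")
  g <- build_conflict_graph(tab)
  expect_identical(length(g$nodes), 8L)
  ed <- conflict_edges(g)
  masks <- cbind(g$nodes[ed[, 1]], g$nodes[ed[, 2]])
  key <- apply(masks, 1L, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(key, c("3-5", "3-6", "5-6"))

  # exhaustive oracle over all pairs for a random 4-sample graph
  set.seed(3)
  p4 <- matrix(stats::runif(12), 3, 4)
  tab4 <- structure(list(p = p4, q = 1 - p4, samples = paste0("S", 1:4)),
                    class = "presence_table")
  g4 <- build_conflict_graph(tab4)
  ed4 <- conflict_edges(g4)
  in_ed <- function(i, j) any((ed4[, 1] == i & ed4[, 2] == j) |
                                (ed4[, 1] == j & ed4[, 2] == i))
  for (i in seq_along(g4$nodes)) for (j in seq_len(i - 1L)) {
    expect_identical(in_ed(i, j),
                     incompatible(g4$nodes[i], g4$nodes[j], n = 4L))
  }

  # empty and full patterns have degree zero
  deg_nodes <- g4$nodes[unique(as.vector(ed4))]
  expect_false(0L %in% deg_nodes)
  expect_false(15L %in% deg_nodes)

  # noiseless laminar data: all conflicting nodes have near-zero weight
  tabl <- table_from_patterns(list(c("A", "B", "C", "D"), c("A", "B"),
                                   c("C", "D"), "A"), paste0(LETTERS[1:4]))
  gl <- build_conflict_graph(tabl)
  edl <- conflict_edges(gl)
  # every conflict is cheap to resolve: at least one endpoint ~ zero weight
  ep <- pmin(gl$weights[edl[, 1L]], gl$weights[edl[, 2L]])
  expect_true(all(ep < 1e-4))
})

test_that("restricted mode covers large n and flags itself", {
  p <- matrix(stats::runif(32), 2, 16)
  tab <- structure(list(p = p, q = 1 - p, samples = paste0("S", 1:16)),
                   class = "presence_table")
  expect_error(build_conflict_graph(tab), "restricted")
  g <- build_conflict_graph(tab, restricted = TRUE)
  expect_false(g$full_enumeration)
  expect_true(all(c(0L, as.integer(2^16 - 1)) %in% g$nodes))
  expect_lte(length(g$nodes), 2L + 2L * (16L + 1L))
})

test_that("graph export writes one row per node", {
  tab <- table_from_patterns(list(c("A", "B"), "C"), c("A", "B", "C"))
  g <- build_conflict_graph(tab)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_conflict_graph(g, path)
  out <- utils::read.delim(path)
  expect_identical(nrow(out), 8L)
  expect_true(all(c("pattern", "weight", "neighbors") %in% names(out)))
})
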