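test_that("hand-sized covers match brute force", {
  # triangle with weights (1,2,3): remove the two cheapest, objective 3
  tri <- list(weights = c(1, 2, 3),
              edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  s <- solve_min_vertex_cover(tri)
  expect_setequal(s$removed, c(1L, 2L))
  expect_equal(s$objective, 3)
  expect_true(s$proven_optimal)

  # path a-b-c with weights (1,5,1): endpoints removed, objective 2
  pth <- list(weights = c(1, 5, 1), edges = rbind(c(1L, 2L), c(2L, 3L)))
  s2 <- solve_min_vertex_cover(pth)
  expect_setequal(s2$removed, c(1L, 3L))
  expect_equal(s2$objective, 2)

  # edgeless graph: nothing removed
  s3 <- solve_min_vertex_cover(list(weights = c(2, 4),
                                    edges = matrix(integer(0), 0, 2)))
  expect_length(s3$removed, 0L)
  expect_equal(s3$objective, 0)
})

test_that("branch-and-bound equals exhaustive search on random graphs", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(4:12, 1L)
    g <- random_weighted_graph(n)
    s <- solve_min_vertex_cover(g)
    oracle <- brute_min_vertex_cover(g$weights, g$edges)
    expect_equal(s$objective, oracle$objective, tolerance = 1e-9)
    # cover validity
    if (nrow(g$edges))
      expect_true(all(g$edges[, 1] %in% s$removed |
                        g$edges[, 2] %in% s$removed))
  }
})

test_that("the laminar DP equals brute force on full conflict graphs", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(3:4, 1L)
    m <- sample(2:6, 1L)
    p <- matrix(stats::runif(m * n), m, n)
    tab <- structure(list(p = p, q = 1 - p, samples = paste0("S", seq_len(n))),
                     class = "presence_table")
    g <- build_conflict_graph(tab)
    s <- solve_min_vertex_cover(g)
    oracle <- brute_min_vertex_cover(g$weights, conflict_edges(g))
    expect_equal(s$objective, oracle$objective, tolerance = 1e-9)
    # kept set is conflict-free and contains the empty and full patterns
    kept <- s$kept
    expect_true(0L %in% kept && as.integer(2^n - 1) %in% kept)
    for (a in seq_along(kept)) for (b in seq_len(a - 1L)) {
      expect_false(incompatible(kept[a], kept[b], n = n))
    }
  }
})

test_that("variants go to their most likely kept pattern with stated ties", {
  tab <- table_from_patterns(list(c("A", "B", "C"), c("A", "B"), "C"),
                             c("A", "B", "C"))
  g <- build_conflict_graph(tab)
  s <- solve_min_vertex_cover(g)
  asg <- assign_variants(s, tab)
  expect_identical(as.integer(asg), c(7L, 3L, 4L))

  # a variant whose ML pattern was removed is reassigned within the kept set
  p <- matrix(c(0.95, 0.95, 0.05,   # {A,B}
                0.95, 0.95, 0.05,
                0.95, 0.95, 0.05,
                0.05, 0.9, 0.9),    # {B,C} crosses, weaker
              4, 3, byrow = TRUE,
              dimnames = list(paste0("v", 1:4), c("A", "B", "C")))
  tab2 <- structure(list(p = p, q = 1 - p, samples = c("A", "B", "C")),
                    class = "presence_table")
  g2 <- build_conflict_graph(tab2)
  s2 <- solve_min_vertex_cover(g2)
  expect_true(pattern_mask(c(0, 1, 1)) %in% s2$removed)
  asg2 <- assign_variants(s2, tab2)
  expect_false(asg2[["v4"]] == pattern_mask(c(0, 1, 1)))
  expect_true(asg2[["v4"]] %in% s2$kept)

  # exact tie between nested kept patterns -> the larger set wins
  tab3 <- structure(list(
    p = matrix(c(1, 1, 0.5), 1, 3, dimnames = list("v1", c("A", "B", "C"))),
    q = matrix(c(0, 0, 0.5), 1, 3, dimnames = list("v1", c("A", "B", "C"))),
    samples = c("A", "B", "C")), class = "presence_table")
  g3 <- build_conflict_graph(tab3)
  s3 <- solve_min_vertex_cover(g3)
  asg3 <- assign_variants(s3, tab3)
  expect_identical(as.integer(asg3), 7L)  # {A,B,C} preferred over {A,B}
})

test_that("solver interface rejects invalid weights", {
  expect_error(solve_min_vertex_cover(list(weights = c(1, Inf),
                                           edges = rbind(c(1L, 2L)))),
               "finite")
})

test_that("LP export writes a well-formed instance", {
  g <- list(weights = c(1, 2), edges = rbind(c(1L, 2L)))
  path <- withr::local_tempfile(fileext = ".lp")
  write_cover_lp(g, path)
  txt <- readLines(path)
  expect_identical(txt[1], "Minimize")
  expect_true(any(grepl("x1 \\+ x2 >= 1", txt)))
  expect_true(any(grepl("Binary", txt)))
})
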