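test_that("count tables round-trip losslessly and reject malformed input", {
  K <- matrix(c(3L, 0L, 7L, 2L), 2, 2,
              dimnames = list(c("v1", "v2"), c("S1", "S2")))
  N <- matrix(c(10L, 5L, 14L, 9L), 2, 2, dimnames = dimnames(K))
  x <- variant_call_matrix(K, N, purity = c(S1 = 0.5, S2 = 0.4),
                           patient_id = "toy")
  td <- withr::local_tempdir()
  write_count_tables(x, file.path(td, "k.tsv"), file.path(td, "n.tsv"),
                     file.path(td, "p.tsv"))
  y <- read_count_tables(file.path(td, "k.tsv"), file.path(td, "n.tsv"),
                         purity = file.path(td, "p.tsv"), patient_id = "toy")
  expect_identical(unname(y$mut_reads), unname(K) + 0)
  expect_identical(unname(y$coverage), unname(N) + 0)
  expect_equal(y$purity, x$purity)
  expect_identical(y$samples, c("S1", "S2"))

  # coverage file carries a different sample column -> structured error
  Nbad <- N
  colnames(Nbad) <- c("S1", "S3")
  utils::write.table(data.frame(variant = rownames(Nbad), Nbad),
                     file.path(td, "nbad.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_count_tables(file.path(td, "k.tsv"),
                                 file.path(td, "nbad.tsv")),
               "sample columns differ")

  # unparseable cell -> error naming the variant
  writeLines(c("variant\tS1\tS2", "v1\t3\t7", "v2\txx\t2"),
             file.path(td, "kbad.tsv"))
  expect_error(read_count_tables(file.path(td, "kbad.tsv"),
                                 file.path(td, "n.tsv")),
               "unparseable.*v2")
})

test_that("variant_call_matrix enforces its invariants", {
  K <- matrix(c(3L, 12L), 1, 2, dimnames = list("v1", c("S1", "S2")))
  N <- matrix(c(10L, 10L), 1, 2, dimnames = dimnames(K))
  expect_error(variant_call_matrix(K, N), "exceeds coverage.*v1.*S2")
  expect_error(variant_call_matrix(K[, 1, drop = FALSE],
                                   N[, 1, drop = FALSE]),
               "at least two samples")
  expect_error(variant_call_matrix(pmin(K, N), N, purity = c(0.5, 1.2)),
               "purity")
})

test_that("annotation columns are tolerated and preserved", {
  td <- withr::local_tempdir()
  writeLines(c("variant\tgene\tS1\tS2", "v1\tKRAS\t5\t0", "v2\tTP53\t3\t8"),
             file.path(td, "k.tsv"))
  writeLines(c("variant\tgene\tS1\tS2", "v1\tKRAS\t20\t20", "v2\tTP53\t20\t20"),
             file.path(td, "n.tsv"))
  x <- read_count_tables(file.path(td, "k.tsv"), file.path(td, "n.tsv"))
  expect_identical(dim(x$mut_reads), c(2L, 2L))
  expect_identical(x$variants$gene, c("KRAS", "TP53"))
})

test_that("purity estimation is definitional, order-invariant and monotone", {
  # founders at VAF 0.25 in every sample -> gamma = 0.5
  pats <- rep(list(c("A", "B")), 6L)
  x <- matrix_from_patterns(pats, c("A", "B"), depth = 1000L, purity = 0.5)
  x$purity <- NULL
  g <- estimate_purity(x)
  expect_equal(unname(g), c(0.5, 0.5), tolerance = 1e-6)

  # median arithmetic: founder VAFs {0.1, 0.2, 0.3} -> gamma = 0.4
  K <- matrix(c(100L, 200L, 300L, 100L, 200L, 300L), 3, 2,
              dimnames = list(paste0("v", 1:3), c("A", "B")))
  N <- matrix(1000L, 3, 2, dimnames = dimnames(K))
  x2 <- variant_call_matrix(K, N)
  expect_equal(unname(estimate_purity(x2)), c(0.4, 0.4), tolerance = 1e-9)

  # invariance to variant row order
  perm <- c(3L, 1L, 2L)
  x3 <- variant_call_matrix(K[perm, ], N[perm, ])
  expect_equal(estimate_purity(x3), estimate_purity(x2))

  # monotone in founder VAFs
  x4 <- variant_call_matrix(K + 50L, N)
  expect_true(all(estimate_purity(x4) >= estimate_purity(x2)))

  # no founders -> warning + fallback
  K5 <- matrix(c(300L, 0L, 0L, 300L), 2, 2,
               dimnames = list(c("v1", "v2"), c("A", "B")))
  N5 <- matrix(1000L, 2, 2, dimnames = dimnames(K5))
  expect_warning(estimate_purity(variant_call_matrix(K5, N5)), "founder")
})

test_that("min_median_coverage filter drops low-coverage samples", {
  pats <- list(c("A", "B", "C"), c("A", "B"), "C")
  x <- matrix_from_patterns(pats, c("A", "B", "C"), depth = 100L)
  x$coverage[, "C"] <- 5L
  x$mut_reads[, "C"] <- pmin(x$mut_reads[, "C"], 5L)
  cfg <- patient_config(min_median_coverage = 50)
  y <- filter_samples(x, cfg)
  expect_identical(y$samples, c("A", "B"))
  expect_identical(filter_samples(x, patient_config())$samples, x$samples)
})
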