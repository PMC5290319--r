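test_that("build_tree realizes laminar families exactly (property test)", {
  set.seed(5)
  for (rep in 1:200) {
    n <- sample(3:8, 1L)
    fam <- random_laminar_family(n)
    samples <- paste0("S", seq_len(n))
    masks <- vapply(fam, function(idx) {
      pattern_mask(seq_len(n) %in% idx)
    }, integer(1L))
    asg <- rep(masks, each = 2L)  # two variants per branch
    names(asg) <- sprintf("v%03d", seq_along(asg))
    attr(asg, "samples") <- samples
    tree <- build_tree(asg)
    # every input pattern is a branch; every branch is input, a singleton
    # leaf, or the trunk
    expect_true(all(masks %in% tree$branches$mask))
    extra <- setdiff(tree$branches$mask, masks)
    expect_true(all(extra %in% c(2^(seq_len(n) - 1L), 2^n - 1)))
    # laminarity of the branch set
    bm <- tree$branches$mask
    for (a in seq_along(bm)) for (b in seq_len(a - 1L)) {
      expect_false(incompatible(bm[a], bm[b], n = n))
    }
    # root-to-leaf paths collect exactly the assigned variants
    for (s in seq_len(n)) {
      on_path <- bm[bitwAnd(bm, as.integer(2^(s - 1L))) != 0L]
      expect_setequal(
        unlist(tree$variants_by_branch[as.character(
          tree$branches$bitstring[match(on_path, bm)])]),
        names(asg)[bitwAnd(asg, as.integer(2^(s - 1L))) != 0L])
    }
  }
})

test_that("small trees have the stated shapes", {
  samples <- c("A", "B", "C")
  asg <- c(v1 = 7L, v2 = 3L)
  attr(asg, "samples") <- samples
  tree <- build_tree(asg)
  expect_identical(tree_clades(tree), list(c("A", "B")))
  nwk <- to_newick(tree)
  expect_match(nwk, "^\\(\\(A:0,B:0\\):1,C:0\\):1;$")
  ph <- as_phylo(tree)
  expect_s3_class(ph, "phylo")
  expect_setequal(ph$tip.label, samples)

  # only the full pattern -> star tree
  asg2 <- c(v1 = 7L); attr(asg2, "samples") <- samples
  expect_length(tree_clades(build_tree(asg2)), 0L)

  # incompatible input is rejected
  asg3 <- c(v1 = 3L, v2 = 6L); attr(asg3, "samples") <- samples
  expect_error(build_tree(asg3), "incompatible")

  # empty-pattern variants are dropped from the tree, reported separately
  asg4 <- c(v1 = 7L, v2 = 0L); attr(asg4, "samples") <- samples
  tr4 <- build_tree(asg4)
  expect_identical(tr4$dropped_variants, "v2")
  expect_false("v2" %in% unlist(tr4$variants_by_branch))
})

test_that("tree construction stays fast at scale", {
  n <- 20L
  samples <- paste0("S", seq_len(n))
  fam <- random_laminar_family(n)
  masks <- vapply(fam, function(idx) pattern_mask(seq_len(n) %in% idx),
                  integer(1L))
  asg <- rep_len(masks, 5000L)
  names(asg) <- sprintf("v%04d", seq_along(asg))
  attr(asg, "samples") <- samples
  expect_lt(system.time(build_tree(asg))[["elapsed"]], 5)
})

test_that("artifact classification compares pattern against baseline", {
  pats <- list(c("A", "B", "C"), c("A", "B"), "C")
  x <- matrix_from_patterns(pats, c("A", "B", "C"), depth = 1500L,
                            purity = 0.5)
  cfg <- patient_config()
  fit <- infer_tree(x, cfg)
  baseline <- binary_classification(x, cfg)
  rep0 <- classify_artifacts(fit$assignments, baseline, x, fit$table, cfg)
  # noiseless high-coverage data: no artifacts
  expect_identical(sum(rep0$counts) - rep0$counts[["concordant"]], 0L)

  # starve one founder cell of reads: under-powered false-negative
  x2 <- x
  x2$coverage["v001", "C"] <- 14L
  x2$mut_reads["v001", "C"] <- 1L
  x2$purity["C"] <- 0.2
  fit2 <- infer_tree(x2, cfg)
  base2 <- binary_classification(x2, cfg)
  rep2 <- classify_artifacts(fit2$assignments, base2, x2, fit2$table, cfg)
  cell <- rep2$cells[rep2$cells$variant == "v001" & rep2$cells$sample == "C", ]
  expect_identical(nrow(cell), 1L)
  expect_match(cell$class, "false-negative")

  # force a baseline false-positive: pattern says absent, test says present
  x3 <- x
  x3$mut_reads["v003", "A"] <- 60L  # VAF 4%: below clonal, above noise
  fit3 <- infer_tree(x3, cfg)
  base3 <- binary_classification(x3, cfg)
  rep3 <- classify_artifacts(fit3$assignments, base3, x3, fit3$table, cfg)
  expect_true(base3["v003", "A"])
  if (!bitwAnd(fit3$assignments[["v003"]], 1L)) {
    expect_identical(
      rep3$classification["v003", "A"], "putative false-positive")
  }
})

test_that("bootstrap support is 1 on clean data and degenerate for 1 rep", {
  # enough variants per branch that a resample missing a whole branch is
  # rare (probability < 1e-3 per replicate)
  pats <- c(rep(list(c("A", "B", "C", "D")), 6L),
            rep(list(c("A", "B")), 6L), rep(list(c("C", "D")), 6L),
            list("A", "B", "C", "D"))
  x <- matrix_from_patterns(pats, c("A", "B", "C", "D"), depth = 1500L)
  cfg <- patient_config(bootstrap_reps = 50L, rng_seed = 11L)
  tree <- bootstrap_support(x, cfg)
  internal <- tree$branches$size >= 2L
  expect_true(all(tree$branches$support[internal] > 0.95))

  cfg1 <- patient_config(bootstrap_reps = 1L, rng_seed = 2L)
  tree1 <- bootstrap_support(x, cfg1)
  expect_true(all(tree1$branches$support %in% c(0, 1)))

  # seeded determinism
  tree2 <- bootstrap_support(x, cfg)
  expect_identical(tree$branches$support, tree2$branches$support)
})
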