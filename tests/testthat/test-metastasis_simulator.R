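# Scaled-down simulator settings keep the suite fast: the hybrid switch and
# the detection size are reduced (stated scale-down; mutations above the
# detectability threshold are unaffected by the switch size).
fast_params <- function(...) {
  sim_params(n_switch = 1000, M = 1e6, ...)
}

test_that("seeded runs are reproducible and q_mig = 0 never seeds", {
  sp <- fast_params(m_mets = 3L, rng_seed = 21L)
  t1 <- simulate_tumor(sp)
  t2 <- simulate_tumor(sp)
  expect_identical(t1$genotypes, t2$genotypes)
  expect_identical(t1$sampled_sites, t2$sampled_sites)
  s1 <- sequence_samples(t1, sp)
  # bit-reproducible end to end (sequencing reseeds from the tumour state)
  set.seed(sp$rng_seed)
  t3 <- simulate_tumor(sp)
  expect_identical(t1$t_stop, t3$t_stop)

  spq <- fast_params(m_mets = 1L, q_mig = 0, rng_seed = 4L, max_retries = 3L)
  expect_error(simulate_tumor(spq), "no further seeding")
})

test_that("single-lineage survival matches 1 - d/b and growth rate b - d", {
  set.seed(31)
  reps <- 20000L
  surv <- metaphylo:::.sim_survival(0.16, 0.1555, reps, 500L)
  p_true <- 1 - 0.1555 / 0.16
  se <- sqrt(p_true * (1 - p_true) / reps)
  expect_lt(abs(surv / reps - p_true), 3 * se)

  # log growth of surviving populations: regression on first-passage times
  # of powers of two between 2^7 and 2^13 (hybrid checkpoints)
  sp <- sim_params(n_switch = 10000, M = 1e6, m_mets = 1L, rng_seed = 6L)
  tm <- simulate_tumor(sp)
  cp <- tm$sites[[1L]]$checkpoints
  ks <- 7:13
  tt <- cp[ks + 1L]
  fit <- stats::lm(I(ks * log(2)) ~ tt)
  slope <- unname(stats::coef(fit)[2L])
  expect_lt(abs(slope - (0.16 - 0.1555)) / (0.16 - 0.1555), 0.25)
})

test_that("mutation accrual per division is close to u", {
  set.seed(41)
  res <- list(extinct = TRUE)
  while (res$extinct) {
    res <- metaphylo:::.grow_site(0.16, 0.1555, 0.145, 0, 0,
                                  20000L, 1L, 2L, 0)
  }
  rate <- length(res$geno_id) / res$births
  expect_lt(abs(rate - 0.145) / 0.145, 0.1)
})

test_that("sequencing realizes the stated expectations and filters", {
  sp <- fast_params(m_mets = 4L, mean_depth = 300, purity = 0.75,
                    rng_seed = 51L)
  tm <- simulate_tumor(sp)
  sq <- sequence_samples(tm, sp)
  x <- sq$matrix
  expect_s3_class(x, "variant_call_matrix")
  expect_identical(x$samples, tm$sample_names)

  # clonal het variant at purity 0.75 -> VAF ~ 0.375
  clonal_everywhere <- rownames(sq$truth$clonal)[
    rowSums(sq$truth$clonal) == 4L]
  founders <- intersect(clonal_everywhere, rownames(x$mut_reads))
  expect_gt(length(founders), 5L)
  vaf <- x$mut_reads[founders, ] / pmax(x$coverage[founders, ], 1)
  expect_lt(abs(mean(vaf) - 0.375), 0.03)

  # detection filter: every reported variant has >= 4 reads and >= 5% VAF
  # somewhere (mean depth > 25)
  hits <- x$mut_reads >= 4 & x$mut_reads >= 0.05 * x$coverage
  expect_true(all(rowSums(hits) > 0))

  # negative-binomial depth: mean about mean_depth, variance about twice
  expect_lt(abs(mean(x$coverage) - 300) / 300, 0.1)
  vr <- stats::var(as.vector(x$coverage)) / mean(x$coverage)
  expect_gt(vr, 1.4); expect_lt(vr, 2.8)

  # error channel at unmutated loci: K ~ Binom(N, e/3) in samples where the
  # variant is truly absent
  absent <- sq$truth$frac[rownames(x$mut_reads), ] == 0
  if (any(absent)) {
    rate <- sum(x$mut_reads[absent]) / sum(x$coverage[absent])
    expect_lt(rate, 0.006)
  }
})

test_that("depth 25 uses the 2-read detection threshold", {
  sp <- fast_params(m_mets = 3L, mean_depth = 25, rng_seed = 61L)
  tm <- simulate_tumor(sp)
  sq <- sequence_samples(tm, sp)
  x <- sq$matrix
  hits <- x$mut_reads >= 2 & x$mut_reads >= 0.05 * x$coverage
  expect_true(all(rowSums(hits) > 0))
  # some reported variant has fewer than 4 supporting reads everywhere
  expect_true(any(apply(x$mut_reads, 1L, max) < 4))
})

test_that("truth matrix A obeys parental antisymmetry and 0.5 convention", {
  sp <- fast_params(m_mets = 5L, rng_seed = 71L)
  tm <- simulate_tumor(sp)
  sq <- sequence_samples(tm, sp)
  A <- sq$truth$A
  expect_true(all(A %in% c(0, 0.5, 1)))
  ones <- which(A == 1, arr.ind = TRUE)
  if (nrow(ones)) expect_true(all(A[ones[, c(2, 1), drop = FALSE]] == 0))
  halves <- which(A == 0.5, arr.ind = TRUE)
  if (nrow(halves)) expect_true(all(A[halves[, c(2, 1), drop = FALSE]] == 0.5))
  expect_true(all(diag(A) == 0))

  # clades are proper non-root subsets of the sampled lesions
  for (cl in sq$truth$clades) {
    expect_gte(length(cl), 2L)
    expect_lt(length(cl), length(tm$sample_names))
    expect_true(all(cl %in% tm$sample_names))
  }
})

test_that("polyphyletic samples mix two sites", {
  sp <- fast_params(m_mets = 3L, polyphyletic_count = 1L, rng_seed = 81L)
  tm <- simulate_tumor(sp)
  sq <- sequence_samples(tm, sp)
  expect_identical(sum(!is.na(sq$truth$mix_partner)), 1L)
})
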