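# Independent oracles and fixture builders used across the suite.

# Exhaustive minimum-weight vertex cover (reference for the exact solvers).
# Vectorized over all 2^n subsets; n <= 16.
brute_min_vertex_cover <- function(weights, edges) {
  n <- length(weights)
  stopifnot(n <= 16L)
  masks <- 0:(2^n - 1)
  # subset weights by bit-DP: w(mask) = w(mask - lowbit) + weight(lowbit)
  wsum <- numeric(2^n)
  if (n > 0) for (mask in seq_len(2^n - 1)) {
    low <- bitwAnd(mask, -mask)
    wsum[mask + 1L] <- wsum[bitwXor(mask, low) + 1L] +
      weights[round(log2(low)) + 1L]
  }
  covers <- rep(TRUE, 2^n)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    em <- bitwOr(2^(edges[r, 1L] - 1L), 2^(edges[r, 2L] - 1L))
    covers <- covers & bitwAnd(masks, em) != 0L
  }
  obj <- ifelse(covers, wsum, Inf)
  best <- which.min(obj)
  list(objective = obj[best],
       removed = which(bitwAnd(masks[best], 2^(seq_len(n) - 1L)) != 0L))
}

# Random connected-ish weighted graph for solver equivalence tests.
random_weighted_graph <- function(n, p_edge = 0.35) {
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  list(weights = stats::runif(n, 0, 5),
       edges = pairs[keep, , drop = FALSE])
}

# Quadrature oracle for the presence posterior: same spike-and-two-segment
# prior, integrated on a dense trapezoid grid in log space (independent of
# the closed-form incomplete-beta path used by the package).
quad_posterior_presence <- function(K, N, gamma, cfg = patient_config(),
                                    grid_n = 1e5) {
  b1 <- cfg$f_absent + 0.01
  u_max <- max(gamma / 2, b1 + 0.01)
  seg <- function(lo, hi, dens) {
    f <- seq(lo, hi, length.out = grid_n)
    ll <- stats::dbinom(K, N, theta_channel(f, cfg$e, cfg$error_channel),
                        log = TRUE)
    w <- rep(1, grid_n); w[c(1L, grid_n)] <- 0.5
    list(max = max(ll),
         val = function(mx) sum(w * exp(ll - mx)) * (hi - lo) /
           (grid_n - 1L) * dens)
  }
  s_abs <- seg(0, cfg$f_absent, 0.5 * (1 - cfg$c0) / b1)
  s_band <- seg(cfg$f_absent, b1, 0.5 * (1 - cfg$c0) / b1)
  s_top <- seg(b1, u_max, 0.5 * (1 - cfg$c0) / (u_max - b1))
  l_spike <- stats::dbinom(K, N, theta_channel(0, cfg$e, cfg$error_channel),
                           log = TRUE)
  mx <- max(s_abs$max, s_band$max, s_top$max, l_spike)
  spike <- cfg$c0 * exp(l_spike - mx)
  a <- s_abs$val(mx); bb <- s_band$val(mx); tp <- s_top$val(mx)
  p <- (bb + tp) / (spike + a + bb + tp)
  list(p = p, q = 1 - p)
}

# A presence table with essentially certain posteriors following a given
# laminar pattern family (for tree/graph fixtures without sequencing noise).
table_from_patterns <- function(patterns, samples, p_hi = 1 - 1e-6,
                                p_lo = 1e-6) {
  m <- length(patterns)
  n <- length(samples)
  p <- matrix(p_lo, m, n,
              dimnames = list(sprintf("v%03d", seq_len(m)), samples))
  for (i in seq_len(m)) p[i, patterns[[i]]] <- p_hi
  structure(list(p = p, q = 1 - p, samples = samples,
                 purity = stats::setNames(rep(0.5, n), samples),
                 patient_id = "fixture"),
            class = "presence_table")
}

# Random laminar (pairwise compatible) pattern family over n samples:
# recursively partitions the sample set, collecting every block.
random_laminar_family <- function(n, max_blocks = 3L) {
  blocks <- list(seq_len(n))
  out <- list(seq_len(n))
  while (length(blocks)) {
    blk <- blocks[[1L]]
    blocks <- blocks[-1L]
    if (length(blk) < 2L || stats::runif(1) < 0.25) next
    k <- sample(2:min(max_blocks, length(blk)), 1L)
    grp <- sample(rep_len(seq_len(k), length(blk)))
    for (g in seq_len(k)) {
      child <- blk[grp == g]
      if (length(child) >= 1L && length(child) < length(blk)) {
        out <- c(out, list(child))
        blocks <- c(blocks, list(child))
      }
    }
  }
  unique(out)
}

# Small noiseless count matrix realizing given sample-subset patterns with
# clonal VAF purity/2 at high coverage.
matrix_from_patterns <- function(patterns, samples, depth = 1000L,
                                 purity = 0.6) {
  m <- length(patterns)
  n <- length(samples)
  N <- matrix(depth, m, n,
              dimnames = list(sprintf("v%03d", seq_len(m)), samples))
  K <- matrix(0L, m, n, dimnames = dimnames(N))
  for (i in seq_len(m)) K[i, patterns[[i]]] <- as.integer(depth * purity / 2)
  variant_call_matrix(K, N,
                      purity = stats::setNames(rep(purity, n), samples),
                      patient_id = "fixture")
}

pam03like_paths <- function() {
  list(
    mut = system.file("extdata", "pam03like_synthetic_mut_reads.tsv",
                      package = "metaphylo"),
    cov = system.file("extdata", "pam03like_synthetic_coverage.tsv",
                      package = "metaphylo"),
    pur = system.file("extdata", "pam03like_synthetic_purity.tsv",
                      package = "metaphylo"))
}

load_pam03like <- function() {
  p <- pam03like_paths()
  read_count_tables(p$mut, p$cov, purity = p$pur,
                    patient_id = "Pam03-like (synthetic)")
}
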