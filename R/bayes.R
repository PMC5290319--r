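#' Posterior probability that a variant is present in a sample
#'
#' Under a binomial likelihood `Binomial(K; N, theta(f))` for the observed
#' variant reads, with the read-error channel `theta(f)` of
#' [theta_channel()], and the spike-and-slab prior
#' `pi(f) = c0 * delta(f) + (1 - c0) * g(f)`, the posterior absence
#' probability `q` is the posterior mass of `{f = 0} U (0, f_absent]` and
#' the presence probability is `p = 1 - q`.
#'
#' The presence prior `g` is purity-aware: with `b1 = f_absent + 0.01` and
#' the heterozygous-diploid clonal ceiling `u_max = max(gamma/2, b1 + 0.01)`,
#' half of the presence mass is uniform on the near-threshold band
#' `(0, b1]` and half uniform on `(b1, u_max]`. Keeping the low-band
#' density independent of purity (and the top segment non-degenerate) makes
#' the posterior absence probability provably non-decreasing in `gamma` for
#' `K = 0` — the defining qualitative property of the model (a sample with
#' little neoplastic content provides weaker evidence of absence) — which a
#' single uniform slab violates in a narrow purity window.
#'
#' Because `theta` is affine in `f`, all integrals reduce to regularized
#' incomplete beta functions and are evaluated in closed form on the log
#' scale, so extreme read counts do not underflow. With `N = 0` the prior
#' masses are returned (panel dropout is not an error).
#'
#' @param K Variant read counts (vector).
#' @param N Total coverage (vector, recycled with `K`).
#' @param gamma Sample purity in (0,1] (vector, recycled).
#' @param config A [patient_config()].
#' @return A list with numeric vectors `p` and `q` (`p + q == 1`).
#' @examples
#' posterior_presence(7, 14, 0.5)     # clear presence
#' posterior_presence(0, 1000, 0.4)   # clear absence
#' @export
posterior_presence <- function(K, N, gamma, config = patient_config()) {
  n <- max(length(K), length(N), length(gamma))
  K <- rep_len(K, n); N <- rep_len(N, n); gamma <- rep_len(gamma, n)
  if (any(K < 0) || any(N < 0) || any(K > N))
    stop("require 0 <= K <= N")
  if (any(gamma <= 0 | gamma > 1))
    stop("purity gamma must lie in (0,1]")
  e <- config$e
  slope <- if (config$error_channel == "third") 1 - 4 * e / 3 else 1 - 2 * e
  th0 <- theta_channel(0, e, config$error_channel)
  b1 <- config$f_absent + 0.01
  u_max <- pmax(gamma / 2, b1 + 0.01)
  th_abs <- theta_channel(config$f_absent, e, config$error_channel)
  th_b1 <- theta_channel(b1, e, config$error_channel)
  th_max <- theta_channel(u_max, e, config$error_channel)
  w_band <- 0.5

  # log integral of dbinom(K; N, theta(f)) df for f in [0, x] (theta affine)
  log_int0 <- function(x) {
    -log(slope) - log(N + 1) + stats::pbeta(x, K + 1, N - K + 1, log.p = TRUE)
  }
  log_diff <- function(la, lb) {  # log(exp(la) - exp(lb)), la >= lb
    d <- lb - la
    out <- la + log1p(-exp(d))
    out[la == -Inf] <- -Inf
    out[d >= 0] <- -Inf  # equal (or degenerate): zero mass
    out
  }
  l0 <- log_int0(th0); la <- log_int0(th_abs); lb1 <- log_int0(th_b1)
  l_abs <- log_diff(la, l0)                 # (0, f_absent]
  l_band <- log_diff(lb1, la)               # (f_absent, b1]
  l_top <- log_diff(log_int0(th_max), lb1)  # (b1, u_max]

  t_spike <- log(config$c0) + stats::dbinom(K, N, th0, log = TRUE)
  lc1 <- log(1 - config$c0)
  t_abs <- lc1 + log(w_band) - log(b1) + l_abs
  t_band <- lc1 + log(w_band) - log(b1) + l_band
  t_top <- lc1 + log(1 - w_band) - log(u_max - b1) + l_top

  mx <- pmax(t_spike, t_abs, t_band, t_top)
  sm <- exp(t_spike - mx) + exp(t_abs - mx) + exp(t_band - mx) +
    exp(t_top - mx)
  p <- (exp(t_band - mx) + exp(t_top - mx)) / sm
  list(p = p, q = 1 - p)
}

#' Per-cell presence posteriors for a whole count matrix
#'
#' Applies [posterior_presence()] elementwise and returns the presence (`p`)
#' and absence (`q`) probability matrices used throughout the pipeline.
#'
#' @param x A [variant_call_matrix()] carrying purities (or they are
#'   estimated via [estimate_purity()]).
#' @param config A [patient_config()].
#' @return An object of class `presence_table`: list with matrices `p`, `q`
#'   (variants x samples), the `samples`, and the purities used.
#' @export
presence_table <- function(x, config = patient_config()) {
  stopifnot(inherits(x, "variant_call_matrix"))
  gamma <- if (is.null(x$purity)) estimate_purity(x, config) else x$purity
  m <- nrow(x$mut_reads); n <- ncol(x$mut_reads)
  post <- posterior_presence(as.vector(x$mut_reads), as.vector(x$coverage),
                             rep(gamma, each = m), config)
  p <- matrix(post$p, m, n, dimnames = dimnames(x$mut_reads))
  structure(list(p = p, q = 1 - p, samples = x$samples, purity = gamma,
                 patient_id = x$patient_id),
            class = "presence_table")
}

#' @export
print.presence_table <- function(x, ...) {
  cat(sprintf("presence_table: %d variants x %d samples (patient %s)\n",
              nrow(x$p), ncol(x$p), x$patient_id))
  invisible(x)
}

#' Export a presence table as a TSV heat matrix
#'
#' @param table A [presence_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_presence_table <- function(table, path) {
  df <- data.frame(variant = rownames(table$p), round(table$p, 6L),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
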