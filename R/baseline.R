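#' One-tailed binomial p-value for variant presence
#'
#' Under the null hypothesis that the variant is absent and every variant
#' read is a false positive arising at rate `p_fpr`, the p-value is
#' `P(X >= K)` for `X ~ Binomial(N, p_fpr)`.
#'
#' @param K Variant reads (vector).
#' @param N Coverage (vector, recycled).
#' @param p_fpr Assumed per-read false-positive rate.
#' @return Numeric vector of p-values (`K = 0` gives 1).
#' @examples
#' binomial_pvalue(1, 14)          # ~0.0678
#' binomial_pvalue(10, 10)         # 0.005^10
#' @export
binomial_pvalue <- function(K, N, p_fpr = 0.005) {
  n <- max(length(K), length(N))
  K <- rep_len(K, n); N <- rep_len(N, n)
  if (any(K < 0) || any(K > N)) stop("require 0 <= K <= N")
  stats::pbinom(K - 1, N, p_fpr, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up rejection at a target FDR
#'
#' Classic step-up procedure over one pooled p-value list: reject the
#' `r` smallest p-values where `r` is the largest rank with
#' `p_(r) <= r/M * fdr`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param fdr Target false-discovery rate.
#' @return Logical vector of rejections, with the realized cutoff (largest
#'   rejected p-value, or `fdr/M` when nothing is rejected) as attribute
#'   `"cutoff"`.
#' @export
fdr_step_up <- function(pvalues, fdr = 0.05) {
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  M <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  ok <- ps <= seq_len(M) / M * fdr
  r <- if (any(ok)) max(which(ok)) else 0L
  reject <- logical(M)
  if (r > 0L) reject[ord[seq_len(r)]] <- TRUE
  attr(reject, "cutoff") <- if (r > 0L) ps[r] else fdr / M
  reject
}

#' Conventional binary present/absent classification
#'
#' Scores each (variant, sample) cell with the one-tailed binomial test at
#' false-positive rate `config$p_fpr` and controls the FDR at `config$fdr`
#' with the step-up method over the pooled per-patient p-values. Rejected
#' cells are classified present.
#'
#' @param x A [variant_call_matrix()].
#' @param config A [patient_config()].
#' @return Logical matrix (variants x samples), `TRUE` = present, with the
#'   realized BH cutoff as attribute `"cutoff"`.
#' @export
binary_classification <- function(x, config = patient_config()) {
  pv <- binomial_pvalue(as.vector(x$mut_reads), as.vector(x$coverage),
                        config$p_fpr)
  rej <- fdr_step_up(pv, config$fdr)
  out <- matrix(rej, nrow(x$mut_reads), ncol(x$mut_reads),
                dimnames = dimnames(x$mut_reads))
  attr(out, "cutoff") <- attr(rej, "cutoff")
  out
}

#' Count evolutionarily incompatible variants under binary classification
#'
#' The classical character-compatibility criterion the Bayesian pipeline is
#' contrasted against: each variant contributes a unit weight to its
#' observed binary pattern, the maximum-weight compatible pattern set is
#' found with the same exact cover machinery, and every variant whose
#' observed pattern is not in the kept set is counted as incompatible.
#'
#' @param binary Logical presence matrix (variants x samples), e.g. from
#'   [binary_classification()].
#' @return Integer count, with the kept pattern masks as attribute
#'   `"kept"` and per-variant incompatibility flags as attribute `"flags"`.
#' @export
count_incompatible_variants <- function(binary) {
  n <- ncol(binary)
  if (n > 14L) stop("binary compatibility count limited to 14 samples")
  masks <- apply(binary, 1L, function(row) pattern_mask(row))
  w <- numeric(2^n)
  tab <- table(masks)
  w[as.integer(names(tab)) + 1L] <- as.numeric(tab)
  sol <- .laminar_cover_dp(w, as.integer(n))
  kept <- as.integer(sol$kept)
  flags <- !(masks %in% kept)
  out <- sum(flags)
  attr(out, "kept") <- kept
  attr(out, "flags") <- stats::setNames(flags, rownames(binary))
  out
}

#' Export a binary classification matrix as TSV
#'
#' @param binary Logical matrix from [binary_classification()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_binary_classification <- function(binary, path) {
  df <- data.frame(variant = rownames(binary), binary * 1L,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
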