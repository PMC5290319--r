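#' Analysis configuration for one patient
#'
#' Bundles the tunable parameters of the Bayesian presence model, the
#' conventional binary baseline and the pipeline filters.
#'
#' @param c0 Prior probability that the variant allele frequency in a sample
#'   is exactly zero (the spike mass of the presence prior).
#' @param e Sequencing error rate per read.
#' @param f_absent Maximal variant allele frequency still considered "absent";
#'   posterior mass on `(0, f_absent]` counts towards absence.
#' @param p_fpr False-positive rate assumed by the one-tailed binomial test of
#'   the conventional binary baseline.
#' @param fdr Target false-discovery rate for the step-up (Benjamini-Hochberg)
#'   correction of the pooled per-patient p-values.
#' @param min_median_coverage Samples whose median coverage falls below this
#'   threshold are excluded before analysis (0 disables the filter).
#' @param bootstrap_reps Number of bootstrap replicates for branch support.
#' @param rng_seed Integer seed used by seeded operations (bootstrap,
#'   permutation null of the subclone detector).
#' @param error_channel How a read error turns into a variant call:
#'   `"third"` assumes a specific substitution arises from one of three
#'   possible erroneous bases, `theta(f) = f(1-e) + (1-f)e/3`; `"full"` uses
#'   `theta(f) = f(1-e) + (1-f)e`.
#' @param subclone_prob Minimal posterior presence probability on both sides
#'   of a conflict for a sample to be split into subclones.
#'
#' @return An object of class `patient_config` (a validated list).
#' @examples
#' cfg <- patient_config()
#' cfg$f_absent
#' @export
patient_config <- function(c0 = 0.5, e = 0.005, f_absent = 0.05,
                           p_fpr = 0.005, fdr = 0.05,
                           min_median_coverage = 0, bootstrap_reps = 1000L,
                           rng_seed = 1L,
                           error_channel = c("third", "full"),
                           subclone_prob = 0.8) {
  error_channel <- match.arg(error_channel)
  probs <- c(c0 = c0, e = e, f_absent = f_absent, p_fpr = p_fpr, fdr = fdr,
             subclone_prob = subclone_prob)
  bad <- probs <= 0 | probs >= 1
  if (any(bad))
    stop("configuration probabilities must lie in (0,1): ",
         paste(names(probs)[bad], collapse = ", "))
  if (min_median_coverage < 0) stop("min_median_coverage must be >= 0")
  if (bootstrap_reps < 0) stop("bootstrap_reps must be >= 0")
  structure(list(c0 = c0, e = e, f_absent = f_absent, p_fpr = p_fpr,
                 fdr = fdr, min_median_coverage = min_median_coverage,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 rng_seed = as.integer(rng_seed),
                 error_channel = error_channel,
                 subclone_prob = subclone_prob),
            class = "patient_config")
}

#' Read-error channel
#'
#' Probability that a read reports the variant allele when the true variant
#' allele fraction is `f`, given sequencing error rate `e`.
#'
#' @param f True variant allele fraction (vector).
#' @param e Per-read sequencing error rate.
#' @param channel `"third"` (default; an error produces one specific base out
#'   of three) or `"full"`.
#' @return Numeric vector of per-read variant probabilities.
#' @export
theta_channel <- function(f, e, channel = "third") {
  if (channel == "third") f * (1 - e) + (1 - f) * e / 3
  else f * (1 - e) + (1 - f) * e
}
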