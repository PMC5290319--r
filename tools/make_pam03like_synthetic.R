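# Builds the SYNTHETIC stand-in for the Pam03 deep targeted sequencing
# tables (the deposited originals are not redistributable here).  Every
# structural fact encoded below is taken from the published description of
# that patient: 10 samples (five liver metastases LiM 1-5, three lung
# metastases LuM 1-3, two primary tumour sections PT 10-11), 90 validated
# variants, per-sample purities between 21 and 48% (LuM 1 lowest), deep
# targeted coverage (median ~300x, mean ~600x) with three low-coverage
# samples (LiM 5, LuM 2-3, mean ~20-30x), an evolutionarily related group
# {LiM 2-5, PT 11}, LiM 1 seeded by a distinct subclone, a lung clade, and
# two clonal driver-like founder variants ("KRAS-like", "ATM-like") that
# were covered only 14 times with a single variant read in LuM 2.  Counts
# are drawn once from the binomial read-error model at the clonal VAF
# gamma/2 and committed; the generator is deterministic (fixed seed).
#
# Run from the repository root:  Rscript tools/make_pam03like_synthetic.R

library(metaphylo)

set.seed(20170131)

samples <- c("LiM 1", "LiM 2", "LiM 3", "LiM 4", "LiM 5",
             "LuM 1", "LuM 2", "LuM 3", "PT 10", "PT 11")
purity <- c(0.35, 0.42, 0.48, 0.45, 0.30, 0.21, 0.24, 0.27, 0.40, 0.38)
depth <- c(300, 350, 500, 4000, 25, 400, 18, 30, 350, 250)
names(purity) <- names(depth) <- samples

in_set <- function(x) samples %in% x
branches <- list(
  founder = list(pattern = rep(TRUE, 10L), n = 40L),
  liver_pt11 = list(pattern = in_set(c("LiM 2", "LiM 3", "LiM 4", "LiM 5",
                                       "PT 11")), n = 8L),
  liver_core = list(pattern = in_set(c("LiM 2", "LiM 3", "LiM 4", "LiM 5")),
                    n = 4L),
  lim34 = list(pattern = in_set(c("LiM 3", "LiM 4")), n = 3L),
  lim23 = list(pattern = in_set(c("LiM 2", "LiM 3")), n = 2L),
  lung = list(pattern = in_set(c("LuM 1", "LuM 2", "LuM 3")), n = 5L),
  lum23 = list(pattern = in_set(c("LuM 2", "LuM 3")), n = 3L))
private_n <- c(3L, 2L, 2L, 2L, 3L, 3L, 2L, 3L, 3L, 2L)  # 25 private variants

pat <- do.call(rbind, unlist(lapply(branches, function(b) {
  rep(list(b$pattern), b$n)
}), recursive = FALSE))
for (s in seq_along(samples)) {
  pat <- rbind(pat, matrix(rep(in_set(samples[s]), private_n[s]),
                           nrow = private_n[s], byrow = TRUE))
}
stopifnot(nrow(pat) == 90L)

vnames <- c("KRAS_like", "ATM_like",
            sprintf("var%02d", seq_len(nrow(pat) - 2L)))
rownames(pat) <- vnames
colnames(pat) <- samples

e <- 0.005
N <- matrix(stats::rnbinom(length(pat), size = 8,
                           mu = rep(depth, each = nrow(pat))),
            nrow(pat), ncol(pat), dimnames = dimnames(pat))
f <- t(t(pat) * (purity / 2))
K <- matrix(stats::rbinom(length(N), as.vector(N),
                          as.vector(theta_channel(f, e))),
            nrow(N), ncol(N), dimnames = dimnames(N))

# the two driver-like founders were sequenced 14 times with one variant
# read in LuM 2 (stated verbatim for the real patient)
N[c("KRAS_like", "ATM_like"), "LuM 2"] <- 14L
K[c("KRAS_like", "ATM_like"), "LuM 2"] <- 1L

x <- variant_call_matrix(K, N, purity = purity,
                         patient_id = "Pam03-like (synthetic)")
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_count_tables(x,
                   "inst/extdata/pam03like_synthetic_mut_reads.tsv",
                   "inst/extdata/pam03like_synthetic_coverage.tsv",
                   "inst/extdata/pam03like_synthetic_purity.tsv")
cat("written: 90 x 10 synthetic stand-in tables\n")
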