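---
title: "Reconstructing metastatic seeding phylogenies: models and methods"
author: "metaphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing metastatic seeding phylogenies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaphylo)
```

# The problem

Multi-region sequencing of a patient's primary tumour and metastases yields,
for every somatic variant and every sample, a pair of read counts: `K`
variant-supporting reads out of `N` total. Reconstructing which subclones
seeded which lesions from these counts is hard for reasons that compound:
bulk samples are impure (often only 20–50% cancer cells), coverage is
non-uniform, the genetic differences between metastases are few, and a naive
binary present/absent call turns borderline cells into artifacts that make
the variant patterns mutually contradictory. `metaphylo` addresses this by
keeping every cell probabilistic until a single global optimization chooses
the most reliable set of mutually compatible mutation patterns, from which
the phylogeny follows uniquely.

# Presence posteriors

For a sample with neoplastic content (purity) $\gamma$, a clonal
heterozygous variant on a diploid background sits at variant allele
fraction (VAF) $\gamma/2$. Reads report the variant with probability
$\theta(f) = f(1-e) + (1-f)\,e/3$ when the true VAF is $f$ and the per-read
error rate is $e$ (an erroneous read shows one specific alternative base
out of three; the coarser channel $\theta(f)=f(1-e)+(1-f)e$ is available
via `error_channel = "full"`). The likelihood of the data is
$\mathrm{Binomial}(K; N, \theta(f))$.

The prior on $f$ mixes a point mass at zero (the variant is absent) with a
purity-aware presence density $g$:
$$\pi(f) = c_0\,\delta(f) + (1-c_0)\,g(f).$$
With $b_1 = f_\mathrm{absent} + 0.01$ and the clonal ceiling
$u_\mathrm{max} = \max(\gamma/2,\; b_1 + 0.01)$, the presence density
places half its mass uniformly on the near-threshold band $(0, b_1]$ and
half uniformly on $(b_1, u_\mathrm{max}]$. The posterior absence
probability $q$ is the posterior mass of
$\{0\} \cup (0, f_\mathrm{absent}]$ — absence tolerates VAFs up to
$f_\mathrm{absent} = 0.05$ — and $p = 1-q$.

**Why the two-segment prior.** The defining qualitative property of the
model is that, for the same $K$ and $N$, a low-purity sample provides
*weaker* evidence of absence than a high-purity one ($q$ non-decreasing in
$\gamma$ at $K = 0$). A single uniform slab
$\mathrm{Unif}(0, \max(\gamma/2, b_1)]$ — the obvious first choice —
violates this measurably: at $N = 20$ the absence posterior dips by up to
0.08 as $\gamma$ crosses $\approx 0.12$, because newly covered
frequencies just above the absence threshold still carry appreciable
likelihood. Fixing the density of the low band independently of purity
and keeping the upper segment non-degenerate removes the dip provably:
the absence-region prior mass no longer depends on $\gamma$, and the
presence mass is (half of) the average of a decreasing likelihood over a
right-growing interval, hence non-increasing in $\gamma$. The exact
functional form of the original model is not public; this is one
admissible instantiation with the stated behaviour.

**Numerics.** Because $\theta$ is affine in $f$, every integral reduces to
regularized incomplete beta functions; the implementation evaluates them
with `pbeta` on the log scale (no quadrature, no underflow at
$N \sim 10^5$), far inside the `1e-8` relative tolerance the contract
asks of numerical integration. Cells with $N = 0$ (panel dropouts) return
the prior masses rather than erroring.

# Reliability-weighted patterns and the conflict graph

A mutation pattern is the subset of samples carrying a variant, encoded as
a length-$n$ binary vector. Given the posteriors, the likelihood that
variant $\mu$ exhibits pattern $v$ is
$L_\mu(v) = \prod_s (p_{\mu s}\ \mathrm{if}\ v_s{=}1\ \mathrm{else}\ q_{\mu s})$;
over all $2^n$ patterns these sum to one. The reliability score of a
pattern pools all variants:
$$\omega_v = -\frac{1}{m}\,\log \prod_\mu \bigl(1 - L_\mu(v)\bigr),$$
the (normalized, nats) log-likelihood against the hypothesis that *no*
variant exhibits $v$. Likelihoods are capped at $1 - 10^{-12}$ so scores
stay finite.

Two patterns are evolutionarily incompatible under the perfect (no
parallel gain) and persistent (no loss) phylogeny assumption exactly when
three witness samples exist: one carrying only the first, one carrying
only the second, one carrying both. The conflict graph has the $2^n$
patterns as nodes weighted by $\omega_v$ and incompatible pairs as edges;
the empty and the founder pattern are always isolated.

# Exact minimum vertex cover without an ILP solver

Selecting the most reliable pairwise-compatible pattern set is the
weighted minimum vertex cover problem on the conflict graph (remove the
least total reliability so that no conflict edge survives). The original
formulation solves a MILP with a commercial solver. No ILP backend is
available in this package's target environment, and none is needed: the
independent sets of the conflict graph are precisely the *laminar*
families of sample subsets (any two nested or disjoint). The package
therefore solves the problem exactly with a dynamic program over subset
decompositions,
$$D(U) = w(U) + \max\Bigl(D(U \setminus \{x\}),\;
  \max_{V \ni x,\ V \subsetneq U} D(V) + D(U \setminus V)\Bigr),$$
where $x$ is a fixed element of $U$ and all weights are non-negative (so
a set compatible with the chosen family is always kept). Submask
enumeration gives $O(3^n)$ time — milliseconds for $n \le 14$ — and the
optimum is proven, deterministic, and tie-broken towards keeping more
patterns. For restricted node sets (more than 14 samples) and for
arbitrary weighted graphs, an exact branch-and-bound maximum-weight
independent set search is used instead; both backends are validated
against exhaustive search in the test suite. Variants are then assigned
to their maximum-likelihood kept pattern (ties: larger sample set, then
lexicographically smallest bitstring).

# Tree, artifacts, bootstrap

The kept patterns form a laminar family, so the rooted tree is unique:
branches are the distinct assigned patterns ordered by containment, the
founder pattern is the trunk, singletons are leaf branches, and each
branch carries its variants (branch length = variant count in the Newick
output; acquired-variant lists go to a sidecar TSV because Newick cannot
carry them portably). Variants assigned the empty pattern are reported as
an absent-everywhere putative false-positive set rather than placed on
the tree.

Putative artifacts are the cells where the conventional binary baseline
(one-tailed binomial test at false-positive rate $p_\mathrm{fpr} = 0.5\%$,
Benjamini–Hochberg step-up at FDR 5% over the pooled per-patient
p-values) disagrees with the assigned pattern. Baseline-present /
pattern-absent cells are putative false-positives; the converse are
false-negatives, split by detection power: with $K^*$ the smallest read
count whose p-value passes the baseline's realized rejection cutoff, the
power is $P(X \ge K^*)$ for $X \sim \mathrm{Binomial}(N,
\theta(\gamma_s/2))$ — a clonal variant at this sample's purity — and
cells below 50% power are *under-powered* false-negatives. The 50%
threshold and the use of the realized BH cutoff are this package's
choices; the original prints neither.

Branch support comes from resampling variants with replacement,
re-running posteriors → conflict graph → cover → assignment per
replicate, and counting the fraction of replicates whose assigned
patterns contain the same sample subset. Purity is held fixed across
replicates (whether the original re-estimates it per replicate is
unstated).

# Subclone detection (admissible reconstruction)

A removed pattern with reliability higher than expected from noise hints
that some sample mixes two evolutionary trajectories (polyclonal seeding
or reseeding). The noise threshold is the 95th percentile of
removed-pattern scores under a permutation null (each variant's presence
probabilities shuffled across samples; 100 permutations, seeded). Removed
patterns above the threshold are revisited at the variant level: a sample
carried by both the removed pattern and a conflicting kept pattern, with
confidently present supporting variants on *both* sides
($p >$ `subclone_prob`, default 0.8), is split into two pseudo-samples
(`"<sample> SC 1"` / `"SC 2"`), and the conflicting pattern is re-homed to
the second. At most two subclones per sample and five sweeps. The
original's pseudo-code is in an inaccessible supplement, so this module is
an admissible reconstruction and is off by default (`--subclones`).

# The metastasis simulator

The benchmark generator is a continuous-time multi-type branching
process. Cells divide at rate $b = 0.16$ and die at rate $d = 0.1555$
per day; a division acquires a neutral point mutation with probability
$u = 0.145$ (a $5\times10^{-10}$/bp rate over a 45 Mb exome) and a CNV
with probability $10^{-3}$; a daughter cell founds a new site with
probability $q_\mathrm{mig} = 10^{-9}$ per division (interpreted
per-division; most attempts go extinct, with survival probability
$1 - d/b \approx 0.028$). The simulation stops when `m_mets` metastases
have reached the detection size $M = 10^8$ cells; those metastases are
sampled.

**Hybrid growth.** Each site is simulated cell by cell (Gillespie) up to
`n_switch` cells ($10^4$ by default) and deterministically afterwards
with frozen clonal composition. A neutral mutation arising at site size
$10^4$ has expected terminal fraction $\le 10^{-4}$, three orders of
magnitude below the 5% VAF reporting threshold, so post-switch mutations
are dropped — except along emigrating founder lineages, which receive
Poisson($u\,b\,\Delta t$) private clonal mutations so that late-seeded
metastases carry realistic private variant loads. Migration emissions
during deterministic growth follow the inhomogeneous Poisson process with
intensity $q_\mathrm{mig}\, b\, n(t)$, inverted in closed form.

**Stopping rule.** Sites never stop growing, so emissions accelerate
exponentially; processing them naively never terminates. Two safeguards
bound the work without biasing the sample: (i) any site seeded at time
$t$ detects no earlier than $t + \ln(M/\texttt{n\_switch})/(b-d)$ (its
stochastic phase adds strictly positive time), so emission processing
stops once the $m$-th candidate detection beats that bound; (ii) at most
$3\,m$ surviving sites are instantiated — the deterministic lag of
roughly $2{,}000$ days dominates detection times, so a site seeded after
the $3m$-th survivor cannot enter the first $m$ detections except with
negligible probability.

**Sequencing.** Each sampled metastasis contributes $10^6$ cells diluted
to the configured purity (polyphyletic samples mix two sites
proportionally to their sizes). Per mutated locus and sample, depth is
negative-binomial with the configured mean and variance twice the mean
(the distribution is stated upstream, the dispersion is not; it is
configurable), and variant reads are binomial at $\theta(f)$ with
$e = 0.5\%$, where $f$ accounts for purity and for copy-number overlaps
resolved by event timing (a deletion acquired after an SNV on the same
haplotype removes it — the "persistence" violations real tumours show).
CNV lengths are log-normal (median $10^5$ bp, $\sigma = 1$), a stand-in
for an empirical length distribution that would require external data;
no two CNVs overlap on one lineage. A locus is reported if some sample
shows VAF $\ge 5\%$ with $\ge 4$ variant reads ($\ge 2$ at mean depth
25).

**What the generator does not emulate.** Selection (all post-founder
mutations are neutral), spatial structure within a site, sequencing
artifacts beyond the binomial error channel (no strand bias, no
alignability effects), and the paper-scale 90,000-phylogeny grid. A green
benchmark therefore certifies the *method* under the stated noise model,
not performance on any particular real dataset.

# Benchmark metrics

The *branching error* is the fraction of true coalescent events (non-root
clades of the true sample tree, derived from the founder-lineage
genealogy) missing from a reconstruction. The *mutation matrix error*
compares ancestor–descendant relations among parsimony-informative
mutations (clonal in at least two but not all sampled lesions — the
between-seeding variants; within-lesion subclonal mutations are
excluded): $A_{ij} = 1$ if $i$ is parental to $j$, $0.5$ for same-branch
pairs (order not required), else 0; the score is the mean absolute
deviation over ordered off-diagonal pairs, with no-information pairs
filled as $A_{ij} - 0.5$ so an uninformative method scores exactly 0.5.
The exact normalization in the source formulation is not visible; mean
absolute deviation is adopted as the form consistent with that fill rule.
A neighbour-joining baseline (Hamming distances on $p > 0.5$ binary
profiles, rooted at an all-zero germline profile) represents classical
distance methods.

Benchmarks condition on replicates in which every true branch carries at
least one detected variant; excluded replicates are counted. The
acceptance-grade benchmark runs scaled down as stated: `n_switch = 2000`
(equivalent above the detection threshold, roughly five-fold faster) and
12–25 replicates per scenario cell instead of thousands.

# Degenerate inputs, tolerances, tie-breaks

* `p + q = 1` holds identically (the posterior is computed as a softmax
  over the three log-mass components).
* Pattern likelihood cap $1 - 10^{-12}$; cover DP weight ties broken at
  $10^{-12}$ towards keeping more nodes; assignment ties towards larger
  sample sets then lexicographic bitstrings — all deterministic.
* Samples failing `min_median_coverage` are dropped before analysis
  (default 0 = off); fewer than two surviving samples is an error.
* Purity defaults to $\min(1, 2 \times \mathrm{median\ founder\ VAF})$
  when not supplied (the source uses externally estimated purities
  without printing an estimator); no founder variants triggers a warning
  and a fall-back to all variants.
* The sampled-metastasis labels `M1, M2, ...` follow seeding chronology,
  not detection order.

# Known limitations

The Pam03-style acceptance fixtures bundled under `inst/extdata` are a
*synthetic stand-in* constructed from the published description of that
patient (sample names, purity range, coverage structure, the described
clade, the two under-covered driver-like cells); the original deposited
tables are not redistributable here, so published artifact counts are not
expected to reproduce exactly on the stand-in. Copy-number handling in
the analysis model is deliberately absent (observed VAFs are interpreted
under a het-diploid model); the simulator, in contrast, does generate
CNV-distorted VAFs, which is part of the noise the benchmarks measure.
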