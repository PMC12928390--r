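---
title: "Rank-based gene-pair classifiers for drug response: models and methods"
author: "pairVote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair classifiers for drug response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ex vivo drug screens on patient-derived acute myeloid leukemia (AML) cells
measure how strongly each drug suppresses cell viability across a
concentration series. Predicting those responses from a sample's
transcriptome would let clinicians prioritize drugs where a screen is
infeasible. Two features of this setting defeat most off-the-shelf
classifiers:

* **Class imbalance.** For most single drugs, sensitive samples are a small
  minority. A classifier that predicts "resistant" for everyone can post a
  high raw accuracy while being clinically useless.
* **Batch effects.** Training and application cohorts are profiled with
  different library preparations and platforms; absolute expression values
  shift enough that cross-cohort normalization becomes its own research
  problem.

`pairVote` implements a k-Top Scoring Pairs (kTSP) classifier, which answers
both problems with one idea: base every decision only on *within-sample
orderings* of gene pairs. An ordering `geneA > geneB` is unchanged by any
strictly increasing transformation of that sample's values, so predictions
are provably invariant to per-sample monotone distortions — the regime that
covers scaling, log transforms, and rank-preserving batch effects — and a
single sample can be classified with no reference cohort at all.

# The kTSP classifier

A **rule** is an oriented gene pair: observing `geneA > geneB` in a sample
contributes a +1 ("sensitive") vote, anything else (including a tie, since
the rule requires a strict inequality) contributes −1. A model is an
ordered, gene-disjoint list of `k` rules; the prediction is the sign of the
vote sum, with ties resolved by a configurable policy that defaults to the
conservative call, "resistant".

## Scoring pairs

For genes a and b with training labels S (sensitive) and R (resistant):

* primary score: `delta = | P(a > b | S) − P(a > b | R) |`, with the
  within-class probabilities estimated as empirical fractions and
  expression ties counted as 1/2. Ties are guaranteed in quantized data, so
  the convention is load-bearing, not cosmetic.
* secondary score: `gamma = | E(rank_a − rank_b | S) − E(rank_a − rank_b | R) |`,
  where ranks are within-sample ranks over the full profile. It breaks
  delta ties in favour of pairs whose ordering margin is larger.

All `G(G−1)/2` pairs are scored in one pass (a small C++ kernel; the scan is
O(G²·n)). Above a configurable cap (default 5000 genes) the matrix is first
reduced to the most variable genes, with a message.

## Selecting disjoint rules

Pairs are oriented so that `P(geneA > geneB | S) ≥ P(geneA > geneB | R)`,
sorted by (delta descending, gamma descending, lexicographic unordered
pair), and accepted greedily, skipping any pair that shares a gene with an
accepted pair, until `kMax` (default 15) rules are available. Gene
disjointness keeps one dominant gene from controlling several votes; the
orientation-independent tie-break makes training deterministic and makes
label-flipping flip every rule's orientation rather than its identity.

## Choosing k

For each candidate `k` the per-training-sample vote sums under the first
`k` rules are compared between classes with a Welch-type standardized mean
difference,

```
score(k) = |mean(votes | S) − mean(votes | R)| / sqrt(varS / nS + varR / nR),
```

and the maximizing `k` in 1–15 is chosen (ties to the smallest `k`,
favouring parsimony). One modification matters: each class variance is
floored at `4k/n`, the sample variance produced by a single discordant vote
per rule. Without a floor, a rule set that perfectly separates the training
samples has zero variance and an infinite score, so the smallest perfectly
separating prefix — often a single rule — would always win, discarding
informative rules and making the ensemble fragile. With the `4k/n` floor
the score of a perfectly separating prefix grows like `sqrt(k)`, so adding
further strong rules is rewarded, while a single strong rule still beats
noise: with one perfect rule followed by coin-flip rules, `score(1)` is
large and `score(2)` drops by an order of magnitude, so `k = 1` is chosen.

# Drug sensitivity quantitation

## Probit dose-response model and AUC

Viability (percent of control) across a seven-point concentration series
(3-fold dilutions from 10 µM down to 0.0137 µM) is modelled on the log10
concentration axis as

```
v(x) = 100 * pnorm(intercept + slope * x),
```

fitted by least squares — the maximum-likelihood estimate under
homoscedastic Gaussian errors. The optimizer is started from the
probit-linearized regression (exact on noiseless data) plus two fallback
starts; non-convergence is recorded on the fit object, never silently
replaced. A perfectly flat series bypasses optimization: the fit stores
slope 0 and the observed mean as its flat level, which may exceed 100 when
cells outgrow controls.

The **AUC** is the mean fitted viability over the screened log10 range
(composite trapezoid, 2048 panels), clipped to [0, 300]. This construction
makes a non-responsive profile score exactly 100, full kill score 0, and
growth-stimulated flat profiles integrate above 100. Samples are called
*sensitive* iff AUC < 100; exactly 100 is resistant.

## DSS and selective DSS

The drug sensitivity scores integrate the *inhibition* curve
`r(x) = 100 − min(v(x), 100)` over the window `[x1, x2]` where it exceeds
an activity threshold `Amin` (default 10%):

```
DSS1 = (AUCr − Amin (x2 − x1)) / ((100 − Amin)(Cmax − Cmin))
DSS2 = DSS1 / log10(Rmax)
DSS3 = DSS2 * (x2 − x1) / (Cmax − Cmin)
```

with `Cmin`, `Cmax`, `x1`, `x2` all on the log10 axis (which keeps every
ratio dimensionless), `Rmax` the top asymptote of the inhibition curve over
the screened range, and `AUCr` the trapezoid area of `r` over `[x1, x2]`.
Crossings of `r(x) = Amin` are found by bisection to 1e−8 after bracketing
on a 4097-point grid: the first up-crossing gives `x1` and the last
down-crossing `x2`, falling back to the range ends when the curve starts or
ends above threshold. If inhibition never exceeds `Amin` the score is 0 by
construction (`x1 = x2`). DSS2 and DSS3 require `Rmax > 1` so the
logarithm is positive; versions are selected with a flag since published
sDSS tables do not always state which variant they used.

The selective score is `sDSS = DSS_patient − mean(DSS_controls)`. When a
cohort provides sDSS rather than AUC, sensitivity is called by a pooled
percentile threshold (default the 95th, type-7 linear interpolation, strict
inequality) across all drugs and samples.

# Expression normalization

The chain mirrors standard practice for the cohorts this method targets:
RPKM is rescaled per sample to TPM (`TPM_ij = RPKM_ij / Σ_i RPKM_ij × 1e6`);
raw counts first become length-normalized rates (`counts / length`) and are
then rescaled the same way, with effective gene lengths a required user
input; matrices are restricted to protein-coding genes; and values enter
the classifier as `log2(TPM + 1)`. The pseudocount defaults to 1 (keeping
zeros at zero) and is configurable; because every downstream decision
depends only on within-sample orderings and `log2(x + c)` is strictly
increasing, the choice cannot change a kTSP prediction — it matters only
for the absolute-value comparators. TPM column sums of 1e6 (relative
tolerance 1e−6) are enforced by class validity, as is non-negativity on
linear scales.

# The benchmarking harness

Comparators (linear and RBF SVM, random forest, elastic net) are tuned by
random search under stratified 5-fold cross-validation, scored by mean
balanced accuracy. Default ranges: SVM cost log-uniform on [1e−3, 1e3], RBF
gamma log-uniform on [1e−5, 10], random forest fixed at 500 trees with
`mtry` uniform on [1, 2√p], elastic-net mixing uniform on [0, 1] and
penalty log-uniform on [1e−4, 10]; 20 draws by default. Two disciplines are
enforced structurally rather than by convention:

* **SMOTE placement.** When class balancing is on, synthetic minority
  samples (`x + u(x_nn − x)` toward one of the 5 nearest minority
  neighbours) are generated *inside* each fold from that fold's training
  portion only, then once more on the full training set for the final
  refit. Balancing before splitting would leak interpolated copies of
  held-out samples into training and bias the fold scores upward.
* **Standardization discipline.** z-score constants are fitted on training
  data only (zero-variance genes map to 0) and applied unchanged to test
  data.

Every comparator exposes a continuous decision score oriented so that
higher means sensitive; for SVMs, whose decision-value sign convention
depends on factor-level bookkeeping, the orientation is calibrated against
the training labels after fitting.

# Evaluation

Reported metrics are sensitivity, specificity, balanced accuracy (their
arithmetic mean — the identity is asserted on every report) and AUROC in
the Mann–Whitney formulation (ties counted 1/2 via mid-ranks). The kTSP
ranking score for AUROC is `(voteSum + k) / 2k`, the only continuous output
a voting classifier has. Rates whose denominator class is absent are
reported as undefined, never as zero. Drugs enter the train/test comparison
only with at least 20 sensitive and 20 resistant training samples and 10
of each in the test cohort (all inclusive bounds).

Per-drug group differences in sDSS between predicted-sensitive and
predicted-resistant samples use a one-sided Wilcoxon rank-sum test (exact
when both groups have ≤ 25 samples and no ties, otherwise the normal
approximation with continuity and tie corrections) with Benjamini–Hochberg
correction across tested drugs; drugs with an empty predicted group are
flagged untested rather than assigned p = 1.

Rule **compliance profiles** summarize, per sample, how many rules point in
their trained direction (+1/−1 votes, sums in [−k, k]) across sample
subgroups such as temporal cohorts. Since the underlying comparisons are
rank-based, compliance is invariant to monotone per-sample transforms. The
two-group comparison is quantified with a seeded bootstrap percentile CI
(1000 resamples) on the difference of group means — a deliberate choice of
a simple, assumption-light quantification. Gene **recurrence** counts, for
each gene, the number of per-drug classifiers using it, reports the
fraction of genes unique to one classifier, and tags each use as "over"
(gene votes sensitive when high) or "under".

# The synthetic cohort generator

The generator produces the statistical structure the classifier assumes,
with known ground truth, so every stage is testable without downloads.
Defaults are the package's study conditions: 1000 genes, 30 sensitive
versus 150 resistant samples (mirroring the minority-sensitive imbalance of
real single-drug screens), 10 embedded pairs, pair fidelity θ = 0.9, effect
size δ = 1.5 on the log2 scale, unit noise.

Background expression is iid Normal(8, 1). For each embedded pair, each
sensitive sample boosts gene a by δ with probability θ and gene b
otherwise; resistant samples are mirrored. Per-sample AUC values are drawn
uniformly from (60, 95) for sensitive and (100, 150) for resistant samples,
so the AUC < 100 threshold reproduces the intended labels exactly, and the
whole cohort is a pure function of its seed.

Two design choices deserve explanation because a naive generator breaks
its own purpose:

* **Per-pair baseline offsets.** If all genes shared one baseline, a
  cross-pairing (gene a of pair i against gene b of pair j) would have the
  same population delta as a true pairing — the marginal class shift of
  each boosted gene, not the pairing itself, carries the signal — and no
  method could recover the intended pairs. Both genes of pair i therefore
  share a baseline offset (`pairSpacing` = 3 log2 units between adjacent
  pairs), which pins cross-pair orderings to the same direction in both
  classes (delta ≲ 0.1) while leaving true-pair deltas untouched.
* **Deterministic pair placement.** Truth pairs occupy the first 2m genes.
  Placement is statistically irrelevant, but deterministic placement means
  two cohorts generated from configs differing only in seed share their
  signal structure, which is what a train/test design requires.

Monotone **batch distortion** applies, per batch, a map
`x → α(x − c)³ + βx + γ` with α ≥ 0, β > 0 drawn from a seed — strictly
increasing for all x by construction — emulating a batch effect that
visibly shifts distributions (the first principal component separates
batches) while preserving every within-sample ordering. Dose-response
curves are generated from the probit model on the standard dilution series
with optional Gaussian viability noise, clipped to [0, 300].

What the generator does *not* emulate: real AML expression marginals,
gene–gene correlation, mutation covariates, plate effects, or non-monotone
(rank-breaking) batch effects. Passing tests therefore demonstrate the
method's internal correctness and its claimed invariances, not clinical
performance on real cohorts.

# Problem sizes and numerical choices

The test suite runs the full study conditions where the claim depends on
them (truth-pair recovery and null calibration over 100 and 50 seeded
replicates, rank invariance over 50 random monotone maps, oracle
equivalence over 200 instances) and reduced cohorts (120 genes, 15/40
samples) where only structure is exercised. The acceptance script averages
a 10-replicate train/test study at full size. Other numerical constants:
trapezoid integration uses 2048 panels; crossing-point bisection stops at
1e−8; percentiles are type-7; optimizer restarts are fixed and finite.
Probit parameter recovery on noiseless curves is exact to 1e−4 and DSS
agrees with a 1e5-point dense-grid oracle to 1e−4.

# Limitations

Binary labels discard intermediate responders by construction; the
AUC = 100 cutoff is standard but hard. The k-selection criterion is a
declared Welch-type statistic — the literature names an analysis-of-variance
approach without fully specifying it, so ours is a documented choice, not a
claimed reproduction. Comparator tuning budgets (draw counts) trade
fidelity for runtime and are configurable. The generator's uniform AUC
ranges and Gaussian expression are transparent simplifications; none of the
package's guarantees depend on them, but absolute benchmark numbers on
synthetic cohorts should not be read as expected clinical accuracy.
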