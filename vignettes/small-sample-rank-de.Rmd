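---
title: "Exact rank-sum differential expression for tiny array studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact rank-sum differential expression for tiny array studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankDE)
```

## The problem

Classic expression-array studies of knockout mice often have three or four
arrays per group — too few for parametric moderated statistics to be
trusted blindly, and few enough that the exact permutation distribution of a
rank test can be enumerated completely. `rankDE` implements the
summary-level analysis used in such designs: a wild-type (WT) versus
conditional-knockout (KO) comparison of mouse corneas at two postnatal ages,
PN11 (3 arrays per group, before eyelid opening) and PN56 (4 per group,
adult), on arrays that report one linear-scale signal and one detection call
(Present / Marginal / Absent) per gene per array.

## Normalization model

Each array is globally rescaled by a single multiplicative factor so that
its trimmed-mean signal equals a target of 150 — the convention of the
instrument software these pivot tables come from. Two choices are made
explicit because the original software does not document them:

* **Trimming is count-based and symmetric.** With `k` signals and trim
  fraction `f` (default 0.02), the `floor(k*f)` smallest and largest values
  are removed before averaging. This makes results deterministic for any
  `k`; percentile-interpolation trimming would differ only microscopically
  at genome scale.
* **A signal floor of 10 is applied after scaling, and only for log-space
  statistics.** All group means are arithmetic means of
  `log2(max(signal, 10))`, so no mean log intensity can fall below
  `log2(10) = 3.3219` (printed 3.32), and fold differences between groups
  are `2^(difference of mean log intensities)` — a ratio of geometric means.
  Raw scaled signals are kept unfloored in the matrix itself.

## The exact test and its adaptive cutoff

For groups of sizes `m >= n`, `exact_rank_sum()` computes the Mann-Whitney
U (pairwise wins of the test group, ties counting one half, i.e. mid-ranks)
and enumerates all `choose(m+n, n)` assignments of the observed values to
the two groups. The two-tailed p-value is the null probability of a U at
least as far from the center `mn/2` as observed. Defining the two tails by
the symmetric distance `|U - mn/2|` (rather than doubling a one-sided tail)
coincides with the usual definition for tie-free data and remains
unambiguous with ties, because the enumeration is over assignments of the
observed multiset — a permutation-exact test.

The discreteness of this test is a feature, not a nuisance. With 3 vs 3
samples only `C(6,3) = 20` assignments exist, so the smallest achievable
two-tailed p is `2/20 = 0.1`: a nominal cutoff of 0.057 is unattainable and
must be relaxed to 0.1 (`min_achievable_p()`, and the `adaptive_min_p` rule
of the filter). With 4 vs 4, the two most extreme of the 70 assignments have
p = 2/70 = 0.029 and 4/70 = 0.0571; the latter rounds to the 0.057 cutoff
used for the adult contrast, which is why `kth_smallest_p()` exists —
it documents, without assuming, that such a cutoff admits exactly the two
most extreme orderings.

Enumeration is capped at 14 total samples (worst case 3432 assignments);
larger designs fall back to the tie-corrected normal approximation and are
flagged `exact = FALSE`. This package targets designs far below that cap.

## The four selection criteria

`compare_groups()` labels each gene `Increased`, `Decreased` or `Unchanged`
for a contrast of reference group A against test group B. All four criteria
must pass for a non-`Unchanged` label:

1. **Fold.** The higher-expressing group's mean exceeds `fold_threshold`
   (default 2) times the lower group's mean, strictly, on floored log2
   means.
2. **Detection.** The higher-expressing group has at least
   `min_present_high` (default 3) Present calls; the requirement is capped
   at the group size, so 3-member groups need 3/3. Marginal calls do not
   count as detected.
3. **Exact p.** The two-tailed exact rank-sum p (computed on floored
   signals, so sub-floor values tie) is at most `p_max` (default 0.057),
   relaxed to `min_achievable_p(m, n)` when `adaptive_min_p = TRUE`.
4. **Pairwise consistency.** Of the `m*n` cross-group sample pairs, at
   least `(m-1)*n` must individually show a fold of `pairwise_fold`
   (default 2) or more in the same direction as the group-mean difference,
   again on floored signals. The original software derived this from its
   probe-level change calls, which cannot be recomputed from summary data;
   re-expressing it as a per-pair fold requirement preserves the rule's
   intent — the difference must hold in essentially every pairing, not just
   on average.

No multiple-testing correction is applied; that is a faithful design choice
of the procedure being implemented, not an oversight, and it is why the
pairwise and detection criteria carry real specificity weight (on null
simulations the full filter calls well under 1% of genes even though the p
criterion alone would admit up to 10% at 3 vs 3).

## Downstream summaries

`build_crosstab()` counts genes over the triple (effect at PN11, effect at
PN56, developmental change between adult and immature WT), a 3x3x3 tensor.
`concordant_counts()` sums the doubly-Increased and doubly-Decreased cells
over the developmental axis; `modulated_overlap_percent()` compares how
often knockout-modulated versus unaffected genes also change
developmentally. The writer renders the tensor with the developmental axis
nested inside the PN56 axis — the published layout — while the internal
array stays layout-agnostic.

`overlap_enrichment()` cross-tabulates two direction-labelled lists,
compares the concordant cells with their independence expectations
(`row_total * col_total / N`), and tests the 3x3 table with Pearson's
chi-square, no continuity correction, df = 4. Genome-scale concordance can
drive p below double-precision underflow, so `log10(p)` is reported
alongside.

`keyword_tally()` counts genes whose GO Biological Process text contains
any of a set of case-insensitive substrings (defaults `"immun"`,
`"inflamm"` — deliberately prefixes, so no word-boundary logic is wanted)
and how many of them are up or down in any supplied contrast. A gene up at
one age and down at the other counts in both tallies.

`fold_activation()` implements dual-luciferase arithmetic: firefly counts
normalized by same-well Renilla counts, treatment mean divided by control
mean (mean-of-ratios, matching the "mean promoter activities" convention),
with the SEM of treatment replicates propagated through the control mean.
Whether that SEM should instead be taken across independent experiments is
not decidable from the procedure's description; per-well SEM is the
conservative computable choice.

## The synthetic generator

`simulate_experiment()` emulates the study design so the whole pipeline is
testable without any external download: WT/KO times PN11 (3 + 3 arrays) and
PN56 (4 + 4), per-gene log2 baselines `N(7, 1.5)`, additive per-sample log2
noise (`sd = 0.3`), and a planted effect of ±2 log2 units (4-fold) in a
configurable fraction (default 5%) of genes per age contrast, applied to
the KO samples. Noise additive in log2 makes signals log-normal, which is
what the pipeline's entirely ratio-based arithmetic presumes. Detection
calls are thresholded on the linear signal (Absent below 90% of the
threshold, Marginal within ±10%, Present above); with the default threshold
of 100 about 57% of calls are Present, matching the detection rates typical
of these arrays. Baseline mean 7 and sd 1.5 put most genes well above the
floor of 10 (log2 = 3.32) while leaving a realistic low-expression tail.

What the generator does **not** emulate: probe-level structure and the
instrument's actual detection-call algorithm, array spatial artifacts,
correlated gene-gene expression, and heavier-tailed real noise. Passing
recovery tests on this generator therefore demonstrates the pipeline's
arithmetic and its operating characteristics under its own model
assumptions — not performance on real arrays.

## Numerical choices and degenerate inputs

* p-value comparisons in the enumeration use a `1e-9` absolute guard so
  floating-point rank sums never drop an assignment that is exactly at the
  observed extremity; the p criterion applies the same guard at its cutoff.
* Ties in `rank_by_fold()` break by gene id, making top-k tables
  deterministic.
* A gene identical in both groups has fold 1 and direction 0; no pair can
  then be "same-direction", and criterion 1 fails anyway.
* An all-sub-floor gene collapses to complete ties: fold 1, p 1,
  `Unchanged` — the floor guarantees the filter cannot fire on noise below
  the detection regime.
* Scaling a constant-zero array is an error (its trimmed mean is 0), as is
  trimming away every value.
* One seed governs a whole simulated experiment; two calls with the same
  configuration are bitwise identical.

## Problem sizes used in the test suite

The suite verifies the exact test against a brute-force enumeration oracle
for all designs up to 5 vs 5, super-uniformity of null p-values with 1200+
replicates at the study's group sizes, filter monotonicity on 600-800-gene
simulations, chi-square agreement with the direct formula on random
fixtures, and parameter recovery (at least 90% sensitivity, at most 1%
false positives for planted 4-fold effects at `sd = 0.3`, 4 vs 4) on five
seeds of 2000-gene experiments — sizes chosen so the whole suite runs in a
few seconds while keeping every binomial margin comfortable.

## Known limitations

* Criterion 4 is a summary-level surrogate for probe-level change calls;
  on real legacy data its pass set can differ from the instrument's.
* The exact test's discreteness makes power step-wise in n; there is no
  way around p = 0.1 at 3 vs 3.
* Published genome-wide counts from the original legacy datasets (global
  DE counts, cross-study overlap enrichments) require those external data
  and are out of reach of the synthetic generator by design; the package
  reproduces the procedure and its desk-scale arithmetic, and verifies the
  rest by property-based testing.
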