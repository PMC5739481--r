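---
title: "Measure panels, high-sensitivity operating points and leaderboard instability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measure panels, high-sensitivity operating points and leaderboard instability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melrank)
```

## The evaluation problem

A melanoma CAD system maps a dermoscopic image to a posterior probability of
malignancy. Open challenges score such systems on a shared, fixed test
cohort — typically a few hundred lesions with a modest number of melanomas —
and publish a leaderboard under one chosen accuracy measure. Global measures
(average precision, AUC of the ROC) summarise performance over every
operating point and weight a missed melanoma the same as a false alarm.
Clinically, the two errors are not symmetric: a missed melanoma can be
fatal, a false alarm costs an unnecessary excision. High-sensitivity
measures — specificity at 95/98/99% sensitivity, or the partial AUC over the
sensitivity band [0.95, 1] — evaluate systems only in the regime a clinic
could actually use. The two families can order the same set of systems very
differently, and `melrank` exists to compute both correctly and to quantify
that disagreement.

## The measure panel and its conventions

All measures are computed from one `scored_cohort` (id, score in [0, 1],
benign/malignant label; melanoma positive) under a single set of
conventions. Where a challenge's exact convention is not public, the choice
below is the package's own, made for exact reproducibility, and is flagged
as such.

**Decision rule.** A lesion is called malignant iff score ≥ threshold. The
`≥` (rather than `>`) makes the threshold equal to the lowest melanoma score
achieve sensitivity 1 deterministically.

**Ties.** Lesions sharing a score move between confusion cells together:
the ROC and PR curves have one operating point per distinct score value.
Under a threshold semantics any per-record tie-break would be fictitious.
With this convention the trapezoidal AUC equals the Mann–Whitney statistic
with ties counted one half — a property the test suite checks against an
exhaustive pairwise oracle on hundreds of random cohorts.

**Average precision** is the uninterpolated step-sum
$\mathrm{AP} = \sum_k (R_k - R_{k-1})\,P_k$ over descending-score rank
positions, tie groups processed as blocks carrying the block-end precision.
No 11-point or interpolated-maximum variants are offered; those are
different estimands.

**Specificity at target sensitivity** uses the empirical rule: the best
specificity among operating points with SE ≥ target. It is exactly
reproducible, conservative, and always defined (threshold at the minimum
melanoma score gives SE = 1). A linear-interpolation variant
(`interpolate = "linear"`) reads specificity off the piecewise-linear ROC at
exactly the target; it is optimistic between attainable points and provided
for comparison only. On a 75-melanoma cohort the targets bite hard:
SE ≥ 0.98 permits at most one missed melanoma and SE ≥ 0.99 permits none,
so these measures hinge on the lowest-scoring one or two melanomas — the
source of both their clinical relevance and their statistical instability.

**Partial AUC** integrates specificity over sensitivity on [se_lo, 1]
(default se_lo = 0.95), treating the empirical ROC as piecewise linear in
sensitivity with linear interpolation at the cut. Integrating over
sensitivity (not over false-positive rate) is what makes "the area from 95%
to 100% sensitivity" well defined, bounded by 1 − se_lo, and equal to that
bound for a perfect classifier; the normalised variant divides by the band
width.

## Gaussian discriminant classifiers

`fit_gda()` fits the two-class Gaussian model in four variants: LDA (pooled
full covariance), QDA (per-class full), and their diagonal counterparts
dLDA/dQDA, which are Gaussian naive-Bayes classifiers. Estimator choices
the model family itself does not fix:

* class means are maximum likelihood; the pooled covariance is the
  within-class estimator with denominator $n-2$, per-class covariances use
  $n_k - 1$ (matching the conventions of standard discriminant-analysis
  implementations, against which the test suite cross-checks posteriors);
* a ridge $\varepsilon$ is added to the covariance diagonal, defaulting to
  $10^{-6}$ times the mean diagonal variance — zero-cost for well-posed
  problems, and it keeps $d \gtrsim n_k$ fits positive definite. With
  `ridge = 0` a singular fit is an error, not a silent pseudo-inverse.

Posteriors are computed in the log domain and mapped through the logistic
function: $\mathrm{logit}\,P(\text{mal}\mid x) = \log f_1(x) - \log f_0(x) +
\mathrm{logit}\,\pi_1$. A posterior outside $(10^{-15}, 1-10^{-15})$ is
flagged *saturated*: at double precision it collapses to exactly 0 or 1, so
several lesions can share the score 1.00 and no posterior threshold can
order them.

**Two sweeps, one curve.** The conventional operating sweep thresholds the
posterior from 0 to 1. The alternative sweeps the class prior: for each
prior in a grid, classify by posterior ≥ ½ and record the confusion point.
Varying the prior adds a constant to every lesion's log-odds, so the two
sweeps induce the same family of decision sets — *provided* the sweep is
computed on the log-odds scale, where lesion $i$ flips exactly at prior
log-odds $-\delta_i$ (its class-conditional log-density difference).
`prior_sweep()` therefore works entirely in log-odds, using a default grid
of 201 points uniform on $[-12, 12]$ augmented with the exact per-lesion
breakpoints, and the package asserts the resulting operating-point set is
*identical* to the threshold sweep's on random cohorts for all four
variants. Unlike the threshold sweep, the prior sweep never pushes scores
through the saturating logistic map, which is why it resolves the
saturated-posterior problem rather than merely relabelling it.

## Resampling

High-sensitivity measures on a cohort with 75 melanomas are functions of
one or two order statistics, so single-split estimates are fragile.
`cv_panel()` runs stratified k-fold cross-validation and, by default,
pools all out-of-fold posteriors into one cohort evaluated once; per-fold
panels are also reported and averaging them is available as
`aggregate = "per_fold"`. Pooling is the default precisely because a fold
with ~15 melanomas makes "specificity at 99% sensitivity" a near-degenerate
quantity. `k = n` is accepted as explicit leave-one-out: singleton folds
are unstratified by construction, their per-fold panels are undefined
(reported as `NA`) and only the pooled panel is meaningful.

`bootstrap_panel()` resamples the scored cohort B times — stratified by
default, preserving the exact class counts, so every resample keeps the
measures defined — and reports the replicate mean, the bootstrap standard
error (the replicate standard deviation) and the 2.5/97.5 percentile
interval. Percentile intervals were chosen over BCa for determinism and
simplicity; they are a documented, replaceable choice. Reproducibility is a
contract: resample b derives its seed from the master seed and the counter
b, so identical seeds give bit-identical results regardless of evaluation
order.

## Ranking and instability

`rank_systems()` orients all seven measures "larger is better" and assigns
competition ranks ("1224": tied systems share the best applicable rank, the
next rank is skipped), the standard convention for published leaderboards
with integer ranks. `rank_instability()` reports, per system, the maximum
rank shift across measure pairs, and per measure pair Kendall's tau-b
between rank vectors, computed by exhaustive pair counting with the tie
correction (leaderboards have tens of systems; quadratic cost is
irrelevant, and the implementation is verified against an independent
brute-force oracle and `stats::cor`).

## What the synthetic generator emulates — and what it does not

The generator mirrors the study conditions of a classification challenge:
a fixed test cohort of 379 lesions of which exactly 75 are melanomas (class
counts are constants of the design, not binomial draws), 900 training
images, and 25 participating systems. Per-system scores are drawn
class-conditionally from Beta mixtures: supported on [0, 1] like
posteriors, with bulk and tail behaviour independently tunable. Scores are
rounded to 10 decimals at generation, the same precision used on disk, so
in-memory and round-tripped analyses agree exactly.

The 25-system suite (`make_rank_reversal_suite()`) ships three frozen
archetypes. The *global optimiser* has excellent bulk separation plus a
small low-scoring melanoma component (and a thin high-scoring benign tail):
top average precision, but reaching 98–99% sensitivity forces the threshold
under the straggler melanomas and specificity collapses. The
*high-sensitivity optimiser* has melanoma scores bounded away from the
benign bulk: modest global measures, excellent high-sensitivity ones. The
remaining 22 systems form a graded mediocre family. The archetype constants
were found once by a seeded search and then frozen, so the engineered
property — rank 1 by average precision, a drop of at least five positions
under specificity at SE = 98%, and tau-b(AP, SE=99%) < 0.8 — is a stable,
tested property of the shipped default seed (2016). It is a qualitative
re-enactment at challenge scale, not a reproduction of any published
leaderboard's numbers, which would require the original submissions.

Real challenge data differ in ways the generator does not model: score
distributions are not Beta-shaped, systems' errors are correlated (they
train on the same images), scores cluster at round values, and real
submissions contain exactly saturated scores. Passing tests on this
substrate therefore validate the *evaluation machinery* — measure
definitions, operating-point extraction, ranking — not any claim about how
real systems behave.

## Numerical and degenerate-input choices

* Score files: comma-separated, decimal point, UTF-8; header auto-detected
  by a non-numeric second field (a single-line file is always data, so
  malformed rows fail loudly rather than being mistaken for headers).
  Scores of exactly 0 or 1 are legal but logged as saturated.
* A cohort must contain both classes for any curve-based measure; a
  single-class cohort is an error, not an NA.
* All-tied scores yield the two endpoints plus (1,1): the chance diagonal,
  AUC ½.
* Unstratified bootstrap resamples that come out single-class are dropped
  with a message; all-dropped is an error.
* Kendall tau-b is NaN when a rank vector is constant (no ordering
  information), mirroring the usual convention.

## Problem sizes used by the tests

The suite validates metric-oracle equivalence on 500 random cohorts of up
to 200 lesions, sweep equivalence on 100 random feature sets across all
four GDA variants, closed-form binormal recovery (AUC $\Phi(1/\sqrt2)
\approx 0.7602$) with pooled 5-fold CV at n = 4000, parameter recovery at
n = 20000, and the full 25-system suite at challenge scale. These sizes
give stable stochastic checks at interactive runtimes and are the package's
chosen reference conditions.

## Limitations

Everything upstream of the score file is out of scope: image reading,
segmentation and feature extraction are not modelled, and the feature
tables here are Gaussian by construction. The measure panel is binary-class
only. The specificity-at-sensitivity convention of any particular challenge
(interpolation, rounding of the melanoma count) is not publicly specified;
the package's empirical rule is one defensible choice and is stated rather
than hidden, with the interpolated variant available for sensitivity
analyses.
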