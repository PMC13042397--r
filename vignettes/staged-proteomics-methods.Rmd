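---
title: "Methods: tipping-stage detection and biomarker selection in staged proteomics"
author: "dnbpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tipping-stage detection and biomarker selection in staged proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnbpipe)
```

## Scope

`dnbpipe` analyses a staged, two-compartment proteomic expression matrix —
proteins by samples, log2 intensities with missing values — collected along
an ordered disease progression. The default vocabulary is the five-stage
esophageal squamous series ESO < MID < MOD < SED < ESCC, sampled in a
lesion (L) and an adjacent non-lesion (N) compartment; any other strict
stage order can be substituted. The pipeline chains:

1. preprocessing (median normalisation, log2 transform, completeness filter);
2. dynamic network biomarker (DNB) analysis calling the *tipping stage*;
3. a pre/post phase split at the tipping stage;
4. normality-gated differential expression with fold-change bounds;
5. fuzzy c-means clustering of per-stage trend profiles;
6. EMT signature scoring with a phase comparison;
7. SVM-RFE biomarker-panel selection with cross-validated AUC;
8. ligand-receptor crosstalk ranking between the L and N compartments.

Because cohorts of this kind are rarely deposited, the package ships a
first-class synthetic generator with planted ground truth; every recovery
and calibration claim below is computed by the test suite or the acceptance
script, on that generator.

## Preprocessing

**Median normalisation.** Each sample column is shifted (log2 scale) or
rescaled (raw scale) so its median over observed values equals the global
median of pre-normalisation column medians. Targeting the global median —
rather than zero — keeps values on the interpretable log2-intensity scale.
The operation is idempotent and commutes with column permutation.

**Missing values are never imputed during preprocessing.** Intensity-
dependent dropout is the dominant missingness mechanism in DIA proteomics,
and imputation would contaminate the within-stage variance and correlation
statistics the DNB analysis depends on. Each downstream operation declares
its own policy: pairwise-complete correlations (DNB), per-sample member
dropping (EMT scores), complete-case testing with a minimum of 3
observations per group (differential expression), and a label-free
per-feature median fill only where learners require a complete matrix
(panel module).

**Completeness filter.** A protein is retained when observed in at least
`min_frac` (default 0.5) of the samples of at least one (stage,
compartment) group. The threshold is a package choice — surfaced in the
configuration — since proteomic pipelines differ widely here; 0.5 keeps
proteins that are cleanly detected in one biological state but absent in
another, which is exactly the pattern stage-specific detection looks for.

## DNB analysis: the composite index

At each stage \(s\) of one compartment, with the stage's samples only, the
package computes per-protein standard deviations (\(n-1\) denominator) and
the matrix of absolute pairwise-complete Pearson correlations. Correlations
backed by fewer than `min_pairs` (default 3) shared observations are
flagged undefined and excluded from averages — never coerced to zero.

A candidate module \(M\) is scored by the composite index

\[
\mathrm{CI}(M, s) \;=\; \frac{\overline{\mathrm{SD}}_{\mathrm{in}} \cdot
  \overline{|\mathrm{PCC}|}_{\mathrm{in}}}
  {\max\!\big(\overline{|\mathrm{PCC}|}_{\mathrm{out}},\ \varepsilon\big)},
\]

where the three terms are the mean member SD, the mean absolute
correlation over member pairs, and the mean absolute correlation between
members and all non-members. Near a critical transition, theory predicts a
group of molecules whose fluctuation and mutual coupling rise while their
coupling to the rest of the system falls, so CI spikes just before the
transition. The floor \(\varepsilon = 0.01\) (configurable) prevents
division blow-up for perfectly decoupled modules. Absolute correlations
are used throughout because coordination strength, not sign, carries the
early-warning signal.

**Module discovery.** The framework the index comes from does not fix a
candidate-search recipe. `dnbpipe` uses the simplest faithful realisation
of "a group with high internal correlation": average-linkage hierarchical
clustering on the distance \(1 - |\mathrm{PCC}|\) (undefined pairs at
distance 1), tree cut at height 0.5, candidates = all groups of at least 5
members. All three knobs are exposed. At small group sizes (around 10-20
samples) chance correlations regularly produce candidate modules in pure
noise — that is why significance is assessed by permutation rather than by
the mere existence of a module; with around 30 samples per group chance
modules essentially vanish at the default cut.

**Tipping call.** Per stage, the best candidate is the CI maximiser (ties:
larger module, then lexicographically smallest member set — determinism).
The tipping stage is the argmax of the per-stage best CI (ties resolved to
the earliest stage). Stages with no candidate score CI = 0 and are flagged.
The CI is computed on normalised log2 data without reference-stage
standardisation; since adding a per-protein constant leaves SDs and
correlations unchanged, per-protein centring would not alter the call
(this location invariance is asserted by a test).

**Permutation significance.** The null shuffles the sample-to-stage
assignment within the compartment (group sizes preserved) and recomputes
each stage's best CI; \(p(s) = (1 + \#\{\mathrm{CI}^{null}_s \ge
\mathrm{CI}^{obs}_s\})/(B+1)\). Note that the p-value of the *argmax* stage
is selection-biased: with five exchangeable stages, around 20% of null
datasets show \(p \le 0.05\) at the argmax, and the calibration test
budgets for exactly that.

**Phase interpretation.** The tipping stage closes the "pre" phase: under
the default order with tipping at MID, pre = {ESO, MID} and post =
{MOD, SED, ESCC} — i.e. the stage after the tipping point marks the start
of the relatively irreversible state. The pipeline feeds the L-compartment
call into the phase split by default and exposes a manual override,
since a final staging decision in practice triangulates both compartments
and biology.

## Differential expression

For each protein with at least 3 observed values per group, the test is
chosen by a Shapiro-Wilk gate at \(\alpha_{norm} = 0.05\) (level and test
are package choices): Welch's t when both groups look normal, Wilcoxon
rank-sum otherwise (exact null when both groups have at most 10 values and
no ties; normal approximation with tie correction otherwise — group sizes
of 5-19 straddle the exact/asymptotic regime). Welch rather than pooled
variance because group sizes are unequal by design (e.g. 19 vs 11).

The fold change is computed on log2 means, \(\mathrm{FC} =
2^{\bar{x}_A - \bar{x}_B}\), and calls use strict inequalities:
up requires \(p < 0.05\) and FC > 1.20; down requires \(p < 0.05\) and
FC < 0.83. Note the asymmetry of the bounds: 1/1.20 ≈ 0.833 > 0.83, so a
mirrored contrast does not automatically mirror the calls. No multiple-
testing correction enters the calls — this reproduces the operational
definition the thresholds come from — but a Benjamini-Hochberg column is
emitted for information.

**Stage-specific proteins** use a pure presence rule: detected in at least
`presence_frac` (default 0.6) of one stage's samples and below that
fraction in every other stage of the compartment.

## Trend clustering

Per-stage mean profiles (mean over observed values; proteins unobserved at
any stage are excluded with reasons) are row-standardised so clusters group
trajectory *shapes*. Fuzzy c-means then alternates the classical updates

\[
u_{ic} = \Big(\sum\nolimits_k (d_{ic}/d_{ik})^{2/(m-1)}\Big)^{-1},
\qquad
c_c = \frac{\sum_i u_{ic}^m x_i}{\sum_i u_{ic}^m},
\]

with Euclidean distance, stopping when the largest center movement falls
below `tol`. Defaults: c = 4 clusters (matching the four canonical trend
shapes: rising, falling, mid-peak, tipping-peak), fuzzifier m = 1.25, best
of 5 seeded restarts by objective (fuzzy c-means is initialisation-
sensitive; restart seeds derive from the master seed so runs stay
deterministic). Membership rows sum to one at every iteration and the
objective is non-increasing; both are recorded by the implementation and
asserted by tests. Core cluster membership uses a 0.5 threshold by
default. The converged objective was cross-checked against an independent
fuzzy c-means implementation (`e1071::cmeans`, which reports the same
functional as a per-point mean).

## EMT scoring

The EMT score of a sample is the mean of its observed mesenchymal-set
values minus the mean of its observed epithelial-set values, in log2
units. Missing members are dropped per sample and set coverage is
reported; a sample loses its score only when an entire set is missing.
The shipped GMT (`inst/extdata/emt_sets_synthetic.gmt`) is an
*illustrative* set for demonstrations, clearly marked non-canonical —
real analyses should supply a curated signature. Phase comparison reuses
the normality-gated two-sample machinery on the score vectors.

## Panel selection

Phase labels (post = positive) feed a linear-SVM recursive feature
elimination: fit on surviving features, rank by squared weight
\(w_j^2\), drop the bottom 10% (at least one), repeat; the reversed
elimination order is the importance ranking. C = 1 throughout, per
standard SVM-RFE practice. Candidate panel sizes are scored by
cross-validated AUC in which the ranking is *re-run inside every training
fold* — selection leakage is excluded by construction and a dedicated
test plants a feature informative only on held-out folds to confirm CV
AUC stays at chance. The default selection rule is fixed k = 7 (the
seven-protein panel setting); a one-standard-error rule is available.
AUC is the Mann-Whitney statistic with midranks, verified against an
exhaustive pair-count oracle and the inversion identity
\(\mathrm{AUC} + \mathrm{AUC}' = 1\).

The benchmarking harness evaluates five learners (linear SVM, RBF SVM,
logistic regression, random forest, k-NN) on identical stratified folds
with fold-internal standardisation. Five learners rather than ten: the
harness, not the roster, is the reusable part, and the set is extensible
via the registry.

**Known limitation.** At the default conditions (64 samples, 300
features, 1-log2-unit panel shift against within-group noise SD drawn
from U(0.5, 1)), the squared-weight ranking recovers on average about
4-5 of the 7 planted features in the top 7, while a univariate |t|
screen would recover about 6 of 7. The multivariate weight ranking lets
overfit noise features displace the weakest planted features at this
sample size; held-out AUC is nonetheless ≥ 0.9 because the recovered
features carry most of the signal. Users whose goal is feature *recovery*
rather than compact classifiers should corroborate the RFE ranking with
univariate statistics.

## Crosstalk ranking

At a chosen stage (default MOD), proteins expressed in at least half of a
compartment's samples are ranked by mean expression, ranks rescaled to
(0, 1]; an annotated ligand-receptor pair scores the product of the
ligand's rank in the source compartment and the receptor's rank in the
target compartment, both directions evaluated, top 50 per direction kept.
Rank-product scoring is deliberately scale-free (invariant to monotone
transforms) and deterministic; it is an "iTALK-style" ranking device, not
a port of any tool, and carries no statistical test — the output is a
ranked shortlist for inspection.

## The synthetic generator

Per sample \(j\) of stage \(s\): \(x_{pj} = b_p + t_p(s) +
\textrm{shifts} + m_j + e_{pj}\) with protein baseline \(b_p \sim
N(20, 2^2)\) log2 units, per-sample loading \(m_j \sim N(0, 0.3^2)\)
(removed by median normalisation), and noise \(e_{pj}\) with per-protein
SD \(\sigma_p \sim U(0.5, 1)\). Planted structure, all in the L
compartment by default:

* **DNB module** (15 proteins): noise built from a shared factor,
  \(e = \kappa\sigma_p(\sqrt{\rho} z_j + \sqrt{1-\rho} w_{pj})\), with
  \(\rho^* = 0.8,\ \kappa = 3\) at the tipping stage (default MID) and
  \(\rho_0 = 0.1,\ \kappa = 1\) elsewhere. The shared-factor construction
  gives the target equicorrelation exactly in expectation at O(d) cost.
* **Trend templates** (50 proteins each): rising (0, .25, .5, .75, 1),
  falling (reversed), mid-peak (0, .5, 1, .5, 0), tipping-peak (1 at the
  tipping rank), scaled to 1 log2 unit.
* **Panel** (7 proteins): +1 log2 unit in post-phase samples.
* **EMT drift** (10 + 10 proteins): ±0.15 log2 units per stage rank.
* **Missingness**: each cell dropped with probability proportional to
  \(\mathrm{logistic}(-(x - q))\) (q = global median), rescaled to an
  expected 20% overall — the intensity-dependent dropout typical of DIA.

Group sizes default to the biopsy-cohort shape (L: 10/19/11/14/10,
N: 8/17/8/10/5). Effect sizes are calibration choices, set once to be
detectable but not trivial — the source cohort publishes no effect-size
estimates. The generator does **not** simulate peptide-level structure,
batch effects, subject pairing, or compartment-correlated signals, so
passing recovery tests demonstrates algorithmic correctness under a clean
generative model, not performance on real cohorts.

## Problem sizes used by the validation suite

The test suite and acceptance script run: tipping recovery at the full
default conditions (2000 proteins, 112 samples, 50 seeds in the test
suite, 20 in the script); DE null calibration at 2000 proteins (5 and 3
seeds respectively); permutation calibration at 300 proteins with B = 99
(20 and 10 seeds); trend recovery on the planted trend proteins of the
default matrix (20 and 10 seeds); panel recovery at 300 features
(20 and 10 seeds); CI oracle equivalence on 100 random instances plus
full enumeration of all 1573 modules of size ≤ 5 in a 12-protein
instance. These sizes are the package's validation design; all are
configurable.

## Numerical and degeneracy conventions

* Correlation pairs with fewer than `min_pairs` shared observations, or a
  zero variance, are NA and excluded from CI averages; a module whose
  member pairs are all undefined is rejected with a reason.
* A protein constant within a stage has SD 0 and undefined correlations.
* Fuzzy c-means distances of exactly zero assign full membership to the
  coincident center(s).
* Zero-variance features receive unit scale during standardisation
  (leaving them centred at zero) rather than dividing by zero.
* Two-group tests on zero-variance-both, equal-mean inputs return p = 1.
* All randomness derives from explicit seeds; derived seeds stay within
  the 32-bit integer range.
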