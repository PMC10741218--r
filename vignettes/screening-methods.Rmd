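---
title: "Screening circadian genotypes for seasonality associations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening circadian genotypes for seasonality associations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronomood)
```

`chronomood` screens candidate circadian clock loci for single-gene and
two-locus (epistatic) associations with seasonality and mood phenotypes,
and separates genotype effects that act on mood directly from those
mediated by chronotype. This vignette is the package's account of the
models behind each stage, the parameters that matter, and the design
choices made where the methodology was genuinely open.

## The synthetic cohort generator

Every stage of the pipeline is validated on cohorts from
`simulate_cohort()`, which emulates the statistical structure a
candidate-gene seasonality study presents:

* **Genotypes.** Nine loci (CLOCK3111, CRY1, CRY2, PER2, PER3A/B/C, the
  PER3 VNTR, ZBTB20), each drawn i.i.d. under Hardy–Weinberg equilibrium
  $( (1-q)^2,\; 2q(1-q),\; q^2 )$ from a configurable minor-allele
  frequency (default $q = 0.3$ for every locus — the real study's allele
  frequencies are not public, so a single mid-range default is declared
  rather than inferred).
* **Clinical covariates.** Gender with the F:M ≈ 197:76 imbalance that
  sex-stratified analyses face, a young-adult age split (≤22 / >22),
  four socioeconomic classes, and anxiety/sleep-disturbance scores.
* **Outcomes.** A shared latent predictor $\eta$ accumulates the planted
  effects. SPAQ is a clipped, rounded Gaussian, $\mathrm{clip}_{[0,24]}
  (\mathrm{round}(7 + \eta + \varepsilon))$ with $\varepsilon \sim
  N(0, \sigma^2)$, $\sigma = 3$ points by default; BDI is analogous on
  0–60; SAD is Bernoulli with $\mathrm{logit}^{-1}(\mathrm{logit}(0.125)
  + \eta)$, matching the ~12.5% prevalence of seasonal symptoms such
  populations report. Linear score / logistic label mirrors the linear
  and logistic regressions used downstream.
* **Planted effects.** A `planted_effect()` adds `beta` to $\eta$ for
  carriers of its target genotype level(s) — both levels jointly for an
  epistatic pair, so `beta = log(5)` on the SAD channel plants an odds
  ratio of exactly 5. Sex-restricted effects multiply the carrier
  indicator by a gender indicator. Mediated effects first shift the
  chronotype mediator, `meq <- meq + a * carrier`, and the outcome then
  receives `b * (meq - mean)`, so the indirect effect is the product
  $a \cdot b$ and `beta` is the residual direct path.
* **Missingness** is MCAR at a configurable per-cell rate (the original
  study does not characterize its missingness mechanism), never touching
  outcomes.

What the generator deliberately does *not* emulate: linkage
disequilibrium between loci, item-level survey structure,
population stratification, and informative missingness. Passing tests
therefore demonstrate that the *procedures* behave as specified on data
satisfying their assumptions — not that real cohorts satisfy them.

The chronotype dispersion `mediator_sd` defaults to 8 (an MEQ-like
spread). The mediation-recovery checks use `mediator_sd = 1`: the
canonical mediation benchmark (a = 0.5, b = 0.6, c′ = 0.2, ACME = 0.30)
presumes a unit-scale mediator, and at dispersion 8 a `b` of 0.6 would
push the bounded score into its clipping region and bias every path
estimate.

## Feature space and encoding

The 14 one-way features are the nine genotypes plus gender, MEQ, MSF,
age group and SES. All $\binom{9}{2} = 36$ genotype pairs are added as
categorical features over the 9 joint levels (324 pair-level
combinations). Non-binary categorical features are one-hot encoded with
the *most frequent observed level* removed as reference (ties broken by
the lexicographically first tied level — an arbitrary but deterministic
rule), and indicator columns absent from every sample are pruned. The
encoding map retains enough information to reconstruct any subject's
original level from its indicator pattern, which the tests exercise as a
round-trip invariant.

MEQ and MSF stay continuous in the design matrix; where a method needs
discrete inputs they are cut into 3 equal-frequency bins, matching
genotype cardinality. Binarization thresholds follow the instruments:
SPAQ ≥ 11 seasonal, BDI ≥ 14 depressed, SAD as recorded.

kNN imputation (k = 5, Euclidean distance over mutually observed
standardized columns, scaled for overlap) and SMOTE (k = 5, synthetic
minority points $x + \lambda (x_{nn} - x)$, $\lambda \sim U(0,1)$) are
fit inside training folds only. The source methodology is silent on
where balancing sits relative to cross-validation; fold-internal
application avoids leaking test subjects into the synthetic minority
points and is the defensible default.

## Consensus feature selection

Five selectors run on each of the 100 training folds (10 repeats × 10
stratified folds):

* **CHI2** — Pearson chi-squared of the (discretized) feature × class
  table; for a 0/1 indicator this is the classic 2×2 statistic
  $N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$.
* **ReliefF** — k = 10 nearest hits/misses per instance, all instances
  used, range-normalized differences.
* **CFS** — best-first forward search over the merit
  $k \bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}$ with symmetrical
  uncertainty as the correlation, stopping after 5 consecutive
  non-improving expansions (subset capped at 20).
* **mRMR** — greedy $I(f;y) - \frac{1}{|S|}\sum_{s \in S} I(f;s)$.
* **JMI** — greedy $\sum_{s \in S} I((f,s); y)$.

Mutual information is the empirical plug-in estimator in bits, verified
in tests both against direct table summation and the identity
$I = H(X) + H(Y) - H(X,Y)$. Ranking methods contribute their top-20 per
fold and the MI subset methods use d = 20 — the source describes a final
top-20 but never a per-fold cardinality, so the final width is mirrored;
CFS self-terminates. The consensus top-20 pools methods by mean
selection frequency (ties by name); the *stable set* is features at
frequency ≥ 0.8 in ≥ 3 of 5 methods, reading "80% of the runs" as 80 of
the 100 fold-runs.

A caveat the tests document honestly: fold-runs of a repeated CV share
~90% of their subjects, so per-method selections are nearly
deterministic given the sample. Under a pure-noise cohort the features
that happen to correlate most with the outcome *in that sample* (the
maximum of ~300 chi-squared draws, independent of n) are selected
consistently by CHI2, mRMR, JMI and CFS alike, so the stable set is
rarely empty under the null. Selection-frequency stability measures
robustness to fold perturbation, not statistical significance — which is
exactly why the pipeline follows it with regression on held-out
significance scales rather than treating stability as inference.

## Classification benchmark

LR (ridge, 4 penalties), SVM (linear/RBF × 3 costs), random forest
(trees × terminal-node caps) and XGBoost (depth × learning rate) are
tuned by inner 5-fold grid search on accuracy, refit, and scored on the
outer test folds against the majority-class baseline. Small lattices are
a deliberate choice: the benchmark's role is comparative, not
leaderboard accuracy. Because training folds are SMOTE-balanced,
classifiers predict near 50/50 under a null; the calibration check
therefore uses a balanced null cohort, where the majority baseline
coincides with chance and accuracy must track it.

## Regression battery

Univariate logistic regression runs per stable feature; on a single
binary indicator the fitted OR equals the contingency cross-product
ratio exactly, which anchors the tests. Wald 95% intervals are the
default (profile likelihood available); complete separation is flagged
and reported with an unbounded interval rather than a spurious one.
Multivariate models start from the full top-20 and apply bidirectional
stepwise-AIC (`MASS::stepAIC`); the AIC trace is asserted non-increasing.
Logistic models serve binary outcomes, linear models the SPAQ/BDI
scores. The adjusted-p method is not stated by the source; Benjamini–
Hochberg is the default with Bonferroni and none as options, applied
within each analysis × stratum × outcome family. Type-III two-way ANOVA
(genotype × gender) uses sum-to-zero contrasts via `car::Anova`, with
Tukey HSD over the four cells; on balanced designs it provably equals
sequential ANOVA, and the tests verify both that identity and agreement
with a QR-based OLS contrast oracle to 1e-8.

## Mediation

Both models are linear — `M ~ T` and `Y ~ T + M` — so ACME = $\hat a
\hat b$, ADE = $\hat c'$, and the total effect equals the reduced-form
slope of `Y ~ T` *exactly* (a nested-OLS identity the tests assert to
1e-10). Inference is a non-parametric bootstrap (default 1000 resamples;
percentile intervals; sign-based two-sided p-values floored at
$2/B$). The mediation call follows the decision rule: mediation
confirmed when the ACME p < 0.10; *full* if additionally the ADE
p ≥ 0.10, *partial* if the ADE is also significant, *none* otherwise.
Logistic-outcome mediation and treatment–mediator interactions are out
of scope.

## Association rules

Subjects become transactions of `FEATURE=LEVEL` items (continuous
clinical scores quartile-binned; genotypes at raw levels), with the
binarized disorder as the designated consequent. Apriori grows
antecedents level-wise with downward-closure pruning, counting support
jointly with the consequent, and keeps rules with support ≥ 0.04,
confidence ≥ 0.7 and total size ≤ 6, sorted by lift (ties: support, then
antecedent). The implementation is asserted equal — rule set and all
three metrics — to exhaustive enumeration on small alphabets. The rule
network maps items to nodes (size = max support) with edges to the
consequent (width = confidence), exported as GraphML/CSV.

## ARACNE networks

Variables (genotypes, MEQ, MSF, the outcome) are discretized to 3
equal-frequency bins; pairwise MI uses the same plug-in estimator as the
selectors. The data-processing inequality motivates the pruning rule: in
a chain $X \to M \to Y$, $I(X;Y) \le \min(I(X;M), I(M;Y))$, so for every
fully connected triplet the weakest edge is removed when strictly below
$(1-\varepsilon)$ times both others ($\varepsilon = 0$ by default;
exact ties remove nothing). All triplets are judged against the original
matrix, making pruning order-independent and limiting removal to one
edge per triplet. Bootstrap resampling (default 100 replicates) scores
each edge by the fraction of replicates retaining it; edges at support
≥ 46% survive. An optional MI floor (`min_mi`) treats near-zero
empirical MI — which is almost surely positive on finite samples — as
absent before pruning; the default of 0 reproduces the plain algorithm.
Genotypes are labeled *direct* (retained edge to the disorder),
*mediated* (no direct edge, but genotype–mediator and mediator–disorder
edges retained) or *none*.

## Problem sizes and numerical choices

The validation suite uses desk-scale problem sizes chosen to give each
check adequate Monte-Carlo resolution: Hardy–Weinberg at n = 10,000
against a binomial oracle; epistatic-OR recovery at n = 500 over 100
replicates; mediation at n = 1000 with 500 bootstraps over 100
replicates; DPI chain removal at n = 5000 over 100 replicates; path
labels at n = 2000 over 50 seeds; null calibration at n = 1000 over 500
replicates; noise-stability at n = 150 over 50 replicates. Determinism
is part of the contract: every stochastic operation takes a seed, and
rerunning any stage — or the whole pipeline — with the same seed
reproduces its artifacts byte for byte.

## Known limitations

* The stable-set criterion is not null-calibrated (see above); treat it
  as a screening device.
* Wald intervals understate uncertainty near separation; separated fits
  are flagged instead of silently reported.
* The DPI prune assumes the indirect dependency is *weaker* on the MI
  scale; near-deterministic mediators can defeat it.
* MCAR missingness and LD-free genotypes make the generator an
  optimistic testbed relative to real cohorts.
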