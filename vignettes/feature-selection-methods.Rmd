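---
title: "Three-stage feature selection for EEG band-power classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-stage feature selection for EEG band-power classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfsel)
```

## The problem

Multiclass motor-imagery brain–computer interfaces commonly classify
Welch band-power (PSD) feature vectors: with 8 electrodes (C3, Cz, C4,
CP1, CP2, P3, Pz, P4) and 12 bands from 8 to 30 Hz in 2 Hz steps, every
analysis window carries 96 features, refreshed 16 times per second
(1 s windows hopped by 32 samples at 512 Hz, i.e. 93.75% overlap).
Most of those features are irrelevant for a given user, and a live BCI
must produce a decision every half second, so the goal is to cut the
96-dimensional vector down to a handful of features without losing
accuracy. `eegfsel` implements a three-stage selection pipeline plus the
supporting neurofuzzy classification protocol.

## The classifier underneath

The wrapper stages need a classifier. `fit_fuzzy_model()` learns
fuzzy if-then rules in one sequential pass: features are min/max
normalized to $[0,1]$ from the learning session, and each sample either
expands the core of the best-matching same-class rule whose conjunctive
activation reaches the vigilance $\rho_v$, or seeds a new rule with a
point core. A rule holds one trapezoid per feature — full membership on
the core $[l_j, u_j]$, linear decay to zero over the fuzziness width
$\gamma_f$ — and fires with the minimum of its per-feature memberships.
`prune_rules()` then plays a second session through the model: each
sample's winning rule collects a success or an error, and rules with
strictly more errors than successes are discarded. With three learning
sessions there are $3 \times 2 = 6$ (learn, prune) permutations
(`build_models()`), and at test time every half-second window is decided
by majority over $48 = 6 \times 8$ votes (`vote_predict()`).

This classifier is a deliberately *static* stand-in for the dynamic
fuzzy-ART family it emulates: the original architecture defines rule
activation through differential equations whose parameters are not
reproducible here. The criterion layer below only needs the per-class
fuzzy sets, which the static model provides faithfully; published
real-data accuracies obtained with the dynamic classifier are therefore
out of reach by construction, and nothing in this package claims them.

Defaults $\rho_v = 0.75$ and $\gamma_f = 0.1$ (normalized units) were
fixed once by the synthetic-recovery tests, not by any publication, and
are plain arguments everywhere.

### Decisions the original description leaves open

* **Winner selection.** Maximal activation wins; ties break to the
  lowest rule index. Rationale: determinism.
* **Pruning guard.** If pruning would leave a class with no rules, its
  best rule (largest success − error, lowest index on ties) is kept.
  The degenerate case is otherwise undefined.
* **Vote ties.** A tied half-second vote repeats the previous decision
  when one exists, else takes the lowest class label.
* **Normalization.** Per-feature min/max from the learning session
  only; test values are clipped into $[0,1]$. A constant feature maps
  to 0.5 (uninformative midpoint).

## Stage 1 — discriminant character

**Statistical route.** For class $i$ and feature $j$, with empirical
prior $P_i$, within-class population variance $\gamma_{ij}$ and total
population variance $\lambda_j$, the normalized variance is
$\tilde\gamma_{ij} = P_i \gamma_{ij} / \lambda_j$. Population (divide
by $n$) variances are used so the law of total variance makes
$\sum_i \tilde\gamma_{ij} \le 1$ exact, with equality iff the class
means of feature $j$ coincide. Two condensations are available:

* the *product* criterion $J(x_j) = \prod_i \tilde\gamma_{ij}$, bounded
  by $(1/C)^C$ ($1/27$ for three classes), attained exactly by features
  with no mean separation — **low values are discriminant**; this is
  the default ranking criterion;
* the *entropy* criterion
  $J(x_j) = \sum_i \tilde\gamma_{ij}\log\tilde\gamma_{ij}$
  (natural log, $0\log 0 = 0$), which ranges in $[-\log C, 0]$; here
  the non-discriminant case sits at the *minimum* $-\log C$, so **high
  values are discriminant**. Each criterion carries its own direction
  tag and `score_run()` always ranks most-discriminant-first; rankings
  from the entropy form are invariant to the log base.

**Fuzzy route.** `intermediate_model()` collapses a learned+pruned
model to one prototype rule per class (feature-wise mean of the class's
rule cores). For each feature the per-class fuzzy sets are compared
pairwise with the fuzzy Jaccard ratio
$F = \int \min(\mu_A, \mu_B) \,/\, \int \max(\mu_A, \mu_B)$, integrated
by the trapezoid rule on a uniform 1001-point grid spanning both
supports (configurable); $F$ near 0 marks a discriminant feature. With
three classes there are three pairs per feature; they are aggregated by
`min` by default — a feature that cleanly separates *any* pair is
useful — with `mean` as the alternative. The pairwise definition does
not dictate an aggregation; `min` is this package's choice.

## Stage 2 — score, order, candidate selection

Each criterion run ranks the features and awards scores
$10, 9, \dots, 1$ to the ten best (ties to the lower feature index), so
every run distributes exactly 55 points. The statistical route scores
once per learning session (3 runs); the fuzzy route once per
(learn, prune) permutation (6 runs). Scores are summed per feature and
the candidate count $K$ is the smallest $k$ whose cumulative score
fraction strictly exceeds $\rho$ (default $\rho = 0.85$): for a single
run the cumulative fractions are $10/55, 19/55, \dots$ and $K = 7$.

## Stage 3 — wrapper selection

Both wrappers score a subset by the **regularity criterion (RC)**: the
mean voted test accuracy over the six ordered (learn, prune, test)
session permutations (`evaluate_subset()`). Within one permutation a
single model is available, so each half-second window aggregates its 8
per-vector votes; the full 48-vote protocol applies at final validation.

* **Order selection** evaluates only the score-ordered prefixes
  $(x_1), (x_1,x_2), \dots$ and keeps the best one (shorter on ties).
* **GMDH forward selection** starts from the best single feature and
  accepts the best one-feature extension only while RC strictly
  improves; the accepted trace is strictly increasing and an accepted
  feature is never swapped out. (A selection step that replaces an
  earlier feature is outside strict forward search; the package treats
  such published sequences as typos and does not emulate them.)

`unified_model()` builds a cross-user subset: per user, the features
every method agrees on (set intersection); across users, the union.
On the shipped per-user reference selections this yields
`{2, 3, 4, 26, 38}` — five features.

## The synthetic world

`generate_sessions()` emulates the structure the method assumes: 3 task
codes (2 = LEFT, 3 = RIGHT, 7 = WORD) in 15 s constant-label blocks
(240 vectors at 16 vectors/s), 4-minute sessions, 96 strictly positive
features. Marginals are lognormal (heavy-tailed, positive — a sensible
band-power surrogate; the real marginals are not characterized
anywhere, so this is a modelling choice with $\sigma_{\log} = 0.4$).
Class signal enters a designated subset of features as a one-vs-rest
multiplicative power shift: each informative feature is modulated by
exactly one class, offset $\text{effect} \times \sigma_{\log}$ in the
log domain, with the designated class rotating across the informative
features. This mirrors task-specific ERD/ERS modulation; an alternative
all-classes staircase was rejected because it makes any single
informative feature fully class-separating, trivializing wrapper
recovery.

What the generator does **not** emulate: temporal autocorrelation
between consecutive windows (real 93.75%-overlap PSD vectors are highly
correlated; here they are independent draws), cross-feature covariance
(neighbouring bands/channels co-vary in real EEG), artifacts, and
non-stationarity across a session. A green recovery test therefore
establishes that the pipeline recovers injected mean-shift structure
under heavy-tailed noise — not that it reproduces competition-data
accuracies.

Test-time scaling: simulation-backed tests shrink sessions to 0.75–1
minute (0.75 min is the smallest *balanced* session — exactly one block
per class) purely to stay inside the test-time budget; block length,
cadence and feature count are kept, and shorter sessions make recovery
strictly harder, never easier. The 4-minute default remains the
generator's stated world.

## Numerical choices and degenerate inputs

* Variances are population variances (exact decomposition above).
* Constant features ($\lambda_j = 0$) are flagged, excluded from
  ranking, and never scored.
* Welch reduction: one Hann-tapered 512-sample periodogram per 1 s
  window; band power is the mean of PSD bins in $[c-1, c+1)$ Hz —
  half-open so adjacent 2 Hz bands never share a bin.
* The Laplacian is the Hjorth nearest-neighbour form with a shipped
  8-channel adjacency map (JSON, configurable); no spherical splines.
* Fuzzy-set integration: trapezoid rule, 1001 points; step-function
  (zero-slope) sets incur $O(h)$ error, about $10^{-3}$ on the unit
  domain.
* An empty prune session leaves a model unchanged; two empty fuzzy sets
  compare as identical ($F = 1$).
* All tie-breaks fall to the lowest index/label, making every stage
  deterministic given its inputs.

## Known limitations

* The classifier is a static approximation (see above); no online
  adaptation during test.
* No raw-recording file formats: the preprocessing entry point takes a
  plain numeric matrix.
* No artifact rejection, by design — the emulated preprocessing chain
  has none.
* The wrapper's cost grows as $O(K^2)$ RC evaluations for GMDH; with
  96 features and default $\rho$ this is modest, but RC evaluation
  itself refits the classifier $6$ times per subset.
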