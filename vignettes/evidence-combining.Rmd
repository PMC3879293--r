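---
title: "Evidence-based combining of multi-view classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based combining of multi-view classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(evicomb)
```

## The problem

Brain-signal classification — and multi-view classification under label
noise generally — suffers from an inherent uncertainty in the training
labels: a subject's mental state drifts, attention lapses, and the recorded
signal for a trial nominally labeled "left hand imagery" may carry as much
evidence for another class. A classifier trained to treat every label as
certain absorbs this noise. `evicomb` instead makes the uncertainty explicit
and then reduces it by fusing several complementary representations (views)
of the same samples.

The machinery is Dempster–Shafer belief-function theory. Over a frame of
discernment $\Omega = \{\omega_1,\dots,\omega_C\}$ (the original classes), a
basic belief assignment (BBA) $m$ puts nonnegative mass on *subsets* of
$\Omega$ with $\sum_{A \subseteq \Omega} m(A) = 1$ and $m(\emptyset) = 0$.
Mass on a non-singleton — say $m(\{\omega_1,\omega_2\})$ — is belief
committed to the disjunction without choosing between its members, which is
exactly the right vocabulary for a sample that might belong to either class.
Belief and plausibility, $bel(A) = \sum_{B \subseteq A} m(B)$ and
$pl(A) = \sum_{B \cap A \neq \emptyset} m(B)$, bound the probability of $A$
from below and above. Two BBAs from independent sources combine by
Dempster's rule (the orthogonal sum),

$$ (m_1 \oplus m_2)(A) \;=\; \frac{1}{1-K} \sum_{B \cap C = A} m_1(B)\,m_2(C),
   \qquad K = \sum_{B \cap C = \emptyset} m_1(B)\,m_2(C), $$

where $K$ is the mass of conflict renormalized away. Decisions are made at
the pignistic level: $BetP(\omega) = \sum_{A \ni \omega} m(A)/|A|$ splits
each focal mass uniformly among its members and the argmax wins.

## The procedure

Training runs per view (see `fit_evidence_ensemble()`):

1. **Confidence relabeling** (`relabel_dataset()`). A one-hidden-layer
   network with $C$ logistic output nodes is trained on the original crisp
   labels. Its *template* $T$ has $T_i$ = mean of output node $i$ over the
   class-$i$ training samples: the confidence level the network typically
   reaches on that class. For each training sample with output vector $O$,
   the gap $D = T - O$ is formed; any negative gap (output above template:
   a confidently assigned class) is clamped to zero. Each class is then
   scored by
   $$ v_i = \frac{\min_j D_j + \varepsilon}{D_i + \varepsilon}, $$
   which is 1 at the smallest gap, stays positive at $D_i = 0$ thanks to
   $\varepsilon$ (default 0.01), and decreases strictly as the gap grows.
   All classes with $v_i > \theta$ form the sample's new label: a *soft*
   (set-valued) label if two or more qualify, otherwise the crisp class
   with the smallest gap. Every distinct soft label becomes a new class,
   so a $C$-class problem can expand to at most $2^C - 1$ classes.
2. **Expert training** (`train_mlp_expert()`). A second network is trained
   on the relabeled data with one output node per crisp-or-soft class
   (one-hot targets). Applying a softmax to its output activations for a
   test sample yields a BBA whose focal elements are the expert's classes —
   each a subset of the original frame.

At test time the per-view BBAs are combined with Dempster's rule and the
pignistic argmax over the original classes decides
(`predict.evidence_ensemble()`). A view whose evidence is in near-total
conflict with the accumulated combination ($K \ge 1 - 10^{-12}$) is skipped
with a warning rather than failing the prediction; the reference protocol
never encounters this, but softmax outputs can collapse to near-certainty on
disagreeing classes for outlying samples.

The point of relabeling *before* fusing is that the three views are
complementary: a sample deep inside the class-overlap region of one view is
usually better separated in another, so its soft label in the first view is
resolved by sharper evidence from the others, and the conflict
renormalization suppresses spurious certainty.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `theta` | uncertainty threshold on the score $v$ (unitless, $(0,\infty)$) | 0.5 | $\theta \ge 1$ forces all labels crisp; smaller admits softer labels. Tunable on validation over a grid (`theta_grid`); the reference protocol scans 0.05–0.95. |
| `epsilon` | guard constant in $v$ | 0.01 | the reference experiments' value |
| `hidden_units` | hidden-layer width | 10 | reference grids scan small widths (2–20) |
| `learning_rate` | batch gradient step | 0.1 | reference range 0.05–0.3 |
| `max_epochs` | training budget | 1000 | the reference stopping budget |
| `patience`, `tol` | early-stopping window on validation accuracy | 10 checks, $10^{-4}$ | validation is checked every epoch; the source protocol says only "several consecutive iterations" |
| `k`, `threshold` (KNN baseline) | neighbor count and similarity cut | 5, 0.3 | $k=5$ is the reference comparison setting; the similarity $1/(1+d)$ is this package's documented choice (the source leaves it open) |
| `m` (CSP) | spatial filters kept per end | 3 | forced by the published count of 24 features over 4 classes; exposed as a parameter |

## The networks

The experts are deliberately plain: one hidden layer, logistic units
throughout, full-batch backpropagation on the summed squared error (the
classic batch delta rule), a fixed learning rate, and uniform
$[-0.5, 0.5]/\sqrt{\text{fan-in}}$ seeded initialization. No momentum or
adaptive optimizer — the method under study is the fusion scheme, and the
base learner is kept at the level of its era. The mean-gradient variant of
the same update was tried and rejected: within the 1000-epoch budget and the
0.05–0.3 learning-rate range it stalls far from convergence on the
benchmark data.

Two details have open alternatives, both configurable:

* **Where the softmax applies.** BBA masses are the softmax of the *raw*
  pre-logistic output activations (default `softmax_on = "raw"`); applying
  it to the logistic outputs instead compresses the mass ratios but changes
  no argmax at a single-expert level. Both are offered because the source
  description ("outputs ... converted using softmax") does not fix the
  operand.
* **The relabeling score.** The $v$ above is the package's reconstruction of
  a formula that is unreadable in the source; it satisfies every property
  the surrounding text states (value 1 at the minimum gap, positive at zero
  gap, strictly decreasing, $\varepsilon$ guards the division). Any
  alternative can be supplied via the `score` hook of `relabel_dataset()`.

## The synthetic benchmark

`make_triangle_views()` generates the three-class two-dimensional Gaussian
benchmark: class $i$'s mean sits on vertex $i$ of an equilateral triangle of
side $d$ (centroid at the origin, vertex 1 on the positive $y$-axis — fixed
for reproducibility), identity covariance, equal class sizes. Views 2 and 3
advance every class mean one vertex clockwise. The side length is the
uncertainty dial: $d = 1$ gives heavy three-class overlap (nearest-mean
accuracy well under 0.75), $d = 3$ near-separability, $d = 10$ essential
certainty. Set totals default to 150/300/500 train/validation/test, split
equally with remainders to the lowest class indices.

Two generator choices the source leaves open are fixed here: the three views
share *labels only* — coordinates are drawn independently per view, which
maximizes the complementary information the fusion exploits and matches the
stated rationale that a sample overlapped in one space may be separable in
another; and per-class counts for totals not divisible by three favor lower
class indices.

`make_synthetic_trials()` emulates band-limited oscillatory EEG trials:
each class projects a band-passed noise source along its own spatial
pattern on top of white sensor noise, so the one-versus-rest CSP stage has
planted ground truth to recover. What it does **not** emulate: eye-blink
and line-noise artifacts, non-stationarity across a session, volume
conduction beyond the linear mixing model, or realistic electrode
geometry. Tests passing on these generators therefore validate the
algorithmic pipeline, not performance on recorded EEG.

## EEG feature stages

* `surface_laplacian()` subtracts the equal-weight mean of four surrounding
  channels from each mapped channel; the neighbor map is user-supplied.
* `butterworth_bandpass()` designs the filter with `signal::butter` and
  applies it forward–backward (`filtfilt`), so the net phase is zero —
  appropriate for offline analysis, not for causal online use. The `order`
  argument is the final filter order (a band-pass of order $2n$ comes from
  an order-$n$ prototype), default 6 over 5–30 Hz.
* `extract_epoch()` keeps a half-open, 0-based sample window (default
  protocol: 0.5–2.5 s after stimulus onset, 500 samples at 250 Hz).
* `fit_csp_ovr()` contrasts each class's average trace-normalized trial
  covariance against the rest, whitens the composite (with a trace-scaled
  ridge, default $10^{-8}$, against singularity), and keeps the first and
  last $m$ eigenvectors per sub-problem; `csp_features()` returns
  $\log(v_j / \sum_k v_k)$ of the projected variances. Trace normalization
  makes the filters invariant to global amplitude rescaling; the
  log-variance share is additionally invariant per trial. A plain
  elementwise log is available via `normalize = FALSE`.
* `psd_features()` estimates Welch band power over the last second of each
  trial: segments of `fs / resolution_hz` samples at 50% overlap, averaged
  periodograms, band bins at 8, 10, ..., 30 Hz per channel (12 bins × 8
  channels = 96 features in the reference recipe). The default taper is
  rectangular: with the segment length matched to the resolution grid,
  on-grid band components fall exactly on bin centers and suffer no
  scalloping, whereas a Hamming taper would smear roughly a quarter of an
  on-bin tone's power into the neighboring 2 Hz bins. For signals dominated
  by off-grid components choose `taper = "hamming"`.
* `unit_normalize()` and `downsample_first_of_k()` reproduce the
  precomputed-feature handling of the reference protocol (unit-length
  feature vectors; first sample of every 8 to undo sliding-window overlap).

## Feature-subspace selection

For a single wide feature space, diversity is manufactured by subspacing:
`directed_random_subset()` draws the same number of features from every
channel block (so every channel is represented), `build_pool()` trains one
network per subset and records validation accuracy and per-sample
correctness, `prune_pool()` keeps the most accurate 30%, and
`forward_search()` greedily grows a committee that minimizes Kuncheva's
non-pairwise inter-rater agreement

$$ \kappa = 1 - \frac{\sum_j l_j (L - l_j)}{N L (L-1) \bar p (1 - \bar p)}, $$

with $l_j$ the number of committee members correct on validation sample $j$
and $\bar p$ the mean accuracy — lower $\kappa$ means more disagreement,
i.e. more diversity. The committee is seeded with the accuracy maximizer;
ties at each admission break by diversity, then accuracy, then pool index.
When $\bar p \in \{0, 1\}$ the statistic is 0/0; the package defines
$\kappa = 1$ there (no disagreement is possible) and warns. Greedy forward
search optimizes one admission at a time, so on occasional pools its final
committee can be marginally *less* diverse than the naive take-the-k-most-
accurate committee; in aggregate it dominates clearly, and the search never
reorders by anything the $\kappa$ scale factor could affect.

## Numerical choices and degenerate inputs

* Subsets of the frame are encoded as bitmasks over the fixed class order:
  set identity is exact, intersection is one `bitwAnd`, and frames are
  capped at 30 classes.
* `make_bba()` renormalizes mass sums off by at most $10^{-6}$ and rejects
  anything worse, naming the offending subset.
* Combination treats $K \ge 1 - 10^{-12}$ as non-combinable (the source
  states only the existential condition); masses below $10^{-15}$ after a
  combination are dropped and the BBA renormalized to bound focal growth.
  `combine_all()` folds pairwise — associativity makes this exact while
  memory stays bounded.
* Crisp-label ties (equal gaps) break to the lowest class index, as do
  pignistic and fixed-rule argmax ties; expanded class lists order crisp
  singletons first, then soft labels by member tuple, so expert output-node
  semantics are reproducible run to run.
* All stochastic entry points take explicit integer seeds and restore the
  caller's RNG state (`withr::with_seed`), so identical seeds reproduce
  results bit-exactly.

## Problem sizes used in the shipped checks

The package's own test suite and acceptance script run entirely on the
synthetic generators at desk scale, chosen to exercise every code path with
comfortable statistical margins: the triangle benchmark at its reference
totals (150/300/500) over 10 generator/training seeds for the directional
comparisons, with the coarse $\theta$ grid 0.2–0.8 in steps of 0.1; CSP
recovery on 8–22 channels with 12–60 trials; and the belief-algebra oracle
checks on frames of 2–4 classes, where exhaustive enumeration is trivial.
The reference protocol's full grids (e.g. $\theta$ at step 0.005, per-subject
hidden-unit scans) remain available through the configuration objects.

## Known limitations

* The worst-case class expansion is exponential in $C$: relabeling can turn
  a $C$-class problem into a $(2^C - 1)$-class one, and Dempster combination
  cost grows with the product of focal-set sizes. For the $C \le 4$ problems
  this package targets, neither matters; for large $C$ the evidence layer
  would need approximation.
* Crisp labels produced by relabeling follow the *network's* most confident
  class, not the original label; under heavy overlap a substantial fraction
  of training samples legitimately change class. This is the method, not a
  bug — but it means "relabeling leaves labels alone" holds only on
  well-separated data.
* The fusion assumes the per-view experts are independent sources of
  evidence; views engineered from the same features (random subspaces)
  violate this mildly, which is precisely why the diversity-driven
  selection exists.
* No handling of EEG artifacts or online (causal) filtering; the
  preprocessing stages are for offline analysis.
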