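---
title: "Methods: multi-objective feature selection for gait-mode recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-objective feature selection for gait-mode recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaitfs)
```

## Overview

`gaitfs` builds user-intent-recognition (UIR) pipelines for lower-limb
prostheses and, at its core, solves feature selection as a two-objective
minimization over feature subsets $S$:

$$ f_1(S) = |S|, \qquad f_2(S) = \text{mean } c\text{-fold CV error of a
classifier trained on } S. $$

This vignette documents the models, the parameter conventions and defaults,
the design choices made where the design was genuinely open, what the
synthetic generators emulate, and the limits of what a green test
establishes. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## Windowing

A recording sampled at $f_s$ Hz is cut into frames of length $L_f$ ms
advanced by an increment $I$ ms; disjoint windowing is the special case
$I = L_f$. Real-time operation requires $\tau \le L_f$ (disjoint) or
$\tau \le I \le L_f$ (overlapped), where $\tau$ is the processing budget.
$\tau$ is carried as a *declared* budget and checked against the
configuration, never measured: wall-clock timing is hardware-dependent and
deliberately outside the test surface.

Open point resolved here: nothing in the problem statement fixes the label
of a frame spanning a mode transition. We use the **majority** of the
per-sample labels, with ties broken by the **latest** sample in the frame —
at a transition, the most recent samples best reflect current intent.
Trailing partial frames are dropped, never padded, because the feature
statistics below assume full-length frames.

## Features

The 17 feature types are the canonical surface-EMG repertoire: time-domain
SSC, ZC, WL, VAR, MAV, MAV1, MAV2, RMS, WAMP, SK, KU; frequency-domain MDF,
MNF, MAXF and order-4 autoregressive coefficients (AR4); and the pairwise
COR (Pearson correlation) and ANG (angle between raw frame vectors, in
$[0, \pi]$). On three channels the full layout expands to
$14 \times 3 + 2 \times 3 + 4 \times 3 = 60$ columns; dropping the five
weak types (MAV1, MAV2, MDF, MNF, MAXF) leaves 45, and removing ZC of the
vertical hip position — a strictly positive signal never crosses zero —
leaves the 44-column training layout.

Conventions chosen once and tested:

* **Variance/moments**: population convention (divide by frame length)
  throughout, including the normalization scales. A zero-variance frame
  returns SK = KU = 0 (with a message) rather than erroring — constant
  frames legitimately occur during standing.
* **Thresholds**: ZC/SSC/WAMP count events exceeding an amplitude
  threshold. Unset thresholds resolve at table-build time to
  $0.01\,\sigma$ of the channel, so they scale with normalized signals;
  they are configurable in `feature_config()`.
* **Spectra**: one-sided periodogram of the mean-removed frame, DC bin
  excluded, so a signal offset (hip position) cannot dominate MAXF.
  MDF is the first bin where cumulative power reaches half the total
  (discrete-bin determinism). AR4 uses Yule–Walker on the mean-removed
  frame (periodogram-consistent); Burg is available via
  `feature_config(ar_method = "burg")`.
* **ANG** is computed on raw (uncentered) frame vectors; whether to center
  first was open, and raw vectors preserve the geometric reading of the
  inner product.
* **Normalization scope**: tables are standardized to column mean 0 and
  unit variance. `crossval_error(..., normalize_scope = "train_only")`
  fits the scaling on each training split only (leakage-free default for
  evaluation); `"global"` reproduces whole-set standardization for users
  who want the original behavior.

## GMOFS

The embedded selector trains a single-hidden-layer perceptron whose input
$i$ is multiplied by a gate $\beta_i \in [0, 1]$ before entering the
network, minimizing

$$ J = \tfrac12 \sum_{l=1}^m \sum_{j=1}^K \big(t_j(l) - o_j(l)\big)^2
 + \lambda \sum_{i=1}^n \big[\alpha \beta_i^2 + (1-\alpha)\,|\beta_i|\big] $$

subject to $0 \le \beta_i \le 1$, $|w_{hj}| \le a$, $|v_{ih}| \le b$.
Weight bounds prevent the network from compensating a small $\beta_i$ with
huge downstream weights, which would break the reading of $\beta$ as
feature importance. Per $\lambda$, features are ranked by $\beta$ and the
smallest descending-order prefix holding $\ge \theta = 95\%$ of
$\sum_i \beta_i$ is selected; sweeping $\lambda$ over the grid (step 1 on
$[0, 30]$, step 10 on $(30, 150]$; 43 values) yields the population whose
non-dominated $(f_1, f_2)$ records form the Pareto front.

Numerical choices:

* **Output delta.** Backpropagation uses
  $\delta_j = (o_j - t_j)\,o_j(1 - o_j)$, the derivative of the squared
  error through a sigmoid output. The gradient is verified against central
  finite differences (20 random instances, step $10^{-5}$, relative
  agreement $\le 10^{-6}$) on every test run.
* **Targets** are one-hot in $\{0.05, 0.95\}$ rather than $\{0, 1\}$:
  sigmoid outputs cannot reach 0/1, and unreachable targets drive weights
  into the bounds. Configurable.
* **Activation** is sigmoid at both layers (not softmax), consistent with
  the $y(1-y)$ factors in the gradients. The hidden layer's $p$ nodes
  include one constant-1 bias node; an input bias is appended after the
  $\beta$ gating.
* **Lasso subgradient** at $\beta_i = 0$ is taken as 0, keeping inactive
  features inactive.
* **Optimizer.** The contract is a constrained local minimum, not a
  specific algorithm; we use L-BFGS-B with the analytic gradients and box
  constraints. MaxIter 100 and TolX/TolFun 0.001 are the reference budget;
  TolFun maps to L-BFGS-B's relative stopping factor
  (`factr = tol_fun * 1e10`, i.e. the stock `1e7` at 0.001). Iteration
  counts are not commensurate across optimizers — a trust-region step and
  an L-BFGS-B step make different progress — so cold starts on larger desk
  problems may need `max_iter` of a few hundred (the README example uses
  400). Training failure to decrease $J$ returns the flagged initial
  model, never a silent success.
* **Warm starts.** Each $\lambda$'s training starts from the previous
  solution; only the first uses the seeded random initialization
  ($\beta \sim U[0.4, 0.6]$, weights uniform in $\pm 0.1\times$ their
  bound). Independent re-initialization at every $\lambda$ (the original
  plan) makes the shrinkage path erratic under this nonconvex cost;
  warm-starting is standard regularization-path practice and preserves the
  per-training contracts. `gmofs_config(warm_start = FALSE)` restores
  per-$\lambda$ re-initialization.
* **Threshold tuning.** The reference procedure raises $\theta$ until the
  masked and unmasked networks perform alike; we expose $\theta$ as
  configuration with default 0.95 rather than re-implement that loop.
* **Degenerate records.** At large $\lambda$ every $\beta_i$ can reach
  exactly 0; such records carry an empty subset, are flagged, and are
  excluded from the Pareto step (an empty subset has no defined error).
* **Step-4 evaluator** is pluggable. The default retrains the same
  constrained-MLP family unpenalized on the subset; the test suite mostly
  passes an LDA evaluator (`make_subset_evaluator(table, "lda")`) for
  speed. Fold assignment is fixed once per run so all subsets are compared
  on identical folds, and results are memoized per subset.

### The $\lambda$ scale

The error term of $J$ is a *sum* over training patterns, so the meaningful
$\lambda$ range grows with $m$. The reference grid $[0, 150]$ corresponds
to windowed training sets of a few thousand patterns (overlapped windowing
at $I = 50$ ms yields 20 patterns per second of recording). At desk scale
this matters: with only a few hundred patterns the penalty dominates from
$\lambda \approx 5$ and all gates collapse. The recovery tests therefore
use $m = 1800$ planted patterns, sized like a real windowed training set —
a property of the stated world, not a tuning knob.

## MOBBO

Candidate subsets are binary masks. One generation sorts the population by
the variant's scalar fitness, assigns rank-$k$ immigration
$\frac12(\cos(\pi (N-k)/N) + 1)$ and emigration
$\frac12(\cos(\pi k/N) + 1)$ (sinusoidal model; rates sum to 1 per rank —
good habitats emigrate bits, poor habitats immigrate them), migrates per
bit from sources drawn proportionally to emigration, mutates each bit with
probability $\mu$, and preserves $E$ elites unchanged. An external
non-dominated archive accumulates every evaluated individual and is what
`run_mobbo()` returns (whether to return archive or final population was
open; the archive is strictly more informative).

The four selection schemes follow the canonical algorithms, with internal
parameters the reference leaves unstated exposed as defaults: VEBBO splits
the population evenly across the two objectives (reshuffled each
generation); NSBBO uses non-dominated rank with crowding-distance
tie-break; NPBBO uses domination count with fitness sharing (radius 0.1 in
normalized objective space — $f_1/d$, $f_2$ raw — since the objectives are
incommensurate); SPBBO uses strength-Pareto fitness from the external
archive. An all-zero mask is repaired by setting one seeded random bit
before evaluation ($f_2$ is undefined on no features; repair is the
standard fix in binary subset EAs). A memoization cache avoids retraining
repeated masks while the evaluation counter keeps counting logical
evaluations, preserving the $N \cdot Gen$ bookkeeping (plus $N$ for the
initial population, reported separately).

## Pareto metrics

`normalized_hypervolume()` is the project's front-quality score: the mean
over front points of the product of objective values,
$\sum_j \prod_i f_{ji} / N_p$, smaller is better. This is **not** the
standard dominated-hypervolume indicator — it needs no reference point and
is not monotone under front refinement; it is kept exactly as defined
because it is the metric this methodology prescribes. The conventional
indicator is exported separately as `dominated_hypervolume()` for users who
want it. `relative_coverage(A, B)` is the percentage of $A$'s points
*weakly* dominated by at least one point of $B$; weak dominance makes
self-coverage 100 % by construction, and exact objective ties count as
covered. Fronts retain duplicate objective vectors: distinct payloads
(different subsets with equal objectives) are meaningful, and
`combine_fronts()` credits every source holding a combined-front vector.

## Evaluation and smoothing

Classifiers are consumed through a uniform fit/predict contract: `"lda"`
and `"qda"` (MASS) and `"mlp"` (the package's constrained perceptron,
unpenalized). Kernel SVMs and decision trees, part of the original roster,
are not available in this build's dependency set and were omitted rather
than hand-rolled — they are evaluation plumbing, not the contribution.
Folds whose training split lacks a class, or where fitting fails, fall
back to majority-class prediction and are flagged.

The majority-vote filter replaces each classified mode with the most
frequent among the $2q + 1$ values centered on it (window shrunk at the
edges; ties resolved by the previous filtered output, or the raw label at
the stream start). It is implemented as a centered filter; deployed
causally it is identical up to an output delay of $q$ output periods,
which `realtime_feasible()` charges against the 300 ms intent-to-motion
budget: $q L_f \le 300$ ms (disjoint) or $q I \le 300$ ms (overlapped).
Whether reported deployment accuracies should align filtered outputs with
shifted ground truth was open; the package evaluates unshifted, and the
delay is accounted for separately by the feasibility check.

## Synthetic data: what it does and does not establish

`simulate_gait_recording()` targets the *statistical* structure the method
assumes — per-mode distinct stride cadence (defaults 0.7/0.9/1.1 Hz for
slow/normal/fast, rising with speed) and amplitude on three channels, a
near-constant standing mode, white measurement noise, schedule-exact
labels — not biomechanics. The default schedule cycles ST/SW/NW/FW with
multi-second dwells over ~60 s, like a laboratory walking trial. Real
signals have stride-to-stride variability, drift, autocorrelated noise and
soft transitions; a green end-to-end test establishes that the machinery
(windowing, features, CV, smoothing) composes correctly and separates
cadence/amplitude-coded modes, not that any subject-level accuracy would
be reproduced.

`generate_planted_table()` plants an informative set $S^*$: feature $j$
elevates the mean of class $((j-1) \bmod K) + 1$ by the effect size (in
noise SDs); other columns are standard Gaussian noise; optional redundant
columns are noisy copies at a configured correlation. The
one-elevated-class-per-feature design is deliberate: with
$K = |S^*| + 1$ classes every planted feature is individually necessary
for minimal error, so "the front contains a subset holding all of $S^*$"
is a well-posed recovery target. (A shared mean gradient across classes —
the obvious alternative — lets a single column separate every class, and
the front collapses to one point.) Recovery tests use effect size 6: the
"strong effect" regime where the Bayes error of the planted subset is
negligible.

## Known limitations

* The selector cost is nonconvex; the $\lambda$ path depends on
  initialization even with warm starts, and subset-size monotonicity in
  $\lambda$ holds as a trend (tested via Spearman correlation), not
  pointwise.
* `MaxIter = 100` is a faithful default but undersized for cold-start
  L-BFGS-B on problems with many classes; see the $\lambda$-scale note.
* No SVM/decision-tree evaluators (dependency availability), no wavelet
  features, no real-valued BBO, no streaming/online deployment code.
* The front metrics reproduce the prescribed definitions; users wanting
  refinement-monotone comparisons should use `dominated_hypervolume()`.
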