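---
title: "Sparse representation and twin SVMs for microcalcification cluster detection"
author: "mcdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse representation and twin SVMs for microcalcification cluster detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clustered microcalcifications (MCs) — groups of at least three calcium
deposits of roughly 0.1–1 mm diameter inside a ~5 mm × 5 mm region — are an
early radiological sign of breast cancer. At the DDSM digitization geometry
(43.5 µm/pixel, 12-bit), a 115 × 115-pixel window spans 5.0025 mm, which is
why the package analyses mammograms through windows of that size. The task
is binary: does a window contain an MC cluster or only normal tissue?

`mcdetect` implements two classifiers built on one shared representation:

* **MCs-SRC** — sparse-representation classification. A test window is
  expressed as a sparse linear combination of a labelled *vocabulary* of
  training windows; the predicted class is the one whose columns reconstruct
  the window with the smaller residual.
* **TWSVMs-SR** — the sparse codes themselves are used as feature vectors
  for a twin support vector machine (TWSVM).

## Sparse coding

Given the vocabulary matrix $A \in \mathbb{R}^{d\times n}$ (one
unit-normalized training window per column, each labelled $\pm 1$) and a
unit-normalized test vector $y$, the code is the minimizer of the
$\ell_1$-regularized least-squares objective

$$ J(c;\lambda) = \|Ac - y\|_2^2 + \lambda \|c\|_1 . $$

This is the standard convex surrogate for the NP-hard sparsest-representation
problem; $\lambda$ (default 0.01, dimensionless because both $A$ and $y$ are
unit-normalized) trades reconstruction error against sparsity. The default
was chosen as a small value that keeps codes sparse without starving the
reconstruction; it is exposed as `sparse.lambda`.

The solver is cyclic coordinate descent on the Gram ("covariance")
formulation — only $A^\top A$, $A^\top y$ and $\|y\|^2$ enter the inner
loop, so coding many windows against one vocabulary reuses a single Gram
matrix. Optimality is certified by a duality gap evaluated at the scaled
dual-feasible point $\nu = 2s(Ac - y)$ with
$s = \min(1, \lambda / \|2A^\top(Ac-y)\|_\infty)$; a result is flagged
`converged` only when the gap falls below `gap_tol` $\cdot(1 + |J|)$
(default $10^{-4}$ relative). Because cyclic coordinate descent has a slow
convergence tail on correlated or rank-deficient dictionaries (near-duplicate
atoms), the solver finishes with an **active-set refinement**: the KKT system
is solved exactly on the discovered support, null-space directions of the
support Gram (which arise when atoms are linearly dependent) are walked until
a coordinate leaves the support, and coordinates violating the subgradient
bound are re-admitted. The refinement is objective-guarded — it is only
accepted when it improves the coordinate-descent point — and brings the
solver into machine-precision agreement with an independent convex-QP oracle
on random instances (verified in the test suite on the split formulation
$c = c^+ - c^-$ solved by a generic bound-constrained method).

Degenerate inputs are handled explicitly: all-zero vocabulary columns are an
error (silently dropping them would desynchronize the labels), a zero test
vector cannot be normalized and errors, NaN/Inf inputs error, and a solve
that exhausts `max_iter` without meeting the gap tolerance is returned
flagged, never silently.

## Classification by residual (MCs-SRC)

For class $i \in \{+1,-1\}$, $\delta_i(c)$ keeps the coefficients on columns
of class $i$ and zeroes the rest; the class residual is
$r_i(y) = \|y - A\,\delta_i(c)\|_2$ and the label is
$\arg\min_i r_i(y)$. The residual uses the class-restricted code: a
class-independent residual $\|y - Ac\|_2$ could not discriminate at all, so
the restriction is essential to the method. Ties ($r_{+1} = r_{-1}$ exactly)
go to class $+1$ — in a screening context the conservative choice is to
flag. The continuous score used for ROC analysis is $r_{-1} - r_{+1}$, the
natural monotone statistic of the argmin rule: larger means more
cluster-like, and relabelling the vocabulary negates it exactly.

## Twin support vector machines

A TWSVM fits two nonparallel planes
$x^\top w^{(1)} + b^{(1)} = 0$ and $x^\top w^{(2)} + b^{(2)} = 0$; plane 1
minimizes $\tfrac12\|Aw^{(1)} + e b^{(1)}\|^2 + c_1 e^\top q$ subject to
$-(Bw^{(1)} + e b^{(1)}) + q \ge e$, $q \ge 0$ (hug class $+1$, keep class
$-1$ at unit margin), and plane 2 is the mirror problem. With
$H = [A\; e]$, $G = [B\; e]$, the Wolfe duals are box-constrained QPs

$$ \max_\alpha\; e^\top\alpha - \tfrac12 \alpha^\top G (H^\top H)^{-1}
   G^\top \alpha, \quad 0 \le \alpha \le c_1 , $$

and the symmetric problem in $\gamma$ with box $c_2$. Three numerical
choices matter:

* $H^\top H$ and $G^\top G$ are only positive semidefinite, so the inverses
  are stabilized with a relative ridge (`twsvm.ridge`, default
  $10^{-7} \times$ mean diagonal).
* Stationarity of the plane-2 Lagrangian gives
  $v = +(G^\top G)^{-1} H^\top \gamma$; the sign is fixed so class $+1$
  patterns sit on the positive side of plane 2, the orientation the
  unit-margin constraint implies, and is verified by KKT tests rather than
  assumed.
* Classification is by the *normalized* perpendicular distance
  $d_i(x) = |x^\top w^{(i)} + b^{(i)}| / \|w^{(i)}\|$ (an unnormalized
  strict-literal mode is available via `twsvm.normalize_distance`); ties go
  to class $+1$, and the ROC score is $d_2 - d_1$.

The duals are solved by cyclic coordinate ascent with a projected-gradient
stationarity certificate; correctness is defined by oracle-equivalence and
KKT tests, not by the algorithm choice. A zero diagonal in the dual Hessian
(possible with a degenerate counter-class matrix) makes the objective linear
in that coordinate and drives it to the box bound, which the solver handles
in closed form.

The kernel variant replaces the pattern blocks by RBF cross-Gram matrices
against the stacked training matrix $C = [A; B]$, giving surfaces
$K(x, C)\,w + b = 0$; plane norms are computed in the kernel feature space.
The kernel convention is $K(x,z) = \exp(-\|x-z\|^2 / (2\sigma^2))$. The
defaults $\sigma = 15$, $c_1 = c_2 = 1000$ are the published configuration
for this task and are deliberately left untouched; TWSVM performance is
reported to be insensitive over a wide parameter range.

## The TWSVMs-SR composition and the vocabulary split

TWSVMs-SR codes every window against the vocabulary and feeds the code
vectors to the TWSVM. One subtlety is essential: **the vocabulary and the
classifier training set must be disjoint**. A training sample coded against
a vocabulary that contains it simply selects itself (a near-one-hot code),
which is nothing like the code of an unseen window, and a classifier trained
on such codes does not generalize (we measured Az dropping from ~0.98 to
~0.66). The package therefore splits the training windows per class into
alternating halves — one builds the vocabulary, the other is coded and
trains the TWSVM — mirroring the separate sparse-learning and training
stages of the original experimental design. MCs-SRC has no classifier
training step, so it uses the full training set as vocabulary.

## Feature transform

The linear transform $D$ applied before coding is a free design choice of
the method; the package default is block-mean downsampling by a factor of 5
(115 × 115 → 23 × 23, i.e. ~0.22 mm blocks) composed with mean removal.
Downsampling keeps the solver fast and acts as a crude matched filter at
the spot scale; mean removal matters because the raw base intensity level
dominates the Euclidean norm of every window — without it, unit
normalization makes all windows nearly collinear and the sparse codes carry
no class information. Identity, 1-D block-mean, and Gaussian
random-projection transforms are also provided; all are explicit matrices
and compose by multiplication.

## Preprocessing

Whole-mammogram preprocessing is a named but unspecified step in the
original pipeline, so the package provides a minimal deterministic stand-in:
intensity clipping, background flattening (subtract a large moving-average
background estimate; window at least 4× the analysis window for full
images), and linear contrast rescaling, each individually toggleable. For
patch-level datasets `preprocessPatches()` flattens each window with a
default window of ~0.8 m (~4 mm), several times the largest spot diameter,
removing the base level and slow background while preserving spot contrast
(verified to within 5% on synthetic spots).

## The phantom generator

The synthetic module emulates DDSM-like patches, not anatomy. A background
is base level + Gaussian-smoothed white noise + a random planar gradient;
spots are additive Gaussian profiles (FWHM = diameter, drawn uniformly in
0.1–1 mm) placed at integer pixel positions inside a ≤ 5 mm cluster box
(default 4 mm, 3–6 spots, centred with jitter ≤ m/4 so the cluster is never
clipped). Defaults: base 1200 DN, texture sd 60 DN, gradient 120 DN
peak-to-peak, spot peak amplitude 8 × texture sd — a clearly-visible,
"high-contrast" regime; spot diameters translate to ≈ 2.3–23 px at the
43.5 µm pitch.

Two generator choices deserve justification:

* **Texture correlation length = 23 px (1 mm).** Parenchymal texture in
  real mammograms lives at the millimetre scale; microcalcifications are
  detectable precisely because they are *sharper* than tissue structure. A
  background correlated at the spot scale would be statistically a spot
  field — indistinguishable from signal by any method, which models sensor
  noise rather than tissue.
* **Hard-core spot placement.** Spot centers keep a minimum separation of
  ~2.9 σ of the widest spot, so each bump's peak is its own and the ground
  truth ("the center pixel gains the configured amplitude") is exact.
  Clinically, countable cluster spots are individually resolvable.

What the phantom does *not* model: anatomical structures (ducts, vessels,
pectoral muscle), the Le Gal morphology types, scatter/blur physics, or the
long-tailed intensity statistics of real film digitization. Passing the
package's tests therefore demonstrates that the algorithm chain is correct
and that it detects spot clusters against correlated texture; it does not
certify clinical performance on real mammograms.

## Evaluation

ROC curves sweep thresholds over the unique scores in descending order with
ties grouped at a single threshold; Az is the trapezoidal area and is
checked (to $10^{-12}$) against an independent Mann–Whitney pair-counting
estimate, which settles the tie convention. Stratified k-fold (default
k = 5) deals shuffled per-class indices round-robin, guaranteeing per-fold
class counts within one of proportional. The stability experiment holds out
a fixed stratified test pool (default 25%), then for each training fraction
(default grid 0.95 down to 0.05) and repeat (default 50) subsamples the
training pool, trains, and scores the pool, reporting mean ± sd of
sensitivity, specificity and Az; per-repeat seeds are derived from the
global seed and the (fraction, repeat) pair, so extending the repeat count
preserves earlier results, and failed repeats are excluded and counted.

## Determinism

Every stochastic operation draws from a locally seeded RNG
(`withSeed`) and restores the caller's RNG state; one global seed fans out
into named per-module streams (`moduleSeed`) so module-level determinism
survives pipeline reordering. All pipeline outputs (images, CSVs, models)
are byte-reproducible for a fixed (config, seed).

## Problem sizes used by the tests and the acceptance script

The full-scale protocol (3000 + 3000 windows, 50 repeats × 20 fractions) is
supported by the API; the shipped verification uses scaled-down analogues
chosen as the smallest sizes at which the measured quantities are stable:
200 + 200 phantom windows with a 75/25 stratified split for the end-to-end
Az checks, a 4-level contrast ladder (peak = 1, 2, 4, 8 × texture sd) for
monotonicity, 50 random instances for solver-oracle agreement, 20 random
problems for the TWSVM dual certificates, and 100 random score sets for the
ROC identity.

## Known limitations

* SRC relies on within-class shared structure; on backgrounds with no
  common support (pure noise at the spot scale) reconstruction residuals
  lose their class information regardless of implementation.
* The decision threshold 0 of the continuous scores is not calibrated;
  sensitivity/specificity at that threshold are asymmetric even when Az is
  high. Threshold selection is left to the user (e.g. from the ROC).
* The kernel TWSVM keeps the full stacked training matrix as reference, so
  kernel-mode models grow linearly with the training set.
* Rank-deficient support Grams are handled exactly in the solver
  refinement, but heavily duplicated vocabulary columns still make the code
  itself non-unique (the objective value and residuals remain unique).
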