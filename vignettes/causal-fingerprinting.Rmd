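---
title: "Causal fingerprinting of brain dynamics: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal fingerprinting of brain dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalprint)
```

## The two-timescale model

Parcellated fMRI aggregates processes on very different timescales: fast
neuronal interactions on the order of milliseconds and slow hemodynamic
responses unfolding over seconds, both sampled only every `dt` seconds
(0.72 s in the reference acquisition). `causalprint` models a recording by
splitting the `p` parcels into `m` *state* regions `x(k)` and `n` *input*
regions `u(k)` and positing the discrete update

    x(k) = Q x(k) + A x(k-1) + B1 u(k) + B2 u(k-1),

where `Q` (zero diagonal) carries fast, *concurrent* directed interactions
within a sampling period, `A` the slow, *lagged* transition, and `B1`/`B2`
the concurrent and lagged input couplings. The model arises from an
implicit–explicit (IMEX) Euler discretization of a continuous system with
separated timescales: each period `dt` is split into a slow sub-interval
`dt - tau` (explicit Euler) and a fast one `tau` (implicit Euler), with
`(dt - tau)/tau = 1/epsilon`. Eliminating the unobserved mid-interval state
gives the closed-form mapping

    Q = tau * F_f,   A = I + (dt - tau) * F_s,
    B1 = tau * G_f,  B2 = (dt - tau) * G_s,

implemented by `imex_discretize()` and inverted by `imex_continuous()`.
Users supply `epsilon` (default 0.2 for simulation fixtures — arbitrary but
stable) rather than `tau`.

The stacked blocks `R = [Q A B1 B2]` (an `m x (2m+2n)` matrix, 90 x 200 at
the reference parcellation) are the *causal signature* of a recording; all
downstream analyses operate on it.

## Identification and its limits

`fit_causal_signature()` estimates the blocks by regularized least squares
on the one-step relation, with each state's regression excluding its own
contemporaneous value so `diag(Q) = 0` holds bit-exactly. Two objective
variants are provided. The default `mode = "ridge"` squares the residual
and penalty norms, which decouples into row-wise closed-form solves. The
`mode = "stated"` variant keeps unsquared Frobenius norms (a group-norm
objective) and is solved by iteratively reweighted least squares to an
objective tolerance of 1e-8; the two agree with ordinary least squares as
`lambda -> 0`.

**Identifiability.** The one-step relation determines only the
state-evolution quantities `Ahat = (I-Q)^{-1} A`, `B1hat = (I-Q)^{-1} B1`,
`B2hat = (I-Q)^{-1} B2`. On exactly noise-free data every contemporaneous
regressor column is a linear combination of the lagged-state and input
columns, so the exact-fit solution set is an affine subspace of dimension
`m - 1` per row: the split of dynamics between `Q` and `A` is not unique,
and *no* estimator can recover the generating blocks from such data (the
scalar case `m = 1`, which has no off-diagonal `Q`, is the exception). The
solver handles the degeneracy by truncating numerically null directions of
the Gram matrix (relative eigenvalue below 1e-11) and returning the
minimum-norm representative. Tests of recovery therefore assert the
identifiable content — zero residual and the state-evolution form — rather
than block-wise equality. On noisy data the estimate is unique but carries
a simultaneity bias of the order of the noise variance (contemporaneous
regressors are correlated with the disturbance), which is the textbook
price of regressing on `x(k)` itself; fingerprinting does not require
unbiasedness, only stability of the estimate across runs of the same
subject, which the `lambda` penalty promotes by shrinking the poorly
determined directions consistently.

Practical consequence: with the synthetic cohorts below, fingerprinting
analyses use `lambda = 2` (roughly `noise_sd * sqrt(T)`, the scale at which
the penalty balances the residual's gradient in the weakly identified
directions), while recovery checks use a vanishing `lambda`.

## Subject fingerprinting

`modal_features()` diagonalizes `A = T L T^{-1}` (and `Q` for the full
feature set) and uses the canonicalized mode vectors — the invariant
directions along which the dynamics evolve independently — as one-shot
subject features. Complex conjugate eigenpairs are converted to real
(Re, Im) pairs; each vector is scaled to unit norm with its
largest-magnitude entry positive (ties broken by lowest index). The
canonicalization matters: cosine distance is not sign-invariant, and
eigenvectors are defined only up to scale and sign, so without it identical
systems could appear maximally distant. Near-defective matrices
(eigenvector condition number above 1e10) fall back to orthogonal real
Schur vectors with a warning; a Jordan decomposition would be the exact
alternative but is numerically meaningless in floating point. Eigenvalues
are retained for inspection but never enter the distance — all modes are
treated as equally informative, in contrast to variance-ranked reductions
such as PCA.

`modal_distance()` compares two feature sets as unordered vector
collections: the minimum over all pairings of summed cosine distances,
solved exactly as a linear assignment problem by an O(n^3) Hungarian
algorithm (verified against brute-force enumeration for up to 7 vectors).
`identify_subject()` returns the nearest library entry, breaking ties by
the lexicographically smallest label, and `evaluate_subject_accuracy()`
implements the cross-condition protocol in which each run serves in turn
as the reference database while all others are queries.

Three feature modes mirror the method's own comparison: `slow` (modes of
`A`; the default and empirically the best), `full` (modes of `A` and `Q`),
and `single` (modes of a one-timescale refit with `Q = 0`, `B1 = 0`).

## Task fingerprinting

`signature_graph()` turns a signature into a graph: node `i` carries row
`i` of `R` as its feature vector, and the row-normalized absolute slow
block `|A|` supplies directed, weighted edges (alternative symmetric and
max-abs normalizations are available; normalization is needed because raw
block scales vary across recordings). The classifier is a five-layer graph
attention network: a GATv2 block (input `2m+2n`, 4 heads of 32 features)
summed with a parallel linear skip path (128 channels), top-k node pooling
at ratio 0.8, a second GATv2 block (2 heads of 32) with a 64-channel skip,
global mean pooling, and a linear log-softmax head over the `C = 8` task
classes. Attention scores follow the GATv2 form
`a' leakyReLU(W_s x_target + W_t x_source + W_e w_edge)` with the edge
weight consumed as a scalar edge feature (configurable), softmax-normalized
over each node's incoming edges; self-loops are added with the graph's mean
edge weight. During training 10% of edges are dropped each epoch (weights
of survivors are not rescaled) and attention coefficients are dropped at
0.30; both are disabled at inference, so evaluation is deterministic.

The network and its backpropagation are implemented directly in R;
gradient correctness is checked against central finite differences in the
test suite. Training hyperparameters are unremarkable and overridable:
Adam at learning rate 1e-3, minibatches of 32, up to 200 epochs with early
stopping on validation loss (patience 20; a stratified 20% carve-out of
the training set is used when no validation set is supplied), all
deterministic under the configuration seed.

## Reachability landscape

`state_evolution()` rewrites the model in explicit form with
`Ahat, B1hat, B2hat` (by linear solves; an error names the condition
number when `I - Q` is numerically singular at 1e12). For a horizon of
`T_M` scans, zero initial state, and inputs `u(0..T_M-1)` bounded in total
energy (`u(T_M)` is taken as zero, respecting the declared input window),
the terminal state unrolls as `x(T_M) = sum_k M_k u(k)` with

    M_k = [k >= 1] Ahat^(T_M-k) B1hat + Ahat^(T_M-1-k) B2hat.

Each region decouples: under the energy bound the maximal terminal
activation of region `i` is the Euclidean norm of row `i` of
`[M_0 ... M_{T_M-1}]`, attained by the unit input aligned with that row;
under the per-entry box bound (`|u| <= 1`, the linear-programming reading
of the constraint) it is the row's l1 norm, so box values always dominate
energy values. Powers of `Ahat` are accumulated iteratively rather than
via eigendecomposition.

A subtlety worth recording: the values are *not* exactly monotone in the
horizon. Because `x(0)` is pinned to zero, the first input has no
concurrent path, so extending the horizon and shifting an optimal input
forward leaves an unmatched `Ahat^T B1hat` term; values can drop by at
most the norm of that row (exact monotonicity does hold when `B1hat = 0`).
The test suite asserts these true properties; violations decay like
`rho(Ahat)^T_M` for stable systems.

`reachability_landscape()` min–max normalizes the values (a constant
vector maps to all ones) and places them row-major in atlas order on the
12 x 12 cortical grid used for visualization, masking unused cells;
`plot()` renders the heatmap. Atlas index order is used for the grid — the
anatomical arrangement of the original figures is a cosmetic divergence.

## The synthetic cohort generator

`generate_cohort()` exists so that every pipeline stage is testable
without any data download; it emulates the multi-subject, multi-task,
two-run design of the reference dataset. One base system is drawn; each
subject perturbs the slow block `A`; each task perturbs `B1`/`B2` and the
input mean pattern; each run redraws inputs and noise. Every generated
state-evolution matrix is rescaled to spectral radius exactly
`stability_margin` (0.9), so all recordings are stationary. The defaults —
20 states, 5 inputs, 300 scans at `dt = 0.72` s — are a scaled-down
analogue of the 90-state/10-input/1190-scan reference design, chosen to
preserve its ratio of samples to regression parameters (about 6) so that
estimation error per run is in a comparable regime; `noise_sd = 0.05`
(5% of the unit signal scale) is moderate noise, and
`subject_spread = 0.2` encodes the strong individual differences reported
for functional connectomes.

Two deliberate design choices: (i) the fast block `Q` is shared across
subjects, and `fast_noise_sd` both perturbs each run's fast blocks and
injects a disturbance through the fast channel (before the `(I-Q)^{-1}`
mixing). This reproduces the documented regime in which fast concurrent
interactions are real but unreliable at the fMRI sampling rate — with a
subject-specific `Q` the full feature set would outrank the slow one on
synthetic data, inverting the qualitative ordering the method reports.
(ii) Noise enters as an additive per-scan disturbance; there is no
hemodynamic convolution, no scanner drift, no motion artifact, and the
true dynamics are exactly linear. Passing tests on these cohorts therefore
demonstrates correctness of the estimators and protocols under the model's
own assumptions, not robustness to the physiological confounds of real
fMRI.

Problem sizes used by the shipped tests and the acceptance script — 50
subjects for the cross-run identification analysis, 20 subjects for the
feature-mode comparison, 8 tasks by 30 subjects for the classifier, 15
subjects for the sampling-interval sweep, with 3–5 seeds per analysis and
classifier training capped at 40 epochs — are the package's standard
small-study configuration; all are parameters of public functions and
scale up freely.

## Numerical choices

* Gram-matrix solves truncate relative eigenvalues below 1e-11; ridge
  penalties add `lambda^2` to the diagonal.
* IRLS for the unsquared objective uses a 1e-10 norm floor in the
  reweighting, stops on an objective change below 1e-8 (relative), and
  warns with the final gap after 500 iterations.
* `(I - Q)` condition numbers are computed by SVD; 1e12 is the
  singularity threshold for simulation and the state-evolution form.
* Eigenvector canonicalization breaks magnitude ties by lowest index;
  assignment ties are resolved by the Hungarian algorithm's deterministic
  scan order; subject ties by lexicographic label.
* All stochastic steps (simulation, cohort generation, dropout,
  initialization) draw from a seed passed explicitly and restore the
  caller's RNG state.

## Limitations

The linear two-timescale model is a deliberate simplification — no
bilinear, threshold, or time-varying dynamics, and no hemodynamic forward
model. The fast/slow split is unidentifiable in the noise-free limit (see
above), so interpretation of individual `Q` entries on real data should be
cautious; the fingerprinting results rely on run-to-run stability, not on
causal consistency of each block. Input regions are user-selected, not
inferred. The task classifier is a trained model and need not transfer
across acquisition protocols.
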