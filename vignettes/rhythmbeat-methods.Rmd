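---
title: "Methods: rhythm-aware beat classification with a tree-regularized BiLSTM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm-aware beat classification with a tree-regularized BiLSTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Arrhythmia screening from long single-lead ECG recordings reduces, in the
AAMI (ANSI/AAMI EC57) framing, to assigning each heartbeat one of five
classes: **N** (normal and bundle-branch-block beats), **S**
(supraventricular ectopic), **V** (ventricular ectopic), **F** (fusion) and
**Q** (paced/unclassifiable). Two properties of the problem shape this
package:

1. **Rhythm matters.** Several classes are defined as much by *when* a beat
   occurs as by its shape. An atrial premature beat (S) conducts through the
   ventricles normally, so its waveform is nearly normal; what marks it is
   prematurity and the rhythm patterns it forms (bigeminy `N-S-N-S-...`,
   trigeminy `N-N-S-...`, runs `S-S-S`). A classifier that sees one beat at a
   time is structurally blind to this.
2. **Black-box models are hard to audit.** A clinician reviewing an
   automated call benefits from a compact, inspectable decision rule.

The package therefore classifies *segments* of `t` consecutive beats with a
bidirectional LSTM, and regularizes the network toward functions that a
small decision tree can imitate.

## Pipeline

### Denoising

Raw ECG carries baseline drift, mains interference and broadband muscle
noise. The signal is decomposed with the orthogonal dyadic discrete wavelet
transform using the Daubechies-6 (db6) filter, whose moderate length smooths
without shifting the ECG fiducial points. Defaults (all in
`wavelet_config()`):

* **depth 8** at 360 Hz — the deepest approximation band then lies below
  about 0.7 Hz, and zeroing it (`drop_approximation = TRUE`) removes
  baseline wander;
* **universal soft threshold** `sigma * sqrt(2 log n)` on every detail band,
  with `sigma` estimated by the median absolute deviation of the finest
  detail band (`median(|d1|)/0.6745`) — the standard wavelet-shrinkage
  recipe;
* **symmetric-reflection padding** up to a multiple of `2^levels`, trimmed
  after reconstruction, so any input length is handled and preserved.

The transform itself is periodized and orthogonal, so reconstruction of
unmodified coefficients is exact to rounding error — a property the test
suite checks directly.

### Beat segmentation

Beats are anchored on annotated R peaks: 0.25 s before to 0.40 s after the
peak, i.e. `round(0.25 fs) + 1 + round(0.4 fs)` samples — **235 samples at
360 Hz with the R peak at 0-based window index 90**. Everything in this
package is 0-based when it refers to window sample positions; published
descriptions of feature points in this framing are sometimes 1-based, so a
±1–3 offset must be kept in mind when comparing landmark indices. Beats
whose window would cross a record boundary are dropped (never padded —
padding would fabricate morphology), and non-beat annotation symbols
(rhythm-change `+`, artifacts) are excluded by the symbol grouping in
`map_annotation_to_aami()`.

### Segments and the train/test split

Consecutive beats are chunked, per record, into non-overlapping segments of
`t` beats (`assemble_segments()`). A trailing partial segment is kept,
zero-padded at batch time, and masked out of the loss. The 90/10 random
split (`split_dataset()`) operates at the *segment* level by default so that
segments stay intact; passing the beat table splits at beat level instead.
Both interpretations of "90% of the heartbeat data" are thus available;
segment-level is the default because the segment is the training unit.

## The classifier

Each timestep's input is the raw beat window (235 values; no per-beat
sub-network). The LSTM cell is the standard gated unit:

$$
\begin{aligned}
i_t &= \sigma(W_i x_t + U_i h_{t-1} + b_i), &
f_t &= \sigma(W_f x_t + U_f h_{t-1} + b_f), \\
o_t &= \sigma(W_o x_t + U_o h_{t-1} + b_o), &
\tilde C_t &= \tanh(W_c x_t + U_c h_{t-1} + b_c), \\
C_t &= f_t \otimes C_{t-1} + i_t \otimes \tilde C_t, &
h_t &= o_t \otimes \tanh(C_t).
\end{aligned}
$$

Two independent cells read the segment left-to-right and right-to-left and
are combined by a **weighted sum** rather than the more common
concatenation:

$$H_t = W_\rightarrow \vec h_t + W_\leftarrow \overset{\leftarrow}h_t + b.$$

The combination weights are shared across timesteps (a per-timestep
parameterization would preclude variable-length segments). A linear +
softmax head maps each $H_t$ to the five class probabilities, and the loss
is mean per-beat categorical cross-entropy over unmasked beats — the
natural choice for a 5-class softmax head — plus an optional penalty
$\lambda \Psi(W)$ (none, L1, L2, or the tree penalty below; L1/L2 act on
weight matrices only, not biases, following the usual convention).

Training is plain backpropagation-through-time with Adam, implemented in
base R matrix algebra, with global gradient-norm clipping
(`max_grad_norm`, default 5) — standard for recurrent nets and doubly
useful here because the tree-penalty gradient can spike when the surrogate
is retrained. Gradients are verified against central finite differences to
better than 1e-4 relative error in the test suite.

Unspecified hyperparameters (hidden width, learning rate, epochs, batch
size) are exposed in `train_config()`; defaults are ordinary choices
(hidden 64, Adam at 1e-3, 30 epochs, batch 64) and every experiment in this
package logs the configuration it actually used.

## Tree regularization

The interpretability device is a **simulated decision tree (SDT)**: a CART
tree fit to the *network's own predictions* $\hat y_n$ on the training
beats (never the ground truth — the tree must imitate the network). Its
complexity is summarized by the **average path length (APL)**: the mean
number of internal decision nodes a sample traverses from root to leaf. A
network whose distilled tree has small APL is, in this operational sense,
simulable by a human.

APL is a step function of the network parameters, hence not differentiable.
A small MLP surrogate $\tilde\Omega(W)$ — one hidden layer of 25 tanh
units, softplus output so the predicted APL is nonnegative — is regressed
on pairs $\{(W_j, \Omega(W_j))\}$ with a ridge penalty
$\varepsilon \lVert \xi \rVert^2$ ($\varepsilon$ default 1e-3), and the
joint objective

$$\min_W \textstyle\sum_n \mathrm{loss}(y_n, \hat y_n(x_n, W)) + \lambda \tilde\Omega(W)$$

is minimized by gradient descent through the surrogate.

Design choices that the method statement leaves open, and how this package
resolves them:

* **Collecting surrogate pairs.** Training-trajectory checkpoints plus
  Gaussian perturbations of each (default scale 0.1 × the parameter
  standard deviation). Each variant is instantiated, predicts the
  distillation set, a tree is distilled, and the true APL recorded.
* **Loop order.** Reconstructed as alternation: warm-up epochs with the
  penalty inactive until the first distillation; thereafter every
  `distill_every` epochs the predictions are refreshed, a tree distilled,
  the surrogate dataset extended and the surrogate retrained, with penalty
  gradients applied in between. With `lambda = 0` the trajectory is
  bit-identical to plain training (all surrogate-side randomness lives in
  its own RNG stream), which the tests assert.
* **Surrogate input scaling.** Parameter vectors are normalized so the
  typical checkpoint-to-checkpoint *distance* is O(1). Per-entry
  standardization would place the data ~sqrt(dim) apart and saturate the
  tanh units, leaving a zero gradient almost everywhere. For the same
  reason the surrogate is trained on slightly jittered inputs
  (`input_jitter`, default 0.3 in distance units, refreshed every few
  iterations): the true APL is piecewise constant, and the jitter fits a
  locally smoothed version whose gradient is usable as a penalty.
* **Tree constraints.** `max_depth = 8`, `min_samples_leaf = 20` by
  default: unconstrained trees make the APL noisy and the distillation
  overfit. APL counts internal decision nodes traversed (equivalently,
  edges on the root-to-leaf path); a single-leaf tree scores 0.
* **Whether the displayed top-k tree is refit or pruned.** Both are
  available: `rank_features()` + `reduced_feature_experiment()` refit on
  the selected feature points; `write_sdt_dot()` renders any tree directly.

Feature importance is normalized total Gini impurity decrease (the
`split_count` alternative is a flag), with deterministic ties broken toward
the lower window index.

## The synthetic benchmark

`benchmark_dataset()` fixes the study conditions for every experiment and
test: records cycling through ventricular/atrial bigeminy and trigeminy,
ventricular and atrial tachycardia, normal sinus rhythm, a
ventricular-run-with-fusion pattern (`V-V-V-F-N-N` — fusion beats follow
ventricular runs), and a paced pattern (`Q`), at 75 bpm with 5% interval
jitter and the default noise model, denoised and segmented at `t = 15`.

Beat morphologies are parametric sums of Gaussian bumps for the P, QRS and
T deflections. Class rules: N has P + narrow QRS + T; V is wide,
large-amplitude, P-less, with discordant T; **S is nearly identical to N**
(only a marginally early, marginally peaked P) because an atrial premature
beat's ventricular conduction is normal — its reliable signal is
*prematurity*, realized by shortening the preceding inter-beat interval to
0.7× base and following it with a compensatory pause; F is an equal blend
of the N and V shapes; Q is a pacing-spike-like stand-in (no physiological
reference defines the "unclassifiable" morphology — flagged here
explicitly). Noise is additive: sinusoidal baseline wander, sinusoidal
mains interference, white Gaussian noise.

What this generator does and does not show: it reproduces the *structural*
properties the method relies on (fixed beat windows, rhythm grammars, a
class whose identity is contextual, additive noise) but not the
morphological diversity, inter-patient variability, or annotation noise of
clinical recordings. Tests passing on it demonstrate that the machinery is
correct and that rhythm context genuinely helps on context-dependent data;
they do not certify clinical performance, and the package makes no claim of
reproducing any specific published accuracy on clinical databases. The
WFDB reader exists so real annotated records can be substituted when
available.

## Problem sizes used by the tests and the acceptance script

All experiments run at desk scale, chosen once: the standard benchmark is
10,000 beats (segments of 15) for the tree-regularization comparison —
λ = 10 vs λ = 0, five training seeds each, hidden width 16, nine epochs
with distillation every three — and 3,000 beats for the segment-length
comparison (t = 15 vs t = 1, three seeds, fifteen epochs). The distillation
set is capped at 4,000 beats (whole segments, deterministically
subsampled). These sizes keep every run reproducible on a single CPU while
leaving the compared quantities well away from their decision boundaries in
our runs.

## Numerical and degenerate-input conventions

* Windows that cross a record boundary: error at `segment_beat()`, dropped
  (and counted) by `build_beats()`.
* Zero-denominator rates (a class absent from truth or predictions):
  reported as `NA`, excluded from averages, never an error.
* A constant-prediction network distills to a single-leaf tree with APL 0
  and fidelity 1.
* Softmax is computed with the row-max subtracted; probabilities sum to 1
  within 1e-9 and cross-entropy clamps probabilities at 1e-300.
* All randomness is seed-controlled; identical seeds give bit-identical
  records, splits, parameter draws and training trajectories.

## Limitations

* Single-lead, database-annotated R peaks; no peak detection, no
  inter-patient split protocol.
* The surrogate's gradient quality depends on the collected (W, APL) pairs;
  early in training (few checkpoints) the penalty can be weak. The history
  tibble logs true APL, fidelity and surrogate holdout MSE at every
  distillation so this is observable.
* Pure-R training: practical for the benchmark sizes above, not for
  million-beat corpora.

## Package shape

Tabular artifacts — beat tables, segment tables, metric tables, training
history, rankings, node reports — are tibbles and compose with dplyr;
fitted models and evaluations provide `tidy()`/`glance()`; records,
confusion matrices and rankings have `autoplot()`/`plot_*()`. Waveforms and
trees, which are not tables, are light S3 objects (`ecg_record`,
`sim_decision_tree`, `bilstm_fit`).
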