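---
title: "Multi-scale attention networks for NIR spectral regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale attention networks for NIR spectral regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectran)
```

## The problem

Near-infrared (NIR) absorbance spectra of bulk corn samples encode the
concentrations of the four major biochemical constituents — moisture,
starch, oil and protein — through overtone and combination bands of O–H,
C–H and N–H vibrations. A calibration model maps a 700-channel absorbance
vector (1100–2498 nm at 2 nm spacing) to the four concentrations (in
percent) simultaneously. The difficulty is twofold: the informative
variation is tiny (a few milli-absorbance riding on a large common
baseline), and it is spread across both narrow local peaks and broad
global shape changes, so a good model must integrate evidence at several
spectral scales.

`spectran` implements a multi-scale attention network (SpecTran) for this
multi-task regression, together with four neural baselines, the training
protocol, and two interpretability primitives. Because the reference corn
benchmark is external, the package ships a synthetic generator that
reproduces its shape and statistics, so that every stage — augmentation,
training, evaluation, attribution — is testable end to end.

## The SpecTran architecture

For a spectrum $x \in \mathbb{R}^{700}$:

1. **Adaptive multi-scale patch embedding.** Three parallel 1-D
   convolutions with kernel size = stride $k \in \{8, 12, 16\}$ produce
   patch sequences $Z_m \in \mathbb{R}^{L_m \times d}$ with
   $L_m = \lfloor 700 / k_m \rfloor$. All branches project to a common
   width $d$ (`d_model`, default 128): the weighted sum that follows
   forces equal widths, and the reference description never gives
   per-branch widths. Branches are truncated to the *first*
   $L = \min_m L_m = 43$ patches (the literal reading of the slice) and
   combined as $Z = \sum_m \alpha_m Z_m$ with
   $\alpha = \mathrm{softmax}(w)$, $w$ learned and initialized to zero
   (equal weights).

2. **Spectral positional encoding.** The classic sinusoidal encoding is
   scaled per position by $1 + \lambda\,p/(L-1)$ with $\lambda = 0.1$, so
   longer-wavelength patches carry a slightly stronger positional signal;
   $\lambda = 0$ recovers the classic encoding exactly, which is the
   oracle our tests compare against. At $L = 1$ the scale is defined as 1
   (with a warning) since $p/(L-1)$ is undefined.

3. **Multi-scale spectral attention.** Four same-padded 1-D convolutions
   (kernels $\{3, 7, 15, 31\}$) with ReLU run along the patch axis, are
   concatenated channel-wise, projected back to $d$, and passed through
   multi-head self-attention; a residual connection and LayerNorm close
   the block.

4. **Enhanced Transformer blocks** (6 by default): multi-head
   self-attention followed by a convolutional feed-forward network
   $\mathrm{conv}_{d \to 4d} \to \mathrm{GELU} \to \mathrm{conv}_{4d \to d}$,
   each sublayer residual + LayerNorm. The first FFN convolution uses
   kernel 3 and the second kernel 1 — the reference leaves the kernels
   unstated; kernel 3 preserves local spectral structure, kernel 1 is a
   pointwise contraction. Dropout 0.1 after the attention and FFN
   sublayers (never mentioned in the reference; exposed in the config and
   set to 0 wherever determinism matters).

5. **Multi-path fusion.** Three parallel 64-dimensional summaries of the
   block output: global (mean over patches → MLP), local (kernel-3 conv →
   max-pool over patches → MLP) and sequential (single-layer BiLSTM with
   32 hidden units per direction, mean over patches). The concatenated
   192-vector is refined by self-attention over the three 64-wide path
   tokens — the only shape-consistent reading of the duplicated fusion
   equations (printed once with and once without a transpose) — and
   re-concatenated to 192.

6. **Hybrid heads.** Four task-specific two-layer MLPs (hidden widths
   64/64/96/128, ordered like the task weights; the reference only says
   "tuned to task difficulty") and one deeper shared MLP (192→128→64→4)
   are blended as $\hat y = \alpha \hat y_\text{task} +
   (1-\alpha)\hat y_\text{shared}$ with a single learnable scalar
   $\alpha \in (0,1)$ parameterized through a logistic map and
   initialized at 0.5.

All forward and backward computation runs on a small reverse-mode
automatic differentiation engine written for this package (`R/tape.R`):
matrices as values, eager evaluation, per-op backward closures. Every op
is verified against central finite differences in the development
history, and the full models are probe-checked the same way.

## Baselines

* **MLP** on the raw 700-channel vector (hidden widths 256/128/64).
* **CNN**: three conv blocks (filters 32/64/64, kernels 3/5/7, each
  batch-norm + ReLU + max-pool 2), flatten, dense 128, linear head. The
  reference gives kernel sizes "e.g. 3, 5, 7" but no counts; all are
  configurable.
* **Transformer encoder**: non-overlapping patch projection (size 16),
  classic sinusoidal encoding, 4 encoder layers (d 128, 4 heads),
  mean-pool, dense head.
* **LSTTN**: patch projection, 2 stacked LSTM layers (hidden 64), the
  dot-product reweighting $\mathrm{Softmax}(HH^\top/\sqrt d)H$, mean-pool
  and four per-task heads.

The raw-versus-projected input split (raw for MLP/CNN, patch tokens for
Transformer/LSTTN) follows the most natural reading of each
architecture's input contract. All baselines train under the identical
loop, loss and schedule as SpecTran.

## Training protocol

The composite loss is
$L = \alpha L_\text{MSE} + \beta L_\text{L1} + \gamma L_\text{weighted}$
with task weights $w = (1.2, 1.0, 1.5, 2.0)$ for (moisture, starch, oil,
protein). The coefficients $\alpha, \beta, \gamma$ are not reported in
the reference; the defaults $(1.0, 0.2, 0.5)$ let the MSE term dominate
with mild L1 robustness and task reweighting, and all three are exposed
in `loss_config()`.

Optimization uses AdamW (decoupled weight decay, default $10^{-4}$) with
global gradient-norm clipping at 1.0 applied *before* the step, and a
one-cycle learning-rate schedule: linear ramp from $\eta_\min$ to
$\eta_\max$ over the first 20% of steps, then cosine annealing
$\eta = \eta_\min + \tfrac12(\eta_\max - \eta_\min)(1 + \cos(\pi t'/T))$
back to $\eta_\min$. $\eta_\min = 10^{-5}$, $\eta_\max = 10^{-3}$ and
batch size 32 are package defaults (unreported in the reference). Early
stopping monitors validation loss with patience 30 over at most 250
epochs; "improvement" means `val < best - 1e-6`, and the best-validation
parameters are restored.

Two standardizations precede the network, both fitted on the training
split only and stored in the model so `predict()` is self-contained:

* **Targets** are z-scored per task; predictions and all reported metrics
  are de-standardized back to percent units.
* **Inputs** are centered per channel and scaled by a single pooled
  spectral standard deviation. NIR spectra vary by a few milli-absorbance
  around a large shared baseline; without this preconditioning, gradient
  training stalls at the target mean. The pooled scale (rather than
  per-channel z-scoring) preserves the relative intensities of absorption
  bands: per-channel scaling amplifies near-constant, uninformative
  channels into unit-variance inputs, which both slows learning of the
  true band structure and contaminates perturbation-based attribution.
  This plays the role of the "preprocessed" spectra the reference feeds
  its network.

## The synthetic generator

`generate_spectra()` emulates the corn benchmark's shape: 80 samples by
default, 700 channels, and concentrations drawn from a multivariate
normal with the benchmark's printed per-constituent means and standard
deviations (moisture 10.234/0.380, starch 3.498/0.177, oil 8.668/0.499,
protein 64.696/0.821 percent), truncated to positive values by redraw
(clipping would distort the distribution shape). Each spectrum is a
linear baseline plus, per constituent, Gaussian absorption bands scaled
by that sample's concentration, plus i.i.d. channel noise (default sd
0.001 absorbance). Band centers are placed so that interpretability
analyses have a known answer — in particular the protein-labelled
constituent absorbs near channels 0–100 and 580–660, the regions a
trained model should highlight for protein. Amplitudes (0.003–0.02
absorbance per percent) were chosen once so that constituent-driven
spectral variation sits at realistic milli-absorbance scale against the
baseline. The nonlinear mode passes the constituent signal through a
saturating map $s \mapsto s_0 \tanh(s/s_0)$ and adds one oil–protein
product interaction band; with $s_0 \to \infty$ and zero interaction it
reduces to the linear mode exactly.

What the generator does *not* emulate: multiplicative scatter and
path-length effects, wavelength-dependent instrument noise, baseline
drift between instruments, and the real constituent covariance structure
(identity by default). Tests passing on synthetic data therefore
establish that the machinery is correct and that the architecture can
learn band-localized structure — not that any accuracy level carries
over to real corn spectra.

## Augmentation

`augment_spectra()` draws two distinct parents uniformly (pairs may
repeat across draws) and a fresh $\alpha \sim U(0.1, 0.9)$ per synthetic
sample, interpolating spectrum and labels with the same $\alpha$; the
defaults grow 80 training samples to 2000. Augmentation is applied to the
training split only: interpolating across splits would leak evaluation
information into training, and the reference is silent on the order of
splitting and augmentation. Convexity gives hard guarantees the tests
exercise: every synthetic sample lies channel-wise inside its parents'
envelope, and any exact linear spectrum–label relation is preserved.

## Interpretability

`perturbation_importance()` slides a window (default 10 channels, stride
5 — the reference does not state its scheme) along the spectrum, replaces
the window with reference values, and records the absolute output change
per task; per-channel scores average over covering windows, optionally
max-normalized per task. The fill values default to the training-set
per-channel mean rather than zeros, because zero absorbance is far
outside the data distribution. `extract_attention()` returns the
post-softmax attention of any enhanced block (head-resolved or
head-averaged; rows sum to 1), and `attention_saliency()` projects a
layer's key-mass onto channels by spreading each patch's mass uniformly
over the 16 channels it covers — a distinct, attention-based estimator,
not a substitute for perturbation importance. Channel axes are channel
indices 0–699 throughout, matching how patch positions map to wavelength
via `patch_to_wavelength()`.

Perturbation importance of a multi-task network is a subtle quantity, and
the ground-truth tests are designed around three facts established while
developing the package. First, because the four tasks share a trunk, a
window replacement that slices an absorption band in half produces a
spectrum unlike anything in the training distribution, and the trunk's
in-distribution cancellations between task features need not survive it —
so some off-band sensitivity is expected even for an accurate model.
Second, the probe therefore uses a fixture in which the probed
constituent's band strength is comparable to the others': localizing a
deliberately weak feature would confound band localization with feature
strength. Third, the perturbation response at a band scales with how far
the probed sample's constituent deviates from the training mean (the fill
value); a near-average sample has an arbitrarily small true response, so
the tests average the profile over the three test samples with the
largest deviation on the probed constituent — the same logic by which
single-sample attribution figures are drawn for informative samples.
Finally, off-band sensitivity shrinks with identification strength: with
$n$ training samples the spurious cross-constituent correlation scales
like $1/\sqrt n$, so the probe trains on a couple of hundred samples with
moderate weight decay, at which point the in-band response exceeds the
largest off-band response several-fold across unrelated seeds.

## Numerical and design choices

* Constituent order is fixed globally to (moisture, starch, oil,
  protein); file readers reorder by header name.
* The wavelength grid is stored as (start, step, n); channel $i$ sits at
  $1100 + 2i$ nm.
* Descriptive statistics default to the population (divide-by-N) standard
  deviation, configurable, since the benchmark table does not state its
  convention.
* Dataset splits round `fractions * N` per part with the last part
  absorbing the remainder.
* LayerNorm uses $\varepsilon = 10^{-5}$; softmax subtracts the row
  maximum; max-pool gradients follow the first argmax on ties.
* Checkpoints store the config plus a hash validated on load; a
  round-trip reproduces forward outputs bit for bit.

## Problem sizes used in tests

The test-suite and the acceptance script run the full pipeline at sizes a
laptop CPU handles in minutes, chosen once as representative: 96-channel
grids with in-range bands for training smoke tests; 200 noiseless samples
for the closed-form linear-recovery oracle; 8 samples / d_model 32 / 2
blocks for the overfitting sanity run (target train MSE below $10^{-3}$
within 500 epochs); 96 samples and a d_model-16 single-block model for
the interpretability ground-truth run. Full-size (80 × 700, d_model 128,
6 blocks) models are exercised for shape, attention and determinism
contracts rather than convergence.

## Known limitations

* The autodiff engine is single-threaded R; training the full-size model
  on thousands of augmented samples is possible but slow — the package's
  purpose is methodological fidelity and testability, not throughput.
* The accuracy figures reported for the external corn benchmark depend on
  that data and on stochastic training; the package reproduces the
  architecture, protocol and printed structural quantities, and makes no
  claim to reproduce benchmark error tables on synthetic data.
* R² on small validation splits is high-variance; the experiment runner
  reports per-task and macro metrics together with a scale-free
  normalized RMSE because averaging raw RMSE across constituents with
  very different scales (as the benchmark tables do) is scale-sensitive.
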