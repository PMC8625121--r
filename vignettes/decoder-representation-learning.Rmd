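---
title: "Encoder-free representation learning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoder-free representation learning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoderfit)
```

## The model

An autoencoder maps n-dimensional data through an m-dimensional (m < n)
bottleneck and back. The decoder half, $g_w$, on its own defines an
m-dimensional manifold in input space: the image of the representation space
under $g_w$. `decoderfit` trains that decoder *without any encoder* by
treating the representation $z_k$ of every training sample as a free
parameter and minimizing the total reconstruction loss

$$\sum_{k=1}^{N} L\big(x_k,\, g_w(z_k)\big)$$

jointly over the weights $w$ and the representations $z_1,\dots,z_N$ by
gradient descent. Geometrically this moves the manifold to lie as close to
the training points as the loss allows; each learned $z_k$ is the coordinate
of sample $k$'s projection onto the manifold. For a single fully connected
linear layer and squared-error loss, the optimal manifold is the principal
subspace, so the linear case has an analytic oracle
(`principal_subspace()`, checked by `subspace_angle()` in the test suite).

For new samples the decoder is frozen and the same optimizer runs over the
representation alone (`infer_representations()`); an encoder is optional and
can be trained afterwards against the frozen decoder (`fit_encoder()`),
including a denoising variant in which the encoder sees freshly corrupted
inputs each epoch while the target stays clean. The naive end-to-end
autoencoder (`fit_autoencoder()`) is the comparison baseline.

## Load: constraints per parameter

The number of training samples needed to specify each part is summarized by
the *load*, the ratio of data constraints to trainable parameters, with the
weight count used as the (upper-bound) proxy for model complexity:

* decoder: $\alpha_d = Nn/(C_d + Nm)$ — the $Nm$ term counts the free
  representations;
* encoder (representations fixed): $\alpha_e = mN/C_e$;
* at equal complexity $C_e = C_d$:
  $\alpha_d = \frac{n}{m}\,\frac{\alpha_e}{1+\alpha_e}$.

A load above 1 means over-determined. Because $n/m$ is typically large, the
decoder is far better specified by the same data than the encoder — the core
quantitative claim the package's experiment reproduces. Biases are excluded
from complexity counts; none of the supported architectures carries bias
terms, so counts equal the constraint-counting logic exactly. Masked
(structurally zero) weights are never trainable and are not counted.

## The regulatory simulator

`simulate_regulatory()` emulates expression of $n$ genes governed by $m$
transcription factors through a weighted bipartite graph:

$$x_i = \mathrm{ReLU}\Big(\textstyle\sum_j a_{ij} w_{ij} z_j + \epsilon_i\Big)$$

with binary adjacency $A$ (exactly `round(connectivity * n * m)` edges,
placed by a seeded draw so the sparsity fraction is exact and testable),
signed uniform weights $W$, gamma-distributed regulator levels $z$, and
optional Gaussian noise added before rectification. Defaults are the
experiment geometry: $n = 1000$, $m = 100$, connectivity 0.1 (90 % of $A$
zero). The generator's gamma parameters (shape 2, scale 1) and weight range
($[-1, 1)$) are this package's choices — positive right-skewed regulator
levels with mean 2 and signed regulation of unit scale keep roughly half of
the pre-activations positive, which is what makes the rectified readout
informative. The generator default noise sd is 0.2; the load-sweep
experiment itself uses the zero-noise preset, where the data are an exact
function of the network and regulator levels.

What the simulator deliberately omits: indirect regulation, regulator-
regulator interaction, time dynamics, count noise, and library-size effects.
Passing tests therefore demonstrate recovery of a known sparse linear-ReLU
generative structure, not performance on real sequencing data.

## Optimization: what is updated, when, and why

* **Weights** receive an Adam step per mini-batch (batch 32 by default) with
  L2 weight decay $10^{-5}$, computed from the element-mean loss. Adam is
  insensitive to constant loss rescaling, so this normalization choice does
  not affect weight dynamics.
* **Representations** receive one momentum-SGD step (momentum 0.9) per epoch
  each, when their batch is visited. The gradient is each sample's own loss
  summed over output dimensions, *not* divided by batch size or dimension:
  the step size is then independent of how the data are batched, and for the
  regulatory decoder the stated learning rate 0.01 sits comfortably inside
  the stability region of the per-sample quadratic subproblem (whose
  curvature is set by the ~`connectivity * n` genes each regulator touches).
* **Initialization**: weights uniform $\pm 1/\sqrt{\mathrm{fan~in}}$;
  representations Normal(0, 0.1²) — small enough to avoid dead rectifier
  zones, with the scale/symmetry degeneracy of the solution
  ($wx = (w/s)(zs)$) tamed by the weight decay.
* **Sign identifiability.** For a single-layer decoder, flipping
  representation dimension $j$ together with weight column $j$ leaves every
  prediction unchanged, so each dimension's sign is a free convention — the
  exact analogue of principal-component sign indeterminacy. After fitting,
  `fit_decoder()` orients every representation column to non-negative mean.
  Under that convention a dimension recovering a non-negative ground-truth
  regulator correlates *positively* with it, and per-dimension Pearson
  correlations (`representation_pcc()`) are directly interpretable. An
  optional hard non-negativity constraint on representations
  (`nonneg_reps`) is available for inference on non-negative latent domains.
* **Test-time inference** runs the representation optimizer with frozen
  weights from a seeded start, stopping at `infer_epochs` (500) or when the
  best loss fails to improve by `infer_tol` ($10^{-6}$) for `infer_patience`
  (100) consecutive epochs; the patience exceeds the ringing period of the
  momentum dynamics so transients are not mistaken for plateaus. The
  rectifier makes inference non-convex; `infer_restarts` reruns from
  different seeds and keeps each sample's best representation (the package
  uses single-start inference in the experiment, where the sparse geometry
  of ten regulators per gene makes trapping rare, and best-of-10 in the
  stress test that re-infers training samples on a much sparser toy
  geometry).

### Learning-rate calibration and the step budget

The published experiment obtained its learning rates from a small grid
search for its own implementation; this implementation normalizes the loss
differently, so the same grid-search step was repeated here once, at the
experiment geometry, over weight rates $\{10^{-3}, 3\times10^{-3},
10^{-2}\}$: the decoder weight rate used by `sweep_config()` is
$3\times10^{-3}$ (representation rate 0.01 with momentum 0.9, encoder and
autoencoder Adam rate $10^{-4}$, as published).

Epoch counts deserve care because one epoch means `ceil(N/32)` weight
updates but exactly one update per representation. Running a fixed epoch
count across a grid of N therefore gives the smallest N a few hundred weight
updates (far too few to converge) and the largest N hundreds of thousands
(far more than needed). `run_load_sweep()` instead holds the *weight-update
budget* constant: epochs are scaled by `epoch_reference_n / N` (clamped to
[1, 20000]), so every run receives the step count that the nominal epochs
would give at the reference N. Joint training additionally needs enough
*epochs* for the representations regardless of N — in practice a few hundred at this geometry — so the sweep driver never scales the decoder's epochs
below `min_epochs = 400`. Both knobs are exposed in `sweep_config()`.

## Evaluation choices

* Representation recovery is the per-dimension Pearson correlation across
  samples between true regulator levels and learned representations,
  aggregated as the unweighted mean over dimensions (the per-dimension
  vector is always retained). Correlating across samples within a dimension
  is the only choice invariant to per-regulator scale, which the model
  cannot and should not pin down. Index alignment is meaningful because the
  decoder's sparsity mask is the true adjacency, making each hidden unit
  identifiable as one regulator. Zero-variance dimensions are reported as
  `NA` and excluded from the mean with a warning.
* Test reconstruction error is the element-mean squared error between the
  test matrix and the reconstruction of the model's test representations
  (inferred for the decoder, forward passes for encoder and autoencoder).
* Data are centered by column means before `principal_subspace()`.

## The load-sweep experiment

`run_load_sweep()` reproduces the simulated-data experiment: for each
training size N and replicate, a fresh network and fresh train/test data
(test size 100) are drawn, the decoder (500 nominal epochs), the encoder on
the frozen pre-trained decoder (500), and the naive autoencoder (1000) are
trained on identical data and evaluated on the shared test set; rows carry
the analytic loads, seeds and a data fingerprint. Per-run seeds derive
deterministically from `base_seed`, so a whole sweep is one number to
reproduce. Failures are recorded per-row and the sweep continues.

The default N grid {15, 25, 50, 100, 300, 1000, 3000, 10000, 15000} spans
decoder loads from below 1 to near the n/m saturation and brackets the three
printed thresholds of the original experiment: $\alpha_d = 1$ (decoder
becomes well-determined), 3.3, and ≈ 9 (autoencoder parity, N > 10,000).

What the package's own reduced-scale runs show (the acceptance script and
`test-acceptance.R` recompute these; problem sizes there are chosen to keep
single-CPU runtimes in minutes — decoder-recovery checks at N ∈ {25, 50}
with 5 replicates, the encoder check at N = 3000 with 5 replicates on a
decoder pre-trained on a 1000-sample subset, and the autoencoder-parity
sweep over N ∈ {1000, 10000} with 1 replicate):

* decoder mean test PCC is ≈ 1 at the probed loads above 1 (2.0 and 3.3);
* the encoder on the frozen pre-trained decoder reaches mean test PCC
  ≈ 0.99 once its own load is comfortably above 1;
* the naive autoencoder's correlations are far lower at low load, and its
  test error remains several-fold above the decoder's everywhere in the
  desk-scale grid — test-MSE parity (within 10%) is *not* observed at or
  below N = 10,000, consistent with the original finding that parity
  requires sample sizes above 10,000. At desk-scale step budgets the
  autoencoder's training loss plateaus well above the decoder's optimum, so
  the parity threshold is reported as censored at the grid maximum;
* the load arithmetic is exact: the experiment configuration gives
  $\alpha_d = 9.90$ at N = 10,000 with $C_d = 10{,}000$.

### A note on the fixed-decoder encoder threshold

The original experiment reports encoder correlations ≥ 0.99 from
$\alpha_d = 3.3$ (N = 50) upward. A closed-form ridge-regression oracle
shows that *any* single linear layer trained on 50 samples is information-
limited here: its weight rows live in the 50-dimensional span of the
training inputs, while the latent image needs 100 dimensions, capping test
PCC near 0.66 at N = 50 and reaching 0.99 only once the encoder's own load
$\alpha_e = mN/C_e$ approaches 1 (N ≈ 1000) — which is exactly what the
encoder-load theory above predicts. This package therefore runs its encoder
check at N = 3000 ($\alpha_d = 9.7$, inside the stated "3.3 and above"
range; $\alpha_e = 3$) and documents the discrepancy at the threshold
itself rather than reproducing it.

## Known limitations

* Supported architectures are stacks of dense or masked linear layers with
  linear/rectifier/leaky-rectifier/sigmoid activations and squared-error or
  binary cross-entropy loss — the experiment's family. No convolutions, no
  biases.
* Canonical sign orientation applies only to single-layer decoders;
  multi-layer stacks have no exact per-column sign symmetry to canonicalize.
* Representation inference is non-convex under rectification; multi-restart
  mitigates but does not guarantee global optima.
* The simulator's idealizations (above) mean quantitative results transfer
  to real expression data only qualitatively.
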