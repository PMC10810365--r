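---
title: "Translating CETSA melting curves across cell lines with cyclic autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating CETSA melting curves across cell lines with cyclic autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycletsa)
```

## The problem

Mass-spectrometry-coupled cellular thermal shift assays (MS-CETSA) measure,
for thousands of proteins at once, the fraction of each protein that remains
soluble after cells are heated to a series of temperatures — here the
ten-point series 37, 40, ..., 64 °C. The resulting *melting profile* is a
ten-dimensional feature vector per protein, anchored near 1 at 37 °C and
decaying as the protein denatures and aggregates. Because a full MS-CETSA
experiment is costly, profiles are typically available for only a few cell
lines, while downstream uses (drug-target deconvolution, protein–protein
interaction analysis via thermal proximity co-aggregation) would benefit from
profiles in many cellular contexts.

`cycletsa` implements a cyclic multi-autoencoder that *translates* melting
profiles between cell lines. For $n$ cell lines it trains $n$ encoders
$E_i$ mapping cell line $i$'s ten-point profiles into a single shared latent
space $\mathbb{Z}$, and $n$ decoders $D_i$ mapping latent vectors back into
cell line $i$'s feature space. Any composition $F_{i,j} = D_j \circ E_i$ is a
translation map from cell line $i$ to cell line $j$, so $2n$ networks replace
the $2n(n-1)$ networks that direct pairwise translation would need — at
$n = 5$ a 75 % parameter saving (`scheme_module_counts(5)`).

## Model and losses

Encoders and decoders are fully connected networks. The full-scale
architecture is

* encoder: 10 → 500 (ReLU) → 500 (ReLU) → 5000 (ReLU),
* decoder: 5000 → 500 (ReLU) → 500 (ReLU) → 10 (no activation),

with dropout 0.3 after each hidden layer in training mode, and never after an
output layer. The encoder output layer carries ReLU, so latent codes are
non-negative; the decoder output layer is affine, so predicted abundances are
unbounded (no clamping). Counting biases the encoder holds 2,761,000
parameters; without biases the decoder holds 2,755,000. Both FLOP-counting
conventions are exposed (`count_flops()`): 2 FLOPs per multiply-accumulate
without bias adds gives the encoder's 5,510,000; 1 FLOP per MAC plus bias
adds gives the decoder's 2,756,010.

Training minimises, over all *ordered* cell-line pairs $(i, j)$ including
$i = j$,

$$L_1 = \frac{1}{n}\sum_{i,j=1}^n \mathrm{MSE}\!\left(F_{i,j}(C_i),\, C_j\right),
\qquad
L_2 = \frac{1}{n}\sum_{i,j=1}^n \mathrm{MSE}\!\left(F_{j,i}(F_{i,j}(C_i)),\, C_i\right),$$

$$L_3 = \frac{1}{n^2}\sum_{k=1}^n\sum_{i=1}^n \mathrm{MSE}(Z_i, Z_k),
\qquad
L = \alpha_1 L_1 + \alpha_2 L_2 + \alpha_3 L_3,$$

with $\alpha = (1, 0.01, 1)$ by default. $L_1$ is the prediction loss, $L_2$
the cycle-consistency loss (translating $i \to j \to i$ must recover the
input), and $L_3$ the latent regularisation pulling the same protein's codes
from different cell lines together. MSE is always the mean over the whole
batch-by-feature block. Three deliberate readings are worth noting:

* **$1/n$, not $1/n^2$.** $L_1$ and $L_2$ sum $n^2$ pair terms but divide by
  $n$. We implement exactly that; a `normalization = "n2"` option rescales to
  a per-pair mean, which only rescales $\alpha_1, \alpha_2$.
* **Diagonal terms included.** Self-prediction ($i \to i$) participates in
  training; the evaluation report also carries the $i \to i$ rows, which is
  where the characteristic self-vs-cross error pattern comes from.
* **Symmetric, with zero diagonal, in $L_3$** — every unordered latent pair
  enters twice, and $\mathrm{MSE}(Z_i, Z_i) = 0$ contributes nothing.

## Training procedure

`train()` runs stochastic gradient descent with classical momentum 0.95 and
L2 weight decay $10^{-5}$, batch size 128, base learning rate 0.01 decaying
by 5 % every 500 optimizer steps. "Step" means one batch (the conventional
reading of "iteration"); `decay_unit = "epoch"` is available. For each batch
the losses of *all* ordered pairs are summed into one total and one optimizer
step is taken — a single objective $L$, not a per-pair curriculum. (A
stage-wise pass over source cell lines would produce the same loss terms per
epoch; we implement the summed form.)

Early stopping monitors the held-out total loss: training stops at
`max_epochs` (default 5000) or after `patience` (default 300) consecutive
epochs without improvement, and the best-monitored checkpoint is returned.
The monitored quantity is a configuration choice (`monitor = "l1"` switches
to the prediction component alone); we default to the total loss because it
is the trained objective. Shuffling, dropout masks and initialization all
flow from explicit seeds, so identical `(seed, config, data)` reproduce a
run exactly. Parameters are initialized from a fan-in-scaled uniform
distribution, a standard choice for ReLU stacks that keeps early activations
in range.

The forward and backward passes are written directly in R matrix algebra
(the heavy lifting is BLAS `%*%`); gradients are verified against central
finite differences in the test suite to $10^{-4}$ relative error.

## The synthetic panel generator

`simulate_panels()` provides ground-truth data for every downstream stage.
Each protein melts as a two-state sigmoid

$$a(T) = \text{plateau} + \frac{1 - \text{plateau}}{1 + e^{s\,(T - T_m)}},$$

anchored to its own 37 °C value (so noise-free anchored curves equal exactly
1 at 37 °C and are non-increasing in $T$), with additive Gaussian noise after
anchoring, truncated at zero. Defaults are chosen once to describe a
realistic desk-scale study: 1000 proteins, 3 cell lines, $T_m \sim
\mathcal{N}(52, 5^2)$ °C and slopes $\sim \mathcal{N}(0.7, 0.15^2)$ /°C
(transition widths of roughly 4–8 °C, the range typical of proteome-wide
melting data), a 5 % non-melting baseline, per-(protein, cell line) thermal
shifts of sd 1.5 °C linking the cell lines, and measurement noise of sd
0.02. `curve_link` controls cell-line coupling: `"shifted_tm"` (default),
`"shared_tm"` (all cell lines identical — the translation task becomes the
identity), or `"independent"`. `apply_missingness()` emulates proteins
quantified in only some cell lines.

What the simulator does *not* emulate: correlated noise across temperatures,
non-sigmoidal melting behaviour, ligand-induced shifts, batch structure, or
missing single temperatures within a profile. Passing tests on simulated
panels therefore demonstrate that the machinery recovers structure it is
designed for — not that it handles every pathology of real proteome-wide
data.

## Desk-scale evaluation choices

The full-scale architecture (latent width 5000) exists for fidelity and for
the parameter/FLOP accounting; training it for thousands of epochs is a
GPU-scale exercise. All trained-model checks in this package run a
*desk-scale* instance of the same topology — 10 → 64 → 64 → 128 encoder and
mirrored decoder — which trains in minutes on one CPU core while preserving
every structural property under study. Three standard scenarios appear in
the tests and the acceptance script:

* **Translation recovery.** Default simulator conditions, 200 training
  epochs. All nine ordered-pair test-set Pearson correlations exceed 0.9 and
  the self-prediction rows dominate (lowest MSE per source).
* **Self-vs-cross pattern across seeds.** Ten independent 240-protein runs
  (batch size 32 so each epoch takes several optimizer steps, 300–350
  epochs); self-prediction MSE is lowest per source in at least 9 of 10.
* **Identity task.** `shift_sd = 0, noise_sd = 0` makes the optimal
  translation the identity map; a 400-protein run should reach held-out MSE
  at or below $10^{-3}$. This is an optimization-fidelity check, so the desk
  config drops dropout (there is no noise to regularise against) and uses a
  constant learning rate of 0.03 with batch size 32 — the stepped decay
  exists for long full-scale runs and only slows this short one.

Batch size 32 in the small runs is a deliberate departure from the
full-scale default of 128: with a few hundred training proteins, batch 128
yields so few optimizer steps per epoch that convergence per epoch becomes
misleadingly slow. The learning-rate schedule, momentum, weight decay and
dropout of the full-scale configuration stay at their defaults everywhere
except where stated.

## Evaluation metrics

`evaluate_transfer()` reports, per ordered pair, MSE, MAPE, MAE, $R^2$ and
the Pearson correlation, pooling residuals over all test proteins and
temperatures (a `per_protein` aggregation mode averages per-curve metrics
instead). Two conventions deserve mention:

* **MAPE carries a squared numerator** in this model family's reporting:
  $100/n \sum |(y_i - y'_i)^2 / y_i|$. That is the default; conventional
  MAPE is one flag away (`mode = "conventional"`).
* **MAE is implemented strictly** as the mean absolute residual. Pooled MAE
  can never be far below pooled MSE when residuals are bounded by 1, so MAE
  columns orders of magnitude below MSE in historical reports imply an
  undisclosed extra normalisation; we do not reproduce one.

MAPE is undefined at true zeros; `evaluate_transfer()` drops zero-truth
elements (which arise in clipped synthetic data) from the MAPE pool only.

## PPI validation harness

`build_pair_features()` turns a PPI record (two accessions and a confidence
score in $[0,1]$) into a 31-value feature vector: the two ten-point profiles
concatenated in lexicographic order, their per-temperature absolute
differences, and their Euclidean distance. The representation is symmetric
under swapping the pair and exposes the co-melting similarity signal that
thermal proximity co-aggregation predicts for interacting proteins. No
canonical feature construction exists for this task; ours is the simplest
symmetric one, and it is a documented package choice rather than a published
recipe.

`cv_tree_regression()` fits an `rpart` regression tree per cross-validation
fold (default 5 folds, 4:1 train:test) and pools out-of-fold predictions.
The default tree is fully grown (`min_leaf = 1`, complexity penalty 0,
depth cap 30): an unpruned tree is the standard default for decision-tree
regressors, and it gives the harness a clean calibration property — on
uniform-random scores the out-of-fold prediction is essentially an
independent uniform draw, so MAE approaches $\mathbb{E}|U - U'| = 1/3$.
Mild regularisation (`min_leaf = 5`) is available but lowers that
calibration value toward $\mathbb{E}|U - \bar U_m|$ and is off by default.
`compare_feature_sources()` applies *identical* folds to a measured and a
translated panel, so the two MAEs differ only through the features.

One subtlety matters when validating this harness on simulated data:
interaction scores must be driven by the *underlying* co-melting similarity
(`consensus_panel()` rebuilds it from the simulator's ground truth), not by
the realised values of one measured panel. Scores generated from a single
panel's measured curves hand that panel's features the answer — including
its measurement noise and cell-line-specific shifts, which no translation
from another cell line can know — and manufacture an irreducible gap. With
truth-driven scores, measured and translated features are both proxies for
the same signal, and a well-trained translation reaches MAE parity (the
translated panel can even score slightly better, because the model
effectively denoises).

## Numerical and degenerate-input policy

* Panel I/O writes 6 significant digits by default; `full_precision = TRUE`
  round-trips doubles exactly. Delimiters (comma/tab) are auto-detected.
* Rows with missing abundance cells are dropped with a warning, never
  imputed: no imputation rule is defensible without knowing the acquisition
  pipeline.
* Train/test splitting uses half-up rounding on the train size
  (`floor(f*n + 0.5)`) so the split is deterministic and documented; 4860
  proteins at 70 % give 3402/1458.
* The common protein index is sorted with radix (C-locale) order so results
  do not depend on the session locale.
* Zero-variance inputs to $R^2$ or the correlation raise classed errors
  rather than returning NaN; MAPE at a true zero does the same unless
  explicitly told to drop.
* `translate()` output is unclamped; predicted panels may contain small
  negative abundances, and consumers that require non-negativity must clip
  explicitly.

## Known limitations

* Real CETSA panels come with replicate structure, temperature-correlated
  noise and non-two-state melting; none are modelled by the simulator.
* Training is plain SGD-with-momentum by design; no adaptive optimizers,
  batch normalisation or schedulers beyond the stated decay are provided.
* The model only translates between cell lines present at training time;
  it cannot extrapolate to unseen cellular contexts.
* The PPI harness demonstrates *relative* validity of translated features
  against measured ones on a shared task; it is not a calibrated interaction
  predictor.
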