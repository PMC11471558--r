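---
title: "Mosaic multimodal integration with scMosaic: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosaic multimodal integration with scMosaic: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell multi-omics experiments increasingly measure several molecular
layers — chromatin accessibility (ATAC peaks), transcriptome (RNA genes) and
surface proteins (antibody-derived tags, ADT) — but rarely all of them in
every batch. A collection of batches in which each batch measured a
different, overlapping subset of modalities and features is a *mosaic*
dataset. scMosaic integrates such data into a common low-dimensional space,
imputes the missing blocks, and removes batch effects, with a deep
generative model whose two latent variables separate what is biological
from what is technical.

## The generative model

For cell $n$ with batch ID $s_n \in \{1,\dots,B\}$ and counts
$x_n^m$ for measured modalities $m \in M_n \subseteq \{\mathrm{ATAC},
\mathrm{RNA}, \mathrm{ADT}\}$, the model posits a biological state
$c \in \mathbb{R}^{d_c}$ and a technical noise $u \in \mathbb{R}^{d_u}$,
both with standard-normal priors, and factorizes

$$p(x, s, c, u) = p(c)\,p(u)\,p(s \mid u) \prod_{m \in M_n} p(x^m \mid c, u).$$

Only $u$ generates the batch ID — a categorical likelihood
$p(s \mid u) = \mathrm{Cat}(s \mid g^s(u))$ — which is the structural
assumption behind the disentanglement: batch identity must be readable from
$u$, never needed from $c$. Counts are Bernoulli with mean
$\lambda^{\mathrm{ATAC}} \in (0,1)$ for binarized accessibility and Poisson
for RNA/ADT, with $\lambda^m = g^m(c, u)$ a per-modality decoder network.
Decoders share their first layers; encoders share their last layers.

### Product-of-experts posterior

Each modality encoder and the batch-ID encoder emit a diagonal-Gaussian
"expert" over the joint latent $z = (c, u)$. The variational posterior is
their product together with the prior; for diagonal Gaussians this has the
closed form

$$\nu = \Big(1 + \sum_i \nu_i^{-1}\Big)^{-1}, \qquad
  \mu = \nu \odot \sum_i \mu_i / \nu_i,$$

so any subset of measured modalities — any mosaic pattern — routes through
the same $M + 1$ networks. A cell with no measured modalities falls back to
prior times batch expert.

One deliberate design choice (the reference formulation leaves it open):
**the batch-ID expert parameterizes only the $u$ dimensions**; its $c$ part
is flat. Because the batch expert's input is a one-hot batch ID, letting it
parameterize $c$ invites a degenerate optimum in which it becomes an
ultra-precise per-batch constant for the biological state: the precision-
weighted product then ignores the modality experts on $c$, embeddings
collapse to one point per batch, and the modality encoders stop receiving
gradient. We observed exactly this failure at desk scale. Restricting the
batch expert to $u$ matches the generative factorization ($s$ depends on
$u$ alone) and removes the failure mode.

### Losses

Three terms are minimized jointly over encoder/decoder parameters, averaged
over minibatches:

* **Negative ELBO** — reconstruction of the measured modalities (Bernoulli
  and Poisson negative log-likelihoods over *observed* features only, via
  the binary feature masks), a batch-ID likelihood term weighted by
  $\gamma$ (default 1000, pushing batch information into $u$), and the
  closed-form KL to the standard-normal prior.
* **Modality alignment** (weight $\alpha$, default 50) — a self-supervised
  pretext task: each measured modality's *unimodal* posterior (prior x
  batch expert x that modality's expert, reusing cached expert parameters)
  is sampled, and the sum of squared deviations of the samples from their
  mean is penalized, pulling the modalities onto one latent geometry.
* **Information bottleneck** (weights $\beta^s = 30$, $\beta^x = 4$) — for
  the joint posterior and each unimodal posterior: *plus* the log-likelihood
  of the true batch under an adversarial classifier on $c$ (minimizing it
  removes batch information from the biological state), plus the KL of the
  $u$ marginal to its prior, minus the batch-decoder log-likelihood on $u$
  (keeping batch information in the technical noise).

The classifiers themselves are trained adversarially: each iteration first
takes $K = 3$ optimizer steps on the classifier cross-entropy with
*detached* latent samples (encoders frozen), then one step on the total
objective with the classifiers frozen. All updates use AdamW.

## Numerical choices

* Encoder inputs: RNA/ADT counts are `log1p`-transformed; ATAC enters
  binary. Inputs are multiplied by the feature mask, so values in
  unmeasured positions can never influence anything (a tested invariant).
* Variance heads emit log-variance, exponentiated and clamped to
  $[10^{-4}, 10^4]$, which keeps the product of experts away from
  degenerate precisions.
* Poisson rates are *library-scaled* by default: the decoder emits a
  normalized rate multiplied by the cell's observed mean count per
  measured feature, so sequencing depth does not leak into $c$. Cells
  lacking a modality use the median library factor of cells that have it
  (`scaleRates = FALSE` gives absolute rates).
* One Monte-Carlo sample per expectation (standard stochastic variational
  practice); validation losses are computed without dropout but with
  sampling, under the run's seeded RNG.
* Early stopping: patience 10 epochs on total validation loss, min-delta 0,
  on a 95:5 batch-stratified split. Stratification is our choice; only the
  ratio is prescribed by the reference setting.
* Hidden layers are Linear -> LayerNorm -> Mish -> Dropout(0.2). The ATAC
  input and reconstruction layers are split into independent per-chromosome
  blocks when peak names parse as `chrom:start-end` (a configurable number
  of equal blocks otherwise).
* Ties in the batch-correction reference choice
  $b^* = \arg\min_b \lVert \bar u_b - \bar u \rVert_2$ break to the lowest
  batch ID; $\bar u$ weights batches equally, not cells.

The whole stack — dense layers, backpropagation, AdamW — is implemented in
base R matrix algebra and verified against finite-difference gradients in
the development process; the product-of-experts, likelihood and KL pieces
are unit-tested against closed forms and brute-force oracles.

## The synthetic-data generator

`simulateMosaic()` draws biological states from a Gaussian mixture over
cell types (centroid spacing `typeSeparation`, default 3, within-type SD
0.5), technical noise as a per-batch offset (`batchShiftScale`, default 1)
plus within-batch noise at 10% of that scale (so `u` is batch-dominated),
and maps $(c, u)$ through *fixed random linear decoders* — sigmoid link for
ATAC, softplus times a library scale for RNA (~1 count/feature, sparse) and
ADT (~20 counts/feature, dense). Counts are Bernoulli/Poisson. Mosaic
patterns and per-batch feature dropout are applied afterwards, so retained
blocks are bit-identical to the full design.

Linear ground truth is intentional: the model's decoders are deep nets,
but a linear map keeps the recovery target identifiable at desk scale, so
imputation can be scored against the true rates rather than against noisy
counts. What the generator does *not* emulate: chromatin co-accessibility
structure, doublets, ambient contamination, overdispersion beyond Poisson,
and nonlinear batch distortions. Passing tests therefore demonstrate that
the machinery recovers structure *generated under the model's assumptions*;
they do not certify performance on real atlases.

Default study conditions (used by the tests and the acceptance script):
3 batches x 500 cells, 4 equally frequent types, unions of 200 ATAC peaks,
120 genes and 40 ADTs.

## Desk-scale training configuration

The published configuration (latents 32 + 2, hidden 1024-128, lr $10^{-4}$,
up to 2000 epochs) is the package default (`runConfig()`), sized for
hundreds of thousands of cells. The bundled experiments run at desk scale —
1500 cells, 360 union features — where we use a proportionally smaller
model ($d_c = 16$, hidden 256-64) and a larger learning rate ($2 \times
10^{-3}$) for at most 200 epochs. These are the package's standard
experiment sizes, chosen so a full study (two trainings plus the metric
suite) completes in minutes on one core.

## Evaluation suite

Batch correction: graph iLISI, graph connectivity, kBET (neighbourhood 50,
10% of cells tested per type label, level 0.05). Biological conservation:
NMI and ARI against a Louvain clustering swept over resolutions 0.1–2.0
(keeping the NMI-maximizing one), isolated-label F1, graph cLISI. Modality
alignment: modality silhouette, FOSCTTM, label-transfer F1, and
cross-modal feature recovery (ATAC AUROC, RNA/ADT Pearson r, averaged over
all feeding combinations). Overall scores weight batch/bio 0.4/0.6 per
space, and batch/modality/bio 0.3/0.3/0.4 for the mosaic score.

Conventions worth knowing: LISI scores use uniform weights over the k
nearest neighbours and are rescaled as $(\mathrm{LISI} - 1)/(L - 1)$;
metric graphs default to $k = 15$; the feature-space graph standardizes
each modality and concatenates 32-component PCA projections — an explicit
simplification of weighted-nearest-neighbour fusion, which is out of scope;
FOSCTTM normalizes the closer-than-match count by $N$, so its worst case at
small $N$ is $(N-1)/N$ rather than 1; Pearson r of a constant prediction is
reported as 0 with a warning.

## Knowledge transfer

`modelTransfer()` reinitializes the batch-ID modules and classifiers for
the query's batch count (they are batch-count-specific) and fine-tunes the
modality encoders/decoders from the pretrained state. `reciprocalMap()`
additionally keeps the reference batches alive: the combined model retains
the pretrained batch-ID parameters for reference batches, appends fresh
ones for query batches, and fine-tuning minibatches draw a `replayFraction`
(default 0.5, uniform) of reference cells, so reference and query embed
into one aligned space. `transferLabels()` then moves labels by a 100-NN
uniform-weight classifier; in cross-tissue mode a planted "query" class and
a deterministic two-component 1-D Gaussian mixture (means initialized at
the probability extremes, tolerance $10^{-4}$) separate novel cells, which
are labeled `"unknown"`.

## Known limitations

* Poisson likelihoods only; no negative-binomial overdispersion.
* The WNN feature-space graph is approximated by concatenated per-modality
  PCA.
* CPU-only; runtimes scale linearly in cells x features, and the default
  2000-epoch configuration is not meant for interactive desk use.
* The novel-type detector assumes the query-probability histogram is
  bimodal; a query that overlaps the reference everywhere yields two
  near-identical mixture components and no `"unknown"` calls.
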