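---
title: "Spatial domain identification with spadom: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial domain identification with spadom: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sequencing-based spatial transcriptomics measures, at each capture spot of
a tissue section, a vector of gene counts together with the spot's planar
position. A central analysis task is to partition the section into
*spatial domains* — contiguous regions with a coherent expression program,
such as cortical layers or tumor compartments. Clustering expression
alone produces spatially fragmented calls; clustering positions alone
ignores biology. spadom learns a low-dimensional spot embedding that
fuses both, then calls and refines domains on that embedding.

## Model

### Spatial neighbor networks

Two graphs over spots drive the model:

* the **SNN**, connecting spots whose Euclidean distance is strictly below
  a radius `rad_cutoff`, or (for hexagonally packed arrays) the union-
  symmetrized 6 nearest neighbors; self-loops are always present, so every
  spot belongs to its own neighborhood;
* the **cell-type-aware SNN (ctaSNN)**, obtained by pruning from the SNN
  every edge whose endpoints fall into different *expression-only*
  preclusters (PCA to 30 components, 15-NN graph, Louvain at resolution
  1.0 — all configurable). Pruning stops the encoder from smoothing
  across boundaries between transcriptionally distinct neighbors.

### Weight-tied graph attention autoencoder

With normalized expressions $x_i$ as inputs ($h_i^{(0)} = x_i$), encoder
layer $k < L$ aggregates over the neighborhood $S_i$:

$$h_i^{(k)} = \sigma\Big(\sum_{j \in S_i} att_{ij}^{(k)} \, W_k h_j^{(k-1)}\Big),$$

while the final encoder layer is a plain linear map
$h_i^{(L)} = \sigma(W_L h_i^{(L-1)})$. The attention logit on edge
$(i,j)$ is $e_{ij} = \mathrm{Sigmoid}(v_s^\top W_k h_i + v_r^\top W_k h_j)$,
softmax-normalized over $S_i$, so each row of attention weights sums
to one. Attention is computed once on the SNN and once on the ctaSNN
(same parameters, different neighbor sets) and mixed convexly,

$$att_{ij} = (1-\alpha)\,att^{spatial}_{ij} + \alpha\,att^{aware}_{ij},$$

with the aware stream defined as 0 on pruned edges. The combination is
used as-is — both streams are already row-stochastic on their own edge
sets and the formula is stated after both softmaxes, so no
re-normalization is applied. The decoder mirrors the encoder with
$\hat W_k = W_k^\top$ and shared attention; weight tying halves the
parameter count and regularizes the reconstruction. Hidden activations
are ELU. The decoder's output layer is deliberately linear (identity
activation) so reconstructions can match arbitrary log-normalized
values — a saturating choice here would bias reconstructions.
Pretraining minimizes

$$\mathcal L_1 = \tfrac12\sum_i \|x_i - \hat h_i^{(0)}\|^2
  + \texttt{wd\_coeff}\cdot\tfrac12\sum_{k<L}\|W_k\|_F^2 .$$

### Multiscale deep subspace clustering

Under the union-of-subspaces assumption, each spot's embedding is a
linear combination of the other spots' embeddings. Every encoder layer
$k$ carries its own self-expression matrix $C_k$ (diagonal hard-masked to
zero at each forward pass), giving the multiscale loss

$$\mathcal L_{mss} = \frac{1}{2L}\sum_k \|Z_k - C_k Z_k\|_F^2, \qquad
  \mathcal L_{reg} = \frac{1}{L}\sum_k \|C_k\|_p .$$

The layer matrices are fused with trainable positive weights
($\tau_k = \mathrm{softplus}(\cdot)$, initialized at 1):
$C_F = \sum_k \tau_k C_k / \sum_k \tau_k$, and the affinity
$\Lambda = \tfrac12(|C_F| + |C_F^\top|)$ feeds normalized spectral
clustering (symmetric normalized Laplacian, $m$ bottom eigenvectors,
row-normalization, k-means with 10 restarts). The norm $p$ of
$\mathcal L_{reg}$ is a free choice of the formulation; we default to
the Frobenius norm because it is smooth and standard in deep subspace
clustering, with an L1 option for sparsity ablations.

### Self-supervised refinement and the total objective

A classifier head (three hidden fully connected ReLU layers,
$d_L \times 128 \times 64 \times 32 \times m$, softmax output) is trained
against the current spectral labels with the standard cross-entropy
$\mathcal L_{sup} = -\tfrac1n \sum_i \log P(i, y_i)$ (a swapped
prediction/target orientation would be degenerate for one-hot targets).
Probabilities are clipped to $[10^{-12}, 1]$ so the loss is always
finite, and the $1/n$ mean keeps its scale independent of the spot
count (a plain sum is available). The total joint objective is

$$\mathcal L_{total} = \mathcal L_1 + \mathcal L_{reg}
  + \lambda\,\mathcal L_{mss} + \mathcal L_{sup},$$

where $\lambda$ is the `cost_ssc` knob (default 0.1; the breast-cancer-
style presets use 1). Gradients of $\mathcal L_{sup}$ flow into both the
head and the encoder by default (a freeze flag disables the latter).

### Training schedule

The package fixes the following training schedule: 500 epochs of
$\mathcal L_1$-only pretraining with the
decoder fed $Z_L$ directly, then 300 joint epochs with the decoder fed
$C_F Z_L$ and the spectral labels refreshed every 50 epochs. Adam with
learning rate $10^{-4}$ drives the autoencoder; the subspace matrices
and head use a $10\times$ larger rate because they start near zero and
otherwise lag the encoder. All gradients are derived analytically and
verified against central finite differences in the test suite
(agreement to $\sim 10^{-9}$ on every parameter group). Self-expression
matrices are dense $n \times n$ objects, so the joint phase is
$O(L n^2)$ in memory and refuses inputs beyond $n = 20\,000$.

### Final domain calling

The embedding $Z_L$ — not the raw counts — is what gets clustered.
Louvain or Leiden run on a 15-NN graph of embedding rows, with a
bisection search over resolution in $[0.05, 5]$ (at most 60 runs) when a
target domain count is requested; the search exploits that the achieved
community count is non-decreasing in resolution and falls back to the
closest count with a warning. The `mclust`/`gmm` route fits a finite
Gaussian mixture via the mclust package, which suits single-cell-
resolution data with fewer samples. Spectral labels from the subspace
module are available as `Y_clu`, but graph/mixture clustering of the
refined embedding is the recommended final call — the subspace stage's
job is to shape the embedding, and spectral clustering is the most
sensitive of the four routes to affinity noise.

An optional refinement pass reassigns every spot to the modal label
within radius `r_refine` (default 50 coordinate units, appropriate for
full-resolution array pixel coordinates; 1.5 in unit-lattice
simulations). The vote is computed simultaneously from the frozen input
labels rather than sequentially — the simultaneous pass is
order-independent, hence deterministic. Ties
keep the spot's own label when it is among the modes, otherwise the
lowest label id wins, and the pass can never invent a label absent from
its input.

## Preprocessing

Spots outside the tissue are removed by mask, zero-count spots are
dropped with a message, counts are scaled to a common library size
(default $10^4$) and log1p-transformed, and the `n_top` most dispersed
genes (variance/mean of the normalized matrix, default 3000, ties broken
by gene id) are kept. Both the HVG count and the dispersion criterion
are package conventions, exposed as configuration.

## What the synthetic generators emulate — and what they do not

`generate_layered_tissue()` emulates a layered section: a square or hex
lattice (unit neighbor spacing, so radii are in lattice units) split
into `k_domains` horizontal bands or Voronoi cells, with Poisson counts
at `baseline_mean` everywhere and `baseline_mean + marker_effect` for
each domain's marker genes inside that domain. The defaults — a
$30\times30$ lattice, 4 bands, 60 genes, 10 markers per domain, marker
effect $5\times$ baseline — give a recovery problem that is clearly
solvable but not trivial: a plain Gaussian mixture on 10 principal
components reaches ARI $\ge 0.8$, leaving headroom the spatial model
must close. `generate_subspace_points()` draws points from a union of
low-dimensional linear subspaces (optionally exactly orthogonal),
exercising the self-expression premise in isolation.

Real tissue data differ in ways these generators do not model: dropout
and overdispersion beyond Poisson, library-size gradients, curved and
interdigitated domain boundaries, batch effects, and segmentation noise.
Passing the synthetic suite therefore demonstrates correctness of the
machinery and recoverability under the stated noise model, not
performance parity on any particular real dataset.

## Numerical choices and degenerate inputs

* Attention logits pass through a sigmoid, so softmax inputs are bounded
  in $(0,1)$ and cannot overflow; a node without a self-loop (empty
  softmax) is rejected.
* ELU is used exactly; its derivative is taken as $e^x$ for $x \le 0$.
* Spectral clustering zero-degree rows get $D^{-1/2} = 0$; k-means uses
  `nstart = 10` under a fixed seed, so label output is deterministic.
* The diagonal of every $C_k$ is projected to zero after each update
  (projection, not penalty), keeping the constraint exact throughout.
* Training aborts with a diagnostic on a non-finite loss instead of
  silently producing NaN artifacts.
* Welch t-tests report $t = 0$, $p = 1$ for genes with zero variance in
  both groups; Benjamini-Hochberg adjustment is applied per domain.
* Distance ties in k-NN construction are broken by lower spot index; the
  radius rule is strict (`<`), matching the stated definition.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on generated data: the
end-to-end benchmark uses the default $30\times30$ lattice (900 spots)
with the full 500 + 300 epoch schedule; the loss-ablation ensemble uses
20 replicates of a $10\times10$ lattice with a 200 + 200 schedule and
narrower layers (64, 16), a scale at which the comparison is stable
while an ensemble remains cheap to rerun; subspace recovery uses 40
points in 6 dimensions. These sizes are the package's own validation
choices and are deliberately far below the multi-thousand-spot datasets
the method targets, which require no new mechanics, only longer runs.

## Known limitations

* Whole-graph training only — no mini-batching; with the dense
  self-expression matrices this caps practical problem size at a few
  thousand spots on one CPU and $n = 20\,000$ by contract.
* The joint phase can trail pure pretraining when the schedule is very
  short; the defaults balance the two phases.
* Histology images, multi-sample integration, trajectory inference and
  UMAP visualization are out of scope; embeddings and labels export as
  CSV for downstream tools.
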