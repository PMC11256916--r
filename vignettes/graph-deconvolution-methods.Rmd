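---
title: "Graph deconvolution of cell-type-specific single-cell Hi-C: models and methods"
author: "scgraphdec authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph deconvolution of cell-type-specific single-cell Hi-C: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-cell Hi-C (scHi-C) resolves cell-type-specific 3D genome
organization, but the assay is costly and its per-cell contact maps are
extremely sparse. Pseudo-bulk scRNA-seq, by contrast, is abundant. This
package implements a graph-deconvolution model that predicts a pseudo-bulk
scHi-C contact map for a cell type from (i) a deeply sequenced *bulk* Hi-C
contact map — which carries the population-averaged structure that the
cell type's map is one component of — and (ii) five 1-D guide tracks binned
at 50 kb: stranded pseudo-bulk expression (scRNA+, scRNA−), stranded CTCF
motif scores, and a CpG score. Expression supplies the cell-type-specific
signal; CTCF and CpG supply cell-type-agnostic structural anchors
(TAD boundaries); the bulk map supplies the structure to deconvolve.

## Preprocessing stack

Applied per chromosome, in this order:

1. **Library-size normalization.** `T' = log(T / sum(T) * alpha + eps)`
   (natural log), with `alpha = 25000` and pseudocount `eps = 1e-8` inside
   the log. Inputs that are positive multiples of each other map to the
   same output (up to the pseudocount), so pseudo-bulks with different cell
   counts become comparable. Empty bins land at `log(eps)`, finite by
   construction. The output is *not* non-negative; the final min-max pass
   restores the [0, 1] contract.
2. **Eigenvalue soft-threshold denoising** (scHi-C targets only — bulk maps
   are deeply covered and skip it). The symmetric matrix is
   eigendecomposed, each eigenvalue shrunk by
   `sign(l) * max(|l| - t, 0)` with `t = 0.5`, and reconstructed as
   `P %*% diag(l') %*% t(P)` (the transpose is the inverse for an
   orthonormal eigenbasis); the result is explicitly re-symmetrized to kill
   round-off asymmetry. Small-magnitude eigenvalues carry high-frequency
   sampling noise; shrinkage never increases the Frobenius norm.
3. **Min-max scaling** to [0, 1], per chromosome (the per-chromosome choice
   is a dialect: applying it genome-wide is a flag away, but per-chromosome
   matches the per-chromosome training geometry). A constant input maps to
   all zeros.

Expression tracks are library-size normalized and min-max scaled; CTCF and
CpG are motif/score tracks, not read counts, so they are only min-max
scaled.

Chromosomes are tiled into 128-bin (6.4 Mbp) diagonal windows: stride 32
for training tiles, stride 16 for prediction, and windows that would
overrun the chromosome end are dropped rather than padded. Chromosomes 7
and 11 — the most gene-dense mouse autosomes — form the default held-out
test set; X, Y and MT are excluded outright.

## The model

Four stages, mirroring the published architecture:

1. **Positional encodings.** Each 128-bin bulk tile is read as a weighted
   graph (edges = off-diagonal contact values; self-loops excluded — the
   diagonal is structurally uninformative). We form the symmetric
   normalized Laplacian `I - D^{-1/2} H D^{-1/2}` with weighted degrees,
   rows of zero degree reducing to identity rows, and take the `k = 16`
   eigenvectors of *smallest* eigenvalue as per-bin coordinates. "Top k" is
   ambiguous in the source description; the low-frequency choice is the
   standard graph-positional-encoding convention and captures
   compartment/TAD-scale topology (a flag selects the largest-eigenvalue
   alternative). Each eigenvector's sign is fixed so its largest-magnitude
   entry is positive (ties to the lowest index), making encodings
   platform-reproducible. Encodings are computed per tile, after min-max
   normalization of the bulk map, so they describe exactly the graph the
   attention sees.
2. **Node feature processor.** The 5 guide channels and 16 encodings form a
   128 x 21 feature block. A window-16 1-D convolution along the bin axis
   (same-length zero padding, centered window) extracts a localized feature
   set, and two pre-LN transformer encoder blocks (4 heads, width
   `d_model = 64`, feed-forward width `2 d`, residual connections, layer
   normalization applied before each sublayer so the residual stream stays
   unnormalized) mix features across all bins. The convolution produces
   `conv_filters = d_model` channels by default. The literal
   single-filter-plus-linear-lift variant remains available
   (`conv_filters = 1`) but is kept only as an ablation: squeezing every
   bin through one scalar makes the representation rank-1, row-wise
   layer normalization then collapses all node latents onto
   `±` one vector, the decoder's Gram matrix degenerates to a near-constant,
   and training stalls at the constant-predictor loss. We verified this
   collapse directly (node-latent standard deviation across bins falls to
   ~1e-4 and the Gram matrix's to ~3e-6 during training).
3. **Graph encoder.** A graph attention (GAT) layer computes, for every
   bulk-graph edge, an additive logit
   `a . LeakyReLU(W1 z_i + W2 z_j + w3 e_ij)` (slope 0.2; the scalar edge
   weight `e_ij` is lifted by the learned vector `w3`), softmax-normalized
   over each node's neighborhood. Self-loops are excluded from the softmax;
   the source node instead contributes a fixed-coefficient `W1 z_i`
   self-term — the only reading consistent with both the aggregation rule
   and the self-loop exclusion. The attention coefficients are the
   deconvolution: edges unsupported by the cell-type-specific guide signal
   are attenuated. Isolated nodes reduce to their self-term. A *mapping*
   stage of two further transformer encoder blocks then produces the node
   latent space `Z` (depth 0 yields the identity).
4. **Graph decoder.** A learned linear projection (plus a skip connection
   from the raw node features) first takes `Z` off the manifold the
   encoder's layer normalizations favour. Both additions are cures for a
   diagnosed optimization pathology: the inner-product (Gram) decoder has
   a saddle at collapsed, rank-one latents — the optimizer reaches it
   within ~50 steps while fitting the constant predictor, gradients
   through the encoder then all but vanish, and training stalls at the
   target-variance loss. The projection lets Gram diagonals vary per bin;
   the feature skip keeps a live gradient path through the collapse
   (the features are fixed and varied, so their contribution to the Gram
   cannot collapse). The inner product `Z' Z'^T / d` (the `1/d` scaling
   keeps the likelihood map in the responsive range of the final sigmoid)
   is then refined together with a second input channel — the bulk tile's
   edges rescaled by the symmetrized GAT attention coefficients
   (`n * sym(alpha) * E`), i.e. the literal deconvolved prior: at uniform
   attention it reduces to the bulk tile itself and learned attention
   modulates it per cell type. Two residual 2-D convolutional blocks
   (3 x 3 kernels, 4 channels, initialized at 0.3 x Glorot scale so the
   sigmoid starts unsaturated) refine the pair, a sigmoid maps to (0, 1),
   and the result is symmetrized by averaging with its transpose.

Width, depth, head count, dropout and optimizer settings are this
package's own defaults (the published account defers them to supplementary
material): `d_model = 64`, 2 + 2 transformer blocks, 4 heads, 1 GAT layer,
2 residual blocks with 4 channels, dropout 0.1 (training only), Adam at
learning rate 1e-3 with global gradient-norm clipping at 1 (without
clipping, higher learning rates occasionally saturate the decoder sigmoid
into a stuck constant-output state). All are exposed in `model_config()` /
`train_config()`.

## Training and prediction

Training minimizes the MSE between predicted and target tiles (targets in
[0, 1] after the preprocessing stack) with Adam; the reference regime is
300 epochs, the desk-scale default 50. All randomness (initialization,
shuffling, dropout) is seed-controlled and loss histories reproduce
exactly; backward passes are hand-derived and verified against numerical
differentiation in the test suite. Prediction tiles a chromosome at stride
16 and averages all predictions covering each bin pair; a constant
prediction is preserved exactly by this overlap averaging, and chromosome
tails unreachable by a full window remain 0 and are counted in an
attribute.

## Evaluation metrics

* **GenomeDISCO-style concordance**: row-normalize each map to a random-walk
  transition matrix (zero rows stay zero), compare `t`-step powers
  (`t = 3` by default) by L1 distance divided by the number of rows nonzero
  in either map, and return `1 - mean_t(d_t)/2`, floored at −1. Identical
  maps score exactly 1.
* **Stratum-adjusted correlation (SCC)**: per diagonal offset up to
  `min(n - 1, 64)` (3.2 Mbp at 50 kb — half the model window), Pearson
  correlation weighted by `N_s * sqrt(var(rank x) var(rank y))`; degenerate
  strata are skipped; optional mean-filter smoothing is off by default at
  this coarse resolution. Invariant under shared affine rescaling.
* **TAD boundary F1**: boundaries are insulation-score minima — the mean
  contact in a `window x window` square straddling the diagonal (default
  500 kb), minima kept when their topographic prominence exceeds 0.1
  profile standard deviations (relative prominence makes calls invariant
  to uniform map rescaling). Predicted and target boundary sets are matched
  greedily nearest-first, one-to-one, within ±1 bin, and
  `F1 = 2TP / (2TP + FP + FN)`. An in-package insulation caller stands in
  for an external pattern-matching TAD caller, keeping the package
  self-contained.

## The synthetic co-assay generator

The generator makes the whole pipeline runnable and testable with no
downloads. One simulated chromosome is defined by: a distance-decay
backbone `p(i,j) ∝ (1 + |i-j|)^(-gamma)` (`gamma = 1`) and a segmentation
of the chromosome into domains of 12–40 bins. Three segments are strong
shared TADs (intensity 3, within the 2–5x enrichment typical of real
TADs). Two segments per cell type are *cell-type-specific sub-TAD splits*:
in the active cell type the segment becomes two strong sub-TADs separated
by an internal midpoint boundary; in every other cell type it remains a
weak background domain. The remaining segments are weak shared background
domains (intensity `1 + (3-1)/4 = 1.5`) in all cell types.

Two properties of this layout are load-bearing. First, weak background
domains: without them, inter-TAD gaps are structureless, the insulation
profile drifts flat through them, and boundary calls land anywhere in the
gap — with them the profile dips exactly at domain junctions, which is
both more realistic (chromosomes are largely tiled by domains) and
required for the generator's deconvolvability contract (every
sufficiently weighted cell-type-specific boundary is detectable in the
bulk map). Second, the sub-TAD construction: the *outer* edges of every
domain sit on the shared segmentation and are therefore present in both
cell types, but the internal midpoint boundary exists only where the
domain is active. The bulk mixture consequently carries the union of both
cell types' sub-TAD boundaries — so a bulk-only baseline necessarily
reports the other cell type's boundaries as false positives, and
deconvolution has something genuine to disentangle. Without this
construction, all boundary *positions* would be common to every cell type
(only intensities would differ) and no prediction could beat the bulk map
at boundary recovery even in principle.

The bulk map draws `5e5` reads multinomially from the mixture
`sum_c w_c p_c` (default weights 0.6/0.4) over unordered bin pairs, each
off-diagonal count mirrored into both cells, so total depth is exact and
counts symmetric. Targets draw `5e4` reads from a single cell type's map —
an order of magnitude sparser, as in real pseudo-bulk scHi-C. Expression
is elevated (amplitude 4, split across the two strand channels) inside the
TADs *active* in that cell type, mixed with `1 - expr_coupling = 0.2`
structure-independent background, and Poisson-sampled at a depth scaling
with `1/noise_sd`; CTCF peaks sit on the cell-type-agnostic domain edges
(the intersection of all cell types' boundary sets — sub-TAD midpoints are
deliberately unmarked) with additive noise, and CpG is a noisy copy of
CTCF (correlation ≥ 0.7 by construction, mirroring their genomic
overlap). Every artifact derives its
own seed from the master seed via `seed + 1000003 * k mod (2^31 - 1)`, so
datasets are bitwise reproducible.

What the generator does *not* emulate: per-cell UMI dropout, batch
effects, compartment-scale (A/B) plaid structure, loop anchors, and
trans-chromosomal contacts. Passing tests therefore demonstrate that the
pipeline recovers block-structured, expression-coupled cell-type
differences from a mixture — not that it reproduces any real dataset's
accuracy.

## Numerical choices and degenerate inputs

* Duplicate unordered pairs in sparse input are an error, never summed —
  silent summing hides upstream double-counting.
* `eigen_denoise` re-symmetrizes its reconstruction; `t = 0` is the
  identity within 1e-8.
* Min-max of a constant array is all zeros (documented degenerate case).
* Zero-degree Laplacian rows become identity rows; edgeless tiles still
  produce finite encodings and a usable (self-term-only) GAT pass.
* Attention softmaxes subtract the row maximum before exponentiation.
* The insulation caller returns no boundaries on constant maps.
* Checkpoints are versioned JSON; loading refuses mismatched feature
  geometry.

## Problem sizes used by the test suite

The architecture-wiring check overfits one clean 128-bin tile — the target
is the *noise-free* preprocessed ground-truth probability map, not a
sparse read sample. This is deliberate: a 5e4-read sampled tile is
effectively full-rank (sampling noise), and its best achievable fit by
*any* rank-32 inner-product decoder is ~0.045 MSE (computable by truncated
eigendecomposition in logit space), so memorizing it to 1e-3 is
mathematically impossible and would test the noise, not the wiring. The
end-to-end deconvolution check trains on six 256-bin synthetic chromosomes
(two cell types, stride-32 tiles, 50 epochs, learning rate 3e-3) and
evaluates on a seventh, held-out chromosome — small enough to train on one
CPU in minutes, large enough that TADs are detectable and the two cell
types' targets are distinguishable. The training-chromosome count and
learning rate were selected by aggregate cell-type-specificity across
three validation chromosomes.

## What the end-to-end benchmark can and cannot show

The deconvolution benchmark trains on six synthetic chromosomes and
evaluates a held-out one. Cell-type specificity — each prediction agreeing
better (by SCC) with its own cell type's target than with the other's —
is a property of the trained model and passes across validation
chromosomes. Boundary recovery relative to the bulk baseline, however, is
bounded by the benchmark's own noise: at a 5e4-read target depth the
insulation caller reports three noise minima for every true edge, and an
oracle control (scoring the exact noise-free cell-type ground truth
against the same targets) *ties* with the bulk baseline (mean F1 0.38 vs
0.40 over six chromosome/cell-type pairs). Because the bulk mixture
differs from each cell type's truth by only the two cell-type-specific
sub-TAD boundaries, no predictor — including a perfect one — can beat the
bulk's boundary F1 by more than target-noise jitter under these
conditions. The package reports both comparisons; the second should be
read as a noise-floor measurement, not a model ranking.

## Known limitations

* The GAT treats each 128-bin tile independently; no information flows
  across tile boundaries except through overlap averaging at prediction.
* The decoder's Gram map is positive semi-definite before refinement; the
  convolutional stage compensates only locally. Very-long-range indefinite
  structure is therefore approximated, not represented exactly.
* Real `.cool` files (HDF5) are not read; the cooler-style container is a
  text mirror of the cooler schema (bins/pixels tables).
* Training is plain single-threaded SGD/Adam; there is no mini-batch
  parallelism, scheduler, or early stopping by default (a fixed epoch
  count mirrors the reference regime; early stopping is available via
  configuration).
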