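---
title: "Quantifying spatial expression patterns and segmenting spatial domains"
author: "SpotPattern authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial expression patterns and segmenting spatial domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpotPattern)
library(SummarizedExperiment)
```

# Scope

Spot-level spatial transcriptomics yields a UMI count matrix $X \in
\mathbb{N}^{N \times D}$ over $N$ spatially barcoded capture locations
(spots) with 2-D coordinates. Two questions dominate downstream analysis:
*which genes vary spatially* (spatially variable genes, SVGs), and *which
contiguous tissue regions share an expression program* (spatial domains).
SpotPattern addresses both with a single, image-based view of the data:
every gene is rendered as a grayscale image on a regular grid, scored by a
quantitative pattern index, tested against complete spatial randomness
(CSR), and the top-scoring genes feed a graph-attention embedding that is
clustered by self-supervised deep embedded clustering.

# The pattern index

## From spots to gene images

On array platforms (10x Visium) spots map one-to-one onto grid cells via
their integer array row/column indices, so no resampling is involved; the
half-empty checkerboard cells of the hexagonal layout are simply marked
invalid. On non-array platforms the spot values are interpolated linearly
(Delaunay triangulation + barycentric weights) onto a regular grid whose
resolution targets about one node per spot — dense enough to lose no
information, coarse enough to invent none. Grid nodes outside the convex
hull of the spots are invalid, which avoids extrapolation artifacts. The
triangulation uses a deterministic $\sim 10^{-9}$ jitter solely to break
the exact cocircularity of lattice-like inputs; barycentric weights are
computed from the unperturbed coordinates. Interpolated values therefore
always lie within the range of the observed spot values, and a constant
gene stays exactly constant.

## Pre-processing

Each gene image is min–max normalized to $[0, 1]$ and smoothed with a
masked, renormalized Gaussian kernel (`sigma = 1` grid unit, truncated at
$4\sigma$). Masked renormalization means invalid pixels neither receive
nor contribute weight, so tissue borders are not darkened and constants
are preserved exactly. The kernel width is a package default: one grid
unit is the natural scale once the grid is matched to the spot spacing,
and the choice is recorded in every run manifest.

## Segmentation

Foreground and background are separated by the isodata iterative-mean
threshold: starting at the global mean, $T \leftarrow
(\overline{v_{>T}} + \overline{v_{\le T}})/2$ until $|\Delta T| <
10^{-6}$. A morphological closing (dilation then erosion, square
structuring element) fills pin-holes inside the foreground; the element
side defaults to 5 for Visium/Slide-seq, 6 for Stereo-seq and 8 for
SeqFISH, tracking platform resolution. Closing uses the infinite-plane
border convention (the array is padded before the dilation), which keeps
the operation extensive and exactly idempotent on full masks, and
supports the even element sizes. Foreground pixels are then grouped into
8-connected regions $F_1, \dots, F_L$ (pixels touching vertically,
horizontally *or diagonally* are connected); the remaining valid pixels
form the background $B$. Genes whose foreground covers no more than
`delRate` (default 1%) of the valid pixels are dropped as too sparse to
score, as are genes constant after normalization and genes without any
background. Dropping happens *before* the cross-gene normalization below,
so a dropped gene can never shift another gene's score.

## The two factors

With $\mu_l, \sigma_l^2$ the mean and *population* variance of region
$F_l$ (size $N_l$), $\mu_B$ the background mean, and $\sigma^2$ the
population variance over all $N'$ valid pixels:

$$\mathrm{Significance} \;=\;
\frac{\frac{1}{L}\sum_{l=1}^{L} (\mu_l - \mu_B)}
     {\sum_{l=1}^{L} \sigma_l / \mu_l}, \qquad
\mathrm{Separability} \;=\; 1 -
\frac{\sum_{l=1}^{L} N_l \sigma_l^2}{N' \sigma^2}.$$

Significance is a foreground-contrast-to-dispersion ratio: it is large
when foreground regions sit well above the background and are internally
homogeneous. Separability is the classic stratified-heterogeneity
statistic — the fraction of total image variance *not* explained within
the foreground regions — and always lies in $[0, 1]$. An $\varepsilon =
10^{-12}$ guards the Significance denominator: perfectly homogeneous
regions ($\sigma_l = 0$) are reachable on synthetic data and would
otherwise divide by zero.

The per-gene index is the product of the two factors after a
normalization $\psi$ *across the gene dimension*:

$$\mathrm{PI}_g = \psi(\mathrm{Significance})_g \times
\psi(\mathrm{Separability})_g.$$

$\psi$ is min–max normalization over the scored genes by default; because
that choice is a convention rather than a law, the raw factors are always
emitted alongside the normalized ones and `psi = "identity"` disables the
rescaling entirely. Ranking is dense on descending index.

# Hypothesis testing

The index is interpreted against the CSR null: the observed values could
have been placed on the locations at random. Testing uses Moran's $I$
(and, for evaluation, Geary's $C$) on the same data that produced the
index. Because no canonical spatial weight matrix exists for this
pipeline, the default is queen contiguity on the valid pixels of the gene
grid — the weights that match the image representation — with kNN weights
on the raw spot coordinates as the alternative (`rule = "knn"`); weights
are binary by default with optional row-standardization. This choice is
the single largest degree of freedom in any Moran-based test and is
therefore surfaced as an explicit, logged option.

The parametric test uses $z = (I - E(I))/\sqrt{V(I)}$ with $E(I) =
-1/(N-1)$ and the standard closed-form variance under either the
randomization assumption (distribution-free; involves the sample
kurtosis; the default) or the normality assumption, and the one-tailed
$p = 1 - \Phi(|z|)$. Note the fold: under the null this $p$ is uniform on
$[0, 0.5]$, so its nominal level is double the usual reading — the
permutation test is the calibrated reference. That test permutes the
values over the locations $D$ times (default 999) and reports the pseudo
p-value $(R+1)/(D+1)$, $R$ counting permutations with $I$ at or above the
observed value (upper tail: clustering). All permutations are evaluated
in one vectorized batch: the centered sum of squares is
permutation-invariant, so each permutation costs one sparse
matrix-vector product. Benjamini–Hochberg FDR control is applied
separately to the parametric and permutation p-value families, and a gene
is called an SVG when **both** FDRs fall below $\alpha$ (default 0.05)
*and* its index is strictly positive.

# The embedding network

Pre-processing removes genes detected in fewer than 10 spots, divides
each spot by its total UMI (pre-log spot sums are exactly 1), applies
$\log(1+x)$, and keeps the 3000 top-index genes (all scored genes when
fewer exist). The spot graph is a *directed* kNN graph on Euclidean
distance — `k = 6` for Visium (hexagonal first ring), 20 for
cellular-resolution platforms — with the self-looped adjacency
$\hat{A} = I + A$ (renormalization trick), so every row degree is exactly
$k + 1$ and no vertex is isolated.

The top 50 principal components $X'$ (deterministic sign convention:
the largest-magnitude loading of each component is positive) are low-pass
filtered over the graph:

$$\tilde{X} = H^t X', \qquad
H = I - \gamma\, \hat{D}^{-1/2} (\hat{D} - \hat{A})\, \hat{D}^{-1/2},$$

with $\gamma = 2/3$ and $t = 2$. On a two-node toy graph this gives
$H = \begin{psmallmatrix} 2/3 & 1/3 \\ 1/3 & 2/3 \end{psmallmatrix}$ and
$H^2 [1, 0]^\top = [5/9, 4/9]^\top$ — a frozen oracle in the test suite.

A single-head 50→50 graph attention layer scores each edge
$e_{ij} = \mathrm{LeakyReLU}(w^\top [W h_i \,\|\, W h_j])$ (negative
slope 0.2, the layer's conventional value), softmax-normalizes over each
vertex's $k$ first-order neighbours, aggregates, and applies an elu
output activation. The aggregand is configurable and the choice matters:
`aggregate = "self"` (the default) sums $\vartheta_{ij} W h_i$, in which
the neighbours enter only through the attention weights — and since those
row-sum to one, the layer reduces exactly to $\mathrm{elu}(W h_i)$ with a
zero gradient into $w$; `aggregate = "neighbors"` is the conventional
$\vartheta_{ij} W h_j$ form. Both are implemented and tested (the
backward pass of each is verified against finite differences); the mode
is logged in every manifest. Parameters initialize uniformly on
$\pm 1/\sqrt{\text{fan-in}}$ under a recorded seed.

# Self-supervised clustering

Cluster centers are initialized by model-based clustering (mclust) or
k-means for a known cluster count, or by Louvain/Leiden at a chosen
resolution on a kNN graph of the embedding. Soft assignments use the
Student's-$t$ kernel with $\nu = 0.5$,

$$q_{ik} \propto \bigl(1 + \|h_i' - \varphi_k\|^2/\nu\bigr)^{-(\nu+1)/2},$$

the auxiliary target sharpens them, $p_{ik} \propto q_{ik}^2 / \sum_i
q_{ik}$ (row-normalized), and the loss is $L = \mathrm{KL}(P \,\|\, Q)$.
The closed-form gradients $\partial L/\partial h_i'$ and $\partial
L/\partial \varphi_k$ (target held constant) drive Adam (learning rate
$10^{-3}$) jointly over $W$, $w$ and the centers; they are verified
against central finite differences at $10^{-5}$ relative tolerance. The
target is recomputed every 3 epochs from all spots; training stops when
the fraction of spots changing hard label between consecutive target
updates drops below `tol` ($10^{-3}$) or at `maxEpochs` (500). "Every
three iterations" is interpreted as three full-graph gradient epochs —
the whole computation is full-batch, so iteration and epoch coincide.
Labels are the row-wise argmax of $Q$.

Because the loss is *re-based* whenever the target is refreshed
(refreshing sets $P$ to a sharpened copy of the current $Q$, which
typically increases $\mathrm{KL}(P\|Q)$ step-wise while assignments are
still sharpening), monotonicity is a within-period property: between
consecutive target updates the optimizer should essentially never
increase the loss, and a converged run ends below where it started. The
tests assert exactly that, not cross-refresh monotonicity.

An optional post-processing pass reassigns each spot to the
strict-majority label among its $k$ nearest neighbours (majority must
exceed half the neighbourhood; ties keep the original label), applied
simultaneously per pass. Partition quality is scored by the adjusted Rand
index and by mutual information normalized by the arithmetic mean of the
entropies.

# The synthetic data generator

`simulateSpotData()` defines the study conditions under which the package
is validated: spots on a regular lattice partitioned into $K$ domains
(horizontal bands; concentric equal-count rings mimicking laminar
cortex-like tissue; or Voronoi regions), marker gene $g$ of domain $d$
drawn $\mathrm{NB}(\mu = \texttt{baseMean} \cdot \texttt{foldChange})$
inside $d$ and $\mathrm{NB}(\texttt{baseMean})$ outside, noise genes
$\mathrm{NB}(\texttt{baseMean})$ everywhere, with $\mathrm{var} = \mu +
\texttt{dispersion}\,\mu^2$ and optional independent dropout. The
negative binomial with gene-level dispersion is the standard
overdispersed model for UMI counts; `baseMean = 2`, `dispersion = 0.5`
are typical of moderately expressed genes on spot-level platforms, and
the benchmark fixture uses $K = 5$ bands, fold change 4, on a
$40 \times 40$ grid. What the generator does *not* emulate: segmentation
noise, spatially varying capture efficiency, spot-size mixing of cell
types, batch effects, and irregular tissue boundaries. Passing the
recovery tests therefore demonstrates correctness of the machinery under
a clean, known truth — not performance on real tissue.

```{r example}
sim <- simulateSpotData(c(20, 20), "bands", nDomains = 3,
                        nMarkersPerDomain = 5, nNoiseGenes = 20, seed = 1)
rec <- scoreGenePatterns(sim@table)
head(as.data.frame(rec[order(-replace(rec$pi, is.na(rec$pi), -1)),
                       c("gene_id", "pi", "significance_raw",
                         "separability_raw")]), 5)
```

# Numerical choices and degenerate inputs

* Constant images: min–max normalization maps them to zeros (0/0
  convention) and the gene is dropped with reason `"constant"` — no
  threshold exists for a flat image.
* Thresholding iterates at most 100 times; convergence is declared at
  $|\Delta T| < 10^{-6}$, and foreground is *strictly above* the
  threshold.
* Ties in kNN construction break by (distance, index) lexicographic
  order; duplicate coordinates warn.
* The permutation count bounds the attainable pseudo p-value at
  $1/(D+1)$; FDR-corrected calls at $\alpha = 0.05$ need $D \gtrsim 200$
  for moderate gene panels.
* The workflow problem sizes used throughout the test suite and the
  acceptance script — $40 \times 40$ spots, 150–502 genes, 199
  permutations, 5 training seeds — were chosen as the smallest sizes at
  which the binomial/Monte-Carlo error bands of the assertions are
  meaningful.

# Known limitations

* The grid resolution for non-array platforms (≈ one node per spot) is a
  design default; published analyses of very dense data sometimes bin
  more aggressively, which changes pixel counts and hence both factors.
* Whether published per-gene Significance/Separability values are pre- or
  post-$\psi$ is ambiguous in the literature this follows; the package
  reports both, and comparisons should say which is used.
* The parametric Moran test is approximate and its folded one-tailed
  p-value runs at twice the nominal level under the null; treat the
  permutation test as authoritative (it is the calibrated one in our
  tests).
* Geary's $C$ is computed for evaluation only and plays no part in SVG
  calling.
* Histology images, multi-sample integration, trajectory inference and
  UMAP visualization are out of scope; embeddings and labels export as
  plain CSV for downstream tools.
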