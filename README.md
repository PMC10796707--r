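# SpotPattern

Quantitative identification of spatially variable genes (SVGs) and
unsupervised spatial-domain segmentation for spot-level spatial
transcriptomics (10x Visium, Slide-seq, Stereo-seq, SeqFISH, or any count
matrix with 2-D coordinates).

## Who this is for

Analysts of spatial transcriptomics who want (a) a *quantitative,
rankable* score of how spatially structured each gene's expression is —
rather than only a p-value — and (b) spatial domains derived from those
genes, with spatial context built into the embedding instead of bolted on
afterwards.

## The method

**Gene scoring.** Each gene's expression is rendered as a grayscale image
on a regular grid (one-to-one from array indices on Visium; Delaunay
linear interpolation elsewhere), normalized, Gaussian-smoothed, and split
into foreground regions $F_1,\dots,F_L$ and background $B$ by isodata
thresholding, morphological closing, and 8-connected labeling. Two
factors are computed from the region statistics
($\mu_l, \sigma_l^2$ per region, $\mu_B$, total variance $\sigma^2$,
$N'$ valid pixels):

$$\mathrm{Significance} =
\frac{\tfrac1L\sum_l (\mu_l - \mu_B)}{\sum_l \sigma_l/\mu_l},
\qquad
\mathrm{Separability} = 1 - \frac{\sum_l N_l \sigma_l^2}{N' \sigma^2},$$

and the per-gene **pattern index** is the product of the two after
min–max normalization across genes. Significance rewards bright,
internally homogeneous foreground; Separability is a
stratified-heterogeneity measure in $[0,1]$.

**Testing.** Each gene is tested against complete spatial randomness with
Moran's $I$: a parametric $z$-test ($E(I) = -1/(N-1)$, closed-form
variance under the randomization or normality assumption, one-tailed
$p = 1-\Phi(|z|)$) and a vectorized permutation test with pseudo p-value
$(R+1)/(D+1)$. Both p-value families are BH-adjusted; an SVG must pass
**both** at FDR < 0.05 with a strictly positive index.

**Domains.** The top-index genes are total-count normalized and
log-transformed; the top 50 PCs are low-pass filtered over the directed
kNN spot graph by $\tilde X = H^t X'$ with
$H = I - \gamma \hat D^{-1/2}(\hat D - \hat A)\hat D^{-1/2}$
($\gamma = 2/3$, $t = 2$), embedded by a single graph-attention layer,
and clustered by deep embedded clustering: Student's-$t$ soft assignments
($\nu = 0.5$) sharpened toward a target distribution under a KL loss,
optimized by Adam with analytic gradients, with optional
majority-vote spatial smoothing of the labels.

A negative-binomial simulator with known domains and known markers
(`simulateSpotData()`) makes the entire pipeline testable offline.

## Worked example

```r
library(SpotPattern)

sim <- simulateSpotData(c(20, 20), "bands", nDomains = 3,
                        nMarkersPerDomain = 5, nNoiseGenes = 20, seed = 1)
rec  <- scoreGenePatterns(sim@table)                  # pattern index
tst  <- runAutocorrTests(sim@table, nPerms = 199, seed = 1)
svgs <- selectSVGs(rec, tst, alpha = 0.05)
head(as.data.frame(svgs[, c("gene_id", "pi", "moran_i", "fdr_perm",
                            "is_svg")]), 4)
```

```
        gene_id        pi   moran_i   fdr_perm is_svg
1 marker_d01_g04 1.0000000 0.3521054 0.01166667   TRUE
2 marker_d02_g04 0.9756953 0.3601558 0.01166667   TRUE
3 marker_d03_g02 0.8408571 0.3098461 0.01166667   TRUE
4 marker_d01_g03 0.8043562 0.2725043 0.01166667   TRUE
```

All 15 true markers are called (`sum(svgs$is_svg)` is 15) and every
noise gene is rejected: `pi` is the cross-gene-normalized pattern index
(the top gene defines 1), `moran_i` around 0.27–0.36 indicates clear
positive spatial autocorrelation on this fixture, and `fdr_perm` is at
the BH-adjusted floor attainable with 199 permutations.

```r
dom <- runDomainWorkflow(
  within(defaultRunConfig(), {
    clustering$init <- "kmeans"; clustering$n_clusters <- 3
    embedding$k <- 6; embedding$min_spots <- 5
  }),
  table = sim@table, trueLabels = sim@trueLabels)
dom$manifest$ari
#> [1] 1
```

The manifest records every parameter, the seed, epoch count, final loss
and — when truth is supplied — the achieved ARI/NMI.

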