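---
title: "Raman spectromics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raman spectromics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectromics)
```

## The problem

A confocal Raman microspectroscopy scan of a tissue section produces one
vibrational spectrum per pixel: a 250 x 250 µm field at 1 µm pitch is 62,500
spectra, each with several hundred wavenumber channels (cm^-1). Treating
pixels as "cells" and channels as "features" lets the single-cell toolbox —
dimensionality reduction, graph clustering, pseudotime, multimodal
integration — segment and interpret tissue without stains. This package
implements that workflow end to end, together with a synthetic scene
generator so every stage is testable without instrument data.

## Data model

`SpectralMap` holds the pixels x channels intensity matrix, a strictly
increasing wavenumber axis, the `(rows, cols)` grid with a physical pixel
size in µm, a per-pixel QC mask, and an append-only provenance list. Pixel
`(row, col)` (0-based) has physical centre
`((col + 0.5) * pixelSize, (row + 0.5) * pixelSize)`, y increasing
downward; all registration arithmetic uses pixel centres. `MSIMap` is the
analogous container for MALDI mass-spectrometry imaging (m/z axis, coarser
grid, typically 50 µm).

## Preprocessing

- **Outlier pixels.** Flagged when the per-pixel total intensity deviates
  from the median by more than `k` (default 5) times the MAD (scaled by
  1.4826). A robust one-parameter rule; flagged pixels keep their grid
  position so spatial plots stay intact.
- **Paraffin bands.** FFPE embedding wax leaves sharp bands at 1064, 1132,
  1294 and 1441 cm^-1; channels within ±10 cm^-1 of each centre are
  dropped. Removal acts on channels (columns), never pixels.
- **Despiking.** Cosmic rays are single-channel spikes: channels whose
  robust z-score within a 5-channel sliding window exceeds 8 are replaced
  by the window median.
- **Baseline.** Asymmetric least squares (Whittaker smoother with
  asymmetric weights; λ = 1e5, p = 0.01), the standard generic choice when
  the vendor baseline algorithm is unavailable.
- **Normalization.** Optional (default on): each retained pixel is scaled
  to the median total intensity, then `log1p`, mimicking count-workflow
  conventions. Whether and how spectra should be normalized before
  clustering is genuinely open; it is a config switch, and every operation
  accepts raw intensities too. Order is despike → baseline → normalize.

## Spatially-unaware clustering

Channel-standardized PCA (20 components by default — more rarely improves
clustering of Raman scans), with a permutation test for component
significance: each permutation independently shuffles a fraction (default
10%) of channels across pixels and recomputes the spectrum of singular
values; the per-dimension p-value is the fraction of permuted component
variances reaching the observed one, `(1 + #exceed)/(nPerm + 1)`. We use
the component variance as the test statistic (rather than a per-feature
loading enrichment score) because it is a single well-defined quantity per
dimension with the right null behaviour: near-uniform p on i.i.d. noise,
and the permutation floor on a planted rank-1 signal.

Clustering builds a kNN graph (k = 20) in PC space, weights edges by the
Jaccard similarity of neighbour sets (shared nearest neighbours), and runs
Louvain modularity at a resolution parameter (default 0.8). Singleton
communities are merged into their strongest-connected cluster. Labels are
re-coded by descending cluster size. Note the well-known behaviour of
modularity on geometric graphs: large uniform point clouds are split at
moderate resolutions, so recovering macro-structure (e.g. two well
separated blobs of hundreds of pixels) needs a low resolution (~0.05);
tissue-scale analyses typically explore several resolutions.

Differential Raman peaks use a one-vs-rest Wilcoxon rank-sum per channel,
`avg_log2fc = log2(mean_in + 1) − log2(mean_out + 1)` (the pseudo-intensity
1 tolerates empty channels), and Bonferroni adjustment across the whole
cluster x channel table (Benjamini–Hochberg optional). Wavenumbers are
reported rounded to one decimal. The true-component-analysis analogue is
plain NMF by multiplicative updates with a seeded random start.

## Spatially-aware clustering

The model in PC space is a Bayesian mixture with multivariate-t errors and
a Potts prior on the pixel lattice:

$$ y_i \mid z_i = k, w_i \sim N(\mu_k, \Sigma / w_i), \qquad
   w_i \sim \Gamma(\nu/2, \nu/2), $$
$$ p(z_i = k \mid z_{N(i)}) \propto \exp\{\gamma\,\#\{j \in N(i): z_j = k\}\}. $$

Gibbs updates are conjugate for the means (Gaussian prior centred on the
data mean, variance 100x the mean data variance) and the shared precision
(Wishart, df = d + 2, centred on the sample precision); the t-scale
weights are Gamma; labels use single-site draws from the exact full
conditional — the same conditional the test suite validates against
exhaustive enumeration on a 2 x 2 lattice. A shared covariance across
clusters keeps the model parsimonious at desk scale. Defaults: ν = 4
(heavy enough tails to absorb spectral outliers), γ = 2 on the
4-connected lattice (square 1 µm pixels), 2000 sweeps with 1000 burn-in.
Final labels are the per-pixel posterior mode over post-burn-in sweeps;
empty clusters are re-seeded from the worst-fitting pixel and logged.

The number of clusters is chosen at the elbow of the negative
pseudo-log-likelihood curve: per sweep we record the Besag pseudo-likelihood
(marginal multivariate-t data density plus the normalized Potts label
conditional at the current state), average it post-burn-in per candidate
`q`, and take the `q` maximizing the perpendicular distance to the chord
between the first and last curve points. A curve with no point below the
chord returns the smallest `q` with a "no clear elbow" flag.

## Trajectories and dynamics

Pseudotime uses a simplified reversed-graph-embedding principal tree: soft
(Gaussian-responsibility) assignment of pixels to latent nodes, node
updates, and a minimum spanning tree over nodes, iterated to convergence.
Pseudotime is the tree-geodesic distance of a pixel's node from the root;
branch points are nodes of degree ≥ 3. The automatic root is the leaf with
the largest summed geodesic distance, so either end of an unbranched path
may be chosen — pseudotime is defined up to orientation.

Spatial trajectories are width-1 Bresenham lines between pixel centres.
The per-wavenumber profile is `log2((I + 1) / (mean I + 1))` with the mean
over the trajectory, smoothed by loess. `loessFit` is an exact per-point
tricube-weighted local polynomial (degree 2), with the neighbourhood
`q = floor(span·n)`; when position gaps leave a window with fewer than
`degree + 1` interior points it widens locally. The pointwise 0.95 band
uses the equivalent-kernel norm with a global residual variance. The
profile default span covers ~12 positions (capped at 0.75): at 1 µm pitch
this preserves tissue-boundary transitions that a fixed 0.75 span would
flatten on long trajectories.

Two dynamics statistics per (cluster, wavenumber), restricted to that
cluster's trajectory positions: `max_variability`, the range of the loess
curve; and `dynamic_fraction`, the share of per-pixel-step loess
derivatives exceeding 0.4 in magnitude. The 0.4 threshold is adopted
verbatim in log2 units per pixel step (1 µm at the native pitch). It is a
demanding threshold: a smooth intensity ramp over tens of micrometres
never reaches 0.4/µm after smoothing — only µm-scale transitions (entering
a fibrotic focus, crossing a vessel) do, which is precisely what it is
meant to count. Cluster comparisons report both the paired t-test across
wavenumbers (primary) and the Welch two-sample variant: the source
workflow names both, which is contradictory for one comparison, so both
are computed and the paired one — matching the paired design of
per-wavenumber metrics — is reported first.

## Multimodal fusion

Registration between imaging frames is a similarity transform (rotation,
isotropic scale, translation) fitted to landmark pairs in closed form via
SVD; the RMS residual is reported as the diagnostic (how many landmarks to
use is left to the operator — the residual tells you when you have
enough). Each MSI pixel centre maps to the nearest Raman pixel centre
(equivalently, its containing Raman pixel); out-of-extent centres are
listed unmatched. Aggregating all Raman pixels under an MSI footprint is
available for the fusion step.

imzML reading supports continuous and processed mode; spectra are
RMS-normalized per pixel, and processed-mode centroids are binned at a 5
ppm tolerance (gap-based greedy merge, intensities summed per bin).

Weighted nearest-neighbour fusion: per pixel, each modality's profile is
predicted from the mean of its within-modality and cross-modality k
nearest neighbours; the modality score is the (cross − within) prediction
error gap scaled by the pixel's bandwidth (distance to the k-th
neighbour), clamped to ±4, and mapped through a softmax (temperature 1) to
weights summing to 1. The clamp stops the softmax saturating on the noise
of two equally informative modalities (an exact copy gives weights 0.5; a
pure-noise partner gives the informative modality > 0.9). The joint
similarity is the weight-blended pair of Gaussian kernels with per-pixel
bandwidth 2x the k-th-neighbour distance — the doubled bandwidth keeps
within-cluster similarities flat so a modality that cannot separate two
planted groups does not pollute the joint neighbourhood — and the joint
SNN graph is clustered by Louvain.

Volcano statistics over paired samples: per feature, log2 fold change of
group means (pseudo-value 1), a paired t-test across samples, and the
standardized mean difference as Cohen's d with pooled SD (the natural
reading of "standardized mean difference").

## Cell typing

Reference spectra per cell type are means of unit-L2-normalized labelled
pixel spectra, re-normalized. Matching uses Pearson correlation on the
fingerprint channels by default (scale-invariant, robust to overall
intensity differences); cosine similarity is the alternative. The default
assignment threshold is 0.7; neither metric nor threshold is prescribed by
the source workflow, so both are configuration. Evaluation is one-vs-rest
over labelled pixels only, since ground truth exists only where
immunolabels exist.

## The synthetic scene generator

Scenes are built from a peak library at literature band positions
(collagen 858/940/1249/1680; nucleic acids 784/1096/1376/1580; paraffin
1064/1132/1294/1441; hemin 1372; cytochrome c configurable — reported as
both 1314 and 1318 cm^-1 in different places, default 1314), Gaussian or
Lorentzian shapes, default width 8 cm^-1 SD. The default axis is the
fingerprint window 400–1800 cm^-1 at 2 cm^-1; an instrument-like preset
covers 300–3000 cm^-1 with 692 channels. Unit amplitudes are scaled by
100 to detector-count-like intensities (and clipped at zero), so the
pseudo-intensity of 1 used in log2 quantities is small relative to signal,
as it is for real counts. Artifacts: per-pixel cosmic-ray spikes, a glass
background of two broad humps (400–600 and 1000–1200 cm^-1), linear
baseline drift, paraffin-contaminated regions.

The gradient scene plants a static region and a "remodeling" region whose
signature amplitude ramps along the trajectory axis, modulated by patchy
foci (square wave, 5 px half-period, 60% contrast) with elevated jitter.
The patchiness is deliberate: it emulates crossing discrete fibrotic foci
and is what makes per-pixel log2 derivatives clear the 0.4 threshold — a
smooth tens-of-µm ramp cannot, under any smoother.

What passing tests on these scenes show — and what they do not: the scenes
have idealized peak shapes, independent channel noise, no instrument point
spread, no topography, and region geometry far cleaner than tissue.
Recovery results (ARI ≈ 1, perfect cell-typing sensitivity at low noise)
certify the algorithms' correctness and their ordering (spatially-aware
beats spatially-unaware clustering on spatially coherent signal), not the
absolute performance to expect on tissue, where reported cell-typing
sensitivity is far lower.

## Problem sizes and numerical choices

Simulations are desk-scale by choice: 40 x 40 lattices (1600 pixels, 5
embedding dimensions) for clustering recovery, 24 x 24 for model-size
selection with shortened chains (400 sweeps; the elbow stabilizes early),
20 x 60 gradient scenes, 300–500 pixels for fusion. Chains are fully
reproducible from a seed (R's RNG drives the C++ sampler). Degenerate
inputs have defined behaviour: zero-MAD outlier rules, zero-total pixels
in normalization (left unscaled, warned), constant spectra under Pearson
(unassigned), all-identical points in SNN clustering (one cluster), exact
similarity ties in matching (first reference, warned), flat elbow curves
(flagged).

## Known limitations

- The principal tree is a simplified reversed graph embedding, not full
  DDRTree; branch detection depends on the node budget.
- Modularity clustering fragments large uniform clusters at default
  resolution (see above); the MRF model assumes a shared covariance.
- imzML support covers the continuous and processed layouts the package
  writes; vendor idiosyncrasies are out of scope.
- Curved or multi-segment trajectories and hexagonal lattices are not
  supported.
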