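# spectromics

Single-cell-genomics-style analysis of spatially resolved Raman
microspectroscopy scans.

A confocal Raman scan of a tissue section yields one vibrational spectrum
per pixel — a 250 × 250 µm field at 1 µm pitch is 62,500 spectra of
several hundred wavenumber channels. Treating pixels as cells and channels
as features opens the single-cell toolbox to label-free tissue imaging.
This package implements that workflow for people analysing hyperspectral
Raman (and paired MALDI mass-spectrometry imaging) data:

- **Spectral QC** — MAD-based outlier pixels, paraffin band removal
  (1064/1132/1294/1441 cm⁻¹), windowed despiking, asymmetric-least-squares
  baseline, total-intensity normalization.
- **Spatially-unaware clustering** — standardized PCA with a permutation
  test for component significance, shared-nearest-neighbor Louvain
  communities, tSNE/UMAP embeddings, one-vs-rest Wilcoxon differential
  Raman peaks, NMF component maps.
- **Spatially-aware clustering** — a Bayesian mixture in PC space with
  multivariate-t errors and a Potts Markov-random-field prior on the pixel
  lattice,
  `p(z_i = k | z_N(i)) ∝ exp{γ·#(neighbors with label k)}`,
  fitted by Gibbs sampling; cluster count chosen at the elbow of the
  negative pseudo-log-likelihood curve.
- **Trajectories** — principal-tree pseudotime with branch detection;
  straight-line spatial trajectories with log2-normalized loess profiles
  and the two dynamics statistics (loess range; fraction of positions with
  |log2 derivative| > 0.4), compared between clusters by paired/Welch
  t-tests.
- **Multimodal fusion** — landmark similarity-transform registration
  (closed-form SVD fit), imzML input with RMS normalization and ppm
  binning, pixel-center correspondence across the 50 µm / 10 µm resolution
  gap, weighted nearest-neighbor integration, paired volcano statistics
  with standardized mean differences.
- **Cell typing** — reference spectra from immunofluorescence-labelled
  pixels, Pearson/cosine matching, sensitivity/specificity scoring.
- **Evaluation** — IoU (Jaccard) matrices with row/column-max averaging,
  adjusted Rand index, detection benchmarks.
- **Synthetic scenes** — a generator of hyperspectral sections with a peak
  library at literature band positions, planted regions/gradients,
  artifacts, paired MSI grids under known transforms, and cell masks, so
  the whole pipeline is testable without instrument data.

## Worked example

```r
library(spectromics)

spec <- sceneSpec(
  gridShape = c(30, 30), seed = 11,
  regions = list(
    list(shape = "rect", rows = c(0, 29), cols = c(15, 29),
         signature = "collagen"),
    list(shape = "ellipse", center = c(8, 8), radii = c(5, 5),
         signature = "nucleic_acids")))
sec <- generateSection(spec)

map <- normalizeSpectra(removeParaffinChannels(sec$map), "total")
map
#> SpectralMap: 900 pixels x 658 channels
#>   grid: 30 x 30 at 1 um/px
#>   wavenumbers: 400.0-1800.0 cm-1
#>   retained pixels: 900 / 900
#>   provenance: generateSection -> removeParaffinChannels -> normalize

emb <- pcaEmbed(map, nDims = 10)
cl  <- snnCluster(emb, kNeighbors = 15, resolution = 0.1, seed = 7)
cl
#> ClusterLabels: 900 pixels, 3 clusters (method: snn )
#>   0   1   2
#> 450 369  81
adjustedRand(cl, sec$truth$regionLabels)
#> [1] 1

fit <- fitMRFClusters(emb, retainedGridGraph(map),
                      mrfConfig(q = 3, gamma = 2, nu = 4, nDims = 10,
                                nIter = 600, burnIn = 300, seed = 7))
adjustedRand(fit$labels, sec$truth$regionLabels)
#> [1] 1

head(subset(differentialPeaks(map, fit$labels), cluster == 1), 4)
#>     cluster wavenumber avg_log2fc         p_raw    p_adjusted fraction_in fraction_out
#> 659       1       1316   2.067463 5.675188e-148 1.120282e-144           1    0.4858757
#> 660       1       1312   2.059020 7.771159e-148 1.534027e-144           1    0.4915254
#> 661       1       1314   2.028139 2.309989e-147 4.559917e-144           1    0.5122411
#> 662       1       1310   2.012482 5.675188e-148 1.120282e-144           1    0.4858757
```

The three planted regions are recovered exactly by both clusterings
(adjusted Rand index 1), and the top differential peaks of the myocardium
cluster sit on the cytochrome c band at 1314 cm⁻¹ — the band the scene
generator planted for that signature. The `paraffin` removal dropped 43 of
701 channels (four ±10 cm⁻¹ windows on a 2 cm⁻¹ axis).

A command-line front end wraps the same functions:

```sh
spectromics simulate --spec scene.yaml --out sim/
spectromics preprocess --in sim/scan.tsv --out scan.qc.tsv
spectromics cluster --in scan.qc.tsv --dims 20 --resolution 0.8 --seed 7
spectromics spatial-cluster --in scan.qc.tsv --q 5 --gamma 2 --iters 2000
spectromics trajectory --in scan.qc.tsv --start 10,10 --end 10,240
spectromics multimodal --raman scan.tsv --msi scan.imzML --landmarks lm.csv
spectromics evaluate --a labels_a.csv --b labels_b.csv
```

(The script installs to `system.file("exec/spectromics",
package = "spectromics")`.)

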