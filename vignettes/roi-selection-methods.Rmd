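---
title: "Selecting informative regions of chromatogram images with a GA-PLS search"
author: "chromROI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting informative regions of chromatogram images with a GA-PLS search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromROI)
```

## The problem

A comprehensive two-dimensional (GC×GC) chromatogram is routinely rendered
as a pseudo-color heat map: a 24-bit raster image whose axes are the two
retention times and whose colors encode signal intensity. For complex
samples — here, Tokaj wines whose volatile profile shifts with age — most
of that image is common matrix signal; the analytically useful variation
is confined to a few regions. chromROI searches for those regions
directly in image space: it partitions the image into a `roi2 × roi1`
grid of subimages, encodes any subset of subimages as a binary
chromosome, and lets a genetic algorithm (GA) minimize the leave-one-out
cross-validation (LOOCV) error of a PLS1 regression built on
color-frequency histograms of the selected subimages.

This is a *variable selection at the level of image regions*: the feature
extracted from a candidate subset is one pooled 256-bin histogram per
color channel over the union of the selected subimages, so every
chromosome yields a feature vector of identical length (`256 ×
n_channels`) and a single PLS architecture serves the whole search.

## Pipeline and model

1. **Grid partition.** An image of `J × K` pixels is split with
   boundaries `floor(i·J/roi2)` / `floor(i·K/roi1)`: near-equal blocks
   (±1 px), no dropped pixels, and boundaries that depend only on the
   image dimensions. The grid is unfolded row-major (row 1 at the image
   top), and this order is used everywhere a region label appears.
2. **Histogram features.** Channels are any subset of R, G, B, grayscale
   (ITU-R 601 luma, `round(0.299R + 0.587G + 0.114B)`) and HSV (hexcone
   conversion, each channel rescaled to 0–255 so all channels share a
   256-bin domain). Histograms hold raw counts: images share dimensions,
   so for a fixed chromosome the pooled pixel count is the same for every
   sample and PLS mean-centering absorbs the scale. Pooling (rather than
   concatenating per-subimage histograms) is what keeps the feature
   length constant across chromosomes; per-subimage concatenation would
   tie the model architecture to the subset size.
3. **PLS1 + LOOCV fitness.** NIPALS PLS1 on column-mean-centered X and
   centered y (no autoscaling by default — all bins share units; a
   `scale` flag exists). The LOOCV loop genuinely refits the model once
   per left-out sample; there is no shortcut formula, so the
   cross-validation error is exactly what a naive loop computes. The
   fitness of a chromosome is that RMSECV, in response units (years).
4. **GA operators.** Roulette-wheel parent selection with probability
   proportional to `1/RMSECV` (the natural minimization transform),
   single-point crossover, independent per-gene mutation, elitism, and a
   repair step that enforces 1–`Nim` selected subimages (an empty
   chromosome gains one random gene; an oversized one has random ones
   cleared). Defaults: population 100, 100 generations, crossover 0.65,
   per-gene mutation 0.05, elitism 0.10, best of 10 restarts. Mutation is
   read as a per-gene flip probability (the standard reading of a GA
   mutation rate); it is configurable. Because fitness is a pure
   function of the gene pattern, evaluations are memoized, and restarts
   share the memo table.
5. **SPXY split.** Calibration/prediction partitioning uses
   Kennard–Stone selection on the joint distance `dx/max(dx) +
   dy/max(dy)`: the calibration set spans both predictor and response
   space, so prediction never extrapolates in y. Ties break toward the
   lowest sample index, which makes the split deterministic. When a
   sample table already carries published C/P labels (as the packaged
   Tokaj roster does), those are honored instead.
6. **Figures of merit.** RMSECV/RMSEP, REP (= RMSE divided by the mean
   reference value; a dimensionless ratio — multiply by 100 for
   percent), R², and a one-sided bias t-test on prediction residuals:
   `t_cal = |mean(e)|·√n / sd(e)` against the one-sided Student-t
   quantile with `n − 1` degrees of freedom (1.8331 at 95% for n = 10).
7. **Interval refinement.** The winning pooled histogram can be refined
   bin-wise: iPLS fits one PLS-LOOCV model per contiguous feature
   interval (equidistant `floor` boundaries; default 48 intervals over
   768 RGB features, i.e. 16-bin windows) and ranks them; iSPA-PLS
   represents each interval by its mean-centered column-mean profile,
   grows minimally collinear interval chains by successive orthogonal
   projections from every starting interval, and scores every chain
   prefix by PLS-LOOCV. With `maxIntervals = 1` it reduces exactly to
   iPLS's top interval.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `roi1`, `roi2` | 5, 5 (sweep adds 10×10) | grid columns/rows |
| `channels` | R, G, B | histogram color channels |
| `popSize`, `generations` | 100, 100 | GA population and cycles |
| `crossoverRate` | 0.65 | pair recombination probability |
| `mutationRate` | 0.05 | per-gene flip probability |
| `elitismRate` | 0.10 | fraction carried over unchanged |
| `nim` | grid size | max subimages per chromosome |
| `nRestarts` | 10 | best-of-n independent runs |
| `nLV` / `lvMax` | 2 / 5 | fixed LV count, or ceiling for selection |
| `nCal` | 28 | SPXY calibration size |

The LV rule, when not fixed, is minimum-RMSECV with a parsimony
tie-break: the smallest LV count within a configurable relative
tolerance (default 0) of the minimum. A fixed `nLV` is the default
inside the GA fitness because re-selecting LV per chromosome multiplies
the LOOCV cost and lets noisy chromosomes shop for a flattering LV
count.

## The synthetic generator

Real wine chromatograms are not redistributable, so validation rests on
a generator that emulates their statistical structure: a scalar
intensity field per sample — Gaussian baseline noise, background peaks
at positions shared by all samples (matrix compounds common to every
wine; response-independent, with mild per-sample amplitude jitter), and
Gaussian peaks confined to designated grid cells whose amplitude is
`gain · y` plus noise — clipped to 0–255 and mapped through a jet-like
256-color ramp to 24-bit RGB. Rendering through a colormap matters:
histogram features must arise from an intensity→color mapping, exactly
as they do in instrument images, not from direct RGB noise.

Defaults mirror the study conditions: 38 samples, 705 × 1195 px, 5 × 5
grid, responses uniform over 6–34 years (the 1989–2017 vintages against
a 2023 reference), two informative cells at grid positions (2,3) and
(1,4) — the positions the wine study found most informative. Planted
peaks are inset 4σ from cell borders so the ground truth stays crisp;
without the inset, peak tails bleed into neighboring cells and "which
cell carries the signal" becomes ambiguous at grid resolution. Gain 3
intensity-units/year against noise σ = 6 gives planted amplitudes
(18–102) that dominate pixel noise but sit well inside the 0–255 range.

What the generator does *not* emulate: modulation-phase structure, peak
tailing, retention-time drift between runs, and detector saturation.
Passing tests therefore demonstrate that the search machinery recovers
localized response-correlated color variation under realistic noise —
not that any particular instrument dataset will behave as cleanly.

## Numerical choices

- NIPALS stops early (with the components extracted so far) when the
  residual covariance with y is numerically zero (norm < 1e−12); a
  first-component failure is a degenerate-input error, which the GA maps
  to an `Inf` fitness sentinel so the search continues.
- All tie-breaks are deterministic: SPXY ties toward the lowest sample
  index; LV selection toward fewer LVs; iSPA-PLS candidates toward lower
  RMSECV, then fewer intervals, then lexicographic interval sets;
  `which.min` everywhere takes the first minimum.
- Every stochastic step (generator, GA, restarts, Monte-Carlo
  reliability) is seeded; restart seeds derive from one master seed, so
  a whole pipeline run is reproducible byte-for-byte in its CSV reports.
- Interval boundaries reuse the same `floor(i·N/n)` rule as the image
  grid; for 10 features in 3 intervals that gives sizes 3, 3, 4.

## Validation problem sizes

The packaged experiments run at sizes chosen to make their statistical
claims checkable by enumeration or repetition: the GA-vs-exhaustive
check uses a 4 × 4 grid (24 samples, 128 × 192 px, chromosomes capped at
2 subimages; 136 possible subsets, enumerated exactly) over 10 master
seeds; the end-to-end recovery experiment runs the full default spec (38
samples, 705 × 1195 px) over 10 master seeds with a desk-scale GA
(population 20, 12 generations, 10 restarts, `Nim` = 4). With two
planted cells and that cap, the worst successful recovery — both planted
cells plus two spurious ones — still yields a Jaccard index of 0.5.

## Known limitations

- The GA has no parsimony pressure beyond `Nim`: a spurious subimage
  that shaves a little off the cross-validated error is kept. The
  Monte-Carlo reliability map (`monteCarloReliability`) is the antidote:
  truly informative cells recur across independent runs.
- Pooled histograms discard *where* within a subimage a color occurs;
  two different spatial patterns with equal color frequencies are
  indistinguishable by design.
- REP is reported as a ratio of RMSE to the mean reference value;
  datasets whose response mean is near zero make it meaningless, and the
  package refuses to compute it then.
- No image registration: images are assumed comparable pixel-for-pixel,
  as when one instrument exports a batch with fixed axes.

## A worked example

```{r example, eval = FALSE}
spec <- syntheticSpec(nSamples = 16, height = 100, width = 150,
                      informativeCells = c(2, 3), peakSigma = 2,
                      nBackgroundPeaks = 10)
ss <- generateSyntheticSet(spec, seed = 1)
cache <- cellHistogramCache(ss$images, ss$grid)
cfg <- gaConfig(popSize = 20, generations = 10, nim = 3, nRestarts = 5,
                nLV = 2)
rr <- runRestarts(cache, ss$y, cfg, masterSeed = 1)
rr$best
recoveryScore(rr$best@bestGenes, ss$truth)
```

The same machinery, at full defaults, is what `runROISelection()` drives
from a sample table of real chromatogram images.
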