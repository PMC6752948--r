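---
title: "Quantifying synaptic nanoarchitecture and function with synaptoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic nanoarchitecture and function with synaptoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoquant)
```

## The scientific problem

Presynaptic active zones (AZs) organize the proteins that dock, prime and
fuse synaptic vesicles — scaffolds such as Bassoon, RIM1 and RIM-BP2, the
priming factor Munc13-1, and voltage-gated Ca~V~2.1 channels.  In gated-STED
(gSTED) images with ~50 nm lateral resolution these proteins appear as
discrete intensity clusters, and the distances between clusters of
different species carry information about how an AZ is organized — for
example, hippocampal mossy-fiber (MF) terminals place Munc13-1 clusters
substantially farther from RIM-BP2 clusters than CA3–CA1 synapses do.

`synaptoquant` implements the full quantification stack such studies rely
on, with every stage testable by parameter recovery on synthetic data:

1. **Segmentation** of protein clusters per channel (threshold → watershed
   → size filter → optional region mask).
2. **Spatial statistics** between two channels: the all-pairs Euclidean
   distance matrix, mean $k$-nearest-neighbor distances $d_k$
   ($k = 1 \dots 5$), neighbor counts within cumulative distances and
   distance intervals, and per-AZ cluster-count proxies.
3. **Line profiles** of finite thickness with per-channel peak detection
   and peak-to-peak distances.
4. **EM quantification** of docked-vesicle density and vesicle size
   classes from active-zone annotation tables.
5. **Autaptic electrophysiology metrics**: evoked amplitude, paired-pulse
   ratio (PPR), sucrose-evoked readily-releasable-pool (RRP) charge,
   vesicular release probability (P~vr~), pharmacological gates.
6. **Aggregation and statistics**: hierarchical averaging, the
   Q3 + 3·IQR extreme-outlier rule, and normality-gated test selection.

## Cluster segmentation

Deconvolved single-plane 8-bit images (nominal 25.25 nm/px over a
25.85 × 25.85 µm field) are thresholded — by Otsu's method by default, or
by an absolute value, which is the recommended mode when several images of
one experiment must share a threshold; either way the value used is logged
in the mask's provenance.  Clusters are then separated by an intensity
watershed (via EBImage) seeded at local maxima at least 50 nm apart (the
nominal resolution; configurable).  Per cluster we report the
intensity-weighted centroid — clusters are defined by their peak
intensities, which motivates weighting; a geometric centroid is available
by flag — the area, the pixel count and the peak intensity.  Clusters
smaller than 0.0025 µm² (the area scale resolvable at 50 nm resolution)
are removed; the cutoff is inclusive: a cluster exactly at 0.0025 µm² is
kept, only strictly smaller ones are dropped.  Region restriction (e.g. to
a ZnT3-positive MF mask) keeps clusters whose *centroid pixel* lies inside
the region; centroid membership was chosen over any-pixel overlap because
it is unambiguous for clusters straddling the mask boundary, and the choice
is surfaced in the function documentation.

On 8-bit plateaus the first pixel in row-major order acts as the peak,
keeping segmentation deterministic.

## Nearest-neighbor statistics

For channels A (neighbors) and B (reference centers) the package computes
the $n_B \times n_A$ Euclidean distance matrix in nm, and per reference
cluster:

- $d_k$, the $k$-th smallest distance, averaged over reference clusters
  (references with fewer than $k$ neighbors contribute *missing* values to
  the mean, not zeros, to avoid downward bias);
- cumulative neighbor counts at 50, 75, 100, 125, 150, 200 and 300 nm
  (distance ≤ threshold), and interval counts as their successive
  differences (0–50, 50–75, 75–100, 100–125, 125–150, 150–200,
  200–300 nm), averaged over *all* reference clusters including those with
  no neighbors.

In self-mode (a channel against itself) the zero self-distance is excluded
exactly once per reference before ranking.  The reference/center channel
is always B; direction matters ($A \to B$ and $B \to A$ summaries differ
in general) and the orientation is stated in every `NeighborSummary`.

A circular AZ of area 0.12 µm² has diameter
$\text{round}(2000\sqrt{0.12/\pi}) = 391$ nm; the number of neighbors with
$d_k < 391$ nm (strict, matching the convention of the per-AZ estimate) is
the proxy used for clusters-per-AZ.  No attempt is made to assign clusters
to specific active zones: cluster-level imaging cannot discriminate
within- from between-AZ neighbors, and the per-AZ count is explicitly a
proxy.

## Line profiles

Profiles are sampled at one-pixel arc spacing along a traced polyline; at
each sample the intensity is the *mean* of `thicknessPx` (default 10,
≈250 nm) bilinear samples perpendicular to the local direction.  Averaging
rather than summing the perpendicular samples keeps the profile on the
intensity scale of the image; peak positions are identical either way.

Peaks are strict local maxima within a ±2-sample comparison window,
plateaus resolved to their center, and peaks whose height above the
profile minimum is below 10% of the dynamic range are discarded — both
defaults chosen to suppress quantization jitter on 8-bit data.  Peaks are
reported at sample resolution by default.  An optional sub-sample
refinement fits a parabola to the *logarithm* of the three samples around
a maximum (Gaussian interpolation, exact for Gaussian-shaped peaks); the
plain-intensity parabola was rejected because for peaks as narrow as the
50 nm PSF (σ ≈ 0.84 px) it leaves a systematic nanometer-scale bias,
whereas the log-domain fit is unbiased on the synthetic fixtures.

Same-channel peak-to-peak distance pairs the two *most intense* peaks (the
reading used for two adjacent clusters of one protein in a side-view
synapse — visually selected double-cluster synapses are dominated by their
two main clusters); cross-channel mode pairs each peak of the first
channel with its nearest peak in the second.  The aggregator admits at
most six profiles per image before averaging per image and then per
animal.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the pipeline is
validated:

- **Scenes** (`makeScene`): a 25.85 × 25.85 µm field at 25.25 nm/px with
  200 AZs (for recovery runs) at least 1 µm apart.  Each AZ holds one
  reference-channel cluster uniform in a 195.5 nm-radius disc (the radius
  of a 0.12 µm² circular AZ) and one paired target-channel cluster at
  radial distance $\max(0, D_\text{true} + \mathcal{N}(0, 20\ \text{nm}))$
  in a uniform direction.  The published pixel size (25.25 nm) and the
  field edge (25.83 µm at 1024 px) are marginally inconsistent; the pixel
  size is exposed as a parameter and defaults to 25.25 nm.  Background
  (non-AZ) clusters are available as a Poisson process but default to
  zero: with unpaired background labeling the nearest-neighbor distance of
  a reference cluster is no longer identified with its paired target, so
  the parameter-recovery condition requires a clean field.
- **Rendering** (`renderSted`): isotropic Gaussian spots with FWHM 50 nm
  (σ = FWHM/2.355) — the published value is a resolution, not a spot
  model, so the simplest consistent model is used — amplitudes uniform in
  150–250 counts, constant background 10, Gaussian read noise (σ = 2 by
  default; Poisson shot noise by flag — the imaging model is otherwise
  unspecified), clipped and quantized to 8 bits.  Cluster placement keeps
  all spots ≥ 300 nm (≈ 3σ + margin) from the field edge to avoid
  truncation bias.
- **Side-view profiles** (`makeSideviewProfiles`): two Gaussian peaks of
  FWHM 50 nm at a known separation; the first peak is aligned to the
  sampling grid, which bounds the sample-resolution peak-to-peak error at
  half a pixel.
- **EM annotations** (`makeEmSample`): AZ and PSD lengths ~250 ± 50 nm,
  docked vesicle counts Poisson at a stated linear density (recovery runs
  use 1.2 per 100 nm), diameters from a small mode (42 ± 5 nm) with a 5%
  large mode (72 ± 4 nm), truncated to (20, 100) nm.
- **Traces** (`makeTraces`): EPSCs as difference-of-exponentials kernels
  (rise 0.5 ms, decay 5 ms) at 10 kHz; sucrose responses as an exponential
  transient of analytic charge (τ = 0.5 s) plus a steady state over a 5 s
  window.

The synthetic data deliberately omit deconvolution artifacts, 3-D
structure, realistic bouton morphology, spatially varying background and
antibody labeling stochasticity.  Passing recovery tests therefore shows
the *analysis* is unbiased under its stated model, not that real images
satisfy that model.

## Coordinates, units and numerical conventions

All distances are nm; areas µm²; charges pC; currents pA.  Image
coordinates have their origin at the center of the top-left pixel, x
rightward, y downward, 0-based pixel indexing.  One top-level seed drives
every generator; each sub-generator derives an independent child stream,
so scenes, images, annotations and traces are byte-identical under a
fixed seed.

## Electrophysiology metrics

- Amplitudes are measured as the mean over ±2 ms around the evoked peak,
  relative to the pre-stimulus baseline (DC-invariant by construction).
- PPR: at a 25 ms interval the second response rides on the decay of the
  first; the default subtracts a single-exponential fit to the
  inter-stimulus decay before measuring the second amplitude (a simple
  shared-baseline mode is available).  Slice mode averages 20 sweeps
  (including failures) and measures the average trace.
- RRP charge: the steady state is the mean over the final 10% of the 5 s
  sucrose window; the transient is the steady-state-subtracted current in
  the response polarity (negative contributions clipped at zero),
  integrated by the trapezoid rule.
- P~vr~ = EPSC charge / RRP charge, with the EPSC charge integrated from
  the stimulus to the return to baseline (≤ 0.5 s).
- Gates: DCG IV inclusion requires ≥ 70% inhibition (inclusive); MF
  identity requires frequency facilitation strictly > 400%; the failure
  rate counts sweeps whose amplitude stays below 3× the baseline noise sd
  (the detection criterion is otherwise unspecified, so a noise-scaled
  default is used) over 30 traces.
- Cohort values are normalized to the mean of the control group of each
  culture.

## Statistics

Hierarchical aggregation averages within image (or culture) and then
within animal.  Extreme outliers are values strictly above Q3 + 3·IQR with
quartiles by linear interpolation of order statistics (R type 7; the SPSS
convention this rule originates from is not uniquely specified, so the
convention is logged with every result); the symmetric lower-tail rule is
available but off by default, matching the one-sided convention.  Group
comparisons follow the assay-specific rule: imaging data always use
Mann-Whitney U; autaptic cohorts use a D'Agostino-Pearson normality gate
to choose one-way ANOVA with Tukey post hoc versus Kruskal-Wallis with
Dunn post hoc; EM cohorts use the same gate to choose Welch's t versus
Mann-Whitney.  For groups smaller than 8 the normality test is unreliable
and the nonparametric branch is taken with a warning.  The
D'Agostino-Pearson and Dunn procedures are implemented from their
published formulas (verified against an independent implementation in the
test suite); all other tests delegate to `stats`.

`n` means different things per assay — animals for imaging, cells for
autapses, active zones for EM — and each `GroupComparison` records which.

## Problem sizes and runtime envelope

Recovery runs use 200 AZs per scene at three generating distances
(100/174/250 nm), 50 noisy profiles, 500 EM active zones and single
noiseless traces — sizes at which every recovery band (2–3 standard
errors) is tight enough to be informative while a full validation run
completes in well under a minute on one core.

## Known limitations

- Watershed separation of same-channel clusters closer than ~2 px is
  unreliable; the recovery scenes place one cluster per channel per AZ so
  cross-channel distances, not same-channel splitting, are validated at
  short range.
- The mask-restriction rule (centroid membership) and the docking rule
  (membrane distance 0) are conventions; both are parameters.
- Mini-EPSC detection by template matching is out of scope, as are
  deconvolution, 3-D segmentation, Ripley-type second-order statistics
  and mixed-effects modeling.

## A worked example

```{r example, eval = FALSE}
gt <- makeScene(sceneSpec(nAZ = 200, dTrue = 174, jitterSD = 20, seed = 1))
res <- analyzeScene(gt, threshold = 40)
res$summary          # mean d_k, cumulative and interval counts
```
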