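# synaptoquant

Quantification of synaptic nanoarchitecture and presynaptic function in R.

Super-resolution (gSTED) imaging resolves presynaptic proteins — Bassoon,
RIM1, RIM-BP2, Munc13-1, Ca~V~2.1 — as discrete clusters at the active
zone, and the distances between clusters of different species describe how
an active zone is organized. `synaptoquant` implements the analysis stack
used to quantify that organization and the matching functional readouts,
for labs analyzing multi-channel STED images, EM active-zone annotations
and autaptic voltage-clamp recordings:

- **Segmentation** — thresholding (Otsu or absolute, always logged),
  watershed cluster separation, the 0.0025 µm² size filter, optional
  region-mask restriction (e.g. a ZnT3 mossy-fiber mask).
- **Cluster spatial statistics** — the all-pairs Euclidean distance matrix
  between two channels, mean *k*-nearest-neighbor distances *d_k*
  (*k* = 1…5), neighbor counts within {50, 75, 100, 125, 150, 200, 300} nm
  and in the corresponding intervals, and per-AZ cluster counts using the
  391 nm diameter of a 0.12 µm² circular active zone
  (`azDiameterFromArea(0.12)`).
- **Line profiles** — finite-thickness (10 px ≈ 250 nm) intensity
  profiles, local-maxima peak detection, within- and between-channel
  peak-to-peak distances, with a ≤ 6 profiles/image aggregation rule.
- **EM quantification** — docked vesicles per 100 nm of active zone,
  small (30–55 nm) / large (>60 nm) vesicle classes, PSD length,
  frequency distributions with mean ± SEM.
- **Electrophysiology** — evoked EPSC amplitude (±2 ms peak averaging),
  paired-pulse ratio, sucrose-evoked RRP charge, P~vr~ = EPSC charge /
  RRP charge, the ≥70% DCG IV inclusion gate, the >400% frequency-
  facilitation mossy-fiber gate, 30-sweep failure rates, per-culture
  control normalization.
- **Statistics** — image→animal aggregation, the Q3 + 3·IQR extreme-
  outlier rule, and assay-specific test selection (Mann-Whitney for
  imaging; D'Agostino-Pearson-gated ANOVA/Tukey vs Kruskal-Wallis/Dunn
  for autapses; Welch t vs Mann-Whitney for EM).
- **Synthetic data** — generators for ground-truth scenes and rendered
  gSTED-like images, side-view two-peak profiles, EM annotation tables
  and current traces, so every stage is validated by parameter recovery.

## Worked example

Generate a field of 200 active zones whose Munc13-1 clusters sit
174 ± 20 nm from their RIM-BP2 clusters, render it, and run the full
segmentation + nearest-neighbor pipeline:

```r
library(synaptoquant)

gt  <- makeScene(sceneSpec(nAZ = 200, dTrue = 174, jitterSD = 20, seed = 1))
res <- analyzeScene(gt, threshold = 40)
res$summary
#> NeighborSummary img1 : Munc13-1 neighbors around RIM-BP2 references
#>   nA = 200 , nB = 200
#>   mean d_k (nm): d1=175.1 d2=1267.5 d3=1599.3 d4=1944.0 d5=2233.4
#>   cumulative counts: <=le50: 0.00  <=le75: 0.00  <=le100: 0.00
#>     <=le125: 0.00  <=le150: 0.10  <=le200: 0.91  <=le300: 1.00
```

The recovered mean nearest-neighbor distance (`d1 = 175.1` nm) matches the
generating distance of 174 nm to within the sampling error of 200 paired
clusters; the higher ranks jump to micrometer scale because each active
zone contains a single cluster pair, so the second-nearest neighbor
belongs to another active zone. The cumulative counts say that on average
0.91 Munc13-1 clusters lie within 200 nm of a RIM-BP2 cluster and
essentially all paired clusters are found by 300 nm.

Expressed by the reporting layer, a mean nearest-neighbor distance of
174 nm at mossy-fiber synapses is `round(percentChange(174, 115))` = 51%
larger than the 115 nm measured at CA3–CA1 synapses.

## Documentation

The methods vignette (`vignettes/synaptoquant-methods.Rmd`) documents the
models, parameter defaults, numerical conventions and the limits of what
the synthetic validation shows.
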