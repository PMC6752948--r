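#' @import methods
#' @importFrom stats rnorm runif rpois quantile sd aggregate wilcox.test
#'   kruskal.test aov TukeyHSD t.test pchisq pnorm setNames na.omit median
NULL

## Coordinate convention used throughout: distances in nm, origin at the
## center of the top-left pixel, x rightward (matrix columns), y downward
## (matrix rows), 0-based pixel indexing.  Pixel (row i, col j) has its
## center at ((j-1)*pixelSize, (i-1)*pixelSize).

#' Scene specification for synthetic gSTED-like fields
#'
#' A `SceneSpec` declares the geometry and statistical structure of a
#' synthetic imaging field: the field extent, pixel pitch, the set of
#' channels, active-zone (AZ) centers, how many clusters of each channel an
#' AZ contains, and the geometric rule linking a target channel to a
#' reference channel (true inter-channel distance plus radial jitter).
#'
#' Target-channel clusters are paired one-to-one with reference-channel
#' clusters: each target lies at radial distance `max(0, dTrue + N(0,
#' jitterSD))` from its reference cluster, in a uniformly random direction.
#' Channels other than the reference/target pair receive `clustersPerAZ`
#' unpaired clusters per AZ.  Background (non-AZ) clusters follow a Poisson
#' process at `backgroundRate` per square micrometer.
#'
#' @slot fieldSize numeric(2), field extent in nm (x, y).
#' @slot pixelSize numeric(1), pixel pitch in nm.
#' @slot channels character, ordered channel names.
#' @slot azCenters numeric matrix (n x 2) of AZ centers in nm; may have zero
#'   rows, in which case [makeScene()] samples `nAZ` centers at least
#'   `azMinSeparation` apart.
#' @slot nAZ integer(1), number of AZs to sample when `azCenters` is empty.
#' @slot azMinSeparation numeric(1), minimum sampled AZ center spacing (nm).
#' @slot azRadius numeric(1), radius (nm) of the disc around an AZ center in
#'   which reference/other clusters are placed.
#' @slot clustersPerAZ named numeric, clusters per AZ for each channel; the
#'   target channel is paired to the reference channel and its entry ignored.
#' @slot referenceChannel,targetChannel character(1), the geometric pairing.
#' @slot dTrue numeric(1), true reference-to-target distance in nm.
#' @slot jitterSD numeric(1), sd (nm) of radial jitter on `dTrue`.
#' @slot backgroundRate numeric(1), background clusters per square micrometer
#'   per channel (placed outside AZ discs).
#' @slot edgeMargin numeric(1), minimum distance (nm) of any cluster from the
#'   field edge (avoids PSF truncation at rendering).
#' @slot seed integer(1), top-level seed; identical specs give byte-identical
#'   scenes.
#' @seealso [sceneSpec()], [makeScene()], [renderSted()]
#' @export
setClass("SceneSpec", representation(
  fieldSize = "numeric", pixelSize = "numeric", channels = "character",
  azCenters = "matrix", nAZ = "integer", azMinSeparation = "numeric",
  azRadius = "numeric", clustersPerAZ = "numeric",
  referenceChannel = "character", targetChannel = "character",
  dTrue = "numeric", jitterSD = "numeric", backgroundRate = "numeric",
  edgeMargin = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@fieldSize) != 2L || any(object@fieldSize <= 0))
    msg <- c(msg, "fieldSize must be two positive numbers (nm)")
  if (length(object@channels) < 1L)
    msg <- c(msg, "at least one channel required")
  if (!object@referenceChannel %in% object@channels)
    msg <- c(msg, "referenceChannel must be one of channels")
  if (!object@targetChannel %in% object@channels)
    msg <- c(msg, "targetChannel must be one of channels")
  if (object@dTrue < 0) msg <- c(msg, "dTrue must be >= 0")
  if (object@jitterSD < 0) msg <- c(msg, "jitterSD must be >= 0")
  if (nrow(object@azCenters) > 0) {
    inx <- object@azCenters[, 1] >= 0 & object@azCenters[, 1] <= object@fieldSize[1]
    iny <- object@azCenters[, 2] >= 0 & object@azCenters[, 2] <= object@fieldSize[2]
    if (!all(inx & iny)) msg <- c(msg, "all azCenters must lie inside the field")
  } else if (object@nAZ < 1L) {
    msg <- c(msg, "nAZ must be >= 1 when azCenters is empty")
  }
  if (!all(object@channels %in% names(object@clustersPerAZ)))
    msg <- c(msg, "clustersPerAZ must name every channel")
  if (length(msg)) msg else TRUE
})

#' Rendering parameters for synthetic STED images
#'
#' @slot psfFWHM numeric(1), full width at half maximum of the isotropic
#'   Gaussian spot model in nm (sigma = FWHM / 2.355).
#' @slot ampRange numeric(2), uniform range of spot peak amplitudes (counts).
#' @slot background numeric(1), constant background level (counts).
#' @slot noiseSD numeric(1), Gaussian read-noise sd (counts).
#' @slot bitDepth integer(1), output bit depth; values are clipped to
#'   `[0, 2^bitDepth - 1]` and rounded.
#' @slot poissonNoise logical(1), add Poisson shot noise before read noise.
#' @seealso [renderParams()], [renderSted()]
#' @export
setClass("RenderParams", representation(
  psfFWHM = "numeric", ampRange = "numeric", background = "numeric",
  noiseSD = "numeric", bitDepth = "integer", poissonNoise = "logical"))

setValidity("RenderParams", function(object) {
  msg <- character()
  if (object@psfFWHM <= 0) msg <- c(msg, "psfFWHM must be > 0")
  if (length(object@ampRange) != 2L || any(object@ampRange < 0) ||
      object@ampRange[1] > object@ampRange[2])
    msg <- c(msg, "ampRange must be an increasing nonnegative pair")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (object@bitDepth < 1L) msg <- c(msg, "bitDepth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic scene
#'
#' Emitted by [makeScene()].  Holds one row per placed cluster with its true
#' centroid, AZ membership and role, plus, for target-channel clusters, the
#' construction distance to their paired reference cluster.
#'
#' @slot clusters data.frame with columns `channel`, `x_nm`, `y_nm`, `az`
#'   (integer AZ index, `NA` for background clusters), `role` (one of
#'   `"reference"`, `"target"`, `"other"`, `"background"`) and `pair_d_nm`
#'   (construction distance, `NA` except for target clusters).
#' @slot azCenters numeric matrix of realized AZ centers (nm).
#' @slot spec the [SceneSpec-class] that produced the scene.
#' @seealso [trueNeighborDistances()], [renderSted()]
#' @export
setClass("GroundTruth", representation(
  clusters = "data.frame", azCenters = "matrix", spec = "SceneSpec"))

setValidity("GroundTruth", function(object) {
  cl <- object@clusters
  need <- c("channel", "x_nm", "y_nm", "az", "role", "pair_d_nm")
  if (!all(need %in% names(cl)))
    return(paste("clusters must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' Multi-channel rendered image
#'
#' A lightweight container for a single-plane multi-channel image: a numeric
#' array `[ny, nx, nchannel]` plus the pixel pitch and channel names.
#'
#' @slot data numeric array, dimensions `ny x nx x nchannel`.
#' @slot pixelSize numeric(1), pixel pitch in nm.
#' @slot channels character, channel names (third array dimension).
#' @slot imageId character(1) identifier.
#' @export
setClass("StedImage", representation(
  data = "array", pixelSize = "numeric", channels = "character",
  imageId = "character"))

setValidity("StedImage", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-d array [ny, nx, nchannel]")
  if (d[3] != length(object@channels))
    return("third dimension must match length(channels)")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  TRUE
})

#' Binary region mask
#'
#' @slot mask logical matrix, same geometry as the image it was derived from.
#' @slot provenance character(1), free-text origin (e.g. `"ZnT3 >= 42"`).
#' @slot threshold numeric(1), threshold value used (NA if not applicable).
#' @slot pixelSize numeric(1), pixel pitch in nm.
#' @seealso [thresholdImage()], [restrictToRegion()]
#' @export
setClass("RegionMask", representation(
  mask = "matrix", provenance = "character", threshold = "numeric",
  pixelSize = "numeric"))

setValidity("RegionMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  TRUE
})

#' Segmented clusters of one channel of one image
#'
#' @slot channel character(1) channel name.
#' @slot imageId character(1).
#' @slot clusters data.frame with columns `label` (unique positive integer),
#'   `x_nm`, `y_nm` (centroid), `area_um2`, `peak` (maximum intensity) and
#'   `pixel_count`.
#' @slot pixelSize numeric(1), nm per pixel.
#' @slot dim integer(2), image dimensions (ny, nx) the clusters came from.
#' @seealso [watershedClusters()], [filterByArea()], [pairwiseDistances()]
#' @export
setClass("ClusterMap", representation(
  channel = "character", imageId = "character", clusters = "data.frame",
  pixelSize = "numeric", dim = "integer"))

setValidity("ClusterMap", function(object) {
  cl <- object@clusters
  need <- c("label", "x_nm", "y_nm", "area_um2", "peak", "pixel_count")
  if (!all(need %in% names(cl)))
    return(paste("clusters must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(cl$label) || any(cl$label <= 0))
    msg <- c(msg, "labels must be unique and positive")
  pxArea <- (object@pixelSize / 1000)^2
  if (nrow(cl) && any(abs(cl$area_um2 - cl$pixel_count * pxArea) > 1e-9))
    msg <- c(msg, "area_um2 must equal pixel_count * (pixelSize/1000)^2")
  if (nrow(cl) && length(object@dim) == 2L) {
    xmax <- (object@dim[2] - 1) * object@pixelSize
    ymax <- (object@dim[1] - 1) * object@pixelSize
    if (any(cl$x_nm < 0 | cl$x_nm > xmax | cl$y_nm < 0 | cl$y_nm > ymax))
      msg <- c(msg, "centroids must lie inside image bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Per-image k-nearest-neighbor summary between two channels
#'
#' Channel A is the channel whose clusters are counted as neighbors; channel
#' B provides the reference centers, matching the convention that distances
#' of all A clusters are ranked from each B cluster and averaged over B.
#'
#' @slot imageId character(1).
#' @slot channelA,channelB character(1), neighbor and reference channels.
#' @slot nA,nB integer(1), cluster counts.
#' @slot meanDk named numeric, mean k-th nearest neighbor distance (nm) for
#'   k = 1..kmax; `NA` where no reference had k neighbors.
#' @slot cumulative named numeric, mean neighbor counts within each
#'   cumulative distance threshold (nm).
#' @slot interval named numeric, mean neighbor counts in successive distance
#'   intervals; sums to the last cumulative entry.
#' @seealso [neighborSummary()]
#' @export
setClass("NeighborSummary", representation(
  imageId = "character", channelA = "character", channelB = "character",
  nA = "integer", nB = "integer", meanDk = "numeric",
  cumulative = "numeric", interval = "numeric"))

setValidity("NeighborSummary", function(object) {
  msg <- character()
  dk <- object@meanDk[!is.na(object@meanDk)]
  if (length(dk) > 1 && any(diff(dk) < -1e-9))
    msg <- c(msg, "mean d_k must be nondecreasing in k")
  if (length(object@cumulative) > 1 && any(diff(object@cumulative) < -1e-9))
    msg <- c(msg, "cumulative counts must be nondecreasing")
  if (length(object@interval) &&
      abs(sum(object@interval) - object@cumulative[length(object@cumulative)]) > 1e-9)
    msg <- c(msg, "interval counts must sum to the last cumulative count")
  if (any(object@cumulative < 0) || any(object@interval < 0))
    msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Intensity profile along a traced line of finite thickness
#'
#' @slot imageId character(1).
#' @slot vertices numeric matrix (>= 2 x 2) of polyline vertices in nm.
#' @slot thicknessPx numeric(1), averaging thickness in pixels (perpendicular
#'   to the local line direction).
#' @slot pixelSize numeric(1), nm per pixel; samples are spaced 1 pixel apart
#'   along the arc.
#' @slot position numeric, arc-length coordinate (nm) of each sample.
#' @slot intensities numeric matrix, samples x channels, column names are
#'   channel names.
#' @seealso [extractProfile()], [findPeaks()]
#' @export
setClass("LineProfile", representation(
  imageId = "character", vertices = "matrix", thicknessPx = "numeric",
  pixelSize = "numeric", position = "numeric", intensities = "matrix"))

setValidity("LineProfile", function(object) {
  msg <- character()
  if (nrow(object@vertices) < 2L) msg <- c(msg, "need >= 2 polyline vertices")
  if (object@thicknessPx < 1) msg <- c(msg, "thickness must be >= 1 pixel")
  if (nrow(object@intensities) != length(object@position))
    msg <- c(msg, "intensity rows must match number of positions")
  if (length(msg)) msg else TRUE
})

#' Detected peaks of one channel of a line profile
#'
#' @slot channel character(1).
#' @slot positions numeric, strictly increasing peak positions in nm along
#'   the profile arc.
#' @slot intensities numeric, peak intensities (same length).
#' @seealso [findPeaks()], [peakToPeak()]
#' @export
setClass("PeakSet", representation(
  channel = "character", positions = "numeric", intensities = "numeric"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@intensities))
    msg <- c(msg, "positions and intensities must have equal length")
  if (length(object@positions) > 1 && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' One electron-microscopy active zone annotation
#'
#' @slot azId character(1) identifier.
#' @slot animal character(1) animal identifier.
#' @slot genotype character(1) group label (e.g. "WT", "KO").
#' @slot azLength numeric(1), active zone length in nm.
#' @slot psdLength numeric(1), post-synaptic density length in nm.
#' @slot vesicles data.frame with columns `diameter_nm` and
#'   `membrane_distance_nm` (distance from vesicle membrane to AZ membrane;
#'   0 means direct contact).
#' @seealso [dockedDensity()], [classifyVesicle()], [makeEmSample()]
#' @export
setClass("AZAnnotation", representation(
  azId = "character", animal = "character", genotype = "character",
  azLength = "numeric", psdLength = "numeric", vesicles = "data.frame"))

setValidity("AZAnnotation", function(object) {
  msg <- character()
  if (object@azLength <= 0) msg <- c(msg, "azLength must be > 0")
  if (object@psdLength <= 0) msg <- c(msg, "psdLength must be > 0")
  v <- object@vesicles
  if (!all(c("diameter_nm", "membrane_distance_nm") %in% names(v)))
    msg <- c(msg, "vesicles needs diameter_nm and membrane_distance_nm")
  else {
    if (nrow(v) && any(v$diameter_nm <= 0)) msg <- c(msg, "diameters must be > 0")
    if (nrow(v) && any(v$membrane_distance_nm < 0))
      msg <- c(msg, "membrane distances must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Sampled current trace
#'
#' @slot current numeric, membrane current samples in pA (uniform sampling).
#' @slot samplingRate numeric(1), Hz.
#' @slot stimTimes numeric, stimulus onset times in s (within the record).
#' @slot windows named list of `c(t0, t1)` solution-application windows (s).
#' @slot meta list of free-form metadata (cell id, culture, group, ...).
#' @seealso [makeTraces()], [evokedAmplitude()], [rrpCharge()]
#' @export
setClass("Trace", representation(
  current = "numeric", samplingRate = "numeric", stimTimes = "numeric",
  windows = "list", meta = "list"))

setValidity("Trace", function(object) {
  msg <- character()
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  dur <- length(object@current) / object@samplingRate
  if (length(object@stimTimes) &&
      (any(object@stimTimes < 0) || any(object@stimTimes > dur)))
    msg <- c(msg, "stimulus times must lie within the record")
  if (length(msg)) msg else TRUE
})

#' Result of a group comparison
#'
#' @slot metric character(1), the compared quantity.
#' @slot assay character(1), one of "imaging", "autapse", "em"; decides the
#'   test-selection rule.
#' @slot groups character, group labels in comparison order.
#' @slot summary data.frame with per-group `n`, `mean`, `sem`.
#' @slot test character(1), the test that was applied.
#' @slot statistic numeric(1), its statistic.
#' @slot p numeric(1), the (omnibus or pairwise) p-value; pairwise details
#'   live in `posthoc`.
#' @slot posthoc data.frame of pairwise comparisons (may have zero rows).
#' @slot alpha numeric(1), significance threshold.
#' @slot notes character, free-form notes (e.g. normality gate outcome).
#' @seealso [compareGroups()]
#' @export
setClass("GroupComparison", representation(
  metric = "character", assay = "character", groups = "character",
  summary = "data.frame", test = "character", statistic = "numeric",
  p = "numeric", posthoc = "data.frame", alpha = "numeric",
  notes = "character"))
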