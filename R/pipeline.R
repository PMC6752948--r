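#' Segment one channel of an image end to end
#'
#' Threshold, watershed, size filter and optional region-mask restriction in
#' one call.
#'
#' @param image a [StedImage-class].
#' @param channel channel name or index.
#' @param threshold `"otsu"` or an absolute value (see [thresholdImage()]).
#' @param minArea size filter in square micrometers.
#' @param minPeakSeparation watershed seed separation in nm.
#' @param region optional [RegionMask-class] restriction (e.g. a ZnT3 mask).
#' @return A [ClusterMap-class].
#' @export
segmentChannel <- function(image, channel, threshold = "otsu",
                           minArea = 0.0025, minPeakSeparation = 50,
                           region = NULL) {
  m <- thresholdImage(image, threshold, channel = channel)
  cm <- watershedClusters(image, m, minPeakSeparation = minPeakSeparation,
                          channel = channel)
  cm <- filterByArea(cm, minArea)
  if (!is.null(region)) cm <- restrictToRegion(cm, region)
  cm
}

#' Render, segment and summarize a synthetic scene
#'
#' The parameter-recovery pipeline: renders a ground-truth scene, segments
#' the reference and target channels independently, and computes the
#' target-around-reference neighbor summary, so the recovered mean d_1 can
#' be compared with the generating distance.
#'
#' @param truth a [GroundTruth-class].
#' @param rp a [RenderParams-class].
#' @param threshold threshold passed to [segmentChannel()]; an absolute
#'   value is applied identically to both channels.
#' @param minArea,minPeakSeparation segmentation settings.
#' @param kMax,thresholds neighbor-summary settings.
#' @return list with `summary` (a [NeighborSummary-class]), `reference` and
#'   `target` ([ClusterMap-class]), and `image`.
#' @examples
#' gt <- makeScene(sceneSpec(nAZ = 20, dTrue = 174, jitterSD = 20, seed = 5))
#' res <- analyzeScene(gt)
#' res$summary
#' @export
analyzeScene <- function(truth, rp = renderParams(), threshold = 40,
                         minArea = 0.0025, minPeakSeparation = 50,
                         kMax = 5L,
                         thresholds = c(50, 75, 100, 125, 150, 200, 300)) {
  spec <- truth@spec
  img <- renderSted(truth, rp)
  ref <- segmentChannel(img, spec@referenceChannel, threshold, minArea,
                        minPeakSeparation)
  tgt <- segmentChannel(img, spec@targetChannel, threshold, minArea,
                        minPeakSeparation)
  ns <- neighborSummary(tgt, ref, kMax = kMax, thresholds = thresholds)
  list(summary = ns, reference = ref, target = tgt, image = img)
}
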