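#' Accessors for synaptoquant containers
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param object a synaptoquant S4 object.
#' @return The corresponding component: `pixelSize()` the pixel pitch in nm,
#'   `channelNames()` the channel names, `clusterTable()` the cluster
#'   data.frame of a [ClusterMap-class] or [GroundTruth-class],
#'   `maskMatrix()` the logical matrix of a [RegionMask-class],
#'   `stedData()` the numeric array of a [StedImage-class],
#'   `vesicleTable()` the vesicle data.frame of an [AZAnnotation-class],
#'   `traceCurrent()` / `traceTimes()` the samples (pA) and their time axis
#'   (s) of a [Trace-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("clusterTable", function(object) standardGeneric("clusterTable"))
#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setGeneric("stedData", function(object) standardGeneric("stedData"))
#' @rdname accessors
#' @export
setGeneric("vesicleTable", function(object) standardGeneric("vesicleTable"))
#' @rdname accessors
#' @export
setGeneric("traceCurrent", function(object) standardGeneric("traceCurrent"))
#' @rdname accessors
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))

#' @rdname accessors
#' @export
setMethod("pixelSize", "SceneSpec", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "StedImage", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ClusterMap", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "RegionMask", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "LineProfile", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setMethod("channelNames", "SceneSpec", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "StedImage", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "LineProfile",
          function(object) colnames(object@intensities))

#' @rdname accessors
#' @export
setMethod("clusterTable", "ClusterMap", function(object) object@clusters)
#' @rdname accessors
#' @export
setMethod("clusterTable", "GroundTruth", function(object) object@clusters)

#' @rdname accessors
#' @export
setMethod("maskMatrix", "RegionMask", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("stedData", "StedImage", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("vesicleTable", "AZAnnotation", function(object) object@vesicles)

#' @rdname accessors
#' @export
setMethod("traceCurrent", "Trace", function(object) object@current)
#' @rdname accessors
#' @export
setMethod("traceTimes", "Trace", function(object)
  (seq_along(object@current) - 1) / object@samplingRate)

#' Extract one channel of a multi-channel image as a matrix
#'
#' @param object a [StedImage-class].
#' @param channel channel name or index.
#' @return numeric matrix `[ny, nx]`.
#' @export
setGeneric("stedChannel", function(object, channel) standardGeneric("stedChannel"))

#' @rdname stedChannel
#' @export
setMethod("stedChannel", "StedImage", function(object, channel) {
  if (is.character(channel)) {
    channel <- match(channel, object@channels)
    if (is.na(channel)) stop("unknown channel")
  }
  object@data[, , channel, drop = TRUE]
})

setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec:", paste(round(object@fieldSize), collapse = " x "),
      "nm field,", object@pixelSize, "nm/px\n")
  naz <- if (nrow(object@azCenters)) nrow(object@azCenters) else object@nAZ
  cat("  channels:", paste(object@channels, collapse = ", "), "\n")
  cat("  AZs:", naz, " dTrue:", object@dTrue, "nm (jitter sd",
      object@jitterSD, "nm),", object@referenceChannel, "->",
      object@targetChannel, "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cl <- object@clusters
  cat("GroundTruth:", nrow(cl), "clusters in",
      length(unique(cl$channel)), "channels,",
      nrow(object@azCenters), "AZs\n")
  print(table(cl$channel, cl$role))
})

setMethod("show", "StedImage", function(object) {
  d <- dim(object@data)
  cat("StedImage", object@imageId, ":", d[1], "x", d[2], "px,",
      d[3], "channel(s) [", paste(object@channels, collapse = ", "),
      "],", object@pixelSize, "nm/px\n")
})

setMethod("show", "RegionMask", function(object) {
  cat("RegionMask:", paste(dim(object@mask), collapse = " x "), "px,",
      sprintf("%.1f%% inside;", 100 * mean(object@mask)),
      object@provenance, "\n")
})

setMethod("show", "ClusterMap", function(object) {
  cat("ClusterMap:", nrow(object@clusters), "clusters, channel",
      object@channel, ", image", object@imageId, "\n")
})

setMethod("show", "NeighborSummary", function(object) {
  cat("NeighborSummary", object@imageId, ":", object@channelA,
      "neighbors around", object@channelB, "references\n")
  cat("  nA =", object@nA, ", nB =", object@nB, "\n")
  cat("  mean d_k (nm):", paste(sprintf("%s=%.1f", names(object@meanDk),
                                        object@meanDk), collapse = " "), "\n")
  cat("  cumulative counts:", paste(sprintf("<=%s: %.2f",
      names(object@cumulative), object@cumulative), collapse = "  "), "\n")
})

setMethod("show", "LineProfile", function(object) {
  cat("LineProfile", object@imageId, ":", length(object@position),
      "samples,", ncol(object@intensities), "channel(s), thickness",
      object@thicknessPx, "px\n")
})

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet (", object@channel, "): ", length(object@positions),
      " peak(s) at ", paste(round(object@positions, 1), collapse = ", "),
      " nm\n", sep = "")
})

setMethod("show", "AZAnnotation", function(object) {
  cat("AZAnnotation", object@azId, "(", object@genotype, "): AZ",
      round(object@azLength), "nm, PSD", round(object@psdLength), "nm,",
      nrow(object@vesicles), "vesicles\n")
})

setMethod("show", "Trace", function(object) {
  cat("Trace:", length(object@current), "samples @",
      object@samplingRate / 1000, "kHz (",
      round(length(object@current) / object@samplingRate, 3), "s ),",
      length(object@stimTimes), "stimuli\n")
})

setMethod("show", "GroupComparison", function(object) {
  cat("GroupComparison [", object@assay, "] metric:", object@metric, "\n")
  print(object@summary, row.names = FALSE)
  cat("  test:", object@test, " statistic =", signif(object@statistic, 4),
      " p =", signif(object@p, 4),
      if (object@p < object@alpha) " (significant)" else " (n.s.)", "\n")
  if (nrow(object@posthoc)) {
    cat("  post hoc:\n")
    print(object@posthoc, row.names = FALSE)
  }
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})
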