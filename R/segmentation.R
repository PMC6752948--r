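#' Threshold a single-channel image into a binary region mask
#'
#' The mask is true where intensity is greater than or equal to the
#' threshold.  The threshold is either given as an absolute value or
#' computed by Otsu's method on the image histogram; either way the value
#' used is stored in the mask's provenance so the segmentation is
#' reproducible (within one experiment the same threshold should be applied
#' to all images).
#'
#' @param image numeric matrix (one channel) or a [StedImage-class] plus
#'   `channel`.
#' @param method `"otsu"` or a single numeric absolute threshold.
#' @param channel channel name/index when `image` is a [StedImage-class].
#' @param maxval intensity range upper bound used by Otsu (defaults to 255,
#'   i.e. 8-bit data).
#' @return A [RegionMask-class].  An all-true or all-false mask triggers a
#'   warning, not an error.
#' @examples
#' gt <- makeScene(sceneSpec(nAZ = 3, seed = 4))
#' img <- renderSted(gt)
#' thresholdImage(img, method = 40, channel = 1)
#' @export
thresholdImage <- function(image, method = "otsu", channel = 1L,
                           maxval = 255) {
  ps <- NA_real_
  if (is(image, "StedImage")) {
    ps <- image@pixelSize
    image <- stedChannel(image, channel)
  }
  stopifnot(is.matrix(image))
  if (is.numeric(method)) {
    thr <- method
    prov <- sprintf("absolute threshold %g", thr)
  } else if (identical(method, "otsu")) {
    thr <- EBImage::otsu(EBImage::Image(image / maxval),
                         range = c(0, 1), levels = maxval + 1) * maxval
    prov <- sprintf("otsu threshold %.3f", thr)
  } else stop("method must be 'otsu' or a numeric threshold")
  mask <- image >= thr
  if (all(mask)) warning("threshold produced an all-true mask")
  if (!any(mask)) warning("threshold produced an all-false mask")
  new("RegionMask", mask = mask, provenance = prov, threshold = thr,
      pixelSize = ps)
}

#' Segment clusters by watershed within a mask
#'
#' Runs an intensity watershed on the masked channel so that each basin,
#' seeded at an intensity local maximum, becomes one cluster, then reports
#' per-cluster centroid (intensity-weighted by default), area, peak
#' intensity and pixel count.  On plateaus of quantized data the first pixel
#' in row-major order acts as the peak, which keeps labels deterministic.
#'
#' @param image numeric matrix or [StedImage-class] (with `channel`).
#' @param mask a [RegionMask-class] from the same image geometry.
#' @param minPeakSeparation minimum separation of watershed seed maxima in
#'   nm (the default equals the nominal 50 nm lateral resolution).
#' @param pixelSize nm per pixel (taken from the image when it is a
#'   [StedImage-class]).
#' @param channel channel of a [StedImage-class] to segment.
#' @param tolerance minimum intensity drop between two maxima for them to
#'   seed distinct basins (counts; 1 suits 8-bit data).
#' @param weighted use the intensity-weighted centroid (`TRUE`, default,
#'   reflecting that clusters are defined by their peak intensities) or the
#'   geometric centroid.
#' @param imageId identifier stored in the result.
#' @param channelName channel name stored in the result.
#' @return A [ClusterMap-class]; an empty mask yields zero clusters.
#' @examples
#' gt <- makeScene(sceneSpec(nAZ = 3, seed = 4))
#' img <- renderSted(gt, renderParams(noiseSD = 0))
#' m <- thresholdImage(img, 40, channel = "Munc13-1")
#' watershedClusters(img, m, channel = "Munc13-1")
#' @export
watershedClusters <- function(image, mask, minPeakSeparation = 50,
                              pixelSize = NULL, channel = 1L,
                              tolerance = 1, weighted = TRUE,
                              imageId = "img1", channelName = NULL) {
  if (is(image, "StedImage")) {
    if (is.null(pixelSize)) pixelSize <- image@pixelSize
    if (is.null(channelName))
      channelName <- if (is.character(channel)) channel else
        image@channels[channel]
    imageId <- image@imageId
    image <- stedChannel(image, channel)
  }
  if (is.null(pixelSize)) pixelSize <- 25.25
  if (is.null(channelName)) channelName <- "ch1"
  m <- maskMatrix(mask)
  if (!identical(dim(m), dim(image)))
    stop("mask geometry does not match image")
  emptyMap <- function() new("ClusterMap", channel = channelName,
    imageId = imageId,
    clusters = data.frame(label = integer(), x_nm = numeric(),
                          y_nm = numeric(), area_um2 = numeric(),
                          peak = numeric(), pixel_count = integer()),
    pixelSize = pixelSize, dim = dim(image))
  if (!any(m)) return(emptyMap())
  ext <- max(1L, round(minPeakSeparation / pixelSize / 2))
  lab <- EBImage::imageData(EBImage::watershed(EBImage::Image(image * m),
                                               tolerance = tolerance,
                                               ext = ext))
  nlab <- max(lab)
  if (nlab == 0L) return(emptyMap())
  idx <- which(lab > 0)
  L <- lab[idx]
  w <- if (weighted) image[idx] else rep(1, length(idx))
  ij <- arrayInd(idx, dim(image))
  xs <- (ij[, 2] - 1) * pixelSize
  ys <- (ij[, 1] - 1) * pixelSize
  sw <- tapply(w, L, sum)
  cl <- data.frame(
    label = as.integer(names(sw)),
    x_nm = as.numeric(tapply(w * xs, L, sum) / sw),
    y_nm = as.numeric(tapply(w * ys, L, sum) / sw),
    pixel_count = as.integer(tapply(w, L, length)),
    peak = as.numeric(tapply(image[idx], L, max)))
  cl$area_um2 <- cl$pixel_count * (pixelSize / 1000)^2
  cl <- cl[order(cl$label), c("label", "x_nm", "y_nm", "area_um2", "peak",
                              "pixel_count")]
  rownames(cl) <- NULL
  new("ClusterMap", channel = channelName, imageId = imageId, clusters = cl,
      pixelSize = pixelSize, dim = dim(image))
}

#' Remove clusters below a minimum area
#'
#' Clusters whose area is strictly smaller than `minArea` are discarded; a
#' cluster exactly at the cutoff is kept.  The default cutoff of 0.0025
#' square micrometers corresponds to the area resolvable at ~50 nm lateral
#' resolution.  Labels of surviving clusters are preserved.
#'
#' @param cm a [ClusterMap-class].
#' @param minArea minimum area in square micrometers (>= 0).
#' @return The filtered [ClusterMap-class], with attribute `removed` giving
#'   the number of removed clusters.
#' @export
filterByArea <- function(cm, minArea = 0.0025) {
  if (minArea < 0) stop("minArea must be >= 0")
  cl <- cm@clusters
  keep <- cl$area_um2 >= minArea
  out <- cm
  out@clusters <- cl[keep, , drop = FALSE]
  rownames(out@clusters) <- NULL
  attr(out, "removed") <- sum(!keep)
  out
}

#' Restrict clusters to a region mask
#'
#' Keeps clusters whose centroid pixel lies inside the region (centroid
#' membership, not any-pixel overlap).  Typical use: restricting Munc13-1 or
#' Cav2.1 clusters to the ZnT3-positive mossy-fiber area.
#'
#' @param cm a [ClusterMap-class].
#' @param region a [RegionMask-class] with the same geometry as the image
#'   the clusters came from.
#' @return The restricted [ClusterMap-class].
#' @export
restrictToRegion <- function(cm, region) {
  m <- maskMatrix(region)
  if (!identical(dim(m), as.integer(cm@dim)))
    stop("region geometry does not match the cluster map's image")
  cl <- cm@clusters
  if (nrow(cl)) {
    j <- pmin(pmax(round(cl$x_nm / cm@pixelSize) + 1, 1), ncol(m))
    i <- pmin(pmax(round(cl$y_nm / cm@pixelSize) + 1, 1), nrow(m))
    keep <- m[cbind(i, j)]
    cl <- cl[keep, , drop = FALSE]
    rownames(cl) <- NULL
  }
  out <- cm
  out@clusters <- cl
  out
}
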