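## bilinear interpolation at 0-based pixel coordinates (x = col, y = row)
bilinearAt <- function(mat, xp, yp) {
  ny <- nrow(mat); nx <- ncol(mat)
  if (any(xp < 0 | xp > nx - 1 | yp < 0 | yp > ny - 1))
    stop("sample point outside image")
  x0 <- pmin(floor(xp), nx - 2); y0 <- pmin(floor(yp), ny - 2)
  fx <- xp - x0; fy <- yp - y0
  i0 <- y0 + 1; j0 <- x0 + 1
  mat[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    mat[cbind(i0, j0 + 1)] * fx * (1 - fy) +
    mat[cbind(i0 + 1, j0)] * (1 - fx) * fy +
    mat[cbind(i0 + 1, j0 + 1)] * fx * fy
}

#' Extract an intensity profile along a polyline of finite thickness
#'
#' Samples every channel at one-pixel arc-length spacing along the traced
#' polyline.  At each arc position the intensity is the mean of
#' `thicknessPx` bilinear samples taken perpendicular to the local segment
#' direction (the standard thick-line-profile tool; 10 px at 25.25 nm/px is
#' about 250 nm).
#'
#' @param image a [StedImage-class] or a single numeric matrix.
#' @param polyline numeric matrix (>= 2 x 2) of vertices in nm.
#' @param thicknessPx perpendicular averaging thickness in pixels (>= 1).
#' @param pixelSize nm per pixel (taken from a [StedImage-class]).
#' @param imageId identifier (taken from a [StedImage-class]).
#' @return A [LineProfile-class].  An error is raised if the line, after
#'   thickness expansion, leaves the image.
#' @export
extractProfile <- function(image, polyline, thicknessPx = 10,
                           pixelSize = NULL, imageId = "img1") {
  if (is(image, "StedImage")) {
    pixelSize <- image@pixelSize
    imageId <- image@imageId
    mats <- lapply(seq_along(image@channels), function(k) stedChannel(image, k))
    names(mats) <- image@channels
  } else {
    mats <- list(ch1 = image)
    if (is.null(pixelSize)) pixelSize <- 25.25
  }
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs at least 2 vertices")
  if (thicknessPx < 1) stop("thickness must be >= 1 pixel")
  seg <- diff(polyline)
  segLen <- sqrt(rowSums(seg^2))
  if (any(segLen == 0)) stop("polyline has zero-length segments")
  cumLen <- c(0, cumsum(segLen))
  total <- cumLen[length(cumLen)]
  s <- seq(0, total, by = pixelSize)
  ## position and local direction at each arc sample
  segIdx <- pmin(findInterval(s, cumLen, rightmost.closed = TRUE),
                 nrow(seg))
  frac <- (s - cumLen[segIdx]) / segLen[segIdx]
  px <- polyline[segIdx, 1] + frac * seg[segIdx, 1]
  py <- polyline[segIdx, 2] + frac * seg[segIdx, 2]
  ux <- seg[segIdx, 1] / segLen[segIdx]
  uy <- seg[segIdx, 2] / segLen[segIdx]
  offs <- (seq_len(thicknessPx) - (thicknessPx + 1) / 2) * pixelSize
  inten <- matrix(NA_real_, length(s), length(mats),
                  dimnames = list(NULL, names(mats)))
  for (k in seq_along(mats)) {
    acc <- matrix(0, length(s), length(offs))
    for (o in seq_along(offs)) {
      qx <- px - uy * offs[o]
      qy <- py + ux * offs[o]
      acc[, o] <- bilinearAt(mats[[k]], qx / pixelSize, qy / pixelSize)
    }
    inten[, k] <- rowMeans(acc)
  }
  new("LineProfile", imageId = imageId, vertices = polyline,
      thicknessPx = thicknessPx, pixelSize = pixelSize, position = s,
      intensities = inten)
}

#' Detect local-maxima peaks in one channel of a line profile
#'
#' A sample (or plateau of equal samples) is a peak when it is strictly
#' greater than every sample within `window` samples on both sides; a
#' plateau is reported at its center.  Peaks whose height above the profile
#' minimum is below `minProminence` times the profile's dynamic range are
#' discarded, which suppresses quantization jitter on 8-bit data.  Profile
#' endpoints are never peaks.
#'
#' @param profile a [LineProfile-class] (or a numeric vector with
#'   `pixelSize` giving its sample spacing).
#' @param channel channel name or index.
#' @param window comparison half-window in samples.
#' @param minProminence minimum peak height as a fraction of the profile
#'   range.
#' @param refine apply 3-point sub-sample refinement to single-sample peaks
#'   by Gaussian interpolation (a parabola on the log intensities, exact for
#'   Gaussian-shaped peaks).  Off by default: peaks are reported at sample
#'   resolution.
#' @param pixelSize sample spacing in nm when `profile` is a bare vector.
#' @return A [PeakSet-class]; empty when no peak qualifies.
#' @examples
#' findPeaks(c(0, 1, 0), pixelSize = 25.25)
#' @export
findPeaks <- function(profile, channel = 1L, window = 2L,
                      minProminence = 0.1, refine = FALSE,
                      pixelSize = 25.25) {
  if (is(profile, "LineProfile")) {
    y <- profile@intensities[, channel]
    pos <- profile@position
    chname <- if (is.character(channel)) channel else
      colnames(profile@intensities)[channel]
    if (is.null(chname)) chname <- "ch1"
  } else {
    y <- as.numeric(profile)
    pos <- (seq_along(y) - 1) * pixelSize
    chname <- "ch1"
  }
  n <- length(y)
  if (n < 3L) stop("need at least 3 samples")
  rng <- diff(range(y))
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peakPos <- numeric(0)
  peakVal <- numeric(0)
  for (q in seq_along(r$values)) {
    a <- starts[q]; b <- ends[q]; v <- r$values[q]
    if (a == 1L || b == n) next          # endpoint plateaus are not peaks
    left <- y[max(1L, a - window):(a - 1L)]
    right <- y[(b + 1L):min(n, b + window)]
    if (all(v > left) && all(v > right)) {
      if (rng > 0 && (v - min(y)) < minProminence * rng) next
      center <- (a + b) / 2
      p <- if (center == floor(center)) pos[center] else
        (pos[floor(center)] + pos[ceiling(center)]) / 2
      if (refine && a == b && min(y[(a - 1L):(a + 1L)]) > 0) {
        ## Gaussian interpolation: a parabola through the log of the three
        ## samples around the maximum is exact for Gaussian-shaped peaks
        ly <- log(y[(a - 1L):(a + 1L)])
        denom <- ly[1] - 2 * ly[2] + ly[3]
        if (denom < 0) {
          delta <- 0.5 * (ly[1] - ly[3]) / denom
          p <- pos[a] + delta * (pos[a + 1L] - pos[a])
        }
      }
      peakPos <- c(peakPos, p)
      peakVal <- c(peakVal, v)
    }
  }
  o <- order(peakPos)
  new("PeakSet", channel = chname, positions = peakPos[o],
      intensities = peakVal[o])
}

#' Peak-to-peak distances within or between channels
#'
#' Same-channel mode (one [PeakSet-class]): the distance between the two
#' largest-intensity peaks, the reading used for two adjacent clusters of
#' the same protein in a side-view synapse; `NA` with a warning when fewer
#' than two peaks exist.  Cross-channel mode (two sets): for each peak of
#' the first set, the distance to the nearest peak of the second set.
#'
#' @param ps1 a [PeakSet-class].
#' @param ps2 optional second [PeakSet-class] for cross-channel mode.
#' @return Same-channel: a single distance in nm (or `NA`).  Cross-channel:
#'   numeric vector, one distance per `ps1` peak.
#' @examples
#' p <- findPeaks(c(0, 5, 0, 0, 4, 0), pixelSize = 25.25)
#' peakToPeak(p)
#' @export
peakToPeak <- function(ps1, ps2 = NULL) {
  if (is.null(ps2)) {
    if (length(ps1@positions) < 2L) {
      warning("fewer than 2 peaks: same-channel distance undefined")
      return(NA_real_)
    }
    top <- order(ps1@intensities, decreasing = TRUE)[1:2]
    return(abs(diff(ps1@positions[top])))
  }
  if (!length(ps1@positions) || !length(ps2@positions))
    stop("both peak sets must be nonempty for cross-channel pairing")
  vapply(ps1@positions, function(p) min(abs(ps2@positions - p)), numeric(1))
}

#' Aggregate per-profile measurements to image and animal level
#'
#' At most `maxPerImage` profiles per image enter the analysis (the first
#' ones in input order; the rest are dropped and counted).  Values are then
#' averaged per image and the image means per animal.
#'
#' @param df data.frame with columns `animal`, `image_id`, `value`.
#' @param maxPerImage maximum number of profiles per image (default 6).
#' @return list with `perImage` and `perAnimal` data.frames; the attribute
#'   `dropped` counts profiles beyond the per-image cap.
#' @export
aggregateProfiles <- function(df, maxPerImage = 6L) {
  stopifnot(all(c("animal", "image_id", "value") %in% names(df)))
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$image_id),
                        function(i) utils::head(i, maxPerImage)))
  dropped <- nrow(df) - length(keep)
  df <- df[sort(keep), , drop = FALSE]
  perImage <- aggregate(value ~ animal + image_id, df, mean, na.rm = TRUE)
  perAnimal <- aggregate(value ~ animal, perImage, mean, na.rm = TRUE)
  out <- list(perImage = perImage, perAnimal = perAnimal)
  attr(out, "dropped") <- dropped
  out
}
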