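#' Generate side-view two-peak line-profile fixtures
#'
#' Emulates intensity profiles across synapses seen in side view: each
#' profile is the sum of two Gaussian peaks separated by `separation` nm,
#' plus optional multiplicative-scale Gaussian noise.  The first peak is
#' aligned to the sampling grid and the pair is padded so both flanks decay
#' to background, which bounds the sample-resolution peak-to-peak error at
#' half a pixel.
#'
#' @param n number of profiles.
#' @param separation true peak-to-peak distance in nm; must be at least two
#'   pixels (below one pixel it is unresolvable and an error is raised).
#' @param pixelSize sample spacing in nm.
#' @param peakFWHM FWHM of each Gaussian peak in nm.
#' @param amplitude peak amplitude (counts) of the first peak.
#' @param relAmp2 amplitude of the second peak relative to the first.
#' @param background constant background level (counts).
#' @param noiseSD Gaussian noise sd as a fraction of `amplitude` (0 = none).
#' @param channel channel name stored in the profiles.
#' @param seed integer seed; profiles are identical across runs at a fixed
#'   seed.
#' @return list of [LineProfile-class], with attribute `separation` (nm) and
#'   attribute `peaks` (true peak positions in nm along the profile).
#' @examples
#' pr <- makeSideviewProfiles(3, separation = 184, noiseSD = 0, seed = 1)
#' @export
makeSideviewProfiles <- function(n, separation, pixelSize = 25.25,
                                 peakFWHM = 50, amplitude = 200,
                                 relAmp2 = 1, background = 5, noiseSD = 0,
                                 channel = "ch1", seed = 1L) {
  stopifnotScalar(separation, "separation")
  if (separation < 2 * pixelSize)
    stop("separation below resolvability: need at least 2 pixels (",
         2 * pixelSize, " nm)")
  sigma <- fwhmToSigma(peakFWHM)
  pad <- ceiling(4 * sigma / pixelSize) + 3L
  p1 <- pad * pixelSize                       # grid-aligned first peak
  p2 <- p1 + separation
  ns <- pad * 2L + ceiling(separation / pixelSize) + 1L
  pos <- (seq_len(ns) - 1) * pixelSize
  shape <- background +
    amplitude * exp(-(pos - p1)^2 / (2 * sigma^2)) +
    amplitude * relAmp2 * exp(-(pos - p2)^2 / (2 * sigma^2))
  withr::with_seed(childSeed(seed, "profiles"), {
    lapply(seq_len(n), function(i) {
      y <- shape
      if (noiseSD > 0) y <- pmax(0, y + rnorm(ns, 0, noiseSD * amplitude))
      prof <- new("LineProfile", imageId = sprintf("sim%03d", i),
                  vertices = rbind(c(0, 0), c(pos[ns], 0)),
                  thicknessPx = 1, pixelSize = pixelSize, position = pos,
                  intensities = matrix(y, ncol = 1,
                                       dimnames = list(NULL, channel)))
      attr(prof, "separation") <- separation
      attr(prof, "peaks") <- c(p1, p2)
      prof
    })
  })
}
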