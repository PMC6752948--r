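#' Construct a scene specification
#'
#' Convenience constructor for [SceneSpec-class] with defaults matching the
#' imaging conditions the pipeline targets: a 25.85 x 25.85 micrometer field
#' sampled at 25.25 nm/px, two channels paired at a true distance `dTrue`.
#'
#' @param fieldSize numeric(2), field extent in nm.
#' @param pixelSize pixel pitch in nm.
#' @param channels ordered channel names; first two default to the
#'   reference/target pair.
#' @param azCenters optional n x 2 matrix of AZ centers (nm); if `NULL`,
#'   [makeScene()] samples `nAZ` centers at least `azMinSeparation` apart.
#' @param nAZ number of active zones when `azCenters` is not given.
#' @param azMinSeparation minimum spacing between sampled AZ centers (nm).
#' @param azRadius placement radius around each AZ center (nm); the default
#'   is the radius of a 0.12 square-micrometer circular AZ.
#' @param clustersPerAZ named counts of clusters per AZ per channel; a single
#'   unnamed number is recycled to all channels.
#' @param referenceChannel,targetChannel the geometrically paired channels.
#' @param dTrue true reference-to-target distance (nm).
#' @param jitterSD radial jitter sd (nm) on `dTrue`.
#' @param backgroundRate background clusters per square micrometer (0 by
#'   default: with background labeling, the nearest-neighbor distance of a
#'   reference cluster is no longer identified with its paired target, so
#'   parameter-recovery scenes keep the field clean; set a positive rate to
#'   emulate non-synaptic labeling).
#' @param edgeMargin minimum cluster distance from the field edge (nm).
#' @param seed integer seed; scenes are byte-identical under the same seed.
#' @return A validated [SceneSpec-class].
#' @examples
#' sp <- sceneSpec(nAZ = 5, dTrue = 174, jitterSD = 20, seed = 1)
#' gt <- makeScene(sp)
#' @export
sceneSpec <- function(fieldSize = c(25850, 25850), pixelSize = 25.25,
                      channels = c("RIM-BP2", "Munc13-1"),
                      azCenters = NULL, nAZ = 50L, azMinSeparation = 1000,
                      azRadius = 195.5, clustersPerAZ = 1,
                      referenceChannel = channels[1],
                      targetChannel = channels[2],
                      dTrue = 174, jitterSD = 20, backgroundRate = 0,
                      edgeMargin = 300, seed = 1L) {
  if (is.null(azCenters)) azCenters <- matrix(numeric(0), 0, 2)
  if (is.null(names(clustersPerAZ)))
    clustersPerAZ <- setNames(rep(clustersPerAZ, length.out = length(channels)),
                              channels)
  new("SceneSpec", fieldSize = fieldSize, pixelSize = pixelSize,
      channels = channels, azCenters = azCenters, nAZ = as.integer(nAZ),
      azMinSeparation = azMinSeparation, azRadius = azRadius,
      clustersPerAZ = clustersPerAZ, referenceChannel = referenceChannel,
      targetChannel = targetChannel, dTrue = dTrue, jitterSD = jitterSD,
      backgroundRate = backgroundRate, edgeMargin = edgeMargin,
      seed = as.integer(seed))
}

#' Construct rendering parameters
#'
#' @param psfFWHM Gaussian spot FWHM in nm (the nominal lateral resolution).
#' @param ampRange uniform peak-amplitude range in counts.
#' @param background constant background level in counts.
#' @param noiseSD Gaussian read-noise sd in counts.
#' @param bitDepth output bit depth (values clipped to `[0, 2^bitDepth-1]`).
#' @param poissonNoise add Poisson shot noise before read noise.
#' @return A validated [RenderParams-class].
#' @export
renderParams <- function(psfFWHM = 50, ampRange = c(150, 250),
                         background = 10, noiseSD = 2, bitDepth = 8L,
                         poissonNoise = FALSE) {
  new("RenderParams", psfFWHM = psfFWHM, ampRange = ampRange,
      background = background, noiseSD = noiseSD,
      bitDepth = as.integer(bitDepth), poissonNoise = poissonNoise)
}

# sample n points at least minSep apart inside [lo, hi] x [lo, hi]
sampleSpacedCenters <- function(n, xmax, ymax, margin, minSep, azName = "AZ") {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  maxTries <- 2000L * n
  while (placed < n) {
    if (tries > maxTries)
      stop(sprintf("could not place %s %d: density too high for field", azName,
                   placed + 1L))
    p <- c(runif(1, margin, xmax - margin), runif(1, margin, ymax - margin))
    ok <- placed == 0L ||
      min(sqrt((pts[seq_len(placed), 1] - p[1])^2 +
               (pts[seq_len(placed), 2] - p[2])^2)) >= minSep
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- p
    }
    tries <- tries + 1L
  }
  pts
}

#' Generate the ground truth of a synthetic scene
#'
#' Places protein clusters according to a [SceneSpec-class]: per active zone,
#' `clustersPerAZ` reference-channel clusters uniform in a disc of radius
#' `azRadius`; one target-channel cluster per reference cluster at radial
#' distance `max(0, dTrue + N(0, jitterSD))` in a uniform direction; other
#' channels unpaired within the disc; plus Poisson background clusters per
#' channel outside the AZ discs.  All placements are rejection-sampled to
#' stay at least `edgeMargin` from the field edge; an AZ whose placements
#' cannot satisfy this raises an error naming the AZ.
#'
#' @param spec a [SceneSpec-class].
#' @return A [GroundTruth-class]; the `pair_d_nm` column of its cluster table
#'   records the construction distance of every target cluster to its paired
#'   reference.
#' @examples
#' gt <- makeScene(sceneSpec(nAZ = 10, dTrue = 100, jitterSD = 0, seed = 7))
#' mean(clusterTable(gt)$pair_d_nm, na.rm = TRUE)  # 100
#' @export
makeScene <- function(spec) {
  validObject(spec)
  withr::with_seed(childSeed(spec@seed, "scene"), {
    fx <- spec@fieldSize[1]; fy <- spec@fieldSize[2]
    m <- spec@edgeMargin
    if (fx <= 2 * m || fy <= 2 * m)
      stop("field too small for the requested edge margin")
    centers <- spec@azCenters
    if (nrow(centers) == 0L)
      centers <- sampleSpacedCenters(spec@nAZ, fx, fy,
                                     m + spec@azRadius,
                                     spec@azMinSeparation)
    naz <- nrow(centers)
    ref <- spec@referenceChannel
    tgt <- spec@targetChannel
    rows <- list()
    inField <- function(p) p[1] >= m && p[1] <= fx - m && p[2] >= m && p[2] <= fy - m
    for (a in seq_len(naz)) {
      nref <- round(spec@clustersPerAZ[[ref]])
      for (r in seq_len(nref)) {
        ## reference cluster uniform in the AZ disc
        for (try in 1:200) {
          th <- runif(1, 0, 2 * pi); rr <- spec@azRadius * sqrt(runif(1))
          p <- centers[a, ] + rr * c(cos(th), sin(th))
          if (inField(p)) break
          if (try == 200) stop(sprintf("AZ %d: cannot place reference cluster inside field", a))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ref, x_nm = p[1], y_nm = p[2], az = a,
          role = "reference", pair_d_nm = NA_real_)
        ## paired target cluster at dTrue (+ radial jitter)
        d <- max(0, spec@dTrue + rnorm(1, 0, spec@jitterSD))
        placed <- FALSE
        for (try in 1:200) {
          th <- runif(1, 0, 2 * pi)
          q <- p + d * c(cos(th), sin(th))
          if (inField(q)) { placed <- TRUE; break }
        }
        if (!placed) stop(sprintf("AZ %d: cannot place target cluster inside field", a))
        rows[[length(rows) + 1L]] <- data.frame(
          channel = tgt, x_nm = q[1], y_nm = q[2], az = a,
          role = "target", pair_d_nm = d)
      }
      ## unpaired clusters for the remaining channels
      for (ch in setdiff(spec@channels, c(ref, tgt))) {
        nch <- round(spec@clustersPerAZ[[ch]])
        for (r in seq_len(nch)) {
          for (try in 1:200) {
            th <- runif(1, 0, 2 * pi); rr <- spec@azRadius * sqrt(runif(1))
            p <- centers[a, ] + rr * c(cos(th), sin(th))
            if (inField(p)) break
            if (try == 200) stop(sprintf("AZ %d: cannot place %s cluster inside field", a, ch))
          }
          rows[[length(rows) + 1L]] <- data.frame(
            channel = ch, x_nm = p[1], y_nm = p[2], az = a,
            role = "other", pair_d_nm = NA_real_)
        }
      }
    }
    ## Poisson background clusters outside the AZ discs
    areaUm2 <- (fx - 2 * m) * (fy - 2 * m) / 1e6
    for (ch in spec@channels) {
      nbg <- rpois(1, spec@backgroundRate * areaUm2)
      placed <- 0L
      tries <- 0L
      while (placed < nbg && tries < 200L * max(nbg, 1L)) {
        p <- c(runif(1, m, fx - m), runif(1, m, fy - m))
        dmin <- if (naz) min(sqrt((centers[, 1] - p[1])^2 +
                                  (centers[, 2] - p[2])^2)) else Inf
        if (dmin > spec@azRadius) {
          rows[[length(rows) + 1L]] <- data.frame(
            channel = ch, x_nm = p[1], y_nm = p[2], az = NA_integer_,
            role = "background", pair_d_nm = NA_real_)
          placed <- placed + 1L
        }
        tries <- tries + 1L
      }
    }
    cl <- if (length(rows)) do.call(rbind, rows) else
      data.frame(channel = character(), x_nm = numeric(), y_nm = numeric(),
                 az = integer(), role = character(), pair_d_nm = numeric())
    rownames(cl) <- NULL
    new("GroundTruth", clusters = cl, azCenters = centers, spec = spec)
  })
}

#' True nearest-neighbor distances from the emitted ground truth
#'
#' Computes, from the emitted centroids (not the construction records), the
#' k-th nearest neighbor distance of every `from`-channel cluster to the
#' `to`-channel clusters by a full all-pairs ranking.
#'
#' @param truth a [GroundTruth-class].
#' @param from reference channel (centers); defaults to the spec's reference.
#' @param to neighbor channel; defaults to the spec's target.
#' @param k neighbor rank (default 1).
#' @return numeric vector, one distance (nm) per `from` cluster; `NA` where
#'   fewer than `k` neighbors exist.
#' @export
trueNeighborDistances <- function(truth, from = NULL, to = NULL, k = 1L) {
  cl <- truth@clusters
  if (is.null(from)) from <- truth@spec@referenceChannel
  if (is.null(to)) to <- truth@spec@targetChannel
  B <- as.matrix(cl[cl$channel == from, c("x_nm", "y_nm")])
  A <- as.matrix(cl[cl$channel == to, c("x_nm", "y_nm")])
  if (!nrow(B)) return(numeric(0))
  if (!nrow(A)) return(rep(NA_real_, nrow(B)))
  dm <- crossDist(B, A)
  as.numeric(apply(dm, 1, function(r)
    if (length(r) >= k) sort(r)[k] else NA_real_))
}

#' Render a ground-truth scene to a multi-channel image
#'
#' Each cluster is rendered as an isotropic Gaussian of FWHM `psfFWHM` at its
#' true centroid with a per-cluster amplitude drawn uniformly from
#' `ampRange`; a constant background, optional Poisson shot noise and
#' Gaussian read noise are added, and the image is quantized to the requested
#' bit depth.  Channels are rendered independently.
#'
#' @param truth a [GroundTruth-class]; all centroids must lie in the field.
#' @param rp a [RenderParams-class].
#' @param imageId identifier stored in the image.
#' @param quantize round and clip to the bit depth (set `FALSE` to obtain the
#'   noiseless continuous intensity, e.g. for linearity checks).
#' @return A [StedImage-class] of dimension `ceiling(fieldSize/pixelSize)`.
#' @examples
#' gt <- makeScene(sceneSpec(nAZ = 3, seed = 2))
#' img <- renderSted(gt, renderParams(noiseSD = 0))
#' @export
renderSted <- function(truth, rp = renderParams(), imageId = "img1",
                       quantize = TRUE) {
  validObject(rp)
  spec <- truth@spec
  ps <- spec@pixelSize
  nx <- as.integer(ceiling(spec@fieldSize[1] / ps))
  ny <- as.integer(ceiling(spec@fieldSize[2] / ps))
  sigma <- fwhmToSigma(rp@psfFWHM)
  cl <- truth@clusters
  maxval <- 2^rp@bitDepth - 1
  arr <- array(0, dim = c(ny, nx, length(spec@channels)))
  withr::with_seed(childSeed(spec@seed, paste0("render:", imageId)), {
    for (ci in seq_along(spec@channels)) {
      mat <- matrix(rp@background, ny, nx)
      sub <- cl[cl$channel == spec@channels[ci], , drop = FALSE]
      if (nrow(sub)) {
        amps <- runif(nrow(sub), rp@ampRange[1], rp@ampRange[2])
        w <- ceiling(4 * sigma / ps)
        for (s in seq_len(nrow(sub))) {
          cx <- sub$x_nm[s] / ps   # 0-based pixel coordinates
          cy <- sub$y_nm[s] / ps
          j0 <- max(1L, floor(cx) - w + 1L); j1 <- min(nx, ceiling(cx) + w + 1L)
          i0 <- max(1L, floor(cy) - w + 1L); i1 <- min(ny, ceiling(cy) + w + 1L)
          jj <- j0:j1; ii <- i0:i1
          gx <- exp(-(((jj - 1) * ps - sub$x_nm[s])^2) / (2 * sigma^2))
          gy <- exp(-(((ii - 1) * ps - sub$y_nm[s])^2) / (2 * sigma^2))
          mat[ii, jj] <- mat[ii, jj] + amps[s] * (gy %o% gx)
        }
      }
      if (rp@poissonNoise) mat[] <- rpois(length(mat), pmax(mat, 0))
      if (rp@noiseSD > 0) mat <- mat + rnorm(length(mat), 0, rp@noiseSD)
      if (quantize) mat <- pmin(pmax(round(mat), 0), maxval)
      arr[, , ci] <- mat
    }
  })
  new("StedImage", data = arr, pixelSize = ps, channels = spec@channels,
      imageId = imageId)
}
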