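#' Classify a vesicle by diameter
#'
#' Small clear vesicles are defined by a diameter between `smallLo` and
#' `smallHi` nm (inclusive), large clear vesicles by a diameter strictly
#' greater than `largeMin` nm; everything else (including the 55-60 nm gap
#' under the defaults) is unclassified.
#'
#' @param diameter vesicle diameter(s) in nm (> 0).
#' @param smallLo,smallHi inclusive small-class band in nm.
#' @param largeMin exclusive lower bound of the large class in nm.  The
#'   default is 60; some reports use 70 for large-vesicle counts, so the
#'   bound is configurable.
#' @return factor with levels `small`, `large`, `unclassified`.
#' @examples
#' classifyVesicle(c(45, 58, 75))
#' @export
classifyVesicle <- function(diameter, smallLo = 30, smallHi = 55,
                            largeMin = 60) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("diameters must be positive")
  if (!(smallLo < smallHi && smallHi <= largeMin))
    stop("need smallLo < smallHi <= largeMin")
  cls <- ifelse(diameter >= smallLo & diameter <= smallHi, "small",
         ifelse(diameter > largeMin, "large", "unclassified"))
  factor(cls, levels = c("small", "large", "unclassified"))
}

#' Docked-vesicle density of one active zone
#'
#' A vesicle is docked when its membrane distance does not exceed
#' `dockDistance` (the default, 0 nm, is direct membrane contact, the usual
#' criterion for high-pressure-frozen tissue).  The density is docked
#' vesicles per 100 nm of AZ length; docked large vesicles are counted
#' separately.
#'
#' @param az an [AZAnnotation-class].
#' @param dockDistance maximum membrane distance (nm) for "docked".
#' @param largeMin large-vesicle diameter bound passed to
#'   [classifyVesicle()].
#' @return list with `density` (docked per 100 nm AZ), `nDocked`,
#'   `nDockedLarge`, `azLength` and `psdLength`.
#' @examples
#' az <- new("AZAnnotation", azId = "a", animal = "m", genotype = "WT",
#'           azLength = 250, psdLength = 250,
#'           vesicles = data.frame(diameter_nm = rep(45, 5),
#'                                 membrane_distance_nm = rep(0, 5)))
#' dockedDensity(az)$density  # 2.0
#' @export
dockedDensity <- function(az, dockDistance = 0, largeMin = 60) {
  v <- az@vesicles
  docked <- v[v$membrane_distance_nm <= dockDistance, , drop = FALSE]
  nLarge <- if (nrow(docked))
    sum(classifyVesicle(docked$diameter_nm, largeMin = largeMin) == "large")
  else 0L
  list(density = 100 * nrow(docked) / az@azLength,
       nDocked = nrow(docked), nDockedLarge = nLarge,
       azLength = az@azLength, psdLength = az@psdLength)
}

#' Per-AZ quantification table for a set of annotations
#'
#' @param azs list of [AZAnnotation-class].
#' @inheritParams dockedDensity
#' @return data.frame with one row per AZ: identifiers, genotype, AZ and PSD
#'   lengths, docked counts and densities.
#' @export
emSummary <- function(azs, dockDistance = 0, largeMin = 60) {
  rows <- lapply(azs, function(az) {
    d <- dockedDensity(az, dockDistance, largeMin)
    data.frame(az_id = az@azId, animal = az@animal, genotype = az@genotype,
               az_length_nm = d$azLength, psd_length_nm = d$psdLength,
               n_docked = d$nDocked, n_docked_large = d$nDockedLarge,
               docked_per_100nm = d$density)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Frequency distribution with group mean and SEM
#'
#' Histogram with half-open bins `[lo, hi)` (the last bin closed), plus the
#' mean and standard error over the input values — the summary reported per
#' active zone in EM quantifications.
#'
#' @param values numeric vector (per-AZ measurements).
#' @param binEdges strictly increasing bin edges.
#' @return list with `counts` (named per bin), `mids`, `mean`, `sem` and `n`
#'   (number of in-range, non-missing values).  Empty input yields zero
#'   counts and `NA` mean/sem.
#' @examples
#' frequencyDistribution(c(1, 2, 3), c(0, 2, 4))$counts  # 1, 2
#' @export
frequencyDistribution <- function(values, binEdges) {
  if (any(diff(binEdges) <= 0)) stop("bin edges must be increasing")
  values <- values[!is.na(values)]
  nb <- length(binEdges) - 1L
  counts <- integer(nb)
  for (b in seq_len(nb)) {
    hi <- binEdges[b + 1L]
    counts[b] <- if (b < nb) sum(values >= binEdges[b] & values < hi)
    else sum(values >= binEdges[b] & values <= hi)
  }
  names(counts) <- paste0("[", binEdges[-length(binEdges)], ",",
                          binEdges[-1], ifelse(seq_len(nb) < nb, ")", "]"))
  list(counts = counts,
       mids = (binEdges[-1] + binEdges[-length(binEdges)]) / 2,
       mean = if (length(values)) mean(values) else NA_real_,
       sem = sem(values),
       n = length(values))
}
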