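#' All-pairs Euclidean distance matrix between two channels
#'
#' Entry `(i, j)` is the Euclidean distance in nm between the i-th reference
#' (channel B) centroid and the j-th neighbor (channel A) centroid, i.e. the
#' matrix is `n_B x n_A`.  Channel B plays the reference/center role in all
#' downstream summaries.
#'
#' @param A neighbor channel: a [ClusterMap-class] or a 2-column matrix of
#'   centroids in nm.
#' @param B reference channel, same types.
#' @return numeric matrix `n_B x n_A`; empty (zero-row or zero-column) when
#'   either side has no clusters, with attribute `empty = TRUE` set.
#' @examples
#' pairwiseDistances(cbind(300, 400), cbind(0, 0))  # 500
#' @export
pairwiseDistances <- function(A, B) {
  coords <- function(x) {
    if (is(x, "ClusterMap")) as.matrix(x@clusters[, c("x_nm", "y_nm")])
    else as.matrix(x)
  }
  a <- coords(A); b <- coords(B)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    dm <- matrix(numeric(0), nrow(b), nrow(a))
    attr(dm, "empty") <- TRUE
    return(dm)
  }
  crossDist(b, a)
}

#' Per-reference k-nearest-neighbor distances
#'
#' For each reference cluster (matrix row), sorts its distances in ascending
#' order and reports the k-th values, k = 1..`kMax`.  In self-mode (same
#' channel against itself) the zero self-distance is excluded exactly once
#' per row before ranking.  References with fewer than k neighbors get `NA`
#' at that k.
#'
#' @param dm distance matrix from [pairwiseDistances()] (`n_B x n_A`).
#' @param kMax largest neighbor rank.
#' @param excludeSelf logical; set `TRUE` when `dm` was computed from a
#'   channel against itself (requires a square matrix with a zero diagonal
#'   ordering, i.e. identical cluster order on both axes).
#' @return numeric matrix `n_B x kMax` of d_k values in nm.
#' @export
knnDistances <- function(dm, kMax = 5L, excludeSelf = FALSE) {
  nB <- nrow(dm); nA <- ncol(dm)
  out <- matrix(NA_real_, nB, kMax,
                dimnames = list(NULL, paste0("d", seq_len(kMax))))
  if (nB == 0L) return(out)
  for (i in seq_len(nB)) {
    r <- dm[i, ]
    if (excludeSelf) {
      if (nA != nB) stop("excludeSelf requires a square self distance matrix")
      r <- r[-i]
    }
    r <- sort(r)
    kk <- min(kMax, length(r))
    if (kk > 0) out[i, seq_len(kk)] <- r[seq_len(kk)]
  }
  out
}

#' Mean k-nearest-neighbor distances
#'
#' Averages the per-reference d_k of [knnDistances()] over reference
#' clusters.  Missing d_k (references with fewer than k neighbors) are
#' dropped from the mean rather than counted as zero.
#'
#' @inheritParams knnDistances
#' @return named numeric vector `d1..dkMax` of mean distances in nm (`NA`
#'   where no reference had k neighbors).
#' @examples
#' dm <- pairwiseDistances(rbind(c(0, 0), c(300, 0)), cbind(100, 0))
#' knnSummary(dm, kMax = 2)  # d1 = 100, d2 = 200
#' @export
knnSummary <- function(dm, kMax = 5L, excludeSelf = FALSE) {
  dk <- knnDistances(dm, kMax, excludeSelf)
  if (nrow(dk) == 0L)
    return(setNames(rep(NA_real_, kMax), paste0("d", seq_len(kMax))))
  colMeans(dk, na.rm = TRUE)
}

#' Mean cumulative and interval neighbor counts
#'
#' For each reference cluster, counts neighbors within each cumulative
#' distance threshold (distance <= threshold) and in the successive
#' intervals between thresholds, then averages over all reference clusters
#' (including those with zero neighbors).
#'
#' @param dm distance matrix from [pairwiseDistances()].
#' @param thresholds strictly increasing cumulative distance thresholds in
#'   nm; the defaults are the sampling distances 50-300 nm.
#' @param excludeSelf as in [knnDistances()].
#' @return list with `cumulative` (named mean counts at each threshold) and
#'   `interval` (named mean counts per interval; the first interval is
#'   0-threshold1).  The interval means sum to the last cumulative mean.
#' @export
intervalCounts <- function(dm, thresholds = c(50, 75, 100, 125, 150, 200, 300),
                           excludeSelf = FALSE) {
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  nB <- nrow(dm)
  cumNames <- paste0("le", thresholds)
  intNames <- paste0(c(0, thresholds[-length(thresholds)]), "-", thresholds)
  if (nB == 0L)
    return(list(cumulative = setNames(rep(NA_real_, length(thresholds)), cumNames),
                interval = setNames(rep(NA_real_, length(thresholds)), intNames)))
  cum <- matrix(0, nB, length(thresholds))
  for (i in seq_len(nB)) {
    r <- dm[i, ]
    if (excludeSelf) {
      if (ncol(dm) != nB) stop("excludeSelf requires a square self distance matrix")
      r <- r[-i]
    }
    cum[i, ] <- vapply(thresholds, function(th) sum(r <= th), numeric(1))
  }
  cumMean <- colMeans(cum)
  intMean <- c(cumMean[1], diff(cumMean))
  list(cumulative = setNames(cumMean, cumNames),
       interval = setNames(intMean, intNames))
}

#' Diameter of a circular active zone of given area
#'
#' @param area area in square micrometers (> 0).
#' @return diameter in nm, rounded to the nearest integer:
#'   `round(2000 * sqrt(area / pi))`.
#' @examples
#' azDiameterFromArea(0.12)  # 391
#' @export
azDiameterFromArea <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0)) stop("area must be > 0")
  round(2000 * sqrt(area / pi))
}

#' Neighbors within one active-zone diameter
#'
#' Counts, per reference cluster, the neighbors strictly closer than the
#' assumed AZ diameter (d_k < diameter).  With the 391 nm default this is
#' the proxy used to estimate how many clusters of a protein fit in a
#' single active zone.
#'
#' @param d a distance matrix (rows = references) or a numeric vector of
#'   distances from one reference.
#' @param diameter AZ diameter in nm (> 0); 391 nm corresponds to the 0.12
#'   square-micrometer ultrastructural AZ area.
#' @param excludeSelf as in [knnDistances()].
#' @return For a matrix: integer vector of per-reference counts with
#'   attributes `mean` and `mode`; for a vector: a single count.
#' @examples
#' clustersWithinAZ(c(50, 120, 200, 380, 420))  # 4
#' @export
clustersWithinAZ <- function(d, diameter = 391, excludeSelf = FALSE) {
  if (diameter <= 0) stop("diameter must be > 0")
  if (is.matrix(d)) {
    n <- nrow(d)
    cnt <- integer(n)
    for (i in seq_len(n)) {
      r <- d[i, ]
      if (excludeSelf) r <- r[-i]
      cnt[i] <- sum(r < diameter)
    }
    attr(cnt, "mean") <- mean(cnt)
    tab <- table(cnt)
    attr(cnt, "mode") <- as.integer(names(tab)[which.max(tab)])
    cnt
  } else {
    sum(d < diameter)
  }
}

#' Full per-image neighbor summary between two channels
#'
#' Convenience wrapper combining [pairwiseDistances()], [knnSummary()] and
#' [intervalCounts()] into a [NeighborSummary-class].
#'
#' @param A neighbor-channel [ClusterMap-class] (clusters counted/ranked).
#' @param B reference-channel [ClusterMap-class] (centers); pass the same
#'   object as `A` for a self comparison (the self-distance is excluded).
#' @param kMax largest neighbor rank.
#' @param thresholds cumulative distance thresholds in nm.
#' @param imageId identifier; defaults to the image id of `A`.
#' @return A [NeighborSummary-class].
#' @export
neighborSummary <- function(A, B, kMax = 5L,
                            thresholds = c(50, 75, 100, 125, 150, 200, 300),
                            imageId = NULL) {
  self <- identical(A, B)
  dm <- pairwiseDistances(A, B)
  ks <- knnSummary(dm, kMax, excludeSelf = self)
  ic <- intervalCounts(dm, thresholds, excludeSelf = self)
  if (is.null(imageId))
    imageId <- if (is(A, "ClusterMap")) A@imageId else "img1"
  chA <- if (is(A, "ClusterMap")) A@channel else "A"
  chB <- if (is(B, "ClusterMap")) B@channel else "B"
  new("NeighborSummary", imageId = imageId, channelA = chA, channelB = chB,
      nA = ncol(dm), nB = nrow(dm), meanDk = ks,
      cumulative = ic$cumulative, interval = ic$interval)
}
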