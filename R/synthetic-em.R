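#' Generate synthetic electron-microscopy active-zone annotations
#'
#' Emulates the tabular output of manual EM annotation: per active zone an
#' AZ length, a PSD length, and a vesicle list with diameters drawn from a
#' two-component mixture (a small-vesicle mode around 30-55 nm and a rare
#' large-vesicle mode above 60 nm) and membrane distances.  Docked vesicles
#' (membrane distance 0) arrive at a stated linear density along the AZ, so
#' the downstream density estimate can be checked by parameter recovery.
#'
#' @param nAZ number of active zones.
#' @param dockedRate mean docked vesicles per 100 nm of AZ; docked counts are
#'   Poisson with mean `dockedRate * azLength / 100`.
#' @param dockedCount optional integer forcing the exact docked count per AZ
#'   (overrides `dockedRate`).
#' @param azLengthMean,azLengthSD AZ length distribution (nm, truncated > 50).
#' @param psdLengthMean,psdLengthSD PSD length distribution (nm, truncated > 50).
#' @param undockedMean mean number of non-docked vesicles per AZ (Poisson);
#'   their membrane distances are uniform on 5-200 nm.
#' @param smallDiamMean,smallDiamSD small-vesicle diameter mode (nm).
#' @param largeFraction fraction of vesicles in the large mode.
#' @param largeDiamMean,largeDiamSD large-vesicle diameter mode (nm).
#' @param genotype,animal labels stored in each annotation; `animal` is
#'   recycled over AZs.
#' @param seed integer seed.
#' @return list of [AZAnnotation-class].
#' @details Vesicle diameters are truncated to the open interval (20, 100)
#'   nm by resampling, the support the annotation format assumes.
#' @examples
#' azs <- makeEmSample(20, dockedRate = 1.2, seed = 3)
#' mean(vapply(azs, function(a) dockedDensity(a)$density, numeric(1)))
#' @export
makeEmSample <- function(nAZ, dockedRate = 1.2, dockedCount = NULL,
                         azLengthMean = 250, azLengthSD = 50,
                         psdLengthMean = 250, psdLengthSD = 50,
                         undockedMean = 8, smallDiamMean = 42,
                         smallDiamSD = 5, largeFraction = 0.05,
                         largeDiamMean = 72, largeDiamSD = 4,
                         genotype = "WT", animal = "m1", seed = 1L) {
  if (azLengthMean <= 0 || psdLengthMean <= 0)
    stop("AZ and PSD lengths must be positive")
  if (dockedRate < 0) stop("dockedRate must be >= 0")
  truncNorm <- function(n, mean, sd, lo, hi) {
    x <- rnorm(n, mean, sd)
    bad <- which(x <= lo | x >= hi)
    while (length(bad)) {
      x[bad] <- rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] <= lo | x[bad] >= hi]
    }
    x
  }
  drawDiameters <- function(n) {
    if (n == 0L) return(numeric(0))
    isLarge <- runif(n) < largeFraction
    d <- numeric(n)
    if (any(!isLarge))
      d[!isLarge] <- truncNorm(sum(!isLarge), smallDiamMean, smallDiamSD, 20, 100)
    if (any(isLarge))
      d[isLarge] <- truncNorm(sum(isLarge), largeDiamMean, largeDiamSD, 20, 100)
    d
  }
  animal <- rep(animal, length.out = nAZ)
  withr::with_seed(childSeed(seed, "em"), {
    lapply(seq_len(nAZ), function(i) {
      azl <- truncNorm(1, azLengthMean, azLengthSD, 50, Inf)
      psd <- truncNorm(1, psdLengthMean, psdLengthSD, 50, Inf)
      nd <- if (!is.null(dockedCount)) as.integer(dockedCount) else
        rpois(1, dockedRate * azl / 100)
      nu <- rpois(1, undockedMean)
      ves <- data.frame(
        diameter_nm = drawDiameters(nd + nu),
        membrane_distance_nm = c(rep(0, nd), runif(nu, 5, 200)))
      new("AZAnnotation", azId = sprintf("az%04d", i), animal = animal[i],
          genotype = genotype, azLength = azl, psdLength = psd,
          vesicles = ves)
    })
  })
}
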