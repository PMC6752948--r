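#' Hierarchical aggregation of a study table
#'
#' Values are first averaged within each parent unit (image or culture) and
#' the parent means then averaged within each animal, reproducing the
#' "averaged per image, then per animal" reporting convention.  Missing
#' values are skipped; permuting row order never changes the result.
#'
#' @param df data.frame with columns `unit`, `parent`, `animal`, `group`,
#'   `metric`, `value`.
#' @return data.frame with one row per (animal, group, metric) holding the
#'   animal-level mean.
#' @examples
#' d <- data.frame(unit = 1:2, parent = c("i1", "i2"), animal = "m1",
#'                 group = "WT", metric = "x", value = c(2, 4))
#' aggregateStudy(d)$value  # 3
#' @export
aggregateStudy <- function(df) {
  need <- c("unit", "parent", "animal", "group", "metric", "value")
  stopifnot(all(need %in% names(df)))
  if (anyDuplicated(df[, c("unit", "metric")]))
    stop("duplicate (unit, metric) rows")
  perParent <- aggregate(value ~ metric + group + animal + parent, df, mean,
                         na.rm = TRUE)
  perAnimal <- aggregate(value ~ metric + group + animal, perParent, mean,
                         na.rm = TRUE)
  perAnimal[order(perAnimal$metric, perAnimal$group, perAnimal$animal), ,
            drop = FALSE]
}

#' Flag extreme outliers (Q3 + 3 IQR rule)
#'
#' Flags values strictly greater than Q3 + 3 IQR, the SPSS "extreme value"
#' criterion; the symmetric lower-tail rule (< Q1 - 3 IQR) is available but
#' off by default, matching the one-sided exclusion convention.  Quartiles
#' use linear interpolation of order statistics (R quantile type 7).
#'
#' @param x numeric vector (>= 4 values; fewer yields no flags and a
#'   warning).
#' @param lower also flag the lower tail.
#' @return logical vector of flags, with attributes `q1`, `q3`, `iqr` and
#'   `upperBound`.
#' @examples
#' extremeOutlierFlags(c(1, 2, 3, 4, 100))  # flags only the 100
#' @export
extremeOutlierFlags <- function(x, lower = FALSE) {
  flags <- rep(FALSE, length(x))
  ok <- !is.na(x)
  if (sum(ok) < 4L) {
    warning("fewer than 4 values: no outlier flagging")
    return(flags)
  }
  q <- quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  up <- q[2] + 3 * iqr
  flags[ok] <- x[ok] > up
  if (lower) flags[ok] <- flags[ok] | x[ok] < q[1] - 3 * iqr
  attr(flags, "q1") <- q[1]
  attr(flags, "q3") <- q[2]
  attr(flags, "iqr") <- iqr
  attr(flags, "upperBound") <- up
  flags
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness statistic and the Anscombe-Glynn
#' kurtosis statistic into the K2 omnibus statistic, referred to a
#' chi-squared distribution with 2 degrees of freedom.  Requires at least 8
#' observations; below that the statistic is unreliable and the caller
#' should fall back to a nonparametric branch.
#'
#' @param x numeric vector (n >= 8).
#' @return list with `statistic` (K2), `p`, `z.skew`, `z.kurt`, `n`.
#' @export
dagostinoPearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance")
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2
  ## skewness (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  ## kurtosis (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xx * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- z1^2 + z2^2
  list(statistic = K2, p = pchisq(K2, df = 2, lower.tail = FALSE),
       z.skew = z1, z.kurt = z2, n = n)
}

#' Dunn's rank-based post hoc test
#'
#' Pairwise z tests on mean ranks after a Kruskal-Wallis comparison, with
#' the usual tie correction.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @param method p-value adjustment passed to [stats::p.adjust()]
#'   (`"none"` by default).
#' @return data.frame with one row per group pair: `group1`, `group2`, `z`,
#'   `p`, `p.adj`.
#' @export
dunnTest <- function(values, groups, method = "none") {
  ok <- !is.na(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  N <- length(values)
  rk <- rank(values)
  glev <- unique(groups)
  Rbar <- tapply(rk, groups, mean)
  nG <- tapply(rk, groups, length)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(glev, 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    sig <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / nG[[i]] + 1 / nG[[j]]))
    z <- (Rbar[[i]] - Rbar[[j]]) / sig
    data.frame(group1 = i, group2 = j, z = z, p = 2 * pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  out$p.adj <- stats::p.adjust(out$p, method = method)
  rownames(out) <- NULL
  out
}

#' Compare groups with the assay-specific test-selection rule
#'
#' Applies the declared decision rule per data type:
#' * `"imaging"`: pairwise Mann-Whitney U tests, always.
#' * `"autapse"`: D'Agostino-Pearson normality per group; all normal (and
#'   all n >= 8): one-way ANOVA with Tukey post hoc; otherwise
#'   Kruskal-Wallis with Dunn post hoc.  Groups with n < 8 force the
#'   nonparametric branch with a warning (the normality test is unreliable
#'   there).
#' * `"em"`: two groups; both normal: Welch's unpaired t test; otherwise
#'   Mann-Whitney U.
#'
#' The test computations delegate to standard routines
#' ([stats::wilcox.test()], [stats::aov()], [stats::kruskal.test()], ...);
#' the selection logic is the implemented contract.
#'
#' @param values numeric vector of per-unit values (animals for imaging,
#'   cells for autapses, active zones for EM).
#' @param groups group label per value (>= 2 groups, none empty).
#' @param assay `"imaging"`, `"autapse"` or `"em"`.
#' @param metric name of the compared quantity.
#' @param alpha significance threshold.
#' @param nUnit what one n counts (documentation only; printed in reports).
#' @return A [GroupComparison-class].
#' @examples
#' compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("WT", "KO"), each = 3),
#'               assay = "imaging")
#' @export
compareGroups <- function(values, groups,
                          assay = c("imaging", "autapse", "em"),
                          metric = "metric", alpha = 0.05,
                          nUnit = c(imaging = "animals", autapse = "cells",
                                    em = "active zones")) {
  assay <- match.arg(assay)
  ok <- !is.na(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  glev <- unique(groups)
  if (length(glev) < 2L) stop("need at least 2 groups")
  nG <- table(groups)[glev]
  if (any(nG == 0)) stop("empty group")
  summ <- data.frame(
    group = glev,
    n = as.integer(nG),
    mean = as.numeric(tapply(values, groups, mean)[glev]),
    sem = as.numeric(tapply(values, groups, sem)[glev]))
  notes <- sprintf("n counts %s; quartile/summary values are mean +/- SEM",
                   nUnit[[assay]])
  posthoc <- data.frame()
  if (assay == "imaging") {
    pairs <- utils::combn(glev, 2)
    rows <- apply(pairs, 2, function(pr) {
      w <- suppressWarnings(wilcox.test(values[groups == pr[1]],
                                        values[groups == pr[2]]))
      data.frame(group1 = pr[1], group2 = pr[2],
                 U = unname(w$statistic), p = w$p.value)
    })
    posthoc <- do.call(rbind, rows)
    test <- "Mann-Whitney U"
    statistic <- posthoc$U[1]
    p <- min(posthoc$p)
  } else if (assay == "autapse") {
    small <- any(nG < 8)
    normal <- !small && all(vapply(glev, function(g)
      dagostinoPearson(values[groups == g])$p > alpha, logical(1)))
    if (small) {
      warning("group with n < 8: defaulting to the nonparametric branch")
      notes <- c(notes, "normality gate skipped (n < 8)")
    } else {
      notes <- c(notes, sprintf("D'Agostino-Pearson gate: %s",
                                if (normal) "normal" else "not normal"))
    }
    if (normal) {
      fit <- aov(values ~ factor(groups))
      an <- summary(fit)[[1]]
      test <- "one-way ANOVA + Tukey"
      statistic <- an[1, "F value"]
      p <- an[1, "Pr(>F)"]
      tk <- TukeyHSD(fit)[[1]]
      posthoc <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                            p.adj = tk[, "p adj"], row.names = NULL)
    } else {
      kw <- kruskal.test(values, factor(groups))
      test <- "Kruskal-Wallis + Dunn"
      statistic <- unname(kw$statistic)
      p <- kw$p.value
      posthoc <- dunnTest(values, groups)
    }
  } else { # em
    if (length(glev) != 2L) stop("EM rule compares exactly 2 groups")
    canGate <- all(nG >= 8)
    normal <- canGate && all(vapply(glev, function(g)
      dagostinoPearson(values[groups == g])$p > alpha, logical(1)))
    if (!canGate) {
      warning("group with n < 8: defaulting to Mann-Whitney")
      notes <- c(notes, "normality gate skipped (n < 8)")
    } else {
      notes <- c(notes, sprintf("D'Agostino-Pearson gate: %s",
                                if (normal) "normal" else "not normal"))
    }
    if (normal) {
      tt <- t.test(values[groups == glev[1]], values[groups == glev[2]],
                   var.equal = FALSE)
      test <- "Welch t"
      statistic <- unname(tt$statistic)
      p <- tt$p.value
    } else {
      w <- suppressWarnings(wilcox.test(values[groups == glev[1]],
                                        values[groups == glev[2]]))
      test <- "Mann-Whitney U"
      statistic <- unname(w$statistic)
      p <- w$p.value
    }
  }
  new("GroupComparison", metric = metric, assay = assay, groups = glev,
      summary = summ, test = test, statistic = as.numeric(statistic),
      p = as.numeric(p), posthoc = posthoc, alpha = alpha, notes = notes)
}

#' Percent change of a value relative to a reference
#'
#' Reporting helper, e.g. for expressing how much farther apart two cluster
#' species sit at one synapse type than at another.
#'
#' @param value,reference numeric.
#' @return `100 * (value / reference - 1)`.
#' @examples
#' percentChange(174, 115)  # ~51
#' @export
percentChange <- function(value, reference) 100 * (value / reference - 1)
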