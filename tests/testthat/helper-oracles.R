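# Independent brute-force oracles used to check the vectorized implementations.

# all-pairs distances by explicit double loop
oracleDistances <- function(b, a) {
  dm <- matrix(NA_real_, nrow(b), nrow(a))
  for (i in seq_len(nrow(b)))
    for (j in seq_len(nrow(a)))
      dm[i, j] <- sqrt((b[i, 1] - a[j, 1])^2 + (b[i, 2] - a[j, 2])^2)
  dm
}

# mean d_k by full sort per row
oracleKnn <- function(dm, kMax) {
  vals <- sapply(seq_len(kMax), function(k) {
    dk <- apply(dm, 1, function(r) {
      r <- sort(r)
      if (length(r) >= k) r[k] else NA_real_
    })
    mean(dk, na.rm = TRUE)
  })
  setNames(vals, paste0("d", seq_len(kMax)))
}

# mean cumulative / interval counts by explicit histogram per row
oracleCounts <- function(dm, thresholds) {
  cum <- t(apply(dm, 1, function(r)
    sapply(thresholds, function(th) sum(r <= th))))
  if (nrow(dm) == 1L) cum <- matrix(cum, nrow = 1)
  cumMean <- colMeans(cum)
  list(cumulative = cumMean, interval = c(cumMean[1], diff(cumMean)))
}

# exact two-sided Mann-Whitney p for tiny samples by exhaustive enumeration
# of all group-label arrangements
oracleMannWhitneyP <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  Uobs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combs <- utils::combn(n + m, n)
  Us <- apply(combs, 2, function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  mu <- n * m / 2
  mean(abs(Us - mu) >= abs(Uobs - mu))
}

# closed-form sum of two Gaussians, for line-profile oracles
twoGaussians <- function(x, p1, p2, amp, sigma, background = 0) {
  background + amp * exp(-(x - p1)^2 / (2 * sigma^2)) +
    amp * exp(-(x - p2)^2 / (2 * sigma^2))
}

# a tiny rendered scene shared by segmentation tests
tinyScene <- function(nAZ = 6, dTrue = 500, jitterSD = 0, seed = 42,
                      fieldUm = 8) {
  sceneSpec(fieldSize = c(fieldUm, fieldUm) * 1000, nAZ = nAZ,
            dTrue = dTrue, jitterSD = jitterSD, seed = seed)
}
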