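## internal helpers

# Deterministic child seed derived from a top-level seed and a stream tag,
# kept inside the 32-bit integer range.
childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

# sigma (nm) of the Gaussian spot model from its FWHM
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# mean +/- sem helpers
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# trapezoidal integral of y over x
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# euclidean distance between rows of two 2-column matrices (nm)
crossDist <- function(b, a) {
  # returns n_b x n_a matrix
  dx <- outer(b[, 1], a[, 1], "-")
  dy <- outer(b[, 2], a[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

stopifnotScalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}
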