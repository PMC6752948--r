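## index range of a time window [t0, t1] within a trace (closed)
windowIdx <- function(trace, t0, t1) {
  tt <- traceTimes(trace)
  which(tt >= t0 & tt <= t1)
}

#' Evoked EPSC amplitude
#'
#' Baseline is the mean current in a window before the stimulus; the peak is
#' the extremum (in the response polarity) within a search window after the
#' stimulus; the amplitude is the absolute difference between the mean of
#' the samples within +/- `peakAvgMs` of the peak and the baseline.
#' Baseline subtraction makes the measure invariant to DC offsets.
#'
#' @param trace a [Trace-class].
#' @param stimTime stimulus time in s (defaults to the trace's first).
#' @param polarity `"negative"` (inward EPSC, default) or `"positive"`.
#' @param baselineMs pre-stimulus baseline window length in ms.
#' @param searchMs post-stimulus peak search window in ms.
#' @param peakAvgMs half-width (ms) of the averaging window around the peak.
#' @param baselineValue optional externally supplied baseline (pA); when
#'   given, the pre-stimulus window is not used.
#' @return amplitude in pA (positive).  Attribute `edge` is `TRUE` when the
#'   peak lies at the search-window boundary (flagged, not an error);
#'   attribute `peakTime` gives the peak time in s.
#' @export
evokedAmplitude <- function(trace, stimTime = NULL,
                            polarity = c("negative", "positive"),
                            baselineMs = 5, searchMs = 20, peakAvgMs = 2,
                            baselineValue = NULL) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "negative") -1 else 1
  if (is.null(stimTime)) {
    if (!length(trace@stimTimes)) stop("no stimulus time available")
    stimTime <- trace@stimTimes[1]
  }
  tt <- traceTimes(trace)
  if (is.null(baselineValue)) {
    bi <- windowIdx(trace, stimTime - baselineMs / 1000, stimTime)
    bi <- bi[tt[bi] < stimTime]
    if (!length(bi)) stop("no pre-stimulus baseline window available")
    baselineValue <- mean(trace@current[bi])
  }
  si <- windowIdx(trace, stimTime, stimTime + searchMs / 1000)
  if (!length(si)) stop("search window outside trace")
  resp <- sgn * (trace@current[si] - baselineValue)
  pk <- which.max(resp)
  edge <- pk == 1L || pk == length(resp)
  peakTime <- tt[si[pk]]
  ai <- windowIdx(trace, peakTime - peakAvgMs / 1000,
                  peakTime + peakAvgMs / 1000)
  amp <- abs(mean(trace@current[ai]) - baselineValue)
  attr(amp, "edge") <- edge
  attr(amp, "peakTime") <- peakTime
  amp
}

#' Evoked EPSC charge
#'
#' Integrates the baseline-subtracted response (in the response polarity,
#' negative excursions clipped at zero) from the stimulus until the current
#' first returns to baseline after the peak, capped at `maxDurS`.
#'
#' @inheritParams evokedAmplitude
#' @param maxDurS integration cap in s.
#' @return charge in pC (pA * s).
#' @export
epscCharge <- function(trace, stimTime = NULL,
                       polarity = c("negative", "positive"),
                       baselineMs = 5, maxDurS = 0.5) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "negative") -1 else 1
  if (is.null(stimTime)) {
    if (!length(trace@stimTimes)) stop("no stimulus time available")
    stimTime <- trace@stimTimes[1]
  }
  tt <- traceTimes(trace)
  bi <- windowIdx(trace, stimTime - baselineMs / 1000, stimTime)
  bi <- bi[tt[bi] < stimTime]
  if (!length(bi)) stop("no pre-stimulus baseline window available")
  base <- mean(trace@current[bi])
  ii <- windowIdx(trace, stimTime, stimTime + maxDurS)
  resp <- pmax(sgn * (trace@current[ii] - base), 0)
  pk <- which.max(resp)
  zero <- which(resp[-seq_len(pk)] <= 0)
  if (length(zero)) {
    end <- pk + zero[1]
    resp <- resp[seq_len(end)]
    ii <- ii[seq_len(end)]
  }
  trapezoid(tt[ii], resp)
}

#' Paired-pulse ratio
#'
#' Ratio of the second to the first evoked amplitude.  At short
#' inter-stimulus intervals the second response rides on the decay of the
#' first; by default that decay is estimated by a single-exponential fit to
#' the inter-stimulus segment and subtracted before the second amplitude is
#' measured (`second = "decay"`).  `second = "baseline"` measures both
#' pulses against the pre-train baseline.  `sliceMode` first averages the
#' supplied sweeps (including possible failures) and then measures the
#' average trace.
#'
#' @param trace a [Trace-class] with two stimulus times, or (in slice mode)
#'   a list of such traces.
#' @param second how to handle the second-pulse baseline (see above).
#' @param sliceMode average the sweeps first, then measure.
#' @param polarity response polarity.
#' @param ... passed to [evokedAmplitude()].
#' @return the ratio amp2/amp1; `NA` with a warning when amp1 is 0.
#' @examples
#' tr <- makeTraces("paired", pprFactor = 1.5, seed = 1)$traces[[1]]
#' pairedPulseRatio(tr)
#' @export
pairedPulseRatio <- function(trace, second = c("decay", "baseline"),
                             sliceMode = FALSE,
                             polarity = c("negative", "positive"), ...) {
  second <- match.arg(second)
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "negative") -1 else 1
  if (sliceMode) trace <- averageTraces(trace)
  if (length(trace@stimTimes) < 2L) stop("need two stimulus times")
  s1 <- trace@stimTimes[1]; s2 <- trace@stimTimes[2]
  a1 <- evokedAmplitude(trace, s1, polarity, ...)
  tt <- traceTimes(trace)
  bi <- windowIdx(trace, s1 - 5 / 1000, s1)
  base <- mean(trace@current[bi[tt[bi] < s1]])
  if (second == "decay") {
    ## fit a * exp(-(t - tpk)/tau) to the inter-stimulus decay and subtract
    pkT <- attr(a1, "peakTime")
    fi <- windowIdx(trace, pkT + 0.002, s2 - 1 / trace@samplingRate)
    r <- sgn * (trace@current[fi] - base)
    ok <- r > 0
    a2 <- NA_real_
    if (sum(ok) >= 5) {
      fit <- try(stats::lm(log(r[ok]) ~ tt[fi][ok]), silent = TRUE)
      if (!inherits(fit, "try-error") && stats::coef(fit)[2] < 0) {
        co <- stats::coef(fit)
        pred <- function(t) exp(co[1] + co[2] * t)
        ii <- windowIdx(trace, s2, s2 + 0.02)
        corrected <- sgn * (trace@current[ii] - base) - pred(tt[ii])
        pk <- which.max(corrected)
        ai <- windowIdx(trace, tt[ii[pk]] - 0.002, tt[ii[pk]] + 0.002)
        a2 <- mean(sgn * (trace@current[ai] - base) - pred(tt[ai]))
      }
    }
    if (is.na(a2))  # decay not fittable (e.g. already back at baseline)
      a2 <- as.numeric(evokedAmplitude(trace, s2, polarity,
                                       baselineValue = base, ...))
  } else {
    a2 <- as.numeric(evokedAmplitude(trace, s2, polarity,
                                     baselineValue = base, ...))
  }
  if (a1 == 0) {
    warning("first amplitude is zero: PPR undefined")
    return(NA_real_)
  }
  as.numeric(a2) / as.numeric(a1)
}

#' Readily-releasable-pool charge from a sucrose application
#'
#' The steady-state current is estimated as the mean over the final 10% of
#' the application window; the transient component is the steady-state-
#' subtracted current in the response polarity (negative contributions
#' clipped at zero) and its trapezoidal integral over the window is the RRP
#' charge.  Subtracting the steady state makes the measure invariant to DC
#' shifts.
#'
#' @param trace a [Trace-class].
#' @param window `c(t0, t1)` in s; defaults to the trace's `"sucrose"`
#'   window.  The canonical application length is 5 s.
#' @param polarity response polarity.
#' @return charge in pC.
#' @examples
#' tr <- makeTraces("sucrose", chargePC = 400, seed = 1)$traces[[1]]
#' rrpCharge(tr)
#' @export
rrpCharge <- function(trace, window = NULL,
                      polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "negative") -1 else 1
  if (is.null(window)) {
    if (is.null(trace@windows$sucrose)) stop("no sucrose window available")
    window <- trace@windows$sucrose
  }
  dur <- length(trace@current) / trace@samplingRate
  if (window[1] < 0 || window[2] > dur) stop("window exceeds trace")
  ii <- windowIdx(trace, window[1], window[2])
  tt <- traceTimes(trace)[ii]
  x <- trace@current[ii]
  ssIdx <- tt >= window[2] - 0.1 * diff(window)
  steady <- mean(x[ssIdx])
  transient <- pmax(sgn * (x - steady), 0)
  trapezoid(tt, transient)
}

#' Vesicular release probability
#'
#' @param epscCharge evoked EPSC charge in pC.
#' @param rrpCharge sucrose RRP charge in pC (> 0).
#' @return the ratio; `NA` with a warning when `rrpCharge` is not positive.
#' @examples
#' pvr(20, 400)  # 0.05
#' @export
pvr <- function(epscCharge, rrpCharge) {
  out <- ifelse(rrpCharge > 0, epscCharge / rrpCharge, NA_real_)
  if (any(!is.na(rrpCharge) & rrpCharge <= 0))
    warning("nonpositive RRP charge: Pvr undefined")
  out
}

#' Percent inhibition and inclusion gate
#'
#' Percent inhibition of synaptic transmission by an agonist (e.g. DCG IV),
#' with the inclusion flag for the criterion that only cells inhibited by at
#' least `threshold` percent are analyzed.
#'
#' @param ampBefore,ampAfter evoked amplitudes before/after application
#'   (`ampBefore` must be > 0).
#' @param threshold inclusion threshold in percent (inclusive).
#' @return list with `pct` and `include`.
#' @examples
#' percentInhibition(1000, 200)  # 80%, included
#' @export
percentInhibition <- function(ampBefore, ampAfter, threshold = 70) {
  if (any(ampBefore <= 0)) stop("ampBefore must be > 0")
  pct <- 100 * (1 - ampAfter / ampBefore)
  list(pct = pct, include = pct >= threshold)
}

#' Frequency facilitation and mossy-fiber identity gate
#'
#' Facilitation is the 1 Hz mean amplitude expressed as a percentage of the
#' low-frequency (0.05 Hz) mean amplitude; inputs are identified as mossy
#' fiber when facilitation strictly exceeds `threshold` percent.
#'
#' @param meanAmpLow mean amplitude at 0.05 Hz stimulation (> 0).
#' @param meanAmp1Hz mean amplitude at 1 Hz stimulation.
#' @param threshold identity threshold in percent (strict).
#' @return list with `pct` and `isMF`.
#' @examples
#' frequencyFacilitation(1, 5)  # 500%, MF
#' @export
frequencyFacilitation <- function(meanAmpLow, meanAmp1Hz, threshold = 400) {
  if (any(meanAmpLow <= 0)) stop("baseline amplitude must be > 0")
  pct <- 100 * meanAmp1Hz / meanAmpLow
  list(pct = pct, isMF = pct > threshold)
}

#' Failure rate over a set of sweeps
#'
#' A sweep fails when its evoked amplitude is below the detection threshold;
#' the default threshold is 3 times the baseline noise sd of each sweep
#' (estimated from the pre-stimulus window).
#'
#' @param traces list of [Trace-class] single-stimulus sweeps (canonically
#'   30).
#' @param detectThreshold absolute amplitude threshold in pA; `NULL` uses
#'   3 x baseline sd per sweep.
#' @param ... passed to [evokedAmplitude()].
#' @return failure fraction in `[0, 1]`, with attribute `nFailures`.
#' @export
failureRate <- function(traces, detectThreshold = NULL, ...) {
  stopifnot(length(traces) >= 1)
  fails <- vapply(traces, function(tr) {
    amp <- evokedAmplitude(tr, ...)
    thr <- detectThreshold
    if (is.null(thr)) {
      s <- tr@stimTimes[1]
      tt <- traceTimes(tr)
      bi <- which(tt >= s - 0.005 & tt < s)
      thr <- 3 * stats::sd(tr@current[bi])
      if (!is.finite(thr) || thr == 0) thr <- .Machine$double.eps
    }
    as.numeric(amp) < thr
  }, logical(1))
  out <- mean(fails)
  attr(out, "nFailures") <- sum(fails)
  out
}

#' Normalize per-cell values to the per-culture control mean
#'
#' Each value is divided by the mean of the control-group values of its own
#' culture, so control means become 1 by construction and cultures are
#' comparable despite day-to-day variability.
#'
#' @param df data.frame with columns `culture`, `group`, `value`.
#' @param controlGroup name of the control group.
#' @return `df` with an added `normalized` column.
#' @examples
#' d <- data.frame(culture = "c1", group = c("WT", "WT", "KO"),
#'                 value = c(2, 4, 3))
#' normalizeToControl(d, "WT")$normalized  # 2/3, 4/3, 1
#' @export
normalizeToControl <- function(df, controlGroup = "WT") {
  stopifnot(all(c("culture", "group", "value") %in% names(df)))
  ctrlMeans <- tapply(df$value[df$group == controlGroup],
                      df$culture[df$group == controlGroup], mean,
                      na.rm = TRUE)
  missing <- setdiff(unique(df$culture), names(ctrlMeans))
  if (length(missing))
    stop("culture(s) without control cells: ", paste(missing, collapse = ", "))
  df$normalized <- df$value / as.numeric(ctrlMeans[as.character(df$culture)])
  df
}
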