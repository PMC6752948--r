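## Difference-of-exponentials EPSC kernel, normalized to unit peak.
## tauRise/tauDecay in s; t in s relative to stimulus onset (0 before).
epscKernel <- function(t, tauRise = 5e-4, tauDecay = 5e-3) {
  tpk <- tauRise * tauDecay / (tauDecay - tauRise) * log(tauDecay / tauRise)
  norm <- exp(-tpk / tauDecay) - exp(-tpk / tauRise)
  k <- ifelse(t >= 0, (exp(-t / tauDecay) - exp(-t / tauRise)) / norm, 0)
  k
}

#' Generate synthetic current traces with known ground truth
#'
#' Emulates autaptic voltage-clamp recordings for the protocols the
#' analysis supports.  Evoked EPSCs are inward (negative) difference-of-
#' exponential currents at the stimulus times; the hypertonic-sucrose
#' response is a decaying transient of known analytic charge plus a steady
#' state.  The true amplitudes/charges are returned alongside the traces.
#'
#' @param protocol one of:
#'   * `"paired"`: two stimuli `isiMs` apart; the second amplitude is
#'     `amplitude * pprFactor`.
#'   * `"sucrose"`: a 5 s application window containing a transient of
#'     analytic charge `chargePC` (pC) plus steady state `steadyPA`.
#'   * `"train"`: `trainN` stimuli at `trainHz`, amplitudes depressing
#'     geometrically by `depression` per stimulus.
#'   * `"dcg"`: two single-stimulus sweeps, the second scaled by
#'     `1 - inhibitionPct/100` (agonist application).
#'   * `"failures"`: `nSweeps` single-stimulus sweeps of which a fraction
#'     `failureFraction` have zero evoked response.
#' @param amplitude first evoked amplitude in pA (reported positive; the
#'   rendered current is negative-going).
#' @param pprFactor paired-pulse ratio of the generated amplitudes.
#' @param isiMs inter-stimulus interval (ms) for `"paired"`.
#' @param chargePC analytic transient charge (pC) for `"sucrose"`.
#' @param sucroseTau transient decay time constant (s).
#' @param steadyPA steady-state current during the sucrose window (pA,
#'   positive magnitude of the inward component).
#' @param trainHz,trainN train frequency (Hz) and stimulus count.
#' @param depression per-stimulus geometric depression factor for `"train"`.
#' @param inhibitionPct percent inhibition for the `"dcg"` after-sweep.
#' @param nSweeps,failureFraction sweep count and failing fraction for
#'   `"failures"`.
#' @param tauRise,tauDecay EPSC kernel time constants (s).
#' @param samplingRate sampling rate in Hz (must be >= 10 kHz).
#' @param noiseSD Gaussian current noise sd in pA.
#' @param baselinePA constant holding-current offset in pA.
#' @param seed integer seed.
#' @return list with elements `traces` (list of [Trace-class]) and `truth`
#'   (list of the generating parameters actually realized, e.g. per-stimulus
#'   amplitudes, the analytic charge, the failing sweep indices).
#' @examples
#' tr <- makeTraces("paired", pprFactor = 1.5, noiseSD = 0, seed = 1)
#' pairedPulseRatio(tr$traces[[1]])
#' @export
makeTraces <- function(protocol = c("paired", "sucrose", "train", "dcg",
                                    "failures"),
                       amplitude = 2000, pprFactor = 1.0, isiMs = 25,
                       chargePC = 400, sucroseTau = 0.5, steadyPA = 100,
                       trainHz = 10, trainN = 50, depression = 0.95,
                       inhibitionPct = 80, nSweeps = 30,
                       failureFraction = 0.2, tauRise = 5e-4,
                       tauDecay = 5e-3, samplingRate = 10000, noiseSD = 0,
                       baselinePA = 0, seed = 1L) {
  protocol <- match.arg(protocol)
  if (samplingRate < 10000) stop("samplingRate must be at least 10 kHz")
  dt <- 1 / samplingRate
  mkTrace <- function(duration, stims, amps, windows = list(), extra = 0) {
    t <- seq(0, duration - dt, by = dt)
    if (length(stims) && any(stims < 0 | stims >= duration))
      stop("stimulus outside trace")
    cur <- rep(baselinePA, length(t)) + extra
    for (i in seq_along(stims))
      cur <- cur - amps[i] * epscKernel(t - stims[i], tauRise, tauDecay)
    if (noiseSD > 0) cur <- cur + rnorm(length(t), 0, noiseSD)
    new("Trace", current = cur, samplingRate = samplingRate,
        stimTimes = stims, windows = windows, meta = list())
  }
  withr::with_seed(childSeed(seed, paste0("traces:", protocol)), {
    switch(protocol,
      paired = {
        isi <- isiMs / 1000
        stims <- c(0.1, 0.1 + isi)
        amps <- c(amplitude, amplitude * pprFactor)
        list(traces = list(mkTrace(0.1 + isi + 0.4, stims, amps)),
             truth = list(amplitudes = amps, ppr = pprFactor))
      },
      sucrose = {
        dur <- 7
        t <- seq(0, dur - dt, by = dt)
        t0 <- 1; t1 <- t0 + 5
        A <- chargePC / sucroseTau        # pA such that integral = chargePC
        cur <- rep(baselinePA, length(t))
        inwin <- t >= t0 & t < t1
        cur[inwin] <- cur[inwin] - steadyPA -
          A * exp(-(t[inwin] - t0) / sucroseTau)
        if (noiseSD > 0) cur <- cur + rnorm(length(t), 0, noiseSD)
        tr <- new("Trace", current = cur, samplingRate = samplingRate,
                  stimTimes = numeric(0),
                  windows = list(sucrose = c(t0, t1)), meta = list())
        list(traces = list(tr),
             truth = list(chargePC = chargePC, steadyPA = steadyPA,
                          tau = sucroseTau))
      },
      train = {
        stims <- 0.1 + (seq_len(trainN) - 1) / trainHz
        amps <- amplitude * depression^(seq_len(trainN) - 1)
        dur <- max(stims) + 0.3
        list(traces = list(mkTrace(dur, stims, amps)),
             truth = list(amplitudes = amps, stimTimes = stims))
      },
      dcg = {
        ampAfter <- amplitude * (1 - inhibitionPct / 100)
        list(traces = list(before = mkTrace(0.5, 0.1, amplitude),
                           after = mkTrace(0.5, 0.1, ampAfter)),
             truth = list(before = amplitude, after = ampAfter,
                          inhibitionPct = inhibitionPct))
      },
      failures = {
        nf <- round(nSweeps * failureFraction)
        fails <- sort(sample.int(nSweeps, nf))
        traces <- lapply(seq_len(nSweeps), function(i) {
          a <- if (i %in% fails) 0 else amplitude
          mkTrace(0.5, 0.1, a)
        })
        list(traces = traces,
             truth = list(failingSweeps = fails,
                          failureRate = nf / nSweeps))
      })
  })
}

#' Pointwise average of a set of traces
#'
#' Used by the slice-mode paired-pulse analysis, which first averages the
#' evoked sweeps (including possible failures) and then measures the average
#' trace.
#'
#' @param traces list of [Trace-class] with identical length, sampling rate
#'   and stimulus times.
#' @return a [Trace-class].
#' @export
averageTraces <- function(traces) {
  stopifnot(length(traces) >= 1)
  n <- vapply(traces, function(tr) length(tr@current), integer(1))
  if (length(unique(n)) != 1L) stop("traces must have equal length")
  cur <- rowMeans(vapply(traces, function(tr) tr@current,
                         numeric(n[1])))
  new("Trace", current = cur, samplingRate = traces[[1]]@samplingRate,
      stimTimes = traces[[1]]@stimTimes, windows = traces[[1]]@windows,
      meta = traces[[1]]@meta)
}
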