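test_that("evoked amplitude: flat trace, DC invariance, attenuation bound", {
  flat <- new("Trace", current = rep(-50, 5000), samplingRate = 10000,
              stimTimes = 0.1, windows = list(), meta = list())
  expect_equal(as.numeric(evokedAmplitude(flat)), 0)

  tr <- makeTraces("paired", amplitude = 2000, pprFactor = 1, noiseSD = 0,
                   seed = 1)$traces[[1]]
  a <- evokedAmplitude(tr)
  shifted <- tr
  shifted@current <- tr@current + 123.4
  expect_equal(as.numeric(evokedAmplitude(shifted)), as.numeric(a),
               tolerance = 1e-9)

  # the +/-2 ms averaging window attenuates a sharp EPSC by a factor given
  # by the kernel's closed form; the measurement must land inside that bound
  dt <- 1 / 10000
  tg <- seq(-0.005, 0.05, by = dt)
  k <- ifelse(tg >= 0, exp(-tg / 5e-3) - exp(-tg / 5e-4), 0)
  k <- k / max(k)
  pk <- which.max(k)
  win <- (pk - 20):(pk + 20)
  atten <- mean(k[win])
  expect_gt(as.numeric(a), 2000 * atten * 0.99)
  expect_lt(as.numeric(a), 2000 * 1.001)
})

test_that("paired-pulse ratio recovers the generator factor", {
  # widely spaced pulses: decay has fully relaxed
  tr <- makeTraces("paired", pprFactor = 1.5, isiMs = 300, noiseSD = 0,
                   seed = 2)$traces[[1]]
  expect_equal(pairedPulseRatio(tr), 1.5, tolerance = 0.01)
  # short 25 ms interval: second response rides on the first's decay
  tr25 <- makeTraces("paired", pprFactor = 1.5, isiMs = 25, noiseSD = 0,
                     seed = 2)$traces[[1]]
  expect_equal(pairedPulseRatio(tr25), 1.5, tolerance = 0.03)
  # identical pulses
  tr1 <- makeTraces("paired", pprFactor = 1, isiMs = 300, noiseSD = 0,
                    seed = 3)$traces[[1]]
  expect_equal(pairedPulseRatio(tr1), 1.0, tolerance = 0.01)
})

test_that("slice-mode PPR on averaged sweeps equals the analytic mean trace", {
  sweeps <- lapply(1:20, function(i)
    makeTraces("paired", pprFactor = 1.3, isiMs = 50, noiseSD = 0,
               seed = 4)$traces[[1]])
  avg <- averageTraces(sweeps)
  expect_equal(traceCurrent(avg), traceCurrent(sweeps[[1]]), tolerance = 1e-12)
  expect_equal(pairedPulseRatio(sweeps, sliceMode = TRUE),
               pairedPulseRatio(sweeps[[1]]), tolerance = 1e-12)
})

test_that("RRP charge matches the analytic transient integral", {
  su <- makeTraces("sucrose", chargePC = 400, steadyPA = 100, noiseSD = 0,
                   seed = 5)
  q <- rrpCharge(su$traces[[1]])
  expect_equal(q, 400, tolerance = 0.02 * 400)
  flat <- new("Trace", current = rep(-20, 70000), samplingRate = 10000,
              stimTimes = numeric(0), windows = list(sucrose = c(1, 6)),
              meta = list())
  expect_equal(rrpCharge(flat), 0)
  shifted <- su$traces[[1]]
  shifted@current <- shifted@current - 200
  expect_equal(rrpCharge(shifted), q, tolerance = 1e-9)
  expect_error(rrpCharge(flat, window = c(1, 100)), "exceeds")
})

test_that("Pvr, inhibition and facilitation gates behave at the boundaries", {
  expect_equal(pvr(20, 400), 0.05)
  expect_equal(pvr(400, 400), 1.0)
  expect_warning(v <- pvr(10, 0), "undefined")
  expect_true(is.na(v))

  pi1 <- percentInhibition(1000, 200)
  expect_equal(pi1$pct, 80); expect_true(pi1$include)
  pi2 <- percentInhibition(1000, 400)
  expect_equal(pi2$pct, 60); expect_false(pi2$include)
  pi3 <- percentInhibition(1000, 300)
  expect_true(pi3$include)                # exactly 70%: "70% or more"
  expect_true(percentInhibition(1000, 0)$include)
  expect_error(percentInhibition(0, 10), "> 0")

  ff <- frequencyFacilitation(1, 5)
  expect_equal(ff$pct, 500); expect_true(ff$isMF)
  expect_false(frequencyFacilitation(1, 4)$isMF)   # exactly 400%: strict
  expect_false(frequencyFacilitation(1, 1)$isMF)
  expect_error(frequencyFacilitation(0, 1), "> 0")
})

test_that("failure rate counts sweeps without a detectable EPSC", {
  flat <- lapply(1:30, function(i)
    new("Trace", current = rep(0, 5000), samplingRate = 10000,
        stimTimes = 0.1, windows = list(), meta = list()))
  expect_equal(as.numeric(failureRate(flat)), 1.0)
  clear <- makeTraces("failures", failureFraction = 0, nSweeps = 30,
                      noiseSD = 2, seed = 6)
  expect_equal(as.numeric(failureRate(clear$traces)), 0.0)
  mixed <- makeTraces("failures", failureFraction = 0.2, nSweeps = 30,
                      noiseSD = 2, seed = 7)
  fr <- failureRate(mixed$traces)
  expect_equal(as.numeric(fr), 0.2)
  expect_identical(attr(fr, "nFailures"), 6L)
})

test_that("amplitude recovery is unbiased under noise", {
  amps <- vapply(1:50, function(i) {
    tr <- makeTraces("paired", amplitude = 2000, pprFactor = 1, isiMs = 300,
                     noiseSD = 20, seed = 100 + i)$traces[[1]]
    as.numeric(evokedAmplitude(tr))
  }, numeric(1))
  # compare against the noiseless measurement (the averaging-window
  # attenuation applies to both)
  tr0 <- makeTraces("paired", amplitude = 2000, pprFactor = 1, isiMs = 300,
                    noiseSD = 0, seed = 1)$traces[[1]]
  a0 <- as.numeric(evokedAmplitude(tr0))
  se <- sd(amps) / sqrt(length(amps))
  expect_lt(abs(mean(amps) - a0), 3 * se)
})

test_that("per-culture control normalization", {
  d <- data.frame(culture = "c1", group = c("WT", "WT", "KO"),
                  value = c(2, 4, 3))
  nd <- normalizeToControl(d, "WT")
  expect_equal(nd$normalized, c(2 / 3, 4 / 3, 1))
  one <- data.frame(culture = "c1", group = "WT", value = 7)
  expect_equal(normalizeToControl(one, "WT")$normalized, 1)

  set.seed(8)
  big <- data.frame(culture = rep(c("c1", "c2", "c3"), each = 10),
                    group = rep(c("WT", "KO"), 15),
                    value = runif(30, 1, 5))
  nb <- normalizeToControl(big, "WT")
  for (cc in unique(big$culture)) {
    ctrl <- mean(big$value[big$culture == cc & big$group == "WT"])
    idx <- big$culture == cc
    expect_equal(nb$normalized[idx], big$value[idx] / ctrl)
  }
  bad <- data.frame(culture = c("c1", "c2"), group = c("WT", "KO"),
                    value = 1:2)
  expect_error(normalizeToControl(bad, "WT"), "c2")
})
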