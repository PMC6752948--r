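test_that("paired target clusters sit at the requested distance", {
  sp <- sceneSpec(nAZ = 1, azCenters = matrix(c(2000, 2000), 1),
                  fieldSize = c(4000, 4000), dTrue = 100, jitterSD = 0,
                  seed = 3)
  gt <- makeScene(sp)
  cl <- clusterTable(gt)
  expect_identical(sum(cl$role == "target"), 1L)
  ref <- cl[cl$role == "reference", ]
  tgt <- cl[cl$role == "target", ]
  d <- sqrt((ref$x_nm - tgt$x_nm)^2 + (ref$y_nm - tgt$y_nm)^2)
  expect_equal(d, 100)

  sp0 <- sceneSpec(nAZ = 1, azCenters = matrix(c(2000, 2000), 1),
                   fieldSize = c(4000, 4000), dTrue = 0, jitterSD = 0,
                   seed = 3)
  cl0 <- clusterTable(makeScene(sp0))
  expect_equal(cl0$x_nm[cl0$role == "reference"],
               cl0$x_nm[cl0$role == "target"])
  expect_equal(cl0$y_nm[cl0$role == "reference"],
               cl0$y_nm[cl0$role == "target"])
})

test_that("sample mean of true NN distances matches the generating distance", {
  gt <- makeScene(sceneSpec(nAZ = 200, dTrue = 174, jitterSD = 20, seed = 1))
  pd <- clusterTable(gt)$pair_d_nm
  pd <- pd[!is.na(pd)]
  expect_length(pd, 200)
  # recompute the mean directly from the emitted ground truth
  expect_lt(abs(mean(pd) - 174), 3 * 20 / sqrt(200))
  # and the construction distances agree with brute-force NN on centroids
  nn <- trueNeighborDistances(gt, k = 1)
  expect_equal(sort(nn), sort(pd), tolerance = 1e-12)
})

test_that("scenes, images, annotations and traces are deterministic under a seed", {
  sp <- sceneSpec(nAZ = 10, dTrue = 150, jitterSD = 15, seed = 9)
  g1 <- makeScene(sp); g2 <- makeScene(sp)
  expect_identical(clusterTable(g1), clusterTable(g2))
  i1 <- renderSted(g1); i2 <- renderSted(g2)
  expect_identical(stedData(i1), stedData(i2))
  p1 <- makeSideviewProfiles(3, 184, noiseSD = 0.05, seed = 5)
  p2 <- makeSideviewProfiles(3, 184, noiseSD = 0.05, seed = 5)
  expect_identical(p1[[2]]@intensities, p2[[2]]@intensities)
  e1 <- makeEmSample(5, seed = 4); e2 <- makeEmSample(5, seed = 4)
  expect_identical(vesicleTable(e1[[3]]), vesicleTable(e2[[3]]))
  t1 <- makeTraces("paired", noiseSD = 5, seed = 8)
  t2 <- makeTraces("paired", noiseSD = 5, seed = 8)
  expect_identical(traceCurrent(t1$traces[[1]]), traceCurrent(t2$traces[[1]]))
})

test_that("rendering: background, argmax position, two-spot profile, linearity", {
  sp <- sceneSpec(nAZ = 1, azCenters = matrix(c(1500, 1500), 1),
                  fieldSize = c(3000, 3000), clustersPerAZ = 0,
                  dTrue = 0, jitterSD = 0, seed = 2)
  # strip all clusters -> pure background
  gt <- makeScene(sp)
  gt@clusters <- gt@clusters[0, , drop = FALSE]
  img <- renderSted(gt, renderParams(noiseSD = 0, background = 10))
  expect_true(all(stedData(img) == 10))

  # single cluster: brightest pixel contains the centroid
  sp1 <- sceneSpec(nAZ = 1, azCenters = matrix(c(1500, 1500), 1),
                   fieldSize = c(3000, 3000), dTrue = 300, jitterSD = 0,
                   seed = 6)
  gt1 <- makeScene(sp1)
  img1 <- renderSted(gt1, renderParams(noiseSD = 0))
  cl <- clusterTable(gt1)
  for (ch in channelNames(img1)) {
    mat <- stedChannel(img1, ch)
    am <- arrayInd(which.max(mat), dim(mat))
    truep <- cl[cl$channel == ch, ]
    expect_equal((am[2] - 1), round(truep$x_nm / pixelSize(img1)))
    expect_equal((am[1] - 1), round(truep$y_nm / pixelSize(img1)))
  }

  # two clusters 300 nm apart: profile along the connecting line has exactly
  # two local maxima, as the closed-form Gaussian sum predicts
  sigma <- 50 / (2 * sqrt(2 * log(2)))
  x <- seq(-100, 400, by = 1)
  closed <- twoGaussians(x, 0, 300, 200, sigma)
  nmax <- sum(diff(sign(diff(closed))) == -2)
  expect_identical(nmax, 2L)
  ref <- cl[cl$role == "reference", ]; tgt <- cl[cl$role == "target", ]
  # render both spots into one channel by relabeling the target
  gt2 <- gt1
  gt2@clusters$channel <- channelNames(img1)[1]
  img2 <- renderSted(gt2, renderParams(noiseSD = 0, ampRange = c(200, 200)))
  u <- c(tgt$x_nm - ref$x_nm, tgt$y_nm - ref$y_nm) / 300
  prof <- extractProfile(stedChannel(img2, 1),
                         rbind(c(ref$x_nm, ref$y_nm) - 150 * u,
                               c(tgt$x_nm, tgt$y_nm) + 150 * u),
                         thicknessPx = 1, pixelSize = pixelSize(img2))
  pk <- findPeaks(prof, minProminence = 0.05)
  expect_length(pk@positions, 2L)

  # linearity: doubling the amplitude doubles noiseless pre-clip values
  rpa <- renderParams(noiseSD = 0, background = 0, ampRange = c(100, 100))
  rpb <- renderParams(noiseSD = 0, background = 0, ampRange = c(200, 200))
  a <- renderSted(gt1, rpa, quantize = FALSE)
  b <- renderSted(gt1, rpb, quantize = FALSE)
  expect_equal(stedData(b), 2 * stedData(a), tolerance = 1e-12)
})

test_that("side-view profiles: peak placement, resolvability error, alignment", {
  expect_error(makeSideviewProfiles(1, separation = 20), "resolvability")
  pr <- makeSideviewProfiles(1, separation = 505, noiseSD = 0, seed = 1)[[1]]
  y <- pr@intensities[, 1]
  ord <- order(y, decreasing = TRUE)
  idx <- sort(ord[1:2])
  expect_identical(diff(idx), 20L)
  expect_equal(diff(attr(pr, "peaks")), 505)
})

test_that("EM sample generator honors docking parameters and errors", {
  expect_error(makeEmSample(2, azLengthMean = -5), "positive")
  azs0 <- makeEmSample(10, dockedRate = 0, seed = 2)
  expect_true(all(vapply(azs0, function(a) dockedDensity(a)$nDocked,
                         numeric(1)) == 0))
  az5 <- makeEmSample(1, dockedCount = 5, azLengthMean = 250, azLengthSD = 0,
                      seed = 2)[[1]]
  expect_equal(dockedDensity(az5)$density, 2.0)
  # diameters stay inside the supported range
  azs <- makeEmSample(50, seed = 7)
  d <- unlist(lapply(azs, function(a) vesicleTable(a)$diameter_nm))
  expect_true(all(d > 20 & d < 100))
})

test_that("trace generator: PPR factor, analytic sucrose charge, bad stimulus", {
  tr1 <- makeTraces("paired", pprFactor = 1.0, noiseSD = 0, seed = 1)
  expect_equal(tr1$truth$amplitudes[2] / tr1$truth$amplitudes[1], 1.0)
  su <- makeTraces("sucrose", chargePC = 250, steadyPA = 0, noiseSD = 0,
                   seed = 1)
  tr <- su$traces[[1]]
  # analytic integral of the transient equals the charge parameter
  tt <- traceTimes(tr)
  w <- tr@windows$sucrose
  ii <- tt >= w[1] & tt <= w[2]
  num <- -sum(diff(tt[ii]) * (tr@current[ii][-1] +
                              tr@current[ii][-sum(ii)]) / 2)
  expect_equal(num, 250 * (1 - exp(-5 / su$truth$tau)), tolerance = 1e-3)
  expect_error(new("Trace", current = rep(0, 100), samplingRate = 10000,
                   stimTimes = 0.5, windows = list(), meta = list()),
               "within the record")
})
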