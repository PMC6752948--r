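test_that("thresholding handles absolute values, blocks and degenerate masks", {
  img <- matrix(10, 20, 20)
  expect_warning(m <- thresholdImage(img, 11), "all-false")
  expect_false(any(maskMatrix(m)))
  expect_warning(m2 <- thresholdImage(img, 5), "all-true")
  expect_true(all(maskMatrix(m2)))

  blocks <- matrix(0, 20, 20)
  blocks[6:10, 3:12] <- 100
  mb <- thresholdImage(blocks, 50)
  expect_identical(maskMatrix(mb), blocks == 100)
})

test_that("automatic threshold keeps true spot centroids inside the mask", {
  gt <- makeScene(tinyScene(nAZ = 2))
  img <- renderSted(gt, renderParams(noiseSD = 0))
  cl <- clusterTable(gt)
  for (ch in channelNames(img)) {
    m <- thresholdImage(img, "otsu", channel = ch)
    mm <- maskMatrix(m)
    sub <- cl[cl$channel == ch, ]
    i <- round(sub$y_nm / pixelSize(img)) + 1
    j <- round(sub$x_nm / pixelSize(img)) + 1
    expect_true(all(mm[cbind(i, j)]))
  }
})

test_that("watershed recovers well-separated spots with sub-pixel centroids", {
  gt <- makeScene(tinyScene(nAZ = 6, dTrue = 500))
  img <- renderSted(gt, renderParams(noiseSD = 0))
  cl <- clusterTable(gt)
  ps <- pixelSize(img)
  for (ch in channelNames(img)) {
    cm <- segmentChannel(img, ch, threshold = 40)
    tab <- clusterTable(cm)
    truep <- cl[cl$channel == ch, ]
    expect_identical(nrow(tab), nrow(truep))
    # each true centroid has a segmented centroid within half a pixel
    for (r in seq_len(nrow(truep))) {
      d <- sqrt((tab$x_nm - truep$x_nm[r])^2 + (tab$y_nm - truep$y_nm[r])^2)
      expect_lt(min(d), ps / 2)
    }
  }
})

test_that("watershed separates two spots and tolerates an empty mask", {
  sp <- sceneSpec(nAZ = 1, azCenters = matrix(c(2000, 2000), 1),
                  fieldSize = c(4000, 4000), dTrue = 300, jitterSD = 0,
                  seed = 12)
  gt <- makeScene(sp)
  gt@clusters$channel <- channelNames(gt@spec)[1]  # both spots, one channel
  img <- renderSted(gt, renderParams(noiseSD = 0))
  m <- thresholdImage(img, 40, channel = 1)
  cm <- watershedClusters(img, m, minPeakSeparation = 100, channel = 1)
  expect_identical(nrow(clusterTable(cm)), 2L)

  suppressWarnings(empty <- thresholdImage(stedChannel(img, 1), 300))
  cm0 <- watershedClusters(stedChannel(img, 1), empty, pixelSize = 25.25)
  expect_identical(nrow(clusterTable(cm0)), 0L)
})

test_that("area filter: boundary inclusion, identity, oracle and idempotence", {
  ps <- sqrt(0.0005) * 1000                 # pixel area 0.0005 um^2
  mk <- function(counts) {
    n <- length(counts)
    new("ClusterMap", channel = "c", imageId = "i",
        clusters = data.frame(label = seq_len(n), x_nm = seq_len(n) * 20,
                              y_nm = seq_len(n) * 20,
                              area_um2 = counts * 0.0005, peak = 100,
                              pixel_count = as.integer(counts)),
        pixelSize = ps, dim = c(200L, 200L))
  }
  cm <- mk(c(2, 5, 8))                      # areas 0.001, 0.0025, 0.004
  kept <- filterByArea(cm, 0.0025)
  expect_identical(nrow(clusterTable(kept)), 2L)
  expect_true(0.0025 %in% clusterTable(kept)$area_um2)  # boundary kept
  expect_identical(clusterTable(filterByArea(cm, 0)), clusterTable(cm))
  expect_error(filterByArea(cm, -1), ">= 0")

  set.seed(77)
  counts <- sample.int(12, 100, replace = TRUE)
  cm2 <- mk(counts)
  out <- filterByArea(cm2, 0.0025)
  oracle <- which(counts * 0.0005 >= 0.0025)
  expect_identical(clusterTable(out)$label, oracle)
  # idempotent, and surviving pixel counts respect the implied minimum
  again <- filterByArea(out, 0.0025)
  expect_identical(clusterTable(again), clusterTable(out))
  expect_true(all(clusterTable(out)$pixel_count >=
                    ceiling(0.0025 / (ps / 1000)^2)))
})

test_that("region restriction uses centroid membership and checks geometry", {
  ps <- 25.25
  mkMask <- function(m) new("RegionMask", mask = m, provenance = "test",
                            threshold = NA_real_, pixelSize = ps)
  n <- 40L
  cm <- new("ClusterMap", channel = "c", imageId = "i",
            clusters = data.frame(label = 1:2,
                                  x_nm = c(0.25, 0.75) * (n - 1) * ps,
                                  y_nm = rep(0.5 * (n - 1) * ps, 2),
                                  area_um2 = 4 * (ps / 1000)^2, peak = 50,
                                  pixel_count = 4L),
            pixelSize = ps, dim = c(n, n))
  full <- mkMask(matrix(TRUE, n, n))
  expect_identical(clusterTable(restrictToRegion(cm, full)),
                   clusterTable(cm))
  left <- matrix(FALSE, n, n); left[, 1:(n / 2)] <- TRUE
  expect_identical(nrow(clusterTable(restrictToRegion(cm, mkMask(left)))), 1L)
  expect_error(restrictToRegion(cm, mkMask(matrix(TRUE, 10, 10))),
               "geometry")

  # random mask against a point-in-mask oracle
  set.seed(5)
  rnd <- matrix(runif(n * n) > 0.5, n, n)
  nc <- 50L
  cl <- data.frame(label = seq_len(nc),
                   x_nm = runif(nc, 0, (n - 1) * ps),
                   y_nm = runif(nc, 0, (n - 1) * ps),
                   area_um2 = 4 * (ps / 1000)^2, peak = 10, pixel_count = 4L)
  cmr <- new("ClusterMap", channel = "c", imageId = "i", clusters = cl,
             pixelSize = ps, dim = c(n, n))
  res <- restrictToRegion(cmr, mkMask(rnd))
  oracle <- vapply(seq_len(nc), function(r)
    rnd[round(cl$y_nm[r] / ps) + 1, round(cl$x_nm[r] / ps) + 1], logical(1))
  expect_identical(clusterTable(res)$label, cl$label[oracle])
})
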