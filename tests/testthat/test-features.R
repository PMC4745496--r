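test_that("colour fractions are channel mass over total mass", {
  # pure red region
  cf <- extractColorFractions(segmentedFixture(flatRgb(4, 4, c(255, 0, 0))))
  expect_equal(unname(cf), c(100, 0, 0))
  # uniform gray: perfect channel symmetry
  cf <- extractColorFractions(segmentedFixture(flatRgb(3, 5, c(80, 80, 80))))
  expect_equal(unname(cf), rep(100 / 3, 3))
  # hand-summed two-pixel case: (100,50,50) twice -> (50, 25, 25)
  img <- flatRgb(1, 2, c(100, 50, 50))
  cf <- extractColorFractions(segmentedFixture(img))
  expect_equal(unname(cf), c(50, 25, 25))
  # empty mask errors
  expect_error(
    extractColorFractions(segmentedFixture(flatRgb(3, 3, c(1, 2, 3)),
                                           matrix(FALSE, 3, 3))),
    class = "tvEmptyRegionError")
})

test_that("colour fractions sum to 100 on random masked images", {
  for (seed in 1:20) {
    img <- randomRgb(8, 8, seed)
    set.seed(seed + 100)
    mask <- matrix(runif(64) < 0.6, 8, 8)
    if (!any(mask)) next
    cf <- extractColorFractions(segmentedFixture(img, mask))
    expect_equal(sum(cf), 100, tolerance = 1e-9)
    expect_true(all(cf >= 0 & cf <= 100))
  }
})

test_that("local entropy is zero on constant regions and bounded above", {
  flat <- segmentedFixture(flatRgb(12, 12, c(90, 90, 90)))
  te <- textureEntropy(flat)
  expect_identical(unique(as.vector(te$entropyMap)), 0)
  expect_identical(te$minEntropy, 0)
  expect_identical(te$maxEntropy, 0)
  expect_identical(te$textureQualityCoefficient, 0)
  # bound: log2(min(levels, window^2)); checked over random images
  for (seed in 1:8) {
    img <- randomRgb(15, 15, seed)
    set.seed(seed)
    mask <- matrix(runif(225) < 0.8, 15, 15)
    if (!any(mask)) next
    te3 <- textureEntropy(segmentedFixture(img, mask), window = 3)
    expect_lte(te3$maxEntropy, log2(9) + 1e-12)
    te9 <- textureEntropy(segmentedFixture(img, mask), window = 9)
    expect_lte(te9$maxEntropy, log2(81) + 1e-12)
    teLow <- textureEntropy(segmentedFixture(img, mask), window = 9,
                            levels = 8)
    expect_lte(teLow$maxEntropy, 3 + 1e-12)
    expect_gte(min(te9$entropyMap), 0)
  }
})

test_that("a window with two equally frequent levels scores one bit", {
  # 3x3 image, one corner masked out: the centre's window holds 4 pixels
  # of each level
  v <- matrix(100, 3, 3)
  v[c(1, 3, 5, 7)] <- 200          # 4 pixels at 200, 5 at 100
  mask <- matrix(TRUE, 3, 3)
  mask[3, 3] <- FALSE              # drop one 100 -> 4 vs 4
  img <- array(rep(v, 3), dim = c(3, 3, 3))
  te <- textureEntropy(segmentedFixture(img, mask), window = 3)
  expect_equal(te$entropyMap[2, 2], 1.0)
  # coefficient is the arithmetic mean of the extrema by definition
  expect_equal(te$textureQualityCoefficient,
               (te$minEntropy + te$maxEntropy) / 2)
})

test_that("pattern-weighted area reproduces the printed weights", {
  w <- areaPatternWeights()
  expect_identical(unname(w), c(0, 1 / 4, 1 / 2, 3 / 4, 7 / 8, 1))
  expect_identical(estimateArea(matrix(FALSE, 5, 5)), 0)
  # an isolated pixel sits in four one-on windows: 4 * 1/4 = 1
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_identical(estimateArea(single), 1)
  # 30 random 6x6 images against the exhaustive enumeration oracle
  set.seed(42)
  for (i in 1:30) {
    b <- matrix(runif(36) < 0.5, 6, 6)
    expect_identical(estimateArea(b), oracleArea(b), label = paste("case", i))
  }
})

test_that("area estimate is translation invariant and monotone", {
  b <- matrix(FALSE, 10, 10)
  b[2:4, 2:5] <- TRUE; b[7, 8] <- TRUE
  shifted <- matrix(FALSE, 10, 10)
  shifted[4:6, 4:7] <- TRUE; shifted[9, 10] <- TRUE
  expect_identical(estimateArea(b), estimateArea(shifted))
  # adding an on pixel never decreases the estimate
  set.seed(3)
  cur <- matrix(FALSE, 8, 8)
  for (p in sample(64)) {
    nxt <- cur; nxt[p] <- TRUE
    expect_gte(estimateArea(nxt), estimateArea(cur))
    cur <- nxt
  }
})

test_that("sRGB <-> CIELAB conversion hits the reference points", {
  white <- rgbToLab(flatRgb(1, 1, c(255, 255, 255)))
  expect_equal(white[1, 1, 1], 100, tolerance = 1e-2)
  expect_equal(abs(white[1, 1, 2]), 0, tolerance = 0.01)
  expect_equal(abs(white[1, 1, 3]), 0, tolerance = 0.01)
  black <- rgbToLab(flatRgb(1, 1, c(0, 0, 0)))
  expect_equal(as.vector(black), c(0, 0, 0), tolerance = 1e-6)
  # round trip within one intensity unit
  img <- randomRgb(6, 6, seed = 8)
  back <- labToRgb(rgbToLab(img))
  expect_lt(max(abs(back - img)), 1)
})

test_that("k-means recovers flat chromatic patches exactly", {
  img <- array(0, dim = c(8, 8, 3))
  patch <- list(c(200, 30, 30), c(30, 200, 30), c(40, 40, 220),
                c(210, 210, 40))
  img[1:4, 1:4, ] <- rep(patch[[1]], each = 16)
  img[1:4, 5:8, ] <- rep(patch[[2]], each = 16)
  img[5:8, 1:4, ] <- rep(patch[[3]], each = 16)
  img[5:8, 5:8, ] <- rep(patch[[4]], each = 16)
  cs <- extractClusters(segmentedFixture(img), k = 4, seed = 1)
  expect_identical(nClusters(cs), 4L)
  lm <- clusterLabels(cs)
  quadrants <- list(lm[1:4, 1:4], lm[1:4, 5:8], lm[5:8, 1:4], lm[5:8, 5:8])
  labs <- vapply(quadrants, function(q) {
    expect_identical(length(unique(as.vector(q))), 1L)
    q[1, 1]
  }, 0L)
  expect_identical(sort(labs), 1:4)   # a bijection patch <-> cluster
  expect_identical(unname(clusterDescriptors(cs)$pixelCount), rep(16L, 4))
})

test_that("k-means degenerate and determinism contracts hold", {
  img <- flatRgb(5, 5, c(120, 60, 30))
  one <- extractClusters(segmentedFixture(img), k = 1, seed = 3)
  expect_equal(unname(clusterMeans(one)[1, ]),
               as.vector(rgbToLab(matrix(c(120, 60, 30), 1))),
               tolerance = 1e-8)
  # same seed twice: identical labels and means
  img2 <- randomRgb(10, 10, seed = 5)
  a <- extractClusters(segmentedFixture(img2), k = 4, seed = 9)
  b <- extractClusters(segmentedFixture(img2), k = 4, seed = 9)
  expect_identical(clusterLabels(a), clusterLabels(b))
  expect_identical(clusterMeans(a), clusterMeans(b))
  # fewer pixels than clusters errors
  tiny <- segmentedFixture(flatRgb(1, 3, c(9, 9, 9)))
  expect_error(extractClusters(tiny, k = 4), class = "tvParameterError")
})

test_that("k-means objective is non-increasing and ends at a fixed point", {
  for (seed in 1:5) {
    img <- randomRgb(12, 12, seed)
    cs <- extractClusters(segmentedFixture(img), k = 4, seed = seed)
    obj <- cs@objective
    expect_true(all(diff(obj) <= 1e-9), info = paste("seed", seed))
    # reassigning every pixel to its nearest final centroid changes nothing
    idx <- which(!is.na(clusterLabels(cs)))
    rgb <- cbind(img[, , 1][idx], img[, , 2][idx], img[, , 3][idx])
    ab <- rgbToLab(rgb)[, 2:3]
    centers <- t(vapply(seq_len(4), function(cl)
      colMeans(ab[clusterLabels(cs)[idx] == cl, , drop = FALSE]),
      numeric(2)))
    d2 <- outer(rowSums(ab^2), rowSums(centers^2), "+") - 2 * ab %*% t(centers)
    expect_identical(max.col(-d2, ties.method = "first"),
                     as.integer(clusterLabels(cs)[idx]))
  }
})

test_that("k-means objective is competitive with a multi-start reference", {
  for (seed in 1:3) {
    img <- randomRgb(14, 14, seed + 40)
    cs <- extractClusters(segmentedFixture(img), k = 4, seed = seed)
    ours <- min(cs@objective)
    idx <- which(!is.na(clusterLabels(cs)))
    ab <- rgbToLab(cbind(img[, , 1][idx], img[, , 2][idx],
                         img[, , 3][idx]))[, 2:3]
    set.seed(seed)
    ref <- stats::kmeans(ab, centers = 4, nstart = 10,
                         algorithm = "Lloyd", iter.max = 100)
    expect_lte(ours, 1.1 * ref$tot.withinss, label = paste("seed", seed))
  }
})
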