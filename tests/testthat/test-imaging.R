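test_that("PNG/TIFF round-trips are bit-exact and errors are typed", {
  dir <- withr::local_tempdir()
  img <- randomRgb(8, 8, seed = 7)
  for (ext in c("png", "tiff")) {
    path <- file.path(dir, paste0("x.", ext))
    writeImage(img, path)
    expect_identical(readImage(path), img * 1.0)
  }
  # tiny 2x2 case
  img2 <- flatRgb(2, 2, c(3, 200, 117))
  writeImage(img2, file.path(dir, "t.png"))
  expect_identical(readImage(file.path(dir, "t.png")), img2)
  # binary encoding contract: only {0, 255} on disk
  b <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  writeImage(b, file.path(dir, "b.png"))
  back <- readImage(file.path(dir, "b.png"))
  expect_true(all(back %in% c(0, 255)))
  expect_identical(back[, , 1] == 255, b)
  # error cases
  txt <- file.path(dir, "not_an_image.txt")
  writeLines("hello", txt)
  expect_error(readImage(txt), class = "tvIOError")
  expect_error(readImage(file.path(dir, "missing.png")),
               class = "tvIOError")
  expect_error(writeImage(img, file.path(dir, "no/such/dir/x.png")),
               class = "tvIOError")
})

test_that("grayscale reads replicate to three channels", {
  dir <- withr::local_tempdir()
  g <- randomGray(5, 4, seed = 2)
  png::writePNG(g / 255, file.path(dir, "g.png"))
  back <- readImage(file.path(dir, "g.png"))
  expect_equal(dim(back), c(5, 4, 3))
  expect_identical(back[, , 1], back[, , 3])
})

test_that("rank-order filter matches the window-sorting oracle", {
  x <- randomGray(7, 7, seed = 3)
  for (rank in 1:9)
    expect_identical(denoiseRankOrder(x, rank), oracleRankFilter(x, rank),
                     info = paste("rank", rank))
  # constant image is a fixed point for every rank
  const <- matrix(42, 6, 6)
  for (rank in c(1, 5, 9))
    expect_identical(denoiseRankOrder(const, rank), const)
  # a lone impulse is erased by the median
  imp <- const; imp[3, 4] <- 255
  expect_identical(denoiseRankOrder(imp, 5), const)
  # parameter validation
  expect_error(denoiseRankOrder(x, 0), class = "tvParameterError")
  expect_error(denoiseRankOrder(x, 10), class = "tvParameterError")
  expect_error(denoiseRankOrder(x, 3, window = 4),
               class = "tvParameterError")
})

test_that("rank-order filter is monotone in rank and preserves size", {
  for (seed in 1:5) {
    x <- randomGray(9, 9, seed)
    prev <- denoiseRankOrder(x, 1)
    for (rank in 2:9) {
      cur <- denoiseRankOrder(x, rank)
      expect_true(all(cur >= prev), info = paste("seed", seed, "rank", rank))
      expect_identical(dim(cur), dim(x))
      prev <- cur
    }
  }
  # RGB input: channels filtered independently, type preserved
  img <- randomRgb(6, 5, seed = 9)
  out <- denoiseRankOrder(img, 5)
  expect_identical(dim(out), dim(img))
  expect_identical(out[, , 2], denoiseRankOrder(img[, , 2], 5))
})

test_that("frame differencing follows the channel-sum threshold contract", {
  bg <- flatRgb(20, 20, c(10, 10, 10))
  # identical frames: empty mask, zeroed image, for any threshold
  seg <- segmentFrameDifference(bg, bg, 0)
  expect_false(any(foregroundMask(seg)))
  expect_true(all(sampleImage(seg) == 0))
  # block of intensity 200 on one channel, threshold 50
  sm <- bg
  sm[5:14, 3:12, 1] <- 200
  seg <- segmentFrameDifference(bg, sm, 50)
  want <- matrix(FALSE, 20, 20); want[5:14, 3:12] <- TRUE
  expect_identical(foregroundMask(seg), want)
  expect_identical(sampleImage(seg)[6, 4, 1], 200)
  expect_identical(sampleImage(seg)[1, 1, 1], 0)
  # strict exceedance: a 1-intensity difference only crosses threshold 0
  sm2 <- bg; sm2[7, 7, 2] <- 11
  seg0 <- segmentFrameDifference(bg, sm2, 0)
  expect_identical(which(foregroundMask(seg0)), (7L - 1L) * 20L + 7L)
  expect_false(any(foregroundMask(segmentFrameDifference(bg, sm2, 1))))
  # darker-than-background objects are found too (absolute difference)
  sm3 <- bg; sm3[2, 2, ] <- 0
  expect_true(foregroundMask(segmentFrameDifference(bg, sm3, 20))[2, 2])
  expect_error(segmentFrameDifference(bg, randomRgb(5, 5)),
               class = "tvShapeError")
})

test_that("foreground mask shrinks as the threshold grows", {
  bg <- randomRgb(15, 15, seed = 1)
  sm <- randomRgb(15, 15, seed = 2)
  prev <- foregroundMask(segmentFrameDifference(bg, sm, 0))
  for (thr in c(30, 90, 200, 400)) {
    cur <- foregroundMask(segmentFrameDifference(bg, sm, thr))
    expect_true(all(prev | !cur))   # cur subset of prev
    prev <- cur
  }
})

test_that("binarization separates levels; Otsu is near the exhaustive optimum", {
  # two-level image in equal halves
  g <- matrix(c(rep(50, 50), rep(200, 50)), 10, 10)
  b <- binarize(g, "otsu")
  thr <- attr(b, "threshold")
  expect_gt(thr, 50); expect_lt(thr, 200)
  expect_true(all(b[g == 200]) && !any(b[g == 50]))  # halves separated
  expect_identical(sum(b), 50L)
  # Otsu's pick is as good as exhaustive search (between-class variance)
  bcv <- function(gray, t) {
    g1 <- gray[gray <= t]; g2 <- gray[gray > t]
    if (!length(g1) || !length(g2)) return(0)
    length(g1) * length(g2) / length(gray)^2 * (mean(g1) - mean(g2))^2
  }
  for (seed in 1:5) {
    gr <- randomGray(12, 12, seed)
    t1 <- attr(binarize(gr, "otsu"), "threshold")
    t0 <- oracleOtsu(gr)
    expect_gte(bcv(gr, t1), 0.999 * bcv(gr, t0), label = paste("seed", seed))
  }
  # fixed thresholding
  expect_true(all(binarize(matrix(128, 4, 4), "fixed",
                           fixedThreshold = 100)))
  expect_false(any(binarize(randomGray(6, 6, 1), "fixed",
                            fixedThreshold = 255)))
  expect_error(binarize(g, "fixed"), class = "tvParameterError")
  # degenerate constant image: nothing exceeds its own level
  expect_false(any(binarize(matrix(7, 3, 3), "otsu")))
})

test_that("two-level separation holds for arbitrary level pairs", {
  set.seed(11)
  for (i in 1:10) {
    lv <- sort(sample(0:255, 2))
    if (diff(lv) < 2) next
    g <- matrix(sample(lv, 64, replace = TRUE), 8, 8)
    if (length(unique(as.vector(g))) < 2) next
    b <- binarize(g, "otsu")
    expect_true(all(b[g == lv[2]]) && !any(b[g == lv[1]]),
                label = paste(lv, collapse = "/"))
  }
})

test_that("mask cleanup keeps the single fruit-sized component", {
  m <- matrix(FALSE, 20, 20)
  m[5:14, 5:14] <- TRUE           # 100-px blob
  m[1, 1] <- TRUE; m[1, 2] <- TRUE            # 2-px speck
  m[19, 2] <- TRUE; m[20, 2] <- TRUE          # 2-px speck
  m[3, 18] <- TRUE; m[4, 18] <- TRUE          # 2-px speck
  out <- postprocessMask(m, 10)
  want <- matrix(FALSE, 20, 20); want[5:14, 5:14] <- TRUE
  expect_identical(out, want)
  # oracle agreement on the labelling underneath
  lab <- oracleComponents(m)
  sizes <- tabulate(lab[lab > 0])
  expect_identical(sort(sizes), sort(c(100L, 2L, 2L, 2L)))
  # single large component passes through unchanged
  expect_identical(postprocessMask(want, 10), want)
  # empty in, empty out
  empty <- matrix(FALSE, 5, 5)
  expect_identical(postprocessMask(empty, 10), empty)
  # all components below the floor: everything goes
  expect_false(any(postprocessMask(m & !want, 10)))
})

test_that("mask cleanup fills enclosed holes but not border-open bays", {
  m <- matrix(FALSE, 12, 12)
  m[3:10, 3:10] <- TRUE
  m[6:7, 6:7] <- FALSE            # enclosed hole
  out <- postprocessMask(m, 4)
  expect_true(all(out[3:10, 3:10]))
  # with hole filling disabled the hole persists
  out2 <- postprocessMask(m, 4, fillHoles = FALSE)
  expect_false(any(out2[6:7, 6:7]))
})

test_that("component labelling agrees with a BFS oracle and is 8-connected", {
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(runif(100) < 0.4, 10, 10)
    ours <- tomatovision:::.label_components_cpp(m)
    theirs <- oracleComponents(m)
    expect_identical(max(ours), max(theirs))
    # same partition up to label permutation
    expect_identical(ours == 0L, theirs == 0L)
    for (l in seq_len(max(ours)))
      expect_identical(length(unique(theirs[ours == l])), 1L)
  }
  diagonalPair <- matrix(FALSE, 3, 3)
  diagonalPair[1, 1] <- diagonalPair[2, 2] <- TRUE
  expect_identical(max(tomatovision:::.label_components_cpp(diagonalPair)), 1L)
})
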