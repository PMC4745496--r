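#' Colour fractions of the fruit surface
#'
#' Percentage of the total summed intensity inside the foreground mask
#' contributed by each channel: `R = 100 * sum(red) / sum(all three)`,
#' and likewise for G and B. The three fractions sum to 100 whenever the
#' masked intensity is positive. Red rises and green falls as the fruit
#' ripens, which is what the maturity grade keys on.
#'
#' @param sample a [SegmentedSample-class] with a non-empty mask.
#' @return named numeric vector `c(R =, G =, B =)` in \[0, 100\].
#' @export
extractColorFractions <- function(sample) {
  stopifnot(is(sample, "SegmentedSample"))
  mask <- sample@mask
  if (!any(mask)) stopEmpty("empty foreground mask: no fruit region")
  sums <- vapply(1:3, function(ch) sum(sample@image[, , ch][mask]), 0)
  total <- sum(sums)
  if (total == 0) {
    warning("masked region has zero intensity; returning zero fractions")
    return(c(R = 0, G = 0, B = 0))
  }
  c(R = 100 * sums[1] / total, G = 100 * sums[2] / total,
    B = 100 * sums[3] / total)
}

#' Local-entropy texture of the fruit surface
#'
#' Converts the masked image to grayscale and computes, at every
#' foreground pixel, the Shannon entropy (bits) of the gray-level
#' histogram in its `window x window` neighbourhood. Only foreground
#' pixels enter the histograms, so the zeroed background does not inject
#' an artificial gray level. The texture quality coefficient is the mean
#' of the entropy extrema over the fruit region: smooth skin scores near
#' zero, lesions and specks push the maximum up.
#'
#' @param sample a [SegmentedSample-class] with a non-empty mask.
#' @param window odd neighbourhood side, default 9.
#' @param levels gray-level count for the histogram, default 256.
#' @return list with `entropyMap` (0 outside the mask), `minEntropy`,
#'   `maxEntropy` and `textureQualityCoefficient`
#'   `= (min + max) / 2`.
#' @export
textureEntropy <- function(sample, window = 9L, levels = 256L) {
  stopifnot(is(sample, "SegmentedSample"))
  window <- as.integer(window); levels <- as.integer(levels)
  if (window < 1L || window %% 2L == 0L)
    stopParameter("window must be a positive odd integer")
  if (levels < 2L) stopParameter("levels must be >= 2")
  mask <- sample@mask
  if (!any(mask)) stopEmpty("empty foreground mask: no fruit region")
  gray <- rgbToGray(sample@image)
  bins <- matrix(pmin(as.integer(floor(gray / 256 * levels)), levels - 1L),
                 nrow(gray), ncol(gray))
  emap <- .local_entropy_cpp(bins, mask, window, levels)
  vals <- emap[mask]
  lo <- min(vals); hi <- max(vals)
  list(entropyMap = emap, minEntropy = lo, maxEntropy = hi,
       textureQualityCoefficient = (lo + hi) / 2)
}

# the six 2x2 pattern weights, keyed by on-pixel count with the
# two-diagonal case split out
areaPatternWeights <- function() {
  c(none = 0, one = 1 / 4, two_adjacent = 1 / 2, two_diagonal = 3 / 4,
    three = 7 / 8, four = 1)
}

#' Pattern-weighted area of a binary object
#'
#' Sub-pixel area estimate: the image is zero-padded by one pixel on all
#' sides so every pixel lies in exactly four 2x2 windows, and each window
#' contributes a weight by its on/off pattern -- 0 (no on pixel), 1/4
#' (one), 1/2 (two adjacent), 3/4 (two diagonal), 7/8 (three), 1 (all
#' four). The sum over windows is the area; an isolated on pixel scores
#' exactly 1.
#'
#' @param image binary matrix (logical, {0,1} or {0,255}).
#' @return non-negative scalar area in pixel units.
#' @export
estimateArea <- function(image) {
  b <- asBinaryMatrix(image)
  h <- nrow(b); w <- ncol(b)
  if (h == 0L || w == 0L || !any(b)) return(0)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- b
  tl <- p[1:(h + 1), 1:(w + 1)]
  tr <- p[1:(h + 1), 2:(w + 2)]
  bl <- p[2:(h + 2), 1:(w + 1)]
  br <- p[2:(h + 2), 2:(w + 2)]
  count <- tl + tr + bl + br
  wts <- areaPatternWeights()
  # lookup by on-pixel count, then lift the two-diagonal patterns from
  # the two-adjacent weight to their own
  byCount <- c(wts[["none"]], wts[["one"]], wts[["two_adjacent"]],
               wts[["three"]], wts[["four"]])
  diagonal <- (count == 2L) & ((tl * br + tr * bl) > 0L)
  sum(byCount[count + 1L]) +
    (wts[["two_diagonal"]] - wts[["two_adjacent"]]) * sum(diagonal)
}

#' Convert between sRGB and CIELAB
#'
#' Per-pixel conversion assuming sRGB primaries and the D65 white point;
#' L* lies in \[0, 100\]. `labToRgb()` is the inverse (clamped to
#' \[0, 255\]).
#'
#' @param image RGB array (`height x width x 3`, \[0, 255\]) or an
#'   `n x 3` matrix of RGB rows.
#' @return array or matrix of the same shape in L*, a*, b*.
#' @export
rgbToLab <- function(image) {
  if (is.matrix(image) && ncol(image) == 3L) {
    return(farver::convert_colour(image, from = "rgb", to = "lab"))
  }
  assertRgb(image)
  d <- dim(image)
  m <- matrix(image, ncol = 3L)
  lab <- farver::convert_colour(m, from = "rgb", to = "lab")
  array(lab, dim = d)
}

#' @rdname rgbToLab
#' @param lab L*a*b* array or `n x 3` matrix.
#' @export
labToRgb <- function(lab) {
  if (is.matrix(lab) && ncol(lab) == 3L) {
    m <- farver::convert_colour(lab, from = "lab", to = "rgb")
    return(pmin(pmax(m, 0), 255))
  }
  d <- dim(lab)
  m <- farver::convert_colour(matrix(lab, ncol = 3L),
                              from = "lab", to = "rgb")
  array(pmin(pmax(m, 0), 255), dim = d)
}

#' Colour clusters of the fruit surface
#'
#' k-means (Lloyd's algorithm) over the foreground pixels in CIELAB.
#' By default only the chromaticity coordinates (a*, b*) are clustered so
#' that illumination shading does not split one surface colour into
#' several clusters; `channels = "lab"` clusters all three coordinates.
#' Initial centroids are `k` distinct pixels sampled uniformly under
#' `seed`; a cluster that empties is re-seeded at the point farthest from
#' its assigned centroid. Iteration stops when no centroid moves more
#' than `tol` (Euclidean) or after `maxIter` sweeps. The run is
#' deterministic for a fixed seed.
#'
#' @param sample a [SegmentedSample-class] with at least `k` foreground
#'   pixels.
#' @param k cluster count, default 4 (one body colour plus shading and
#'   lesion clusters is what tomato surfaces need in practice).
#' @param seed RNG seed for initialisation, default 0.
#' @param maxIter iteration cap, default 300.
#' @param tol convergence tolerance on centroid movement, default 1e-4.
#' @param channels `"ab"` (default) or `"lab"`.
#' @param fitSample when the foreground holds more pixels than this, the
#'   Lloyd iterations run on a uniform subsample of this size and the
#'   resulting centroids label the full pixel set (the usual shortcut for
#'   megapixel rasters); the stored cluster means are always the
#'   centroids of the full membership. Default 20000.
#' @return a [ClusterSet-class].
#' @export
extractClusters <- function(sample, k = 4L, seed = 0L, maxIter = 300L,
                            tol = 1e-4, channels = c("ab", "lab"),
                            fitSample = 20000L) {
  stopifnot(is(sample, "SegmentedSample"))
  channels <- match.arg(channels)
  k <- as.integer(k)
  mask <- sample@mask
  idx <- which(mask)
  n <- length(idx)
  if (k < 1L) stopParameter("k must be >= 1")
  if (n < k)
    stopParameter("fewer foreground pixels (", n, ") than clusters (", k, ")")
  rgb <- foregroundRgb(sample@image, idx)
  lab <- rgbToLab(rgb)
  x <- if (channels == "ab") lab[, 2:3, drop = FALSE] else lab
  if (n > fitSample) {
    sub <- withSeed(seed + 1, sort(sample.int(n, fitSample)))
    km <- lloydKmeans(x[sub, , drop = FALSE], k, seed = seed,
                      maxIter = maxIter, tol = tol)
    km$labels <- assignToCenters(x, km$centers)
  } else {
    km <- lloydKmeans(x, k, seed = seed, maxIter = maxIter, tol = tol)
  }
  labelMap <- matrix(NA_integer_, nrow(mask), ncol(mask))
  labelMap[idx] <- km$labels
  means <- matrix(NA_real_, k, 3L,
                  dimnames = list(NULL, c("L", "a", "b")))
  for (cl in seq_len(k)) means[cl, ] <- colMeans(lab[km$labels == cl, ,
                                                     drop = FALSE])
  desc <- clusterDescriptorTable(sample, labelMap, rgb, idx, k)
  new("ClusterSet", k = k, labelMap = labelMap, means = means,
      descriptors = desc, channels = channels, objective = km$objective)
}

# n x 3 matrix of the RGB triples at linear indices `idx`
foregroundRgb <- function(image, idx) {
  planeLen <- dim(image)[1] * dim(image)[2]
  cbind(image[idx], image[idx + planeLen], image[idx + 2 * planeLen])
}

# nearest-center labels with empty-cluster repair
assignToCenters <- function(x, centers) {
  cross <- x %*% t(centers)
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * cross
  labels <- max.col(-d2, ties.method = "first")
  for (cl in seq_len(nrow(centers))) {
    if (!any(labels == cl))
      labels[which.max(d2[cbind(seq_along(labels), labels)])] <- cl
  }
  labels
}

# plain Lloyd iterations on an n x p matrix; deterministic under seed.
# Initial centroids are k distinct rows sampled uniformly; coincident
# coordinates are tolerated -- the duplicate cluster empties and the
# repair step re-seeds it at the farthest point.
lloydKmeans <- function(x, k, seed = 0L, maxIter = 300L, tol = 1e-4) {
  centers <- withSeed(seed, x[sample.int(nrow(x), k), , drop = FALSE])
  res <- .lloyd_kmeans_cpp(x, centers, as.integer(maxIter), as.numeric(tol))
  list(centers = res$centers, labels = res$labels,
       objective = res$objective)
}

clusterDescriptorTable <- function(sample, labelMap, rgb, idx, k) {
  h <- nrow(labelMap)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  labs <- labelMap[idx]
  out <- data.frame(cluster = seq_len(k), pixelCount = 0L,
                    meanR = NA_real_, meanG = NA_real_, meanB = NA_real_,
                    area = 0, rowMin = NA_integer_, rowMax = NA_integer_,
                    colMin = NA_integer_, colMax = NA_integer_)
  for (cl in seq_len(k)) {
    sel <- labs == cl
    out$pixelCount[cl] <- sum(sel)
    if (!any(sel)) next
    out$meanR[cl] <- mean(rgb[sel, 1]); out$meanG[cl] <- mean(rgb[sel, 2])
    out$meanB[cl] <- mean(rgb[sel, 3])
    out$rowMin[cl] <- min(rows[sel]); out$rowMax[cl] <- max(rows[sel])
    out$colMin[cl] <- min(cols[sel]); out$colMax[cl] <- max(cols[sel])
    # pattern-weighted area is translation invariant: evaluate on the
    # cluster's bounding box, not the whole canvas
    m <- matrix(FALSE, out$rowMax[cl] - out$rowMin[cl] + 1L,
                out$colMax[cl] - out$colMin[cl] + 1L)
    m[cbind(rows[sel] - out$rowMin[cl] + 1L,
            cols[sel] - out$colMin[cl] + 1L)] <- TRUE
    out$area[cl] <- estimateArea(m)
  }
  out
}
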