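#' Read an 8-bit image from disk
#'
#' Reads PNG, TIFF or JPEG into a `height x width x 3` numeric array with
#' intensities in \[0, 255\]. Grayscale files are replicated to three
#' channels; an alpha channel, if present, is dropped. JPEG is lossy, so
#' a warning is emitted when one is read.
#'
#' @param path file path; format is taken from the extension.
#' @return numeric `height x width x 3` array in \[0, 255\].
#' @seealso [writeImage()]
#' @export
readImage <- function(path) {
  if (!file.exists(path)) stopIO("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      warning("JPEG is lossy; round-trips are not bit-exact: ", path)
      jpeg::readJPEG(path)
    },
    stopIO("unsupported image format '", ext, "': ", path)
  ), error = function(e) {
    if (inherits(e, "tvError")) stop(e)
    stopIO("failed to read image ", path, ": ", conditionMessage(e))
  })
  if (is.matrix(raw)) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 1L)
    raw <- array(rep(raw[, , 1], 3L), dim = c(dim(raw)[1:2], 3L))
  round(raw * 255)
}

#' Write an image to disk
#'
#' Accepts an RGB array (`height x width x 3`, \[0, 255\]), a grayscale
#' matrix (\[0, 255\]) or a binary matrix (logical or {0, 1}); binary
#' images are written with on pixels at 255. PNG and TIFF round-trip
#' bit-exactly.
#'
#' @param image raster to write.
#' @param path destination; the extension selects the format.
#' @export
writeImage <- function(image, path) {
  if (!dir.exists(dirname(path)))
    stopIO("cannot write image: no such directory: ", dirname(path))
  if (is.logical(image)) image <- image * 255
  if (is.matrix(image)) {
    u <- unique(as.vector(image))
    if (all(u %in% c(0, 1)) && length(u) <= 2L && any(u == 1)) image <- image * 255
    assertGray(image)
  } else assertRgb(image)
  x <- image / 255
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
      png  = png::writePNG(x, target = path),
      tif  = ,
      tiff = tiff::writeTIFF(x, where = path, bits.per.sample = 8L),
      jpg  = ,
      jpeg = jpeg::writeJPEG(x, target = path, quality = 0.95),
      stopIO("unsupported image format '", ext, "': ", path)
    )
    TRUE
  }, error = function(e) {
    if (inherits(e, "tvError")) stop(e)
    stopIO("failed to write image ", path, ": ", conditionMessage(e))
  })
  invisible(ok)
}

#' Rank-order noise filtering
#'
#' Slides a `window x window` neighbourhood over the image and replaces
#' each pixel (per channel) with the `rank`-th smallest value in the
#' neighbourhood. Rank `ceiling(window^2 / 2)` is the median filter, the
#' default for impulse-noise removal; higher ranks remove ever more
#' low-intensity noise. Borders are reflected symmetrically so the output
#' has the input's size.
#'
#' @param image RGB array or grayscale matrix in \[0, 255\].
#' @param rank order statistic in `[1, window^2]`; default the median.
#' @param window odd neighbourhood side length, default 3.
#' @return filtered image of the same type and size.
#' @export
denoiseRankOrder <- function(image, rank = NULL, window = 3L) {
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L ||
      window %% 2L == 0L)
    stopParameter("window must be a positive odd integer")
  if (is.null(rank)) rank <- ceiling(window^2 / 2)
  rank <- as.integer(rank)
  if (length(rank) != 1L || is.na(rank) || rank < 1L || rank > window^2)
    stopParameter("rank must lie in [1, window^2] = [1, ", window^2, "]")
  if (is.matrix(image)) {
    assertGray(image)
    return(.rank_filter_cpp(image, rank, window))
  }
  assertRgb(image)
  out <- image
  for (ch in 1:3) out[, , ch] <- .rank_filter_cpp(image[, , ch], rank, window)
  out
}

#' Foreground segmentation by two-frame differencing
#'
#' The acquisition protocol captures the empty chamber (background frame)
#' and then the same scene with the fruit (sample frame). A pixel is
#' foreground iff the sum over channels of absolute intensity differences
#' exceeds `threshold`; the sample frame is returned with background
#' pixels zeroed.
#'
#' @param background,sample RGB arrays of identical size, \[0, 255\].
#' @param threshold non-negative intensity-difference threshold on the
#'   0--255 scale (summed over the three channels); default 30.
#' @return a [SegmentedSample-class].
#' @export
segmentFrameDifference <- function(background, sample, threshold = 30) {
  assertRgb(background, "background")
  assertRgb(sample, "sample")
  if (!identical(dim(background), dim(sample)))
    stopShape("background and sample frames must have identical dimensions")
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stopParameter("threshold must be a non-negative scalar")
  maskedSample(sample, frameDiffMask(background, sample, threshold),
               threshold)
}

# channel-summed absolute frame difference, thresholded
frameDiffMask <- function(background, sample, threshold) {
  diffSum <- abs(sample[, , 1] - background[, , 1]) +
             abs(sample[, , 2] - background[, , 2]) +
             abs(sample[, , 3] - background[, , 3])
  diffSum > threshold
}

# build a SegmentedSample from a raster and mask, zeroing background
maskedSample <- function(image, mask, threshold = NA_real_) {
  assertRgb(image)
  if (!identical(dim(mask), dim(image)[1:2]))
    stopShape("mask dimensions differ from image dimensions")
  img <- image * array(rep(mask, 3L), dim = dim(image))
  new("SegmentedSample", image = img, mask = mask,
      threshold = as.numeric(threshold))
}

#' Binarize a grayscale image
#'
#' Hard thresholding: a pixel is on iff its intensity strictly exceeds
#' the threshold. With `method = "otsu"` the threshold maximises Otsu's
#' between-class variance criterion over the 256 gray levels; with
#' `method = "fixed"` the caller supplies it.
#'
#' @param image grayscale matrix in \[0, 255\].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixedThreshold intensity threshold, required when
#'   `method = "fixed"`.
#' @return logical matrix (`TRUE` = on).
#' @export
binarize <- function(image, method = c("otsu", "fixed"),
                     fixedThreshold = NULL) {
  method <- match.arg(method)
  assertGray(image)
  threshold <- if (method == "fixed") {
    if (is.null(fixedThreshold))
      stopParameter("method = \"fixed\" requires fixedThreshold")
    fixedThreshold
  } else {
    if (length(unique(as.vector(image))) < 2L) {
      # degenerate: no split exists; Otsu is undefined, nothing exceeds max
      max(image)
    } else {
      EBImage::otsu(image / 255, range = c(0, 1), levels = 256L) * 255
    }
  }
  structure(image > threshold, threshold = threshold)
}

#' Remove speckle from a foreground mask
#'
#' Labels 8-connected foreground components, discards those smaller than
#' `minComponentArea`, and keeps only the largest surviving component --
#' the single fruit region the downstream features assume. With
#' `fillHoles = TRUE` (the default) enclosed background pockets inside
#' that component are folded into the foreground: a fruit silhouette is
#' simply connected, and very dark lesions can otherwise fall below the
#' frame-difference threshold and punch holes in it.
#'
#' @param mask logical matrix.
#' @param minComponentArea minimum component size in pixels; default 64.
#' @param fillHoles fill enclosed background pockets; default TRUE.
#' @return cleaned logical mask of the same size.
#' @export
postprocessMask <- function(mask, minComponentArea = 64L,
                            fillHoles = TRUE) {
  mask <- asBinaryMatrix(mask, "mask")
  if (minComponentArea < 0) stopParameter("minComponentArea must be >= 0")
  if (!any(mask)) return(mask)
  lab <- .label_components_cpp(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minComponentArea)
  if (!length(keep)) return(mask & FALSE)
  best <- keep[which.max(sizes[keep])]
  out <- lab == best
  if (fillHoles) {
    bg <- .label_components_cpp(!out)
    borderLabs <- setdiff(unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1],
                                   bg[, ncol(bg)])), 0L)
    hole <- bg > 0L & !(bg %in% borderLabs)
    out[hole] <- TRUE
  }
  out
}
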