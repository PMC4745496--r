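#' @import methods
NULL

#' Segmented tomato sample
#'
#' Pairs an RGB raster with the foreground mask produced by two-frame
#' background differencing. Pixels outside the mask are zeroed in the
#' stored image, so downstream feature extractors only ever see fruit
#' surface.
#'
#' @slot image numeric `height x width x 3` array, intensities in \[0, 255\].
#' @slot mask logical `height x width` matrix; `TRUE` marks foreground.
#' @slot threshold the intensity-difference threshold that produced the mask.
#'
#' @exportClass SegmentedSample
setClass("SegmentedSample",
  representation(image = "array", mask = "matrix", threshold = "numeric"),
  validity = function(object) {
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L)
      return("image must be a height x width x 3 array")
    if (!is.logical(object@mask))
      return("mask must be a logical matrix")
    if (!identical(dim(object@mask), d[1:2]))
      return("mask dimensions differ from image dimensions")
    r <- range(object@image)
    if (r[1] < 0 || r[2] > 255)
      return("image intensities must lie in [0, 255]")
    bgIdx <- which(!object@mask)
    planeLen <- prod(d[1:2])
    for (ch in 0:2)
      if (any(object@image[bgIdx + ch * planeLen] != 0))
        return("pixels outside the mask must be zeroed")
    TRUE
  }
)

#' Colour cluster decomposition of a fruit surface
#'
#' Result of k-means clustering of foreground pixels in CIELAB
#' chromaticity. Holds the per-pixel label map, cluster centroids and
#' per-cluster descriptors used by the disease classifier.
#'
#' @slot k number of clusters.
#' @slot labelMap integer `height x width` matrix with labels `1..k` on
#'   foreground pixels and `NA` elsewhere.
#' @slot means `k x 3` matrix of cluster centroids in L*, a*, b*
#'   (L* is the mean lightness of members even when clustering used
#'   chromaticity only).
#' @slot descriptors `data.frame` with one row per cluster: pixel count,
#'   mean R/G/B, pattern-weighted area, bounding box.
#' @slot channels `"ab"` or `"lab"` -- the coordinates that were clustered.
#' @slot objective within-cluster sum of squared distances at each Lloyd
#'   iteration (non-increasing).
#'
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(k = "integer", labelMap = "matrix", means = "matrix",
                 descriptors = "data.frame", channels = "character",
                 objective = "numeric"),
  validity = function(object) {
    if (object@k < 1L) return("k must be positive")
    lab <- object@labelMap[!is.na(object@labelMap)]
    if (length(lab) && (min(lab) < 1L || max(lab) > object@k))
      return("labels must lie in 1..k")
    if (nrow(object@means) != object@k || ncol(object@means) != 3L)
      return("means must be a k x 3 matrix")
    if (nrow(object@descriptors) != object@k)
      return("descriptors must have one row per cluster")
    TRUE
  }
)

#' Principal component model
#'
#' Eigendecomposition of the covariance of mean-centred feature vectors.
#' Components are sorted by decreasing eigenvalue and the rotation matrix
#' has orthonormal columns.
#'
#' @slot center feature means used for centring.
#' @slot eigenvalues variances along the components, non-increasing.
#' @slot rotation `p x p` orthonormal eigenvector matrix (columns).
#' @slot nComponents number of components retained by [pcaTransform()].
#'
#' @exportClass PcaModel
setClass("PcaModel",
  representation(center = "numeric", eigenvalues = "numeric",
                 rotation = "matrix", nComponents = "integer"),
  validity = function(object) {
    p <- length(object@center)
    if (!identical(dim(object@rotation), c(p, p)))
      return("rotation must be p x p")
    if (length(object@eigenvalues) != p)
      return("one eigenvalue per feature dimension required")
    if (is.unsorted(rev(object@eigenvalues + 1e-12)))
      return("eigenvalues must be non-increasing")
    if (object@nComponents < 1L || object@nComponents > p)
      return("nComponents out of range")
    TRUE
  }
)

#' Linear discriminant model
#'
#' Fisher discriminant directions (between- over within-class scatter
#' maximisers) plus the Gaussian equal-covariance linear scoring rule used
#' for prediction: score_k(x) = b0_k + sum_j b_kj x_j.
#'
#' @slot classes class labels in fit order (prediction ties break to the
#'   earliest).
#' @slot prior class priors from training frequencies.
#' @slot means class centroid matrix, one row per class.
#' @slot weights `p x K` matrix of discriminant weights b_k.
#' @slot intercepts length-K vector of intercepts b0_k.
#' @slot directions `p x m` matrix, `m <= K - 1`, of Fisher projection
#'   directions.
#'
#' @exportClass LdaModel
setClass("LdaModel",
  representation(classes = "character", prior = "numeric", means = "matrix",
                 weights = "matrix", intercepts = "numeric",
                 directions = "matrix"),
  validity = function(object) {
    K <- length(object@classes)
    if (length(object@prior) != K || nrow(object@means) != K ||
        ncol(object@weights) != K || length(object@intercepts) != K)
      return("per-class slots must agree with the number of classes")
    if (ncol(object@directions) > max(1L, K - 1L))
      return("at most K - 1 discriminant directions are admissible")
    if (abs(sum(object@prior) - 1) > 1e-8) return("priors must sum to 1")
    TRUE
  }
)

#' Quadratic discriminant model
#'
#' Per-class Gaussian with its own covariance; prediction minimises the
#' quadratic form (x - mu_k)' Sigma_k^-1 (x - mu_k) - 2 log pi_k +
#' log |Sigma_k|.
#'
#' @slot classes class labels in fit order.
#' @slot prior class priors pi_k = n_k / n.
#' @slot means class mean matrix, one row per class.
#' @slot covariances list of per-class covariance matrices (maximum
#'   likelihood, 1/n_k normalisation), regularised to be invertible.
#' @slot covInverses list of the corresponding inverses.
#' @slot logDets log-determinants of the covariances.
#'
#' @exportClass QdaModel
setClass("QdaModel",
  representation(classes = "character", prior = "numeric", means = "matrix",
                 covariances = "list", covInverses = "list",
                 logDets = "numeric"),
  validity = function(object) {
    K <- length(object@classes)
    if (length(object@prior) != K || nrow(object@means) != K ||
        length(object@covariances) != K || length(object@logDets) != K)
      return("per-class slots must agree with the number of classes")
    if (abs(sum(object@prior) - 1) > 1e-8) return("priors must sum to 1")
    TRUE
  }
)

#' k-nearest-neighbour model
#'
#' Stores the (standardised) training matrix and labels; prediction takes
#' the majority label among the k Euclidean-nearest training points, with
#' ties broken by the nearest single neighbour and then by the lowest
#' class index.
#'
#' @slot x standardised training feature matrix.
#' @slot labels training labels (character, in registration with rows of
#'   `x`).
#' @slot classes unique class labels in fit order (tie-break order).
#' @slot k neighbour count.
#' @slot center,scale standardisation applied to training features and to
#'   queries at prediction time.
#'
#' @exportClass KnnModel
setClass("KnnModel",
  representation(x = "matrix", labels = "character", classes = "character",
                 k = "integer", center = "numeric", scale = "numeric"),
  validity = function(object) {
    if (object@k < 1L || object@k > nrow(object@x))
      return("k must lie in [1, number of training points]")
    if (length(object@labels) != nrow(object@x))
      return("one label per training row required")
    if (length(object@center) != ncol(object@x) ||
        length(object@scale) != ncol(object@x))
      return("center/scale must match the feature dimension")
    TRUE
  }
)

#' Specification of one synthetic tomato sample
#'
#' All knobs of the synthetic image generator. The seed fully determines
#' the rendered frames and ground truth.
#'
#' @slot maturity ripeness in \[0, 1\]: 0 fully green, 1 deep red.
#' @slot disease one of `"none"`, `"early_blight"`, `"late_blight"`,
#'   `"bacterial_canker"`, `"gray_mold"`, `"bacterial_speck"`.
#' @slot lesionFraction target fraction of fruit area covered by lesions,
#'   in \[0, 0.4\].
#' @slot fruitAxes ellipse semi-axes (row, column) in pixels.
#' @slot noiseImpulse per-pixel salt-and-pepper probability.
#' @slot noiseBlur Gaussian blur sigma in pixels (0 disables).
#' @slot seed RNG seed.
#' @slot canvas image size `c(height, width)`.
#'
#' @exportClass SampleSpec
setClass("SampleSpec",
  representation(maturity = "numeric", disease = "character",
                 lesionFraction = "numeric", fruitAxes = "numeric",
                 noiseImpulse = "numeric", noiseBlur = "numeric",
                 seed = "integer", canvas = "integer"),
  validity = function(object) {
    if (object@maturity < 0 || object@maturity > 1)
      return("maturity must lie in [0, 1]")
    if (!object@disease %in% c("none", diseaseArchetypes()))
      return(paste0("unknown disease archetype: ", object@disease))
    if (object@lesionFraction < 0 || object@lesionFraction > 0.4)
      return("lesionFraction must lie in [0, 0.4]")
    if (length(object@fruitAxes) != 2L || any(object@fruitAxes <= 0))
      return("fruitAxes must be two positive semi-axes")
    if (object@noiseImpulse < 0 || object@noiseImpulse > 1)
      return("noiseImpulse must be a probability")
    if (object@noiseBlur < 0) return("noiseBlur must be non-negative")
    if (length(object@canvas) != 2L || any(object@canvas < 8L))
      return("canvas must be at least 8 x 8")
    if (object@disease == "none" && object@lesionFraction > 0)
      return("lesionFraction must be 0 when disease is 'none'")
    if (object@disease != "none" && object@lesionFraction <= 0)
      return("infected samples need a positive lesionFraction")
    if (2 * object@fruitAxes[1] > object@canvas[1] - 4 ||
        2 * object@fruitAxes[2] > object@canvas[2] - 4)
      return("fruit does not fit on the canvas")
    TRUE
  }
)

#' Trained model bundle for the three decision tasks
#'
#' @slot maturity classifier for the unripe/medium/ripe grade.
#' @slot health classifier for healthy vs risky.
#' @slot disease classifier over disease archetypes (fit on infected
#'   training samples only).
#' @slot featureNames list with the feature-column order each task's
#'   classifier expects (`$maturity`, `$health`, `$disease`).
#' @slot metrics training diagnostics (cross-validated accuracies).
#'
#' @exportClass ModelSet
setClass("ModelSet",
  representation(maturity = "ANY", health = "ANY", disease = "ANY",
                 featureNames = "list", metrics = "list"))

setMethod("show", "SegmentedSample", function(object) {
  d <- dim(object@image)
  cat("SegmentedSample:", d[1], "x", d[2], "RGB raster,",
      sum(object@mask), "foreground pixels",
      sprintf("(%.1f%%)\n", 100 * mean(object@mask)))
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet: k =", object@k, "on", object@channels, "coordinates\n")
  cat("  sizes:", paste(object@descriptors$pixelCount, collapse = ", "), "\n")
})

setMethod("show", "PcaModel", function(object) {
  cat("PcaModel:", length(object@center), "features,",
      object@nComponents, "components retained\n")
  cat("  eigenvalues:",
      paste(signif(object@eigenvalues, 4), collapse = ", "), "\n")
})

setMethod("show", "LdaModel", function(object) {
  cat("LdaModel:", length(object@classes), "classes (",
      paste(object@classes, collapse = ", "), ")\n")
})

setMethod("show", "QdaModel", function(object) {
  cat("QdaModel:", length(object@classes), "classes (",
      paste(object@classes, collapse = ", "), ")\n")
})

setMethod("show", "KnnModel", function(object) {
  cat("KnnModel: k =", object@k, "over", nrow(object@x),
      "training points,", length(object@classes), "classes\n")
})

setMethod("show", "SampleSpec", function(object) {
  cat(sprintf("SampleSpec: maturity %.2f, disease %s, canvas %d x %d, seed %d\n",
              object@maturity, object@disease, object@canvas[1],
              object@canvas[2], object@seed))
})

setMethod("show", "ModelSet", function(object) {
  cat("ModelSet with tasks: maturity, health, disease\n")
  if (length(object@metrics))
    cat("  CV accuracy:",
        paste(names(object@metrics), signif(unlist(object@metrics), 3),
              sep = " = ", collapse = ", "), "\n")
})
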