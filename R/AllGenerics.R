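#' Predict class labels from a fitted classifier
#'
#' Common prediction generic for the four classifier types. All rules are
#' deterministic: ties break to the earliest class in fit order (and, for
#' KNN, first to the nearest single neighbour among tied classes).
#'
#' @param object a fitted [LdaModel-class], [QdaModel-class] or
#'   [KnnModel-class].
#' @param newdata numeric matrix (rows are samples) or a single numeric
#'   vector, in the feature order used at fit time.
#' @return character vector of predicted class labels.
#' @export
setGeneric("predictLabels", function(object, newdata)
  standardGeneric("predictLabels"))

#' Accessors for pipeline objects
#'
#' `sampleImage()` and `foregroundMask()` read the raster and mask of a
#' [SegmentedSample-class]; `nClusters()`, `clusterMeans()`,
#' `clusterLabels()` and `clusterDescriptors()` read a
#' [ClusterSet-class].
#'
#' @param object the object to read from.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleImage", function(object) standardGeneric("sampleImage"))
#' @rdname accessors
#' @export
setGeneric("foregroundMask", function(object) standardGeneric("foregroundMask"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("clusterMeans", function(object) standardGeneric("clusterMeans"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("clusterDescriptors", function(object)
  standardGeneric("clusterDescriptors"))

#' @rdname accessors
#' @export
setMethod("sampleImage", "SegmentedSample", function(object) object@image)
#' @rdname accessors
#' @export
setMethod("foregroundMask", "SegmentedSample", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("nClusters", "ClusterSet", function(object) object@k)
#' @rdname accessors
#' @export
setMethod("clusterMeans", "ClusterSet", function(object) object@means)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterSet", function(object) object@labelMap)
#' @rdname accessors
#' @export
setMethod("clusterDescriptors", "ClusterSet",
          function(object) object@descriptors)
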