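# JSON (de)serialisation of trained models: portable, text-only,
# endianness-free, versioned by a format tag.

modelToList <- function(model) {
  if (is.null(model)) return(NULL)
  cls <- class(model)[1]
  slots <- slotNames(cls)
  dropNegZero <- function(v) {
    if (is.numeric(v)) return(v + 0)        # -0 + 0 == +0
    if (is.list(v)) return(lapply(v, dropNegZero))
    v
  }
  payload <- lapply(stats::setNames(slots, slots), function(s) {
    v <- methods::slot(model, s)
    if (isS4(v)) modelToList(v) else dropNegZero(v)
  })
  list(class = cls, payload = payload)
}

listToModel <- function(x) {
  if (is.null(x)) return(NULL)
  cls <- x$class
  p <- x$payload
  restoreMatrix <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }
  # a JSON list of equally-sized matrices comes back as a 3-D array
  restoreMatrixList <- function(x) {
    if (is.array(x) && length(dim(x)) == 3L)
      return(lapply(seq_len(dim(x)[1]), function(i)
        restoreMatrix(x[i, , ])))
    lapply(x, restoreMatrix)
  }
  switch(cls,
    KnnModel = new("KnnModel", x = restoreMatrix(p$x),
                   labels = as.character(p$labels),
                   classes = as.character(p$classes),
                   k = as.integer(p$k), center = as.numeric(p$center),
                   scale = as.numeric(p$scale)),
    PcaModel = new("PcaModel", center = as.numeric(p$center),
                   eigenvalues = as.numeric(p$eigenvalues),
                   rotation = restoreMatrix(p$rotation),
                   nComponents = as.integer(p$nComponents)),
    LdaModel = new("LdaModel", classes = as.character(p$classes),
                   prior = as.numeric(p$prior),
                   means = restoreMatrix(p$means),
                   weights = restoreMatrix(p$weights),
                   intercepts = as.numeric(p$intercepts),
                   directions = restoreMatrix(p$directions)),
    QdaModel = new("QdaModel", classes = as.character(p$classes),
                   prior = as.numeric(p$prior),
                   means = restoreMatrix(p$means),
                   covariances = restoreMatrixList(p$covariances),
                   covInverses = restoreMatrixList(p$covInverses),
                   logDets = as.numeric(p$logDets)),
    PcaKnnModel = new("PcaKnnModel", pca = listToModel(p$pca),
                      knn = listToModel(p$knn)),
    stopData("unknown model class in file: ", cls))
}

#' Save and load trained model bundles
#'
#' Models are written as versioned JSON -- a portable, endianness-safe
#' text format -- and reconstructed exactly (numbers survive via full
#' decimal precision).
#'
#' @param models a [ModelSet-class].
#' @param path file path for the JSON bundle.
#' @return `loadModels()` returns the [ModelSet-class].
#' @export
saveModels <- function(models, path) {
  stopifnot(is(models, "ModelSet"))
  if (!dir.exists(dirname(path)))
    stopIO("cannot write models: no such directory: ", dirname(path))
  bundle <- list(format = "tomatovision-models/1",
                 featureNames = models@featureNames,
                 metrics = models@metrics,
                 maturity = modelToList(models@maturity),
                 health = modelToList(models@health),
                 disease = modelToList(models@disease))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname saveModels
#' @export
loadModels <- function(path) {
  if (!file.exists(path)) stopIO("no such model file: ", path)
  bundle <- jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyMatrix = TRUE)
  if (!identical(bundle$format, "tomatovision-models/1"))
    stopData("unrecognised model file format: ", bundle$format)
  toModel <- function(x) {
    if (is.null(x)) return(NULL)
    listToModel(x)
  }
  new("ModelSet",
      maturity = toModel(bundle$maturity),
      health = toModel(bundle$health),
      disease = toModel(bundle$disease),
      featureNames = lapply(bundle$featureNames, as.character),
      metrics = as.list(bundle$metrics))
}
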