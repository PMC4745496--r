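#' Pipeline configuration
#'
#' Bundles every tunable of the inspection pipeline with its default.
#' The defaults are the conditions the rest of the package (tests,
#' acceptance runs, CLI) operates under.
#'
#' @param denoiseRank rank of the 3x3 rank-order filter (5 = median).
#' @param denoiseWindow odd window side for denoising.
#' @param segmentationThreshold channel-summed intensity difference above
#'   which a pixel is foreground.
#' @param minComponentArea speckle-removal floor for mask components.
#' @param entropyWindow odd window side for local entropy.
#' @param entropyLevels gray levels for the entropy histogram.
#' @param k colour cluster count.
#' @param clusterChannels `"ab"` or `"lab"`.
#' @param clusterSeed seed for k-means initialisation.
#' @param classifier decision-layer classifier: `"lda"` (default),
#'   `"knn"`, `"qda"` or `"pca+knn"`. Linear discriminants are the
#'   default because the lesion descriptors separate the classes nearly
#'   linearly, where nearest-neighbour distance dilutes the few
#'   informative coordinates across the whole feature vector.
#' @param knnK neighbour count for KNN-based classifiers.
#' @param pcaComponents components retained by `"pca+knn"`.
#' @param lesionContrastMin CIELAB chromaticity distance from the
#'   dominant cluster above which a cluster counts as lesion tissue.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(denoiseRank = 5L, denoiseWindow = 3L,
                           segmentationThreshold = 30,
                           minComponentArea = 64L,
                           entropyWindow = 9L, entropyLevels = 256L,
                           k = 4L, clusterChannels = "ab",
                           clusterSeed = 0L,
                           classifier = c("lda", "knn", "qda", "pca+knn"),
                           knnK = 5L, pcaComponents = 4L,
                           lesionContrastMin = 20) {
  classifier <- match.arg(classifier)
  cfg <- list(denoiseRank = as.integer(denoiseRank),
              denoiseWindow = as.integer(denoiseWindow),
              segmentationThreshold = as.numeric(segmentationThreshold),
              minComponentArea = as.integer(minComponentArea),
              entropyWindow = as.integer(entropyWindow),
              entropyLevels = as.integer(entropyLevels),
              k = as.integer(k),
              clusterChannels = match.arg(clusterChannels, c("ab", "lab")),
              clusterSeed = as.integer(clusterSeed),
              classifier = classifier, knnK = as.integer(knnK),
              pcaComponents = as.integer(pcaComponents),
              lesionContrastMin = as.numeric(lesionContrastMin))
  if (cfg$denoiseWindow %% 2L == 0L || cfg$denoiseWindow < 1L)
    stopParameter("denoiseWindow must be odd and positive")
  if (cfg$denoiseRank < 1L || cfg$denoiseRank > cfg$denoiseWindow^2)
    stopParameter("denoiseRank outside [1, denoiseWindow^2]")
  if (cfg$segmentationThreshold < 0)
    stopParameter("segmentationThreshold must be >= 0")
  if (cfg$entropyWindow %% 2L == 0L || cfg$entropyWindow < 1L)
    stopParameter("entropyWindow must be odd and positive")
  if (cfg$k < 1L) stopParameter("k must be >= 1")
  if (cfg$knnK < 1L) stopParameter("knnK must be >= 1")
  structure(cfg, class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @return `configDigest()`: 8-hex-digit digest that changes iff any
#'   configuration field changes.
#' @export
configDigest <- function(config) {
  fnv1a32(paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), ""), sep = "=",
    collapse = ";"))
}

featureNamesFor <- function(k) {
  base <- c("R", "G", "B", "minEntropy", "maxEntropy",
            "textureCoefficient", "area")
  cl <- c(paste0("clusterContrast", seq_len(k)),
          paste0("clusterRelArea", seq_len(k)))
  les <- c("lesionRelArea", "lesionContrast", "lesionDeltaL",
           "lesionDeltaA", "lesionDeltaB", "spotCount", "meanSpotArea",
           "ringScore", "brightLesionFraction", "darkSpotCount",
           "darkSpotFraction")
  # health keys on texture and lesion evidence; the colour fractions and
  # fruit size vary with maturity, not with infection, and only add
  # nuisance variance to that decision
  list(maturity = base[1:6],
       health = c("maxEntropy", "textureCoefficient", "clusterContrast1",
                  "clusterRelArea1", les),
       disease = les, all = c(base, cl, les))
}

# count- and fraction-valued descriptors span orders of magnitude
# (3 specks vs a 6000-px blotch); classifiers see them log-compressed
# so that "present at all" is not crushed by "present in bulk"
taskTransform <- function(x) {
  for (cc in intersect(colnames(x),
                       c("spotCount", "meanSpotArea", "darkSpotCount")))
    x[, cc] <- log1p(x[, cc])
  if ("darkSpotFraction" %in% colnames(x))
    x[, "darkSpotFraction"] <- log1p(1000 * x[, "darkSpotFraction"])
  if ("lesionRelArea" %in% colnames(x))
    x[, "lesionRelArea"] <- log1p(100 * x[, "lesionRelArea"])
  x
}

#' Run the inspection pipeline on one frame pair
#'
#' Denoise (rank-order filter) -> two-frame segmentation -> mask cleanup
#' -> colour fractions, local-entropy texture, Otsu binarisation with
#' pattern-weighted area, CIELAB k-means clusters -> fixed-order feature
#' vector. The clusters are ordered by decreasing chromaticity contrast
#' against the dominant (largest) cluster so features are comparable
#' across samples; clusters whose contrast exceeds
#' `config$lesionContrastMin` form the lesion candidate region from
#' which spot and shape descriptors are computed.
#'
#' @param background,sample RGB frames (arrays or image file paths).
#' @param config a [pipelineConfig()].
#' @return list with `features` (named numeric), `clusters`
#'   ([ClusterSet-class]), `segmented` ([SegmentedSample-class]),
#'   `texture`, `area` and `lesionMask`.
#' @export
extractFeatures <- function(background, sample,
                            config = pipelineConfig()) {
  if (is.character(background)) background <- readImage(background)
  if (is.character(sample)) sample <- readImage(sample)
  denBg <- denoiseRankOrder(background, config$denoiseRank,
                            config$denoiseWindow)
  denSm <- denoiseRankOrder(sample, config$denoiseRank,
                            config$denoiseWindow)
  rawMask <- frameDiffMask(denBg, denSm, config$segmentationThreshold)
  mask <- postprocessMask(rawMask, config$minComponentArea)
  if (!any(mask))
    stopEmpty("no foreground region after segmentation and cleanup")
  seg <- maskedSample(denSm, mask, config$segmentationThreshold)
  cf <- extractColorFractions(seg)
  te <- textureEntropy(seg, config$entropyWindow, config$entropyLevels)
  gray <- rgbToGray(sampleImage(seg))
  bin <- binarize(gray, "otsu")
  area <- estimateArea(unclass(bin))
  clusters <- extractClusters(seg, k = config$k, seed = config$clusterSeed,
                              channels = config$clusterChannels)
  cd <- clusterFeatureBlock(seg, clusters, config, gray)
  features <- c(cf,
                minEntropy = te$minEntropy, maxEntropy = te$maxEntropy,
                textureCoefficient = te$textureQualityCoefficient,
                area = area, cd$clusterFeatures, cd$lesionFeatures)
  list(features = features, clusters = clusters, segmented = seg,
       texture = te[c("minEntropy", "maxEntropy",
                      "textureQualityCoefficient")],
       area = area, lesionMask = cd$lesionMask)
}

# cluster-contrast ordering + lesion descriptors
clusterFeatureBlock <- function(seg, clusters, config, gray) {
  k <- nClusters(clusters)
  desc <- clusterDescriptors(clusters)
  means <- clusterMeans(clusters)
  dominant <- which.max(desc$pixelCount)
  ab0 <- means[dominant, c("a", "b")]
  contrast <- sqrt((means[, "a"] - ab0[1])^2 + (means[, "b"] - ab0[2])^2)
  fgCount <- sum(foregroundMask(seg))
  relArea <- desc$pixelCount / fgCount
  ord <- order(-contrast, seq_len(k))
  clusterFeatures <- stats::setNames(
    c(contrast[ord], relArea[ord]),
    c(paste0("clusterContrast", seq_len(k)),
      paste0("clusterRelArea", seq_len(k))))

  lesionClusters <- which(contrast > config$lesionContrastMin)
  labelMap <- clusterLabels(clusters)
  lesionMask <- !is.na(labelMap) & matrix(labelMap %in% lesionClusters,
                                          nrow(labelMap), ncol(labelMap))
  fgIdx <- which(foregroundMask(seg))
  labFg <- rgbToLab(foregroundRgb(sampleImage(seg), fgIdx))
  lf <- lesionDescriptors(seg, lesionMask, means, dominant, contrast,
                          fgCount, fgIdx, labFg, gray)
  list(clusterFeatures = clusterFeatures, lesionFeatures = lf,
       lesionMask = lesionMask)
}

lesionDescriptors <- function(seg, lesionMask, means, dominant, contrast,
                              fgCount, fgIdx, labFg, gray) {
  out <- c(lesionRelArea = 0, lesionContrast = 0, lesionDeltaL = 0,
           lesionDeltaA = 0, lesionDeltaB = 0, spotCount = 0,
           meanSpotArea = 0, ringScore = 0, brightLesionFraction = 0,
           darkSpotCount = 0, darkSpotFraction = 0)
  img <- sampleImage(seg)
  mask <- foregroundMask(seg)
  # cluster-independent dark-spot census: pixels far darker than the
  # fruit body (catches specks too small to win a colour cluster). The
  # mask is eroded first so the blur-softened fruit boundary, which
  # fades toward the dark chamber, cannot masquerade as spots.
  core <- erodeMask(mask, 3L)
  bodyGray <- stats::median(gray[mask])
  darkMask <- core & (gray < 0.6 * bodyGray)
  if (any(darkMask)) {
    dcomp <- .label_components_cpp(darkMask)
    dsz <- tabulate(dcomp[dcomp > 0L])
    dsz <- dsz[dsz >= 3L]            # ignore 1-2 px noise residue
    out["darkSpotCount"] <- length(dsz)
    out["darkSpotFraction"] <- sum(dsz) / fgCount
  }
  n <- sum(lesionMask)
  if (n == 0) return(out)
  lab <- labFg[lesionMask[fgIdx], , drop = FALSE]
  lesionLab <- colMeans(lab)
  lab0 <- means[dominant, ]
  # a small dilation re-joins lesion fragments (e.g. the alternating
  # annuli of a ringed lesion land in different colour clusters) before
  # spot statistics are taken
  dil <- dilateMask(lesionMask, 2L) & mask
  comp <- .label_components_cpp(dil)
  nComp <- max(comp)
  bodyL <- mean(labFg[, 1])
  out["lesionRelArea"] <- n / fgCount
  out["lesionContrast"] <- max(contrast)
  out["lesionDeltaL"] <- unname(lesionLab[1] - lab0["L"])
  out["lesionDeltaA"] <- unname(lesionLab[2] - lab0["a"])
  out["lesionDeltaB"] <- unname(lesionLab[3] - lab0["b"])
  out["spotCount"] <- nComp
  out["meanSpotArea"] <- n / nComp
  out["ringScore"] <- ringScore(gray, comp, mask)
  out["brightLesionFraction"] <- mean(lab[, 1] > bodyL + 12)
  out
}

erodeMask <- function(m, iter = 1L) !dilateMask(!m, iter)

# 8-neighbourhood binary dilation, `iter` passes
dilateMask <- function(m, iter = 1L) {
  h <- nrow(m); w <- ncol(m)
  for (it in seq_len(iter)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    down <- rbind(FALSE, m[-h, , drop = FALSE])
    horiz <- m | up | down
    left <- cbind(horiz[, -1, drop = FALSE], FALSE)
    right <- cbind(FALSE, horiz[, -w, drop = FALSE])
    m <- horiz | left | right
  }
  m
}

# radial oscillation of gray intensity around the largest lesion blob:
# concentric-ring lesions alternate dark/darker annuli as radius grows,
# blotches and patches are radially monotone
ringScore <- function(gray, comp, fgMask) {
  sizes <- tabulate(comp[comp > 0L])
  if (!length(sizes)) return(0)
  idx <- which(comp == which.max(sizes))
  if (length(idx) < 30L) return(0)
  h <- nrow(comp)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  cy <- mean(rows); cx <- mean(cols)
  rmax <- stats::quantile(sqrt((rows - cy)^2 + (cols - cx)^2), 0.95)
  if (rmax < 6) return(0)
  # all fruit pixels inside the lesion's radius, not only cluster members
  fidx <- which(fgMask)
  fr <- ((fidx - 1L) %% h) + 1L
  fc <- ((fidx - 1L) %/% h) + 1L
  d <- sqrt((fr - cy)^2 + (fc - cx)^2)
  keep <- d <= rmax
  if (sum(keep) < 60L) return(0)
  nb <- 8L
  bins <- pmin(floor(d[keep] / (rmax + 1e-9) * nb) + 1L, nb)
  g <- gray[fidx][keep]
  prof <- vapply(seq_len(nb), function(b)
    if (any(bins == b)) mean(g[bins == b]) else NA_real_, 0)
  prof <- prof[!is.na(prof)]
  if (length(prof) < 4L) return(0)
  dp <- diff(prof)
  dp <- dp[abs(dp) > 3]   # ignore sub-noise wiggles
  if (length(dp) < 2L) return(0)
  mean(sign(dp[-1]) != sign(dp[-length(dp)]))
}

#' Feature table for a dataset
#'
#' Runs [extractFeatures()] over every sample of a generated dataset (or
#' a manifest pointing at frame pairs on disk) and returns one row per
#' sample together with the ground-truth labels.
#'
#' @param dataset result of [generateDataset()], or a manifest
#'   `data.frame` with `background`/`sample` file paths and label
#'   columns.
#' @param config a [pipelineConfig()].
#' @param verbose print progress.
#' @return `data.frame`: `sample_id`, label columns, then the feature
#'   columns.
#' @export
extractFeatureTable <- function(dataset, config = pipelineConfig(),
                                verbose = FALSE) {
  if (is.data.frame(dataset)) {
    manifest <- dataset
    getPair <- function(i) list(background = manifest$background[i],
                                sample = manifest$sample[i])
  } else {
    manifest <- dataset$manifest
    getPair <- function(i) dataset$samples[[i]][c("background", "sample")]
  }
  n <- nrow(manifest)
  if (n == 0L) stopData("empty manifest")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (verbose) message("features: ", manifest$sample_id[i])
    pair <- getPair(i)
    fe <- extractFeatures(pair$background, pair$sample, config)
    rows[[i]] <- as.data.frame(as.list(fe$features))
  }
  feat <- do.call(rbind, rows)
  cbind(manifest[, intersect(c("sample_id", "maturity", "maturity_label",
                               "health_label", "disease_label",
                               "lesion_fraction"), names(manifest)),
                 drop = FALSE],
        feat)
}

fitTaskClassifier <- function(x, labels, config) {
  switch(config$classifier,
    knn = knnFit(x, labels, k = min(config$knnK, nrow(x))),
    lda = ldaFit(x, labels),
    qda = qdaFit(x, labels),
    `pca+knn` = {
      pca <- pcaFit(x, nComponents = min(config$pcaComponents, ncol(x)))
      new("PcaKnnModel", pca = pca,
          knn = knnFit(pcaTransform(pca, x), labels,
                       k = min(config$knnK, nrow(x))))
    })
}

#' PCA-then-KNN classifier
#'
#' Projects features onto the retained principal components and runs KNN
#' in the reduced space.
#'
#' @slot pca the [PcaModel-class] projection.
#' @slot knn the [KnnModel-class] fitted on projected training data.
#' @exportClass PcaKnnModel
setClass("PcaKnnModel", representation(pca = "PcaModel", knn = "KnnModel"))

#' @describeIn predictLabels project onto principal components, then the
#'   KNN rule.
#' @export
setMethod("predictLabels", "PcaKnnModel", function(object, newdata) {
  predictLabels(object@knn, pcaTransform(object@pca, newdata))
})

#' Train the three decision-layer classifiers
#'
#' Fits the maturity (u/m/r), health (healthy/risky) and disease
#' (archetype) classifiers configured in `config` on a feature table
#' from [extractFeatureTable()]. The disease classifier is fit on
#' infected rows only. Each task reports a stratified 5-fold
#' cross-validated accuracy.
#'
#' @param featTable feature table with `maturity_label`, `health_label`
#'   and `disease_label` columns.
#' @param config a [pipelineConfig()].
#' @param cvFolds folds for the reported cross-validated accuracy
#'   (0 disables).
#' @return a [ModelSet-class].
#' @export
trainModels <- function(featTable, config = pipelineConfig(),
                        cvFolds = 5L) {
  fn <- featureNamesFor(config$k)
  for (col in c("maturity_label", "health_label", "disease_label"))
    if (!col %in% names(featTable)) stopData("missing label column: ", col)
  checkCounts <- function(labels, task) {
    tab <- table(labels)
    if (length(tab) < 2L)
      stopData(task, ": need >= 2 classes, got ",
               paste(names(tab), collapse = ", "))
    if (any(tab < 2L))
      stopData(task, ": class ", names(tab)[which.min(tab)],
               " has fewer than 2 samples")
  }
  xm <- taskTransform(as.matrix(featTable[, fn$maturity, drop = FALSE]))
  xh <- taskTransform(as.matrix(featTable[, fn$health, drop = FALSE]))
  infected <- featTable$health_label == "risky"
  xd <- taskTransform(as.matrix(featTable[infected, fn$disease,
                                          drop = FALSE]))
  checkCounts(featTable$maturity_label, "maturity")
  checkCounts(featTable$health_label, "health")
  checkCounts(featTable$disease_label[infected], "disease")
  metrics <- list()
  if (cvFolds > 0L) {
    metrics$maturity <- cvAccuracy(xm, featTable$maturity_label, config,
                                   cvFolds)
    metrics$health <- cvAccuracy(xh, featTable$health_label, config,
                                 cvFolds)
    metrics$disease <- cvAccuracy(xd, featTable$disease_label[infected],
                                  config, cvFolds)
  }
  new("ModelSet",
      maturity = fitTaskClassifier(xm, featTable$maturity_label, config),
      health = fitTaskClassifier(xh, featTable$health_label, config),
      disease = fitTaskClassifier(xd, featTable$disease_label[infected],
                                  config),
      featureNames = fn[c("maturity", "health", "disease")],
      metrics = metrics)
}

# deterministic stratified k-fold CV accuracy
cvAccuracy <- function(x, labels, config, folds = 5L) {
  n <- nrow(x)
  folds <- min(folds, min(table(labels)))
  if (folds < 2L) return(NA_real_)
  fold <- integer(n)
  withSeed(1L, for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  })
  correct <- 0L
  for (f in seq_len(folds)) {
    test <- fold == f
    fit <- tryCatch(fitTaskClassifier(x[!test, , drop = FALSE],
                                      labels[!test], config),
                    error = function(e) NULL)
    if (is.null(fit)) next
    correct <- correct +
      sum(predictLabels(fit, x[test, , drop = FALSE]) == labels[test])
  }
  correct / n
}

#' Analyze one frame pair end to end
#'
#' Runs the full pipeline and the three trained classifiers, returning a
#' structured report. If segmentation leaves no foreground, the report
#' carries `health = NULL` (and nulls downstream) plus a diagnostic
#' message instead of failing.
#'
#' @param background,sample RGB frames (arrays or file paths).
#' @param models a trained [ModelSet-class].
#' @param config the [pipelineConfig()] used at training time.
#' @param sampleId identifier echoed into the report.
#' @return report list (JSON-ready; see [writeReport()]).
#' @export
analyzeSample <- function(background, sample, models,
                          config = pipelineConfig(),
                          sampleId = "sample") {
  stopifnot(is(models, "ModelSet"))
  report <- list(schema = "tomatovision-report/1",
                 sample_id = sampleId,
                 config_digest = configDigest(config))
  fe <- tryCatch(extractFeatures(background, sample, config),
                 tvEmptyRegionError = function(e) e)
  if (inherits(fe, "tvEmptyRegionError")) {
    message("analyzeSample: ", conditionMessage(fe))
    report$diagnostic <- conditionMessage(fe)
    report[c("color_fractions", "texture", "area", "clusters",
             "maturity", "health", "disease")] <-
      list(NULL, NULL, NULL, NULL, NULL, NULL, NULL)
    return(report)
  }
  f <- fe$features
  maturity <- assessMaturity(f, models)
  health <- classifyHealth(f, models)
  disease <- if (health == "risky")
    classifyDisease(f, models, health = health) else "none"
  report$color_fractions <- as.list(f[c("R", "G", "B")])
  report$texture <- fe$texture
  report$area <- fe$area
  report$clusters <- clusterDescriptors(fe$clusters)
  report$features <- as.list(f)
  report$maturity <- maturity
  report$health <- health
  report$disease <- disease
  report
}

#' Write a report as JSON
#'
#' @param report list from [analyzeSample()] or [evaluateModels()].
#' @param path destination file; its directory must exist.
#' @export
writeReport <- function(report, path) {
  if (!dir.exists(dirname(path)))
    stopIO("cannot write report: no such directory: ", dirname(path))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  invisible(path)
}

#' Evaluate trained models against ground truth
#'
#' Predicts maturity, health and disease for every row of a labelled
#' feature table and reports per-task accuracy and confusion matrices
#' (rows: truth, columns: prediction). Disease accuracy is computed over
#' truly infected samples only.
#'
#' @param featTable labelled feature table from [extractFeatureTable()].
#' @param models a trained [ModelSet-class].
#' @return list with `accuracy` (named numeric, percent), `confusion`
#'   (list of tables) and `predictions` (data.frame).
#' @export
evaluateModels <- function(featTable, models) {
  stopifnot(is(models, "ModelSet"))
  if (nrow(featTable) == 0L) stopData("empty feature table")
  need <- unique(unlist(models@featureNames))
  missing <- setdiff(need, names(featTable))
  if (length(missing))
    stopData("feature table lacks model columns: ",
             paste(missing, collapse = ", "))
  x <- as.matrix(featTable[, need, drop = FALSE])
  predM <- assessMaturity(x, models)
  predH <- classifyHealth(x, models)
  infected <- featTable$health_label == "risky"
  predD <- rep("none", nrow(featTable))
  if (any(infected))
    predD[infected] <- classifyDisease(x[infected, , drop = FALSE],
                                       models, health = "risky")
  conf <- function(truth, pred) {
    lev <- sort(unique(c(truth, pred)))
    table(truth = factor(truth, lev), predicted = factor(pred, lev))
  }
  acc <- c(maturity = 100 * mean(predM == featTable$maturity_label),
           health = 100 * mean(predH == featTable$health_label),
           disease = if (any(infected))
             100 * mean(predD[infected] ==
                        featTable$disease_label[infected]) else NA_real_)
  list(accuracy = acc,
       confusion = list(
         maturity = conf(featTable$maturity_label, predM),
         health = conf(featTable$health_label, predH),
         disease = conf(featTable$disease_label[infected],
                        predD[infected])),
       predictions = data.frame(sample_id = featTable$sample_id,
                                maturity = predM, health = predH,
                                disease = predD,
                                stringsAsFactors = FALSE))
}
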