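as2dMatrix <- function(newdata, p, what = "newdata") {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != p)
    stopShape(what, " has ", ncol(newdata), " columns; model expects ", p)
  newdata
}

#' Fit a principal component model
#'
#' Mean-centres the data and eigendecomposes its covariance matrix.
#' Components come back sorted by decreasing eigenvalue; the eigenvalue
#' sum equals the total variance of the centred data.
#'
#' @param x numeric matrix, rows are samples.
#' @param nComponents components retained by [pcaTransform()]; default
#'   all.
#' @return a [PcaModel-class].
#' @export
pcaFit <- function(x, nComponents = ncol(x)) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopData("PCA needs at least 2 samples")
  p <- ncol(x)
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L || nComponents > p)
    stopParameter("nComponents must lie in [1, ", p, "]")
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  covm <- crossprod(xc) / (nrow(x) - 1L)
  ed <- eigen(covm, symmetric = TRUE)
  new("PcaModel", center = center, eigenvalues = pmax(ed$values, 0),
      rotation = ed$vectors, nComponents = nComponents)
}

#' Project data onto principal components
#'
#' Centers `newdata` with the model mean and multiplies by the retained
#' eigenvectors (Y = XV).
#'
#' @param model a [PcaModel-class].
#' @param newdata matrix or vector in the model's feature space.
#' @return matrix of projected coordinates, `nComponents` columns.
#' @export
pcaTransform <- function(model, newdata) {
  stopifnot(is(model, "PcaModel"))
  newdata <- as2dMatrix(newdata, length(model@center))
  sweep(newdata, 2L, model@center) %*%
    model@rotation[, seq_len(model@nComponents), drop = FALSE]
}

# pooled within-class and between-class scatter matrices
scatterMatrices <- function(x, labels) {
  classes <- unique(labels)
  p <- ncol(x)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  grand <- colMeans(x)
  for (cl in classes) {
    xi <- x[labels == cl, , drop = FALSE]
    mi <- colMeans(xi)
    Sw <- Sw + crossprod(sweep(xi, 2L, mi))
    Sb <- Sb + nrow(xi) * tcrossprod(mi - grand)
  }
  list(Sw = Sw, Sb = Sb, classes = classes)
}

regularizeCov <- function(sigma) {
  p <- ncol(sigma)
  ok <- tryCatch({ solve(sigma); min(eigen(sigma, symmetric = TRUE,
                                           only.values = TRUE)$values) > 0 },
                 error = function(e) FALSE)
  if (!ok) sigma <- sigma + diag(1e-6 * max(sum(diag(sigma)) / p, 1), p)
  sigma
}

#' Fit a linear discriminant model
#'
#' Discriminant directions maximise the ratio of between-class to
#' (pooled) within-class scatter, from the generalized eigenproblem
#' `Sw^-1 Sb`; at most `K - 1` directions are kept. Prediction uses the
#' equal-covariance Gaussian linear scores
#' `score_k(x) = b0_k + b_k . x` with
#' `b_k = Sigma^-1 mu_k`, `b0_k = -mu_k . b_k / 2 + log pi_k`.
#' A singular pooled covariance is ridge-regularised.
#'
#' @param x numeric feature matrix, rows are samples.
#' @param labels class label per row; at least two classes with two
#'   samples each.
#' @return an [LdaModel-class].
#' @export
ldaFit <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stopShape("one label per row required")
  classes <- unique(labels)
  if (length(classes) < 2L) stopData("LDA needs at least 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L))
    stopData("every class needs >= 2 samples; short: ",
             paste(names(counts)[counts < 2L], collapse = ", "))
  p <- ncol(x)
  sm <- scatterMatrices(x, labels)
  n <- nrow(x)
  sigma <- regularizeCov(sm$Sw / (n - length(classes)))
  sigmaInv <- solve(sigma)
  means <- t(vapply(classes, function(cl)
    colMeans(x[labels == cl, , drop = FALSE]), numeric(p)))
  prior <- as.numeric(counts) / n
  weights <- sigmaInv %*% t(means)                     # p x K
  intercepts <- -0.5 * colSums(t(means) * weights) + log(prior)
  # Fisher directions from Sw^-1 Sb (kept for projections/diagnostics)
  ev <- eigen(solve(regularizeCov(sm$Sw)) %*% sm$Sb)
  m <- min(length(classes) - 1L, p)
  dirs <- Re(ev$vectors[, seq_len(m), drop = FALSE])
  dirs <- sweep(dirs, 2L, sqrt(colSums(dirs^2)), "/")
  new("LdaModel", classes = classes, prior = prior, means = means,
      weights = weights, intercepts = intercepts, directions = dirs)
}

#' @describeIn predictLabels linear discriminant rule: the class with the
#'   maximal linear score, ties to the earliest class in fit order.
#' @export
setMethod("predictLabels", "LdaModel", function(object, newdata) {
  newdata <- as2dMatrix(newdata, nrow(object@weights))
  scores <- newdata %*% object@weights +
    matrix(object@intercepts, nrow(newdata), length(object@intercepts),
           byrow = TRUE)
  object@classes[max.col(scores, ties.method = "first")]
})

#' Fit a quadratic discriminant model
#'
#' Per class: sample mean `mu_k`, maximum-likelihood covariance
#' `Sigma_k = (1/n_k) sum (x - mu_k)(x - mu_k)'` and prior
#' `pi_k = n_k / n`. Covariances that are not positive-definite gain a
#' ridge `epsilon I`, `epsilon = 1e-6 trace(Sigma_k) / p`, so classes
#' with constant features still fit.
#'
#' @inheritParams ldaFit
#' @return a [QdaModel-class].
#' @export
qdaFit <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stopShape("one label per row required")
  classes <- unique(labels)
  if (length(classes) < 2L) stopData("QDA needs at least 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L))
    stopData("every class needs >= 2 samples; short: ",
             paste(names(counts)[counts < 2L], collapse = ", "))
  p <- ncol(x)
  means <- matrix(NA_real_, length(classes), p)
  covs <- vector("list", length(classes))
  invs <- vector("list", length(classes))
  logDets <- numeric(length(classes))
  for (i in seq_along(classes)) {
    xi <- x[labels == classes[i], , drop = FALSE]
    means[i, ] <- colMeans(xi)
    sigma <- crossprod(sweep(xi, 2L, means[i, ])) / nrow(xi)
    sigma <- regularizeCov(sigma)
    covs[[i]] <- sigma
    invs[[i]] <- solve(sigma)
    logDets[i] <- determinant(sigma, logarithm = TRUE)$modulus
  }
  new("QdaModel", classes = classes,
      prior = as.numeric(counts) / nrow(x), means = means,
      covariances = covs, covInverses = invs, logDets = logDets)
}

#' @describeIn predictLabels quadratic discriminant rule: the class
#'   minimising `(x - mu_k)' Sigma_k^-1 (x - mu_k) - 2 log(pi_k) +
#'   log|Sigma_k|`.
#' @export
setMethod("predictLabels", "QdaModel", function(object, newdata) {
  newdata <- as2dMatrix(newdata, ncol(object@means))
  K <- length(object@classes)
  cost <- matrix(NA_real_, nrow(newdata), K)
  for (k in seq_len(K)) {
    d <- sweep(newdata, 2L, object@means[k, ])
    cost[, k] <- rowSums((d %*% object@covInverses[[k]]) * d) -
      2 * log(object@prior[k]) + object@logDets[k]
  }
  object@classes[max.col(-cost, ties.method = "first")]
})

#' Fit a k-nearest-neighbour model
#'
#' Stores the training set standardised per feature (zero mean, unit
#' variance; constant features keep scale 1) so Euclidean distance is
#' not dominated by large-scale features such as area.
#'
#' @inheritParams ldaFit
#' @param k neighbour count, default 5.
#' @param standardize standardise features before distance computation
#'   (default TRUE).
#' @return a [KnnModel-class].
#' @export
knnFit <- function(x, labels, k = 5L, standardize = TRUE) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stopShape("one label per row required")
  k <- as.integer(k)
  if (k < 1L || k > nrow(x))
    stopParameter("k must lie in [1, ", nrow(x), "]")
  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")
  new("KnnModel", x = xs, labels = labels, classes = unique(labels),
      k = k, center = center, scale = scl)
}

#' @describeIn predictLabels majority label among the k Euclidean-nearest
#'   training points; vote ties break to the class owning the nearest
#'   single neighbour among the tied classes, then to the earliest class
#'   in fit order.
#' @export
setMethod("predictLabels", "KnnModel", function(object, newdata) {
  newdata <- as2dMatrix(newdata, ncol(object@x))
  q <- sweep(sweep(newdata, 2L, object@center), 2L, object@scale, "/")
  trainSq <- rowSums(object@x^2)
  out <- character(nrow(q))
  for (i in seq_len(nrow(q))) {
    d2 <- trainSq - 2 * drop(object@x %*% q[i, ]) + sum(q[i, ]^2)
    ord <- order(d2, seq_along(d2))     # stable for exact distance ties
    nb <- ord[seq_len(object@k)]
    votes <- table(factor(object@labels[nb], levels = object@classes))
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) { out[i] <- top; next }
    # nearest single neighbour among tied classes, then lowest class index
    firstHit <- vapply(top, function(cl)
      min(which(object@labels[nb] == cl)), 0L)
    out[i] <- top[order(firstHit, match(top, object@classes))[1L]]
  }
  out
})

#' Grade fruit maturity
#'
#' Applies the trained maturity classifier to the colour/entropy
#' sub-vector of the features (`R`, `G`, `B`, `minEntropy`, `maxEntropy`,
#' `textureCoefficient`) and returns `u`, `m` or `r`.
#'
#' @param features named feature vector (or matrix with named columns)
#'   from [extractFeatures()].
#' @param models a trained [ModelSet-class] from [trainModels()].
#' @return character maturity grade(s).
#' @export
assessMaturity <- function(features, models) {
  stopifnot(is(models, "ModelSet"))
  if (is.null(models@maturity)) stopState("maturity classifier not trained")
  predictLabels(models@maturity,
                featureSubset(features, models@featureNames$maturity))
}

#' Classify fruit health
#'
#' Healthy-versus-risky decision from the full feature vector; the
#' cluster-contrast and lesion descriptors carry most of the signal.
#'
#' @inheritParams assessMaturity
#' @return `"healthy"` or `"risky"` per sample.
#' @export
classifyHealth <- function(features, models) {
  stopifnot(is(models, "ModelSet"))
  if (is.null(models@health)) stopState("health classifier not trained")
  predictLabels(models@health,
                featureSubset(features, models@featureNames$health))
}

#' Assign a disease archetype
#'
#' For samples judged risky, predicts one of the five rendered
#' archetypes from the lesion descriptors (lesion chromaticity, relative
#' area, spot count and shape scores). Healthy samples return `"none"`
#' with a warning, as the archetype question only makes sense on
#' infected fruit.
#'
#' @inheritParams assessMaturity
#' @param health health label(s) previously assigned to the sample(s).
#' @return archetype label(s), `"none"` for healthy samples.
#' @export
classifyDisease <- function(features, models, health = "risky") {
  stopifnot(is(models, "ModelSet"))
  if (is.null(models@disease)) stopState("disease classifier not trained")
  x <- featureSubset(features, models@featureNames$disease)
  health <- rep_len(health, nrow(x))
  out <- rep("none", nrow(x))
  if (any(health == "healthy"))
    warning("classifyDisease called on healthy sample(s); returning \"none\"")
  if (any(health != "healthy"))
    out[health != "healthy"] <-
      predictLabels(models@disease, x[health != "healthy", , drop = FALSE])
  out
}

featureSubset <- function(features, cols) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  features <- as.matrix(features)
  missing <- setdiff(cols, colnames(features))
  if (length(missing))
    stopShape("feature columns missing: ", paste(missing, collapse = ", "))
  taskTransform(features[, cols, drop = FALSE])
}
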