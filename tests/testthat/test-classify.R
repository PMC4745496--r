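test_that("PCA matches closed forms and an independent eigen oracle", {
  # points exactly on y = 2x: first direction prop. (1,2)/sqrt(5)
  t <- seq(-3, 3, length.out = 21)
  xy <- cbind(t, 2 * t)
  m <- pcaFit(xy)
  v1 <- m@rotation[, 1]
  expect_equal(abs(sum(v1 * c(1, 2) / sqrt(5))), 1, tolerance = 1e-10)
  expect_equal(m@eigenvalues[2], 0, tolerance = 1e-10)
  # full retention reconstructs the centred data exactly
  set.seed(1)
  x <- matrix(rnorm(40, sd = 3), 10, 4)
  mFull <- pcaFit(x)
  proj <- pcaTransform(mFull, x)
  rec <- proj %*% t(mFull@rotation)
  expect_equal(rec, sweep(x, 2, colMeans(x)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # eigenvalues agree with characteristic-polynomial root finding
  C <- stats::cov(x)
  roots <- sort(Re(polyroot(rev(pracma::charpoly(C)))), decreasing = TRUE)
  expect_equal(mFull@eigenvalues, roots, tolerance = 1e-8)
  # eigenvector property C v = lambda v, orthonormality
  for (j in 1:4)
    expect_equal(as.vector(C %*% mFull@rotation[, j]),
                 mFull@eigenvalues[j] * mFull@rotation[, j],
                 tolerance = 1e-8)
  expect_equal(crossprod(mFull@rotation), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  # trace identity: eigenvalue sum = total variance
  expect_equal(sum(mFull@eigenvalues), sum(diag(C)), tolerance = 1e-8)
  expect_error(pcaFit(x[1, , drop = FALSE]), class = "tvDataError")
})

test_that("PCA projection bookkeeping", {
  set.seed(2)
  x <- matrix(rnorm(60), 15, 4)
  m <- pcaFit(x, nComponents = 2)
  # the model's own centre projects to the origin
  expect_equal(as.vector(pcaTransform(m, m@center)), c(0, 0),
               tolerance = 1e-12)
  # variance along component j is lambda_j
  proj <- pcaTransform(m, x)
  expect_equal(apply(proj, 2, stats::var), m@eigenvalues[1:2],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(pcaTransform(m, matrix(0, 2, 3)), class = "tvShapeError")
})

test_that("LDA finds the symmetric two-class direction and scores 100%", {
  set.seed(3)
  n <- 60
  a <- matrix(rnorm(2 * n), n, 2)
  b <- matrix(rnorm(2 * n), n, 2) + 10
  x <- rbind(a, b)
  y <- rep(c("a", "b"), each = n)
  m <- ldaFit(x, y)
  d <- m@directions[, 1]
  expect_equal(abs(sum(d * c(1, 1) / sqrt(2))), 1, tolerance = 0.05)
  expect_identical(predictLabels(m, x), y)
  expect_error(ldaFit(a, rep("a", n)), class = "tvDataError")
  # class means predict to their own class; equidistant point ties to
  # the first-fit class under equal priors
  expect_identical(predictLabels(m, m@means), m@classes)
  expect_identical(predictLabels(m, c(5, 5)), "a")
})

test_that("LDA direction maximises the Fisher ratio over random probes", {
  set.seed(4)
  x <- rbind(matrix(rnorm(40), 20, 2),
             matrix(rnorm(40, 3), 20, 2),
             cbind(rnorm(20, 6), rnorm(20, -2)))
  y <- rep(c("a", "b", "c"), each = 20)
  m <- ldaFit(x, y)
  sm <- local({
    grand <- colMeans(x)
    Sw <- matrix(0, 2, 2); Sb <- matrix(0, 2, 2)
    for (cl in unique(y)) {
      xi <- x[y == cl, ]
      Sw <- Sw + crossprod(sweep(xi, 2, colMeans(xi)))
      Sb <- Sb + nrow(xi) * tcrossprod(colMeans(xi) - grand)
    }
    list(Sw = Sw, Sb = Sb)
  })
  fisher <- function(d) (t(d) %*% sm$Sb %*% d) / (t(d) %*% sm$Sw %*% d)
  ours <- fisher(m@directions[, 1])
  for (i in 1:1000) {
    d <- rnorm(2)
    expect_lte(fisher(d / sqrt(sum(d^2)))[1], ours[1] + 1e-9)
  }
})

test_that("LDA predictions agree with an independent implementation", {
  set.seed(5)
  x <- rbind(matrix(rnorm(100), 50, 2),
             matrix(rnorm(100, 2.5), 50, 2))
  y <- rep(c("a", "b"), each = 50)
  m <- ldaFit(x, y)
  ref <- MASS::lda(x, grouping = y)
  grid <- as.matrix(expand.grid(seq(-3, 6, 0.5), seq(-3, 6, 0.5)))
  dimnames(grid) <- NULL
  ours <- predictLabels(m, grid)
  theirs <- as.character(predict(ref, grid)$class)
  expect_gt(mean(ours == theirs), 0.99)
})

test_that("QDA recovers generator parameters at large n", {
  set.seed(6)
  n <- 10000
  mu1 <- c(0, 1, -1); mu2 <- c(2, -1, 0.5)
  A1 <- matrix(c(1, 0.3, 0, 0.3, 1.2, -0.2, 0, -0.2, 0.8), 3, 3)
  S1 <- crossprod(A1); S2 <- diag(c(0.5, 1.5, 1))
  x1 <- matrix(rnorm(3 * n), n, 3) %*% chol(S1) + rep(mu1, each = n)
  x2 <- matrix(rnorm(3 * n), n, 3) %*% chol(S2) + rep(mu2, each = n)
  m <- qdaFit(rbind(x1, x2), rep(c("g1", "g2"), each = n))
  expect_lt(max(abs(m@means[1, ] - mu1)), 0.05)
  expect_lt(max(abs(m@means[2, ] - mu2)), 0.05)
  frob <- function(A) sqrt(sum(A^2))
  expect_lt(frob(m@covariances[[1]] - S1) / frob(S1), 0.05)
  expect_lt(frob(m@covariances[[2]] - S2) / frob(S2), 0.05)
  expect_equal(sum(m@prior), 1)
})

test_that("QDA rule matches direct evaluation of the quadratic form", {
  set.seed(7)
  x <- rbind(matrix(rnorm(60), 30, 2),
             matrix(rnorm(60, 2, 2), 30, 2))
  y <- rep(c("a", "b"), each = 30)
  m <- qdaFit(x, y)
  pts <- matrix(rnorm(40, 1, 2), 20, 2)
  direct <- apply(pts, 1, function(p) {
    cost <- vapply(seq_along(m@classes), function(k) {
      d <- p - m@means[k, ]
      drop(t(d) %*% solve(m@covariances[[k]]) %*% d) -
        2 * log(m@prior[k]) +
        determinant(m@covariances[[k]], logarithm = TRUE)$modulus
    }, 0)
    m@classes[which.min(cost)]
  })
  expect_identical(predictLabels(m, pts), unname(direct))
  # class means with equal priors and covariances map to themselves
  xb <- rbind(x[1:30, ], x[1:30, ] + 5)
  mb <- qdaFit(xb, y)
  expect_identical(predictLabels(mb, mb@means), mb@classes)
  # agreement with an independent implementation
  ref <- MASS::qda(x, grouping = y)
  expect_gt(mean(predictLabels(m, pts) ==
                 as.character(predict(ref, pts)$class)), 0.94)
})

test_that("QDA with equal covariances reduces to LDA on a grid", {
  set.seed(8)
  base <- matrix(rnorm(200), 100, 2)
  x <- rbind(base, sweep(base, 2, c(-4, 3), "+"))  # identical class shape
  y <- rep(c("a", "b"), each = 100)
  qm <- qdaFit(x, y)
  lm_ <- ldaFit(x, y)
  grid <- as.matrix(expand.grid(seq(-6, 4, 0.25), seq(-4, 6, 0.25)))
  expect_gt(mean(predictLabels(qm, grid) == predictLabels(lm_, grid)), 0.99)
})

test_that("QDA handles degenerate classes via regularisation", {
  x <- cbind(c(rnorm(10), rnorm(10, 5)), rep(1, 20))  # constant feature
  y <- rep(c("a", "b"), each = 10)
  m <- qdaFit(x, y)
  expect_identical(length(m@covInverses), 2L)
  expect_true(all(is.finite(m@logDets)))
  expect_identical(predictLabels(m, c(0, 1)), "a")
})

test_that("KNN matches a brute-force neighbour sort with stated tie rules", {
  set.seed(9)
  x <- matrix(rnorm(100), 50, 2)
  y <- sample(c("a", "b", "c"), 50, replace = TRUE)
  m <- knnFit(x, y, k = 5, standardize = FALSE)
  pts <- matrix(rnorm(30), 15, 2)
  brute <- apply(pts, 1, function(p) {
    d <- sqrt(colSums((t(x) - p)^2))
    nb <- order(d)[1:5]
    votes <- table(factor(y[nb], levels = unique(y)))
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    # nearest single neighbour among tied classes, then fit order
    for (i in nb) if (y[i] %in% top) return(y[i])
  })
  expect_identical(predictLabels(m, pts), unname(brute))
  # agreement with an independent implementation (no vote ties: k odd,
  # two classes)
  y2 <- rep(c("a", "b"), 25)
  m2 <- knnFit(x, y2, k = 5, standardize = FALSE)
  ref <- as.character(class::knn(x, pts, factor(y2), k = 5))
  expect_identical(predictLabels(m2, pts), ref)
})

test_that("KNN degenerate contracts: exact hit, k = n, pair tie", {
  x <- matrix(c(0, 0, 1, 1, 4, 4), 3, 2, byrow = TRUE)
  y <- c("a", "b", "b")
  m1 <- knnFit(x, y, k = 1, standardize = FALSE)
  expect_identical(predictLabels(m1, x), y)   # zero distance wins
  # k = n predicts the global majority everywhere
  mAll <- knnFit(x, y, k = 3, standardize = FALSE)
  set.seed(10)
  pts <- matrix(rnorm(20, 2), 10, 2)
  expect_identical(unique(predictLabels(mAll, pts)), "b")
  # k = 2 with one neighbour of each label: the nearer one decides
  m2 <- knnFit(x[1:2, ], y[1:2], k = 2, standardize = FALSE)
  expect_identical(predictLabels(m2, c(0.1, 0.1)), "a")
  expect_identical(predictLabels(m2, c(0.9, 0.9)), "b")
  expect_error(knnFit(x, y, k = 4), class = "tvParameterError")
  expect_error(knnFit(x, y, k = 0), class = "tvParameterError")
})

test_that("classifiers are deterministic across repeated fits", {
  set.seed(11)
  x <- matrix(rnorm(80), 40, 2)
  y <- rep(c("a", "b"), 20)
  pts <- matrix(rnorm(20), 10, 2)
  for (fit in list(ldaFit, qdaFit, function(x, y) knnFit(x, y, k = 3))) {
    m1 <- fit(x, y); m2 <- fit(x, y)
    expect_identical(predictLabels(m1, pts), predictLabels(m2, pts))
  }
})
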