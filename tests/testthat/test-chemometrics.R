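# PCA/Q/T2 screening, dataset splitting, NIPALS PLS and cross-validation.

test_that("range-covering split reproduces the 80/20 bookkeeping", {
  set.seed(1)
  y <- rnorm(144)
  s <- splitIndices(y, fraction = 0.8, seed = 1)
  expect_equal(sum(s == "calibration"), 116L)
  expect_equal(sum(s == "validation"), 28L)

  s2 <- splitIndices(c(1, 2), fraction = 0.5, seed = 1)
  expect_equal(sort(s2), c("calibration", "validation"))

  # validation range within the full range; calibration covers the range
  covered <- 0
  for (seed in 1:20) {
    sp <- splitIndices(y, 0.8, seed)
    yv <- y[sp == "validation"]
    yc <- y[sp == "calibration"]
    expect_gte(min(yv), min(y))
    expect_lte(max(yv), max(y))
    if (diff(range(yc)) >= 0.9 * diff(range(y))) covered <- covered + 1
  }
  expect_gte(covered, 20 * 0.9)
  expect_error(splitIndices(y, 1.2), "fraction")
  expect_identical(splitIndices(y, 0.8, 5), splitIndices(y, 0.8, 5))
})

test_that("pca matches a brute-force covariance eigendecomposition", {
  set.seed(10)
  X <- matrix(rnorm(20 * 8), 20, 8)
  pca <- pcaFit(X, k = 5)
  eig <- eigen(cov(X), symmetric = TRUE)
  expect_equal(pca@eigenvalues[1:8], eig$values, tolerance = 1e-8)
  for (j in 1:5)
    expect_equal(abs(sum(pca@loadings[, j] * eig$vectors[, j])), 1,
                 tolerance = 1e-8)

  same <- matrix(rep(1:4, each = 5), 5, 4)
  p0 <- pcaFit(same, k = 1)
  expect_equal(p0@eigenvalues, rep(0, 4), tolerance = 1e-12)
  expect_equal(as.numeric(pcaScores(p0, same)), rep(0, 5), tolerance = 1e-12)

  r1 <- outer(rnorm(6), rnorm(4))
  pr <- pcaFit(r1, k = 1)
  expect_equal(max(qStatistic(pr, r1)), 0, tolerance = 1e-12)
  expect_error(pcaFit(X, k = 30), "k must be")
})

test_that("Q and T2 statistics match brute-force projections", {
  set.seed(11)
  X <- matrix(rnorm(30 * 10), 30, 10)
  pca <- pcaFit(X, k = 3)
  xbar <- colMeans(X)
  expect_equal(qStatistic(pca, xbar), 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(t2Statistic(pca, xbar), 0, tolerance = 1e-12,
               ignore_attr = TRUE)

  c0 <- 2.5
  along <- xbar + c0 * pca@loadings[, 1]
  expect_equal(qStatistic(pca, along), 0, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(t2Statistic(pca, along), c0^2 / pca@eigenvalues[1],
               tolerance = 1e-10, ignore_attr = TRUE)

  # brute-force oracle on random samples
  P <- pca@loadings
  for (i in 1:5) {
    xc <- X[i, ] - xbar
    proj <- P %*% (t(P) %*% xc)
    expect_equal(qStatistic(pca, X[i, ]), sum((xc - proj)^2),
                 tolerance = 1e-10, ignore_attr = TRUE)
    t2hand <- sum((t(P) %*% xc)^2 / pca@eigenvalues[1:3])
    expect_equal(t2Statistic(pca, X[i, ]), t2hand, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("control limits behave asymptotically and monotonically", {
  set.seed(12)
  X <- matrix(rnorm(5000 * 3), 5000, 3)
  pca <- pcaFit(X, k = 1)
  lim <- controlLimits(pca, 0.99)
  expect_equal(lim[["t2"]], qchisq(0.99, 1), tolerance = 0.01)

  X2 <- matrix(rnorm(100 * 6), 100, 6)
  p2 <- pcaFit(X2, k = 2)
  l50 <- controlLimits(p2, 0.5)
  l99 <- controlLimits(p2, 0.99)
  expect_lt(l50[["q"]], l99[["q"]])
  expect_lt(l50[["t2"]], l99[["t2"]])
  expect_error(controlLimits(p2, 1.5), "alpha")
})

test_that("joint Q/T2 rule flags injected anomalies and not clean data", {
  set.seed(13)
  n <- 60
  scoresTrue <- matrix(rnorm(n * 3), n, 3) %*% diag(c(4, 2, 1))
  load <- qr.Q(qr(matrix(rnorm(12 * 3), 12, 3)))
  X <- scoresTrue %*% t(load) + matrix(rnorm(n * 12, sd = 0.05), n, 12)
  # the joint rule needs the anomaly to be extreme both within the model
  # subspace (T2) and off it (Q): scale one sample and add a channel spike
  # at ten times the noise amplitude
  spiked <- X
  spiked[7, ] <- 3 * spiked[7, ]
  spiked[7, 3] <- spiked[7, 3] + 0.5
  res <- detectOutliers(spiked)
  expect_true(res$flagged[7])
  expect_lte(sum(res$flagged), 2)

  expect_warning(out1 <- detectOutliers(X[1, , drop = FALSE]), "fewer than 2")
  expect_equal(out1$flagged, FALSE)
})

test_that("NIPALS PLS collapses to least squares where it must", {
  # p = 1: identical to the simple regression line
  set.seed(14)
  x <- rnorm(20)
  y <- 2 + 3 * x + rnorm(20, sd = 0.1)
  m <- plsFit(matrix(x), y, nLV = 1)
  ls <- lm(y ~ x)
  expect_equal(predict(m, matrix(x)), unname(fitted(ls)), tolerance = 1e-10)

  # full rank: equals the minimum-norm least-squares fit (pseudoinverse)
  X <- matrix(rnorm(15 * 6), 15, 6)
  yy <- rnorm(15)
  mf <- plsFit(X, yy, nLV = 6)
  Xc <- sweep(X, 2, colMeans(X))
  bPinv <- MASS::ginv(Xc) %*% (yy - mean(yy))
  expect_equal(predict(mf, X), as.numeric(mean(yy) + Xc %*% bPinv),
               tolerance = 1e-8)

  # exact recovery of a 3-factor structure with noiseless response
  T3 <- matrix(rnorm(40 * 3), 40, 3)
  P3 <- matrix(rnorm(10 * 3), 10, 3)
  X3 <- T3 %*% t(P3)
  y3 <- T3 %*% c(1, -2, 0.5)
  m3 <- plsFit(X3, as.numeric(y3), nLV = 3)
  expect_lt(max(abs(predict(m3, X3) - y3)), 1e-8)

  expect_error(plsFit(X, yy, nLV = 20), "nLV")
  expect_error(plsFit(X, rep(1, 15), nLV = 2), "zero-variance")
})

test_that("PLS is deterministic", {
  set.seed(15)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  expect_identical(plsFit(X, y, 4)@coef, plsFit(X, y, 4)@coef)
})

test_that("venetian blinds interleave folds by index", {
  expect_equal(venetianBlinds(10, 10), 0:9)
  f <- venetianBlinds(116, 10)
  expect_equal(f[1:12], c(0:9, 0:1))
  sizes <- as.integer(table(f))
  expect_equal(sort(sizes, decreasing = TRUE), c(rep(12L, 6), rep(11L, 4)))
  expect_equal(sort(unique(f)), 0:9)
  expect_error(venetianBlinds(5, 10), "at least as many")
})

test_that("cross-validation selects a parsimonious latent structure", {
  set.seed(16)
  T3 <- matrix(rnorm(50 * 3), 50, 3)
  P3 <- matrix(rnorm(12 * 3), 12, 3)
  X <- T3 %*% t(P3)
  y <- as.numeric(T3 %*% c(2, -1, 0.5))
  cv <- crossValidate(X, y, maxLV = 8, nFolds = 10)
  expect_lt(cv$rmsecv[3], 1e-6)
  expect_lte(cv$nLV, 4)

  # every sample held out exactly once
  expect_equal(sort(unique(cv$folds)), 0:9)
  expect_equal(length(cv$cvPred), 50)
  expect_true(all(is.finite(cv$cvPred)))

  # pure noise: little structure to find
  yn <- rnorm(50)
  cvn <- crossValidate(X, yn, maxLV = 8, nFolds = 10)
  expect_lte(cvn$nLV, 5)

  cv1 <- crossValidate(X, y, maxLV = 1, nFolds = 10)
  expect_equal(cv1$nLV, 1L)
})

test_that("model statistics match independent arithmetic", {
  set.seed(17)
  x <- rnorm(24)
  y <- 1 + 2 * x + rnorm(24, sd = 0.3)
  X <- matrix(x)
  cal <- 1:20
  val <- 21:24
  cv <- crossValidate(X[cal, , drop = FALSE], y[cal], maxLV = 1, nFolds = 10)
  m <- plsFit(X[cal, , drop = FALSE], y[cal], 1, analyte = "demo")
  st <- modelStatistics(m, X[cal, , drop = FALSE], y[cal],
                        X[val, , drop = FALSE], y[val], cv)
  predCal <- predict(m, X[cal, , drop = FALSE])
  predVal <- predict(m, X[val, , drop = FALSE])
  expect_equal(st$rmsec, sqrt(sum((y[cal] - predCal)^2) / 20), tolerance = 1e-12)
  expect_equal(st$r2_c,
               1 - sum((y[cal] - predCal)^2) / sum((y[cal] - mean(y[cal]))^2),
               tolerance = 1e-12)
  expect_equal(st$rmsep, sqrt(sum((y[val] - predVal)^2) / 4), tolerance = 1e-12)
  expect_equal(st$n_lv, 1L)
  expect_equal(st$n, 20L)

  # definition anchors: perfect predictions and mean predictor
  yv <- c(1, 2, 3, 4)
  expect_equal(sqrt(mean((yv - yv)^2)), 0)
  expect_equal(1 - sum((yv - mean(yv))^2) / sum((yv - mean(yv))^2), 0)
})

test_that("RMSEC does not typically exceed RMSECV", {
  diffs <- numeric(20)
  for (s in 1:20) {
    set.seed(200 + s)
    X <- matrix(rnorm(40 * 15), 40, 15)
    y <- X %*% rnorm(15, sd = 0.3) + rnorm(40, sd = 0.5)
    cv <- crossValidate(X, as.numeric(y), maxLV = 5, nFolds = 5)
    m <- plsFit(X, as.numeric(y), cv$nLV)
    rmsec <- sqrt(mean((as.numeric(y) - predict(m, X))^2))
    diffs[s] <- sqrt(mean((as.numeric(y) - cv$cvPred)^2)) - rmsec
  }
  expect_gt(median(diffs), 0)
})
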