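# The synthetic vineyard generator: layout geometry, chemistry fields,
# stream mechanics and the manual signature.

test_that("layout produces the expected block grid", {
  lay <- vineyardLayout(rows = 3, blocksPerRow = 12)
  expect_equal(nrow(lay$blocks), 36)
  expect_equal(anyDuplicated(lay$blocks$block_id), 0L)

  one <- vineyardLayout(rows = 1, blocksPerRow = 1, vinesPerBlock = 5,
                        vineSpacing = 1, origin = c(10, 20))
  expect_equal(c(one$blocks$x, one$blocks$y), c(10 + 2.5, 20))

  # hand geometry oracle for a 2 x 2 grid
  g <- vineyardLayout(rows = 2, blocksPerRow = 2, vinesPerBlock = 5,
                      vineSpacing = 1, rowSpacing = 2.2)$blocks
  expected <- rbind(c(2.5, 0), c(7.5, 0), c(2.5, 2.2), c(7.5, 2.2))
  expect_equal(unname(cbind(g$x, g$y)), expected)
  d <- as.matrix(dist(expected))
  expect_equal(as.matrix(dist(cbind(g$x, g$y))), d)
  expect_error(vineyardLayout(rows = 0), "positive")
})

test_that("rotated layouts preserve pairwise geometry", {
  g0 <- vineyardLayout(rows = 2, blocksPerRow = 3)$blocks
  g45 <- vineyardLayout(rows = 2, blocksPerRow = 3, rowAzimuth = 45)$blocks
  expect_equal(as.numeric(dist(cbind(g45$x, g45$y))),
               as.numeric(dist(cbind(g0$x, g0$y))), tolerance = 1e-12)
})

test_that("chemistry respects ranges, limits and ripening monotonicity", {
  lay <- vineyardLayout()
  params <- analyteFieldParams()
  chem <- generateChemistry(lay, params, nDates = 4, seed = 3)
  for (a in c("tss", "anthocyanins", "polyphenols")) {
    r <- params[[a]]$globalRange
    expect_true(all(chem[[a]] >= r[1] & chem[[a]] <= r[2]))
  }

  # fully correlated limit: one value per analyte per date
  pInf <- analyteFieldParams(correlationLength = Inf)
  for (a in c("tss", "anthocyanins", "polyphenols")) pInf[[a]]$noiseSd <- 0
  cInf <- generateChemistry(lay, pInf, nDates = 2, seed = 5)
  for (d in 1:2)
    expect_equal(length(unique(round(cInf$tss[cInf$date_index == d], 10))), 1L)

  # strictly increasing date means, zero noise -> strictly increasing blocks
  p0 <- analyteFieldParams()
  for (a in c("tss", "anthocyanins", "polyphenols")) p0[[a]]$noiseSd <- 0
  c0 <- generateChemistry(lay, p0, nDates = 4, seed = 5)
  m <- tapply(c0$tss, c0$date_index, mean)
  expect_true(all(diff(m) > 0))

  expect_error(generateChemistry(lay, params, nDates = 0), "nDates")
})

test_that("chemistry is reproducible and spatially autocorrelated", {
  skip_if_not_installed("ape")
  lay <- vineyardLayout()
  a <- generateChemistry(lay, nDates = 4, seed = 11)
  b <- generateChemistry(lay, nDates = 4, seed = 11)
  expect_identical(a, b)

  # permutation oracle: observed Moran's I beats a permuted field >= 9/10
  coords <- cbind(lay$blocks$x, lay$blocks$y)
  W <- 1 / as.matrix(dist(coords))
  diag(W) <- 0
  wins <- 0
  for (s in 1:10) {
    chem <- generateChemistry(lay, nDates = 1, seed = 100 + s)
    f <- chem$tss
    obs <- ape::Moran.I(f, W)$observed
    set.seed(999 + s)
    perm <- ape::Moran.I(sample(f), W)$observed
    wins <- wins + (obs > perm)
  }
  expect_gte(wins, 9)
})

test_that("stream length follows the acquisition geometry", {
  # floor(5 m / (5 km/h) * 18 Hz) = 64 spectra per 5-vine block pass
  expect_equal(floor(5 / (5000 / 3600) * 18), 64)
  world <- defaultWorld()
  counts <- vapply(world$streams[["1"]], nSpectra, 1L)
  expect_true(all(counts == 64L))
  expect_true(all(vapply(world$streams[["1"]], nChannels, 1L) == 215L))
})

test_that("noise-free single-class streams are constant and deterministic", {
  lay <- vineyardLayout()
  sim <- simConfig(classMixture = c(cluster = 1), scatterSlopeSd = 0,
                   scatterOffsetSd = 0, channelNoiseSd = 0,
                   passSlopeSd = 0, passOffsetSd = 0, passShapeSd = 0)
  chem <- generateChemistry(lay, nDates = 1, seed = 1)
  st <- simulateStream(lay$blocks[1, ], chem[1, ], defaultEndmembers(sim$wavelengths),
                       sim, layout = lay, seed = 4)
  m <- spectraMatrix(st)
  expect_equal(m[1, ], m[2, ], tolerance = 1e-15)

  st2 <- simulateStream(lay$blocks[1, ], chem[1, ], defaultEndmembers(sim$wavelengths),
                        sim, layout = lay, seed = 4)
  expect_identical(spectraMatrix(st), spectraMatrix(st2))
})

test_that("doubling spectral SNR doubles the analyte imprint", {
  # variance-decomposition oracle: the concentration-regression slope at the
  # band centre doubles with SNR, so attributable variance quadruples
  lay <- vineyardLayout()
  sim <- simConfig(classMixture = c(cluster = 1), scatterSlopeSd = 0,
                   scatterOffsetSd = 0, channelNoiseSd = 0,
                   passSlopeSd = 0, passOffsetSd = 0, passShapeSd = 0)
  em <- defaultEndmembers(sim$wavelengths)
  p1 <- analyteFieldParams()
  p2 <- analyteFieldParams()
  p2$tss$spectralSnr <- 2 * p1$tss$spectralSnr
  chem <- generateChemistry(lay, p1, nDates = 1, seed = 2)
  bandCh <- which.min(abs(sim$wavelengths - em$cluster$bands$tss$center))
  getVals <- function(params) vapply(1:10, function(b) {
    spectraMatrix(simulateStream(lay$blocks[b, ], chem[b, ], em, sim, params,
                                 lay, seed = 50))[1, bandCh]
  }, numeric(1))
  s1 <- coef(lm(getVals(p1) ~ chem$tss[1:10]))[2]
  s2 <- coef(lm(getVals(p2) ~ chem$tss[1:10]))[2]
  expect_equal(unname(s2 / s1), 2, tolerance = 1e-8)
})

test_that("class labels follow the configured mixture", {
  # pooled cluster count over 50 seeds within the binomial 99% band
  lay <- vineyardLayout()
  sim <- simConfig()
  em <- defaultEndmembers(sim$wavelengths)
  chem <- generateChemistry(lay, nDates = 1, seed = 1)
  total <- 0L
  nTot <- 0L
  for (s in 1:50) {
    st <- simulateStream(lay$blocks[1, ], chem[1, ], em, sim, layout = lay,
                         seed = 1000 + s)
    total <- total + sum(classLabels(st) == "cluster")
    nTot <- nTot + nSpectra(st)
  }
  lo <- qbinom(0.005, nTot, 0.35)
  hi <- qbinom(0.995, nTot, 0.35)
  expect_gte(total, lo)
  expect_lte(total, hi)
})

test_that("signature matches the cluster endmember and converges", {
  sim0 <- simConfig(scatterSlopeSd = 0, scatterOffsetSd = 0,
                    channelNoiseSd = 0)
  em <- defaultEndmembers(sim0$wavelengths)
  params <- analyteFieldParams()
  sig0 <- makeSignature(em, sim0, params, nSpectraAvg = 1, seed = 1)
  base <- em$cluster$base
  for (a in c("tss", "anthocyanins", "polyphenols")) {
    b <- em$cluster$bands[[a]]
    base <- base + params[[a]]$spectralSnr * 0.5 *
      exp(-((sim0$wavelengths - b$center) / b$width)^2)
  }
  expect_equal(spectraMatrix(sig0), base, tolerance = 1e-12)

  sim <- simConfig()
  expect_equal(nChannels(makeSignature(em, sim, params, 5, seed = 2)), 215L)
  devSmall <- max(abs(spectraMatrix(makeSignature(em, sim, params, 4, seed = 3)) - base))
  devLarge <- max(abs(spectraMatrix(makeSignature(em, sim, params, 400, seed = 3)) - base))
  expect_lt(devLarge, devSmall)
  expect_error(makeSignature(em, sim, params, 0), "nSpectraAvg")
})
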