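# Multilevel B-spline approximation and prediction maps.

scatterFixture <- function(n = 36, seed = 21) {
  set.seed(seed)
  data.frame(x = runif(n, 0, 60), y = runif(n, 0, 10),
             z = sin(runif(n, 0, 3)) + runif(n, 0, 0.5))
}

test_that("constant fields are reproduced everywhere", {
  pts <- scatterFixture()
  s <- mbaFit(pts$x, pts$y, rep(4.2, nrow(pts)), nLevels = 4)
  gx <- seq(min(pts$x), max(pts$x), length.out = 20)
  gy <- seq(min(pts$y), max(pts$y), length.out = 10)
  g <- expand.grid(x = gx, y = gy)
  expect_equal(mbaEvaluate(s, g$x, g$y), rep(4.2, nrow(g)), tolerance = 1e-9)
})

test_that("a single point is interpolated exactly", {
  s <- mbaFit(3, 7, 2.5, nLevels = 3)
  expect_equal(mbaEvaluate(s, 3, 7), 2.5, tolerance = 1e-9)
})

test_that("multilevel residuals shrink below 1e-3 of the data range", {
  pts <- scatterFixture()
  s <- mbaFit(pts$x, pts$y, pts$z, nLevels = 8)
  resid <- mbaResidual(s, pts$x, pts$y, pts$z)
  expect_lt(resid, 1e-3 * diff(range(pts$z)))
})

test_that("residual max-norm is non-increasing in levels", {
  pts <- scatterFixture(seed = 22)
  resids <- vapply(1:8, function(L)
    mbaResidual(mbaFit(pts$x, pts$y, pts$z, nLevels = L), pts$x, pts$y, pts$z),
    numeric(1))
  expect_true(all(diff(resids) <= 1e-12))
})

test_that("surfaces are translation and value-scale equivariant", {
  pts <- scatterFixture(seed = 23)
  s0 <- mbaFit(pts$x, pts$y, pts$z, nLevels = 5)
  sT <- mbaFit(pts$x + 100, pts$y - 50, pts$z, nLevels = 5)
  sS <- mbaFit(pts$x, pts$y, 3 * pts$z, nLevels = 5)
  qx <- quantile(pts$x, c(0.2, 0.5, 0.8))
  qy <- quantile(pts$y, c(0.2, 0.5, 0.8))
  v0 <- mbaEvaluate(s0, qx, qy)
  expect_equal(mbaEvaluate(sT, qx + 100, qy - 50), v0, tolerance = 1e-9)
  expect_equal(mbaEvaluate(sS, qx, qy), 3 * v0, tolerance = 1e-9)
})

test_that("rasters sample the same pointwise function at any resolution", {
  pts <- scatterFixture(seed = 24)
  bbox <- c(0, 60, 0, 10)
  s <- mbaFit(pts$x, pts$y, pts$z, nLevels = 6, bbox = bbox)
  coarse <- mbaMap(s, list(origin = c(0, 0), cellSize = 2, nCols = 30,
                           nRows = 5))
  fine <- mbaMap(s, list(origin = c(0, 0), cellSize = 1, nCols = 60,
                         nRows = 10))
  # the 2 m cell centre (1, 1) equals no fine-cell centre, so compare by
  # evaluating the surface directly at the coarse centres
  cx <- (seq_len(30) - 0.5) * 2
  expect_equal(coarse@values[1, ], mbaEvaluate(s, cx, rep(1, 30)),
               tolerance = 1e-12)
  # and a fine raster restricted to shared area reproduces the surface too
  fx <- (seq_len(60) - 0.5) * 1
  expect_equal(fine@values[1, ], mbaEvaluate(s, fx, rep(0.5, 60)),
               tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(mbaFit(1:3, 1:3, 1:3, bbox = c(0, 0, 0, 1)), "zero area")
  expect_error(mbaFit(1:3, 1:3, c(1, NA, 3)), "finite")
  pts <- scatterFixture()
  s <- mbaFit(pts$x, pts$y, pts$z, nLevels = 3)
  expect_error(mbaEvaluate(s, 1e6, 0), "outside")
  expect_error(mbaMap(s, list(origin = c(-100, 0), cellSize = 1, nCols = 5,
                              nRows = 5)), "outside")
})

test_that("map series share grid and scale and track ripening", {
  world <- defaultWorld()
  blocks <- world$layout$blocks
  chem <- world$chemistry
  byDate <- lapply(split(chem, chem$date_index), function(df)
    data.frame(x = blocks$x[match(df$block_id, blocks$block_id)],
               y = blocks$y[match(df$block_id, blocks$block_id)],
               value = df$tss))
  maps <- renderSeries(byDate, blocks, analyte = "tss")
  expect_equal(length(maps), 4L)
  zl <- t(vapply(maps, function(m) m@zlim, numeric(2)))
  expect_true(all(zl[, 1] == zl[1, 1] & zl[, 2] == zl[1, 2]))
  means <- vapply(maps, function(m) mean(m@values, na.rm = TRUE), numeric(1))
  expect_true(all(diff(means) > 0))   # monotone ripening propagates to maps

  one <- renderSeries(byDate[1], blocks, analyte = "tss")
  expect_equal(length(one), 1L)

  # anthocyanins and polyphenols are spatially coupled
  mkSeries <- function(a) lapply(split(chem, chem$date_index), function(df)
    data.frame(x = blocks$x[match(df$block_id, blocks$block_id)],
               y = blocks$y[match(df$block_id, blocks$block_id)],
               value = df[[a]]))
  mA <- renderSeries(mkSeries("anthocyanins"), blocks)[[3]]
  mP <- renderSeries(mkSeries("polyphenols"), blocks)[[3]]
  ok <- !is.na(mA@values) & !is.na(mP@values)
  expect_gt(cor(mA@values[ok], mP@values[ok]), 0.5)
})

test_that("ESRI ASCII export round-trips the raster", {
  pts <- scatterFixture(seed = 25)
  s <- mbaFit(pts$x, pts$y, pts$z, nLevels = 5)
  grid <- list(origin = c(min(pts$x), min(pts$y)), cellSize = 2,
               nCols = 10, nRows = 4)
  map <- mbaMap(s, grid)
  path <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(map, path)
  lines <- readLines(path)
  expect_match(lines[1], "ncols 10")
  body <- do.call(rbind, lapply(lines[7:10], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  expect_equal(body[4, ], unname(map@values[1, ]), tolerance = 1e-4)
})
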