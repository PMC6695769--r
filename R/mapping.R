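# Raster prediction maps from per-block analyte values, via MBA surfaces.

#' Rasterise an MBA surface into a PredictionMap
#'
#' Evaluates the surface at cell centres of a regular grid. Cells farther
#' than \code{maskDistance} from every block centroid are emitted as no-data
#' so maps do not extrapolate beyond the plot.
#'
#' @param surface an \linkS4class{MBASurface}
#' @param grid list with \code{origin} (x, y), \code{cellSize} (metres),
#'   \code{nCols}, \code{nRows}; see \code{\link{mapGrid}}
#' @param blocks optional data.frame of block centroids used for masking
#' @param maskDistance metres (default 4.4 = twice the standard row spacing)
#' @param analyte,dateIndex map metadata
#' @param zlim optional shared colour-scale bounds
#' @return a \linkS4class{PredictionMap}
#' @export
mbaMap <- function(surface, grid, blocks = NULL, maskDistance = 4.4,
                   analyte = "", dateIndex = 1L, zlim = NULL) {
  cx <- grid$origin[1] + (seq_len(grid$nCols) - 0.5) * grid$cellSize
  cy <- grid$origin[2] + (seq_len(grid$nRows) - 0.5) * grid$cellSize
  g <- expand.grid(x = cx, y = cy)
  b <- surface@bbox
  if (any(g$x < b[1] | g$x > b[2] | g$y < b[3] | g$y > b[4]))
    stop("grid extends outside the surface bounding box")
  vals <- mbaEvaluate(surface, g$x, g$y)
  if (!is.null(blocks)) {
    d2 <- outer(g$x, blocks$x, "-")^2 + outer(g$y, blocks$y, "-")^2
    vals[sqrt(apply(d2, 1, min)) > maskDistance] <- NA_real_
  }
  values <- matrix(vals, nrow = grid$nRows, ncol = grid$nCols, byrow = TRUE)
  if (is.null(zlim)) zlim <- range(vals, na.rm = TRUE)
  new("PredictionMap", origin = as.numeric(grid$origin),
      cellSize = grid$cellSize, values = values, analyte = analyte,
      dateIndex = as.integer(dateIndex), zlim = as.numeric(zlim))
}

#' Default map grid over a block layout
#'
#' 1 m cells over the layout bounding box padded by one row spacing.
#'
#' @param blocks data.frame of block centroids
#' @param cellSize cell edge (metres, default 1)
#' @param pad padding around the centroid bounding box (metres, default 2.2)
#' @return list with \code{origin}, \code{cellSize}, \code{nCols},
#'   \code{nRows}, \code{bbox}
#' @export
mapGrid <- function(blocks, cellSize = 1, pad = 2.2) {
  xr <- range(blocks$x) + c(-pad, pad)
  yr <- range(blocks$y) + c(-pad, pad)
  nCols <- max(1L, ceiling((xr[2] - xr[1]) / cellSize))
  nRows <- max(1L, ceiling((yr[2] - yr[1]) / cellSize))
  list(origin = c(xr[1], yr[1]), cellSize = cellSize,
       nCols = nCols, nRows = nRows,
       bbox = c(xr[1], xr[1] + nCols * cellSize,
                yr[1], yr[1] + nRows * cellSize))
}

#' Render a comparable map series across dates
#'
#' Fits one MBA surface per date to per-block values and rasterises them on
#' a shared grid with shared colour-scale bounds (min/max over all dates),
#' so the temporal evolution is visually comparable.
#'
#' @param valuesByDate named list (date index -> data.frame with \code{x},
#'   \code{y}, \code{value})
#' @param blocks data.frame of block centroids (masking)
#' @param grid optional grid from \code{\link{mapGrid}}
#' @param nLevels MBA levels (default 8)
#' @param analyte map metadata
#' @param maskDistance metres (default 4.4)
#' @return named list of \linkS4class{PredictionMap}, one per date
#' @export
renderSeries <- function(valuesByDate, blocks, grid = NULL, nLevels = 8L,
                         analyte = "", maskDistance = 4.4) {
  if (!length(valuesByDate)) stop("need at least one date")
  if (is.null(grid)) grid <- mapGrid(blocks)
  surfaces <- lapply(valuesByDate, function(df)
    mbaFit(df$x, df$y, df$value, nLevels = nLevels, bbox = grid$bbox))
  maps <- mapply(function(s, d) mbaMap(s, grid, blocks, maskDistance,
                                       analyte = analyte,
                                       dateIndex = as.integer(d)),
                 surfaces, names(valuesByDate), SIMPLIFY = FALSE)
  zlim <- range(unlist(lapply(maps, function(m) range(m@values, na.rm = TRUE))))
  lapply(maps, function(m) initialize(m, zlim = zlim))
}

#' Write a PredictionMap as an ESRI ASCII grid
#'
#' @param map a \linkS4class{PredictionMap}
#' @param path output path (.asc)
#' @param nodata no-data value written for masked cells (default -9999)
#' @return invisibly, \code{path}
#' @export
writeAsciiGrid <- function(map, path, nodata = -9999) {
  v <- map@values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.6f", map@origin[1]),
           sprintf("yllcorner %.6f", map@origin[2]),
           sprintf("cellsize %.6f", map@cellSize),
           sprintf("NODATA_value %g", nodata))
  # ESRI ASCII rows run north to south; our row 1 is the southernmost
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                function(r) paste(sprintf("%.6g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

setMethod("show", "PredictionMap", function(object) {
  cat(sprintf("PredictionMap (%s, date %d): %d x %d cells of %.2f m, scale [%.3g, %.3g]\n",
              if (nzchar(object@analyte)) object@analyte else "unnamed",
              object@dateIndex, nrow(object@values), ncol(object@values),
              object@cellSize, object@zlim[1], object@zlim[2]))
})
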