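# Multilevel B-spline approximation (MBA) of scattered data: uniform cubic
# B-spline control lattices fitted coarse-to-fine, each level to the
# residuals of the previous ones, following the classic BA/MBA construction.

# Uniform cubic B-spline basis values B_0..B_3 at local parameter t in [0,1].
cubicBasis <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

# Map coordinates to (cell index i in 0..m-1, local parameter t).
latticeParam <- function(u, lo, hi, m) {
  s <- (u - lo) / (hi - lo) * m
  i <- pmin(pmax(floor(s), 0), m - 1)
  list(i = as.integer(i), t = s - i)
}

# One BA pass: control lattice ((m+3) x (n+3)) approximating residuals z at
# scattered (x, y). Control points without data support stay 0.
baFit <- function(x, y, z, bbox, m, n) {
  px <- latticeParam(x, bbox[1], bbox[2], m)
  py <- latticeParam(y, bbox[3], bbox[4], n)
  Bx <- cubicBasis(px$t)
  By <- cubicBasis(py$t)
  num <- matrix(0, m + 3, n + 3)
  den <- matrix(0, m + 3, n + 3)
  for (p in seq_along(x)) {
    w <- outer(Bx[p, ], By[p, ])          # 4 x 4 weights
    sw2 <- sum(w^2)
    phi <- w * z[p] / sw2
    ir <- px$i[p] + 1:4
    jc <- py$i[p] + 1:4
    num[ir, jc] <- num[ir, jc] + w^2 * phi
    den[ir, jc] <- den[ir, jc] + w^2
  }
  ctrl <- num / den
  ctrl[den == 0] <- 0
  ctrl
}

# Evaluate one lattice at scattered (x, y).
baEvaluate <- function(ctrl, x, y, bbox) {
  m <- nrow(ctrl) - 3
  n <- ncol(ctrl) - 3
  px <- latticeParam(x, bbox[1], bbox[2], m)
  py <- latticeParam(y, bbox[3], bbox[4], n)
  Bx <- cubicBasis(px$t)
  By <- cubicBasis(py$t)
  out <- numeric(length(x))
  for (p in seq_along(x)) {
    sub <- ctrl[px$i[p] + 1:4, py$i[p] + 1:4]
    out[p] <- sum(outer(Bx[p, ], By[p, ]) * sub)
  }
  out
}

#' Fit a multilevel B-spline surface to scattered points
#'
#' Level 0 approximates the (mean-subtracted) data with the local weighted
#' least-squares control assignment of the BA algorithm on the initial
#' lattice; each subsequent level doubles the lattice resolution and fits the
#' residuals of the accumulated surface. The maximum absolute residual at the
#' data points is non-increasing across levels.
#'
#' @param x,y,z numeric vectors of point coordinates (metres) and values
#' @param nLevels number of levels (default 8)
#' @param initialCells integer (m0, n0) cells of the coarsest lattice;
#'   (1, 1) gives the minimal 4 x 4 control lattice
#' @param bbox optional (xmin, xmax, ymin, ymax); defaults to the point
#'   bounding box, padded where degenerate. A supplied zero-area bbox is an
#'   error.
#' @return an \linkS4class{MBASurface}
#' @export
mbaFit <- function(x, y, z, nLevels = 8L, initialCells = c(1L, 1L),
                   bbox = NULL) {
  if (length(x) < 1) stop("need at least one point")
  if (length(y) != length(x) || length(z) != length(x))
    stop("x, y, z must have equal length")
  if (any(!is.finite(z))) stop("point values must be finite")
  if (nLevels < 1) stop("nLevels must be >= 1")
  if (is.null(bbox)) {
    bbox <- c(range(x), range(y))
    if (bbox[2] - bbox[1] == 0) bbox[1:2] <- bbox[1:2] + c(-0.5, 0.5)
    if (bbox[4] - bbox[3] == 0) bbox[3:4] <- bbox[3:4] + c(-0.5, 0.5)
  } else {
    if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3])
      stop("degenerate bounding box: zero area")
    if (any(x < bbox[1] | x > bbox[2] | y < bbox[3] | y > bbox[4]))
      stop("points outside the supplied bounding box")
  }
  offset <- mean(z)
  resid <- z - offset
  lattices <- vector("list", nLevels)
  m <- as.integer(initialCells[1])
  n <- as.integer(initialCells[2])
  for (lev in seq_len(nLevels)) {
    ctrl <- baFit(x, y, resid, bbox, m, n)
    resid <- resid - baEvaluate(ctrl, x, y, bbox)
    lattices[[lev]] <- ctrl
    m <- m * 2L
    n <- n * 2L
  }
  new("MBASurface", lattices = lattices, bbox = bbox, offset = offset,
      nLevels = as.integer(nLevels),
      initialCells = as.integer(initialCells))
}

#' Evaluate a multilevel B-spline surface at points
#'
#' Sums the per-level cubic B-spline surfaces plus the stored mean offset;
#' the result is a smooth (C2) surface. Points must lie inside the model's
#' bounding box.
#'
#' @param surface an \linkS4class{MBASurface}
#' @param x,y numeric vectors of evaluation coordinates
#' @return numeric vector of surface values
#' @export
mbaEvaluate <- function(surface, x, y) {
  b <- surface@bbox
  if (any(x < b[1] | x > b[2] | y < b[3] | y > b[4]))
    stop("evaluation points outside the model bounding box")
  out <- rep(surface@offset, length(x))
  for (ctrl in surface@lattices)
    out <- out + baEvaluate(ctrl, x, y, b)
  out
}

#' Maximum absolute residual of a surface at its data points
#'
#' @param surface an \linkS4class{MBASurface}
#' @param x,y,z the fitted points
#' @return numeric scalar
#' @export
mbaResidual <- function(surface, x, y, z) {
  max(abs(mbaEvaluate(surface, x, y) - z))
}

setMethod("show", "MBASurface", function(object) {
  top <- dim(object@lattices[[object@nLevels]])
  cat(sprintf("MBASurface: %d levels, finest lattice %d x %d, bbox [%.1f, %.1f] x [%.1f, %.1f]\n",
              object@nLevels, top[1], top[2], object@bbox[1], object@bbox[2],
              object@bbox[3], object@bbox[4]))
})
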