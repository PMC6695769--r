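#' @import methods
#' @importFrom stats rnorm runif sd var qf qnorm qchisq predict coef lm
#'   lm.fit poly setNames complete.cases dist
#' @importFrom utils head tail write.csv read.csv count.fields packageVersion
NULL

#' SpectralStream: an ordered sequence of georeferenced spectra
#'
#' A container for one or more spectra sharing a common wavelength axis, as
#' acquired continuously from a moving platform. Rows of \code{spectra} are
#' individual spectra; columns are channels. Optional hidden class labels
#' (\code{"cluster"}, \code{"leaf"}, \code{"wood"}, \code{"gap"}) carry the
#' simulator's ground truth for filter evaluation and are never used by the
#' analysis itself.
#'
#' @slot spectra numeric matrix, n spectra x p channels (absorbance units).
#' @slot wavelengths numeric vector of length p, nm, strictly increasing.
#' @slot timestamp numeric vector of length n, seconds, non-decreasing.
#' @slot position n x 2 numeric matrix of planar coordinates (metres).
#' @slot sourceId character scalar identifying the acquisition source.
#' @slot classLabel character vector of length n (or 0 when unknown).
#'
#' @export
setClass("SpectralStream",
  representation(
    spectra     = "matrix",
    wavelengths = "numeric",
    timestamp   = "numeric",
    position    = "matrix",
    sourceId    = "character",
    classLabel  = "character"
  ),
  prototype(
    spectra     = matrix(numeric(0), 0, 0),
    wavelengths = numeric(0),
    timestamp   = numeric(0),
    position    = matrix(numeric(0), 0, 2),
    sourceId    = "unknown",
    classLabel  = character(0)
  )
)

setValidity("SpectralStream", function(object) {
  n <- nrow(object@spectra)
  p <- ncol(object@spectra)
  msg <- character(0)
  if (length(object@wavelengths) != p)
    msg <- c(msg, "wavelength axis length must equal number of channels")
  if (p > 1 && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (any(!is.finite(object@spectra)))
    msg <- c(msg, "spectral values must be finite")
  if (length(object@timestamp) != n)
    msg <- c(msg, "one timestamp per spectrum required")
  if (n > 1 && any(diff(object@timestamp) < 0))
    msg <- c(msg, "timestamps must be non-decreasing")
  if (nrow(object@position) != n || ncol(object@position) != 2)
    msg <- c(msg, "position must be an n x 2 matrix")
  if (length(object@classLabel) != 0 && length(object@classLabel) != n)
    msg <- c(msg, "classLabel must be empty or one label per spectrum")
  if (length(msg)) msg else TRUE
})

#' SpectralSignature: a reference grape-cluster spectrum
#'
#' The manually acquired, averaged spectral signature of grape clusters used
#' to retain cluster spectra from on-the-go streams by cosine similarity.
#'
#' @slot wavelengths numeric vector, nm, strictly increasing.
#' @slot values numeric vector of absorbance values, non-zero norm.
#' @slot nSourceSpectra integer, how many manual spectra were averaged.
#'
#' @export
setClass("SpectralSignature",
  representation(
    wavelengths    = "numeric",
    values         = "numeric",
    nSourceSpectra = "integer"
  )
)

setValidity("SpectralSignature", function(object) {
  msg <- character(0)
  if (length(object@wavelengths) != length(object@values))
    msg <- c(msg, "wavelengths and values must have the same length")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "signature values must be finite")
  if (sqrt(sum(object@values^2)) == 0)
    msg <- c(msg, "signature must have non-zero norm")
  if (length(msg)) msg else TRUE
})

#' CalibrationSet: block-averaged spectra paired with reference chemistry
#'
#' Holds the sample matrix entering chemometric modelling (one pre-processed,
#' block-averaged spectrum per block x date), the reference chemistry for the
#' three analytes, sample metadata, and the calibration/validation split.
#'
#' @slot X numeric matrix, n samples x p channels.
#' @slot wavelengths numeric vector of length p.
#' @slot chemistry data.frame with columns \code{tss}, \code{anthocyanins},
#'   \code{polyphenols}, one row per sample (analyte units).
#' @slot meta data.frame with at least \code{block_id} and \code{date_index}.
#' @slot split character vector: \code{"calibration"}/\code{"validation"},
#'   or length 0 before splitting.
#'
#' @export
setClass("CalibrationSet",
  representation(
    X           = "matrix",
    wavelengths = "numeric",
    chemistry   = "data.frame",
    meta        = "data.frame",
    split       = "character"
  )
)

setValidity("CalibrationSet", function(object) {
  n <- nrow(object@X)
  msg <- character(0)
  if (any(!is.finite(object@X)))
    msg <- c(msg, "X must not contain missing or non-finite values")
  if (length(object@wavelengths) != ncol(object@X))
    msg <- c(msg, "wavelength axis must match ncol(X)")
  if (nrow(object@chemistry) != n)
    msg <- c(msg, "chemistry must have one row per sample")
  if (nrow(object@meta) != n)
    msg <- c(msg, "meta must have one row per sample")
  if (length(object@split) != 0) {
    if (length(object@split) != n)
      msg <- c(msg, "split must label every sample")
    if (!all(object@split %in% c("calibration", "validation")))
      msg <- c(msg, "split labels must be 'calibration' or 'validation'")
  }
  if (length(msg)) msg else TRUE
})

#' PCAModel: mean-centered principal component model with outlier limits
#'
#' @slot center numeric vector of column means.
#' @slot loadings p x k orthonormal loading matrix.
#' @slot eigenvalues all min(n-1, p) eigenvalues of the centered covariance,
#'   non-increasing; the trailing ones feed the Q-residual control limit.
#' @slot k integer, number of retained components.
#' @slot qLimit,t2Limit numeric control limits at confidence \code{alpha}.
#' @slot alpha numeric confidence level in (0, 1).
#' @slot n integer, number of training samples.
#'
#' @export
setClass("PCAModel",
  representation(
    center      = "numeric",
    loadings    = "matrix",
    eigenvalues = "numeric",
    k           = "integer",
    qLimit      = "numeric",
    t2Limit     = "numeric",
    alpha       = "numeric",
    n           = "integer"
  )
)

setValidity("PCAModel", function(object) {
  msg <- character(0)
  if (ncol(object@loadings) != object@k)
    msg <- c(msg, "loadings must have k columns")
  if (any(diff(object@eigenvalues) > 1e-8))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (any(object@eigenvalues < -1e-8))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (length(msg)) msg else TRUE
})

#' PLSModel: univariate-response partial least squares regression model
#'
#' Fitted by sequential NIPALS latent-variable extraction with X-deflation.
#' Prediction is \eqn{\hat y = \bar y + (x - \bar x)^T b}.
#'
#' @slot xCenter numeric vector of predictor column means.
#' @slot yCenter numeric scalar response mean.
#' @slot weights p x k weight matrix W.
#' @slot loadingsX p x k X-loading matrix P.
#' @slot loadingsY numeric vector of k y-loadings q.
#' @slot coef numeric regression vector b of length p.
#' @slot nLV integer, number of latent variables.
#' @slot treatment character, the pre-processing chain code the model expects.
#' @slot analyte character, the response the model predicts.
#'
#' @export
setClass("PLSModel",
  representation(
    xCenter   = "numeric",
    yCenter   = "numeric",
    weights   = "matrix",
    loadingsX = "matrix",
    loadingsY = "numeric",
    coef      = "numeric",
    nLV       = "integer",
    treatment = "character",
    analyte   = "character"
  )
)

setValidity("PLSModel", function(object) {
  msg <- character(0)
  if (object@nLV < 1L)
    msg <- c(msg, "nLV must be >= 1")
  if (length(object@coef) != length(object@xCenter))
    msg <- c(msg, "regression vector must match predictor dimension")
  if (length(msg)) msg else TRUE
})

#' MBASurface: multilevel cubic B-spline approximation of scattered data
#'
#' A hierarchy of uniform cubic B-spline control lattices over a rectangular
#' domain; each level's lattice doubles in resolution and is fitted to the
#' residuals of the coarser levels. Evaluation sums the per-level surfaces
#' plus the stored data-mean offset.
#'
#' @slot lattices list of control-point matrices ((m+3) x (n+3) per level).
#' @slot bbox numeric vector (xmin, xmax, ymin, ymax).
#' @slot offset numeric, the data mean subtracted before fitting.
#' @slot nLevels integer.
#' @slot initialCells integer vector (m0, n0): cells of the coarsest lattice.
#'
#' @export
setClass("MBASurface",
  representation(
    lattices     = "list",
    bbox         = "numeric",
    offset       = "numeric",
    nLevels      = "integer",
    initialCells = "integer"
  )
)

setValidity("MBASurface", function(object) {
  msg <- character(0)
  if (length(object@bbox) != 4)
    msg <- c(msg, "bbox must be (xmin, xmax, ymin, ymax)")
  if (object@bbox[2] <= object@bbox[1] || object@bbox[4] <= object@bbox[3])
    msg <- c(msg, "bounding box must have positive area")
  if (length(object@lattices) != object@nLevels)
    msg <- c(msg, "one control lattice per level required")
  if (length(msg)) msg else TRUE
})

#' PredictionMap: a raster of interpolated analyte values for one date
#'
#' @slot origin numeric (x, y) of the lower-left cell corner (metres).
#' @slot cellSize numeric cell edge length (metres).
#' @slot values numeric matrix, nRows x nCols, row 1 = southernmost row;
#'   \code{NA} outside the mapped region.
#' @slot analyte character.
#' @slot dateIndex integer.
#' @slot zlim numeric (min, max) shared colour-scale bounds across dates.
#'
#' @export
setClass("PredictionMap",
  representation(
    origin    = "numeric",
    cellSize  = "numeric",
    values    = "matrix",
    analyte   = "character",
    dateIndex = "integer",
    zlim      = "numeric"
  )
)
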