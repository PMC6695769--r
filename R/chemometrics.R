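# Chemometric modelling: PCA-based Q / Hotelling-T2 outlier screening,
# range-covering calibration/validation split, NIPALS PLS with
# venetian-blinds cross-validation and the full set of model statistics.

#' Build a CalibrationSet
#'
#' @param X numeric matrix, n samples x p channels
#' @param wavelengths numeric vector of length p
#' @param chemistry data.frame of analyte reference values (one row/sample)
#' @param meta data.frame of sample metadata (block_id, date_index, ...)
#' @return a \linkS4class{CalibrationSet}
#' @export
CalibrationSet <- function(X, wavelengths, chemistry, meta) {
  new("CalibrationSet", X = as.matrix(X), wavelengths = as.numeric(wavelengths),
      chemistry = chemistry, meta = meta, split = character(0))
}

#' @rdname splitLabels
#' @export
setMethod("splitLabels", "CalibrationSet", function(x) x@split)

#' @rdname chemistry
#' @export
setMethod("chemistry", "CalibrationSet", function(x) x@chemistry)

#' @rdname sampleMeta
#' @export
setMethod("sampleMeta", "CalibrationSet", function(x) x@meta)

#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "CalibrationSet", function(x) x@X)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "CalibrationSet", function(x) x@wavelengths)

setMethod("show", "CalibrationSet", function(object) {
  cat(sprintf("CalibrationSet: %d samples x %d channels\n", nrow(object@X),
              ncol(object@X)))
  cat("  analytes:", paste(names(object@chemistry), collapse = ", "), "\n")
  if (length(object@split))
    cat(sprintf("  split: %d calibration / %d validation\n",
                sum(object@split == "calibration"),
                sum(object@split == "validation")))
})

#' Range-covering calibration/validation split
#'
#' The calibration set receives \code{ceiling(fraction x n)} samples. The
#' validation draw is stratified over the response range: samples are ranked
#' by \code{y}, the ranking is cut into as many nearly equal consecutive bins
#' as there are validation samples, and each bin contributes one randomly
#' chosen validation sample. Both sets therefore cover the entire range of
#' the response. Deterministic under \code{seed}.
#'
#' @param y numeric response vector
#' @param fraction calibration fraction in (0, 1), default 0.8
#' @param seed integer RNG seed
#' @return character vector of \code{"calibration"}/\code{"validation"}
#' @export
splitIndices <- function(y, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- length(y)
  if (n < 2) stop("need at least two samples to split")
  nCal <- ceiling(fraction * n)
  nVal <- n - nCal
  split <- rep("calibration", n)
  if (nVal > 0) {
    set.seed(seed)
    ord <- order(y)
    sizes <- rep(n %/% nVal, nVal) + (seq_len(nVal) <= n %% nVal)
    bins <- split(ord, rep(seq_len(nVal), times = sizes))
    valIdx <- vapply(bins, function(b) b[sample.int(length(b), 1)], 1L)
    split[valIdx] <- "validation"
  } else {
    warning("calibration fraction leaves no validation samples")
  }
  split
}

#' Split a CalibrationSet on one analyte's response
#'
#' @param dataset a \linkS4class{CalibrationSet}
#' @param analyte column of \code{chemistry(dataset)} to stratify on
#' @param fraction calibration fraction (default 0.8)
#' @param seed integer RNG seed
#' @return the dataset with its \code{split} slot filled
#' @export
splitDataset <- function(dataset, analyte = "tss", fraction = 0.8, seed = 1L) {
  y <- chemistry(dataset)[[analyte]]
  if (is.null(y)) stop("unknown analyte: ", analyte)
  initialize(dataset, split = splitIndices(y, fraction, seed))
}

#' Fit a mean-centered principal component model
#'
#' Singular value decomposition of the centered sample matrix; eigenvalues
#' are those of the sample covariance. All min(n-1, p) eigenvalues are kept
#' for the Q-limit computation; \code{k} loadings are retained. Control
#' limits at \code{alpha} are attached (see \code{\link{controlLimits}}).
#'
#' @param X numeric matrix, n x p
#' @param k number of retained components, <= min(n-1, p)
#' @param alpha confidence level for the outlier control limits
#' @return a \linkS4class{PCAModel}
#' @export
pcaFit <- function(X, k, alpha = 0.99) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  kmax <- min(n - 1, p)
  if (k > kmax) stop("k must be <= min(n-1, p)")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = kmax)
  lam <- (sv$d[seq_len(kmax)]^2) / (n - 1)
  model <- new("PCAModel", center = ctr,
               loadings = sv$v[, seq_len(k), drop = FALSE],
               eigenvalues = lam, k = as.integer(k),
               qLimit = NA_real_, t2Limit = NA_real_,
               alpha = alpha, n = as.integer(n))
  lim <- controlLimits(model, alpha)
  model@qLimit <- lim[["q"]]
  model@t2Limit <- lim[["t2"]]
  model
}

#' PCA scores of samples
#'
#' @param pca a \linkS4class{PCAModel}
#' @param X numeric matrix or vector of samples
#' @return n x k score matrix
#' @export
pcaScores <- function(pca, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(as.matrix(X), 2, pca@center) %*% pca@loadings
}

#' Q residual (squared reconstruction error) per sample
#'
#' \eqn{Q = \|(x - \bar x) - P P^T (x - \bar x)\|^2}: the squared distance of
#' a sample from its projection onto the retained PCA subspace.
#'
#' @param pca a \linkS4class{PCAModel}
#' @param X numeric matrix or vector of samples
#' @return numeric vector of Q statistics
#' @export
qStatistic <- function(pca, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Xc <- sweep(as.matrix(X), 2, pca@center)
  T <- Xc %*% pca@loadings
  res <- Xc - T %*% t(pca@loadings)
  rowSums(res^2)
}

#' Hotelling T-squared statistic per sample
#'
#' \eqn{T^2 = \sum_{i \le k} t_i^2 / \lambda_i}: the Mahalanobis-type
#' distance within the retained PCA subspace.
#'
#' @param pca a \linkS4class{PCAModel}
#' @param X numeric matrix or vector of samples
#' @return numeric vector of T2 statistics
#' @export
t2Statistic <- function(pca, X) {
  lam <- pca@eigenvalues[seq_len(pca@k)]
  if (any(lam <= 0)) stop("degenerate component: zero eigenvalue retained")
  T <- pcaScores(pca, X)
  rowSums(sweep(T^2, 2, lam, "/"))
}

#' Q and Hotelling T-squared control limits
#'
#' The T2 limit is \eqn{k(n-1)/(n-k) F_\alpha(k, n-k)}; the Q limit follows
#' the Jackson-Mudholkar approximation from the trailing eigenvalues (those
#' beyond the retained k).
#'
#' @param pca a \linkS4class{PCAModel}
#' @param alpha confidence level in (0, 1)
#' @return named numeric vector \code{c(q=, t2=)}; the Q limit is \code{Inf}
#'   when there is no residual variance beyond k components
#' @export
controlLimits <- function(pca, alpha = 0.99) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  n <- pca@n
  k <- pca@k
  if (n <= k) stop("need n > k for control limits")
  t2 <- k * (n - 1) / (n - k) * qf(alpha, k, n - k)
  lam <- pca@eigenvalues
  trailing <- if (length(lam) > k) lam[(k + 1):length(lam)] else numeric(0)
  trailing <- trailing[trailing > .Machine$double.eps * max(lam, 1)]
  if (!length(trailing)) {
    q <- Inf
  } else {
    th1 <- sum(trailing)
    th2 <- sum(trailing^2)
    th3 <- sum(trailing^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
    z <- qnorm(alpha)
    q <- th1 * (z * sqrt(2 * th2 * h0^2) / th1 +
                  1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  }
  c(q = q, t2 = t2)
}

#' Screen a sample matrix for spectral outliers
#'
#' Fits a PCA retaining the smallest number of components capturing at least
#' \code{varCapture} of the variance and flags samples whose Q residual and
#' Hotelling T2 both exceed their \code{alpha} control limits (joint rule,
#' single pass, no iterative refitting).
#'
#' @param X numeric matrix, n x p
#' @param varCapture variance fraction the retained components must explain
#' @param alpha confidence level of the control limits
#' @return list with \code{flagged} (logical per sample), \code{pca},
#'   \code{q}, \code{t2}
#' @export
detectOutliers <- function(X, varCapture = 0.95, alpha = 0.99) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) {
    warning("fewer than 2 samples: no outlier screening possible")
    return(list(flagged = rep(FALSE, n), pca = NULL,
                q = rep(NA_real_, n), t2 = rep(NA_real_, n)))
  }
  probe <- pcaFit(X, k = 1L, alpha = alpha)
  lam <- probe@eigenvalues
  if (sum(lam) == 0) {
    warning("zero-variance matrix: no outlier screening possible")
    return(list(flagged = rep(FALSE, n), pca = NULL,
                q = rep(0, n), t2 = rep(0, n)))
  }
  k <- which(cumsum(lam) / sum(lam) >= varCapture)[1]
  k <- min(k, n - 2L)          # keep n > k for the limits
  k <- max(k, 1L)
  pca <- pcaFit(X, k = k, alpha = alpha)
  q <- qStatistic(pca, X)
  t2 <- t2Statistic(pca, X)
  list(flagged = q > pca@qLimit & t2 > pca@t2Limit, pca = pca, q = q, t2 = t2)
}

#' Fit a univariate-response PLS model (NIPALS)
#'
#' Sequential latent-variable extraction with X-deflation: for each
#' component, the weight vector is the normalised covariance direction
#' \eqn{w = X^T y / \|X^T y\|}, scores \eqn{t = Xw}, loadings
#' \eqn{p = X^T t / t^T t}, \eqn{q = y^T t / t^T t}, then \eqn{X \leftarrow
#' X - t p^T}. The regression vector is \eqn{b = W (P^T W)^{-1} q}. X and y
#' are mean-centered internally; no autoscaling (spectral channels share
#' units).
#'
#' @param X numeric matrix, n x p
#' @param y numeric response vector of length n
#' @param nLV number of latent variables, <= min(n-1, p)
#' @param treatment character tag recording the pre-processing the model
#'   expects (bookkeeping only)
#' @param analyte character tag for the response
#' @return a \linkS4class{PLSModel}
#' @export
plsFit <- function(X, y, nLV, treatment = "none", analyte = "") {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (nLV < 1 || nLV > min(n - 1, p))
    stop("nLV must be between 1 and min(n-1, p)")
  if (var(y) == 0) stop("zero-variance response")
  xc <- colMeans(X)
  yc <- mean(y)
  E <- sweep(X, 2, xc)
  f <- y - yc
  W <- matrix(0, p, nLV)
  P <- matrix(0, p, nLV)
  qv <- numeric(nLV)
  for (a in seq_len(nLV)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps)
      stop("no covariance left to extract at component ", a)
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    pl <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - t %*% t(pl)
    W[, a] <- w
    P[, a] <- pl
    qv[a] <- qa
  }
  b <- as.numeric(W %*% solve(crossprod(P, W), qv))
  new("PLSModel", xCenter = xc, yCenter = yc, weights = W, loadingsX = P,
      loadingsY = qv, coef = b, nLV = as.integer(nLV),
      treatment = treatment, analyte = analyte)
}

#' Predict from a PLS model
#'
#' @param object a \linkS4class{PLSModel}
#' @param newdata numeric matrix or vector of samples (same pre-processing
#'   as the training matrix)
#' @param ... ignored
#' @return numeric vector of predictions
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  as.numeric(object@yCenter +
               sweep(as.matrix(newdata), 2, object@xCenter) %*% object@coef)
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel (%s): %d latent variables, %d channels, treatment %s\n",
              if (nzchar(object@analyte)) object@analyte else "unnamed",
              object@nLV, length(object@coef), object@treatment))
})

setMethod("show", "PCAModel", function(object) {
  ev <- object@eigenvalues
  cat(sprintf("PCAModel: %d components (of %d), %.1f%% variance; Q limit %.4g, T2 limit %.4g (alpha %.2f)\n",
              object@k, length(ev),
              100 * sum(ev[seq_len(object@k)]) / max(sum(ev), .Machine$double.eps),
              object@qLimit, object@t2Limit, object@alpha))
})

#' Venetian-blinds fold assignment
#'
#' Sample i (0-based, dataset order) belongs to fold \code{i mod nFolds}.
#' Folds partition the samples and their sizes differ by at most one; the
#' assignment depends on dataset order by construction.
#'
#' @param n number of samples
#' @param nFolds number of folds (default 10)
#' @return integer vector of 0-based fold labels
#' @export
venetianBlinds <- function(n, nFolds = 10L) {
  if (n < nFolds) stop("need at least as many samples as folds")
  (seq_len(n) - 1L) %% as.integer(nFolds)
}

#' Cross-validate PLS over latent-variable counts
#'
#' For each LV count from 1 to \code{maxLV}, refits on every venetian-blinds
#' fold complement and predicts the held-out fold; RMSECV pools the held-out
#' predictions. The selected LV count minimises RMSECV (ties go to the
#' smallest count).
#'
#' @param X numeric matrix (calibration samples, pre-processed)
#' @param y numeric response vector
#' @param maxLV largest LV count to try (default 15; reduced if a training
#'   fold cannot support it)
#' @param nFolds number of venetian-blinds folds (default 10)
#' @return list with \code{rmsecv} (vector over LV counts), \code{nLV}
#'   (selected), \code{cvPred} (held-out predictions at the selected count),
#'   \code{folds}
#' @export
crossValidate <- function(X, y, maxLV = 15L, nFolds = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- venetianBlinds(n, nFolds)
  minTrain <- min(table(factor(folds, levels = 0:(nFolds - 1))))
  lvCap <- min(maxLV, n - max(table(folds)) - 1, ncol(X))
  if (lvCap < 1) stop("degenerate folds: no latent variable fits possible")
  pred <- matrix(NA_real_, n, lvCap)
  for (fd in 0:(nFolds - 1)) {
    hold <- folds == fd
    for (a in seq_len(lvCap)) {
      m <- plsFit(X[!hold, , drop = FALSE], y[!hold], a)
      pred[hold, a] <- predict(m, X[hold, , drop = FALSE])
    }
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  nLV <- which.min(rmsecv)
  list(rmsecv = rmsecv, nLV = nLV, cvPred = pred[, nLV], folds = folds)
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

#' Model performance statistics
#'
#' RMSE and determination coefficient on the calibration set, the pooled
#' cross-validation predictions and the external validation set, in the
#' layout of a calibration-table row. R-squared is explained variance,
#' \eqn{1 - SSE/SST}, with SST about each set's own mean.
#'
#' @param model a fitted \linkS4class{PLSModel}
#' @param Xcal,ycal calibration samples and responses
#' @param Xval,yval external validation samples and responses
#' @param cv result of \code{\link{crossValidate}} on the calibration set
#' @return one-row data.frame with n, sd, range, n_lv, rmsec, r2_c, rmsecv,
#'   r2_cv, rmsep, r2_p
#' @export
modelStatistics <- function(model, Xcal, ycal, Xval, yval, cv) {
  if (!length(ycal) || !length(yval)) stop("empty calibration or validation set")
  pc <- predict(model, Xcal)
  pv <- predict(model, Xval)
  data.frame(
    analyte = model@analyte,
    treatment = model@treatment,
    n = length(ycal),
    sd = sd(ycal),
    range_min = min(ycal), range_max = max(ycal),
    n_lv = model@nLV,
    rmsec = rmse(ycal, pc), r2_c = r2(ycal, pc),
    rmsecv = rmse(ycal, cv$cvPred), r2_cv = r2(ycal, cv$cvPred),
    rmsep = rmse(yval, pv), r2_p = r2(yval, pv),
    stringsAsFactors = FALSE
  )
}

#' Train one analyte model end to end
#'
#' Applies the treatment chain, splits on the analyte's response, selects the
#' LV count by venetian-blinds cross-validation on the calibration set, fits
#' the final model and computes all statistics.
#'
#' @param dataset a \linkS4class{CalibrationSet} (raw block-averaged spectra)
#' @param analyte response column name
#' @param treatment treatment code string (e.g. \code{"D1W15"})
#' @param maxLV largest LV count tried (default 15)
#' @param nFolds venetian-blinds folds (default 10)
#' @param fraction calibration fraction (default 0.8)
#' @param seed integer RNG seed for the split
#' @return list with \code{model}, \code{stats} (one-row data.frame),
#'   \code{cv}, \code{split}
#' @export
trainAnalyteModel <- function(dataset, analyte, treatment = "D1W15",
                              maxLV = 15L, nFolds = 10L, fraction = 0.8,
                              seed = 1L) {
  wl <- wavelengths(dataset)
  stepNm <- if (length(wl) > 1) wl[2] - wl[1] else 1
  Xp <- applyChain(treatment, spectraMatrix(dataset), step = stepNm)
  y <- chemistry(dataset)[[analyte]]
  if (is.null(y)) stop("unknown analyte: ", analyte)
  split <- splitIndices(y, fraction, seed)
  cal <- split == "calibration"
  Xc <- Xp[cal, , drop = FALSE]
  yc <- y[cal]
  Xv <- Xp[!cal, , drop = FALSE]
  yv <- y[!cal]
  cv <- crossValidate(Xc, yc, maxLV = maxLV, nFolds = nFolds)
  model <- plsFit(Xc, yc, cv$nLV, treatment = treatment, analyte = analyte)
  stats <- modelStatistics(model, Xc, yc, Xv, yv, cv)
  list(model = model, stats = stats, cv = cv, split = split)
}
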