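# Scatter-correction and derivative pre-processing of block-averaged
# spectra, driven by compact treatment codes ("D1W15", "SNV + DT D1W15").

#' Standard normal variate
#'
#' Per-spectrum standardisation: subtract the mean, divide by the sample
#' standard deviation. Removes multiplicative scatter between spectra.
#'
#' @param values numeric vector (one spectrum), length >= 2
#' @return standardised vector with mean 0 and sample sd 1
#' @export
snv <- function(values) {
  if (length(values) < 2) stop("snv requires at least 2 channels")
  s <- sd(values)
  if (s == 0) stop("snv undefined for zero-variance spectrum")
  (values - mean(values)) / s
}

#' Polynomial detrend
#'
#' Subtracts the least-squares polynomial of the given degree in the channel
#' index, leaving residuals orthogonal to the polynomial basis. Degree 0 is
#' mean-centering.
#'
#' @param values numeric vector (one spectrum)
#' @param degree polynomial degree (default 2, the classic SNV-detrend pair)
#' @return detrended vector
#' @export
detrend <- function(values, degree = 2L) {
  n <- length(values)
  if (degree >= n) stop("detrend degree must be smaller than the spectrum length")
  if (degree == 0) return(values - mean(values))
  i <- seq_len(n)
  fit <- lm.fit(cbind(1, stats::poly(i, degree)), values)
  as.numeric(fit$residuals)
}

#' Savitzky-Golay smoothing / derivative filter
#'
#' Local least-squares polynomial filtering: at each interior channel the
#' value is the \code{deriv}-order derivative at the centre of the polynomial
#' fitted over the moving window, scaled by \code{step^-deriv} so that
#' derivatives are per nm. The (window-1)/2 channels at each edge are the
#' fitted polynomial of the nearest full window evaluated at the edge
#' positions, which preserves the spectrum length. Convolution coefficients
#' are computed, not tabulated.
#'
#' @param values numeric vector (one spectrum)
#' @param window odd window size in channels (e.g. 15)
#' @param polyorder local polynomial order (default 2); must be < window
#' @param deriv derivative order (0 = smoothing); must be <= polyorder
#' @param step channel step in nm used to scale derivatives (default 1)
#' @return filtered vector, same length as the input
#' @export
savgol <- function(values, window = 15L, polyorder = 2L, deriv = 1L,
                   step = 1) {
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (deriv > polyorder) stop("deriv must not exceed polyorder")
  if (length(values) < window) stop("spectrum shorter than the filter window")
  as.numeric(signal::sgolayfilt(values, p = polyorder, n = window, m = deriv,
                                ts = step))
}

#' Parse a spectral treatment code
#'
#' Grammar: steps joined by \code{+}; \code{SNV}, \code{DT} (polynomial
#' detrend, default degree 2) and \code{DnWm} (Savitzky-Golay n-th derivative
#' with window m) in application order, e.g. \code{"SNV + DT D1W15"} = SNV,
#' then detrend, then first-derivative Savitzky-Golay with a 15-channel
#' window. Whitespace separates a trailing \code{DnWm} from \code{DT}.
#'
#' @param code character scalar; "" or "none" yields an empty chain
#' @param detrendDegree degree used for \code{DT} steps
#' @param polyorder Savitzky-Golay polynomial order for \code{DnWm} steps
#' @return list of steps, each a list with \code{type} and parameters
#' @export
parseTreatment <- function(code, detrendDegree = 2L, polyorder = 2L) {
  code <- trimws(code)
  if (code == "" || tolower(code) == "none") return(list())
  tokens <- unlist(strsplit(code, "[+[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  steps <- list()
  for (tok in tokens) {
    up <- toupper(tok)
    if (up == "SNV") {
      steps[[length(steps) + 1]] <- list(type = "snv")
    } else if (up == "DT") {
      steps[[length(steps) + 1]] <- list(type = "detrend",
                                         degree = detrendDegree)
    } else if (grepl("^D[0-9]+W[0-9]+$", up)) {
      d <- as.integer(sub("^D([0-9]+)W[0-9]+$", "\\1", up))
      w <- as.integer(sub("^D[0-9]+W([0-9]+)$", "\\1", up))
      steps[[length(steps) + 1]] <- list(type = "savgol", deriv = d,
                                         window = w,
                                         polyorder = max(polyorder, d))
    } else {
      stop("unrecognised treatment token: ", tok)
    }
  }
  steps
}

#' Format a treatment chain back to its code string
#'
#' @param chain list of steps from \code{\link{parseTreatment}}
#' @return character scalar
#' @export
formatTreatment <- function(chain) {
  if (!length(chain)) return("none")
  parts <- vapply(chain, function(s) switch(s$type,
    snv = "SNV",
    detrend = "DT",
    savgol = sprintf("D%dW%d", s$deriv, s$window),
    stop("unknown step type")), character(1))
  sub(" D", " D", paste(parts, collapse = " + "))
}

#' Apply a treatment chain to a matrix of spectra
#'
#' Steps are applied row-wise in listed order. Any step failure is reported
#' with the offending row index.
#'
#' @param chain a treatment chain (list of steps) or a code string
#' @param X numeric matrix, spectra as rows sharing one wavelength axis
#' @param step channel step in nm (scales Savitzky-Golay derivatives)
#' @return matrix of the same dimensions
#' @export
applyChain <- function(chain, X, step = 1) {
  if (is.character(chain)) chain <- parseTreatment(chain)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (!length(chain)) return(X)
  out <- X
  for (i in seq_len(nrow(out))) {
    row <- out[i, ]
    for (s in chain) {
      row <- tryCatch(switch(s$type,
        snv = snv(row),
        detrend = detrend(row, s$degree),
        savgol = savgol(row, s$window, s$polyorder, s$deriv, step = step),
        stop("unknown step type: ", s$type)),
        error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e)),
                                 call. = FALSE))
    }
    out[i, ] <- row
  }
  out
}
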