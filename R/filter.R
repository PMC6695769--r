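# Cosine-similarity filtering of on-the-go spectra against the manual
# grape-cluster signature, and per-block averaging of the survivors.

#' Cosine similarity between a spectrum and a signature
#'
#' \eqn{\cos(x, s) = \langle x, s\rangle / (\|x\| \|s\|)}; invariant to
#' positive rescaling of either argument. With \code{centered = TRUE} both
#' vectors are mean-centered first (Pearson-type variant); the default
#' operates on raw absorbance values.
#'
#' @param x numeric vector (spectrum values)
#' @param s numeric vector (signature values), same length
#' @param centered mean-center both vectors first (default FALSE)
#' @return similarity in [-1, 1]
#' @export
cosineSimilarity <- function(x, s, centered = FALSE) {
  if (length(x) != length(s))
    stop("spectrum and signature lengths differ")
  if (centered) {
    x <- x - mean(x)
    s <- s - mean(s)
  }
  nx <- sqrt(sum(x^2))
  ns <- sqrt(sum(s^2))
  if (nx == 0 || ns == 0) stop("zero-norm input to cosine similarity")
  sum(x * s) / (nx * ns)
}

# Vectorised over stream rows; same definition as cosineSimilarity.
streamSimilarities <- function(stream, signature, centered = FALSE) {
  m <- spectraMatrix(stream)
  s <- spectraMatrix(signature)
  if (ncol(m) != length(s))
    stop("stream and signature wavelength axes differ in length")
  # tolerate sub-channel rounding (stream CSVs carry 4 decimals)
  if (max(abs(wavelengths(stream) - wavelengths(signature))) > 1e-3)
    stop("stream and signature wavelength axes differ")
  if (centered) {
    m <- m - rowMeans(m)
    s <- s - mean(s)
  }
  nx <- sqrt(rowSums(m^2))
  ns <- sqrt(sum(s^2))
  if (any(nx == 0) || ns == 0) stop("zero-norm input to cosine similarity")
  as.numeric(m %*% s) / (nx * ns)
}

#' Retain grape-cluster spectra by signature similarity
#'
#' Keeps exactly the spectra whose cosine similarity to the signature is at
#' least \code{threshold} (field-experiment default 0.993), preserving stream
#' order. The report carries every similarity value, so retention can be
#' audited against the threshold.
#'
#' @param stream a \linkS4class{SpectralStream}
#' @param signature a \linkS4class{SpectralSignature}
#' @param threshold similarity threshold in (0, 1]
#' @param centered use centered cosine (see \code{\link{cosineSimilarity}})
#' @return list with \code{retained} (sub-stream) and \code{report}, a list
#'   with \code{block_id}, \code{n_input}, \code{n_retained},
#'   \code{threshold}, \code{similarity_values}, \code{retained_index}
#' @export
filterStream <- function(stream, signature, threshold = 0.993,
                         centered = FALSE) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  sims <- streamSimilarities(stream, signature, centered = centered)
  keep <- which(sims >= threshold)
  list(
    retained = stream[keep],
    report = list(block_id = stream@sourceId,
                  n_input = nSpectra(stream),
                  n_retained = length(keep),
                  threshold = threshold,
                  similarity_values = sims,
                  retained_index = keep)
  )
}

#' Average retained spectra into one block spectrum
#'
#' Channel-wise arithmetic mean of the retained sub-stream; the averaged
#' spectrum's position is the centroid of the member positions and its
#' timestamp their mean. Blocks retaining fewer than \code{minCount} spectra
#' are rejected with an error naming the block.
#'
#' @param retained a \linkS4class{SpectralStream} of retained spectra
#' @param minCount minimum number of member spectra (default 5)
#' @return a one-spectrum \linkS4class{SpectralStream}
#' @export
averageBlock <- function(retained, minCount = 5L) {
  n <- nSpectra(retained)
  if (n < minCount)
    stop(sprintf("insufficient spectra for block '%s': %d retained, %d required",
                 retained@sourceId, n, minCount))
  SpectralStream(colMeans(spectraMatrix(retained)),
                 wavelengths(retained),
                 timestamp = mean(timestamps(retained)),
                 position = matrix(colMeans(positions(retained)), 1, 2),
                 sourceId = retained@sourceId)
}

#' Precision and recall of the filter against hidden class labels
#'
#' Evaluates a filtering result on a simulated stream whose ground-truth
#' labels are known: precision = retained cluster spectra / retained spectra,
#' recall = retained cluster spectra / cluster spectra present.
#'
#' @param stream the input \linkS4class{SpectralStream} with class labels
#' @param report the \code{report} element returned by
#'   \code{\link{filterStream}}
#' @param positiveClass label counted as positive (default "cluster")
#' @return named numeric vector \code{c(precision=, recall=)}
#' @export
filterFidelity <- function(stream, report, positiveClass = "cluster") {
  lab <- classLabels(stream)
  if (!length(lab)) stop("stream carries no ground-truth labels")
  keep <- report$retained_index
  tp <- sum(lab[keep] == positiveClass)
  c(precision = if (length(keep)) tp / length(keep) else NA_real_,
    recall = tp / sum(lab == positiveClass))
}
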