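#' Construct a SpectralStream
#'
#' @param spectra numeric matrix (n spectra x p channels) or a single numeric
#'   vector for a one-spectrum stream.
#' @param wavelengths numeric vector of channel wavelengths (nm), strictly
#'   increasing.
#' @param timestamp numeric vector of acquisition times (seconds); defaults to
#'   0, 1, 2, ...
#' @param position n x 2 matrix of planar coordinates (metres); defaults to
#'   the origin.
#' @param sourceId character scalar.
#' @param classLabel optional character vector of hidden ground-truth labels.
#'
#' @return a \linkS4class{SpectralStream}
#' @export
SpectralStream <- function(spectra, wavelengths, timestamp = NULL,
                           position = NULL, sourceId = "unknown",
                           classLabel = character(0)) {
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)
  spectra <- as.matrix(spectra)
  dimnames(spectra) <- NULL
  n <- nrow(spectra)
  if (is.null(timestamp)) timestamp <- as.numeric(seq_len(n) - 1L)
  if (is.null(position)) position <- matrix(0, n, 2)
  position <- as.matrix(position)
  dimnames(position) <- NULL
  new("SpectralStream", spectra = spectra, wavelengths = as.numeric(wavelengths),
      timestamp = as.numeric(timestamp), position = position,
      sourceId = sourceId, classLabel = as.character(classLabel))
}

#' @rdname nSpectra
#' @export
setMethod("nSpectra", "SpectralStream", function(x) nrow(x@spectra))

#' @rdname nChannels
#' @export
setMethod("nChannels", "SpectralStream", function(x) ncol(x@spectra))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectralStream", function(x) x@wavelengths)

#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectralStream", function(x) x@spectra)

#' @rdname positions
#' @export
setMethod("positions", "SpectralStream", function(x) x@position)

#' @rdname timestamps
#' @export
setMethod("timestamps", "SpectralStream", function(x) x@timestamp)

#' @rdname classLabels
#' @export
setMethod("classLabels", "SpectralStream", function(x) x@classLabel)

#' Subset a stream by spectrum index
#'
#' @param x a \linkS4class{SpectralStream}
#' @param i integer or logical index over spectra
#' @param j,...,drop ignored
#' @return a \linkS4class{SpectralStream} with the selected spectra, in the
#'   order given by \code{i}
#' @export
setMethod("[", "SpectralStream", function(x, i, j, ..., drop = FALSE) {
  i <- seq_len(nSpectra(x))[i]
  new("SpectralStream",
      spectra = x@spectra[i, , drop = FALSE],
      wavelengths = x@wavelengths,
      timestamp = x@timestamp[i],
      position = x@position[i, , drop = FALSE],
      sourceId = x@sourceId,
      classLabel = if (length(x@classLabel)) x@classLabel[i] else character(0))
})

#' Concatenate spectral streams sharing a wavelength axis
#'
#' @param streams list of \linkS4class{SpectralStream}
#' @param sourceId character scalar for the combined stream
#' @return a single \linkS4class{SpectralStream}
#' @export
bindStreams <- function(streams, sourceId = "combined") {
  stopifnot(length(streams) >= 1)
  wl <- wavelengths(streams[[1]])
  for (s in streams)
    if (!isTRUE(all.equal(wavelengths(s), wl)))
      stop("streams do not share a wavelength axis")
  lab <- lapply(streams, classLabels)
  haveLab <- all(vapply(lab, length, 1L) > 0)
  new("SpectralStream",
      spectra = do.call(rbind, lapply(streams, spectraMatrix)),
      wavelengths = wl,
      timestamp = unlist(lapply(streams, timestamps), use.names = FALSE),
      position = do.call(rbind, lapply(streams, positions)),
      sourceId = sourceId,
      classLabel = if (haveLab) unlist(lab, use.names = FALSE) else character(0))
}

setMethod("show", "SpectralStream", function(object) {
  wl <- object@wavelengths
  cat(sprintf("SpectralStream: %d spectra x %d channels", nrow(object@spectra),
              ncol(object@spectra)))
  if (length(wl)) cat(sprintf(" (%.1f-%.1f nm)", min(wl), max(wl)))
  cat(sprintf("\n  source: %s", object@sourceId))
  if (length(object@classLabel)) {
    tab <- table(object@classLabel)
    cat("\n  labels:", paste(names(tab), tab, sep = "=", collapse = " "))
  }
  cat("\n")
})

#' Construct a SpectralSignature
#'
#' @param wavelengths numeric vector (nm)
#' @param values numeric vector of absorbance values
#' @param nSourceSpectra integer, number of averaged source spectra
#' @return a \linkS4class{SpectralSignature}
#' @export
SpectralSignature <- function(wavelengths, values, nSourceSpectra = 1L) {
  new("SpectralSignature", wavelengths = as.numeric(wavelengths),
      values = as.numeric(values), nSourceSpectra = as.integer(nSourceSpectra))
}

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectralSignature", function(x) x@wavelengths)

#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectralSignature", function(x) x@values)

#' @rdname nChannels
#' @export
setMethod("nChannels", "SpectralSignature", function(x) length(x@values))

setMethod("show", "SpectralSignature", function(object) {
  cat(sprintf("SpectralSignature: %d channels, average of %d spectra\n",
              length(object@values), object@nSourceSpectra))
})
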