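#' Number of spectra in a stream
#' @param x a \linkS4class{SpectralStream}
#' @return integer count
#' @export
setGeneric("nSpectra", function(x) standardGeneric("nSpectra"))

#' Number of spectral channels
#' @param x a spectral object
#' @return integer count
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Wavelength axis accessor
#' @param x a spectral object
#' @return numeric vector of wavelengths (nm)
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Spectral value matrix accessor
#' @param x a spectral object
#' @return numeric matrix (spectra as rows) or vector for a signature
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' Position accessor
#' @param x a \linkS4class{SpectralStream}
#' @return n x 2 matrix of planar coordinates (metres)
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' Timestamp accessor
#' @param x a \linkS4class{SpectralStream}
#' @return numeric vector (seconds)
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' Hidden ground-truth class labels (simulator bookkeeping)
#' @param x a \linkS4class{SpectralStream}
#' @return character vector, possibly empty
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Calibration/validation split accessor
#' @param x a \linkS4class{CalibrationSet}
#' @return character vector of split labels (possibly empty)
#' @export
setGeneric("splitLabels", function(x) standardGeneric("splitLabels"))

#' Reference chemistry accessor
#' @param x a \linkS4class{CalibrationSet}
#' @return data.frame of analyte reference values
#' @export
setGeneric("chemistry", function(x) standardGeneric("chemistry"))

#' Sample metadata accessor
#' @param x a \linkS4class{CalibrationSet}
#' @return data.frame of sample metadata
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))
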