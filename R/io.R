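# Stream / chemistry / layout I/O and GPS-based block allocation.
#
# Stream CSV dialect: one row per spectrum; columns timestamp, x, y,
# optionally class, then one column per channel headed "wl_<nm>". UTF-8,
# '.' decimal. All coordinates are planar metres in a local projected frame;
# geographic lon/lat inputs are converted on ingest by a local
# equirectangular approximation, adequate at vineyard scale (< 1 km).

#' Convert geographic coordinates to local planar metres
#'
#' Local equirectangular approximation about \code{origin}: x = R cos(lat0)
#' dlon, y = R dlat, with R = 6371008.8 m.
#'
#' @param lon,lat numeric vectors, degrees
#' @param origin numeric (lon0, lat0), degrees
#' @return n x 2 matrix of (x, y) metres
#' @export
lonlatToLocal <- function(lon, lat, origin) {
  R <- 6371008.8
  lat0 <- origin[2] * pi / 180
  cbind(R * cos(lat0) * (lon - origin[1]) * pi / 180,
        R * (lat - origin[2]) * pi / 180)
}

#' Write a spectral stream to CSV
#'
#' Writes the package's stream dialect and a sidecar \code{<path>.json} with
#' provenance (software version, optional seed and configuration hash).
#'
#' @param stream a \linkS4class{SpectralStream}
#' @param path output CSV path
#' @param seed optional integer recorded in the sidecar
#' @param configHash optional character recorded in the sidecar
#' @param labels write the hidden class labels as a \code{class} column
#'   (default FALSE; ground truth is normally written separately)
#' @return invisibly, \code{path}
#' @export
writeStream <- function(stream, path, seed = NULL, configHash = NULL,
                        labels = FALSE) {
  df <- data.frame(timestamp = timestamps(stream),
                   x = positions(stream)[, 1],
                   y = positions(stream)[, 2])
  if (labels && length(classLabels(stream)))
    df$class <- classLabels(stream)
  m <- spectraMatrix(stream)
  colnames(m) <- sprintf("wl_%.4f", wavelengths(stream))
  write.csv(cbind(df, as.data.frame(m)), path, row.names = FALSE)
  writeProvenance(path, seed = seed, configHash = configHash)
  invisible(path)
}

writeProvenance <- function(path, seed = NULL, configHash = NULL) {
  prov <- list(software = "vinespec",
               version = as.character(utils::packageVersion("vinespec")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(seed)) prov$seed <- seed
  if (!is.null(configHash)) prov$config_hash <- configHash
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(NULL)
}

#' Read a spectral stream from CSV
#'
#' Validates the dialect: the channel headers must declare a strictly
#' increasing wavelength axis and every row must have the full number of
#' fields; ragged rows are reported with their line numbers.
#'
#' @param path CSV file path
#' @return a \linkS4class{SpectralStream}
#' @export
readStream <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])
    stop("ragged rows in ", path, " at line(s): ",
         paste(head(bad, 10), collapse = ", "))
  }
  df <- read.csv(path, check.names = FALSE)
  wlCols <- grep("^wl_", names(df))
  if (!length(wlCols)) stop("no channel columns (wl_*) found in ", path)
  wl <- as.numeric(sub("^wl_", "", names(df)[wlCols]))
  if (any(is.na(wl)))
    stop("unparseable wavelength header in ", path)
  if (length(wl) > 1 && any(diff(wl) <= 0))
    stop("wavelength header must be strictly increasing in ", path)
  m <- as.matrix(df[, wlCols, drop = FALSE])
  if (any(!is.finite(m))) stop("non-finite spectral values in ", path)
  SpectralStream(m, wl,
                 timestamp = df$timestamp,
                 position = cbind(df$x, df$y),
                 sourceId = basename(path),
                 classLabel = if ("class" %in% names(df))
                   as.character(df$class) else character(0))
}

#' Write / read a signature spectrum as CSV
#'
#' @param signature a \linkS4class{SpectralSignature}
#' @param path CSV path
#' @return \code{writeSignature}: invisibly \code{path};
#'   \code{readSignature}: a \linkS4class{SpectralSignature}
#' @export
writeSignature <- function(signature, path) {
  write.csv(data.frame(wavelength = wavelengths(signature),
                       value = spectraMatrix(signature)),
            path, row.names = FALSE)
  writeProvenance(path)
  invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
  df <- read.csv(path)
  SpectralSignature(df$wavelength, df$value)
}

#' Allocate stream spectra to vine blocks by GPS position
#'
#' Each spectrum is assigned to the nearest block centroid provided it lies
#' within \code{maxDistance}; otherwise it is discarded. Ties in distance go
#' to the lexicographically lower \code{block_id}. The allocation is
#' exhaustive and disjoint: per-block counts plus the discard count always
#' sum to the stream length.
#'
#' @param stream a \linkS4class{SpectralStream}
#' @param blocks data.frame with \code{block_id}, \code{x}, \code{y}
#' @param maxDistance metres; default half the standard 2.20 m row spacing
#' @return list with \code{substreams} (named list block_id -> stream; only
#'   non-empty blocks present), \code{assignment} (character vector, NA =
#'   discarded) and \code{nDiscarded}
#' @export
allocateToBlocks <- function(stream, blocks, maxDistance = 1.10) {
  if (is.null(blocks) || nrow(blocks) == 0) stop("blocks must be non-empty")
  if (maxDistance <= 0) stop("maxDistance must be positive")
  n <- nSpectra(stream)
  ord <- order(blocks$block_id)
  blocks <- blocks[ord, ]
  assignment <- rep(NA_character_, n)
  if (n > 0) {
    pos <- positions(stream)
    d2 <- outer(pos[, 1], blocks$x, "-")^2 + outer(pos[, 2], blocks$y, "-")^2
    # first index among ties = lower block_id because rows are sorted
    best <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(d2[cbind(seq_len(n), best)])
    keep <- dmin <= maxDistance
    assignment[keep] <- blocks$block_id[best[keep]]
  }
  ids <- unique(assignment[!is.na(assignment)])
  substreams <- lapply(ids, function(id) stream[which(assignment == id)])
  names(substreams) <- ids
  list(substreams = substreams, assignment = assignment,
       nDiscarded = sum(is.na(assignment)))
}

#' Convert reflectance to absorbance (and back)
#'
#' Absorbance A = log10(1/R); the wavelength axis is unchanged.
#'
#' @param stream a \linkS4class{SpectralStream} in reflectance units
#' @return a \linkS4class{SpectralStream} in the other unit
#' @export
reflectanceToAbsorbance <- function(stream) {
  m <- spectraMatrix(stream)
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)
    stop(sprintf("non-positive reflectance at spectrum %d, channel %d (%.4f nm)",
                 bad[1, 1], bad[1, 2], wavelengths(stream)[bad[1, 2]]))
  }
  initialize(stream, spectra = log10(1 / m))
}

#' @rdname reflectanceToAbsorbance
#' @export
absorbanceToReflectance <- function(stream) {
  initialize(stream, spectra = 10^(-spectraMatrix(stream)))
}

#' Write / read block chemistry and layout tables
#'
#' @param chemistryTable data.frame from \code{\link{generateChemistry}}
#' @param blocks data.frame of block centroids
#' @param path CSV path
#' @return the table (readers) or invisibly \code{path} (writers)
#' @export
writeChemistry <- function(chemistryTable, path) {
  write.csv(chemistryTable, path, row.names = FALSE)
  writeProvenance(path)
  invisible(path)
}

#' @rdname writeChemistry
#' @export
readChemistry <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname writeChemistry
#' @export
writeBlocks <- function(blocks, path) {
  write.csv(blocks, path, row.names = FALSE)
  writeProvenance(path)
  invisible(path)
}

#' @rdname writeChemistry
#' @export
readBlocks <- function(path) read.csv(path, stringsAsFactors = FALSE)
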