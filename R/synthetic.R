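# Synthetic vineyard world: layout, block chemistry with spatial structure,
# class-labelled on-the-go spectral streams, and the manual cluster signature.

ANALYTES <- c("tss", "anthocyanins", "polyphenols")

#' Instrument wavelength axis
#'
#' The spectrometer emits 215 channels over the 570-990 nm range. The nominal
#' 2 nm resolution would give 211 points; the printed channel count (215) is
#' treated as authoritative and the axis is derived as 215 evenly spaced
#' points over the range, so model matrices have the published dimensionality.
#'
#' @param start,end range ends in nm
#' @param nChannels number of channels
#' @return numeric vector of wavelengths (nm)
#' @export
instrumentWavelengths <- function(start = 570, end = 990, nChannels = 215) {
  seq(start, end, length.out = nChannels)
}

#' Circular measuring-spot area
#'
#' Area of the instrument's circular measuring spot from its diameter.
#'
#' @param diameter_cm spot diameter in cm (default 1.9)
#' @return area in cm^2
#' @export
spotArea <- function(diameter_cm = 1.9) pi * diameter_cm^2 / 4

#' Acquisition/simulation configuration
#'
#' @param seed integer RNG seed used by stream simulation.
#' @param wavelengthStart,wavelengthEnd spectral range (nm).
#' @param nChannels channels per spectrum.
#' @param acquisitionRate spectra per second (Hz).
#' @param platformSpeed vehicle speed (km/h).
#' @param classMixture named probabilities over \code{cluster}, \code{leaf},
#'   \code{wood}, \code{gap}; must sum to 1. The cluster fraction within the
#'   defoliated fruiting zone is not an instrument property; 0.35 is the
#'   package default.
#' @param scatterSlopeSd,scatterOffsetSd per-spectrum multiplicative slope and
#'   additive offset noise (dimensionless / absorbance).
#' @param channelNoiseSd independent per-channel noise sd (absorbance).
#' @param passSlopeSd,passOffsetSd per-pass (block-level) scatter drift that
#'   is common to all spectra of one pass and therefore does not average out.
#' @param passShapeSd amplitude sd of a smooth per-pass spectral perturbation
#'   (a random combination of broad Gaussian bumps), emulating slowly varying
#'   canopy-geometry and stray-light effects that change between passes but
#'   not within one; absorbance units.
#' @param blockLength along-row length of one block (metres); the pipeline
#'   sets it to vines_per_block x vine_spacing.
#' @return a list of class \code{vinespec_simconfig}
#' @export
simConfig <- function(seed = 1L,
                      wavelengthStart = 570, wavelengthEnd = 990,
                      nChannels = 215L,
                      acquisitionRate = 18, platformSpeed = 5,
                      classMixture = c(cluster = 0.35, leaf = 0.40,
                                       wood = 0.10, gap = 0.15),
                      scatterSlopeSd = 0.01, scatterOffsetSd = 0.005,
                      channelNoiseSd = 0.01,
                      passSlopeSd = 0.03, passOffsetSd = 0.012,
                      passShapeSd = 0.012,
                      blockLength = 5.0) {
  if (length(classMixture) == 0)
    stop("classMixture must not be empty")
  if (abs(sum(classMixture) - 1) > 1e-8)
    stop("classMixture must sum to 1")
  if (acquisitionRate <= 0 || platformSpeed <= 0)
    stop("acquisition rate and platform speed must be positive")
  structure(list(
    seed = as.integer(seed),
    wavelengths = instrumentWavelengths(wavelengthStart, wavelengthEnd,
                                        nChannels),
    acquisitionRate = acquisitionRate,
    platformSpeed = platformSpeed,
    classMixture = classMixture,
    scatterSlopeSd = scatterSlopeSd,
    scatterOffsetSd = scatterOffsetSd,
    channelNoiseSd = channelNoiseSd,
    passSlopeSd = passSlopeSd,
    passOffsetSd = passOffsetSd,
    passShapeSd = passShapeSd,
    blockLength = blockLength
  ), class = "vinespec_simconfig")
}

#' Vineyard layout: rows of vine blocks on a planar grid
#'
#' Places \code{rows x blocksPerRow} block centroids along parallel rows.
#' Blocks are runs of \code{vinesPerBlock} consecutive vines; the centroid of
#' block b in a row sits at (b - 1/2) block lengths along the row. The whole
#' grid is rotated by \code{rowAzimuth} about \code{origin}.
#'
#' @param rows number of rows (>= 1)
#' @param blocksPerRow blocks per row (>= 1)
#' @param vinesPerBlock vines per block
#' @param rowSpacing metres between rows (default 2.20)
#' @param vineSpacing metres between vines within a row (default 1.0)
#' @param origin numeric (x, y) of the grid origin in metres
#' @param rowAzimuth rotation of the row direction, degrees
#' @return list with elements \code{layout} (the parameters) and
#'   \code{blocks}, a data.frame with columns \code{block_id},
#'   \code{row_index}, \code{block_index}, \code{x}, \code{y}
#' @export
vineyardLayout <- function(rows = 3L, blocksPerRow = 12L, vinesPerBlock = 5L,
                           rowSpacing = 2.20, vineSpacing = 1.0,
                           origin = c(0, 0), rowAzimuth = 0) {
  if (rows < 1 || blocksPerRow < 1 || vinesPerBlock < 1)
    stop("layout dimensions must be positive")
  if (rowSpacing <= 0 || vineSpacing <= 0)
    stop("spacings must be positive")
  blockLength <- vinesPerBlock * vineSpacing
  g <- expand.grid(block_index = seq_len(blocksPerRow), row_index = seq_len(rows))
  along <- (g$block_index - 0.5) * blockLength
  cross <- (g$row_index - 1) * rowSpacing
  th <- rowAzimuth * pi / 180
  blocks <- data.frame(
    block_id = sprintf("R%dB%02d", g$row_index, g$block_index),
    row_index = g$row_index,
    block_index = g$block_index,
    x = origin[1] + along * cos(th) - cross * sin(th),
    y = origin[2] + along * sin(th) + cross * cos(th),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(round(cbind(blocks$x, blocks$y), 9)))
    stop("block centroids are not unique")
  list(
    layout = list(rows = rows, blocksPerRow = blocksPerRow,
                  vinesPerBlock = vinesPerBlock, rowSpacing = rowSpacing,
                  vineSpacing = vineSpacing, origin = origin,
                  rowAzimuth = rowAzimuth, blockLength = blockLength),
    blocks = blocks
  )
}

#' Default per-analyte field parameters
#'
#' Global ranges follow the observed berry composition of the campaign the
#' generator emulates: TSS 10.7-25.2 degrees Brix, anthocyanins
#' 0.09-4.64 mg/berry, total polyphenols 0.14-4.70 AU/berry, with per-date
#' means rising monotonically from veraison to harvest. \code{spectralSnr}
#' controls how strongly each analyte imprints on cluster spectra and
#' decreases tss > anthocyanins > polyphenols, reflecting the decreasing
#' spectral accessibility of the three analytes in the VIS/SW-NIR range.
#'
#' @param correlationLength spatial correlation length of the latent block
#'   field, metres
#' @param couplingRho correlation between the anthocyanin and polyphenol
#'   latent fields (their spatial patterns are near-duplicates in ripe fruit)
#' @return nested list of per-analyte parameters
#' @export
analyteFieldParams <- function(correlationLength = 15, couplingRho = 0.8) {
  list(
    tss = list(globalRange = c(10.7, 25.2),
               dateMeans = c(14.0, 17.0, 20.0, 22.5),
               fieldSd = 2.2, noiseSd = 0.4, spectralSnr = 0.20),
    anthocyanins = list(globalRange = c(0.09, 4.64),
                        dateMeans = c(0.9, 1.8, 2.7, 3.4),
                        fieldSd = 0.75, noiseSd = 0.15, spectralSnr = 0.055),
    polyphenols = list(globalRange = c(0.14, 4.70),
                       dateMeans = c(1.1, 2.0, 2.9, 3.6),
                       fieldSd = 0.80, noiseSd = 0.20, spectralSnr = 0.018),
    correlationLength = correlationLength,
    couplingRho = couplingRho
  )
}

# Sample one zero-mean unit-variance Gaussian field over block centroids with
# squared-exponential covariance. Degenerate (e.g. infinite-length) kernels
# are handled through the eigendecomposition with clamped eigenvalues.
sampleSpatialField <- function(coords, correlationLength) {
  n <- nrow(coords)
  if (is.infinite(correlationLength)) {
    return(rep(rnorm(1), n))
  }
  d <- as.matrix(dist(coords))
  K <- exp(-d^2 / (2 * correlationLength^2))
  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  as.numeric(e$vectors %*% (sqrt(lam) * rnorm(n)))
}

#' Generate block reference chemistry across dates
#'
#' For each analyte a smooth latent spatial field is drawn once over block
#' centroids (squared-exponential covariance) and reused across dates, so
#' maps evolve coherently; per-date means shift the field, independent noise
#' is added, and values are clipped to the configured global range. The
#' anthocyanin and polyphenol fields share a common latent component with
#' correlation \code{couplingRho}.
#'
#' @param layout result of \code{\link{vineyardLayout}}
#' @param params result of \code{\link{analyteFieldParams}}
#' @param nDates number of measurement dates (>= 1)
#' @param seed integer RNG seed
#' @return data.frame with columns \code{block_id}, \code{date_index},
#'   \code{tss}, \code{anthocyanins}, \code{polyphenols}
#' @export
generateChemistry <- function(layout, params = analyteFieldParams(),
                              nDates = 4L, seed = 1L) {
  if (nDates < 1) stop("nDates must be >= 1")
  blocks <- layout$blocks
  coords <- cbind(blocks$x, blocks$y)
  nb <- nrow(blocks)
  set.seed(seed)
  zTss <- sampleSpatialField(coords, params$correlationLength)
  zCommon <- sampleSpatialField(coords, params$correlationLength)
  uAnt <- sampleSpatialField(coords, params$correlationLength)
  uPol <- sampleSpatialField(coords, params$correlationLength)
  rho <- params$couplingRho
  latent <- list(
    tss = zTss,
    anthocyanins = sqrt(rho) * zCommon + sqrt(1 - rho) * uAnt,
    polyphenols = sqrt(rho) * zCommon + sqrt(1 - rho) * uPol
  )
  out <- expand.grid(block_id = blocks$block_id,
                     date_index = seq_len(nDates),
                     stringsAsFactors = FALSE)
  for (a in ANALYTES) {
    p <- params[[a]]
    dm <- p$dateMeans
    if (length(dm) < nDates)
      dm <- c(dm, rep(dm[length(dm)], nDates - length(dm)))
    if (any(diff(dm) < 0))
      stop("date means must be monotone non-decreasing")
    vals <- numeric(nb * nDates)
    for (d in seq_len(nDates)) {
      idx <- (d - 1) * nb + seq_len(nb)
      vals[idx] <- dm[d] + p$fieldSd * latent[[a]] +
        rnorm(nb, sd = p$noiseSd)
    }
    out[[a]] <- pmin(pmax(vals, p$globalRange[1]), p$globalRange[2])
  }
  out
}

#' Default spectral endmembers for the four stream classes
#'
#' Idealised absorbance shapes for grape cluster, leaf, wood and canopy-gap
#' returns over the instrument's wavelength axis, plus the per-analyte
#' Gaussian absorption bands through which cluster chemistry imprints on
#' cluster spectra. Shapes are synthetic: a pigment-dominated cluster curve
#' with a water band near 970 nm, a chlorophyll-peaked leaf curve with a
#' red-edge drop, a gently sloped wood continuum and a weak flat gap return.
#'
#' @param wavelengths numeric wavelength axis (nm)
#' @return list with one element per class; the cluster element carries a
#'   \code{bands} list of per-analyte \code{center}, \code{width},
#'   \code{loading}
#' @export
defaultEndmembers <- function(wavelengths = instrumentWavelengths()) {
  w <- wavelengths
  gauss <- function(c0, s) exp(-((w - c0) / s)^2)
  list(
    cluster = list(
      base = 0.30 + 0.85 * gauss(620, 80) + 0.30 * gauss(970, 45) -
        0.00035 * (w - 570),
      bands = list(
        tss = list(center = 905, width = 28, loading = 1),
        anthocyanins = list(center = 612, width = 34, loading = 1),
        polyphenols = list(center = 755, width = 30, loading = 1)
      )
    ),
    leaf = list(base = 0.25 + 1.05 * gauss(672, 32) + 0.45 * gauss(590, 45) +
                  0.18 * gauss(970, 45)),
    wood = list(base = 0.62 - 0.00085 * (w - 570) + 0.10 * gauss(970, 60)),
    gap = list(base = rep(0.13, length(w)))
  )
}

# Absorbance spectra for n draws of one class at given chemistry (0-1 scaled
# concentrations), without per-spectrum noise. Matrix n x p.
classBaseSpectrum <- function(class, endmembers, conc01, snr, wavelengths) {
  base <- endmembers[[class]]$base
  if (class == "cluster") {
    for (a in names(conc01)) {
      b <- endmembers$cluster$bands[[a]]
      base <- base + snr[[a]] * b$loading * conc01[[a]] *
        exp(-((wavelengths - b$center) / b$width)^2)
    }
  }
  base
}

scaleConc <- function(chemRow, params) {
  out <- list()
  for (a in ANALYTES) {
    r <- params[[a]]$globalRange
    out[[a]] <- (chemRow[[a]] - r[1]) / (r[2] - r[1])
  }
  out
}

#' Simulate one on-the-go pass over a block
#'
#' Emits \code{floor(blockLength / speed x rate)} spectra whose classes are
#' drawn independently from the configured class mixture. Cluster spectra are
#' the cluster endmember plus per-analyte Gaussian bands scaled by the 0-1
#' scaled block concentration and \code{spectralSnr}; all spectra then
#' receive a per-pass scatter drift, a per-spectrum multiplicative slope and
#' additive offset, and independent channel noise. Positions advance along
#' the row at speed/rate metres per spectrum; the true class of every
#' spectrum is stored as a hidden label for filter evaluation only.
#'
#' @param block one-row data.frame from \code{\link{vineyardLayout}$blocks}
#' @param chemRow one-row data.frame of the block's chemistry on the date
#' @param endmembers result of \code{\link{defaultEndmembers}}
#' @param sim result of \code{\link{simConfig}}
#' @param params result of \code{\link{analyteFieldParams}} (for ranges and
#'   spectral SNRs)
#' @param layout result of \code{\link{vineyardLayout}} (row direction)
#' @param seed integer RNG seed
#' @param t0 timestamp of the first spectrum (seconds)
#' @return a \linkS4class{SpectralStream} with hidden class labels
#' @export
simulateStream <- function(block, chemRow, endmembers, sim,
                           params = analyteFieldParams(), layout = NULL,
                           seed = sim$seed, t0 = 0) {
  classes <- names(sim$classMixture)
  missing <- setdiff(classes, names(endmembers))
  if (length(missing))
    stop("endmembers missing for classes: ", paste(missing, collapse = ", "))
  w <- sim$wavelengths
  p <- length(w)
  speed <- sim$platformSpeed * 1000 / 3600          # m/s
  n <- floor(sim$blockLength / speed * sim$acquisitionRate)
  set.seed(seed)
  lab <- sample(classes, n, replace = TRUE, prob = sim$classMixture)
  conc01 <- scaleConc(chemRow, params)
  snr <- lapply(ANALYTES, function(a) params[[a]]$spectralSnr)
  names(snr) <- ANALYTES
  bases <- lapply(classes, classBaseSpectrum, endmembers = endmembers,
                  conc01 = conc01, snr = snr, wavelengths = w)
  names(bases) <- classes
  passSlope <- rnorm(1, sd = sim$passSlopeSd)
  passOffset <- rnorm(1, sd = sim$passOffsetSd)
  shapeSd <- if (is.null(sim$passShapeSd)) 0 else sim$passShapeSd
  passShape <- if (shapeSd > 0) {
    ctr <- runif(4, min(w), max(w))
    wid <- runif(4, 60, 120)
    amp <- rnorm(4, sd = shapeSd)
    colSums(amp * t(exp(-((outer(w, ctr, "-")) / rep(wid, each = p))^2)))
  } else rep(0, p)
  slopes <- 1 + passSlope + rnorm(n, sd = sim$scatterSlopeSd)
  offsets <- passOffset + rnorm(n, sd = sim$scatterOffsetSd)
  noise <- matrix(rnorm(n * p, sd = sim$channelNoiseSd), n, p)
  X <- t(vapply(seq_len(n),
                function(i) bases[[lab[i]]] * slopes[i] + passShape + offsets[i],
                numeric(p))) + noise
  th <- if (is.null(layout)) 0 else layout$layout$rowAzimuth * pi / 180
  stepLen <- speed / sim$acquisitionRate
  along <- (seq_len(n) - (n + 1) / 2) * stepLen
  pos <- cbind(block$x + along * cos(th), block$y + along * sin(th))
  SpectralStream(X, w,
                 timestamp = t0 + (seq_len(n) - 1) / sim$acquisitionRate,
                 position = pos,
                 sourceId = block$block_id,
                 classLabel = lab)
}

#' Build the manual grape-cluster signature
#'
#' Averages \code{nSpectraAvg} noise-bearing cluster-class spectra generated
#' at mid-range chemistry, emulating the manually acquired and averaged
#' signature used to filter on-the-go streams.
#'
#' @param endmembers result of \code{\link{defaultEndmembers}}
#' @param sim result of \code{\link{simConfig}}
#' @param params result of \code{\link{analyteFieldParams}}
#' @param nSpectraAvg number of spectra to average (>= 1)
#' @param seed integer RNG seed
#' @return a \linkS4class{SpectralSignature}
#' @export
makeSignature <- function(endmembers, sim, params = analyteFieldParams(),
                          nSpectraAvg = 50L, seed = sim$seed) {
  if (nSpectraAvg < 1) stop("nSpectraAvg must be >= 1")
  w <- sim$wavelengths
  p <- length(w)
  conc01 <- list(tss = 0.5, anthocyanins = 0.5, polyphenols = 0.5)
  snr <- lapply(ANALYTES, function(a) params[[a]]$spectralSnr)
  names(snr) <- ANALYTES
  base <- classBaseSpectrum("cluster", endmembers, conc01, snr, w)
  set.seed(seed)
  slopes <- 1 + rnorm(nSpectraAvg, sd = sim$scatterSlopeSd)
  offsets <- rnorm(nSpectraAvg, sd = sim$scatterOffsetSd)
  noise <- matrix(rnorm(nSpectraAvg * p, sd = sim$channelNoiseSd),
                  nSpectraAvg, p)
  X <- outer(slopes, base) + offsets + noise
  SpectralSignature(w, colMeans(X), nSourceSpectra = nSpectraAvg)
}

#' Simulate the full campaign: streams for every block and date
#'
#' @param layout result of \code{\link{vineyardLayout}}
#' @param chemistryTable result of \code{\link{generateChemistry}}
#' @param endmembers result of \code{\link{defaultEndmembers}}
#' @param sim result of \code{\link{simConfig}}
#' @param params result of \code{\link{analyteFieldParams}}
#' @param seed integer base seed; per-stream seeds are derived from it
#' @return nested list \code{streams[[date_index]][[block_id]]} of
#'   \linkS4class{SpectralStream}
#' @export
simulateCampaign <- function(layout, chemistryTable,
                             endmembers = defaultEndmembers(sim$wavelengths),
                             sim = simConfig(), params = analyteFieldParams(),
                             seed = sim$seed) {
  blocks <- layout$blocks
  dates <- sort(unique(chemistryTable$date_index))
  out <- vector("list", length(dates))
  names(out) <- as.character(dates)
  for (d in dates) {
    byBlock <- vector("list", nrow(blocks))
    names(byBlock) <- blocks$block_id
    for (b in seq_len(nrow(blocks))) {
      blk <- blocks[b, ]
      chem <- chemistryTable[chemistryTable$block_id == blk$block_id &
                               chemistryTable$date_index == d, ]
      sseed <- as.integer((as.numeric(seed) * 10007 + d * 1009 + b * 101) %%
                            2147483629)
      byBlock[[b]] <- simulateStream(blk, chem, endmembers, sim, params,
                                     layout, seed = sseed,
                                     t0 = (b - 1) * 10)
    }
    out[[as.character(d)]] <- byBlock
  }
  out
}
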