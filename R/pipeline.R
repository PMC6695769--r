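# Config-driven end-to-end orchestration: simulate -> allocate -> filter ->
# average -> pre-process -> outlier screen -> train -> map.

#' Default run configuration
#'
#' One document governs a run; every field can be overridden, and
#' \code{\link{readRunConfig}} merges a YAML file over these defaults.
#' Allocation uses half the block length (2.5 m by default) as the maximum
#' centroid distance so that a pass over a 5-vine block maps entirely to that
#' block; the stricter half-row-spacing default of
#' \code{\link{allocateToBlocks}} suits cross-row discarding when several
#' rows are driven in one stream.
#'
#' @param seed integer master seed; all stage seeds derive from it
#' @return nested list of class \code{vinespec_config}
#' @export
runConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    layout = list(rows = 3L, blocksPerRow = 12L, vinesPerBlock = 5L,
                  rowSpacing = 2.20, vineSpacing = 1.0,
                  origin = c(0, 0), rowAzimuth = 0),
    nDates = 4L,
    sim = list(),                       # overrides for simConfig()
    field = list(),                     # overrides for analyteFieldParams()
    filter = list(threshold = 0.993, minCount = 5L, centered = FALSE,
                  signatureSpectra = 50L),
    allocation = list(maxDistance = 2.5),
    treatments = c(tss = "D1W15", anthocyanins = "D1W15",
                   polyphenols = "SNV + DT D1W15"),
    model = list(fraction = 0.8, nFolds = 10L, maxLV = 15L),
    map = list(cellSize = 1, nLevels = 8L, maskDistance = 4.4)
  ), class = "vinespec_config")
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' @param path YAML file; missing fields fall back to \code{\link{runConfig}}
#' @return a validated config list
#' @export
readRunConfig <- function(path) {
  cfg <- mergeConfig(unclass(runConfig()), yaml::read_yaml(path))
  validateConfig(structure(cfg, class = "vinespec_config"))
}

#' Validate a run configuration
#'
#' @param config a config list
#' @return the config, invisibly, or an error naming the offending field
#' @export
validateConfig <- function(config) {
  with(config, {
    if (layout$rows < 1 || layout$blocksPerRow < 1)
      stop("config error: layout dimensions must be positive")
    if (filter$threshold <= 0 || filter$threshold > 1)
      stop("config error: filter threshold must be in (0, 1]")
    if (model$fraction <= 0 || model$fraction >= 1)
      stop("config error: calibration fraction must be in (0, 1)")
    if (nDates < 1) stop("config error: nDates must be >= 1")
  })
  invisible(config)
}

stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 2654435 + stage * 40503) %% 2147483629)
}

fileHash <- function(path) unname(tools::md5sum(path))

#' Build the calibration dataset from simulated streams
#'
#' Runs allocation, signature filtering and per-block averaging for every
#' date, assembling the block x date sample matrix in block-major,
#' date-minor order (each block's dates consecutive), paired with the
#' reference chemistry.
#'
#' @param world result of \code{\link{simulateWorld}}
#' @param config a run configuration
#' @return list with \code{dataset} (a \linkS4class{CalibrationSet}),
#'   \code{counts} (per-stage spectra bookkeeping) and \code{fidelity}
#'   (pooled filter precision/recall vs hidden labels)
#' @export
buildDataset <- function(world, config = runConfig()) {
  blocks <- world$layout$blocks
  dates <- sort(unique(world$chemistry$date_index))
  rows <- list()
  nIn <- 0L
  nAlloc <- 0L
  nRet <- 0L
  tp <- 0L
  fp <- 0L
  fn <- 0L
  avg <- list()
  for (d in dates) {
    stream <- bindStreams(world$streams[[as.character(d)]],
                          sourceId = sprintf("date%d", d))
    nIn <- nIn + nSpectra(stream)
    alloc <- allocateToBlocks(stream, blocks,
                              maxDistance = config$allocation$maxDistance)
    for (id in names(alloc$substreams)) {
      sub <- alloc$substreams[[id]]
      sub@sourceId <- id
      nAlloc <- nAlloc + nSpectra(sub)
      fr <- filterStream(sub, world$signature,
                         threshold = config$filter$threshold,
                         centered = config$filter$centered)
      nRet <- nRet + fr$report$n_retained
      lab <- classLabels(sub)
      if (length(lab)) {
        keep <- fr$report$retained_index
        tp <- tp + sum(lab[keep] == "cluster")
        fp <- fp + sum(lab[keep] != "cluster")
        fn <- fn + sum(lab[-keep] == "cluster")
      }
      blockAvg <- tryCatch(
        averageBlock(fr$retained, minCount = config$filter$minCount),
        error = function(e) {
          warning(conditionMessage(e), call. = FALSE)
          NULL
        })
      if (!is.null(blockAvg))
        avg[[paste(id, d, sep = "|")]] <- blockAvg
    }
  }
  if (!length(avg))
    stop("insufficient spectra: no block retained the minimum number of ",
         "cluster spectra at threshold ", config$filter$threshold)
  # block-major, date-minor sample order
  keys <- expand.grid(date = dates, block = blocks$block_id,
                      stringsAsFactors = FALSE)
  keys <- keys[order(keys$block, keys$date), c("block", "date")]
  keyId <- paste(keys$block, keys$date, sep = "|")
  missing <- setdiff(keyId, names(avg))
  if (length(missing))
    warning("blocks excluded (insufficient retained spectra): ",
            paste(missing, collapse = ", "))
  keyId <- intersect(keyId, names(avg))
  X <- do.call(rbind, lapply(avg[keyId], spectraMatrix))
  meta <- data.frame(
    block_id = sub("\\|.*$", "", keyId),
    date_index = as.integer(sub("^.*\\|", "", keyId)),
    stringsAsFactors = FALSE)
  chemKey <- paste(world$chemistry$block_id, world$chemistry$date_index,
                   sep = "|")
  chem <- world$chemistry[match(keyId, chemKey),
                          c("tss", "anthocyanins", "polyphenols")]
  rownames(chem) <- NULL
  dataset <- CalibrationSet(X, world$wavelengths, chem, meta)
  list(dataset = dataset,
       counts = list(spectra_in = nIn, allocated = nAlloc, retained = nRet,
                     samples = nrow(X)),
       fidelity = c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_))
}

#' Simulate the full synthetic world for a configuration
#'
#' @param config a run configuration
#' @return list with \code{layout}, \code{chemistry}, \code{endmembers},
#'   \code{sim}, \code{field}, \code{signature}, \code{streams},
#'   \code{wavelengths}
#' @export
simulateWorld <- function(config = runConfig()) {
  validateConfig(config)
  lay <- do.call(vineyardLayout, config$layout[c("rows", "blocksPerRow",
                                                "vinesPerBlock", "rowSpacing",
                                                "vineSpacing", "origin",
                                                "rowAzimuth")])
  sim <- do.call(simConfig, mergeConfig(
    list(seed = stageSeed(config$seed, 1L),
         blockLength = lay$layout$blockLength), config$sim))
  field <- do.call(analyteFieldParams,
                   config$field[intersect(names(config$field),
                                          c("correlationLength", "couplingRho"))])
  chem <- generateChemistry(lay, field, nDates = config$nDates,
                            seed = stageSeed(config$seed, 2L))
  em <- defaultEndmembers(sim$wavelengths)
  sig <- makeSignature(em, sim, field,
                       nSpectraAvg = config$filter$signatureSpectra,
                       seed = stageSeed(config$seed, 3L))
  streams <- simulateCampaign(lay, chem, em, sim, field,
                              seed = stageSeed(config$seed, 4L))
  list(layout = lay, chemistry = chem, endmembers = em, sim = sim,
       field = field, signature = sig, streams = streams,
       wavelengths = sim$wavelengths)
}

#' Run the full pipeline and write artifacts
#'
#' Executes simulate, allocate, filter, average, outlier screening, model
#' training per analyte and map rendering, writing all artifacts and a run
#' manifest under \code{outDir}. Any stage failure aborts with the stage
#' name.
#'
#' @param config a run configuration (see \code{\link{runConfig}})
#' @param outDir output directory (created if needed); NULL = no files
#' @return list with \code{dataset}, \code{stats} (per-analyte model
#'   statistics, calibration-table shaped), \code{models}, \code{maps},
#'   \code{outliers}, \code{counts}, \code{fidelity}, \code{manifest}
#' @export
runAll <- function(config = runConfig(), outDir = NULL) {
  validateConfig(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  t0 <- Sys.time()
  world <- stage("simulate", simulateWorld(config))
  built <- stage("filter", buildDataset(world, config))
  dataset <- built$dataset

  wl <- world$wavelengths
  stepNm <- wl[2] - wl[1]
  screen <- stage("outlier-screen", {
    Xs <- applyChain("D1W15", spectraMatrix(dataset), step = stepNm)
    detectOutliers(Xs)
  })
  keep <- !screen$flagged
  if (any(!keep))
    dataset <- CalibrationSet(spectraMatrix(dataset)[keep, , drop = FALSE],
                              wl, chemistry(dataset)[keep, , drop = FALSE],
                              sampleMeta(dataset)[keep, , drop = FALSE])

  fits <- list()
  statsRows <- list()
  for (a in names(config$treatments)) {
    fits[[a]] <- stage(paste0("train-", a),
      trainAnalyteModel(dataset, a, config$treatments[[a]],
                        maxLV = config$model$maxLV,
                        nFolds = config$model$nFolds,
                        fraction = config$model$fraction,
                        seed = stageSeed(config$seed, 5L)))
    statsRows[[a]] <- fits[[a]]$stats
  }
  stats <- do.call(rbind, statsRows)
  rownames(stats) <- NULL

  maps <- stage("map", {
    blocks <- world$layout$blocks
    meta <- sampleMeta(dataset)
    grid <- mapGrid(blocks, cellSize = config$map$cellSize,
                    pad = world$layout$layout$rowSpacing)
    out <- list()
    for (a in names(fits)) {
      Xp <- applyChain(config$treatments[[a]], spectraMatrix(dataset),
                       step = stepNm)
      pred <- predict(fits[[a]]$model, Xp)
      byDate <- split(data.frame(
        x = blocks$x[match(meta$block_id, blocks$block_id)],
        y = blocks$y[match(meta$block_id, blocks$block_id)],
        value = pred), meta$date_index)
      out[[a]] <- renderSeries(byDate, blocks, grid = grid,
                               nLevels = config$map$nLevels, analyte = a,
                               maskDistance = config$map$maskDistance)
    }
    out
  })

  manifest <- list(
    version = as.character(utils::packageVersion("vinespec")),
    seed = config$seed,
    counts = c(built$counts,
               list(outliers_flagged = sum(screen$flagged),
                    samples_modelled = nrow(spectraMatrix(dataset)))),
    stages = c("simulate", "allocate", "filter", "average", "outlier-screen",
               "train", "map"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeChemistry(world$chemistry, file.path(outDir, "chemistry.csv"))
    writeBlocks(world$layout$blocks, file.path(outDir, "blocks.csv"))
    writeSignature(world$signature, file.path(outDir, "signature.csv"))
    dsPath <- file.path(outDir, "dataset.csv")
    dsm <- spectraMatrix(dataset)
    colnames(dsm) <- sprintf("wl_%.4f", wl)
    write.csv(cbind(sampleMeta(dataset), chemistry(dataset),
                    as.data.frame(dsm)), dsPath, row.names = FALSE)
    write.csv(stats, file.path(outDir, "model_statistics.csv"),
              row.names = FALSE)
    for (a in names(fits)) {
      m <- fits[[a]]$model
      jsonlite::write_json(list(
        analyte = a, treatment = m@treatment, n_lv = m@nLV,
        x_center = m@xCenter, y_center = m@yCenter, coef = m@coef),
        file.path(outDir, sprintf("model_%s.json", a)), digits = NA)
      for (d in names(maps[[a]]))
        writeAsciiGrid(maps[[a]][[d]],
                       file.path(outDir, sprintf("map_%s_date%s.asc", a, d)))
    }
    yaml::write_yaml(unclass(config), file.path(outDir, "config.yaml"))
    arts <- list.files(outDir, pattern = "\\.(csv|asc|json|yaml)$",
                       full.names = TRUE)
    arts <- arts[!grepl("manifest\\.json$|csv\\.json$", arts)]
    manifest$artifact_hashes <- stats::setNames(
      vapply(arts, fileHash, character(1)), basename(arts))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(dataset = dataset, stats = stats, models = lapply(fits, `[[`, "model"),
       fits = fits, maps = maps, outliers = screen, counts = manifest$counts,
       fidelity = built$fidelity, manifest = manifest, world = world)
}
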