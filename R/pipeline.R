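#' @include AllClasses.R AllGenerics.R
NULL

#' Serialize a network to a structured JSON file
#'
#' @param model a [BPNetwork-class] or [BPNetworkFit-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNetworkJSON <- function(model, path) {
  if (is(model, "BPNetworkFit")) model <- model@model
  obj <- list(W = model@W, theta = model@theta, Wout = model@Wout,
              alpha = model@alpha, hiddenTransfer = model@hiddenTransfer,
              outputTransfer = model@outputTransfer,
              indicatorNames = colnames(model@W))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a network serialized by [writeNetworkJSON()]
#'
#' @param path JSON file.
#' @return a [BPNetwork-class].
#' @export
readNetworkJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(obj$W)
  if (!is.null(obj$indicatorNames)) colnames(W) <- obj$indicatorNames
  new("BPNetwork", W = W, theta = as.numeric(obj$theta),
      Wout = matrix(as.numeric(obj$Wout), nrow = 1), # single output
      alpha = as.numeric(obj$alpha),
      hiddenTransfer = obj$hiddenTransfer,
      outputTransfer = obj$outputTransfer)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the complete early-warning pipeline
#'
#' Executes impute -> scale -> split -> train -> predict -> detect-markers
#' -> correlate -> ewi -> flag on one cohort, writing every intermediate
#' artifact to `outDir` together with a manifest (stage, outputs, MD5
#' checksums, wall times). Reruns with an identical configuration and seed
#' produce identical artifact checksums.
#'
#' @param data an [IndicatorExperiment-class]; alternatively give `file`.
#' @param file path of a delimited indicator table (see
#'   [readIndicatorTable()]).
#' @param outcome outcome indicator name (required with `file`).
#' @param outDir output directory, created if needed.
#' @param imputeK KNN imputation neighbour count.
#' @param splitFraction,splitMode see [splitSamples()].
#' @param trainConfig a [bpnnControl()] list; the pipeline default is the
#'   gentler early-stopped detection regime (see [bpnnControl()]), not the
#'   prediction-oriented `bpnnControl()` defaults.
#' @param markerMode,percentile,minSize see [runMarkerDetection()].
#' @param ewiEpsilon,flagK see [computeEWI()] and [flagWarnings()].
#' @param seed global seed; propagated to the split and to network
#'   initialisation (overrides `trainConfig$seed`).
#' @return (invisibly) a list with every stage result (`data`, `scaled`,
#'   `split`, `fit`, `predictions`, `module`, `correlation`, `ewi`) and the
#'   `manifest` data.frame.
#' @export
runPipeline <- function(data = NULL, file = NULL, outcome = NULL,
                        outDir = tempfile("keymarker_run_"),
                        imputeK = 5L, splitFraction = 0.75,
                        splitMode = "sequential",
                        trainConfig = bpnnControl(hiddenDim = 15L,
                                                  maxEpochs = 1500L,
                                                  learningRate = 0.02,
                                                  initScale = 0.03),
                        markerMode = "vector", percentile = 95,
                        minSize = 2L, ewiEpsilon = 1e-8, flagK = 3,
                        seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  trainConfig$seed <- as.integer(seed)
  manifest <- data.frame(stage = character(0), outputs = character(0),
                         md5 = character(0), seconds = numeric(0))
  note <- function(stage, paths, t0) {
    sums <- unname(tools::md5sum(paths))
    manifest <<- rbind(manifest, data.frame(
      stage = stage, outputs = paste(basename(paths), collapse = ";"),
      md5 = paste(sums, collapse = ";"),
      seconds = round(as.numeric(Sys.time()) - t0, 3)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## 1. load
  t0 <- as.numeric(Sys.time())
  data <- run_stage("load", {
    if (is.null(data)) {
      if (is.null(file)) stop("give 'data' or 'file'")
      readIndicatorTable(file, outcomeName = outcome)
    } else data
  })
  f_raw <- .write_tsv_indicator(data, file.path(outDir, "raw.tsv"))
  note("load", f_raw, t0)

  ## 2. impute
  t0 <- as.numeric(Sys.time())
  imputed <- run_stage("impute", knnImpute(data, k = imputeK))
  note("impute", .write_tsv_indicator(imputed, file.path(outDir, "imputed.tsv")), t0)

  ## 3. scale
  t0 <- as.numeric(Sys.time())
  scaled <- run_stage("scale", minMaxScale(imputed))
  f1 <- .write_tsv_indicator(scaled, file.path(outDir, "scaled.tsv"))
  f2 <- .write_tsv(metadata(scaled)$scaleTable,
                   file.path(outDir, "scale_params.tsv"))
  note("scale", c(f1, f2), t0)

  ## 4. split
  t0 <- as.numeric(Sys.time())
  split <- run_stage("split",
                     splitSamples(scaled, fraction = splitFraction,
                                  mode = splitMode, seed = seed))
  fs <- file.path(outDir, "split.json")
  jsonlite::write_json(list(train = split@train, test = split@test,
                            fraction = split@fraction, mode = split@mode),
                       fs, auto_unbox = TRUE)
  note("split", fs, t0)

  ## 5. train
  t0 <- as.numeric(Sys.time())
  fit <- run_stage("train", trainNetwork(selectSamples(scaled, split@train),
                                         config = trainConfig))
  fm <- file.path(outDir, "model.json")
  writeNetworkJSON(fit, fm)
  fd <- .write_tsv(data.frame(epoch = seq_along(geTrace(fit)),
                              GE = geTrace(fit)),
                   file.path(outDir, "diagnostics.tsv"))
  note("train", c(fm, fd), t0)

  ## 6. predict
  t0 <- as.numeric(Sys.time())
  pred <- run_stage("predict", predictNetwork(fit, scaled))
  fp <- .write_tsv(data.frame(sample_id = sampleIDs(scaled),
                              set = ifelse(sampleIDs(scaled) %in% split@train,
                                           "train", "test"),
                              predicted = pred$predictions,
                              observed = outcomeVector(scaled),
                              relative_error = pred$relativeErrors),
                   file.path(outDir, "predictions.tsv"))
  note("predict", fp, t0)

  ## 7. detect markers
  t0 <- as.numeric(Sys.time())
  module <- run_stage("detect-markers",
                      runMarkerDetection(fit, mode = markerMode,
                                         percentile = percentile,
                                         minSize = minSize))
  fmk <- .write_tsv(data.frame(indicator = names(importanceScores(module)),
                               importance = unname(importanceScores(module)),
                               in_module = names(importanceScores(module)) %in%
                                 moduleMembers(module)),
                    file.path(outDir, "markers.tsv"))
  fnw <- file.path(outDir, "tree.newick")
  writeLines(treeToNewick(mergeTree(module)), fnw)
  flt <- .write_tsv(mergeTable(mergeTree(module)),
                    file.path(outDir, "linkage.tsv"))
  note("detect-markers", c(fmk, fnw, flt), t0)

  ## 8. correlate
  t0 <- as.numeric(Sys.time())
  corr <- run_stage("correlate", moduleCorrelationReport(scaled, module))
  fw <- .write_tsv(as.data.frame(corr@within),
                   file.path(outDir, "correlation_within.tsv"))
  fc <- .write_tsv(as.data.frame(corr@cross),
                   file.path(outDir, "correlation_cross.tsv"))
  fsum <- file.path(outDir, "correlation_summary.json")
  jsonlite::write_json(list(blockStats = corr@blockStats, delta = corr@delta,
                            n = corr@nSamples),
                       fsum, auto_unbox = TRUE, digits = NA)
  note("correlate", c(fw, fc, fsum), t0)

  ## 9. ewi + flag
  t0 <- as.numeric(Sys.time())
  ewi <- run_stage("ewi", flagWarnings(computeEWI(scaled, module,
                                                  epsilon = ewiEpsilon),
                                       k = flagK))
  fe <- .write_tsv(data.frame(sample_id = ewi@sampleIDs, ybar = ewi@ybar,
                              skewness = ewi@skew, EWI = ewi@ewi,
                              saturated = ewi@saturated,
                              flagged = seq_along(ewi@ewi) %in% ewi@flagged,
                              GLU = unname(outcomeCurve(imputed))),
                   file.path(outDir, "ewi.tsv"))
  note("ewi", fe, t0)

  fman <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, fman, auto_unbox = TRUE, digits = NA)

  invisible(list(data = data, imputed = imputed, scaled = scaled,
                 split = split, fit = fit, predictions = pred,
                 module = module, correlation = corr, ewi = ewi,
                 manifest = manifest, outDir = outDir))
}

.write_tsv_indicator <- function(x, path) {
  writeIndicatorTable(x, path)
  path
}
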