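#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#' @importFrom stats predict
NULL

#' IndicatorExperiment: a clinical indicator table with missingness mask
#'
#' The central data container of the package. It extends
#' [SummarizedExperiment::SummarizedExperiment] with two aligned assays:
#' `"values"`, the numeric indicator matrix (indicators as rows, samples as
#' columns, following the SummarizedExperiment convention), and `"mask"`, a
#' logical matrix that is `TRUE` exactly where a value is missing. Metadata
#' records the designated outcome indicator (e.g. fasting glucose), whether
#' the values have been min-max scaled, and -- after scaling -- the
#' per-indicator (min, max) table needed for the exact inverse transform.
#'
#' @section Invariants:
#' * sample IDs and indicator names are unique;
#' * `mask` is `TRUE` exactly where `values` is `NA`;
#' * when `scaled` is `TRUE`, every observed value lies in `[0, 1]`.
#'
#' @export
setClass("IndicatorExperiment", contains = "SummarizedExperiment")

setValidity("IndicatorExperiment", function(object) {
  msg <- character(0)
  an <- assayNames(object)
  if (!all(c("values", "mask") %in% an))
    return("assays must contain 'values' and 'mask'")
  v <- assay(object, "values")
  m <- assay(object, "mask")
  if (!is.logical(m) || !identical(dim(v), dim(m)))
    msg <- c(msg, "'mask' must be a logical matrix with the shape of 'values'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "indicator names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample IDs must be present and unique")
  if (any(m != is.na(v)))
    msg <- c(msg, "'mask' must be TRUE exactly where 'values' is NA")
  md <- metadata(object)
  if (is.null(md$outcomeName) || !md$outcomeName %in% rownames(object))
    msg <- c(msg, "metadata 'outcomeName' must name one indicator")
  if (isTRUE(md$scaled)) {
    obs <- v[!m]
    if (length(obs) && (min(obs) < -1e-9 || max(obs) > 1 + 1e-9))
      msg <- c(msg, "scaled values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IndicatorExperiment
#'
#' @param values numeric matrix of indicator values, either samples x
#'   indicators (the natural table layout, `byRow = TRUE`, default) or
#'   indicators x samples (`byRow = FALSE`). `NA` entries are treated as
#'   missing.
#' @param outcomeName name of the designated outcome indicator; must be one
#'   of the indicator names.
#' @param sampleIDs,indicatorNames optional label vectors; taken from the
#'   dimnames of `values` when omitted.
#' @param scaled logical flag marking min-max scaled data.
#' @param scaleTable optional data.frame with columns `indicator`, `min`,
#'   `max` recording the scaling transform.
#' @return an [IndicatorExperiment-class] object.
#' @examples
#' x <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), c("A", "B", "GLU")))
#' ie <- IndicatorExperiment(x, outcomeName = "GLU")
#' @export
IndicatorExperiment <- function(values, outcomeName, sampleIDs = NULL,
                                indicatorNames = NULL, scaled = FALSE,
                                scaleTable = NULL) {
  values <- as.matrix(values)
  byRow <- TRUE
  if (!is.null(indicatorNames) && !is.null(rownames(values)) &&
      all(indicatorNames %in% rownames(values)) &&
      !all(indicatorNames %in% colnames(values)))
    byRow <- FALSE
  if (byRow) values <- t(values)
  if (!is.null(indicatorNames)) rownames(values) <- indicatorNames
  if (!is.null(sampleIDs)) colnames(values) <- sampleIDs
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("I%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  mask <- is.na(values)
  se <- SummarizedExperiment(assays = list(values = values, mask = mask),
                             metadata = list(outcomeName = outcomeName,
                                             scaled = scaled,
                                             scaleTable = scaleTable))
  obj <- new("IndicatorExperiment", se)
  validObject(obj)
  obj
}

#' Three-layer backpropagation regression network
#'
#' Holds all parameters of a trained (or freshly initialised) network:
#' the input-to-hidden weight matrix `W` (hidden x input), the hidden node
#' thresholds `theta`, the hidden-to-output weights `Wout` (output x hidden),
#' the output thresholds `alpha`, and the transfer function selections
#' (`"logistic"` or `"tanh"`) for the two layers.
#'
#' @export
setClass("BPNetwork",
  representation(W = "matrix", theta = "numeric", Wout = "matrix",
                 alpha = "numeric", hiddenTransfer = "character",
                 outputTransfer = "character"))

setValidity("BPNetwork", function(object) {
  msg <- character(0)
  H <- nrow(object@W)
  if (length(object@theta) != H)
    msg <- c(msg, "length(theta) must equal the hidden dimension")
  if (ncol(object@Wout) != H)
    msg <- c(msg, "ncol(Wout) must equal the hidden dimension")
  if (length(object@alpha) != nrow(object@Wout))
    msg <- c(msg, "length(alpha) must equal the output dimension")
  ok <- c("logistic", "tanh")
  if (!object@hiddenTransfer %in% ok || !object@outputTransfer %in% ok)
    msg <- c(msg, "transfer functions must be 'logistic' or 'tanh'")
  if (length(msg)) msg else TRUE
})

#' A fitted network with training diagnostics
#'
#' Returned by [trainNetwork()]. Bundles the final [BPNetwork-class] with the
#' per-epoch training error trace, the per-sample half-squared errors and
#' predictions on the training set, and the configuration used.
#'
#' @export
setClass("BPNetworkFit",
  representation(model = "BPNetwork", geTrace = "numeric", finalGE = "numeric",
                 perSampleGE = "numeric", predictions = "numeric",
                 config = "list"))

#' A detected key-marker module
#'
#' The result of [detectModule()] / [runMarkerDetection()]: the member
#' indicators of the module (sorted by importance, descending), the
#' complement, the cut height and percentile applied, per-indicator
#' importance scores, the clustering mode, and the full merge tree (a base R
#' `hclust` object).
#'
#' @export
setClass("MarkerModule",
  representation(members = "character", complement = "character",
                 importance = "numeric", cutHeight = "numeric",
                 percentile = "numeric", minSize = "integer",
                 mode = "character", tree = "ANY"))

setValidity("MarkerModule", function(object) {
  msg <- character(0)
  if (length(intersect(object@members, object@complement)))
    msg <- c(msg, "members and complement must be disjoint")
  all_ind <- union(object@members, object@complement)
  if (!all(all_ind %in% names(object@importance)))
    msg <- c(msg, "importance must be named for every indicator")
  if (length(msg)) msg else TRUE
})

#' Within- versus cross-module Spearman correlation report
#'
#' Produced by [moduleCorrelationReport()]. `within` is the symmetric
#' module-by-module Spearman matrix (unit diagonal); `cross` is the
#' module-by-complement matrix; `blockStats` summarises `|rho|` per block and
#' `delta` is the coherence contrast `mean|rho|_within - mean|rho|_cross`.
#'
#' @export
setClass("CorrelationReport",
  representation(within = "matrix", cross = "matrix",
                 blockStats = "data.frame", delta = "numeric",
                 nSamples = "integer"))

#' Per-sample composite early-warning index series
#'
#' Produced by [computeEWI()], optionally augmented with flags by
#' [flagWarnings()]. Stores, for every sample, the column mean `ybar` of the
#' row-standardized marker scores, the column skewness `skew`, the index
#' `ewi = ybar / skew`, a `saturated` marker for samples where the skewness
#' fell below the division guard, and -- after flagging -- the indices of
#' strong warning samples with the rule parameters used.
#'
#' @export
setClass("EWISeries",
  representation(sampleIDs = "character", ybar = "numeric", skew = "numeric",
                 ewi = "numeric", saturated = "logical", epsilon = "numeric",
                 flagged = "integer", flagK = "numeric", flagMethod = "character"))

setValidity("EWISeries", function(object) {
  n <- length(object@sampleIDs)
  if (length(object@ybar) != n || length(object@skew) != n ||
      length(object@ewi) != n || length(object@saturated) != n)
    return("ybar, skew, ewi and saturated must have one entry per sample")
  if (length(object@flagged) && any(object@flagged < 1 | object@flagged > n))
    return("flagged indices out of range")
  TRUE
})

#' Parameters of the synthetic cohort generator
#'
#' Created by [syntheticSpec()]; consumed by [generateIndicatorData()]. The
#' defaults reproduce the cohort shape the method targets: 200 samples, 28
#' input indicators plus one continuous outcome, a planted 7-member marker
#' module with latent-factor loading 0.8, six planted pre-onset anomaly
#' samples, and 2\% missingness.
#'
#' @export
setClass("SyntheticSpec",
  representation(nSamples = "integer", nIndicators = "integer",
                 moduleSize = "integer", lambda = "numeric",
                 outcomeBeta = "numeric", outcomeNoiseSD = "numeric",
                 nAnomalies = "integer", anomalyShift = "numeric",
                 anomalySkewness = "numeric", anomalyStrength = "numeric",
                 missingRate = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  if (object@moduleSize > object@nIndicators)
    msg <- c(msg, "moduleSize must not exceed nIndicators")
  if (object@moduleSize < 1L || object@nIndicators < 2L || object@nSamples < 2L)
    msg <- c(msg, "dimensions must be positive (>= 2 samples and indicators)")
  if (object@lambda < 0 || object@lambda >= 1)
    msg <- c(msg, "lambda must lie in [0, 1)")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (object@nAnomalies < 0L || object@nAnomalies > object@nSamples)
    msg <- c(msg, "nAnomalies must lie in [0, nSamples]")
  if (length(msg)) msg else TRUE
})

#' Train/test partition of a sample cohort
#'
#' Returned by [splitSamples()]. `train` and `test` are disjoint ordered
#' subsets of the sample IDs whose union is the full cohort.
#'
#' @export
setClass("SplitIndex",
  representation(train = "character", test = "character", fraction = "numeric",
                 mode = "character"))

setValidity("SplitIndex", function(object) {
  if (length(intersect(object@train, object@test)))
    return("train and test must be disjoint")
  if (length(object@train) < 1L || length(object@test) < 1L)
    return("both sides of the split must be nonempty")
  TRUE
})
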