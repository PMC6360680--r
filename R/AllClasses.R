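#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' FeatureTable: a sample-by-feature intensity matrix with binary labels
#'
#' The central data container: a fully observed numeric matrix of intensities
#' (rows = samples, columns = m/z features) plus a binary group label per
#' sample. Construct with [featureTable()].
#'
#' @slot intensities numeric matrix, samples in rows, features in columns;
#'   dimnames carry sample and feature identifiers.
#' @slot labels integer vector of 0/1 group labels, one per sample.
#' @export
setClass("FeatureTable",
  representation(intensities = "matrix", labels = "integer"))

setValidity("FeatureTable", function(object) {
  x <- object@intensities
  msg <- character()
  if (!is.numeric(x)) msg <- c(msg, "intensities must be numeric")
  if (nrow(x) < 4L) msg <- c(msg, "need at least 4 samples")
  if (any(!is.finite(x))) msg <- c(msg, "intensities must be finite (preprocess first)")
  if (length(object@labels) != nrow(x))
    msg <- c(msg, "labels must have one entry per sample")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (length(unique(object@labels)) != 2L)
    msg <- c(msg, "both label values must be present")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    msg <- c(msg, "feature ids (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' RawFeatureTable: an unpreprocessed intensity table
#'
#' As read from disk: intensities may contain missing values, labels and a
#' replicate map are optional. Preprocess with [averageDuplicates()],
#' [missingValueFilter()] and [imputeZero()] (or [preprocessFeatureTable()])
#' to obtain a [FeatureTable-class].
#'
#' @slot intensities numeric matrix (samples in rows) possibly containing NA.
#' @slot labels optional numeric 0/1 vector.
#' @slot replicateMap optional character vector mapping each sample to its
#'   biological unit (for duplicate averaging).
#' @export
setClass("RawFeatureTable",
  representation(intensities = "matrix",
                 labels = "numericOrNULL",
                 replicateMap = "characterOrNULL"))

setValidity("RawFeatureTable", function(object) {
  x <- object@intensities
  msg <- character()
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    msg <- c(msg, "feature ids (colnames) must be present and unique")
  if (!is.null(object@labels) && length(object@labels) != nrow(x))
    msg <- c(msg, "labels must have one entry per sample")
  if (!is.null(object@replicateMap) && length(object@replicateMap) != nrow(x))
    msg <- c(msg, "replicateMap must cover all samples")
  if (length(msg)) msg else TRUE
})

#' SimulationDesign: parameters of the layered synthetic generator
#'
#' @slot nSamples number of samples (default 200).
#' @slot nFeatures number of features (default 1000).
#' @slot structure one of "three_layer", "two_layer", "one_layer",
#'   "noise_layer".
#' @slot bernoulliProb success probability of the Bernoulli response
#'   (default 0.4).
#' @slot delta lower bound imposed on each noise column's univariate
#'   regression p-value, in `[0, 1)`.
#' @slot seed integer seed making the dataset fully reproducible.
#' @export
setClass("SimulationDesign",
  representation(nSamples = "integer", nFeatures = "integer",
                 structure = "character", bernoulliProb = "numeric",
                 delta = "numeric", seed = "integer"))

setValidity("SimulationDesign", function(object) {
  msg <- character()
  if (!(object@structure %in% names(.layerSizeTable)))
    msg <- c(msg, sprintf("unknown structure '%s'", object@structure))
  else if (object@nFeatures < sum(.layerSizeTable[[object@structure]][1:3]))
    msg <- c(msg, "nFeatures smaller than the structured layers")
  if (object@nSamples < 4L) msg <- c(msg, "nSamples must be >= 4")
  if (!is.finite(object@bernoulliProb) ||
      object@bernoulliProb <= 0 || object@bernoulliProb >= 1)
    msg <- c(msg, "bernoulliProb must be in (0, 1)")
  if (!is.finite(object@delta) || object@delta < 0 || object@delta >= 1)
    msg <- c(msg, "delta must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' LayerStructure: ground-truth layer membership of simulated features
#'
#' @slot assignment character vector (one per feature) with values
#'   "layer1_strong", "layer1_group", "layer2", "layer3", "noise".
#' @slot parentMap integer vector (one per feature): index of the parent
#'   feature for layer-2/3 children, NA elsewhere.
#' @export
setClass("LayerStructure",
  representation(assignment = "character", parentMap = "integer"))

setValidity("LayerStructure", function(object) {
  msg <- character()
  if (length(object@assignment) != length(object@parentMap))
    msg <- c(msg, "assignment and parentMap lengths differ")
  ok <- c("layer1_strong", "layer1_group", "layer2", "layer3", "noise")
  if (!all(object@assignment %in% ok))
    msg <- c(msg, "unknown layer label in assignment")
  child <- object@assignment %in% c("layer2", "layer3")
  if (any(child & is.na(object@parentMap)))
    msg <- c(msg, "every layer-2/3 feature needs a parent")
  if (any(!child & !is.na(object@parentMap)))
    msg <- c(msg, "only layer-2/3 features may have a parent")
  if (length(msg)) msg else TRUE
})

#' BiplotModel: rank-2 orthogonal + predictive decomposition
#'
#' Result of [fitBiplot()]: the approximation
#' X ~ t_pred a_pred' + t_ortho a_ortho' of the centered (optionally
#' autoscaled) data matrix, where t_ortho is the leading principal-component
#' score of the part of X orthogonal to the projected response and t_pred is
#' the first PLS score of the orthogonal-signal-corrected matrix.
#'
#' @slot tPred,tOrtho numeric score vectors (length n).
#' @slot aPred,aOrtho numeric loading vectors (length p).
#' @slot wPred,wOrtho score weights t't used by the biplot inner product.
#' @slot yHat projection of the label vector onto the column space of the
#'   centered matrix.
#' @slot columnMeans,columnScales centering/scaling applied to each column.
#' @slot scaled logical: was unit-variance autoscaling applied?
#' @export
setClass("BiplotModel",
  representation(tPred = "numeric", aPred = "numeric",
                 tOrtho = "numeric", aOrtho = "numeric",
                 wPred = "numeric", wOrtho = "numeric",
                 yHat = "numeric",
                 columnMeans = "numeric", columnScales = "numeric",
                 scaled = "logical"))

setValidity("BiplotModel", function(object) {
  msg <- character()
  n <- length(object@tPred); p <- length(object@aPred)
  if (length(object@tOrtho) != n) msg <- c(msg, "score lengths differ")
  if (length(object@aOrtho) != p) msg <- c(msg, "loading lengths differ")
  if (object@wPred < 0 || object@wOrtho < 0)
    msg <- c(msg, "score weights must be nonnegative")
  nt <- sqrt(sum(object@tOrtho^2)) * sqrt(sum(object@yHat^2))
  if (nt > 0 && abs(sum(object@tOrtho * object@yHat)) > 1e-8 * nt)
    msg <- c(msg, "t_ortho must be orthogonal to the projected response")
  if (length(msg)) msg else TRUE
})

#' ConfidenceEllipse: a group's score ellipse
#'
#' @slot center length-2 mean of the group scores on (predictive,
#'   orthogonal) axes.
#' @slot covariance 2x2 unbiased sample covariance of the group scores.
#' @slot coverage coverage probability (default 0.95).
#' @slot radiusSq chi-square(2 df) quantile at `coverage`: the squared
#'   Mahalanobis radius of the ellipse.
#' @export
setClass("ConfidenceEllipse",
  representation(center = "numeric", covariance = "matrix",
                 coverage = "numeric", radiusSq = "numeric"))

setValidity("ConfidenceEllipse", function(object) {
  msg <- character()
  if (length(object@center) != 2L) msg <- c(msg, "center must be length 2")
  if (!all(dim(object@covariance) == 2L)) msg <- c(msg, "covariance must be 2x2")
  ev <- tryCatch(eigen(object@covariance, symmetric = TRUE,
                       only.values = TRUE)$values, error = function(e) NA)
  if (anyNA(ev) || any(ev <= 0))
    msg <- c(msg, "covariance must be positive definite")
  if (object@radiusSq <= 0) msg <- c(msg, "radiusSq must be positive")
  if (length(msg)) msg else TRUE
})

#' AngularRange: a set of angle intervals on the circle
#'
#' Intervals are stored as (start, width) pairs in radians with start in
#' `[0, 2*pi)` and width in `(0, 2*pi)`; an interval covers the arc swept
#' counter-clockwise from its start. `fullCircle = TRUE` means every
#' direction is inside (and the interval list is empty).
#'
#' @slot intervals numeric matrix with columns `start` and `width`.
#' @slot fullCircle logical.
#' @export
setClass("AngularRange",
  representation(intervals = "matrix", fullCircle = "logical"))

setValidity("AngularRange", function(object) {
  msg <- character()
  iv <- object@intervals
  if (ncol(iv) != 2L) msg <- c(msg, "intervals must have 2 columns")
  if (object@fullCircle && nrow(iv) > 0L)
    msg <- c(msg, "full circle implies an empty interval list")
  if (nrow(iv) > 0L) {
    if (any(iv[, 2L] <= 0 | iv[, 2L] >= 2 * pi))
      msg <- c(msg, "interval widths must be in (0, 2*pi)")
  }
  if (length(msg)) msg else TRUE
})

#' SelectionParams: tuning parameters of the BCR selection
#'
#' @slot tau top fraction of loading-arrow magnitudes retained (default
#'   0.05).
#' @slot coverage confidence-ellipse coverage (default 0.95).
#' @slot filterAlpha weak-separability filter level: candidates whose
#'   univariate logistic slope p-value exceeds this are dropped (default
#'   0.10).
#' @slot autoscale logical: unit-variance scale columns before fitting.
#' @slot scoreDisplayScale multiplier applied to scores for display only
#'   (default 0.001); selection is invariant to it.
#' @slot weightedArrows logical: use sqrt(t't)-weighted loading coordinates
#'   for angles/magnitudes (covariance geometry) instead of the raw
#'   loadings plotted in biplots (default FALSE).
#' @export
setClass("SelectionParams",
  representation(tau = "numeric", coverage = "numeric",
                 filterAlpha = "numeric", autoscale = "logical",
                 scoreDisplayScale = "numeric", weightedArrows = "logical"))

setValidity("SelectionParams", function(object) {
  msg <- character()
  if (object@tau <= 0 || object@tau > 1) msg <- c(msg, "tau must be in (0, 1]")
  if (object@coverage <= 0 || object@coverage >= 1)
    msg <- c(msg, "coverage must be in (0, 1)")
  if (object@filterAlpha < 0 || object@filterAlpha > 1)
    msg <- c(msg, "filterAlpha must be in [0, 1]")
  if (object@scoreDisplayScale <= 0)
    msg <- c(msg, "scoreDisplayScale must be positive")
  if (length(msg)) msg else TRUE
})

#' SelectionResult: outcome of the BCR selection
#'
#' @slot perGroup named list (one entry per group label) with elements
#'   `wedgeMembers`, `topCandidates`, `selected` (integer feature indices)
#'   and `filteredOut` (data.frame with columns `index`, `pValue`).
#' @slot unionSelected integer indices selected for at least one group.
#' @slot magnitudes,angles per-feature loading-arrow magnitude and angle
#'   (radians, in `[0, 2*pi)`; NA for zero-length arrows).
#' @slot featureIds feature identifiers.
#' @export
setClass("SelectionResult",
  representation(perGroup = "list", unionSelected = "integer",
                 magnitudes = "numeric", angles = "numeric",
                 featureIds = "character"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  for (g in names(object@perGroup)) {
    e <- object@perGroup[[g]]
    if (!all(c("wedgeMembers", "topCandidates", "filteredOut", "selected")
             %in% names(e))) {
      msg <- c(msg, "perGroup entries incomplete"); next
    }
    if (!all(e$topCandidates %in% e$wedgeMembers))
      msg <- c(msg, "top candidates must lie in the wedge")
    if (!all(e$selected %in% e$topCandidates))
      msg <- c(msg, "selected must be top candidates")
    if (!setequal(e$selected, setdiff(e$topCandidates, e$filteredOut$index)))
      msg <- c(msg, "selected must equal top candidates minus filtered")
  }
  if (!setequal(object@unionSelected,
                unique(unlist(lapply(object@perGroup, `[[`, "selected")))))
    msg <- c(msg, "unionSelected must be the union over groups")
  if (length(msg)) msg else TRUE
})

#' BenchmarkResult: per-method, per-layer replicate-averaged counts
#'
#' @slot records data.frame with columns structure, delta, level, method,
#'   layer, meanCount, sdCount, nReps.
#' @slot posthoc data.frame of logistic-regression post-analyses of the
#'   noise variables each method detected (may have zero rows).
#' @export
setClass("BenchmarkResult",
  representation(records = "data.frame", posthoc = "data.frame"))
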