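#' @include AllClasses.R
NULL

#' Accessors for feature tables and models
#'
#' `intensities()` returns the sample-by-feature matrix, `sampleLabels()`
#' the 0/1 group labels, `sampleIds()`/`featureIds()` the identifiers.
#'
#' @param x a [FeatureTable-class], [RawFeatureTable-class] or, where it
#'   applies, a [SelectionResult-class].
#' @return the requested component.
#' @aliases intensities sampleLabels sampleIds featureIds
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

setMethod("intensities", "FeatureTable", function(x) x@intensities)
setMethod("intensities", "RawFeatureTable", function(x) x@intensities)
setMethod("sampleLabels", "FeatureTable", function(x) x@labels)
setMethod("sampleLabels", "RawFeatureTable", function(x) x@labels)
setMethod("sampleIds", "FeatureTable", function(x) rownames(x@intensities))
setMethod("sampleIds", "RawFeatureTable", function(x) rownames(x@intensities))
setMethod("featureIds", "FeatureTable", function(x) colnames(x@intensities))
setMethod("featureIds", "RawFeatureTable", function(x) colnames(x@intensities))
setMethod("featureIds", "SelectionResult", function(x) x@featureIds)

setMethod("dim", "FeatureTable", function(x) dim(x@intensities))
setMethod("dim", "RawFeatureTable", function(x) dim(x@intensities))

#' Score and loading accessors for a fitted biplot model
#'
#' @param object a [BiplotModel-class].
#' @return numeric vector(s); `scoreWeights()` returns the named pair
#'   `c(pred = t_pred' t_pred, ortho = t_ortho' t_ortho)` used as the biplot
#'   inner-product weights.
#' @aliases predScores orthoScores predLoadings orthoLoadings scoreWeights
#'   responseProjection
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("predScores", function(object) standardGeneric("predScores"))
#' @rdname model-accessors
#' @export
setGeneric("orthoScores", function(object) standardGeneric("orthoScores"))
#' @rdname model-accessors
#' @export
setGeneric("predLoadings", function(object) standardGeneric("predLoadings"))
#' @rdname model-accessors
#' @export
setGeneric("orthoLoadings", function(object) standardGeneric("orthoLoadings"))
#' @rdname model-accessors
#' @export
setGeneric("scoreWeights", function(object) standardGeneric("scoreWeights"))
#' @rdname model-accessors
#' @export
setGeneric("responseProjection",
           function(object) standardGeneric("responseProjection"))

setMethod("predScores", "BiplotModel", function(object) object@tPred)
setMethod("orthoScores", "BiplotModel", function(object) object@tOrtho)
setMethod("predLoadings", "BiplotModel", function(object) object@aPred)
setMethod("orthoLoadings", "BiplotModel", function(object) object@aOrtho)
setMethod("scoreWeights", "BiplotModel",
          function(object) c(pred = object@wPred, ortho = object@wOrtho))
setMethod("responseProjection", "BiplotModel", function(object) object@yHat)

#' Selection-result accessors
#'
#' `selectedFeatures()` returns the union of per-group selected feature
#' indices (or ids); `groupSelection()` the per-group detail list.
#'
#' @param object a [SelectionResult-class].
#' @param group group label ("0" or "1"); NULL returns all groups.
#' @param ids return feature identifiers instead of column indices.
#' @aliases selectedFeatures groupSelection
#' @name selection-accessors
NULL

#' @rdname selection-accessors
#' @export
setGeneric("selectedFeatures",
           function(object, ids = FALSE) standardGeneric("selectedFeatures"))
#' @rdname selection-accessors
#' @export
setGeneric("groupSelection",
           function(object, group = NULL) standardGeneric("groupSelection"))

setMethod("selectedFeatures", "SelectionResult", function(object, ids = FALSE) {
  idx <- sort(object@unionSelected)
  if (ids) object@featureIds[idx] else idx
})

setMethod("groupSelection", "SelectionResult", function(object, group = NULL) {
  if (is.null(group)) return(object@perGroup)
  g <- as.character(group)
  if (!g %in% names(object@perGroup))
    stop("no such group label: ", g)
  object@perGroup[[g]]
})

#' Layer-structure accessors
#'
#' @param x a [LayerStructure-class].
#' @aliases layerAssignment parentMap
#' @name layer-accessors
NULL

#' @rdname layer-accessors
#' @export
setGeneric("layerAssignment", function(x) standardGeneric("layerAssignment"))
#' @rdname layer-accessors
#' @export
setGeneric("parentMap", function(x) standardGeneric("parentMap"))

setMethod("layerAssignment", "LayerStructure", function(x) x@assignment)
setMethod("parentMap", "LayerStructure", function(x) x@parentMap)

#' Benchmark-result accessors
#'
#' @param x a [BenchmarkResult-class].
#' @aliases benchmarkRecords benchmarkPosthoc
#' @name benchmark-accessors
NULL

#' @rdname benchmark-accessors
#' @export
setGeneric("benchmarkRecords", function(x) standardGeneric("benchmarkRecords"))
#' @rdname benchmark-accessors
#' @export
setGeneric("benchmarkPosthoc", function(x) standardGeneric("benchmarkPosthoc"))

setMethod("benchmarkRecords", "BenchmarkResult", function(x) x@records)
setMethod("benchmarkPosthoc", "BenchmarkResult", function(x) x@posthoc)

setMethod("show", "FeatureTable", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("FeatureTable: %d samples x %d features\n", d[1L], d[2L]))
  tab <- table(object@labels)
  cat(sprintf("labels: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "RawFeatureTable", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("RawFeatureTable: %d samples x %d features (%d missing cells)\n",
              d[1L], d[2L], sum(is.na(object@intensities))))
  if (!is.null(object@replicateMap))
    cat(sprintf("replicates: %d biological units\n",
                length(unique(object@replicateMap))))
})

setMethod("show", "BiplotModel", function(object) {
  cat(sprintf("BiplotModel: %d samples x %d features%s\n",
              length(object@tPred), length(object@aPred),
              if (object@scaled) " (autoscaled)" else ""))
  cat(sprintf("score weights: pred %.4g, ortho %.4g\n",
              object@wPred, object@wOrtho))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d features selected (union over %d groups)\n",
              length(object@unionSelected), length(object@perGroup)))
  for (g in names(object@perGroup)) {
    e <- object@perGroup[[g]]
    cat(sprintf("  group %s: wedge %d -> top %d -> selected %d (filtered %d)\n",
                g, length(e$wedgeMembers), length(e$topCandidates),
                length(e$selected), nrow(e$filteredOut)))
  }
})

setMethod("show", "AngularRange", function(object) {
  if (object@fullCircle) {
    cat("AngularRange: full circle\n")
  } else {
    iv <- object@intervals
    cat("AngularRange:",
        paste(sprintf("[%.2f deg + %.2f deg)", iv[, 1L] * 180 / pi,
                      iv[, 2L] * 180 / pi), collapse = ", "), "\n")
  }
})

setMethod("show", "BenchmarkResult", function(object) {
  r <- object@records
  cat(sprintf("BenchmarkResult: %d records (%s)\n", nrow(r),
              paste(unique(r$method), collapse = ", ")))
})
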