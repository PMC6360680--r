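#' Construct a FeatureTable
#'
#' Builds the central [FeatureTable-class] container from a sample-by-feature
#' numeric matrix and a binary label per sample. A `SummarizedExperiment`
#' (features in rows, samples in columns, as is conventional there) can also
#' be supplied together with the name of a two-level `colData` column.
#'
#' @param x numeric matrix (samples in rows, features in columns) or a
#'   `SummarizedExperiment`.
#' @param labels binary group labels, one per sample: numeric 0/1, logical,
#'   or any two-level factor/character vector (levels are mapped to 0/1 in
#'   sort order). For a `SummarizedExperiment`, the name of the `colData`
#'   column holding the labels.
#' @param ... for a `SummarizedExperiment`: `assay` selects the assay
#'   (default first).
#' @return a [FeatureTable-class].
#' @examples
#' x <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("f", 1:5)))
#' ft <- featureTable(x, rep(0:1, each = 4))
#' dim(ft)
#' @export
featureTable <- function(x, labels, ...) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop("the SummarizedExperiment package is required for this input")
    se <- x
    mat <- t(SummarizedExperiment::assay(se, ...))
    cd <- SummarizedExperiment::colData(se)
    if (!is.character(labels) || !labels %in% colnames(cd))
      stop("'labels' must name a colData column of the SummarizedExperiment")
    return(featureTable(mat, cd[[labels]]))
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  methods::new("FeatureTable", intensities = x,
               labels = .asBinaryLabels(labels))
}

.asBinaryLabels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (length(lv) != 2L)
      stop("labels must take exactly two values, got: ",
           paste(lv, collapse = ", "))
    return(as.integer(labels == lv[2L]))
  }
  if (!all(labels %in% c(0, 1)))
    stop("numeric labels must be 0/1")
  as.integer(labels)
}

#' Construct a RawFeatureTable
#'
#' @param x numeric matrix, samples in rows; may contain NA.
#' @param labels optional binary labels (any two-level coding).
#' @param replicateMap optional character vector mapping each sample to its
#'   biological unit, used by [averageDuplicates()].
#' @return a [RawFeatureTable-class].
#' @export
rawFeatureTable <- function(x, labels = NULL, replicateMap = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (!is.null(labels)) labels <- as.numeric(.asBinaryLabels(labels))
  if (!is.null(replicateMap)) replicateMap <- as.character(replicateMap)
  methods::new("RawFeatureTable", intensities = x, labels = labels,
               replicateMap = replicateMap)
}
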