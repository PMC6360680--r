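## Feature-table I/O and the standard LC-MS preprocessing chain:
## average technical duplicates -> drop features with too many missing
## values -> impute the remainder with zero (no noticeable peak).

#' Read a delimited feature table
#'
#' Reads a CSV/TSV intensity table (delimiter inferred from the extension,
#' or set `sep`). In the canonical orientation samples are rows: the first
#' column holds sample ids and the remaining columns features; with
#' `orientation = "features_in_rows"` the first column holds feature ids
#' and each remaining column is a sample, and the result is transposed.
#' Empty cells and the `naStrings` tokens become missing values.
#'
#' @param path file path.
#' @param orientation "samples_in_rows" (default) or "features_in_rows".
#' @param labelCol name of the label column (samples-in-rows only); NULL
#'   if the table carries no labels.
#' @param replicateCol optional name of a column mapping samples to
#'   biological units.
#' @param naStrings tokens treated as missing (case-insensitive; default
#'   "", "NA", "NaN").
#' @param sep field delimiter; NULL infers "," for .csv, tab otherwise.
#' @return a [RawFeatureTable-class].
#' @export
readFeatureTable <- function(path,
                             orientation = c("samples_in_rows",
                                             "features_in_rows"),
                             labelCol = "label", replicateCol = NULL,
                             naStrings = c("", "NA", "NaN"), sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  naStrings <- unique(c(naStrings, toupper(naStrings), tolower(naStrings)))
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          na.strings = naStrings, data.table = FALSE,
                          fill = FALSE)
  if (ncol(dt) < 2L) stop("feature table needs an id column plus data")
  ids <- as.character(dt[[1L]])
  dt <- dt[, -1L, drop = FALSE]
  if (orientation == "features_in_rows") {
    if (anyDuplicated(ids)) stop("duplicate feature ids in input")
    x <- t(as.matrix(dt))
    colnames(x) <- ids
    return(rawFeatureTable(x))
  }
  labels <- NULL
  if (!is.null(labelCol)) {
    if (!labelCol %in% colnames(dt))
      stop("label column '", labelCol, "' not found")
    labels <- dt[[labelCol]]
    dt <- dt[, setdiff(colnames(dt), labelCol), drop = FALSE]
  }
  repMap <- NULL
  if (!is.null(replicateCol)) {
    if (!replicateCol %in% colnames(dt))
      stop("replicate column '", replicateCol, "' not found")
    repMap <- as.character(dt[[replicateCol]])
    dt <- dt[, setdiff(colnames(dt), replicateCol), drop = FALSE]
  }
  if (anyDuplicated(colnames(dt))) stop("duplicate feature ids in input")
  x <- as.matrix(dt)
  if (!is.numeric(x)) stop("non-numeric intensity values in input")
  rownames(x) <- ids
  rawFeatureTable(x, labels = labels, replicateMap = repMap)
}

#' Average technical duplicates
#'
#' Cell-wise mean per biological unit, ignoring missing values; a cell
#' missing in every replicate of a unit stays missing. Labels must agree
#' within a unit.
#'
#' @param raw a [RawFeatureTable-class] with a replicate map.
#' @return a [RawFeatureTable-class] with one row per biological unit.
#' @export
averageDuplicates <- function(raw) {
  stopifnot(methods::is(raw, "RawFeatureTable"))
  if (is.null(raw@replicateMap))
    stop("averageDuplicates needs a replicate map")
  units <- unique(raw@replicateMap)
  x <- raw@intensities
  out <- matrix(NA_real_, length(units), ncol(x),
                dimnames = list(units, colnames(x)))
  labels <- if (is.null(raw@labels)) NULL else rep(NA_real_, length(units))
  for (i in seq_along(units)) {
    rows <- which(raw@replicateMap == units[i])
    if (length(rows) == 0L) stop("biological unit without samples")
    m <- colMeans(x[rows, , drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[i, ] <- m
    if (!is.null(labels)) {
      lv <- unique(raw@labels[rows])
      if (length(lv) != 1L)
        stop("conflicting labels within biological unit ", units[i])
      labels[i] <- lv
    }
  }
  rawFeatureTable(out, labels = labels, replicateMap = NULL)
}

#' Drop features with too many missing values
#'
#' A feature is excluded when its missing fraction is greater than or
#' equal to `maxMissingFrac` (inclusive boundary: 30% missing is dropped
#' at the default 0.30).
#'
#' @param raw a [RawFeatureTable-class].
#' @param maxMissingFrac missing-fraction cutoff in `[0, 1]` (default
#'   0.30).
#' @return the filtered [RawFeatureTable-class].
#' @export
missingValueFilter <- function(raw, maxMissingFrac = 0.30) {
  stopifnot(methods::is(raw, "RawFeatureTable"),
            maxMissingFrac >= 0, maxMissingFrac <= 1)
  frac <- colMeans(is.na(raw@intensities))
  keep <- frac < maxMissingFrac
  message(sum(!keep), " of ", length(keep),
          " features dropped (missing fraction >= ", maxMissingFrac, ")")
  rawFeatureTable(raw@intensities[, keep, drop = FALSE],
                  labels = raw@labels, replicateMap = raw@replicateMap)
}

#' Impute remaining missing cells with zero
#'
#' Missing intensities are set to 0 (no noticeable peak at the feature).
#' Requires binary labels; returns the analysis-ready container.
#'
#' @param raw a [RawFeatureTable-class] with labels.
#' @return a [FeatureTable-class].
#' @export
imputeZero <- function(raw) {
  stopifnot(methods::is(raw, "RawFeatureTable"))
  if (is.null(raw@labels)) stop("labels are required")
  x <- raw@intensities
  nMissing <- sum(is.na(x))
  x[is.na(x)] <- 0
  message(nMissing, " missing cell(s) imputed with zero")
  featureTable(x, raw@labels)
}

#' Standard preprocessing chain
#'
#' [averageDuplicates()] (when a replicate map is present) then
#' [missingValueFilter()] then [imputeZero()], in that fixed order; the
#' chain is idempotent.
#'
#' @param raw a [RawFeatureTable-class].
#' @param maxMissingFrac cutoff for [missingValueFilter()].
#' @return a [FeatureTable-class].
#' @export
preprocessFeatureTable <- function(raw, maxMissingFrac = 0.30) {
  if (!is.null(raw@replicateMap)) raw <- averageDuplicates(raw)
  imputeZero(missingValueFilter(raw, maxMissingFrac))
}

#' Write a selection result as TSV
#'
#' One row per (feature, group) for every wedge member, ordered by feature
#' index then group, with columns feature_id, group, angle_deg, magnitude,
#' logistic_p and status ("selected", "filtered" or "wedge_only").
#'
#' @param result a [SelectionResult-class].
#' @param path output path.
#' @return invisibly, the written data.frame.
#' @export
writeSelection <- function(result, path) {
  stopifnot(methods::is(result, "SelectionResult"))
  rows <- list()
  for (g in names(result@perGroup)) {
    e <- result@perGroup[[g]]
    idx <- sort(e$wedgeMembers)
    if (length(idx) == 0L) next
    status <- rep("wedge_only", length(idx))
    status[idx %in% e$selected] <- "selected"
    status[idx %in% e$filteredOut$index] <- "filtered"
    pv <- rep(NA_real_, length(idx))
    m <- match(idx, e$filteredOut$index)
    pv[!is.na(m)] <- e$filteredOut$pValue[m[!is.na(m)]]
    rows[[g]] <- data.frame(
      feature_id = result@featureIds[idx], group = g,
      angle_deg = result@angles[idx] * 180 / pi,
      magnitude = result@magnitudes[idx],
      logistic_p = pv, status = status)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(), group = character(),
               angle_deg = numeric(), magnitude = numeric(),
               logistic_p = numeric(), status = character())
  df <- df[order(match(df$feature_id, result@featureIds), df$group), ]
  rownames(df) <- NULL
  data.table::fwrite(df, path, sep = "\t", na = "NA")
  invisible(df)
}
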