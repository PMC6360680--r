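## Replicated simulation benchmark: run every selector over a grid of
## structures, noise conditions (delta) and selection levels, count the
## detected features per ground-truth layer, and average over replicates.
## Replicate r of the grid uses seed baseSeed + r - 1, so any sub-grid
## reproduces the identical datasets.

.benchmarkMethods <- c("bcr", "fdr_bh", "fdr_by", "stocsyo")

#' Specify a benchmark grid
#'
#' @param structures subset of the four layer structures.
#' @param deltas noise p-value floors (default `c(0, 0.03, 0.05, 0.10)`).
#' @param levels selection levels, ascending: tau for BCR, q for FDR,
#'   alpha for STOCSYO (default the seven levels 0.01-0.20).
#' @param methods subset of `c("bcr", "fdr_bh", "fdr_by", "stocsyo")`.
#' @param nReps replicates per condition (reference study used 1000; 100
#'   is the scaled-down default here).
#' @param baseSeed integer seed of replicate 1.
#' @param posthoc also run the logistic post-analysis of detected noise
#'   variables per replicate (default FALSE).
#' @return a list of class "BenchmarkGrid".
#' @export
benchmarkGrid <- function(structures = "three_layer",
                          deltas = c(0, 0.03, 0.05, 0.10),
                          levels = c(0.01, 0.03, 0.05, 0.07, 0.10, 0.15, 0.20),
                          methods = .benchmarkMethods,
                          nReps = 100L, baseSeed = 1L, posthoc = FALSE) {
  stopifnot(all(structures %in% names(.layerSizeTable)),
            all(methods %in% .benchmarkMethods),
            nReps >= 1L, !is.unsorted(levels))
  structure(list(structures = structures, deltas = deltas, levels = levels,
                 methods = methods, nReps = as.integer(nReps),
                 baseSeed = as.integer(baseSeed), posthoc = posthoc),
            class = "BenchmarkGrid")
}

#' Count selected features per ground-truth layer
#'
#' The two layer-1 sublayers (strong and group-wise) are combined into one
#' "layer1" count, matching how benchmark tables are reported; the strong
#' subcount is returned separately as "layer1_strong" for convenience.
#'
#' @param selected integer vector of selected feature indices.
#' @param truth a [LayerStructure-class].
#' @return named numeric vector with counts for layer1, layer2, layer3,
#'   noise and layer1_strong.
#' @export
countByLayer <- function(selected, truth) {
  a <- layerAssignment(truth)
  stopifnot(all(selected >= 1L & selected <= length(a)))
  sel <- a[selected]
  c(layer1 = sum(sel %in% c("layer1_strong", "layer1_group")),
    layer2 = sum(sel == "layer2"),
    layer3 = sum(sel == "layer3"),
    noise = sum(sel == "noise"),
    layer1_strong = sum(sel == "layer1_strong"))
}

#' Logistic post-analysis of detected noise variables
#'
#' Multivariate logistic regression of the label on the selected noise
#' columns only: the model p-value is the likelihood-ratio test against
#' the intercept-only model, and the classification rate is the in-sample
#' accuracy at probability threshold 0.5. With at least as many selected
#' variables as samples the fit is ridge-stabilized (via glmnet, flagged;
#' no p-value in that case).
#'
#' @param table a [FeatureTable-class].
#' @param noiseSelected integer indices of the detected noise variables.
#' @return list with `applicable`, `modelP`, `classificationRate`,
#'   `nVariables`, `ridge`.
#' @export
noisePosthoc <- function(table, noiseSelected) {
  noiseSelected <- as.integer(noiseSelected)
  if (length(noiseSelected) == 0L)
    return(list(applicable = FALSE, modelP = NA_real_,
                classificationRate = NA_real_, nVariables = 0L,
                ridge = FALSE))
  x <- intensities(table)[, noiseSelected, drop = FALSE]
  y <- sampleLabels(table)
  if (length(noiseSelected) >= nrow(x) - 1L) {
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop("glmnet is required for the ridge-stabilized fallback")
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = 1e-3)
    pr <- as.vector(stats::predict(fit, x, type = "response"))
    return(list(applicable = TRUE, modelP = NA_real_,
                classificationRate = mean((pr > 0.5) == y),
                nVariables = length(noiseSelected), ridge = TRUE))
  }
  fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y,
                                         family = stats::binomial()))
  dev <- fit$deviance
  nullDev <- fit$null.deviance
  p <- stats::pchisq(nullDev - dev, df = length(noiseSelected),
                     lower.tail = FALSE)
  list(applicable = TRUE, modelP = p,
       classificationRate = mean((fit$fitted.values > 0.5) == y),
       nVariables = length(noiseSelected), ridge = FALSE)
}

#' Run the replicated benchmark
#'
#' For each structure, delta and replicate: generate a dataset with seed
#' `baseSeed + rep - 1`, fit the biplot model once, then apply every
#' method at every level and count detections per ground-truth layer.
#' Univariate logistic p-values for the BCR weak filter are computed once
#' per dataset and shared across levels. Deterministic given the grid.
#'
#' @param grid a grid from [benchmarkGrid()].
#' @return a [BenchmarkResult-class].
#' @examples
#' g <- benchmarkGrid("one_layer", deltas = 0, levels = 0.05,
#'                    methods = "fdr_bh", nReps = 2, baseSeed = 42)
#' head(benchmarkRecords(runBenchmark(g)))
#' @export
runBenchmark <- function(grid) {
  stopifnot(inherits(grid, "BenchmarkGrid"))
  layers <- c("layer1", "layer2", "layer3", "noise")
  acc <- list()       # running per-layer counts, keyed by condition
  post <- list()
  failures <- 0L
  for (structure in grid$structures) for (delta in grid$deltas) {
    for (rep in seq_len(grid$nReps)) {
      seed <- grid$baseSeed + rep - 1L
      sim <- tryCatch(
        generateDataset(simulationDesign(structure, delta = delta,
                                         seed = seed)),
        error = function(e) NULL)
      if (is.null(sim)) { failures <- failures + 1L; next }
      tab <- sim$table
      truth <- sim$truth
      noiseIdx <- which(layerAssignment(truth) == "noise")
      model <- if (any(c("bcr", "stocsyo") %in% grid$methods))
        fitBiplot(tab) else NULL
      pvals <- if (any(c("fdr_bh", "fdr_by") %in% grid$methods))
        ttestPvalues(tab) else NULL
      logisticCache <- new.env(parent = emptyenv())
      logisticCache$p <- rep(NA_real_, ncol(intensities(tab)))
      for (level in grid$levels) for (method in grid$methods) {
        sel <- switch(method,
          bcr = {
            res <- selectFeatures(model, tab,
                                  selectionParams(tau = level),
                                  pValues = logisticCache)
            selectedFeatures(res)
          },
          fdr_bh = which(fdrSelect(pvals, level, "bh")),
          fdr_by = which(fdrSelect(pvals, level, "by")),
          stocsyo = which(stocsyoSelect(tab, level, model = model)))
        counts <- countByLayer(sel, truth)
        key <- paste(structure, delta, level, method, sep = "|")
        acc[[key]] <- rbind(acc[[key]], counts)
        if (grid$posthoc) {
          ph <- noisePosthoc(tab, intersect(sel, noiseIdx))
          post[[length(post) + 1L]] <-
            data.frame(structure = structure, delta = delta, level = level,
                       method = method, rep = rep,
                       modelP = ph$modelP,
                       classificationRate = ph$classificationRate,
                       nVariables = ph$nVariables, ridge = ph$ridge)
        }
      }
    }
  }
  if (failures > 0L)
    warning(failures, " replicate(s) failed to generate and were excluded")
  records <- do.call(rbind, lapply(names(acc), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    m <- acc[[key]]
    data.frame(structure = parts[1L], delta = as.numeric(parts[2L]),
               level = as.numeric(parts[3L]), method = parts[4L],
               layer = layers,
               meanCount = colMeans(m[, layers, drop = FALSE]),
               sdCount = apply(m[, layers, drop = FALSE], 2L, stats::sd),
               nReps = nrow(m), row.names = NULL)
  }))
  posthoc <- if (length(post)) do.call(rbind, post) else
    data.frame(structure = character(), delta = numeric(),
               level = numeric(), method = character(), rep = integer(),
               modelP = numeric(), classificationRate = numeric(),
               nVariables = integer(), ridge = logical())
  methods::new("BenchmarkResult", records = records, posthoc = posthoc)
}

#' Replicate-averaged counts of weak-filter removals per layer
#'
#' Runs the full BCR pipeline on freshly generated datasets and counts, per
#' ground-truth layer, the variables that entered the top-fraction candidate
#' set but were removed by the weak-separability filter (union over the two
#' group labels), averaged over replicates.
#'
#' @param structure layer structure (see [layerSizes()]).
#' @param delta noise p-value floor.
#' @param tau top fraction used for the candidate cut.
#' @param nReps number of replicates.
#' @param baseSeed seed of replicate 1 (replicate r uses baseSeed + r - 1).
#' @param filterAlpha weak-filter level (default 0.10).
#' @return list with `meanRemoved` and `sdRemoved` (named per-layer
#'   vectors) and `nReps`.
#' @export
filteredVariableAudit <- function(structure, delta = 0, tau = 0.10,
                                  nReps = 100L, baseSeed = 1L,
                                  filterAlpha = 0.10) {
  counts <- vapply(seq_len(nReps), function(rep) {
    sim <- generateDataset(simulationDesign(structure, delta = delta,
                                            seed = baseSeed + rep - 1L))
    model <- fitBiplot(sim$table)
    res <- suppressWarnings(
      selectFeatures(model, sim$table,
                     selectionParams(tau = tau, filterAlpha = filterAlpha)))
    removed <- unique(unlist(lapply(res@perGroup,
                                    function(e) e$filteredOut$index)))
    countByLayer(as.integer(removed), sim$truth)[1:4]
  }, numeric(4))
  list(meanRemoved = rowMeans(counts),
       sdRemoved = apply(counts, 1L, stats::sd),
       nReps = nReps)
}
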