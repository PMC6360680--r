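## Layered synthetic generator used throughout the benchmark.
##
## Structure of a generated dataset (n samples, p features):
##   layer 1 (30 features)  - 8 strong uniform-shift variables, 5 independent
##                            bivariate normal pairs, 4 trivariate triplets,
##                            all shifted by the binary response Y;
##   layer 2 (90 features)  - each layer-1 variable split into 3 children by
##                            random proportions, children summing to
##                            parent + noise;
##   layer 3 (270 features) - each layer-2 variable split likewise;
##   noise                  - i.i.d. N(0,1) columns, rejection-resampled
##                            until the univariate regression p-value with Y
##                            is >= delta.

# layer sizes: layer1 / layer2 / layer3 / noise
.layerSizeTable <- list(
  three_layer = c(30L, 90L, 270L, 610L),
  two_layer   = c(30L, 90L,   0L, 880L),
  one_layer   = c(30L,  0L,   0L, 970L),
  noise_layer = c( 0L,  0L,   0L, 1000L))

# covariance blocks and Y-dependent mean shifts of the layer-1 groups
.covBlockA <- matrix(c(1, 0.4, 0.4, 0.4), 2L, 2L)
.covBlockB <- matrix(c(12, 10, 8, 10, 12, 10, 8, 10, 12), 3L, 3L)
.pairShift <- c(0, 0.5)
.tripletShift <- c(1, 2, 3)

#' Layer sizes of a simulation structure
#'
#' @param structure one of "three_layer", "two_layer", "one_layer",
#'   "noise_layer".
#' @return named integer vector with layer1/layer2/layer3/noise sizes
#'   (summing to 1000 for the default designs).
#' @export
layerSizes <- function(structure) {
  if (!structure %in% names(.layerSizeTable))
    stop("unknown structure '", structure, "'")
  stats::setNames(.layerSizeTable[[structure]],
                  c("layer1", "layer2", "layer3", "noise"))
}

#' Specify a synthetic-data design
#'
#' Captures every parameter of the layered generator so that
#' [generateDataset()] is a pure function of the design.
#'
#' @param structure layer structure; see [layerSizes()].
#' @param nSamples number of samples (default 200).
#' @param nFeatures number of features (default 1000; noise fills whatever
#'   the structured layers do not).
#' @param bernoulliProb response success probability (default 0.4).
#' @param delta lower bound on the univariate regression p-value of each
#'   noise column with the response, in `[0, 1)` (default 0).
#' @param seed integer seed.
#' @return a [SimulationDesign-class].
#' @examples
#' d <- simulationDesign("three_layer", seed = 1)
#' layerSizes("three_layer")
#' @export
simulationDesign <- function(structure = c("three_layer", "two_layer",
                                           "one_layer", "noise_layer"),
                             nSamples = 200L, nFeatures = 1000L,
                             bernoulliProb = 0.4, delta = 0, seed = 1L) {
  structure <- match.arg(structure)
  methods::new("SimulationDesign", nSamples = as.integer(nSamples),
               nFeatures = as.integer(nFeatures), structure = structure,
               bernoulliProb = as.numeric(bernoulliProb),
               delta = as.numeric(delta), seed = as.integer(seed))
}

#' Draw the binary response
#'
#' Independent Bernoulli draws; uses the current RNG stream.
#'
#' @param nSamples number of samples.
#' @param prob success probability, strictly inside (0, 1).
#' @return integer 0/1 vector.
#' @export
generateResponse <- function(nSamples, prob = 0.4) {
  if (!is.finite(prob) || prob <= 0 || prob >= 1)
    stop("prob must be a finite number strictly inside (0, 1)")
  stats::rbinom(nSamples, 1L, prob)
}

#' Generate the 30 layer-1 variables
#'
#' Columns 1-4 are `U(0,1) + 0.8 - 2Y` (strong variables aligned with label
#' 0), columns 5-8 are `U(0,1) - 1.2 + 2Y` (aligned with label 1; the two
#' quadruples are mirror images). Columns 9-18 are five independent bivariate
#' normal pairs with mean `Y * (0, 0.5)` and covariance block A; columns
#' 19-30 are four trivariate triplets with mean `Y * (1, 2, 3)` and
#' covariance block B.
#'
#' @param labels 0/1 response vector.
#' @return numeric matrix with `length(labels)` rows and 30 columns.
#' @export
generateLayer1 <- function(labels) {
  n <- length(labels)
  out <- matrix(0, n, 30L)
  for (p in 1:4) out[, p] <- stats::runif(n) + 0.8 - 2 * labels
  for (p in 5:8) out[, p] <- stats::runif(n) - 1.2 + 2 * labels
  cholA <- chol(.covBlockA)
  for (p in c(9L, 11L, 13L, 15L, 17L)) {
    z <- matrix(stats::rnorm(2L * n), n, 2L) %*% cholA
    out[, p + 0:1] <- z + outer(labels, .pairShift)
  }
  cholB <- chol(.covBlockB)
  for (p in c(19L, 22L, 25L, 28L)) {
    z <- matrix(stats::rnorm(3L * n), n, 3L) %*% cholB
    out[, p + 0:2] <- z + outer(labels, .tripletShift)
  }
  out
}

#' Split a parent variable into three child variables
#'
#' Per sample, three `U(0,1)` proportions `u1, u2, u3` and a noise term
#' `eps ~ N(0, max(x, 0)/10)` (variance; zero when the parent is
#' non-positive) are drawn; child i is `u_i / (u1+u2+u3) * (x + eps)`, so
#' the children sum to `x + eps` exactly.
#'
#' @param parent numeric vector of parent values (one per sample).
#' @return list with `children` (n x 3 matrix) and `eps` (the noise draws).
#' @export
decomposeParent <- function(parent) {
  if (any(!is.finite(parent))) stop("parent values must be finite")
  n <- length(parent)
  u <- matrix(stats::runif(3L * n), n, 3L)
  eps <- stats::rnorm(n, 0, sqrt(pmax(parent, 0) / 10))
  children <- u / rowSums(u) * (parent + eps)
  list(children = children, eps = eps)
}

#' Generate delta-controlled noise columns
#'
#' Each column is drawn i.i.d. `N(0, 1)` and redrawn until the two-sided
#' p-value of the slope in a simple linear regression of the response on
#' the column is at least `delta`. (For a single regressor this p-value is
#' identical to the Pearson correlation test's, which is what is computed.)
#'
#' @param labels 0/1 response vector.
#' @param count number of noise columns.
#' @param delta p-value floor in `[0, 1)`.
#' @param maxAttempts per-column resampling cap (default 10000).
#' @return numeric matrix with `length(labels)` rows and `count` columns.
#' @export
generateNoise <- function(labels, count, delta = 0, maxAttempts = 10000L) {
  if (!is.finite(delta) || delta < 0 || delta >= 1)
    stop("delta must be in [0, 1)")
  n <- length(labels)
  if (count == 0L) return(matrix(0, n, 0L))
  out <- matrix(stats::rnorm(n * count), n, count)
  if (delta > 0) {
    df <- n - 2L
    yc <- labels - mean(labels)
    sy <- sqrt(sum(yc^2))
    pOf <- function(m) {
      xc <- sweep(m, 2L, colMeans(m))
      r <- as.vector(crossprod(xc, yc)) / (sqrt(colSums(xc^2)) * sy)
      tt <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
      2 * stats::pt(tt, df, lower.tail = FALSE)
    }
    bad <- which(pOf(out) < delta)
    attempt <- 1L
    while (length(bad)) {
      attempt <- attempt + 1L
      if (attempt > maxAttempts)
        stop("noise generation failed for column(s) ",
             paste(utils::head(bad, 5L), collapse = ", "),
             ": attempt cap exceeded")
      redraw <- matrix(stats::rnorm(n * length(bad)), n, length(bad))
      out[, bad] <- redraw
      bad <- bad[pOf(redraw) < delta]
    }
  }
  out
}

#' Generate a full synthetic dataset
#'
#' Assembles, in this fixed order: the response, layer 1, layer 2 (three
#' children per layer-1 variable, parent-by-parent), layer 3 (children of
#' the layer-2 variables), then the noise columns. Fully deterministic
#' given `design@seed`.
#'
#' @param design a [SimulationDesign-class].
#' @return list with elements `table` (a [FeatureTable-class]) and `truth`
#'   (a [LayerStructure-class]).
#' @examples
#' sim <- generateDataset(simulationDesign("two_layer", seed = 7))
#' dim(sim$table)
#' table(layerAssignment(sim$truth))
#' @export
generateDataset <- function(design) {
  stopifnot(methods::is(design, "SimulationDesign"))
  methods::validObject(design)
  sizes <- layerSizes(design@structure)
  p <- design@nFeatures
  nNoise <- p - sum(sizes[1:3])
  n <- design@nSamples

  set.seed(design@seed)
  y <- generateResponse(n, design@bernoulliProb)
  x <- matrix(0, n, p)
  assignment <- rep("noise", p)
  parent <- rep(NA_integer_, p)

  col <- 0L
  if (sizes[["layer1"]] > 0L) {
    x[, 1:30] <- generateLayer1(y)
    assignment[1:8] <- "layer1_strong"
    assignment[9:30] <- "layer1_group"
    col <- 30L
  }
  if (sizes[["layer2"]] > 0L) {
    for (j in 1:30) {
      x[, col + 1:3] <- decomposeParent(x[, j])$children
      assignment[col + 1:3] <- "layer2"
      parent[col + 1:3] <- j
      col <- col + 3L
    }
  }
  if (sizes[["layer3"]] > 0L) {
    for (j in 31:120) {
      x[, col + 1:3] <- decomposeParent(x[, j])$children
      assignment[col + 1:3] <- "layer3"
      parent[col + 1:3] <- j
      col <- col + 3L
    }
  }
  if (nNoise > 0L)
    x[, col + seq_len(nNoise)] <- generateNoise(y, nNoise, design@delta)

  dimnames(x) <- list(sprintf("S%03d", seq_len(n)),
                      sprintf("x%04d", seq_len(p)))
  list(table = featureTable(x, y),
       truth = methods::new("LayerStructure", assignment = assignment,
                            parentMap = parent))
}
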