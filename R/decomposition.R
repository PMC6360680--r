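## Rank-2 biplot decomposition: direct orthogonal signal correction (one
## component) followed by first-component PLS, giving
##   X ~ t_pred a_pred' + t_ortho a_ortho'
## on the centered (optionally autoscaled) matrix. The weighted inner
## product of two loading arrows equals the covariance of the corresponding
## columns of the rank-2 reconstruction; the weighted cosine equals their
## correlation.

#' Center (and optionally autoscale) a feature table
#'
#' @param table a [FeatureTable-class].
#' @param autoscale divide each centered column by its standard deviation
#'   (unit-variance scaling). Constant columns are left centered with scale
#'   1 and a warning; scaling is optional because it can down-weight
#'   high-abundance signal.
#' @return list with `X` (centered matrix), `center`, `scale`.
#' @export
centerTable <- function(table, autoscale = FALSE) {
  x <- intensities(table)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  scl <- rep(1, ncol(x))
  if (autoscale) {
    s <- sqrt(colSums(xc^2) / max(nrow(x) - 1L, 1L))
    zero <- s <= .Machine$double.eps * max(s, 1)
    if (any(zero))
      warning(sum(zero), " constant column(s) left unscaled")
    scl[!zero] <- s[!zero]
    xc <- sweep(xc, 2L, scl, "/")
  }
  list(X = xc, center = ctr, scale = scl)
}

#' Project the response onto the column space of the data
#'
#' Orthogonal projection of Y onto span of the columns of the centered
#' matrix, computed through a rank-revealing SVD (relative singular-value
#' tolerance 1e-10). Note that with many more features than samples and a
#' full-row-rank centered matrix the column space contains every
#' mean-centered vector, so the projection equals `Y - mean(Y)` up to
#' numerical error.
#'
#' @param Xc centered matrix (n x p).
#' @param y response vector of length n.
#' @return the projected response (length n).
#' @export
projectResponse <- function(Xc, y) {
  stopifnot(nrow(Xc) == length(y))
  sv <- svd(Xc, nu = min(dim(Xc)), nv = 0L)
  if (length(sv$d) == 0L || max(sv$d) <= 0) {
    warning("data matrix is zero; projected response set to 0")
    return(rep(0, length(y)))
  }
  keep <- sv$d > 1e-10 * sv$d[1L]
  u <- sv$u[, keep, drop = FALSE]
  as.vector(u %*% crossprod(u, y))
}

#' First Y-orthogonal component (direct orthogonal signal correction)
#'
#' Deflates the centered matrix by the projector onto the projected
#' response, takes `t_ortho` as the leading principal-component score of
#' the deflated matrix, and computes its loading from the full centered
#' matrix: `a_ortho = Xc' t_ortho / (t_ortho' t_ortho)`. The sign of
#' `t_ortho` is fixed by making its largest-magnitude entry positive.
#'
#' @param Xc centered matrix.
#' @param yHat projected response from [projectResponse()].
#' @return list with `tOrtho` and `aOrtho`.
#' @export
orthogonalComponent <- function(Xc, yHat) {
  stopifnot(nrow(Xc) == length(yHat))
  ss <- sum(yHat^2)
  m <- if (ss > 0) Xc - yHat %*% (crossprod(yHat, Xc) / ss) else Xc
  tOrtho <- .leadingScore(m)
  if (is.null(tOrtho))
    stop("degenerate decomposition: no variation orthogonal to the response")
  i <- which.max(abs(tOrtho))
  if (tOrtho[i] < 0) tOrtho <- -tOrtho
  aOrtho <- as.vector(crossprod(Xc, tOrtho)) / sum(tOrtho^2)
  list(tOrtho = tOrtho, aOrtho = aOrtho)
}

# leading principal-component score t = M v1 = u1 d1 of a matrix, via the
# (n x n) Gram matrix when p > n; NULL if M is numerically zero
.leadingScore <- function(m) {
  if (ncol(m) >= nrow(m)) {
    g <- tcrossprod(m)
    e <- eigen(g, symmetric = TRUE)
    if (e$values[1L] <= max(dim(m)) * .Machine$double.eps * sum(abs(diag(g))) ||
        e$values[1L] <= 0) return(NULL)
    e$vectors[, 1L] * sqrt(e$values[1L])
  } else {
    sv <- svd(m, nu = 1L, nv = 0L)
    if (sv$d[1L] <= max(dim(m)) * .Machine$double.eps * sum(sv$d)) return(NULL)
    sv$u[, 1L] * sv$d[1L]
  }
}

#' First PLS component of the signal-corrected matrix
#'
#' PLS1: the unit-norm weight vector is proportional to
#' `Xcorr' (y - mean(y))` (it maximizes the covariance of the score with
#' the response among unit-norm weights); `t_pred = Xcorr w`;
#' `a_pred = Xcorr' t_pred / (t_pred' t_pred)`. Signs are fixed so that
#' the covariance of `t_pred` with the centered response is nonnegative.
#'
#' @param Xcorr the orthogonal-signal-corrected matrix
#'   `Xc - t_ortho a_ortho'`.
#' @param y response vector.
#' @return list with `tPred`, `aPred`, `w`.
#' @export
plsFirstComponent <- function(Xcorr, y) {
  stopifnot(nrow(Xcorr) == length(y))
  yc <- y - mean(y)
  w <- as.vector(crossprod(Xcorr, yc))
  nw <- sqrt(sum(w^2))
  if (nw <= .Machine$double.eps * nrow(Xcorr) * max(abs(Xcorr), 1))
    stop("degenerate decomposition: response carries no signal")
  w <- w / nw
  tPred <- as.vector(Xcorr %*% w)
  if (sum(tPred * yc) < 0) {
    w <- -w
    tPred <- -tPred
  }
  aPred <- as.vector(crossprod(Xcorr, tPred)) / sum(tPred^2)
  list(tPred = tPred, aPred = aPred, w = w)
}

#' Fit the rank-2 biplot model
#'
#' Chains centering, response projection, orthogonal signal correction and
#' first-component PLS into a [BiplotModel-class].
#'
#' @param table a [FeatureTable-class].
#' @param autoscale unit-variance scale columns first (default FALSE;
#'   centering only).
#' @return a [BiplotModel-class].
#' @examples
#' sim <- generateDataset(simulationDesign("one_layer", seed = 3))
#' m <- fitBiplot(sim$table)
#' scoreWeights(m)
#' @export
fitBiplot <- function(table, autoscale = FALSE) {
  stopifnot(methods::is(table, "FeatureTable"))
  y <- sampleLabels(table)
  cen <- centerTable(table, autoscale = autoscale)
  yHat <- projectResponse(cen$X, y)
  orth <- orthogonalComponent(cen$X, yHat)
  xCorr <- cen$X - tcrossprod(orth$tOrtho, orth$aOrtho)
  pred <- plsFirstComponent(xCorr, y)
  ids <- featureIds(table)
  methods::new("BiplotModel",
               tPred = stats::setNames(pred$tPred, sampleIds(table)),
               aPred = stats::setNames(pred$aPred, ids),
               tOrtho = stats::setNames(orth$tOrtho, sampleIds(table)),
               aOrtho = stats::setNames(orth$aOrtho, ids),
               wPred = sum(pred$tPred^2), wOrtho = sum(orth$tOrtho^2),
               yHat = yHat, columnMeans = cen$center,
               columnScales = cen$scale, scaled = autoscale)
}

#' Biplot covariance and correlation between two features
#'
#' `biplotCovariance()` returns the weighted inner product of the loading
#' arrows of features q and r,
#' `a_pred[q] w_pred a_pred[r] + a_ortho[q] w_ortho a_ortho[r]`, which
#' equals the inner product of columns q and r of the rank-2
#' reconstruction. `biplotCorrelation()` is the correspondingly weighted
#' cosine of the angle between the two arrows, equal to the Pearson
#' correlation of the reconstruction columns.
#'
#' @param model a [BiplotModel-class].
#' @param q,r feature indices (or ids).
#' @return a numeric scalar (vectorized over `q`/`r` of equal length).
#' @export
biplotCovariance <- function(model, q, r) {
  q <- .featureIndex(model, q)
  r <- .featureIndex(model, r)
  model@aPred[q] * model@wPred * model@aPred[r] +
    model@aOrtho[q] * model@wOrtho * model@aOrtho[r]
}

#' @rdname biplotCovariance
#' @export
biplotCorrelation <- function(model, q, r) {
  num <- biplotCovariance(model, q, r)
  vq <- biplotCovariance(model, q, q)
  vr <- biplotCovariance(model, r, r)
  if (any(vq <= 0) || any(vr <= 0))
    stop("biplot correlation undefined for zero-norm loading arrows")
  unname(num / sqrt(vq * vr))
}

.featureIndex <- function(model, j) {
  p <- length(model@aPred)
  if (is.character(j)) {
    i <- match(j, names(model@aPred))
    if (anyNA(i)) stop("unknown feature id: ", paste(j[is.na(i)], collapse = ", "))
    return(i)
  }
  j <- as.integer(j)
  if (any(j < 1L | j > p)) stop("feature index out of range")
  j
}

#' Rank-2 reconstruction of the modeled matrix
#'
#' Convenience: `t_pred a_pred' + t_ortho a_ortho'` (on the centered,
#' optionally autoscaled scale).
#'
#' @param model a [BiplotModel-class].
#' @return numeric n x p matrix.
#' @export
reconstructRank2 <- function(model) {
  tcrossprod(model@tPred, model@aPred) +
    tcrossprod(model@tOrtho, model@aOrtho)
}
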