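## BCR selection: for each group label, fit a confidence ellipse to the
## group's (predictive, orthogonal) scores, take the angular wedge between
## the two tangent lines from the origin to that ellipse, collect the
## loading arrows falling inside the wedge, keep those in the top tau
## fraction of arrow magnitudes, drop candidates failing a univariate
## logistic weak-separability test, and finally union over groups.

.TWO_PI <- 2 * pi

#' Selection parameters
#'
#' @param tau top fraction of loading-arrow magnitudes retained within the
#'   wedge (default 0.05, i.e. top 5%).
#' @param coverage confidence-ellipse coverage (default 0.95).
#' @param filterAlpha weak-separability level: a candidate whose univariate
#'   logistic slope p-value exceeds this is filtered out (default 0.10; no
#'   multiplicity control, by design).
#' @param autoscale unit-variance scale columns when fitting (default
#'   FALSE).
#' @param scoreDisplayScale display-only multiplier for scores in plots
#'   (default 0.001); the selection is invariant to it.
#' @param weightedArrows use `sqrt(t't)`-weighted loading coordinates for
#'   angle/magnitude (covariance geometry) instead of the raw loadings as
#'   plotted (default FALSE).
#' @return a [SelectionParams-class].
#' @export
selectionParams <- function(tau = 0.05, coverage = 0.95, filterAlpha = 0.10,
                            autoscale = FALSE, scoreDisplayScale = 0.001,
                            weightedArrows = FALSE) {
  methods::new("SelectionParams", tau = tau, coverage = coverage,
               filterAlpha = filterAlpha, autoscale = autoscale,
               scoreDisplayScale = scoreDisplayScale,
               weightedArrows = weightedArrows)
}

#' Fit a group's confidence ellipse
#'
#' Mean and unbiased covariance of the group's scores on the (predictive,
#' orthogonal) axes; the squared Mahalanobis radius is the chi-square
#' quantile with 2 df at the requested coverage.
#'
#' @param scores n x 2 score matrix, columns ordered (predictive,
#'   orthogonal).
#' @param groupMask logical vector picking the group's samples.
#' @param coverage coverage probability (default 0.95).
#' @return a [ConfidenceEllipse-class].
#' @export
fitGroupEllipse <- function(scores, groupMask, coverage = 0.95) {
  stopifnot(ncol(scores) == 2L, length(groupMask) == nrow(scores))
  pts <- scores[groupMask, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("degenerate group: need at least 3 samples to fit an ellipse")
  s <- stats::cov(pts)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= max(ev, 0) * 1e-12) || any(ev <= 0))
    stop("degenerate group: singular score covariance")
  methods::new("ConfidenceEllipse", center = colMeans(pts), covariance = s,
               coverage = coverage, radiusSq = stats::qchisq(coverage, 2L))
}

#' Angular range subtended by an ellipse seen from the origin
#'
#' The wedge between the two tangent lines from the origin to the ellipse
#' `(x - c)' S^{-1} (x - c) = q`. A direction u is tangent when
#' `(u' S^{-1} c)^2 = (u' S^{-1} u)(c' S^{-1} c - q)`. If the origin lies
#' inside or on the ellipse, every direction intersects it and the range
#' is the full circle (with a warning).
#'
#' @param e a [ConfidenceEllipse-class].
#' @return an [AngularRange-class] containing the direction of the ellipse
#'   center.
#' @export
ellipseAngularRange <- function(e) {
  stopifnot(methods::is(e, "ConfidenceEllipse"))
  p <- solve(e@covariance)
  cen <- e@center
  k <- as.numeric(cen %*% p %*% cen) - e@radiusSq
  if (k <= 0) {
    warning("origin inside the confidence ellipse: full-circle range")
    return(methods::new("AngularRange",
                        intervals = matrix(numeric(), 0L, 2L,
                                           dimnames = list(NULL, c("start", "width"))),
                        fullCircle = TRUE))
  }
  pc <- as.vector(p %*% cen)
  q <- tcrossprod(pc) - k * p          # u' Q u = 0 at tangent directions
  a <- q[1L, 1L]; b <- q[1L, 2L]; cc <- q[2L, 2L]
  # a cos^2 + 2b sin cos + cc sin^2 = 0  <=>  R cos(2phi - psi) = -(a+cc)/2
  r <- sqrt(((a - cc) / 2)^2 + b^2)
  psi <- atan2(b, (a - cc) / 2)
  val <- max(-1, min(1, -(a + cc) / (2 * r)))
  phi <- (psi + c(1, -1) * acos(val)) / 2   # two tangent lines (mod pi)
  thetaC <- atan2(cen[2L], cen[1L])
  # per tangent line, the touching point sits at t* u with
  # t* = (u'Pc)/(u'Pu): its sign picks the direction along the line
  dirs <- vapply(phi, function(ph) {
    u <- c(cos(ph), sin(ph))
    tstar <- sum(u * pc) / drop(u %*% p %*% u)
    if (tstar >= 0) ph else ph + pi
  }, numeric(1))
  # return the interval between the two directions that contains thetaC
  rel <- (dirs - thetaC + pi) %% .TWO_PI - pi
  lo <- thetaC + min(rel); hi <- thetaC + max(rel)
  methods::new("AngularRange",
               intervals = matrix(c(lo %% .TWO_PI, hi - lo), 1L, 2L,
                                  dimnames = list(NULL, c("start", "width"))),
               fullCircle = FALSE)
}

#' Wedge membership of loading arrows
#'
#' Feature j belongs to the range iff its loading arrow
#' `(a_pred[j], a_ortho[j])` has nonzero length and its angle lies inside
#' one of the (closed) intervals; zero-length arrows are never members.
#'
#' @param aPred,aOrtho loading vectors from the model the range was
#'   computed on.
#' @param range an [AngularRange-class].
#' @return logical vector of length p.
#' @export
wedgeMembership <- function(aPred, aOrtho, range) {
  stopifnot(methods::is(range, "AngularRange"),
            length(aPred) == length(aOrtho))
  len <- sqrt(aPred^2 + aOrtho^2)
  nz <- len > 0
  if (range@fullCircle) return(nz)
  ang <- atan2(aOrtho, aPred) %% .TWO_PI
  inside <- rep(FALSE, length(aPred))
  tol <- 1e-12
  for (i in seq_len(nrow(range@intervals))) {
    d <- (ang - range@intervals[i, 1L]) %% .TWO_PI
    inside <- inside | d <= range@intervals[i, 2L] + tol
  }
  inside & nz
}

#' Top-fraction magnitude cut
#'
#' Arrow magnitudes are ranked over all p features; the threshold is the
#' nearest-rank (1 - tau) quantile, and members must exceed it strictly.
#' With `tau = 1` every member survives.
#'
#' @param aPred,aOrtho loading vectors.
#' @param members logical wedge-membership vector.
#' @param tau top fraction in (0, 1].
#' @return logical vector: members in the top tau fraction of magnitudes.
#' @export
magnitudeTopFraction <- function(aPred, aOrtho, members, tau) {
  stopifnot(tau > 0, tau <= 1, length(members) == length(aPred))
  m <- sqrt(aPred^2 + aOrtho^2)
  k <- ceiling((1 - tau) * length(m))
  thr <- if (k < 1L) -Inf else sort(m, partial = k)[k]
  members & m > thr
}

#' Weak-separability filter
#'
#' For each candidate feature, a univariate logistic regression of the
#' label on the raw (uncentered) intensities is fitted; the candidate is
#' removed iff the two-sided Wald p-value of the slope exceeds
#' `filterAlpha`. Complete separation or non-convergence counts as p = 0
#' (kept); a constant column is removed with p recorded as 1.
#'
#' @param table a [FeatureTable-class].
#' @param candidates integer vector of candidate feature indices.
#' @param filterAlpha removal level (default 0.10).
#' @param pValues optional precomputed per-feature p-values (NA = compute):
#'   a numeric vector of length p, or an environment with a numeric field
#'   `p` used as a read/write cache (the benchmark harness shares fits
#'   across levels this way).
#' @return list with `kept` (integer indices), `removed` (data.frame with
#'   columns `index`, `pValue`) and `pValues` (per-candidate p-values).
#' @export
weakFilter <- function(table, candidates, filterAlpha = 0.10,
                       pValues = NULL) {
  candidates <- as.integer(candidates)
  x <- intensities(table)
  stopifnot(all(candidates >= 1L & candidates <= ncol(x)))
  y <- sampleLabels(table)
  cache <- if (is.environment(pValues)) pValues else NULL
  lookup <- if (is.environment(pValues)) pValues$p else pValues
  p <- vapply(candidates, function(j) {
    if (!is.null(lookup) && !is.na(lookup[j])) return(lookup[j])
    logisticSlopeP(x[, j], y)
  }, numeric(1))
  if (!is.null(cache)) cache$p[candidates] <- p
  removed <- p > filterAlpha
  list(kept = candidates[!removed],
       removed = data.frame(index = candidates[removed],
                            pValue = p[removed]),
       pValues = stats::setNames(p, candidates))
}

#' Univariate logistic slope p-value
#'
#' Two-sided Wald test of the slope in `glm(y ~ x, binomial)`, with the
#' conventions used by [weakFilter()]: constant predictor gives 1,
#' separation or non-convergence gives 0.
#'
#' @param x numeric predictor.
#' @param y 0/1 response.
#' @return p-value in `[0, 1]`.
#' @export
logisticSlopeP <- function(x, y) {
  if (stats::var(x) == 0) return(1)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial()),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged ||
      any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8))
    return(0)                      # (quasi-)separation: slope unbounded
  rmat <- qr.R(fit$qr)
  se <- sqrt(diag(chol2inv(rmat)))
  z <- fit$coefficients[2L] / se[2L]
  if (!is.finite(z)) return(0)
  2 * stats::pnorm(-abs(z))
}

#' Run the full BCR selection
#'
#' For each of the two group labels: confidence ellipse of the group's
#' scores, origin-tangent angular wedge, wedge membership of the loading
#' arrows, top-tau magnitude cut (quantile over all features), and the
#' weak-separability filter; the final selection is the union over groups.
#' A group whose ellipse is degenerate contributes an empty set with a
#' warning.
#'
#' @param model a [BiplotModel-class] fitted on `table`.
#' @param table the [FeatureTable-class] the model was fitted on.
#' @param params a [SelectionParams-class].
#' @param pValues optional precomputed per-feature logistic p-values (see
#'   [weakFilter()]).
#' @return a [SelectionResult-class].
#' @examples
#' sim <- generateDataset(simulationDesign("one_layer", seed = 11))
#' model <- fitBiplot(sim$table)
#' res <- selectFeatures(model, sim$table, selectionParams(tau = 0.05))
#' selectedFeatures(res)
#' @export
selectFeatures <- function(model, table, params = selectionParams(),
                           pValues = NULL) {
  stopifnot(methods::is(model, "BiplotModel"),
            methods::is(table, "FeatureTable"),
            methods::is(params, "SelectionParams"))
  methods::validObject(params)
  y <- sampleLabels(table)
  scores <- cbind(pred = model@tPred, ortho = model@tOrtho)
  if (params@weightedArrows) {
    aPred <- model@aPred * sqrt(model@wPred)
    aOrtho <- model@aOrtho * sqrt(model@wOrtho)
  } else {
    aPred <- model@aPred
    aOrtho <- model@aOrtho
  }
  mags <- sqrt(aPred^2 + aOrtho^2)
  angs <- ifelse(mags > 0, atan2(aOrtho, aPred) %% .TWO_PI, NA_real_)

  perGroup <- list()
  for (g in c(0L, 1L)) {
    entry <- tryCatch({
      ell <- fitGroupEllipse(scores, y == g, params@coverage)
      rng <- ellipseAngularRange(ell)
      members <- which(wedgeMembership(aPred, aOrtho, rng))
      topMask <- magnitudeTopFraction(aPred, aOrtho,
                                      seq_along(aPred) %in% members,
                                      params@tau)
      top <- which(topMask)
      flt <- weakFilter(table, top, params@filterAlpha, pValues = pValues)
      list(wedgeMembers = members, topCandidates = top,
           filteredOut = flt$removed, selected = flt$kept)
    }, error = function(e) {
      warning("group ", g, " contributes no features: ",
              conditionMessage(e))
      list(wedgeMembers = integer(), topCandidates = integer(),
           filteredOut = data.frame(index = integer(), pValue = numeric()),
           selected = integer())
    })
    perGroup[[as.character(g)]] <- entry
  }
  un <- unlist(lapply(perGroup, `[[`, "selected"))
  methods::new("SelectionResult", perGroup = perGroup,
               unionSelected = as.integer(sort(unique(un))),
               magnitudes = unname(mags), angles = unname(angs),
               featureIds = featureIds(table))
}
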