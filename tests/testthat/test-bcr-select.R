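test_that("group ellipse uses the chi-square radius and rejects degenerate groups", {
  set.seed(30)
  sc <- matrix(rnorm(200), 100, 2)
  mask <- rep(c(TRUE, FALSE), 50)
  e <- fitGroupEllipse(sc, mask, coverage = 0.95)
  expect_equal(e@radiusSq, 5.991465, tolerance = 1e-6)
  expect_equal(e@center, colMeans(sc[mask, ]))
  expect_equal(e@covariance, cov(sc[mask, ]))
  # identical points: singular covariance
  same <- matrix(1, 10, 2)
  expect_error(fitGroupEllipse(same, rep(TRUE, 10)), "degenerate")
  expect_error(fitGroupEllipse(sc, c(TRUE, TRUE, rep(FALSE, 98))),
               "at least 3")
  # coverage calibration: ~95% of bivariate normal points fall inside
  set.seed(31)
  big <- matrix(rnorm(2e4), 1e4, 2) %*% chol(matrix(c(2, 1, 1, 3), 2, 2))
  e2 <- fitGroupEllipse(big, rep(TRUE, 1e4))
  d2 <- mahalanobis(big, e2@center, e2@covariance)
  expect_lt(abs(mean(d2 <= e2@radiusSq) - 0.95), 3 * sqrt(0.95 * 0.05 / 1e4))
})

test_that("tangent wedge matches the closed form and the sweep oracle", {
  # circular ellipse of radius 1 centered at (2, 0): half-angle asin(1/2)
  e <- makeCircularEllipse(c(2, 0), r = 1)
  rng <- ellipseAngularRange(e)
  b <- rangeBounds(rng, 0)
  expect_equal(b[1], -pi / 6, tolerance = 1e-9)
  expect_equal(b[2], pi / 6, tolerance = 1e-9)
  # center at the origin: full circle
  expect_warning(full <- ellipseAngularRange(makeCircularEllipse(c(0, 0))),
                 "full-circle")
  expect_true(full@fullCircle)
  # random ellipses with the origin outside vs a boundary sweep oracle
  set.seed(32)
  tol <- 0.1 * pi / 180
  tried <- 0
  for (i in 1:10) {
    a <- matrix(rnorm(4), 2, 2)
    s <- crossprod(a) + 0.05 * diag(2)
    cen <- rnorm(2, sd = 4)
    e <- methods::new("ConfidenceEllipse", center = cen, covariance = s,
                      coverage = 0.95, radiusSq = qchisq(0.95, 2))
    k <- drop(cen %*% solve(s) %*% cen) - e@radiusSq
    if (k <= 0) next                 # origin inside: full circle, skip
    tried <- tried + 1
    rng <- ellipseAngularRange(e)
    thetaC <- atan2(cen[2], cen[1])
    got <- rangeBounds(rng, thetaC)
    want <- sweepWedgeOracle(e, nPoints = 1e6)
    expect_equal(got[1], want[1], tolerance = tol)
    expect_equal(got[2], want[2], tolerance = tol)
  }
  expect_gte(tried, 3)
})

test_that("wedge membership handles wrap-around, boundaries and zero arrows", {
  rng <- makeRange(350, 20)          # wraps through 0 degrees
  ang <- c(5, 355, 350, 10, 180, 11, 349) * pi / 180
  aPred <- cos(ang); aOrtho <- sin(ang)
  aPred <- c(aPred, 0); aOrtho <- c(aOrtho, 0)   # plus a zero-length arrow
  got <- wedgeMembership(aPred, aOrtho, rng)
  expect_identical(got, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # full circle keeps every nonzero arrow
  fullc <- methods::new("AngularRange",
                        intervals = matrix(numeric(), 0, 2),
                        fullCircle = TRUE)
  expect_identical(wedgeMembership(aPred, aOrtho, fullc),
                   c(rep(TRUE, 7), FALSE))
})

test_that("top-fraction cut uses the nearest-rank quantile over all features", {
  aPred <- 1:10; aOrtho <- rep(0, 10)
  all10 <- rep(TRUE, 10)
  expect_identical(which(magnitudeTopFraction(aPred, aOrtho, all10, 0.2)),
                   9:10)
  expect_identical(which(magnitudeTopFraction(aPred, aOrtho, all10, 1)),
                   1:10)
  # quantile over all features even when membership is restricted
  members <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_identical(which(magnitudeTopFraction(aPred, aOrtho, members, 0.2)),
                   integer(0))
  expect_error(magnitudeTopFraction(aPred, aOrtho, all10, 0), "tau")
})

test_that("weak filter keeps separators and removes nulls at the filter rate", {
  # perfectly separating column: separation convention keeps it (p = 0)
  y <- rep(c(0L, 1L), each = 10)
  x <- cbind(sep = as.numeric(y), const = rep(2, 20),
             noise = rnorm(20))
  ft <- featureTable(x, y)
  flt <- weakFilter(ft, 1:2, filterAlpha = 0.10)
  expect_true(1 %in% flt$kept)
  expect_true(2 %in% flt$removed$index)
  expect_equal(flt$removed$pValue[flt$removed$index == 2], 1)
  # null columns are removed with probability ~ 1 - alpha
  set.seed(33)
  n <- 60; pNull <- 400
  ftN <- featureTable(matrix(rnorm(n * pNull), n, pNull),
                      rep(c(0L, 1L), each = n / 2))
  fltN <- weakFilter(ftN, seq_len(pNull), filterAlpha = 0.10)
  frac <- nrow(fltN$removed) / pNull
  expect_lt(abs(frac - 0.90), 3 * sqrt(0.9 * 0.1 / pNull) + 0.02)
})

test_that("selection respects nesting, scale invariance and tau monotonicity", {
  sim <- generateDataset(simulationDesign("one_layer", seed = 34))
  tab <- sim$table
  model <- fitBiplot(tab)
  res <- suppressWarnings(
    selectFeatures(model, tab, selectionParams(tau = 0.05)))
  for (g in c("0", "1")) {
    e <- groupSelection(res, g)
    expect_true(all(e$selected %in% e$topCandidates))
    expect_true(all(e$topCandidates %in% e$wedgeMembers))
    expect_setequal(e$selected, setdiff(e$topCandidates, e$filteredOut$index))
  }
  expect_setequal(selectedFeatures(res),
                  unique(unlist(lapply(groupSelection(res), `[[`, "selected"))))
  # common positive rescaling of the data leaves the selection unchanged
  tabS <- featureTable(intensities(tab) * 3.7, sampleLabels(tab))
  resS <- suppressWarnings(
    selectFeatures(fitBiplot(tabS), tabS, selectionParams(tau = 0.05)))
  expect_identical(selectedFeatures(resS), selectedFeatures(res))
  expect_identical(groupSelection(resS, "0")$topCandidates,
                   groupSelection(res, "0")$topCandidates)
  # larger tau can only grow the selected sets
  taus <- c(0.02, 0.05, 0.10)
  sel <- lapply(taus, function(tt) selectedFeatures(suppressWarnings(
    selectFeatures(model, tab, selectionParams(tau = tt)))))
  expect_true(all(sel[[1]] %in% sel[[2]]))
  expect_true(all(sel[[2]] %in% sel[[3]]))
})

test_that("strong variables split 4/4 across the predictive axis", {
  sim <- generateDataset(simulationDesign("three_layer", seed = 35))
  m <- fitBiplot(sim$table)
  aP <- predLoadings(m)
  expect_true(all(aP[1:4] < 0))      # aligned with label 0
  expect_true(all(aP[5:8] > 0))      # aligned with label 1
})
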