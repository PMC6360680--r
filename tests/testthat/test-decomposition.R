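test_that("centering and autoscaling behave on plain and degenerate columns", {
  ft <- featureTable(matrix(c(1, 3, 5, 7, 2, 2, 2, 2), 4, 2,
                            dimnames = list(NULL, c("a", "const"))),
                     c(0, 1, 0, 1))
  cen <- centerTable(ft)
  expect_equal(unname(cen$X[, 1]), c(-3, -1, 1, 3))
  expect_equal(max(abs(colMeans(cen$X))), 0)
  expect_warning(cs <- centerTable(ft, autoscale = TRUE), "constant")
  expect_equal(unname(cs$scale[2]), 1)           # constant column unscaled
  expect_equal(unname(cs$X[, 2]), rep(0, 4))
  sdA <- sd(c(1, 3, 5, 7))
  expect_equal(unname(cs$X[, 1]), c(-3, -1, 1, 3) / sdA)
})

test_that("response projection matches least squares and is idempotent", {
  xc <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2)
  expect_equal(projectResponse(xc, c(1, 1, 1)), c(1, 1, 0))
  # y already in the column space -> returned unchanged
  y <- xc %*% c(2, -1)
  expect_equal(projectResponse(xc, as.vector(y)), as.vector(y))
  # y orthogonal to all columns -> zero
  expect_equal(projectResponse(xc, c(0, 0, 5)), c(0, 0, 0))
  expect_warning(z <- projectResponse(matrix(0, 3, 2), c(1, 2, 3)), "zero")
  expect_equal(z, c(0, 0, 0))
})

test_that("orthogonal component equals the leading PC of the deflated matrix", {
  set.seed(20)
  xc <- scale(matrix(rnorm(15), 5, 3), scale = FALSE)
  y <- c(1, 0, 1, 0, 1)
  yh <- projectResponse(xc, y)
  oc <- orthogonalComponent(xc, yh)
  # brute-force dense SVD oracle on the deflated matrix
  m <- xc - yh %*% (crossprod(yh, xc) / sum(yh^2))
  sv <- svd(m)
  tOracle <- sv$u[, 1] * sv$d[1]
  expect_equal(abs(sum(oc$tOrtho * tOracle)) /
                 (sqrt(sum(oc$tOrtho^2)) * sqrt(sum(tOracle^2))),
               1, tolerance = 1e-10)
  expect_equal(sum(oc$tOrtho^2), sum(tOracle^2), tolerance = 1e-10)
  # orthogonality to the projected response, by construction
  expect_lt(abs(sum(oc$tOrtho * yh)),
            1e-10 * sqrt(sum(oc$tOrtho^2)) * sqrt(sum(yh^2)))
  # loading uses the full centered matrix
  expect_equal(oc$aOrtho,
               as.vector(crossprod(xc, oc$tOrtho)) / sum(oc$tOrtho^2))
  # fully response-aligned data leaves nothing orthogonal
  rank1 <- yh %*% t(c(1, 2, 3))
  expect_error(orthogonalComponent(rank1, yh), "degenerate")
})

test_that("first PLS component matches NIPALS and maximizes covariance", {
  # rank-1 aligned case: scores proportional to the centered response
  y <- c(0, 0, 1, 1, 0, 1)
  yc <- y - mean(y)
  v <- c(2, -1, 0.5, 3)
  xr <- yc %*% t(v)
  pc <- plsFirstComponent(xr, y)
  expect_equal(cor(pc$tPred, yc), 1, tolerance = 1e-12)
  expect_equal(pc$aPred / v, rep(pc$aPred[1] / v[1], 4), tolerance = 1e-10)
  # iterative NIPALS oracle on a random 6 x 4 fixture
  set.seed(21)
  x <- scale(matrix(rnorm(24), 6, 4), scale = FALSE)
  pc <- plsFirstComponent(x, y)
  u <- yc
  for (i in 1:100) {
    w <- as.vector(crossprod(x, u)); w <- w / sqrt(sum(w^2))
    tt <- as.vector(x %*% w)
    q <- sum(yc * tt) / sum(tt^2)
    u <- yc * q
  }
  if (sum(tt * yc) < 0) tt <- -tt
  expect_equal(pc$tPred, tt, tolerance = 1e-10)
  # among random unit-norm weights, none beats the PLS weight's covariance
  set.seed(22)
  best <- abs(sum((x %*% pc$w) * yc))
  for (i in 1:500) {
    wr <- rnorm(4); wr <- wr / sqrt(sum(wr^2))
    expect_lte(abs(sum((x %*% wr) * yc)), best + 1e-10)
  }
  # flat response carries no signal
  expect_error(plsFirstComponent(matrix(0, 6, 4), y), "degenerate")
})

test_that("fitted models are deterministic, equivariant and separate the labels", {
  sim <- generateDataset(simulationDesign("one_layer", seed = 23))
  m1 <- fitBiplot(sim$table)
  m2 <- fitBiplot(sim$table)
  expect_identical(predScores(m1), predScores(m2))
  expect_identical(orthoLoadings(m1), orthoLoadings(m2))
  # permuting samples permutes scores and leaves loadings unchanged
  set.seed(24)
  perm <- sample(nrow(intensities(sim$table)))
  tabP <- featureTable(intensities(sim$table)[perm, ],
                       sampleLabels(sim$table)[perm])
  mP <- fitBiplot(tabP)
  expect_equal(unname(predScores(mP)), unname(predScores(m1)[perm]),
               tolerance = 1e-9)
  expect_equal(unname(predLoadings(mP)), unname(predLoadings(m1)),
               tolerance = 1e-9)
  # predictive scores separate the groups: positive 1-D silhouette
  y <- sampleLabels(sim$table)
  tp <- predScores(m1)
  sil <- vapply(seq_along(tp), function(i) {
    a <- mean(abs(tp[i] - tp[y == y[i]][-match(i, which(y == y[i]))]))
    b <- mean(abs(tp[i] - tp[y != y[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  # sign convention: predictive score covaries positively with the label
  expect_gt(cov(tp, y), 0)
})

test_that("biplot covariance/correlation identities hold against the reconstruction", {
  ft <- makeToyTable(n = 16, p = 8, seed = 25)
  m <- fitBiplot(ft)
  x2 <- reconstructRank2(m)
  gram <- crossprod(x2)
  for (q in 1:8) for (r in 1:8)
    expect_equal(unname(biplotCovariance(m, q, r)), gram[q, r],
                 tolerance = 1e-9)
  # correlation identity and bounds
  cc <- outer(1:8, 1:8, function(q, r)
    mapply(function(a, b) biplotCorrelation(m, a, b), q, r))
  expect_true(all(cc >= -1 - 1e-12 & cc <= 1 + 1e-12))
  expect_equal(diag(cc), rep(1, 8), tolerance = 1e-12)
  corOracle <- cor(x2)
  expect_equal(cc, unname(corOracle), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(biplotCovariance(m, 0, 1), "range")
  expect_error(biplotCovariance(m, 1, 9), "range")
})
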