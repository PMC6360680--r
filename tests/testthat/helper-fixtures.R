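# small in-code fixtures shared across test files

# balanced random table with a handful of informative features
makeToyTable <- function(n = 20, p = 6, nInformative = 2, seed = 42,
                         effect = 3) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  for (j in seq_len(nInformative)) x[, j] <- x[, j] + effect * y
  featureTable(x, y)
}

# a circular confidence ellipse of effective radius r at the given center
makeCircularEllipse <- function(center, r = 1, coverage = 0.95) {
  q <- qchisq(coverage, 2)
  methods::new("ConfidenceEllipse", center = as.numeric(center),
               covariance = diag(2) * r^2 / q, coverage = coverage,
               radiusSq = q)
}

# angular interval helper
makeRange <- function(startDeg, widthDeg) {
  methods::new("AngularRange",
               intervals = matrix(c(startDeg, widthDeg) * pi / 180, 1, 2,
                                  dimnames = list(NULL, c("start", "width"))),
               fullCircle = FALSE)
}

# boundary-point sweep oracle for the wedge subtended by an ellipse:
# angles of many points on the ellipse boundary, reduced to a (lo, hi)
# interval relative to the direction of the center
sweepWedgeOracle <- function(e, nPoints = 1e6) {
  l <- t(chol(e@covariance))
  phi <- seq(0, 2 * pi, length.out = nPoints)
  pts <- t(e@center + sqrt(e@radiusSq) * l %*% rbind(cos(phi), sin(phi)))
  thetaC <- atan2(e@center[2], e@center[1])
  rel <- (atan2(pts[, 2], pts[, 1]) - thetaC + pi) %% (2 * pi) - pi
  thetaC + range(rel)
}

# relative (lo, hi) of a one-interval AngularRange around a reference angle
rangeBounds <- function(rng, thetaC) {
  start <- unname(rng@intervals[1, 1])
  width <- unname(rng@intervals[1, 2])
  relLo <- (start - thetaC + pi) %% (2 * pi) - pi
  c(thetaC + relLo, thetaC + relLo + width)
}
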