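## Comparison selectors: per-feature two-sample t-tests with BH/BY
## false-discovery-rate control, and OPLS-coupled statistical total
## correlation spectroscopy (correlation-cutoff) selection.

#' Per-feature Welch t-test p-values
#'
#' Two-sided unpaired Welch t-test of each feature between the two label
#' groups, vectorized over features. A feature with zero variance in both
#' groups gets p = 1 when the group means are equal and p = 0 otherwise.
#'
#' @param table a [FeatureTable-class].
#' @return numeric p-value vector (length p, named by feature id).
#' @export
ttestPvalues <- function(table) {
  x <- intensities(table)
  y <- sampleLabels(table)
  i0 <- y == 0L
  n0 <- sum(i0); n1 <- sum(!i0)
  if (n0 < 2L || n1 < 2L) stop("both groups need at least 2 samples")
  x0 <- x[i0, , drop = FALSE]; x1 <- x[!i0, , drop = FALSE]
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  v0 <- colSums(sweep(x0, 2L, m0)^2) / (n0 - 1L)
  v1 <- colSums(sweep(x1, 2L, m1)^2) / (n1 - 1L)
  se2 <- v0 / n0 + v1 / n1
  df <- se2^2 / (v0^2 / (n0^2 * (n0 - 1L)) + v1^2 / (n1^2 * (n1 - 1L)))
  p <- rep(NA_real_, ncol(x))
  zero <- se2 == 0
  p[zero] <- ifelse(m0[zero] == m1[zero], 1, 0)
  tt <- abs(m0[!zero] - m1[!zero]) / sqrt(se2[!zero])
  p[!zero] <- 2 * stats::pt(tt, df[!zero], lower.tail = FALSE)
  stats::setNames(p, colnames(x))
}

#' FDR step-up selection (Benjamini-Hochberg / Benjamini-Yekutieli)
#'
#' BH: reject the ordered p-values up to the largest i with
#' `p_(i) <= i q / m`. BY: the same with q replaced by `q / H(m)`,
#' `H(m) = sum(1/i)`, valid under arbitrary dependence. Implemented via
#' `stats::p.adjust`, which realizes exactly these step-up rules.
#'
#' @param pvals p-value vector in `[0, 1]`.
#' @param q target false-discovery rate.
#' @param variant "bh" or "by".
#' @return logical rejection vector.
#' @export
fdrSelect <- function(pvals, q, variant = c("bh", "by")) {
  variant <- match.arg(variant)
  stopifnot(all(pvals >= 0 & pvals <= 1), q > 0, q < 1)
  stats::p.adjust(pvals, method = toupper(variant)) <= q
}

#' Correlation cutoff at a significance level
#'
#' The |r| value whose two-sided correlation test p-value equals `alpha`
#' at sample size n: `r = t* / sqrt(n - 2 + t*^2)` with t* the Student-t
#' critical value at `alpha` with n - 2 df.
#'
#' @param alpha two-sided significance level.
#' @param n sample size (>= 4).
#' @return the cutoff correlation in (0, 1).
#' @export
correlationCutoff <- function(alpha, n) {
  stopifnot(n >= 4L, alpha > 0, alpha < 1)
  tstar <- stats::qt(1 - alpha / 2, n - 2L)
  tstar / sqrt(n - 2L + tstar^2)
}

#' STOCSY-OPLS correlation selection
#'
#' Selects feature j iff the absolute Pearson correlation of its column
#' with the response reaches the cutoff of [correlationCutoff()]. By
#' default the correlations are computed on the orthogonal-signal-corrected
#' matrix `Xc - t_ortho a_ortho'` (the OPLS coupling); `corrected = FALSE`
#' uses the raw centered columns instead. Zero-variance features are never
#' selected.
#'
#' @param table a [FeatureTable-class].
#' @param alpha significance level of the cutoff.
#' @param corrected correlate the OSC-corrected matrix (default TRUE).
#' @param model optional prefitted [BiplotModel-class] to reuse the
#'   orthogonal component.
#' @return logical selection vector (length p).
#' @export
stocsyoSelect <- function(table, alpha, corrected = TRUE, model = NULL) {
  x <- intensities(table)
  y <- sampleLabels(table)
  if (corrected) {
    if (is.null(model)) model <- fitBiplot(table)
    xc <- sweep(sweep(x, 2L, model@columnMeans), 2L, model@columnScales, "/")
    xc <- xc - tcrossprod(model@tOrtho, model@aOrtho)
  } else {
    xc <- sweep(x, 2L, colMeans(x))
  }
  yc <- y - mean(y)
  xcc <- sweep(xc, 2L, colMeans(xc))
  num <- as.vector(crossprod(xcc, yc))
  den <- sqrt(colSums(xcc^2)) * sqrt(sum(yc^2))
  r <- ifelse(den > 0, num / den, 0)
  abs(r) >= correlationCutoff(alpha, nrow(x))
}
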