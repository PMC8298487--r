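# Region splitting by metabolic rate and the study's statistical toolkit:
# exact Wilcoxon signed-rank (enumeration with ties and zero handling),
# Spearman rank correlation with exact small-n permutation p, Pearson
# correlation, and the repeatability coefficient of variation.

#' Split a region by metabolic rate of glucose
#'
#' The high subregion contains parent voxels with MR_glu strictly greater
#' than the threshold; everything else in the parent (including voxels at
#' exactly the threshold) goes to the low subregion.
#'
#' @param mrglu 3D array of MR_glu (umol/100 cm^3/min).
#' @param parent logical 3D parent mask on the same grid.
#' @param threshold split threshold (default 11 umol/100 cm^3/min).
#' @return A [RegionSet-class].
#' @export
splitHiLo <- function(mrglu, parent, threshold = 11) {
  if (!identical(dim(mrglu), dim(parent)))
    stop("MR_glu map grid does not match the parent mask")
  hi <- parent & !is.na(mrglu) & mrglu > threshold
  lo <- parent & !hi
  new("RegionSet", parent = parent, hi = hi, lo = lo,
      threshold = threshold)
}

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet: %d parent voxels, %d HI / %d LO (threshold %g)\n",
              sum(object@parent), sum(object@hi), sum(object@lo),
              object@threshold))
})

#' Unweighted region mean
#'
#' Mean of a map over a mask; an empty mask yields NA so missingness
#' propagates instead of failing.
#'
#' @param map numeric array.
#' @param mask logical array on the same grid.
#' @return scalar mean or NA.
#' @export
regionMean <- function(map, mask) {
  if (!identical(dim(map), dim(mask)))
    stop("map grid does not match mask grid")
  if (!any(mask)) return(NA_real_)
  mean(map[mask], na.rm = TRUE)
}

# exact distribution of the positive-rank sum over all 2^n sign
# assignments, with average ranks for ties: generating-function convolution
# over doubled ranks (integers even with .5 average ranks)
signedRankDistribution <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  maxs <- sum(r2)
  p <- numeric(maxs + 1L); p[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), p[seq_len(maxs + 1L - r)])
    p <- (p + shifted) / 2
  }
  p  # p[k+1] = P(2V = k)
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped; tied
#' absolute differences receive average ranks. For up to `exactMax` non-zero
#' differences the p-value is computed from the exact null distribution over
#' all sign assignments (conditional on the observed ranks); beyond that a
#' normal approximation with tie correction is used.
#'
#' @param x,y paired samples (incomplete pairs are dropped).
#' @param exactMax largest n for exact enumeration (default 25).
#' @return list with `statistic` (V, sum of positive ranks), `p`, `n`
#'   (non-zero differences used), `method`, and `note` when degenerate.
#' @export
wilcoxonSignedRank <- function(x, y, exactMax = 25) {
  keep <- stats::complete.cases(x, y)
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p = 1, n = 0L, method = "degenerate",
                note = "all differences zero"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exactMax) {
    dist <- signedRankDistribution(r)
    k <- as.integer(round(2 * V))
    pLower <- sum(dist[seq_len(k + 1L)])
    pUpper <- sum(dist[(k + 1L):length(dist)])
    p <- min(1, 2 * min(pLower, pUpper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = V, p = p, n = n, method = method, note = NULL)
}

# all permutations of 1..n as a matrix (n! rows); n <= 8 in practice
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Rank and product-moment correlation
#'
#' Spearman rank correlation (average ranks for ties) with an exact
#' permutation p-value for n <= `exactMax` (full enumeration of the n!
#' orderings) and a t-approximation beyond, plus the complementary Pearson
#' correlation with its t-distribution p-value.
#'
#' @param x,y paired samples; incomplete pairs are dropped (n >= 3 required).
#' @param exactMax largest n for exact permutation enumeration (default 8).
#' @return list with `spearman` (rho, p, method), `pearson` (r, p), and `n`.
#'   With zero variance in either variable the correlations are NA with a
#'   note.
#' @export
rankCorrelation <- function(x, y, exactMax = 8) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(spearman = list(rho = NA_real_, p = NA_real_,
                                method = "undefined"),
                pearson = list(r = NA_real_, p = NA_real_), n = n,
                note = "zero variance"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exactMax) {
    perms <- allPermutations(n)
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- (matrix(ryc[perms], nrow(perms), n) %*% rxc) / denom
    pS <- mean(abs(rhos) >= abs(rho) - 1e-12)
    methodS <- "exact permutation"
  } else {
    tS <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    pS <- min(1, 2 * stats::pt(-abs(tS), df = n - 2))
    methodS <- "t approximation"
  }
  pr <- stats::cor.test(x, y, method = "pearson")
  list(spearman = list(rho = rho, p = pS, method = methodS),
       pearson = list(r = unname(pr$estimate), p = pr$p.value),
       n = n)
}

#' Repeatability coefficient of variation
#'
#' Per-subject two-point CV, SD(pair)/mean(pair) x 100, averaged over
#' subjects (`method = "mean"`, symmetric and scale-free) or root mean
#' square (`method = "rms"`). Subjects with non-positive pair means are
#' excluded with a warning.
#'
#' @param a,b paired repeated measurements (incomplete pairs dropped).
#' @param method "mean" or "rms" aggregation.
#' @return CV in percent.
#' @export
repeatabilityCv <- function(a, b, method = c("mean", "rms")) {
  method <- match.arg(method)
  keep <- stats::complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  m <- (a + b) / 2
  bad <- m <= 0
  if (any(bad)) {
    warning(sum(bad), " subject(s) with non-positive pair mean excluded")
    a <- a[!bad]; b <- b[!bad]; m <- m[!bad]
  }
  if (length(m) == 0L) return(NA_real_)
  cvs <- abs(a - b) / sqrt(2) / m * 100  # SD of a pair = |a-b|/sqrt(2)
  switch(method, mean = mean(cvs), rms = sqrt(mean(cvs^2)))
}
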