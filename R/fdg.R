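# Basis-function estimation of the irreversible two-tissue compartment net
# uptake rate K_i, and conversion to the metabolic rate of glucose.
#
# Model: C(t) = theta1 * int_0^t C_P + theta2 * (exp(-beta t) (x) C_P)(t)
# with theta1 = K1 k3/(k2+k3) = K_i, theta2 = K1 k2/(k2+k3), beta = k2+k3.

#' Build the basis set for the irreversible two-tissue model
#'
#' One irreversible basis (the running integral of the plasma input) plus
#' `nBeta` convolution bases with logarithmically spaced clearance rates,
#' all computed on a fine grid and then frame-averaged.
#'
#' @param input a plasma [BloodCurve-class] covering the scan. A whole-blood
#'   curve is rejected: the glucose pathway requires plasma input.
#' @param schedule a [FrameSchedule-class].
#' @param nBeta number of clearance-rate bases (default 50).
#' @param betaMin,betaMax grid endpoints in 1/min (defaults 0.02 and 1.0).
#' @return A [BasisSet-class].
#' @export
buildBasis <- function(input, schedule, nBeta = 50, betaMin = 0.02,
                       betaMax = 1.0) {
  if (curveKind(input) != "plasma")
    stop("basis construction requires a plasma input curve")
  betas <- exp(seq(log(betaMin), log(betaMax), length.out = nBeta))
  tgrid <- fineGrid(input, schedule)
  dt <- tgrid[2L] - tgrid[1L]
  cp <- sampleShiftedCurve(input, tgrid, 0)
  B <- matrix(0, nrow = nFrames(schedule), ncol = nBeta + 1L)
  # integrals taken in minutes so that the regression coefficients carry
  # the conventional ml/cm^3/min units (the grid itself is in seconds)
  B[, 1L] <- frameAverage(tgrid, cumTrapz(cp, dt) / 60, schedule)
  for (i in seq_len(nBeta)) {
    conv <- expConvLinear(cp, dt, betas[i] / 60) / 60
    B[, i + 1L] <- frameAverage(tgrid, conv, schedule)
  }
  new("BasisSet", betas = betas, basis = B, schedule = schedule,
      fineTime = tgrid, fineInput = cp)
}

# frame-averaged convolution basis at an arbitrary clearance rate (1/min)
basisColumn <- function(basis, beta) {
  dt <- basis@fineTime[2L] - basis@fineTime[1L]
  conv <- expConvLinear(basis@fineInput, dt, beta / 60) / 60
  frameAverage(basis@fineTime, conv, basis@schedule)
}

#' @rdname buildBasis
#' @param basis a [BasisSet-class].
#' @export
basisBetas <- function(basis) basis@betas

#' @rdname buildBasis
#' @export
basisMatrix <- function(basis) basis@basis

setMethod("show", "BasisSet", function(object) {
  cat(sprintf("BasisSet: %d betas on [%.3g, %.3g] 1/min, %d frames\n",
              length(object@betas), min(object@betas), max(object@betas),
              nFrames(object@schedule)))
})

# Non-negative least squares for a two-column design: try the unconstrained
# solution, fall back to the better single-column fit when a coefficient
# goes negative. Returns c(theta1, theta2, rss).
nnls2 <- function(a1, a2, y, sy2 = sum(y^2)) {
  a11 <- sum(a1 * a1); a12 <- sum(a1 * a2); a22 <- sum(a2 * a2)
  b1 <- sum(a1 * y); b2 <- sum(a2 * y)
  det <- a11 * a22 - a12 * a12
  th1 <- th2 <- 0
  if (det > 1e-300) {
    th1 <- (a22 * b1 - a12 * b2) / det
    th2 <- (a11 * b2 - a12 * b1) / det
  }
  if (th1 < 0 || th2 < 0 || det <= 1e-300) {
    t1 <- if (a11 > 0) max(b1 / a11, 0) else 0
    t2 <- if (a22 > 0) max(b2 / a22, 0) else 0
    r1 <- sy2 - 2 * t1 * b1 + t1^2 * a11
    r2 <- sy2 - 2 * t2 * b2 + t2^2 * a22
    if (r1 <= r2) { th1 <- t1; th2 <- 0; rss <- r1 }
    else { th1 <- 0; th2 <- t2; rss <- r2 }
  } else {
    rss <- sy2 - th1 * b1 - th2 * b2
  }
  c(th1, th2, max(rss, 0))
}

#' Fit the net uptake rate K_i with the basis-function method
#'
#' For each clearance rate beta the TAC is regressed (non-negative linear
#' least squares) on the irreversible basis and the beta convolution basis;
#' the beta minimizing the residual is selected (ties go to the smallest
#' beta, the smoothest solution). K_i is the irreversible coefficient.
#'
#' After the grid stage, `refineBeta = TRUE` (the default) polishes beta by
#' a golden-section search between the flanking grid nodes, removing the
#' grid-quantization error; the voxelwise [kiImage()] path leaves it off.
#'
#' @param tac a [RegionTAC-class] on the same schedule as the basis, or a
#'   numeric vector of per-frame activities.
#' @param basis a [BasisSet-class].
#' @param refineBeta logical, continuous local refinement of beta.
#' @return A [KiResult-class].
#' @export
fitKi <- function(tac, basis, refineBeta = TRUE) {
  y <- if (is(tac, "RegionTAC")) {
    if (!isTRUE(all.equal(frameStart(tacSchedule(tac)),
                          frameStart(basis@schedule))))
      stop("TAC schedule does not match basis schedule")
    tacActivity(tac)
  } else as.numeric(tac)
  if (length(y) != nrow(basis@basis))
    stop("TAC length does not match basis")
  if (all(y == 0))
    return(new("KiResult", ki = 0, beta = basis@betas[1L], theta2 = 0,
               rss = 0))
  sy2 <- sum(y^2)
  best <- c(0, 0, Inf); bestI <- 1L
  for (i in seq_along(basis@betas)) {
    f <- nnls2(basis@basis[, 1L], basis@basis[, i + 1L], y, sy2)
    if (f[3L] < best[3L] - 1e-12 * sy2) {  # strict improvement: ties -> smallest beta
      best <- f; bestI <- i
    }
  }
  bestBeta <- basis@betas[bestI]
  if (refineBeta) {
    nb <- length(basis@betas)
    lo <- log(basis@betas[max(bestI - 1L, 1L)])
    hi <- log(basis@betas[min(bestI + 1L, nb)])
    rssAt <- function(lb) nnls2(basis@basis[, 1L],
                                basisColumn(basis, exp(lb)), y, sy2)[3L]
    lb <- goldenSection(rssAt, lo, hi, tol = 1e-5)
    fR <- nnls2(basis@basis[, 1L], basisColumn(basis, exp(lb)), y, sy2)
    if (fR[3L] <= best[3L]) {
      best <- fR; bestBeta <- exp(lb)
    }
  }
  new("KiResult", ki = best[1L], beta = bestBeta, theta2 = best[2L],
      rss = best[3L])
}

#' @rdname fitKi
#' @param fit a [KiResult-class].
#' @export
kiValue <- function(fit) fit@ki

setMethod("show", "KiResult", function(object) {
  cat(sprintf("KiResult: Ki=%.4g ml/cm^3/min, beta=%.3g 1/min, theta2=%.4g\n",
              object@ki, object@beta, object@theta2))
})

#' Voxelwise K_i image
#'
#' Applies the basis-function fit to every (masked) voxel. The computation
#' is vectorized over voxels but contractually identical to looping
#' [fitKi()] voxel by voxel.
#'
#' @param image a [DynamicImage-class] on the basis schedule.
#' @param basis a [BasisSet-class].
#' @param mask optional logical 3D array restricting the fit.
#' @return 3D numeric array of K_i (ml plasma/cm^3/min); zero (or NA outside
#'   a supplied mask) elsewhere.
#' @export
kiImage <- function(image, basis, mask = NULL) {
  if (!isTRUE(all.equal(frameStart(imageSchedule(image)),
                        frameStart(basis@schedule))))
    stop("image schedule does not match basis schedule")
  d <- dim(imageData(image))
  out <- array(NA_real_, d[1:3])
  idx <- if (is.null(mask)) seq_len(prod(d[1:3])) else which(mask)
  if (length(idx) == 0L) return(out)
  Y <- matrix(imageData(image), ncol = d[4L])[idx, , drop = FALSE]
  Yt <- t(Y)                                  # frames x voxels
  sy2 <- colSums(Yt^2)
  a1 <- basis@basis[, 1L]
  a11 <- sum(a1 * a1)
  b1 <- as.numeric(crossprod(a1, Yt))         # per voxel
  bestRss <- rep(Inf, length(idx))
  bestKi <- numeric(length(idx))
  tol <- 1e-12 * pmax(sy2, 1e-300)
  for (i in seq_along(basis@betas)) {
    a2 <- basis@basis[, i + 1L]
    a12 <- sum(a1 * a2); a22 <- sum(a2 * a2)
    b2 <- as.numeric(crossprod(a2, Yt))
    det <- a11 * a22 - a12 * a12
    th1 <- (a22 * b1 - a12 * b2) / det
    th2 <- (a11 * b2 - a12 * b1) / det
    rss <- sy2 - th1 * b1 - th2 * b2
    bad <- which(th1 < 0 | th2 < 0 | !is.finite(th1) | !is.finite(th2))
    if (length(bad)) {
      t1 <- pmax(b1[bad] / a11, 0)
      t2 <- if (a22 > 0) pmax(b2[bad] / a22, 0) else 0
      r1 <- sy2[bad] - 2 * t1 * b1[bad] + t1^2 * a11
      r2 <- sy2[bad] - 2 * t2 * b2[bad] + t2^2 * a22
      use1 <- r1 <= r2
      th1[bad] <- ifelse(use1, t1, 0)
      rss[bad] <- pmax(ifelse(use1, r1, r2), 0)
    }
    better <- rss < bestRss - tol
    if (any(better)) {
      bestRss[better] <- rss[better]
      bestKi[better] <- th1[better]
    }
  }
  bestKi[sy2 == 0] <- 0
  out[idx] <- bestKi
  out
}

#' Forward irreversible two-tissue compartment model
#'
#' Frame-averaged tissue curve for rate constants (K1, k2, k3) with k4 = 0:
#' C(t) = theta1 int_0^t C_P + theta2 (exp(-beta t) (x) C_P)(t) with
#' theta1 = K1 k3/(k2+k3), theta2 = K1 k2/(k2+k3), beta = k2+k3.
#'
#' @param K1 plasma-to-tissue transport, ml/cm^3/min.
#' @param k2,k3 rate constants, 1/min.
#' @param input a plasma [BloodCurve-class].
#' @param schedule a [FrameSchedule-class].
#' @return A [RegionTAC-class].
#' @export
model2tcmIrr <- function(K1, k2, k3, input, schedule) {
  if (curveKind(input) != "plasma")
    stop("the irreversible model requires a plasma input curve")
  beta <- k2 + k3
  theta1 <- if (beta > 0) K1 * k3 / beta else 0
  theta2 <- if (beta > 0) K1 * k2 / beta else K1
  tgrid <- fineGrid(input, schedule)
  dt <- tgrid[2L] - tgrid[1L]
  cp <- sampleShiftedCurve(input, tgrid, 0)
  y <- theta1 * cumTrapz(cp, dt) / 60 +
    theta2 * expConvLinear(cp, dt, beta / 60) / 60
  # /60: rate constants are per minute, the grid is in seconds
  regionTAC(schedule, frameAverage(tgrid, y, schedule), region = "model")
}

#' Construct a blood glucose record
#'
#' @param before,after venous whole-blood glucose (mmol/l) measured before
#'   and after the cold-exposure scan.
#' @param ratio plasma-to-whole-blood glucose ratio (default 1.1).
#' @param p2 optional laboratory plasma glucose (mmol/l).
#' @return A [GlucoseRecord-class].
#' @export
glucoseRecord <- function(before, after, ratio = 1.1, p2 = NA_real_) {
  new("GlucoseRecord", before = before, after = after, ratio = ratio,
      p2 = p2)
}

#' @rdname glucoseRecord
#' @param glucose a [GlucoseRecord-class].
#' @export
meanPlasmaGlucose <- function(glucose) {
  (glucose@before * glucose@ratio + glucose@after * glucose@ratio) / 2
}

#' Metabolic rate of glucose from K_i
#'
#' \deqn{MR_{glu} = \bar{C}^P_{glu} \cdot K_i / LC} reported in
#' umol/100 cm^3/min: the plasma glucose (mmol/l = umol/ml) times K_i
#' (ml/cm^3/min) gives umol/cm^3/min, and the factor 100 converts to the
#' per-100 cm^3 reporting convention. The lumped constant LC relating FDG to
#' glucose kinetics is assumed 1.
#'
#' @param ki K_i as a scalar, vector or 3D array (ml plasma/cm^3/min).
#' @param glucose a [GlucoseRecord-class] or a plasma glucose value (mmol/l).
#' @param LC lumped constant (> 0), default 1.
#' @param useP2 use the laboratory plasma value instead of the converted
#'   whole-blood mean (the alternative MR_glu2 estimate).
#' @return MR_glu with the shape of `ki`, in umol/100 cm^3/min.
#' @export
computeMrglu <- function(ki, glucose, LC = 1, useP2 = FALSE) {
  if (LC <= 0) stop("LC must be positive")
  cglu <- if (is(glucose, "GlucoseRecord")) {
    if (useP2) {
      if (is.na(glucose@p2)) stop("no laboratory plasma glucose available")
      glucose@p2
    } else meanPlasmaGlucose(glucose)
  } else {
    if (useP2) stop("useP2 requires a GlucoseRecord")
    as.numeric(glucose)
  }
  if (length(cglu) != 1L || is.na(cglu)) stop("glucose value missing")
  cglu * ki * 100 / LC
}
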