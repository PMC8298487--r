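# [15O]water single-tissue compartment model with arterial blood volume and
# input delay. Reported units follow the field convention: F in
# ml/100 cm^3/min, V_T and V_A in ml/100 cm^3, delay in seconds. Internally
# everything is per cm^3 and per second.

# instantaneous 1TCM tissue + blood signal on a fine grid
# F, VT, VA in reporting units; returns list(t, y) on the fine grid
model1tcmFine <- function(F, VT, VA, delay, input, tgrid, scaledTissue = TRUE) {
  Fp <- F / 100 / 60          # ml/cm^3/s
  VTp <- VT / 100             # ml/cm^3
  VAp <- VA / 100             # dimensionless
  ca <- sampleShiftedCurve(input, tgrid, delay)
  dt <- tgrid[2L] - tgrid[1L]
  k <- if (VTp > 0) Fp / VTp else 0
  tissue <- if (Fp > 0) Fp * expConvLinear(ca, dt, k) else numeric(length(ca)) * 0
  scale <- if (scaledTissue) (1 - VAp) else 1
  VAp * ca + scale * tissue
}

#' Forward single-tissue compartment model
#'
#' Computes the operational-equation prediction
#' \deqn{C(t) = V_A' C_A(t-\Delta) + (1-V_A') F' \int_0^t C_A(s-\Delta)
#'   e^{-(F'/V_T')(t-s)} ds}
#' with primed quantities in per-cm^3 units (\eqn{V_A' = V_A/100} etc.), and
#' returns the time-average of C(t) over each frame rather than a mid-time
#' sample, since early 5 s frames change rapidly within a frame.
#'
#' @param F perfusion, ml/100 cm^3/min.
#' @param VT distribution volume, ml/100 cm^3.
#' @param VA arterial blood volume, ml/100 cm^3.
#' @param delay input delay in seconds (positive: tracer arrives later).
#' @param input a [BloodCurve-class], sampled finely enough to resolve the
#'   bolus (a grid of 1 s or finer is recommended).
#' @param schedule a [FrameSchedule-class].
#' @param scaledTissue logical; if TRUE (default) the tissue term is scaled
#'   by (1 - V_A'), the common convention in water perfusion quantification.
#'   FALSE gives the unscaled variant.
#' @return A [RegionTAC-class] of frame-averaged model values.
#' @export
model1tcm <- function(F, VT, VA, delay, input, schedule,
                      scaledTissue = TRUE) {
  tgrid <- fineGrid(input, schedule)
  y <- model1tcmFine(F, VT, VA, delay, input, tgrid, scaledTissue)
  regionTAC(schedule, frameAverage(tgrid, y, schedule), region = "model")
}

#' Fit the single-tissue compartment model to a water TAC
#'
#' Weighted nonlinear least squares of the operational equation over the
#' frames starting inside the fit window (default: the first three minutes),
#' with frame-duration weights. The input delay is handled by a multistart
#' search: on a delay grid (-10 to +30 s, 2 s step) the model is linear in
#' (V_A', (1-V_A')F') at fixed washout rate k = F'/V_T', so a profiled
#' linear solve over a k grid seeds a joint four-parameter
#' Levenberg-Marquardt refinement. Per-parameter coefficients of variation
#' come from the asymptotic covariance (inverse of J'WJ scaled by the
#' residual variance).
#'
#' @param tac a [RegionTAC-class]. Frames with negative start times or after
#'   a gap (bracketing frames) are ignored.
#' @param input a [BloodCurve-class] covering the window.
#' @param window fit window in seconds (frames with start < window enter).
#' @param delayGrid numeric, delay multistart grid in seconds.
#' @param scaledTissue see [model1tcm()].
#' @return A [WaterFitResult-class].
#' @export
fit1tcm <- function(tac, input, window = 180,
                    delayGrid = seq(-10, 30, by = 2), scaledTissue = TRUE) {
  sched <- tacSchedule(tac)
  keep <- frameStart(sched) >= 0 & frameStart(sched) < window
  # drop post-gap bracketing frames
  ends <- frameEnd(sched); starts <- frameStart(sched)
  gap <- c(FALSE, starts[-1L] > ends[-nFrames(sched)] + 1e-6)
  keep <- keep & !cumsum(gap)
  if (sum(keep) < 8L)
    stop("need at least 8 frames inside the fit window")
  sub <- frameSchedule(starts[keep], frameDuration(sched)[keep])
  obs <- tacActivity(tac)[keep]
  w <- frameDuration(sub) / sum(frameDuration(sub))

  if (all(obs == 0)) {
    return(new("WaterFitResult",
               estimates = c(F = NA_real_, VT = NA_real_, VA = NA_real_,
                             delay = NA_real_),
               cv = c(F = NA_real_, VT = NA_real_, VA = NA_real_,
                      delay = NA_real_),
               rss = 0, converged = FALSE, degenerate = TRUE,
               window = window))
  }

  tgrid <- fineGrid(input, sub)
  dt <- tgrid[2L] - tgrid[1L]
  # washout-rate grid spanning physiologic F/V_T ratios (per second)
  kGrid <- exp(seq(log(2 / 90 / 60), log(60 / 25 / 60), length.out = 30))

  best <- list(rss = Inf)
  for (d in delayGrid) {
    ca <- sampleShiftedCurve(input, tgrid, d)
    caF <- frameAverage(tgrid, ca, sub)
    for (k in kGrid) {
      conv <- expConvLinear(ca, dt, k)
      convF <- frameAverage(tgrid, conv, sub)
      # C = theta1 * ca + theta2 * conv ; theta1 = VA', theta2 = (1-VA')F'
      A <- cbind(caF, convF)
      AtWA <- crossprod(A, w * A)
      AtWy <- crossprod(A, w * obs)
      th <- tryCatch(solve(AtWA, AtWy), error = function(e) c(0, 0))
      th[1L] <- min(max(th[1L], 0), 0.99)
      th[2L] <- max(th[2L], 1e-8)
      r <- obs - A %*% th
      rss <- sum(w * r^2)
      if (rss < best$rss)
        best <- list(rss = rss, delay = d, k = k, th = as.numeric(th))
    }
  }

  VA0 <- best$th[1L] * 100
  Fp0 <- if (scaledTissue) best$th[2L] / max(1 - best$th[1L], 0.01)
         else best$th[2L]
  F0 <- Fp0 * 100 * 60
  VT0 <- Fp0 / best$k * 100
  p0 <- c(F = F0, VT = min(max(VT0, 5), 150), VA = VA0, delay = best$delay)

  residFun <- function(p) {
    m <- tryCatch(
      tacActivity(model1tcm(p[1L], p[2L], p[3L], p[4L], input, sub,
                            scaledTissue)),
      error = function(e) rep(1e6, length(obs)))
    sqrt(w) * (m - obs)
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = residFun,
    lower = c(0, 1e-2, 0, min(delayGrid) - 10),
    upper = c(1000, 1000, 100, max(delayGrid) + 10),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  est <- fit$par
  names(est) <- c("F", "VT", "VA", "delay")
  rss <- fit$deviance
  converged <- fit$info %in% 1:4

  # asymptotic covariance from the weighted Jacobian at the solution
  cv <- rep(NA_real_, 4); names(cv) <- names(est)
  dof <- length(obs) - 4L
  if (dof > 0) {
    J <- fit$hessian  # J'J from nls.lm
    sigma2 <- rss / dof
    covm <- tryCatch(solve(J) * sigma2, error = function(e) NULL)
    if (!is.null(covm)) {
      se <- sqrt(pmax(diag(covm), 0))
      cv <- ifelse(abs(est) > 1e-12, se / abs(est) * 100, Inf)
      names(cv) <- names(est)
    }
  }
  new("WaterFitResult", estimates = est, cv = cv, rss = rss,
      converged = converged, degenerate = FALSE, window = window)
}

#' @rdname fit1tcm
#' @param fit a [WaterFitResult-class].
#' @export
fitEstimates <- function(fit) fit@estimates

#' @rdname fit1tcm
#' @export
fitCV <- function(fit) fit@cv

#' @rdname fit1tcm
#' @export
fitConverged <- function(fit) fit@converged

#' @rdname fit1tcm
#' @export
fitDegenerate <- function(fit) fit@degenerate

setMethod("show", "WaterFitResult", function(object) {
  if (object@degenerate) {
    cat("WaterFitResult: degenerate (no signal)\n")
  } else {
    e <- object@estimates; cv <- object@cv
    cat(sprintf(
      "WaterFitResult: F=%.2f (CV %.1f%%), VT=%.1f, VA=%.2f (CV %.1f%%), delay=%.1f s%s\n",
      e["F"], cv["F"], e["VT"], e["VA"], cv["VA"], e["delay"],
      if (object@converged) "" else " [not converged]"))
  }
})

#' Construct a residual-FDG background model
#'
#' @param kind "constant", "linear" or "exponential".
#' @param b0,b1 background level (kBq/ml) at the anchor times. For the
#'   constant kind only `b0` is used.
#' @param t0,t1 anchor times (s), the mid-times of the two bracketing 60 s
#'   frames.
#' @return A [BackgroundModel-class].
#' @export
backgroundModel <- function(kind, b0, b1 = b0, t0 = -30, t1 = 1230) {
  new("BackgroundModel", kind = kind, b0 = b0, b1 = b1, t0 = t0, t1 = t1)
}

# frame-averaged background level for each frame of a schedule
backgroundFrameMeans <- function(bg, schedule) {
  ts <- frameStart(schedule); te <- frameEnd(schedule)
  switch(bg@kind,
    constant = rep(bg@b0, nFrames(schedule)),
    linear = {
      slope <- (bg@b1 - bg@b0) / (bg@t1 - bg@t0)
      bg@b0 + slope * ((ts + te) / 2 - bg@t0)   # frame mean of a line
    },
    exponential = {
      k <- log(bg@b1 / bg@b0) / (bg@t1 - bg@t0)
      if (abs(k) < 1e-15) rep(bg@b0, nFrames(schedule))
      else bg@b0 * (exp(k * (te - bg@t0)) - exp(k * (ts - bg@t0))) /
        (k * (te - ts))
    })
}

#' Subtract residual-FDG background from a water TAC
#'
#' Removes the modelled residual [18F]FDG contribution (constant, linear or
#' exponential between the bracketing-frame anchors) from every frame, using
#' the exact frame average of the background curve. Corrected values may go
#' negative under noise.
#'
#' @param tac a [RegionTAC-class].
#' @param bg a [BackgroundModel-class] anchored at the bracketing-frame
#'   mid-times.
#' @return A corrected [RegionTAC-class].
#' @export
subtractFdgBackground <- function(tac, bg) {
  corr <- tacActivity(tac) - backgroundFrameMeans(bg, tacSchedule(tac))
  regionTAC(tacSchedule(tac), corr, region = tac@region,
            voxels = tac@voxels)
}

#' Estimate a background model from bracketing frames
#'
#' Identifies the pre-injection frame (ending at or before time 0) and the
#' late post-injection frame (starting after a gap) of a reheated-scan TAC
#' and anchors a background model of the requested kind at their mid-times.
#'
#' @param tac a [RegionTAC-class] including the bracketing frames.
#' @param kind background model kind.
#' @return list with `background` (a [BackgroundModel-class]) and `main`
#'   (the TAC restricted to the main dynamic frames).
#' @export
estimateBackground <- function(tac, kind = "linear") {
  sched <- tacSchedule(tac)
  starts <- frameStart(sched); ends <- frameEnd(sched)
  pre <- which(ends <= 1e-6)
  gap <- c(FALSE, starts[-1L] > ends[-nFrames(sched)] + 1e-6)
  post <- which(cumsum(gap) > 0 & starts > 0)
  if (length(pre) == 0L || length(post) == 0L)
    stop("TAC has no bracketing frames")
  pre <- pre[length(pre)]; post <- post[1L]
  mid <- frameMid(sched)
  act <- tacActivity(tac)
  main <- setdiff(seq_len(nFrames(sched)), c(pre, post))
  list(background = backgroundModel(kind, b0 = act[pre], b1 = act[post],
                                    t0 = mid[pre], t1 = mid[post]),
       main = regionTAC(frameSchedule(starts[main],
                                      frameDuration(sched)[main]),
                        act[main], region = tac@region,
                        voxels = tac@voxels))
}

#' Coefficient-of-variation quality control
#'
#' A fit is rejected for the perfusion report when CV(F) exceeds the limit,
#' and independently for the blood-volume report when CV(V_A) exceeds it, so
#' a subject can contribute a perfusion value while its V_A is excluded.
#'
#' @param results list of [WaterFitResult-class] objects.
#' @param cvLimit acceptance limit in percent (default 100).
#' @return data.frame with logical columns `acceptPerfusion` and `acceptVA`.
#' @export
qcFilter <- function(results, cvLimit = 100) {
  cvF <- vapply(results, function(r) r@cv[["F"]], numeric(1))
  cvA <- vapply(results, function(r) r@cv[["VA"]], numeric(1))
  data.frame(acceptPerfusion = !is.na(cvF) & cvF <= cvLimit,
             acceptVA = !is.na(cvA) & cvA <= cvLimit)
}
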