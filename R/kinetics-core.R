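# Shared numerics for compartment-model forward computation. All convolution
# and integration routines treat the sampled input as a piecewise-linear
# function of time, for which they are exact (up to round-off); accuracy is
# then governed solely by how finely the input resolves the bolus.

# y(t) = int_0^t u(s) exp(-k (t - s)) ds for piecewise-linear u on a uniform
# grid with step dt. Exact per-segment integration, evaluated by a linear
# recurrence (stats::filter).
expConvLinear <- function(u, dt, k) {
  n <- length(u)
  if (n == 0L) return(numeric(0))
  kd <- k * dt
  if (kd < 1e-7) {
    # series expansion of the segment weights to avoid cancellation
    phi2 <- dt * (0.5 - kd / 6 + kd^2 / 24)
    phi1 <- dt * (0.5 - kd / 3 + kd^2 / 8)
    E <- exp(-kd)
  } else {
    E <- exp(-kd)
    one_E <- -expm1(-kd)
    phi2 <- (kd + expm1(-kd)) / (k * kd)   # 1/k - (1-E)/(k^2 dt)
    phi1 <- one_E / k - phi2
  }
  b <- phi1 * u[-n] + phi2 * u[-1L]
  c(0, as.numeric(stats::filter(b, E, method = "recursive")))
}

# cumulative trapezoidal integral on a uniform grid
cumTrapz <- function(u, dt) {
  n <- length(u)
  c(0, cumsum((u[-n] + u[-1L]) * dt / 2))
}

# Average an instantaneous curve y(t), tabulated on the uniform grid t, over
# each frame of a schedule. Uses the exact integral of the piecewise-linear
# interpolant between frame boundaries.
frameAverage <- function(t, y, schedule) {
  dt <- t[2L] - t[1L]
  Y <- cumTrapz(y, dt)
  bounds <- c(frameStart(schedule), frameEnd(schedule))
  if (min(bounds) < t[1L] - 1e-9 || max(bounds) > t[length(t)] + 1e-9)
    stop("curve grid does not cover the frame schedule")
  # exact integral of the linear interpolant up to an off-grid point
  intAt <- function(tb) {
    i <- pmin(pmax(floor((tb - t[1L]) / dt) + 1, 1), length(t) - 1L)
    h <- tb - t[i]
    Y[i] + y[i] * h + (y[i + 1L] - y[i]) * h^2 / (2 * dt)
  }
  nf <- nFrames(schedule)
  b <- intAt(bounds)
  (b[(nf + 1L):(2L * nf)] - b[1:nf]) / frameDuration(schedule)
}

# Sample a blood curve on a uniform grid after shifting it by `delay`
# seconds (positive delay moves the curve later). Times before the first
# sample are taken as zero activity; times beyond the last sample are an
# error because the fit window would be uncovered.
sampleShiftedCurve <- function(curve, tgrid, delay = 0) {
  tq <- tgrid - delay
  tc <- curveTime(curve)
  if (max(tq) > max(tc) + 1e-6)
    stop("input curve does not cover the fit window after delay shift")
  out <- stats::approx(tc, curveActivity(curve), xout = tq,
                       yleft = 0, rule = 2)$y
  out
}

# Uniform fine grid covering a schedule (and t = 0), with step no larger
# than the input curve's own sampling.
fineGrid <- function(curve, schedule, dtMax = 1) {
  dt <- min(min(diff(curveTime(curve))), dtMax)
  t0 <- min(0, frameStart(schedule)[1L], curveTime(curve)[1L])
  t1 <- scanEnd(schedule)
  n <- ceiling((t1 - t0) / dt)   # uniform grid ending exactly at t1
  seq(t0, t1, length.out = n + 1L)
}
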