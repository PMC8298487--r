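# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: closed forms, brute-force loops and
# full enumerations at tiny n.

# frame-averaged 1TCM prediction for a mono-exponential input
# C_A(t) = A exp(-a t), delay 0, via the analytic convolution integral
oracle1tcmExpInput <- function(F, VT, VA, A, a, schedule) {
  Fp <- F / 100 / 60; VTp <- VT / 100; VAp <- VA / 100
  k <- Fp / VTp
  intExp <- function(r, t0, t1) {
    if (abs(r) < 1e-14) t1 - t0 else (exp(-r * t0) - exp(-r * t1)) / r
  }
  mapply(function(ts, te) {
    (VAp * A * intExp(a, ts, te) +
       (1 - VAp) * Fp * A *
         (intExp(k, ts, te) - intExp(a, ts, te)) / (a - k)) / (te - ts)
  }, frameStart(schedule), frameEnd(schedule))
}

# per-frame mean over mask voxels by an explicit loop
oracleMaskMean <- function(arr4d, mask) {
  nf <- dim(arr4d)[4]
  out <- numeric(nf)
  idx <- which(mask, arr.ind = TRUE)
  for (f in seq_len(nf)) {
    s <- 0
    for (r in seq_len(nrow(idx)))
      s <- s + arr4d[idx[r, 1], idx[r, 2], idx[r, 3], f]
    out[f] <- s / nrow(idx)
  }
  out
}

# exact two-sided signed-rank p by explicit enumeration of all sign vectors
oracleWilcoxonP <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    vs[m + 1] <- sum(r[signs == 1])
  }
  pLow <- mean(vs <= v + 1e-9)
  pHigh <- mean(vs >= v - 1e-9)
  min(1, 2 * min(pLow, pHigh))
}

# exact two-sided Spearman permutation p by full enumeration of orderings
oracleSpearmanP <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- gtoolsPermutations(n)
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  mean(abs(rhos) >= obs - 1e-12)
}

# all permutations of 1..n, written independently of the package internals
gtoolsPermutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  out <- NULL
  sub <- gtoolsPermutations(n - 1)
  for (i in 1:n) {
    rest <- (1:n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

# continuous nonlinear least squares for the irreversible 2TCM basis model:
# minimize over (theta1, theta2, beta) with beta free (not on a grid).
# Coarse log-beta scan followed by 1-D minimization, with profiled linear
# non-negative (theta1, theta2).
oracleBruteKi <- function(y, input, schedule, betaLim = c(0.005, 2)) {
  tac1 <- tacActivity(model2tcmIrr(1, 0, 1, input, schedule))
  solveAt <- function(beta) {
    tacB <- tacActivity(model2tcmIrr(1, beta, 0, input, schedule))
    A <- cbind(tac1, tacB)
    th <- tryCatch(pmax(qr.solve(A, y), 0), error = function(e) c(0, 0))
    list(th = th, rss = sum((y - A %*% th)^2))
  }
  prof <- function(logBeta) solveAt(exp(logBeta))$rss
  scan <- seq(log(betaLim[1]), log(betaLim[2]), length.out = 25)
  vals <- vapply(scan, prof, numeric(1))
  i <- which.min(vals)
  lo <- scan[max(i - 1, 1)]; hi <- scan[min(i + 1, length(scan))]
  o <- optimize(prof, interval = c(lo, hi), tol = 1e-8)
  sol <- solveAt(exp(o$minimum))
  list(ki = sol$th[1], theta2 = sol$th[2], beta = exp(o$minimum),
       rss = sol$rss)
}

# small default schedules used throughout
waterSchedule <- function() parseFrameSchedule("1x10,8x5,4x10,2x15,3x20,2x30,6x60")
fdgSchedule <- function() parseFrameSchedule(
  "1x10,8x5,4x10,2x15,3x20,2x30,6x60,4x150,5x300")
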