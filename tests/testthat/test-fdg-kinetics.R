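test_that("basis betas are log-spaced with exact endpoints", {
  input <- genInputFdg(fdgSchedule())
  basis <- buildBasis(input, fdgSchedule())
  b <- basisBetas(basis)
  expect_length(b, 50)
  expect_equal(b[1], 0.02)
  expect_equal(b[50], 1.0)
  ratios <- b[-1] / b[-50]
  expect_lt(max(abs(ratios - (1.0 / 0.02)^(1 / 49))), 1e-12)
})

test_that("a whole-blood input is rejected for the glucose pathway", {
  wb <- genInputWater(fdgSchedule())
  expect_error(buildBasis(wb, fdgSchedule()), "plasma")
})

test_that("the beta = 1 convolution basis matches the analytic form for an exponential input", {
  sched <- fdgSchedule()
  a <- 0.002                      # per second
  tg <- seq(0, 2760, by = 0.25)
  input <- bloodCurve(tg, 30 * exp(-a * tg), kind = "plasma")
  basis <- buildBasis(input, sched)
  amin <- a * 60; beta <- 1.0
  iE <- function(r, t0, t1) if (abs(r) < 1e-14) (t1 - t0)
                            else (exp(-r * t0) - exp(-r * t1)) / r
  ana <- mapply(function(ts, te) {
    30 * (iE(amin, ts / 60, te / 60) - iE(beta, ts / 60, te / 60)) /
      (beta - amin) / ((te - ts) / 60)
  }, frameStart(sched), frameEnd(sched))
  expect_lt(max(abs(basisMatrix(basis)[, 51] - ana)) / max(ana), 1e-4)
  # zero input gives zero bases
  z <- buildBasis(bloodCurve(tg, rep(0, length(tg)), kind = "plasma"),
                  sched)
  expect_true(all(basisMatrix(z) == 0))
})

test_that("K_i recovers the analytic K1 k3/(k2+k3) on noiseless data", {
  sched <- fdgSchedule()
  input <- genInputFdg(sched)
  basis <- buildBasis(input, sched)
  tac <- model2tcmIrr(0.1, 0.2, 0.05, input, sched)
  fit <- fitKi(tac, basis)
  expect_lt(abs(kiValue(fit) - 0.02) / 0.02, 0.01)
  expect_lt(abs(fit@beta - 0.25) / 0.25, 0.1)
  # no trapping: K_i vanishes up to beta-grid quantization
  tac0 <- model2tcmIrr(0.1, 0.2, 0, input, sched)
  expect_lt(kiValue(fitKi(tac0, basis)), 2e-4)
  # zero TAC short-circuits
  z <- fitKi(regionTAC(sched, rep(0, nFrames(sched))), basis)
  expect_equal(kiValue(z), 0)
  expect_equal(z@rss, 0)
})

test_that("K_i is accurate across the physiologic beta range (random draws)", {
  sched <- fdgSchedule()
  input <- genInputFdg(sched)
  basis <- buildBasis(input, sched)
  set.seed(411)
  for (i in 1:15) {
    K1 <- runif(1, 0.02, 0.3)
    beta <- runif(1, 0.03, 0.85)
    k3 <- runif(1, 0.1, 0.5) * beta
    k2 <- beta - k3
    kiTrue <- K1 * k3 / beta
    # with beta refinement the quantization error disappears
    fit <- fitKi(model2tcmIrr(K1, k2, k3, input, sched), basis)
    expect_lt(abs(kiValue(fit) - kiTrue) / kiTrue, 1e-3)
    expect_lt(abs(fit@beta - beta) / beta, 0.01)
    # the grid-only stage stays within one grid step's induced error
    gfit <- fitKi(model2tcmIrr(K1, k2, k3, input, sched), basis,
                  refineBeta = FALSE)
    expect_lt(abs(kiValue(gfit) - kiTrue) / kiTrue, 0.08)
  }
})

test_that("fitKi is scale-equivariant", {
  sched <- fdgSchedule()
  input <- genInputFdg(sched)
  basis <- buildBasis(input, sched)
  tac <- tacActivity(model2tcmIrr(0.08, 0.25, 0.06, input, sched))
  f1 <- fitKi(regionTAC(sched, tac), basis)
  f2 <- fitKi(regionTAC(sched, 3.7 * tac), basis)
  expect_equal(kiValue(f2), 3.7 * kiValue(f1), tolerance = 1e-9)
  expect_equal(f2@theta2, 3.7 * f1@theta2, tolerance = 1e-9)
  expect_equal(f2@beta, f1@beta)
})

test_that("Patlak slope cross-checks K_i on late noiseless data", {
  sched <- fdgSchedule()
  input <- genInputFdg(sched)
  K1 <- 0.1; k2 <- 0.2; k3 <- 0.05
  kiTrue <- K1 * k3 / (k2 + k3)
  tac <- tacActivity(model2tcmIrr(K1, k2, k3, input, sched))
  # Patlak: C(t)/C_P(t) vs int C_P / C_P is linear with slope K_i at late t
  tg <- seq(0, 2700, by = 0.5)
  cp <- approx(curveTime(input), curveActivity(input), xout = tg,
               yleft = 0, rule = 2)$y
  intcp <- cumsum(c(0, (cp[-1] + cp[-length(cp)]) / 2 * 0.5)) / 60
  mid <- frameMid(sched)
  late <- which(mid > 1200)
  cpf <- approx(tg, cp, xout = mid[late])$y
  xf <- approx(tg, intcp, xout = mid[late])$y / cpf
  yf <- tac[late] / cpf
  slope <- coef(lm(yf ~ xf))[2]
  expect_lt(abs(slope - kiTrue) / kiTrue, 0.05)
})

test_that("basis residual is no worse than a continuous brute-force fit", {
  sched <- fdgSchedule()
  input <- genInputFdg(sched)
  basis <- buildBasis(input, sched)
  set.seed(412)
  for (i in 1:5) {
    K1 <- runif(1, 0.03, 0.2)
    beta <- runif(1, 0.05, 0.8)
    k3 <- runif(1, 0.15, 0.45) * beta
    k2 <- beta - k3
    y <- tacActivity(model2tcmIrr(K1, k2, k3, input, sched))
    gridFit <- fitKi(regionTAC(sched, y), basis)
    brute <- oracleBruteKi(y, input, sched)
    # allow for the brute-force optimizer itself being imperfect
    expect_lte(gridFit@rss, max(1.05 * brute$rss, 1e-10))
  }
})

test_that("voxelwise K_i maps equal the per-voxel loop exactly", {
  sched <- fdgSchedule()
  input <- genInputFdg(sched)
  basis <- buildBasis(input, sched)
  dims <- c(4, 4, 2)
  mask <- array(FALSE, dims); mask[1:3, 1:3, ] <- TRUE
  set.seed(413)
  nf <- nFrames(sched)
  base <- tacActivity(model2tcmIrr(0.1, 0.2, 0.05, input, sched))
  data <- array(0, c(dims, nf))
  flat <- matrix(data, ncol = nf)
  for (v in which(mask))
    flat[v, ] <- base * runif(1, 0.2, 2) + rnorm(nf, 0, 0.3)
  img <- dynamicImage(array(flat, c(dims, nf)), sched)
  kmap <- kiImage(img, basis, mask = mask)
  for (v in which(mask)) {
    ref <- kiValue(fitKi(flat[v, ], basis, refineBeta = FALSE))
    expect_equal(kmap[v], ref, tolerance = 1e-10)
  }
  expect_true(all(is.na(kmap[!mask])))
  # two-compartment phantom: region means recover truth
  phantom <- genDynamicImage(
    list(a = array(c(TRUE, FALSE), dims), b = array(c(FALSE, TRUE), dims)),
    list(a = list(type = "fdg", K1 = 0.1, k2 = 0.2, k3 = 0.05),
         b = list(type = "fdg", K1 = 0.05, k2 = 0.2, k3 = 0)),
    input, sched, noise = 0)
  km <- kiImage(phantom, basis)
  expect_lt(abs(mean(km[array(c(TRUE, FALSE), dims)]) - 0.02) / 0.02, 0.02)
  expect_lt(mean(km[array(c(FALSE, TRUE), dims)]), 2e-4)
})

test_that("MR_glu follows the declared unit convention", {
  expect_equal(computeMrglu(0.002, 5.0), 1.0)
  expect_equal(computeMrglu(0, 5.0), 0)
  expect_equal(computeMrglu(0.002, 5.0, LC = 2), 0.5)
  # linear in K_i, zero-preserving on arrays
  ki <- array(c(0, 0.01, 0.02, 0), c(2, 2, 1))
  g <- glucoseRecord(4.5, 5.0, ratio = 1.1)
  m <- computeMrglu(ki, g)
  expect_equal(dim(m), dim(ki))
  expect_equal(m[ki == 0], c(0, 0))
  expect_equal(computeMrglu(2 * ki, g), 2 * m)
  # the plasma mean uses the 1.1 conversion of both samples
  expect_equal(meanPlasmaGlucose(g), (4.5 + 5.0) * 1.1 / 2)
  # laboratory plasma variant
  g2 <- glucoseRecord(4.5, 5.0, p2 = 6.0)
  expect_equal(computeMrglu(0.01, g2, useP2 = TRUE), 6.0 * 0.01 * 100)
  expect_error(computeMrglu(0.01, g, useP2 = TRUE), "laboratory")
})
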