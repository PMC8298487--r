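test_that("forward 1TCM matches the analytic convolution for an exponential input", {
  sched <- waterSchedule()
  A <- 50; a <- 0.01
  tg <- seq(0, 620, by = 0.01)
  input <- bloodCurve(tg, A * exp(-a * tg))
  for (p in list(c(18.3, 70, 7.3), c(5, 40, 2), c(45, 85, 12))) {
    mod <- tacActivity(model1tcm(p[1], p[2], p[3], 0, input, sched))
    ana <- oracle1tcmExpInput(p[1], p[2], p[3], A, a, sched)
    expect_lt(max(abs(mod - ana) / ana), 1e-8)
  }
})

test_that("degenerate parameter values give the expected identities", {
  sched <- waterSchedule()
  input <- genInputWater(sched)
  expect_true(all(tacActivity(model1tcm(0, 70, 0, 0, input, sched)) == 0))
  # a pure-blood voxel: V_A = 100, F = 0 reproduces the frame-averaged
  # delayed input
  pure <- tacActivity(model1tcm(0, 70, 100, 5, input, sched))
  tg <- seq(0, 600, by = 0.5)
  ca <- approx(curveTime(input), curveActivity(input), xout = tg - 5,
               yleft = 0, rule = 2)$y
  ends <- c(frameStart(sched), 600)
  ref <- vapply(seq_len(nFrames(sched)), function(i) {
    sel <- tg >= ends[i] & tg <= ends[i + 1]
    mean(ca[sel])
  }, numeric(1))
  expect_lt(max(abs(pure - ref)), 0.05 * max(ref))
})

test_that("forward model is monotone increasing in V_A", {
  sched <- waterSchedule()
  input <- genInputWater(sched)
  vas <- c(0, 2, 5, 10, 20)
  tacs <- vapply(vas, function(v)
    sum(tacActivity(model1tcm(10, 60, v, 3, input, sched))), numeric(1))
  expect_true(all(diff(tacs) > 0))
})

test_that("noiseless fits recover the generating parameters exactly", {
  sched <- waterSchedule()
  input <- genInputWater(sched)
  set.seed(301)
  for (i in 1:8) {
    F <- runif(1, 2, 60); VT <- runif(1, 30, 90)
    VA <- runif(1, 0.3, 15); D <- runif(1, 0, 20)
    tac <- model1tcm(F, VT, VA, D, input, sched)
    fit <- fit1tcm(tac, input)
    est <- fitEstimates(fit)
    expect_true(fitConverged(fit))
    expect_lt(abs(est["F"] - F) / F, 1e-3)
    expect_lt(abs(est["VT"] - VT) / VT, 1e-3)
    expect_lt(abs(est["VA"] - VA) / VA, 1e-3)
    expect_lt(abs(est["delay"] - D), 0.1)
  }
})

test_that("at the V_A -> 0 identifiability boundary the fit still reproduces the data", {
  # with essentially no blood component, V_A and delay trade off below
  # machine precision; the fit must still match the TAC and nail F and V_T
  sched <- waterSchedule()
  input <- genInputWater(sched)
  tac <- model1tcm(25, 60, 0, 8, input, sched)
  fit <- fit1tcm(tac, input)
  est <- fitEstimates(fit)
  expect_lt(abs(est["F"] - 25) / 25, 0.01)
  expect_lt(abs(est["VT"] - 60) / 60, 0.01)
  expect_lt(est["VA"], 0.3)
  pred <- tacActivity(model1tcm(est["F"], est["VT"], est["VA"],
                                est["delay"], input, sched))
  expect_lt(max(abs(pred - tacActivity(tac))), 1e-6 * max(tacActivity(tac)))
})

test_that("a shifted input is attributed to the delay parameter", {
  sched <- waterSchedule()
  input <- genInputWater(sched)
  tac <- model1tcm(18.3, 70, 7.3, 10, input, sched)
  fit <- fit1tcm(tac, input)
  expect_lt(abs(fitEstimates(fit)["delay"] - 10), 0.5)
})

test_that("all-zero TACs flag as degenerate, not as a fit", {
  sched <- waterSchedule()
  input <- genInputWater(sched)
  fit <- fit1tcm(regionTAC(sched, rep(0, 26)), input)
  expect_true(fitDegenerate(fit))
  expect_true(is.na(fitEstimates(fit)["F"]))
})

test_that("fit CVs scale sensibly with noise and feed the QC filter", {
  sched <- waterSchedule()
  input <- genInputWater(sched)
  truth <- tacActivity(model1tcm(18.3, 70, 7.3, 5, input, sched))
  set.seed(99)
  noisy <- regionTAC(sched, truth * (1 + rnorm(26, 0, 0.05)))
  fit <- fit1tcm(noisy, input)
  cv <- fitCV(fit)
  expect_true(all(cv[c("F", "VA")] > 0))
  expect_lt(cv[["F"]], 100)
})

test_that("QC acceptance is independent for perfusion and V_A", {
  mk <- function(cvF, cvVA) new("WaterFitResult",
    estimates = c(F = 10, VT = 60, VA = 5, delay = 3),
    cv = c(F = cvF, VT = 10, VA = cvVA, delay = 5), rss = 1,
    converged = TRUE, degenerate = FALSE, window = 180)
  res <- qcFilter(list(mk(30, 150), mk(0, 0), mk(120, 40)))
  expect_equal(res$acceptPerfusion, c(TRUE, TRUE, FALSE))
  expect_equal(res$acceptVA, c(FALSE, TRUE, TRUE))
  strict <- qcFilter(list(mk(30, 150), mk(0, 0)), cvLimit = 0)
  expect_equal(strict$acceptPerfusion, c(FALSE, TRUE))
})
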