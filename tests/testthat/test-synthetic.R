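smallConfig <- function(...) generatorConfig(gridDim = c(8, 8, 4), ...)

test_that("water input is a non-negative bolus peaking inside the first minute", {
  sched <- waterSchedule()
  cur <- genInputWater(sched)
  act <- curveActivity(cur)
  expect_true(all(act >= 0))
  tPeak <- curveTime(cur)[which.max(act)]
  expect_lt(tPeak, 60)
  # peak at the analytic gamma-variate mode t0 + tp
  expect_equal(tPeak, 12 + 18, tolerance = 1)
  # dose linearity and the zero-dose identity
  expect_equal(curveActivity(genInputWater(sched, dose = 2)), 2 * act)
  expect_true(all(curveActivity(genInputWater(sched, dose = 0)) == 0))
})

test_that("FDG input is non-negative, integrable, and decays after the peak", {
  sched <- fdgSchedule()
  cur <- genInputFdg(sched)
  act <- curveActivity(cur)
  expect_true(all(act >= 0))
  expect_true(all(is.finite(act)))
  ip <- which.max(act)
  late <- act[seq(ip + 240, length(act), by = 120)]
  expect_true(all(diff(late) < 0))
})

test_that("noiseless dynamic images carry the exact forward model", {
  sched <- waterSchedule()
  input <- genInputWater(sched)
  dims <- c(4, 4, 2)
  m1 <- array(FALSE, dims); m1[1:2, , ] <- TRUE
  m2 <- array(FALSE, dims); m2[3:4, , ] <- TRUE
  img <- genDynamicImage(
    list(t = m1, b = m2),
    list(t = list(type = "water", F = 18.3, VT = 70, VA = 7.3, delay = 5),
         b = list(type = "blood")),
    input, sched, noise = 0)
  ref <- tacActivity(model1tcm(18.3, 70, 7.3, 5, input, sched))
  expect_equal(tacActivity(extractVoiTac(img, m1)), ref, tolerance = 1e-12)
  # fitting the noiseless image recovers the truth (pipeline round-trip)
  fit <- fit1tcm(extractVoiTac(img, m1), input)
  expect_lt(abs(fitEstimates(fit)["F"] - 18.3) / 18.3, 1e-3)
  expect_lt(abs(fitEstimates(fit)["VA"] - 7.3) / 7.3, 1e-3)
})

test_that("image noise variance scales with activity over frame duration", {
  sched <- frameSchedule(c(0, 10), c(10, 40))
  input <- bloodCurve(seq(0, 60, 0.5), rep(20, 121))
  dims <- c(30, 30, 2)
  mask <- array(TRUE, dims)
  set.seed(61)
  img <- genDynamicImage(list(b = mask), list(b = list(type = "blood")),
                         input, sched, noise = 0.4)
  flat <- matrix(imageData(img), ncol = 2)
  v1 <- var(flat[, 1]); v2 <- var(flat[, 2])
  # equal activity, 4x duration -> 4x smaller variance
  expect_equal(v1 / v2, 4, tolerance = 0.35)
  expect_equal(v1, 0.4^2 * 20 * 60 / 10, tolerance = 0.15 * v1)
})

test_that("multi-echo generation round-trips through the separation", {
  ffs <- c(0, 35, 80)
  et <- genMultiecho(ffs, psi = 25, r2star = 45)
  res <- separateWaterFat(et)
  expect_lt(max(abs(ffValues(res) - ffs)), 0.3)
  # FF = 0 voxel: magnitude decays purely by R2*
  et0 <- genMultiecho(0, psi = 30, r2star = 50)
  mags <- Mod(et0@signal[1, ])
  expect_equal(mags, exp(-50 * et0@te), tolerance = 1e-12)
})

test_that("a fixed seed reproduces the cohort exactly", {
  c1 <- genCohort(smallConfig(nSubjects = 2), seed = 5)
  c2 <- genCohort(smallConfig(nSubjects = 2), seed = 5)
  expect_identical(c1$truth, c2$truth)
  expect_identical(imageData(c1$subjects[[1]]$water$baseline),
                   imageData(c2$subjects[[1]]$water$baseline))
  expect_identical(c1$subjects[[2]]$echoes$cooling$cold1@signal,
                   c2$subjects[[2]]$echoes$cooling$cold1@signal)
  c3 <- genCohort(smallConfig(nSubjects = 2), seed = 6)
  expect_false(identical(c1$truth, c2$truth) &&
                 identical(imageData(c1$subjects[[1]]$water$baseline),
                           imageData(c3$subjects[[1]]$water$baseline)))
})

test_that("truth parameters respect the physiologic bounds", {
  coh <- genCohort(smallConfig(nSubjects = 12), seed = 8)
  tt <- coh$truth
  expect_true(all(tt$F_baseline >= 2 & tt$F_baseline <= 60))
  expect_true(all(tt$VA_cold >= 0.3 & tt$VA_cold <= 15))
  expect_true(all(tt$FF_baseline >= 40 & tt$FF_baseline <= 95))
  expect_true(all(tt$Ki_sBAT > 0))
})

test_that("cohort effect sizes and FF-MRglu coupling match the configured targets", {
  # aggregate across several small cohorts for a stable Monte-Carlo check
  dFF <- NULL; dVA <- NULL; ffB <- NULL; mr <- NULL
  for (seed in 1:6) {
    tt <- genCohort(smallConfig(nSubjects = 12), seed = seed)$truth
    dFF <- c(dFF, tt$FF_cold1 - tt$FF_baseline)
    dVA <- c(dVA, tt$VA_cold - tt$VA_baseline)
    ffB <- c(ffB, tt$FF_baseline); mr <- c(mr, tt$mrglu_sBAT)
  }
  n <- length(dFF)
  expect_lt(abs(mean(dFF) - (-2.13)), 3 * sd(dFF) / sqrt(n))
  expect_lt(abs(mean(dVA) - 4.0), 3 * sd(dVA) / sqrt(n) + 0.3)
  rho <- cor(ffB, mr, method = "spearman")
  expect_lt(abs(rho - (-0.88)), 0.1)
})

test_that("the generated reheated scan supports background estimation", {
  coh <- genCohort(smallConfig(nSubjects = 1), seed = 9)
  sub <- coh$subjects[[1]]
  tac <- extractVoiTac(sub$water$reheated, coh$masks$sBAT)
  est <- estimateBackground(tac, kind = "exponential")
  expect_equal(est$background@t0, -30)
  expect_equal(est$background@t1, 1230)
  # anchors near the generated background level (noise permitting)
  expect_equal(est$background@b0, sub$truth$background["b0"],
               tolerance = 0.5, ignore_attr = TRUE)
  expect_equal(nFrames(tacSchedule(est$main)), 26)
})

test_that("writeCohort emits the documented file tree", {
  d <- withr::local_tempdir()
  coh <- genCohort(smallConfig(nSubjects = 1), seed = 10)
  writeCohort(coh, d)
  expect_true(file.exists(file.path(d, "mask_sBAT.nii.gz")))
  expect_true(file.exists(file.path(d, "truth.csv")))
  expect_true(file.exists(file.path(d, "tes.json")))
  sd <- file.path(d, "sub-01")
  expect_true(file.exists(file.path(sd, "water_baseline.nii.gz")))
  expect_true(file.exists(file.path(sd, "water_baseline_frames.json")))
  expect_true(file.exists(file.path(sd, "fdg_cold.nii.gz")))
  expect_true(file.exists(file.path(sd, "me_cooling_cold1_real.nii.gz")))
  expect_true(file.exists(file.path(sd, "study.yaml")))
  # the written water image round-trips
  img <- readDynamicImage(file.path(sd, "water_baseline.nii.gz"),
                          file.path(sd, "water_baseline_frames.json"))
  expect_equal(imageData(img),
               imageData(coh$subjects[[1]]$water$baseline),
               tolerance = 1e-6, ignore_attr = TRUE)
})
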