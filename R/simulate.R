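# Synthetic-data generator. Produces ground-truth-known arterial input
# functions, dynamic PET images under 1TCM/2TCM kinetics, multi-echo
# water-fat MRI and a full 12-subject four-condition cohort whose fat
# fraction is negatively coupled to the metabolic rate of glucose. Defaults
# are anchored to the study's group means and dispersions; a fixed seed
# fixes the entire dataset.

# truncated normal via inverse-CDF (exactly one uniform draw per variate,
# which keeps the RNG stream layout stable)
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Synthetic arterial input functions
#'
#' `genInputWater` builds a gamma-variate bolus with an exponential
#' recirculation tail on a fine grid, peaking inside the first minute (the
#' injections were fast boluses). `genInputFdg` uses a tri-exponential
#' (Feng-type) plasma model appropriate for a 45 min scan. Both are
#' deterministic given their arguments.
#'
#' @param schedule a [FrameSchedule-class]; the curve covers it with margin.
#' @param dose dose scale (multiplies the whole curve).
#' @param dt grid step in seconds.
#' @param t0 tracer arrival time (s).
#' @param alpha,tp gamma-variate shape and time-to-peak (s); the bolus mode
#'   is at `t0 + tp`.
#' @param peak bolus peak activity (kBq/ml) at `dose = 1`.
#' @return A whole-blood (`genInputWater`) or plasma (`genInputFdg`)
#'   [BloodCurve-class].
#' @export
genInputWater <- function(schedule, dose = 1, dt = 0.5, t0 = 12,
                          alpha = 2.5, tp = 18, peak = 60) {
  tEnd <- scanEnd(schedule) + 60
  t <- seq(0, tEnd, by = dt)
  u <- pmax(t - t0, 0)
  bolus <- ifelse(u > 0, (u / tp)^alpha * exp(alpha * (1 - u / tp)), 0)
  recirc <- 0.15 * (1 - exp(-u / 40)) * exp(-u / 350)
  bloodCurve(t, dose * peak * (bolus + recirc), kind = "wholeblood")
}

#' @rdname genInputWater
#' @export
genInputFdg <- function(schedule, dose = 1, dt = 0.5, t0 = 30) {
  tEnd <- scanEnd(schedule) + 60
  t <- seq(0, tEnd, by = dt)
  tm <- pmax(t - t0, 0) / 60   # minutes since arrival
  # tri-exponential plasma model, scaled to a realistic aorta peak
  A1 <- 851.1; A2 <- 21.9; A3 <- 20.8
  l1 <- -4.134; l2 <- -0.1191; l3 <- -0.0104
  cp <- (A1 * tm - A2 - A3) * exp(l1 * tm) + A2 * exp(l2 * tm) +
    A3 * exp(l3 * tm)
  cp <- pmax(cp, 0) * ifelse(t > t0, 1, 0)
  bloodCurve(t, dose * cp / 2, kind = "plasma")
}

#' Generate a dynamic PET image from known kinetics
#'
#' Every voxel of a region follows the frame-averaged forward model of that
#' region's kinetic parameters; aorta-type regions carry the pure input
#' (a 100% blood voxel). An optional residual-FDG background is added to the
#' tissue regions. Noise is additive Gaussian, either with variance
#' proportional to activity / frame duration (`"scaled"`, the count-rate
#' heuristic) or proportional to the activity itself (`"proportional"`).
#'
#' @param regions named list of logical 3D masks (disjoint).
#' @param params named list (same names) of kinetic descriptions: either
#'   `list(type = "water", F, VT, VA, delay)`,
#'   `list(type = "fdg", K1, k2, k3)` (optionally `kiVoxel`, a per-voxel K_i
#'   vector replacing the region K_i while keeping beta and theta2), or
#'   `list(type = "blood")`.
#' @param input a [BloodCurve-class] (whole blood for water/blood regions,
#'   plasma for FDG).
#' @param schedule a [FrameSchedule-class].
#' @param noise noise scale; 0 gives the exact forward model.
#' @param noiseModel `"scaled"` or `"proportional"`.
#' @param background optional [BackgroundModel-class] added to non-blood
#'   regions (frame-averaged).
#' @param voxelSize numeric(3), mm.
#' @return A [DynamicImage-class].
#' @export
genDynamicImage <- function(regions, params, input, schedule, noise = 0,
                            noiseModel = c("scaled", "proportional"),
                            background = NULL, voxelSize = c(4, 4, 4)) {
  noiseModel <- match.arg(noiseModel)
  dims <- dim(regions[[1L]])
  nf <- nFrames(schedule)
  img <- matrix(0, nrow = prod(dims), ncol = nf)
  bg <- if (is.null(background)) rep(0, nf)
        else backgroundFrameMeans(background, schedule)
  tgrid <- fineGrid(input, schedule)
  caF <- frameAverage(tgrid, sampleShiftedCurve(input, tgrid, 0), schedule)
  for (nm in names(regions)) {
    idx <- which(regions[[nm]])
    if (length(idx) == 0L) next
    p <- params[[nm]]
    tacs <- switch(p$type,
      blood = matrix(caF, nrow = length(idx), ncol = nf, byrow = TRUE),
      water = {
        m <- tacActivity(model1tcm(p$F, p$VT, p$VA, p$delay, input,
                                   schedule)) + bg
        matrix(m, nrow = length(idx), ncol = nf, byrow = TRUE)
      },
      fdg = {
        beta <- p$k2 + p$k3
        th2 <- p$K1 * p$k2 / beta
        b1 <- tacActivity(model2tcmIrr(1, 0, 1, input, schedule))  # pure integral
        bb <- tacActivity(model2tcmIrr(0.5, beta, 0, input, schedule)) /
          (0.5)  # conv basis with unit theta2
        ki <- if (!is.null(p$kiVoxel)) p$kiVoxel
              else rep(p$K1 * p$k3 / beta, length(idx))
        outer(ki, b1) + matrix(th2 * bb + bg, nrow = length(idx),
                               ncol = nf, byrow = TRUE)
      },
      stop("unknown region type: ", p$type))
    img[idx, ] <- tacs
  }
  if (noise > 0) {
    sd <- switch(noiseModel,
      scaled = noise * sqrt(pmax(img, 0) *
        matrix(60 / frameDuration(schedule), nrow = nrow(img), ncol = nf,
               byrow = TRUE)),
      proportional = noise * abs(img))
    img <- img + stats::rnorm(length(img), 0, 1) * sd
  }
  dynamicImage(array(img, dim = c(dims, nf)), schedule,
               voxelSize = voxelSize)
}

#' Generate a multi-echo water-fat signal
#'
#' Exact forward model of the separation signal equation, optionally with
#' complex Gaussian noise.
#'
#' @param ff fat fraction in percent (vector, one per voxel).
#' @param psi field map in Hz (scalar or per voxel).
#' @param r2star R2* in 1/s (scalar or per voxel).
#' @param te echo times in seconds.
#' @param spectrum a [FatSpectrum-class].
#' @param s0 total magnitude at TE = 0 (scalar or per voxel).
#' @param snr signal-to-noise ratio s0 / (noise SD per channel); Inf for
#'   noiseless.
#' @param phase0 global phase in radians.
#' @return An [EchoTrain-class] (voxels x echoes).
#' @export
genMultiecho <- function(ff, psi = 0, r2star = 0, te = studyEchoTimes(),
                         spectrum = fatSpectrum(), s0 = 1, snr = Inf,
                         phase0 = 0) {
  nVox <- length(ff)
  psi <- rep_len(psi, nVox); r2star <- rep_len(r2star, nVox)
  s0 <- rep_len(s0, nVox)
  f <- fatPhasor(spectrum, te)
  W <- s0 * (1 - ff / 100); Fm <- s0 * ff / 100
  base <- outer(W, rep(1 + 0i, length(te))) + outer(Fm, f)
  mod <- exp(outer(2i * pi * psi - r2star, te)) * exp(1i * phase0)
  S <- base * mod
  if (is.finite(snr) && snr > 0) {
    sd <- mean(s0) / snr
    S <- S + complex(real = stats::rnorm(length(S), 0, sd),
                     imaginary = stats::rnorm(length(S), 0, sd))
  }
  echoTrain(te, S)
}

#' Generator configuration
#'
#' Study conditions of the synthetic cohort: sample size, geometry, noise
#' levels and the condition effect sizes (anchored to the study's group
#' means and dispersions). The fat fraction is coupled to the metabolic rate
#' of glucose through a latent per-subject score that simultaneously raises
#' K_i and lowers FF, targeting a Spearman correlation of about -0.88.
#'
#' @param nSubjects cohort size (default 12).
#' @param gridDim image grid (default 32 x 32 x 16).
#' @param voxelSize voxel size in mm.
#' @param petNoise noise scale of the dynamic images ("scaled" model).
#' @param mriSnr multi-echo SNR.
#' @param pilotSubject subject whose cooling-protocol MRI uses the pilot
#'   sequence (FF offset +3.9 pp, corrected during analysis); 0 for none.
#' @param ... overrides for the effect-size fields (see the function body).
#' @return named list of generator settings.
#' @export
generatorConfig <- function(nSubjects = 12, gridDim = c(32, 32, 16),
                            voxelSize = c(4, 4, 4), petNoise = 0.5,
                            mriSnr = 50, pilotSubject = 1, ...) {
  cfg <- list(
    nSubjects = nSubjects, gridDim = gridDim, voxelSize = voxelSize,
    petNoise = petNoise, mriSnr = mriSnr, pilotSubject = pilotSubject,
    # water kinetics (ml/100 cm^3/min, ml/100 cm^3, s)
    perfBase = c(mean = 13.2, sd = 9.3), perfLim = c(2, 60),
    dPerfCold = c(mean = 5.2, sd = 6.7),
    dPerfReheat = c(mean = 8.4, sd = 8.1), dPerfReheatSlope = 4.0,
    vaBase = c(mean = 2.9, sd = 2.0), vaLim = c(0.3, 15),
    dVACold = c(mean = 4.0, sd = 1.45), dVAColdSlope = 2.4,
    dVAReheat = c(mean = -0.5, sd = 1.8),
    vt = c(mean = 70, sd = 10), vtLim = c(30, 90),
    delayLim = c(2, 12),
    # glucose metabolism
    mrglu = c(mean = 10, sd = 7), mrgluLim = c(0.5, 50),
    mrgluSat = c(mean = 1.5, sd = 0.4), mrgluSatLim = c(0.2, 5),
    k2Lim = c(0.15, 0.35), k1OverKiLim = c(3, 6),
    gluWB = c(mean = 4.6, sd = 0.3),
    # fat fraction (percent); latent coupling slope and residual SD give
    # SD(FF) ~ 7.4 and rho(FF, MRglu) ~ -0.88
    ffBase = c(mean = 80, slope = -6.5, sd = 3.5), ffLim = c(40, 95),
    ffSat = c(mean = 84.8, sd = 5.4), ffSatLim = c(60, 95),
    dFFCold1 = c(mean = -2.13, slope = -1.8, sd = 1.7),
    dFFCold2 = c(mean = -2.17, slope = -2.2, sd = 2.3),
    dFFReheat = c(mean = -1.24, slope = -1.0, sd = 2.0),
    dFFSat = c(cold1 = 0.47, cold2 = -0.15, reheated = -0.43, sd = 0.9),
    ffRepeatSd = 1.4,   # control-vs-cooling baseline difference (pp)
    dFFControl = c(cold1 = -0.11, cold2 = -0.17, reheated = 0.30,
                   sd = 1.3),
    ffVoxelSd = 1.5, ffVoxelCoupling = -0.05,
    # residual-FDG background of the reheated water scan (kBq/ml)
    bgLevel = c(min = 1.5, max = 4), bgGrowth = c(min = 1.05, max = 1.35),
    psiSd = 20, psiGradient = 10, r2starRange = c(35, 55),
    waterFrames = "1x10,8x5,4x10,2x15,3x20,2x30,6x60",
    fdgFrames = "1x10,8x5,4x10,2x15,3x20,2x30,6x60,4x150,5x300")
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

# rectangular masks with proportions fixed relative to the grid
cohortMasks <- function(gridDim) {
  box <- function(fx, fy, fz) {
    m <- array(FALSE, gridDim)
    ix <- max(1, round(fx[1] * gridDim[1])):round(fx[2] * gridDim[1])
    iy <- max(1, round(fy[1] * gridDim[2])):round(fy[2] * gridDim[2])
    iz <- max(1, round(fz[1] * gridDim[3])):round(fz[2] * gridDim[3])
    m[ix, iy, iz] <- TRUE
    m
  }
  list(sBAT = box(c(0.10, 0.35), c(0.25, 0.75), c(0.30, 0.70)),
       SAT = box(c(0.65, 0.90), c(0.25, 0.75), c(0.30, 0.70)),
       aorta = box(c(0.47, 0.53), c(0.47, 0.53), c(0.20, 0.80)))
}

# named-vector constructor that strips names inherited from config scalars
nv <- function(...) {
  args <- list(...)
  stats::setNames(vapply(args, function(z) unname(z)[1L], numeric(1)),
                  names(args))
}

# per-subject truth: all kinetic and FF parameters for every condition
genSubjectTruth <- function(cfg, id) {
  z <- stats::rnorm(1)
  perfB <- rtruncnorm(1, cfg$perfBase["mean"], cfg$perfBase["sd"],
                      cfg$perfLim[1], cfg$perfLim[2])
  perfC <- min(max(perfB + stats::rnorm(1, cfg$dPerfCold["mean"],
                                        cfg$dPerfCold["sd"]),
                   cfg$perfLim[1]), cfg$perfLim[2])
  perfR <- min(max(perfB + cfg$dPerfReheat["mean"] +
                     cfg$dPerfReheatSlope * z +
                     stats::rnorm(1, 0, cfg$dPerfReheat["sd"]),
                   cfg$perfLim[1]), cfg$perfLim[2])
  vaB <- rtruncnorm(1, cfg$vaBase["mean"], cfg$vaBase["sd"],
                    cfg$vaLim[1], cfg$vaLim[2])
  vaC <- min(max(vaB + cfg$dVACold["mean"] + cfg$dVAColdSlope * z +
                   stats::rnorm(1, 0, cfg$dVACold["sd"]),
                 cfg$vaLim[1]), cfg$vaLim[2])
  vaR <- min(max(vaB + stats::rnorm(1, cfg$dVAReheat["mean"],
                                    cfg$dVAReheat["sd"]),
                 cfg$vaLim[1]), cfg$vaLim[2])
  vt <- rtruncnorm(3, cfg$vt["mean"], cfg$vt["sd"], cfg$vtLim[1],
                   cfg$vtLim[2])
  delay <- stats::runif(1, cfg$delayLim[1], cfg$delayLim[2])

  mrglu <- min(max(cfg$mrglu["mean"] + cfg$mrglu["sd"] * z,
                   cfg$mrgluLim[1]), cfg$mrgluLim[2])
  mrgluSat <- rtruncnorm(1, cfg$mrgluSat["mean"], cfg$mrgluSat["sd"],
                         cfg$mrgluSatLim[1], cfg$mrgluSatLim[2])
  gluBefore <- rtruncnorm(1, cfg$gluWB["mean"], cfg$gluWB["sd"], 3, 7)
  gluAfter <- rtruncnorm(1, cfg$gluWB["mean"], cfg$gluWB["sd"], 3, 7)
  cglu <- (gluBefore + gluAfter) * 1.1 / 2
  ki <- mrglu / (100 * cglu)
  kiSat <- mrgluSat / (100 * cglu)
  k2 <- stats::runif(1, cfg$k2Lim[1], cfg$k2Lim[2])
  K1 <- ki * stats::runif(1, cfg$k1OverKiLim[1], cfg$k1OverKiLim[2])
  k3 <- k2 * ki / (K1 - ki)
  k2Sat <- stats::runif(1, cfg$k2Lim[1], cfg$k2Lim[2])
  K1Sat <- kiSat * stats::runif(1, cfg$k1OverKiLim[1], cfg$k1OverKiLim[2])
  k3Sat <- k2Sat * kiSat / (K1Sat - kiSat)

  ffB <- min(max(cfg$ffBase["mean"] + cfg$ffBase["slope"] * z +
                   stats::rnorm(1, 0, cfg$ffBase["sd"]),
                 cfg$ffLim[1]), cfg$ffLim[2])
  dC1 <- cfg$dFFCold1["mean"] + cfg$dFFCold1["slope"] * z +
    stats::rnorm(1, 0, cfg$dFFCold1["sd"])
  dC2 <- cfg$dFFCold2["mean"] + cfg$dFFCold2["slope"] * z +
    stats::rnorm(1, 0, cfg$dFFCold2["sd"])
  dRh <- cfg$dFFReheat["mean"] + cfg$dFFReheat["slope"] * z +
    stats::rnorm(1, 0, cfg$dFFReheat["sd"])
  ffSatB <- rtruncnorm(1, cfg$ffSat["mean"], cfg$ffSat["sd"],
                       cfg$ffSatLim[1], cfg$ffSatLim[2])
  dSat <- cfg$dFFSat[c("cold1", "cold2", "reheated")] +
    stats::rnorm(3, 0, cfg$dFFSat["sd"])

  bgB0 <- stats::runif(1, cfg$bgLevel["min"], cfg$bgLevel["max"])
  bgB1 <- bgB0 * stats::runif(1, cfg$bgGrowth["min"], cfg$bgGrowth["max"])

  list(id = id, z = z,
       water = list(
         baseline = nv(F = perfB, VT = vt[1], VA = vaB, delay = delay),
         cold1 = nv(F = perfC, VT = vt[2], VA = vaC, delay = delay),
         reheated = nv(F = perfR, VT = vt[3], VA = vaR, delay = delay)),
       fdg = list(sBAT = nv(K1 = K1, k2 = k2, k3 = k3, ki = ki),
                  SAT = nv(K1 = K1Sat, k2 = k2Sat, k3 = k3Sat,
                           ki = kiSat)),
       glucose = glucoseRecord(unname(gluBefore), unname(gluAfter),
                               ratio = 1.1,
                               p2 = unname(cglu) +
                                 stats::rnorm(1, 0, 0.2)),
       mrglu = nv(sBAT = mrglu, SAT = mrgluSat),
       ff = list(
         cooling = nv(baseline = ffB, cold1 = ffB + dC1,
                      cold2 = ffB + dC2, reheated = ffB + dRh),
         satCooling = nv(baseline = ffSatB, cold1 = ffSatB + dSat[1],
                         cold2 = ffSatB + dSat[2],
                         reheated = ffSatB + dSat[3])),
       background = nv(b0 = bgB0, b1 = bgB1))
}

#' Generate a synthetic cooling-reheating cohort
#'
#' Builds, for each subject: dynamic [15O]water images at baseline, cold and
#' reheating (the reheated scan with bracketing frames and a residual-FDG
#' background, growing exponentially by default), one cold [18F]FDG scan,
#' multi-echo MRI at all four conditions for both the cooling-reheating and
#' the (temperature-effect-free) control protocol, region masks and glucose
#' records, together with the full truth table. A fixed seed fixes the whole
#' dataset.
#'
#' @param config from [generatorConfig()].
#' @param seed integer RNG seed.
#' @return A `simCohort` list: `config`, `seed`, `masks`, `subjects` (each
#'   with images, echo trains, glucose, truth) and `truth` (data.frame).
#' @export
genCohort <- function(config = generatorConfig(), seed = 1) {
  set.seed(seed)
  cfg <- config
  masks <- cohortMasks(cfg$gridDim)
  waterSched <- parseFrameSchedule(cfg$waterFrames)
  # reheated scan: pre-injection 60 s frame and another 20 min post
  reheatSched <- frameSchedule(
    c(-60, frameStart(waterSched), 1200),
    c(60, frameDuration(waterSched), 60))
  fdgSched <- parseFrameSchedule(cfg$fdgFrames)
  waterInput <- genInputWater(reheatSched)
  fdgInput <- genInputFdg(fdgSched)
  te <- studyEchoTimes()
  spectrum <- fatSpectrum()

  echoIdx <- which(masks$sBAT | masks$SAT)
  inSBAT <- masks$sBAT[echoIdx]
  nEcho <- length(echoIdx)

  subjects <- vector("list", cfg$nSubjects)
  truthRows <- NULL
  for (s in seq_len(cfg$nSubjects)) {
    tr <- genSubjectTruth(cfg, s)

    # voxel-level metabolic heterogeneity: a fixed ramp over each region
    ramp <- function(n) if (n > 1) seq(0.4, 1.6, length.out = n) else 1
    mrgluVox <- numeric(nEcho)
    mrgluVox[inSBAT] <- tr$mrglu["sBAT"] * ramp(sum(inSBAT))
    mrgluVox[!inSBAT] <- tr$mrglu["SAT"] * ramp(sum(!inSBAT))
    cglu <- meanPlasmaGlucose(tr$glucose)
    kiVoxSBAT <- mrgluVox[inSBAT] / (100 * cglu)
    kiVoxSAT <- mrgluVox[!inSBAT] / (100 * cglu)

    # anatomical FF texture, mildly coupled to voxel metabolism
    ffAnat <- stats::rnorm(nEcho, 0, cfg$ffVoxelSd) +
      cfg$ffVoxelCoupling * (mrgluVox - stats::ave(mrgluVox, inSBAT))
    relMet <- mrgluVox / stats::ave(mrgluVox, inSBAT)  # ~1 on average

    ffVox <- function(protocol, condition) {
      if (protocol == "cooling") {
        base <- ifelse(inSBAT, tr$ff$cooling["baseline"],
                       tr$ff$satCooling["baseline"])
        dlt <- ifelse(inSBAT,
                      tr$ff$cooling[condition] - tr$ff$cooling["baseline"],
                      tr$ff$satCooling[condition] -
                        tr$ff$satCooling["baseline"])
        # cold-induced lipid consumption scales with voxel metabolism
        v <- base + ffAnat + dlt * ifelse(inSBAT, relMet, 1)
      } else {
        base <- ifelse(inSBAT, tr$ffControl["baseline"],
                       tr$ffControlSat["baseline"])
        dlt <- ifelse(inSBAT,
                      tr$ffControl[condition] - tr$ffControl["baseline"],
                      tr$ffControlSat[condition] -
                        tr$ffControlSat["baseline"])
        v <- base + ffAnat + dlt
      }
      pmin(pmax(v, 0), 100)
    }

    # control protocol: repeat-measurement offset, no temperature effects
    ctlB <- tr$ff$cooling["baseline"] + stats::rnorm(1, 0, cfg$ffRepeatSd)
    ctlSatB <- tr$ff$satCooling["baseline"] +
      stats::rnorm(1, 0, cfg$ffRepeatSd)
    dCtl <- cfg$dFFControl[c("cold1", "cold2", "reheated")] +
      stats::rnorm(3, 0, cfg$dFFControl["sd"])
    tr$ffControl <- nv(baseline = ctlB, cold1 = ctlB + dCtl[1],
                       cold2 = ctlB + dCtl[2], reheated = ctlB + dCtl[3])
    tr$ffControlSat <- nv(baseline = ctlSatB, cold1 = ctlSatB + dCtl[1],
                          cold2 = ctlSatB + dCtl[2],
                          reheated = ctlSatB + dCtl[3])

    # dynamic water scans
    water <- list()
    for (cond in c("baseline", "cold1", "reheated")) {
      p <- tr$water[[if (cond == "cold1") "cold1" else cond]]
      sched <- if (cond == "reheated") reheatSched else waterSched
      bg <- if (cond == "reheated")
        backgroundModel("exponential", tr$background["b0"],
                        tr$background["b1"], t0 = -30, t1 = 1230)
      else NULL
      water[[cond]] <- genDynamicImage(
        masks,
        list(sBAT = list(type = "water", F = p["F"], VT = p["VT"],
                         VA = p["VA"], delay = p["delay"]),
             SAT = list(type = "water", F = 2.5, VT = 30, VA = 1,
                        delay = p["delay"]),
             aorta = list(type = "blood")),
        waterInput, sched, noise = cfg$petNoise, noiseModel = "scaled",
        background = bg, voxelSize = cfg$voxelSize)
    }

    # cold FDG scan with voxelwise K_i heterogeneity
    fdgImg <- genDynamicImage(
      masks,
      list(sBAT = list(type = "fdg", K1 = tr$fdg$sBAT["K1"],
                       k2 = tr$fdg$sBAT["k2"], k3 = tr$fdg$sBAT["k3"],
                       kiVoxel = kiVoxSBAT),
           SAT = list(type = "fdg", K1 = tr$fdg$SAT["K1"],
                      k2 = tr$fdg$SAT["k2"], k3 = tr$fdg$SAT["k3"],
                      kiVoxel = kiVoxSAT),
           aorta = list(type = "blood")),
      fdgInput, fdgSched, noise = cfg$petNoise, noiseModel = "scaled",
      voxelSize = cfg$voxelSize)

    # multi-echo MRI, both protocols, all four conditions
    echoes <- list(cooling = list(), control = list())
    pilot <- (s == cfg$pilotSubject)
    for (protocol in c("cooling", "control")) {
      for (cond in FF_CONDITIONS) {
        ff <- ffVox(protocol, cond)
        if (pilot && protocol == "cooling")
          ff <- pmin(ff + 3.9, 100)   # pilot sequence reads high
        psi <- stats::rnorm(1, 0, cfg$psiSd) +
          cfg$psiGradient * seq(-1, 1, length.out = nEcho)
        r2 <- stats::runif(1, cfg$r2starRange[1], cfg$r2starRange[2])
        echoes[[protocol]][[cond]] <- genMultiecho(
          ff, psi = psi, r2star = r2, te = te, spectrum = spectrum,
          s0 = 1, snr = cfg$mriSnr)
      }
    }

    subjects[[s]] <- list(
      id = s, truth = tr, water = water, fdg = fdgImg, echoes = echoes,
      echoIdx = echoIdx, pilot = pilot,
      glucose = tr$glucose, mrgluVox = mrgluVox)

    truthRows <- rbind(truthRows, data.frame(
      subject = s, z = tr$z,
      F_baseline = tr$water$baseline["F"], F_cold = tr$water$cold1["F"],
      F_reheated = tr$water$reheated["F"],
      VA_baseline = tr$water$baseline["VA"], VA_cold = tr$water$cold1["VA"],
      VA_reheated = tr$water$reheated["VA"],
      delay = tr$water$baseline["delay"],
      Ki_sBAT = tr$fdg$sBAT["ki"], mrglu_sBAT = tr$mrglu["sBAT"],
      FF_baseline = tr$ff$cooling["baseline"],
      FF_cold1 = tr$ff$cooling["cold1"], FF_cold2 = tr$ff$cooling["cold2"],
      FF_reheated = tr$ff$cooling["reheated"],
      row.names = NULL))
  }

  structure(list(config = cfg, seed = seed, masks = masks,
                 waterSchedule = waterSched, reheatSchedule = reheatSched,
                 fdgSchedule = fdgSched, waterInput = waterInput,
                 fdgInput = fdgInput, te = te, spectrum = spectrum,
                 subjects = subjects, truth = truthRows),
            class = "simCohort")
}

#' @export
print.simCohort <- function(x, ...) {
  cat(sprintf("simCohort: %d subjects, grid %s, seed %d\n",
              length(x$subjects),
              paste(x$config$gridDim, collapse = "x"), x$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the file tree the analysis tools read: per subject NIfTI dynamic
#' images with frame-schedule JSON sidecars, multi-echo magnitude/phase
#' NIfTI pairs with an echo-time sidecar, masks, a glucose YAML and the
#' cohort truth table CSV.
#'
#' @param cohort a `simCohort` from [genCohort()].
#' @param dir output directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- cohort$config$voxelSize
  for (nm in names(cohort$masks))
    writeMask(cohort$masks[[nm]], file.path(dir, paste0("mask_", nm,
                                                        ".nii.gz")), vs)
  jsonlite::write_json(list(te_s = cohort$te),
                       file.path(dir, "tes.json"), digits = NA)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  grid <- cohort$config$gridDim
  for (sub in cohort$subjects) {
    sd <- file.path(dir, sprintf("sub-%02d", sub$id))
    dir.create(sd, showWarnings = FALSE)
    for (cond in names(sub$water)) {
      writeDynamicImage(sub$water[[cond]],
                        file.path(sd, paste0("water_", cond, ".nii.gz")),
                        file.path(sd, paste0("water_", cond,
                                             "_frames.json")))
    }
    writeDynamicImage(sub$fdg, file.path(sd, "fdg_cold.nii.gz"),
                      file.path(sd, "fdg_cold_frames.json"))
    for (protocol in names(sub$echoes)) {
      for (cond in names(sub$echoes[[protocol]])) {
        sig <- sub$echoes[[protocol]][[cond]]@signal
        full <- array(0, c(grid, length(cohort$te)))
        fullI <- array(0, c(grid, length(cohort$te)))
        for (e in seq_along(cohort$te)) {
          slab <- array(0, grid); slab[sub$echoIdx] <- Re(sig[, e])
          full[, , , e] <- slab
          slab[sub$echoIdx] <- Im(sig[, e])
          fullI[, , , e] <- slab
        }
        base <- file.path(sd, paste0("me_", protocol, "_", cond))
        RNifti::writeNifti(RNifti::asNifti(full),
                           paste0(base, "_real.nii.gz"))
        RNifti::writeNifti(RNifti::asNifti(fullI),
                           paste0(base, "_imag.nii.gz"))
      }
    }
    g <- sub$glucose
    yaml::write_yaml(list(glucose = list(before = g@before,
                                         after = g@after, ratio = g@ratio,
                                         p2 = g@p2),
                          pilot = sub$pilot),
                     file.path(sd, "study.yaml"))
  }
  invisible(dir)
}
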