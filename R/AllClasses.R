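#' @import methods
NULL

#' Frame schedule of a dynamic acquisition
#'
#' Per-frame start times and durations (seconds) of a dynamic PET or MRI
#' acquisition. Frames must not overlap but gaps are allowed, e.g. a
#' bracketing frame acquired 20 min after injection, and a pre-injection
#' frame may start at a negative time relative to injection.
#'
#' @slot start numeric, frame start times in seconds (strictly increasing).
#' @slot duration numeric, frame durations in seconds (all positive).
#' @export
setClass("FrameSchedule",
  representation(start = "numeric", duration = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@start) != length(object@duration))
      msg <- c(msg, "start and duration must have equal length")
    if (length(object@start) == 0L)
      msg <- c(msg, "schedule must contain at least one frame")
    if (any(!is.finite(object@start)) || any(!is.finite(object@duration)))
      msg <- c(msg, "frame times must be finite")
    else {
      if (any(object@duration <= 0))
        msg <- c(msg, "all frame durations must be positive")
      if (length(object@start) > 1L && any(diff(object@start) <= 0))
        msg <- c(msg, "frame starts must be strictly increasing")
      ends <- object@start + object@duration
      if (length(object@start) > 1L &&
          any(object@start[-1L] < ends[-length(ends)] - 1e-9))
        msg <- c(msg, "frames must not overlap")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Blood activity curve
#'
#' A finely sampled whole-blood or plasma activity concentration curve
#' (kBq/ml) versus time (seconds), typically an image-derived input function.
#'
#' @slot time numeric, sample times in seconds (strictly increasing).
#' @slot activity numeric, activity concentration in kBq/ml.
#' @slot kind character, either "wholeblood" or "plasma".
#' @export
setClass("BloodCurve",
  representation(time = "numeric", activity = "numeric", kind = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@time) != length(object@activity))
      msg <- c(msg, "time and activity must have equal length")
    if (length(object@time) < 2L)
      msg <- c(msg, "curve needs at least two samples")
    else if (any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    if (!object@kind %in% c("wholeblood", "plasma"))
      msg <- c(msg, "kind must be 'wholeblood' or 'plasma'")
    if (is.null(msg)) TRUE else msg
  })

#' Region time-activity curve
#'
#' Frame-averaged activity concentration in a volume of interest, paired
#' with its frame schedule.
#'
#' @slot schedule a [FrameSchedule-class].
#' @slot activity numeric, kBq/ml, one value per frame.
#' @slot region character label.
#' @slot voxels integer, number of voxels averaged.
#' @export
setClass("RegionTAC",
  representation(schedule = "FrameSchedule", activity = "numeric",
                 region = "character", voxels = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@activity) != length(object@schedule@start))
      msg <- c(msg, "one activity value per frame required")
    if (object@voxels < 1L)
      msg <- c(msg, "voxel count must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Dynamic image
#'
#' A 4D dynamic image: one 3D activity volume (kBq/ml, decay-corrected to
#' injection time) per frame of a [FrameSchedule-class].
#'
#' @slot data 4D numeric array, dims (x, y, z, frame).
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot schedule a [FrameSchedule-class].
#' @export
setClass("DynamicImage",
  representation(data = "array", voxelSize = "numeric",
                 schedule = "FrameSchedule"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@data)
    if (length(d) != 4L)
      msg <- c(msg, "data must be a 4D array")
    else if (d[4L] != length(object@schedule@start))
      msg <- c(msg, "number of volumes must equal number of frames")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be three positive lengths (mm)")
    if (any(!is.finite(object@data)))
      msg <- c(msg, "activity values must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Single-tissue compartment model fit result
#'
#' Parameter record of a [15O]water fit: perfusion F (ml/100 cm^3/min),
#' distribution volume V_T (ml/100 cm^3), arterial blood volume V_A
#' (ml/100 cm^3) and input delay (s), with per-parameter coefficients of
#' variation (%), residual sum of squares and convergence diagnostics.
#'
#' @slot estimates named numeric (F, VT, VA, delay).
#' @slot cv named numeric, asymptotic SE / estimate x 100, in percent.
#' @slot rss numeric, weighted residual sum of squares.
#' @slot converged logical.
#' @slot degenerate logical, TRUE when the TAC carried no signal.
#' @slot window numeric, fit window in seconds.
#' @export
setClass("WaterFitResult",
  representation(estimates = "numeric", cv = "numeric", rss = "numeric",
                 converged = "logical", degenerate = "logical",
                 window = "numeric"))

#' Residual-FDG background model
#'
#' Background activity during a reheated [15O]water scan, anchored at the
#' mid-times of the two bracketing 60 s frames (immediately before injection
#' and 20 min after).
#'
#' @slot kind character, "constant", "linear" or "exponential".
#' @slot b0,b1 numeric, background level (kBq/ml) at the anchors.
#' @slot t0,t1 numeric, anchor times in seconds (t1 > t0).
#' @export
setClass("BackgroundModel",
  representation(kind = "character", b0 = "numeric", b1 = "numeric",
                 t0 = "numeric", t1 = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("constant", "linear", "exponential"))
      msg <- c(msg, "kind must be constant, linear or exponential")
    if (object@t1 <= object@t0)
      msg <- c(msg, "t1 must be greater than t0")
    if (object@kind == "exponential" && (object@b0 <= 0 || object@b1 <= 0))
      msg <- c(msg, "exponential background requires positive anchors")
    if (is.null(msg)) TRUE else msg
  })

#' Basis set for the irreversible two-tissue compartment model
#'
#' One irreversible basis (running integral of the plasma input) and a grid
#' of convolution bases exp(-beta t) (x) C_P(t), all frame-averaged over the
#' schedule. Betas are logarithmically spaced clearance rates in 1/min.
#'
#' @slot betas numeric, clearance rates in 1/min, strictly increasing.
#' @slot basis numeric matrix, frames x (1 + length(betas)); column 1 is the
#'   irreversible basis.
#' @slot schedule the [FrameSchedule-class] the bases were averaged over.
#' @slot fineTime,fineInput the fine time grid (s) and plasma input samples
#'   the bases were computed from, kept for continuous beta refinement.
#' @export
setClass("BasisSet",
  representation(betas = "numeric", basis = "matrix",
                 schedule = "FrameSchedule", fineTime = "numeric",
                 fineInput = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(diff(object@betas) <= 0))
      msg <- c(msg, "betas must be strictly increasing")
    if (ncol(object@basis) != length(object@betas) + 1L)
      msg <- c(msg, "basis must have one column per beta plus one")
    if (nrow(object@basis) != length(object@schedule@start))
      msg <- c(msg, "basis must have one row per frame")
    if (is.null(msg)) TRUE else msg
  })

#' Net uptake rate fit result
#'
#' @slot ki numeric, net uptake rate K_i in ml plasma/cm^3/min.
#' @slot beta numeric, selected clearance rate in 1/min.
#' @slot theta2 numeric, reversible-component coefficient in ml/cm^3/min.
#' @slot rss numeric, residual sum of squares.
#' @export
setClass("KiResult",
  representation(ki = "numeric", beta = "numeric", theta2 = "numeric",
                 rss = "numeric"))

#' Blood glucose record
#'
#' Venous whole-blood glucose before and after the cold-exposure scan
#' (mmol/l), a plasma-to-whole-blood conversion ratio, and an optional
#' laboratory plasma value used for the alternative metabolic-rate estimate.
#'
#' @slot before,after numeric, whole-blood glucose (mmol/l).
#' @slot ratio numeric, plasma-to-whole-blood ratio (default 1.1).
#' @slot p2 numeric, laboratory plasma glucose (mmol/l) or NA.
#' @export
setClass("GlucoseRecord",
  representation(before = "numeric", after = "numeric", ratio = "numeric",
                 p2 = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@before <= 0 || object@after <= 0 || object@ratio <= 0)
      msg <- c(msg, "glucose values and ratio must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Fat spectral model
#'
#' Chemical shifts of the fat peaks relative to water (ppm, negative for
#' resonances below water) with normalized relative amplitudes, at a given
#' field strength.
#'
#' @slot shift numeric, ppm relative to water.
#' @slot amplitude numeric, non-negative, summing to 1.
#' @slot field numeric, field strength in tesla.
#' @export
setClass("FatSpectrum",
  representation(shift = "numeric", amplitude = "numeric", field = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@shift) != length(object@amplitude))
      msg <- c(msg, "shift and amplitude must have equal length")
    if (any(object@amplitude < 0))
      msg <- c(msg, "amplitudes must be non-negative")
    if (abs(sum(object@amplitude) - 1) > 1e-8)
      msg <- c(msg, "amplitudes must sum to 1")
    if (object@field <= 0) msg <- c(msg, "field must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Multi-echo gradient-echo signal
#'
#' Complex per-voxel signal at each echo time. Voxels are rows, echoes
#' columns; a single voxel is a one-row matrix.
#'
#' @slot te numeric, echo times in seconds, strictly increasing.
#' @slot signal complex matrix, voxels x echoes.
#' @export
setClass("EchoTrain",
  representation(te = "numeric", signal = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (any(diff(object@te) <= 0))
      msg <- c(msg, "echo times must be strictly increasing")
    if (length(object@te) < 3L)
      msg <- c(msg, "at least 3 echoes are required")
    if (ncol(object@signal) != length(object@te))
      msg <- c(msg, "signal must have one column per echo")
    if (!is.complex(object@signal))
      msg <- c(msg, "signal must be complex")
    if (is.null(msg)) TRUE else msg
  })

#' Water-fat separation result
#'
#' Per-voxel water and fat magnitudes, fat fraction (%), field map (Hz),
#' R2* (1/s), residual and a flag for unusable voxels.
#'
#' @slot water,fat numeric, component magnitudes.
#' @slot ff numeric, fat fraction in percent (0-100).
#' @slot psi numeric, field map in Hz.
#' @slot r2star numeric, effective transverse relaxation rate in 1/s.
#' @slot rss numeric, residual sum of squares.
#' @slot flagged logical, TRUE where the voxel could not be solved.
#' @export
setClass("FFResult",
  representation(water = "numeric", fat = "numeric", ff = "numeric",
                 psi = "numeric", r2star = "numeric", rss = "numeric",
                 flagged = "logical"))

#' Metabolic-rate partition of a region
#'
#' Split of a parent mask into a high subregion (metabolic rate of glucose
#' strictly above the threshold) and the complementary low subregion.
#'
#' @slot parent,hi,lo logical arrays on a common grid.
#' @slot threshold numeric, in umol/100 cm^3/min.
#' @export
setClass("RegionSet",
  representation(parent = "array", hi = "array", lo = "array",
                 threshold = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@parent), dim(object@hi)) ||
        !identical(dim(object@parent), dim(object@lo)))
      msg <- c(msg, "parent, hi and lo must share a grid")
    if (any(object@hi & object@lo))
      msg <- c(msg, "hi and lo must be disjoint")
    if (!identical(as.logical(object@parent),
                   as.logical(object@hi | object@lo)))
      msg <- c(msg, "hi and lo must partition the parent")
    if (is.null(msg)) TRUE else msg
  })
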