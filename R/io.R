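#' Construct a blood activity curve
#'
#' @param time numeric, seconds, strictly increasing.
#' @param activity numeric, kBq/ml.
#' @param kind "wholeblood" or "plasma".
#' @return A [BloodCurve-class].
#' @export
bloodCurve <- function(time, activity, kind = "wholeblood") {
  new("BloodCurve", time = as.numeric(time), activity = as.numeric(activity),
      kind = kind)
}

#' @rdname bloodCurve
#' @param curve a [BloodCurve-class].
#' @export
curveTime <- function(curve) curve@time

#' @rdname bloodCurve
#' @export
curveActivity <- function(curve) curve@activity

#' @rdname bloodCurve
#' @export
curveKind <- function(curve) curve@kind

setMethod("show", "BloodCurve", function(object) {
  cat(sprintf("BloodCurve (%s): %d samples, %g-%g s, peak %.3g kBq/ml\n",
              object@kind, length(object@time), min(object@time),
              max(object@time), max(object@activity)))
})

#' Convert a whole-blood curve to plasma
#'
#' Multiplies activity by the plasma-to-whole-blood ratio (default 1.1, the
#' typical mean ratio for FDG) and relabels the curve as plasma. Refuses to
#' convert a curve that is already plasma.
#'
#' @param curve a whole-blood [BloodCurve-class].
#' @param ratio plasma-to-whole-blood activity ratio.
#' @return A plasma [BloodCurve-class].
#' @export
toPlasma <- function(curve, ratio = 1.1) {
  if (curveKind(curve) != "wholeblood")
    stop("curve is already plasma; refusing to convert twice")
  bloodCurve(curve@time, curve@activity * ratio, kind = "plasma")
}

#' Read / write a blood curve as CSV
#'
#' Columns `time_s`, `activity_kBq_ml` and optionally `kind`.
#'
#' @param curve a [BloodCurve-class].
#' @param path CSV file path.
#' @param kind fallback kind when the file has no `kind` column.
#' @export
writeBloodCurve <- function(curve, path) {
  utils::write.csv(data.frame(time_s = curve@time,
                              activity_kBq_ml = curve@activity,
                              kind = curve@kind),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBloodCurve
#' @export
readBloodCurve <- function(path, kind = "wholeblood") {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "activity_kBq_ml") %in% names(d)))
    stop("curve CSV needs columns time_s and activity_kBq_ml")
  if ("kind" %in% names(d)) kind <- as.character(d$kind[1L])
  bloodCurve(d$time_s, d$activity_kBq_ml, kind = kind)
}

#' Construct a region time-activity curve
#'
#' @param schedule a [FrameSchedule-class] (or compact string / sidecar path).
#' @param activity numeric, kBq/ml per frame.
#' @param region character label.
#' @param voxels number of voxels averaged.
#' @return A [RegionTAC-class].
#' @export
regionTAC <- function(schedule, activity, region = "", voxels = 1L) {
  new("RegionTAC", schedule = readFrameSchedule(schedule),
      activity = as.numeric(activity), region = region,
      voxels = as.integer(voxels))
}

#' @rdname regionTAC
#' @param tac a [RegionTAC-class].
#' @export
tacActivity <- function(tac) tac@activity

#' @rdname regionTAC
#' @export
tacSchedule <- function(tac) tac@schedule

setMethod("show", "RegionTAC", function(object) {
  cat(sprintf("RegionTAC '%s': %d frames, %d voxels\n", object@region,
              nFrames(object@schedule), object@voxels))
})

#' Read / write a region TAC as CSV
#'
#' Columns `frame_start_s`, `frame_duration_s`, `activity_kBq_ml`.
#'
#' @param tac a [RegionTAC-class].
#' @param path CSV file path.
#' @export
writeRegionTAC <- function(tac, path) {
  utils::write.csv(data.frame(frame_start_s = frameStart(tac@schedule),
                              frame_duration_s = frameDuration(tac@schedule),
                              activity_kBq_ml = tac@activity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegionTAC
#' @export
readRegionTAC <- function(path) {
  d <- utils::read.csv(path)
  regionTAC(frameSchedule(d$frame_start_s, d$frame_duration_s),
            d$activity_kBq_ml)
}

#' Construct a dynamic image
#'
#' @param data 4D array (x, y, z, frame) of activity (kBq/ml).
#' @param schedule a [FrameSchedule-class] (or compact string / sidecar path).
#' @param voxelSize numeric(3), mm.
#' @return A [DynamicImage-class].
#' @export
dynamicImage <- function(data, schedule, voxelSize = c(1, 1, 1)) {
  new("DynamicImage", data = data, voxelSize = as.numeric(voxelSize),
      schedule = readFrameSchedule(schedule))
}

#' @rdname dynamicImage
#' @param image a [DynamicImage-class].
#' @export
imageData <- function(image) image@data

#' @rdname dynamicImage
#' @export
imageSchedule <- function(image) image@schedule

#' @rdname dynamicImage
#' @export
voxelSize <- function(image) image@voxelSize

setMethod("show", "DynamicImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("DynamicImage: %dx%dx%d voxels, %d frames\n",
              d[1L], d[2L], d[3L], d[4L]))
})

#' Read / write dynamic images and masks as NIfTI
#'
#' 4D NIfTI for dynamic images (frames along the 4th axis, schedule from a
#' JSON sidecar) and 3D NIfTI for binary masks. Masks must share the image
#' grid exactly; no resampling is performed.
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @param frames schedule sidecar path, compact string, or
#'   [FrameSchedule-class].
#' @param image a [DynamicImage-class].
#' @param mask logical 3D array.
#' @param voxelSize numeric(3), mm, used when writing a mask.
#' @export
readDynamicImage <- function(path, frames) {
  nii <- RNifti::readNifti(path)
  arr <- array(as.numeric(nii), dim = dim(nii))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  vs <- RNifti::pixdim(nii)[1:3]
  dynamicImage(arr, readFrameSchedule(frames), voxelSize = vs)
}

#' @rdname readDynamicImage
#' @export
writeDynamicImage <- function(image, path, frames = NULL) {
  nii <- RNifti::asNifti(image@data)
  RNifti::pixdim(nii) <- c(image@voxelSize, 1)
  RNifti::writeNifti(nii, path)
  if (!is.null(frames)) writeFrameSchedule(image@schedule, frames)
  invisible(path)
}

#' @rdname readDynamicImage
#' @export
readMask <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- array(as.numeric(nii), dim = dim(nii))
  if (length(dim(arr)) != 3L) stop("mask must be a 3D volume")
  arr > 0.5
}

#' @rdname readDynamicImage
#' @export
writeMask <- function(mask, path, voxelSize = c(1, 1, 1)) {
  nii <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(nii) <- voxelSize
  RNifti::writeNifti(nii, path)
  invisible(path)
}

checkMaskGrid <- function(image, mask) {
  if (!identical(dim(image@data)[1:3], dim(mask)[1:3]))
    stop("mask grid does not match image grid")
  if (!any(mask)) stop("mask is empty")
  invisible(TRUE)
}

#' Extract a VOI time-activity curve
#'
#' Unweighted per-frame mean activity over the mask voxels.
#'
#' @param image a [DynamicImage-class].
#' @param mask logical 3D array on the image grid with at least one voxel.
#' @param region character label for the resulting TAC.
#' @return A [RegionTAC-class].
#' @export
extractVoiTac <- function(image, mask, region = "") {
  checkMaskGrid(image, mask)
  idx <- which(mask)
  nf <- nFrames(image@schedule)
  flat <- matrix(image@data, ncol = nf)
  act <- colMeans(flat[idx, , drop = FALSE])
  regionTAC(image@schedule, act, region = region, voxels = length(idx))
}

#' Image-derived input function
#'
#' Whole-blood curve from an arterial (ascending-aorta) VOI, sampled at the
#' frame mid-times. The frame of maximum mask-mean activity is reported as a
#' first-pass QC aid (NA when the image carries no signal).
#'
#' @param image a [DynamicImage-class].
#' @param mask logical 3D aorta mask.
#' @return list with `curve` (a whole-blood [BloodCurve-class]) and
#'   `firstPassFrame` (integer frame index or NA).
#' @export
imageDerivedInput <- function(image, mask) {
  tac <- extractVoiTac(image, mask, region = "aorta")
  act <- tacActivity(tac)
  fp <- if (all(act == 0)) NA_integer_ else which.max(act)
  # samples at frame mid-times, plus a terminal anchor at the scan end so
  # the curve covers the full span of its own acquisition
  tm <- frameMid(image@schedule)
  nf <- length(tm)
  list(curve = bloodCurve(c(tm, scanEnd(image@schedule)),
                          c(act, act[nf]), kind = "wholeblood"),
       firstPassFrame = fp)
}

#' Read a study configuration YAML
#'
#' Free-form study configuration (glucose records, background model choice,
#' file locations). A `glucose` block with `before`, `after` and optional
#' `ratio`, `p2` fields is converted to a [GlucoseRecord-class].
#'
#' @param path YAML file path.
#' @return named list; `$glucose` is a [GlucoseRecord-class] when present.
#' @export
readStudyConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$glucose)) {
    g <- cfg$glucose
    cfg$glucose <- glucoseRecord(g$before, g$after,
                                 ratio = if (is.null(g$ratio)) 1.1 else g$ratio,
                                 p2 = if (is.null(g$p2)) NA_real_ else g$p2)
  }
  cfg
}
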