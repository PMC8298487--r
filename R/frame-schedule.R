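#' Construct a frame schedule
#'
#' @param start numeric, frame start times (s).
#' @param duration numeric, frame durations (s).
#' @return A [FrameSchedule-class].
#' @examples
#' frameSchedule(c(0, 10, 15), c(10, 5, 5))
#' @export
frameSchedule <- function(start, duration) {
  new("FrameSchedule", start = as.numeric(start),
      duration = as.numeric(duration))
}

#' Parse a compact frame-schedule string
#'
#' Parses shorthand like `"1x10,8x5,4x10"` (count x duration in seconds)
#' into contiguous frames starting at `t0`.
#'
#' @param spec character scalar, comma-separated `<count>x<duration_s>`
#'   tokens.
#' @param t0 start time of the first frame (s), default 0.
#' @return A [FrameSchedule-class].
#' @examples
#' sched <- parseFrameSchedule("1x10,8x5,4x10,2x15,3x20,2x30,6x60")
#' nFrames(sched)   # 26
#' scanEnd(sched)   # 600 s
#' @export
parseFrameSchedule <- function(spec, t0 = 0) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(trimws(spec)))
    stop("frame schedule spec must be a non-empty string")
  tokens <- trimws(strsplit(spec, ",", fixed = TRUE)[[1L]])
  durs <- unlist(lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([0-9]+)x([0-9.]+)$", tok))[[1L]]
    if (length(m) != 3L)
      stop("malformed frame token: '", tok, "'")
    count <- as.integer(m[2L]); dur <- as.numeric(m[3L])
    if (is.na(count) || count < 1L)
      stop("malformed frame token: '", tok, "' (count must be >= 1)")
    if (is.na(dur) || dur <= 0)
      stop("malformed frame token: '", tok, "' (duration must be > 0)")
    rep(dur, count)
  }))
  start <- t0 + cumsum(c(0, durs[-length(durs)]))
  frameSchedule(start, durs)
}

#' Format a contiguous frame schedule as a compact string
#'
#' Inverse of [parseFrameSchedule()] for contiguous schedules starting at 0.
#'
#' @param schedule a [FrameSchedule-class].
#' @return character scalar like `"1x10,8x5"`.
#' @export
formatFrameSchedule <- function(schedule) {
  ends <- schedule@start + schedule@duration
  if (abs(schedule@start[1L]) > 1e-9 ||
      (nFrames(schedule) > 1L &&
       any(abs(schedule@start[-1L] - ends[-nFrames(schedule)]) > 1e-9)))
    stop("only contiguous schedules starting at 0 have a compact form")
  r <- rle(schedule@duration)
  paste(paste0(r$lengths, "x", format(r$values, trim = TRUE)),
        collapse = ",")
}

#' @describeIn frameSchedule number of frames.
#' @param schedule a [FrameSchedule-class].
#' @export
nFrames <- function(schedule) length(schedule@start)

#' Frame timing accessors
#'
#' @param schedule a [FrameSchedule-class].
#' @return numeric vector of per-frame start times, durations, mid-times or
#'   end times (s); `scanEnd` returns the end of the last frame.
#' @export
frameStart <- function(schedule) schedule@start

#' @rdname frameStart
#' @export
frameDuration <- function(schedule) schedule@duration

#' @rdname frameStart
#' @export
frameMid <- function(schedule) schedule@start + schedule@duration / 2

#' @rdname frameStart
#' @export
frameEnd <- function(schedule) schedule@start + schedule@duration

#' @rdname frameStart
#' @export
scanEnd <- function(schedule) max(frameEnd(schedule))

#' Read / write a frame-schedule JSON sidecar
#'
#' The sidecar holds `frame_start` and `frame_duration` arrays in seconds.
#' `readFrameSchedule` also accepts a compact "1x10,8x5" string in place of
#' a path.
#'
#' @param x a [FrameSchedule-class] (write) or path / compact string (read).
#' @param path file path of the JSON sidecar.
#' @export
writeFrameSchedule <- function(x, path) {
  jsonlite::write_json(list(frame_start = x@start,
                            frame_duration = x@duration),
                       path, digits = NA)
  invisible(path)
}

#' @rdname writeFrameSchedule
#' @export
readFrameSchedule <- function(x) {
  if (is(x, "FrameSchedule")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (file.exists(x)) {
    j <- jsonlite::read_json(x, simplifyVector = TRUE)
    frameSchedule(j$frame_start, j$frame_duration)
  } else {
    parseFrameSchedule(x)
  }
}

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %g-%g s\n", nFrames(object),
              min(object@start), scanEnd(object)))
})
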