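## Rule-based behavioral scoring from calibrated pose tracks: freezing,
## sheltering and flight ethograms, speed traces, and peri-stimulus
## behavioral summaries.

## maximal runs of TRUE -> data.frame(startFrame, endFrame) (1-based, inclusive)
.runsOf <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(startFrame = starts[keep], endFrame = ends[keep])
}

## frame run -> seconds: frame i covers [(i-1)/fps, i/fps)
.runsToIntervals <- function(runs, fps) {
  data.frame(start_s = (runs$startFrame - 1) / fps, end_s = runs$endFrame / fps)
}

.framesFromIntervals <- function(intervals, nFrames, fps) {
  out <- logical(nFrames)
  for (i in seq_len(nrow(intervals))) {
    a <- max(1L, as.integer(floor(intervals$start_s[i] * fps + 1e-9)) + 1L)
    b <- min(nFrames, as.integer(ceiling(intervals$end_s[i] * fps - 1e-9)))
    if (b >= a) out[a:b] <- TRUE
  }
  out
}

#' Per-frame, per-keypoint movement flags
#'
#' A keypoint is "moving" at frame `i` if its Euclidean displacement
#' between frames `i - 1` and `i` is at least `thresh` millimetres
#' (inclusive: a displacement of exactly the threshold counts as
#' movement). Frame 1 has no backward difference and copies frame 2's
#' flags.
#'
#' @param track a [PoseTrack-class].
#' @param thresh displacement threshold in mm (default 2).
#' @return logical matrix, frames x parts.
#' @export
movementFlags <- function(track, thresh = 2) {
  stopifnot(is(track, "PoseTrack"), thresh > 0)
  n <- dim(track@coords)[1]
  if (n < 2) stop("movement flags need at least two frames")
  dx <- track@coords[-1, , "x", drop = FALSE] -
        track@coords[-n, , "x", drop = FALSE]
  dy <- track@coords[-1, , "y", drop = FALSE] -
        track@coords[-n, , "y", drop = FALSE]
  disp <- sqrt(dx[, , 1, drop = FALSE]^2 + dy[, , 1, drop = FALSE]^2)
  disp <- matrix(disp, n - 1, length(track@parts))
  flags <- rbind(disp[1, ] >= thresh, disp >= thresh)
  dimnames(flags) <- list(NULL, track@parts)
  flags
}

#' Classify freezing bouts
#'
#' Freezing is the cessation of all movement except breathing,
#' operationalized as frames in which no more than one keypoint moves
#' `thresh` mm or more between consecutive frames, sustained for at
#' least `minDur` seconds. Candidate frames form maximal runs; a run of
#' `k` frames lasts `k / fps` seconds and becomes a freezing bout when
#' that duration reaches `minDur` (inclusive).
#'
#' @param track a [PoseTrack-class].
#' @param thresh movement threshold, mm (default 2).
#' @param minDur minimum bout duration, seconds (default 0.5).
#' @return data.frame of intervals (`start_s`, `end_s`) with the
#'   per-frame logical series as attribute `frames`.
#' @export
classifyFreezing <- function(track, thresh = 2, minDur = 0.5) {
  stopifnot(is(track, "PoseTrack"))
  if (!isTRUE(track@fps > 0)) stop("track fps is required")
  flags <- movementFlags(track, thresh)
  candidate <- rowSums(flags) <= 1L
  runs <- .runsOf(candidate)
  minFrames <- ceiling(minDur * track@fps - 1e-9)
  runs <- runs[runs$endFrame - runs$startFrame + 1L >= minFrames, ,
               drop = FALSE]
  frames <- logical(length(candidate))
  for (i in seq_len(nrow(runs))) frames[runs$startFrame[i]:runs$endFrame[i]] <- TRUE
  out <- .runsToIntervals(runs, track@fps)
  attr(out, "frames") <- frames
  out
}

#' Classify sheltering
#'
#' A frame counts as sheltering when every non-tail keypoint lies within
#' the shelter's y-axis limits and at least half of the non-tail
#' keypoints lie within its x-axis limits. Tail keypoints are ignored
#' entirely. No minimum duration applies.
#'
#' @param track a [PoseTrack-class].
#' @param arena an [ArenaGeometry-class] providing the shelter bounding
#'   box in mm.
#' @return data.frame of intervals with per-frame attribute `frames`.
#' @export
classifySheltering <- function(track, arena) {
  stopifnot(is(track, "PoseTrack"), is(arena, "ArenaGeometry"))
  body <- bodyParts(track)
  if (!length(body)) stop("no non-tail keypoints in the schema")
  bb <- arena@shelterBBox
  x <- track@coords[, body, "x", drop = FALSE]
  y <- track@coords[, body, "y", drop = FALSE]
  dim(x) <- dim(y) <- c(dim(track@coords)[1], length(body))
  inY <- y >= bb["ymin"] & y <= bb["ymax"]
  inX <- x >= bb["xmin"] & x <= bb["xmax"]
  frames <- rowSums(inY) == length(body) &
            rowSums(inX) >= length(body) / 2
  out <- .runsToIntervals(.runsOf(frames), track@fps)
  attr(out, "frames") <- frames
  out
}

#' Centroid speed trace
#'
#' Speed is the finite difference of the non-tail-keypoint centroid:
#' `v[i] = ||centroid[i + 1] - centroid[i]|| * fps`, one sample per
#' inter-frame step, timestamped at the step midpoint. An optional
#' centred boxcar smooths the trace.
#'
#' @param track a [PoseTrack-class] with at least two frames.
#' @param smoothWin odd boxcar width in samples; `NULL` (default) for no
#'   smoothing.
#' @return a [SpeedTrace-class] in mm/s.
#' @export
computeSpeed <- function(track, smoothWin = NULL) {
  stopifnot(is(track, "PoseTrack"))
  n <- dim(track@coords)[1]
  if (n < 2) stop("speed needs at least two frames")
  body <- bodyParts(track)
  cx <- rowMeans(matrix(track@coords[, body, "x"], n, length(body)))
  cy <- rowMeans(matrix(track@coords[, body, "y"], n, length(body)))
  v <- sqrt(diff(cx)^2 + diff(cy)^2) * track@fps
  if (!is.null(smoothWin)) v <- pmax(movingMean(v, smoothWin), 0)
  SpeedTrace(t = (seq_len(n - 1) - 0.5) / track@fps, v = v, fps = track@fps)
}

#' Classify flight bouts
#'
#' Flight is scored as sustained supra-threshold speed: maximal runs of
#' speed samples `>= vThresh` lasting at least `minDur` seconds. The
#' defaults (150 mm/s for 0.2 s) are package choices — the escape
#' literature has no single convention — and should be tuned per assay.
#'
#' @param speed a [SpeedTrace-class].
#' @param vThresh speed threshold, mm/s (default 150).
#' @param minDur minimum bout duration, seconds (default 0.2).
#' @return data.frame of intervals with per-frame attribute `frames`
#'   (one flag per speed sample).
#' @export
classifyFlight <- function(speed, vThresh = 150, minDur = 0.2) {
  stopifnot(is(speed, "SpeedTrace"))
  fast <- speed@v >= vThresh
  runs <- .runsOf(fast)
  minFrames <- ceiling(minDur * speed@fps - 1e-9)
  runs <- runs[runs$endFrame - runs$startFrame + 1L >= minFrames, ,
               drop = FALSE]
  frames <- logical(length(fast))
  for (i in seq_len(nrow(runs))) frames[runs$startFrame[i]:runs$endFrame[i]] <- TRUE
  out <- data.frame(start_s = speed@t[runs$startFrame],
                    end_s = speed@t[runs$endFrame])
  attr(out, "frames") <- frames
  out
}

#' Score a full ethogram from a pose track
#'
#' Runs the freezing, sheltering and flight classifiers and assembles
#' the three (independent, possibly overlapping) channels into an
#' [Ethogram-class]. Flight flags, computed on inter-frame speed
#' samples, are mapped to the later frame of each step.
#'
#' @param track a [PoseTrack-class].
#' @param arena an [ArenaGeometry-class].
#' @param freezeThresh,freezeMinDur freezing parameters (mm, s).
#' @param flightThresh,flightMinDur flight parameters (mm/s, s).
#' @return an [Ethogram-class] with channels `freezing`, `sheltering`,
#'   `flight`.
#' @export
scoreEthogram <- function(track, arena, freezeThresh = 2, freezeMinDur = 0.5,
                          flightThresh = 150, flightMinDur = 0.2) {
  n <- dim(track@coords)[1]
  fr <- classifyFreezing(track, freezeThresh, freezeMinDur)
  sh <- classifySheltering(track, arena)
  fl <- classifyFlight(computeSpeed(track), flightThresh, flightMinDur)
  flightFrames <- c(FALSE, attr(fl, "frames"))
  Ethogram(list(freezing = attr(fr, "frames"),
                sheltering = attr(sh, "frames"),
                flight = flightFrames),
           fps = track@fps)
}

#' Maximal state intervals of an ethogram channel
#'
#' @param etho an [Ethogram-class].
#' @param channel channel name.
#' @return data.frame with `start_s`, `end_s` (seconds).
#' @export
stateIntervals <- function(etho, channel) {
  stopifnot(is(etho, "Ethogram"))
  if (!channel %in% names(etho@channels))
    stop(sprintf("no channel '%s'", channel))
  .runsToIntervals(.runsOf(etho@channels[[channel]]), etho@fps)
}

#' Pre/post-stimulus behavioral fractions
#'
#' Fraction of time each ethogram channel is active in the windows
#' `[anchor - window, anchor)` and `[anchor, anchor + window)`, where
#' the anchor is the first loom (or dim) onset of the timeline. Frames
#' are attributed to a window by their centre time. Windows extending
#' beyond the recording are truncated with a warning.
#'
#' @param etho an [Ethogram-class].
#' @param timeline an [EventTimeline-class].
#' @param window half-window, seconds (15 and 30 are the conventional
#'   choices).
#' @return data.frame with one row per channel: `channel`, `preFrac`,
#'   `postFrac`.
#' @export
periStimulusSummary <- function(etho, timeline, window = 30) {
  stopifnot(is(etho, "Ethogram"), is(timeline, "EventTimeline"), window > 0)
  ev <- events(timeline)
  stim <- ev[ev$kind %in% c("loom", "dim"), , drop = FALSE]
  if (!nrow(stim)) stop("timeline has no stimulus events")
  anchor <- min(stim$onset)
  n <- length(etho@channels[[1]])
  tc <- (seq_len(n) - 0.5) / etho@fps
  if (anchor - window < 0 || anchor + window > n / etho@fps)
    warning("window extends beyond the recording; truncating")
  pre <- tc >= anchor - window & tc < anchor
  post <- tc >= anchor & tc < anchor + window
  data.frame(
    channel = names(etho@channels),
    preFrac = vapply(etho@channels, function(ch) mean(ch[pre]), 1),
    postFrac = vapply(etho@channels, function(ch) mean(ch[post]), 1),
    row.names = NULL)
}

#' Maximum speed within a time window
#'
#' @param speed a [SpeedTrace-class].
#' @param window numeric `(start_s, end_s)`.
#' @return mm/s.
#' @export
topSpeed <- function(speed, window) {
  stopifnot(is(speed, "SpeedTrace"), length(window) == 2)
  sel <- speed@t >= window[1] & speed@t <= window[2]
  if (!any(sel)) stop("window contains no speed samples")
  max(speed@v[sel])
}

#' Stimulus-aligned speed heatmap
#'
#' One row per animal/trial, columns spanning `[-window, +window]`
#' around the first loom onset at the common frame rate. Values are
#' looked up at the nearest speed sample; out-of-range cells are `NA`.
#'
#' @param speeds list of [SpeedTrace-class] objects with a common `fps`.
#' @param timeline an [EventTimeline-class].
#' @param window half-window, seconds.
#' @return numeric matrix (trials x time) with the relative time axis in
#'   attribute `time`.
#' @export
speedHeatmap <- function(speeds, timeline, window = 30) {
  stopifnot(length(speeds) >= 1)
  fps <- unique(vapply(speeds, function(s) s@fps, 1))
  if (length(fps) != 1)
    stop("speed traces must share a common fps; resample first")
  ev <- events(timeline)
  stim <- ev[ev$kind %in% c("loom", "dim"), , drop = FALSE]
  if (!nrow(stim)) stop("timeline has no stimulus events")
  anchor <- min(stim$onset)
  tau <- seq(-window, window, by = 1 / fps)
  mat <- t(vapply(speeds, function(s) {
    idx <- round((anchor + tau - s@t[1]) * fps) + 1
    out <- rep(NA_real_, length(tau))
    ok <- idx >= 1 & idx <= length(s@v)
    out[ok] <- s@v[idx[ok]]
    out
  }, numeric(length(tau))))
  attr(mat, "time") <- tau
  mat
}

## ---------------------------------------------------------------------------
## Pose-table I/O
## ---------------------------------------------------------------------------

#' Read a pose-keypoint CSV (three-row-header dialect)
#'
#' Reads the standard pose-estimation export: a three-row header
#' (scorer / bodyparts / coords) over an index column and `x`,
#' `y`\[, `likelihood`\] columns per body part, one row per frame.
#' Coordinates are divided by `arena@pxPerMm` to calibrate to
#' millimetres. Keypoints with likelihood below `minLikelihood` are
#' linearly interpolated from neighbouring confident frames.
#'
#' @param path CSV path.
#' @param fps frames per second (pose tables do not record it).
#' @param arena an [ArenaGeometry-class]; its `pxPerMm` calibrates the
#'   coordinates.
#' @param tailParts keypoint names treated as tail (default: any name
#'   containing "tail").
#' @param minLikelihood confidence threshold for interpolation
#'   (default 0.6); ignored when the table has no likelihood columns.
#' @return a [PoseTrack-class] in mm units.
#' @export
readPoseTrack <- function(path, fps, arena = ArenaGeometry(),
                          tailParts = NULL, minLikelihood = 0.6) {
  hdr <- read.csv(path, header = FALSE, nrows = 3,
                  colClasses = "character")
  body <- read.csv(path, header = FALSE, skip = 3)
  partsRow <- as.character(unlist(hdr[2, -1]))
  coordsRow <- as.character(unlist(hdr[3, -1]))
  parts <- unique(partsRow)
  hasLik <- "likelihood" %in% coordsRow
  n <- nrow(body)
  coords <- array(NA_real_, c(n, length(parts), 2),
                  dimnames = list(NULL, parts, c("x", "y")))
  lik <- if (hasLik) matrix(NA_real_, n, length(parts),
                            dimnames = list(NULL, parts))
         else matrix(numeric(), 0, 0)
  for (j in seq_along(parts)) {
    cols <- which(partsRow == parts[j]) + 1L  # +1 for the index column
    cc <- coordsRow[cols - 1L]
    coords[, j, "x"] <- as.numeric(body[[cols[cc == "x"]]])
    coords[, j, "y"] <- as.numeric(body[[cols[cc == "y"]]])
    if (hasLik) lik[, j] <- as.numeric(body[[cols[cc == "likelihood"]]])
  }
  if (hasLik) {
    for (j in seq_along(parts)) {
      bad <- lik[, j] < minLikelihood
      if (any(bad) && !all(bad)) {
        good <- which(!bad)
        for (ax in c("x", "y"))
          coords[bad, j, ax] <- approx(good, coords[good, j, ax],
                                       xout = which(bad), rule = 2)$y
      }
    }
  }
  coords <- coords / arena@pxPerMm
  if (is.null(tailParts)) tailParts <- grep("tail", parts, value = TRUE)
  if (any(coords[, , "x"] < -1 | coords[, , "x"] > arena@width + 1,
          na.rm = TRUE) ||
      any(coords[, , "y"] < -1 | coords[, , "y"] > arena@length + 1,
          na.rm = TRUE))
    warning("calibrated coordinates fall outside the arena bounds")
  PoseTrack(coords, fps = fps, parts = parts, tailParts = tailParts,
            likelihood = lik)
}

#' @importFrom stats approx
NULL

#' Write a pose track in the three-row-header CSV dialect
#'
#' Inverse of [readPoseTrack()] (likelihood columns are written when
#' present). Coordinates are multiplied by `pxPerMm` so that a
#' write/read round trip through the same [ArenaGeometry-class] is the
#' identity.
#'
#' @param track a [PoseTrack-class].
#' @param path output CSV path.
#' @param scorer first-header-row label.
#' @param pxPerMm calibration used to convert mm back to pixels.
#' @return `path`, invisibly.
#' @export
writePoseTrack <- function(track, path, scorer = "loometry", pxPerMm = 1) {
  n <- dim(track@coords)[1]
  hasLik <- length(track@likelihood) > 0
  per <- if (hasLik) 3L else 2L
  parts <- track@parts
  cols <- vector("list", length(parts) * per)
  coordNames <- character(length(parts) * per)
  partNames <- character(length(parts) * per)
  k <- 1L
  for (j in seq_along(parts)) {
    cols[[k]] <- track@coords[, j, "x"] * pxPerMm; coordNames[k] <- "x"
    partNames[k] <- parts[j]; k <- k + 1L
    cols[[k]] <- track@coords[, j, "y"] * pxPerMm; coordNames[k] <- "y"
    partNames[k] <- parts[j]; k <- k + 1L
    if (hasLik) {
      cols[[k]] <- track@likelihood[, j]; coordNames[k] <- "likelihood"
      partNames[k] <- parts[j]; k <- k + 1L
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste(c("scorer", rep(scorer, length(cols))), collapse = ","),
    paste(c("bodyparts", partNames), collapse = ","),
    paste(c("coords", coordNames), collapse = ",")), con)
  body <- do.call(cbind, cols)
  write.table(cbind(seq_len(n) - 1L, format(body, trim = TRUE, digits = 10)),
              con, sep = ",", col.names = FALSE, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
NULL

#' Export an ethogram
#'
#' `writeEthogramBED()` writes a BED-like TSV (`channel`, `start_s`,
#' `end_s`, one row per maximal state interval); `writeEthogramWide()`
#' writes the per-frame wide CSV (`frame`, `time_s`, one 0/1 column per
#' channel).
#'
#' @param etho an [Ethogram-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEthogramBED <- function(etho, path) {
  rows <- do.call(rbind, lapply(names(etho@channels), function(ch) {
    iv <- stateIntervals(etho, ch)
    if (nrow(iv)) cbind(channel = ch, iv) else NULL
  }))
  if (is.null(rows))
    rows <- data.frame(channel = character(), start_s = numeric(),
                       end_s = numeric())
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEthogramBED
#' @export
writeEthogramWide <- function(etho, path) {
  n <- length(etho@channels[[1]])
  df <- data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1) / etho@fps)
  for (ch in names(etho@channels)) df[[ch]] <- as.integer(etho@channels[[ch]])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
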