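#' @import methods
#' @importFrom stats sd median var coef fft pt pf qt qnorm plogis
#'   t.test shapiro.test wilcox.test aov p.adjust lm predict rnorm runif
#'   rpois rbinom quantile complete.cases setNames
#' @importFrom utils read.csv write.csv packageVersion head tail
NULL

## ---------------------------------------------------------------------------
## Stimulus specifications
## ---------------------------------------------------------------------------

#' Looming stimulus specification
#'
#' Parameters of an expanding-disc ("looming") stimulus train: a dark disc
#' appears at `startDiam` degrees of visual angle, expands linearly to
#' `endDiam` over `expandDur` seconds, holds for `holdDur` seconds, then
#' disappears; this is repeated `nReps` times with `interRepInterval`
#' seconds between the end of one repetition and the start of the next.
#' The defaults reproduce the standard overhead-threat assay: 2° to 20°
#' in 250 ms, 250 ms hold, 15 repetitions, 500 ms gap (fundamental
#' period 1 s).
#'
#' @slot startDiam,endDiam degrees of visual angle at onset / full expansion.
#' @slot expandDur,holdDur,interRepInterval durations in seconds.
#' @slot nReps number of repetitions in a train.
#' @export
setClass("LoomSpec",
  representation(startDiam = "numeric", endDiam = "numeric",
                 expandDur = "numeric", holdDur = "numeric",
                 interRepInterval = "numeric", nReps = "integer"),
  prototype(startDiam = 2, endDiam = 20, expandDur = 0.25, holdDur = 0.25,
            interRepInterval = 0.5, nReps = 15L))

setValidity("LoomSpec", function(object) {
  msgs <- character()
  if (!(object@startDiam < object@endDiam))
    msgs <- c(msgs, "startDiam must be smaller than endDiam")
  for (s in c("expandDur", "holdDur", "interRepInterval"))
    if (!isTRUE(slot(object, s) > 0))
      msgs <- c(msgs, sprintf("%s must be > 0", s))
  if (object@nReps < 1L) msgs <- c(msgs, "nReps must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @param startDiam,endDiam,expandDur,holdDur,interRepInterval,nReps see slots.
#' @rdname LoomSpec-class
#' @return A validated `LoomSpec` object.
#' @examples
#' spec <- LoomSpec()                 # the standard 2->20 degree train
#' stimulusFundamentalFreq(spec)      # 1 Hz
#' @export
LoomSpec <- function(startDiam = 2, endDiam = 20, expandDur = 0.25,
                     holdDur = 0.25, interRepInterval = 0.5, nReps = 15) {
  new("LoomSpec", startDiam = as.numeric(startDiam),
      endDiam = as.numeric(endDiam), expandDur = as.numeric(expandDur),
      holdDur = as.numeric(holdDur),
      interRepInterval = as.numeric(interRepInterval),
      nReps = as.integer(nReps))
}

#' Dimming stimulus specification
#'
#' A disc of constant angular size whose contrast ramps linearly from
#' `contrastStart` to `contrastEnd` (fractions of full contrast) over
#' `rampDur` seconds, holds for `holdDur`, then disappears. Defaults:
#' 20° disc, 0 to 0.75 contrast in 250 ms, 250 ms hold, 15 repetitions
#' with 500 ms gaps — a salient but non-threatening control stimulus.
#'
#' @slot diam degrees of visual angle (constant).
#' @slot contrastStart,contrastEnd contrast as a fraction in \[0, 1\].
#' @slot rampDur,holdDur,interRepInterval seconds.
#' @slot nReps repetitions per train.
#' @export
setClass("DimSpec",
  representation(diam = "numeric", contrastStart = "numeric",
                 contrastEnd = "numeric", rampDur = "numeric",
                 holdDur = "numeric", interRepInterval = "numeric",
                 nReps = "integer"),
  prototype(diam = 20, contrastStart = 0, contrastEnd = 0.75,
            rampDur = 0.25, holdDur = 0.25, interRepInterval = 0.5,
            nReps = 15L))

setValidity("DimSpec", function(object) {
  msgs <- character()
  if (!(object@contrastStart >= 0 && object@contrastStart <= object@contrastEnd &&
        object@contrastEnd <= 1))
    msgs <- c(msgs, "need 0 <= contrastStart <= contrastEnd <= 1")
  for (s in c("rampDur", "holdDur", "interRepInterval"))
    if (!isTRUE(slot(object, s) > 0))
      msgs <- c(msgs, sprintf("%s must be > 0", s))
  if (object@nReps < 1L) msgs <- c(msgs, "nReps must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @param diam,contrastStart,contrastEnd,rampDur,holdDur,interRepInterval,nReps
#'   see slots.
#' @rdname DimSpec-class
#' @export
DimSpec <- function(diam = 20, contrastStart = 0, contrastEnd = 0.75,
                    rampDur = 0.25, holdDur = 0.25, interRepInterval = 0.5,
                    nReps = 15) {
  new("DimSpec", diam = as.numeric(diam),
      contrastStart = as.numeric(contrastStart),
      contrastEnd = as.numeric(contrastEnd), rampDur = as.numeric(rampDur),
      holdDur = as.numeric(holdDur),
      interRepInterval = as.numeric(interRepInterval), nReps = as.integer(nReps))
}

#' Foot-shock specification
#'
#' @slot current shock current in mA (default 0.75).
#' @slot duration seconds (default 2).
#' @slot coterminating if `TRUE` the shock ends exactly when the paired
#'   stimulus train ends.
#' @export
setClass("ShockSpec",
  representation(current = "numeric", duration = "numeric",
                 coterminating = "logical"),
  prototype(current = 0.75, duration = 2, coterminating = TRUE))

setValidity("ShockSpec", function(object) {
  if (!isTRUE(object@duration > 0)) "duration must be > 0" else TRUE
})

#' @param current,duration,coterminating see slots.
#' @rdname ShockSpec-class
#' @export
ShockSpec <- function(current = 0.75, duration = 2, coterminating = TRUE) {
  new("ShockSpec", current = as.numeric(current),
      duration = as.numeric(duration), coterminating = isTRUE(coterminating))
}

#' Optogenetic laser epoch
#'
#' One continuous or pulsed illumination epoch on the session clock.
#'
#' @slot onset,offset seconds on the session clock.
#' @slot wavelength nm.
#' @slot mode `"continuous"` or `"pulsed"`.
#' @slot pulseRate Hz (pulsed mode).
#' @slot pulseWidth seconds per pulse (pulsed mode).
#' @slot power mW.
#' @export
setClass("LaserEpoch",
  representation(onset = "numeric", offset = "numeric", wavelength = "numeric",
                 mode = "character", pulseRate = "numeric",
                 pulseWidth = "numeric", power = "numeric"),
  prototype(mode = "continuous", pulseRate = NA_real_, pulseWidth = NA_real_,
            power = 5))

setValidity("LaserEpoch", function(object) {
  msgs <- character()
  if (!isTRUE(object@offset > object@onset))
    msgs <- c(msgs, "offset must exceed onset")
  if (!object@mode %in% c("continuous", "pulsed"))
    msgs <- c(msgs, "mode must be 'continuous' or 'pulsed'")
  if (object@mode == "pulsed") {
    if (!isTRUE(object@pulseRate > 0) || !isTRUE(object@pulseWidth > 0))
      msgs <- c(msgs, "pulsed mode requires positive pulseRate and pulseWidth")
    else if (!isTRUE(object@pulseWidth <= 1 / object@pulseRate))
      msgs <- c(msgs, "pulseWidth must not exceed the pulse period")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param onset,offset,wavelength,mode,pulseRate,pulseWidth,power see slots.
#' @rdname LaserEpoch-class
#' @export
LaserEpoch <- function(onset, offset, wavelength, mode = "continuous",
                       pulseRate = NA_real_, pulseWidth = NA_real_,
                       power = 5) {
  new("LaserEpoch", onset = as.numeric(onset), offset = as.numeric(offset),
      wavelength = as.numeric(wavelength), mode = mode,
      pulseRate = as.numeric(pulseRate), pulseWidth = as.numeric(pulseWidth),
      power = as.numeric(power))
}

## ---------------------------------------------------------------------------
## Event timeline
## ---------------------------------------------------------------------------

#' Session event timeline
#'
#' An ordered set of typed stimulus events (`loom`, `dim`, `shock`,
#' `laser`) on a shared session clock in seconds, origin at recording
#' start. This is the object that aligns stimuli with photometry TTL
#' pulses and with pose-track frame times.
#'
#' @slot events a `data.frame` with columns `onset`, `offset` (seconds)
#'   and `kind` (character), sorted by onset.
#' @slot payload arbitrary per-timeline metadata (e.g. the generating
#'   stimulus specification).
#' @export
setClass("EventTimeline",
  representation(events = "data.frame", payload = "list"),
  prototype(events = data.frame(onset = numeric(), offset = numeric(),
                                kind = character()),
            payload = list()))

setValidity("EventTimeline", function(object) {
  ev <- object@events
  msgs <- character()
  if (!all(c("onset", "offset", "kind") %in% names(ev)))
    return("events must have columns onset, offset, kind")
  if (nrow(ev)) {
    if (is.unsorted(ev$onset)) msgs <- c(msgs, "events must be sorted by onset")
    if (any(ev$onset < 0)) msgs <- c(msgs, "onsets must be non-negative")
    if (any(ev$offset < ev$onset)) msgs <- c(msgs, "offset must be >= onset")
    ## events of one kind must not overlap
    for (k in unique(ev$kind)) {
      e <- ev[ev$kind == k, , drop = FALSE]
      if (nrow(e) > 1 && any(e$onset[-1] < e$offset[-nrow(e)] - 1e-12))
        msgs <- c(msgs, sprintf("overlapping '%s' events", k))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @param events,payload see slots.
#' @rdname EventTimeline-class
#' @export
EventTimeline <- function(events, payload = list()) {
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  new("EventTimeline", events = events, payload = payload)
}

#' @describeIn EventTimeline-class number of events.
#' @param x an `EventTimeline`.
#' @export
setMethod("length", "EventTimeline", function(x) nrow(x@events))

setMethod("show", "EventTimeline", function(object) {
  ev <- object@events
  cat(sprintf("EventTimeline with %d events", nrow(ev)))
  if (nrow(ev)) {
    kinds <- table(ev$kind)
    cat(" (", paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
        ")", sep = "")
    cat(sprintf("\n  span: %.3f-%.3f s\n", min(ev$onset), max(ev$offset)))
  } else cat("\n")
})

#' Accessors for event timelines
#'
#' `events()` returns the full event table; `onsets()`/`offsets()` the
#' onset/offset times, optionally restricted to one event kind.
#'
#' @param x an [EventTimeline-class].
#' @param kind optional event kind (`"loom"`, `"dim"`, `"shock"`, `"laser"`).
#' @return `events()`: a data.frame; `onsets()`/`offsets()`: numeric seconds.
#' @export
events <- function(x) x@events

#' @rdname events
#' @export
onsets <- function(x, kind = NULL) {
  ev <- x@events
  if (!is.null(kind)) ev <- ev[ev$kind == kind, , drop = FALSE]
  ev$onset
}

#' @rdname events
#' @export
offsets <- function(x, kind = NULL) {
  ev <- x@events
  if (!is.null(kind)) ev <- ev[ev$kind == kind, , drop = FALSE]
  ev$offset
}

## ---------------------------------------------------------------------------
## Arena, pose, ethogram
## ---------------------------------------------------------------------------

#' Arena geometry and pixel calibration
#'
#' Rectangular open-field arena with a shelter tube against the rear
#' wall. Coordinates are millimetres, origin at the front-left corner,
#' y increasing toward the rear (shelter) wall. The defaults are a
#' 460 mm x 300 mm floor with a 75 mm-wide, 150 mm-long shelter centred
#' on the rear wall.
#'
#' @slot width,length arena extent in mm (x and y axes).
#' @slot shelterBBox numeric of length 4: `xmin`, `xmax`, `ymin`, `ymax` (mm).
#' @slot pxPerMm calibration scalar used when importing pixel-unit pose
#'   tables.
#' @export
setClass("ArenaGeometry",
  representation(width = "numeric", length = "numeric",
                 shelterBBox = "numeric", pxPerMm = "numeric"),
  prototype(width = 460, length = 300,
            shelterBBox = c(xmin = 192.5, xmax = 267.5,
                            ymin = 150, ymax = 300),
            pxPerMm = 1))

setValidity("ArenaGeometry", function(object) {
  b <- object@shelterBBox
  msgs <- character()
  if (length(b) != 4) return("shelterBBox must have 4 elements")
  if (!isTRUE(object@pxPerMm > 0)) msgs <- c(msgs, "pxPerMm must be > 0")
  if (!(b[1] < b[2] && b[3] < b[4])) msgs <- c(msgs, "degenerate shelterBBox")
  if (b[1] < 0 || b[2] > object@width || b[3] < 0 || b[4] > object@length)
    msgs <- c(msgs, "shelterBBox must lie inside the arena")
  if (length(msgs)) msgs else TRUE
})

#' @param width,length,shelterBBox,pxPerMm see slots.
#' @rdname ArenaGeometry-class
#' @export
ArenaGeometry <- function(width = 460, length = 300,
                          shelterBBox = c(xmin = (width - 75) / 2,
                                          xmax = (width + 75) / 2,
                                          ymin = length - 150,
                                          ymax = length),
                          pxPerMm = 1) {
  bb <- as.numeric(shelterBBox)
  names(bb) <- c("xmin", "xmax", "ymin", "ymax")
  new("ArenaGeometry", width = as.numeric(width), length = as.numeric(length),
      shelterBBox = bb, pxPerMm = as.numeric(pxPerMm))
}

#' Default 14-keypoint body schema
#'
#' Keypoint names used by the pose generator and assumed by the default
#' readers: 11 body parts plus a 3-point tail. The tail subset is
#' excluded from sheltering and speed computations.
#' @return character vector of part names; the tail subset carries the
#'   attribute `tail`.
#' @export
defaultBodyParts <- function() {
  parts <- c("nose", "left_ear", "right_ear", "head", "spine1", "spine2",
             "spine3", "left_forepaw", "right_forepaw", "left_hindpaw",
             "right_hindpaw", "tail_base", "tail_mid", "tail_tip")
  attr(parts, "tail") <- c("tail_base", "tail_mid", "tail_tip")
  parts
}

#' Calibrated pose-keypoint track
#'
#' Per-frame (x, y) coordinates in millimetres for a fixed set of named
#' keypoints, sampled at `fps` frames per second, with an optional
#' per-keypoint tracking-likelihood matrix.
#'
#' @slot fps frames per second.
#' @slot parts ordered keypoint names.
#' @slot tailParts subset of `parts` treated as the tail.
#' @slot coords numeric array `frames x parts x 2` (x, y in mm).
#' @slot likelihood numeric matrix `frames x parts` (may be 0 x 0 when
#'   the source table carried no likelihood column).
#' @export
setClass("PoseTrack",
  representation(fps = "numeric", parts = "character",
                 tailParts = "character", coords = "array",
                 likelihood = "matrix"),
  prototype(likelihood = matrix(numeric(), 0, 0)))

setValidity("PoseTrack", function(object) {
  msgs <- character()
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 2)
    return("coords must be a frames x parts x 2 array")
  if (d[2] != length(object@parts))
    msgs <- c(msgs, "coords second dimension must match parts")
  if (!all(object@tailParts %in% object@parts))
    msgs <- c(msgs, "tailParts must be a subset of parts")
  if (!isTRUE(object@fps > 0)) msgs <- c(msgs, "fps must be > 0")
  if (anyNA(object@coords)) msgs <- c(msgs, "coords must be complete")
  if (length(msgs)) msgs else TRUE
})

#' @param coords,fps,parts,tailParts,likelihood see slots. `parts` defaults
#'   to [defaultBodyParts()] with its tail attribute.
#' @rdname PoseTrack-class
#' @export
PoseTrack <- function(coords, fps, parts = defaultBodyParts(),
                      tailParts = attr(parts, "tail"),
                      likelihood = matrix(numeric(), 0, 0)) {
  if (is.null(tailParts)) tailParts <- character()
  dimnames(coords) <- list(NULL, as.character(parts), c("x", "y"))
  new("PoseTrack", fps = as.numeric(fps), parts = as.character(parts),
      tailParts = as.character(tailParts), coords = coords,
      likelihood = likelihood)
}

#' @describeIn PoseTrack-class number of frames.
#' @param x a `PoseTrack`.
#' @export
setMethod("nrow", "PoseTrack", function(x) dim(x@coords)[1])

setMethod("show", "PoseTrack", function(object) {
  cat(sprintf("PoseTrack: %d frames x %d parts at %g fps (%.1f s)\n",
              dim(object@coords)[1], length(object@parts), object@fps,
              dim(object@coords)[1] / object@fps))
  cat("  tail subset:", paste(object@tailParts, collapse = ", "), "\n")
})

#' Non-tail part names of a pose track
#' @param track a [PoseTrack-class].
#' @return character vector.
#' @export
bodyParts <- function(track) setdiff(track@parts, track@tailParts)

#' Per-frame behavioral state channels
#'
#' Binary per-frame series for the independent behavioral definitions
#' (freezing, sheltering, flight). Channels may overlap. Interval
#' representations (maximal runs, in seconds) are derived on demand via
#' [stateIntervals()].
#'
#' @slot fps frames per second.
#' @slot channels named list of logical vectors of equal length.
#' @export
setClass("Ethogram",
  representation(fps = "numeric", channels = "list"))

setValidity("Ethogram", function(object) {
  ch <- object@channels
  if (!length(ch)) return("at least one channel required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  n <- unique(vapply(ch, length, 1L))
  if (length(n) != 1) return("channels must have equal length")
  if (!all(vapply(ch, is.logical, TRUE))) return("channels must be logical")
  if (!isTRUE(object@fps > 0)) return("fps must be > 0")
  TRUE
})

#' @param channels,fps see slots.
#' @rdname Ethogram-class
#' @export
Ethogram <- function(channels, fps) {
  new("Ethogram", fps = as.numeric(fps), channels = channels)
}

setMethod("show", "Ethogram", function(object) {
  n <- length(object@channels[[1]])
  cat(sprintf("Ethogram: %d frames at %g fps (%.1f s)\n", n, object@fps,
              n / object@fps))
  for (nm in names(object@channels))
    cat(sprintf("  %-10s %5.1f%% of frames\n", nm,
                100 * mean(object@channels[[nm]])))
})

#' Instantaneous locomotion speed derived from a pose track
#'
#' Speeds are finite differences of the non-tail centroid, one value per
#' inter-frame step, timestamped at frame midpoints.
#'
#' @slot t seconds (midpoint of each inter-frame step).
#' @slot v speed in mm/s, same length as `t`.
#' @slot fps frames per second of the source track.
#' @export
setClass("SpeedTrace",
  representation(t = "numeric", v = "numeric", fps = "numeric"))

setValidity("SpeedTrace", function(object) {
  if (length(object@t) != length(object@v)) return("t and v lengths differ")
  if (any(object@v < 0)) return("speeds must be non-negative")
  TRUE
})

#' @param t,v,fps see slots.
#' @rdname SpeedTrace-class
#' @export
SpeedTrace <- function(t, v, fps) {
  new("SpeedTrace", t = as.numeric(t), v = as.numeric(v),
      fps = as.numeric(fps))
}

setMethod("show", "SpeedTrace", function(object) {
  cat(sprintf("SpeedTrace: %d samples, median %.1f mm/s, max %.1f mm/s\n",
              length(object@v), median(object@v), max(object@v)))
})

## ---------------------------------------------------------------------------
## Photometry
## ---------------------------------------------------------------------------

#' Two-channel fiber-photometry recording
#'
#' @slot fs sampling rate, Hz.
#' @slot ch465 calcium-dependent (465 nm excitation) fluorescence.
#' @slot ch405 isosbestic (405 nm excitation) fluorescence, same length.
#' @slot ttl event timestamps in seconds (e.g. loom-train TTL rising edges).
#' @export
setClass("PhotometryRecording",
  representation(fs = "numeric", ch465 = "numeric", ch405 = "numeric",
                 ttl = "numeric"),
  prototype(ttl = numeric()))

setValidity("PhotometryRecording", function(object) {
  msgs <- character()
  if (length(object@ch465) != length(object@ch405))
    msgs <- c(msgs, "channel lengths differ")
  if (!isTRUE(object@fs > 0)) msgs <- c(msgs, "fs must be > 0")
  span <- length(object@ch465) / object@fs
  if (length(object@ttl) && (any(object@ttl < 0) || any(object@ttl > span)))
    msgs <- c(msgs, "ttl timestamps outside recording span")
  if (length(msgs)) msgs else TRUE
})

#' @param ch465,ch405,fs,ttl see slots.
#' @rdname PhotometryRecording-class
#' @export
PhotometryRecording <- function(ch465, ch405, fs, ttl = numeric()) {
  new("PhotometryRecording", fs = as.numeric(fs), ch465 = as.numeric(ch465),
      ch405 = as.numeric(ch405), ttl = as.numeric(ttl))
}

setMethod("show", "PhotometryRecording", function(object) {
  cat(sprintf("PhotometryRecording: %d samples at %g Hz (%.1f s), %d TTL events\n",
              length(object@ch465), object@fs,
              length(object@ch465) / object@fs, length(object@ttl)))
})

#' airPLS baseline-estimation parameters
#'
#' @slot lam second-difference smoothness penalty (lambda); larger values
#'   give stiffer baselines. Default `1e8`, suited to slow photobleaching
#'   at ~100 Hz sampling.
#' @slot maxIter maximum reweighting iterations.
#' @slot ratioTol convergence threshold: stop when the summed negative
#'   residual falls below `ratioTol` times the summed absolute signal.
#' @export
setClass("AirplsParams",
  representation(lam = "numeric", maxIter = "integer", ratioTol = "numeric"),
  prototype(lam = 1e8, maxIter = 50L, ratioTol = 0.001))

setValidity("AirplsParams", function(object) {
  msgs <- character()
  if (!isTRUE(object@lam > 0)) msgs <- c(msgs, "lam must be > 0")
  if (object@maxIter < 1L) msgs <- c(msgs, "maxIter must be >= 1")
  if (!(object@ratioTol > 0 && object@ratioTol < 1))
    msgs <- c(msgs, "ratioTol must be in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' @param lam,maxIter,ratioTol see slots.
#' @rdname AirplsParams-class
#' @export
AirplsParams <- function(lam = 1e8, maxIter = 50, ratioTol = 0.001) {
  new("AirplsParams", lam = as.numeric(lam), maxIter = as.integer(maxIter),
      ratioTol = as.numeric(ratioTol))
}

#' Processed photometry result (zdFF)
#'
#' Output of the full motion-correction chain: per-channel smoothing,
#' airPLS baseline subtraction, standardization, robust non-negative fit
#' of the standardized isosbestic channel to the standardized signal
#' channel (`y = a*x + b`), and subtraction of the fitted reference.
#'
#' @slot zdff corrected, standardized trace (same length as the input).
#' @slot base465,base405 airPLS baselines of the smoothed channels.
#' @slot a,b reference-fit slope (constrained `a >= 0`) and intercept.
#' @slot fs sampling rate, Hz.
#' @slot ttl event timestamps carried over from the recording.
#' @slot params provenance: every parameter used by every stage.
#' @export
setClass("ZdffResult",
  representation(zdff = "numeric", base465 = "numeric", base405 = "numeric",
                 a = "numeric", b = "numeric", fs = "numeric",
                 ttl = "numeric", params = "list"))

setValidity("ZdffResult", function(object) {
  msgs <- character()
  if (object@a < 0) msgs <- c(msgs, "slope a must be non-negative")
  if (length(object@zdff) != length(object@base465))
    msgs <- c(msgs, "zdff and baselines must share the input length")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ZdffResult", function(object) {
  cat(sprintf("ZdffResult: %d samples at %g Hz; reference fit a = %.4f, b = %.4f\n",
              length(object@zdff), object@fs, object@a, object@b))
})

#' Trials x time matrix of a signal aligned to event onsets
#'
#' @slot mat numeric matrix, one row per event.
#' @slot time seconds relative to onset (columns).
#' @slot eventIds identifiers of the rows (e.g. onset times).
#' @export
setClass("PeriEventMatrix",
  representation(mat = "matrix", time = "numeric", eventIds = "character"))

setValidity("PeriEventMatrix", function(object) {
  if (ncol(object@mat) != length(object@time))
    return("time axis must match matrix columns")
  if (nrow(object@mat) != length(object@eventIds))
    return("eventIds must match matrix rows")
  TRUE
})

setMethod("show", "PeriEventMatrix", function(object) {
  cat(sprintf("PeriEventMatrix: %d events x %d samples, t in [%.2f, %.2f] s\n",
              nrow(object@mat), ncol(object@mat), min(object@time),
              max(object@time)))
})

#' @describeIn PeriEventMatrix-class extract the numeric matrix.
#' @param object a `PeriEventMatrix`.
#' @export
periMatrix <- function(object) object@mat

#' @describeIn PeriEventMatrix-class the relative time axis (seconds).
#' @export
periTime <- function(object) object@time

## ---------------------------------------------------------------------------
## Statistics containers
## ---------------------------------------------------------------------------

#' Regression fit with confidence band
#'
#' Common container for the logistic (freezing probability ~ zdFF) and
#' linear (speed ~ zdFF) couplings. Use [predictBand()] to evaluate the
#' fitted curve with its 95% band.
#'
#' @slot kind `"logistic"` or `"linear"`.
#' @slot coefficients named numeric: `intercept`, `slope`.
#' @slot vcov 2x2 covariance matrix of the coefficients.
#' @slot n number of observations.
#' @slot converged,separated fitting diagnostics (separation applies to
#'   the logistic case: one predictor value splits the classes exactly).
#' @slot sigma residual standard deviation (linear case; `NA` otherwise).
#' @export
setClass("RegressionFit",
  representation(kind = "character", coefficients = "numeric",
                 vcov = "matrix", n = "integer", converged = "logical",
                 separated = "logical", sigma = "numeric"),
  prototype(converged = TRUE, separated = FALSE, sigma = NA_real_))

setValidity("RegressionFit", function(object) {
  msgs <- character()
  if (!object@kind %in% c("logistic", "linear"))
    msgs <- c(msgs, "kind must be 'logistic' or 'linear'")
  V <- object@vcov
  if (!all(dim(V) == c(2, 2)) || max(abs(V - t(V))) > 1e-8 * (1 + max(abs(V))))
    msgs <- c(msgs, "vcov must be symmetric 2x2")
  else if (any(eigen(V, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    msgs <- c(msgs, "vcov must be positive semidefinite")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("%s RegressionFit (n = %d): intercept = %.4f, slope = %.4f\n",
              object@kind, object@n, object@coefficients["intercept"],
              object@coefficients["slope"]))
  if (object@separated)
    cat("  warning: perfect separation detected; slope is not identified\n")
})

#' @describeIn RegressionFit-class coefficient accessor.
#' @param object a `RegressionFit`.
#' @param ... ignored.
#' @export
setMethod("coef", "RegressionFit", function(object, ...) object@coefficients)

#' Hypothesis-test result
#'
#' @slot statistic test statistic.
#' @slot df degrees of freedom (vector of length 1 or 2 for F tests).
#' @slot p p value.
#' @slot direction sign of the effect (first group/condition minus second).
#' @slot method test name.
#' @slot paired whether the samples were paired/within-subject.
#' @export
setClass("TestResult",
  representation(statistic = "numeric", df = "numeric", p = "numeric",
                 direction = "numeric", method = "character",
                 paired = "logical"),
  prototype(direction = NA_real_, paired = FALSE))

setValidity("TestResult", function(object) {
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    "p must lie in [0, 1]" else TRUE
})

TestResult <- function(statistic, df, p, direction = NA_real_, method,
                       paired = FALSE) {
  new("TestResult", statistic = as.numeric(statistic), df = as.numeric(df),
      p = as.numeric(p), direction = as.numeric(direction), method = method,
      paired = paired)
}

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s%s: statistic = %.4f, df = %s, p = %.4g\n", object@method,
              if (object@paired) " (paired)" else "", object@statistic,
              paste(signif(object@df, 6), collapse = ", "), object@p))
})

#' @describeIn TestResult-class the p value.
#' @param object a `TestResult`.
#' @export
pValue <- function(object) object@p

#' @describeIn TestResult-class the test statistic.
#' @export
testStatistic <- function(object) object@statistic
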