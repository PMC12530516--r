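## Stimulus-schedule modeling: exact event timelines and continuous
## trajectories (angular diameter, contrast) for looming, dimming, shock
## and laser epochs. Clock convention: seconds, origin at recording start.

#' Period and fundamental frequency of a stimulus train
#'
#' The repetition period is measured offset-to-onset: one repetition
#' lasts `expandDur + holdDur` (or `rampDur + holdDur`), followed by the
#' inter-repetition interval. With the default looming parameters
#' (0.25 + 0.25 + 0.5 s) the train repeats at exactly 1 Hz, which is the
#' frequency at which stimulus-locked calcium transients appear in the
#' signal spectrum.
#'
#' @param spec a [LoomSpec-class] or [DimSpec-class].
#' @return `stimulusPeriod()`: seconds; `stimulusFundamentalFreq()`: Hz.
#' @examples
#' stimulusFundamentalFreq(LoomSpec())  # 1
#' @export
stimulusPeriod <- function(spec) {
  validObject(spec)
  active <- if (is(spec, "LoomSpec")) spec@expandDur else spec@rampDur
  active + spec@holdDur + spec@interRepInterval
}

#' @rdname stimulusPeriod
#' @export
stimulusFundamentalFreq <- function(spec) 1 / stimulusPeriod(spec)

#' Build a looming (or dimming) stimulus train
#'
#' Lays out `nReps` repetitions on the session clock. Repetition `k`
#' (0-based) starts at `t0 + k * period` where
#' `period = activeDur + holdDur + interRepInterval`, and ends
#' `activeDur + holdDur` later (the disc disappears instantaneously; the
#' gap to the next onset is the inter-repetition interval).
#'
#' @param spec a [LoomSpec-class] (kind `"loom"`) or [DimSpec-class]
#'   (kind `"dim"`).
#' @param t0 onset of the first repetition, seconds on the session clock.
#' @return an [EventTimeline-class] with one event per repetition.
#' @examples
#' tl <- buildLoomTrain(LoomSpec(), t0 = 0)
#' onsets(tl)          # 0, 1, ..., 14
#' @export
buildLoomTrain <- function(spec, t0 = 0) {
  stopifnot(is(spec, "LoomSpec") || is(spec, "DimSpec"))
  validObject(spec)
  if (t0 < 0) stop("t0 must be non-negative")
  active <- if (is(spec, "LoomSpec")) spec@expandDur else spec@rampDur
  period <- stimulusPeriod(spec)
  on <- t0 + (seq_len(spec@nReps) - 1) * period
  kind <- if (is(spec, "LoomSpec")) "loom" else "dim"
  EventTimeline(data.frame(onset = on, offset = on + active + spec@holdDur,
                           kind = kind),
                payload = list(spec = spec))
}

#' @rdname buildLoomTrain
#' @export
buildDimTrain <- function(spec = DimSpec(), t0 = 0) buildLoomTrain(spec, t0)

#' Compose a multi-wave extinction session
#'
#' Extinction sessions present several waves of the looming train with a
#' rest between waves. The gap is measured offset-to-onset: each wave
#' starts `gap` seconds after the previous wave's last event ends.
#'
#' @param spec a [LoomSpec-class].
#' @param nWaves number of waves (default 3).
#' @param gap rest between waves, seconds (default 60).
#' @param t0 onset of the first wave.
#' @return an [EventTimeline-class] with `nWaves * nReps` loom events.
#' @export
buildExtinctionSession <- function(spec = LoomSpec(), nWaves = 3, gap = 60,
                                   t0 = 0) {
  stopifnot(nWaves >= 1, gap > 0)
  ev <- NULL
  start <- t0
  for (w in seq_len(nWaves)) {
    tl <- buildLoomTrain(spec, start)
    ev <- rbind(ev, events(tl))
    start <- max(events(tl)$offset) + gap
  }
  EventTimeline(ev, payload = list(spec = spec, nWaves = nWaves, gap = gap))
}

#' Angular diameter of the looming disc within one repetition
#'
#' Piecewise-linear trajectory: the disc expands linearly from
#' `startDiam` to `endDiam` over `expandDur`, then holds at `endDiam`
#' for `holdDur`. `t` is time within the repetition.
#'
#' @param spec a [LoomSpec-class].
#' @param t seconds since repetition onset (vectorized); must lie in
#'   `[0, expandDur + holdDur]`.
#' @return degrees of visual angle.
#' @examples
#' loomDiameterAt(LoomSpec(), c(0, 0.125, 0.25, 0.5))  # 2, 11, 20, 20
#' @export
loomDiameterAt <- function(spec, t) {
  stopifnot(is(spec, "LoomSpec"))
  validObject(spec)
  if (any(t < 0 | t > spec@expandDur + spec@holdDur))
    stop("t outside the event span [0, expandDur + holdDur]")
  ifelse(t <= spec@expandDur,
         spec@startDiam + (spec@endDiam - spec@startDiam) * t / spec@expandDur,
         spec@endDiam)
}

#' Contrast of the dimming disc within one repetition
#'
#' Linear ramp from `contrastStart` to `contrastEnd` over `rampDur`,
#' then hold. Contrast is a fraction in \[0, 1\]; multiply by 100 only at
#' I/O boundaries.
#'
#' @param spec a [DimSpec-class].
#' @param t seconds since repetition onset (vectorized), in
#'   `[0, rampDur + holdDur]`.
#' @return contrast fraction.
#' @export
dimContrastAt <- function(spec, t) {
  stopifnot(is(spec, "DimSpec"))
  validObject(spec)
  if (any(t < 0 | t > spec@rampDur + spec@holdDur))
    stop("t outside the event span [0, rampDur + holdDur]")
  ifelse(t <= spec@rampDur,
         spec@contrastStart +
           (spec@contrastEnd - spec@contrastStart) * t / spec@rampDur,
         spec@contrastEnd)
}

#' Build a fear-updating session (loom train + co-terminating shock)
#'
#' The updating paradigm pairs the looming train with a foot-shock that
#' ends exactly when the train ends: shock onset is the train offset
#' minus the shock duration. The `shockOnly` variant keeps the shock at
#' the same absolute time but emits no loom events.
#'
#' @param loom a [LoomSpec-class].
#' @param shock a [ShockSpec-class]; must be co-terminating.
#' @param t0 train onset, seconds.
#' @param shockOnly emit the shock without the visual stimulus.
#' @return an [EventTimeline-class].
#' @examples
#' tl <- buildUpdatingSession(LoomSpec(), ShockSpec(), t0 = 0)
#' tail(events(tl), 1)   # shock spanning [12.5, 14.5]
#' @export
buildUpdatingSession <- function(loom = LoomSpec(), shock = ShockSpec(),
                                 t0 = 0, shockOnly = FALSE) {
  stopifnot(is(loom, "LoomSpec"), is(shock, "ShockSpec"))
  validObject(loom); validObject(shock)
  if (!shock@coterminating)
    stop("updating sessions require a co-terminating shock")
  train <- buildLoomTrain(loom, t0)
  trainEnd <- max(events(train)$offset)
  if (shock@duration > trainEnd - t0)
    stop("shock duration exceeds the stimulus train duration")
  shockEv <- data.frame(onset = trainEnd - shock@duration, offset = trainEnd,
                        kind = "shock")
  ev <- if (shockOnly) shockEv else rbind(events(train), shockEv)
  EventTimeline(ev, payload = list(loom = loom, shock = shock,
                                   shockOnly = shockOnly))
}

#' Derive optogenetic laser epochs from a stimulus timeline
#'
#' Two regimes are used with activity-dependent engram tools:
#' `"labeling"` — one continuous 75 s epoch (473 nm blue light, 5 mW)
#' anchored at `anchor` seconds, opening the tagging window;
#' `"inhibition"` — one pulsed epoch (595 nm, 10 Hz, 20 ms pulses, 5 mW)
#' from 30 s before to 30 s after the first stimulus onset of the
#' timeline.
#'
#' @param mode `"labeling"` or `"inhibition"`.
#' @param timeline an [EventTimeline-class]; inhibition mode requires at
#'   least one loom or dim event.
#' @param anchor labeling-epoch onset, seconds (default 60: one minute
#'   into the acclimation period).
#' @return list of [LaserEpoch-class] objects (length 1).
#' @export
buildLaserEpochs <- function(mode = c("labeling", "inhibition"),
                             timeline = NULL, anchor = 60) {
  mode <- match.arg(mode)
  if (mode == "labeling") {
    return(list(LaserEpoch(onset = anchor, offset = anchor + 75,
                           wavelength = 473, mode = "continuous", power = 5)))
  }
  if (is.null(timeline) || !length(timeline))
    stop("inhibition mode requires a timeline with stimulus events")
  ev <- events(timeline)
  stim <- ev[ev$kind %in% c("loom", "dim"), , drop = FALSE]
  if (!nrow(stim)) stop("inhibition mode requires loom or dim events")
  first <- min(stim$onset)
  list(LaserEpoch(onset = first - 30, offset = first + 30, wavelength = 595,
                  mode = "pulsed", pulseRate = 10, pulseWidth = 0.02,
                  power = 5))
}

## ---------------------------------------------------------------------------
## Timeline I/O
## ---------------------------------------------------------------------------

#' Read and write event timelines as JSON
#'
#' The on-disk form is `{"events": [{"onset": .., "offset": .., "kind":
#' ".."}, ...]}` with seconds on a 0-based session clock. `payload`
#' metadata is not serialized (it may hold arbitrary S4 objects);
#' round-tripping preserves the event table exactly.
#'
#' @param timeline an [EventTimeline-class].
#' @param path file path.
#' @return `readTimelineJSON()` returns an [EventTimeline-class];
#'   `writeTimelineJSON()` returns `path` invisibly.
#' @export
writeTimelineJSON <- function(timeline, path) {
  ev <- events(timeline)
  jsonlite::write_json(list(events = ev), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTimelineJSON
#' @export
readTimelineJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(obj$events)
  ev$onset <- as.numeric(ev$onset)
  ev$offset <- as.numeric(ev$offset)
  ev$kind <- as.character(ev$kind)
  EventTimeline(ev)
}

#' Import TTL rising-edge timestamps
#'
#' Accepts either a plain text file with one timestamp (seconds) per
#' line or a CSV with a named column. Timestamps mark loom-train onsets
#' on the acquisition clock; per-repetition onsets are reconstructed
#' from the stimulus specification with [ttlToLoomOnsets()].
#'
#' @param path file path.
#' @param column column name when `path` is a CSV; `NULL` reads one
#'   float per line.
#' @return numeric timestamps, seconds.
#' @export
readTTL <- function(path, column = NULL) {
  if (is.null(column)) {
    ts <- as.numeric(readLines(path))
  } else {
    df <- read.csv(path)
    if (!column %in% names(df))
      stop(sprintf("column '%s' not found in %s", column, path))
    ts <- as.numeric(df[[column]])
  }
  if (anyNA(ts)) stop("non-numeric TTL timestamps")
  sort(ts)
}

#' Expand TTL train markers into per-repetition loom onsets
#'
#' Each TTL timestamp is taken as the onset of one full train described
#' by `spec`; the per-repetition onsets follow at multiples of the
#' train period.
#'
#' @param ttl numeric train-onset timestamps, seconds.
#' @param spec a [LoomSpec-class].
#' @return numeric vector of per-repetition onsets.
#' @export
ttlToLoomOnsets <- function(ttl, spec = LoomSpec()) {
  period <- stimulusPeriod(spec)
  as.numeric(vapply(sort(ttl),
                    function(t0) t0 + (seq_len(spec@nReps) - 1) * period,
                    numeric(spec@nReps)))
}
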