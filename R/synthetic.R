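## Seeded generators for pose tracks, photometry recordings and
## cell-count tables with recorded ground truth. Every generator is a
## pure function of (specification, seed): the global RNG state is
## saved and restored around the draw.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  force(expr)
}

#' Behavioral bout script
#'
#' Ordered sequence of scripted behavioral states with durations,
#' driving [genPoseTrack()]. States: `locomote` (correlated random
#' walk, ~90 mm/s), `freeze` (static body + tracking jitter), `shelter`
#' (body inside the shelter tube with small dithering), `flight`
#' (straight dash toward the shelter at ~300 mm/s).
#'
#' @param states character vector from
#'   `c("locomote", "freeze", "shelter", "flight")`.
#' @param durations seconds per bout, positive.
#' @param jitterSd per-frame, per-keypoint tracking jitter in mm
#'   (default 0.3, a typical pose-estimation residual).
#' @param fps frames per second (default 30).
#' @return data.frame (`state`, `duration`) with attributes `jitterSd`
#'   and `fps`.
#' @export
boutScript <- function(states, durations, jitterSd = 0.3, fps = 30) {
  vocab <- c("locomote", "freeze", "shelter", "flight")
  if (!all(states %in% vocab))
    stop(sprintf("states must be among: %s", paste(vocab, collapse = ", ")))
  if (length(states) != length(durations) || any(durations <= 0))
    stop("durations must be positive, one per state")
  out <- data.frame(state = states, duration = durations)
  attr(out, "jitterSd") <- jitterSd
  attr(out, "fps") <- fps
  out
}

## 14-keypoint body template: offsets (mm) from the centroid of the
## non-tail parts, mouse facing +y. Matches defaultBodyParts() order.
.bodyTemplate <- function() {
  rbind(nose = c(0, 45), left_ear = c(-12, 32), right_ear = c(12, 32),
        head = c(0, 30), spine1 = c(0, 15), spine2 = c(0, 0),
        spine3 = c(0, -15), left_forepaw = c(-14, 18),
        right_forepaw = c(14, 18), left_hindpaw = c(-14, -12),
        right_hindpaw = c(14, -12), tail_base = c(0, -28),
        tail_mid = c(0, -48), tail_tip = c(0, -68))
}

#' Generate a pose track from a bout script
#'
#' Simulates a 14-keypoint mouse as a rigid body template following a
#' scripted centroid trajectory, with independent Gaussian tracking
#' jitter per keypoint and frame, and returns the track together with
#' the ground-truth ethogram implied by the script. During `locomote`
#' the centroid performs a persistent random walk (3 mm/frame) kept in
#' the front part of the arena; `freeze` holds the centroid; `shelter`
#' teleports the body into the shelter tube and dithers it (2.5
#' mm/frame) so that sheltering does not read as freezing; `flight`
#' dashes toward the shelter entrance at 10 mm/frame. Coordinates are
#' clamped to the arena.
#'
#' @param script a [boutScript()].
#' @param arena an [ArenaGeometry-class].
#' @param seed integer seed (generation is a pure function of
#'   script/arena/seed).
#' @return list with `track` (a [PoseTrack-class]) and `truth` (an
#'   [Ethogram-class] with channels `freezing`, `sheltering`,
#'   `flight`).
#' @export
genPoseTrack <- function(script, arena = ArenaGeometry(), seed = 1) {
  fps <- attr(script, "fps")
  jitterSd <- attr(script, "jitterSd")
  template <- .bodyTemplate()
  parts <- defaultBodyParts()
  stopifnot(identical(rownames(template), as.character(parts)))
  nb <- pmax(1L, as.integer(round(script$duration * fps)))
  n <- sum(nb)
  shelterCenter <- c(mean(arena@shelterBBox[c("xmin", "xmax")]),
                     mean(arena@shelterBBox[c("ymin", "ymax")]))
  ## roaming bounds keep every template point (tail included) inside the
  ## arena and every non-tail point clear of the shelter y-limits
  lo <- c(40, 75)
  hi <- c(arena@width - 40, min(arena@length - 60,
                                arena@shelterBBox["ymin"] - 25))
  if (max(abs(range(script$duration))) * fps > 1e7)
    warning("script implies an implausibly long traversal")
  .withSeed(seed, {
    cx <- numeric(n); cy <- numeric(n)
    pos <- c(mean(c(lo[1], hi[1])), mean(c(lo[2], hi[2])))
    heading <- runif(1, 0, 2 * pi)
    frame <- 0L
    states <- rep(script$state, nb)
    for (b in seq_len(nrow(script))) {
      st <- script$state[b]
      for (k in seq_len(nb[b])) {
        frame <- frame + 1L
        if (st == "locomote") {
          heading <- heading + rnorm(1, 0, 0.4)
          step <- 3 * c(cos(heading), sin(heading))
          pos <- pos + step
          ## reflect off the roaming bounds
          for (ax in 1:2) {
            if (pos[ax] < lo[ax]) { pos[ax] <- 2 * lo[ax] - pos[ax]
                                    heading <- heading + pi / 2 }
            if (pos[ax] > hi[ax]) { pos[ax] <- 2 * hi[ax] - pos[ax]
                                    heading <- heading + pi / 2 }
          }
        } else if (st == "flight") {
          target <- c(shelterCenter[1], arena@shelterBBox["ymin"] - 40)
          dirv <- target - pos
          dst <- sqrt(sum(dirv^2))
          if (dst > 12) {
            pos <- pos + 10 * dirv / dst
          } else {
            ## pace at flight speed near the entrance
            heading <- runif(1, 0, 2 * pi)
            pos <- pmin(pmax(pos + 10 * c(cos(heading), sin(heading)), lo), hi)
          }
        } else if (st == "shelter") {
          if (k == 1L) pos <- shelterCenter - c(0, 35)
          step <- 2.5 * c(cos(runif(1, 0, 2 * pi)), sin(runif(1, 0, 2 * pi)))
          cand <- pos + step
          box <- shelterCenter - c(0, 35)
          cand <- pmin(pmax(cand, box - 8), box + 8)
          pos <- cand
        } ## freeze: pos unchanged
        cx[frame] <- pos[1]; cy[frame] <- pos[2]
      }
    }
    coords <- array(NA_real_, c(n, nrow(template), 2))
    jx <- matrix(rnorm(n * nrow(template), 0, jitterSd), n)
    jy <- matrix(rnorm(n * nrow(template), 0, jitterSd), n)
    coords[, , 1] <- pmin(pmax(outer(cx, template[, 1], `+`) + jx, 0),
                          arena@width)
    coords[, , 2] <- pmin(pmax(outer(cy, template[, 2], `+`) + jy, 0),
                          arena@length)
    track <- PoseTrack(coords, fps = fps, parts = parts)
    ## freezing/flight ground truth follows the script; sheltering is a
    ## geometric definition, so its truth is containment of the
    ## noiseless template (a freeze scripted inside the shelter IS
    ## sheltering)
    bodyIdx <- which(!parts %in% attr(parts, "tail"))
    bb <- arena@shelterBBox
    inY <- vapply(seq_len(n), function(i)
      all(cy[i] + template[bodyIdx, 2] >= bb["ymin"] &
          cy[i] + template[bodyIdx, 2] <= bb["ymax"]), TRUE)
    inX <- vapply(seq_len(n), function(i)
      sum(cx[i] + template[bodyIdx, 1] >= bb["xmin"] &
          cx[i] + template[bodyIdx, 1] <= bb["xmax"]) >=
        length(bodyIdx) / 2, TRUE)
    truth <- Ethogram(list(freezing = states == "freeze",
                           sheltering = inY & inX,
                           flight = states == "flight"), fps = fps)
    list(track = track, truth = truth)
  })
}

#' Photometry simulation specification
#'
#' Defaults describe a 60 s, 100 Hz two-channel recording: a shared
#' double-exponential photobleaching baseline, a shared low-frequency
#' motion artifact (Ornstein-Uhlenbeck process low-passed at 0.5 Hz),
#' calcium transients (double-exponential kernel, 50 ms rise / 800 ms
#' decay) only in the signal channel, channel coupling
#' `ch465 = aTrue * (bleach + artifact) + bTrue + transients + noise`,
#' and independent Gaussian sensor noise per channel.
#'
#' @param fs Hz. @param duration seconds.
#' @param bleach list `A0` (offset), `A1`, `tau1`, `A2`, `tau2`.
#' @param artifactSd stationary SD of the shared motion artifact.
#' @param artifactTau OU time constant, seconds.
#' @param artifactCutoff low-pass corner, Hz.
#' @param transientAmp peak transient amplitude (signal units).
#' @param tauRise,tauDecay transient kernel time constants, seconds.
#' @param aTrue,bTrue channel coupling (slope must be non-negative).
#' @param noiseSd per-channel Gaussian noise SD.
#' @param eventTimes transient onset times, seconds.
#' @return a list of class `"PhotometrySimSpec"`.
#' @export
photometrySimSpec <- function(fs = 100, duration = 60,
                              bleach = list(A0 = 0.8, A1 = 0.6, tau1 = 400,
                                            A2 = 0.2, tau2 = 60),
                              artifactSd = 0.04, artifactTau = 0.5,
                              artifactCutoff = 0.5, transientAmp = 0.05,
                              tauRise = 0.05, tauDecay = 0.8, aTrue = 0.8,
                              bTrue = 0.1, noiseSd = 0.005,
                              eventTimes = numeric()) {
  stopifnot(fs > 0, duration > 0, tauRise > 0, tauDecay > 0, aTrue >= 0)
  structure(list(fs = fs, duration = duration, bleach = bleach,
                 artifactSd = artifactSd, artifactTau = artifactTau,
                 artifactCutoff = artifactCutoff,
                 transientAmp = transientAmp, tauRise = tauRise,
                 tauDecay = tauDecay, aTrue = aTrue, bTrue = bTrue,
                 noiseSd = noiseSd, eventTimes = eventTimes),
            class = "PhotometrySimSpec")
}

#' Generate a two-channel photometry recording with known ground truth
#'
#' @param spec a [photometrySimSpec()].
#' @param seed integer seed.
#' @return list with `recording` (a [PhotometryRecording-class], TTL =
#'   the event times) and `truth` (transient times and amplitude,
#'   `aTrue`, `bTrue`, the shared bleaching baseline and artifact, and
#'   the per-channel noiseless baselines).
#' @export
genPhotometry <- function(spec = photometrySimSpec(), seed = 1) {
  stopifnot(inherits(spec, "PhotometrySimSpec"))
  n <- as.integer(round(spec$fs * spec$duration))
  t <- (seq_len(n) - 1) / spec$fs
  bl <- spec$bleach
  bleach <- bl$A0 + bl$A1 * exp(-t / bl$tau1) + bl$A2 * exp(-t / bl$tau2)
  ## transient kernel, peak-normalized
  kt <- seq(0, 5, by = 1 / spec$fs)
  kern <- exp(-kt / spec$tauDecay) - exp(-kt / spec$tauRise)
  kern <- kern / max(kern)
  transients <- numeric(n)
  for (et in spec$eventTimes) {
    i0 <- as.integer(round(et * spec$fs)) + 1L
    if (i0 < 1 || i0 > n) next
    idx <- i0:min(n, i0 + length(kern) - 1L)
    transients[idx] <- transients[idx] +
      spec$transientAmp * kern[seq_along(idx)]
  }
  .withSeed(seed, {
    ## OU artifact, then zero-phase low-pass, rescaled to the target SD
    rho <- exp(-1 / (spec$fs * spec$artifactTau))
    innov <- rnorm(n, 0, spec$artifactSd * sqrt(1 - rho^2))
    ou <- as.numeric(stats::filter(innov, rho, method = "recursive"))
    bf <- signal::butter(2, spec$artifactCutoff / (spec$fs / 2), "low")
    art <- as.numeric(signal::filtfilt(bf, ou))
    if (sd(art) > 0) art <- art * spec$artifactSd / sd(art)
    shared <- bleach + art
    ch405 <- shared + rnorm(n, 0, spec$noiseSd)
    ch465 <- spec$aTrue * shared + spec$bTrue + transients +
             rnorm(n, 0, spec$noiseSd)
    rec <- PhotometryRecording(
      ch465 = ch465, ch405 = ch405, fs = spec$fs,
      ttl = spec$eventTimes[spec$eventTimes >= 0 &
                            spec$eventTimes <= (n - 1) / spec$fs])
    list(recording = rec,
         truth = list(transientTimes = spec$eventTimes,
                      transientAmp = spec$transientAmp,
                      aTrue = spec$aTrue, bTrue = spec$bTrue,
                      bleach = bleach, artifact = art,
                      base465 = spec$aTrue * bleach + spec$bTrue,
                      base405 = bleach, transients = transients))
  })
}

#' Generate a per-mouse, per-region cell-count table
#'
#' For each mouse and region: sampled DAPI density and counted area are
#' drawn around realistic confocal values; the EYFP-tagged population
#' is Poisson; double-positive cells are Binomial(`n_eyfp`,
#' `trueReact`); additional c-Fos cells among the untagged population
#' are Binomial with rate `trueCfos`, so `n_double <= min(n_eyfp,
#' n_cfos)` holds by construction.
#'
#' @param groups named list; each element is a list with `nMice`,
#'   `trueReact` (per-region or scalar reactivation probability),
#'   `trueCfos` and `nEyfpMean`.
#' @param regions character region names (default the seven regions of
#'   the defensive circuit and hippocampus panels).
#' @param seed integer seed.
#' @return data.frame in the [validateRegionCounts()] schema, with the
#'   generating probabilities as attributes `trueReact`/`trueCfos`.
#' @export
genRegionCounts <- function(groups, regions = c("SCs", "SCd", "PAGdm",
                                                "PAGdl", "PAGl", "dDG",
                                                "vCA1"), seed = 1) {
  .withSeed(seed, {
    rows <- list()
    mouseId <- 0L
    for (g in names(groups)) {
      gi <- groups[[g]]
      react <- rep_len(gi$trueReact, length(regions))
      cfos <- rep_len(gi$trueCfos, length(regions))
      if (any(react < 0 | react > 1 | cfos < 0 | cfos > 1))
        stop("probabilities must lie in [0, 1]")
      for (m in seq_len(gi$nMice)) {
        mouseId <- mouseId + 1L
        for (ri in seq_along(regions)) {
          density <- runif(1, 0.0010, 0.0020)       # cells/um^2
          area <- runif(1, 4, 8) * 1e5              # um^2 counted
          total <- floor(density * area)
          nEyfp <- rpois(1, gi$nEyfpMean)
          nEyfp <- min(nEyfp, total)
          nDouble <- rbinom(1, nEyfp, react[ri])
          nCfos <- nDouble + rbinom(1, total - nEyfp, cfos[ri])
          rows[[length(rows) + 1L]] <- data.frame(
            mouse = sprintf("m%03d", mouseId), group = g,
            region = regions[ri], dapi_density = density,
            region_area = area, n_images = 4L, n_eyfp = nEyfp,
            n_cfos = nCfos, n_double = nDouble)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "trueReact") <- lapply(groups, `[[`, "trueReact")
    attr(out, "trueCfos") <- lapply(groups, `[[`, "trueCfos")
    validateRegionCounts(out)
    out
  })
}
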