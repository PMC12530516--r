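## Shared fixtures and small oracles used across the suite.

## intersection-over-union of two logical vectors
iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

## a pose track built directly from a centroid path (no jitter):
## all 14 template keypoints ride rigidly on the path
trackFromPath <- function(cx, cy, fps = 30, parts = defaultBodyParts()) {
  template <- rbind(c(0, 45), c(-12, 32), c(12, 32), c(0, 30), c(0, 15),
                    c(0, 0), c(0, -15), c(-14, 18), c(14, 18), c(-14, -12),
                    c(14, -12), c(0, -28), c(0, -48), c(0, -68))
  n <- length(cx)
  coords <- array(NA_real_, c(n, length(parts), 2))
  coords[, , 1] <- outer(cx, template[seq_along(parts), 1], `+`)
  coords[, , 2] <- outer(cy, template[seq_along(parts), 2], `+`)
  PoseTrack(coords, fps = fps, parts = parts)
}

## fully static track at a fixed centroid
staticTrack <- function(nFrames, cx = 230, cy = 100, fps = 30) {
  trackFromPath(rep(cx, nFrames), rep(cy, nFrames), fps = fps)
}

## track for the freezing-boundary searches: continuous supra-threshold
## motion with all keypoints held static for `holdSteps` inter-frame
## steps in the middle (the immobile period spans holdSteps/fps seconds)
embeddedStillTrack <- function(holdSteps, fps = 30, step = 5,
                               motionFrames = 30) {
  dx <- c(rep(step, motionFrames), rep(0, holdSteps),
          rep(step, motionFrames))
  cx <- 40 + cumsum(c(0, dx)) %% 300
  trackFromPath(cx, rep(100, length(cx)), fps = fps)
}

## standard loom-locked synthetic recording used by photometry tests
loomLockedRecording <- function(seed, t0 = 20, duration = 60, ...) {
  tl <- buildLoomTrain(LoomSpec(), t0 = t0)
  genPhotometry(photometrySimSpec(duration = duration,
                                  eventTimes = onsets(tl, "loom"), ...),
                seed = seed)
}

## brute-force BH step-up q values (independent oracle): on sorted p,
## q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, mapped back
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}
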