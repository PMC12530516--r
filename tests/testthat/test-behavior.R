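test_that("movement flags threshold per-part displacement at 2 mm inclusive", {
  tr <- staticTrack(20)
  expect_false(any(movementFlags(tr)))
  ## one part displaced exactly 2 mm in one step is flagged at that frame
  coords <- tr@coords
  coords[10:20, "nose", "x"] <- coords[10:20, "nose", "x"] + 2
  tr2 <- PoseTrack(coords, fps = 30)
  fl <- movementFlags(tr2, thresh = 2)
  expect_true(fl[10, "nose"])
  expect_false(fl[11, "nose"])
  expect_false(any(fl[, colnames(fl) != "nose"]))
  ## just under threshold is not movement
  coords[10:20, "nose", "x"] <- tr@coords[10:20, "nose", "x"] + 1.99
  expect_false(any(movementFlags(PoseTrack(coords, fps = 30))))
  expect_error(movementFlags(staticTrack(1)), "two frames")
})

test_that("movement flags equal brute-force pairwise distances on random walks", {
  set.seed(11)
  n <- 120
  coords <- array(rnorm(n * 14 * 2, sd = 1.2), c(n, 14, 2))
  coords <- coords + 100
  tr <- PoseTrack(coords, fps = 30)
  fl <- movementFlags(tr, thresh = 2)
  oracle <- matrix(NA, n, 14)
  for (i in 2:n) for (p in 1:14)
    oracle[i, p] <- sqrt(sum((coords[i, p, ] - coords[i - 1, p, ])^2)) >= 2
  oracle[1, ] <- oracle[2, ]
  expect_identical(unname(fl), oracle)
})

test_that("freezing requires at most one moving part for at least 0.5 s", {
  ## full-track immobility gives one interval spanning the whole track
  tr <- staticTrack(300)  # 10 s at 30 fps
  iv <- classifyFreezing(tr)
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$start_s, iv$end_s), c(0, 10))
  ## an immobility run of exactly 0.5 s counts; 0.4 s does not
  iv15 <- classifyFreezing(embeddedStillTrack(15))
  expect_equal(nrow(iv15), 1L)
  expect_equal(iv15$end_s - iv15$start_s, 0.5)
  expect_equal(nrow(classifyFreezing(embeddedStillTrack(12))), 0L)
  ## one moving part does not break a freeze; two do
  tr2 <- staticTrack(60)
  coords <- tr2@coords
  coords[, "nose", "x"] <- coords[, "nose", "x"] + cumsum(rep(3, 60))
  expect_equal(nrow(classifyFreezing(PoseTrack(coords, fps = 30))), 1L)
  coords[, "head", "y"] <- coords[, "head", "y"] + cumsum(rep(3, 60))
  expect_equal(nrow(classifyFreezing(PoseTrack(coords, fps = 30))), 0L)
})

test_that("raising the movement threshold never removes freezing frames", {
  set.seed(5)
  sc <- boutScript(rep(c("locomote", "freeze"), 4), rep(c(2, 1.5), 4))
  tr <- genPoseTrack(sc, seed = 9)$track
  prev <- attr(classifyFreezing(tr, thresh = 1), "frames")
  for (th in c(2, 3, 5, 8)) {
    cur <- attr(classifyFreezing(tr, thresh = th), "frames")
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("freezing intervals are invariant under time reversal", {
  sc <- boutScript(c("locomote", "freeze", "locomote"), c(2, 1, 2))
  tr <- genPoseTrack(sc, seed = 21)$track
  rev <- PoseTrack(tr@coords[dim(tr@coords)[1]:1, , , drop = FALSE],
                   fps = tr@fps)
  f1 <- attr(classifyFreezing(tr), "frames")
  f2 <- attr(classifyFreezing(rev), "frames")
  ## boundary frames may shift by one (frame-1 flag copying); interior match
  expect_gt(iou(f1, base::rev(f2)), 0.9)
})

test_that("sheltering follows the all-in-y, half-in-x containment rule", {
  arena <- ArenaGeometry()
  ## whole body centred in the shelter
  tr <- staticTrack(10, cx = 230, cy = 190)
  iv <- classifySheltering(tr, arena)
  expect_equal(nrow(iv), 1L)
  expect_true(all(attr(iv, "frames")))
  ## body far from the shelter
  expect_equal(nrow(classifySheltering(staticTrack(10), arena)), 0L)
})

test_that("sheltering x-rule boundary sits exactly at half the non-tail parts", {
  ## even-count schema: 4 body parts + 1 tail part
  parts <- c("a", "b", "c", "d", "tail_base")
  attr(parts, "tail") <- "tail_base"
  arena <- ArenaGeometry()
  bb <- arena@shelterBBox
  mk <- function(nInX) {
    ## all parts inside y-limits; nInX of the 4 body parts inside x-limits
    x <- c(rep(bb["xmin"] + 5, nInX), rep(bb["xmin"] - 20, 4 - nInX), 100)
    y <- rep(bb["ymin"] + 40, 5)
    coords <- array(NA_real_, c(5, 5, 2))
    for (f in 1:5) { coords[f, , 1] <- x; coords[f, , 2] <- y }
    PoseTrack(coords, fps = 30, parts = parts)
  }
  expect_true(all(attr(classifySheltering(mk(2), arena), "frames")))
  expect_false(any(attr(classifySheltering(mk(1), arena), "frames")))
})

test_that("sheltering ignores arbitrary tail motion", {
  set.seed(2)
  tr <- staticTrack(40, cx = 230, cy = 190)
  coords <- tr@coords
  for (p in c("tail_base", "tail_mid", "tail_tip")) {
    coords[, p, "x"] <- runif(40, 0, 460)
    coords[, p, "y"] <- runif(40, 0, 300)
  }
  wild <- PoseTrack(coords, fps = 30)
  expect_true(all(attr(classifySheltering(wild, ArenaGeometry()), "frames")))
})

test_that("speed is the fps-scaled finite difference of the body centroid", {
  expect_equal(computeSpeed(staticTrack(20))@v, rep(0, 19))
  ## centroid moving 10 mm per frame at 30 fps -> 300 mm/s
  tr <- trackFromPath(seq(40, by = 10, length.out = 30), rep(100, 30))
  expect_equal(computeSpeed(tr)@v, rep(300, 29))
  ## random track equals brute-force differencing of the non-tail centroid
  set.seed(3)
  n <- 80
  coords <- array(rnorm(n * 14 * 2, 100, 5), c(n, 14, 2))
  tr2 <- PoseTrack(coords, fps = 25)
  sp <- computeSpeed(tr2)
  body <- seq_len(11)  # non-tail in the default schema
  cen <- cbind(rowMeans(coords[, body, 1]), rowMeans(coords[, body, 2]))
  oracle <- sqrt(rowSums((cen[-1, ] - cen[-n, ])^2)) * 25
  expect_equal(sp@v, oracle)
  expect_equal(sp@t, (seq_len(n - 1) - 0.5) / 25)
})

test_that("speed scales linearly with a calibration error", {
  set.seed(8)
  n <- 50
  coords <- array(rnorm(n * 14 * 2, 100, 4), c(n, 14, 2))
  v1 <- computeSpeed(PoseTrack(coords, fps = 30))@v
  v2 <- computeSpeed(PoseTrack(coords * 2.5, fps = 30))@v
  expect_equal(v2, 2.5 * v1)
})

test_that("flight requires sustained supra-threshold speed", {
  fps <- 30
  mkSpeed <- function(v) SpeedTrace(t = (seq_along(v) - 0.5) / fps, v = v,
                                    fps = fps)
  expect_equal(nrow(classifyFlight(mkSpeed(rep(100, 60)))), 0L)
  ## a run of exactly minDur at threshold is one bout
  v <- c(rep(0, 20), rep(150, 6), rep(0, 20))
  iv <- classifyFlight(mkSpeed(v), vThresh = 150, minDur = 0.2)
  expect_equal(nrow(iv), 1L)
  ## one sample shorter fails the minimum duration
  v2 <- c(rep(0, 20), rep(150, 5), rep(0, 20))
  expect_equal(nrow(classifyFlight(mkSpeed(v2), vThresh = 150,
                                   minDur = 0.2)), 0L)
})

test_that("peri-stimulus fractions equal brute-force frame counting", {
  fps <- 20
  n <- 1200  # 60 s
  tl <- buildLoomTrain(LoomSpec(), t0 = 30)
  ## saturated and step channels
  stepCh <- c(rep(FALSE, 600), rep(TRUE, 600))  # on from t = 30
  etho <- Ethogram(list(on = rep(TRUE, n), step = stepCh), fps = fps)
  ps <- periStimulusSummary(etho, tl, window = 15)
  expect_equal(ps$preFrac, c(1, 0))
  expect_equal(ps$postFrac, c(1, 1))
  ## random channel matches direct enumeration over frame centres
  set.seed(4)
  rnd <- runif(n) < 0.3
  ps2 <- periStimulusSummary(Ethogram(list(r = rnd), fps = fps), tl,
                             window = 15)
  tc <- (seq_len(n) - 0.5) / fps
  expect_equal(ps2$preFrac, mean(rnd[tc >= 15 & tc < 30]))
  expect_equal(ps2$postFrac, mean(rnd[tc >= 30 & tc < 45]))
  expect_warning(periStimulusSummary(etho, tl, window = 40), "truncat")
})

test_that("top speed is the window maximum", {
  sp <- SpeedTrace(t = seq(0.5, 59.5, by = 1), v = rep(7, 60), fps = 1)
  expect_equal(topSpeed(sp, c(10, 20)), 7)
  v <- rep(1, 60); v[25] <- 400
  sp2 <- SpeedTrace(t = seq(0.5, 59.5, by = 1), v = v, fps = 1)
  expect_equal(topSpeed(sp2, c(20, 30)), 400)
  expect_equal(topSpeed(sp2, c(40, 50)), 1)
  expect_error(topSpeed(sp2, c(70, 80)), "no speed samples")
  ## brute-force max on a random trace
  set.seed(6)
  v3 <- runif(60, 0, 500)
  sp3 <- SpeedTrace(t = seq(0.5, 59.5, by = 1), v = v3, fps = 1)
  sel <- sp3@t >= 12 & sp3@t <= 33
  expect_equal(topSpeed(sp3, c(12, 33)), max(v3[sel]))
})

test_that("speed heatmap aligns rows to the first loom onset", {
  fps <- 30
  tl <- buildLoomTrain(LoomSpec(), t0 = 30)
  static <- computeSpeed(staticTrack(1800, fps = fps))
  ## impulse exactly at the onset sample
  n <- 1800
  cx <- rep(100, n); cx[901:n] <- 110  # one 10 mm step at t = 30 s
  mover <- computeSpeed(trackFromPath(cx, rep(100, n), fps = fps))
  mat <- speedHeatmap(list(static, mover), tl, window = 10)
  tau <- attr(mat, "time")
  expect_equal(mat[1, ], rep(0, length(tau)), ignore_attr = TRUE)
  spike <- which(mat[2, ] > 0)
  expect_length(spike, 1)
  expect_equal(unname(mat[2, spike]), 10 * fps)
  ## speed samples sit at step midpoints: the onset step lands within
  ## one frame of the t = 0 column
  expect_lte(abs(tau[spike]), 1 / fps)
  ## row means equal per-track window recomputation
  set.seed(12)
  coords <- array(rnorm(1800 * 14 * 2, 200, 3), c(1800, 14, 2))
  rndSpeed <- computeSpeed(PoseTrack(coords, fps = fps))
  m2 <- speedHeatmap(list(rndSpeed), tl, window = 10)
  idx <- round((30 + attr(m2, "time") - rndSpeed@t[1]) * fps) + 1
  expect_equal(unname(rowMeans(m2)), mean(rndSpeed@v[idx]))
})

test_that("pose tracks round-trip through the three-row-header CSV", {
  sc <- boutScript(c("locomote", "freeze"), c(2, 1))
  tr <- genPoseTrack(sc, seed = 14)$track
  path <- withr::local_tempfile(fileext = ".csv")
  writePoseTrack(tr, path, pxPerMm = 2.5)
  arena <- ArenaGeometry(pxPerMm = 2.5)
  back <- readPoseTrack(path, fps = 30, arena = arena)
  expect_equal(back@parts, tr@parts)
  expect_equal(back@tailParts, tr@tailParts)
  expect_equal(back@coords, tr@coords, tolerance = 1e-7)
})

test_that("low-likelihood keypoints are interpolated on import", {
  n <- 10
  coords <- array(100, c(n, 2, 2))
  coords[, 1, 1] <- seq(10, 100, by = 10)
  lik <- matrix(1, n, 2)
  lik[5, 1] <- 0.1  # frame 5 of part 1 unreliable
  coords[5, 1, 1] <- 9999
  tr <- PoseTrack(coords, fps = 30, parts = c("a", "tail_b"),
                  tailParts = "tail_b", likelihood = lik)
  path <- withr::local_tempfile(fileext = ".csv")
  writePoseTrack(tr, path)
  back <- readPoseTrack(path, fps = 30,
                        arena = ArenaGeometry(width = 5000, length = 5000,
                                              shelterBBox = c(0, 10, 0, 10)),
                        tailParts = "tail_b", minLikelihood = 0.6)
  expect_equal(unname(back@coords[5, 1, 1]), 50)  # linear interpolation
})

test_that("ethogram exports list maximal intervals per channel", {
  etho <- Ethogram(list(freezing = c(rep(FALSE, 10), rep(TRUE, 20),
                                     rep(FALSE, 10)),
                        sheltering = rep(FALSE, 40)), fps = 10)
  bed <- withr::local_tempfile(fileext = ".tsv")
  writeEthogramBED(etho, bed)
  tab <- read.delim(bed)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$channel, "freezing")
  expect_equal(c(tab$start_s, tab$end_s), c(1, 3))
  wide <- withr::local_tempfile(fileext = ".csv")
  writeEthogramWide(etho, wide)
  w <- read.csv(wide)
  expect_equal(w$freezing, as.integer(etho@channels$freezing))
})
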