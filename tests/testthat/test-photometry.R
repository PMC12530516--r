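test_that("moving mean matches brute-force windowed averages", {
  expect_identical(movingMean(1:10, 1), 1:10)
  expect_equal(movingMean(rep(3.5, 40), 7), rep(3.5, 40))
  set.seed(1)
  x <- rnorm(101)
  for (win in c(3, 9, 25)) {
    got <- movingMean(x, win)
    h <- (win - 1) / 2
    oracle <- vapply(seq_along(x), function(i)
      mean(x[max(1, i - h):min(length(x), i + h)]), 1)
    expect_equal(got, oracle)
  }
  expect_error(movingMean(x, 4), "odd")
  expect_error(movingMean(x, 201), "length")
})

test_that("airPLS reproduces peak-free baselines", {
  ## constant series: baseline equals the series
  x <- rep(2, 200)
  z <- airplsBaseline(x, AirplsParams())
  expect_equal(as.numeric(z), x, tolerance = 1e-6)
  ## pure linear ramp: second differences vanish, baseline is the ramp
  ramp <- seq(0, 5, length.out = 500)
  z2 <- airplsBaseline(ramp, AirplsParams(lam = 1e5))
  expect_lt(max(abs(ramp - z2)), 1e-3 * diff(range(ramp)))
  expect_true(attr(z2, "converged"))
  expect_error(airplsBaseline(1:3), "5 samples")
})

test_that("airPLS recovers transient heights over a curved baseline", {
  fs <- 100
  t <- seq(0, 30, by = 1 / fs)
  base <- 1.5 * exp(-t / 40) + 0.02 * t / 30
  peaks <- numeric(length(t))
  heights <- c(0.30, 0.45, 0.25)
  centers <- c(6, 15, 24)
  for (k in 1:3)
    peaks <- peaks + heights[k] * exp(-(t - centers[k])^2 / (2 * 0.3^2))
  x <- base + peaks
  z <- airplsBaseline(x, AirplsParams(lam = 1e7))
  corrected <- x - z
  got <- vapply(centers, function(cc) max(corrected[abs(t - cc) < 1]), 1)
  expect_lt(max(abs(got - heights) / heights), 0.05)
  ## baseline stays at or below the signal around the peaks
  expect_lt(max(z - x), 0.02 * diff(range(x)))
})

test_that("standardization yields exact zero mean and unit sd", {
  set.seed(2)
  x <- rnorm(500, 7, 3)
  z <- standardizeSeries(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  ## affine invariance
  expect_equal(standardizeSeries(5 * x - 2), z)
  ## already-standard series maps to itself
  expect_equal(standardizeSeries(z), z)
  expect_error(standardizeSeries(rep(1, 10)), "zero-variance")
})

test_that("reference fit is exact on identical channels and clamps at zero", {
  set.seed(3)
  x <- rnorm(200)
  b <- fitReference(x, x)
  expect_equal(unname(b["a"]), 1, tolerance = 1e-6)
  expect_equal(unname(b["b"]), 0, tolerance = 1e-6)
  ## negative empirical slope clamps to zero
  y <- -0.5 * x + rnorm(200, 0, 0.1)
  b2 <- fitReference(x, y)
  expect_identical(unname(b2["a"]), 0)
  expect_error(fitReference(x[1:5], x[1:5]), "length")
})

test_that("reference fit recovers coupling under Huber contamination", {
  set.seed(4)
  n <- 1e4
  x <- rnorm(n)
  noise <- rnorm(n, 0, 0.2)
  out <- sample(n, n * 0.05)
  noise[out] <- noise[out] + rnorm(length(out), 3, 2)  # heavy outliers
  y <- 0.8 * x + 0.1 + noise
  b <- fitReference(x, y)
  expect_lt(abs(b["a"] - 0.8), 0.05)
  expect_lt(abs(b["b"] - 0.1), 0.05)
})

test_that("with an infinite Huber constant the fit is ordinary least squares", {
  set.seed(5)
  x <- rnorm(300)
  y <- 0.6 * x + 0.3 + rnorm(300, 0, 0.1)
  b <- fitReference(x, y, cHuber = Inf)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(b["a"]), unname(ols[2]), tolerance = 1e-8)
  expect_equal(unname(b["b"]), unname(ols[1]), tolerance = 1e-8)
})

test_that("huber fit agrees with an independent robust regression", {
  skip_if_not_installed("MASS")
  set.seed(6)
  x <- rnorm(2000)
  y <- 0.7 * x + 0.2 + rt(2000, df = 3) * 0.2
  b <- fitReference(x, y)
  rl <- MASS::rlm(y ~ x, k = 1.345, maxit = 100)
  expect_equal(unname(b["a"]), unname(coef(rl)[2]), tolerance = 0.02)
  expect_equal(unname(b["b"]), unname(coef(rl)[1]), tolerance = 0.02)
})

test_that("duplicated channels cancel to a flat zdFF", {
  g <- loomLockedRecording(seed = 30)
  rec <- g$recording
  dup <- PhotometryRecording(ch465 = rec@ch405, ch405 = rec@ch405,
                             fs = rec@fs, ttl = rec@ttl)
  z <- computeZdff(dup)
  expect_lt(max(abs(z@zdff)), 0.1)
  expect_equal(z@a, 1, tolerance = 1e-6)
})

test_that("zdFF is invariant to affine rescaling of the raw channels", {
  g <- loomLockedRecording(seed = 31)
  rec <- g$recording
  z1 <- computeZdff(rec)
  ## pure gain changes leave every stage invariant
  zg <- computeZdff(PhotometryRecording(ch465 = 40 * rec@ch465,
                                        ch405 = 7 * rec@ch405,
                                        fs = rec@fs, ttl = rec@ttl))
  expect_equal(zg@zdff, z1@zdff, tolerance = 1e-6)
  ## offsets enter only through the airPLS stopping rule (sum |x|);
  ## the result is invariant to within that criterion
  zo <- computeZdff(PhotometryRecording(ch465 = 40 * rec@ch465 + 3,
                                        ch405 = 7 * rec@ch405 - 1,
                                        fs = rec@fs, ttl = rec@ttl))
  expect_lt(max(abs(zo@zdff - z1@zdff)), 1e-3)
})

test_that("zdFF recovers transient times as local maxima", {
  peakOffsets <- function(g, z) {
    fs <- z@fs
    vapply(g$truth$transientTimes, function(tt) {
      i0 <- round(tt * fs) + 1
      win <- z@zdff[(i0 - 30):(i0 + 30)]
      kpk <- which.max(g$truth$transients[(i0 - 30):(i0 + 30)])
      which.max(win) - kpk
    }, 1)
  }
  ## noise-free recording: the shared bleach + motion artifact must cancel
  ## in the reference subtraction, leaving peaks within +/- 2 samples
  g0 <- loomLockedRecording(seed = 32, noiseSd = 0)
  z0 <- computeZdff(g0$recording)
  expect_gte(mean(abs(peakOffsets(g0, z0)) <= 2), 0.9)
  ## under sensor noise the kernel's flat top limits argmax precision to
  ## roughly the smoothing scale; detection within 100 ms must still hold
  g1 <- loomLockedRecording(seed = 32)
  z1 <- computeZdff(g1$recording)
  expect_gte(mean(abs(peakOffsets(g1, z1)) <= 10), 0.9)
})

test_that("noise-only recordings give bounded zdFF variance", {
  set.seed(33)
  sds <- vapply(1:5, function(k) {
    n <- 3000
    rec <- PhotometryRecording(ch465 = rnorm(n), ch405 = rnorm(n), fs = 100)
    sd(computeZdff(rec, smoothWin = 1)@zdff)
  }, 1)
  ## independent channels: zdff = z465 - a*z405 - b has sd sqrt(1 + a^2) <= 2
  expect_true(all(sds < 2))
})

test_that("peri-event matrix slices rows by nearest-sample alignment", {
  n <- 6000
  z <- new("ZdffResult", zdff = rep(1.5, n), base465 = numeric(n),
           base405 = numeric(n), a = 1, b = 0, fs = 100, ttl = numeric(),
           params = list())
  pem <- periEventMatrix(z, c(20, 30), window = c(2, 2))
  expect_equal(dim(periMatrix(pem)), c(2L, 401L))
  expect_true(all(periMatrix(pem) == 1.5))
  expect_equal(periTime(pem), seq(-2, 2, by = 0.01))
  ## impulse at each event shows up in the t = 0 column only
  zz <- numeric(n)
  ev <- c(10, 25, 40)
  zz[round(ev * 100) + 1] <- 9
  z2 <- new("ZdffResult", zdff = zz, base465 = numeric(n),
            base405 = numeric(n), a = 1, b = 0, fs = 100, ttl = numeric(),
            params = list())
  pem2 <- periEventMatrix(z2, ev, window = c(1, 1))
  m <- periMatrix(pem2)
  expect_true(all(m[, periTime(pem2) == 0] == 9))
  expect_equal(sum(m != 0), 3)
  ## brute-force slicing oracle on a random trace
  set.seed(7)
  zr <- rnorm(n)
  z3 <- new("ZdffResult", zdff = zr, base465 = numeric(n),
            base405 = numeric(n), a = 1, b = 0, fs = 100, ttl = numeric(),
            params = list())
  pem3 <- periEventMatrix(z3, 12.345, window = c(0.5, 0.5))
  i0 <- round(12.345 * 100) + 1
  expect_equal(periMatrix(pem3)[1, ], zr[(i0 - 50):(i0 + 50)])
  ## events at the edge are dropped with a warning
  expect_warning(pem4 <- periEventMatrix(z3, c(0.1, 30), window = c(1, 1)),
                 "dropped")
  expect_equal(nrow(periMatrix(pem4)), 1L)
})

test_that("pre/post AUC matches the trapezoid oracle and is additive", {
  n <- 6001
  mkz <- function(v) new("ZdffResult", zdff = v, base465 = numeric(n),
                         base405 = numeric(n), a = 1, b = 0, fs = 100,
                         ttl = numeric(), params = list())
  expect_equal(aucPrePost(mkz(numeric(n)), 30), c(pre = 0, post = 0))
  ## unit-constant trace integrates to the window length
  expect_equal(aucPrePost(mkz(rep(1, n)), 30, 15), c(pre = 15, post = 15))
  set.seed(8)
  v <- rnorm(n)
  z <- mkz(v)
  got <- aucPrePost(z, 30, 15)
  if (requireNamespace("pracma", quietly = TRUE)) {
    i0 <- 3001
    tgrid <- (0:(n - 1)) / 100
    expect_equal(unname(got["pre"]),
                 pracma::trapz(tgrid[(i0 - 1500):i0], v[(i0 - 1500):i0]),
                 tolerance = 1e-9)
    expect_equal(unname(got["post"]),
                 pracma::trapz(tgrid[i0:(i0 + 1500)], v[i0:(i0 + 1500)]),
                 tolerance = 1e-9)
  }
  ## additivity: AUC[a,b] + AUC[b,c] = AUC[a,c]
  expect_equal(unname(got["pre"] + got["post"]),
               unname(aucPrePost(z, 15, 15)["post"] +
                      aucPrePost(z, 45, 15)["pre"]), tolerance = 1e-9)
  expect_error(aucPrePost(z, 2, 15), "beyond")
})

test_that("magnitude spectrum localizes a pure tone within one bin", {
  fs <- 100
  n <- 3000
  v <- sin(2 * pi * 2.5 * (0:(n - 1)) / fs)
  z <- new("ZdffResult", zdff = v, base465 = numeric(n),
           base405 = numeric(n), a = 1, b = 0, fs = fs, ttl = numeric(),
           params = list())
  sp <- magnitudeSpectrum(z, c(0, 30))
  expect_lt(abs(dominantFrequency(sp) - 2.5), fs / n + 1e-9)
  expect_error(magnitudeSpectrum(z, c(0, 0.02)), "too short")
})

test_that("loom-locked synthetic recordings peak at the stimulus fundamental", {
  g <- loomLockedRecording(seed = 34)
  z <- computeZdff(g$recording)
  sp <- magnitudeSpectrum(z, c(20, 35))
  binWidth <- 1 / 15
  expect_lt(abs(dominantFrequency(sp) - 1), binWidth + 1e-9)
})

test_that("white-noise spectra have no reproducible dominant peak", {
  peaks <- vapply(1:6, function(sd0) {
    set.seed(sd0 + 50)
    n <- 2000
    z <- new("ZdffResult", zdff = rnorm(n), base465 = numeric(n),
             base405 = numeric(n), a = 1, b = 0, fs = 100, ttl = numeric(),
             params = list())
    dominantFrequency(magnitudeSpectrum(z, c(0, 20)))
  }, 1)
  expect_gt(length(unique(peaks)), 3)
})

test_that("behavior-triggered averages equal column statistics", {
  n <- 6000
  set.seed(9)
  v <- rnorm(n)
  z <- new("ZdffResult", zdff = v, base465 = numeric(n),
           base405 = numeric(n), a = 1, b = 0, fs = 100, ttl = numeric(),
           params = list())
  bouts <- c(10, 20, 35, 50)
  bta <- behaviorTriggeredAverage(z, bouts, window = c(2, 2))
  pem <- periMatrix(periEventMatrix(z, bouts, window = c(2, 2)))
  expect_equal(bta$mean, colMeans(pem))
  expect_equal(bta$sem, apply(pem, 2, sd) / sqrt(4))
  ## single bout: mean is the row, SEM identically zero
  one <- behaviorTriggeredAverage(z, 10, window = c(2, 2))
  expect_equal(one$mean, pem[1, ])
  expect_equal(one$sem, rep(0, ncol(pem)))
  expect_error(behaviorTriggeredAverage(z, numeric()), "no bout")
})

test_that("photometry CSVs round-trip and infer the sampling rate", {
  g <- loomLockedRecording(seed = 35, duration = 10)
  rec <- PhotometryRecording(ch465 = g$recording@ch465,
                             ch405 = g$recording@ch405, fs = 100,
                             ttl = c(2, 5.5))
  path <- withr::local_tempfile(fileext = ".csv")
  writePhotometry(rec, path)
  back <- readPhotometry(path)
  expect_equal(back@fs, 100, tolerance = 1e-6)
  expect_equal(back@ch465, rec@ch465, tolerance = 1e-6)
  expect_equal(back@ttl, c(2, 5.5), tolerance = 1e-6)
  ## non-monotone time is rejected with the offending row
  df <- read.csv(path)
  df$time_s[5] <- df$time_s[7]
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(readPhotometry(bad), "non-monotone")
})
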