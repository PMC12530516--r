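## Two-channel fiber-photometry processing: moving-mean smoothing, airPLS
## baseline removal, standardization, robust non-negative isosbestic
## regression, and stimulus-locked analyses of the corrected zdFF trace.

#' Centred moving mean
#'
#' Boxcar average of odd width `win`; near the edges the window shrinks
#' symmetrically so the output has the input length and no phase shift.
#'
#' @param x numeric series.
#' @param win odd window width in samples, `>= 1`.
#' @return smoothed series, same length as `x`.
#' @export
movingMean <- function(x, win) {
  n <- length(x)
  if (win < 1 || win %% 2 != 1) stop("win must be odd and >= 1")
  if (win > n) stop("win exceeds the series length")
  if (win == 1) return(x)
  h <- (win - 1) %/% 2
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - h)
  hi <- pmin(n, idx + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' airPLS baseline estimation
#'
#' Adaptive iteratively reweighted penalized least squares. Each
#' iteration solves the weighted Whittaker system
#' `(W + lambda * t(D) %*% D) z = W x` with `D` the second-difference
#' operator, then reweights: points at or above the current baseline
#' (residual `d = x - z >= 0`, i.e. candidate peaks) get weight 0, and
#' points below get `exp(iter * |d_i| / sum(|d_neg|))`, so the baseline
#' is attracted to the signal's lower envelope while remaining smooth.
#' Iteration stops when the summed negative residual drops below
#' `ratioTol * sum(|x|)` or after `maxIter` iterations (then the last
#' iterate is returned with a warning and attribute
#' `converged = FALSE`).
#'
#' @param x numeric series (length >= 5).
#' @param params an [AirplsParams-class]; `lam` trades smoothness
#'   against fidelity (default 1e8, appropriate for slow photobleaching
#'   sampled at ~100 Hz).
#' @return baseline series with logical attribute `converged`.
#' @references Zhang, Z.-M., Chen, S. & Liang, Y.-Z. Baseline correction
#'   using adaptive iteratively reweighted penalized least squares.
#'   Analyst 135, 1138-1146 (2010).
#' @export
airplsBaseline <- function(x, params = AirplsParams()) {
  validObject(params)
  n <- length(x)
  if (n < 5) stop("airPLS needs at least 5 samples")
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- Matrix::crossprod(D)
  w <- rep(1, n)
  absx <- sum(abs(x))
  z <- x
  converged <- FALSE
  for (iter in seq_len(params@maxIter)) {
    A <- Matrix::Diagonal(x = w) + params@lam * DtD
    z <- as.numeric(Matrix::solve(A, w * x))
    d <- x - z
    neg <- d < 0
    sumNeg <- sum(abs(d[neg]))
    if (sumNeg < params@ratioTol * absx) { converged <- TRUE; break }
    w[!neg] <- 0
    w[neg] <- exp(iter * abs(d[neg]) / sumNeg)
  }
  if (!converged)
    warning(sprintf("airPLS did not converge in %d iterations", params@maxIter))
  attr(z, "converged") <- converged
  z
}

#' Standardize a series to zero mean and unit standard deviation
#'
#' @param x numeric series with positive standard deviation.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
standardizeSeries <- function(x) {
  s <- sd(x)
  if (!isTRUE(s > 0)) stop("cannot standardize a zero-variance series")
  (x - mean(x)) / s
}

#' Non-negative robust reference regression
#'
#' Fits the (standardized) isosbestic reference `x` to the signal
#' channel `y` as `y = a*x + b` by iteratively reweighted least squares
#' with Huber weights (tuning constant `cHuber`, scale from the MAD of
#' the residuals), with the slope clamped to `a >= 0`: motion and
#' bleaching artifacts can only add the reference in with non-negative
#' gain. With `cHuber = Inf` the fit reduces to ordinary least squares.
#'
#' @param ref reference (isosbestic) series.
#' @param sig signal series, same length (>= 10).
#' @param cHuber Huber tuning constant in residual-scale units
#'   (default 1.345, 95% Gaussian efficiency).
#' @param maxIter,tol convergence controls.
#' @param method `"huber"` (default) or `"lasso"` (non-negative lasso
#'   via glmnet with a small penalty; requires the glmnet package).
#' @return named numeric `c(a = , b = )` with attribute `iterations`.
#' @export
fitReference <- function(ref, sig, cHuber = 1.345, maxIter = 100,
                         tol = 1e-10, method = c("huber", "lasso")) {
  method <- match.arg(method)
  n <- length(ref)
  if (length(sig) != n || n < 10)
    stop("ref and sig must have equal length >= 10")
  if (method == "lasso") {
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop("method = 'lasso' requires the glmnet package")
    f <- glmnet::glmnet(cbind(ref, ref), sig, lower.limits = 0,
                        lambda = 1e-4, standardize = FALSE)
    a <- sum(as.numeric(f$beta))
    b <- as.numeric(f$a0)
    out <- c(a = max(a, 0), b = b)
    attr(out, "iterations") <- 1L
    return(out)
  }
  fitWLS <- function(w) {
    sw <- sum(w)
    xb <- sum(w * ref) / sw
    yb <- sum(w * sig) / sw
    sxx <- sum(w * (ref - xb)^2)
    a <- if (sxx > 0) sum(w * (ref - xb) * (sig - yb)) / sxx else 0
    if (a < 0) a <- 0
    c(a = a, b = yb - a * xb)
  }
  beta <- fitWLS(rep(1, n))
  for (iter in seq_len(maxIter)) {
    r <- sig - beta["a"] * ref - beta["b"]
    s <- median(abs(r - median(r))) * 1.4826
    if (s <= .Machine$double.eps * max(1, sd(sig))) break
    w <- pmin(1, cHuber * s / abs(r))
    w[!is.finite(w)] <- 1
    betaNew <- fitWLS(w)
    if (max(abs(betaNew - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- betaNew
      attr(beta, "iterations") <- iter
      return(beta)
    }
    beta <- betaNew
  }
  if (is.finite(cHuber) && iter >= maxIter)
    stop("reference regression did not converge")
  attr(beta, "iterations") <- iter
  beta
}

#' Full zdFF processing chain
#'
#' Composition of the motion-correction pipeline for a two-channel
#' recording: (1) centred moving mean on both channels (default window
#' `fs * 0.04` s rounded to the nearest odd sample count); (2) airPLS
#' baseline estimation and subtraction per channel; (3) per-channel
#' standardization; (4) robust non-negative fit of the standardized
#' isosbestic channel to the standardized signal channel; (5)
#' `zdff = std465 - (a * std405 + b)`. The result is invariant to
#' affine rescaling of the raw channel units.
#'
#' @param rec a [PhotometryRecording-class].
#' @param smoothWin odd smoothing window in samples; `NULL` uses the
#'   default above.
#' @param airpls an [AirplsParams-class].
#' @param cHuber Huber tuning constant for the reference fit.
#' @param method reference-fit method, see [fitReference()].
#' @return a [ZdffResult-class].
#' @export
computeZdff <- function(rec, smoothWin = NULL, airpls = AirplsParams(),
                        cHuber = 1.345, method = "huber") {
  stopifnot(is(rec, "PhotometryRecording"))
  validObject(rec)
  if (is.null(smoothWin)) {
    smoothWin <- round(rec@fs * 0.04)
    if (smoothWin %% 2 == 0) smoothWin <- smoothWin + 1
    smoothWin <- max(smoothWin, 1)
  }
  s465 <- movingMean(rec@ch465, smoothWin)
  s405 <- movingMean(rec@ch405, smoothWin)
  b465 <- airplsBaseline(s465, airpls)
  b405 <- airplsBaseline(s405, airpls)
  z465 <- standardizeSeries(s465 - b465)
  z405 <- standardizeSeries(s405 - b405)
  beta <- fitReference(z405, z465, cHuber = cHuber, method = method)
  zdff <- z465 - (beta["a"] * z405 + beta["b"])
  new("ZdffResult", zdff = as.numeric(zdff), base465 = as.numeric(b465),
      base405 = as.numeric(b405), a = unname(beta["a"]),
      b = unname(beta["b"]), fs = rec@fs, ttl = rec@ttl,
      params = list(smoothWin = smoothWin, lam = airpls@lam,
                    maxIter = airpls@maxIter, ratioTol = airpls@ratioTol,
                    cHuber = cHuber, method = method,
                    airplsConverged465 = attr(b465, "converged"),
                    airplsConverged405 = attr(b405, "converged")))
}

## nearest-sample index of a time point (1-based; t = 0 -> sample 1)
.sampleAt <- function(t, fs) as.integer(round(t * fs)) + 1L

#' Event-aligned peri-event matrix
#'
#' Extracts one row of the zdFF trace per event, spanning
#' `[-window[1], +window[2]]` seconds around each onset at the native
#' sampling rate (nearest-sample alignment: the `t = 0` column is the
#' sample closest to the onset). Events too close to the recording
#' edges are dropped with a warning.
#'
#' @param z a [ZdffResult-class].
#' @param eventTimes onset timestamps, seconds.
#' @param window numeric `(pre_s, post_s)`, both positive.
#' @return a [PeriEventMatrix-class].
#' @export
periEventMatrix <- function(z, eventTimes, window = c(15, 15)) {
  stopifnot(is(z, "ZdffResult"), length(window) == 2, all(window > 0))
  preN <- as.integer(round(window[1] * z@fs))
  postN <- as.integer(round(window[2] * z@fs))
  n <- length(z@zdff)
  rows <- list()
  kept <- character()
  for (tt in eventTimes) {
    i0 <- .sampleAt(tt, z@fs)
    if (i0 - preN < 1 || i0 + postN > n) next
    rows[[length(rows) + 1L]] <- z@zdff[(i0 - preN):(i0 + postN)]
    kept <- c(kept, format(tt))
  }
  if (length(rows) < length(eventTimes))
    warning(sprintf("dropped %d event(s) too close to the recording edge",
                    length(eventTimes) - length(rows)))
  if (!length(rows)) stop("no usable events")
  new("PeriEventMatrix", mat = do.call(rbind, rows),
      time = (-preN:postN) / z@fs, eventIds = kept)
}

#' Pre/post-stimulus area under the curve
#'
#' Trapezoidal integral of the zdFF trace over `[onset - w, onset]` and
#' `[onset, onset + w]` on the native sample grid (the onset sample is
#' shared, so the two integrals add exactly to the integral over the
#' full window).
#'
#' @param z a [ZdffResult-class].
#' @param onset stimulus onset, seconds.
#' @param halfWindow half-window `w` in seconds (default 15).
#' @return named numeric `c(pre = , post = )`, units zdFF x s.
#' @export
aucPrePost <- function(z, onset, halfWindow = 15) {
  stopifnot(is(z, "ZdffResult"), halfWindow > 0)
  fs <- z@fs
  i0 <- .sampleAt(onset, fs)
  w <- as.integer(round(halfWindow * fs))
  n <- length(z@zdff)
  if (i0 - w < 1 || i0 + w > n)
    stop("AUC window extends beyond the recording")
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) / fs
  c(pre = trap(z@zdff[(i0 - w):i0]), post = trap(z@zdff[i0:(i0 + w)]))
}

#' One-sided magnitude spectrum of a zdFF segment
#'
#' Detrends the segment (mean removal plus, by default, removal of the
#' slow trend via a moving-mean high-pass), optionally applies a Hann
#' taper, and returns the one-sided FFT magnitude with its frequency
#' axis. [dominantFrequency()] reports the frequency of the largest
#' non-DC bin — for a stimulus-locked recording this sits at the
#' stimulus train's fundamental frequency (1 Hz for the default looming
#' train).
#'
#' The slow-trend removal exists because the baseline-removal stage has
#' a finite cutoff (about 0.05 Hz at the default penalty and sampling
#' rate) and leaves sub-0.1 Hz residue in the corrected trace; without
#' detrending, that residue — not stimulus-locked activity — can occupy
#' the lowest spectral bins. The default 5 s window places the
#' high-pass edge near 0.2 Hz, far below stimulus rates of interest
#' (attenuation at 1 Hz is below 1%).
#'
#' @param z a [ZdffResult-class].
#' @param segment numeric `(start_s, end_s)`.
#' @param taper `"none"` (default) or `"hann"`.
#' @param detrendWin slow-trend moving-mean window in seconds (default
#'   5); `NULL` for mean removal only.
#' @return data.frame with columns `freq` (Hz) and `magnitude`.
#' @export
magnitudeSpectrum <- function(z, segment, taper = c("none", "hann"),
                              detrendWin = 5) {
  stopifnot(is(z, "ZdffResult"), length(segment) == 2)
  taper <- match.arg(taper)
  i1 <- max(1L, .sampleAt(segment[1], z@fs))
  i2 <- min(length(z@zdff), .sampleAt(segment[2], z@fs))
  x <- z@zdff[i1:i2]
  n <- length(x)
  if (n < 8) stop("segment too short for a spectrum")
  if (!is.null(detrendWin)) {
    win <- round(detrendWin * z@fs)
    if (win %% 2 == 0) win <- win + 1
    if (win >= 3 && win <= n) x <- x - movingMean(x, win)
  }
  x <- x - mean(x)
  if (taper == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  nf <- floor(n / 2) + 1L
  data.frame(freq = (seq_len(nf) - 1) * z@fs / n,
             magnitude = Mod(fft(x))[seq_len(nf)])
}

#' @rdname magnitudeSpectrum
#' @param spectrum a data.frame as returned by `magnitudeSpectrum()`.
#' @return `dominantFrequency()`: Hz of the maximal non-DC bin.
#' @export
dominantFrequency <- function(spectrum) {
  nonDC <- spectrum[spectrum$freq > 0, , drop = FALSE]
  nonDC$freq[which.max(nonDC$magnitude)]
}

#' Behavior-triggered average of the zdFF trace
#'
#' Aligns the trace to behavioral bout onsets (freezing or flight
#' starts) and returns the across-bout mean with its standard error.
#'
#' @param z a [ZdffResult-class].
#' @param boutOnsets bout start times, seconds (at least one usable).
#' @param window numeric `(pre_s, post_s)`.
#' @return list with `time`, `mean`, `sem` (zero vector when a single
#'   bout is usable) and `n` (number of bouts used).
#' @export
behaviorTriggeredAverage <- function(z, boutOnsets, window = c(5, 5)) {
  if (!length(boutOnsets)) stop("no bout onsets supplied")
  pem <- periEventMatrix(z, boutOnsets, window)
  m <- periMatrix(pem)
  sem <- if (nrow(m) > 1) apply(m, 2, sd) / sqrt(nrow(m))
         else rep(0, ncol(m))
  list(time = periTime(pem), mean = colMeans(m), sem = sem, n = nrow(m))
}

## ---------------------------------------------------------------------------
## Photometry I/O
## ---------------------------------------------------------------------------

#' Read a two-channel photometry CSV
#'
#' Expects columns `time_s`, `ch465`, `ch405`, `ttl` (0/1 pulse train).
#' The sampling rate is inferred from `time_s` and must be uniform to
#' within 1%; TTL rising edges become event timestamps.
#'
#' @param path CSV path.
#' @return a [PhotometryRecording-class].
#' @export
readPhotometry <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "ch465", "ch405", "ttl")
  if (!all(need %in% names(df)))
    stop(sprintf("photometry CSV must have columns %s",
                 paste(need, collapse = ", ")))
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    stop(sprintf("non-monotone time_s at row %d", which(dt <= 0)[1] + 1L))
  if ((max(dt) - min(dt)) / mean(dt) > 0.01)
    stop("time_s is not uniformly sampled (tolerance 1%)")
  fs <- 1 / mean(dt)
  rising <- which(diff(c(0L, as.integer(df$ttl > 0))) == 1L)
  PhotometryRecording(ch465 = df$ch465, ch405 = df$ch405, fs = fs,
                      ttl = df$time_s[rising] - df$time_s[1])
}

#' Write a photometry recording as CSV
#'
#' Inverse of [readPhotometry()]: writes `time_s`, `ch465`, `ch405` and
#' a one-sample TTL pulse at each event timestamp.
#'
#' @param rec a [PhotometryRecording-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePhotometry <- function(rec, path) {
  n <- length(rec@ch465)
  ttl <- integer(n)
  ttl[.sampleAt(rec@ttl, rec@fs)] <- 1L
  df <- data.frame(time_s = (seq_len(n) - 1) / rec@fs, ch465 = rec@ch465,
                   ch405 = rec@ch405, ttl = ttl)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a zdFF result
#'
#' Writes the trace (`time_s`, `zdff`, `base465`, `base405`) as CSV and
#' the full provenance (fit coefficients and every stage parameter) as
#' a JSON sidecar at `paste0(path, ".json")`.
#'
#' @param z a [ZdffResult-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeZdff <- function(z, path) {
  n <- length(z@zdff)
  write.csv(data.frame(time_s = (seq_len(n) - 1) / z@fs, zdff = z@zdff,
                       base465 = z@base465, base405 = z@base405),
            path, row.names = FALSE)
  jsonlite::write_json(c(list(a = z@a, b = z@b, fs = z@fs, ttl = z@ttl),
                         z@params),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}
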