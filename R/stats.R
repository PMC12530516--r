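## Neural-behavioral statistical couplings and the general testing
## machinery: logistic/linear regression with 95% bands, Pearson
## correlation, t tests behind a Shapiro-Wilk normality gate,
## repeated-measures ANOVA with post-hoc paired tests, and BH-FDR.

#' Logistic regression of a binary behavior on the neural signal
#'
#' Maximum-likelihood fit of `P(y = 1) = plogis(b0 + b1 * x)` by
#' Newton-Raphson with step-halving (the log-likelihood never decreases
#' across iterations). Used to couple freezing probability to the zdFF
#' signal. Perfect separation (a threshold of `x` that splits the
#' classes exactly) leaves the slope unidentified; it is detected
#' up front and flagged, and the returned coefficients are the last
#' finite iterate.
#'
#' @param x numeric predictor (e.g. zdFF samples).
#' @param y binary response (0/1 or logical), both classes present.
#' @param maxIter,tol Newton-Raphson controls.
#' @return a [RegressionFit-class] (`kind = "logistic"`); the slot
#'   `separated` flags separation.
#' @export
logisticFit <- function(x, y, maxIter = 50, tol = 1e-10) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (any(!is.finite(x))) stop("x must be finite")
  n <- length(x)
  separated <- max(x[y == 0]) < min(x[y == 1]) ||
               max(x[y == 1]) < min(x[y == 0])
  X <- cbind(1, x)
  beta <- c(log(mean(y) / (1 - mean(y))), 0)
  loglik <- function(b) {
    eta <- pmin(pmax(X %*% b, -30), 30)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta)
  converged <- FALSE
  H <- diag(2)
  for (iter in seq_len(maxIter)) {
    eta <- pmin(pmax(as.numeric(X %*% beta), -30), 30)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    g <- crossprod(X, y - mu)
    H <- crossprod(X, X * W)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    ## step-halving keeps the log-likelihood non-decreasing
    fac <- 1
    repeat {
      cand <- beta + fac * as.numeric(step)
      llNew <- loglik(cand)
      if (llNew >= ll - 1e-12 || fac < 1e-8) break
      fac <- fac / 2
    }
    if (abs(llNew - ll) < tol * (1 + abs(ll))) {
      beta <- cand; ll <- llNew; converged <- TRUE; break
    }
    beta <- cand; ll <- llNew
  }
  if (separated)
    warning("perfect separation: logistic slope is not identified")
  V <- tryCatch(solve(H), error = function(e) matrix(Inf, 2, 2))
  V <- (V + t(V)) / 2
  new("RegressionFit", kind = "logistic",
      coefficients = c(intercept = beta[1], slope = beta[2]),
      vcov = V, n = as.integer(n), converged = converged,
      separated = separated, sigma = NA_real_)
}

#' Linear regression of behavior on the neural signal
#'
#' Ordinary least squares of `y` on `x` (e.g. locomotion speed on zdFF)
#' wrapped into the common [RegressionFit-class] container with a 95%
#' mean-prediction band.
#'
#' @param x numeric predictor with positive variance.
#' @param y numeric response, `n >= 3`.
#' @return a [RegressionFit-class] (`kind = "linear"`).
#' @export
linearFit <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need n >= 3 paired observations")
  if (!isTRUE(var(x) > 0)) stop("predictor has zero variance")
  fit <- lm(y ~ x)
  V <- vcov(fit)
  dimnames(V) <- NULL
  new("RegressionFit", kind = "linear",
      coefficients = c(intercept = unname(coef(fit)[1]),
                       slope = unname(coef(fit)[2])),
      vcov = (V + t(V)) / 2, n = as.integer(n), converged = TRUE,
      separated = FALSE, sigma = summary(fit)$sigma)
}

#' @importFrom stats vcov
NULL

#' Evaluate a regression fit with its 95% confidence band
#'
#' Linear fits: the classical mean-prediction band (t quantile), which
#' widens away from the predictor mean. Logistic fits: the delta-method
#' band on the linear predictor mapped through the inverse link, so the
#' band stays inside (0, 1).
#'
#' @param fit a [RegressionFit-class].
#' @param newx predictor values at which to evaluate.
#' @param level confidence level (default 0.95).
#' @return data.frame with `x`, `fit`, `lwr`, `upr`.
#' @export
predictBand <- function(fit, newx, level = 0.95) {
  stopifnot(is(fit, "RegressionFit"))
  b <- fit@coefficients
  eta <- b["intercept"] + b["slope"] * newx
  X <- cbind(1, newx)
  se <- sqrt(pmax(rowSums((X %*% fit@vcov) * X), 0))
  if (fit@kind == "linear") {
    q <- qt(1 - (1 - level) / 2, df = fit@n - 2)
    data.frame(x = newx, fit = eta, lwr = eta - q * se, upr = eta + q * se)
  } else {
    q <- qnorm(1 - (1 - level) / 2)
    data.frame(x = newx, fit = plogis(eta), lwr = plogis(eta - q * se),
               upr = plogis(eta + q * se))
  }
}

#' Pearson correlation with t-transform p value
#'
#' @param x,y numeric vectors, `n >= 3`, neither constant.
#' @return list with `r`, `p`, `n` and `t` (the test statistic,
#'   `n - 2` df).
#' @export
pearsonCor <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need n >= 3 paired observations")
  if (!isTRUE(sd(x) > 0) || !isTRUE(sd(y) > 0))
    stop("constant input has no defined correlation")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n,
       t = unname(ct$statistic))
}

#' @importFrom stats cor.test
NULL

#' Two-sample Student t test
#'
#' Unpaired comparisons assume equal variances (classical Student
#' test); paired comparisons use the paired test. The direction slot
#' records the sign of `mean(a) - mean(b)`.
#'
#' @param a,b numeric samples (equal length when `paired`).
#' @param paired logical.
#' @return a [TestResult-class].
#' @export
tTest <- function(a, b, paired = FALSE) {
  ht <- t.test(a, b, paired = paired, var.equal = !paired)
  TestResult(statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, direction = sign(mean(a) - mean(b)),
             method = if (paired) "paired Student t" else
                      "unpaired Student t", paired = paired)
}

#' Shapiro-Wilk normality gate
#'
#' @param x numeric sample (3-5000 values).
#' @param alpha gate level (default 0.05).
#' @return list with `normal` (logical: `p >= alpha`), `p` and `W`.
#' @export
shapiroGate <- function(x, alpha = 0.05) {
  ht <- shapiro.test(x)
  list(normal = ht$p.value >= alpha, p = ht$p.value,
       W = unname(ht$statistic))
}

#' Gated two-group comparison
#'
#' Applies the Shapiro-Wilk gate to both samples (to the paired
#' differences when `paired`); when normality is not rejected the
#' Student t test is used, otherwise the rank-based equivalent
#' (Mann-Whitney U unpaired, Wilcoxon signed-rank paired).
#'
#' @inheritParams tTest
#' @param alpha normality-gate level.
#' @return a [TestResult-class]; the `method` slot names the branch
#'   taken.
#' @export
groupCompare <- function(a, b, paired = FALSE, alpha = 0.05) {
  normal <- if (paired) shapiroGate(a - b, alpha)$normal
            else shapiroGate(a, alpha)$normal && shapiroGate(b, alpha)$normal
  if (normal) return(tTest(a, b, paired = paired))
  ht <- suppressWarnings(wilcox.test(a, b, paired = paired))
  TestResult(statistic = unname(ht$statistic), df = NA_real_,
             p = ht$p.value, direction = sign(median(a) - median(b)),
             method = if (paired) "Wilcoxon signed-rank" else
                      "Mann-Whitney U", paired = paired)
}

#' Repeated-measures one-way ANOVA with post-hoc paired t tests
#'
#' Within-subject F test of a condition effect from a complete
#' subject x condition table, fitted via `aov(value ~ condition +
#' Error(subject))`. With two conditions the F statistic equals the
#' squared paired-t statistic. When the omnibus test is significant at
#' `alpha`, all pairwise paired t tests are run; their p values are not
#' adjusted here (pass them to [bhFDR()] to build an FDR family).
#'
#' @param table numeric matrix or data.frame, subjects in rows,
#'   conditions in columns, no missing cells.
#' @param alpha omnibus threshold gating the post-hoc tests.
#' @return list with `omnibus` (a [TestResult-class]) and `posthoc`
#'   (data.frame of pairwise paired t tests, or `NULL`).
#' @export
rmAnova <- function(table, alpha = 0.05) {
  m <- as.matrix(table)
  if (anyNA(m)) stop("subject x condition table has missing cells")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and conditions")
  if (is.null(colnames(m))) colnames(m) <- paste0("cond", seq_len(ncol(m)))
  long <- data.frame(
    value = as.numeric(m),
    condition = factor(rep(colnames(m), each = nrow(m))),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))))
  fit <- aov(value ~ condition + Error(subject / condition), data = long)
  tab <- summary(fit)[["Error: subject:condition"]][[1]]
  Fval <- tab["condition", "F value"]
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  p <- tab["condition", "Pr(>F)"]
  omnibus <- TestResult(statistic = Fval, df = c(df1, df2), p = p,
                        method = "repeated-measures ANOVA", paired = TRUE)
  posthoc <- NULL
  if (!is.na(p) && p < alpha && ncol(m) > 1) {
    prs <- combn(colnames(m), 2)
    posthoc <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      res <- tTest(m[, prs[1, k]], m[, prs[2, k]], paired = TRUE)
      data.frame(cond1 = prs[1, k], cond2 = prs[2, k],
                 t = res@statistic, df = res@df, p = res@p)
    }))
  }
  list(omnibus = omnibus, posthoc = posthoc)
}

#' @importFrom utils combn
NULL

#' Benjamini-Hochberg adjusted q values
#'
#' Step-up FDR adjustment: on sorted p values,
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and mapped back to
#' the input order. The adjustment is monotone (order-preserving) and
#' idempotent.
#'
#' @param pvals numeric p values in \[0, 1\].
#' @return q values, same order as the input.
#' @export
bhFDR <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Tidy export of test results
#'
#' One row per comparison: `test`, `groups`, `n`, `statistic`, `df`,
#' `p`, `q`.
#'
#' @param results list of [TestResult-class] objects.
#' @param groups character labels, one per result.
#' @param n sample sizes, one per result.
#' @param path optional TSV output path.
#' @return the tidy data.frame (written to `path` when given).
#' @export
tidyResults <- function(results, groups, n, path = NULL) {
  df <- data.frame(
    test = vapply(results, function(r) r@method, ""),
    groups = groups,
    n = n,
    statistic = vapply(results, function(r) r@statistic, 1),
    df = vapply(results, function(r) paste(signif(r@df, 6), collapse = ","), ""),
    p = vapply(results, function(r) r@p, 1))
  df$q <- bhFDR(df$p)
  if (!is.null(path))
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
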