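#' Two-way consistency intraclass correlation, single rater (ICC(3,1))
#'
#' Consistency form of the ICC for two fixed raters, computed from the
#' two-way (subject + rater) ANOVA decomposition:
#' `(MSR - MSE) / (MSR + (k - 1) MSE)` with k = 2. Insensitive to a constant
#' shift between the raters, which is the agreement notion appropriate when
#' a systematic offset between observers is not counted as disagreement.
#'
#' @param x,y paired measurements of the two observers (equal length, n >= 3).
#' @return ICC estimate in [-1, 1].
#' @export
icc_consistency <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("unaligned series")
  if (n < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  k <- 2
  dat <- cbind(x, y)
  row_m <- rowMeans(dat)
  if (stats::var(row_m) < 1e-14 * max(1, mean(dat)^2))
    stop("degenerate series: zero between-patient variance")
  grand <- mean(dat)
  col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Kendall's tau-b rank correlation
#'
#' Tau with the standard tie correction, the rank-agreement coefficient used
#' alongside the ICC.
#'
#' @param x,y paired measurements (equal length, n >= 3).
#' @return tau-b estimate in [-1, 1].
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("unaligned series")
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("degenerate series: all values tied")
  unname(stats::cor(x, y, method = "kendall"))
}

#' BCa bootstrap confidence interval
#'
#' Patient-level resampling with replacement; bias-correction `z0` from the
#' proportion of bootstrap replicates below the point estimate, acceleration
#' `a` from the jackknife, and the usual BCa-adjusted percentile endpoints.
#'
#' @param data vector, matrix or data.frame; rows are the resampling units.
#' @param statistic function of a resampled `data` returning a scalar.
#' @param n_boot number of bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed for the resampling.
#' @return list with `estimate`, `lower`, `upper`, `level`, `n_boot`,
#'   `flags` (may contain "degenerate" when the bootstrap distribution
#'   collapses and the CI is the point estimate).
#' @export
bca_ci <- function(data, statistic, n_boot = 10000L, level = 0.95, seed = 1L) {
  take <- function(d, idx) if (is.null(dim(d))) d[idx] else d[idx, , drop = FALSE]
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n < 3L) stop("need at least 3 resampling units")
  t0 <- statistic(data)
  tb <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(statistic(take(data, idx)), error = function(e) NA_real_)
    }, 0)
  })
  n_bad <- sum(!is.finite(tb))
  if (n_bad > 0.01 * n_boot)
    stop(sprintf("statistic undefined on %d of %d bootstrap replicates", n_bad, n_boot))
  tb <- tb[is.finite(tb)]
  res <- list(estimate = t0, level = level, n_boot = n_boot, flags = character(0))
  if (max(tb) - min(tb) < 1e-14 * max(1, abs(t0))) {
    res$lower <- t0; res$upper <- t0
    res$flags <- "degenerate"
    return(res)
  }
  B <- length(tb)
  prop <- (sum(tb < t0) + 0.5 * sum(tb == t0)) / B
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop)
  jack <- vapply(seq_len(n), function(i) statistic(take(data, -i)), 0)
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom < 1e-30) 0 else sum((jm - jack)^3) / (6 * denom)
  alpha <- (1 - level) / 2
  adj <- function(q) {
    z <- z0 + stats::qnorm(q)
    stats::pnorm(z0 + z / (1 - a * z))
  }
  qs <- stats::quantile(tb, probs = c(adj(alpha), adj(1 - alpha)),
                        names = FALSE, type = 6)
  res$lower <- qs[1]; res$upper <- qs[2]
  res
}

#' Hochberg step-up multiplicity adjustment
#'
#' Adjusted p-values of the Hochberg step-up procedure controlling the
#' family-wise error rate, mapped back to the input order.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
hochberg_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "hochberg")
}

#' Joint-bootstrap comparison of agreement coefficients across methods
#'
#' Compares the inter-observer agreement coefficient (ICC or Kendall tau-b)
#' between every pair of segmentation methods. One patient-level resample per
#' replicate drives all methods simultaneously, preserving the cross-method
#' correlation of the paired series; the two-sided p-value is the bootstrap
#' distribution's position relative to zero with a +1 continuity correction,
#' and Hochberg correction is applied across the method pairs (per
#' coefficient).
#'
#' @param pairs_by_method named list; per method a data.frame with columns
#'   `obs1`, `obs2` over the same patients.
#' @param coefficient "icc" or "tau".
#' @param n_boot bootstrap replicates.
#' @param level confidence level for the percentile CI on the difference.
#' @param seed resampling seed.
#' @return data.frame with one row per ordered method pair: `method_a`,
#'   `method_b`, `delta` (coef a - coef b), `lower`, `upper`, `p_raw`,
#'   `p_hochberg` (self-pairs carry delta 0, p 1 and are outside the
#'   correction family).
#' @export
compare_agreement <- function(pairs_by_method, coefficient = c("icc", "tau"),
                              n_boot = 2000L, level = 0.95, seed = 1L) {
  coefficient <- match.arg(coefficient)
  coef_fn <- if (coefficient == "icc")
    function(d) icc_consistency(d$obs1, d$obs2)
  else
    function(d) kendall_tau_b(d$obs1, d$obs2)
  methods <- names(pairs_by_method)
  M <- length(methods)
  ns <- vapply(pairs_by_method, nrow, 1L)
  if (length(unique(ns)) != 1L) stop("unaligned series: methods cover different patients")
  n <- ns[1]

  t0 <- vapply(pairs_by_method, coef_fn, 0)
  tb <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, M, dimnames = list(NULL, methods))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      for (m in seq_len(M))
        out[b, m] <- tryCatch(
          coef_fn(pairs_by_method[[m]][idx, , drop = FALSE]),
          error = function(e) NA_real_)
    }
    out
  })

  alpha <- (1 - level) / 2
  rows <- list()
  for (ai in seq_len(M)) for (bi in seq_len(M)) {
    if (ai == bi) {
      rows[[length(rows) + 1L]] <- data.frame(
        method_a = methods[ai], method_b = methods[bi], delta = 0,
        lower = 0, upper = 0, p_raw = 1, p_hochberg = NA_real_)
      next
    }
    d <- tb[, ai] - tb[, bi]
    d <- d[is.finite(d)]
    B <- length(d)
    p <- min(1, 2 * min((1 + sum(d <= 0)) / (B + 1), (1 + sum(d >= 0)) / (B + 1)))
    ci <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE, type = 6)
    rows[[length(rows) + 1L]] <- data.frame(
      method_a = methods[ai], method_b = methods[bi],
      delta = t0[ai] - t0[bi], lower = ci[1], upper = ci[2],
      p_raw = p, p_hochberg = NA_real_)
  }
  res <- do.call(rbind, rows)
  # Hochberg family: the unordered non-self pairs, mirrored to both orders
  un <- res$method_a != res$method_b & match(res$method_a, methods) < match(res$method_b, methods)
  adj <- hochberg_adjust(res$p_raw[un])
  key <- function(a, b) paste(pmin(match(a, methods), match(b, methods)),
                              pmax(match(a, methods), match(b, methods)))
  lut <- stats::setNames(adj, key(res$method_a[un], res$method_b[un]))
  nonself <- res$method_a != res$method_b
  res$p_hochberg[nonself] <- lut[key(res$method_a[nonself], res$method_b[nonself])]
  res$p_hochberg[!nonself] <- 1
  rownames(res) <- NULL
  res
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference observer1 - observer2), SD of the differences,
#' 95% limits of agreement (bias +/- 1.96 SD), and normal-theory 95% CIs for
#' the bias (`SE = SD/sqrt(n)`) and for each limit (`SE = SD * sqrt(3/n)`).
#'
#' @param x,y paired measurements of the two observers (n >= 3).
#' @return list of class `bland_altman` with bias, sd_diff, limits and CIs,
#'   the per-patient (mean, difference) points and the indices of patients
#'   outside the limits; zero-variance differences collapse the limits and
#'   are flagged.
#' @export
bland_altman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("unaligned series")
  if (n < 3L) stop("need at least 3 paired observations")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  lo <- bias - 1.96 * s
  hi <- bias + 1.96 * s
  se_bias <- s / sqrt(n)
  se_lim <- s * sqrt(3 / n)
  flags <- if (s == 0) "degenerate" else character(0)
  structure(list(
    bias = bias, sd_diff = s, lower_limit = lo, upper_limit = hi,
    bias_ci = c(bias - 1.96 * se_bias, bias + 1.96 * se_bias),
    lower_limit_ci = c(lo - 1.96 * se_lim, lo + 1.96 * se_lim),
    upper_limit_ci = c(hi - 1.96 * se_lim, hi + 1.96 * se_lim),
    points = data.frame(mean = (x + y) / 2, difference = d),
    outside = which(d < lo | d > hi),
    n = n, flags = flags), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.2f cm3, limits (%.2f, %.2f), n = %d\n",
              x$bias, x$lower_limit, x$upper_limit, x$n))
  invisible(x)
}

#' Absolute difference of observer means per method
#'
#' @param mean1,mean2 per-method mean MTV of observer 1 and 2 (cm^3).
#' @return `|mean1 - mean2|` rounded to 1 decimal (cm^3), vectorised.
#' @export
evaluator_mean_difference <- function(mean1, mean2) {
  round(abs(mean1 - mean2), 1)
}

#' Relative difference of two volumes as an integer percentage
#'
#' @param v1 reference volume (> 0), cm^3.
#' @param v2 comparison volume, cm^3.
#' @return `round(100 * (v1 - v2) / v1)` as an integer.
#' @export
relative_difference_percent <- function(v1, v2) {
  if (any(v1 <= 0)) stop("reference volume must be > 0")
  as.integer(round(100 * (v1 - v2) / v1))
}

#' Descriptive MTV statistics per method and observer
#'
#' @param measurements long measurement table (patient_id, observer, method,
#'   mtv_cm3).
#' @return data.frame with mean, sd, min, q1, median, q3, max per
#'   (method, observer).
#' @export
descriptive_stats <- function(measurements) {
  out <- list()
  for (mn in unique(measurements$method)) for (obs in sort(unique(measurements$observer))) {
    v <- measurements$mtv_cm3[measurements$method == mn & measurements$observer == obs]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      method = mn, observer = obs, mean = mean(v), sd = stats::sd(v),
      min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v))
  }
  do.call(rbind, out)
}
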