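#' Administrative censoring at a fixed horizon
#'
#' Records with follow-up beyond the horizon become censored at the horizon;
#' the 5-year horizon is the default analysis window.
#'
#' @param sample data.frame with columns `time_years` and `event`.
#' @param horizon_years censoring horizon, > 0.
#' @return the sample with times truncated and events beyond the horizon
#'   set to 0.
#' @export
censor_at <- function(sample, horizon_years = 5) {
  if (horizon_years <= 0) stop("horizon must be > 0")
  over <- sample$time_years > horizon_years
  sample$event[over] <- 0L
  sample$time_years[over] <- horizon_years
  sample
}

#' Five-year event indicator for ROC construction
#'
#' Event = progression/death within the horizon; patients still event-free at
#' the horizon are controls; patients censored event-free before the horizon
#' carry no 5-year label and are excluded (`NA`), with the exclusion count
#' attached as an attribute.
#'
#' @param sample data.frame with `time_years`, `event`.
#' @param horizon_years outcome horizon.
#' @return integer vector (1/0/NA) with attribute `n_excluded`.
#' @export
binary_outcome_at <- function(sample, horizon_years = 5) {
  out <- ifelse(sample$event == 1 & sample$time_years <= horizon_years, 1L,
                ifelse(sample$time_years >= horizon_years, 0L, NA_integer_))
  attr(out, "n_excluded") <- sum(is.na(out))
  out
}

#' Empirical ROC curve and Youden-optimal cut-off
#'
#' Builds the empirical ROC of a volume marker against a binary outcome over
#' all observed candidate cut-offs (classification rule: marker >= cut-off
#' predicts the event). The optimal cut-off maximises Youden's
#' J = Se + Sp - 1, ties broken toward the larger cut-off; the AUC is the
#' trapezoidal area.
#'
#' @param marker numeric marker values (e.g. per-patient mean MTV of the two
#'   observers).
#' @param outcome binary 0/1 outcome; NAs are dropped pairwise.
#' @return list of class `roc_result`: `auc`, `cutoff`, `sensitivity` and
#'   `specificity` in percent, and the full `curve` (cutoff, se, sp, fpr).
#' @export
roc_optimal_cutoff <- function(marker, outcome) {
  keep <- !is.na(marker) & !is.na(outcome)
  marker <- marker[keep]; outcome <- as.integer(outcome[keep])
  if (length(unique(outcome)) < 2L)
    stop("both outcome classes must be present")
  cand <- sort(unique(marker))
  pos <- marker[outcome == 1]; neg <- marker[outcome == 0]
  se <- vapply(cand, function(c) mean(pos >= c), 0)
  sp <- vapply(cand, function(c) mean(neg < c), 0)
  curve <- data.frame(cutoff = c(cand, Inf), se = c(se, 0), sp = c(sp, 1))
  curve$fpr <- 1 - curve$sp
  o <- order(curve$fpr, curve$se)
  fpr <- c(0, curve$fpr[o], 1)   # anchors (0,0) and (1,1)
  tpr <- c(0, curve$se[o], 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- se + sp - 1
  best <- max(which(j == max(j)))   # ties toward the larger cut-off
  structure(list(auc = auc, cutoff = cand[best],
                 sensitivity = 100 * se[best], specificity = 100 * sp[best],
                 n = length(marker), curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f, cut-off %.1f cm3 (Se %.1f%%, Sp %.1f%%, n = %d)\n",
              x$auc, x$cutoff, x$sensitivity, x$specificity, x$n))
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with Greenwood standard errors.
#'
#' @param times,events follow-up times (years) and 0/1 event indicators.
#' @return list of class `km_curve` with the step-function table, a
#'   `survival_at(t)` evaluator (probability in percent), and the median
#'   survival time (NA when not reached).
#' @export
km_curve <- function(times, events) {
  if (!length(times)) stop("need at least 1 record")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                    surv = fit$surv, std_err = fit$std.err * fit$surv)
  s_at <- function(t) {
    s <- c(1, fit$surv)[findInterval(t, fit$time) + 1L]
    100 * s
  }
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  structure(list(table = tab, survival_at = s_at, median = med, fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d times, S(5y) = %.1f%%, median %s\n",
              nrow(x$table), x$survival_at(5),
              if (is.na(x$median)) "not reached" else sprintf("%.2f y", x$median)))
  invisible(x)
}

#' Log-rank test between two groups
#'
#' @param times,events pooled follow-up data.
#' @param group two-level grouping vector.
#' @return list with `chisq` (1 df) and `p`.
#' @export
log_rank <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("need two non-empty groups")
  if (sum(events) == 0) stop("no events in either group")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation with Efron handling of tied event times
#' (Breslow available behind the `ties` flag). Covariates must each vary
#' across patients and at least one event must be present.
#'
#' @param sample data.frame with `time_years`, `event` and the covariate
#'   columns.
#' @param covariates character vector of covariate column names.
#' @param ties "efron" (default) or "breslow".
#' @return data.frame of class `cox_fit`: per covariate the coefficient, SE,
#'   HR, 95% CI bounds and p-value.
#' @export
cox_fit <- function(sample, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(sample$event) < 1L) stop("no events: Cox model undefined")
  for (cv in covariates)
    if (length(unique(sample[[cv]])) < 2L)
      stop(sprintf("covariate '%s' is constant across patients", cv))
  fml <- stats::as.formula(paste("survival::Surv(time_years, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = sample, ties = ties)
  if (any(!is.finite(stats::coef(fit))) || any(sqrt(diag(fit$var)) > 50))
    stop("Cox fit did not converge (monotone likelihood or separation)")
  s <- summary(fit)
  out <- data.frame(covariate = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    se = s$coefficients[, "se(coef)"],
                    hr = s$coefficients[, "exp(coef)"],
                    lower = exp(s$coefficients[, "coef"] - 1.96 * s$coefficients[, "se(coef)"]),
                    upper = exp(s$coefficients[, "coef"] + 1.96 * s$coefficients[, "se(coef)"]),
                    p = s$coefficients[, "Pr(>|z|)"])
  rownames(out) <- NULL
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Applies the Kaplan-Meier estimator with the censoring indicator as the
#' event; the median of that curve is the median follow-up.
#'
#' @param times,events follow-up data (events in the usual orientation; they
#'   are flipped internally).
#' @return list with `median_years`, 95% `ci`, and `reached` (FALSE when the
#'   median is not reached, in which case the maximum follow-up time is
#'   returned as an upper bound).
#' @export
reverse_km_median_followup <- function(times, events) {
  if (!length(times)) stop("need at least 1 record")
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  q <- stats::quantile(fit, probs = 0.5)
  med <- unname(q$quantile)
  if (is.na(med))
    return(list(median_years = max(times), ci = c(NA_real_, NA_real_),
                reached = FALSE))
  list(median_years = med, ci = unname(c(q$lower, q$upper)), reached = TRUE)
}

#' Absolute difference between the two evaluators' cut-offs
#'
#' @param cutoff_1,cutoff_2 per-evaluator ROC cut-offs (cm^3, > 0).
#' @return `|cutoff_1 - cutoff_2|`.
#' @export
cutoff_disagreement <- function(cutoff_1, cutoff_2) {
  if (any(cutoff_1 <= 0) || any(cutoff_2 <= 0)) stop("cut-offs must be > 0")
  abs(cutoff_1 - cutoff_2)
}

#' Inter-observer disagreement in low-MTV classification
#'
#' Counts patients classified into the low-MTV (good prognosis) group by each
#' evaluator's own measurements and cut-off, and returns the absolute
#' difference of the two counts.
#'
#' @param mtv_obs1,mtv_obs2 aligned per-patient MTVs (cm^3).
#' @param cutoff_1,cutoff_2 the evaluators' cut-offs.
#' @return list with `low_1`, `low_2` and `delta_low` = `|low_1 - low_2|`.
#' @export
classification_disagreement <- function(mtv_obs1, mtv_obs2, cutoff_1, cutoff_2) {
  if (length(mtv_obs1) != length(mtv_obs2)) stop("unaligned patient lists")
  low1 <- sum(mtv_obs1 < cutoff_1)
  low2 <- sum(mtv_obs2 < cutoff_2)
  list(low_1 = low1, low_2 = low2, delta_low = abs(low1 - low2))
}
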