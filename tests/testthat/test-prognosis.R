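test_that("the 5-year administrative censoring rule is applied record-wise", {
  s <- data.frame(time_years = c(6.2, 3.0, 5.0), event = c(1L, 1L, 1L))
  r <- censor_at(s, 5)
  expect_equal(r$time_years, c(5, 3, 5))
  expect_equal(r$event, c(0L, 1L, 1L))
  empty <- data.frame(time_years = numeric(0), event = integer(0))
  expect_equal(nrow(censor_at(empty)), 0L)
  expect_error(censor_at(s, 0), "> 0")
})

test_that("5-year outcome labels exclude early event-free censoring", {
  s <- data.frame(time_years = c(2, 6, 3, 5), event = c(1L, 0L, 0L, 0L))
  o <- binary_outcome_at(s, 5)
  expect_equal(as.integer(o), c(1L, 0L, NA_integer_, 0L))
  expect_equal(attr(o, "n_excluded"), 1L)
})

test_that("the ROC cut-off maximises Youden's J with ties toward the larger value", {
  r <- roc_optimal_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$cutoff, 3)
  expect_equal(c(r$sensitivity, r$specificity), c(100, 100))
  expect_error(roc_optimal_cutoff(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("the empirical AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  m <- rlnorm(80); y <- rbinom(80, 1, stats::plogis(scale(log(m))))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  mine <- roc_optimal_cutoff(m, y)
  ref <- pROC::roc(y, m, direction = "<", quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("an uninformative marker gives a null AUC", {
  set.seed(17)
  m <- rlnorm(2000); y <- rbinom(2000, 1, 0.4)
  r <- roc_optimal_cutoff(m, y)
  expect_lt(abs(r$auc - 0.5), 0.03)
})

test_that("the Youden cut-off is rank-based and invariant to monotone transforms", {
  set.seed(23)
  m <- rlnorm(60); y <- rbinom(60, 1, stats::plogis(scale(log(m))))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  a <- roc_optimal_cutoff(m, y)
  b <- roc_optimal_cutoff(log(m), y)
  expect_equal(b$cutoff, log(a$cutoff))
  expect_equal(c(a$auc, a$sensitivity, a$specificity),
               c(b$auc, b$sensitivity, b$specificity))
})

test_that("Kaplan-Meier steps match the product-limit hand computation", {
  none <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_equal(none$table$surv, c(1, 1, 1))
  expect_equal(none$survival_at(2.5), 100)

  four <- km_curve(1:4, rep(1, 4))
  expect_equal(four$table$surv, c(0.75, 0.5, 0.25, 0))

  # censoring before the first event shrinks the risk set without a step
  mix <- km_curve(c(1, 2, 3), c(0, 1, 1))
  expect_equal(mix$table$surv[mix$table$time == 2], 0.5)  # 1 * (1 - 1/2)
  expect_equal(mix$table$surv[mix$table$time == 3], 0)
  # S is non-increasing, right-continuous, S(0) = 1
  expect_equal(mix$survival_at(0), 100)
  expect_true(all(diff(mix$table$surv) <= 0))
})

test_that("the log-rank statistic matches a hand-filled event-time table", {
  t1 <- c(1, 2, 3); t2 <- c(4, 5, 6)   # complete separation, no censoring
  times <- c(t1, t2); events <- rep(1L, 6)
  grp <- rep(c("A", "B"), each = 3)
  # oracle: hypergeometric O-E and variance per distinct event time
  oe <- 0; vv <- 0
  for (tt in sort(times)) {
    at_risk <- times >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & grp == "A")
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & grp == "A")
    oe <- oe + d1 - d * n1 / n
    if (n > 1) vv <- vv + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  lr <- log_rank(times, events, grp)
  expect_equal(lr$chisq, oe^2 / vv, tolerance = 1e-10)
  same <- log_rank(c(t1, t1), rep(1L, 6), rep(c("A", "B"), each = 3))
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  # symmetric in group labels
  lr2 <- log_rank(times, events, rev(grp))
  expect_equal(lr$chisq, lr2$chisq)
  expect_error(log_rank(t1, c(1, 1, 1), rep("A", 3)), "two non-empty")
  expect_error(log_rank(times, rep(0L, 6), grp), "no events")
})

test_that("the Cox coefficient matches a brute-force partial-likelihood grid", {
  d <- data.frame(time_years = c(1, 2, 3, 4, 5, 6, 7, 8),
                  event = rep(1L, 8),
                  x = c(1, 0, 1, 0, 1, 0, 0, 1))
  # oracle: grid search over the hand-written partial likelihood (no ties)
  pl <- function(beta) {
    o <- order(d$time_years)
    tt <- d$time_years[o]; x <- d$x[o]
    sum(vapply(seq_along(tt), function(i) {
      beta * x[i] - log(sum(exp(beta * x[d$time_years >= tt[i]])))
    }, 0))
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_hat <- grid[which.max(vapply(grid, pl, 0))]
  fit <- cox_fit(d, "x")
  expect_equal(fit$coef, beta_hat, tolerance = 5e-4)
  expect_equal(fit$hr, exp(fit$coef))
  expect_equal(fit$lower, exp(fit$coef - 1.96 * fit$se))
  expect_error(cox_fit(transform(d, event = 0L), "x"), "no events")
  expect_error(cox_fit(transform(d, x = 1), "x"), "constant")
})

test_that("null Cox simulations keep coefficients within twice their SE most of the time", {
  set.seed(55)
  hits <- vapply(1:60, function(r) {
    n <- 120
    d <- data.frame(time_years = rexp(n, 0.2), event = 1L,
                    x = rbinom(n, 1, 0.5))
    f <- cox_fit(d, "x")
    abs(f$coef) < 2 * f$se
  }, TRUE)
  expect_gte(mean(hits), 0.85)   # ~95% expected, wide Monte-Carlo margin
})

test_that("reverse Kaplan-Meier median follow-up flips the censoring indicator", {
  all_cens <- reverse_km_median_followup(rep(4.2, 5), rep(0L, 5))
  expect_true(all_cens$reached)
  expect_equal(all_cens$median_years, 4.2)
  all_events <- reverse_km_median_followup(1:5, rep(1L, 5))
  expect_false(all_events$reached)
  expect_equal(all_events$median_years, 5)  # upper bound
  times <- c(1, 2, 3, 4, 5, 6); events <- c(0, 1, 0, 1, 0, 0)
  rkm <- reverse_km_median_followup(times, events)
  flipped <- km_curve(times, 1 - events)
  expect_equal(rkm$median_years, flipped$median)
})

test_that("published per-evaluator cut-offs reproduce the disagreement arithmetic", {
  tab <- read.csv(system.file("extdata", "reader_cutoffs.csv", package = "petmtv"))
  gaps <- cutoff_disagreement(tab$cutoff_1, tab$cutoff_2)
  names(gaps) <- tab$method
  expect_equal(unname(gaps["percent41"]), 72)
  expect_equal(unname(gaps["suv2.5"]), 7)
  expect_equal(cutoff_disagreement(300, 300), 0)
  expect_error(cutoff_disagreement(-1, 5), "> 0")
})

test_that("low-MTV classification disagreement counts patients below each cut-off", {
  r <- classification_disagreement(c(100, 400), c(100, 200), 300, 300)
  expect_equal(r$delta_low, 1L)
  same <- classification_disagreement(c(1, 2, 3), c(1, 2, 3), 2.5, 2.5)
  expect_equal(same$delta_low, 0L)
  # three-patient case with cut-off and measurement shifts, counted by hand:
  # obs1 {120, 310, 520} vs cut-off 300 -> 1 low; obs2 {140, 260, 480} vs
  # cut-off 250 -> 1 low; |1 - 1| = 0
  r3 <- classification_disagreement(c(120, 310, 520), c(140, 260, 480), 300, 250)
  expect_equal(r3$low_1, 1L); expect_equal(r3$low_2, 1L)
  expect_equal(r3$delta_low, 0L)
  expect_error(classification_disagreement(1:3, 1:4, 2, 2), "unaligned")
})

test_that("a strong volume effect separates the simulated survival curves", {
  sig <- vapply(1:10, function(s) {
    co <- simulate_cohort(239, agreement_study_phantom(),
                          surv_cfg = survival_config(), seed = 70 + s,
                          images = FALSE)
    rec <- censor_at(co$records)
    lr <- log_rank(rec$time_years, rec$event, rec$volume_group)
    km_hi <- km_curve(rec$time_years[rec$volume_group == 1],
                      rec$event[rec$volume_group == 1])
    km_lo <- km_curve(rec$time_years[rec$volume_group == 0],
                      rec$event[rec$volume_group == 0])
    lr$p < 0.05 && km_hi$survival_at(5) < km_lo$survival_at(5)
  }, TRUE)
  expect_gte(mean(sig), 0.9)
})
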