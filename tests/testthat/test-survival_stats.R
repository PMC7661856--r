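test_that("Kaplan-Meier estimate follows the product-limit rule", {
  # censoring before the last event: subject censored at t=2 leaves the
  # risk set, so the final event drops the curve to zero
  km <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 3], 0)
  # censoring after the last event: (2/3) * (1/2) survives at t = 3
  km2 <- km_estimate(c(1, 3, 3.5), c(TRUE, TRUE, FALSE))
  expect_equal(km2$surv[km2$time == 3], 1 / 3)

  all_cens <- km_estimate(c(2, 5, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(all_cens$surv == 1))
  one <- km_estimate(5, TRUE)
  expect_equal(one$surv, 0)
  expect_error(km_estimate(numeric(0), logical(0)), "no observations")
  expect_true(all(diff(km$surv) <= 0))
})

test_that("pooling two identical groups reproduces the group curve", {
  set.seed(5)
  tm <- rexp(30, 0.1); ev <- runif(30) < 0.7
  km_g <- km_estimate(tm, ev)
  km_p <- km_estimate(c(tm, tm), c(ev, ev))
  expect_equal(km_p$surv, km_g$surv)
  expect_equal(km_p$n_risk, 2 * km_g$n_risk)
})

test_that("log-rank test matches the hand-worked 4-subject fixture", {
  lr <- logrank_test(c(1, 3, 2, 4), c(TRUE, TRUE, TRUE, FALSE),
                     c("a", "a", "b", "b"))
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 4 / 3, tolerance = 1e-12)
  expect_equal(lr$chi_square, (2 - 4 / 3)^2 / (13 / 18), tolerance = 1e-12)
  expect_equal(round(lr$chi_square, 3), 0.615)
})

test_that("log-rank chi-square equals survival::survdiff on random data", {
  set.seed(88)
  for (i in 1:20) {
    d <- make_survival_groups(sample(10:60, 1), 0.08, runif(1, 0.05, 0.25))
    lr <- logrank_test(d$time, d$event, d$group)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-9)
  }
})

test_that("log-rank is zero for identical groups and errors degenerately", {
  tm <- c(1, 2, 5, 7); ev <- c(TRUE, TRUE, FALSE, TRUE)
  lr <- logrank_test(c(tm, tm), c(ev, ev), rep(c("a", "b"), each = 4))
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(c(1, 2), c(FALSE, FALSE), c("a", "b")),
               "no events")
})

test_that("cutpoint scan finds the separating threshold", {
  marker <- c(1, 2, 3, 10, 11, 12)
  time <- c(2, 3, 2.5, 30, 28, 26)
  event <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  cp <- find_optimal_cutpoint(marker, time, event, minprop = 0.1)
  expect_gte(cp$threshold, 3)
  expect_lt(cp$threshold, 10)
  expect_equal(cp$n_high, 3)
  expect_equal(cp$n_low, 3)
  # minprop 0.5 admits only the 3/3 split
  cp2 <- find_optimal_cutpoint(marker, time, event, minprop = 0.49)
  expect_equal(cp2$threshold, 6.5)
  expect_equal(cp2$n_candidates, 1)
  expect_error(find_optimal_cutpoint(rep(1, 6), time, event),
               "identical")
})

test_that("cutpoint is invariant under strictly monotone marker maps", {
  set.seed(17)
  n <- 60
  marker <- rnorm(n)
  tm <- rexp(n, 0.1 * exp(0.5 * (marker < 0)))
  ev <- runif(n) < 0.8
  cp <- find_optimal_cutpoint(marker, tm, ev)
  cp2 <- find_optimal_cutpoint(exp(marker), tm, ev)
  expect_equal(cp2$statistic, cp$statistic, tolerance = 1e-9)
  expect_equal(as.character(cp2$group_assignment),
               as.character(cp$group_assignment))
  expect_equal(cp2$naive_logrank_p, cp$naive_logrank_p, tolerance = 1e-9)
})

test_that("dichotomize uses a strict boundary for the high group", {
  expect_equal(as.character(dichotomize(5.0, 5.0)), "low")
  expect_equal(as.character(dichotomize(5.1, 5.0)), "high")
  expect_equal(length(dichotomize(numeric(0), 1)), 0)
  g <- dichotomize(c(a = 1, b = 9), 5)
  expect_equal(names(g), c("a", "b"))
})

test_that("Cox fit recovers a known hazard ratio", {
  set.seed(23)
  d <- make_survival_groups(250, 0.05, 0.10)   # true HR (b vs a) = 2
  fit <- cox_fit(d, "group")
  hr <- fit$table$hr[fit$table$term == "groupb"]
  expect_gte(hr, 1.7)
  expect_lte(hr, 2.35)
  expect_true(fit$convergence)
  expect_equal(fit$table$hr, exp(fit$table$coef))
  expect_true(all(fit$table$ci_low <= fit$table$hr &
                    fit$table$hr <= fit$table$ci_high))
})

test_that("constant covariates are dropped with a warning", {
  set.seed(9)
  d <- make_survival_groups(40, 0.05, 0.1)
  d$flat <- 1
  expect_warning(fit <- cox_fit(d, c("group", "flat")), "no variation")
  expect_false("flat" %in% sub("[a-z]+$", "", fit$table$term))
  d$group <- "a"
  expect_error(suppressWarnings(cox_fit(d, c("group", "flat"))),
               "no identifiable")
})

test_that("Cox Wald chi-square approximates the log-rank chi-square", {
  set.seed(61)
  d <- make_survival_groups(100, 0.06, 0.12)   # n = 200
  fit <- cox_fit(d, "group")
  wald <- (fit$table$coef / fit$table$se)^2
  lr <- logrank_test(d$time, d$event, d$group)
  expect_lt(abs(wald - lr$chi_square) / lr$chi_square, 0.15)
})

test_that("Cox coefficient estimates are unbiased over replicates", {
  set.seed(301)
  est <- replicate(100, {
    d <- make_survival_groups(150, 0.05, 0.05 * 2)   # true log-HR 0.693
    fit <- cox_fit(d, "group")
    fit$table$coef[fit$table$term == "groupb"]
  })
  expect_lt(abs(mean(est) - log(2)), 0.1)
})

test_that("the selection-adjusted p-value is more conservative than naive", {
  set.seed(44)
  n <- 80
  marker <- rnorm(n)
  tm <- rexp(n, 0.1); ev <- runif(n) < 0.7   # no true association
  cp <- find_optimal_cutpoint(marker, tm, ev)
  expect_gte(cp$adjusted_p, cp$naive_logrank_p)
  expect_lte(cp$adjusted_p, 1)
})
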