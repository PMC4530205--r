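test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  # S(2) = (2/3) * (1/2) = 1/3
  expect_equal(unname(km_surv_prob(km, 2)), 1 / 3)
  # no events: survival stays at 1
  km0 <- km_estimate(c(5, 7, 9), c(0, 0, 0))
  expect_equal(unname(km_surv_prob(km0, 9)), 1)
  # simulated exponential: estimate tracks the truth inside the band
  set.seed(61)
  t_ev <- rexp(1000, 0.05)
  kme <- km_estimate(t_ev, rep(1, 1000))
  s20 <- summary(kme$fit, times = 20)
  expect_gt(s20$upper, exp(-0.05 * 20))
  expect_lt(s20$lower, exp(-0.05 * 20))
})

test_that("log-rank agrees with survdiff and with the Cox score test", {
  set.seed(62)
  time <- rexp(150, 0.03); event <- rbinom(150, 1, 0.8)
  group <- rep(c(0, 1), 75)
  lr <- logrank_test(time, event, group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(lr$chi_square, sd_$chisq, tolerance = 1e-10)
  cox <- survival::coxph(survival::Surv(time, event) ~ group,
                         ties = "breslow")
  expect_equal(lr$chi_square, unname(summary(cox)$sctest["test"]),
               tolerance = 1e-6)
  # duplicated groups: no separation
  lr0 <- logrank_test(rep(time, 2), rep(event, 2), rep(c("a", "b"),
                                                       each = 150))
  expect_lt(lr0$chi_square, 1e-10)
  expect_error(logrank_test(time, event, rep("a", 150)), "2 groups")
})

test_that("log-rank has the advertised power and size", {
  rej <- vapply(1:40, function(s) {
    withr::with_seed(s, {
      g <- rep(c(0, 1), each = 100)
      t_ev <- rexp(200, 0.02 * ifelse(g == 1, 3, 1))
      cens <- runif(200, 0, 80)
      logrank_test(pmin(t_ev, cens), as.integer(t_ev <= cens), g)$p < 0.05
    })
  }, logical(1))
  expect_gte(mean(rej), 0.99)
  size <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, {
      g <- rep(c(0, 1), each = 60)
      t_ev <- rexp(120, 0.02)
      logrank_test(t_ev, rep(1L, 120), g)$p < 0.05
    })
  }, logical(1))
  expect_lt(abs(mean(size) - 0.05), 0.05)
})

test_that("Cox fits recover simulated hazard ratios", {
  set.seed(63)
  x <- rbinom(2000, 1, 0.5)
  t_ev <- rexp(2000, 0.02 * exp(log(2) * x))
  cens <- runif(2000, 0, 120)
  fit <- cox_fit(data.frame(x = x), pmin(t_ev, cens),
                 as.integer(t_ev <= cens))
  expect_gt(fit$terms$hr, 1.8); expect_lt(fit$terms$hr, 2.2)
  expect_true(fit$r2 > 0 && fit$r2 < 1)
  # uncensored two-group exponential: HR consistent with the rate ratio
  t2 <- rexp(2000, 0.02 * exp(log(3) * x))
  fit2 <- cox_fit(data.frame(x = x), t2, rep(1L, 2000))
  rate_ratio <- (sum(x) / sum(t2[x == 1])) / (sum(1 - x) / sum(t2[x == 0]))
  expect_equal(fit2$terms$hr, rate_ratio, tolerance = 0.05)
  # collinear covariates are an error
  expect_error(cox_fit(data.frame(a = x, b = x), t2, rep(1L, 2000)),
               "singular")
})

test_that("R2 increases when a truly informative covariate is added", {
  set.seed(64)
  x1 <- rbinom(500, 1, 0.5); x2 <- rbinom(500, 1, 0.5)
  t_ev <- rexp(500, 0.02 * exp(0.9 * x1 + 0.9 * x2))
  f1 <- cox_fit(data.frame(x1 = x1), t_ev, rep(1L, 500))
  f12 <- cox_fit(data.frame(x1 = x1, x2 = x2), t_ev, rep(1L, 500))
  expect_gt(f12$r2, f1$r2)
})

test_that("stepwise selection keeps informative terms and is deterministic", {
  sim <- function(seed) {
    withr::with_seed(seed, {
      X <- as.data.frame(matrix(rbinom(400 * 10, 1, 0.4), 400, 10))
      names(X) <- c("inf1", "inf2", sprintf("noise%d", 1:8))
      t_ev <- rexp(400, 0.02 * exp(log(2.5) * (X$inf1 + X$inf2)))
      cens <- runif(400, 0, 100)
      list(X = X, time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
    })
  }
  hits <- vapply(1:10, function(s) {
    d <- sim(s)
    sel <- stepwise_select(d$X, time = d$time, event = d$event,
                           model = "cox")$selected
    all(c("inf1", "inf2") %in% sel)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  d <- sim(99)
  s1 <- stepwise_select(d$X, time = d$time, event = d$event, model = "cox")
  s2 <- stepwise_select(d$X, time = d$time, event = d$event, model = "cox")
  expect_identical(s1$selected, s2$selected)
  # a single candidate meeting the stay level is retained
  one <- stepwise_select(d$X["inf1"], time = d$time, event = d$event,
                         model = "cox")
  expect_identical(one$selected, "inf1")
  # forced variables survive even when non-significant
  forced <- stepwise_select(d$X[c("noise1", "inf1")], time = d$time,
                            event = d$event, model = "cox",
                            forced = "noise1")
  expect_true("noise1" %in% forced$selected)
})

test_that("stepwise on pure noise selects few variables", {
  false_sel <- vapply(1:10, function(s) {
    withr::with_seed(s + 500, {
      X <- as.data.frame(matrix(rbinom(300 * 8, 1, 0.5), 300, 8))
      names(X) <- sprintf("n%d", 1:8)
      t_ev <- rexp(300, 0.03)
      length(stepwise_select(X, time = t_ev, event = rep(1L, 300),
                             model = "cox")$selected)
    })
  }, numeric(1))
  # with stay = 0.05 the expected number of retained noise terms is well
  # below one per candidate set
  expect_lt(mean(false_sel), 1.5)
})

test_that("odds ratios carry Wald intervals and the Haldane correction", {
  o <- odds_ratio_2x2(28, 15, 30, 64)
  expect_equal(round(o$or, 2), 3.98)
  expect_equal(round(o$ci, 2), c(1.86, 8.54))
  o2 <- odds_ratio_2x2(21, 7, 39, 72)
  expect_equal(round(o2$or, 2), 5.54)
  expect_equal(round(o2$ci, 2), c(2.16, 14.18))
  expect_equal(odds_ratio_2x2(9, 9, 9, 9)$or, 1)
  oz <- odds_ratio_2x2(5, 0, 3, 7)
  expect_true(oz$corrected)
  expect_error(odds_ratio_2x2(5, 0, 3, 7, haldane = FALSE), "zero cell")
  expect_error(odds_ratio_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("univariate logistic regression reproduces the 2x2 odds ratio", {
  x <- rep(c(1, 1, 0, 0), c(28, 15, 30, 64))
  y <- rep(c(1, 0, 1, 0), c(28, 15, 30, 64))
  fit <- logistic_fit(data.frame(exposed = x), y)
  expect_equal(fit$terms$or, 28 * 64 / (15 * 30), tolerance = 1e-6)
  o <- odds_ratio_2x2(28, 15, 30, 64)
  expect_equal(fit$terms$p, o$p, tolerance = 1e-4)
  expect_error(logistic_fit(data.frame(x = rep(1, 10)),
                            rep(c(0, 1), 5)), "singular|constant")
  expect_error(logistic_fit(data.frame(x = rnorm(10)), rep(1, 10)),
               "both classes")
})

test_that("logistic Wald intervals achieve nominal coverage", {
  cover <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      x <- rbinom(150, 1, 0.5)
      y <- rbinom(150, 1, 0.4)          # true coefficient 0
      f <- logistic_fit(data.frame(x = x), y)
      f$terms$lower <= 1 && 1 <= f$terms$upper
    })
  }, logical(1))
  expect_equal(mean(cover), 0.95, tolerance = 0.04)
})

test_that("rank correlation and group comparisons behave canonically", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_corr(x, exp(x)), 1)
  expect_equal(spearman_corr(x, -x), -1)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 2:1), "3 pairs")
  set.seed(65)
  xy <- MASS::mvrnorm(139, c(0, 0), matrix(c(1, 0.6, 0.6, 1), 2))
  expect_equal(spearman_corr(xy[, 1], xy[, 2]), 0.58, tolerance = 0.15)

  # identical groups: t and exact Mann-Whitney give p = 1
  g <- c(1, 2, 3, 4)
  expect_equal(group_compare(g, g, kind = "t")$p, 1)
  expect_equal(group_compare(g, g, kind = "mannwhitney")$p, 1)
  # Pearson chi-square on the B2M table exceeds 10 (hand value 13.3)
  chi <- group_compare(matrix(c(28, 30, 15, 64), 2), kind = "chi2")
  expect_equal(chi$statistic, 13.32, tolerance = 0.01)
})
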