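test_that("cohort proportions report rounded percentages that sum to 100", {
  p <- cohort_proportions(rep(c("low", "high"), c(31, 41)))
  expect_equal(p$percent[p$category == "low"], 43.10)
  expect_equal(p$percent[p$category == "high"], 56.90)

  p <- cohort_proportions(rep("high", 10))
  expect_equal(p$n, c(0, 10))
  expect_equal(p$percent, c(0, 100))

  set.seed(4)
  for (i in 1:25) {
    n <- sample(3:400, 1)
    p <- cohort_proportions(sample(c("low", "high"), n, replace = TRUE,
                                   prob = c(runif(1), 1)))
    expect_lte(abs(sum(p$percent) - 100), 0.01)
  }
  expect_error(cohort_proportions(character(0)), "empty")
})

test_that("Fisher's exact p agrees with full hypergeometric enumeration", {
  # enumeration oracle: all tables with the observed margins
  fisher_enum <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    as <- max(0, c1 - (n - r1)):min(r1, c1)
    pr <- dhyper(as, c1, n - c1, r1)
    p_obs <- dhyper(a, c1, n - c1, r1)
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }

  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$p_value, 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p_value, 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 0)$p_value, 1)  # degenerate margin

  set.seed(77)
  for (i in 1:100) {
    x <- as.vector(rmultinom(1, sample(4:40, 1), runif(4)))
    if (sum(x[1:2]) == 0 || sum(x[3:4]) == 0 ||
        sum(x[c(1, 3)]) == 0 || sum(x[c(2, 4)]) == 0) next
    expect_equal(fisher_exact_2x2(x[1], x[2], x[3], x[4])$p_value,
                 fisher_enum(x[1], x[2], x[3], x[4]), tolerance = 1e-9)
  }
})

test_that("Pearson chi-square without continuity correction", {
  r <- chi_square_2x2(25, 25, 25, 25)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # hand evaluation: all expected counts are 20, sum((O-E)^2/E) = 4*100/20
  r <- chi_square_2x2(30, 10, 10, 30)
  expect_equal(r$statistic, 20)
  expect_equal(r$p_value, pchisq(20, 1, lower.tail = FALSE))

  # doubling all cells doubles the statistic
  r2 <- chi_square_2x2(60, 20, 20, 60)
  expect_equal(r2$statistic, 40)

  expect_error(chi_square_2x2(5, 5, 0, 0), "expected")
})

test_that("Kaplan-Meier estimate matches hand product-limit results", {
  # all censored: flat at 1
  km <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km$survival == 1))

  # 2 patients, events at 1 and 2
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$survival, c(0.5, 0))

  # event@1, censor@2, event@3: S = 2/3 after t=1, 0 after t=3
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)

  # non-increasing, starts <= 1; equals empirical survival with no censoring
  set.seed(12)
  t <- rexp(40); e <- rep(1, 40)
  km <- km_estimate(t, e)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_lte(km$survival[1], 1)
  emp <- vapply(km$time, function(x) mean(t > x), 0)
  expect_equal(km$survival, emp, tolerance = 1e-12)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
  # missing times are excluded
  km2 <- km_estimate(c(1, NA, 2), c(1, 1, 1))
  expect_equal(nrow(km2), 2)
})

test_that("log-rank test matches the hand-computed 6-patient example", {
  time <- c(2, 4, 6, 3, 5, 7)
  event <- c(1, 1, 0, 1, 0, 1)
  group <- c("A", "A", "A", "B", "B", "B")
  r <- logrank_test(time, event, group)
  # O = 2, E = 1.4, V = 0.74 accumulated over event times 2, 3, 4, 7
  expect_equal(r$statistic, 0.4864864865, tolerance = 1e-9)
  expect_equal(r$p_value, 0.4854988026, tolerance = 1e-9)
  expect_equal(r$statistic, logrank_oracle(time, event, group),
               tolerance = 1e-9)

  # symmetric in group order
  set.seed(31)
  tt <- rexp(30); ee <- rbinom(30, 1, 0.7); gg <- rep(c("x", "y"), 15)
  expect_equal(logrank_test(tt, ee, gg)$statistic,
               logrank_test(tt, ee, factor(gg, c("y", "x")))$statistic,
               tolerance = 1e-12)

  # identical groups: statistic 0, p = 1
  r3 <- logrank_test(c(time, time), c(event, event),
                     rep(c("A", "B"), each = 6))
  expect_equal(r3$statistic, 0, tolerance = 1e-12)
  expect_equal(r3$p_value, 1, tolerance = 1e-12)

  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "no events")
  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")), "two groups")
})

test_that("log-rank p is consistent with a permutation null", {
  set.seed(99)
  n <- 20
  time <- round(rexp(n, 0.1), 2)
  event <- rbinom(n, 1, 0.8)
  group <- rep(c("A", "B"), each = 10)
  obs <- logrank_oracle(time, event, group)
  p_asym <- logrank_test(time, event, group)$p_value

  B <- 4000
  stats <- replicate(B, logrank_oracle(time, event, sample(group)))
  p_perm <- mean(stats >= obs - 1e-12)
  # Monte-Carlo error ~0.008 plus the chi-square approximation gap at n=20
  expect_lt(abs(p_perm - p_asym), 0.05)
})

test_that("survival report joins categories with follow-up and tests groups", {
  patients <- data.frame(patient_id = sprintf("p%d", 1:6),
                         category = rep(c("low", "high"), each = 3))
  fup <- data.frame(patient_id = sprintf("p%d", 1:7),
                    time_months = c(10, 20, 30, 5, 8, NA, 50),
                    event = c(1, 0, 1, 1, 1, 1, 0))
  rep <- survival_report(patients, fup)
  expect_equal(rep$n_matched, 5)  # p6 has no usable time, p7 no category
  expect_equal(rep$n_dropped, 1)
  expect_named(rep$km, c("low", "high"))
  expect_s3_class(rep$km$low, "data.frame")
  expect_true(rep$logrank$p_value >= 0 && rep$logrank$p_value <= 1)
})
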