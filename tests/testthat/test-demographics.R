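test_that("summary-based and vector-based Welch tests agree to 1e-12", {
  set.seed(42)
  for (i in 1:10) {
    x1 <- rnorm(sample(5:60, 1), mean = runif(1, -2, 2), sd = runif(1, .5, 3))
    x2 <- rnorm(sample(5:60, 1), mean = runif(1, -2, 2), sd = runif(1, .5, 3))
    a <- welchFromSummary(mean(x1), sd(x1), length(x1),
                          mean(x2), sd(x2), length(x2))
    b <- welchFromVectors(x1, x2)
    expect_equal(unname(a$statistic), unname(b$statistic), tolerance = 1e-12)
    expect_equal(unname(a$parameter), unname(b$parameter), tolerance = 1e-12)
  }
})

test_that("Welch test matches a direct textbook recomputation", {
  set.seed(7)
  x1 <- rnorm(50, 0, 1); x2 <- rnorm(50, 1, 1)
  v1 <- var(x1) / 50; v2 <- var(x2) / 50
  t_ref <- (mean(x1) - mean(x2)) / sqrt(v1 + v2)
  df_ref <- (v1 + v2)^2 / (v1^2 / 49 + v2^2 / 49)
  res <- welchFromVectors(x1, x2)
  expect_equal(unname(res$statistic), t_ref, tolerance = 1e-12)
  expect_equal(unname(res$parameter), df_ref, tolerance = 1e-12)
})

test_that("Welch test symmetry, degenerate input, and df bounds hold", {
  same <- welchFromSummary(5, 2, 20, 5, 2, 20)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  ab <- welchFromSummary(3, 1, 12, 4, 2, 30)
  ba <- welchFromSummary(4, 2, 30, 3, 1, 12)
  expect_equal(unname(ab$statistic), -unname(ba$statistic))
  expect_equal(unname(ab$parameter), unname(ba$parameter))

  expect_error(welchFromSummary(1, 0, 10, 2, 1, 10), "positive")
  expect_error(welchFromSummary(1, 1, 1, 2, 1, 10), "at least 2")

  set.seed(1)
  for (i in 1:20) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    r <- welchFromSummary(0, runif(1, .2, 4), n1, 1, runif(1, .2, 4), n2)
    expect_lte(unname(r$parameter), n1 + n2 - 2)
    expect_gte(unname(r$parameter), min(n1, n2) - 1)
  }
})

test_that("p-values fall monotonically in |t| at fixed df", {
  ts <- seq(0.1, 4, by = 0.3)
  ps <- sapply(ts, function(t0) 2 * pt(t0, df = 30, lower.tail = FALSE))
  expect_true(all(diff(ps) < 0))
})

test_that("2x2 chi-squared matches a hand computation of sum (O-E)^2/E", {
  tab <- c(55, 55, 43, 40)
  m <- matrix(tab, 2, byrow = TRUE)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  ref <- sum((m - E)^2 / E)
  res <- chisq2x2(55, 55, 43, 40)
  expect_equal(unname(res$statistic), ref, tolerance = 1e-12)
  expect_equal(unname(res$parameter), 1)

  # transpose invariance and exact independence
  expect_equal(unname(chisq2x2(55, 43, 55, 40)$statistic),
               unname(res$statistic))
  expect_equal(unname(chisq2x2(20, 10, 40, 20)$statistic), 0)
  expect_equal(unname(chisq2x2(10, 0, 0, 10)$statistic), 20)
  expect_error(chisq2x2(0, 0, 5, 5), "margin")
})

test_that("cohort summary reproduces design sex ratios and spec moments", {
  co <- generateCohort(syntheticSpec(), seed = 12)
  s <- summarizeCohort(co)
  sr <- attr(s, "sex_ratio")
  expect_equal(unname(sr["case"]), 1)
  expect_equal(unname(sr["control"]), 43 / 40)

  # sampled group means near the generating values (3 standard errors)
  row <- s[s$descriptor == "ticv", ]
  expect_lt(abs(row$mean_case - 212.94), 3 * 30.07 / sqrt(110))
  expect_lt(abs(row$mean_control - 217.56), 3 * 25.94 / sqrt(83))
  ager <- s[s$descriptor == "age", ]
  expect_gte(ager$min_case, 7); expect_lte(ager$max_case, 18)
})

test_that("degenerate and single-group cohorts are handled explicitly", {
  co <- handCohort(3)
  co$age <- rep(10, nrow(co))
  s <- summarizeCohort(co)
  expect_true(s$degenerate[s$descriptor == "age"])
  expect_true(is.na(s$t[s$descriptor == "age"]))

  one <- co[co$diagnosis == 1, ]
  expect_error(summarizeCohort(one), "both diagnosis groups")
})
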