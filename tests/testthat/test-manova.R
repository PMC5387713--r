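test_that("design coding follows the +/-1 factorial convention", {
  co <- handCohort(3)  # balanced 2x2
  X <- buildDesign(co)
  expect_identical(colnames(X),
                   c("(Intercept)", "sex", "diagnosis", "interaction"))
  expect_equal(unname(colMeans(X)), c(1, 0, 0, 0))
  expect_equal(X[, "interaction"], X[, "sex"] * X[, "diagnosis"])
  male_asd <- which(co$sex == 1 & co$diagnosis == 1)[1]
  expect_equal(unname(X[male_asd, ]), c(1, 1, 1, 1))
  female_td <- which(co$sex == -1 & co$diagnosis == -1)[1]
  expect_equal(unname(X[female_td, ]), c(1, -1, -1, 1))

  expect_warning(buildDesign(co[co$sex == 1 | co$diagnosis == -1, ]),
                 "empty sex-by-diagnosis cell")
})

test_that("noise-free responses are interpolated exactly", {
  co <- handCohort(4)
  X <- buildDesign(co)
  B0 <- matrix(c(1, 2, -3, 0.5, 0, 1, 2, -1), nrow = 4)
  Y <- X %*% B0
  fit <- fitMvReg(X, Y)
  expect_equal(unname(fit@B), unname(B0), tolerance = 1e-10)
  expect_lt(max(abs(fit@E)), 1e-18)
})

test_that("a single response reduces to univariate least squares", {
  co <- handCohort(5)
  X <- buildDesign(co)
  set.seed(10)
  y <- rnorm(nrow(co))
  fit <- fitMvReg(X, matrix(y))
  ref <- lm(y ~ sex * diagnosis, data = co)
  # same model in a different parameterization: compare fitted values
  expect_equal(drop(X %*% fit@B), unname(fitted(ref)), tolerance = 1e-10)
  # and the scalar Wilks ratio E/(E+H)
  lam <- wilksLambda(fit)
  expect_equal(lam, sum(resid(ref)^2) /
                 sum((y - mean(y))^2), tolerance = 1e-12)
  # p = 1 Rao transform is the exact overall regression F
  r <- raoF(lam, p = 1, vH = fit@vH, vE = fit@vE)
  aov_f <- summary(ref)$fstatistic
  expect_equal(r$F, unname(aov_f[1]), tolerance = 1e-10)
  expect_equal(unname(c(r$d1, r$d2)), unname(aov_f[2:3]))
})

test_that("H + E reconstructs the total corrected SSCP on random fits", {
  set.seed(20)
  for (i in 1:5) {
    co <- handCohort(sample(3:6, 1))
    X <- buildDesign(co)
    Y <- matrix(rnorm(nrow(co) * 5), ncol = 5)
    fit <- fitMvReg(X, Y)
    Tot <- crossprod(sweep(Y, 2, colMeans(Y)))
    expect_equal(fit@H + fit@E, Tot, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(fit@vH, 3)
    expect_equal(fit@vE, nrow(co) - 4)
  }
})

test_that("Wilks lambda equals the eigenvalue product of E^-1 H", {
  co <- handCohort(6)
  X <- buildDesign(co)
  set.seed(30)
  Y <- matrix(rnorm(nrow(co) * 4), ncol = 4)
  fit <- fitMvReg(X, Y)
  ev <- Re(eigen(solve(fit@E) %*% fit@H, only.values = TRUE)$values)
  expect_equal(wilksLambda(fit), prod(1 / (1 + ev)), tolerance = 1e-10)
})

test_that("Wilks lambda is invariant under nonsingular response mixing", {
  co <- handCohort(6)
  X <- buildDesign(co)
  set.seed(31)
  Y <- matrix(rnorm(nrow(co) * 5), ncol = 5)
  lam <- wilksLambda(fitMvReg(X, Y))
  for (i in 1:3) {
    A <- matrix(rnorm(25), 5, 5)
    expect_equal(wilksLambda(fitMvReg(X, Y %*% A)), lam, tolerance = 1e-9)
  }
})

test_that("Rao transform reproduces the printed df pair and exact cases", {
  r <- raoF(0.3, p = 165, vH = 3, vE = 189)
  expect_equal(r$d1, 495)
  expect_equal(r$d2_rounded, 76)

  # vH = 1 yields the exact F on (p, vE - p + 1) df
  r1 <- raoF(0.6, p = 4, vH = 1, vE = 30)
  expect_equal(r1$t, 1)
  expect_equal(unname(c(r1$d1, r1$d2)), c(4, 27))
  expect_equal(r1$F, (1 - 0.6) / 0.6 * 27 / 4, tolerance = 1e-12)

  expect_error(raoF(0, 3, 3, 10), "lambda")
  expect_error(raoF(-0.1, 3, 3, 10), "lambda")
})

test_that("omnibus table has one decided row per metric", {
  ce <- simulateExperiment(tinySpec(), seed = 40)
  ce <- ticvNormalize(ce)
  ce <- residualizeConfounds(ce)
  s1 <- omnibusStep1(ce)
  expect_equal(nrow(s1), length(metricNames(ce)))
  expect_named(s1, c("metric", "lambda", "F", "d1", "d2", "d2_rounded",
                     "p", "p_adj", "reject"))
  expect_true(all(s1$lambda > 0 & s1$lambda <= 1))
  expect_true(all(s1$p_adj >= s1$p))
})

test_that("predictor LOO recovers a planted interaction and ignores removed signal", {
  sp <- tinySpec(p = 10, n_case = 60, n_ctrl = 50, delta = 1.2,
                 n_targets = 4)
  hits <- vapply(1:20, function(i) {
    ce <- simulateExperiment(sp, seed = 100 + i)
    ce <- ticvNormalize(ce); ce <- residualizeConfounds(ce)
    co <- cohortTable(ce)
    tab <- predictorLooStep2(metricPanel(ce, "CD"), buildDesign(co))
    tab$predictor[which.min(tab$p)] == "interaction"
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # a predictor already residualized out of Y carries no partial signal
  ce <- simulateExperiment(sp, seed = 200)
  co <- cohortTable(ce)
  X <- buildDesign(co)
  Y <- metricPanel(ce, "CD")
  Yr <- Y - X[, "interaction"] %*%
    t(crossprod(Y, X[, "interaction"])) / sum(X[, "interaction"]^2)
  tab <- predictorLooStep2(Yr, X)
  ix <- tab$predictor == "interaction"
  expect_gt(tab$partial_lambda[ix], 0.9)
  expect_gt(tab$p[ix], 0.5)
})

test_that("step-2 output carries both df conventions", {
  ce <- simulateExperiment(tinySpec(), seed = 50)
  co <- cohortTable(ce)
  Y <- metricPanel(ce, "CD")
  tab <- predictorLooStep2(Y, buildDesign(co))
  p <- ncol(Y); vE <- nrow(Y) - 4
  expect_equal(unique(tab$df1), p)
  expect_equal(unique(tab$df2), vE - p + 1)
  expect_equal(unique(tab$df1_alt), 3)
  expect_equal(unique(tab$df2_alt), vE - p)
})
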