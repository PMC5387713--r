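test_that("covariance partition matches hand computation and shapes", {
  Y <- matrix(c(1, 2, 4, 0, 1, -1), nrow = 3)   # 3 subjects, 2 responses
  X <- cbind(`(Intercept)` = 1, x1 = c(1, 0, -1))
  b <- partitionCovariance(Y, X)
  expect_equal(dim(b$S_yy), c(2, 2))
  expect_equal(dim(b$S_yx), c(2, 1))
  expect_equal(dim(b$S_xx), c(1, 1))
  # hand: cov of column 1 = ((1-7/3)^2+(2-7/3)^2+(4-7/3)^2)/2
  expect_equal(b$S_yy[1, 1], sum((c(1, 2, 4) - 7 / 3)^2) / 2)
  expect_equal(unname(b$S_yx[1, 1]),
               sum((c(1, 2, 4) - 7 / 3) * c(1, 0, -1)) / 2)
  expect_equal(b$S_xx[1, 1], 1)
  expect_equal(b$S_yx, t(cov(X[, 2, drop = FALSE], Y)),
               ignore_attr = TRUE)
  Yz <- Y; Yz[, 2] <- 5
  expect_error(partitionCovariance(Yz, X), "zero-variance")
})

test_that("whiten-and-SVD canonical correlations match stats::cancor", {
  set.seed(60)
  for (i in 1:5) {
    n <- 40; p <- sample(3:6, 1); q <- 3
    Y <- matrix(rnorm(n * p), n)
    X <- matrix(rnorm(n * q), n)
    X[, 1] <- X[, 1] + 0.5 * Y[, 1]
    res <- ccaFit(Y, X)
    ref <- cancor(X, Y)
    expect_equal(canonicalCors(res), ref$cor, tolerance = 1e-8)
  }
})

test_that("single-predictor CCA is the multiple correlation coefficient", {
  set.seed(61)
  Y <- matrix(rnorm(50 * 4), 50)
  x <- rnorm(50) + Y[, 2]
  r1 <- canonicalCors(ccaFit(Y, cbind(x = x)))[1]
  R2 <- summary(lm(x ~ Y))$r.squared
  expect_equal(r1, sqrt(R2), tolerance = 1e-10)
})

test_that("first canonical correlation matches brute-force maximization", {
  set.seed(62)
  n <- 60
  Y <- matrix(rnorm(n * 2), n)
  X <- matrix(rnorm(n * 2), n)
  X[, 1] <- X[, 1] + 0.8 * Y[, 1] - 0.4 * Y[, 2]
  r1 <- canonicalCors(ccaFit(Y, X))[1]
  # grid over unit vectors a = (cos t, sin t), b = (cos u, sin u)
  theta <- seq(0, pi, length.out = 1500)
  U <- Y %*% rbind(cos(theta), sin(theta))
  V <- X %*% rbind(cos(theta), sin(theta))
  cc <- cor(U, V)
  expect_equal(r1, max(abs(cc)), tolerance = 1e-3)
})

test_that("canonical correlations are invariant under block-wise mixing", {
  set.seed(63)
  Y <- matrix(rnorm(45 * 5), 45)
  X <- matrix(rnorm(45 * 3), 45)
  r <- canonicalCors(ccaFit(Y, X))
  A <- matrix(rnorm(25), 5); B <- matrix(rnorm(9), 3)
  r2 <- canonicalCors(ccaFit(Y %*% A, X %*% B))
  expect_equal(r, r2, tolerance = 1e-8)
})

test_that("canonical variates realize the correlations and are orthogonal", {
  set.seed(64)
  Y <- matrix(rnorm(80 * 6), 80)
  X <- matrix(rnorm(80 * 3), 80)
  X <- X + Y[, 1:3] * 0.6
  res <- ccaFit(Y, X)
  r <- canonicalCors(res)
  s <- length(r)
  cc <- cor(res@yscores, res@xscores)
  expect_equal(diag(cc), r, tolerance = 1e-8)
  expect_lt(max(abs(cc[upper.tri(cc)]), abs(cc[lower.tri(cc)])), 1e-8)
  cu <- cor(res@yscores)
  expect_lt(max(abs(cu[upper.tri(cu)])), 1e-8)
  cv <- cor(res@xscores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
})

test_that("CCA-form Wilks lambda equals the determinant-ratio lambda", {
  set.seed(65)
  for (i in 1:5) {
    co <- handCohort(sample(5:8, 1))
    X <- buildDesign(co)
    Y <- matrix(rnorm(nrow(co) * sample(3:7, 1)), nrow(co))
    lam_det <- wilksLambda(fitMvReg(X, Y))
    lam_cca <- ccaWilks(ccaFit(Y, X))
    expect_equal(lam_cca, lam_det, tolerance = 1e-10)
  }
})

test_that("CCA-route predictor LOO decides exactly as the regression route", {
  sp <- tinySpec(p = 8, n_case = 40, n_ctrl = 34, delta = 1, n_targets = 3)
  for (seed in c(70, 71)) {
    ce <- simulateExperiment(sp, seed = seed)
    ce <- ticvNormalize(ce); ce <- residualizeConfounds(ce)
    co <- cohortTable(ce)
    X <- buildDesign(co)
    Y <- metricPanel(ce, "CD")
    t2 <- predictorLooStep2(Y, X)
    t3 <- predictorLooStep3(Y, X)
    expect_equal(t3$partial_lambda, t2$partial_lambda, tolerance = 1e-9)
    expect_equal(t3$F, t2$F, tolerance = 1e-8)
    expect_identical(t3$reject, t2$reject)
  }
})

test_that("a pure-noise predictor carries no partial CCA signal", {
  set.seed(72)
  Y <- matrix(rnorm(70 * 5), 70)
  x_signal <- rnorm(70) + Y[, 1]
  x_noise <- rnorm(70)
  X <- cbind(`(Intercept)` = 1, signal = x_signal, noise = x_noise)
  tab <- predictorLooStep3(Y, X)
  expect_gt(tab$partial_lambda[tab$predictor == "noise"], 0.9)
  expect_lt(tab$p[tab$predictor == "signal"], 0.01)
})

test_that("region LOO equals brute-force dual Wilks evaluations", {
  sp <- tinySpec(p = 9, delta = 1.5, n_targets = 3)
  ce <- simulateExperiment(sp, seed = 80)
  ce <- ticvNormalize(ce); ce <- residualizeConfounds(ce)
  co <- cohortTable(ce)
  X <- buildDesign(co)
  Y <- metricPanel(ce, "CD")
  tab <- responseLooStep4(Y, X, atlas = sp$atlas)
  lam_full <- wilksLambda(fitMvReg(X, Y))
  for (j in c(1, 4, 9)) {
    lam_red <- wilksLambda(fitMvReg(X, Y[, -j]))
    expect_equal(tab$partial_lambda[j], lam_full / lam_red,
                 tolerance = 1e-12)
  }
  expect_identical(tab$parcel, colnames(Y))
  expect_identical(tab$hemisphere, hemisphere(sp$atlas))
})

test_that("region LOO ranking is column-order invariant and flags targets", {
  sp <- tinySpec(p = 10, n_case = 60, n_ctrl = 50, delta = 1.5,
                 n_targets = 3)
  ce <- simulateExperiment(sp, seed = 81)
  ce <- ticvNormalize(ce); ce <- residualizeConfounds(ce)
  co <- cohortTable(ce)
  X <- buildDesign(co)
  Y <- metricPanel(ce, "CD")
  tab <- responseLooStep4(Y, X)
  perm <- sample(ncol(Y))
  tab_p <- responseLooStep4(Y[, perm], X)
  expect_equal(tab_p$F[order(tab_p$parcel)], tab$F[order(tab$parcel)],
               tolerance = 1e-10)
  top <- tab$parcel[order(-tab$F)][1:3]
  expect_setequal(top, sp$target_parcels)

  # a near-duplicate of a pure-noise parcel adds no informative signal
  set.seed(811)
  Y2 <- cbind(Y, dup = Y[, 5] + rnorm(nrow(Y), sd = 1e-3 * sd(Y[, 5])))
  colnames(Y2) <- c(colnames(Y), "lh.dup")
  tab2 <- responseLooStep4(Y2, X)
  expect_gt(tab2$p[tab2$parcel == "lh.dup"], 0.05)
  expect_false(tab2$reject[tab2$parcel == "lh.dup"])
})

test_that("BH step-up reproduces hand-applied decisions", {
  r <- bhFdr(c(0.001, 0.008, 0.039, 0.041), alpha = 0.05)
  expect_true(all(r$reject))          # largest p <= (4/4) * 0.05
  expect_equal(r$p_adj[4], 0.041)

  expect_false(any(bhFdr(rep(1, 6))$reject))

  one <- bhFdr(0.04)
  expect_true(one$reject)
  expect_equal(one$p_adj, 0.04)

  # adjusted p monotone in the raw-p ranking
  set.seed(90)
  p <- runif(25)
  adj <- bhFdr(p)$p_adj
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bhFdr(c(0.2, 1.2)), "\\[0, 1\\]")
})
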