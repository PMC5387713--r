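# Log-determinant of a symmetric positive-definite matrix via Cholesky;
# working in log space keeps determinant ratios finite at p = 165.
.logdetSPD <- function(M, what = "E") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch) ||
      any(diag(ch) <= sqrt(.Machine$double.eps) * max(diag(ch))))
    stop("matrix '", what, "' is singular or near-singular: the response ",
         "dimension p is too close to the error df; reduce the number of ",
         "parcels or increase the sample size")
  2 * sum(log(diag(ch)))
}

#' Build the hypothesis design matrix
#'
#' Fixed-effects 2x2 factorial design: intercept, sex (+1 male / -1
#' female), diagnosis (+1 case / -1 control) and their elementwise product,
#' the sex-by-diagnosis interaction. The number of hypothesis predictors is
#' `q = 3`. A cohort with equal numbers of males and females has a
#' sex-column mean of zero.
#'
#' @param cohort a validated cohort `data.frame`.
#' @return numeric matrix with columns `(Intercept)`, `sex`, `diagnosis`,
#'   `interaction`; warns when a sex-by-diagnosis cell is empty (such a
#'   design fails at fit time).
#' @examples
#' co <- generateCohort(syntheticSpec(), seed = 1)
#' colMeans(buildDesign(co))
#' @export
buildDesign <- function(cohort) {
  cohort <- validateCohort(cohort)
  X <- cbind(`(Intercept)` = 1, sex = cohort$sex, diagnosis = cohort$diagnosis,
             interaction = cohort$sex * cohort$diagnosis)
  cells <- table(factor(cohort$sex, c(-1, 1)),
                 factor(cohort$diagnosis, c(-1, 1)))
  if (any(cells == 0))
    warning("empty sex-by-diagnosis cell(s): the design is rank deficient ",
            "and downstream tests will fail")
  X
}

#' Fit a fixed-effects multivariate multiple regression
#'
#' Least-squares fit of a subjects-by-parcels response matrix on a design
#' matrix whose first column is the intercept. Returns the coefficient
#' matrix together with the hypothesis SSCP `H` (fitted values about the
#' response means, measuring the `q` non-intercept predictors jointly) and
#' the error SSCP `E` (residual cross-products), with `vH = q` and
#' `vE = N - q - 1`. With the intercept in the model, `H + E` equals the
#' total SSCP about the column means.
#'
#' @param X design matrix (intercept first column), e.g. [buildDesign()].
#' @param Y subjects-by-parcels numeric response matrix.
#' @param vE optional override of the error degrees of freedom (used for
#'   honest accounting after confound residualization); the SSCP matrices
#'   are unaffected.
#' @return an [MvFit-class] object.
#' @export
fitMvReg <- function(X, Y, vE = NULL) {
  Y <- as.matrix(Y)
  N <- nrow(Y)
  q <- ncol(X) - 1L
  if (N <= q + 1) stop("need N > q + 1 subjects")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank error: design matrix X'X is singular")
  fit <- lm.fit(X, Y)
  B <- as.matrix(fit$coefficients)
  R <- as.matrix(fit$residuals)
  Fhat <- Y - R
  Fc <- sweep(Fhat, 2, colMeans(Y))
  H <- crossprod(Fc)
  E <- crossprod(R)
  H <- (H + t(H)) / 2
  E <- (E + t(E)) / 2
  new("MvFit", B = B, H = H, E = E, vH = q,
      vE = if (is.null(vE)) N - q - 1 else vE,
      p = ncol(Y), N = N,
      predictors = colnames(X),
      responses = colnames(Y) %||% sprintf("y%d", seq_len(ncol(Y))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wilks' lambda of a multivariate fit
#'
#' `Lambda = det(E) / det(E + H)`, evaluated through Cholesky
#' log-determinants for numerical stability at large response dimension.
#' Values near 1 indicate no effect; small values indicate a strong joint
#' effect of the hypothesis predictors.
#'
#' @param x an [MvFit-class] object.
#' @param ... unused.
#' @return Wilks' lambda in (0, 1].
#' @export
setMethod("wilksLambda", "MvFit", function(x, ...) {
  ld_E <- .logdetSPD(x@E, "E")
  ld_T <- .logdetSPD(x@E + x@H, "E + H")
  min(exp(ld_E - ld_T), 1)
})

#' Rao's F approximation for Wilks' lambda
#'
#' Converts Wilks' lambda to an approximately F-distributed statistic.
#' With `t = sqrt((p^2 vH^2 - 4) / (p^2 + vH^2 - 5))` (set to 1 when the
#' expression degenerates, i.e. `p * vH <= 2`),
#' `w = vE + vH - (p + vH + 1)/2`, `d1 = p * vH` and
#' `d2 = w * t - (d1 - 2)/2`, the statistic is
#' `F = ((1 - Lambda^(1/t)) / Lambda^(1/t)) * d2 / d1` on `(d1, d2)`
#' degrees of freedom. The transform is exact when `p <= 2` or `vH <= 2`;
#' in particular `vH = 1` yields the exact F on `(p, vE - p + 1)` df and
#' `p = 1` the exact univariate F on `(vH, vE)` df.
#'
#' @param lambda Wilks' lambda in (0, 1].
#' @param p number of response variables.
#' @param vH,vE hypothesis and error degrees of freedom.
#' @return one-row `data.frame` with `lambda`, `F`, `d1`, `d2` (raw),
#'   `d2_rounded`, `p.value`, and the intermediates `w`, `t`.
#' @examples
#' raoF(0.5, p = 165, vH = 3, vE = 189)[, c("d1", "d2_rounded")]
#' @export
raoF <- function(lambda, p, vH, vE) {
  if (!is.finite(lambda) || lambda <= 0 || lambda > 1)
    stop("lambda must lie in (0, 1]")
  if (p < 1 || vH < 1 || vE < 1) stop("p, vH, vE must be >= 1")
  num <- p^2 * vH^2 - 4
  den <- p^2 + vH^2 - 5
  tt <- if (num <= 0 || den <= 0) 1 else sqrt(num / den)
  w <- vE + vH - (p + vH + 1) / 2
  d1 <- p * vH
  d2 <- w * tt - (d1 - 2) / 2
  if (d2 <= 0) stop("nonpositive denominator df (d2 = ", round(d2, 2),
                    "): p is too large for the available error df")
  lam_t <- lambda^(1 / tt)
  Fstat <- (1 - lam_t) / lam_t * d2 / d1
  data.frame(lambda = lambda, F = Fstat, d1 = d1, d2 = d2,
             d2_rounded = round(d2), p.value = pf(Fstat, d1, d2,
                                                  lower.tail = FALSE),
             w = w, t = tt)
}

.effectiveVE <- function(ce, N, q) {
  vE <- N - q - 1
  md <- S4Vectors::metadata(ce)
  if (isTRUE(md$residualized) && isTRUE(md$adjust_df))
    vE <- vE - (md$confound_rank - 1L)
  vE
}

#' Step 1: omnibus Wilks-lambda test per metric panel
#'
#' For every metric panel, tests the omnibus null hypothesis that neither
#' sex, diagnosis nor their interaction has any effect on the regional
#' values, via Wilks' lambda and Rao's F approximation, followed by
#' Benjamini-Hochberg FDR correction across the metric family. Metrics
#' whose null is rejected advance to the predictor and region leave-one-out
#' analyses.
#'
#' @param ce a (typically normalized and residualized)
#'   [ConnectomeExperiment].
#' @param alpha FDR level (default 0.05).
#' @return `data.frame` with one row per metric: `metric`, `lambda`, `F`,
#'   `d1`, `d2`, `d2_rounded`, `p`, `p_adj`, `reject`.
#' @export
omnibusStep1 <- function(ce, alpha = 0.05) {
  co <- cohortTable(ce)
  X <- buildDesign(co)
  q <- ncol(X) - 1L
  vE <- .effectiveVE(ce, nrow(co), q)
  rows <- lapply(metricNames(ce), function(m) {
    fit <- fitMvReg(X, metricPanel(ce, m), vE = vE)
    r <- raoF(wilksLambda(fit), p = fit@p, vH = fit@vH, vE = fit@vE)
    data.frame(metric = m, lambda = r$lambda, F = r$F, d1 = r$d1,
               d2 = r$d2, d2_rounded = r$d2_rounded, p = r$p.value)
  })
  out <- do.call(rbind, rows)
  fdr <- bhFdr(out$p, alpha)
  out$p_adj <- fdr$p_adj
  out$reject <- fdr$reject
  out
}

# Shared core of the Step 2/3 predictor leave-one-out tables. lambda_fun
# maps a design matrix (with intercept) to a full-vs-intercept Wilks
# lambda; the two steps differ only in how that lambda is computed.
.predictorLoo <- function(Y, X, alpha, vE, lambda_fun) {
  p <- ncol(Y)
  q <- ncol(X) - 1L
  if (vE - p + 1 < 1)
    stop("insufficient df: vE - p + 1 = ", vE - p + 1,
         "; reduce the number of parcels or increase the sample size")
  lambda_full <- lambda_fun(X)
  preds <- setdiff(colnames(X), "(Intercept)")
  rows <- lapply(preds, function(pj) {
    X_red <- X[, setdiff(colnames(X), pj), drop = FALSE]
    partial <- min(lambda_full / lambda_fun(X_red), 1)
    Fstat <- (1 - partial) / partial * (vE - p + 1) / p
    data.frame(predictor = pj, partial_lambda = partial, F = Fstat,
               df1 = p, df2 = vE - p + 1,
               df1_alt = q, df2_alt = vE - p,
               p = pf(Fstat, p, vE - p + 1, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  fdr <- bhFdr(out$p, alpha)
  out$p_adj <- fdr$p_adj
  out$reject <- fdr$reject
  out
}

#' Step 2: predictor leave-one-out partial-F tests
#'
#' Quantifies each predictor's contribution by a reduced-model analysis:
#' for each of sex, diagnosis and the interaction, the design is refit with
#' that column deleted and the partial Wilks lambda is
#' `Lambda(full) / Lambda(reduced)`. A single deleted predictor gives the
#' exact transform `F = ((1 - L)/L) * (vE - p + 1)/p` on
#' `(p, vE - p + 1)` degrees of freedom; the columns `df1_alt`/`df2_alt`
#' additionally report the `(q, vE - p)` convention for comparison with
#' analyses that used it. BH-FDR is applied across the three predictors.
#'
#' @param Y subjects-by-parcels response matrix (normalized/residualized).
#' @param X hypothesis design from [buildDesign()].
#' @param alpha FDR level.
#' @param vE error degrees of freedom (default `N - q - 1`).
#' @return `data.frame` with one row per predictor: `predictor`,
#'   `partial_lambda`, `F`, `df1`, `df2`, `df1_alt`, `df2_alt`, `p`,
#'   `p_adj`, `reject`.
#' @export
predictorLooStep2 <- function(Y, X, alpha = 0.05,
                              vE = nrow(Y) - ncol(X)) {
  Y <- as.matrix(Y)
  .predictorLoo(Y, X, alpha, vE,
                function(Xk) wilksLambda(fitMvReg(Xk, Y)))
}
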