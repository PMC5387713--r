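#' Partitioned sample covariance of a response and predictor block
#'
#' Computes the blocks of the joint sample covariance matrix of the
#' responses `Y` and the non-intercept predictor columns of `X`:
#' `S_yy` (p x p), `S_yx` (p x q) and `S_xx` (q x q), on centered columns
#' with denominator `N - 1`.
#'
#' @param Y subjects-by-parcels response matrix.
#' @param X design matrix; an `"(Intercept)"` column is dropped.
#' @return list with `S_yy`, `S_yx`, `S_xx`, `n`.
#' @export
partitionCovariance <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  keep <- setdiff(colnames(X) %||% sprintf("x%d", seq_len(ncol(X))),
                  "(Intercept)")
  colnames(X) <- colnames(X) %||% sprintf("x%d", seq_len(ncol(X)))
  X <- X[, keep, drop = FALSE]
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same number of rows")
  if (nrow(Y) < 3) stop("need at least 3 subjects")
  zero_y <- which(apply(Y, 2, var) == 0)
  zero_x <- which(apply(X, 2, var) == 0)
  if (length(zero_y) || length(zero_x))
    stop("degenerate covariance: zero-variance column(s): ",
         paste(c(colnames(Y)[zero_y], colnames(X)[zero_x]), collapse = ", "))
  list(S_yy = cov(Y), S_yx = cov(Y, X), S_xx = cov(X), n = nrow(Y))
}

#' Canonical correlation analysis
#'
#' Finds the canonical correlations `r_k` — the square roots of the
#' eigenvalues of `S_yy^-1 S_yx S_xx^-1 S_xy` — and the associated
#' coefficient vectors. Rather than forming that product, both blocks are
#' whitened through Cholesky factors of `S_yy` and `S_xx` and a singular
#' value decomposition of the whitened cross-covariance is taken, which is
#' symmetric in the two blocks and stable at large `p`. Singular values are
#' clamped to \[0, 1\] against roundoff; each response-side coefficient
#' vector is scaled so its largest-magnitude entry is positive.
#'
#' `canonicalCorrelations()` operates on covariance blocks; [ccaFit()]
#' computes the blocks from data and additionally returns subject-level
#' canonical variate scores.
#'
#' @param blocks covariance blocks from [partitionCovariance()].
#' @param Y,X optional centered-data matrices; when supplied, variate
#'   scores are computed.
#' @return a [CcaResult-class] object.
#' @export
canonicalCorrelations <- function(blocks, Y = NULL, X = NULL) {
  S_yy <- blocks$S_yy; S_yx <- blocks$S_yx; S_xx <- blocks$S_xx
  p <- nrow(S_yy); q <- nrow(S_xx)
  if (p >= blocks$n)
    stop("p >= N: the response covariance is singular; reduce the number ",
         "of parcels or increase the sample size")
  R_yy <- tryCatch(chol(S_yy), error = function(e)
    stop("rank error: S_yy is not positive definite"))
  R_xx <- tryCatch(chol(S_xx), error = function(e)
    stop("rank error: S_xx is singular"))
  # M = t(R_yy)^-1 S_yx R_xx^-1, the cross-covariance of the whitened blocks
  A <- backsolve(R_yy, S_yx, transpose = TRUE)
  M <- t(backsolve(R_xx, t(A), transpose = TRUE))
  sv <- svd(M)
  s <- min(p, q)
  r <- pmin(pmax(sv$d[seq_len(s)], 0), 1)
  ycoef <- backsolve(R_yy, sv$u[, seq_len(s), drop = FALSE])
  xcoef <- backsolve(R_xx, sv$v[, seq_len(s), drop = FALSE])
  for (k in seq_len(s)) {
    sgn <- sign(ycoef[which.max(abs(ycoef[, k])), k])
    if (sgn < 0) { ycoef[, k] <- -ycoef[, k]; xcoef[, k] <- -xcoef[, k] }
  }
  yscores <- xscores <- matrix(numeric(0), nrow = 0, ncol = s)
  if (!is.null(Y) && !is.null(X)) {
    Yc <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
    Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
    yscores <- Yc %*% ycoef
    xscores <- Xc %*% xcoef
  }
  new("CcaResult", cor = r, ycoef = ycoef, xcoef = xcoef,
      yscores = yscores, xscores = xscores, n = blocks$n)
}

#' @rdname canonicalCorrelations
#' @export
ccaFit <- function(Y, X) {
  blocks <- partitionCovariance(Y, X)
  keep <- setdiff(colnames(as.matrix(X)) %||%
                    sprintf("x%d", seq_len(ncol(as.matrix(X)))),
                  "(Intercept)")
  Xd <- as.matrix(X)
  colnames(Xd) <- colnames(Xd) %||% sprintf("x%d", seq_len(ncol(Xd)))
  canonicalCorrelations(blocks, Y = Y, X = Xd[, keep, drop = FALSE])
}

#' Wilks' lambda from canonical correlations
#'
#' The CCA form of Wilks' statistic, `Lambda = prod(1 - r_k^2)`. On the
#' same response/design pair this equals the determinant-ratio lambda of
#' the multivariate regression, which is why the predictor leave-one-out
#' inferences of the regression and CCA routes coincide.
#'
#' @param result a [CcaResult-class].
#' @return Wilks' lambda in \[0, 1\].
#' @export
ccaWilks <- function(result) {
  prod(1 - canonicalCors(result)^2)
}

#' Step 3: predictor leave-one-out in the CCA frame
#'
#' Recomputes the canonical correlation analysis with each predictor
#' removed in turn; the partial Wilks lambda
#' `prod(1 - r_k^2, full) / prod(1 - r_k^2, reduced)` is transformed to a
#' partial F exactly as in Step 2, giving decisions identical to the
#' regression route on the same inputs.
#'
#' @inheritParams predictorLooStep2
#' @return `data.frame` as in [predictorLooStep2()].
#' @export
predictorLooStep3 <- function(Y, X, alpha = 0.05,
                              vE = nrow(Y) - ncol(X)) {
  Y <- as.matrix(Y)
  if (ncol(X) - 1L < 2) stop("predictor LOO needs q >= 2")
  .predictorLoo(Y, X, alpha, vE,
                function(Xk) ccaWilks(ccaFit(Y, Xk)))
}

#' Step 4: per-region response leave-one-out partial-F tests
#'
#' Quantifies each parcel's contribution to the joint effect by removing
#' that response variable: partial
#' `Lambda_j = Lambda(all p responses) / Lambda(p - 1 responses)`, with the
#' reduced model using `p' = p - 1` responses. The deletion of a single
#' response admits the exact transform
#' `F = ((1 - L)/L) * (vE - p + 1)/vH` on `(vH, vE - p + 1)` degrees of
#' freedom. Both lambdas are determinant ratios, so the per-parcel partials
#' reduce to diagonal elements of `E^-1` and `(E + H)^-1`; the identity
#' `partial_j = ((E+H)^-1)_jj / (E^-1)_jj` evaluates all parcels from two
#' matrix inversions. BH-FDR is applied across parcels and the critical
#' partial-F at the FDR level (the smallest F among rejected parcels) is
#' attached as an attribute.
#'
#' @param Y subjects-by-parcels response matrix (normalized/residualized).
#' @param X hypothesis design from [buildDesign()].
#' @param alpha FDR level.
#' @param vE error degrees of freedom (default `N - q - 1`).
#' @param atlas optional [ParcelAtlas] supplying hemisphere tags.
#' @return `data.frame` in atlas/column order, one row per parcel:
#'   `parcel`, `hemisphere`, `partial_lambda`, `F`, `df1`, `df2`, `p`,
#'   `p_adj`, `reject`; attributes `"critical_F"` and `"alpha"`.
#' @export
responseLooStep4 <- function(Y, X, alpha = 0.05,
                             vE = nrow(Y) - ncol(X), atlas = NULL) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  vH <- ncol(X) - 1L
  if (vE - p + 1 < 1)
    stop("insufficient df: vE - p + 1 = ", vE - p + 1,
         "; reduce the number of parcels or increase the sample size")
  fit <- fitMvReg(X, Y)
  Einv <- chol2inv(chol(fit@E))
  Tinv <- chol2inv(chol(fit@E + fit@H))
  partial <- pmin(diag(Tinv) / diag(Einv), 1)
  Fstat <- (1 - partial) / partial * (vE - p + 1) / vH
  pval <- pf(Fstat, vH, vE - p + 1, lower.tail = FALSE)
  labels <- colnames(Y) %||% sprintf("parcel%d", seq_len(p))
  hemi <- if (!is.null(atlas)) {
    hemisphere(atlas)[match(labels, parcelLabels(atlas))]
  } else sub("\\..*$", "", labels)
  fdr <- bhFdr(pval, alpha)
  out <- data.frame(parcel = labels, hemisphere = hemi,
                    partial_lambda = partial, F = Fstat,
                    df1 = vH, df2 = vE - p + 1,
                    p = pval, p_adj = fdr$p_adj, reject = fdr$reject)
  attr(out, "critical_F") <- if (any(out$reject)) min(out$F[out$reject]) else Inf
  attr(out, "alpha") <- alpha
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment (via [stats::p.adjust()] with `method = "BH"`):
#' adjusted p-values are monotone in the raw-p ranking and a hypothesis is
#' rejected iff its adjusted p-value is at most `alpha`.
#'
#' @param pvalues raw p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return list with `p_adj` and logical `reject`.
#' @examples
#' bhFdr(c(0.001, 0.008, 0.039, 0.041), alpha = 0.05)
#' @export
bhFdr <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  p_adj <- p.adjust(pvalues, method = "BH")
  list(p_adj = p_adj, reject = p_adj <= alpha)
}
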