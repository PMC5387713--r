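#' Confound model specification
#'
#' Describes the nuisance design used for residualization: age, acquisition
#' site (dummy-coded), a selection of DAS intelligence scales, and their
#' interactions. The default interaction structure is all pairwise products
#' plus the age x site x DAS three-way product; `"threeway"` restricts to
#' the three-way product only, `"pairwise"` to pairwise only, `"none"` to
#' main effects.
#'
#' `adjust_df` controls whether downstream multivariate tests subtract the
#' rank of the confound projection from the error degrees of freedom.
#' The default (`FALSE`) keeps `vE = N - q - 1` computed from the
#' hypothesis design alone, matching the convention of the analysis this
#' package reproduces; `TRUE` enables honest degrees-of-freedom accounting
#' and is what the package's own calibration checks use.
#'
#' @param das_scales DAS scales entering the model; subset of
#'   `c("gca", "v", "nv", "s", "snc")`. Default `"gca"` (general conceptual
#'   ability).
#' @param interactions one of `"full"` (pairwise + three-way, default),
#'   `"pairwise"`, `"threeway"`, `"none"`.
#' @param adjust_df subtract confound rank from error df downstream
#'   (default `FALSE`).
#' @return a list of class `"ConfoundSpec"`.
#' @export
confoundSpec <- function(das_scales = "gca",
                         interactions = c("full", "pairwise", "threeway",
                                          "none"),
                         adjust_df = FALSE) {
  das_scales <- match.arg(tolower(das_scales),
                          c("gca", "v", "nv", "s", "snc"), several.ok = TRUE)
  structure(list(das_scales = das_scales,
                 interactions = match.arg(interactions),
                 adjust_df = isTRUE(adjust_df)),
            class = "ConfoundSpec")
}

#' Build the confound design matrix
#'
#' Constructs the intercept + confound design: age (optionally also age
#' squared), site dummies, the selected DAS scales, and the interaction
#' terms requested in the [confoundSpec()]. Site enters through treatment
#' dummies via [stats::model.matrix()].
#'
#' @param cohort a validated cohort `data.frame`.
#' @param spec a `ConfoundSpec`.
#' @param include_age2 add the square of age as a main-effect column
#'   (used by [quadraticAgeTest()]).
#' @return numeric design matrix with an `"(Intercept)"` column; errors on
#'   rank deficiency naming the dependent columns.
#' @export
confoundDesign <- function(cohort, spec = confoundSpec(),
                           include_age2 = FALSE) {
  cohort <- validateCohort(cohort)
  dat <- data.frame(age = cohort$age, site = factor(cohort$site))
  das_cols <- paste0("das_", spec$das_scales)
  for (dc in das_cols) dat[[dc]] <- cohort[[dc]]
  main <- c("age", if (nlevels(dat$site) > 1) "site", das_cols)
  terms <- main
  if (spec$interactions %in% c("full", "pairwise")) {
    pairs <- utils::combn(main, 2, paste, collapse = ":")
    terms <- c(terms, pairs)
  }
  if (spec$interactions %in% c("full", "threeway") && "site" %in% main) {
    terms <- c(terms, paste("age", "site", das_cols, sep = ":"))
  }
  if (include_age2) {
    dat$age2 <- cohort$age^2
    terms <- c(terms, "age2")
  }
  X <- model.matrix(stats::reformulate(terms), dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinearity error: confound design is rank deficient; ",
         "dependent column(s): ", paste(dep, collapse = ", "))
  }
  X
}

#' Normalize metric values by total intracranial volume
#'
#' Divides every subject's regional values by that subject's TICV to remove
#' head-size effects, the first preprocessing stage of the pipeline. On a
#' `ConnectomeExperiment` the normalized metrics are recorded in the object
#' metadata; individual metrics can be exempted through `metrics`.
#'
#' @param x a subjects-by-parcels matrix or a [ConnectomeExperiment].
#' @param cohort cohort `data.frame` (matrix method only).
#' @param metrics metrics to normalize (`ConnectomeExperiment` method;
#'   default all).
#' @return object of the same class with normalized values.
#' @export
setGeneric("ticvNormalize",
           function(x, cohort, metrics) standardGeneric("ticvNormalize"))

#' @rdname ticvNormalize
#' @export
setMethod("ticvNormalize", "matrix", function(x, cohort, metrics) {
  cohort <- validateCohort(cohort)
  if (any(cohort$ticv <= 0)) stop("ticv must be positive")
  stopifnot(nrow(x) == nrow(cohort))
  x / cohort$ticv
})

#' @rdname ticvNormalize
#' @export
setMethod("ticvNormalize", "ConnectomeExperiment",
          function(x, cohort, metrics) {
  if (missing(metrics)) metrics <- metricNames(x)
  co <- cohortTable(x)
  for (m in metrics)
    SummarizedExperiment::assay(x, m) <-
      sweep(SummarizedExperiment::assay(x, m), 2, co$ticv, "/")
  S4Vectors::metadata(x)$ticv_normalized <-
    union(S4Vectors::metadata(x)$ticv_normalized, metrics)
  validObject(x)
  x
})

.residualize <- function(Y, design) {
  fit <- lm.fit(design, Y)
  R <- as.matrix(fit$residuals)
  dimnames(R) <- dimnames(Y)
  R
}

#' Residualize metric panels against the confound design
#'
#' Replaces each parcel column by its least-squares residual against the
#' confound design (intercept, age, site, DAS and their interactions per
#' the [confoundSpec()]). Residuals are exactly orthogonal to every
#' confound column and the operation is idempotent. The rank of the
#' projected-out design is stored in the object metadata so downstream
#' tests can optionally adjust their error degrees of freedom.
#'
#' @param x a subjects-by-parcels matrix or [ConnectomeExperiment].
#' @param cohort cohort `data.frame` (matrix method only).
#' @param spec a [confoundSpec()].
#' @param include_age2 also project out the square of age (used when the
#'   [quadraticAgeTest()] rejects).
#' @return object of the same class holding residuals.
#' @export
setGeneric("residualizeConfounds",
           function(x, cohort, spec = confoundSpec(), include_age2 = FALSE)
             standardGeneric("residualizeConfounds"))

#' @rdname residualizeConfounds
#' @export
setMethod("residualizeConfounds", "matrix",
          function(x, cohort, spec, include_age2) {
  design <- confoundDesign(cohort, spec, include_age2 = include_age2)
  .residualize(x, design)
})

#' @rdname residualizeConfounds
#' @export
setMethod("residualizeConfounds", "ConnectomeExperiment",
          function(x, cohort, spec, include_age2) {
  co <- cohortTable(x)
  design <- confoundDesign(co, spec, include_age2 = include_age2)
  for (m in metricNames(x)) {
    Y <- metricPanel(x, m)
    SummarizedExperiment::assay(x, m) <- t(.residualize(Y, design))
  }
  S4Vectors::metadata(x)$residualized <- TRUE
  S4Vectors::metadata(x)$confound_rank <- qr(design)$rank
  S4Vectors::metadata(x)$adjust_df <- spec$adjust_df
  validObject(x)
  x
})

#' Reduced-model test for a quadratic age effect
#'
#' Tests, per metric panel, the null hypothesis that the regression
#' coefficient of age squared is zero in the confound model: the confound
#' design is fit with and without the `age^2` column, the partial Wilks
#' lambda is the ratio of the two error-SSCP determinants, and — the
#' deleted hypothesis having a single degree of freedom — the exact
#' transform `F = ((1 - L)/L) * (vE - p + 1)/p` with `(p, vE - p + 1)`
#' degrees of freedom applies. When run on a `ConnectomeExperiment` the
#' test is applied to every metric with Benjamini-Hochberg correction
#' across the metric family.
#'
#' @param x a subjects-by-parcels matrix or [ConnectomeExperiment]
#'   (values normalized but not yet residualized).
#' @param cohort cohort `data.frame` (matrix method only).
#' @param spec a [confoundSpec()].
#' @param alpha rejection level (default 0.05).
#' @return matrix method: one-row `data.frame` with `lambda`, `F`, `df1`,
#'   `df2`, `p`, `reject`; experiment method: one row per metric plus
#'   `p_adj` from the 5-metric BH family.
#' @export
setGeneric("quadraticAgeTest",
           function(x, cohort, spec = confoundSpec(), alpha = 0.05)
             standardGeneric("quadraticAgeTest"))

#' @rdname quadraticAgeTest
#' @export
setMethod("quadraticAgeTest", "matrix", function(x, cohort, spec, alpha) {
  cohort <- validateCohort(cohort)
  X_full <- confoundDesign(cohort, spec, include_age2 = TRUE)
  X_red <- confoundDesign(cohort, spec, include_age2 = FALSE)
  N <- nrow(x); p <- ncol(x)
  q_full <- ncol(X_full) - 1L
  vE <- N - q_full - 1
  if (vE - p + 1 < 1)
    stop("insufficient error df: need N - q - 1 - p + 1 >= 1 (have ",
         vE - p + 1, ")")
  E_full <- crossprod(.residualize(x, X_full))
  E_red <- crossprod(.residualize(x, X_red))
  lambda <- exp(.logdetSPD(E_full) - .logdetSPD(E_red))
  lambda <- min(lambda, 1)
  Fstat <- (1 - lambda) / lambda * (vE - p + 1) / p
  pval <- pf(Fstat, p, vE - p + 1, lower.tail = FALSE)
  data.frame(lambda = lambda, F = Fstat, df1 = p, df2 = vE - p + 1,
             p = pval, reject = pval <= alpha)
})

#' @rdname quadraticAgeTest
#' @export
setMethod("quadraticAgeTest", "ConnectomeExperiment",
          function(x, cohort, spec, alpha) {
  co <- cohortTable(x)
  rows <- lapply(metricNames(x), function(m)
    cbind(metric = m, quadraticAgeTest(metricPanel(x, m), co, spec, alpha)))
  out <- do.call(rbind, rows)
  fdr <- bhFdr(out$p, alpha)
  out$p_adj <- fdr$p_adj
  out$reject <- fdr$reject
  rownames(out) <- NULL
  out
})
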