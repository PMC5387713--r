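#' Welch's unequal-variance t test from summary statistics
#'
#' Computes Welch's two-sample t statistic
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' fractional degrees of freedom and a two-sided p-value. Useful when only
#' published group means and standard deviations are available; on raw data
#' [welchFromVectors()] gives the identical result.
#'
#' @param m1,s1,n1 mean, standard deviation and size of group 1.
#' @param m2,s2,n2 mean, standard deviation and size of group 2.
#' @return an object of class `"htest"` with the `t` statistic (sign follows
#'   group1 minus group2), fractional `df` and two-sided `p.value`.
#' @examples
#' welchFromSummary(12.32, 3.46, 110, 12.76, 3.57, 83)
#' @export
welchFromSummary <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  tstat <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  structure(list(statistic = c(t = tstat), parameter = c(df = df),
                 p.value = p, method = "Welch two sample t-test (from summaries)",
                 alternative = "two.sided",
                 data.name = sprintf("group1 (n=%d) vs group2 (n=%d)", n1, n2),
                 estimate = c(`mean of group1` = m1, `mean of group2` = m2)),
            class = "htest")
}

#' Welch's t test from raw vectors
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE` (Welch's
#' test); numerically identical to [welchFromSummary()] applied to the
#' vectors' sample means, standard deviations and lengths.
#'
#' @param x1,x2 numeric vectors (length >= 2, finite).
#' @return an object of class `"htest"`.
#' @export
welchFromVectors <- function(x1, x2) {
  if (length(x1) < 2 || length(x2) < 2)
    stop("each group needs at least 2 observations")
  if (!all(is.finite(x1)) || !all(is.finite(x2)))
    stop("inputs must be finite")
  stats::t.test(x1, x2, var.equal = FALSE)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Pearson's chi-squared statistic without continuity correction by default
#' (a flag enables the Yates correction), on the 2x2 table
#' `rbind(c(a, b), c(c, d))` — typically group by sex counts.
#'
#' @param a,b,c,d cell counts (row 1: a, b; row 2: c, d).
#' @param correct apply Yates' continuity correction (default `FALSE`).
#' @return an object of class `"htest"` with `chi2` statistic, `df = 1` and
#'   p-value.
#' @examples
#' chisq2x2(55, 55, 43, 40)   # case M/F vs control M/F
#' @export
chisq2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a row or column margin is zero")
  suppressWarnings(stats::chisq.test(tab, correct = correct))
}

#' Cohort demographic summary table
#'
#' Per-group means, standard deviations and observed ranges of age, TICV and
#' the five DAS scores, with a Welch t test per row comparing case (+1) and
#' control (-1) diagnosis groups, in the style of a study demographics
#' table. Rows whose within-group standard deviation is zero are flagged and
#' their Welch test skipped. Sex ratios (males:females) per group are
#' attached as an attribute.
#'
#' @param cohort a validated cohort `data.frame`.
#' @return a `data.frame` with one row per descriptor (`age`, `ticv`,
#'   `das_v`, `das_nv`, `das_s`, `das_gca`, `das_snc`) and columns
#'   `mean_case`, `sd_case`, `min_case`, `max_case`, `mean_control`,
#'   `sd_control`, `min_control`, `max_control`, `t`, `df`, `p`,
#'   `degenerate`; attribute `"sex_ratio"` holds the per-group male:female
#'   ratios.
#' @export
summarizeCohort <- function(cohort) {
  cohort <- validateCohort(cohort)
  if (length(unique(cohort$diagnosis)) < 2)
    stop("cohort must contain both diagnosis groups")
  case <- cohort[cohort$diagnosis == 1, ]
  ctrl <- cohort[cohort$diagnosis == -1, ]
  vars <- c("age", "ticv", "das_v", "das_nv", "das_s", "das_gca", "das_snc")
  rows <- lapply(vars, function(v) {
    x1 <- case[[v]]; x2 <- ctrl[[v]]
    degenerate <- sd(x1) == 0 || sd(x2) == 0
    if (degenerate) {
      tt <- list(statistic = NA_real_, parameter = NA_real_,
                 p.value = NA_real_)
    } else tt <- welchFromVectors(x1, x2)
    data.frame(descriptor = v,
               mean_case = mean(x1), sd_case = sd(x1),
               min_case = min(x1), max_case = max(x1),
               mean_control = mean(x2), sd_control = sd(x2),
               min_control = min(x2), max_control = max(x2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = unname(tt$p.value), degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  attr(out, "sex_ratio") <- c(
    case = sum(case$sex == 1) / sum(case$sex == -1),
    control = sum(ctrl$sex == 1) / sum(ctrl$sex == -1))
  attr(out, "n") <- c(case = nrow(case), control = nrow(ctrl))
  out
}
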