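#' Parcel atlas
#'
#' An ordered set of named brain parcels with a hemisphere tag. The parcel
#' order is fixed and shared by every metric panel keyed to the atlas: all
#' multivariate response matrices use this column order, and region-wise
#' result tables are reported in it.
#'
#' Labels follow the `lh.`/`rh.`/`mid.` prefix convention of surface
#' parcellation exports; [defaultAtlas()] ships a 165-parcel
#' Destrieux-style atlas (74 cortical labels per hemisphere, the brain stem,
#' and unassigned midline fillers).
#'
#' @param labels character vector of unique parcel labels, each prefixed
#'   `lh.`, `rh.` or `mid.`.
#' @param x a `ParcelAtlas`.
#'
#' @return `ParcelAtlas()` returns a validated atlas object;
#'   `parcelLabels()` the label vector; `hemisphere()` the per-parcel
#'   hemisphere tag (`"lh"`, `"rh"` or `"mid"`).
#'
#' @examples
#' atl <- defaultAtlas()
#' length(atl)
#' table(hemisphere(atl))
#' @aliases ParcelAtlas parcelLabels hemisphere
#' @export ParcelAtlas
#' @exportClass ParcelAtlas
ParcelAtlas <- setClass("ParcelAtlas",
  slots = c(labels = "character", hemisphere = "character"))

setValidity("ParcelAtlas", function(object) {
  msg <- character()
  if (length(object@labels) == 0L)
    msg <- c(msg, "atlas must contain at least one parcel")
  if (anyDuplicated(object@labels))
    msg <- c(msg, sprintf("duplicated parcel labels: %s",
      paste(unique(object@labels[duplicated(object@labels)]), collapse = ", ")))
  if (length(object@hemisphere) != length(object@labels))
    msg <- c(msg, "hemisphere tag must match label length")
  if (!all(object@hemisphere %in% c("lh", "rh", "mid")))
    msg <- c(msg, "hemisphere tags must be 'lh', 'rh' or 'mid'")
  if (length(msg)) msg else TRUE
})

.hemiFromLabel <- function(labels) {
  hemi <- sub("\\..*$", "", labels)
  if (!all(hemi %in% c("lh", "rh", "mid")))
    stop("parcel labels must carry an 'lh.', 'rh.' or 'mid.' prefix; ",
         "offending: ", paste(utils::head(labels[!hemi %in% c("lh", "rh", "mid")], 3),
                              collapse = ", "))
  hemi
}

#' @rdname ParcelAtlas-class
#' @export
setMethod("parcelLabels", "ParcelAtlas", function(x) x@labels)

#' @rdname ParcelAtlas-class
#' @export
setMethod("hemisphere", "ParcelAtlas", function(x) x@hemisphere)

#' @rdname ParcelAtlas-class
#' @export
setMethod("length", "ParcelAtlas", function(x) length(x@labels))

setMethod("show", "ParcelAtlas", function(object) {
  cat("ParcelAtlas with", length(object@labels), "parcels (",
      sum(object@hemisphere == "lh"), "lh /",
      sum(object@hemisphere == "rh"), "rh /",
      sum(object@hemisphere == "mid"), "midline )\n")
})

#' Container for a cohort and its regional metric panels
#'
#' `ConnectomeExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]:
#' each assay is one metric panel (parcels in rows, subjects in columns),
#' `colData` holds the per-subject demographics (site, sex and diagnosis
#' codes, age, DAS scores, TICV) and `rowData` carries the parcel atlas.
#' Subjects are columns so that the usual Bioconductor sample-wise
#' conventions apply; [metricPanel()] returns the transposed
#' subjects-by-parcels response matrix used by the statistical layer.
#'
#' Sex is coded +1 for males and -1 for females; diagnosis +1 for the case
#' (ASD) group and -1 for controls (TD), so the sex-by-diagnosis interaction
#' column is the elementwise product of the two codes.
#'
#' @param panels named list of subjects-by-parcels numeric matrices, one per
#'   metric (canonical metric names: `area`, `thickness`, `curvature`,
#'   `volume`, `CD`). Rows must follow `cohort` order; columns the atlas
#'   order.
#' @param cohort a validated cohort `data.frame` as returned by
#'   [readCohort()] or [generateCohort()].
#' @param atlas a [ParcelAtlas].
#' @param x a `ConnectomeExperiment`.
#' @param metric metric (assay) name.
#'
#' @return `ConnectomeExperiment()` returns the assembled object.
#'   `cohortTable()` the cohort as a `data.frame`; `metricPanel()` a
#'   subjects-by-parcels matrix; `parcelAtlas()` the atlas; `metricNames()`
#'   the assay names.
#'
#' @examples
#' ce <- simulateExperiment(syntheticSpec(), seed = 1)
#' ce
#' dim(metricPanel(ce, "CD"))
#' @aliases ConnectomeExperiment cohortTable metricPanel parcelAtlas
#'   metricNames
#' @export ConnectomeExperiment
#' @exportClass ConnectomeExperiment
setClass("ConnectomeExperiment", contains = "SummarizedExperiment")

.cohortCols <- c("subject_id", "site", "sex", "diagnosis", "age",
                 "das_v", "das_nv", "das_s", "das_gca", "das_snc", "ticv")

#' Validate a cohort data frame
#'
#' Checks the invariants of the cohort data model: the full column set,
#' no missing values, sex and diagnosis codes in \{-1, +1\}, positive age
#' and TICV, and unique subject identifiers.
#'
#' @param cohort a `data.frame` with columns `subject_id`, `site`, `sex`,
#'   `diagnosis`, `age`, `das_v`, `das_nv`, `das_s`, `das_gca`, `das_snc`,
#'   `ticv`.
#' @return `cohort`, invisibly, with `site` as factor; errors describe every
#'   violated invariant.
#' @export
validateCohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("cohort must be a non-empty data.frame")
  missing_cols <- setdiff(.cohortCols, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(.cohortCols, c("subject_id", "site"))
  for (cn in num_cols) {
    if (!is.numeric(cohort[[cn]]))
      stop("cohort column '", cn, "' must be numeric")
  }
  if (!all(complete.cases(cohort[, .cohortCols])))
    stop("cohort contains missing values in row(s): ",
         paste(which(!complete.cases(cohort[, .cohortCols])), collapse = ", "))
  if (anyDuplicated(cohort$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(cohort$subject_id[duplicated(cohort$subject_id)]),
               collapse = ", "))
  if (!all(cohort$sex %in% c(-1, 1)))
    stop("sex codes must be +1 (male) or -1 (female)")
  if (!all(cohort$diagnosis %in% c(-1, 1)))
    stop("diagnosis codes must be +1 (case) or -1 (control)")
  if (any(cohort$age <= 0)) stop("age must be positive")
  if (any(cohort$ticv <= 0)) stop("ticv must be positive")
  cohort$site <- factor(cohort$site)
  invisible(cohort)
}

#' @rdname ConnectomeExperiment-class
#' @export
ConnectomeExperiment <- function(panels, cohort, atlas) {
  cohort <- validateCohort(cohort)
  stopifnot(is(atlas, "ParcelAtlas"))
  if (is.null(names(panels)) || any(names(panels) == ""))
    stop("panels must be a named list of matrices")
  assays <- lapply(names(panels), function(nm) {
    m <- panels[[nm]]
    if (!is.matrix(m) || !is.numeric(m))
      stop("panel '", nm, "' must be a numeric matrix")
    if (nrow(m) != nrow(cohort))
      stop("panel '", nm, "' has ", nrow(m), " rows but the cohort has ",
           nrow(cohort), " subjects")
    if (ncol(m) != length(atlas))
      stop("panel '", nm, "' has ", ncol(m), " columns but the atlas has ",
           length(atlas), " parcels")
    if (!all(is.finite(m))) {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
      stop("panel '", nm, "' has a non-finite value at subject ", bad[1],
           ", parcel ", bad[2])
    }
    t(unname(m))
  })
  names(assays) <- names(panels)
  cd <- S4Vectors::DataFrame(cohort, row.names = cohort$subject_id)
  rd <- S4Vectors::DataFrame(label = parcelLabels(atlas),
                             hemisphere = hemisphere(atlas),
                             row.names = parcelLabels(atlas))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = cd, rowData = rd)
  new("ConnectomeExperiment", se)
}

setValidity("ConnectomeExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  missing_cols <- setdiff(.cohortCols, colnames(cd))
  if (length(missing_cols))
    msg <- c(msg, paste("colData missing:", paste(missing_cols, collapse = ", ")))
  else {
    if (!all(cd$sex %in% c(-1, 1)) || !all(cd$diagnosis %in% c(-1, 1)))
      msg <- c(msg, "sex and diagnosis must be coded -1/+1")
    if (any(cd$ticv <= 0)) msg <- c(msg, "ticv must be positive")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("label", "hemisphere") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry parcel 'label' and 'hemisphere'")
  for (nm in SummarizedExperiment::assayNames(object))
    if (!all(is.finite(SummarizedExperiment::assay(object, nm))))
      msg <- c(msg, paste0("assay '", nm, "' contains non-finite values"))
  if (length(msg)) msg else TRUE
})

#' @rdname ConnectomeExperiment-class
#' @export
setMethod("cohortTable", "ConnectomeExperiment", function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  rownames(df) <- NULL
  df[, .cohortCols]
})

#' @rdname ConnectomeExperiment-class
#' @export
setMethod("metricPanel", "ConnectomeExperiment", function(x, metric) {
  if (!metric %in% SummarizedExperiment::assayNames(x))
    stop("no metric panel '", metric, "'; available: ",
         paste(SummarizedExperiment::assayNames(x), collapse = ", "))
  m <- t(SummarizedExperiment::assay(x, metric))
  dimnames(m) <- list(colnames(x), rownames(x))
  m
})

#' @rdname ConnectomeExperiment-class
#' @export
setMethod("parcelAtlas", "ConnectomeExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  ParcelAtlas(labels = rd$label, hemisphere = rd$hemisphere)
})

#' @rdname ConnectomeExperiment-class
#' @export
setMethod("metricNames", "ConnectomeExperiment",
          function(x) SummarizedExperiment::assayNames(x))

setMethod("show", "ConnectomeExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  n_case <- sum(cd$diagnosis == 1); n_ctrl <- sum(cd$diagnosis == -1)
  cat("ConnectomeExperiment:", ncol(object), "subjects (",
      n_case, "case /", n_ctrl, "control ) x", nrow(object), "parcels\n")
  cat("metrics:", paste(SummarizedExperiment::assayNames(object),
                        collapse = ", "), "\n")
  norm <- S4Vectors::metadata(object)$ticv_normalized
  if (!is.null(norm)) cat("TICV-normalized:", paste(norm, collapse = ", "), "\n")
  if (isTRUE(S4Vectors::metadata(object)$residualized))
    cat("confound-residualized (design rank ",
        S4Vectors::metadata(object)$confound_rank, ")\n", sep = "")
})

#' Multivariate regression fit
#'
#' Holds the least-squares coefficients and the hypothesis/error
#' sums-of-squares-and-cross-products (SSCP) matrices of a fixed-effects
#' multivariate multiple regression of a metric panel on a design matrix.
#' `H` measures the joint effect of the `vH = q` non-intercept predictors
#' (corrected for the intercept) and `E` the residual; with an intercept in
#' the model, `H + E` equals the total SSCP about the column means.
#'
#' @slot B coefficient matrix, one row per design column.
#' @slot H,E hypothesis and error SSCP matrices (p x p).
#' @slot vH,vE hypothesis and error degrees of freedom (`q` and `N - q - 1`).
#' @slot p number of response variables; `N` number of subjects.
#' @slot predictors,responses column names of design and panel.
#'
#' @aliases MvFit
#' @exportClass MvFit
setClass("MvFit",
  slots = c(B = "matrix", H = "matrix", E = "matrix",
            vH = "numeric", vE = "numeric", p = "numeric", N = "numeric",
            predictors = "character", responses = "character"))

setValidity("MvFit", function(object) {
  msg <- character()
  if (!isSymmetric(unname(object@H), tol = 1e-8) ||
      !isSymmetric(unname(object@E), tol = 1e-8))
    msg <- c(msg, "H and E must be symmetric")
  if (object@vH < 1 || object@vE < 1)
    msg <- c(msg, "degrees of freedom must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MvFit", function(object) {
  cat("MvFit:", object@p, "responses,", object@N, "subjects; vH =",
      object@vH, ", vE =", object@vE, "\n")
  cat("predictors:", paste(object@predictors, collapse = ", "), "\n")
})

#' Canonical correlation analysis result
#'
#' Canonical correlations and variates linking a response block (metric
#' panel) to a predictor block (design columns). Correlations are the
#' singular values of the whitened cross-covariance, clamped to \[0, 1\] and
#' in nonincreasing order; each response-side coefficient vector is scaled
#' so its largest-magnitude entry is positive, fixing the sign convention.
#'
#' @slot cor canonical correlations `r_k`, `k = 1..s`, `s = min(p, q)`.
#' @slot ycoef,xcoef canonical coefficient matrices (columns are `a_k`,
#'   `b_k`).
#' @slot yscores,xscores subject-level canonical variates `u_k = a_k' y`,
#'   `v_k = b_k' x` (zero-row matrices when the result was built from
#'   covariances alone).
#' @slot n sample size behind the covariances.
#'
#' @param x a `CcaResult`.
#' @return `canonicalCors()` returns the vector of canonical correlations.
#' @aliases CcaResult canonicalCors
#' @exportClass CcaResult
setClass("CcaResult",
  slots = c(cor = "numeric", ycoef = "matrix", xcoef = "matrix",
            yscores = "matrix", xscores = "matrix", n = "numeric"))

setValidity("CcaResult", function(object) {
  msg <- character()
  if (any(object@cor < -1e-8) || any(object@cor > 1 + 1e-8))
    msg <- c(msg, "canonical correlations must lie in [0, 1]")
  if (is.unsorted(rev(object@cor), strictly = FALSE))
    msg <- c(msg, "canonical correlations must be nonincreasing")
  if (length(msg)) msg else TRUE
})

#' @rdname CcaResult-class
#' @export
setMethod("canonicalCors", "CcaResult", function(x) x@cor)

setMethod("show", "CcaResult", function(object) {
  cat("CcaResult:", length(object@cor), "canonical correlation(s)\n")
  print(round(object@cor, 4))
})
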