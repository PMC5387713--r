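#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats pf pt pchisq cov lm.fit model.matrix qf qnorm rnorm runif
#'   sd setNames var p.adjust complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

#' @rdname ParcelAtlas-class
#' @export
setGeneric("parcelLabels", function(x) standardGeneric("parcelLabels"))

#' @rdname ParcelAtlas-class
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))

#' @rdname ConnectomeExperiment-class
#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))

#' @rdname ConnectomeExperiment-class
#' @export
setGeneric("metricPanel", function(x, metric) standardGeneric("metricPanel"))

#' @rdname ConnectomeExperiment-class
#' @export
setGeneric("parcelAtlas", function(x) standardGeneric("parcelAtlas"))

#' @rdname ConnectomeExperiment-class
#' @export
setGeneric("metricNames", function(x) standardGeneric("metricNames"))

#' @rdname wilksLambda
#' @export
setGeneric("wilksLambda", function(x, ...) standardGeneric("wilksLambda"))

#' @rdname CcaResult-class
#' @export
setGeneric("canonicalCors", function(x) standardGeneric("canonicalCors"))
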