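#' Pipeline configuration
#'
#' Bundles everything [runPipeline()] needs: exactly one data source
#' (an assembled [ConnectomeExperiment-class], a set of input file paths,
#' or a simulation spec plus seed), the confound specification, the FDR
#' level, and the gating behaviour.
#'
#' @param ce a [ConnectomeExperiment-class], or `NULL`.
#' @param cohort_file,panel_files,atlas_file input paths: a cohort table,
#'   a named vector/list of metric panel files, and optionally an atlas
#'   file (default atlas when omitted).
#' @param spec a [syntheticSpec()] for simulated input.
#' @param seed integer seed (required with `spec`).
#' @param confounds a [confoundSpec()].
#' @param alpha FDR level in (0, 1), default 0.05.
#' @param force_all_steps run Steps 2-4 for every metric regardless of the
#'   Step-1 decision (exploratory; recorded in provenance).
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(ce = NULL, cohort_file = NULL, panel_files = NULL,
                           atlas_file = NULL, spec = NULL, seed = NULL,
                           confounds = confoundSpec(), alpha = 0.05,
                           force_all_steps = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  sources <- c(!is.null(ce), !is.null(cohort_file), !is.null(spec))
  if (sum(sources) != 1L)
    stop("exactly one of {ce, input files, simulation spec} must be given")
  if (!is.null(spec) && is.null(seed))
    stop("a seed is required with a simulation spec")
  if (!is.null(cohort_file) && is.null(panel_files))
    stop("panel_files are required with cohort_file")
  structure(list(ce = ce, cohort_file = cohort_file,
                 panel_files = panel_files, atlas_file = atlas_file,
                 spec = spec, seed = seed, confounds = confounds,
                 alpha = alpha, force_all_steps = isTRUE(force_all_steps)),
            class = "PipelineConfig")
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[setdiff(names(config), "ce")], tmp, version = 2,
          compress = FALSE)
  unname(tools::md5sum(tmp))
}

.loadExperiment <- function(config) {
  if (!is.null(config$ce)) return(config$ce)
  if (!is.null(config$spec))
    return(simulateExperiment(config$spec, config$seed))
  atlas <- if (is.null(config$atlas_file)) defaultAtlas()
           else readParcelAtlas(config$atlas_file)
  cohort <- readCohort(config$cohort_file)
  panels <- lapply(config$panel_files, readMetricPanel,
                   atlas = atlas, cohort = cohort)
  names(panels) <- names(config$panel_files)
  ConnectomeExperiment(panels, cohort, atlas)
}

#' Run the four-step multivariate analysis pipeline
#'
#' End-to-end orchestration: dataset validation, the demographic analysis
#' (Welch t per descriptor, chi-squared on the sex-by-group table), TICV
#' normalization, the reduced-model quadratic-age test (whose FDR decision
#' determines whether age squared joins the confound design), confound
#' residualization, the Step-1 omnibus Wilks test per metric, and — for
#' metrics whose omnibus null is rejected — the Step-2 predictor
#' leave-one-out, Step-3 CCA leave-one-out and Step-4 per-region tests.
#' Deterministic given the configuration (and seed, for simulated input).
#'
#' @param config a [pipelineConfig()].
#' @param verbose emit progress messages to standard error (default FALSE).
#' @return a list of class `"PipelineReport"` with elements `demographics`
#'   (summary table plus the sex chi-squared test), `age2_test` (table and
#'   `age2_included` decision), `step1`, `step2`, `step3`, `step4`
#'   (the latter three keyed by advanced metric), `advanced` (metric
#'   names), and `provenance`.
#' @examples
#' cfg <- pipelineConfig(spec = syntheticSpec(delta = calibratedDelta()),
#'                       seed = 11)
#' rep <- runPipeline(cfg)
#' rep$step1
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message("[connmanova] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ce <- stage("load", .loadExperiment(config))
  co <- cohortTable(ce)
  val <- validateDataset(co, setNames(
    lapply(metricNames(ce), metricPanel, x = ce), metricNames(ce)),
    parcelAtlas(ce))
  if (!val$ok)
    stop("pipeline stage 'validate' failed: ",
         paste(val$violations, collapse = "; "))
  say("dataset: ", val$n_subjects, " subjects, ", val$n_parcels,
      " parcels, ", val$n_metrics, " metrics")

  demo <- stage("demographics", {
    tab <- summarizeCohort(co)
    sexchi <- chisq2x2(sum(co$diagnosis == 1 & co$sex == 1),
                       sum(co$diagnosis == 1 & co$sex == -1),
                       sum(co$diagnosis == -1 & co$sex == 1),
                       sum(co$diagnosis == -1 & co$sex == -1))
    list(table = tab, sex_chi2 = unname(sexchi$statistic),
         sex_chi2_df = unname(sexchi$parameter),
         sex_chi2_p = sexchi$p.value)
  })

  ce <- stage("ticv_normalize", ticvNormalize(ce))
  age2 <- stage("quadratic_age_test",
                quadraticAgeTest(ce, spec = config$confounds,
                                 alpha = config$alpha))
  age2_included <- any(age2$reject)
  say("age^2 term ", if (age2_included) "retained" else "discarded",
      " after the reduced-model test")
  ce <- stage("residualize",
              residualizeConfounds(ce, spec = config$confounds,
                                   include_age2 = age2_included))

  step1 <- stage("step1_omnibus", omnibusStep1(ce, alpha = config$alpha))
  advanced <- step1$metric[step1$reject]
  if (config$force_all_steps) advanced <- step1$metric
  say("step 1: ", sum(step1$reject), " metric(s) rejected [",
      paste(step1$metric[step1$reject], collapse = ", "), "]")

  X <- buildDesign(co)
  q <- ncol(X) - 1L
  vE <- .effectiveVE(ce, nrow(co), q)
  atlas <- parcelAtlas(ce)
  step2 <- step3 <- step4 <- list()
  for (m in advanced) {
    Y <- metricPanel(ce, m)
    step2[[m]] <- stage("step2_predictor_loo",
                        predictorLooStep2(Y, X, alpha = config$alpha,
                                          vE = vE))
    step3[[m]] <- stage("step3_cca_loo",
                        predictorLooStep3(Y, X, alpha = config$alpha,
                                          vE = vE))
    step4[[m]] <- stage("step4_region_loo",
                        responseLooStep4(Y, X, alpha = config$alpha,
                                         vE = vE, atlas = atlas))
    say("steps 2-4 done for ", m)
  }

  provenance <- list(package = "connmanova",
                     version = as.character(packageVersion("connmanova")),
                     seed = config$seed, alpha = config$alpha,
                     force_all_steps = config$force_all_steps,
                     config_hash = .configHash(config),
                     n_subjects = nrow(co), n_parcels = length(atlas))
  structure(list(demographics = demo,
                 age2_test = list(table = age2,
                                  age2_included = age2_included),
                 step1 = step1, step2 = step2, step3 = step3, step4 = step4,
                 advanced = advanced, provenance = provenance),
            class = "PipelineReport")
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("PipelineReport (", x$provenance$n_subjects, "subjects x",
      x$provenance$n_parcels, "parcels )\n")
  cat("age^2 retained:", x$age2_test$age2_included, "\n")
  cat("Step 1 rejected:", paste(x$step1$metric[x$step1$reject],
                                collapse = ", ") , "\n")
  for (m in x$advanced) {
    s2 <- x$step2[[m]]
    cat("  ", m, "- predictors rejected:",
        paste(s2$predictor[s2$reject], collapse = ", "), "\n")
    cat("  ", m, "- parcels rejected (step 4):",
        sum(x$step4[[m]]$reject), "\n")
  }
  invisible(x)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Export a pipeline report to disk
#'
#' Writes a TSV per analysis stage (`demographics.tsv`, `age2_test.tsv`,
#' `step1_omnibus.tsv` and, for each advanced metric, the combined
#' `step2_predictor_loo.tsv`, `step3_cca_loo.tsv` and — sorted descending
#' by partial F — `step4_region_loo.tsv`), a machine-readable
#' `report.json`, and `manifest.txt` with the MD5 of every written file.
#' The export carries no timestamps, so rewriting an unchanged report to
#' the same directory reproduces identical hashes.
#'
#' @param report a `PipelineReport`.
#' @param out output directory (created if necessary).
#' @return invisibly, the manifest as a named vector of MD5 hashes.
#' @export
writeReport <- function(report, out) {
  stopifnot(inherits(report, "PipelineReport"))
  if (!dir.exists(out))
    if (!dir.create(out, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out)
  files <- character()
  demo <- report$demographics$table
  demo_out <- cbind(demo, sex_chi2 = report$demographics$sex_chi2,
                    sex_chi2_p = report$demographics$sex_chi2_p)
  files <- c(files, .writeTsv(demo_out, file.path(out, "demographics.tsv")))
  files <- c(files, .writeTsv(report$age2_test$table,
                              file.path(out, "age2_test.tsv")))
  files <- c(files, .writeTsv(report$step1,
                              file.path(out, "step1_omnibus.tsv")))
  bindWithMetric <- function(lst) do.call(rbind, lapply(names(lst),
    function(m) cbind(metric = m, lst[[m]])))
  if (length(report$advanced)) {
    files <- c(files, .writeTsv(bindWithMetric(report$step2),
                                file.path(out, "step2_predictor_loo.tsv")))
    files <- c(files, .writeTsv(bindWithMetric(report$step3),
                                file.path(out, "step3_cca_loo.tsv")))
    s4 <- bindWithMetric(lapply(report$step4, function(df) {
      df <- df[order(-df$F), ]
      df$critical_F <- attr(df, "critical_F") %||% Inf
      df
    }))
    files <- c(files, .writeTsv(s4, file.path(out, "step4_region_loo.tsv")))
  }
  json_path <- file.path(out, "report.json")
  jsonlite::write_json(list(
    provenance = report$provenance,
    age2_included = report$age2_test$age2_included,
    advanced = as.list(report$advanced),
    step1 = report$step1,
    sex_chi2 = report$demographics$sex_chi2,
    sex_chi2_p = report$demographics$sex_chi2_p),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, json_path)
  hashes <- tools::md5sum(files)
  manifest <- file.path(out, "manifest.txt")
  writeLines(sprintf("%s  %s", hashes, basename(names(hashes))), manifest)
  invisible(c(hashes, setNames(tools::md5sum(manifest), manifest)))
}
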