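.detectSep <- function(path, sep = c("auto", "\t", ",")) {
  sep <- match.arg(sep)
  if (sep != "auto") return(sep)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("schema error: file is empty: ", path)
  if (grepl("\t", header)) "\t" else ","
}

.codeFromLabels <- function(x, col, plus, minus) {
  if (is.numeric(x)) {
    if (!all(x %in% c(-1, 1)))
      stop("column '", col, "' must be coded -1/+1 or labelled ",
           plus, "/", minus)
    return(x)
  }
  x <- toupper(trimws(as.character(x)))
  out <- ifelse(x %in% plus, 1, ifelse(x %in% minus, -1, NA_real_))
  if (anyNA(out))
    stop("column '", col, "' has unrecognized label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Read and write cohort tables
#'
#' The cohort file is a delimited table (tab or comma, auto-detected from
#' the header, overridable) with columns `subject_id`, `site`, `sex`,
#' `diagnosis`, `age`, `das_v`, `das_nv`, `das_s`, `das_gca`, `das_snc`,
#' `ticv`. Sex may be given as `M`/`F` (or `MALE`/`FEMALE`) and diagnosis
#' as `ASD`/`TD` (or `CASE`/`CONTROL`); both are mapped to the +1/-1 coding
#' used by the design matrix (+1 male, -1 female; +1 case, -1 control).
#'
#' @param path file path.
#' @param sep `"auto"` (default), `"\t"` or `","`.
#' @param cohort a validated cohort `data.frame`.
#' @return `readCohort()` a validated cohort `data.frame`;
#'   `writeCohort()` the path, invisibly.
#' @examples
#' co <- generateCohort(syntheticSpec(), seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' writeCohort(co, f)
#' identical(readCohort(f)$ticv, co$ticv)
#' @export
readCohort <- function(path, sep = c("auto", "\t", ",")) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  sep <- .detectSep(path, match.arg(sep))
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0L) stop("schema error: cohort file has no data rows")
  missing_cols <- setdiff(.cohortCols, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, .cohortCols]
  num_cols <- setdiff(.cohortCols, c("subject_id", "site", "sex", "diagnosis"))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v))
      stop("parse error: non-numeric '", cn, "' in row(s) ",
           paste(which(is.na(v)), collapse = ", "))
    df[[cn]] <- v
  }
  sex_raw <- suppressWarnings(as.numeric(df$sex))
  df$sex <- if (!anyNA(sex_raw)) sex_raw else
    .codeFromLabels(df$sex, "sex", c("M", "MALE", "1", "+1"),
                    c("F", "FEMALE", "-1"))
  dx_raw <- suppressWarnings(as.numeric(df$diagnosis))
  df$diagnosis <- if (!anyNA(dx_raw)) dx_raw else
    .codeFromLabels(df$diagnosis, "diagnosis", c("ASD", "CASE", "1", "+1"),
                    c("TD", "CONTROL", "-1"))
  co <- validateCohort(df)
  co
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, path, sep = "\t") {
  cohort <- validateCohort(cohort)
  out <- cohort
  num_cols <- setdiff(.cohortCols, c("subject_id", "site"))
  for (cn in num_cols) out[[cn]] <- sprintf("%.17g", cohort[[cn]])
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write metric panel files
#'
#' A metric panel file holds one subjects-by-parcels value table: a
#' `subject_id` column followed by one column per parcel label. Rows and
#' columns may appear in any order; on reading they are aligned to the
#' cohort's subject order and the atlas's parcel order, so downstream
#' response matrices always share one ordering.
#'
#' @param path file path.
#' @param atlas a [ParcelAtlas] defining the parcel set and order.
#' @param cohort a validated cohort `data.frame` defining the subject order.
#' @param sep `"auto"` (default), `"\t"` or `","`.
#' @param panel subjects-by-parcels numeric matrix with parcel labels as
#'   column names (row order = cohort order).
#' @return `readMetricPanel()` a subjects-by-parcels matrix aligned to
#'   `cohort` and `atlas` (values written by `writeMetricPanel()` round-trip
#'   bitwise); `writeMetricPanel()` the path, invisibly.
#' @export
readMetricPanel <- function(path, atlas, cohort, sep = c("auto", "\t", ",")) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  cohort <- validateCohort(cohort)
  sep <- .detectSep(path, match.arg(sep))
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
  if (!"subject_id" %in% names(df))
    stop("schema error: panel lacks a 'subject_id' column")
  labs <- setdiff(names(df), "subject_id")
  unknown <- setdiff(labs, parcelLabels(atlas))
  if (length(unknown))
    stop("unknown parcel(s) not in atlas: ", paste(unknown, collapse = ", "))
  absent <- setdiff(parcelLabels(atlas), labs)
  if (length(absent))
    stop("alignment error: panel missing atlas parcel(s): ",
         paste(absent, collapse = ", "))
  extra_subj <- setdiff(df$subject_id, cohort$subject_id)
  if (length(extra_subj))
    stop("alignment error: panel subject(s) not in cohort: ",
         paste(extra_subj, collapse = ", "))
  lost_subj <- setdiff(cohort$subject_id, df$subject_id)
  if (length(lost_subj))
    stop("alignment error: cohort subject(s) missing from panel: ",
         paste(lost_subj, collapse = ", "))
  m <- as.matrix(df[match(cohort$subject_id, df$subject_id),
                    parcelLabels(atlas), drop = FALSE])
  if (!is.numeric(m) || !all(is.finite(m))) {
    bad <- which(!is.finite(suppressWarnings(matrix(as.numeric(m), nrow(m)))),
                 arr.ind = TRUE)[1, ]
    stop("value error: non-finite value at subject '",
         cohort$subject_id[bad[1]], "', parcel '",
         parcelLabels(atlas)[bad[2]], "'")
  }
  rownames(m) <- cohort$subject_id
  m
}

#' @rdname readMetricPanel
#' @export
writeMetricPanel <- function(panel, cohort, path, sep = "\t") {
  cohort <- validateCohort(cohort)
  stopifnot(nrow(panel) == nrow(cohort))
  header <- c("subject_id", colnames(panel))
  body <- cbind(cohort$subject_id,
                matrix(sprintf("%.17g", panel), nrow = nrow(panel)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  writeLines(apply(body, 1, paste, collapse = sep), con)
  invisible(path)
}

#' Consistency report for a cohort with metric panels
#'
#' Report-only validation of a dataset: per-panel subject/parcel alignment,
#' value ranges, finiteness, and group counts. Violations are listed, never
#' thrown.
#'
#' @param cohort a cohort `data.frame`.
#' @param panels named list of subjects-by-parcels matrices.
#' @param atlas a [ParcelAtlas] (default [defaultAtlas()]).
#' @return a list with elements `n_subjects`, `n_parcels`, `n_metrics`,
#'   `group_counts`, a per-panel summary `data.frame`, and a character
#'   vector `violations` (empty when the dataset is fully consistent).
#' @export
validateDataset <- function(cohort, panels, atlas = defaultAtlas()) {
  violations <- character()
  co <- tryCatch(validateCohort(cohort), error = function(e) {
    violations <<- c(violations, conditionMessage(e)); cohort
  })
  group_counts <- c(case = sum(co$diagnosis == 1),
                    control = sum(co$diagnosis == -1),
                    female = sum(co$sex == -1), male = sum(co$sex == 1))
  rows <- lapply(names(panels), function(nm) {
    m <- panels[[nm]]
    if (nrow(m) != nrow(co))
      violations <<- c(violations, sprintf(
        "panel '%s': %d rows vs %d subjects", nm, nrow(m), nrow(co)))
    if (ncol(m) != length(atlas))
      violations <<- c(violations, sprintf(
        "panel '%s': %d columns vs %d atlas parcels", nm, ncol(m),
        length(atlas)))
    nf <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(nf))
      violations <<- c(violations, sprintf(
        "panel '%s': non-finite value at subject %d, parcel %d",
        nm, nf[1, 1], nf[1, 2]))
    data.frame(metric = nm, n_subjects = nrow(m), n_parcels = ncol(m),
               min = suppressWarnings(min(m[is.finite(m)])),
               max = suppressWarnings(max(m[is.finite(m)])),
               n_nonfinite = nrow(nf))
  })
  list(n_subjects = nrow(co), n_parcels = length(atlas),
       n_metrics = length(panels), group_counts = group_counts,
       panel_summary = do.call(rbind, rows), violations = violations,
       ok = length(violations) == 0L)
}
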