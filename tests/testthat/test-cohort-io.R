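test_that("cohort write-then-read round trip preserves values and counts", {
  co <- generateCohort(syntheticSpec(), seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCohort(co, f)
  back <- readCohort(f)
  expect_identical(back$subject_id, co$subject_id)
  for (v in c("age", "ticv", "das_v", "das_gca"))
    expect_identical(back[[v]], co[[v]])
  expect_equal(sum(back$diagnosis == 1), 110)
  expect_equal(sum(back$diagnosis == -1), 83)
  expect_equal(sum(back$sex == -1), 95)
})

test_that("text labels for sex and diagnosis map onto the +/-1 codes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,site,sex,diagnosis,age,das_v,das_nv,das_s,das_gca,das_snc,ticv",
    "a,site1,M,ASD,10,100,100,100,100,100,210",
    "b,site2,F,TD,12,95,96,97,98,99,220"), f)
  co <- readCohort(f)
  expect_equal(co$sex, c(1, -1))
  expect_equal(co$diagnosis, c(1, -1))
})

test_that("cohort reader raises specific schema, parse and integrity errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_error(readCohort(f), "empty")

  writeLines(c("subject_id,sex,diagnosis", "a,M,ASD"), f)
  expect_error(readCohort(f), "site")

  co <- handCohort(2)
  writeCohort(co, f)
  tx <- readLines(f)
  tx[2] <- sub("^(\\S+\\t\\S+\\t\\S+\\t\\S+\\t)\\S+", "\\1not_an_age", tx[2])
  writeLines(tx, f)
  expect_error(readCohort(f), "non-numeric 'age' in row\\(s\\) 1")

  co$subject_id[2] <- co$subject_id[1]
  expect_error(validateCohort(co), "duplicate subject_id")
})

test_that("single-subject cohort file is accepted", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,site,sex,diagnosis,age,das_v,das_nv,das_s,das_gca,das_snc,ticv",
    "solo,site1,1,-1,9.5,100,100,100,100,100,200"), f)
  expect_equal(nrow(readCohort(f)), 1)
})

test_that("metric panel round trip is bitwise and permutation-invariant", {
  sp <- syntheticSpec()
  co <- generateCohort(sp, seed = 4)
  pan <- generatePanels(sp, co, seed = 5)$CD
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMetricPanel(pan, co, f)
  back <- readMetricPanel(f, sp$atlas, co)
  expect_identical(unname(back), unname(pan))

  # shuffle rows and columns in the file; reading must realign
  lines <- readLines(f)
  header <- strsplit(lines[1], "\t")[[1]]
  perm_c <- c(1, 1 + sample(length(header) - 1))
  body <- do.call(rbind, strsplit(lines[-1], "\t"))[sample(nrow(pan)), perm_c]
  writeLines(c(paste(header[perm_c], collapse = "\t"),
               apply(body, 1, paste, collapse = "\t")), f)
  shuffled <- readMetricPanel(f, sp$atlas, co)
  expect_identical(unname(shuffled), unname(pan))
})

test_that("panel reader names the offending parcel or subject", {
  sp <- tinySpec()
  co <- generateCohort(sp, seed = 1)
  pan <- generatePanels(sp, co, seed = 2)$CD
  f <- withr::local_tempfile(fileext = ".tsv")

  writeMetricPanel(pan[, -3], co, f)
  expect_error(readMetricPanel(f, sp$atlas, co),
               parcelLabels(sp$atlas)[3], fixed = TRUE)

  writeMetricPanel(pan[-1, ], co[-1, ], f)
  expect_error(readMetricPanel(f, sp$atlas, co), co$subject_id[1],
               fixed = TRUE)
})

test_that("dataset validation reports dimensions and pinpoints violations", {
  sp <- syntheticSpec()
  co <- generateCohort(sp, seed = 6)
  pans <- generatePanels(sp, co, seed = 7)
  rep <- validateDataset(co, pans, sp$atlas)
  expect_true(rep$ok)
  expect_equal(rep$n_subjects, 193)
  expect_equal(rep$n_parcels, 165)
  expect_equal(rep$n_metrics, 5)
  expect_equal(unname(rep$group_counts[c("case", "control")]), c(110, 83))

  pans$CD[5, 9] <- NaN
  rep2 <- validateDataset(co, pans, sp$atlas)
  expect_false(rep2$ok)
  expect_length(rep2$violations, 1)
  expect_match(rep2$violations, "subject 5, parcel 9")
})

test_that("default atlas has 165 parcels and round-trips through a file", {
  atl <- defaultAtlas()
  expect_length(atl, 165)
  expect_equal(as.integer(table(hemisphere(atl))[c("lh", "rh", "mid")]),
               c(74L, 74L, 17L))
  expect_true(all(defaultTargetParcels() %in% parcelLabels(atl)))
  f <- withr::local_tempfile(fileext = ".txt")
  writeParcelAtlas(atl, f)
  expect_identical(parcelLabels(readParcelAtlas(f)), parcelLabels(atl))
  writeLines(c("lh.ok", "xx.bad"), f)
  expect_error(readParcelAtlas(f), "prefix")
})

test_that("experiment container aligns panels, cohort and atlas", {
  sp <- tinySpec()
  ce <- simulateExperiment(sp, seed = 11)
  expect_s4_class(ce, "ConnectomeExperiment")
  expect_equal(dim(metricPanel(ce, "CD")),
               c(sp$n_case + sp$n_ctrl, length(sp$atlas)))
  expect_identical(metricNames(ce), names(sp$baseline))
  expect_identical(parcelLabels(parcelAtlas(ce)), parcelLabels(sp$atlas))
  expect_error(metricPanel(ce, "nope"), "available")
  co <- cohortTable(ce)
  bad <- co; bad$ticv[1] <- -1
  expect_error(ConnectomeExperiment(
    list(CD = metricPanel(ce, "CD")), bad, sp$atlas), "positive")
})
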