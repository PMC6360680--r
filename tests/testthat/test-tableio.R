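writeToyCsv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

test_that("reading handles orientation, NA tokens and malformed input", {
  path <- writeToyCsv(c("sample_id,label,f1,f2",
                        "s1,0,1.5,2.0",
                        "s2,1,NA,4.0",
                        "s3,0,3.5,"))
  raw <- readFeatureTable(path)
  expect_identical(dim(raw), c(3L, 2L))
  expect_identical(featureIds(raw), c("f1", "f2"))
  expect_true(is.na(intensities(raw)["s2", "f1"]))
  expect_true(is.na(intensities(raw)["s3", "f2"]))
  expect_equal(sampleLabels(raw), c(0, 1, 0))
  # features in rows: transposed to the canonical orientation
  pathT <- writeToyCsv(c("feature_id,s1,s2,s3",
                         "f1,1.5,2.5,3.5",
                         "f2,2.0,4.0,6.0"))
  rawT <- readFeatureTable(pathT, orientation = "features_in_rows")
  expect_identical(dim(rawT), c(3L, 2L))
  expect_equal(unname(intensities(rawT)[, "f1"]), c(1.5, 2.5, 3.5))
  # missing label column and duplicate feature ids are input errors
  expect_error(readFeatureTable(path, labelCol = "phenotype"), "label")
  pathD <- writeToyCsv(c("feature_id,s1,s2", "f1,1,2", "f1,3,4"))
  expect_error(readFeatureTable(pathD, orientation = "features_in_rows"),
               "duplicate")
})

test_that("duplicate averaging ignores missing cells and keeps all-missing cells", {
  x <- matrix(c(2, 4, NA, 4, NA, NA), 2, 3,
              dimnames = list(c("r1", "r2"), c("f1", "f2", "f3")))
  raw <- rawFeatureTable(x, labels = c(1, 1), replicateMap = c("m1", "m1"))
  avg <- averageDuplicates(raw)
  expect_identical(dim(avg), c(1L, 3L))
  expect_equal(unname(intensities(avg)[1, ]), c(3, 4, NA))
  expect_equal(sampleLabels(avg), 1)
  expect_error(averageDuplicates(rawFeatureTable(x)), "replicate map")
  # conflicting labels within a unit are an error
  bad <- rawFeatureTable(x, labels = c(0, 1), replicateMap = c("m1", "m1"))
  expect_error(averageDuplicates(bad), "conflicting")
})

test_that("missing-value filter drops at the inclusive 30% boundary", {
  x <- matrix(1, 10, 3, dimnames = list(NULL, c("f30", "f20", "f0")))
  x[1:3, 1] <- NA          # exactly 30% missing: dropped
  x[1:2, 2] <- NA          # 20% missing: kept
  raw <- rawFeatureTable(x, labels = rep(c(0, 1), 5))
  suppressMessages(flt <- missingValueFilter(raw))
  expect_identical(featureIds(flt), c("f20", "f0"))
  # complete table unchanged
  suppressMessages(same <- missingValueFilter(rawFeatureTable(x[, 3, drop = FALSE],
                                                              labels = rep(c(0, 1), 5))))
  expect_identical(unname(intensities(same)), unname(x[, 3, drop = FALSE]))
})

test_that("zero imputation completes the table and validates labels", {
  x <- matrix(c(1, NA, 3, 4, 5, 6, 7, 8), 4, 2,
              dimnames = list(NULL, c("f1", "f2")))
  raw <- rawFeatureTable(x, labels = c(0, 1, 0, 1))
  suppressMessages(ft <- imputeZero(raw))
  expect_s4_class(ft, "FeatureTable")
  expect_equal(unname(intensities(ft)[2, "f1"]), 0)
  expect_error(imputeZero(rawFeatureTable(x)), "labels")
  expect_error(rawFeatureTable(x, labels = c(0, 1, 2, 1)), "two values|0/1")
})

test_that("the preprocessing chain is ordered and idempotent", {
  set.seed(60)
  x <- matrix(rnorm(8 * 10), 8, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  x[1:4, 1] <- NA                       # 50% missing after averaging too
  x[1, 2] <- NA                         # recoverable by averaging
  raw <- rawFeatureTable(x, labels = rep(c(0, 0, 1, 1), each = 2),
                         replicateMap = rep(c("u1", "u2", "u3", "u4"), each = 2))
  ft <- suppressMessages(preprocessFeatureTable(raw))
  expect_s4_class(ft, "FeatureTable")
  expect_false("f1" %in% featureIds(ft))  # >= 30% missing dropped
  expect_true("f2" %in% featureIds(ft))   # averaged over the observed replicate
  expect_true(all(is.finite(intensities(ft))))
  # idempotence: re-running the chain on the clean table changes nothing
  raw2 <- rawFeatureTable(intensities(ft), labels = sampleLabels(ft))
  ft2 <- suppressMessages(preprocessFeatureTable(raw2))
  expect_identical(intensities(ft2), intensities(ft))
})

test_that("selection results round-trip through the TSV writer", {
  sim <- generateDataset(simulationDesign("one_layer", seed = 61))
  res <- suppressWarnings(selectFeatures(fitBiplot(sim$table), sim$table,
                                         selectionParams(tau = 0.05)))
  path <- tempfile(fileext = ".tsv")
  df <- writeSelection(res, path)
  back <- read.delim(path)
  expect_identical(nrow(back), nrow(df))
  for (g in c("0", "1")) {
    e <- groupSelection(res, g)
    expect_setequal(back$feature_id[back$group == as.integer(g) &
                                      back$status == "selected"],
                    featureIds(res)[e$selected])
    expect_setequal(back$feature_id[back$group == as.integer(g) &
                                      back$status == "filtered"],
                    featureIds(res)[e$filteredOut$index])
  }
  # empty selection: header-only file
  emptyRes <- res
  emptyRes@perGroup <- lapply(res@perGroup, function(e) {
    e$wedgeMembers <- integer(); e$topCandidates <- integer()
    e$selected <- integer()
    e$filteredOut <- data.frame(index = integer(), pValue = numeric())
    e
  })
  emptyRes@unionSelected <- integer()
  path2 <- tempfile(fileext = ".tsv")
  writeSelection(emptyRes, path2)
  expect_identical(nrow(read.delim(path2)), 0L)
})
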