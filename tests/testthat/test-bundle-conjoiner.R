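# Bundles, scalarization, Dixon's Q-test and matrix aggregation.

test_that("bundles behave as ordered sets under select/deselect", {
  toy <- genToyStore(fixtureSpec(nMaterials = 5))
  b <- toy$bundle
  u <- b@substanceUuids[1]
  expect_identical(selectSubstance(b, u), b)          # already present
  b2 <- deselectSubstance(b, u)
  expect_length(b2@substanceUuids, 4)
  expect_identical(deselectSubstance(b2, u), b2)      # absent: unchanged
  sel <- b@selections[[1]]
  expect_identical(selectEndpoint(b, sel), b)
  expect_length(deselectEndpoint(b, sel)@selections, 1)

  expect_error(createBundle(toy$store, "TOYS-0000-unknown"),
               class = "enmkit_notfound_error")
  dm <- buildMatrix(toy$store, b)
  expect_identical(nrow(matrixValues(dm)), 5L)
})

test_that("scalarize maps value shapes as documented", {
  expect_identical(scalarize(Measurement("e", loValue = 10, upValue = 20)), 15)
  expect_identical(
    scalarize(Measurement("e", loValue = -30, errorValue = 2, unit = "mV")),
    -30)
  expect_identical(
    scalarize(Measurement("e", textValue = "image_001.tif")), NA_real_)
  expect_identical(scalarize(Measurement("e", upValue = 5)), 5)
})

test_that("Dixon's Q-test reproduces hand-computed decisions (alpha = 0.05, n = 3..10)", {
  cases <- list(
    ## values, expected excluded values (in exclusion order), Q of first test
    list(v = c(1, 2, 10),                 excl = numeric(0),  Q = 8 / 9),
    list(v = c(1, 1.01, 100),             excl = 100,         Q = 98.99 / 99),
    list(v = c(0.10, 0.11, 0.12, 0.35),   excl = 0.35,        Q = 0.92),
    list(v = c(5, 5, 5),                  excl = numeric(0),  Q = NA),
    list(v = c(-10, 1, 1.1, 1.2),         excl = -10,         Q = 11 / 11.2),
    list(v = c(2.0, 2.1, 2.2, 2.3, 3.0),  excl = numeric(0),  Q = 0.7),
    list(v = c(2.0, 2.1, 2.2, 2.3, 3.1),  excl = 3.1,         Q = 0.8 / 1.1),
    list(v = c(10, 11, 12, 13, 14, 30),   excl = 30,          Q = 16 / 20),
    list(v = c(1:6, 20),                  excl = 20,          Q = 14 / 19),
    list(v = c(1:7, 20),                  excl = 20,          Q = 13 / 18),
    list(v = seq(10, 14, by = 0.5),       excl = numeric(0),  Q = 0.5 / 3.5),
    list(v = c(seq(1, 1.8, by = 0.1), 9), excl = 9,           Q = 7.2 / 7.9))
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    d <- dixonOutliers(cs$v, alpha = 0.05)
    expect_equal(sort(d$excluded$value), sort(cs$excl),
                 info = sprintf("case %d exclusion set", k))
    if (length(cs$excl))
      expect_equal(d$excluded$Q[1], cs$Q, tolerance = 1e-12,
                   info = sprintf("case %d Q statistic", k))
    expect_identical(d$nInput, length(cs$v))
    expect_identical(length(d$kept) + nrow(d$excluded), length(cs$v))
  }
})

test_that("critical values match the published two-sided table", {
  expect_identical(dixonCriticalValue(4, 0.05), 0.829)
  expect_identical(dixonCriticalValue(3, 0.05), 0.970)
  expect_identical(dixonCriticalValue(7, 0.05), 0.568)
  expect_identical(dixonCriticalValue(10, 0.05), 0.530)
  expect_error(dixonCriticalValue(4, 0.2), class = "enmkit_validation_error")
  expect_error(dixonCriticalValue(31, 0.05), class = "enmkit_validation_error")
})

test_that("values outside the test domain are never excluded", {
  expect_identical(nrow(dixonOutliers(c(1, 100))$excluded), 0L)
  expect_identical(nrow(dixonOutliers(c(5, 5, 5))$excluded), 0L)
  big <- c(rnorm(30), 50)  # n = 31 > tabulated domain
  expect_identical(nrow(dixonOutliers(big)$excluded), 0L)
})

test_that("enlarging an outlier's distance never un-excludes it (monotonicity)", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    base <- rnorm(n - 1)
    shift <- max(base) + runif(1, 0.5, 2) * diff(range(base)) + 0.5
    excludedBefore <- FALSE
    for (extra in c(0, 1, 3, 10, 100)) {
      d <- dixonOutliers(c(base, shift + extra), alpha = 0.05)
      nowExcluded <- (shift + extra) %in% d$excluded$value
      if (excludedBefore) expect_true(nowExcluded)
      excludedBefore <- nowExcluded
    }
  }
})

test_that("aggregation means the kept values and reports the method", {
  a <- aggregateValues(c(0.10, 0.11, 0.12, 0.35))
  expect_equal(a$value, 0.11)
  expect_identical(a$report@method, "MEAN_AFTER_DIXON")
  expect_identical(a$report@nInput, 4L)
  expect_equal(a$report@excluded$value, 0.35)
  expect_true(all(a$report@excluded$Q >= a$report@excluded$Qcrit))

  single <- aggregateValues(7.3)
  expect_identical(single$value, 7.3)
  expect_identical(single$report@method, "SINGLE")

  expect_equal(aggregateValues(c(1, 2, 3))$value, 2)  # Q = 0.5 < 0.970
  expect_identical(aggregateValues(c(1, 2))$report@method, "MEAN")
  expect_error(aggregateValues(numeric(0)), class = "enmkit_validation_error")
})

test_that("the injected-outlier cell aggregates to the clean replicate mean", {
  toy <- genToyStore(fixtureSpec())
  dm <- buildMatrix(toy$store, toy$bundle)
  truth <- toy$groundTruth
  for (i in seq_len(nrow(truth))) {
    ep <- truth$endpoint[i]
    col <- grep(paste0("^", ep), colnames(matrixValues(dm)), value = TRUE)
    expect_length(col, 1)
    got <- matrixValues(dm)[truth$uuid[i], col]
    expect_equal(unname(got), truth$cleanMean[i], tolerance = 1e-12)
    rep <- cellReport(dm, truth$uuid[i], col)
    if (truth$outlierInjected[i]) {
      expect_identical(nrow(rep@excluded), 1L)
      expect_identical(rep@nInput, truth$nClean[i] + 1L)
    }
  }
})

test_that("substances without data get missing cells; text measurements are skipped", {
  toy <- genToyStore(fixtureSpec(nMaterials = 2))
  extra <- Substance(makeIdentifier("TOYS", "no-data"), name = "no-data")
  store <- addSubstance(toy$store, extra)
  b <- selectSubstance(toy$bundle, extra@uuid, store)
  dm <- buildMatrix(store, b)
  expect_true(all(is.na(matrixValues(dm)[extra@uuid, ])))
  ## the text measurement in the fixture contributed no value anywhere
  reports <- dm@reports
  nIn <- sum(vapply(reports, function(r) r@nInput, 1L))
  sm <- endpointSummary(store)
  expect_identical(nIn, sum(sm$records) - 1L)  # one text record in store
})

test_that("matrix equals the naive group-by-mean oracle on outlier-free random stores", {
  for (seed in 1:50) {
    rs <- genRandomStore(seed, maxMeasurements = 50)
    dm <- buildMatrix(rs$store, rs$bundle)
    oracle <- naiveGroupMeans(rs$store, rs$bundle)
    expect_identical(sum(!is.na(matrixValues(dm))), nrow(oracle))
    for (i in seq_len(nrow(oracle))) {
      col <- oracleColumnName(oracle$endpoint[i], oracle$sig[i],
                              oracle$unit[i])
      expect_identical(unname(matrixValues(dm)[oracle$uuid[i], col]),
                       oracle$value[i],
                       info = sprintf("seed %d cell %s/%s", seed,
                                      oracle$uuid[i], col))
    }
  }
})

test_that("shuffling measurement insertion order never changes a cell", {
  rs <- genRandomStore(99)
  dm1 <- buildMatrix(rs$store, rs$bundle)
  set.seed(1)
  store2 <- SubstanceStore()
  for (u in sample(substanceIds(rs$store)))
    store2 <- addSubstance(store2, getSubstance(rs$store, u))
  for (u in sample(studyIds(rs$store))) {
    pa <- getStudy(rs$store, u)
    pa@effects <- rev(pa@effects)
    store2 <- addStudy(store2, pa)
  }
  dm2 <- buildMatrix(store2, rs$bundle)
  expect_identical(matrixValues(dm2), matrixValues(dm1))
})

test_that("per-cell report nInput equals the count of matching measurements", {
  toy <- genToyStore(fixtureSpec(nMaterials = 3))
  dm <- buildMatrix(toy$store, toy$bundle)
  for (key in names(dm@reports)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ep <- trimws(sub(" \\(.*$", "", sub("@.*$", "", parts[2])))
    n <- 0L
    for (pa in studiesOf(toy$store, parts[1]))
      for (m in pa@effects)
        if (m@endpoint == ep && !is.na(scalarize(m))) n <- n + 1L
    expect_identical(dm@reports[[key]]@nInput, n)
  }
})

test_that("unit mismatches within a key leave the cell missing and are logged", {
  store <- SubstanceStore()
  u <- makeIdentifier("TEST", "mix")
  store <- addSubstance(store, Substance(u, name = "mix"))
  store <- addStudy(store, ProtocolApplication(
    makeIdentifier("TEST", "mix|size"), u,
    Protocol("P-CHEM", "PC_GRANULOMETRY_SECTION", "particle size"),
    effects = list(Measurement("particle size", loValue = 50, unit = "nm"),
                   Measurement("particle size", loValue = 0.05, unit = "um"))))
  b <- createBundle(store, u, list(
    endpointSelection("P-CHEM", "PC_GRANULOMETRY_SECTION", "particle size")))
  dm <- buildMatrix(store, b)
  expect_true(all(is.na(matrixValues(dm))))
  expect_identical(nrow(dm@conflicts), 1L)
  expect_match(dm@conflicts$units, "nm vs um")
})

test_that("matrix CSV and JSON exports carry rows, feature keys and reports", {
  toy <- genToyStore(fixtureSpec(nMaterials = 2))
  dm <- buildMatrix(toy$store, toy$bundle)
  csv <- withr::local_tempfile(fileext = ".csv")
  exportMatrixCSV(dm, csv)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_identical(back$substance, rownames(matrixValues(dm)))
  expect_identical(colnames(back)[-1], colnames(matrixValues(dm)))
  doc <- jsonlite::fromJSON(exportMatrixJSON(dm), simplifyVector = FALSE)
  expect_identical(unlist(doc$rows), rownames(matrixValues(dm)))
  expect_length(doc$reports, sum(!is.na(matrixValues(dm))))
})
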