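# Configurable spreadsheet parser: mapping configs, layouts, blocks, joins.

test_that("a minimal ROW-layout config validates; unknown keywords are named", {
  cfg <- list(idPrefix = "FCSV", layout = "ROW",
              substance = list(key = list(column = "name")),
              studies = list(list(
                protocol = list(topcategory = "P-CHEM", endpoint = "size"),
                endpoints = list(list(endpoint = "size",
                                      lo = list(column = "size"))))))
  expect_s4_class(loadConfig(cfg), "TemplateConfig")

  bad <- cfg
  bad$studies[[1]]$endpoints[[1]]$lo <- list(colum_iteration = "size")
  err <- tryCatch(loadConfig(bad), error = identity)
  expect_s3_class(err, "enmkit_config_error")
  expect_match(conditionMessage(err), "colum_iteration")
})

test_that("layout-contradicting locators are config errors", {
  cfg <- list(idPrefix = "FCSV", layout = "ROW",
              substance = list(key = list(row = "name")),
              studies = list(list(
                protocol = list(topcategory = "P-CHEM", endpoint = "size"),
                endpoints = list(list(endpoint = "size",
                                      lo = list(column = "size"))))))
  expect_error(loadConfig(cfg), "contradicts ROW layout",
               class = "enmkit_config_error")
  cfg$layout <- "COLUMN"
  cfg$substance$key <- list(row = "name")
  expect_error(loadConfig(cfg), "contradicts COLUMN layout",
               class = "enmkit_config_error")
})

test_that("the shipped corona-style CSV config parses its own fixture", {
  dir <- withr::local_tempdir()
  wb <- genTemplateWorkbook(fixtureSpec(nMaterials = 3), "ROW", dir = dir)
  expect_s4_class(loadConfig(wb$configFile), "TemplateConfig")
  res <- parseWorkbook(wb$file, loadConfig(wb$configFile))
  expect_length(res$substances, 3)
})

test_that("ROW toy parses to one substance per material and one study per endpoint", {
  wb <- genTemplateWorkbook(fixtureSpec(nMaterials = 3, replicates = 1), "ROW")
  res <- parseWorkbook(list(Sheet1 = wb$sheet), wb$config)
  expect_length(res$substances, 3)
  expect_length(res$protocolApplications, 6)  # size + zeta per material
  s <- res$substances[[1]]
  expect_identical(s@ownerName, "fixture generator")
  roles <- vapply(s@composition, function(c) c@role, "")
  expect_setequal(roles, c("CORE", "COATING"))
  ## every measurement carries its unit
  units <- unlist(lapply(res$protocolApplications, function(pa)
    vapply(pa@effects, function(m) m@unit, "")))
  expect_true(all(units %in% c("nm", "mV")))
})

test_that("replicate rows accumulate into one protocol application per study block", {
  wb <- genTemplateWorkbook(fixtureSpec(nMaterials = 2, replicates = 3), "ROW")
  res <- parseWorkbook(list(Sheet1 = wb$sheet), wb$config)
  expect_length(res$substances, 2)
  expect_length(res$protocolApplications, 4)
  expect_true(all(vapply(res$protocolApplications,
                         function(pa) length(pa@effects), 1L) == 3L))
})

test_that("an empty data region yields no substances and no error", {
  wb <- genTemplateWorkbook(fixtureSpec(nMaterials = 1, replicates = 1), "ROW")
  empty <- wb$sheet[1, , drop = FALSE]  # header only
  res <- parseWorkbook(list(Sheet1 = empty), wb$config)
  expect_length(res$substances, 0)
  expect_length(res$protocolApplications, 0)
})

test_that("ROW, COLUMN (transpose) and BLOCK renderings parse to identical stores", {
  spec <- fixtureSpec(nMaterials = 4, replicates = 2)
  results <- lapply(c("ROW", "COLUMN", "BLOCK"), function(layout) {
    wb <- genTemplateWorkbook(spec, layout)
    parseWorkbook(list(Sheet1 = wb$sheet), wb$config)
  })
  expect_equal(results[[1]]$substances, results[[2]]$substances)
  expect_equal(results[[1]]$protocolApplications,
               results[[2]]$protocolApplications)
  expect_equal(results[[1]]$substances, results[[3]]$substances)
  expect_equal(results[[1]]$protocolApplications,
               results[[3]]$protocolApplications)
})

test_that("re-import with clear semantics is idempotent", {
  dir <- withr::local_tempdir()
  wb <- genTemplateWorkbook(fixtureSpec(nMaterials = 3), "ROW", dir = dir)
  cfg <- loadConfig(wb$configFile)
  store1 <- importWorkbook(SubstanceStore(), wb$file, cfg)
  store2 <- importWorkbook(store1, wb$file, cfg,
                           clearComposition = TRUE, clearStudies = TRUE)
  expect_equal(store2, store1)
})

test_that("non-numeric value cells fall back to text with a warning; counts reconcile", {
  sheet <- rbind(c("name", "size nm"),
                 c("mat-A", "41"),
                 c("mat-B", "see notes"),
                 c("", "99"))
  cfg <- list(idPrefix = "FCSV", layout = "ROW",
              substance = list(key = list(column = "name")),
              studies = list(list(
                protocol = list(topcategory = "P-CHEM",
                                category = "PC_GRANULOMETRY_SECTION",
                                endpoint = "size"),
                endpoints = list(list(endpoint = "size",
                                      lo = list(column = "size nm"),
                                      unit = "nm")))))
  expect_warning(
    expect_warning(res <- parseWorkbook(list(Sheet1 = sheet), cfg),
                   "recorded as text"),
    "empty substance key")
  expect_length(res$substances, 2)       # empty-key row skipped
  expect_identical(res$log$skippedRecords, 1L)
  expect_identical(res$log$textFallbacks, 1L)
  ## conservation: measurements == non-empty mapped value groups
  expect_identical(res$log$measurements, res$log$valueGroupsNonEmpty)
  expect_identical(res$log$measurements, 2L)
  matB <- res$substances[[makeIdentifier("FCSV", "mat-B")]]
  expect_false(is.null(matB))
  paB <- Filter(function(pa) pa@substanceUuid == matB@uuid,
                res$protocolApplications)[[1]]
  expect_identical(paB@effects[[1]]@textValue, "see notes")
})

test_that("missing sheets are I/O errors", {
  wb <- genTemplateWorkbook(fixtureSpec(nMaterials = 1), "ROW")
  cfg <- wb$config
  cfg$sheet <- "NoSuchSheet"
  expect_error(parseWorkbook(list(Sheet1 = wb$sheet), cfg),
               class = "enmkit_io_error")
})

test_that("locateBlocks splits marker-delimited regions as documented", {
  sheet <- matrix("", nrow = 10, ncol = 2)
  sheet[2, 1] <- "#BLOCK one"; sheet[3:4, 1] <- "data"
  sheet[5, 1] <- "#BLOCK two"; sheet[6:10, 1] <- "data"
  b <- locateBlocks(sheet, list(start = "^#BLOCK"))
  expect_identical(b$start, c(3L, 6L))
  expect_identical(b$end, c(4L, 10L))
  expect_identical(b$end - b$start + 1L, c(2L, 5L))

  ## no markers: one block spanning all rows
  plain <- matrix("x", nrow = 4, ncol = 1)
  b2 <- locateBlocks(plain, NULL)
  expect_identical(b2, data.frame(start = 1L, end = 4L))

  ## explicit end pattern, unmatched at EOF -> closed at last row + warning
  sheet2 <- matrix("", nrow = 5, ncol = 1)
  sheet2[1, 1] <- "BEGIN"; sheet2[2:3, 1] <- "d"
  sheet2[4, 1] <- "END"
  sheet2[5, 1] <- "x"
  b3 <- locateBlocks(sheet2, list(start = "^BEGIN", end = "^END"))
  expect_identical(b3, data.frame(start = 2L, end = 3L))
  sheet3 <- matrix(c("BEGIN", "d", "d"), ncol = 1)
  expect_warning(b4 <- locateBlocks(sheet3, list(start = "^BEGIN",
                                                 end = "^END")),
                 "no end marker")
  expect_identical(b4, data.frame(start = 2L, end = 3L))
})

test_that("blocks in two sheets are paired by their join key", {
  ## sheet A: materials in 3 keyed blocks; sheet B: toxicity rows keyed alike
  sheetA <- rbind(
    c("key", "name"),
    c("#B", ""), c("K1", "mat-1"),
    c("#B", ""), c("K2", "mat-2"),
    c("#B", ""), c("K3", "mat-3"))
  sheetB <- rbind(
    c("key", "viability"),
    c("#B", ""), c("K1", "91"), c("K1", "89"),
    c("#B", ""), c("K2", "75"),
    c("#B", ""), c("K3", "60"))
  cfg <- list(
    idPrefix = "MNTX", layout = "BLOCK", sheet = "materials",
    blockMarkers = list(start = "^#B"),
    sheetLinks = list(
      list(sheet = "materials", key = list(column = "key")),
      list(sheet = "assays", key = list(column = "key"))),
    substance = list(key = list(column = "key"),
                     name = list(column = "name")),
    studies = list(
      list(sheet = "assays",
           protocol = list(topcategory = "TOX",
                           category = "TO_CYTOTOXICITY_SECTION",
                           endpoint = "percentage viable cells"),
           endpoints = list(list(endpoint = "percentage viable cells",
                                 lo = list(column = "viability"),
                                 unit = "%")))))
  res <- parseWorkbook(list(materials = sheetA, assays = sheetB), cfg)
  expect_length(res$substances, 3)
  expect_length(res$protocolApplications, 3)
  byName <- vapply(res$protocolApplications, function(pa)
    getElement(res$substances[[pa@substanceUuid]]@name, 1), "")
  counts <- vapply(res$protocolApplications, function(pa)
    length(pa@effects), 1L)
  expect_identical(unname(counts[order(byName)]), c(2L, 1L, 1L))
})

test_that("CSV files round-trip through the file reader", {
  dir <- withr::local_tempdir()
  wb <- genTemplateWorkbook(fixtureSpec(nMaterials = 2, replicates = 1),
                            "ROW", dir = dir)
  fromFile <- parseWorkbook(wb$file, wb$config)
  inMemory <- parseWorkbook(list(Sheet1 = wb$sheet), wb$config)
  expect_equal(fromFile$substances, inMemory$substances)
  expect_equal(fromFile$protocolApplications,
               inMemory$protocolApplications)
})

test_that("the toy RDF dump imports with the default predicate map", {
  imp <- importNanoWikiRDF(genToyRDF(2))
  expect_length(imp$substances, 2)
  expect_length(imp$protocolApplications, 4)  # size + zeta per material
  expect_identical(imp$log$unmappedPredicates, 2L)
  expect_true(all(grepl("^NWKI-", names(imp$substances))))
  eps <- sort(unique(unlist(lapply(imp$protocolApplications, function(pa)
    vapply(pa@effects, function(m) m@endpoint, "")))))
  expect_identical(eps, c("particle size", "zeta potential"))
  cit <- imp$protocolApplications[[1]]@citation$title
  expect_match(cit, "^doi:")

  ## empty graph -> empty result
  emptyRdf <- '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"/>'
  imp0 <- importNanoWikiRDF(emptyRdf)
  expect_length(imp0$substances, 0)
})
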