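## Deterministic fixture generators: toy template workbooks with known
## ground truth, random stores for aggregation oracles, and a corona-like
## dataset (a library of surface-modified gold nanoparticles whose log2
## cell association is linear in two zeta potentials and two serum-protein
## relative abundances) with known coefficients. All randomness flows
## through R's generator seeded explicitly from the spec, so the same
## spec always produces byte-identical artifacts.

.ALKYL_AMINES <- c(
  "octylamine" = "CCCCCCCCN",
  "dodecylamine" = "CCCCCCCCCCCCN",
  "hexadecylamine" = "CCCCCCCCCCCCCCCCN",
  "octadecylamine" = "CCCCCCCCCCCCCCCCCCN",
  "hexadecyltrimethylammonium" = "CCCCCCCCCCCCCCCC[N+](C)(C)C",
  "11-amino-1-undecanethiol" = "NCCCCCCCCCCCS")

#' Specification of the synthetic study conditions
#'
#' Collects every tunable of the fixture generators with the defaults used
#' throughout the tests: 5 materials with size and zeta-potential
#' endpoints measured in 3 replicates, one injected outlier 10 noise-sd
#' away from its cell mean, a quarter of the measurements rendered as
#' intervals and a quarter carrying error values, plus one text (raw-file)
#' record; and a corona-like block of 105 particles with fixed true
#' coefficients and log2-scale Gaussian noise (sd 0.6).
#'
#' @param seed integer seed; every generator call is reproducible from it.
#' @param nMaterials,replicates toy-template dimensions.
#' @param endpoints named list of per-endpoint settings (mean, sd, unit).
#' @param nOutliers number of injected outliers across cells.
#' @param outlierMagnitude outlier distance from the cell mean in sd
#'   units.
#' @param intervalFraction,errorFraction fraction of measurements stored
#'   as lo/up intervals and as value+error.
#' @param corona list(n, beta (named, first element intercept), noiseSd).
#' @return a list of class \code{enmFixtureSpec}.
#' @export
fixtureSpec <- function(seed = 42, nMaterials = 5, replicates = 3,
                        endpoints = list(
                          `particle size` = list(mean = 50, sd = 5,
                                                 unit = "nm",
                                                 category = "PC_GRANULOMETRY_SECTION"),
                          `zeta potential` = list(mean = -30, sd = 3,
                                                  unit = "mV",
                                                  category = "ZETA_POTENTIAL_SECTION")),
                        nOutliers = 1, outlierMagnitude = 10,
                        intervalFraction = 0.25, errorFraction = 0.25,
                        corona = list(
                          n = 105,
                          beta = c(`(Intercept)` = 5,
                                   zp_synth = 0.05,
                                   zp_serum = 0.08,
                                   ab_alb = 2,
                                   ab_apoa1 = -1.5),
                          noiseSd = 0.6)) {
  structure(list(seed = seed, nMaterials = nMaterials,
                 replicates = replicates, endpoints = endpoints,
                 nOutliers = nOutliers, outlierMagnitude = outlierMagnitude,
                 intervalFraction = intervalFraction,
                 errorFraction = errorFraction, corona = corona),
            class = "enmFixtureSpec")
}

## --- toy store -----------------------------------------------------------

#' Generate a toy store with replicates and injected outliers
#'
#' Builds a store of \code{nMaterials} gold-core/amine-coated substances,
#' each with every configured endpoint measured in \code{replicates}
#' replicate measurements (a mix of point values, intervals centred on
#' the drawn value, and values with errors, so every measurement shape
#' occurs), one raw-data text record, and \code{nOutliers} additional
#' replicate values displaced \code{outlierMagnitude} noise-sd from the
#' cell mean. The ground truth lists, per (substance, endpoint), the
#' clean replicate mean an aggregation that rejects the outlier must
#' reproduce.
#'
#' @param spec a [fixtureSpec()].
#' @return list(store, bundle, groundTruth, outlierCells).
#' @export
genToyStore <- function(spec = fixtureSpec()) {
  set.seed(spec$seed)
  store <- SubstanceStore()
  coatings <- .ALKYL_AMINES[1 + (seq_len(spec$nMaterials) - 1) %%
                              length(.ALKYL_AMINES)]
  materialNames <- sprintf("NM-%03d", seq_len(spec$nMaterials))
  truth <- list()
  cells <- expand.grid(material = materialNames,
                       endpoint = names(spec$endpoints),
                       stringsAsFactors = FALSE)
  outlierCells <- cells[sample.int(nrow(cells),
                                   min(spec$nOutliers, nrow(cells))), ,
                        drop = FALSE]
  for (k in seq_len(spec$nMaterials)) {
    nm <- materialNames[k]
    uuid <- makeIdentifier("TOYS", nm)
    store <- addSubstance(store, Substance(
      uuid = uuid, name = nm, ownerName = "fixture generator",
      substanceType = "gold nanoparticle",
      composition = list(
        Component("CORE", name = "gold", smiles = "[Au]"),
        Component("COATING", name = names(coatings)[k],
                  smiles = unname(coatings[k])))))
    for (epName in names(spec$endpoints)) {
      ep <- spec$endpoints[[epName]]
      vals <- stats::rnorm(spec$replicates, ep$mean, ep$sd)
      isOutlier <- any(outlierCells$material == nm &
                       outlierCells$endpoint == epName)
      allVals <- vals
      if (isOutlier)
        allVals <- c(vals, mean(vals) + spec$outlierMagnitude * ep$sd)
      shapes <- stats::runif(length(allVals))
      effects <- lapply(seq_along(allVals), function(i) {
        v <- allVals[i]
        if (shapes[i] < spec$intervalFraction) {
          d <- abs(stats::rnorm(1, 0, ep$sd / 4))
          Measurement(epName, loValue = v - d, upValue = v + d,
                      unit = ep$unit)
        } else if (shapes[i] < spec$intervalFraction + spec$errorFraction) {
          Measurement(epName, loValue = v,
                      errorValue = abs(stats::rnorm(1, 0, ep$sd / 4)),
                      errQualifier = "SD", unit = ep$unit)
        } else {
          Measurement(epName, loValue = v, unit = ep$unit)
        }
      })
      if (k == 1 && epName == names(spec$endpoints)[1])
        effects <- c(effects, list(
          Measurement(epName, textValue = "raw/image_001.tif",
                      unit = ep$unit)))
      pa <- ProtocolApplication(
        uuid = makeIdentifier("TOYS", paste(nm, epName, sep = "|")),
        substanceUuid = uuid,
        protocol = Protocol("P-CHEM", ep$category, epName),
        effects = effects, reliability = 2,
        citation = list(title = "synthetic fixture", year = 2026,
                        owner = "enmkit"))
      store <- addStudy(store, pa)
      truth[[length(truth) + 1L]] <- data.frame(
        uuid = uuid, material = nm, endpoint = epName,
        cleanMean = mean(vals), nClean = length(vals),
        outlierInjected = isOutlier, stringsAsFactors = FALSE)
    }
  }
  selections <- lapply(names(spec$endpoints), function(epName)
    endpointSelection("P-CHEM", spec$endpoints[[epName]]$category, epName))
  bundle <- createBundle(store, substanceUuids = substanceIds(store),
                         selections = selections, id = 1L,
                         name = "toy bundle")
  list(store = store, bundle = bundle, groundTruth = do.call(rbind, truth),
       outlierCells = outlierCells)
}

## --- toy template workbooks ------------------------------------------------

.toyTable <- function(spec) {
  set.seed(spec$seed)
  coatings <- .ALKYL_AMINES[1 + (seq_len(spec$nMaterials) - 1) %%
                              length(.ALKYL_AMINES)]
  materialNames <- sprintf("NM-%03d", seq_len(spec$nMaterials))
  rows <- list()
  for (k in seq_len(spec$nMaterials)) {
    for (r in seq_len(spec$replicates)) {
      vals <- vapply(spec$endpoints, function(ep)
        stats::rnorm(1, ep$mean, ep$sd), 0)
      rows[[length(rows) + 1L]] <- c(
        name = materialNames[k], core = "[Au]",
        coating = unname(coatings[k]),
        stats::setNames(sprintf("%.6g", vals), names(spec$endpoints)))
    }
  }
  hdr <- c("name", "core smiles", "coating smiles", names(spec$endpoints))
  m <- do.call(rbind, rows)
  dimnames(m) <- NULL
  rbind(hdr, m)
}

.toyConfig <- function(spec, layout) {
  locate <- function(what)
    if (layout == "COLUMN") list(row = what) else list(column = what)
  cfg <- list(
    templateName = paste0("toy-", tolower(layout)),
    idPrefix = "TOYS", layout = layout,
    substance = list(
      key = locate("name"), name = locate("name"),
      ownerName = list(literal = "fixture generator"),
      substanceType = list(literal = "gold nanoparticle"),
      composition = list(
        list(role = "CORE", name = list(literal = "gold"),
             smiles = locate("core smiles")),
        list(role = "COATING", smiles = locate("coating smiles")))),
    studies = lapply(names(spec$endpoints), function(epName) {
      ep <- spec$endpoints[[epName]]
      list(protocol = list(topcategory = "P-CHEM", category = ep$category,
                           endpoint = epName),
           endpoints = list(list(endpoint = epName, lo = locate(epName),
                                 unit = ep$unit)))
    }))
  if (layout == "BLOCK")
    cfg$blockMarkers <- list(start = "^#MATERIAL")
  cfg
}

#' Generate a toy template workbook with its mapping configuration
#'
#' Renders the same synthetic dataset as a ROW-layout sheet (records are
#' rows under a header), its exact transpose in COLUMN layout (records are
#' columns, labels in column 1), or a BLOCK layout (one marker-delimited
#' block of replicate rows per material), together with the matching
#' mapping configuration and the ground truth. Parsing any rendering
#' yields the same store, which is what the layout-equivalence tests
#' check.
#'
#' @param spec a [fixtureSpec()].
#' @param layout "ROW", "COLUMN" or "BLOCK".
#' @param dir directory for the CSV and config files; when NULL the sheet
#'   is returned in memory only.
#' @return list(sheet, config, file, configFile, groundTruth): ground
#'   truth has one row per (material, endpoint) with the expected
#'   replicate mean.
#' @export
genTemplateWorkbook <- function(spec = fixtureSpec(), layout = "ROW",
                                dir = NULL) {
  layout <- match.arg(layout, c("ROW", "COLUMN", "BLOCK"))
  base <- .toyTable(spec)   # ROW rendering incl. header
  sheet <- if (layout == "ROW") {
    base
  } else if (layout == "COLUMN") {
    t(base)
  } else {
    hdr <- base[1, , drop = FALSE]
    out <- hdr
    dataRows <- base[-1, , drop = FALSE]
    for (nm in unique(dataRows[, 1])) {
      marker <- matrix("", nrow = 1, ncol = ncol(base))
      marker[1, 1] <- paste0("#MATERIAL ", nm)
      out <- rbind(out, marker, dataRows[dataRows[, 1] == nm, , drop = FALSE])
    }
    out
  }
  config <- .toyConfig(spec, layout)
  ## ground truth: per-material per-endpoint replicate means
  dataRows <- base[-1, , drop = FALSE]
  truth <- do.call(rbind, lapply(unique(dataRows[, 1]), function(nm) {
    sub <- dataRows[dataRows[, 1] == nm, , drop = FALSE]
    data.frame(material = nm,
               endpoint = names(spec$endpoints),
               mean = vapply(seq_along(spec$endpoints), function(j)
                 mean(as.numeric(sub[, 3 + j])), 0),
               n = nrow(sub), stringsAsFactors = FALSE)
  }))
  file <- configFile <- NULL
  if (!is.null(dir)) {
    file <- file.path(dir, paste0("toy-", tolower(layout), ".csv"))
    utils::write.table(sheet, file, sep = ",", row.names = FALSE,
                       col.names = FALSE, qmethod = "double")
    configFile <- file.path(dir, paste0("toy-", tolower(layout), ".json"))
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, pretty = TRUE),
               configFile)
  }
  list(sheet = sheet, config = config, file = file, configFile = configFile,
       groundTruth = truth)
}

## --- random stores for the aggregation oracle ------------------------------

#' Random outlier-free stores for conjoiner oracle checks
#'
#' Draws a small store (at most \code{maxMeasurements} measurements) of
#' point-valued replicates whose replicate sets are rejection-sampled so
#' that Dixon screening at the given alpha excludes nothing -- the
#' generator's definition of an outlier-free store. On such stores the
#' matrix must equal a naive group-by-mean.
#'
#' @param seed integer seed.
#' @param maxMeasurements cap on total measurements.
#' @param alpha Dixon level the sets must survive.
#' @return list(store, bundle).
#' @export
genRandomStore <- function(seed, maxMeasurements = 50, alpha = 0.05) {
  set.seed(seed)
  endpointPool <- list(
    list(endpoint = "particle size", category = "PC_GRANULOMETRY_SECTION",
         unit = "nm", mean = 60, sd = 10),
    list(endpoint = "zeta potential", category = "ZETA_POTENTIAL_SECTION",
         unit = "mV", mean = -25, sd = 6),
    list(endpoint = "percentage viable cells",
         category = "TO_CYTOTOXICITY_SECTION", unit = "%", mean = 70,
         sd = 12))
  nSub <- sample(3:6, 1)
  store <- SubstanceStore()
  total <- 0L
  for (k in seq_len(nSub)) {
    nm <- sprintf("RND-%02d", k)
    uuid <- makeIdentifier("RNDS", paste0(seed, "|", nm))
    store <- addSubstance(store, Substance(uuid, name = nm,
                                           ownerName = "random fixture"))
    for (ep in endpointPool) {
      if (total >= maxMeasurements) break
      nRep <- sample(1:3, 1)
      nRep <- min(nRep, maxMeasurements - total)
      repeat {
        vals <- stats::rnorm(nRep, ep$mean, ep$sd)
        if (nRep < 3 ||
            nrow(dixonOutliers(vals, alpha)$excluded) == 0) break
      }
      conc <- sample(c(NA, 10, 100), 1)
      conds <- if (!is.na(conc))
        list(concentration = list(value = conc, unit = "ug/mL"))
      else list()
      effects <- lapply(vals, function(v)
        Measurement(ep$endpoint, loValue = v, unit = ep$unit,
                    conditions = conds))
      store <- addStudy(store, ProtocolApplication(
        uuid = makeIdentifier("RNDS",
                              paste(seed, nm, ep$endpoint, sep = "|")),
        substanceUuid = uuid,
        protocol = Protocol("P-CHEM", ep$category, ep$endpoint),
        effects = effects))
      total <- total + nRep
    }
  }
  selections <- lapply(endpointPool, function(ep)
    endpointSelection("P-CHEM", ep$category, ep$endpoint))
  bundle <- createBundle(store, substanceUuids = substanceIds(store),
                         selections = selections, id = 1L,
                         name = "random bundle")
  list(store = store, bundle = bundle)
}

## --- corona-like dataset ----------------------------------------------------

#' Generate a corona-like NanoQSAR dataset with known coefficients
#'
#' Emulates a library of surface-modified gold nanoparticles: each
#' particle gets a gold core, an amine coating, zeta potentials measured
#' after synthesis and after serum exposure (one endpoint, distinguished
#' by a \code{medium} condition), relative abundances of two adsorbed
#' serum proteins, and a net cell association generated on the log2 scale
#' as intercept + beta . features + Gaussian noise and stored on the
#' natural scale -- the log2 transform is applied back via a PMML derived
#' field, not hard-coded.
#'
#' @param spec a [fixtureSpec()]; \code{spec$corona} holds n, beta and
#'   noiseSd.
#' @param noiseSd override for the noise level (e.g. 0 for the noiseless
#'   variant).
#' @param seed override for the seed.
#' @param buildStore when FALSE only the design, target and truth are
#'   generated (fast path for repeated simulation); the store and bundle
#'   are NULL.
#' @return list(store, bundle, beta, features (true design data.frame),
#'   target (log2-scale truth + noise), pmml (XML text), alias (PMML
#'   field -> matrix column), featureNames.
#' @export
genCoronaLike <- function(spec = fixtureSpec(), noiseSd = NULL,
                          seed = NULL, buildStore = TRUE) {
  cor <- spec$corona
  if (!is.null(noiseSd)) cor$noiseSd <- noiseSd
  set.seed(seed %||% spec$seed)
  n <- cor$n
  beta <- cor$beta
  featureNames <- setdiff(names(beta), "(Intercept)")

  ## columns named after the PMML derived fields the model is fitted on
  X <- data.frame(
    zp_synth = stats::runif(n, -60, 40),
    zp_serum = stats::runif(n, -30, 5),
    ab_alb = stats::rlnorm(n, meanlog = -2, sdlog = 0.6),
    ab_apoa1 = stats::rlnorm(n, meanlog = -3, sdlog = 0.6),
    check.names = FALSE)
  yLog2 <- beta[["(Intercept)"]] +
    as.matrix(X) %*% beta[featureNames] +
    stats::rnorm(n, 0, cor$noiseSd)
  yLog2 <- as.numeric(yLog2)
  yNatural <- 2^yLog2

  pmml <- .coronaTrainingPMML()
  alias <- c(
    zeta_synthesis = "zeta potential@medium=after synthesis (mV)",
    zeta_serum = "zeta potential@medium=after serum exposure (mV)",
    abundance_ALB = "protein relative abundance@protein=ALB",
    abundance_APOA1 = "protein relative abundance@protein=APOA1",
    cell_association = "net cell association (a.u.)")
  featureNames <- setdiff(names(beta), "(Intercept)")
  rownames(X) <- vapply(sprintf("AuNP-%03d", seq_len(n)), function(nm)
    makeIdentifier("CRNA", nm), "")
  if (!isTRUE(buildStore))
    return(list(store = NULL, bundle = NULL, beta = beta, features = X,
                target = yLog2, pmml = pmml, alias = alias,
                featureNames = featureNames))

  coatings <- .ALKYL_AMINES[1 + (seq_len(n) - 1) %% length(.ALKYL_AMINES)]
  store <- SubstanceStore()
  for (i in seq_len(n)) {
    nm <- sprintf("AuNP-%03d", i)
    uuid <- makeIdentifier("CRNA", nm)
    store <- addSubstance(store, Substance(
      uuid, name = nm, ownerName = "corona fixture",
      substanceType = "gold nanoparticle",
      composition = list(
        Component("CORE", name = "gold", smiles = "[Au]"),
        Component("COATING", name = names(coatings)[i],
                  smiles = unname(coatings[i])))))
    addM <- function(st, endpoint, category, value, unit, conds = list()) {
      addStudy(st, ProtocolApplication(
        uuid = makeIdentifier("CRNA", paste(nm, endpoint,
                                            paste(unlist(conds),
                                                  collapse = ","),
                                            sep = "|")),
        substanceUuid = uuid,
        protocol = Protocol(
          if (endpoint == "net cell association") "TOX" else "P-CHEM",
          category, endpoint),
        effects = list(Measurement(endpoint, loValue = value, unit = unit,
                                   conditions = conds))))
    }
    store <- addM(store, "zeta potential", "ZETA_POTENTIAL_SECTION",
                  X$zp_synth[i], "mV",
                  list(medium = "after synthesis"))
    store <- addM(store, "zeta potential", "ZETA_POTENTIAL_SECTION",
                  X$zp_serum[i], "mV",
                  list(medium = "after serum exposure"))
    store <- addM(store, "protein relative abundance",
                  "PROTEOMICS_SECTION", X$ab_alb[i], "",
                  list(protein = "ALB"))
    store <- addM(store, "protein relative abundance",
                  "PROTEOMICS_SECTION", X$ab_apoa1[i], "",
                  list(protein = "APOA1"))
    store <- addM(store, "net cell association",
                  "TO_CELL_ASSOCIATION_SECTION", yNatural[i], "a.u.")
  }
  selections <- list(
    endpointSelection("P-CHEM", "ZETA_POTENTIAL_SECTION", "zeta potential",
                      conditions = "medium"),
    endpointSelection("P-CHEM", "PROTEOMICS_SECTION",
                      "protein relative abundance", conditions = "protein"),
    endpointSelection("TOX", "TO_CELL_ASSOCIATION_SECTION",
                      "net cell association", conditions = character(0)))
  bundle <- createBundle(store, substanceUuids = substanceIds(store),
                         selections = selections, id = 2L,
                         name = "corona bundle")

  list(store = store, bundle = bundle, beta = beta, features = X,
       target = yLog2, pmml = pmml, alias = alias,
       featureNames = featureNames)
}

## Training PMML: pass the four descriptors through and derive the
## log2-transformed cell association target.
.coronaTrainingPMML <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<PMML version="4.2" xmlns="http://www.dmg.org/PMML-4_2">\n',
    '  <DataDictionary numberOfFields="5">\n',
    '    <DataField name="zeta_synthesis" optype="continuous" dataType="double"/>\n',
    '    <DataField name="zeta_serum" optype="continuous" dataType="double"/>\n',
    '    <DataField name="abundance_ALB" optype="continuous" dataType="double"/>\n',
    '    <DataField name="abundance_APOA1" optype="continuous" dataType="double"/>\n',
    '    <DataField name="cell_association" optype="continuous" dataType="double"/>\n',
    '  </DataDictionary>\n',
    '  <TransformationDictionary>\n',
    '    <DerivedField name="zp_synth" optype="continuous" dataType="double">\n',
    '      <FieldRef field="zeta_synthesis"/>\n',
    '    </DerivedField>\n',
    '    <DerivedField name="zp_serum" optype="continuous" dataType="double">\n',
    '      <FieldRef field="zeta_serum"/>\n',
    '    </DerivedField>\n',
    '    <DerivedField name="ab_alb" optype="continuous" dataType="double">\n',
    '      <FieldRef field="abundance_ALB"/>\n',
    '    </DerivedField>\n',
    '    <DerivedField name="ab_apoa1" optype="continuous" dataType="double">\n',
    '      <FieldRef field="abundance_APOA1"/>\n',
    '    </DerivedField>\n',
    '    <DerivedField name="cell_association_log2" optype="continuous" dataType="double">\n',
    '      <Apply function="log2">\n',
    '        <FieldRef field="cell_association"/>\n',
    '      </Apply>\n',
    '    </DerivedField>\n',
    '  </TransformationDictionary>\n',
    '</PMML>\n')
}

#' Toy RDF/XML dump of a wiki-style nanomaterial knowledge base
#'
#' Writes a small RDF/XML document in the vocabulary of the default
#' predicate map, for exercising [importNanoWikiRDF()] without any
#' download. This is a synthetic stand-in, not an excerpt of any real
#' dump.
#'
#' @param nMaterials number of materials.
#' @param path output file; when NULL the XML text is returned.
#' @return the path (or XML text).
#' @export
genToyRDF <- function(nMaterials = 2, path = NULL) {
  ns <- "https://example.org/nanowiki#"
  mats <- vapply(seq_len(nMaterials), function(i) paste0(
    '  <rdf:Description rdf:about="', ns, 'material', i, '">\n',
    '    <rdfs:label>Toy oxide ', i, '</rdfs:label>\n',
    '    <nw:materialType>metal oxide</nw:materialType>\n',
    '    <nw:primaryParticleSize>', 20 + 5 * i, '</nw:primaryParticleSize>\n',
    '    <nw:zetaPotential>', -20 - i, '</nw:zetaPotential>\n',
    '    <nw:unmappedThing>ignored</nw:unmappedThing>\n',
    '    <dcterms:source>doi:10.1000/toy.', i, '</dcterms:source>\n',
    '  </rdf:Description>\n'), "")
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"\n',
    '         xmlns:dcterms="http://purl.org/dc/terms/"\n',
    '         xmlns:nw="', ns, '">\n',
    paste(mats, collapse = ""), '</rdf:RDF>\n')
  if (!is.null(path)) { writeLines(xml, path); return(invisible(path)) }
  xml
}
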