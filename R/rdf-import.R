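## Importer for wiki-style RDF/XML dumps of nanomaterial data. The dump
## vocabulary is not fixed, so the mapping from predicates to endpoints is
## itself a configuration file; a default map covering the toy vocabulary
## used by the fixture generator ships with the package.

.defaultPredicateMap <- function() {
  path <- system.file("extdata", "nanowiki-predicates.json",
                      package = "enmkit")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Import an RDF/XML nanomaterial dump
#'
#' Reads an RDF/XML document and maps each \code{rdf:Description} node with
#' a label to a substance; predicates listed in the predicate map's
#' \code{measurements} table become measurements with the configured
#' endpoint, category and unit, and the citation predicate populates the
#' study citation. Identifiers are minted from the resource IRI with the
#' map's prefix (default \code{"NWKI"}). Triples with unmapped predicates
#' are counted, not fatal.
#'
#' @param path RDF/XML file path or literal XML text.
#' @param predicateMap list as in
#'   \code{inst/extdata/nanowiki-predicates.json}; default map used when
#'   NULL.
#' @return list(substances, protocolApplications, log).
#' @export
importNanoWikiRDF <- function(path, predicateMap = NULL) {
  if (is.null(predicateMap)) predicateMap <- .defaultPredicateMap()
  doc <- xml2::read_xml(path)
  nsMap <- xml2::xml_ns(doc)
  rdfNs <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  prefix <- chr1(predicateMap$prefix, "NWKI")
  measMap <- predicateMap$measurements %||% list()
  labelPred <- chr1(predicateMap$labelPredicate,
                    "http://www.w3.org/2000/01/rdf-schema#label")
  typePred <- chr1(predicateMap$typePredicate)
  citePred <- chr1(predicateMap$citationPredicate,
                   "http://purl.org/dc/terms/source")

  expandName <- function(node) {
    ## resolve prefixed node name to a full predicate IRI
    qn <- xml2::xml_name(node, ns = nsMap)
    if (!grepl(":", qn, fixed = TRUE)) return(qn)
    parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
    uri <- unname(nsMap[parts[1]])
    if (is.na(uri) || is.null(uri)) qn else paste0(uri, parts[2])
  }

  substances <- list()
  pas <- list()
  unmapped <- 0L
  rdfPrefix <- names(nsMap)[nsMap == rdfNs][1]
  if (is.na(rdfPrefix))
    enmStop("document does not declare the RDF namespace",
            "enmkit_io_error")
  descr <- xml2::xml_find_all(doc,
                              paste0("//", rdfPrefix, ":Description"),
                              ns = nsMap)

  for (node in descr) {
    about <- xml2::xml_attr(node, "about")
    if (is.na(about)) next
    label <- NA_character_; stype <- NA_character_; cite <- NA_character_
    meas <- list()
    for (child in xml2::xml_children(node)) {
      pred <- expandName(child)
      val <- .trimCell(xml2::xml_text(child))
      if (pred == labelPred) label <- val
      else if (!is.na(typePred) && pred == typePred) stype <- val
      else if (pred == citePred) cite <- val
      else if (!is.null(measMap[[pred]])) {
        mm <- measMap[[pred]]
        num <- suppressWarnings(as.numeric(val))
        meas[[length(meas) + 1L]] <- list(
          endpoint = chr1(mm$endpoint), topcategory = chr1(mm$topcategory, "P-CHEM"),
          category = chr1(mm$category, ""), unit = chr1(mm$unit, ""),
          value = num, text = if (is.na(num)) val else NA_character_)
      } else unmapped <- unmapped + 1L
    }
    if (is.na(label) && length(meas) == 0) next
    uuid <- makeIdentifier(prefix, about)
    substances[[uuid]] <- Substance(uuid = uuid,
                                    name = chr1(label, about),
                                    substanceType = stype,
                                    ownerName = "nanowiki")
    for (k in seq_along(meas)) {
      mm <- meas[[k]]
      m <- if (!is.na(mm$value))
        Measurement(mm$endpoint, loValue = mm$value, unit = mm$unit)
      else Measurement(mm$endpoint, textValue = mm$text, unit = mm$unit)
      paUuid <- makeIdentifier(prefix, paste(about, mm$endpoint, sep = "|"))
      if (is.null(pas[[paUuid]])) {
        pas[[paUuid]] <- ProtocolApplication(
          uuid = paUuid, substanceUuid = uuid,
          protocol = Protocol(mm$topcategory, mm$category, mm$endpoint),
          effects = list(m),
          citation = list(title = cite, owner = "nanowiki"))
      } else {
        pa <- pas[[paUuid]]
        pa@effects <- c(pa@effects, list(m))
        pas[[paUuid]] <- pa
      }
    }
  }
  list(substances = substances[sort(names(substances))],
       protocolApplications = pas[sort(names(pas))],
       log = list(unmappedPredicates = unmapped))
}
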