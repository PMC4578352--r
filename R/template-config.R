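## JSON mapping configurations for the spreadsheet template parser.
##
## A configuration maps an arbitrary spreadsheet layout onto the data
## model. The keyword vocabulary (documented in the package vignette):
##
##   templateName  idPrefix  layout (ROW|COLUMN|BLOCK)  sheet  delimiter
##   blockMarkers {start, end}          -- dynamic-block layouts
##   sheetLinks  [{sheet, key}]         -- key-based joins across sheets
##   substance {key, name, publicName, ownerName, substanceType,
##              externalIds, composition [{role, name, smiles, inchi}]}
##   studies [{sheet, protocol {topcategory, category, endpoint,
##              guideline, annotationIri},
##             parameters {..}, conditions {..},
##             endpoints [{endpoint, endpointIri, lo, up, error, text,
##                         unit, loQualifier, upQualifier, errQualifier,
##                         conditions {..}}]}]
##
## Every mapped cell is located by exactly one locator keyword:
##   {"cell": "B2"}          fixed cell (A1 notation)
##   {"column": name|index}  column, record = row (ROW/BLOCK layouts)
##   {"row": label|index}    row, record = column (COLUMN layout)
##   {"anchor": {"rowOffset": r, "colOffset": c}}  relative to block anchor
##   {"literal": value}      constant, no cell read

.LOCATOR_KEYS <- c("cell", "column", "row", "anchor", "literal")

.KEYWORDS <- list(
  top = c("templateName", "idPrefix", "layout", "sheet", "delimiter",
          "blockMarkers", "sheetLinks", "substance", "studies"),
  blockMarkers = c("start", "end"),
  sheetLink = c("sheet", "key"),
  substance = c("key", "name", "publicName", "ownerName", "substanceType",
                "externalIds", "composition"),
  component = c("role", "name", "smiles", "inchi"),
  study = c("sheet", "protocol", "parameters", "conditions", "endpoints"),
  protocol = c("topcategory", "category", "endpoint", "guideline",
               "annotationIri"),
  endpoint = c("endpoint", "endpointIri", "lo", "up", "error", "text",
               "unit", "loQualifier", "upQualifier", "errQualifier",
               "conditions"),
  anchor = c("rowOffset", "colOffset"))

#' @rdname loadConfig
#' @export
setClass("TemplateConfig", representation(config = "list"))

.configStop <- function(msg) enmStop(msg, "enmkit_config_error")

.checkKeywords <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    .configStop(sprintf("unknown keyword '%s' in %s", unknown[1], where))
}

.isLocator <- function(x)
  is.list(x) && length(intersect(names(x), .LOCATOR_KEYS)) > 0

.checkLocator <- function(x, layout, where) {
  if (!is.list(x))
    .configStop(sprintf("%s: locator must be an object with one of %s",
                        where, paste(.LOCATOR_KEYS, collapse = ", ")))
  .checkKeywords(x, .LOCATOR_KEYS, where)
  hits <- intersect(names(x), .LOCATOR_KEYS)
  if (length(hits) != 1)
    .configStop(sprintf("%s: locator must use exactly one of %s",
                        where, paste(.LOCATOR_KEYS, collapse = ", ")))
  if (hits == "row" && layout == "ROW")
    .configStop(sprintf("%s: a 'row' locator contradicts ROW layout (records are rows)",
                        where))
  if (hits == "column" && layout == "COLUMN")
    .configStop(sprintf("%s: a 'column' locator contradicts COLUMN layout (records are columns)",
                        where))
  if (hits == "anchor") {
    if (layout != "BLOCK")
      .configStop(sprintf("%s: 'anchor' locators require BLOCK layout", where))
    .checkKeywords(x$anchor, .KEYWORDS$anchor, paste0(where, ".anchor"))
  }
  if (hits == "cell") cellToRC(x$cell)  # validates A1 notation
  invisible(TRUE)
}

.checkLocatorMap <- function(x, layout, where) {
  for (nm in names(x))
    .checkLocator(x[[nm]], layout, paste0(where, ".", nm))
}

#' Load and validate a template mapping configuration
#'
#' Reads a JSON mapping configuration (see the vignette for the keyword
#' vocabulary) and validates every keyword, locator and the consistency of
#' locators with the declared layout: a \code{row} locator is rejected
#' under ROW layout, a \code{column} locator under COLUMN layout, and
#' \code{anchor} locators are only allowed for BLOCK layouts.
#'
#' @param doc path to a JSON file, a JSON string, or an equivalent list.
#' @return a validated \code{TemplateConfig}.
#' @export
loadConfig <- function(doc) {
  if (is.character(doc)) {
    txt <- if (length(doc) == 1 && file.exists(doc))
      paste(readLines(doc, warn = FALSE), collapse = "\n") else doc
    doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  }
  if (!is.list(doc)) .configStop("configuration must be a JSON object")
  .checkKeywords(doc, .KEYWORDS$top, "configuration")
  layout <- chr1(doc$layout, "ROW")
  if (!(layout %in% c("ROW", "COLUMN", "BLOCK")))
    .configStop(sprintf("layout must be ROW, COLUMN or BLOCK, got '%s'",
                        layout))
  doc$layout <- layout
  prefix <- chr1(doc$idPrefix, "")
  if (!grepl("^[A-Z0-9]{4}$", prefix))
    .configStop("idPrefix must be a 4-character code matching [A-Z0-9]{4}")
  if (!is.null(doc$blockMarkers)) {
    .checkKeywords(doc$blockMarkers, .KEYWORDS$blockMarkers, "blockMarkers")
    if (!isNonEmptyString(chr1(doc$blockMarkers$start)))
      .configStop("blockMarkers.start must be a pattern")
  }
  if (!is.null(doc$sheetLinks)) {
    for (i in seq_along(doc$sheetLinks)) {
      lk <- doc$sheetLinks[[i]]
      .checkKeywords(lk, .KEYWORDS$sheetLink, sprintf("sheetLinks[%d]", i))
      if (!isNonEmptyString(chr1(lk$sheet)))
        .configStop(sprintf("sheetLinks[%d] needs a sheet name", i))
      .checkLocator(lk$key, layout, sprintf("sheetLinks[%d].key", i))
    }
  }
  if (is.null(doc$substance)) .configStop("configuration needs a substance block")
  .checkKeywords(doc$substance, .KEYWORDS$substance, "substance")
  if (is.null(doc$substance$key)) .configStop("substance.key locator is required")
  .checkLocator(doc$substance$key, layout, "substance.key")
  for (nm in intersect(names(doc$substance),
                       c("name", "publicName", "ownerName", "substanceType")))
    .checkLocator(doc$substance[[nm]], layout, paste0("substance.", nm))
  if (!is.null(doc$substance$externalIds))
    .checkLocatorMap(doc$substance$externalIds, layout,
                     "substance.externalIds")
  for (i in seq_along(doc$substance$composition)) {
    comp <- doc$substance$composition[[i]]
    where <- sprintf("substance.composition[%d]", i)
    .checkKeywords(comp, .KEYWORDS$component, where)
    if (!isNonEmptyString(chr1(comp$role)) ||
        !(comp$role %in% .COMPONENT_ROLES))
      .configStop(paste0(where, ": role must be one of ",
                         paste(.COMPONENT_ROLES, collapse = ", ")))
    for (nm in intersect(names(comp), c("name", "smiles", "inchi")))
      .checkLocator(comp[[nm]], layout, paste0(where, ".", nm))
  }
  if (is.null(doc$studies) || length(doc$studies) == 0)
    .configStop("configuration needs at least one study mapping")
  for (i in seq_along(doc$studies)) {
    st <- doc$studies[[i]]
    where <- sprintf("studies[%d]", i)
    .checkKeywords(st, .KEYWORDS$study, where)
    if (is.null(st$protocol)) .configStop(paste0(where, " needs a protocol"))
    .checkKeywords(st$protocol, .KEYWORDS$protocol, paste0(where, ".protocol"))
    if (!is.null(st$parameters))
      .checkLocatorMap(st$parameters, layout, paste0(where, ".parameters"))
    if (!is.null(st$conditions))
      .checkLocatorMap(st$conditions, layout, paste0(where, ".conditions"))
    if (is.null(st$endpoints) || length(st$endpoints) == 0)
      .configStop(paste0(where, " needs at least one endpoint mapping"))
    for (j in seq_along(st$endpoints)) {
      ep <- st$endpoints[[j]]
      ewhere <- sprintf("%s.endpoints[%d]", where, j)
      .checkKeywords(ep, .KEYWORDS$endpoint, ewhere)
      if (!isNonEmptyString(chr1(ep$endpoint)))
        .configStop(paste0(ewhere, " needs an endpoint name"))
      valueLocs <- intersect(names(ep), c("lo", "up", "error", "text"))
      if (length(valueLocs) == 0)
        .configStop(paste0(ewhere, " maps no value locator (lo/up/error/text)"))
      for (nm in valueLocs)
        .checkLocator(ep[[nm]], layout, paste0(ewhere, ".", nm))
      if (!is.null(ep$unit) && .isLocator(ep$unit))
        .checkLocator(ep$unit, layout, paste0(ewhere, ".unit"))
      if (!is.null(ep$conditions))
        .checkLocatorMap(ep$conditions, layout, paste0(ewhere, ".conditions"))
      nms <- names(ep$conditions)
      if (anyDuplicated(nms))
        .configStop(paste0(ewhere, ": condition names must be unique"))
    }
  }
  new("TemplateConfig", config = doc)
}

setMethod("show", "TemplateConfig", function(object) {
  cat(sprintf("TemplateConfig '%s' (%s layout, prefix %s): %d study mapping(s)\n",
              chr1(object@config$templateName, "?"), object@config$layout,
              object@config$idPrefix, length(object@config$studies)))
})
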