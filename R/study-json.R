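## Stable JSON serialization of protocol applications. Keys are camelCase
## (loValue/upValue/errorValue ...), key order is fixed by construction and
## missing numeric fields are emitted as null rather than omitted so that
## downstream column alignment is stable.

.valueMapToList <- function(x) {
  if (length(x) == 0) return(stats::setNames(list(), character(0)))
  lapply(x, function(v) list(value = v$value %||% NA,
                             unit = chr1(v$unit, "")))
}

.measurementToList <- function(m) {
  list(
    endpoint = m@endpoint,
    endpointIri = m@endpointIri,
    conditions = .valueMapToList(m@conditions),
    result = list(
      loQualifier = m@loQualifier, loValue = m@loValue,
      upQualifier = m@upQualifier, upValue = m@upValue,
      errQualifier = m@errQualifier, errorValue = m@errorValue,
      unit = m@unit, textValue = m@textValue))
}

studyToList <- function(pa) {
  list(
    uuid = pa@uuid,
    substanceUuid = pa@substanceUuid,
    protocol = list(
      topcategory = pa@protocol@topcategory,
      category = pa@protocol@category,
      endpoint = pa@protocol@endpoint,
      guideline = as.list(pa@protocol@guideline),
      annotationIri = pa@protocol@annotationIri),
    parameters = .valueMapToList(pa@parameters),
    citation = list(title = chr1(pa@citation$title),
                    year = int1(pa@citation$year),
                    owner = chr1(pa@citation$owner)),
    reliability = list(value = pa@reliability,
                       purposeFlag = chr1(pa@reliabilityFlags$purposeFlag),
                       studyResultType = chr1(pa@reliabilityFlags$studyResultType)),
    effects = lapply(pa@effects, .measurementToList))
}

#' Serialize a protocol application to JSON
#'
#' Emits the study document shape used throughout the toolkit: a protocol
#' block, parameters, citation, reliability (Klimisch score and flags) and
#' an \code{effects} array whose entries carry endpoint, conditions and a
#' result object with keys loQualifier/loValue/upQualifier/upValue/
#' errQualifier/errorValue/unit/textValue. Parsing the output with
#' [parseStudy()] reproduces the input object. The schema is shipped at
#' \code{system.file("schema", "study.schema.json", package = "enmkit")}.
#'
#' @param pa a [ProtocolApplication()].
#' @param pretty pretty-print the JSON.
#' @return character scalar with the JSON document.
#' @export
serializeStudy <- function(pa, pretty = FALSE) {
  stopifnot(is(pa, "ProtocolApplication"))
  as.character(jsonlite::toJSON(studyToList(pa), auto_unbox = TRUE,
                                null = "null", na = "null", digits = NA,
                                pretty = pretty))
}

.schemaStop <- function(path, what = "missing required element") {
  enmStop(sprintf("study document schema error at %s: %s", path, what),
          "enmkit_schema_error")
}

.parseValueMap <- function(x) {
  if (is.null(x) || length(x) == 0) return(list())
  lapply(x, function(v) {
    if (is.list(v) && !is.null(names(v)))
      list(value = v$value, unit = chr1(v$unit, ""))
    else list(value = v, unit = "")
  })
}

.parseMeasurement <- function(e, path) {
  if (is.null(e$endpoint)) .schemaStop(paste0(path, ".endpoint"))
  r <- e$result
  if (is.null(r)) .schemaStop(paste0(path, ".result"))
  Measurement(endpoint = e$endpoint, endpointIri = chr1(e$endpointIri),
              conditions = .parseValueMap(e$conditions),
              loQualifier = chr1(r$loQualifier), loValue = num1(r$loValue),
              upQualifier = chr1(r$upQualifier), upValue = num1(r$upValue),
              errQualifier = chr1(r$errQualifier),
              errorValue = num1(r$errorValue),
              unit = chr1(r$unit, ""), textValue = chr1(r$textValue))
}

.KNOWN_STUDY_KEYS <- c("uuid", "substanceUuid", "protocol", "parameters",
                       "citation", "reliability", "effects")

#' Parse a study JSON document
#'
#' Inverse of [serializeStudy()]. Unknown top-level keys are preserved in
#' the \code{extras} slot. Structural problems raise an error of class
#' \code{enmkit_schema_error} naming the JSON path; a Klimisch score
#' outside \code{{1,2,3,4}} raises \code{enmkit_validation_error}.
#'
#' @param doc JSON text, or an already-parsed list.
#' @return a [ProtocolApplication()].
#' @export
parseStudy <- function(doc) {
  if (is.character(doc))
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  if (is.null(doc$protocol)) .schemaStop("$.protocol")
  if (!isNonEmptyString(chr1(doc$protocol$endpoint)))
    .schemaStop("$.protocol.endpoint", "missing or empty endpoint")
  if (is.null(doc$effects) || length(doc$effects) == 0)
    .schemaStop("$.effects", "missing or empty effects array")
  rel <- doc$reliability
  relValue <- int1(if (is.list(rel)) rel$value else rel)
  if (!is.na(relValue) && !(relValue %in% 1:4))
    enmStop(sprintf("reliability (Klimisch score) must be in {1,2,3,4}, got %s",
                    relValue), "enmkit_validation_error")
  effects <- lapply(seq_along(doc$effects), function(i)
    .parseMeasurement(doc$effects[[i]], sprintf("$.effects[%d]", i)))
  guide <- doc$protocol$guideline
  protocol <- Protocol(
    topcategory = chr1(doc$protocol$topcategory, "P-CHEM"),
    category = chr1(doc$protocol$category, ""),
    endpoint = doc$protocol$endpoint,
    guideline = if (length(guide)) unlist(guide, use.names = FALSE)
                else character(0),
    annotationIri = chr1(doc$protocol$annotationIri))
  extras <- doc[setdiff(names(doc), .KNOWN_STUDY_KEYS)]
  if (length(extras) == 0) extras <- list()
  ProtocolApplication(
    uuid = chr1(doc$uuid), substanceUuid = chr1(doc$substanceUuid),
    protocol = protocol, effects = effects,
    parameters = .parseValueMap(doc$parameters),
    citation = list(title = chr1(doc$citation$title),
                    year = int1(doc$citation$year),
                    owner = chr1(doc$citation$owner)),
    reliability = relValue,
    reliabilityFlags = list(
      purposeFlag = chr1(if (is.list(rel)) rel$purposeFlag else NULL),
      studyResultType = chr1(if (is.list(rel)) rel$studyResultType else NULL)),
    extras = extras)
}
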