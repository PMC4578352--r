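## Core data model: substances with composition, protocol applications and
## measurements. Nanomaterials are represented as substances whose
## composition lists a core plus coatings/functionalisations; experimental
## results hang off protocol applications, never off bare structures.

.COMPONENT_ROLES <- c("CORE", "COATING", "FUNCTIONALISATION",
                      "CONSTITUENT", "ADDITIVE", "IMPURITY")
.TOPCATEGORIES <- c("P-CHEM", "TOX", "ECOTOX", "ENV-FATE")

#' @rdname Component
#' @export
setClass("Component",
  representation(role = "character", name = "character",
                 smiles = "character", inchi = "character",
                 proportion = "list"),
  prototype(role = "CONSTITUENT", name = NA_character_,
            smiles = NA_character_, inchi = NA_character_,
            proportion = list()),
  validity = function(object) {
    if (!(object@role %in% .COMPONENT_ROLES))
      return(sprintf("role must be one of %s",
                     paste(.COMPONENT_ROLES, collapse = ", ")))
    if (is.na(object@name) && is.na(object@smiles) && is.na(object@inchi))
      return("a component needs at least a name or a structure (SMILES/InChI)")
    TRUE
  })

#' A component of a substance's composition
#'
#' A substance (nanomaterial) is composed of components, each with a role
#' (core, coating, functionalisation, ...) and optionally a chemical
#' structure given as SMILES and/or InChI. The proportion, when known, is a
#' list with elements \code{lo}, \code{up}, \code{typical} and \code{unit}.
#'
#' @param role one of CORE, COATING, FUNCTIONALISATION, CONSTITUENT,
#'   ADDITIVE, IMPURITY.
#' @param name component name (optional if a structure is given).
#' @param smiles,inchi structure notations (optional if a name is given).
#' @param proportion optional list(lo, up, typical, unit).
#' @return a \code{Component} object.
#' @examples
#' Component("CORE", name = "gold", smiles = "[Au]")
#' @export
Component <- function(role, name = NA_character_, smiles = NA_character_,
                      inchi = NA_character_, proportion = list()) {
  new("Component", role = chr1(role), name = chr1(name),
      smiles = chr1(smiles), inchi = chr1(inchi), proportion = proportion)
}

#' @rdname Protocol
#' @export
setClass("Protocol",
  representation(topcategory = "character", category = "character",
                 endpoint = "character", guideline = "character",
                 annotationIri = "character"),
  prototype(topcategory = "P-CHEM", category = "", endpoint = "",
            guideline = character(0), annotationIri = NA_character_),
  validity = function(object) {
    if (!(object@topcategory %in% .TOPCATEGORIES))
      return(sprintf("topcategory must be one of %s",
                     paste(.TOPCATEGORIES, collapse = ", ")))
    if (!isNonEmptyString(object@endpoint))
      return("protocol endpoint must be non-empty")
    TRUE
  })

#' Test protocol description
#'
#' Identifies what was measured: the top category (physicochemical,
#' toxicity, ecotoxicity or environmental fate), a category corresponding
#' to a harmonized-template section (e.g. granulometry, zeta potential),
#' the endpoint name, and optionally the guidelines followed and an
#' ontology IRI annotation.
#'
#' @param topcategory one of P-CHEM, TOX, ECOTOX, ENV-FATE.
#' @param category section-like category text, e.g.
#'   \code{"PC_GRANULOMETRY_SECTION"}.
#' @param endpoint endpoint name, non-empty.
#' @param guideline character vector of guideline references.
#' @param annotationIri optional ontology IRI.
#' @return a \code{Protocol} object.
#' @export
Protocol <- function(topcategory, category = "", endpoint = "",
                     guideline = character(0),
                     annotationIri = NA_character_) {
  new("Protocol", topcategory = chr1(topcategory),
      category = chr1(category, ""), endpoint = chr1(endpoint),
      guideline = as.character(guideline), annotationIri = chr1(annotationIri))
}

#' @rdname Measurement
#' @export
setClass("Measurement",
  representation(endpoint = "character", endpointIri = "character",
                 conditions = "list",
                 loQualifier = "character", loValue = "numeric",
                 upQualifier = "character", upValue = "numeric",
                 errQualifier = "character", errorValue = "numeric",
                 unit = "character", textValue = "character"),
  prototype(endpoint = "", endpointIri = NA_character_, conditions = list(),
            loQualifier = NA_character_, loValue = NA_real_,
            upQualifier = NA_character_, upValue = NA_real_,
            errQualifier = NA_character_, errorValue = NA_real_,
            unit = "", textValue = NA_character_),
  validity = function(object) {
    if (!isNonEmptyString(object@endpoint))
      return("measurement endpoint must be non-empty")
    if (is.na(object@loValue) && is.na(object@upValue) &&
        is.na(object@textValue))
      return("measurement needs at least one of loValue, upValue, textValue")
    if (!is.na(object@loValue) && !is.na(object@upValue) &&
        object@loValue > object@upValue)
      return("loValue must be <= upValue")
    if (!is.na(object@errorValue) && object@errorValue < 0)
      return("errorValue must be >= 0")
    if (length(object@conditions) &&
        is.null(names(object@conditions)))
      return("conditions must be a named list")
    TRUE
  })

## Normalize a conditions/parameters map: every entry becomes
## list(value =, unit =).
normalizeValueMap <- function(x) {
  if (length(x) == 0) return(list())
  out <- lapply(x, function(v) {
    if (is.list(v)) list(value = v$value, unit = chr1(v$unit, ""))
    else list(value = v, unit = "")
  })
  names(out) <- names(x)
  out
}

#' One endpoint readout
#'
#' A measurement carries a single result for an endpoint under named
#' experimental conditions (concentration, exposure time, cell line,
#' size-distribution percentile, ...). The result is either a single value
#' (\code{loValue} with qualifier \code{"="}), an interval
#' (\code{loValue}/\code{upValue} with \code{">="}/\code{"<="} qualifiers),
#' a value with a measurement error, or a text value such as a link to a
#' raw data file.
#'
#' Qualifiers default to \code{"="} for a single value and to
#' \code{">="}/\code{"<="} for an interval.
#'
#' @param endpoint endpoint name.
#' @param loValue,upValue numeric bounds (either may be missing).
#' @param loQualifier,upQualifier comparison qualifiers.
#' @param errorValue non-negative measurement error.
#' @param errQualifier error qualifier text (e.g. \code{"SD"}).
#' @param unit unit text; \code{""} when dimensionless or unknown.
#' @param textValue text result or raw-data file reference.
#' @param conditions named list of conditions; values may be atomic or
#'   \code{list(value =, unit =)}.
#' @param endpointIri optional ontology IRI for the endpoint.
#' @return a \code{Measurement} object.
#' @examples
#' Measurement("zeta potential", loValue = -30, unit = "mV")
#' Measurement("particle size", loValue = 40, upValue = 60, unit = "nm",
#'             conditions = list(percentile = "D50"))
#' @export
Measurement <- function(endpoint, loValue = NA_real_, upValue = NA_real_,
                        loQualifier = NA_character_,
                        upQualifier = NA_character_,
                        errorValue = NA_real_, errQualifier = NA_character_,
                        unit = "", textValue = NA_character_,
                        conditions = list(), endpointIri = NA_character_) {
  loValue <- num1(loValue); upValue <- num1(upValue)
  loQualifier <- chr1(loQualifier); upQualifier <- chr1(upQualifier)
  if (!is.na(loValue) && !is.na(upValue)) {
    if (is.na(loQualifier)) loQualifier <- ">="
    if (is.na(upQualifier)) upQualifier <- "<="
  } else if (!is.na(loValue)) {
    if (is.na(loQualifier)) loQualifier <- "="
  } else if (!is.na(upValue)) {
    if (is.na(upQualifier)) upQualifier <- "<="
  }
  new("Measurement", endpoint = chr1(endpoint), endpointIri = chr1(endpointIri),
      conditions = normalizeValueMap(conditions),
      loQualifier = loQualifier, loValue = loValue,
      upQualifier = upQualifier, upValue = upValue,
      errQualifier = chr1(errQualifier), errorValue = num1(errorValue),
      unit = chr1(unit, ""), textValue = chr1(textValue))
}

#' @rdname ProtocolApplication
#' @export
setClass("ProtocolApplication",
  representation(uuid = "character", substanceUuid = "character",
                 protocol = "Protocol", parameters = "list",
                 citation = "list", reliability = "integer",
                 reliabilityFlags = "list", effects = "list",
                 extras = "list"),
  prototype(uuid = NA_character_, substanceUuid = NA_character_,
            parameters = list(), citation = list(),
            reliability = NA_integer_, reliabilityFlags = list(),
            effects = list(), extras = list()),
  validity = function(object) {
    if (!isPrefixedIdentifier(object@uuid))
      return("protocol application uuid must be a prefixed identifier")
    if (!is.na(object@reliability) && !(object@reliability %in% 1:4))
      return("reliability (Klimisch score) must be in {1,2,3,4}")
    if (!all(vapply(object@effects, is, TRUE, class2 = "Measurement")))
      return("effects must be a list of Measurement objects")
    TRUE
  })

#' One application of a test protocol to a substance
#'
#' Records the protocol, its parameters, the literature citation, the
#' Klimisch reliability score (1 = reliable without restrictions, 2 =
#' reliable with restrictions, 3 = not reliable, 4 = not assignable) and
#' the set of resulting measurements.
#'
#' @param uuid prefixed identifier (see [makeIdentifier()]).
#' @param substanceUuid identifier of the substance studied.
#' @param protocol a [Protocol()].
#' @param effects list of [Measurement()] objects.
#' @param parameters named list of protocol parameters (atomic values or
#'   \code{list(value =, unit =)}).
#' @param citation list with elements \code{title}, \code{year},
#'   \code{owner}.
#' @param reliability Klimisch score in \code{1:4}, or \code{NA}.
#' @param reliabilityFlags optional list of purpose/study flags.
#' @param extras unknown keys preserved from parsed JSON documents.
#' @return a \code{ProtocolApplication} object.
#' @export
ProtocolApplication <- function(uuid, substanceUuid, protocol,
                                effects = list(), parameters = list(),
                                citation = list(), reliability = NA,
                                reliabilityFlags = list(), extras = list()) {
  new("ProtocolApplication", uuid = chr1(uuid),
      substanceUuid = chr1(substanceUuid), protocol = protocol,
      parameters = normalizeValueMap(parameters),
      citation = list(title = chr1(citation$title),
                      year = int1(citation$year),
                      owner = chr1(citation$owner)),
      reliability = int1(reliability),
      reliabilityFlags = list(
        purposeFlag = chr1(reliabilityFlags$purposeFlag),
        studyResultType = chr1(reliabilityFlags$studyResultType)),
      effects = effects, extras = extras)
}

#' @rdname Substance
#' @export
setClass("Substance",
  representation(uuid = "character", name = "character",
                 publicName = "character", substanceType = "character",
                 ownerName = "character",
                 referenceSubstanceUuid = "character",
                 externalIds = "list", composition = "list"),
  prototype(uuid = NA_character_, name = NA_character_,
            publicName = NA_character_, substanceType = NA_character_,
            ownerName = NA_character_,
            referenceSubstanceUuid = NA_character_,
            externalIds = list(), composition = list()),
  validity = function(object) {
    if (!isPrefixedIdentifier(object@uuid))
      return("substance uuid must be a prefixed identifier")
    if (!all(vapply(object@composition, is, TRUE, class2 = "Component")))
      return("composition must be a list of Component objects")
    if (length(object@externalIds)) {
      systems <- vapply(object@externalIds, function(e) chr1(e$system, ""), "")
      if (anyDuplicated(systems))
        return("external id systems must be unique per substance")
    }
    TRUE
  })

#' A substance (nanomaterial) record
#'
#' Nanomaterials are stored as substances: an identified material with an
#' owner (manufacturer or source file), a type label or ontology IRI, a
#' composition (list of [Component()]), identifiers in external systems,
#' and a reference to the chemical structure of the main component.
#'
#' @param uuid prefixed identifier (see [makeIdentifier()]).
#' @param name substance name.
#' @param publicName public name, defaults to \code{name}.
#' @param substanceType type label or ontology IRI (e.g. nanoparticle type).
#' @param ownerName manufacturer or source-file name.
#' @param referenceSubstanceUuid identifier of the main-component
#'   structure.
#' @param externalIds list of \code{list(system =, value =)} pairs, systems
#'   unique.
#' @param composition list of [Component()] objects (may be empty).
#' @return a \code{Substance} object.
#' @examples
#' Substance(makeIdentifier("TOYS", "G15.AC"), name = "G15.AC",
#'           composition = list(Component("CORE", smiles = "[Au]")))
#' @export
Substance <- function(uuid, name = NA_character_, publicName = name,
                      substanceType = NA_character_,
                      ownerName = NA_character_,
                      referenceSubstanceUuid = NA_character_,
                      externalIds = list(), composition = list()) {
  new("Substance", uuid = chr1(uuid), name = chr1(name),
      publicName = chr1(publicName), substanceType = chr1(substanceType),
      ownerName = chr1(ownerName),
      referenceSubstanceUuid = chr1(referenceSubstanceUuid),
      externalIds = externalIds, composition = composition)
}

#' @rdname SubstanceStore
#' @export
setClass("SubstanceStore",
  representation(substances = "list", studies = "list"),
  prototype(substances = list(), studies = list()),
  validity = function(object) {
    subUuids <- names(object@substances)
    for (pa in object@studies)
      if (!(pa@substanceUuid %in% subUuids))
        return(sprintf("study %s references unknown substance %s",
                       pa@uuid, pa@substanceUuid))
    TRUE
  })

#' In-memory substance store
#'
#' Holds substances keyed by uuid and protocol applications keyed by uuid,
#' with referential integrity between the two. All listings are sorted by
#' uuid so query results never depend on insertion order.
#'
#' @return an empty \code{SubstanceStore}.
#' @seealso [addSubstance()], [addStudy()], [endpointSummary()]
#' @export
SubstanceStore <- function() new("SubstanceStore")
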