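#' @rdname createBundle
#' @export
setClass("Bundle",
  representation(id = "integer", name = "character",
                 substanceUuids = "character", selections = "list"),
  prototype(id = NA_integer_, name = "", substanceUuids = character(0),
            selections = list()),
  validity = function(object) {
    if (anyDuplicated(object@substanceUuids))
      return("bundle substance uuids must be unique")
    sigs <- vapply(object@selections, .selectionSignature, "")
    if (anyDuplicated(sigs))
      return("bundle endpoint selections must be unique")
    TRUE
  })

## Default distinguishing conditions: measurements that differ in any of
## these are put in different matrix columns.
.DEFAULT_DISTINGUISHING <- c("concentration", "exposure time", "cell line",
                             "percentile")

#' Describe one endpoint selection of a bundle
#'
#' @param topcategory,category,endpoint protocol coordinates of the
#'   endpoint.
#' @param conditions names of the conditions that distinguish matrix
#'   columns for this endpoint; defaults to concentration, exposure time,
#'   cell line and percentile.
#' @return a list usable in [createBundle()].
#' @export
endpointSelection <- function(topcategory, category, endpoint,
                              conditions = .DEFAULT_DISTINGUISHING) {
  list(topcategory = chr1(topcategory), category = chr1(category, ""),
       endpoint = chr1(endpoint), conditions = as.character(conditions))
}

.selectionSignature <- function(sel) {
  paste(sel$topcategory, sel$category, sel$endpoint,
        paste(sort(sel$conditions), collapse = ","), sep = "|")
}

#' Bundles: selected substances and endpoints
#'
#' A bundle names an ordered set of substances and an ordered set of
#' endpoint selections; [buildMatrix()] turns it into a modelling matrix.
#' Selecting an already-present item is a no-op (set semantics) and
#' deselecting an absent one leaves the bundle unchanged.
#'
#' @param store a [SubstanceStore()]; membership is validated against it.
#' @param substanceUuids character vector of substance identifiers.
#' @param selections list of [endpointSelection()] entries.
#' @param id,name bundle metadata.
#' @return a \code{Bundle}.
#' @export
createBundle <- function(store, substanceUuids = character(0),
                         selections = list(), id = 1L, name = "bundle") {
  unknown <- setdiff(substanceUuids, names(store@substances))
  if (length(unknown))
    enmStop(paste0("unknown substance uuid(s): ",
                   paste(unknown, collapse = ", ")),
            "enmkit_notfound_error")
  new("Bundle", id = as.integer(id), name = chr1(name, "bundle"),
      substanceUuids = unique(as.character(substanceUuids)),
      selections = selections)
}

#' @describeIn createBundle add a substance (no-op when present).
#' @param bundle a \code{Bundle}.
#' @param uuid substance identifier to (de)select.
#' @export
selectSubstance <- function(bundle, uuid, store = NULL) {
  if (!is.null(store) && !(uuid %in% names(store@substances)))
    enmStop(paste0("unknown substance uuid(s): ", uuid),
            "enmkit_notfound_error")
  if (!(uuid %in% bundle@substanceUuids))
    bundle@substanceUuids <- c(bundle@substanceUuids, uuid)
  bundle
}

#' @describeIn createBundle remove a substance (no-op when absent).
#' @export
deselectSubstance <- function(bundle, uuid) {
  bundle@substanceUuids <- setdiff(bundle@substanceUuids, uuid)
  bundle
}

#' @describeIn createBundle add an endpoint selection (no-op when present).
#' @param selection an [endpointSelection()].
#' @export
selectEndpoint <- function(bundle, selection) {
  sigs <- vapply(bundle@selections, .selectionSignature, "")
  if (!(.selectionSignature(selection) %in% sigs))
    bundle@selections <- c(bundle@selections, list(selection))
  bundle
}

#' @describeIn createBundle remove an endpoint selection (no-op when
#'   absent).
#' @export
deselectEndpoint <- function(bundle, selection) {
  sigs <- vapply(bundle@selections, .selectionSignature, "")
  bundle@selections <- bundle@selections[sigs != .selectionSignature(selection)]
  bundle
}

setMethod("show", "Bundle", function(object) {
  cat(sprintf("Bundle %d '%s': %d substances, %d endpoint selections\n",
              object@id, object@name, length(object@substanceUuids),
              length(object@selections)))
})
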