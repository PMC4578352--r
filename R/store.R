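#' Add or replace a substance in a store
#'
#' Inserting a substance whose uuid is already present replaces the record
#' (imports are idempotent). \code{clearComposition} resets the stored
#' composition even when the incoming record has none;
#' \code{clearStudies} drops all protocol applications of that substance,
#' mirroring the two checkboxes of a data-upload form.
#'
#' @param store a [SubstanceStore()].
#' @param substance a [Substance()].
#' @param clearComposition,clearStudies logical flags, see above.
#' @return the updated store.
#' @export
addSubstance <- function(store, substance, clearComposition = FALSE,
                         clearStudies = FALSE) {
  stopifnot(is(store, "SubstanceStore"), is(substance, "Substance"))
  if (isTRUE(clearComposition)) {
    old <- store@substances[[substance@uuid]]
    if (!is.null(old) && length(substance@composition) == 0)
      substance@composition <- list()
  }
  store@substances[[substance@uuid]] <- substance
  if (isTRUE(clearStudies)) {
    keep <- vapply(store@studies,
                   function(pa) pa@substanceUuid != substance@uuid, TRUE)
    store@studies <- store@studies[keep]
  }
  store
}

#' Add a protocol application to a store
#'
#' The referenced substance must already be in the store and the study
#' must carry at least one measurement; persisted records without effects
#' are rejected.
#'
#' @param store a [SubstanceStore()].
#' @param pa a [ProtocolApplication()].
#' @return the updated store.
#' @export
addStudy <- function(store, pa) {
  stopifnot(is(store, "SubstanceStore"), is(pa, "ProtocolApplication"))
  if (!(pa@substanceUuid %in% names(store@substances)))
    enmStop(sprintf("study %s references unknown substance %s",
                    pa@uuid, pa@substanceUuid), "enmkit_validation_error")
  if (length(pa@effects) == 0)
    enmStop(sprintf("study %s has no measurements", pa@uuid),
            "enmkit_validation_error")
  store@studies[[pa@uuid]] <- pa
  store
}

#' @describeIn addSubstance substance uuids present, sorted.
#' @export
substanceIds <- function(store) sort(names(store@substances))

#' @describeIn addSubstance retrieve one substance, or error with class
#'   \code{enmkit_notfound_error}.
#' @param uuid record identifier.
#' @export
getSubstance <- function(store, uuid) {
  s <- store@substances[[uuid]]
  if (is.null(s))
    enmStop(sprintf("unknown substance %s", uuid), "enmkit_notfound_error")
  s
}

#' @describeIn addStudy study uuids present, sorted.
#' @export
studyIds <- function(store) sort(names(store@studies))

#' @describeIn addStudy retrieve one protocol application.
#' @param uuid record identifier.
#' @export
getStudy <- function(store, uuid) {
  s <- store@studies[[uuid]]
  if (is.null(s))
    enmStop(sprintf("unknown study %s", uuid), "enmkit_notfound_error")
  s
}

#' @describeIn addStudy protocol applications of one substance, sorted by
#'   uuid.
#' @param substanceUuid substance identifier.
#' @export
studiesOf <- function(store, substanceUuid) {
  sel <- vapply(store@studies,
                function(pa) pa@substanceUuid == substanceUuid, TRUE)
  out <- store@studies[sel]
  out[order(names(out))]
}

#' Summary of available endpoints
#'
#' One row per distinct (topcategory, category, endpoint) combination in
#' the store with the number of measurements recorded for it; counts sum
#' to the total number of measurements. Rows are sorted lexicographically,
#' so the summary is invariant to insertion order.
#'
#' @param store a [SubstanceStore()].
#' @param substanceUuid optional; restrict to a single substance.
#' @return data.frame with columns topcategory, category, endpoint,
#'   records.
#' @export
endpointSummary <- function(store, substanceUuid = NULL) {
  empty <- data.frame(topcategory = character(0), category = character(0),
                      endpoint = character(0), records = integer(0),
                      stringsAsFactors = FALSE)
  studies <- store@studies
  if (!is.null(substanceUuid))
    studies <- Filter(function(pa) pa@substanceUuid == substanceUuid, studies)
  if (length(studies) == 0) return(empty)
  rows <- do.call(rbind, lapply(studies, function(pa) {
    data.frame(topcategory = pa@protocol@topcategory,
               category = pa@protocol@category,
               endpoint = vapply(pa@effects, function(m) m@endpoint, ""),
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(list(records = rep(1L, nrow(rows))),
                          rows[c("topcategory", "category", "endpoint")],
                          FUN = sum)
  agg <- agg[order(agg$topcategory, agg$category, agg$endpoint), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg$records <- as.integer(agg$records)
  agg
}

setMethod("show", "SubstanceStore", function(object) {
  nMeas <- sum(vapply(object@studies, function(pa) length(pa@effects), 1L))
  cat(sprintf("SubstanceStore: %d substances, %d protocol applications, %d measurements\n",
              length(object@substances), length(object@studies), nMeas))
})

setMethod("show", "Substance", function(object) {
  cat(sprintf("Substance %s '%s' (%d components)\n", object@uuid,
              object@name, length(object@composition)))
})

setMethod("show", "ProtocolApplication", function(object) {
  cat(sprintf("ProtocolApplication %s [%s/%s/%s] %d measurement(s)\n",
              object@uuid, object@protocol@topcategory,
              object@protocol@category, object@protocol@endpoint,
              length(object@effects)))
})

setMethod("show", "Measurement", function(object) {
  val <- if (!is.na(object@textValue)) object@textValue
         else paste(stats::na.omit(c(object@loValue, object@upValue)),
                    collapse = " .. ")
  cat(sprintf("Measurement '%s': %s %s\n", object@endpoint, val, object@unit))
})
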