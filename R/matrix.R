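## Conversion of a bundle into a modelling matrix. Two measurements land
## in the same column exactly when their feature keys -- endpoint,
## category and the values of the selection's distinguishing conditions --
## are equal. Replicates within a cell are aggregated by mean after
## Dixon's Q-test screening.

#' @rdname buildMatrix
#' @export
setClass("FeatureKey",
  representation(endpoint = "character", category = "character",
                 conditions = "list", unit = "character"),
  prototype(endpoint = "", category = "", conditions = list(), unit = ""))

featureKey <- function(endpoint, category, conditions = list(), unit = "") {
  if (length(conditions))
    conditions <- conditions[order(names(conditions))]
  new("FeatureKey", endpoint = endpoint, category = category,
      conditions = conditions, unit = unit)
}

#' @describeIn buildMatrix deterministic text form of a feature key, used
#'   as the matrix column name and CSV header.
#' @param key a \code{FeatureKey}.
#' @export
featureKeyString <- function(key) {
  sig <- ""
  if (length(key@conditions))
    sig <- paste0("@", paste(names(key@conditions),
                             vapply(key@conditions, function(v)
                               chr1(as.character(v), ""), ""),
                             sep = "=", collapse = ";"))
  u <- if (nzchar(key@unit)) paste0(" (", key@unit, ")") else ""
  paste0(key@endpoint, sig, u)
}

## Signature used for grouping (unit intentionally not part of identity;
## see conflicts handling below).
.cellKeySig <- function(endpoint, category, condSig)
  paste(endpoint, category, condSig, sep = "\r")

#' @rdname buildMatrix
#' @export
setClass("DataMatrix",
  representation(values = "matrix", keys = "list", reports = "list",
                 conflicts = "data.frame", bundleId = "integer"),
  validity = function(object) {
    if (!is.null(object@values) && length(object@values) &&
        !is.numeric(object@values))
      return("values must be a numeric matrix")
    TRUE
  })

#' Build the modelling matrix of a bundle
#'
#' Rows are the bundle's substances (sorted by uuid), columns are the
#' distinct feature keys found among the selected endpoints (sorted by
#' their text form), and each cell is the [aggregateValues()] result over
#' all scalarizable measurements of that substance matching the key.
#' Text-only measurements are skipped. Measurements that agree on the key
#' but disagree on the unit are a conflict: the cell is left missing and
#' the conflict is logged (no automatic unit conversion is attempted).
#' The result is bit-reproducible from (store, bundle).
#'
#' @param store a [SubstanceStore()].
#' @param bundle a [createBundle()] result.
#' @param alpha Dixon significance level used by the aggregation.
#' @return a \code{DataMatrix}: numeric matrix in \code{@values} with one
#'   [aggregateValues()] report per present cell in \code{@reports}
#'   (named \code{"<uuid>\r<column>"}), feature keys in \code{@keys} and
#'   a conflict log in \code{@conflicts}.
#' @export
buildMatrix <- function(store, bundle, alpha = 0.05) {
  stopifnot(is(store, "SubstanceStore"), is(bundle, "Bundle"))
  rows <- sort(bundle@substanceUuids)

  ## collect (substance, key-signature, value, unit) tuples
  tup <- list()
  for (sel in bundle@selections) {
    for (uuid in rows) {
      for (pa in studiesOf(store, uuid)) {
        if (pa@protocol@topcategory != sel$topcategory) next
        if (nzchar(sel$category) && pa@protocol@category != sel$category) next
        for (m in pa@effects) {
          if (m@endpoint != sel$endpoint) next
          dis <- m@conditions[intersect(sort(sel$conditions),
                                        names(m@conditions))]
          condVals <- lapply(dis, function(v) v$value)
          condSig <- if (length(condVals))
            paste(names(condVals), vapply(condVals, function(v)
              chr1(as.character(v), ""), ""), sep = "=", collapse = ";")
          else ""
          v <- scalarize(m)
          tup[[length(tup) + 1L]] <- list(
            uuid = uuid, endpoint = m@endpoint,
            category = pa@protocol@category, condSig = condSig,
            conditions = condVals, unit = m@unit, value = v)
        }
      }
    }
  }

  conflicts <- data.frame(uuid = character(0), column = character(0),
                          units = character(0), stringsAsFactors = FALSE)
  if (length(tup) == 0) {
    values <- matrix(NA_real_, nrow = length(rows), ncol = 0,
                     dimnames = list(rows, character(0)))
    return(new("DataMatrix", values = values, keys = list(),
               reports = list(), conflicts = conflicts,
               bundleId = bundle@id))
  }

  sigs <- vapply(tup, function(t)
    .cellKeySig(t$endpoint, t$category, t$condSig), "")
  uniqueSigs <- sort(unique(sigs))

  ## one FeatureKey per column; unit = the (consensus) unit of the column
  keys <- list()
  colNames <- character(length(uniqueSigs))
  for (i in seq_along(uniqueSigs)) {
    members <- tup[sigs == uniqueSigs[i]]
    units <- vapply(members, function(t) t$unit, "")
    tab <- sort(table(units), decreasing = TRUE)
    unit <- names(tab)[1]
    k <- featureKey(members[[1]]$endpoint, members[[1]]$category,
                    members[[1]]$conditions, unit)
    keys[[i]] <- k
    colNames[i] <- featureKeyString(k)
  }
  ord <- order(colNames)
  keys <- keys[ord]
  colNames <- colNames[ord]
  uniqueSigs <- uniqueSigs[ord]

  values <- matrix(NA_real_, nrow = length(rows), ncol = length(colNames),
                   dimnames = list(rows, colNames))
  reports <- list()
  tupUuids <- vapply(tup, function(t) t$uuid, "")
  for (j in seq_along(uniqueSigs)) {
    inCol <- sigs == uniqueSigs[j]
    for (i in seq_along(rows)) {
      cell <- tup[inCol & tupUuids == rows[i]]
      if (length(cell) == 0) next
      units <- unique(vapply(cell, function(t) t$unit, ""))
      if (length(units) > 1 || units[1] != keys[[j]]@unit) {
        conflicts <- rbind(conflicts, data.frame(
          uuid = rows[i], column = colNames[j],
          units = paste(sort(units), collapse = " vs "),
          stringsAsFactors = FALSE))
        next
      }
      vals <- vapply(cell, function(t) t$value, 0)
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) next
      agg <- aggregateValues(vals, alpha)
      values[i, j] <- agg$value
      reports[[paste(rows[i], colNames[j], sep = "\r")]] <- agg$report
    }
  }
  new("DataMatrix", values = values, keys = keys, reports = reports,
      conflicts = conflicts, bundleId = bundle@id)
}

#' @describeIn buildMatrix numeric matrix of cell values (rows =
#'   substances, columns = feature keys).
#' @param x a \code{DataMatrix}.
#' @export
matrixValues <- function(x) x@values

#' @describeIn buildMatrix the aggregation report of one cell, or NULL.
#' @param uuid,column cell coordinates (row name, column name).
#' @export
cellReport <- function(x, uuid, column)
  x@reports[[paste(uuid, column, sep = "\r")]]

#' @describeIn buildMatrix write the matrix as CSV (rows = substances,
#'   header = feature key strings).
#' @param path output file.
#' @export
exportMatrixCSV <- function(x, path) {
  df <- data.frame(substance = rownames(x@values), x@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn buildMatrix serialize the matrix with per-cell reports to
#'   JSON.
#' @export
exportMatrixJSON <- function(x, path = NULL) {
  cells <- lapply(names(x@reports), function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    r <- x@reports[[k]]
    list(substance = parts[1], column = parts[2], value = r@result,
         nInput = r@nInput, method = r@method,
         excluded = r@excluded$value)
  })
  doc <- list(rows = rownames(x@values), columns = colnames(x@values),
              values = unname(apply(x@values, 1, as.list, simplify = FALSE)),
              reports = cells,
              conflicts = x@conflicts)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, na = "null", digits = NA)
  if (!is.null(path)) { writeLines(json, path); invisible(path) }
  else as.character(json)
}

setMethod("show", "DataMatrix", function(object) {
  cat(sprintf("DataMatrix: %d substances x %d features (%d cells filled, %d conflicts)\n",
              nrow(object@values), ncol(object@values),
              sum(!is.na(object@values)), nrow(object@conflicts)))
})
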