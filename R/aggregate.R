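#' @rdname aggregateValues
#' @export
setClass("AggregationReport",
  representation(nInput = "integer", valuesUsed = "numeric",
                 excluded = "data.frame", method = "character",
                 result = "numeric"),
  validity = function(object) {
    if (object@nInput != length(object@valuesUsed) + nrow(object@excluded))
      return("nInput must equal |valuesUsed| + |excluded|")
    if (!(object@method %in% c("MEAN_AFTER_DIXON", "MEAN", "SINGLE")))
      return("unknown aggregation method")
    TRUE
  })

#' Reduce a measurement to a single number
#'
#' Heterogeneous results are mapped to one value for the modelling matrix:
#' a single value is taken as is (a reported error does not move the point
#' value), an interval is replaced by its midpoint, and text-only results
#' (e.g. raw-data file links) yield \code{NA} -- they are kept in the store
#' for provenance but excluded from matrices.
#'
#' @param m a [Measurement()].
#' @return numeric scalar, or \code{NA} for text-only measurements.
#' @export
scalarize <- function(m) {
  stopifnot(is(m, "Measurement"))
  if (!is.na(m@loValue) && !is.na(m@upValue)) (m@loValue + m@upValue) / 2
  else if (!is.na(m@loValue)) m@loValue
  else if (!is.na(m@upValue)) m@upValue
  else NA_real_
}

#' Aggregate replicate values into one cell value
#'
#' Arithmetic mean of the values retained after [dixonOutliers()]
#' screening at the given significance level. The method recorded in the
#' report is \code{SINGLE} for one value, \code{MEAN} when the sample is
#' outside the Q-test domain (n = 2 or n > 30), and
#' \code{MEAN_AFTER_DIXON} otherwise (even when nothing was excluded).
#'
#' @param values numeric vector with at least one value.
#' @param alpha Dixon significance level, default 0.05.
#' @return list(value = numeric scalar, report = AggregationReport).
#' @examples
#' aggregateValues(c(0.10, 0.11, 0.12, 0.35))$value  # 0.11
#' @export
aggregateValues <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) == 0)
    enmStop("no values to aggregate", "enmkit_validation_error")
  if (length(values) == 1) {
    d <- list(kept = values,
              excluded = data.frame(value = numeric(0), Q = numeric(0),
                                    Qcrit = numeric(0), side = character(0),
                                    variant = character(0),
                                    stringsAsFactors = FALSE),
              nInput = 1L)
    method <- "SINGLE"
  } else {
    d <- dixonOutliers(values, alpha)
    method <- if (length(values) >= 3 && length(values) <= 30)
      "MEAN_AFTER_DIXON" else "MEAN"
  }
  result <- mean(d$kept)
  list(value = result,
       report = new("AggregationReport", nInput = as.integer(d$nInput),
                    valuesUsed = d$kept, excluded = d$excluded,
                    method = method, result = result))
}

setMethod("show", "AggregationReport", function(object) {
  cat(sprintf("AggregationReport: %s of %d/%d values -> %g (%d excluded)\n",
              object@method, length(object@valuesUsed), object@nInput,
              object@result, nrow(object@excluded)))
})
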