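## Leverage applicability domain. The leverage of a query point x (with
## intercept) is h = x' (X'X)^-1 x over the training design X; points with
## h above the conventional warning threshold h* = 3p/n are flagged
## outside the domain, i.e. structurally far from the training cloud.

#' @rdname fitAD
#' @export
setClass("ADModel",
  representation(featureNames = "character", xtxInv = "matrix",
                 p = "integer", n = "integer", threshold = "numeric"),
  validity = function(object) {
    if (object@p < 1 || object@n < object@p)
      return("need n >= p >= 1")
    TRUE
  })

.designMatrix <- function(table, featureNames) {
  df <- as.data.frame(table, check.names = FALSE)
  missing <- setdiff(featureNames, colnames(df))
  if (length(missing))
    enmStop(paste0("missing feature column(s): ",
                   paste(missing, collapse = ", ")),
            "enmkit_validation_error")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(df[, featureNames, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

#' Leverage applicability domain of a training design
#'
#' Defines the region of descriptor space in which a model's predictions
#' are considered reliable: queries whose leverage exceeds h* = 3p/n (p =
#' number of model parameters including the intercept, n = training size)
#' are flagged out of domain. Training leverages satisfy the hat-matrix
#' identities sum(h) = p and h <= 1.
#'
#' @param table training feature table (complete numeric rows).
#' @param featureNames columns to use; default all.
#' @return an \code{ADModel}.
#' @export
fitAD <- function(table, featureNames = NULL) {
  df <- as.data.frame(table, check.names = FALSE)
  if (is.null(featureNames)) featureNames <- colnames(df)
  X <- .designMatrix(df, featureNames)
  if (anyNA(X))
    enmStop("training design must be complete (no missing values)",
            "enmkit_validation_error")
  xtx <- crossprod(X)
  xtxInv <- tryCatch(solve(xtx), error = function(e)
    enmStop("singular design matrix: leverage is undefined",
            "enmkit_validation_error"))
  p <- ncol(X); n <- nrow(X)
  new("ADModel", featureNames = featureNames, xtxInv = xtxInv,
      p = as.integer(p), n = as.integer(n), threshold = 3 * p / n)
}

#' @describeIn fitAD leverage h of each row of a query table.
#' @param ad an \code{ADModel}.
#' @export
leverage <- function(ad, table) {
  X <- .designMatrix(table, ad@featureNames)
  rowSums((X %*% ad@xtxInv) * X)
}

#' @describeIn fitAD leverage plus in/out-of-domain flag (h <= 3p/n).
#' @export
inDomain <- function(ad, table) {
  h <- leverage(ad, table)
  data.frame(leverage = h, inDomain = !is.na(h) & h <= ad@threshold)
}

setMethod("show", "ADModel", function(object) {
  cat(sprintf("ADModel: p = %d, n = %d, leverage threshold h* = %.4f\n",
              object@p, object@n, object@threshold))
})
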