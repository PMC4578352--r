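#' Fit-and-apply preprocessing for feature tables
#'
#' Scaling and missing-value handling are fitted on training data only and
#' reapplied verbatim at prediction time, so train and query features go
#' through exactly the same transformation. \code{standardize} centres to
#' mean 0 and scales to (sample) standard deviation 1; \code{minmax} maps
#' to [0, 1]. Constant columns cannot be scaled: they are flagged and left
#' unchanged. Imputation fills missing values with the training column
#' mean or median. A column that is entirely missing cannot be used at
#' all and raises an error.
#'
#' @param table matrix or data.frame of numeric features.
#' @param scaling one of "none", "standardize", "minmax".
#' @param impute one of "none", "mean", "median".
#' @return list(table = transformed data.frame, transformer = fitted
#'   transformer for [applyTransformer()]).
#' @export
preprocess <- function(table, scaling = c("none", "standardize", "minmax"),
                       impute = c("none", "mean", "median")) {
  tr <- fitTransformer(table, scaling, impute)
  list(table = applyTransformer(tr, table), transformer = tr)
}

#' @describeIn preprocess fit the transformer without applying it.
#' @export
fitTransformer <- function(table,
                           scaling = c("none", "standardize", "minmax"),
                           impute = c("none", "mean", "median")) {
  scaling <- match.arg(scaling)
  impute <- match.arg(impute)
  m <- as.matrix(as.data.frame(table, check.names = FALSE))
  storage.mode(m) <- "double"
  allMissing <- colnames(m)[colSums(!is.na(m)) == 0]
  if (length(allMissing))
    enmStop(paste0("column(s) entirely missing: ",
                   paste(allMissing, collapse = ", ")),
            "enmkit_validation_error")
  fill <- switch(impute,
    none = NULL,
    mean = colMeans(m, na.rm = TRUE),
    median = apply(m, 2, stats::median, na.rm = TRUE))
  if (!is.null(fill))  # scaling parameters are fitted on imputed data
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- fill[j]
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  rng <- apply(m, 2, function(x) diff(range(x, na.rm = TRUE)))
  constant <- colnames(m)[!is.na(sds) & sds == 0]
  structure(list(
    scaling = scaling, impute = impute, columns = colnames(m),
    fill = fill,
    center = colMeans(m, na.rm = TRUE),
    scale = sds,
    min = apply(m, 2, min, na.rm = TRUE),
    range = rng,
    constantColumns = constant), class = "enmTransformer")
}

#' @describeIn preprocess apply a fitted transformer to new data (columns
#'   are matched by name; extra columns pass through untouched).
#' @param transformer a fitted transformer.
#' @export
applyTransformer <- function(transformer, table) {
  stopifnot(inherits(transformer, "enmTransformer"))
  df <- as.data.frame(table, check.names = FALSE)
  for (nm in intersect(transformer$columns, colnames(df))) {
    x <- as.numeric(df[[nm]])
    if (!is.null(transformer$fill)) x[is.na(x)] <- transformer$fill[[nm]]
    if (nm %in% transformer$constantColumns) { df[[nm]] <- x; next }
    x <- switch(transformer$scaling,
      none = x,
      standardize = (x - transformer$center[[nm]]) / transformer$scale[[nm]],
      minmax = (x - transformer$min[[nm]]) / transformer$range[[nm]])
    df[[nm]] <- x
  }
  df
}
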