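## Multiple linear regression NanoQSAR modelling. The fit itself is
## ordinary least squares via stats::lm on the (PMML-transformed,
## preprocessed) feature table; the trained model travels as a ModelBundle
## whose payload is a base64-serialized blob, so a registry can store it
## opaquely and reload it with bit-identical behaviour.

#' @rdname trainMLR
#' @export
setClass("ModelBundle",
  representation(algorithmId = "character", selectedFeatures = "character",
                 predictedFeature = "character", pmml = "character",
                 coefficients = "numeric", stats = "list",
                 payload = "character", ad = "ANY"),
  prototype(pmml = NA_character_, ad = NULL))

.bundleEssentials <- function(bundle)
  list(algorithmId = bundle@algorithmId,
       selectedFeatures = bundle@selectedFeatures,
       predictedFeature = bundle@predictedFeature,
       pmml = bundle@pmml,
       coefficients = bundle@coefficients,
       stats = bundle@stats)

.encodePayload <- function(essentials, transformer, ad = NULL)
  jsonlite::base64_enc(serialize(list(essentials = essentials,
                                      transformer = transformer, ad = ad),
                                 connection = NULL, version = 2))

.decodePayload <- function(payload)
  unserialize(jsonlite::base64_dec(payload))

.transformerOf <- function(bundle) .decodePayload(bundle@payload)$transformer

#' Train a multiple linear regression model
#'
#' Fits the prediction feature on the remaining (or explicitly selected)
#' features by ordinary least squares. An optional PMML spec is applied
#' first (feature selection and derived fields -- including a derived
#' target such as a log2-transformed cell association), then the
#' preprocessing options; the fitted transformer is stored in the bundle
#' and reapplied verbatim at prediction time. Rows with a missing target
#' are excluded from training with a logged count. A rank-deficient
#' design is an error naming the collinear columns.
#'
#' @param table feature table (matrix, data.frame or \code{DataMatrix}).
#' @param predictionFeature name of the target column (after PMML
#'   transformation, when a spec is given).
#' @param features predictor columns; default all but the target.
#' @param pmml optional [parsePMML()] spec, or a path/XML text.
#' @param alias optional PMML-name to column-name map, see [applySpec()].
#' @param scaling,impute preprocessing options, see [preprocess()].
#' @param ad fit a leverage applicability domain ([fitAD()]) on the
#'   training features and attach it to the bundle.
#' @return a \code{ModelBundle}; coefficients, R^2, residual sd and
#'   training size are exposed in \code{@coefficients} and \code{@stats}.
#' @export
trainMLR <- function(table, predictionFeature, features = NULL, pmml = NULL,
                     alias = NULL, scaling = "none", impute = "none",
                     ad = TRUE) {
  if (is(table, "DataMatrix")) table <- as.data.frame(table@values,
                                                      check.names = FALSE)
  pmmlText <- NA_character_
  if (!is.null(pmml)) {
    if (!is(pmml, "PMMLSpec")) pmml <- parsePMML(pmml)
    pmmlText <- pmml@source
    table <- applySpec(pmml, table, alias = alias)
  }
  df <- as.data.frame(table, check.names = FALSE)
  if (!(predictionFeature %in% colnames(df)))
    enmStop(sprintf("prediction feature '%s' not found", predictionFeature),
            "enmkit_validation_error")
  if (is.null(features)) features <- setdiff(colnames(df), predictionFeature)
  y <- as.numeric(df[[predictionFeature]])
  keep <- !is.na(y)
  nDroppedTarget <- sum(!keep)
  df <- df[keep, , drop = FALSE]; y <- y[keep]

  tr <- fitTransformer(df[, features, drop = FALSE], scaling, impute)
  Xdf <- applyTransformer(tr, df[, features, drop = FALSE])
  complete <- stats::complete.cases(Xdf)
  Xdf <- Xdf[complete, , drop = FALSE]; y <- y[complete]
  n <- length(y); p <- length(features) + 1L
  if (n < p + 2)
    enmStop(sprintf("need at least %d complete rows to fit %d parameters, have %d",
                    p + 2, p, n), "enmkit_validation_error")

  fitData <- data.frame(.y = y, Xdf, check.names = FALSE)
  fml <- stats::as.formula(paste0(".y ~ ",
    paste(sprintf("`%s`", features), collapse = " + ")))
  fit <- stats::lm(fml, data = fitData)
  coefs <- stats::coef(fit)
  names(coefs) <- c("(Intercept)", features)
  if (anyNA(coefs)) {
    bad <- names(coefs)[is.na(coefs)]
    enmStop(paste0("rank-deficient design; collinear column(s): ",
                   paste(bad, collapse = ", ")), "enmkit_validation_error")
  }
  sm <- suppressWarnings(summary(fit))  # noiseless fixtures fit perfectly
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- names(coefs)
  modelStats <- list(r2 = unname(sm$r.squared), sigma = unname(sm$sigma),
                     n = n, droppedMissingTarget = nDroppedTarget,
                     se = as.list(se))
  adModel <- if (isTRUE(ad)) fitAD(Xdf, features) else NULL

  bundle <- new("ModelBundle", algorithmId = "mlr",
                selectedFeatures = features,
                predictedFeature = predictionFeature,
                pmml = pmmlText, coefficients = coefs, stats = modelStats,
                payload = "", ad = adModel)
  bundle@payload <- .encodePayload(.bundleEssentials(bundle), tr, adModel)
  bundle
}

#' Predict with a trained model bundle
#'
#' Applies the stored PMML transformation, the stored preprocessing
#' transformer and the regression coefficients to new rows. When an
#' applicability domain is attached, each prediction is annotated with its
#' leverage and an in/out-of-domain flag.
#'
#' @param object a \code{ModelBundle}.
#' @param newdata feature table supplying the model's selected features.
#' @return data.frame with column \code{prediction} (plus \code{leverage}
#'   and \code{inDomain} when an AD model is attached).
#' @export
setMethod("predict", "ModelBundle", function(object, newdata, ...) {
  df <- if (is(newdata, "DataMatrix"))
    as.data.frame(newdata@values, check.names = FALSE)
  else as.data.frame(newdata, check.names = FALSE)
  if (!is.na(object@pmml)) {
    spec <- parsePMML(object@pmml)
    ## only transform when raw inputs are provided, not pre-transformed ones
    if (!all(object@selectedFeatures %in% colnames(df)) ||
        any(spec@dataFields$name %in% colnames(df)))
      df <- applySpec(spec, df)
  }
  missing <- setdiff(object@selectedFeatures, colnames(df))
  if (length(missing))
    enmStop(paste0("missing feature column(s): ",
                   paste(missing, collapse = ", ")),
            "enmkit_validation_error")
  tr <- .transformerOf(object)
  Xdf <- applyTransformer(tr, df[, object@selectedFeatures, drop = FALSE])
  X <- cbind(1, as.matrix(Xdf))
  storage.mode(X) <- "double"
  pred <- as.numeric(X %*% object@coefficients)
  out <- data.frame(prediction = pred)
  rownames(out) <- rownames(df)
  if (!is.null(object@ad)) {
    flags <- inDomain(object@ad, Xdf)
    out$leverage <- flags$leverage
    out$inDomain <- flags$inDomain
  }
  out
})

#' Write / read a model bundle as JSON
#'
#' The JSON document carries the algorithm id, selected features,
#' predicted feature, the PMML text, the exposed coefficients and the
#' opaque base64 payload. The payload round-trips byte-identically, so a
#' reloaded bundle predicts bit-identically to the fresh one.
#'
#' @param bundle a \code{ModelBundle}.
#' @param path output file.
#' @return \code{writeModelBundle}: the path, invisibly;
#'   \code{readModelBundle}: the reconstructed \code{ModelBundle}.
#' @export
writeModelBundle <- function(bundle, path) {
  doc <- c(.bundleEssentials(bundle), list(payload = bundle@payload))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, na = "null",
                              digits = NA), path)
  invisible(path)
}

#' @rdname writeModelBundle
#' @export
readModelBundle <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dec <- .decodePayload(doc$payload)
  ess <- dec$essentials
  new("ModelBundle", algorithmId = ess$algorithmId,
      selectedFeatures = ess$selectedFeatures,
      predictedFeature = ess$predictedFeature,
      pmml = ess$pmml, coefficients = ess$coefficients,
      stats = ess$stats, payload = doc$payload, ad = dec$ad)
}

setMethod("show", "ModelBundle", function(object) {
  cat(sprintf("ModelBundle '%s': %s ~ %s (n = %d, R^2 = %.4f)\n",
              object@algorithmId, object@predictedFeature,
              paste(object@selectedFeatures, collapse = " + "),
              object@stats$n, object@stats$r2))
})
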