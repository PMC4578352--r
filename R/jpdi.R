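## JSON train/predict exchange protocol with a pluggable algorithm
## registry. An algorithm is a pair of endpoints (in-process callables
## here; an HTTP front end can wrap them) that consume and produce JSON
## documents: the training request carries exactly the dataset, the
## prediction feature and the tuning parameters -- nothing else from the
## store -- and the model document the service returns is stored opaquely
## and handed back verbatim for predictions, so algorithm providers keep
## no state.

.ALGORITHM_CLASSES <- c("Regression", "Classification", "Clustering")

#' @rdname registerAlgorithm
#' @export
setClass("AlgorithmRegistry", representation(env = "environment"))

#' Describe an algorithm for the registry
#'
#' @param name unique algorithm name.
#' @param train,predict endpoint callables; each takes a JSON request text
#'   and returns a JSON response text.
#' @param ontologyClass one of Regression, Classification, Clustering.
#' @param description,tags,references metadata.
#' @param parameters list of tuning-parameter definitions
#'   (\code{list(name =, type =, default =, mandatory =)}).
#' @return an algorithm record (list).
#' @export
algorithmRecord <- function(name, train, predict,
                            ontologyClass = "Regression",
                            description = "", tags = character(0),
                            references = character(0), parameters = list()) {
  if (!isNonEmptyString(name))
    enmStop("algorithm name required", "enmkit_validation_error")
  if (!is.function(train) || !is.function(predict))
    enmStop("both train and predict endpoints are required",
            "enmkit_validation_error")
  if (!(ontologyClass %in% .ALGORITHM_CLASSES))
    enmStop(paste0("ontologyClass must be one of ",
                   paste(.ALGORITHM_CLASSES, collapse = ", ")),
            "enmkit_validation_error")
  list(name = name, description = description, tags = tags,
       references = references, train = train, predict = predict,
       ontologyClass = ontologyClass, parameters = parameters)
}

#' Algorithm registry with register/get/modify/remove semantics
#'
#' Mirrors a POST/GET/PATCH/DELETE resource: algorithms are registered
#' under a unique name, can be listed, retrieved, patched field-by-field
#' and removed. [defaultRegistry()] ships the built-in multiple linear
#' regression plus named placeholders for partial least squares, support
#' vector machines and RBF networks (registered but raising
#' not-implemented on use).
#'
#' @param registry an \code{AlgorithmRegistry}.
#' @param record an [algorithmRecord()].
#' @return the registry (invisibly) for the mutators; records or names
#'   for the accessors.
#' @export
registerAlgorithm <- function(registry, record) {
  if (!is.null(registry@env$algorithms[[record$name]]))
    enmStop(sprintf("algorithm '%s' already registered", record$name),
            "enmkit_validation_error")
  registry@env$algorithms[[record$name]] <- record
  invisible(registry)
}

#' @rdname registerAlgorithm
#' @export
algorithmRegistry <- function() {
  env <- new.env(parent = emptyenv())
  env$algorithms <- list()
  new("AlgorithmRegistry", env = env)
}

#' @rdname registerAlgorithm
#' @export
listAlgorithms <- function(registry) sort(names(registry@env$algorithms))

#' @rdname registerAlgorithm
#' @param name algorithm name.
#' @export
getAlgorithm <- function(registry, name) {
  rec <- registry@env$algorithms[[name]]
  if (is.null(rec))
    enmStop(sprintf("unknown algorithm '%s'", name), "enmkit_notfound_error")
  rec
}

#' @rdname registerAlgorithm
#' @export
removeAlgorithm <- function(registry, name) {
  getAlgorithm(registry, name)  # errors when absent
  registry@env$algorithms[[name]] <- NULL
  invisible(registry)
}

#' @rdname registerAlgorithm
#' @param patch named list of fields to modify (PATCH semantics).
#' @export
modifyAlgorithm <- function(registry, name, patch) {
  rec <- getAlgorithm(registry, name)
  for (nm in names(patch)) rec[[nm]] <- patch[[nm]]
  registry@env$algorithms[[name]] <- rec
  invisible(registry)
}

## --- request/response documents ------------------------------------------

.tableToDataset <- function(table) {
  df <- as.data.frame(table, check.names = FALSE)
  list(features = as.list(colnames(df)),
       ids = as.list(rownames(df)),
       rows = lapply(seq_len(nrow(df)), function(i)
         as.list(stats::setNames(as.numeric(df[i, ]), colnames(df)))))
}

.datasetToTable <- function(ds) {
  feats <- unlist(ds$features)
  rows <- lapply(ds$rows, function(r)
    vapply(feats, function(f) num1(r[[f]]), 0))
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  colnames(tab) <- feats
  rownames(tab) <- unlist(ds$ids)
  tab
}

#' Compose a JPDI-style training request
#'
#' The request JSON contains exactly three components: the dataset, the
#' prediction feature and the tuning parameters.
#'
#' @param table feature table.
#' @param predictionFeature target column name.
#' @param parameters named list of tuning parameters.
#' @return JSON text.
#' @export
trainRequest <- function(table, predictionFeature, parameters = list()) {
  doc <- list(dataset = .tableToDataset(table),
              predictionFeature = predictionFeature,
              parameters = parameters)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, na = "null",
                                digits = I(17)))
}

#' Train and predict through the JSON exchange protocol
#'
#' \code{trainViaJPDI} sends a [trainRequest()] to the named algorithm's
#' train endpoint and stores the returned model document as-is (opaquely).
#' \code{predictViaJPDI} posts back (i) that stored document and (ii) the
#' dataset restricted to the features the model selected, and returns the
#' predictions. A model produced by one algorithm cannot be used with
#' another.
#'
#' @param registry an [algorithmRegistry()].
#' @param name registered algorithm name.
#' @param table feature table.
#' @param predictionFeature target column name.
#' @param parameters named list of tuning parameters.
#' @return \code{trainViaJPDI}: list(algorithm, document) where document
#'   is the verbatim model JSON; \code{predictViaJPDI}: numeric vector of
#'   predictions.
#' @export
trainViaJPDI <- function(registry, name, table, predictionFeature,
                         parameters = list()) {
  rec <- getAlgorithm(registry, name)
  request <- trainRequest(table, predictionFeature, parameters)
  document <- rec$train(request)
  list(algorithm = name, document = document)
}

#' @rdname trainViaJPDI
#' @param model a \code{trainViaJPDI} result.
#' @export
predictViaJPDI <- function(registry, model, table) {
  rec <- getAlgorithm(registry, model$algorithm)
  parsed <- jsonlite::fromJSON(model$document, simplifyVector = FALSE)
  if (!identical(chr1(parsed$algorithmId), model$algorithm))
    enmStop(sprintf("model was produced by '%s', not '%s'",
                    chr1(parsed$algorithmId), model$algorithm),
            "enmkit_validation_error")
  feats <- unlist(parsed$selectedFeatures)
  df <- as.data.frame(table, check.names = FALSE)
  have <- intersect(feats, colnames(df))
  request <- as.character(jsonlite::toJSON(
    list(dataset = .tableToDataset(df[, have, drop = FALSE]),
         model = parsed),
    auto_unbox = TRUE, na = "null", digits = I(17)))
  response <- rec$predict(request)
  out <- jsonlite::fromJSON(response, simplifyVector = FALSE)
  vapply(out$predictions, num1, 0)
}

## --- built-in services ----------------------------------------------------

.mlrTrainEndpoint <- function(requestJson) {
  req <- jsonlite::fromJSON(requestJson, simplifyVector = FALSE)
  table <- .datasetToTable(req$dataset)
  params <- req$parameters %||% list()
  bundle <- trainMLR(table, req$predictionFeature,
                     scaling = chr1(params$scaling, "none"),
                     impute = chr1(params$impute, "none"),
                     ad = isTRUE(params$ad %||% TRUE))
  doc <- c(.bundleEssentials(bundle), list(payload = bundle@payload))
  doc$coefficients <- as.list(doc$coefficients)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, na = "null",
                                digits = I(17)))
}

.mlrPredictEndpoint <- function(requestJson) {
  req <- jsonlite::fromJSON(requestJson, simplifyVector = FALSE)
  table <- .datasetToTable(req$dataset)
  dec <- .decodePayload(req$model$payload)
  ess <- dec$essentials
  bundle <- new("ModelBundle", algorithmId = ess$algorithmId,
                selectedFeatures = ess$selectedFeatures,
                predictedFeature = ess$predictedFeature, pmml = ess$pmml,
                coefficients = ess$coefficients, stats = ess$stats,
                payload = req$model$payload, ad = dec$ad)
  pred <- predict(bundle, table)
  as.character(jsonlite::toJSON(list(predictions = pred$prediction),
                                auto_unbox = FALSE, na = "null",
                                digits = I(17)))
}

.notImplementedEndpoint <- function(name) {
  force(name)
  function(requestJson)
    enmStop(sprintf("algorithm '%s' is registered but not implemented", name),
            "enmkit_notimplemented_error")
}

#' @rdname registerAlgorithm
#' @export
defaultRegistry <- function() {
  reg <- algorithmRegistry()
  registerAlgorithm(reg, algorithmRecord(
    "mlr", .mlrTrainEndpoint, .mlrPredictEndpoint,
    ontologyClass = "Regression",
    description = "ordinary least squares multiple linear regression",
    tags = c("regression", "linear"),
    parameters = list(
      list(name = "scaling", type = "string", default = "none",
           mandatory = FALSE),
      list(name = "impute", type = "string", default = "none",
           mandatory = FALSE))))
  for (stub in c("pls", "svm", "rbf-network"))
    registerAlgorithm(reg, algorithmRecord(
      stub, .notImplementedEndpoint(stub), .notImplementedEndpoint(stub),
      ontologyClass = "Regression",
      description = "placeholder registration; raises not-implemented"))
  reg
}
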