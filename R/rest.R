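## Transport-agnostic service layer mirroring the resource layout of a
## substance database API: /substance (search, upload), per-substance
## composition/study/studysummary, /bundle with PUT select/deselect and
## /bundle/{id}/matrix, and /query for endpoint and similarity searches.
## handleRequest() is the whole contract -- list(status, body) in, JSON-
## ready list out -- so it can be mounted on any HTTP front end (an
## optional httpuv adapter is provided) and tested in-process. The layer
## adds no computation: every response equals the corresponding direct
## library call.

#' @rdname newService
#' @export
setClass("EnmService", representation(env = "environment"))

#' Create a service over a substance store
#'
#' @param store initial [SubstanceStore()].
#' @return an \code{EnmService}; state (store, bundles) lives in the
#'   service and is mutated by POST/PUT requests.
#' @export
newService <- function(store = SubstanceStore()) {
  env <- new.env(parent = emptyenv())
  env$store <- store
  env$bundles <- list()
  env$nextBundleId <- 1L
  new("EnmService", env = env)
}

.substanceToList <- function(s) {
  list(uuid = s@uuid, name = s@name, publicName = s@publicName,
       substanceType = s@substanceType, ownerName = s@ownerName,
       referenceSubstanceUuid = s@referenceSubstanceUuid,
       externalIds = s@externalIds,
       composition = lapply(s@composition, function(c)
         list(role = c@role, name = c@name, smiles = c@smiles,
              inchi = c@inchi)))
}

.paginate <- function(items, query) {
  page <- max(0L, int1(query[["page"]], 0L))    # [[: no partial matching
  pagesize <- max(1L, int1(query[["pagesize"]], 10L))
  from <- page * pagesize + 1L
  to <- min(length(items), from + pagesize - 1L)
  slice <- if (from > length(items)) list()
           else items[from:to]
  list(total = length(items), page = page, pagesize = pagesize,
       items = slice)
}

.ok <- function(body) list(status = 200L, body = body)
.notFound <- function(msg) list(status = 404L, body = list(error = msg))
.badRequest <- function(msg, diagnostics = NULL)
  list(status = 400L, body = list(error = msg, diagnostics = diagnostics))

#' Dispatch one request against a service
#'
#' Routes (mirroring the substance/bundle resource layout):
#' \itemize{
#' \item GET /substance -- paginated listing (query: page, pagesize)
#' \item POST /substance -- upload: body list(file, template,
#'   clearComposition, clearStudies)
#' \item GET /substance/\{uuid\}, /composition, /study, /studysummary
#' \item GET/POST /bundle; GET /bundle/\{id\}
#' \item PUT /bundle/\{id\}/substance, /bundle/\{id\}/property -- body
#'   list(action = "select"|"deselect", ...)
#' \item GET /bundle/\{id\}/matrix
#' \item GET /query -- either (smiles, threshold) similarity search or
#'   (topcategory/category/endpoint) measurement search
#' }
#'
#' @param service an [newService()] result.
#' @param method HTTP verb ("GET", "POST", "PUT").
#' @param path resource path, e.g. \code{"/substance/XXXX-..."}.
#' @param query named list of query parameters.
#' @param body named list (parsed request body).
#' @return list(status = integer, body = JSON-ready list).
#' @export
handleRequest <- function(service, method, path, query = list(),
                          body = NULL) {
  env <- service@env
  store <- env$store
  parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  resource <- if (length(parts)) parts[1] else ""

  if (resource == "substance") {
    if (length(parts) == 1) {
      if (method == "GET") {
        ids <- substanceIds(store)
        pg <- .paginate(ids, query)
        pg$substance <- lapply(pg$items, function(u)
          .substanceToList(getSubstance(store, u)))
        pg$items <- NULL
        return(.ok(pg))
      }
      if (method == "POST") {
        res <- tryCatch(
          importWorkbook(store, body$file, body$template,
                         clearComposition = isTRUE(body$clearComposition),
                         clearStudies = isTRUE(body$clearStudies)),
          error = function(e) e)
        if (inherits(res, "error"))
          return(.badRequest("import failed",
                             diagnostics = conditionMessage(res)))
        env$store <- res
        return(.ok(list(imported = length(substanceIds(res)) -
                          length(substanceIds(store)))))
      }
    }
    uuid <- parts[2]
    s <- tryCatch(getSubstance(store, uuid), error = function(e) NULL)
    if (is.null(s)) return(.notFound(sprintf("unknown substance %s", uuid)))
    sub <- if (length(parts) >= 3) parts[3] else ""
    if (sub == "") return(.ok(.substanceToList(s)))
    if (sub == "composition")
      return(.ok(.substanceToList(s)$composition))
    if (sub == "study") {
      studies <- lapply(studiesOf(store, uuid), studyToList)
      return(.ok(unname(studies)))
    }
    if (sub == "studysummary") {
      sm <- endpointSummary(store, uuid)
      return(.ok(lapply(seq_len(nrow(sm)), function(i) as.list(sm[i, ]))))
    }
    return(.notFound(sprintf("unknown resource %s", path)))
  }

  if (resource == "bundle") {
    if (length(parts) == 1) {
      if (method == "GET") {
        pg <- .paginate(unname(lapply(env$bundles, function(b)
          list(id = b@id, name = b@name,
               substances = length(b@substanceUuids),
               selections = length(b@selections)))), query)
        pg$bundle <- pg$items; pg$items <- NULL
        return(.ok(pg))
      }
      if (method == "POST") {
        b <- tryCatch(createBundle(
          store, substanceUuids = unlist(body$substances) %||% character(0),
          selections = lapply(body$selections, function(sel)
            endpointSelection(sel$topcategory, sel$category, sel$endpoint,
                              unlist(sel$conditions) %||%
                                .DEFAULT_DISTINGUISHING)),
          id = env$nextBundleId,
          name = chr1(body$name, "bundle")), error = function(e) e)
        if (inherits(b, "error"))
          return(.badRequest(conditionMessage(b)))
        env$bundles[[as.character(b@id)]] <- b
        env$nextBundleId <- env$nextBundleId + 1L
        return(.ok(list(id = b@id)))
      }
    }
    b <- env$bundles[[parts[2]]]
    if (is.null(b)) return(.notFound(sprintf("unknown bundle %s", parts[2])))
    sub <- if (length(parts) >= 3) parts[3] else ""
    if (sub == "" && method == "GET")
      return(.ok(list(id = b@id, name = b@name,
                      substances = as.list(b@substanceUuids),
                      selections = b@selections)))
    if (sub == "substance" && method == "PUT") {
      b <- if (identical(body$action, "deselect"))
        deselectSubstance(b, body$uuid)
      else tryCatch(selectSubstance(b, body$uuid, store),
                    error = function(e) e)
      if (inherits(b, "error")) return(.badRequest(conditionMessage(b)))
      env$bundles[[parts[2]]] <- b
      return(.ok(list(id = b@id, substances = as.list(b@substanceUuids))))
    }
    if (sub == "property" && method == "PUT") {
      sel <- endpointSelection(body$topcategory, body$category,
                               body$endpoint,
                               unlist(body$conditions) %||%
                                 .DEFAULT_DISTINGUISHING)
      b <- if (identical(body$action, "deselect")) deselectEndpoint(b, sel)
           else selectEndpoint(b, sel)
      env$bundles[[parts[2]]] <- b
      return(.ok(list(id = b@id, selections = b@selections)))
    }
    if (sub == "matrix" && method == "GET") {
      dm <- buildMatrix(store, b)
      return(.ok(jsonlite::fromJSON(exportMatrixJSON(dm),
                                    simplifyVector = FALSE)))
    }
    return(.notFound(sprintf("unknown resource %s", path)))
  }

  if (resource == "query" && method == "GET") {
    if (!is.null(query$smiles)) {
      hits <- similaritySearch(store, query$smiles,
                               num1(query$threshold, 0.6))
      return(.ok(lapply(seq_len(nrow(hits)), function(i) as.list(hits[i, ]))))
    }
    sm <- endpointSummary(store)
    for (f in c("topcategory", "category", "endpoint"))
      if (!is.null(query[[f]])) sm <- sm[sm[[f]] == query[[f]], , drop = FALSE]
    return(.ok(lapply(seq_len(nrow(sm)), function(i) as.list(sm[i, ]))))
  }

  .notFound(sprintf("unknown resource %s", path))
}

#' Serve the API over HTTP
#'
#' Thin adapter mounting [handleRequest()] on httpuv. Request bodies and
#' responses are JSON. Intended for interactive use; the in-process
#' handler is the tested contract.
#'
#' @param service an [newService()] result.
#' @param port TCP port.
#' @return the httpuv server handle (stop with
#'   \code{httpuv::stopServer()}).
#' @export
serveHttp <- function(service, port = 8080) {
  if (!requireNamespace("httpuv", quietly = TRUE))
    enmStop("serveHttp requires the httpuv package", "enmkit_io_error")
  app <- list(call = function(req) {
    body <- NULL
    if (!is.null(req$rook.input)) {
      txt <- rawToChar(req$rook.input$read())
      if (nzchar(txt))
        body <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
    }
    query <- list()
    if (nzchar(req$QUERY_STRING %||% "")) {
      for (kv in strsplit(sub("^\\?", "", req$QUERY_STRING), "&")[[1]]) {
        p <- strsplit(kv, "=", fixed = TRUE)[[1]]
        query[[utils::URLdecode(p[1])]] <- utils::URLdecode(p[2])
      }
    }
    res <- handleRequest(service, req$REQUEST_METHOD, req$PATH_INFO,
                         query, body)
    list(status = res$status,
         headers = list("Content-Type" = "application/json"),
         body = as.character(jsonlite::toJSON(res$body, auto_unbox = TRUE,
                                              na = "null", digits = NA)))
  })
  httpuv::startServer("127.0.0.1", port, app)
}
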