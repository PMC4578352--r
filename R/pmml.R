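## PMML subset: DataDictionary (feature selection) and
## TransformationDictionary (derived-field arithmetic). Supported Apply
## functions are the arithmetic and magnitude operations plus logarithms:
## +, -, *, /, abs, ln, log10, exp, and log2 (an extension used for
## log2-transformed modelling targets). Model elements are not parsed;
## writePMMLRegression() emits a minimal RegressionModel for export.

.PMML_FUNCTIONS <- c("+", "-", "*", "/", "abs", "ln", "log10", "exp", "log2")

#' @rdname parsePMML
#' @export
setClass("PMMLSpec",
  representation(dataFields = "data.frame", derivedFields = "list",
                 source = "character", notices = "character"))

.pmmlExpr <- function(node, known, fieldName) {
  name <- xml2::xml_name(node)
  if (name == "FieldRef") {
    f <- xml2::xml_attr(node, "field")
    if (!(f %in% known))
      enmStop(sprintf("derived field '%s' references undeclared or later field '%s'",
                      fieldName, f), "enmkit_pmml_error")
    list(kind = "field", field = f)
  } else if (name == "Constant") {
    list(kind = "const", value = as.numeric(xml2::xml_text(node)))
  } else if (name == "Apply") {
    fn <- xml2::xml_attr(node, "function")
    if (!(fn %in% .PMML_FUNCTIONS))
      enmStop(sprintf("unsupported PMML function '%s' in derived field '%s'",
                      fn, fieldName), "enmkit_pmml_error")
    args <- lapply(xml2::xml_children(node), .pmmlExpr, known = known,
                   fieldName = fieldName)
    list(kind = "apply", fn = fn, args = args)
  } else {
    enmStop(sprintf("unsupported expression element '%s' in derived field '%s'",
                    name, fieldName), "enmkit_pmml_error")
  }
}

#' Parse a PMML data/transformation dictionary
#'
#' Reads the \code{DataDictionary} (the input features a model selects)
#' and the \code{TransformationDictionary} (derived fields computed from
#' them) of a PMML 4.x document. Field references must resolve to a data
#' field or an earlier derived field: forward references and cycles are
#' rejected, as are functions outside the supported set. PMML elements
#' other than the two dictionaries are ignored with a recorded notice.
#'
#' @param x path to a PMML file, or PMML XML text.
#' @return a \code{PMMLSpec} with \code{@dataFields} (name, optype,
#'   dataType), \code{@derivedFields} (named expression trees) and
#'   \code{@notices}.
#' @export
parsePMML <- function(x) {
  doc <- xml2::read_xml(x)
  xml2::xml_ns_strip(doc)
  notices <- character(0)
  for (child in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(child)
    if (!(nm %in% c("DataDictionary", "TransformationDictionary", "Header")))
      notices <- c(notices, sprintf("ignored PMML element '%s'", nm))
  }
  dfNodes <- xml2::xml_find_all(doc, "./DataDictionary/DataField")
  dataFields <- data.frame(
    name = xml2::xml_attr(dfNodes, "name"),
    optype = xml2::xml_attr(dfNodes, "optype"),
    dataType = xml2::xml_attr(dfNodes, "dataType"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(dataFields$name))
    enmStop("duplicate DataField names", "enmkit_pmml_error")
  derivedNodes <- xml2::xml_find_all(doc,
                                     "./TransformationDictionary/DerivedField")
  derived <- list()
  known <- dataFields$name
  for (node in derivedNodes) {
    nm <- xml2::xml_attr(node, "name")
    if (nm %in% c(known))
      enmStop(sprintf("derived field '%s' redefines an existing field", nm),
              "enmkit_pmml_error")
    kids <- xml2::xml_children(node)
    if (length(kids) != 1)
      enmStop(sprintf("derived field '%s' must have exactly one expression", nm),
              "enmkit_pmml_error")
    derived[[nm]] <- .pmmlExpr(kids[[1]], known, nm)
    known <- c(known, nm)
  }
  new("PMMLSpec", dataFields = dataFields, derivedFields = derived,
      source = as.character(doc), notices = notices)
}

.applyFn <- function(fn, args, log) {
  a <- args[[1]]
  b <- if (length(args) > 1) args[[2]] else NULL
  out <- suppressWarnings(switch(fn,
    "+" = a + b, "-" = if (is.null(b)) -a else a - b,
    "*" = a * b,
    "/" = {
      r <- a / b
      nz <- !is.na(b) & b == 0
      if (any(nz)) {
        log$events <- c(log$events,
                        sprintf("division by zero in %d row(s)", sum(nz)))
        r[nz] <- NA_real_
      }
      r
    },
    "abs" = abs(a), "ln" = log(a), "log10" = log10(a),
    "log2" = log2(a), "exp" = exp(a)))
  bad <- (!is.na(out) & !is.finite(out)) | is.nan(out)
  if (any(bad, na.rm = TRUE)) {
    log$events <- c(log$events,
                    sprintf("non-finite result of '%s' in %d row(s)", fn,
                            sum(bad, na.rm = TRUE)))
    out[bad] <- NA_real_
  }
  out
}

.evalExpr <- function(expr, env, n, log) {
  switch(expr$kind,
    field = env[[expr$field]],
    const = rep(expr$value, n),
    apply = .applyFn(expr$fn,
                     lapply(expr$args, .evalExpr, env = env, n = n,
                            log = log), log))
}

#' Apply a PMML spec to a feature table
#'
#' Selects the declared data fields from a [buildMatrix()] result (or any
#' numeric table) and evaluates the derived fields. When derived fields
#' are declared the output consists of exactly those columns; otherwise
#' the selected data fields pass through. Rows are preserved; an output
#' cell is missing iff a referenced input cell is missing or an arithmetic
#' fault (division by zero, log of a non-positive value) occurred, and
#' every fault is logged in the \code{"transformLog"} attribute.
#'
#' @param spec a [parsePMML()] result.
#' @param x a \code{DataMatrix}, matrix or data.frame with named numeric
#'   columns.
#' @param alias optional named character vector mapping PMML field names
#'   to column names of \code{x} (PMML names are rarely legal spreadsheet
#'   headers).
#' @return data.frame of transformed features with attribute
#'   \code{transformLog}.
#' @export
applySpec <- function(spec, x, alias = NULL) {
  stopifnot(is(spec, "PMMLSpec"))
  tab <- if (is(x, "DataMatrix")) x@values else as.matrix(x)
  cols <- colnames(tab)
  env <- new.env(parent = emptyenv())
  for (nm in spec@dataFields$name) {
    colName <- if (!is.null(alias) && nm %in% names(alias)) alias[[nm]] else nm
    if (!(colName %in% cols))
      enmStop(sprintf("PMML data field '%s' not found; available columns: %s",
                      nm, paste(cols, collapse = ", ")),
              "enmkit_pmml_error")
    env[[nm]] <- as.numeric(tab[, colName])
  }
  n <- nrow(tab)
  log <- new.env(parent = emptyenv()); log$events <- character(0)
  for (nm in names(spec@derivedFields))
    env[[nm]] <- .evalExpr(spec@derivedFields[[nm]], env, n, log)
  outNames <- if (length(spec@derivedFields)) names(spec@derivedFields)
              else spec@dataFields$name
  out <- as.data.frame(stats::setNames(
    lapply(outNames, function(nm) env[[nm]]), outNames),
    check.names = FALSE, optional = TRUE)
  rownames(out) <- rownames(tab)
  attr(out, "transformLog") <- log$events
  out
}

#' Write a minimal PMML regression document
#'
#' Exports a trained linear model as a PMML 4.2 \code{RegressionModel}
#' with its \code{DataDictionary}, so coefficients travel in a standard,
#' platform-independent form.
#'
#' @param coefficients named numeric vector; first element the intercept.
#' @param predictedFeature name of the predicted field.
#' @param path optional output file.
#' @return the XML text (invisibly when written to a file).
#' @export
writePMMLRegression <- function(coefficients, predictedFeature, path = NULL) {
  feats <- setdiff(names(coefficients), "(Intercept)")
  fields <- paste0(
    sprintf('    <DataField name="%s" optype="continuous" dataType="double"/>\n',
            c(feats, predictedFeature)), collapse = "")
  preds <- paste0(
    sprintf('      <NumericPredictor name="%s" coefficient="%.17g"/>\n',
            feats, unname(coefficients[feats])), collapse = "")
  mining <- paste0(
    sprintf('    <MiningField name="%s" usageType="%s"/>\n',
            c(feats, predictedFeature),
            c(rep("active", length(feats)), "target")), collapse = "")
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<PMML version="4.2" xmlns="http://www.dmg.org/PMML-4_2">\n',
    '  <Header description="multiple linear regression"/>\n',
    '  <DataDictionary numberOfFields="', length(feats) + 1, '">\n', fields,
    '  </DataDictionary>\n',
    '  <RegressionModel functionName="regression" modelName="mlr">\n',
    '    <MiningSchema>\n', mining, '    </MiningSchema>\n',
    '    <RegressionTable intercept="',
    sprintf("%.17g", unname(coefficients["(Intercept)"])), '">\n', preds,
    '    </RegressionTable>\n',
    '  </RegressionModel>\n',
    '</PMML>\n')
  if (!is.null(path)) { writeLines(xml, path); return(invisible(xml)) }
  xml
}

setMethod("show", "PMMLSpec", function(object) {
  cat(sprintf("PMMLSpec: %d data fields, %d derived fields\n",
              nrow(object@dataFields), length(object@derivedFields)))
})
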