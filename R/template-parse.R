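## The template parsing engine. Sheets are normalized to character
## matrices; a mapping configuration (see template-config.R) is then
## evaluated against "records" -- rows (ROW layout), columns (COLUMN
## layout) or rows within marker-delimited blocks (BLOCK layout).

.trimCell <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return(NA_character_)
  x <- trimws(as.character(x))
  if (!nzchar(x)) NA_character_ else x
}

.sheetToMatrix <- function(x) {
  m <- as.matrix(as.data.frame(x, stringsAsFactors = FALSE))
  storage.mode(m) <- "character"
  dimnames(m) <- NULL
  m
}

#' Read a workbook into character matrices
#'
#' Accepts a CSV file (RFC 4180, configurable delimiter), an XLSX workbook
#' (requires the readxl package) or a named list of data frames / matrices
#' (in-memory sheets). All cell values are kept as text; typing happens
#' during mapping.
#'
#' @param workbook path or named list of sheets.
#' @param delimiter CSV field delimiter.
#' @return named list of character matrices.
#' @export
readWorkbook <- function(workbook, delimiter = ",") {
  if (is.list(workbook) && !is.data.frame(workbook)) {
    if (is.null(names(workbook)))
      names(workbook) <- paste0("Sheet", seq_along(workbook))
    return(lapply(workbook, .sheetToMatrix))
  }
  if (is.data.frame(workbook) || is.matrix(workbook))
    return(list(Sheet1 = .sheetToMatrix(workbook)))
  if (!is.character(workbook) || !file.exists(workbook))
    enmStop(sprintf("workbook file not found: %s", workbook),
            "enmkit_io_error")
  ext <- tolower(tools::file_ext(workbook))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      enmStop("reading XLSX requires the readxl package", "enmkit_io_error")
    sheets <- readxl::excel_sheets(workbook)
    out <- lapply(sheets, function(s)
      .sheetToMatrix(readxl::read_excel(workbook, sheet = s,
                                        col_names = FALSE,
                                        col_types = "text")))
    names(out) <- sheets
    return(out)
  }
  df <- utils::read.table(workbook, sep = delimiter, header = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE,
                          fill = TRUE, quote = "\"", comment.char = "")
  list(Sheet1 = .sheetToMatrix(df))
}

#' Locate dynamic blocks in a sheet
#'
#' Splits a sheet organized as a sequence of dynamic blocks (each with a
#' variable number of rows) into non-overlapping row intervals. A row is a
#' start marker when any of its cells matches \code{markers$start}; a
#' block contains the rows after its marker up to (exclusive) the next
#' start marker, a row matching \code{markers$end} if given, or the end of
#' the sheet. A start marker not closed before the end of the sheet
#' closes the block at the last row, with a warning. Without any marker
#' the whole region is a single block.
#'
#' @param sheet character matrix (see [readWorkbook()]).
#' @param markers list(start = regex, end = optional regex), or NULL.
#' @param fromRow first row considered (use 2 to skip a header row).
#' @return data.frame with columns start, end (1-based, inclusive).
#' @export
locateBlocks <- function(sheet, markers = NULL, fromRow = 1L) {
  n <- nrow(sheet)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < fromRow) return(empty)
  rowMatches <- function(pattern, i)
    any(grepl(pattern, stats::na.omit(sheet[i, ])), na.rm = TRUE)
  if (is.null(markers) || is.null(markers$start))
    return(data.frame(start = fromRow, end = n))
  starts <- which(vapply(fromRow:n, function(i)
    rowMatches(markers$start, i), TRUE)) + fromRow - 1L
  if (length(starts) == 0) return(data.frame(start = fromRow, end = n))
  ends <- if (!is.null(markers$end))
    which(vapply(fromRow:n, function(i)
      rowMatches(markers$end, i), TRUE)) + fromRow - 1L
  else integer(0)
  out <- empty
  for (k in seq_along(starts)) {
    s <- starts[k] + 1L
    limit <- n
    nxt <- starts[starts > starts[k]]
    if (length(nxt)) limit <- min(limit, nxt[1] - 1L)
    e <- ends[ends >= s]
    if (length(e) && e[1] <= limit) {
      limit <- e[1] - 1L
    } else if (!is.null(markers$end) && limit == n) {
      enmWarn(sprintf("block starting at row %d has no end marker; closed at last row",
                      starts[k]))
    }
    if (s > limit) {
      enmWarn(sprintf("empty block at row %d dropped", starts[k]))
      next
    }
    out <- rbind(out, data.frame(start = s, end = limit))
  }
  out
}

## --- locator resolution -------------------------------------------------

.resolveLocator <- function(loc, ctx) {
  if (!is.list(loc)) return(.trimCell(loc))   # bare literal
  if (!is.null(loc$literal)) return(loc$literal)
  m <- ctx$sheet
  if (!is.null(loc$cell)) {
    rc <- cellToRC(loc$cell)
    if (rc[1] > nrow(m) || rc[2] > ncol(m)) return(NA_character_)
    return(.trimCell(m[rc[1], rc[2]]))
  }
  if (!is.null(loc$column)) {
    col <- if (is.numeric(loc$column)) as.integer(loc$column)
           else match(loc$column, ctx$header)
    if (is.na(col))
      enmStop(sprintf("column '%s' not found in sheet header", loc$column),
              "enmkit_io_error")
    if (col > ncol(m)) return(NA_character_)
    return(.trimCell(m[ctx$rowIndex, col]))
  }
  if (!is.null(loc$row)) {
    row <- if (is.numeric(loc$row)) as.integer(loc$row)
           else match(loc$row, ctx$labels)
    if (is.na(row))
      enmStop(sprintf("row label '%s' not found in sheet", loc$row),
              "enmkit_io_error")
    if (row > nrow(m)) return(NA_character_)
    return(.trimCell(m[row, ctx$colIndex]))
  }
  if (!is.null(loc$anchor)) {
    r <- ctx$anchorRow + int1(loc$anchor$rowOffset, 0L)
    c <- 1L + int1(loc$anchor$colOffset, 0L)
    if (is.na(r) || r < 1 || r > nrow(m) || c < 1 || c > ncol(m))
      return(NA_character_)
    return(.trimCell(m[r, c]))
  }
  NA_character_
}

## numeric coercion with text fallback; returns list(num, text)
.resolveValue <- function(loc, ctx, state) {
  raw <- .resolveLocator(loc, ctx)
  if (is.null(raw) || (length(raw) == 1 && is.na(raw)))
    return(list(num = NA_real_, text = NA_character_, present = FALSE))
  if (is.numeric(raw)) return(list(num = as.numeric(raw),
                                   text = NA_character_, present = TRUE))
  num <- suppressWarnings(as.numeric(raw))
  if (is.na(num)) {
    state$textFallbacks <- state$textFallbacks + 1L
    state$warnings <- c(state$warnings,
                        sprintf("non-numeric value '%s' recorded as text", raw))
    return(list(num = NA_real_, text = as.character(raw), present = TRUE))
  }
  list(num = num, text = NA_character_, present = TRUE)
}

.resolveConditionMap <- function(map, ctx) {
  if (is.null(map) || length(map) == 0) return(list())
  out <- list()
  for (nm in names(map)) {
    raw <- .resolveLocator(map[[nm]], ctx)
    if (length(raw) == 1 && is.na(raw)) next
    num <- suppressWarnings(as.numeric(raw))
    out[[nm]] <- if (!is.na(num) && !is.numeric(raw)) num else raw
  }
  out
}

## --- main parser --------------------------------------------------------

.recordsForSheet <- function(mat, layout, markers) {
  if (layout == "ROW") {
    rows <- which(apply(mat, 1, function(r) any(!is.na(vapply(r, .trimCell, "")))))
    rows <- setdiff(rows, 1L)  # row 1 is the header
    list(list(records = lapply(rows, function(i)
      list(mode = "ROW", rowIndex = i)), anchorRow = NA_integer_))
  } else if (layout == "COLUMN") {
    cols <- setdiff(seq_len(ncol(mat)), 1L)  # column 1 holds the labels
    cols <- cols[vapply(cols, function(j)
      any(!is.na(vapply(mat[, j], .trimCell, ""))), TRUE)]
    list(list(records = lapply(cols, function(j)
      list(mode = "COLUMN", colIndex = j)), anchorRow = NA_integer_))
  } else {  # BLOCK: header row 1, blocks below
    blocks <- locateBlocks(mat, markers, fromRow = 2L)
    lapply(seq_len(nrow(blocks)), function(b) {
      rows <- blocks$start[b]:blocks$end[b]
      rows <- rows[vapply(rows, function(i)
        any(!is.na(vapply(mat[i, ], .trimCell, ""))), TRUE)]
      list(records = lapply(rows, function(i)
        list(mode = "BLOCK", rowIndex = i)),
        anchorRow = blocks$start[b])
    })
  }
}

.makeCtx <- function(mat, rec, anchorRow) {
  list(sheet = mat,
       header = if (!is.null(rec$rowIndex)) as.character(mat[1, ]) else NULL,
       labels = if (!is.null(rec$colIndex)) as.character(mat[, 1]) else NULL,
       rowIndex = rec$rowIndex, colIndex = rec$colIndex,
       anchorRow = anchorRow)
}

#' Parse a spreadsheet workbook into the data model
#'
#' Applies a mapping configuration to a workbook and produces one
#' [Substance()] per distinct substance key and one
#' [ProtocolApplication()] per (substance, study mapping) group, with all
#' measurements carrying the mapped units and conditions. Identifiers are
#' minted with [makeIdentifier()] under the configuration's
#' \code{idPrefix}, so re-parsing the same file yields identical
#' identifiers. Records with an empty substance key are skipped with a
#' warning; a non-numeric cell mapped to a value locator is recorded as a
#' text value with a warning.
#'
#' @param workbook path to CSV/XLSX, or a named list of in-memory sheets.
#' @param config a [loadConfig()] result (or anything it accepts).
#' @return list(substances, protocolApplications, log); the log reconciles
#'   counts (records, skippedRecords, measurements, valueGroupsNonEmpty,
#'   textFallbacks, warnings).
#' @export
parseWorkbook <- function(workbook, config) {
  if (!is(config, "TemplateConfig")) config <- loadConfig(config)
  cfg <- config@config
  sheets <- readWorkbook(workbook, delimiter = chr1(cfg$delimiter, ","))
  mainName <- chr1(cfg$sheet, names(sheets)[1])
  if (!(mainName %in% names(sheets)))
    enmStop(sprintf("sheet '%s' not found in workbook", mainName),
            "enmkit_io_error")
  layout <- cfg$layout
  prefix <- cfg$idPrefix

  state <- new.env(parent = emptyenv())
  state$textFallbacks <- 0L; state$warnings <- character(0)
  state$skipped <- 0L; state$records <- 0L
  state$valueGroups <- 0L; state$measurements <- 0L

  substances <- list()
  pas <- list()
  paEffects <- list()  # accumulated effects per pa uuid

  ## linked sheets: key -> records, per sheet name
  linkKeyLoc <- list()
  linkedRecords <- list()
  if (!is.null(cfg$sheetLinks)) {
    for (lk in cfg$sheetLinks) linkKeyLoc[[lk$sheet]] <- lk$key
    for (sheetName in setdiff(names(linkKeyLoc), mainName)) {
      if (!(sheetName %in% names(sheets)))
        enmStop(sprintf("sheet '%s' not found in workbook", sheetName),
                "enmkit_io_error")
      mat <- sheets[[sheetName]]
      groups <- .recordsForSheet(mat, layout, cfg$blockMarkers)
      byKey <- list()
      for (g in groups) {
        if (length(g$records) == 0) next
        ctx <- .makeCtx(mat, g$records[[1]], g$anchorRow)
        k <- .trimCell(.resolveLocator(linkKeyLoc[[sheetName]], ctx))
        if (is.na(k)) next
        byKey[[k]] <- list(records = g$records, anchorRow = g$anchorRow,
                           mat = mat)
      }
      linkedRecords[[sheetName]] <- byKey
    }
  }

  studyIdx <- seq_along(cfg$studies)
  localStudies <- studyIdx[vapply(studyIdx, function(i) {
    s <- chr1(cfg$studies[[i]]$sheet, mainName); s == mainName }, TRUE)]
  remoteStudies <- setdiff(studyIdx, localStudies)

  buildProtocol <- function(p, ctx) {
    ep <- if (.isLocator(p$endpoint)) .resolveLocator(p$endpoint, ctx)
          else chr1(p$endpoint, "")
    Protocol(topcategory = chr1(p$topcategory, "P-CHEM"),
             category = chr1(p$category, ""),
             endpoint = ep,
             guideline = unlist(p$guideline) %||% character(0),
             annotationIri = chr1(p$annotationIri))
  }

  ensurePA <- function(subUuid, subKey, i, ctx) {
    paId <- paste(subUuid, i, sep = "\r")
    if (is.null(pas[[paId]])) {
      st <- cfg$studies[[i]]
      pas[[paId]] <<- list(
        uuid = makeIdentifier(prefix, paste(subKey, "study", i, sep = "|")),
        substanceUuid = subUuid,
        protocol = buildProtocol(st$protocol, ctx),
        parameters = .resolveConditionMap(st$parameters, ctx))
      paEffects[[paId]] <<- list()
    }
    paId
  }

  extractMeasurements <- function(st, ctx) {
    out <- list()
    for (ep in st$endpoints) {
      lo <- if (!is.null(ep$lo)) .resolveValue(ep$lo, ctx, state)
            else list(num = NA_real_, text = NA_character_, present = FALSE)
      up <- if (!is.null(ep$up)) .resolveValue(ep$up, ctx, state)
            else list(num = NA_real_, text = NA_character_, present = FALSE)
      err <- if (!is.null(ep$error)) .resolveValue(ep$error, ctx, state)
             else list(num = NA_real_, text = NA_character_, present = FALSE)
      txt <- if (!is.null(ep$text)) .trimCell(.resolveLocator(ep$text, ctx))
             else NA_character_
      textValue <- chr1(txt)
      for (fb in list(lo, up, err))  # non-numeric cells fall back to text
        if (!is.null(fb$text) && !is.na(fb$text) && is.na(textValue))
          textValue <- fb$text
      present <- lo$present || up$present || err$present || !is.na(textValue)
      if (!present) next
      state$valueGroups <- state$valueGroups + 1L
      if (is.na(lo$num) && is.na(up$num) && is.na(textValue)) next
      unit <- if (is.null(ep$unit)) ""
              else if (.isLocator(ep$unit)) chr1(.resolveLocator(ep$unit, ctx), "")
              else chr1(ep$unit, "")
      conds <- c(.resolveConditionMap(st$conditions, ctx),
                 .resolveConditionMap(ep$conditions, ctx))
      m <- Measurement(endpoint = chr1(ep$endpoint),
                       endpointIri = chr1(ep$endpointIri),
                       loValue = lo$num, upValue = up$num,
                       loQualifier = chr1(ep$loQualifier),
                       upQualifier = chr1(ep$upQualifier),
                       errorValue = err$num,
                       errQualifier = chr1(ep$errQualifier),
                       unit = unit, textValue = textValue,
                       conditions = conds)
      state$measurements <- state$measurements + 1L
      out[[length(out) + 1L]] <- m
    }
    out
  }

  ensureSubstance <- function(key, ctx) {
    uuid <- makeIdentifier(prefix, key)
    if (!is.null(substances[[uuid]])) return(uuid)
    sub <- cfg$substance
    resolveOr <- function(loc, default = NA_character_) {
      if (is.null(loc)) default else chr1(.resolveLocator(loc, ctx), default)
    }
    composition <- list()
    refUuid <- NA_character_
    for (comp in sub$composition) {
      nm <- resolveOr(comp$name); sm <- resolveOr(comp$smiles)
      ic <- resolveOr(comp$inchi)
      if (is.na(nm) && is.na(sm) && is.na(ic)) next
      composition[[length(composition) + 1L]] <-
        Component(comp$role, name = nm, smiles = sm, inchi = ic)
      if (comp$role == "CORE" && !is.na(sm) && is.na(refUuid))
        refUuid <- makeIdentifier(prefix, paste0("structure|", sm))
    }
    extIds <- list()
    for (sysName in names(sub$externalIds)) {
      v <- resolveOr(sub$externalIds[[sysName]])
      if (!is.na(v))
        extIds[[length(extIds) + 1L]] <- list(system = sysName, value = v)
    }
    substances[[uuid]] <<- Substance(
      uuid = uuid, name = resolveOr(sub$name, key),
      publicName = resolveOr(sub$publicName, resolveOr(sub$name, key)),
      substanceType = resolveOr(sub$substanceType),
      ownerName = resolveOr(sub$ownerName),
      referenceSubstanceUuid = refUuid,
      externalIds = extIds, composition = composition)
    uuid
  }

  mat <- sheets[[mainName]]
  groups <- .recordsForSheet(mat, layout, cfg$blockMarkers)
  for (g in groups) {
    groupKey <- NA_character_
    groupUuid <- NA_character_
    for (rec in g$records) {
      ctx <- .makeCtx(mat, rec, g$anchorRow)
      state$records <- state$records + 1L
      key <- .trimCell(.resolveLocator(cfg$substance$key, ctx))
      if (is.na(key)) {
        state$skipped <- state$skipped + 1L
        state$warnings <- c(state$warnings,
                            "record with empty substance key skipped")
        next
      }
      uuid <- ensureSubstance(key, ctx)
      if (is.na(groupKey)) { groupKey <- key; groupUuid <- uuid }
      for (i in localStudies) {
        paId <- ensurePA(uuid, key, i, ctx)
        ms <- extractMeasurements(cfg$studies[[i]], ctx)
        if (length(ms)) paEffects[[paId]] <- c(paEffects[[paId]], ms)
      }
    }
    ## studies on linked sheets: processed once per block, joined by key
    if (length(remoteStudies) && !is.na(groupKey)) {
      for (i in remoteStudies) {
        st <- cfg$studies[[i]]
        lr <- linkedRecords[[st$sheet]][[groupKey]]
        if (is.null(lr)) next
        for (rec in lr$records) {
          ctx <- .makeCtx(lr$mat, rec, lr$anchorRow)
          paId <- ensurePA(groupUuid, groupKey, i, ctx)
          ms <- extractMeasurements(st, ctx)
          if (length(ms)) paEffects[[paId]] <- c(paEffects[[paId]], ms)
        }
      }
    }
  }

  ## materialize protocol applications (drop empty ones)
  paList <- list()
  for (paId in names(pas)) {
    eff <- paEffects[[paId]]
    if (length(eff) == 0) next
    p <- pas[[paId]]
    paList[[p$uuid]] <- ProtocolApplication(
      uuid = p$uuid, substanceUuid = p$substanceUuid,
      protocol = p$protocol, parameters = p$parameters, effects = eff)
  }
  for (w in unique(state$warnings)) enmWarn(w)
  list(substances = substances[sort(names(substances))],
       protocolApplications = paList[sort(names(paList))],
       log = list(records = state$records, skippedRecords = state$skipped,
                  measurements = state$measurements,
                  valueGroupsNonEmpty = state$valueGroups,
                  textFallbacks = state$textFallbacks,
                  warnings = state$warnings))
}

#' Import a workbook into a store
#'
#' Parses the workbook with [parseWorkbook()] and adds the result to the
#' store. The two flags mirror a data-upload form: clear existing
#' composition records and/or study records of re-imported materials, so
#' re-importing the same file is idempotent.
#'
#' @param store a [SubstanceStore()].
#' @inheritParams parseWorkbook
#' @param clearComposition,clearStudies see [addSubstance()].
#' @return the updated store.
#' @export
importWorkbook <- function(store, workbook, config,
                           clearComposition = FALSE, clearStudies = FALSE) {
  res <- parseWorkbook(workbook, config)
  for (s in res$substances)
    store <- addSubstance(store, s, clearComposition = clearComposition,
                          clearStudies = clearStudies)
  for (pa in res$protocolApplications) store <- addStudy(store, pa)
  store
}
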