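## Shared helpers for the test suite. Everything is generated in code; no
## binary fixtures.

## A minimal valid protocol application for serialization tests.
makeTestPA <- function(uuid = makeIdentifier("TEST", "pa-1"),
                       substanceUuid = makeIdentifier("TEST", "sub-1"),
                       effects = list(
                         Measurement("zeta potential", loValue = -30,
                                     unit = "mV"))) {
  ProtocolApplication(
    uuid = uuid, substanceUuid = substanceUuid,
    protocol = Protocol("P-CHEM", "ZETA_POTENTIAL_SECTION",
                        "zeta potential", guideline = "ISO 13099"),
    effects = effects, parameters = list(pH = list(value = 7, unit = "")),
    citation = list(title = "doi:10.1000/test", year = 2015, owner = "lab"),
    reliability = 2)
}

## Independent naive aggregation oracle: group scalarized measurements by
## (substance, endpoint, category, distinguishing-condition signature) and
## average, with no outlier screening. Deliberately written as a flat scan,
## unlike the implementation.
naiveGroupMeans <- function(store, bundle) {
  rows <- list()
  for (sel in bundle@selections) {
    for (uuid in sort(bundle@substanceUuids)) {
      for (pa in studiesOf(store, uuid)) {
        if (pa@protocol@topcategory != sel$topcategory) next
        if (nzchar(sel$category) && pa@protocol@category != sel$category)
          next
        for (m in pa@effects) {
          if (m@endpoint != sel$endpoint) next
          v <- scalarize(m)
          if (is.na(v)) next
          keep <- intersect(sort(sel$conditions), names(m@conditions))
          sig <- paste(vapply(keep, function(k)
            paste0(k, "=", as.character(m@conditions[[k]]$value)), ""),
            collapse = ";")
          rows[[length(rows) + 1L]] <- data.frame(
            uuid = uuid, endpoint = m@endpoint,
            category = pa@protocol@category, sig = sig, unit = m@unit,
            value = v, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(uuid = character(0), key = character(0),
                      mean = numeric(0)))
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ uuid + endpoint + category + sig + unit,
                          df, FUN = mean)
  agg
}

## Map a naive-oracle row to the DataMatrix column name.
oracleColumnName <- function(endpoint, sig, unit) {
  s <- if (nzchar(sig)) paste0("@", sig) else ""
  u <- if (nzchar(unit)) paste0(" (", unit, ")") else ""
  paste0(endpoint, s, u)
}
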