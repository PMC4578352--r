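## Chemical similarity over substance components. Structures are encoded
## as hashed linear-path fingerprints (OpenBabel FP2 via
## ChemmineR/ChemmineOB: substructure paths of length up to 7 atoms,
## folded to 1024 bits) and compared with the Tanimoto coefficient. The
## generator is a tagged, swappable strategy: fingerprints with different
## tags never get compared.

.FP_TAG <- "openbabel-FP2/1024"

#' @rdname fingerprintSMILES
#' @export
setClass("Fingerprint",
  representation(bits = "logical", tag = "character"),
  validity = function(object) {
    if (length(object@bits) == 0) return("empty bitset container")
    TRUE
  })

.smilesToFPMatrix <- function(smiles) {
  sdf <- tryCatch(
    suppressWarnings(suppressMessages(
      ChemmineR::smiles2sdf(stats::setNames(smiles, seq_along(smiles))))),
    error = function(e)
      enmStop(paste0("unparsable SMILES among: ",
                     paste(smiles, collapse = ", ")),
              "enmkit_structure_error"))
  out <- matrix(FALSE, nrow = length(smiles), ncol = 1024)
  ## bondless molecules (bare metal cores like [Au]) have no linear paths:
  ## their fingerprint is legitimately empty
  ok <- suppressWarnings(ChemmineR::validSDF(sdf))
  if (any(ok)) {
    fp <- ChemmineR::fingerprintOB(sdf[ok], "FP2")
    out[which(ok), ] <- fp@fpma > 0
  }
  out
}

#' Hashed path fingerprint of a structure
#'
#' Computes the 1024-bit linear-substructure-path fingerprint (paths of up
#' to 7 atoms, OpenBabel FP2) of a SMILES string. The result is
#' deterministic and independent of the SMILES writing order, so canonical
#' and non-canonical forms of the same molecule give identical bitsets.
#' Single atoms without bonds (e.g. a bare metal core \code{"[Au]"})
#' legitimately produce an empty bitset.
#'
#' @param smiles a SMILES string.
#' @return a \code{Fingerprint} (logical bitset plus generator tag).
#' @examples
#' \dontrun{fingerprintSMILES("CCCCCCCCN")  # octyl amine}
#' @export
fingerprintSMILES <- function(smiles) {
  if (!isNonEmptyString(smiles))
    enmStop("smiles must be a non-empty string", "enmkit_structure_error")
  m <- .smilesToFPMatrix(smiles)
  new("Fingerprint", bits = as.logical(m[1, ]), tag = .FP_TAG)
}

#' Tanimoto coefficient of two fingerprints
#'
#' |a AND b| / |a OR b|, in [0, 1]. Two empty bitsets have an undefined
#' ratio; it is defined as 0 with a warning. Fingerprints from different
#' generators are not comparable and raise an error.
#'
#' @param a,b \code{Fingerprint} objects with identical tags.
#' @return numeric scalar in [0, 1].
#' @export
tanimotoSimilarity <- function(a, b) {
  stopifnot(is(a, "Fingerprint"), is(b, "Fingerprint"))
  if (!identical(a@tag, b@tag))
    enmStop(sprintf("fingerprint generator mismatch: '%s' vs '%s'",
                    a@tag, b@tag), "enmkit_validation_error")
  union <- sum(a@bits | b@bits)
  if (union == 0) {
    enmWarn("both fingerprints are empty; similarity defined as 0")
    return(0)
  }
  sum(a@bits & b@bits) / union
}

#' Similarity search over substance components
#'
#' Fingerprints the query and every component structure in the store and
#' returns the substances having at least one component with Tanimoto
#' similarity at or above the threshold, sorted by their best component
#' similarity (descending) and annotated with the matching component's
#' role -- so a hit can be read as "similar coating" or "similar core".
#' Components without a parsable structure are skipped.
#'
#' @param store a [SubstanceStore()].
#' @param smiles query structure.
#' @param threshold minimum Tanimoto similarity in [0, 1].
#' @return data.frame(uuid, name, similarity, role, component, smiles),
#'   one row per hit substance; attribute \code{"components"} holds the
#'   full per-component similarity table.
#' @export
similaritySearch <- function(store, smiles, threshold = 0.6) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    enmStop("threshold must be in [0, 1]", "enmkit_validation_error")
  empty <- data.frame(uuid = character(0), name = character(0),
                      similarity = numeric(0), role = character(0),
                      component = character(0), smiles = character(0),
                      stringsAsFactors = FALSE)
  comps <- list()
  for (uuid in substanceIds(store)) {
    s <- store@substances[[uuid]]
    for (comp in s@composition) {
      if (is.na(comp@smiles)) next
      comps[[length(comps) + 1L]] <- list(
        uuid = uuid, name = chr1(s@name, uuid), role = comp@role,
        component = chr1(comp@name, comp@smiles), smiles = comp@smiles)
    }
  }
  if (length(comps) == 0) return(structure(empty, components = empty))
  qfp <- fingerprintSMILES(smiles)
  compSmiles <- vapply(comps, function(c) c$smiles, "")
  fpm <- .smilesToFPMatrix(compSmiles)
  sims <- vapply(seq_along(comps), function(i) {
    bits <- as.logical(fpm[i, ])
    union <- sum(bits | qfp@bits)
    if (union == 0) 0 else sum(bits & qfp@bits) / union
  }, 0)
  detail <- data.frame(
    uuid = vapply(comps, function(c) c$uuid, ""),
    name = vapply(comps, function(c) c$name, ""),
    similarity = sims,
    role = vapply(comps, function(c) c$role, ""),
    component = vapply(comps, function(c) c$component, ""),
    smiles = compSmiles, stringsAsFactors = FALSE)
  hits <- detail[detail$similarity >= threshold, , drop = FALSE]
  if (nrow(hits) == 0) return(structure(empty, components = detail))
  best <- do.call(rbind, lapply(split(hits, hits$uuid), function(g)
    g[which.max(g$similarity), , drop = FALSE]))
  best <- best[order(-best$similarity, best$uuid), , drop = FALSE]
  rownames(best) <- NULL
  structure(best, components = detail)
}

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint [%s]: %d/%d bits set\n", object@tag,
              sum(object@bits), length(object@bits)))
})
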