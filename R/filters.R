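#' PAINS substructure patterns
#'
#' Loads a SMARTS pattern file (tab-separated: `smarts<TAB>family` per
#' line, `#` comments allowed).  The file shipped with the package is a
#' curated subset of the published pan-assay interference (PAINS)
#' substructure families, hand-written from their public descriptions; it
#' is a replaceable data file, and any file in the same format can stand in
#' for it.  Every pattern is validated against a probe structure at load
#' time; an invalid SMARTS is a configuration error.
#'
#' @param path pattern file; default is the file shipped under
#'   `extdata/pains_smarts.tsv`.
#' @return data.frame with columns `smarts`, `family`.
#' @export
pains_patterns <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pains_smarts.tsv", package = "sigscreen",
                        mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  assert_that(length(lines) > 0L, "empty PAINS pattern file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pat <- data.frame(smarts = vapply(parts, `[`, character(1), 1L),
                    family = vapply(parts, `[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  probe <- probe_sdfset()
  for (k in seq_len(nrow(pat))) {
    ok <- tryCatch({
      suppressWarnings(ChemmineR::smartsSearchOB(probe, pat$smarts[k],
                                                 uniqueMatches = FALSE))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("invalid SMARTS pattern '", pat$smarts[k], "' (family ",
                  pat$family[k], ")", call. = FALSE)
  }
  pat
}

probe_sdfset <- function() {
  suppressWarnings(ChemmineR::smiles2sdf(c(probe = "OC(=O)c1ccccc1O")))
}

new_filter_report <- function(kept_records, removed, provenance) {
  structure(list(kept = sig_library(kept_records, provenance),
                 removed = removed),
            class = "sig_filter_report")
}

#' @export
print.sig_filter_report <- function(x, ...) {
  cat(sprintf("<filter report: %d kept, %d removed>\n",
              length(x$kept), nrow(x$removed)))
  if (nrow(x$removed)) print(utils::head(x$removed, 10L))
  invisible(x)
}

# SDFset over the records that can carry substructure matches (>= 2 atoms,
# molfile available); returns list(sdfset, idx into records).
records_sdfset <- function(records) {
  has <- vapply(records, function(r)
    !is.null(r$molfile) && nrow(r$structure$atoms) >= 2L, logical(1))
  idx <- which(has)
  if (!length(idx)) return(list(sdfset = NULL, idx = integer(0)))
  txt <- unlist(lapply(records[idx], function(r) strsplit(r$molfile, "\n", fixed = TRUE)[[1L]]))
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(txt))
  list(sdfset = sdfset, idx = idx)
}

#' Remove pan-assay interference compounds (PAINS)
#'
#' Flags every library compound matching at least one PAINS SMARTS pattern
#' and removes it, recording the matching family.  PAINS are promiscuous or
#' artifact-prone structures (quinones/quinone methides, rhodanines,
#' catechols, redox cyclers, covalent electrophiles, ...) that interfere
#' with many assays and would confound structure-activity modelling.
#'
#' @param lib a `sig_library`.
#' @param patterns data.frame as returned by [pains_patterns()]; must be
#'   non-empty.
#' @return a `sig_filter_report`: list with `kept` (a `sig_library`) and
#'   `removed` (data.frame `id`, `reason` of the form `pains:<family>`).
#' @export
pains_filter <- function(lib, patterns = pains_patterns()) {
  assert_that(is.data.frame(patterns) && nrow(patterns) > 0L,
              "PAINS pattern list must be non-empty")
  recs <- lib$records
  reason <- rep(NA_character_, length(recs))
  ss <- records_sdfset(recs)
  if (length(ss$idx)) {
    for (k in seq_len(nrow(patterns))) {
      hits <- suppressWarnings(
        ChemmineR::smartsSearchOB(ss$sdfset, patterns$smarts[k],
                                  uniqueMatches = FALSE))
      hit_idx <- ss$idx[hits > 0]
      new_hit <- hit_idx[is.na(reason[hit_idx])]
      reason[new_hit] <- paste0("pains:", patterns$family[k])
    }
  }
  removed <- data.frame(id = vapply(recs[!is.na(reason)], function(r) r$id, character(1), USE.NAMES = FALSE),
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  new_filter_report(recs[is.na(reason)], removed, lib$provenance)
}

# Unique signature-key sets for Tanimoto similarity.
signature_key_set <- function(x, heights = 0:2) {
  if (inherits(x, "sig_molsig")) names(x)
  else names(molecular_signature(x, heights = heights))
}

#' Signature-set Tanimoto similarity
#'
#' Tanimoto (Jaccard) coefficient between the sets of unique atomic
#' Signatures of two molecules: `|A & B| / |A | B|`.
#'
#' @param a,b molecules (`sig_mol`/`sig_compound`) or `sig_molsig` objects.
#' @param heights Signature heights used when featurizing.
#' @export
signature_tanimoto <- function(a, b, heights = 0:2) {
  sa <- signature_key_set(a, heights)
  sb <- signature_key_set(b, heights)
  u <- length(union(sa, sb))
  if (u == 0L) return(0)
  length(intersect(sa, sb)) / u
}

#' Remove near-duplicate structures
#'
#' Removes library compounds whose signature-set Tanimoto similarity to any
#' reference compound reaches the threshold.  Used to drop compounds
#' structurally similar to identified PAINS (or to any other reference set)
#' before modelling.
#'
#' @param lib library to filter.
#' @param reference reference `sig_library` compared against.
#' @param threshold similarity in `[0, 1]` at or above which a compound is
#'   removed (default 0.9).
#' @param heights Signature heights for the similarity sets.
#' @return a `sig_filter_report` with removal reasons
#'   `near_duplicate_of:<reference id>`.
#' @export
near_duplicate_filter <- function(lib, reference, threshold = 0.9, heights = 0:2) {
  assert_that(is.numeric(threshold) && threshold >= 0 && threshold <= 1,
              "threshold must be in [0, 1]")
  ref_sets <- lapply(reference$records, signature_key_set, heights = heights)
  recs <- lib$records
  reason <- rep(NA_character_, length(recs))
  for (k in seq_along(recs)) {
    sk <- signature_key_set(recs[[k]], heights)
    for (r in seq_along(ref_sets)) {
      u <- length(union(sk, ref_sets[[r]]))
      sim <- if (u == 0L) 0 else length(intersect(sk, ref_sets[[r]])) / u
      if (sim >= threshold) {
        reason[k] <- paste0("near_duplicate_of:", reference$records[[r]]$id)
        break
      }
    }
  }
  removed <- data.frame(id = vapply(recs[!is.na(reason)], function(r) r$id, character(1), USE.NAMES = FALSE),
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  new_filter_report(recs[is.na(reason)], removed, lib$provenance)
}
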